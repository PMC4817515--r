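# Gene families: construction from a clustering, core/accessory/unique
# classification, truly-unique-gene (TUG) counts, and the species-unique
# core-gene screen against outgroup proteomes.

#' Assemble gene families from a clustering
#'
#' @param membership named vector (gene_id -> cluster) as returned by
#'   [mcl_cluster()] (its `membership` element is also accepted directly).
#' @param genes gene table covering all clustered genes (columns `gene_id`,
#'   `genome_id`), or a list of [proteome()] objects.
#' @return an object of class `"gene_family_set"`: `families` (named list
#'   family_id -> gene ids), `classification` (core / accessory / unique per
#'   family), `pa` (the [pa_matrix()] with copy counts), `tug_counts`
#'   (per-genome truly-unique-gene counts), and `members` (long data frame).
#' @export
gene_family_set <- function(membership, genes) {
  if (inherits(membership, "mcl_result")) membership <- membership$membership
  if (is.list(genes) && !is.data.frame(genes)) genes <- combined_gene_table(genes)
  if (!all(names(membership) %in% genes$gene_id)) {
    stop_input("membership contains genes absent from the gene table")
  }
  if (!all(genes$gene_id %in% names(membership))) {
    stop_input("gene '%s' is not covered by the clustering",
               setdiff(genes$gene_id, names(membership))[1])
  }
  genome_ids <- sort(unique(genes$genome_id))
  counts <- table(factor(genes$genome_id, genome_ids))
  if (any(counts == 0)) stop_input("genome with zero genes")

  cl <- membership[genes$gene_id]
  fam_id <- sprintf("FAM%05d", as.integer(cl))
  members <- data.frame(family_id = fam_id, gene_id = genes$gene_id,
                        genome_id = genes$genome_id, stringsAsFactors = FALSE)
  members <- members[order(members$family_id, members$gene_id), ]
  rownames(members) <- NULL
  families <- split(members$gene_id, members$family_id)

  copy <- table(factor(members$family_id, names(families)),
                factor(members$genome_id, genome_ids))
  copy <- matrix(as.integer(copy), nrow(copy), dimnames = dimnames(copy))
  pa <- pa_matrix(copy > 0, copy)

  n_genomes <- rowSums(copy > 0)
  classification <- ifelse(n_genomes == length(genome_ids), "core",
                           ifelse(n_genomes == 1, "unique", "accessory"))
  names(classification) <- names(families)

  uniq <- names(classification)[classification == "unique"]
  tug <- stats::setNames(integer(length(genome_ids)), genome_ids)
  if (length(uniq)) {
    um <- members[members$family_id %in% uniq, ]
    tt <- table(factor(um$genome_id, genome_ids))
    tug[names(tt)] <- as.integer(tt)
  }

  structure(list(families = families, classification = classification,
                 pa = pa, tug_counts = tug, members = members),
            class = "gene_family_set")
}

#' @export
print.gene_family_set <- function(x, ...) {
  cl <- table(x$classification)
  n_of <- function(k) if (k %in% names(cl)) cl[[k]] else 0L
  cat(sprintf("<gene_family_set> %d families over %d genomes (core %d, accessory %d, unique %d)\n",
              length(x$families), ncol(x$pa),
              n_of("core"), n_of("accessory"), n_of("unique")))
  invisible(x)
}

#' Summarize a family set: pan/core counts and per-genome TUGs
#'
#' @param gfs a [gene_family_set()].
#' @return a list with `pan_families`, `core_families`, `accessory_families`,
#'   `unique_families` and `tug_counts` (genes in single-genome families, per
#'   genome).
#' @export
classify_families <- function(gfs) {
  cl <- gfs$classification
  list(pan_families = length(gfs$families),
       core_families = sum(cl == "core"),
       accessory_families = sum(cl == "accessory"),
       unique_families = sum(cl == "unique"),
       tug_counts = gfs$tug_counts)
}

#' Single-copy core families
#'
#' Families with exactly one member in every genome: the stricter reading of
#' "at least one single protein member per genome", used for the concatenated
#' core-sequence tree.
#'
#' @param gfs a [gene_family_set()].
#' @return character vector of family ids.
#' @export
single_copy_core <- function(gfs) {
  copies <- attr(gfs$pa, "copy_counts")
  names(gfs$families)[rowSums(copies == 1L) == ncol(copies)]
}

#' Core families unique to the ingroup species
#'
#' Screens every core family of the ingroup against a set of outgroup
#' proteomes; a family is species-unique when none of its member proteins has
#' any above-threshold hit in any outgroup proteome.
#'
#' @param gfs a classified [gene_family_set()] for the ingroup.
#' @param proteomes the ingroup proteome list (sequence source for members).
#' @param outgroup_proteomes non-empty list of outgroup [proteome()]s.
#' @param thresholds a [similarity_thresholds()].
#' @param scoring a [scoring_scheme()].
#' @param prefilter_k,prefilter_min shared k-mer prefilter settings (see
#'   [build_similarity_graph()]).
#' @return a list with `unique_core` (family ids with no outgroup hit) and
#'   `shared_core` (core families with at least one outgroup hit).
#' @export
unique_core_genes <- function(gfs, proteomes, outgroup_proteomes,
                              thresholds = similarity_thresholds(),
                              scoring = scoring_scheme(),
                              prefilter_k = 4L, prefilter_min = 8L) {
  if (!length(outgroup_proteomes)) stop_param("outgroup must be non-empty")
  core <- names(gfs$classification)[gfs$classification == "core"]
  genes <- combined_gene_table(proteomes)
  seq_of <- stats::setNames(genes$protein_seq, genes$gene_id)
  out_genes <- combined_gene_table(outgroup_proteomes)
  core_gene_ids <- unlist(gfs$families[core], use.names = FALSE)
  n_in <- length(core_gene_ids)
  all_seqs <- c(seq_of[core_gene_ids], stats::setNames(out_genes$protein_seq,
                                                       out_genes$gene_id))
  db_len <- sum(nchar(out_genes$protein_seq))
  cand <- candidate_pairs(unname(all_seqs), k = prefilter_k,
                          min_shared = prefilter_min)
  # keep only ingroup-vs-outgroup candidates
  cross <- (cand$i <= n_in) != (cand$j <= n_in)
  cand <- cand[cross, , drop = FALSE]
  hit_genes <- character(0)
  if (nrow(cand)) {
    qi <- ifelse(cand$i <= n_in, cand$i, cand$j)
    sj <- ifelse(cand$i <= n_in, cand$j, cand$i)
    for (j in unique(sj)) {
      ii <- qi[sj == j]
      h <- align_many(Biostrings::AAStringSet(unname(all_seqs[ii])),
                      all_seqs[[j]], scoring, db_len)
      pass <- h$evalue <= thresholds$e_max &
        h$identity >= thresholds$pid_min &
        pmin(h$cov_query, h$cov_subject) >= thresholds$cov_min
      hit_genes <- union(hit_genes, names(all_seqs)[ii][pass])
    }
  }
  fam_of_gene <- rep(core, lengths(gfs$families[core]))
  names(fam_of_gene) <- core_gene_ids
  hit_fams <- unique(unname(fam_of_gene[intersect(hit_genes, core_gene_ids)]))
  list(unique_core = setdiff(core, hit_fams), shared_core = hit_fams)
}
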