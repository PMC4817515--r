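# Markov clustering (MCL) of the weighted similarity graph.
#
# Canonical formulation: build a column-stochastic transition matrix from the
# symmetrized edge weights with self-loops, then alternate expansion (matrix
# power) and inflation (entrywise power + column renormalization), pruning
# tiny entries, until the matrix stops changing. Clusters are read off as the
# connected components of the converged matrix's non-zero structure. The
# implementation uses sparse matrices throughout, so it scales to all-vs-all
# proteome graphs.

#' MCL parameters
#'
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters. 1.5 is the conventional coarse setting for ortholog graphs.
#' @param expansion matrix power used for expansion (integer >= 2).
#' @param pruning_epsilon entries below this are dropped after each step.
#' @param max_iter iteration cap.
#' @param convergence_tol maximum absolute change defining convergence.
#' @return a list of class `"mcl_params"`.
#' @export
mcl_params <- function(inflation = 1.5, expansion = 2L,
                       pruning_epsilon = 1e-6, max_iter = 200L,
                       convergence_tol = 1e-8) {
  if (inflation <= 1) stop_param("inflation must be > 1")
  if (expansion < 2) stop_param("expansion must be an integer >= 2")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 pruning_epsilon = pruning_epsilon,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

# symmetric sparse adjacency from a similarity graph or edge list
as_adjacency <- function(graph) {
  if (inherits(graph, "similarity_graph")) {
    ids <- graph$genes$gene_id
    ed <- graph$edges
  } else if (is.data.frame(graph)) {
    ed <- graph
    ids <- sort(unique(c(ed$u, ed$v)))
  } else if (is.matrix(graph) || inherits(graph, "Matrix")) {
    m <- methods::as(methods::as(methods::as(Matrix::Matrix(graph), "dMatrix"),
                                 "generalMatrix"), "CsparseMatrix")
    return(m)
  } else {
    stop_param("unsupported graph input")
  }
  n <- length(ids)
  w <- if (is.null(ed$weight)) rep(1, nrow(ed)) else ed$weight
  # symmetrize by the max over duplicate / reciprocal entries
  dt <- data.table::data.table(i = pmin(match(ed$u, ids), match(ed$v, ids)),
                               j = pmax(match(ed$u, ids), match(ed$v, ids)),
                               w = w)
  dt <- dt[, .(w = max(w)), by = .(i, j)]
  dt <- dt[dt$i != dt$j]
  Matrix::sparseMatrix(i = c(dt$i, dt$j), j = c(dt$j, dt$i),
                       x = rep(dt$w, 2), dims = c(n, n),
                       dimnames = list(ids, ids))
}

col_max_sparse <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  out <- numeric(ncol(m))
  dp <- diff(m@p)
  if (length(m@x)) {
    cols <- rep.int(seq_len(ncol(m)), dp)
    mx <- tapply(m@x, cols, max)
    out[as.integer(names(mx))] <- mx
  }
  out
}

col_normalize <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering of a similarity graph
#'
#' @param graph a [build_similarity_graph()] result, an edge data frame with
#'   columns `u`, `v` and optional `weight`, or a (sparse) symmetric
#'   non-negative adjacency matrix with dimnames.
#' @param params an [mcl_params()].
#' @param isolated optional character vector of node ids with no edges, to be
#'   returned as singleton families (nodes of a `similarity_graph` are taken
#'   from its gene table automatically).
#' @return an object of class `"mcl_result"`: `membership` (named integer
#'   vector gene -> family index), `n_iter`, `converged`.
#' @export
mcl_cluster <- function(graph, params = mcl_params(), isolated = NULL) {
  if (inherits(graph, "similarity_graph")) {
    isolated <- setdiff(graph$genes$gene_id, c(graph$edges$u, graph$edges$v))
    has_edges <- nrow(graph$edges) > 0
    adj <- if (has_edges) as_adjacency(graph$edges) else NULL
  } else {
    adj <- as_adjacency(graph)
    has_edges <- !is.null(adj) && nrow(adj) > 0
  }
  membership <- integer(0)
  n_iter <- 0L
  converged <- TRUE
  if (has_edges) {
    if (any(adj@x < 0)) stop_param("edge weights must be >= 0")
    n <- nrow(adj)
    ids <- rownames(adj)
    # self-loops at the column maximum (the usual MCL loop weight)
    loop <- col_max_sparse(adj)
    loop[loop == 0] <- 1
    m <- col_normalize(adj + Matrix::Diagonal(n, x = loop))
    converged <- FALSE
    for (it in seq_len(params$max_iter)) {
      n_iter <- it
      m_new <- m
      for (e in seq_len(params$expansion - 1L)) m_new <- m_new %*% m
      m_new@x <- m_new@x^params$inflation
      m_new <- col_normalize(m_new)
      m_new@x[m_new@x < params$pruning_epsilon] <- 0
      m_new <- Matrix::drop0(m_new)
      m_new <- col_normalize(m_new)
      delta <- max(abs(m_new - m))
      m <- m_new
      if (delta < params$convergence_tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning("MCL did not converge within max_iter; returning current partition")
    }
    nz <- Matrix::summary(methods::as(m, "TsparseMatrix"))
    g <- igraph::graph_from_data_frame(
      data.frame(from = nz$i, to = nz$j), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership
    membership <- stats::setNames(as.integer(comp[as.character(seq_len(n))]), ids)
  }
  if (length(isolated)) {
    extra <- stats::setNames(seq_along(isolated) + max(c(membership, 0L)),
                             isolated)
    membership <- c(membership, extra)
  }
  # renumber clusters by first appearance for stable ids
  first <- !duplicated(membership)
  relabel <- stats::setNames(seq_len(sum(first)), membership[first])
  membership <- stats::setNames(as.integer(relabel[as.character(membership)]),
                                names(membership))
  structure(list(membership = membership, n_iter = n_iter,
                 converged = converged, params = params),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("<mcl_result> %d nodes in %d clusters (%d iterations%s)\n",
              length(x$membership), length(unique(x$membership)), x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
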