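---
title: "Methods: strain pan-genomics with pancog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain pan-genomics with pancog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pancog reconstructs the comparative-genomics workflow used for strain-level
bacterial pan-genome studies: ortholog family construction from all-vs-all
protein similarity, pan/core-genome profiling with an openness verdict,
distance-based phylogenomics, average nucleotide identity, Dollo-parsimony
reconstruction of gene-family gain and loss, and a compositional screen for
horizontally acquired genes. This vignette documents the models, the
parameters that matter, the numerical choices, and what the bundled
simulator does and does not emulate.

## The similarity graph and gene families

Every protein is compared against every other protein by Smith–Waterman
local alignment (BLOSUM62; affine gaps, opening 10, extension 1 per
residue). An edge between two genes requires all three of:

* E-value ≤ 1e-4 (Karlin–Altschul estimate with the standard gapped
  BLOSUM62 calibration, λ = 0.267, K = 0.041, database size = total
  residues in the proteome set);
* identity ≥ 30% of alignment columns;
* alignment coverage ≥ 80% of **both** sequences.

The E-value here is a calibrated estimate rather than a BLAST replica; edge
decisions are dominated by the identity and coverage floors, so any
monotone, sensibly scaled estimate yields the same graph. Within-genome
(paralog) pairs are retained so that duplicated genes cluster with their
family. A shared-4-mer prefilter (≥ 8 shared 4-mers) limits the quadratic
alignment stage to plausibly homologous pairs; unrelated 300-residue
proteins share ~0.5 4-mers on average while any pair passing the 30%/80%
thresholds shares far more, and the test suite verifies on simulated data
that the prefiltered edge set is identical to the no-prefilter edge set.

Families are produced by Markov clustering (MCL) of the weighted graph
(weights = bit scores, symmetrized by the maximum of the two directions).
The canonical iteration is used: self-loops at the column maximum,
column-stochastic normalization, then alternating expansion (matrix square)
and inflation (entrywise power 1.5 with renormalization), pruning entries
below 1e-6, until the matrix changes by less than 1e-8 or 200 iterations.
Clusters are the connected components of the converged matrix's non-zero
structure. Inflation 1.5 is the conventional coarse setting for ortholog
graphs; it is exposed as a parameter. The implementation is sparse-matrix
based and is checked against an independent dense-matrix transcription of
the same definition on planted-clique graphs.

A family is **core** when at least one member is present in every genome,
**unique** when exactly one genome is represented (its genes are the truly
unique genes, TUGs), **accessory** otherwise. The stricter single-copy
reading of core (exactly one member per genome) is available separately and
is what the core-sequence tree uses, since concatenation requires an
unambiguous representative per genome. Bidirectional best hits (best
above-threshold hit in each direction; ties broken by higher score, then
lower E-value, then lexicographic subject id, making outputs deterministic)
are computed on the same graph as an orthology relation.

## Pan/core profiles and the openness verdict

For an ordering of the G genomes, the pan size after n additions is the
cumulative union of families and the core size the cumulative intersection.
Profile means and SDs are taken over genome orderings: exhaustively when
G! is within the ordering budget (always for G ≤ 8 at the default budget of
1000), otherwise over seeded random permutations — an unbiased estimate of
the same means, since every ordering is equally likely. Monotonicity (pan
non-decreasing, core non-increasing) is asserted for every single ordering,
not only the means.

The pan trend is fitted as P(n) = κ·n^γ by least squares on the log-log
scale, and the decay of newly discovered families as N(n) = k·n^(−α) for
n ≥ 2 (the n = 1 value is the first genome's entire complement, not a
discovery increment). The pan-genome is called **open** when γ ≥ 0.05 or
α ≤ 1 (Heaps-law openness), else closed. The literature states openness
qualitatively (the trend "has not reached a plateau"), so both thresholds
are explicit parameters rather than buried constants; γ ≥ 0.05 encodes
"visibly still growing on a log-log plot" and α ≤ 1 is the standard
Heaps-law criterion for an unbounded gene repertoire.

## Distances, trees and ANI

Two distance constructions feed neighbor-joining:

* **Core-sequence distances**: for each genome pair, the members of every
  single-copy core family are globally aligned (end-gap-free, same scoring
  scheme as the search); mismatches and aligned columns are pooled over all
  families — equivalent to a p-distance on the concatenated core alignment —
  and Poisson-corrected, d = −ln(1 − p). Pooling (rather than averaging
  per-family distances) weights every aligned column equally, which is what
  concatenation does.
* **Gene-content distances**: d(i,j) = 1 − Jaccard similarity of family
  sets, the classical pan-genome tree metric.

Trees are built with canonical neighbor-joining. NJ reconstructs additive
distance matrices exactly (topology and branch lengths; verified to 1e-9
over random trees of 5–20 leaves); on real, non-additive input it can emit
slightly negative branch lengths, which are clamped to zero with a warning.
Maximum-likelihood inference is deliberately out of scope: the claims this
package supports (strain clustering, outlier lineages) are topological, and
NJ on Poisson-corrected distances preserves them. Rooting is by a named
outgroup or by midpoint.

ANI follows the classical fragment formulation: the query genome is cut
into consecutive 1020-nt fragments; each fragment is placed on the subject
genome by exact 14-mer seeding with a diagonal vote (both strands), aligned
end-gap-free against the seeded window (±60 nt), and kept when it reaches
30% identity over at least 70% of its length; ANI is the mean identity of
kept fragments, averaged over the two directions, in percent. When no
fragment passes, ANI is reported as undefined (an error condition), never
silently 0. The seed-and-vote placement replaces an exhaustive
fragment-vs-genome alignment; at within-species divergence (≥ ~90%
identity) a 1020-nt fragment virtually always retains seed k-mers on the
true diagonal, and the self/reverse-complement/known-substitution tests
confirm the placement does not bias the estimate.

## Dollo gain/loss reconstruction

Under the Dollo model each family is gained exactly once and may be lost
repeatedly. Given the carrier leaves of a family on a rooted strain tree,
the loss-minimizing single-gain reconstruction is closed-form: the gain sits
on the branch into the MRCA of all carriers, and one loss sits on the branch
into every maximal carrier-free subtree below the gain node. The test suite
verifies minimality exhaustively against a search over all single-gain
assignments for every rooted binary tree shape with up to 6 leaves and every
non-empty presence pattern (unlabeled shapes; the computation depends on the
shape and the pattern only, so labeled duplicates add nothing).

Per node, acquisitions (families gained on the incoming branch) and
inheritances (present at the parent, not lost) are tabulated, with
per-label breakdowns; family labels are assigned by majority vote of member
genes, ties labeled "ambiguous". The gain/loss stage conventionally uses a
looser family definition than the pan-genome clustering — 50% identity over
50% of both sequences — so the package re-clusters the similarity graph at
those thresholds for this stage; both matrices are first-class outputs. The
default tree for this stage is the midpoint-rooted core-sequence NJ tree,
but any rooted Newick is accepted.

## The compositional HGT screen

The screen is a deliberately transparent substitute for HMM-based genomic
island detectors: its purpose is the procedure — flag genes, report the
mobilome fraction, intersect with TUGs — with auditable statistics.

Each gene's **atypicality** is the mean per-codon log-likelihood ratio of
its own synonymous codon usage against the genome-wide usage (pseudocount
0.5 per codon within each synonymous set), i.e. a per-gene estimate of the
KL divergence between gene-local and genome-wide synonymous codon
distributions. Its null distribution scales inversely with gene length, so
the flag threshold is calibrated per genome on a null simulation of
native-composition genes whose lengths are resampled from the genome's own
genes: the threshold is the 95th percentile of null scores (a 5%
false-positive budget). A gene is flagged when its atypicality exceeds the
threshold **and** its GC3 deviates from the genome's by at least 0.05
**and** it is at least 300 nt long. The GC3 co-criterion is set near 1.8
standard deviations of the gene-level GC3 of a typical 300-codon gene: it
keeps the joint rule strictly inside the 5% budget while costing no
sensitivity against donors whose GC differs by ≥ 0.1. Short genes are
excluded because codon-usage estimates on < 100 codons are too noisy to
support a call either way.

## The synthetic strain-pangenome generator

Every stage is validated against a seeded simulator with complete ground
truth. The generative model:

* **Strain tree**: pure-birth (Yule) at rate 1 per lineage, stopped by a
  final exponential interval after the n-th lineage; ultrametric with
  strictly positive branch lengths.
* **Gene content**: `n_core_root` families at the root; along each branch
  of length b, gains arrive as Poisson(gain_rate·b) (each new family is
  born once — Dollo-compatible by construction) and each present family is
  lost with probability 1 − exp(−loss_rate·b). Gains materialize at the end
  of their branch, so a family is never lost on the branch it arose on.
* **Sequences**: i.i.d. per-site protein substitution with probability
  1 − exp(−subst_rate·b) per branch; the coding sequence is carried along
  and mutated codons are re-encoded from the genome's codon table. This is
  sufficient to exercise identity/coverage thresholds, the core-sequence
  distances and ANI without a full codon model; it has no indels, so real
  alignment-length variation is not emulated.
* **Paralogs**: each family duplicates with probability 0.02 per branch,
  exercising the single-copy-core distinction.
* **HGT genes**: each leaf receives alien singletons making up
  `hgt_fraction` of its genes, drawn de novo from an alien codon table at
  GC 0.45 (native 0.60) with a preferred-codon (translational) bias of 0.6
  on top — donor genomes have their own codon preferences, and a pure
  GC-offset model without synonymous bias would make alien genes nearly
  indistinguishable from native usage at realistic gene lengths. The alien
  table's GC3 is re-tuned by root-finding so `alien_gc` keeps its meaning
  independently of the bias strength.
* **Labels**: families draw functional labels from a pool of glycosyl
  hydrolase families (GH13, GH43, GH23, GH25, …) and eggNOG category
  letters at frequencies loosely mirroring a saccharolytic gut bacterium,
  so the per-label gain/loss summaries have realistic structure.

The defaults — 12 strains, 400 root families, gain 3 and loss 0.3 per unit
branch, 1% per-site divergence, 300-residue proteins, 10% alien genes —
are the desk-scale study conditions used by the test suite and the
acceptance script. What the simulator does **not** emulate: intergenic
DNA, operon and synteny rearrangements, indels, rate heterogeneity across
sites or lineages, homologous recombination, and HGT by copy between
lineages (alien genes are born de novo). Passing tests therefore
demonstrate algorithmic correctness against a faithful gene-content model,
not robustness to every artifact of real assemblies.

## Numerical choices and degenerate inputs

* FASTA ids are the token before the first whitespace; duplicate ids are
  rejected; alphabet violations are reported with record and position.
* Newick round-trips preserve topology, labels and branch lengths to at
  least 6 decimals; unbalanced parentheses are reported with a character
  offset.
* All error paths raise typed conditions (`pancog_format_error`,
  `pancog_parameter_error`, `pancog_input_error`, `pancog_ani_undefined`).
* MCL is deterministic for a fixed input and invariant to node relabeling;
  cluster ids are renumbered by first appearance.
* Synonymous frequencies for amino acids absent from a gene set default to
  uniform over the synonymous set, keeping per-amino-acid sums at 1.
* A constant pan profile fits γ = 0 exactly (R² defined as 1 in the
  zero-variance case) and zero new-family counts give α = ∞, hence
  "closed".
* Degenerate simulator regimes behave as the model dictates: zero rates
  give identical genomes; zero branch lengths give zero divergence.

## Problem sizes used by the tests and the acceptance script

The suite exercises the full pipeline at the 12-strain defaults (~3300
genes; family recovery there is exact, adjusted Rand index 1.0) and checks
each algorithm against an independent oracle at the scale where the oracle
is exhaustive: full-DP alignment on hundreds of short pairs, dense-matrix
MCL on 50 planted graphs, all tree shapes with ≤ 6 leaves for Dollo, 100
additive matrices for NJ, full 720-ordering enumeration for the profiles,
and 25–30 kb genomes for ANI. These sizes were chosen so each oracle is
complete while the whole suite stays comfortably interactive.

## Known limitations

* E-values are calibrated estimates, not BLAST-identical; absolute values
  should not be compared across tools.
* The concatenated core tree uses pairwise (not multiple) alignment;
  adequate for distance pooling, not for per-column analyses.
* The Dollo gain node is unidentifiable when losses erase all carriers on
  one side of the true gain; the reconstruction then returns the (correct)
  parsimony optimum, which postdates the true gain. The acceptance script
  reports gain-branch recovery on the identifiable subset.
* The HGT screen detects compositional atypicality only; ameliorated or
  same-GC transfers are invisible to it, as they are to all purely
  compositional detectors.
* Openness verdicts on very few genomes (G < 6) are fragile regardless of
  method; the profile SDs are reported so users can judge.
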