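# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (enumeration / closed form / brute force) and share no
# code with the implementation paths they check.

# --- maximum nested base-pairing by exhaustive recursion (n <= ~14) -------
.oracle_can_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# max pairs over all well-nested structures with hairpin loops >= min_loop
oracle_max_pairs <- function(seq, min_loop = 3L) {
  v <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)                 # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (.oracle_can_pair(v[i], v[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(v) < 2L) return(0L)
  rec(1L, length(v))
}

# --- degenerate primer expansion (IUPAC -> concrete sequence set) ---------
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_expand_primer <- function(primer) {
  sets <- IUPAC_ORACLE[strsplit(toupper(primer), "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# all placements of any concrete expansion with <= max_mismatch literal
# mismatches (union over the expansion set)
oracle_match_positions <- function(primer, ref_seq, max_mismatch = 0L) {
  exps <- oracle_expand_primer(primer)
  L <- nchar(primer)
  rv <- strsplit(ref_seq, "")[[1]]
  n_start <- length(rv) - L + 1L
  hits <- logical(n_start)
  for (e in exps) {
    ev <- strsplit(e, "")[[1]]
    mm <- integer(n_start)
    for (p in seq_len(L))
      mm <- mm + (rv[p:(p + n_start - 1L)] != ev[p])
    hits <- hits | (mm <= max_mismatch)
  }
  which(hits)
}

# --- random additive trees and their path-length metric -------------------
# random unrooted binary tree with positive branch lengths; returns the
# ape tree and its exact leaf-to-leaf path-length matrix
oracle_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE, tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

# four-point condition check (additivity witness)
oracle_is_additive <- function(D, tol = 1e-8) {
  n <- nrow(D)
  if (n < 4L) return(TRUE)
  idx <- utils::combn(n, 4L)
  for (c_ in seq_len(ncol(idx))) {
    q <- idx[, c_]
    s <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                D[q[1], q[3]] + D[q[2], q[4]],
                D[q[1], q[4]] + D[q[2], q[3]]))
    if (abs(s[2] - s[3]) > tol) return(FALSE)
  }
  TRUE
}

# unordered bipartition set of an unrooted ape tree, via ape's prop.part on
# the tree rooted at the first (alphabetical) tip
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= length(labs) - 2L)
      out <- c(out, paste(sort(side), collapse = ";"))
  }
  sort(unique(out))
}

same_topology <- function(t1, t2) {
  setequal(oracle_bipartitions(t1), oracle_bipartitions(t2))
}

# --- misc -----------------------------------------------------------------
rand_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant a sequence into a host-derived gene after a reference locus and
# return the mutated gene (no host divergence: exact exon frame)
plant_intron <- function(locus, intron, ref = ref_16S()) {
  paste0(substr(ref$sequence, 1, locus), intron,
         substr(ref$sequence, locus + 1, ref$length))
}
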