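# Per-locus phylogenetics: center-star MSA, p/JC distances, Saitou-Nei
# neighbor joining, bootstrap supports, junction conservation profiles.

JC_SATURATION_CAP <- 5.0
JC_P_MAX <- 0.749

#' Center-star progressive multiple alignment
#'
#' Aligns every member pairwise (global, affine gaps) to a center sequence -
#' the member with the highest total pairwise alignment score - and merges
#' the pairwise alignments column-wise ("once a gap, always a gap").
#' Adequate for the high-identity within-locus intron sets this package
#' builds; not suitable for deeply divergent input.
#'
#' @param seqs named character vector of DNA strings (>= 2).
#' @param scoring see [align_scoring()].
#' @return Named character vector of equal-length aligned strings
#'   (gap = `-`).
#' @export
align_msa <- function(seqs, scoring = align_scoring()) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  n <- length(seqs)
  if (length(unique(nchar(seqs))) == 1L && n > 1L &&
      all(nchar(seqs) == nchar(seqs[1L]))) {
    # equal lengths: try the trivial columnwise alignment first; accept it
    # when sequences are near-identical (no indels to resolve)
    pid <- mean(vapply(seq_len(n), function(i)
      mean(chars(seqs[[i]]) == chars(seqs[[1L]])), numeric(1)))
    if (pid >= 0.5) return(seqs)
  }
  mat <- .substitution_matrix(scoring)
  aln_pair <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = abs(scoring$gap_open),
      gapExtension = abs(scoring$gap_ext))
    list(score = Biostrings::score(pa),
         a = as.character(Biostrings::alignedPattern(pa)),
         b = as.character(Biostrings::alignedSubject(pa)))
  }
  # choose the center
  score_sum <- numeric(n)
  pair_cache <- vector("list", n)
  for (i in seq_len(n)) pair_cache[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pr <- aln_pair(seqs[[i]], seqs[[j]])
    score_sum[i] <- score_sum[i] + pr$score
    score_sum[j] <- score_sum[j] + pr$score
    pair_cache[[i]][[j]] <- pr
  }
  c_idx <- which.max(score_sum)
  center <- seqs[[c_idx]]
  others <- setdiff(seq_len(n), c_idx)
  # per-member alignment to the center
  pals <- lapply(others, function(j) {
    if (c_idx < j) {
      pr <- pair_cache[[c_idx]][[j]]
      list(center = pr$a, member = pr$b)
    } else {
      pr <- pair_cache[[j]][[c_idx]]
      list(center = pr$b, member = pr$a)
    }
  })
  # master gap profile: for each center position (0 = before first), the
  # maximum insertion length any member needs there
  Lc <- nchar(center)
  ins_max <- integer(Lc + 1L)
  parsed <- lapply(pals, function(al) {
    cc <- chars(al$center); mc <- chars(al$member)
    ins_here <- integer(Lc + 1L)
    cpos <- 0L
    for (t in seq_along(cc)) {
      if (cc[t] == "-") ins_here[cpos + 1L] <- ins_here[cpos + 1L] + 1L
      else cpos <- cpos + 1L
    }
    ins_here
  })
  for (ih in parsed) ins_max <- pmax(ins_max, ih)
  # lay a sequence out on the master column frame
  layout_member <- function(al) {
    cc <- chars(al$center); mc <- chars(al$member)
    out <- character(0)
    cpos <- 0L
    t <- 1L
    Tn <- length(cc)
    while (cpos <= Lc) {
      # emit the insertion block after center position cpos
      block <- character(0)
      while (t <= Tn && cc[t] == "-") { block <- c(block, mc[t]); t <- t + 1L }
      block <- c(block, rep("-", ins_max[cpos + 1L] - length(block)))
      out <- c(out, block)
      if (cpos == Lc) break
      # emit the column for center position cpos+1
      out <- c(out, mc[t])
      t <- t + 1L
      cpos <- cpos + 1L
    }
    paste(out, collapse = "")
  }
  center_aln <- {
    out <- character(0)
    cc <- chars(center)
    for (cpos in 0:Lc) {
      out <- c(out, rep("-", ins_max[cpos + 1L]))
      if (cpos < Lc) out <- c(out, cc[cpos + 1L])
    }
    paste(out, collapse = "")
  }
  res <- character(n)
  res[c_idx] <- center_aln
  for (k in seq_along(others)) res[others[k]] <- layout_member(pals[[k]])
  names(res) <- names(seqs)
  stopifnot(length(unique(nchar(res))) == 1L)
  res
}

#' Pairwise distances from an alignment
#'
#' Pairwise deletion: for each pair, columns where either sequence has a gap
#' are dropped. `p` is the mismatch proportion over compared columns; `JC`
#' is the Jukes-Cantor transform `-(3/4) ln(1 - 4p/3)`, capped at a
#' documented maximum of 5.0 substitutions/site (with a `saturated`
#' attribute) when `p >= 0.749` makes the logarithm argument nonpositive or
#' unstable.
#'
#' @param aligned named character vector of equal-length aligned sequences.
#' @param model `"p"` or `"JC"`.
#' @return A `dist`-like square matrix (class `DistanceMatrix`) with taxa
#'   labels, attribute `saturated` (logical matrix).
#' @export
pairwise_distances <- function(aligned, model = c("p", "JC")) {
  model <- match.arg(model)
  stopifnot(length(aligned) >= 2L, !is.null(names(aligned)))
  if (length(unique(nchar(aligned))) != 1L)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  n <- length(aligned)
  M <- do.call(rbind, lapply(aligned, chars))
  D <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    if (!any(ok))
      stop("pair ", names(aligned)[i], "/", names(aligned)[j],
           " has no comparable columns", call. = FALSE)
    p <- mean(M[i, ok] != M[j, ok])
    d <- if (model == "p") p else {
      if (p >= JC_P_MAX) { sat[i, j] <- sat[j, i] <- TRUE; JC_SATURATION_CAP }
      else -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- sat
  attr(D, "model") <- model
  class(D) <- c("DistanceMatrix", "matrix", "array")
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classic agglomerative NJ with the Q-criterion, standard branch-length
#' formulas, negative branch lengths clamped to zero, and deterministic
#' tie-breaking: among equal-Q pairs the pair whose clusters contain the
#' lexicographically smallest leaf labels is joined. Exact (topology and
#' branch lengths) on additive distance matrices.
#'
#' @param D symmetric distance matrix with taxa labels (>= 2 taxa; the
#'   2-taxon case returns the single edge of that length).
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(D) {
  D <- unclass(D)
  labs <- rownames(D)
  stopifnot(!is.null(labs), nrow(D) == ncol(D))
  if (any(D < 0) || any(abs(D - t(D)) > 1e-12))
    stop("distance matrix must be symmetric and non-negative", call. = FALSE)
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 taxa", call. = FALSE)
  bl <- function(x) format(max(0, x), digits = 12, scientific = FALSE)
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", labs[1L], bl(D[1, 2] / 2),
                   labs[2L], bl(D[1, 2] / 2))
    return(ape::read.tree(text = nwk))
  }
  # active nodes: newick fragments + sort keys (smallest leaf label inside)
  frag <- labs
  key <- labs
  Dm <- D
  while (nrow(Dm) > 3L) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(ck)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(li), frag[j], bl(lj))
    newkey <- min(key[i], key[j])
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(Dm2) <- colnames(Dm2) <- NULL
    Dm <- Dm2
  }
  # terminal 3-node star
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], bl(l1), frag[2L], bl(l2),
                 frag[3L], bl(l3))
  ape::read.tree(text = nwk)
}

# canonical bipartition keys for the internal edges of an unrooted tree:
# each split is represented by the side NOT containing the alphabetically
# first taxon, as a sorted ';'-joined label string
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  n_tip <- length(tips)
  res <- character(0)
  internal <- which(tree$edge[, 2] > n_tip)
  for (e in internal) {
    node <- tree$edge[e, 2]
    below <- tips[unlist(.descendant_tips(tree, node))]
    side <- if (anchor %in% below) setdiff(tips, below) else below
    if (length(side) >= 2L && length(side) <= n_tip - 2L)
      res <- c(res, paste(sort(side), collapse = ";"))
  }
  unique(res)
}

.descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .descendant_tips, tree = tree))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (seeded), rebuilds the NJ
#' tree per replicate, and reports for every internal edge of the
#' point-estimate tree the percentage of replicates containing the same
#' bipartition. Supports are attached as internal node labels.
#'
#' @param aligned named character vector of aligned sequences.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed (resampling only).
#' @param model distance model, see [pairwise_distances()].
#' @return list with `tree` (point-estimate `phylo`, node labels =
#'   supports), `supports` (named numeric vector keyed by bipartition).
#' @export
bootstrap_support <- function(aligned, n_reps = 1000L, seed = 1L,
                              model = "JC") {
  stopifnot(n_reps >= 1L)
  L <- unique(nchar(aligned))
  stopifnot(length(L) == 1L)
  if (L < 2L) stop("alignment must have >= 2 columns", call. = FALSE)
  M <- do.call(rbind, lapply(aligned, chars))
  point <- nj_tree(pairwise_distances(aligned, model))
  bips <- tree_bipartitions(point)
  hits <- setNames(numeric(length(bips)), bips)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- setNames(apply(M[, cols, drop = FALSE], 1L, paste,
                                collapse = ""), names(aligned))
      rep_tree <- tryCatch(nj_tree(pairwise_distances(rep_aln, model)),
                           error = function(e) NULL)
      if (is.null(rep_tree)) next
      rb <- tree_bipartitions(rep_tree)
      hits[bips %in% rb] <- hits[bips %in% rb] + 1
    }
  })
  supports <- 100 * hits / n_reps
  # attach as node labels
  tree <- point
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  labels <- rep("", n_node)
  anchor <- sort(tree$tip.label)[1L]
  for (nd in seq_len(n_node)) {
    node <- n_tip + nd
    below <- tree$tip.label[unlist(.descendant_tips(tree, node))]
    side <- if (anchor %in% below) setdiff(tree$tip.label, below) else below
    keybp <- paste(sort(side), collapse = ";")
    if (keybp %in% names(supports))
      labels[nd] <- sprintf("%g", supports[[keybp]])
  }
  tree$node.label <- labels
  list(tree = tree, supports = supports)
}

#' Group intron calls into per-locus profiles
#'
#' @param calls an `intron_calls` data.frame.
#' @return Named list (by locus) of `intron_calls` subsets; every call
#'   appears in exactly one profile.
#' @export
locus_profiles <- function(calls) {
  split(calls, calls$locus)
}

#' Junction conservation profile of a locus
#'
#' Builds a position-frequency matrix over boundary-anchored junction
#' columns: the first `junction_window` nt of each member intron (5'
#' junction) followed by its last `junction_window` nt (3' junction), and
#' the per-column information content `2 - H` (Shannon entropy, log2, gaps
#' excluded). Conserved intron cores at the junctions show up as
#' high-information columns against a low-information interior.
#'
#' @param calls `intron_calls` with >= 2 members with intact junctions.
#' @param junction_window columns per junction side.
#' @return list of class `LocusProfile`: `locus`, `members`, `pfm` (4 x 2w
#'   counts matrix), `ic` (bits per column, in `[0, 2]`).
#' @export
junction_consensus <- function(calls, junction_window = 12L) {
  calls <- calls[!calls$truncated, , drop = FALSE]
  if (nrow(calls) < 2L)
    stop("need >= 2 members with intact junctions", call. = FALSE)
  w <- junction_window
  stopifnot(all(nchar(calls$sequence) >= 2L * w))
  block <- vapply(calls$sequence, function(s)
    paste0(substr(s, 1L, w), substr(s, nchar(s) - w + 1L, nchar(s))),
    character(1))
  M <- do.call(rbind, lapply(block, chars))
  pfm <- vapply(seq_len(2L * w), function(j)
    vapply(DNA_BASES, function(b) sum(M[, j] == b), numeric(1)),
    numeric(4))
  rownames(pfm) <- DNA_BASES
  ic <- apply(pfm, 2L, function(col) {
    tot <- sum(col)
    if (tot == 0) return(0)
    p <- col[col > 0] / tot
    2 + sum(p * log2(p))
  })
  structure(list(locus = calls$locus[1L], members = calls, pfm = pfm,
                 ic = ic),
            class = "LocusProfile")
}

#' @export
print.LocusProfile <- function(x, ...) {
  cat(sprintf("<LocusProfile locus %d: %d members, mean IC %.2f bits>\n",
              x$locus, nrow(x$members), mean(x$ic)))
  invisible(x)
}

#' Write a position-frequency matrix profile as TSV
#' @param profile a `LocusProfile`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  d <- data.frame(column = seq_along(profile$ic), t(profile$pfm),
                  IC_bits = profile$ic)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean pairwise identity of an alignment
#'
#' Identity is identical-residue columns over the full alignment length, so
#' gap columns count against identity. Used to refuse cross-locus
#' comparison: introns from different loci share too little identity for
#' meaningful alignment-based phylogenetics.
#' @param aligned named character vector of aligned sequences.
#' @return Mean pairwise identity in `[0, 1]`.
#' @export
mean_pairwise_identity <- function(aligned) {
  stopifnot(length(aligned) >= 2L)
  M <- do.call(rbind, lapply(aligned, chars))
  n <- length(aligned)
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + mean(M[i, ] == M[j, ] & M[i, ] != "-")
    cnt <- cnt + 1L
  }
  tot / cnt
}
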