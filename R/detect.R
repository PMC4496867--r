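# Structural intron detection: insertions relative to the intron-free
# reference, locus snapping, excision/re-ligation, GFF3/TSV/FASTA export.

FLANK_NT <- 15L

#' Detect intron insertions in a 16S gene
#'
#' Aligns the query against the intron-free reference and emits one call per
#' maximal run of inserted query positions of length `>= min_insert`. The
#' locus of a call is the reference position directly before the insertion
#' point; raw loci are snapped onto the canonical 13-locus set within
#' `snap_tolerance` nt to absorb alignment jitter at repetitive junctions.
#' Runs truncated by a fragment end are emitted with `truncated = TRUE`
#' (these route to the PRU category downstream).
#'
#' @param query DNA string of the (possibly intron-containing) gene.
#' @param ref a [ref_16S()] `ReferenceModel`.
#' @param min_insert minimum insertion length called as an intron (nt).
#'   The default of 12 separates even the smallest hairpin introns from
#'   alignment noise.
#' @param host_id identifier recorded in the calls.
#' @param snap_tolerance max distance (nt) for canonical-locus snapping.
#' @param scoring see [align_scoring()].
#' @return A data.frame of intron calls (class `intron_calls`) with columns
#'   `host_id`, `locus`, `canonical`, `host_start`, `host_end`, `length`,
#'   `truncated`, `sequence`, `upstream_flank`, `downstream_flank`,
#'   sorted by locus.
#' @export
detect_insertions <- function(query, ref = ref_16S(), min_insert = 12L,
                              host_id = "query", snap_tolerance = 3L,
                              scoring = align_scoring()) {
  query <- toupper(query)
  cm <- align_to_reference(query, ref, scoring, query_id = host_id)
  # drop weakly anchored terminal islands: with a cheap gap extension the
  # aligner will chase short chance matches beyond a fragment end (inside
  # trailing intron sequence), which would fabricate novel loci. Interior
  # islands are never touched - the genuine exon block between tandem loci
  # is only 7 nt and must survive.
  rp <- cm$ref_pos
  min_anchor <- 16L
  repeat {
    r <- rle(!is.na(rp))
    ends <- cumsum(r$lengths)
    isl <- data.frame(start = (ends - r$lengths + 1L)[r$values],
                      end = ends[r$values])
    if (nrow(isl) <= 1L) break
    changed <- FALSE
    first <- isl[1L, ]
    if (first$end - first$start + 1L < min_anchor) {
      rp[first$start:first$end] <- NA_integer_
      changed <- TRUE
    }
    last <- isl[nrow(isl), ]
    if (last$end - last$start + 1L < min_anchor) {
      rp[last$start:last$end] <- NA_integer_
      changed <- TRUE
    }
    if (!changed) break
  }
  cm$ref_pos <- rp
  runs <- na_runs(cm$ref_pos)
  calls <- empty_calls()
  n <- nchar(query)
  if (nrow(runs)) {
    runs <- runs[runs$end - runs$start + 1L >= min_insert, , drop = FALSE]
  }
  # resolve each run: snap/slip the junction onto the canonical frame
  work <- list()
  for (k in seq_len(nrow(runs))) {
    work <- c(work, .resolve_run(runs$start[k], runs$end[k], cm$ref_pos,
                                 query, ref, min_insert, snap_tolerance))
  }
  # tandem clusters are re-parsed from exon anchors: the global aligner can
  # merge closely spaced insertions (saving a gap opening by deleting or
  # mismatching the short exon block between the loci), so whenever any
  # cluster locus is involved the whole cluster region is re-derived from
  # the long unique exon segments flanking it
  for (cluster in list(c(901L, 908L, 919L), c(1205L, 1213L))) {
    idx <- which(vapply(work, function(w)
      isTRUE(w$canonical) && w$locus %in% cluster && !w$trunc5 && !w$trunc3,
      logical(1)))
    if (!length(idx)) next
    parsed <- .parse_cluster(query, ref, cluster, min_insert, cm$ref_pos)
    if (!is.null(parsed)) work <- c(work[-idx], parsed)
  }
  work <- work[order(vapply(work, function(w) w$locus, integer(1)))]
  seen_loci <- integer()
  for (w in work) {
    s <- w$s; e <- w$e; locus <- w$locus; canonical <- w$canonical
    trunc5 <- w$trunc5; trunc3 <- w$trunc3
    if (locus %in% seen_loci) {
      warning("second insertion at locus ", locus, " in ", host_id,
              "; kept as novel", call. = FALSE)
      canonical <- FALSE
    }
    seen_loci <- c(seen_loci, locus)
    up <- if (s > 1L) substr(query, max(1L, s - FLANK_NT), s - 1L) else ""
    down <- if (e < n) substr(query, e + 1L, min(n, e + FLANK_NT)) else ""
    calls[nrow(calls) + 1L, ] <- list(
      host_id = host_id, locus = locus, canonical = canonical,
      host_start = s, host_end = e, length = e - s + 1L,
      truncated = trunc5 || trunc3,
      sequence = substr(query, s, e),
      upstream_flank = up, downstream_flank = down)
  }
  calls <- calls[order(calls$locus), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("intron_calls", "data.frame")
  calls
}

# --- run resolution -------------------------------------------------------
# A run of inserted query positions becomes one or more intron calls.
# Three alignment artifacts must be undone; all are consequences of the
# scoring that keeps global insertion detection robust:
#  * boundary slip - the intron's first (last) bases resemble the exon
#    after (before) the insertion point, so the aligner consumes a few
#    reference positions with intron content and the raw locus drifts;
#  * deletion-form tandem merge - closely spaced insertions are merged
#    into one gap and the short exon blocks between the loci are deleted
#    from the reference (two gap opens beat three);
#  * impostor-form tandem merge - as above, except the skipped reference
#    blocks are consumed by mismatching columns just outside the run.
# Recovery leans on the canonical locus frame: the exon blocks between
# closely spaced canonical loci are known reference segments, and a merged
# run must contain them (possibly with host substitutions) between its
# component introns.

.resolve_run <- function(s, e, rp, query, ref, min_insert, snap_tolerance) {
  n <- nchar(query)
  trunc5 <- s == 1L
  trunc3 <- e == n
  if (trunc5 && trunc3) return(list())
  raw <- if (!trunc5) rp[s - 1L] else rp[e + 1L] - 1L
  snap <- snap_to_canonical(raw, tolerance = snap_tolerance)
  locus <- snap$position
  canonical <- snap$canonical
  if (canonical) {
    # a substitution next to the insertion point can make the aligner
    # trade an exon base into the gap run, shifting the apparent locus by
    # the snap offset; host exons carry no indels relative to the
    # reference frame, so sliding the span recovers the true boundaries
    d <- locus - raw
    if (d != 0L && !trunc5 && !trunc3 && s + d >= 1L && e + d <= n) {
      s <- s + d
      e <- e + d
    }
  } else if (!trunc5 && !trunc3) {
    slip <- .recover_slip(s, e, raw, query, ref, n)
    if (!is.null(slip)) {
      s <- slip$s; e <- slip$e; locus <- slip$locus; canonical <- TRUE
    }
  }
  list(list(s = s, e = e, locus = locus, canonical = canonical,
            trunc5 = trunc5, trunc3 = trunc3))
}

# boundary slip beyond the snap tolerance. The aligner slips when the
# intron's first (last) bases happen to match the reference just after
# (before) a canonical locus; it then consumes those reference positions
# with intron content and the true exon copy is pushed into the far end of
# the run. The signature is therefore that copy: a run tail (head) that
# agrees with the reference block between the canonical locus and the raw
# locus.
.recover_slip <- function(s, e, raw, query, ref, n, max_slip = 8L) {
  cl <- canonical_loci()
  for (L in cl[cl < raw & raw - cl <= max_slip]) {
    d <- raw - L
    if (e - d < s || s - d < 1L) next
    tail_win <- substr(query, e - d + 1L, e)
    if (.nmismatch(tail_win, substr(ref$sequence, L + 1L, raw)) <=
        ceiling(d / 2))
      return(list(s = s - d, e = e - d, locus = L))
  }
  for (L in cl[cl > raw & cl - raw <= max_slip]) {
    d <- L - raw
    if (s + d > e || e + d > n) next
    head_win <- substr(query, s, s + d - 1L)
    if (.nmismatch(head_win, substr(ref$sequence, raw + 1L, L)) <=
        ceiling(d / 2))
      return(list(s = s + d, e = e + d, locus = L))
  }
  NULL
}

.nmismatch <- function(a, b) {
  sum(chars(a) != chars(b))
}

# --- tandem cluster parsing ----------------------------------------------
# The canonical locus set contains two clusters of closely spaced loci
# (901/908/919 and 1205/1213). Insertions there sit so close together that
# the global aligner cannot be trusted to keep them apart: merging two
# gaps saves a gap opening and costs only the few-nucleotide exon block
# between the loci. The cluster region is therefore re-derived directly:
# long exon anchors flanking the whole cluster are located in the query
# (30 nt is unique and tolerant of host substitutions), and the region in
# between is parsed as intron?-block-intron?-block-intron?, placing each
# known inter-locus exon block at its best-mismatch position. A zero-length
# segment means the locus is unoccupied. Returns parts for the occupied
# loci, or NULL when the region cannot be parsed (calls then stand as
# aligned).

.parse_cluster <- function(query, ref, cluster, min_insert, ref_pos,
                           anchor_w = 30L, max_anchor_mm = 8L) {
  k <- length(cluster)
  l1 <- cluster[1L]; lk <- cluster[k]
  if (l1 - anchor_w < 1L || lk + anchor_w > ref$length) return(NULL)
  a_left <- substr(ref$sequence, l1 - anchor_w + 1L, l1)
  a_right <- substr(ref$sequence, lk + 1L, lk + anchor_w)
  pl <- .best_match_pos(query, a_left)
  pr <- .best_match_pos(query, a_right)
  if (is.null(pl) || is.null(pr) ||
      pl$mm > max_anchor_mm || pr$mm > max_anchor_mm) return(NULL)
  x0 <- pl$pos + anchor_w - 1L   # query position carrying reference l1
  z0 <- pr$pos                   # query position carrying reference lk + 1
  reg_s <- x0 + 1L
  reg_e <- z0 - 1L
  if (reg_e < reg_s) return(NULL)
  blocks <- vapply(seq_len(k - 1L), function(i)
    substr(ref$sequence, cluster[i] + 1L, cluster[i + 1L]), character(1))
  cand <- lapply(blocks, function(b)
    .block_candidates(query, reg_s, reg_e, b,
                      tol = ceiling(0.25 * nchar(b)), ref_pos))
  if (any(vapply(cand, nrow, integer(1)) == 0L)) return(NULL)
  seg_ok <- function(len) len == 0L || len >= min_insert
  d <- nchar(blocks)
  # parse selection is lexicographic on an effective block score (total
  # mismatches minus a bonus of 2 per fully aligned block: a candidate made
  # of columns the aligner itself matched to the reference is the aligner's
  # own block placement, while a chance copy sits inside a gap run), then
  # fewest introns (a chance copy must not invent an insertion), then the
  # largest minimum intron length (a chance copy just inside a long intron
  # would split it into an implausibly lopsided pair), then leftmost.
  best <- NULL
  consider <- function(sc, segs, p) {
    lens <- segs[, 2L] - segs[, 1L] + 1L
    pos_lens <- lens[lens > 0L]
    key <- c(sc, length(pos_lens), -min(c(pos_lens, .Machine$integer.max)))
    if (is.null(best) ||
        (key[1L] < best$key[1L]) ||
        (key[1L] == best$key[1L] && key[2L] < best$key[2L]) ||
        (key[1L] == best$key[1L] && key[2L] == best$key[2L] &&
         key[3L] < best$key[3L]))
      best <<- list(key = key, segs = segs, p = p)
  }
  if (k == 2L) {
    for (i in seq_len(nrow(cand[[1L]]))) {
      p1 <- cand[[1L]]$pos[i]
      if (!seg_ok(p1 - reg_s) || !seg_ok(reg_e - (p1 + d[1L] - 1L))) next
      consider(cand[[1L]]$mm[i] - 2 * cand[[1L]]$af[i],
               rbind(c(reg_s, p1 - 1L), c(p1 + d[1L], reg_e)), p1)
    }
  } else {
    for (i in seq_len(nrow(cand[[1L]]))) {
      p1 <- cand[[1L]]$pos[i]
      if (!seg_ok(p1 - reg_s)) next
      for (j in seq_len(nrow(cand[[2L]]))) {
        p2 <- cand[[2L]]$pos[j]
        if (p2 < p1 + d[1L]) next
        if (!seg_ok(p2 - (p1 + d[1L])) ||
            !seg_ok(reg_e - (p2 + d[2L] - 1L))) next
        consider(cand[[1L]]$mm[i] + cand[[2L]]$mm[j] -
                   2 * (cand[[1L]]$af[i] + cand[[2L]]$af[j]),
                 rbind(c(reg_s, p1 - 1L),
                       c(p1 + d[1L], p2 - 1L),
                       c(p2 + d[2L], reg_e)), c(p1, p2))
      }
    }
  }
  if (is.null(best)) return(NULL)
  bounds <- best$segs
  parts <- list()
  for (j in seq_len(k)) {
    if (bounds[j, 2L] < bounds[j, 1L]) next        # unoccupied locus
    parts[[length(parts) + 1L]] <- list(
      s = bounds[j, 1L], e = bounds[j, 2L], locus = cluster[j],
      canonical = TRUE, trunc5 = FALSE, trunc3 = FALSE)
  }
  if (!length(parts)) NULL else parts
}

# position and mismatch count of the best (fewest mismatches, leftmost)
# ungapped placement of `probe` in `query`
.best_match_pos <- function(query, probe) {
  qv <- chars(query)
  pv <- chars(probe)
  L <- length(pv)
  n_start <- length(qv) - L + 1L
  if (n_start < 1L) return(NULL)
  mm <- integer(n_start)
  for (p in seq_len(L))
    mm <- mm + (qv[p:(p + n_start - 1L)] != pv[p])
  i <- which.min(mm)
  list(pos = i, mm = mm[i])
}

# all placements of `block` within query[s..e] with mismatches <= tol,
# sorted by mismatches then position; `af` is the fraction of the
# placement's columns that the global alignment matched to the reference
.block_candidates <- function(query, s, e, block, tol, ref_pos) {
  bv <- chars(block)
  d <- length(bv)
  if (e - s + 1L < d)
    return(data.frame(pos = integer(), mm = integer(), af = numeric()))
  qv <- chars(substr(query, s, e))
  n_start <- length(qv) - d + 1L
  mm <- integer(n_start)
  for (p in seq_len(d))
    mm <- mm + (qv[p:(p + n_start - 1L)] != bv[p])
  keep <- which(mm <= tol)
  af <- vapply(keep, function(i)
    mean(!is.na(ref_pos[(s + i - 1L):(s + i + d - 2L)])), numeric(1))
  out <- data.frame(pos = s + keep - 1L, mm = mm[keep], af = af)
  out[order(out$mm, out$pos), , drop = FALSE]
}

empty_calls <- function() {
  structure(
    data.frame(host_id = character(), locus = integer(), canonical = logical(),
               host_start = integer(), host_end = integer(), length = integer(),
               truncated = logical(), sequence = character(),
               upstream_flank = character(), downstream_flank = character(),
               stringsAsFactors = FALSE),
    class = c("intron_calls", "data.frame"))
}

#' Snap a raw insertion locus onto the canonical set
#'
#' @param raw_locus integer position from the alignment.
#' @param canonical the canonical locus set.
#' @param tolerance maximum absolute distance for snapping.
#' @return list with `position` and `canonical` (logical). Raw loci with no
#'   canonical locus within `tolerance` are returned unchanged and flagged
#'   `canonical = FALSE` ("novel locus").
#' @export
snap_to_canonical <- function(raw_locus, canonical = canonical_loci(),
                              tolerance = 2L) {
  stopifnot(tolerance >= 0L, length(raw_locus) == 1L)
  d <- abs(canonical - raw_locus)
  hit <- which(d <= tolerance)
  if (length(hit) > 1L)
    stop("ambiguous snap: ", raw_locus, " is within ", tolerance,
         " of multiple canonical loci", call. = FALSE)
  if (length(hit) == 1L)
    list(position = as.integer(canonical[hit]), canonical = TRUE)
  else
    list(position = as.integer(raw_locus), canonical = FALSE)
}

#' Excise intron calls and re-ligate the exons
#'
#' Models the post-transcriptional splicing outcome: removes every call span
#' from the host sequence and joins the exons in order.
#'
#' @param query the host DNA string the calls were made on.
#' @param calls an `intron_calls` data.frame (non-overlapping spans).
#' @return The ligated exon sequence (character).
#' @export
excise_and_ligate <- function(query, calls) {
  if (nrow(calls) == 0L) return(query)
  calls <- calls[order(calls$host_start), , drop = FALSE]
  if (any(calls$host_start[-1L] <= calls$host_end[-nrow(calls)]))
    stop("overlapping calls cannot be excised", call. = FALSE)
  if (calls$host_start[1L] < 1L || calls$host_end[nrow(calls)] > nchar(query))
    stop("call span outside the query", call. = FALSE)
  keep <- rep(TRUE, nchar(query))
  for (k in seq_len(nrow(calls)))
    keep[calls$host_start[k]:calls$host_end[k]] <- FALSE
  paste(chars(query)[keep], collapse = "")
}

#' Write intron calls as GFF3
#'
#' One `intron` feature per call, 1-based inclusive coordinates on the host
#' sequence, with `locus`, `length` and `truncated` attributes.
#'
#' @param calls an `intron_calls` data.frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_calls_gff3 <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_len(nrow(calls))) {
    attrs <- sprintf("ID=intron_%s_%d;locus=%d;length=%d;truncated=%s",
                     calls$host_id[k], calls$locus[k], calls$locus[k],
                     calls$length[k], tolower(calls$truncated[k]))
    writeLines(paste(calls$host_id[k], "archintron", "intron",
                     calls$host_start[k], calls$host_end[k], ".", "+", ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Write intron calls as TSV
#' @param calls an `intron_calls` data.frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write intron sequences as FASTA
#'
#' Headers follow the `hostID|locusN` convention.
#' @param calls an `intron_calls` data.frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_intron_fasta <- function(calls, path) {
  seqs <- setNames(calls$sequence,
                   sprintf("%s|locus%d", calls$host_id, calls$locus))
  write_fasta(seqs, path)
}
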