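# Intron classification: ORF finding, LAGLI-DADG motif scanning, base-pair
# maximization folding, bulge-helix-bulge junction detection, GC statistics.

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# LAGLI-DADG motif as a packaged position-class pattern. Each element is the
# admissible residue set for one position; a match tolerates at most
# `max_mismatch` violating positions. The canonical LAGLIDADG nonapeptide
# satisfies every position.
LAGLIDADG_PATTERN <- list(
  c("L", "I", "V", "M", "F", "A"),
  c("L", "I", "V", "M", "F", "A"),
  c("G", "A", "S"),
  c("L", "I", "V", "M", "F"),
  c("L", "I", "V", "M", "F"),
  "D",
  c("G", "A", "S"),
  c("D", "E"),
  "G")

translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in an intron sequence
#'
#' Scans all six frames for ORFs beginning at a start codon (ATG/GTG/TTG,
#' the bacterial/archaeal repertoire of translation table 11) and ending at
#' the next in-frame stop or at the end of the sequence. Within each
#' stop-bounded segment the first start codon (longest ORF) is reported.
#'
#' @param seq DNA string.
#' @param min_aa minimum peptide length (amino acids, stop excluded).
#' @return data.frame with columns `start`, `end` (1-based inclusive on the
#'   forward strand), `strand`, `peptide`, `length_aa`, sorted by
#'   `length_aa` decreasing.
#' @export
find_orfs <- function(seq, min_aa = 50L) {
  seq <- toupper(seq)
  assert_dna(seq, allow_n = FALSE, what = "intron sequence")
  stopifnot(min_aa >= 10L)
  n <- nchar(seq)
  hits <- list()
  scan_strand <- function(s, strand) {
    L <- nchar(s)
    for (off in 0:2) {
      nc <- (L - off) %/% 3L
      if (nc < 2L) next
      starts_nt <- off + 3L * (seq_len(nc) - 1L) + 1L
      codons <- substring(s, starts_nt, starts_nt + 2L)
      stops <- which(codons %in% STOP_CODONS)
      seg_begin <- c(1L, stops + 1L)
      seg_end <- c(stops, nc)
      seg_has_stop <- c(rep(TRUE, length(stops)), FALSE)
      for (g in seq_along(seg_begin)) {
        b <- seg_begin[g]; e <- seg_end[g]
        if (seg_has_stop[g]) e_pep <- e - 1L else e_pep <- e
        if (e_pep < b) next
        st <- which(codons[b:e_pep] %in% START_CODONS)
        if (!length(st)) next
        st <- b + st[1L] - 1L
        len_aa <- e_pep - st + 1L
        if (len_aa < min_aa) next
        pep <- translate_dna(substr(s, starts_nt[st],
                                    starts_nt[e_pep] + 2L))
        nt_start <- starts_nt[st]
        nt_end <- if (seg_has_stop[g]) starts_nt[e] + 2L else starts_nt[e_pep] + 2L
        if (strand == "+") {
          hits[[length(hits) + 1L]] <<- data.frame(
            start = nt_start, end = nt_end, strand = "+",
            peptide = pep, length_aa = len_aa)
        } else {
          hits[[length(hits) + 1L]] <<- data.frame(
            start = L - nt_end + 1L, end = L - nt_start + 1L, strand = "-",
            peptide = pep, length_aa = len_aa)
        }
      }
    }
  }
  scan_strand(seq, "+")
  scan_strand(revcomp(seq), "-")
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), peptide = character(),
                      length_aa = integer()))
  out <- do.call(rbind, hits)
  out <- out[order(-out$length_aa, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a peptide for LAGLI-DADG motifs
#'
#' Counts non-overlapping occurrences (left to right) of the packaged
#' LAGLI-DADG position-class pattern, tolerating `max_mismatch` violating
#' positions per occurrence. The count is capped at 2 and mapped onto the
#' two architectures of homing endonucleases: one copy = homodimeric enzyme
#' (one motif per subunit), two copies = monomeric enzyme carrying both
#' motifs on a single chain.
#'
#' @param peptide amino-acid string (>= 20 aa).
#' @param max_mismatch tolerated violating positions per match.
#' @return list with `count` (0, 1 or 2), `positions` (data.frame
#'   `start_aa`, `end_aa`), and `form` (`"none"`, `"homodimer"` or
#'   `"monomer"`).
#' @export
scan_laglidadg <- function(peptide, max_mismatch = 1L) {
  peptide <- toupper(peptide)
  stopifnot(nchar(peptide) >= 20L)
  aa <- chars(peptide)
  m <- length(LAGLIDADG_PATTERN)
  pos <- integer()
  i <- 1L
  while (i <= length(aa) - m + 1L) {
    mism <- 0L
    for (k in seq_len(m)) {
      if (!(aa[i + k - 1L] %in% LAGLIDADG_PATTERN[[k]])) mism <- mism + 1L
      if (mism > max_mismatch) break
    }
    if (mism <= max_mismatch) {
      pos <- c(pos, i)
      i <- i + m            # non-overlapping
    } else i <- i + 1L
  }
  count <- min(length(pos), 2L)
  list(count = count,
       positions = data.frame(start_aa = pos, end_aa = pos + m - 1L),
       form = c("none", "homodimer", "monomer")[count + 1L])
}

#' Fold a sequence by base-pair maximization
#'
#' Nussinov dynamic programming over the pairs AU/AT, GC and GU/GT with a
#' minimum hairpin loop. This deliberately replaces free-energy folding: the
#' package cares about the existence and position of pairing (hairpin arms,
#' BHB helices), not about thermodynamics.
#'
#' @param seq DNA or RNA string.
#' @param min_loop minimum number of unpaired positions enclosed by a pair.
#' @return list with `pairs` (maximum base-pair count), `structure`
#'   (dot-bracket string; ties broken toward pairing the 5'-most candidate)
#'   and `paired_fraction`.
#' @export
#' @examples
#' nussinov_fold("GCGAAACGC")$pairs  # 3
nussinov_fold <- function(seq, min_loop = 3L) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 1L, min_loop >= 3L)
  res <- nussinov_fold_cpp(chartr("U", "T", seq), as.integer(min_loop))
  res$paired_fraction <- 2 * res$pairs / nchar(seq)
  res
}

# stacked complementary run starting with w[a]:w[e], extending inward
.stack_len <- function(w, a, e, limit) {
  h <- 0L
  while (h < limit && a + h < e - h &&
         .pairs_ok(w[a + h], w[e - h])) h <- h + 1L
  h
}
.pairs_ok <- function(x, y) {
  (x == "A" && y == "T") || (x == "T" && y == "A") ||
  (x == "G" && y == "C") || (x == "C" && y == "G") ||
  (x == "G" && y == "T") || (x == "T" && y == "G")
}
.pair_weight <- function(x, y) {
  if ((x == "G" && y == "C") || (x == "C" && y == "G")) 2L else 1L
}

#' Detect a bulge-helix-bulge motif at an intron's junctions
#'
#' Builds the junction window (the last `window` exon nt upstream, the first
#' and last `window` nt of the intron, and the first `window` exon nt
#' downstream) and searches it for the splicing-competent geometry: a
#' central helix of stacked pairs formed between the intron's 5' and 3'
#' ends, flanked by two unpaired bulges that each contain one exon-intron
#' boundary - the hypothesized excision locations. The helix is scored by
#' GC-weighted pair count (GC = 2, AT/GU = 1); chance complementarity in
#' random junctions occasionally produces a short helix, which is why the
#' acceptance threshold is a score, not just a minimum helix length.
#'
#' @param call one intron call (single row of an `intron_calls` data.frame,
#'   or a list with `sequence`, `upstream_flank`, `downstream_flank`,
#'   `truncated`).
#' @param window junction window size (nt, >= 10).
#' @param min_helix minimum helix length (bp).
#' @param min_bulge minimum bulge length (nt).
#' @param score_min minimum GC-weighted helix score to accept the motif.
#' @return A list of class `BHBMotif` with `helix_len`, `bulge5_len`,
#'   `bulge3_len`, `excision_sites` (positions of the first and last intron
#'   nt within the window), and `score`; or `NULL` if no admissible helix
#'   reaches `score_min`.
#' @export
detect_bhb <- function(call, window = 12L, min_helix = 4L, min_bulge = 2L,
                       score_min = 10L) {
  stopifnot(window >= 10L)
  call <- as.list(call)
  if (isTRUE(call$truncated))
    stop("truncated call: junction incomplete, route to PRU", call. = FALSE)
  up <- call$upstream_flank
  down <- call$downstream_flank
  if (!nzchar(up) || !nzchar(down))
    stop("both exon flanks are required for BHB detection", call. = FALSE)
  intron <- call$sequence
  len <- nchar(intron)
  up_tail <- substr(up, max(1L, nchar(up) - window + 1L), nchar(up))
  down_head <- substr(down, 1L, min(window, nchar(down)))
  if (len <= 2L * window) {
    ipart <- intron
  } else {
    ipart <- paste0(substr(intron, 1L, window),
                    substr(intron, len - window + 1L, len))
  }
  w <- chars(paste0(up_tail, ipart, down_head))
  b1 <- nchar(up_tail)                  # boundary after position b1
  b2 <- b1 + nchar(ipart)               # boundary after position b2
  # helix 5' strand must start inside the intron leaving an unpaired bulge
  # spanning boundary b1; 3' strand must end inside the intron leaving an
  # unpaired bulge spanning boundary b2
  best <- NULL
  a_hi <- b2 - 2L * min_helix
  e_hi <- b2 + 1L - min_bulge
  if (b1 + min_bulge > a_hi) return(NULL)
  for (a in (b1 + min_bulge):a_hi) {
    e_lo <- a + 2L * min_helix - 1L
    if (e_lo > e_hi) next
    for (e in e_lo:e_hi) {
      h <- .stack_len(w, a, e, limit = floor((e - a + 1L) / 2))
      if (h < min_helix) next
      score <- sum(vapply(seq_len(h) - 1L, function(k)
        .pair_weight(w[a + k], w[e - k]), integer(1)))
      if (is.null(best) || score > best$score ||
          (score == best$score && h > best$helix_len)) {
        best <- list(helix_len = h,
                     bulge5_len = a - b1,
                     bulge3_len = b2 - e + 1L,
                     excision_sites = c(b1 + 1L, b2),
                     score = score)
      }
    }
  }
  if (is.null(best) || best$score < score_min) return(NULL)
  class(best) <- "BHBMotif"
  best
}

#' @export
print.BHBMotif <- function(x, ...) {
  cat(sprintf("<BHB: helix %d bp, bulges %d/%d nt, score %d>\n",
              x$helix_len, x$bulge5_len, x$bulge3_len, x$score))
  invisible(x)
}

#' Classification parameters
#'
#' @param min_aa minimum qualifying ORF length (aa).
#' @param hp_max_len maximum hairpin-intron length (nt, exclusive).
#' @param paired_min minimum paired fraction for the hairpin category.
#' @param bhb_window,bhb_min_helix,bhb_min_bulge,bhb_score_min see
#'   [detect_bhb()].
#' @param motif_max_mismatch see [scan_laglidadg()].
#' @return A parameter list.
#' @export
classify_params <- function(min_aa = 50L, hp_max_len = 50L, paired_min = 0.5,
                            bhb_window = 12L, bhb_min_helix = 4L,
                            bhb_min_bulge = 2L, bhb_score_min = 10L,
                            motif_max_mismatch = 1L) {
  list(min_aa = min_aa, hp_max_len = hp_max_len, paired_min = paired_min,
       bhb_window = bhb_window, bhb_min_helix = bhb_min_helix,
       bhb_min_bulge = bhb_min_bulge, bhb_score_min = bhb_score_min,
       motif_max_mismatch = motif_max_mismatch)
}

#' Classify one intron call
#'
#' Applies the four-category decision in fixed order: (1) a truncated call
#' is PRU (partial); (2) a qualifying ORF carrying at least one LAGLI-DADG
#' motif makes the intron HE (homing-endonuclease coding); (3) a short
#' (< 50 nt) intron that folds back on itself (paired fraction >= 0.5) and
#' presents a BHB motif is HP (hairpin); (4) an intron with both junctions
#' intact and no qualifying ORF is REMNANT; (5) anything else is PRU
#' (uncharacterized). GC content is always reported.
#'
#' @param call one intron call (row of an `intron_calls` data.frame).
#' @param params see [classify_params()].
#' @return list with `category` (`"HE"`, `"HP"`, `"REMNANT"`, `"PRU"`),
#'   `motif_count`, `motif_form`, `orf` (best qualifying ORF row or `NULL`),
#'   `hairpin` (list `pairs`, `paired_fraction`, or `NULL` for long
#'   introns), `bhb` ([detect_bhb()] result or `NULL`), and `gc` (fraction).
#' @export
classify_intron <- function(call, params = classify_params()) {
  call <- as.list(call)
  gc <- gc_fraction(call$sequence)
  len <- nchar(call$sequence)
  out <- list(category = "PRU", motif_count = 0L, motif_form = "none",
              orf = NULL, hairpin = NULL, bhb = NULL, gc = gc)
  if (isTRUE(call$truncated)) return(out)
  # (2) homing endonuclease: qualifying ORF with >= 1 motif
  orfs <- find_orfs(call$sequence, min_aa = params$min_aa)
  for (k in seq_len(nrow(orfs))) {
    if (nchar(orfs$peptide[k]) < 20L) next
    scan <- scan_laglidadg(orfs$peptide[k],
                           max_mismatch = params$motif_max_mismatch)
    if (scan$count >= 1L) {
      out$category <- "HE"
      out$motif_count <- scan$count
      out$motif_form <- scan$form
      out$orf <- orfs[k, , drop = FALSE]
      return(out)
    }
  }
  # (3) hairpin
  if (len < params$hp_max_len) {
    fold <- nussinov_fold(call$sequence)
    out$hairpin <- list(pairs = fold$pairs,
                        paired_fraction = fold$paired_fraction)
    bhb <- tryCatch(
      detect_bhb(call, window = params$bhb_window,
                 min_helix = params$bhb_min_helix,
                 min_bulge = params$bhb_min_bulge,
                 score_min = params$bhb_score_min),
      error = function(e) NULL)
    out$bhb <- bhb
    if (fold$paired_fraction >= params$paired_min && !is.null(bhb)) {
      out$category <- "HP"
      return(out)
    }
  }
  # (4) remnant: intact junctions, no qualifying ORF at all
  if (nrow(orfs) == 0L && nzchar(call$upstream_flank) &&
      nzchar(call$downstream_flank)) {
    out$category <- "REMNANT"
    return(out)
  }
  out                                  # (5) PRU
}

#' Classify a table of intron calls
#'
#' @param calls an `intron_calls` data.frame.
#' @param params see [classify_params()].
#' @return data.frame with one row per call: `host_id`, `locus`, `length`,
#'   `truncated`, `category`, `motif_count`, `motif_form`, `orf_span`,
#'   `paired_fraction`, `bhb_helix`, `gc`.
#' @export
classify_introns <- function(calls, params = classify_params()) {
  rows <- lapply(seq_len(nrow(calls)), function(k) {
    cl <- classify_intron(calls[k, , drop = FALSE], params)
    data.frame(
      host_id = calls$host_id[k], locus = calls$locus[k],
      length = calls$length[k], truncated = calls$truncated[k],
      category = cl$category, motif_count = cl$motif_count,
      motif_form = cl$motif_form,
      orf_span = if (is.null(cl$orf)) "" else
        sprintf("%d-%d(%s)", cl$orf$start, cl$orf$end, cl$orf$strand),
      paired_fraction = if (is.null(cl$hairpin)) NA_real_ else
        cl$hairpin$paired_fraction,
      bhb_helix = if (is.null(cl$bhb)) NA_integer_ else cl$bhb$helix_len,
      gc = cl$gc)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(host_id = character(), locus = integer(), length = integer(),
               truncated = logical(), category = character(),
               motif_count = integer(), motif_form = character(),
               orf_span = character(), paired_fraction = numeric(),
               bhb_helix = integer(), gc = numeric())
  rownames(out) <- NULL
  out
}

#' GC content summary
#'
#' Per-sequence GC fraction (G+C over A+C+G+T; ambiguity codes are excluded
#' from numerator and denominator), summarized as population mean and
#' standard deviation in percent.
#'
#' @param seqs character vector of DNA strings (non-empty).
#' @return list with `mean` and `sd` (percent), and `gc` (per-sequence
#'   fractions).
#' @export
#' @examples
#' gc_summary(c("GGCC", "ATAT"))
gc_summary <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence list", call. = FALSE)
  stopifnot(all(nchar(seqs) > 0L))
  gc <- vapply(seqs, gc_fraction, numeric(1), USE.NAMES = FALSE)
  n <- length(gc)
  m <- mean(gc) * 100
  s <- if (n > 1L) sqrt(sum((gc * 100 - m)^2) / n) else 0
  list(mean = m, sd = s, gc = gc)
}
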