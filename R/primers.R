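# Degenerate "universal" primer auditing: IUPAC matching on the reference,
# footprints, locus interruption, amplicon intron content.

#' Read a primer list
#'
#' Three-column TSV: `name`, `sequence` (IUPAC codes), `orientation`
#' (`F`/`R`). Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return data.frame of validated primers.
#' @export
read_primers <- function(path) {
  p <- read_tsv_fixture(path)
  stopifnot(all(c("name", "sequence", "orientation") %in% names(p)))
  for (k in seq_len(nrow(p)))
    validate_primer(p$sequence[k], p$orientation[k], p$name[k])
  p$sequence <- toupper(p$sequence)
  p
}

validate_primer <- function(sequence, orientation, name = "primer") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop(name, ": invalid IUPAC character in primer sequence", call. = FALSE)
  if (nchar(sequence) < 15L || nchar(sequence) > 30L)
    stop(name, ": primer length must be 15-30 nt", call. = FALSE)
  if (!orientation %in% c("F", "R"))
    stop(name, ": orientation must be 'F' or 'R'", call. = FALSE)
  invisible(TRUE)
}

#' Match a primer against the reference
#'
#' Reports every ungapped placement with at most `max_mismatch`
#' IUPAC-compatible mismatches. Reverse-orientation primers are matched as
#' their reverse complement; footprints are always reported on
#' forward-strand reference coordinates.
#'
#' @param sequence primer sequence (IUPAC codes, 5'->3').
#' @param orientation `"F"` or `"R"`.
#' @param ref a [ref_16S()] `ReferenceModel`.
#' @param max_mismatch maximum tolerated mismatches.
#' @param name primer name recorded in the output.
#' @return data.frame of footprints: `name`, `ref_start`, `ref_end`,
#'   `mismatches`, sorted by `mismatches` then `ref_start`.
#' @export
match_primer <- function(sequence, orientation = "F", ref = ref_16S(),
                         max_mismatch = 1L, name = "primer") {
  sequence <- toupper(sequence)
  validate_primer(sequence, orientation, name)
  probe <- if (orientation == "R") revcomp(sequence) else sequence
  pc <- chars(probe)
  rc_ <- chars(ref$sequence)
  L <- length(pc)
  n <- ref$length
  if (L > n) stop("primer longer than reference", call. = FALSE)
  n_start <- n - L + 1L
  mm <- integer(n_start)
  for (p in seq_len(L)) {
    allowed <- IUPAC_SETS[[pc[p]]]
    mm <- mm + !(rc_[p:(p + n_start - 1L)] %in% allowed)
  }
  keep <- which(mm <= max_mismatch)
  hits <- data.frame(name = rep(name, length(keep)), ref_start = keep,
                     ref_end = keep + L - 1L, mismatches = mm[keep])
  hits[order(hits$mismatches, hits$ref_start), , drop = FALSE]
}

#' Best placement among a primer's footprints
#'
#' Fewest mismatches, then smallest reference start.
#' @param footprints data.frame from [match_primer()].
#' @return One-row data.frame (or zero rows if there was no placement).
#' @export
best_footprint <- function(footprints) {
  if (nrow(footprints) == 0L) return(footprints)
  footprints[order(footprints$mismatches, footprints$ref_start)[1L], ,
             drop = FALSE]
}

#' Audit primers for intron-locus interruption
#'
#' A footprint `[s, e]` spans locus `L` iff `s <= L < e`: the insertion
#' point between positions `L` and `L + 1` lies strictly inside the
#' annealing region. An insertion at the footprint's terminal 3' boundary
#' (i.e. `L = e`) does not interrupt annealing.
#'
#' @param footprints data.frame with one best footprint per primer
#'   (columns `name`, `ref_start`, `ref_end`).
#' @param loci integer vector of insertion loci.
#' @return data.frame `name`, `loci_spanned` (semicolon-joined),
#'   `n_loci`, `interrupted`, sorted by primer name.
#' @export
audit_primer_set <- function(footprints, loci = canonical_loci()) {
  loci <- sort(as.integer(loci))
  rows <- lapply(seq_len(nrow(footprints)), function(k) {
    s <- footprints$ref_start[k]; e <- footprints$ref_end[k]
    sp <- loci[s <= loci & loci < e]
    data.frame(name = footprints$name[k],
               loci_spanned = paste(sp, collapse = ";"),
               n_loci = length(sp), interrupted = length(sp) > 0L)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), loci_spanned = character(),
               n_loci = integer(), interrupted = logical())
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the intron content of an amplicon
#'
#' Given a forward and a reverse primer footprint on the reference and a
#' gene's intron calls, reports what a PCR amplicon would contain. A primer
#' whose annealing region spans an occupied locus cannot prime: the outcome
#' is flagged `no_amplification` rather than raising an error.
#'
#' @param fwd,rev one-row footprint data.frames ([best_footprint()]).
#' @param calls `intron_calls` for the gene (loci on reference coordinates).
#' @return list with `no_amplification` (logical), `exon_span`
#'   (`c(start, end)` on the reference), `introns` (the contained calls),
#'   `exon_length`, `inflated_length` (exon + intron nt).
#' @export
amplicon_intron_content <- function(fwd, rev, calls) {
  stopifnot(nrow(fwd) == 1L, nrow(rev) == 1L)
  if (!(fwd$ref_start < rev$ref_start))
    stop("forward footprint must lie 5' of the reverse footprint",
         call. = FALSE)
  occupied <- calls$locus
  spans <- function(fp) any(fp$ref_start <= occupied & occupied < fp$ref_end)
  if (spans(fwd) || spans(rev))
    return(list(no_amplification = TRUE, exon_span = NULL, introns = NULL,
                exon_length = NA_integer_, inflated_length = NA_integer_))
  span <- c(fwd$ref_start, rev$ref_end)
  inside <- calls[occupied >= fwd$ref_end & occupied < rev$ref_start, ,
                  drop = FALSE]
  exon_len <- span[2L] - span[1L] + 1L
  list(no_amplification = FALSE, exon_span = span, introns = inside,
       exon_length = exon_len,
       inflated_length = exon_len + sum(inside$length))
}

#' Curated per-locus intron inventory
#'
#' The packaged transcription of the curated archaeal 16S intron inventory:
#' per-locus counts of homing-endonuclease CDS introns (split by LAGLI-DADG
#' motif copy number), short hairpin introns, and
#' partial/remnant/uncharacterized introns, plus the "universal" primers
#' whose annealing site spans each locus. Typographically ambiguous cells
#' are flagged in the `note` column.
#'
#' @return data.frame with columns `locus`, `taxa`, `n_cds`, `cds_m1`,
#'   `cds_m2`, `n_hp`, `n_pru`, `primers`, `note`.
#' @export
curated_locus_table <- function() {
  read_tsv_fixture(extdata("table1_loci.tsv"))
}

#' Primer-to-locus interruption map from the curated inventory
#'
#' @return data.frame `name`, `loci_spanned`, `n_loci`, `interrupted` (one
#'   row per distinct primer named in the curated table).
#' @export
curated_primer_map <- function() {
  t1 <- curated_locus_table()
  pairs <- do.call(rbind, lapply(seq_len(nrow(t1)), function(k) {
    ps <- strsplit(t1$primers[k], ";", fixed = TRUE)[[1]]
    ps <- ps[nzchar(ps)]
    if (!length(ps)) return(NULL)
    data.frame(name = ps, locus = t1$locus[k])
  }))
  out <- do.call(rbind, lapply(split(pairs, pairs$name), function(d) {
    data.frame(name = d$name[1L],
               loci_spanned = paste(sort(d$locus), collapse = ";"),
               n_loci = nrow(d), interrupted = TRUE)
  }))
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
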