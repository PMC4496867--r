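# Reference coordinate frame: packaged 16S reference, semi-global alignment,
# query<->reference coordinate maps, V-region lookup, tandem-locus geometry.

.ref_cache <- new.env(parent = emptyenv())

#' Packaged 16S reference model
#'
#' Returns the packaged intron-free 16S rRNA gene reference that defines the
#' coordinate frame used throughout the package ("E. coli numbering": loci
#' are 1-based positions on this sequence). The packaged sequence is a
#' documented synthetic stand-in of the standard length (1542 nt) with
#' Thermoproteales-like GC content; the V1-V9 hypervariable intervals follow
#' the common E. coli interval convention.
#'
#' @return An object of class `ReferenceModel`: a list with elements `id`,
#'   `sequence` (character, 1542 nt, alphabet ACGT), `length`, and
#'   `v_regions` (data.frame with columns `name`, `start`, `end`).
#' @export
#' @examples
#' ref <- ref_16S()
#' ref$length
ref_16S <- function() {
  if (!is.null(.ref_cache$ref)) return(.ref_cache$ref)
  seqs <- read_fasta(extdata("ref16S_synthetic.fasta"))
  v <- read_tsv_fixture(extdata("v_regions.tsv"))[, c("name", "start", "end")]
  ref <- new_reference_model(names(seqs)[1], seqs[[1]], v)
  .ref_cache$ref <- ref
  ref
}

#' Construct a reference model
#'
#' @param id short identifier for the reference sequence.
#' @param sequence DNA string over \{A,C,G,T\} (no ambiguity codes).
#' @param v_regions data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive, non-overlapping, sorted, within the sequence).
#' @return A `ReferenceModel` object.
#' @export
new_reference_model <- function(id, sequence, v_regions) {
  sequence <- toupper(sequence)
  assert_dna(sequence, allow_n = FALSE, what = "reference sequence")
  v <- v_regions[order(v_regions$start), , drop = FALSE]
  stopifnot(all(v$start >= 1L), all(v$end <= nchar(sequence)),
            all(v$start <= v$end))
  if (nrow(v) > 1L && any(v$start[-1L] <= v$end[-nrow(v)]))
    stop("v_regions overlap", call. = FALSE)
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 v_regions = v),
            class = "ReferenceModel")
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat(sprintf("<ReferenceModel %s: %d nt, GC %.1f%%, %d V-regions>\n",
              x$id, x$length, 100 * gc_fraction(x$sequence),
              nrow(x$v_regions)))
  invisible(x)
}

#' The canonical intron insertion loci
#'
#' The 13 insertion loci at which 16S rRNA gene introns have been curated in
#' thermophilic Archaea, expressed as the reference position directly before
#' the insertion point.
#'
#' @return Integer vector of length 13.
#' @export
canonical_loci <- function() {
  c(374L, 548L, 722L, 781L, 803L, 901L, 908L, 919L, 978L, 1093L, 1205L,
    1213L, 1391L)
}

#' Alignment scoring parameters
#'
#' Defaults favor a single long gap per intron over many short gaps: a
#' stiff gap opening against a very cheap extension. The extension must be
#' cheap because a gene can carry a dozen introns of up to ~900 nt; if
#' extending gaps were expensive, the optimal alignment would simply stop
#' before the later introns instead of gapping across all of them (the
#' exon blocks between tandem loci are as short as 7 nt and cannot pay for
#' an expensive crossing). The opening must be stiff (more than twice the
#' largest chance-match run expected inside an intron) so that short
#' accidental matches of intron content to the reference cannot profitably
#' split an insertion gap in two; a genuine inter-intron exon block is
#' never suppressed by this because its reference positions have to be
#' consumed either way. The mismatch penalty is stiff for the same reason:
#' a cheap mismatch would let the aligner absorb a short exon block between
#' tandem introns by mismatching intron bases across it, merging the two
#' insertions into one; at -6 the expected cost of mismatching intron
#' content against exon exceeds the gap opening saved.
#'
#' @param match,mismatch substitution scores. `N` never matches (scored as a
#'   mismatch against everything) so that locus placement stays conservative.
#' @param gap_open,gap_ext affine gap penalties (negative numbers).
#' @return A list of scoring parameters.
#' @export
align_scoring <- function(match = 2, mismatch = -6, gap_open = -30,
                          gap_ext = -0.05) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_ext <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

.substitution_matrix <- function(scoring) {
  letters5 <- c(DNA_BASES, "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch  # N matches nothing, including N
  m
}

#' Align a query gene to the reference frame
#'
#' Semi-global alignment of a (possibly intron-containing, possibly partial)
#' 16S gene against the packaged reference: terminal unaligned stretches of
#' the query are free, internal insertions appear as flagged runs in the
#' coordinate map. Insertions are left-normalized so that repeats do not
#' shift the insertion point to the right.
#'
#' @param query DNA string (>= 200 nt, alphabet ACGTN).
#' @param ref a [ref_16S()] `ReferenceModel`.
#' @param scoring see [align_scoring()].
#' @param query_id identifier stored in the map.
#' @return A `CoordinateMap`: list with `query_id`, `ref_pos` (integer vector
#'   of length `nchar(query)`; `NA` flags query positions inserted relative
#'   to the reference, including unalignable terminal overhangs), and
#'   `score`.
#' @export
#' @examples
#' ref <- ref_16S()
#' cm <- align_to_reference(ref$sequence, ref)
#' map_position(cm, 374)
align_to_reference <- function(query, ref = ref_16S(),
                               scoring = align_scoring(),
                               query_id = "query") {
  query <- toupper(query)
  assert_dna(query, allow_n = TRUE, what = "query")
  if (nchar(query) < 200L)
    stop("query shorter than 200 nt; refusing to place loci on fragments ",
         "this small", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(ref$sequence),
    type = "local",
    substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_ext))
  ap <- chars(as.character(Biostrings::pattern(pa)))
  as_ <- chars(as.character(Biostrings::subject(pa)))
  qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  rpos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  ref_pos <- rep(NA_integer_, nchar(query))
  for (i in seq_along(ap)) {
    pgap <- ap[i] == "-"
    sgap <- as_[i] == "-"
    if (!pgap && !sgap) {
      qpos <- qpos + 1L; rpos <- rpos + 1L
      ref_pos[qpos] <- rpos
    } else if (!pgap) {          # insertion in query
      qpos <- qpos + 1L
    } else {                     # deletion in query
      rpos <- rpos + 1L
    }
  }
  cm <- structure(list(query_id = query_id, query = query, ref_pos = ref_pos,
                       score = Biostrings::score(pa)),
                  class = "CoordinateMap")
  left_normalize(cm)
}

# Shift internal inserted runs as far left as sequence identity allows
# (VCF-style left alignment of insertions).
left_normalize <- function(cm) {
  q <- chars(cm$query)
  rp <- cm$ref_pos
  n <- length(rp)
  runs <- na_runs(rp)
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- runs$end[k]
    if (s == 1L || e == n) next  # terminal overhang, nothing to normalize
    while (s > 1L && !is.na(rp[s - 1L]) && q[s - 1L] == q[e]) {
      rp[e] <- rp[s - 1L]
      rp[s - 1L] <- NA_integer_
      s <- s - 1L; e <- e - 1L
    }
  }
  cm$ref_pos <- rp
  cm
}

# maximal runs of NA in an integer vector -> data.frame(start, end)
na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' @export
print.CoordinateMap <- function(x, ...) {
  n_ins <- sum(is.na(x$ref_pos))
  cat(sprintf("<CoordinateMap %s: %d nt, %d inserted, score %.1f>\n",
              x$query_id, length(x$ref_pos), n_ins, x$score))
  invisible(x)
}

#' Map a query position into reference coordinates
#'
#' @param cmap a `CoordinateMap` from [align_to_reference()].
#' @param query_pos 1-based position(s) on the query.
#' @return Integer vector: the reference position, or `NA` for positions
#'   inserted relative to the reference.
#' @export
map_position <- function(cmap, query_pos) {
  stopifnot(inherits(cmap, "CoordinateMap"))
  if (any(query_pos < 1L | query_pos > length(cmap$ref_pos)))
    stop("query position out of range 1..", length(cmap$ref_pos),
         call. = FALSE)
  cmap$ref_pos[query_pos]
}

#' Export a coordinate map as TSV
#'
#' Two columns: `query_pos` and `ref_pos` (`I` for inserted positions).
#' @param cmap a `CoordinateMap`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_coord_map <- function(cmap, path) {
  rp <- ifelse(is.na(cmap$ref_pos), "I", as.character(cmap$ref_pos))
  write.table(data.frame(query_pos = seq_along(cmap$ref_pos), ref_pos = rp),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' V-region membership of a reference position
#'
#' @param ref a `ReferenceModel`.
#' @param position 1-based reference position(s).
#' @return Character vector: the V-region name (`"V1"`..`"V9"`) or `NA` if
#'   the position lies outside all packaged hypervariable intervals.
#' @export
#' @examples
#' v_region_of(ref_16S(), canonical_loci())  # all NA: loci avoid V-regions
v_region_of <- function(ref, position) {
  stopifnot(inherits(ref, "ReferenceModel"))
  if (any(position < 1L | position > ref$length))
    stop("position out of range 1..", ref$length, call. = FALSE)
  v <- ref$v_regions
  vapply(position, function(p) {
    hit <- which(v$start <= p & p <= v$end)
    if (length(hit)) v$name[hit[1L]] else NA_character_
  }, character(1))
}

#' Find tandem (closely spaced) insertion loci
#'
#' Pairs of loci whose insertion points are separated by at most `max_gap`
#' exon nucleotides. Under the "position directly before insertion"
#' convention the separation between loci a < b is `b - a`: the exon
#' nucleotides strictly between the two insertion points. The canonical set
#' contains two such pairs (901/908 separated by 7 nt; 1205/1213 by 8 nt),
#' the geometry that makes co-conversion homing of a downstream intron
#' possible.
#'
#' @param loci integer vector of distinct locus positions.
#' @param max_gap maximum separation (nt) to report.
#' @return data.frame with columns `locus_a`, `locus_b`, `separation`,
#'   sorted by `locus_a`.
#' @export
#' @examples
#' find_tandem_loci(canonical_loci(), max_gap = 10)
find_tandem_loci <- function(loci, max_gap = 10L) {
  stopifnot(max_gap >= 1L, !anyDuplicated(loci))
  loci <- sort(as.integer(loci))
  out <- data.frame(locus_a = integer(), locus_b = integer(),
                    separation = integer())
  if (length(loci) >= 2L) {
    for (i in seq_len(length(loci) - 1L)) {
      for (j in (i + 1L):length(loci)) {
        sep <- loci[j] - loci[i]
        if (sep <= max_gap)
          out[nrow(out) + 1L, ] <- list(loci[i], loci[j], sep)
      }
    }
  }
  out[order(out$locus_a), , drop = FALSE]
}
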