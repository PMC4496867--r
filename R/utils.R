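# Small shared helpers. Nothing here is exported.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of concrete bases each matches
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  paste(unname(IUPAC_COMPLEMENT[chars]), collapse = "")
}

# Evaluate expr with a private, restored RNG state. All randomized package
# code routes through this so that callers' RNG streams are untouched and
# every result is reproducible from an integer seed.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483587)
}

assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alpha), seq))
    stop(what, " contains characters outside {", paste(strsplit(alpha, "")[[1]],
         collapse = ","), "}", call. = FALSE)
  invisible(seq)
}

# read a TSV with '#' comment header lines
read_tsv_fixture <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

extdata <- function(file) {
  p <- system.file("extdata", file, package = "archintron")
  if (!nzchar(p)) stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

gc_fraction <- function(seq) {
  v <- chars(toupper(seq))
  n <- sum(v %in% DNA_BASES)
  if (n == 0L) return(NA_real_)
  sum(v %in% c("G", "C")) / n
}

# simple FASTA reader/writer (plain text, uncompressed)
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) "" else
      paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  setNames(toupper(seqs), ids)
}

write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s))
      writeLines(substring(s, seq(1, nchar(s), width),
                           pmin(seq(1, nchar(s), width) + width - 1L, nchar(s))),
                 con)
  }
  invisible(path)
}
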