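ref <- ref_16S()

test_that("an exact reference substring matches at its own coordinates", {
  p <- substr(ref$sequence, 500, 519)
  hits <- match_primer(p, "F", ref, max_mismatch = 0)
  expect_true(any(hits$ref_start == 500 & hits$ref_end == 519 &
                  hits$mismatches == 0))
})

test_that("reverse-orientation primers report forward-strand footprints", {
  p <- archintron:::revcomp(substr(ref$sequence, 900, 919))
  hits <- match_primer(p, "R", ref, max_mismatch = 0)
  expect_equal(hits$ref_start, 900)
  expect_equal(hits$ref_end, 919)
  expect_equal(hits$mismatches, 0)
})

test_that("IUPAC matching equals the brute-force expansion oracle", {
  set.seed(123)
  codes <- c("R", "Y", "S", "W", "K", "M", "N")
  for (rep in 1:12) {
    L <- sample(15:20, 1)
    start <- sample(ref$length - L, 1)
    p <- substr(ref$sequence, start, start + L - 1)
    # degenerate-ize up to 4 positions (codes chosen to keep the original
    # base inside the set half the time, arbitrary otherwise)
    npos <- sample(1:4, 1)
    pos <- sample(L, npos)
    pv <- strsplit(p, "")[[1]]
    pv[pos] <- sample(codes, npos, replace = TRUE)
    p <- paste(pv, collapse = "")
    mm <- sample(0:1, 1)
    mine <- match_primer(p, "F", ref, max_mismatch = mm)$ref_start
    oracle <- oracle_match_positions(p, ref$sequence, max_mismatch = mm)
    expect_setequal(mine, oracle)
  }
})

test_that("primer validation rejects malformed input", {
  expect_error(match_primer("ACGTACGTACGTACGZ", "F", ref), "IUPAC")
  expect_error(match_primer("ACGT", "F", ref), "15-30")
  expect_error(match_primer(strrep("A", 20), "X", ref), "orientation")
})

test_that("span predicate boundaries are exact: s <= L < e", {
  fp <- data.frame(name = "p", ref_start = 900L, ref_end = 919L,
                   mismatches = 0L)
  rec <- audit_primer_set(fp, loci = c(899L, 900L, 918L, 919L))
  expect_equal(rec$loci_spanned, "900;918")
  expect_equal(rec$n_loci, 2L)
  # and a footprint away from all loci spans nothing
  rec0 <- audit_primer_set(data.frame(name = "q", ref_start = 10L,
                                      ref_end = 30L, mismatches = 0L))
  expect_false(rec0$interrupted)
})

test_that("footprint (900,919) is interrupted by both tandem loci 901/908", {
  fp <- data.frame(name = "Ab909R_demo", ref_start = 900L, ref_end = 919L,
                   mismatches = 0L)
  rec <- audit_primer_set(fp, canonical_loci())
  expect_true(rec$interrupted)
  expect_equal(rec$loci_spanned, "901;908")
})

test_that("the curated primer map reproduces the published audit", {
  pm <- curated_primer_map()
  expect_equal(nrow(pm), 13L)                      # distinct primer names
  expect_equal(sum(pm$n_loci >= 2), 5L)            # five span two loci
  expect_setequal(pm$name[pm$n_loci >= 2],
                  c("Ab909R", "Ab906F", "926wF", "U926R", "Ab927R"))
  expect_equal(pm$loci_spanned[pm$name == "Ab909R"], "901;908")
  # per-locus lists verbatim from the curated table
  t1 <- curated_locus_table()
  for (k in seq_len(nrow(t1))) {
    ps <- strsplit(t1$primers[k], ";")[[1]]
    for (p in ps[nzchar(ps)])
      expect_match(pm$loci_spanned[pm$name == p],
                   as.character(t1$locus[k]))
  }
})

test_that("best_footprint prefers fewest mismatches then leftmost", {
  fps <- data.frame(name = "p", ref_start = c(40L, 10L, 20L),
                    ref_end = c(59L, 29L, 39L), mismatches = c(0L, 1L, 0L))
  best <- best_footprint(fps)
  expect_equal(best$ref_start, 20L)
})

test_that("a primer drawn from an intron has no reference footprint", {
  gi <- generate_intron("REMNANT", 781, seed = 55)
  p <- substr(gi$sequence, 40, 59)
  expect_equal(nrow(match_primer(p, "F", ref, max_mismatch = 1)), 0L)
})

test_that("amplicon intron content reports contained and blocking introns", {
  intron <- rand_dna_str(700, seed = 77)
  host <- plant_intron(781, intron)
  calls <- detect_insertions(host, ref, host_id = "amp")
  fwd <- data.frame(name = "f", ref_start = 700L, ref_end = 719L,
                    mismatches = 0L)
  rev <- data.frame(name = "r", ref_start = 881L, ref_end = 900L,
                    mismatches = 0L)
  rep1 <- amplicon_intron_content(fwd, rev, calls)
  expect_false(rep1$no_amplification)
  expect_equal(nrow(rep1$introns), 1L)
  expect_equal(rep1$exon_length, 201L)
  expect_equal(rep1$inflated_length, 201L + 700L)
  # primer pair flanking no occupied locus
  fwd2 <- data.frame(name = "f2", ref_start = 10L, ref_end = 29L,
                     mismatches = 0L)
  rev2 <- data.frame(name = "r2", ref_start = 301L, ref_end = 320L,
                     mismatches = 0L)
  rep2 <- amplicon_intron_content(fwd2, rev2, calls)
  expect_equal(nrow(rep2$introns), 0L)
  expect_equal(rep2$inflated_length, rep2$exon_length)
  # a footprint covering the occupied locus blocks amplification
  fwd3 <- data.frame(name = "f3", ref_start = 770L, ref_end = 789L,
                     mismatches = 0L)
  rep3 <- amplicon_intron_content(fwd3, rev, calls)
  expect_true(rep3$no_amplification)
  expect_error(amplicon_intron_content(rev, fwd, calls), "5'")
})

test_that("demo primers parse, validate and match the packaged reference", {
  p <- read_primers(system.file("extdata", "demo_primers.tsv",
                                package = "archintron"))
  expect_equal(nrow(p), 6L)
  fps <- do.call(rbind, lapply(seq_len(nrow(p)), function(k)
    best_footprint(match_primer(p$sequence[k], p$orientation[k], ref,
                                name = p$name[k]))))
  expect_equal(nrow(fps), 6L)
  expect_true(all(fps$mismatches == 0L))
  rec <- audit_primer_set(fps)
  expect_equal(sum(rec$interrupted), 4L)
  expect_equal(rec$loci_spanned[rec$name == "synAb909R"], "901;908")
})
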