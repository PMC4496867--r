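# ORF finding, motif scanning, folding, BHB detection, category decisions.

make_orf <- function(n_aa, seed = 1) {
  set.seed(seed)
  aa <- c("M", sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M"),
                      n_aa - 1, replace = TRUE))
  codons <- vapply(aa, function(a) {
    cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cods[1]
  }, character(1))
  paste(c(codons, "TAA"), collapse = "")
}

test_that("find_orfs recovers a constructed ORF on either strand", {
  orf <- make_orf(160, seed = 3)
  seq <- paste0(rand_dna_str(40, seed = 4), "TAATAG", orf, "TAGTAA",
                rand_dna_str(40, seed = 5))
  hits <- find_orfs(seq, min_aa = 150)
  plus <- hits[hits$strand == "+", ]
  expect_gte(nrow(plus), 1L)
  expect_equal(plus$length_aa[1], 160L)
  expect_equal(substr(seq, plus$start[1], plus$start[1] + 2), "ATG")
  # reverse complement: same ORF on the minus strand, same forward span
  rc <- archintron:::revcomp(seq)
  rhits <- find_orfs(rc, min_aa = 150)
  minus <- rhits[rhits$strand == "-", ]
  expect_gte(nrow(minus), 1L)
  expect_equal(minus$length_aa[1], 160L)
  expect_equal(minus$peptide[1], plus$peptide[1])
})

test_that("stop-saturated sequence has no ORFs", {
  expect_equal(nrow(find_orfs(strrep("TAA", 60), min_aa = 50)), 0L)
})

test_that("find_orfs validates input", {
  expect_error(find_orfs("ACGTX"), "intron sequence")
  expect_error(find_orfs(rand_dna_str(100, 1), min_aa = 5), "min_aa")
})

test_that("LAGLI-DADG scan counts copies and assigns the enzyme form", {
  set.seed(8)
  bg <- paste(sample(c("P", "Q", "E", "K", "R", "H", "N"), 300, TRUE),
              collapse = "")   # alphabet disjoint from the motif classes
  one <- paste0(substr(bg, 1, 100), "LAGLIDADG", substr(bg, 110, 300))
  two <- paste0(substr(bg, 1, 50), "LAGLIDADG", substr(bg, 60, 200),
                "LAGLIDADG", substr(bg, 210, 300))
  expect_equal(scan_laglidadg(bg)$count, 0L)
  expect_equal(scan_laglidadg(bg)$form, "none")
  s1 <- scan_laglidadg(one)
  expect_equal(s1$count, 1L)
  expect_equal(s1$form, "homodimer")
  s2 <- scan_laglidadg(two)
  expect_equal(s2$count, 2L)
  expect_equal(s2$form, "monomer")
  expect_gte(s2$positions$start_aa[2] - s2$positions$start_aa[1], 80L)
  # one tolerated mismatch still matches
  expect_equal(scan_laglidadg(paste0(substr(bg, 1, 100), "LAGLIDKDG",
                                     substr(bg, 110, 300)))$count, 1L)
})

test_that("nussinov_fold matches the stated examples", {
  expect_equal(nussinov_fold("GCGAAACGC")$pairs, oracle_max_pairs("GCGAAACGC"))
  expect_equal(nussinov_fold("GCGAAACGC")$pairs, 3L)
  expect_equal(nussinov_fold("AAAAA")$pairs, 0L)
  expect_equal(nussinov_fold("GCGAAACGC")$structure, "(((...)))")
})

test_that("nussinov_fold equals the exhaustive oracle for short sequences", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    s <- rand_dna_str(n)
    expect_equal(nussinov_fold(s)$pairs, oracle_max_pairs(s), info = s)
  }
  # structures are well-nested and consistent with the pair count
  s <- rand_dna_str(12, seed = 17)
  f <- nussinov_fold(s)
  expect_equal(sum(strsplit(f$structure, "")[[1]] == "("), f$pairs)
})

test_that("planted BHB junctions are detected; shuffled ones are not", {
  gi <- generate_intron("REMNANT", 781, seed = 31)
  host <- plant_intron(781, gi$sequence)
  call <- detect_insertions(host, host_id = "h")[1, ]
  bhb <- detect_bhb(call)
  expect_s3_class(bhb, "BHBMotif")
  expect_gte(bhb$helix_len, 4L)
  expect_gte(bhb$bulge5_len, 2L)
  expect_gte(bhb$bulge3_len, 2L)
  # shuffle the junction-proximal 12 nt at both intron ends (seeded)
  set.seed(5)
  shuf <- function(x) paste(sample(strsplit(x, "")[[1]]), collapse = "")
  seqv <- call$sequence
  broken <- paste0(shuf(substr(seqv, 1, 12)),
                   substr(seqv, 13, nchar(seqv) - 12),
                   shuf(substr(seqv, nchar(seqv) - 11, nchar(seqv))))
  call2 <- call
  call2$sequence <- broken
  expect_null(detect_bhb(call2))
  # truncated calls are rejected (routed to PRU)
  call3 <- call
  call3$truncated <- TRUE
  expect_error(detect_bhb(call3), "truncated")
})

test_that("detect_bhb is invariant to exon flank extension beyond the window", {
  gi <- generate_intron("HP", 901, seed = 32)
  host <- plant_intron(901, gi$sequence)
  call <- detect_insertions(host, host_id = "h")[1, ]
  b1 <- detect_bhb(call, window = 12)
  call2 <- call
  call2$upstream_flank <- substr(ref_16S()$sequence, 901 - 29, 901)
  b2 <- detect_bhb(call2, window = 12)
  expect_identical(b1$helix_len, b2$helix_len)
  expect_identical(b1$score, b2$score)
})

test_that("classification follows the decision order on constructed calls", {
  ref <- ref_16S()
  # HE: 700-nt class intron with a two-motif ORF
  he <- generate_intron("HE2", 1213, seed = 41)
  host <- plant_intron(1213, he$sequence)
  call <- detect_insertions(host, host_id = "h1")[1, ]
  cl <- classify_intron(call)
  expect_equal(cl$category, "HE")
  expect_equal(cl$motif_count, 2L)
  expect_equal(cl$motif_form, "monomer")
  expect_false(is.null(cl$orf))
  # HP: short hairpin with BHB
  hp <- generate_intron("HP", 901, seed = 42)
  expect_lt(nchar(hp$sequence), 50)
  host <- plant_intron(901, hp$sequence)
  call <- detect_insertions(host, host_id = "h2")[1, ]
  cl <- classify_intron(call)
  expect_equal(cl$category, "HP")
  expect_gte(cl$hairpin$paired_fraction, 0.5)
  # REMNANT: mid-size, ORF-free, intact junctions
  rem <- generate_intron("REMNANT", 781, seed = 43)
  host <- plant_intron(781, rem$sequence)
  call <- detect_insertions(host, host_id = "h3")[1, ]
  cl <- classify_intron(call)
  expect_equal(cl$category, "REMNANT")
  # PRU: truncated
  call$truncated <- TRUE
  expect_equal(classify_intron(call)$category, "PRU")
  expect_true(is.finite(cl$gc))
})

test_that("gc_summary matches hand computations and generator targets", {
  expect_equal(gc_summary("GGCC")[c("mean", "sd")], list(mean = 100, sd = 0))
  expect_equal(gc_summary("ATAT")[c("mean", "sd")], list(mean = 0, sd = 0))
  expect_error(gc_summary(character(0)), "empty")
  # ambiguity codes excluded from both numerator and denominator
  expect_equal(gc_summary("GCNNAT")$mean, 50)
  kinds <- rep(c("HE1", "HE2", "REMNANT", "HP"), each = 50)
  gcs <- vapply(seq_along(kinds), function(i)
    gc_fraction <- gc_summary(generate_intron(kinds[i], 781,
                                              seed = 7000 + i)$sequence)$mean,
    numeric(1))
  expect_lt(abs(mean(gcs) - 57), 2)
})
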