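ref <- ref_16S()

test_that("an intron-free gene yields no calls", {
  calls <- detect_insertions(ref$sequence, ref, host_id = "clean")
  expect_s3_class(calls, "intron_calls")
  expect_equal(nrow(calls), 0L)
})

test_that("a planted 700-nt insertion is called at its locus", {
  intron <- rand_dna_str(700, seed = 7)
  q <- plant_intron(781, intron)
  calls <- detect_insertions(q, ref, host_id = "g1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$locus, 781L)
  expect_true(calls$canonical)
  expect_equal(calls$length, 700L)
  expect_false(calls$truncated)
  expect_equal(calls$sequence, intron)
  expect_equal(nchar(calls$upstream_flank), 15L)
  expect_equal(calls$downstream_flank,
               substr(ref$sequence, 782, 796))
})

test_that("tandem insertions at 901 and 908 are both recovered", {
  i1 <- rand_dna_str(120, seed = 1)
  i2 <- rand_dna_str(150, seed = 2)
  q <- plant_intron(908, i2)
  q <- paste0(substr(q, 1, 901), i1, substr(q, 902, nchar(q)))
  calls <- detect_insertions(q, ref, host_id = "g2")
  expect_equal(calls$locus, c(901L, 908L))
  expect_equal(diff(calls$locus), 7L)
})

test_that("no call shorter than min_insert is emitted", {
  q <- plant_intron(548, rand_dna_str(11, seed = 3))
  calls <- detect_insertions(q, ref, min_insert = 12L)
  expect_equal(nrow(calls), 0L)
  calls <- detect_insertions(q, ref, min_insert = 8L)
  # short inserts may be absorbed or called; if called, never below floor
  expect_true(all(calls$length >= 8L))
})

test_that("snapping tolerates jitter and flags novel loci", {
  expect_equal(snap_to_canonical(780)$position, 781L)
  expect_true(snap_to_canonical(780)$canonical)
  expect_equal(snap_to_canonical(781), list(position = 781L, canonical = TRUE))
  s <- snap_to_canonical(600)
  expect_equal(s$position, 600L)
  expect_false(s$canonical)
  expect_error(snap_to_canonical(904, tolerance = 4), "ambiguous")
})

test_that("excision round-trips the generator exactly and conserves GC", {
  cfg <- generator_config(seed = 21, n_hosts = 2, loci_plan = data.frame(
    locus = c(374, 781, 1093), kind = c("HE1", "REMNANT", "HP")))
  ds <- generate_dataset(cfg)
  for (h in names(ds$hosts)) {
    calls <- detect_insertions(ds$hosts[[h]], ref, host_id = h)
    restored <- excise_and_ligate(ds$hosts[[h]], calls)
    expect_identical(restored, ds$source_exons[[h]])
    expect_identical(gc_summary(restored)$mean,
                     gc_summary(ds$source_exons[[h]])$mean)
  }
})

test_that("excision handles edge cases", {
  q <- plant_intron(781, rand_dna_str(50, seed = 9))
  expect_identical(excise_and_ligate(q, detect_insertions(q, ref)[0, ]), q)
  calls <- detect_insertions(q, ref)
  bad <- rbind(calls, calls)
  expect_error(excise_and_ligate(q, bad), "overlap")
})

test_that("detected loci are stable when another intron is added", {
  i1 <- rand_dna_str(200, seed = 5)
  q1 <- plant_intron(781, i1)
  c1 <- detect_insertions(q1, ref)
  i2 <- rand_dna_str(300, seed = 6)
  q2 <- paste0(substr(q1, 1, 1391 + 200), i2,
               substr(q1, 1392 + 200, nchar(q1)))
  c2 <- detect_insertions(q2, ref)
  expect_equal(c2$locus, c(781L, 1391L))
  expect_equal(c2$locus[1], c1$locus)
  # excising only the first intron leaves the second detectable
  part <- excise_and_ligate(q2, c2[1, , drop = FALSE])
  c3 <- detect_insertions(part, ref)
  expect_equal(c3$locus, 1391L)
})

test_that("a fragment ending inside an intron yields a truncated call", {
  intron <- rand_dna_str(400, seed = 10)
  frag <- paste0(substr(ref$sequence, 1, 919), substr(intron, 1, 180))
  calls <- detect_insertions(frag, ref, host_id = "frag")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$locus, 919L)
  expect_true(calls$truncated)
  expect_equal(calls$downstream_flank, "")
})

test_that("GFF3 and TSV exports carry the calls", {
  q <- plant_intron(781, rand_dna_str(60, seed = 12))
  calls <- detect_insertions(q, ref, host_id = "gX")
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_calls_gff3(calls, gff)
  write_calls_tsv(calls, tsv)
  write_intron_fasta(calls, fa)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  expect_match(lines[2], "\tintron\t782\t841\t.*locus=781")
  expect_equal(read.delim(tsv)$locus, 781L)
  expect_match(readLines(fa)[1], "^>gX\\|locus781$")
})

test_that("round-trip recovery across a seeded batch is essentially exact", {
  hit <- 0L; tot <- 0L
  for (s in 1:5) {
    cfg <- generator_config(seed = 100 + s, n_hosts = 2,
      loci_plan = data.frame(locus = c(548, 908, 1213, 1391),
                             kind = c("REMNANT", "HE1", "HE2", "HP")))
    ds <- generate_dataset(cfg)
    for (h in names(ds$hosts)) {
      want <- sort(ds$truth$locus[ds$truth$host_id == h])
      got <- sort(detect_insertions(ds$hosts[[h]], ref, host_id = h)$locus)
      tot <- tot + length(want)
      hit <- hit + sum(want %in% got)
    }
  }
  expect_gte(hit / tot, 0.99)
})
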