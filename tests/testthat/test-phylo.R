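# Distances, neighbor joining, bootstrap, MSA, junction profiles.

test_that("pairwise distances match closed forms", {
  aln <- c(a = strrep("A", 100), b = strrep("A", 100))
  expect_equal(unname(pairwise_distances(aln, "p")["a", "b"]), 0)
  # 1 difference in 100 columns
  bv <- paste0(strrep("A", 99), "C")
  aln <- c(a = strrep("A", 100), b = bv)
  expect_equal(unname(pairwise_distances(aln, "p")["a", "b"]), 0.01)
  expect_equal(unname(pairwise_distances(aln, "JC")["a", "b"]),
               -0.75 * log(1 - 0.04 / 3))
  # pairwise deletion: 10 gapped columns, 9 diffs among the remaining 90
  a <- paste0(strrep("-", 10), strrep("A", 90))
  b <- paste0(strrep("C", 10), strrep("C", 9), strrep("A", 81))
  expect_equal(unname(pairwise_distances(c(x = a, y = b), "p")["x", "y"]),
               0.1)
})

test_that("JC distances saturate at the documented cap", {
  aln <- c(a = strrep("ACGT", 25), b = strrep("CATG", 25))  # p = 1
  D <- pairwise_distances(aln, "JC")
  expect_equal(unname(D["a", "b"]), 5.0)
  expect_true(attr(D, "saturated")["a", "b"])
  # JC >= p everywhere below saturation
  for (p in seq(0.01, 0.7, by = 0.07)) {
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_gte(jc, p)
  }
})

test_that("distance computation rejects incomparable pairs", {
  aln <- c(a = "AC--", b = "--GT")
  expect_error(pairwise_distances(aln, "p"), "no comparable")
  expect_error(pairwise_distances(c(a = "ACGT", b = "ACG"), "p"),
               "not aligned")
})

test_that("nj_tree is exact on the worked additive 4-taxon case", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 8; D["A", "D"] <- 9
  D["B", "C"] <- 9; D["B", "D"] <- 10; D["C", "D"] <- 7
  D <- D + t(D)
  expect_true(oracle_is_additive(D))
  tr <- nj_tree(D)
  # topology ((A,B),(C,D)) and exact path lengths
  expect_true(setequal(oracle_bipartitions(tr), "C;D"))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D, tolerance = 1e-12)
  # leaf branch lengths A:1 B:2 C:3 D:4
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(bl[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("nj_tree handles 2- and 3-taxon inputs", {
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(D2)
  expect_equal(sum(t2$edge.length), 4)
  D3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D3["a", "b"] <- 2; D3["a", "c"] <- 3; D3["b", "c"] <- 5
  D3 <- D3 + t(D3)
  t3 <- nj_tree(D3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(D3), ], D3, tolerance = 1e-12)
})

test_that("nj_tree validates its input", {
  D <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "symmetric")
  D2 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D2), "non-negative")
})

test_that("equidistant taxa are joined by the lexicographic tie-break", {
  labs <- c("delta", "alpha", "charlie", "bravo")
  D <- matrix(2, 4, 4, dimnames = list(labs, labs))
  diag(D) <- 0
  tr <- nj_tree(D)
  # alpha and bravo joined first -> they form a cherry
  expect_true("alpha;bravo" %in% oracle_bipartitions(tr) ||
              "charlie;delta" %in% oracle_bipartitions(tr))
})

test_that("NJ recovers random additive trees exactly (property)", {
  for (s in 1:15) {
    n <- sample(4:8, 1)
    case <- oracle_additive_case(n, seed = 1000 + s)
    expect_true(oracle_is_additive(case$D))
    tr <- nj_tree(case$D)
    expect_true(same_topology(tr, case$tree), info = paste("seed", s))
    got <- ape::cophenetic.phylo(tr)[rownames(case$D), colnames(case$D)]
    expect_equal(got, case$D, tolerance = 1e-9, info = paste("seed", s))
  }
})

test_that("bootstrap gives full support to an unambiguous split", {
  aln <- c(a1 = strrep("A", 40), a2 = strrep("A", 40),
           b1 = strrep("C", 40), b2 = strrep("C", 40))
  # perturb one sequence per group minimally so distances are defined
  substr(aln["a2"], 1, 1) <- "G"
  substr(aln["b2"], 1, 1) <- "T"
  bs <- bootstrap_support(aln, n_reps = 100, seed = 3, model = "p")
  expect_equal(unname(bs$supports["b1;b2"]), 100)
})

test_that("bootstrap supports are reproducible and order-invariant", {
  cfg <- generator_config(seed = 61, n_hosts = 6,
    loci_plan = data.frame(locus = 1093, kind = "REMNANT"),
    group_divergence = 0.08)
  ds <- generate_dataset(cfg)
  aln <- align_msa(ds$introns)
  b1 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  b2 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  expect_identical(b1$supports, b2$supports)
  perm <- sample(seq_along(aln))
  b3 <- bootstrap_support(aln[perm], n_reps = 50, seed = 9)
  expect_setequal(names(b3$supports), names(b1$supports))
})

test_that("center-star MSA handles indels and degenerates gracefully", {
  seqs <- c(s1 = "ACGTACGTACGT", s2 = "ACGTACGGTACGT", s3 = "ACGTACGTACG")
  aln <- align_msa(seqs)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_equal(gsub("-", "", aln), seqs)
  # identical-length, high-identity input returns columnwise alignment
  seqs2 <- c(a = "ACGTACGT", b = "ACGAACGT")
  expect_equal(align_msa(seqs2), seqs2)
})

test_that("junction consensus separates conserved cores from interiors", {
  cfg <- generator_config(seed = 71, n_hosts = 8,
    loci_plan = data.frame(locus = 781, kind = "REMNANT"),
    group_divergence = 0.10, indiv_divergence = 0.05)
  ds <- generate_dataset(cfg)
  calls <- do.call(rbind, lapply(names(ds$hosts), function(h)
    detect_insertions(ds$hosts[[h]], host_id = h)))
  prof <- junction_consensus(calls, junction_window = 12)
  expect_s3_class(prof, "LocusProfile")
  expect_true(all(colSums(prof$pfm) == nrow(calls)))
  expect_true(all(prof$ic >= 0 & prof$ic <= 2 + 1e-12))
  # conserved 9-nt cores at each end flank mutable interior columns
  core_cols <- c(1:9, 16:24)
  interior_cols <- c(10:15)
  expect_gt(mean(prof$ic[core_cols]), mean(prof$ic[interior_cols]))
  # identical members give 2 bits everywhere
  same <- calls[rep(1, 3), ]
  expect_equal(unname(junction_consensus(same)$ic), rep(2, 24))
  expect_error(junction_consensus(calls[1, ]), ">= 2 members")
})

test_that("uniformly random columns carry almost no information", {
  set.seed(88)
  fake <- data.frame(
    host_id = sprintf("m%03d", 1:200), locus = 781L, canonical = TRUE,
    host_start = 1L, host_end = 40L, length = 40L, truncated = FALSE,
    sequence = replicate(200, rand_dna_str(40)),
    upstream_flank = "A", downstream_flank = "A")
  prof <- junction_consensus(fake, junction_window = 10)
  expect_lt(mean(prof$ic), 0.1)
})

test_that("per-locus grouping partitions calls", {
  cfg <- generator_config(seed = 81, n_hosts = 2, loci_plan = data.frame(
    locus = c(374, 781, 1391), kind = "REMNANT"))
  ds <- generate_dataset(cfg)
  calls <- do.call(rbind, lapply(names(ds$hosts), function(h)
    detect_insertions(ds$hosts[[h]], host_id = h)))
  profs <- locus_profiles(calls)
  expect_equal(sum(vapply(profs, nrow, integer(1))), nrow(calls))
  expect_setequal(names(profs), c("374", "781", "1391"))
})

test_that("geography-structured introns form monophyletic groups", {
  cfg <- generator_config(seed = 91, n_hosts = 10,
    loci_plan = data.frame(locus = 1213, kind = "HE2"),
    geography = c("YNP", "Japan"), group_divergence = 0.10,
    indiv_divergence = 0.01)
  ds <- generate_dataset(cfg)
  aln <- align_msa(ds$introns)
  tr <- nj_tree(pairwise_distances(aln, "JC"))
  groups <- split(sprintf("%s|locus1213", ds$truth$host_id),
                  ds$truth$geography)
  bips <- oracle_bipartitions(tr)
  split_key <- vapply(groups, function(g) paste(sort(g), collapse = ";"),
                      character(1))
  expect_true(any(split_key %in% bips))
})

test_that("cross-locus sets are refused for phylogenetic comparison", {
  a <- generate_intron("REMNANT", 374, seed = 101)$sequence
  b <- generate_intron("REMNANT", 1391, seed = 102)$sequence
  c_ <- generate_intron("REMNANT", 722, seed = 103)$sequence
  aln <- align_msa(c(x = a, y = b, z = c_))
  expect_lt(mean_pairwise_identity(aln), 0.5)
})
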