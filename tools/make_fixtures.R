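# Regenerates the plain-text fixtures under inst/extdata/.
# Run from the package root: Rscript tools/make_fixtures.R
# The packaged reference is a SYNTHETIC stand-in for the E. coli rrnB 16S
# gene (see fixture headers): same length (1542 nt) so that the standard
# position numbering convention applies, but with Thermoproteales-like GC
# (~67 %) so simulated hosts match the GC regime of the organisms modelled.

set.seed(165420)

n_ref <- 1542L
gc <- 0.67
bases <- sample(c("A", "C", "G", "T"), n_ref, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
ref <- paste(bases, collapse = "")

writeLines(c(
  paste0(">ref16S_synthetic length=1542 gc=0.67 ",
         "synthetic stand-in for the E. coli rrnB 16S gene; positions are ",
         "used as the standard 16S numbering frame; seed=165420"),
  substring(ref, seq(1, n_ref, 60), pmin(seq(1, n_ref, 60) + 59, n_ref))
), "inst/extdata/ref16S_synthetic.fasta")

# V-region intervals on the standard E. coli 16S frame (1-based, inclusive).
# Widely used interval convention for hypervariable regions V1-V9.
v <- data.frame(
  name  = paste0("V", 1:9),
  start = c(69, 137, 433, 576, 822, 986, 1117, 1243, 1435),
  end   = c(99, 242, 497, 682, 879, 1043, 1173, 1294, 1465),
  source = "E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)"
)
con <- file("inst/extdata/v_regions.tsv", "w")
writeLines(c(
  "# Hypervariable regions V1-V9 of the 16S rRNA gene, standard E. coli",
  "# numbering, 1-based inclusive intervals. Interval set follows the",
  "# commonly used amplicon-design convention on the rrnB frame.",
  "name\tstart\tend\tsource"), con)
write.table(v, con, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
close(con)

# Curated per-locus intron inventory for archaeal 16S genes (13 canonical
# loci). cds = homing-endonuclease coding introns, with the split by
# LAGLI-DADG motif copy number (one / two); hp = short (<50 nt)
# hairpin-forming introns; pru = partial/remnant/uncharacterized.
# Cells whose published layout is typographically ambiguous are flagged in
# the note column; tests avoid flagged cells.
t1 <- data.frame(
  locus = c(374, 548, 722, 781, 803, 901, 908, 919, 978, 1093, 1205, 1213, 1391),
  taxa = c(
    "Pyrobaculum;Caldivirga",
    "Pyrobaculum;Thermoproteus;Staphylothermus;Desulfurococcales",
    "Caldiarchaeum",
    "Pyrobaculum;Thermoproteus;Vulcanisaeta;Thermoproteales;Caldivirga;Caldiarchaeum",
    "Desulfurococcales",
    "Pyrobaculum;Caldivirga;Desulfurococcales",
    "Pyrobaculum;Caldivirga;Aeropyrum;Caldiarchaeum",
    "Pyrobaculum;Thermoproteus;Caldivirga;Vulcanisaeta;Caldiarchaeum;Desulfurococcales",
    "Caldiarchaeum",
    "Pyrobaculum;Thermoproteus;Desulfurococcales",
    "Pyrobaculum;Thermoproteus;Desulfurococcales",
    "Pyrobaculum;Thermoproteus",
    "Pyrobaculum;Thermoproteus;Vulcanisaeta"),
  n_cds   = c(5, 2, 0, 14, 0, 0, 4, 6, 0, 15, 2, 18, 15),
  cds_m1  = c(5, 0, 0, 2, 0, 0, 1, 2, 0, 4, 0, 4, 7),
  cds_m2  = c(0, 2, 0, 4, 0, 0, 3, 3, 0, 11, 2, 14, 2),
  n_hp    = c(1, 13, 0, 0, 0, 8, 0, 2, 9, 7, 17, 0, 0),
  n_pru   = c(0, 0, 2, 28, 3, 0, 6, 7, 0, 9, 0, 2, 5),
  primers = c("Kb366F", "", "", "Ab779F", "Ab789F;Arc806R", "Ab909R",
              "Ab909R;Ab906F;926wF;U926R;Ab927R",
              "Ab906F;926wF;U926R;Ab927R;A934R",
              "", "", "", "", "UA1406R;N1406R;U1406R"),
  note = c("", "", "", "cds+pru totals 42 vs printed per-locus max 41; transcribed as-is",
           "", "", "", "hp/pru split ambiguous in published layout",
           "", "hp/pru split ambiguous in published layout",
           "cds entry conflicts with text stating locus is hairpin-only", "", "")
)
con <- file("inst/extdata/table1_loci.tsv", "w")
writeLines(c(
  "# Curated inventory of intron insertion loci in archaeal 16S rRNA genes.",
  "# locus: standard E. coli-numbered position directly before the insertion.",
  "# n_cds: homing-endonuclease CDS introns (cds_m1/cds_m2 = with one/two",
  "# LAGLI-DADG motif copies); n_hp: short (<50 nt) hairpin introns;",
  "# n_pru: partial/remnant/uncharacterized. primers: 'universal' archaeal",
  "# primers whose annealing site spans the locus (semicolon-separated).",
  "locus\ttaxa\tn_cds\tcds_m1\tcds_m2\tn_hp\tn_pru\tprimers\tnote"), con)
write.table(t1, con, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
close(con)

# Demo primer list. SYNTHETIC: sequences are drawn from the packaged
# synthetic reference (exact or lightly degenerate) so that end-to-end demo
# runs produce clean footprints. Real primer catalogs are user input.
sub <- function(s, e) substr(ref, s, e)
rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
# degenerate codes chosen to contain the underlying reference base
degcode <- function(base) switch(base, A = "R", G = "R", C = "Y", T = "Y")
degenerize <- function(x, pos) {
  for (p in pos) substr(x, p, p) <- degcode(substr(x, p, p))
  x
}
primers <- data.frame(
  name = c("synA008F", "synKb366F", "syn515Fdeg", "synAb779F", "synAb909R", "synU1406R"),
  sequence = c(
    sub(8, 27),
    sub(357, 376),
    degenerize(sub(506, 525), c(10, 15)),
    sub(770, 789),
    rc(sub(900, 919)),
    rc(sub(1385, 1404))),
  orientation = c("F", "F", "F", "F", "R", "R")
)
stopifnot(nchar(primers$sequence) == 20)
con <- file("inst/extdata/demo_primers.tsv", "w")
writeLines(c(
  "# Demo primer list (SYNTHETIC): sequences drawn from the packaged",
  "# synthetic reference; orientation R primers are given 5'->3' on the",
  "# reverse strand, as in standard primer catalogs.",
  "name\tsequence\torientation"), con)
write.table(primers, con, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
close(con)

cat("fixtures written\n")
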