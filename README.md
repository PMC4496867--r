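# archintron

Detection, classification and primer auditing of archaeal 16S rRNA gene
introns.

## The problem

Several thermophilic archaeal lineages — above all the order
Thermoproteales (Crenarchaeota) — carry mobile intron sequences inside
their 16S rRNA genes. These introns are excised post-transcriptionally by
the tRNA splicing endoribonuclease, which recognizes a bulge-helix-bulge
(BHB) RNA motif formed at the intron-exon junctions, and many of them
encode homing endonucleases bearing one or two LAGLI-DADG motifs that
drive their own propagation. Curated insertions are confined to 13 loci on
the standard E. coli-numbered 16S coordinate frame
(374, 548, 722, 781, 803, 901, 908, 919, 978, 1093, 1205, 1213, 1391),
all outside the hypervariable regions V1–V9. Because these loci sit in the
most conserved parts of the gene — exactly where "universal" archaeal
primers anneal — intron-bearing organisms are prone to being missed or
misread by standard amplicon surveys.

`archintron` re-implements this analysis as a tested, reusable pipeline
for anyone who works with (hyper)thermophile 16S data:

* **Detection** — semi-global alignment of a gene against a packaged
  intron-free reference frame; each maximal run of inserted positions
  ≥ 12 nt becomes an intron call with a locus (the reference position
  directly before the insertion point, per the field convention), with
  dedicated recovery of the closely spaced tandem clusters 901/908/919 and
  1205/1213.
* **Classification** — each call is assigned one of four categories in
  fixed order: `PRU` (partial/truncated), `HE` (an ORF ≥ 50 aa carrying at
  least one LAGLI-DADG motif; one copy = homodimeric enzyme, two copies =
  monomeric), `HP` (< 50 nt, paired fraction ≥ 0.5 under base-pair
  maximization, BHB motif present), `REMNANT` (intact junctions, no
  qualifying ORF), else `PRU`.
* **Primer audit** — IUPAC-aware matching of degenerate primers on the
  reference; a footprint `[s, e]` is interrupted by locus `L` iff
  `s ≤ L < e`; amplicon reports predict contained or blocking introns for
  primer pairs.
* **Phylogenetics** — per-locus center-star alignment, p/Jukes-Cantor
  distances, Saitou–Nei neighbor joining (exact on additive matrices),
  bootstrap supports by column resampling, and junction-conservation
  profiles (position frequency matrix + information content in bits).
* **Synthetic data** — a fully seeded generator plants introns of every
  category (with BHB junction cores, LAGLIDADG-bearing ORFs, GC steered to
  57 % against 67 % GC hosts, geography-correlated divergence) so every
  stage is testable against ground truth with no downloads.

## Worked example

```r
library(archintron)

cfg <- generator_config(seed = 7, n_hosts = 3,
  loci_plan = data.frame(locus = c(374, 781, 901, 908, 1213),
                         kind  = c("HE1", "HE2", "HP", "REMNANT", "HE2")))
ds <- generate_dataset(cfg)

calls <- do.call(rbind, lapply(names(ds$hosts), function(h)
  detect_insertions(ds$hosts[[h]], host_id = h)))
classify_introns(calls)[1:5, c("host_id", "locus", "length", "category",
                               "motif_count", "gc")]
#>   host_id locus length category motif_count    gc
#> 1  host01   374    677       HE           1 0.575
#> 2  host01   781    860       HE           2 0.564
#> 3  host01   901     36       HP           0 0.611
#> 4  host01   908    280  REMNANT           0 0.607
#> 5  host01  1213    817       HE           2 0.576
```

Every planted intron is recovered at its locus and category: the two-motif
ORFs classify as monomeric homing endonucleases, the 36-nt hairpin as
`HP`, the ORF-free 280-nt insert as `REMNANT`. Intron GC lands at the
generator's 57 % target (`gc_summary(calls$sequence)` gives
58.6 ± 1.9 %, versus ~67 % for the host genes).

```r
find_tandem_loci(sort(unique(calls$locus)))
#>   locus_a locus_b separation
#> 1     901     908          7
```

The 901/908 pair is separated by seven exon nucleotides — the geometry
that lets homing at one locus co-convert its downstream neighbour.

```r
p <- read_primers(system.file("extdata", "demo_primers.tsv",
                              package = "archintron"))
fps <- do.call(rbind, lapply(seq_len(nrow(p)), function(k)
  best_footprint(match_primer(p$sequence[k], p$orientation[k],
                              name = p$name[k]))))
audit_primer_set(fps)
#>         name loci_spanned n_loci interrupted
#> 1 syn515Fdeg                   0       FALSE
#> 2   synA008F                   0       FALSE
#> 3  synAb779F          781      1        TRUE
#> 4  synAb909R      901;908      2        TRUE
#> 5  synKb366F          374      1        TRUE
#> 6  synU1406R         1391      1        TRUE
```

The demo reverse primer annealing at 900–919 is interrupted by both tandem
loci at once, mirroring the behaviour of the published Ab909R. The curated
inventory itself is available as `curated_locus_table()` /
`curated_primer_map()` (13 primers, 5 of them spanning two loci).

```r
prof <- calls[calls$locus == 1213, ]
aln  <- align_msa(setNames(prof$sequence, prof$host_id))
bs   <- bootstrap_support(aln, n_reps = 100, seed = 1)
ape::write.tree(bs$tree)
#> (host01:0.01628655246,host02:0.00986802805,host03:0.02265061271);
```

`run_pipeline()` composes all stages and writes GFF3/TSV/FASTA/Newick
outputs plus a JSON report; the same stages are scriptable through the
CLI wrapper (`inst/cli/archintron.R`) with subcommands `simulate`,
`detect`, `classify`, `primers`, `phylo` and `run-all`.

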