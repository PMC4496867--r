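# Synthetic data with full ground truth: Thermoproteales-like 16S hosts
# (reference-derived, substitutions only, so locus truth is exact) carrying
# planted introns of every category, with BHB junction cores, LAGLI-DADG
# bearing ORFs, GC steering, and geography-correlated divergence.

INTRON_KINDS <- c("HE1", "HE2", "HP", "REMNANT", "TRUNCATED")
CORE5_NT <- 9L   # 3 nt bulge + 6 bp helix strand at the 5' end
CORE3_NT <- 9L   # 6 bp helix strand + 3 nt bulge at the 3' end
STOP_KILLER <- "CTAGCTAGCTAG"  # stop codons in all six frames; no start codons

#' Generator configuration
#'
#' The defaults encode the sequence world the generator emulates: hosts
#' derived from the packaged reference at 5 % divergence (substitutions
#' only), introns with a GC target of 57 % against 67 % GC hosts,
#' homing-endonuclease introns of 650-900 nt (often > 700 nt), hairpin
#' introns below 50 nt, and remnants in between.
#'
#' @param seed master seed; all randomness derives from it.
#' @param n_hosts number of full-length host genes.
#' @param host_divergence expected substitutions/site from the reference.
#' @param loci_plan data.frame with columns `locus`, `kind`
#'   (one of `r paste(INTRON_KINDS, collapse = ", ")`). Default: one
#'   homing-endonuclease intron at every canonical locus.
#' @param intron_gc GC fraction target for intron sequences.
#' @param he_len,remnant_len,hp_len length ranges (nt) per intron kind.
#' @param geography group labels cycled over hosts.
#' @param group_divergence extra substitutions/site applied per geography
#'   group to intron interiors (junction cores are protected).
#' @param indiv_divergence per-member substitutions/site on intron
#'   interiors.
#' @return A validated config list (class `GeneratorConfig`).
#' @export
generator_config <- function(seed = 1L, n_hosts = 4L, host_divergence = 0.05,
                             loci_plan = data.frame(
                               locus = canonical_loci(), kind = "HE1"),
                             intron_gc = 0.57,
                             he_len = c(650L, 900L),
                             remnant_len = c(120L, 400L),
                             hp_len = c(30L, 48L),
                             geography = c("YNP", "Japan"),
                             group_divergence = 0,
                             indiv_divergence = 0.01) {
  stopifnot(n_hosts >= 1L, host_divergence >= 0, host_divergence <= 0.3,
            intron_gc > 0, intron_gc < 1,
            all(loci_plan$kind %in% INTRON_KINDS),
            hp_len[2L] < 50L, he_len[1L] >= 200L,
            group_divergence >= 0, indiv_divergence >= 0)
  dup <- duplicated(loci_plan$locus[loci_plan$kind != "TRUNCATED"])
  if (any(dup))
    stop("loci_plan has duplicate non-truncated loci", call. = FALSE)
  structure(list(seed = as.integer(seed), n_hosts = as.integer(n_hosts),
                 host_divergence = host_divergence, loci_plan = loci_plan,
                 intron_gc = intron_gc, he_len = he_len,
                 remnant_len = remnant_len, hp_len = hp_len,
                 geography = geography, group_divergence = group_divergence,
                 indiv_divergence = indiv_divergence),
            class = "GeneratorConfig")
}

# GC-steered random DNA
.rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a host 16S gene
#'
#' Seeded i.i.d. substitution of the packaged reference at the requested
#' expected rate; no indels, so host exon coordinates equal reference
#' coordinates and planted locus truth is exact.
#'
#' @param ref a [ref_16S()] `ReferenceModel`.
#' @param divergence expected substitutions/site in `[0, 0.3]`.
#' @param seed integer seed.
#' @return DNA string of length `ref$length`.
#' @export
generate_host <- function(ref = ref_16S(), divergence = 0.05, seed = 1L) {
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must be in [0, 0.3]", call. = FALSE)
  with_seed(seed, {
    v <- chars(ref$sequence)
    hit <- which(stats::runif(length(v)) < divergence)
    for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
    paste(v, collapse = "")
  })
}

# codon table: codons per amino acid with their GC counts
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- names(gc)
      tab <<- split(codons, gc)
    }
    tab
  }
})

# reverse-translate a peptide, greedily steering GC toward target
.reverse_translate <- function(peptide, gc_target) {
  tab <- .codon_table()
  aa <- chars(peptide)
  out <- character(length(aa))
  gc_n <- 0; tot <- 0
  for (i in seq_along(aa)) {
    cods <- tab[[aa[i]]]
    gcs <- vapply(cods, function(cd) sum(chars(cd) %in% c("G", "C")),
                  numeric(1))
    dev <- abs((gc_n + gcs) / (tot + 3) - gc_target)
    pick <- which(dev == min(dev))
    cd <- cods[sample(pick, 1L)]
    out[i] <- cd
    gc_n <- gc_n + gcs[[cd]]; tot <- tot + 3
  }
  paste(out, collapse = "")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
# composition bias toward residues with GC-rich codons (the Ala/Gly/Arg/Pro
# bias of thermophile proteomes); keeps the codon-level GC steering able to
# reach the intron GC target inside long ORFs
AA20_W <- c(3, 1, 1, 2, 1, 3, 1, 1, 1, 2, 1, 1, 2, 1, 3, 1, 1, 2, 1, 1)

# random interior guaranteed free of ORFs >= ~50 aa: random GC-steered
# segments of <= 100 nt interleaved with stop cassettes covering all six
# frames
.orf_free_interior <- function(n, gc) {
  if (n <= 0L) return("")
  out <- character(0)
  left <- n
  while (left > 0L) {
    seg <- min(left, 100L)
    out <- c(out, .rand_dna(seg, gc))
    left <- left - seg
    if (left > 0L) {
      k <- min(left, nchar(STOP_KILLER))
      out <- c(out, substr(STOP_KILLER, 1L, k))
      left <- left - k
    }
  }
  paste(out, collapse = "")
}

#' Generate one synthetic intron
#'
#' Every intron starts with a 3-nt bulge and a 6-bp GC helix strand and ends
#' with the reverse complement of that helix strand and another 3-nt bulge:
#' the two strands pair into the central helix of a bulge-helix-bulge
#' junction motif whose bulges contain the two excision sites.
#' Kind-specific interiors: `HE1`/`HE2` carry an ORF (ATG start, table-11
#' repertoire) with one or two literal LAGLIDADG motifs; `HP` introns are
#' < 50 nt with complementary arms folding into a hairpin; `REMNANT`
#' interiors are ORF-free by construction (stop cassettes in all six
#' frames); `TRUNCATED` introns are remnant-like and flagged so that
#' dataset assembly cuts the host inside them.
#'
#' @param kind one of `r paste(INTRON_KINDS, collapse = ", ")`.
#' @param locus insertion locus recorded in the truth record.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with `sequence` and `truth` (list: `locus`, `kind`,
#'   `length`, `motifs`, `orf_span` or `NULL`, `truncated`).
#' @export
generate_intron <- function(kind = "HE1", locus = 781L,
                            config = generator_config(), seed = 1L) {
  kind <- match.arg(kind, INTRON_KINDS)
  gc <- config$intron_gc
  with_seed(seed, {
    bulge5 <- paste(sample(c("A", "T"), 3L, replace = TRUE), collapse = "")
    helix1 <- paste(sample(c("G", "C"), 6L, replace = TRUE), collapse = "")
    helix2 <- revcomp(helix1)
    bulge3 <- paste(sample(c("A", "T"), 3L, replace = TRUE), collapse = "")
    truth <- list(locus = as.integer(locus), kind = kind, motifs = 0L,
                  orf_span = NULL, truncated = kind == "TRUNCATED")
    if (kind %in% c("HE1", "HE2")) {
      len <- sample(config$he_len[1L]:config$he_len[2L], 1L)
      n_motif <- if (kind == "HE2") 2L else 1L
      aa_len <- max(130L, (len - 80L) %/% 3L)
      aa_len <- min(aa_len, (len - 30L) %/% 3L - 2L)
      pep <- c("M", sample(AA20, aa_len - 1L, replace = TRUE,
                           prob = AA20_W))
      pep[16:24] <- chars("LAGLIDADG")
      if (n_motif == 2L) pep[106:114] <- chars("LAGLIDADG")
      pep <- paste(pep, collapse = "")
      orf <- paste0(.reverse_translate(pep, gc), "TAA")
      pad_total <- len - 18L - nchar(orf)
      pad1 <- pad_total %/% 2L
      pad2 <- pad_total - pad1
      seqs <- paste0(bulge5, helix1, .orf_free_interior(pad1, gc), orf,
                     .orf_free_interior(pad2, gc), helix2, bulge3)
      truth$motifs <- n_motif
      truth$orf_span <- c(9L + pad1 + 1L, 9L + pad1 + nchar(orf))
    } else if (kind == "HP") {
      len <- sample(config$hp_len[1L]:config$hp_len[2L], 1L)
      if ((len - 22L) %% 2L != 0L) len <- len - 1L
      arm_n <- (len - 22L) %/% 2L
      arm <- .rand_dna(arm_n, gc)
      loop <- paste(sample(c("A", "T"), 4L, replace = TRUE), collapse = "")
      seqs <- paste0(bulge5, helix1, arm, loop, revcomp(arm), helix2, bulge3)
    } else {  # REMNANT / TRUNCATED
      len <- sample(config$remnant_len[1L]:config$remnant_len[2L], 1L)
      seqs <- paste0(bulge5, helix1, .orf_free_interior(len - 18L, gc),
                     helix2, bulge3)
    }
    truth$length <- nchar(seqs)
    list(sequence = seqs, truth = truth)
  })
}

# substitute interior positions at the given rate; junction cores are
# protected and substitutions inside a forward ORF never create a stop
mutate_intron <- function(sequence, rate, orf_span = NULL, seed = 1L) {
  if (rate <= 0) return(sequence)
  with_seed(seed, {
    v <- chars(sequence)
    n <- length(v)
    protected <- c(seq_len(min(CORE5_NT, n)),
                   seq.int(max(1L, n - CORE3_NT + 1L), n))
    cand <- setdiff(which(stats::runif(n) < rate), protected)
    for (i in cand) {
      repl <- sample(setdiff(DNA_BASES, v[i]))
      for (b in repl) {
        if (!is.null(orf_span) && i >= orf_span[1L] && i <= orf_span[2L]) {
          off <- i - orf_span[1L]
          c0 <- i - off %% 3L
          codon <- paste0(
            if (c0 == i) b else v[c0],
            if (c0 + 1L == i) b else v[c0 + 1L],
            if (c0 + 2L == i) b else v[c0 + 2L])
          if (codon %in% STOP_CODONS) next
        }
        v[i] <- b
        break
      }
    }
    paste(v, collapse = "")
  })
}

#' Generate a full synthetic dataset
#'
#' Builds `n_hosts` reference-derived host genes and plants every
#' non-truncated `loci_plan` entry on every host; each `TRUNCATED` entry is
#' planted on a dedicated fragment host that is cut inside the intron.
#' Geography groups are cycled over hosts; members of a locus share a
#' per-locus base intron, plus group-level substitutions (shared within a
#' group) and individual substitutions, all confined to the intron interior
#' so the junction cores stay conserved. Deterministic under the config
#' seed.
#'
#' @param config a [generator_config()].
#' @return list with `hosts` (named character vector), `truth` (data.frame:
#'   `host_id`, `locus`, `kind`, `start`, `end`, `motifs`, `geography`,
#'   `truncated`), `introns` (named character vector, `hostID|locusN`
#'   naming), `source_exons` (the intron-free host genes), and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  ref <- ref_16S()
  plan <- config$loci_plan
  plan_full <- plan[plan$kind != "TRUNCATED", , drop = FALSE]
  plan_trunc <- plan[plan$kind == "TRUNCATED", , drop = FALSE]
  groups <- rep(config$geography, length.out = config$n_hosts)
  hosts <- character(0)
  source_exons <- character(0)
  introns <- character(0)
  truth <- list()
  base_introns <- lapply(seq_len(nrow(plan_full)), function(k)
    generate_intron(plan_full$kind[k], plan_full$locus[k], config,
                    seed = child_seed(config$seed, 1000L + plan_full$locus[k])))
  # group-level variants of each base intron
  variants <- lapply(seq_len(nrow(plan_full)), function(k) {
    b <- base_introns[[k]]
    setNames(lapply(seq_along(unique(groups)), function(g)
      mutate_intron(b$sequence, config$group_divergence,
                    orf_span = b$truth$orf_span,
                    seed = child_seed(config$seed,
                                      2000L + plan_full$locus[k] * 7L + g))),
      unique(groups))
  })
  for (i in seq_len(config$n_hosts)) {
    hid <- sprintf("host%02d", i)
    exon <- generate_host(ref, config$host_divergence,
                          seed = child_seed(config$seed, i))
    source_exons[hid] <- exon
    if (nrow(plan_full)) {
      ord <- order(plan_full$locus)
      members <- lapply(seq_len(nrow(plan_full)), function(k) {
        b <- base_introns[[k]]
        mutate_intron(variants[[k]][[groups[i]]], config$indiv_divergence,
                      orf_span = b$truth$orf_span,
                      seed = child_seed(config$seed,
                                        3000L + plan_full$locus[k] * 11L + i))
      })
      # assemble 5'->3', tracking the growing offset
      pieces <- character(0)
      prev <- 0L
      offset <- 0L
      for (k in ord) {
        L <- plan_full$locus[k]
        pieces <- c(pieces, substr(exon, prev + 1L, L), members[[k]])
        start <- L + offset + 1L
        end <- start + nchar(members[[k]]) - 1L
        truth[[length(truth) + 1L]] <- data.frame(
          host_id = hid, locus = L, kind = plan_full$kind[k],
          start = start, end = end,
          motifs = base_introns[[k]]$truth$motifs,
          geography = groups[i], truncated = FALSE)
        introns[sprintf("%s|locus%d", hid, L)] <- members[[k]]
        offset <- offset + nchar(members[[k]])
        prev <- L
      }
      pieces <- c(pieces, substr(exon, prev + 1L, nchar(exon)))
      hosts[hid] <- paste(pieces, collapse = "")
    } else {
      hosts[hid] <- exon
    }
  }
  # dedicated fragment hosts for truncated entries
  for (k in seq_len(nrow(plan_trunc))) {
    hid <- sprintf("frag%02d", k)
    L <- plan_trunc$locus[k]
    exon <- generate_host(ref, config$host_divergence,
                          seed = child_seed(config$seed, 500L + k))
    gi <- generate_intron("TRUNCATED", L, config,
                          seed = child_seed(config$seed, 1500L + L))
    cut <- max(30L, nchar(gi$sequence) %/% 2L)
    frag <- paste0(substr(exon, 1L, L), substr(gi$sequence, 1L, cut))
    source_exons[hid] <- substr(exon, 1L, L)
    hosts[hid] <- frag
    truth[[length(truth) + 1L]] <- data.frame(
      host_id = hid, locus = L, kind = "TRUNCATED",
      start = L + 1L, end = L + cut, motifs = 0L,
      geography = groups[1L], truncated = TRUE)
    introns[sprintf("%s|locus%d", hid, L)] <- substr(gi$sequence, 1L, cut)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(host_id = character(), locus = integer(), kind = character(),
               start = integer(), end = integer(), motifs = integer(),
               geography = character(), truncated = logical())
  list(hosts = hosts, truth = truth, introns = introns,
       source_exons = source_exons, config = config)
}

#' Write a synthetic dataset to disk
#'
#' Hosts and introns as FASTA, the truth table as TSV with a reproducibility
#' header echoing the configuration (seed included).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$config
  files <- c(hosts = file.path(dir, "hosts.fasta"),
             introns = file.path(dir, "introns.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(dataset$hosts, files["hosts"])
  write_fasta(dataset$introns, files["introns"])
  con <- file(files["truth"], "w")
  writeLines(sprintf(
    "# archintron synthetic dataset: seed=%d n_hosts=%d host_divergence=%g intron_gc=%g group_divergence=%g indiv_divergence=%g",
    cfg$seed, cfg$n_hosts, cfg$host_divergence, cfg$intron_gc,
    cfg$group_divergence, cfg$indiv_divergence), con)
  write.table(dataset$truth, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  invisible(files)
}
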