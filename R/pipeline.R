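# Pipeline orchestration: detect -> classify -> primer audit -> per-locus
# phylogenetics, with a machine-readable JSON report, plus the subcommand
# CLI used by inst/cli/archintron.R.

#' Run the full intron analysis pipeline
#'
#' Detects insertions in every input gene against the packaged reference
#' frame, classifies each call, audits the primer list against the union of
#' canonical and detected loci, reports tandem-locus geometry and GC
#' statistics, and (for loci with enough members) builds per-locus
#' neighbor-joining trees with bootstrap supports and junction conservation
#' profiles. All outputs are written under `out_dir`; a JSON report with a
#' single isolated timestamp line makes runs byte-comparable.
#'
#' @param genes named character vector of gene sequences, or path to a
#'   multi-FASTA file.
#' @param primers data.frame (`name`, `sequence`, `orientation`) or path to
#'   a primer TSV; `NULL` skips the audit.
#' @param out_dir output directory.
#' @param min_insert,max_mismatch,min_members,bootstrap,seed pipeline
#'   parameters: minimum insertion length, primer mismatch tolerance,
#'   minimum per-locus members for a tree, bootstrap replicates, seed.
#' @param params classification parameters, see [classify_params()].
#' @return The report, invisibly (list; also written as `report.json`).
#' @export
run_pipeline <- function(genes, primers = NULL, out_dir = tempfile("archintron_"),
                         min_insert = 12L, max_mismatch = 1L,
                         min_members = 3L, bootstrap = 100L, seed = 1L,
                         params = classify_params()) {
  if (is.character(genes) && length(genes) == 1L && file.exists(genes))
    genes <- read_fasta(genes)
  if (length(genes) == 0L) stop("no input genes", call. = FALSE)
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("input genes must be named", call. = FALSE)
  if (is.character(primers) && length(primers) == 1L)
    primers <- read_primers(primers)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- ref_16S()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  calls <- stage("detect", {
    all <- lapply(names(genes), function(id)
      detect_insertions(genes[[id]], ref, min_insert = min_insert,
                        host_id = id))
    out <- do.call(rbind, all)
    class(out) <- c("intron_calls", "data.frame")
    out
  })
  cls <- stage("classify", classify_introns(calls, params))

  audit <- NULL
  if (!is.null(primers)) {
    audit <- stage("primers", {
      fps <- do.call(rbind, lapply(seq_len(nrow(primers)), function(k)
        best_footprint(match_primer(primers$sequence[k],
                                    primers$orientation[k], ref,
                                    max_mismatch = max_mismatch,
                                    name = primers$name[k]))))
      loci <- sort(unique(c(canonical_loci(), calls$locus)))
      list(footprints = fps, records = audit_primer_set(fps, loci))
    })
  }

  phylo <- stage("phylo", {
    res <- list()
    for (prof in locus_profiles(calls[!calls$truncated, , drop = FALSE])) {
      if (nrow(prof) < min_members) next
      locus <- prof$locus[1L]
      seqs <- setNames(prof$sequence,
                       sprintf("%s|locus%d", prof$host_id, locus))
      aln <- align_msa(seqs)
      if (mean_pairwise_identity(aln) < 0.2) next
      bs <- bootstrap_support(aln, n_reps = bootstrap,
                              seed = child_seed(seed, locus))
      nwk <- file.path(out_dir, sprintf("locus%d.nwk", locus))
      ape::write.tree(bs$tree, nwk)
      prof_path <- file.path(out_dir, sprintf("locus%d_junction_pfm.tsv",
                                              locus))
      jc <- junction_consensus(prof)
      write_profile_tsv(jc, prof_path)
      res[[as.character(locus)]] <- list(
        locus = locus, n_members = nrow(prof), tree_file = basename(nwk),
        pfm_file = basename(prof_path),
        mean_ic = mean(jc$ic))
    }
    res
  })

  # per-locus counts by category (curated-table layout)
  locus_counts <- stage("report", {
    if (nrow(cls)) {
      agg <- table(factor(cls$locus), factor(cls$category,
                   levels = c("HE", "HP", "REMNANT", "PRU")))
      d <- as.data.frame.matrix(agg)
      d <- cbind(locus = as.integer(rownames(d)), d)
      rownames(d) <- NULL
      d
    } else data.frame(locus = integer(), HE = integer(), HP = integer(),
                      REMNANT = integer(), PRU = integer())
  })

  files <- c(calls_gff3 = "calls.gff3", calls_tsv = "calls.tsv",
             introns_fasta = "introns.fasta",
             classification_tsv = "classification.tsv")
  write_calls_gff3(calls, file.path(out_dir, files["calls_gff3"]))
  write_calls_tsv(calls, file.path(out_dir, files["calls_tsv"]))
  if (nrow(calls))
    write_intron_fasta(calls, file.path(out_dir, files["introns_fasta"]))
  else
    writeLines(character(0), file.path(out_dir, files["introns_fasta"]))
  write.table(cls, file.path(out_dir, files["classification_tsv"]),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(audit)) {
    write.table(audit$records, file.path(out_dir, "primer_audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, primer_audit_tsv = "primer_audit.tsv")
  }

  gc_introns <- if (nrow(calls)) gc_summary(calls$sequence) else NULL
  gc_hosts <- gc_summary(unname(genes))
  report <- list(
    parameters = list(min_insert = min_insert, max_mismatch = max_mismatch,
                      min_members = min_members, bootstrap = bootstrap,
                      seed = seed, n_genes = length(genes)),
    n_calls = nrow(calls),
    locus_counts = locus_counts,
    tandem_loci = find_tandem_loci(sort(unique(calls$locus)), max_gap = 10L),
    gc = list(
      intron_mean = if (is.null(gc_introns)) NA else gc_introns$mean,
      intron_sd = if (is.null(gc_introns)) NA else gc_introns$sd,
      host_mean = gc_hosts$mean, host_sd = gc_hosts$sd),
    primer_audit = if (is.null(audit)) NULL else list(
      n_primers = nrow(audit$records),
      n_interrupted = sum(audit$records$interrupted),
      n_multi_locus = sum(audit$records$n_loci >= 2L)),
    phylo = phylo,
    files = as.list(files))
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  # timestamp isolated on its own line so byte comparisons can drop it
  writeLines(c(sprintf("{\"timestamp\": \"%s\",",
                       format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               sub("^\\{", " \"report\": {", json), "}"),
             file.path(out_dir, "report.json"))
  report$out_dir <- out_dir
  invisible(report)
}

cli_fail <- function(msg) {
  message("error: ", msg)
  2L
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `detect`, `classify`, `primers`, `phylo`,
#' `run-all`. Returns an exit status (0 success, 2 validation error); the
#' installed script `inst/cli/archintron.R` forwards it to `quit()`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly.
#' @export
intron_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: archintron <command> [options]",
    "commands:",
    "  simulate  --seed N --n-hosts N --out DIR",
    "  detect    --input genes.fasta --min-insert N --out calls.gff3",
    "  classify  --input genes.fasta --out classification.tsv",
    "  primers   --primers primers.tsv --max-mismatch N --out audit.tsv",
    "  phylo     --input genes.fasta --locus N --bootstrap N --seed N --out tree.nwk",
    "  run-all   --input genes.fasta [--primers primers.tsv] --out DIR",
    sep = "\n")
  if (length(args) < 1L) return(invisible(cli_fail(usage)))
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
  }
  res <- tryCatch(switch(
    cmd,
    "simulate" = {
      seed <- as.integer(opt("--seed", "1"))
      nh <- as.integer(opt("--n-hosts", "4"))
      out <- opt("--out")
      if (is.null(out)) stop("--out is required")
      ds <- generate_dataset(generator_config(seed = seed, n_hosts = nh))
      write_dataset(ds, out)
      message("simulated ", length(ds$hosts), " hosts, ",
              nrow(ds$truth), " introns -> ", out)
      0L
    },
    "detect" = {
      input <- opt("--input")
      if (is.null(input) || !file.exists(input))
        stop("--input FASTA is required")
      out <- opt("--out", "calls.gff3")
      genes <- read_fasta(input)
      calls <- do.call(rbind, lapply(names(genes), function(id)
        detect_insertions(genes[[id]], host_id = id,
                          min_insert = as.integer(opt("--min-insert", "12")))))
      write_calls_gff3(calls, out)
      write_calls_tsv(calls, paste0(out, ".tsv"))
      message(nrow(calls), " calls -> ", out)
      0L
    },
    "classify" = {
      input <- opt("--input")
      if (is.null(input) || !file.exists(input))
        stop("--input FASTA is required")
      out <- opt("--out", "classification.tsv")
      genes <- read_fasta(input)
      calls <- do.call(rbind, lapply(names(genes), function(id)
        detect_insertions(genes[[id]], host_id = id)))
      cls <- classify_introns(calls)
      write.table(cls, out, sep = "\t", quote = FALSE, row.names = FALSE)
      message(nrow(cls), " classifications -> ", out)
      0L
    },
    "primers" = {
      pfile <- opt("--primers")
      if (is.null(pfile) || !file.exists(pfile))
        stop("--primers TSV is required")
      out <- opt("--out", "primer_audit.tsv")
      primers <- read_primers(pfile)
      fps <- do.call(rbind, lapply(seq_len(nrow(primers)), function(k)
        best_footprint(match_primer(
          primers$sequence[k], primers$orientation[k],
          max_mismatch = as.integer(opt("--max-mismatch", "1")),
          name = primers$name[k]))))
      rec <- audit_primer_set(fps)
      write.table(rec, out, sep = "\t", quote = FALSE, row.names = FALSE)
      message(sum(rec$interrupted), "/", nrow(rec),
              " primers interrupted -> ", out)
      0L
    },
    "phylo" = {
      input <- opt("--input")
      if (is.null(input) || !file.exists(input))
        stop("--input FASTA is required")
      locus <- as.integer(opt("--locus"))
      if (is.na(locus)) stop("--locus is required")
      out <- opt("--out", sprintf("locus%d.nwk", locus))
      genes <- read_fasta(input)
      calls <- do.call(rbind, lapply(names(genes), function(id)
        detect_insertions(genes[[id]], host_id = id)))
      prof <- calls[calls$locus == locus & !calls$truncated, , drop = FALSE]
      if (nrow(prof) < 3L) stop("fewer than 3 members at locus ", locus)
      aln <- align_msa(setNames(prof$sequence,
                                sprintf("%s|locus%d", prof$host_id, locus)))
      bs <- bootstrap_support(aln,
                              n_reps = as.integer(opt("--bootstrap", "1000")),
                              seed = as.integer(opt("--seed", "1")))
      ape::write.tree(bs$tree, out)
      message("tree with supports -> ", out)
      0L
    },
    "run-all" = {
      input <- opt("--input")
      if (is.null(input) || !file.exists(input))
        stop("--input FASTA is required")
      out <- opt("--out", "archintron_out")
      primers <- opt("--primers")
      run_pipeline(input, primers = primers, out_dir = out,
                   seed = as.integer(opt("--seed", "1")),
                   bootstrap = as.integer(opt("--bootstrap", "100")))
      message("report -> ", file.path(out, "report.json"))
      0L
    },
    stop("unknown command '", cmd, "'\n", usage)),
    error = function(e) cli_fail(conditionMessage(e)))
  invisible(res)
}
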