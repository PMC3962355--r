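# End-to-end pipeline: QC -> discovery -> conservation -> targets ->
# enrichment, with a machine-readable output manifest. Identical
# config + seed gives identical output checksums.

#' Pipeline configuration
#'
#' File paths plus every stage parameter at its documented default. All
#' paths are checked before any compute; parameters are forwarded to the
#' stage functions.
#'
#' @param reads,genome paths to the read FASTQ and genome FASTA (required).
#' @param transcripts,known,contaminants,obo,annotations,study optional
#'   paths: transcript FASTA, known-miRNA FASTA, contaminant FASTA, OBO
#'   file, annotation TSV (`gene`, `term` columns), study gene list (one id
#'   per line). Stages without inputs are skipped.
#' @param out_dir output directory (created if missing).
#' @param qc a [qc_params()] list.
#' @param thresholds a [bona_fide_thresholds()] list.
#' @param max_loci,min_map_len mapping parameters.
#' @param min_stack_count,merge_gap,flank stack/excision parameters.
#' @param ddg_cutoff target retention threshold (default -10 kcal/mol).
#' @param alpha enrichment significance threshold (default 0.01,
#'   uncorrected).
#' @param prefix species prefix for miRNA names (default "spi").
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, genome, transcripts = NULL, known = NULL,
                            contaminants = NULL, obo = NULL,
                            annotations = NULL, study = NULL,
                            out_dir = "coralmir_out", qc = qc_params(),
                            thresholds = bona_fide_thresholds(),
                            max_loci = 5, min_map_len = 18,
                            min_stack_count = 10, merge_gap = 2, flank = 70,
                            ddg_cutoff = -10, alpha = 0.01, prefix = "spi") {
  if (missing(reads) || is.null(reads))
    stop("config error: reads path is required", call. = FALSE)
  if (missing(genome) || is.null(genome))
    stop("config error: genome path is required", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

manifest_row <- function(path, stage) {
  n <- length(readLines(path, warn = FALSE))
  data.frame(file = basename(path), stage = stage,
             md5 = unname(tools::md5sum(path)), rows = n,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes QC, miRNA discovery, conservation naming, target prediction and
#' GO enrichment, writing each stage's outputs (TSV/FASTA/GFF3) and a
#' manifest with checksums and row counts. Stage input/output counts (the
#' read funnel) are logged via [message()].
#'
#' @param config a [pipeline_config()].
#' @return the manifest data.frame, invisibly; outputs land in
#'   `config$out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- config[c("reads", "genome", "transcripts", "known",
                    "contaminants", "obo", "annotations", "study")]
  for (p in Filter(Negate(is.null), paths))
    if (!file.exists(p))
      stop(sprintf("config error: missing input file %s", p), call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  note <- function(path, stage)
    manifest[[length(manifest) + 1]] <<- manifest_row(path, stage)

  # --- QC ---
  reads <- read_fastq(config$reads)
  contaminants <- if (!is.null(config$contaminants))
    read_fasta(config$contaminants) else NULL
  qc <- run_qc(reads, config$qc, contaminants)
  message(sprintf("qc: %d raw -> %d clean reads",
                  qc$report$counts[["raw"]],
                  qc$report$counts[["post_length"]]))
  write_records(qc$reads, out("clean.fastq"), "fastq")
  write_tsv(data.frame(stage = names(qc$report$counts),
                       reads = as.integer(qc$report$counts)),
            out("qc_report.tsv"))
  write_tsv(qc$report$composition, out("composition.tsv"))
  note(out("clean.fastq"), "qc")
  note(out("qc_report.tsv"), "qc")
  note(out("composition.tsv"), "qc")

  # --- discovery + conservation ---
  genome <- read_fasta(config$genome)
  known <- if (!is.null(config$known)) read_fasta(config$known) else NULL
  disc <- discover_mirnas(qc$reads, genome, known = known,
                          thresholds = config$thresholds,
                          min_len = config$min_map_len,
                          max_loci = config$max_loci,
                          min_count = config$min_stack_count,
                          merge_gap = config$merge_gap,
                          flank = config$flank)
  message(sprintf(
    "discover: %d alignments, %d stacks, %d candidates, %d bona fide",
    nrow(disc$alignments), nrow(disc$stacks),
    if (is.null(disc$candidates)) 0L else nrow(disc$candidates),
    if (is.null(disc$verdicts)) 0L else sum(disc$verdicts$passed)))
  names_df <- assign_names(disc$verdicts, disc$hits, prefix = config$prefix)
  if (!is.null(disc$candidates)) {
    cand <- disc$candidates
    gff <- data.frame(seqid = cand$contig, source = "coralmir",
                      type = "pre_miRNA", start = cand$start + 1L,
                      end = cand$end, score = ".", strand = cand$strand,
                      phase = ".",
                      attributes = paste0("ID=", cand$candidate))
    writeLines(c("##gff-version 3",
                 apply(gff, 1, paste, collapse = "\t")),
               out("precursors.gff3"))
    write_records(data.frame(id = cand$candidate, desc = "",
                             seq = cand$seq),
                  out("precursors.fasta"), "fasta")
    mature_named <- merge(names_df, cand[, c("candidate", "mature_seq")],
                          by = "candidate")
    write_records(data.frame(id = mature_named$name, desc = "",
                             seq = mature_named$mature_seq),
                  out("mature.fasta"), "fasta")
    # mature sequences are printed in the lower-case RNA dialect
    mat_lines <- readLines(out("mature.fasta"))
    body <- !startsWith(mat_lines, ">")
    mat_lines[body] <- as_rna_lower(mat_lines[body])
    writeLines(mat_lines, out("mature.fasta"))
    write_tsv(disc$verdicts, out("verdicts.tsv"))
    write_tsv(names_df, out("mirna_names.tsv"))
    note(out("precursors.gff3"), "discover")
    note(out("precursors.fasta"), "discover")
    note(out("mature.fasta"), "discover")
    note(out("verdicts.tsv"), "discover")
    note(out("mirna_names.tsv"), "conserve")
  }

  # --- targets ---
  targets <- NULL
  if (!is.null(config$transcripts) && nrow(names_df) > 0) {
    transcripts <- read_fasta(config$transcripts)
    utrs <- extract_all_utrs(transcripts)
    mature_named <- merge(names_df,
                          disc$candidates[, c("candidate", "mature_seq")],
                          by = "candidate")
    matures <- data.frame(id = mature_named$name,
                          seq = mature_named$mature_seq)
    targets <- predict_targets(matures, utrs, cutoff = config$ddg_cutoff)
    message(sprintf("targets: %d sites scored, %d retained",
                    nrow(targets), sum(targets$retained)))
    write_tsv(targets, out("targets.tsv"))
    note(out("targets.tsv"), "targets")
  }

  # --- enrichment ---
  if (!is.null(config$obo) && !is.null(config$annotations) &&
      !is.null(targets)) {
    dag <- parse_obo(config$obo)
    ann <- read.delim(config$annotations, stringsAsFactors = FALSE)
    background <- unique(ann$gene)
    study <- if (!is.null(config$study))
      readLines(config$study) else
        unique(targets$transcript[targets$retained])
    study <- intersect(study, background)
    if (length(study) > 0) {
      closed <- propagate(ann, dag)
      enr <- enrich(study, background, closed, dag, method = "elim",
                    alpha = config$alpha)
      message(sprintf("enrich: %d terms tested, %d significant",
                      nrow(enr), sum(enr$significant)))
      write_tsv(enr, out("enrichment.tsv"))
      note(out("enrichment.tsv"), "enrich")
    }
  }

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, out("manifest.tsv"))
  invisible(manifest)
}

#' Generate a synthetic study and run the full pipeline on it
#'
#' Writes simulated inputs (genome, reads, transcripts, known miRNAs,
#' contaminants, ontology, annotations) under `out_dir/inputs`, then runs
#' [run_all()] on them.
#'
#' @param sim a [sim_config()].
#' @param out_dir output directory.
#' @param ... overrides forwarded to [pipeline_config()].
#' @return list with `manifest`, the simulation `truth` tables and the
#'   `config` used.
#' @export
run_all_simulated <- function(sim = sim_config(), out_dir = "coralmir_out",
                              ...) {
  indir <- file.path(out_dir, "inputs")
  dir.create(indir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(sim)
  lib <- simulate_reads(gen$genome, gen$truth, sim)
  tx <- simulate_transcripts(
    data.frame(id = gen$truth$hairpin, seq = gen$truth$mature_seq), sim)
  onto <- simulate_ontology(sim, genes = tx$transcripts$id)
  contam <- read_fasta(system.file("extdata",
                                   "synthetic_contaminants.fasta",
                                   package = "coralmir"))
  p <- list(reads = file.path(indir, "reads.fastq"),
            genome = file.path(indir, "genome.fasta"),
            transcripts = file.path(indir, "transcripts.fasta"),
            known = file.path(indir, "known.fasta"),
            contaminants = file.path(indir, "contaminants.fasta"),
            obo = file.path(indir, "ontology.obo"),
            annotations = file.path(indir, "annotations.tsv"))
  write_records(lib$reads, p$reads, "fastq")
  write_records(gen$genome, p$genome, "fasta")
  write_records(tx$transcripts, p$transcripts, "fasta")
  write_records(gen$known, p$known, "fasta")
  write_records(contam, p$contaminants, "fasta")
  write_obo(onto$dag, p$obo)
  write_tsv(onto$annotations, p$annotations)
  cfg <- pipeline_config(reads = p$reads, genome = p$genome,
                         transcripts = p$transcripts, known = p$known,
                         contaminants = p$contaminants, obo = p$obo,
                         annotations = p$annotations, out_dir = out_dir,
                         ...)
  manifest <- run_all(cfg)
  list(manifest = manifest, config = cfg,
       truth = list(hairpins = gen$truth, reads = lib$labels,
                    sites = tx$truth, enriched_term = onto$truth))
}

#' Write an ontology DAG as an OBO-subset file
#'
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    isa <- if (length(dag$parents[[t]]))
      paste0("is_a: ", dag$parents[[t]]) else character(0)
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: ", dag$names[[t]]), isa, "")
  }
  writeLines(lines, path)
  invisible(path)
}
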