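# End-to-end orchestration: build references -> simulate or ingest reads ->
# align -> QC -> call sites -> differential report, with per-stage logging,
# a provenance manifest, and full determinism given (config, seed).

#' Validate a pipeline run configuration
#'
#' @param references data.frame with `id`, `sequence`, optional `weight`,
#'   `category` -- the (consensus) reference panel.
#' @param samples data.frame with one row per sample: `sample_id`,
#'   `genotype`, `library` (`"BS"` or `"nonBS"`), and either `fastq` (path
#'   to reads) or `n_reads` (simulate that many reads).
#' @param methylation_maps named list (by genotype) of methylation maps
#'   (`id`, `position`, `fraction`) used when samples are simulated.
#' @param out_dir run directory (created; one directory per run).
#' @param min_coverage,min_methylation,min_conversion,max_mismatch
#'   calling/QC thresholds (defaults 5, 0.20, 0.98, 2).
#' @param spikein_fraction fraction of simulated reads drawn from the
#'   spike-in conversion control.
#' @param conversion_efficiency,over_conversion,seq_error_rate simulator
#'   parameters for simulated samples.
#' @param seed integer master seed; sample-level seeds are derived from it.
#' @return validated config (class `run_config`).
#' @export
run_config <- function(references, samples, methylation_maps = list(),
                       out_dir = tempfile("rbsmeth_run_"),
                       min_coverage = 5, min_methylation = 0.20,
                       min_conversion = 0.98, max_mismatch = 2,
                       spikein_fraction = 0.05,
                       conversion_efficiency = 0.99, over_conversion = 0.01,
                       seq_error_rate = 0.001, seed = 1) {
  stopifnot(is.data.frame(references),
            all(c("id", "sequence") %in% names(references)),
            is.data.frame(samples),
            all(c("sample_id", "genotype", "library") %in% names(samples)))
  if (!all(samples$library %in% c("BS", "nonBS")))
    stop("sample library must be 'BS' or 'nonBS'", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  simulated <- is.null(samples$fastq)
  if (!simulated) {
    missing <- samples$fastq[!file.exists(samples$fastq)]
    if (length(missing))
      stop("sample FASTQ not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  } else if (is.null(samples$n_reads)) {
    stop("samples need either a fastq column or an n_reads column",
         call. = FALSE)
  }
  for (x in c(min_methylation, min_conversion, spikein_fraction,
              conversion_efficiency, over_conversion, seq_error_rate))
    if (x < 0 || x > 1) stop("fractions must lie in [0,1]", call. = FALSE)
  stopifnot(min_coverage >= 1, max_mismatch >= 0)
  structure(list(references = references, samples = samples,
                 methylation_maps = methylation_maps, out_dir = out_dir,
                 min_coverage = min_coverage,
                 min_methylation = min_methylation,
                 min_conversion = min_conversion,
                 max_mismatch = max_mismatch,
                 spikein_fraction = spikein_fraction,
                 conversion_efficiency = conversion_efficiency,
                 over_conversion = over_conversion,
                 seq_error_rate = seq_error_rate,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full RBS-seq analysis pipeline
#'
#' Stages: reference conversion, per-sample read acquisition (simulation
#' with the genotype's methylation map, or FASTQ ingestion), three-letter
#' alignment, spike-in conversion QC (BS libraries; a failing sample is
#' halted at QC and produces no site calls), site calling, and a
#' differential report of every mutant genotype against the wild type
#' (genotype `"wt"` when present, otherwise the first genotype). All stage
#' outputs land under `config$out_dir`; a manifest records the seed, config
#' hash, package version and every output file. Re-running with an
#' identical config reproduces identical site tables.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return list with `refs`, per-sample `qc`, `calls`, `rates`,
#'   `differential`, `halted` (samples stopped at QC) and `manifest`,
#'   invisibly mirrored on disk.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(obj, rel) {
    path <- file.path(config$out_dir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, rel)
    path
  }

  stage <- "build-ref"
  res <- tryCatch({
    say("stage %s", stage)
    refs_df <- config$references
    if (is.null(refs_df$category)) refs_df$category <- "tRNA"
    control <- make_spikein(length = 1068, gc_fraction = 0.5,
                            seed = config$seed, control_id = "RLuc_control")
    all_ids <- c(refs_df$id, control$control_id)
    all_seqs <- c(refs_df$sequence, control$sequence)
    all_cats <- c(refs_df$category, "spikein")
    refs <- refset(all_ids, all_seqs, category = all_cats)
    write_reference_dir(data.frame(consensus_id = all_ids,
                                   sequence = all_seqs),
                        file.path(config$out_dir, "refs"))
    outputs <- c(outputs, "refs/consensus.fasta",
                 "refs/consensus.converted.fasta", "refs/manifest.tsv")

    calls <- list(); qcs <- list(); rates <- list(); halted <- character(0)
    for (i in seq_len(nrow(config$samples))) {
      smp <- config$samples[i, ]
      stage <- paste0("reads:", smp$sample_id)
      is_bs <- smp$library == "BS"
      if (!is.null(config$samples$fastq)) {
        reads <- read_fastq(smp$fastq)
      } else {
        mm <- config$methylation_maps[[smp$genotype]]
        cfg <- sim_config(refs_df, methylation_map = mm,
                          n_reads = smp$n_reads,
                          conversion_efficiency = config$conversion_efficiency,
                          over_conversion = config$over_conversion,
                          seq_error_rate = config$seq_error_rate,
                          spikein_fraction = if (is_bs) config$spikein_fraction else 0,
                          seed = config$seed + i)
        sim <- if (is_bs) simulate_bisulfite_reads(cfg, control)
               else simulate_rnaseq_reads(cfg)
        reads <- sim$reads
        fq <- file.path(config$out_dir, "reads",
                        paste0(smp$sample_id, ".fastq"))
        dir.create(dirname(fq), recursive = TRUE, showWarnings = FALSE)
        write_fastq(reads, fq)
        outputs <- c(outputs, file.path("reads", basename(fq)))
      }
      say("sample %s: %d reads", smp$sample_id, nrow(reads))

      stage <- paste0("align:", smp$sample_id)
      aln <- align_reads(reads, refs, max_mismatch = config$max_mismatch,
                         convert_reads = is_bs)
      sam <- file.path(config$out_dir, "aln",
                       paste0(smp$sample_id, ".sam"))
      dir.create(dirname(sam), recursive = TRUE, showWarnings = FALSE)
      write_sam(aln, reads, refs, sam)
      outputs <- c(outputs, file.path("aln", basename(sam)))
      rates[[smp$sample_id]] <-
        classify_alignment_rate(aln, nrow(reads), refs)

      stage <- paste0("call:", smp$sample_id)
      pile <- tally_pileup(aln, reads, refs)
      if (is_bs) {
        qc <- qc_conversion(
          pile[pile$reference_id == control$control_id, , drop = FALSE],
          min_conversion = config$min_conversion)
        qcs[[smp$sample_id]] <- qc
        if (!qc$pass) {
          say("sample %s HALTED at QC: conversion %.2f%% < %.0f%%",
              smp$sample_id, 100 * qc$global_conversion,
              100 * config$min_conversion)
          halted <- c(halted, smp$sample_id)
          next
        }
      }
      endo <- pile[pile$reference_id != control$control_id, , drop = FALSE]
      smp_calls <- call_sites(endo, min_coverage = config$min_coverage,
                              min_methylation = config$min_methylation,
                              qc = qcs[[smp$sample_id]])
      calls[[smp$sample_id]] <- smp_calls
      emit(smp_calls, file.path("calls", paste0(smp$sample_id, ".tsv")))
    }

    stage <- "differential"
    say("stage %s", stage)
    genotype_of <- setNames(config$samples$genotype, config$samples$sample_id)
    called_geno <- unique(genotype_of[names(calls)])
    wt <- if ("wt" %in% called_geno) "wt" else called_geno[1]
    differential <- list()
    if (length(called_geno) > 1L && length(calls)) {
      wt_sample <- names(calls)[genotype_of[names(calls)] == wt][1]
      for (s in names(calls)) {
        if (genotype_of[s] == wt) next
        d <- differential_sites(calls[[wt_sample]], calls[[s]])
        differential[[s]] <- d
        emit(d, file.path("differential", paste0(s, "_vs_", wt, ".tsv")))
      }
    }
    if (length(calls) > 1L) {
      mat <- methylation_matrix(calls)
      emit(data.frame(site = rownames(mat), mat, check.names = FALSE),
           "heatmap_matrix.tsv")
    }

    stage <- "manifest"
    cfg_for_hash <- config
    cfg_for_hash$out_dir <- NULL
    yaml_path <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(unclass(cfg_for_hash), yaml_path)
    outputs <- c(outputs, "config.yaml")
    manifest <- list(
      package = "rbsmeth",
      version = as.character(utils::packageVersion("rbsmeth")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(yaml_path)),
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      halted_at_qc = halted,
      outputs = c(outputs, "manifest.json", "run.log"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    list(refs = refs, qc = qcs, calls = calls, rates = rates,
         differential = differential, halted = halted, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
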