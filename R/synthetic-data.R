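# Read simulator with known ground truth, emulating tRNA-enriched RBS-seq /
# RNA-seq libraries: short stranded single-end reads (65-95 nt size
# selection window), per-site methylation fractions, bisulfite conversion
# efficiency, a methylation-free spike-in control, and sequencing error.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the simulator emulates: tRNA gel
#' size-selection window of 65-95 nt, conversion efficiency 0.99 (above the
#' 0.98 QC gate), and a low per-base sequencing error. `over_conversion` is
#' the probability that a truly methylated C is nonetheless read as T; no
#' empirical rate is available for it, so the default 0.01 is a free
#' parameter of the simulator.
#'
#' @param references data.frame with columns `id`, `sequence`, optional
#'   `weight` (relative abundance; default equal) and `category`
#'   (`"tRNA"`/`"rRNA"`; default `"tRNA"`).
#' @param methylation_map data.frame with columns `id`, `position` (1-based C
#'   position in that reference), `fraction` in \[0,1\]. May have zero rows.
#' @param n_reads number of endogenous + spike-in reads to simulate.
#' @param conversion_efficiency probability an unmethylated C reads as T.
#' @param over_conversion probability a methylated C reads as T.
#' @param seq_error_rate per-base substitution error rate.
#' @param read_length_range integer length-2 vector, min/max read length.
#' @param spikein_fraction fraction of reads drawn from the spike-in control.
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(references, methylation_map = NULL, n_reads = 10000,
                       conversion_efficiency = 0.99, over_conversion = 0.01,
                       seq_error_rate = 0.001,
                       read_length_range = c(65, 95),
                       spikein_fraction = 0, seed = 1) {
  stopifnot(is.data.frame(references),
            all(c("id", "sequence") %in% names(references)),
            n_reads >= 0,
            length(read_length_range) == 2,
            read_length_range[1] <= read_length_range[2])
  for (x in c(conversion_efficiency, over_conversion, seq_error_rate,
              spikein_fraction))
    if (x < 0 || x > 1) stop("fractions must lie in [0,1]", call. = FALSE)
  if (is.null(references$weight)) references$weight <- 1
  if (is.null(references$category)) references$category <- "tRNA"
  if (is.null(methylation_map))
    methylation_map <- data.frame(id = character(), position = integer(),
                                  fraction = numeric())
  if (nrow(methylation_map)) {
    stopifnot(all(c("id", "position", "fraction") %in% names(methylation_map)),
              all(methylation_map$fraction >= 0 & methylation_map$fraction <= 1))
    for (i in seq_len(nrow(methylation_map))) {
      r <- match(methylation_map$id[i], references$id)
      if (is.na(r))
        stop("methylation_map references unknown id: ",
             methylation_map$id[i], call. = FALSE)
      p <- methylation_map$position[i]
      if (p < 1 || p > nchar(references$sequence[r]) ||
          substr(references$sequence[r], p, p) != "C")
        stop(sprintf("methylation_map position %d of %s is not a cytosine",
                     p, methylation_map$id[i]), call. = FALSE)
    }
  }
  structure(list(references = references,
                 methylation_map = methylation_map,
                 n_reads = as.integer(n_reads),
                 conversion_efficiency = conversion_efficiency,
                 over_conversion = over_conversion,
                 seq_error_rate = seq_error_rate,
                 read_length_range = as.integer(read_length_range),
                 spikein_fraction = spikein_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a methylation-free spike-in control
#'
#' Emulates an in vitro transcribed mRNA control (no m5C by construction)
#' that is mixed into each library to measure bisulfite conversion
#' efficiency: after complete conversion, none of its cytosines should read
#' as C.
#'
#' @param length control length in nt (>= 100; shorter controls carry too
#'   few cytosines for a stable conversion-rate estimate).
#' @param gc_fraction target GC content.
#' @param seed integer seed.
#' @param control_id identifier.
#' @return list with `control_id`, `sequence`, `n_cytosines`, class
#'   `spikein_control`.
#' @export
make_spikein <- function(length = 1000, gc_fraction = 0.5, seed = 1,
                         control_id = "spikein") {
  if (length < 100)
    stop("spike-in control must be >= 100 nt", call. = FALSE)
  sequence <- withr_seed(seed, random_dna(length, gc_fraction))
  structure(list(control_id = control_id, sequence = sequence,
                 n_cytosines = length(c_positions_of(sequence))),
            class = "spikein_control")
}

#' Generate a spike-in control with an exact cytosine count
#'
#' Rejection-samples generator seeds until the control carries exactly the
#' requested number of cytosines; used to emulate a conversion control with
#' a fixed cytosine inventory (e.g. the 178 cytosines of an in vitro
#' transcribed luciferase control) at a given length.
#'
#' @param length control length in nt.
#' @param n_cytosines exact cytosine count required.
#' @param seed_start first generator seed to try (seeds are scanned
#'   upward deterministically).
#' @param max_tries give up after this many seeds.
#' @inheritParams make_spikein
#' @return a [make_spikein()] result with `n_cytosines` as requested.
#' @export
calibrate_spikein <- function(length = 1068, n_cytosines = 178,
                              seed_start = 1, max_tries = 10000,
                              control_id = "RLuc_control") {
  gc <- 2 * n_cytosines / length  # expected GC putting C at the target
  for (seed in seq(seed_start, length.out = max_tries)) {
    sp <- make_spikein(length, gc, seed, control_id = control_id)
    if (sp$n_cytosines == n_cytosines) return(sp)
  }
  stop("no seed in range produced exactly ", n_cytosines, " cytosines",
       call. = FALSE)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a bisulfite-converted (RBS-seq) read set with ground truth
#'
#' Each read is drawn from a reference chosen by abundance weight (or from
#' the spike-in control with probability `spikein_fraction`), with uniform
#' start and length within the configured window (full-length when the
#' reference is shorter than the minimum). Every cytosine in the read is
#' methylated with its site's true fraction; methylated Cs read as C with
#' probability 1 - over_conversion, unmethylated Cs read as T with
#' probability conversion_efficiency. Per-base sequencing error is applied
#' last. Reads are sense-strand only (stranded library).
#'
#' @param config a [sim_config()].
#' @param control optional [make_spikein()] result; required when
#'   `spikein_fraction > 0`.
#' @return list with `reads` (data.frame `read_id`, `sequence`, `quality`),
#'   `truth_reads` (read_id, source_id, start, length), `truth_sites`
#'   (id, position, fraction for every reference C position, 0 where not in
#'   the methylation map).
#' @export
simulate_bisulfite_reads <- function(config, control = NULL) {
  simulate_reads_impl(config, control, bisulfite = TRUE)
}

#' Simulate a non-bisulfite (RNA-seq) read set
#'
#' As [simulate_bisulfite_reads()] but with no conversion step; used for
#' species-specific reference derivation and composition baselines.
#'
#' @inheritParams simulate_bisulfite_reads
#' @return as [simulate_bisulfite_reads()] (truth_sites carries the map
#'   fractions but no conversion was applied).
#' @export
simulate_rnaseq_reads <- function(config, control = NULL) {
  simulate_reads_impl(config, control, bisulfite = FALSE)
}

simulate_reads_impl <- function(config, control, bisulfite) {
  stopifnot(inherits(config, "sim_config"))
  if (config$spikein_fraction > 0 && is.null(control))
    stop("spikein_fraction > 0 requires a spike-in control", call. = FALSE)
  refs <- config$references
  if (!is.null(control)) {
    if (any(config$methylation_map$id == control$control_id))
      stop("spike-in control cytosines must not appear in the methylation map",
           call. = FALSE)
    if (control$n_cytosines == 0L)
      stop("unusable spike-in control: contains no cytosines", call. = FALSE)
  }
  seqs <- setNames(as.list(refs$sequence), refs$id)
  cats <- setNames(refs$category, refs$id)
  if (!is.null(control)) {
    seqs[[control$control_id]] <- control$sequence
    cats[control$control_id] <- "spikein"
  }
  # per-reference methylation fraction lookup over C positions
  meth <- lapply(names(seqs), function(id) {
    cp <- c_positions_of(seqs[[id]])
    f <- setNames(rep(0, length(cp)), cp)
    mm <- config$methylation_map[config$methylation_map$id == id, ]
    if (nrow(mm)) f[as.character(mm$position)] <- mm$fraction
    f
  })
  names(meth) <- names(seqs)

  withr_seed(config$seed, {
    n <- config$n_reads
    ids <- refs$id
    w <- refs$weight / sum(refs$weight)
    is_spike <- if (config$spikein_fraction > 0)
      runif(n) < config$spikein_fraction else rep(FALSE, n)
    src <- character(n)
    src[!is_spike] <- sample(ids, sum(!is_spike), replace = TRUE, prob = w)
    if (any(is_spike)) src[is_spike] <- control$control_id
    len_choices <- seq(config$read_length_range[1],
                       config$read_length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    reflen <- vapply(seqs[src], nchar, integer(1))
    lens <- pmin(lens, reflen)  # full-length reads for short references
    starts <- floor(runif(n) * (reflen - lens + 1)) + 1L
    out_seq <- character(n)
    for (i in seq_len(n)) {
      s <- seqs[[src[i]]]
      ch <- seq_chars(substr(s, starts[i], starts[i] + lens[i] - 1L))
      if (bisulfite) {
        cpos <- which(ch == "C")
        if (length(cpos)) {
          fr <- unname(meth[[src[i]]][as.character(cpos + starts[i] - 1L)])
          methylated <- runif(length(cpos)) < fr
          reads_as_c <- ifelse(methylated,
                               runif(length(cpos)) >= config$over_conversion,
                               runif(length(cpos)) >= config$conversion_efficiency)
          ch[cpos[!reads_as_c]] <- "T"
        }
      }
      if (config$seq_error_rate > 0) {
        err <- which(runif(length(ch)) < config$seq_error_rate)
        for (e in err) {
          ch[e] <- sample(setdiff(DNA_BASES, ch[e]), 1)
        }
      }
      out_seq[i] <- paste(ch, collapse = "")
    }
    read_id <- sprintf("read%06d", seq_len(n))
    truth_sites <- do.call(rbind, lapply(names(meth), function(id) {
      if (length(meth[[id]]) == 0L) return(NULL)
      data.frame(id = id, position = as.integer(names(meth[[id]])),
                 fraction = unname(meth[[id]]), stringsAsFactors = FALSE)
    }))
    list(reads = data.frame(read_id = read_id, sequence = out_seq,
                            quality = strrep("I", nchar(out_seq)),
                            stringsAsFactors = FALSE),
         truth_reads = data.frame(read_id = read_id, source_id = src,
                                  start = starts, length = lens,
                                  category = unname(cats[src]),
                                  stringsAsFactors = FALSE),
         truth_sites = truth_sites)
  })
}

#' Expected observed methylation under the conversion model
#'
#' With conversion efficiency `e`, over-conversion `o` and true methylation
#' `m`, a site's expected C fraction among C+T reads is
#' `m (1 - o) + (1 - m)(1 - e)`: methylated molecules survive conversion
#' with probability 1 - o, and unmethylated molecules fail to convert with
#' probability 1 - e.
#'
#' @param m true methylation fraction.
#' @param e conversion efficiency.
#' @param o over-conversion rate.
#' @return expected observed methylation fraction.
#' @export
expected_observed_methylation <- function(m, e, o = 0) {
  m * (1 - o) + (1 - m) * (1 - e)
}

#' Write reads to FASTQ
#' @param reads data.frame with `read_id`, `sequence`, optional `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (is.null(reads$quality)) strrep("I", nchar(reads$sequence))
          else reads$quality
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  idx <- seq(1, length(lines), by = 4)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             sequence = toupper(lines[idx + 1]),
             quality = lines[idx + 3],
             stringsAsFactors = FALSE)
}
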