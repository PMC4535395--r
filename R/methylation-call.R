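# Per-cytosine pileup, percent methylation, spike-in conversion QC,
# threshold site calling, and differential methylation between genotypes.
#
# Percent methylation at a position is the number of mapped cytosines
# divided by the combined total of mapped cytosines and mapped thymines;
# other bases (A/G/N: sequencing errors over a C position) are tallied but
# excluded from the denominator.

#' Tally per-cytosine pileups from alignments
#'
#' For every original-C position of every reference, counts reads showing C
#' (unconverted, i.e. methylated or conversion failure), T (converted), or
#' another base. Multimapped reads contribute their fractional weight
#' (1 / number of cochampions) so total counts are conserved.
#'
#' @param alignments output of [align_reads()] (original read bases are
#'   taken from `reads`).
#' @param reads the reads data.frame that was aligned.
#' @param refs the [refset()] used for alignment.
#' @return data.frame with one row per reference C position: `reference_id`,
#'   `position`, `n_C`, `n_T`, `n_other`, `coverage` (= n_C + n_T),
#'   `methylation` (n_C / coverage, `NA` when coverage is 0).
#' @export
tally_pileup <- function(alignments, reads, refs) {
  stopifnot(inherits(refs, "refset"))
  unknown <- setdiff(unique(alignments$reference_id), names(refs))
  if (length(unknown))
    stop("alignments reference unknown reference(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  read_seq <- setNames(toupper(reads$sequence), reads$read_id)

  per_ref <- lapply(names(refs), function(id) {
    cp <- refs[[id]]$c_positions
    ncp <- length(cp)
    tallies <- matrix(0, nrow = 3, ncol = ncp,
                      dimnames = list(c("C", "T", "other"), NULL))
    aln <- alignments[alignments$reference_id == id, , drop = FALSE]
    if (nrow(aln) && ncp) {
      rs <- read_seq[aln$read_id]
      rl <- nchar(rs)
      for (i in seq_len(nrow(aln))) {
        s <- aln$start[i]
        e <- s + rl[i] - 1L
        hit <- which(cp >= s & cp <= e)
        if (!length(hit)) next
        b <- substring(rs[i], cp[hit] - s + 1L, cp[hit] - s + 1L)
        row <- ifelse(b == "C", 1L, ifelse(b == "T", 2L, 3L))
        for (k in seq_along(hit))
          tallies[row[k], hit[k]] <- tallies[row[k], hit[k]] + aln$weight[i]
      }
    }
    if (ncp == 0L) return(NULL)
    cov <- tallies[1, ] + tallies[2, ]
    data.frame(reference_id = id, position = cp,
               n_C = tallies[1, ], n_T = tallies[2, ],
               n_other = tallies[3, ], coverage = cov,
               methylation = ifelse(cov > 0, tallies[1, ] / cov, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_ref)
  if (is.null(out)) out <- data.frame(reference_id = character(),
                                      position = integer(), n_C = numeric(),
                                      n_T = numeric(), n_other = numeric(),
                                      coverage = numeric(),
                                      methylation = numeric())
  rownames(out) <- NULL
  out
}

#' Percent methylation from C/T counts
#'
#' @param n_C mapped cytosine count (fractional counts allowed).
#' @param n_T mapped thymine count.
#' @return `n_C / (n_C + n_T)`; `NA` (undefined, not 0) when the denominator
#'   is zero. Vectorised.
#' @export
percent_methylation <- function(n_C, n_T) {
  denom <- n_C + n_T
  ifelse(denom > 0, n_C / denom, NA_real_)
}

#' Spike-in conversion-efficiency QC
#'
#' The spike-in control is transcribed in vitro and carries no m5C, so every
#' C read at a control position is a conversion failure. The global
#' conversion rate is the aggregate `sum(n_T) / sum(n_C + n_T)` over all
#' control cytosines (an aggregate rate, not a per-cytosine minimum, which
#' would be unattainable at low per-site depth); per-cytosine rates are
#' reported alongside. Libraries below `min_conversion` fail QC and must not
#' proceed to site calling.
#'
#' @param control_pileups pileup rows (from [tally_pileup()]) restricted to
#'   the spike-in control reference.
#' @param min_conversion QC gate (default 0.98).
#' @return object of class `conversion_qc`: list with `control_id`,
#'   `global_conversion`, `n_control_cytosines` (covered), `per_site`
#'   (position, conversion), `pass`.
#' @export
qc_conversion <- function(control_pileups, min_conversion = 0.98) {
  covered <- control_pileups[control_pileups$coverage > 0, , drop = FALSE]
  if (nrow(covered) == 0L)
    stop("qc_error: no covered control cytosines; library unusable",
         call. = FALSE)
  global <- sum(covered$n_T) / sum(covered$n_C + covered$n_T)
  structure(list(
    control_id = unique(covered$reference_id),
    global_conversion = global,
    n_control_cytosines = nrow(covered),
    per_site = data.frame(position = covered$position,
                          conversion = covered$n_T /
                            (covered$n_C + covered$n_T)),
    min_conversion = min_conversion,
    pass = global >= min_conversion), class = "conversion_qc")
}

#' @export
print.conversion_qc <- function(x, ...) {
  cat(sprintf("<conversion_qc> %s: %.2f%% conversion over %d cytosines -> %s\n",
              x$control_id, 100 * x$global_conversion,
              x$n_control_cytosines, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Call candidate m5C sites by coverage and methylation thresholds
#'
#' A site is `methylated` when its coverage (C+T reads) is at least
#' `min_coverage` and its methylation fraction at least `min_methylation`
#' (both inclusive); `unmethylated` when covered but below the methylation
#' threshold; `no_call` below the coverage threshold. Called sites are
#' candidate m5C sites: other cytosine modifications can also resist
#' bisulfite conversion.
#'
#' @param pileups output of [tally_pileup()].
#' @param min_coverage minimum C+T reads (default 5).
#' @param min_methylation minimum methylation fraction (default 0.20).
#' @param qc optional [qc_conversion()] result; calling a library that
#'   failed QC is an error.
#' @return `pileups` with added `status` column and threshold attributes.
#' @export
call_sites <- function(pileups, min_coverage = 5, min_methylation = 0.20,
                       qc = NULL) {
  if (!is.null(qc) && !qc$pass)
    stop("library failed conversion QC (",
         sprintf("%.2f%%", 100 * qc$global_conversion),
         "); site calls would be invalid", call. = FALSE)
  status <- ifelse(pileups$coverage < min_coverage, "no_call",
                   ifelse(pileups$methylation >= min_methylation,
                          "methylated", "unmethylated"))
  out <- pileups
  out$status <- status
  attr(out, "min_coverage") <- min_coverage
  attr(out, "min_methylation") <- min_methylation
  out
}

#' Global cytosine abundance of aligned reads
#'
#' Fraction of C among aligned read bases over endogenous (non-spike-in)
#' references: near zero in a well-converted bisulfite library (sparse
#' methylation plus the conversion-failure channel), and equal to the
#' reference C composition for unconverted RNA-seq.
#'
#' @param alignments output of [align_reads()].
#' @param reads the aligned reads.
#' @param refs the [refset()] used.
#' @return fraction of C among aligned (weighted) bases.
#' @export
global_cytosine_abundance <- function(alignments, reads, refs) {
  cats <- attr(refs, "category")
  aln <- alignments[cats[alignments$reference_id] != "spikein", , drop = FALSE]
  if (nrow(aln) == 0L) stop("no aligned endogenous bases", call. = FALSE)
  read_seq <- setNames(toupper(reads$sequence), reads$read_id)
  # weight per aligned read copy; count each read's bases once per champion
  nc <- vapply(strsplit(read_seq[aln$read_id], "", fixed = TRUE),
               function(ch) sum(ch == "C"), numeric(1))
  sum(nc * aln$weight) / sum(nchar(read_seq[aln$read_id]) * aln$weight)
}

#' Differential methylation between two genotypes
#'
#' Compares per-site calls of a wild-type and a mutant library over the same
#' reference set. Sites without a confident call (`no_call`) in either
#' genotype are excluded. A site methylated in wild type is `lost` when the
#' mutant falls below the calling threshold, `reduced` when both are
#' methylated but the mutant fraction is lower by at least `margin`
#' (absolute), and `unchanged` otherwise.
#'
#' @param calls_wt,calls_mutant outputs of [call_sites()] on the same
#'   reference set.
#' @param margin absolute methylation decrease required for `reduced`.
#' @return data.frame of compared sites with both fractions and a `change`
#'   column (`lost`, `reduced`, `unchanged`).
#' @export
differential_sites <- function(calls_wt, calls_mutant, margin = 0.20) {
  key <- function(x) paste(x$reference_id, x$position)
  if (!setequal(unique(calls_wt$reference_id),
                unique(calls_mutant$reference_id)))
    stop("genotypes were called on different reference sets", call. = FALSE)
  m <- match(key(calls_wt), key(calls_mutant))
  wt <- calls_wt[!is.na(m), , drop = FALSE]
  mu <- calls_mutant[m[!is.na(m)], , drop = FALSE]
  keep <- wt$status == "methylated" & mu$status != "no_call"
  wt <- wt[keep, , drop = FALSE]
  mu <- mu[keep, , drop = FALSE]
  min_meth <- attr(calls_mutant, "min_methylation")
  if (is.null(min_meth)) min_meth <- 0.20
  change <- ifelse(mu$methylation < min_meth, "lost",
                   ifelse(wt$methylation - mu$methylation >= margin,
                          "reduced", "unchanged"))
  data.frame(reference_id = wt$reference_id, position = wt$position,
             methylation_wt = wt$methylation,
             methylation_mutant = mu$methylation,
             change = change, stringsAsFactors = FALSE)
}

#' Heatmap matrix of percent methylation across samples
#'
#' Long-to-wide helper mirroring per-sample methylation heatmaps: rows are
#' sites, columns samples, cells percent methylation (0-100), `NA` where the
#' sample had no call (rendered white/blank downstream).
#'
#' @param calls_list named list of [call_sites()] outputs (one per sample).
#' @return matrix with `reference_id:position` rownames.
#' @export
methylation_matrix <- function(calls_list) {
  stopifnot(length(calls_list) >= 1, !is.null(names(calls_list)))
  keys <- sort(unique(unlist(lapply(calls_list, function(x)
    paste(x$reference_id, x$position, sep = ":")))))
  out <- matrix(NA_real_, nrow = length(keys), ncol = length(calls_list),
                dimnames = list(keys, names(calls_list)))
  for (s in names(calls_list)) {
    x <- calls_list[[s]]
    k <- paste(x$reference_id, x$position, sep = ":")
    ok <- x$status != "no_call"
    out[k[ok], s] <- 100 * x$methylation[ok]
  }
  out
}
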