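# In-silico methyl-chop PCR: bisulfite conversion of a template with a
# chosen methylation state, PCR amplicon extraction with primer-base
# incorporation (including deliberate dCAPS mismatches), and restriction
# digest prediction. Methylation of a cytosine inside (or, via a dCAPS
# primer, adjacent to) a recognition site decides whether the site survives
# conversion, so cut vs uncut bands report the site's methylation state.

#' Restriction enzyme definition
#'
#' @param name enzyme name.
#' @param recognition recognition sequence over the IUPAC alphabet.
#' @param cut_offset bases after which the cut falls, counted from the start
#'   of the recognition site on the top strand (0..length(recognition)).
#' @return object of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGTRYSWKMBDHVN]", recognition))
    stop("recognition must be an IUPAC string", call. = FALSE)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

#' Built-in methyl-chop enzymes
#'
#' `HpyCH4IV` recognises `A^CGT` and `HinfI` recognises `G^ANTC`
#' (`^` marks the cut).
#'
#' @param name `"HpyCH4IV"` or `"HinfI"`.
#' @return an [enzyme()].
#' @export
chop_enzyme <- function(name = c("HpyCH4IV", "HinfI")) {
  name <- match.arg(name)
  switch(name,
         HpyCH4IV = enzyme("HpyCH4IV", "ACGT", 1L),
         HinfI = enzyme("HinfI", "GANTC", 1L))
}

#' Read an enzyme table (name, recognition, cut_offset) from TSV
#' @param path TSV path.
#' @return list of [enzyme()] objects named by enzyme name.
#' @export
read_enzyme_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- Map(enzyme, tab$name, tab$recognition, tab$cut_offset)
  setNames(out, tab$name)
}

#' Bisulfite-convert a template with a given methylation state
#'
#' Every unmethylated cytosine becomes thymine; methylated cytosines are
#' protected and retained. With every C methylated this is the identity;
#' with none methylated it equals full in-silico conversion.
#'
#' @param sequence DNA template.
#' @param methylated_positions 1-based positions of methylated cytosines
#'   (must all be C in `sequence`).
#' @return converted DNA string.
#' @export
bs_convert_template <- function(sequence, methylated_positions = integer(0)) {
  sequence <- check_dna(sequence, what = "template")
  ch <- seq_chars(sequence)
  mp <- as.integer(methylated_positions)
  if (length(mp) && any(mp < 1 | mp > length(ch) | ch[mp] != "C"))
    stop("methylated position is not a cytosine of the template",
         call. = FALSE)
  conv <- which(ch == "C")
  conv <- setdiff(conv, mp)
  ch[conv] <- "T"
  paste(ch, collapse = "")
}

#' PCR primer (optionally dCAPS)
#'
#' @param sequence primer sequence, 5'->3'.
#' @param name primer name.
#' @return object of class `pcr_primer`.
#' @export
pcr_primer <- function(sequence, name = "primer") {
  structure(list(sequence = check_dna(sequence, allow_n = FALSE,
                                      what = "primer"),
                 name = name), class = "pcr_primer")
}

#' Derive a dCAPS primer from a perfectly matching one
#'
#' A dCAPS primer carries a deliberate mismatch near its 3' end so that PCR
#' incorporation of the mismatched base creates a restriction site only for
#' one conversion outcome of the adjacent target cytosine.
#'
#' @param matching_sequence primer sequence matching the template.
#' @param mismatch_from_3prime position of the mismatch counted from the 3'
#'   end (the 3'-terminal base is position 1).
#' @param base the base to substitute.
#' @param name primer name.
#' @return a [pcr_primer()] with a `mismatch_from_3prime` field.
#' @export
dcaps_primer <- function(matching_sequence, mismatch_from_3prime, base,
                         name = "dCAPS") {
  matching_sequence <- check_dna(matching_sequence, allow_n = FALSE,
                                 what = "primer")
  L <- nchar(matching_sequence)
  if (mismatch_from_3prime < 1 || mismatch_from_3prime > L)
    stop("mismatch position outside primer", call. = FALSE)
  if (mismatch_from_3prime <= 2)
    stop("dCAPS mismatch must not fall in the 3'-terminal 2 bases",
         call. = FALSE)
  pos <- L - mismatch_from_3prime + 1L
  ch <- seq_chars(matching_sequence)
  if (ch[pos] == base)
    stop("substituted base equals the template base; not a mismatch",
         call. = FALSE)
  ch[pos] <- toupper(base)
  p <- pcr_primer(paste(ch, collapse = ""), name = name)
  p$mismatch_from_3prime <- as.integer(mismatch_from_3prime)
  p
}

# all annealing starts of a primer (given in template-strand orientation)
# on the template: <= max_mismatch mismatches, none in the positions given
# by `clamp_idx` (indices within the oriented primer that correspond to its
# 3'-terminal 2 bases).
anneal_sites <- function(oriented, template, max_mismatch, clamp_idx) {
  lp <- nchar(oriented)
  lt <- nchar(template)
  if (lp > lt) return(integer(0))
  pc <- seq_chars(oriented)
  tc <- seq_chars(template)
  starts <- integer(0)
  for (s in seq_len(lt - lp + 1L)) {
    mm <- which(pc != tc[s:(s + lp - 1L)])
    if (length(mm) <= max_mismatch && !any(mm %in% clamp_idx))
      starts <- c(starts, s)
  }
  starts
}

#' Build a PCR amplicon from a (converted) template and two primers
#'
#' The forward primer anneals to the template strand as written; the
#' reverse primer anneals as its reverse complement. Each primer may carry
#' up to `max_mismatch` mismatches, but none in its 3'-terminal 2 bases
#' (polymerase extension requires a matched 3' end). Primer bases --
#' including deliberate dCAPS mismatches -- overwrite the template within
#' the primer footprints, reproducing PCR incorporation of mismatches.
#'
#' @param template the (bisulfite-converted) template, sense strand.
#' @param fwd_primer,rev_primer [pcr_primer()] objects (reverse primer given
#'   5'->3' on the opposite strand, as synthesised).
#' @param max_mismatch annealing mismatch tolerance per primer (default 2).
#' @return the amplicon sequence (top strand).
#' @export
build_amplicon <- function(template, fwd_primer, rev_primer,
                           max_mismatch = 2) {
  template <- check_dna(template, what = "template")
  stopifnot(inherits(fwd_primer, "pcr_primer"),
            inherits(rev_primer, "pcr_primer"))
  lf <- nchar(fwd_primer$sequence)
  lr <- nchar(rev_primer$sequence)
  # fwd primer: 3' end is its last base; rev primer (revcomp'd onto the top
  # strand): 3' end corresponds to the first bases of its footprint
  f_sites <- anneal_sites(fwd_primer$sequence, template, max_mismatch,
                          clamp_idx = c(lf - 1L, lf))
  r_oriented <- revcomp(rev_primer$sequence)
  r_sites <- anneal_sites(r_oriented, template, max_mismatch,
                          clamp_idx = c(1L, 2L))
  for (nm in list(list(fwd_primer$name, f_sites),
                  list(rev_primer$name, r_sites))) {
    if (length(nm[[2]]) == 0L)
      stop("primer ", nm[[1]], " fails to anneal", call. = FALSE)
    if (length(nm[[2]]) > 1L)
      stop("primer ", nm[[1]], " anneals at multiple sites: ",
           paste(nm[[2]], collapse = ", "), call. = FALSE)
  }
  fs <- f_sites[1]
  re <- r_sites[1] + lr - 1L
  if (re <= fs + lf - 1L)
    stop("primer footprints do not define a forward amplicon", call. = FALSE)
  amp <- seq_chars(substr(template, fs, re))
  amp[seq_len(lf)] <- seq_chars(fwd_primer$sequence)
  amp[seq(length(amp) - lr + 1L, length(amp))] <- seq_chars(r_oriented)
  paste(amp, collapse = "")
}

#' Predict the restriction digest of an amplicon
#'
#' Finds all matches of the enzyme's IUPAC recognition sequence on the top
#' strand and (for non-palindromic recognition) of its reverse complement,
#' cuts after `cut_offset` bases of each top-strand match (and the mirrored
#' offset for bottom-strand matches), and returns the fragment pattern.
#'
#' @param amplicon amplicon sequence (double-stranded PCR product; top
#'   strand given).
#' @param enz an [enzyme()].
#' @return object of class `digest_prediction`: list with
#'   `amplicon_length`, `cut_positions` (cut after these top-strand
#'   positions), `fragment_lengths` (ascending; sums to the amplicon
#'   length), `digested`.
#' @export
digest <- function(amplicon, enz) {
  amplicon <- check_dna(amplicon, what = "amplicon")
  stopifnot(inherits(enz, "enzyme"))
  subject <- Biostrings::DNAString(amplicon)
  pat <- Biostrings::DNAString(enz$recognition)
  top <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  cuts <- IRanges::start(top) + enz$cut_offset - 1L
  rc <- Biostrings::reverseComplement(pat)
  if (as.character(rc) != as.character(pat)) {
    bottom <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
    cuts <- c(cuts, IRanges::end(bottom) - enz$cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts >= 1 & cuts < nchar(amplicon)]
  frags <- diff(c(0L, cuts, nchar(amplicon)))
  structure(list(amplicon_length = nchar(amplicon),
                 enzyme = enz$name,
                 cut_positions = cuts,
                 fragment_lengths = sort(frags),
                 digested = length(cuts) > 0L),
            class = "digest_prediction")
}

#' @export
print.digest_prediction <- function(x, ...) {
  cat(sprintf("<digest_prediction> %s on %d bp: %s\n", x$enzyme,
              x$amplicon_length,
              if (x$digested)
                paste0("fragments ", paste(x$fragment_lengths, collapse = " + "))
              else "undigested"))
  invisible(x)
}

#' Predict methyl-chop band patterns for both methylation states of a site
#'
#' Runs the full in-silico assay twice -- once with the target cytosine
#' methylated (protected from conversion) and once unmethylated (converted
#' to T) -- and reports both digest patterns plus whether the assay is
#' informative (the patterns differ).
#'
#' @param template unconverted template sequence containing the site.
#' @param site_position 1-based position of the assayed cytosine.
#' @param enz an [enzyme()].
#' @param fwd_primer,rev_primer [pcr_primer()] objects.
#' @param other_methylated additional positions treated as methylated in
#'   both states (default none).
#' @return object of class `assay_report`: list with `site_position`,
#'   `methylated` and `unmethylated` [digest()] predictions, and
#'   `informative`.
#' @export
assay_report <- function(template, site_position, enz, fwd_primer,
                         rev_primer, other_methylated = integer(0)) {
  template <- check_dna(template, what = "template")
  if (substr(template, site_position, site_position) != "C")
    stop("assayed site is not a cytosine", call. = FALSE)
  states <- list(
    methylated = bs_convert_template(
      template, c(site_position, other_methylated)),
    unmethylated = bs_convert_template(template, other_methylated))
  preds <- lapply(states, function(conv) {
    amp_start <- anneal_sites(fwd_primer$sequence, conv, 2,
                              clamp_idx = c(nchar(fwd_primer$sequence) - 1L,
                                            nchar(fwd_primer$sequence)))
    amp <- build_amplicon(conv, fwd_primer, rev_primer)
    if (length(amp_start) == 1L) {
      span <- c(amp_start, amp_start + nchar(amp) - 1L)
      if (site_position < span[1] || site_position > span[2])
        stop("assayed site lies outside the amplicon", call. = FALSE)
    }
    digest(amp, enz)
  })
  structure(list(site_position = site_position,
                 enzyme = enz$name,
                 methylated = preds$methylated,
                 unmethylated = preds$unmethylated,
                 informative = !identical(
                   preds$methylated$fragment_lengths,
                   preds$unmethylated$fragment_lengths)),
            class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  cat(sprintf("<assay_report> %s at position %d (%s)\n", x$enzyme,
              x$site_position,
              if (x$informative) "informative" else "uninformative"))
  cat("  methylated:   "); print(x$methylated)
  cat("  unmethylated: "); print(x$unmethylated)
  invisible(x)
}

#' ASCII virtual gel of one or more digest predictions
#'
#' @param predictions named list of [digest()] results (lane names).
#' @param width character width of the gel.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
virtual_gel <- function(predictions, width = 40) {
  maxlen <- max(vapply(predictions, `[[`, integer(1), "amplicon_length"))
  lines <- c(sprintf("%-12s %s", "bp", paste(rep("-", width), collapse = "")))
  for (lane in names(predictions)) {
    frags <- predictions[[lane]]$fragment_lengths
    row <- rep(" ", width)
    pos <- pmax(1L, pmin(width, round(width * frags / maxlen)))
    row[pos] <- "#"
    lines <- c(lines, sprintf("%-12s %s  (%s)", lane,
                              paste(row, collapse = ""),
                              paste(sort(frags, decreasing = TRUE),
                                    collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
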