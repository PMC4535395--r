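# Three-letter (bisulfite-aware) read alignment. Reads are C->T collapsed
# before matching so that an unconverted (methylated) C in a read matches
# the T at the reference's original-C position; original read bases are kept
# alongside for methylation tallying. Alignment is ungapped: the references
# are short structural RNAs and the analysis is substitution-based, so
# indel-containing reads are treated as unalignable.

#' Align one read against a converted reference set
#'
#' The read is C->T converted for matching only and scanned ungapped over
#' every offset of every converted reference. The minimal-mismatch
#' alignment(s) are returned: ties across references yield all cochampions
#' with `ambiguous = TRUE`; ties within one reference at different offsets
#' keep the leftmost offset. Reads shorter than 20 nt are rejected.
#'
#' @param read DNA sequence of the read (original bases, not pre-converted).
#' @param refs a [refset()].
#' @param max_mismatch maximum allowed mismatches in three-letter space
#'   (default 2).
#' @return data.frame of alignments (zero rows when nothing aligns): columns
#'   `read_id`, `reference_id`, `start`, `mismatches`, `n_cochampions`,
#'   `ambiguous`, `weight`.
#' @export
align_read <- function(read, refs, max_mismatch = 2) {
  read <- check_dna(read, what = "read")
  if (nchar(read) < 20)
    stop("reads shorter than 20 nt are rejected", call. = FALSE)
  align_reads(data.frame(read_id = "read", sequence = read,
                         stringsAsFactors = FALSE),
              refs, max_mismatch = max_mismatch)
}

#' Align a batch of bisulfite-converted reads
#'
#' @param reads data.frame with columns `read_id`, `sequence` (original read
#'   bases). Reads shorter than 20 nt are dropped (they count as unaligned).
#' @param refs a [refset()] of converted references.
#' @param max_mismatch maximum mismatches in three-letter space.
#' @param convert_reads collapse read Cs to T before matching (`TRUE` for
#'   bisulfite libraries; set `FALSE` to align unconverted RNA-seq reads
#'   against the original reference sequences).
#' @return data.frame of champion alignments, one row per (read,
#'   cochampion reference); `weight = 1 / n_cochampions` so multimapped
#'   reads contribute fractionally and total counts are conserved.
#'   Cochampions are ordered by lexicographic `reference_id`, making output
#'   independent of reference input order.
#' @export
align_reads <- function(reads, refs, max_mismatch = 2,
                        convert_reads = TRUE) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (!inherits(refs, "refset") || length(refs) == 0L)
    stop("refs must be a non-empty refset", call. = FALSE)
  keep <- nchar(reads$sequence) >= 20
  reads <- reads[keep, , drop = FALSE]
  empty <- data.frame(read_id = character(), reference_id = character(),
                      start = integer(), mismatches = integer(),
                      n_cochampions = integer(), ambiguous = logical(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  # lexicographic reference order fixes cochampion ordering deterministically
  ref_ids <- sort(names(refs))
  ref_seq <- if (convert_reads)
    vapply(refs[ref_ids], function(r) r$converted_sequence, character(1))
  else
    vapply(refs[ref_ids], function(r) r$source_sequence, character(1))
  query <- toupper(reads$sequence)
  if (convert_reads) query <- gsub("C", "T", query, fixed = TRUE)
  hits <- cpp_scan_align(query, unname(ref_seq), as.integer(max_mismatch))
  if (nrow(hits) == 0L) return(empty)
  ncoh <- table(hits$read_idx)
  n_cochampions <- as.integer(ncoh[as.character(hits$read_idx)])
  data.frame(read_id = reads$read_id[hits$read_idx],
             reference_id = ref_ids[hits$ref_idx],
             start = hits$start,
             mismatches = hits$mismatches,
             n_cochampions = n_cochampions,
             ambiguous = n_cochampions >= 2L,
             weight = 1 / n_cochampions,
             stringsAsFactors = FALSE)
}

# Align unconverted (RNA-seq) reads against a single plain sequence;
# convenience used by species rRNA consensus derivation.
align_plain_reads <- function(reads, id, sequence, max_mismatch = 6) {
  refs <- refset(id, sequence, category = "rRNA")
  align_reads(reads, refs, max_mismatch = max_mismatch,
              convert_reads = FALSE)
}

#' Per-category mapping rates
#'
#' Fraction of reads aligned per reference category (tRNA / rRNA / spike-in)
#' plus the unaligned remainder; the four fractions sum to 1. A read whose
#' cochampions span several categories contributes fractionally to each.
#'
#' @param alignments output of [align_reads()].
#' @param total_reads total number of reads in the library (aligned or not).
#' @param refs the [refset()] used for alignment.
#' @return named numeric vector: `tRNA`, `rRNA`, `spikein`, `unaligned`.
#' @export
classify_alignment_rate <- function(alignments, total_reads, refs) {
  stopifnot(total_reads > 0)
  cats <- attr(refs, "category")
  out <- c(tRNA = 0, rRNA = 0, spikein = 0)
  if (nrow(alignments)) {
    w <- tapply(alignments$weight,
                cats[alignments$reference_id],
                sum)
    out[names(w)] <- w / total_reads
  }
  c(out, unaligned = 1 - sum(out))
}

#' Write alignments as SAM
#'
#' One record per champion alignment; ambiguity is carried in tags
#' (`NH:i` = number of cochampions, `NM:i` = three-letter mismatches,
#' `XA:i:1` flags ambiguous placements). Sequences are the original read
#' bases so methylation can be re-tallied from the SAM.
#'
#' @param alignments output of [align_reads()].
#' @param reads the reads data.frame that was aligned.
#' @param refs the [refset()] used.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, refs, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              vapply(names(refs), function(id)
                sprintf("@SQ\tSN:%s\tLN:%d", id,
                        nchar(refs[[id]]$source_sequence)), character(1)),
              "@PG\tID:rbsmeth\tPN:rbsmeth")
  seqs <- setNames(reads$sequence, reads$read_id)
  quals <- if (!is.null(reads$quality)) setNames(reads$quality, reads$read_id)
           else setNames(strrep("I", nchar(reads$sequence)), reads$read_id)
  body <- character(nrow(alignments))
  if (nrow(alignments)) {
    body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tNH:i:%d\tXA:i:%d",
                    alignments$read_id, alignments$reference_id,
                    alignments$start,
                    nchar(seqs[alignments$read_id]),
                    seqs[alignments$read_id], quals[alignments$read_id],
                    alignments$mismatches, alignments$n_cochampions,
                    as.integer(alignments$ambiguous))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
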