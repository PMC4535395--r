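# Small sequence helpers shared across modules. Sequences are plain
# uppercase character strings over {A,C,G,T,N} (DNA alphabet; references are
# stored as DNA, T not U), coordinates 1-based inclusive on the sense strand.

DNA_BASES <- c("A", "C", "G", "T")

#' Validate a DNA sequence string
#'
#' @param x character scalar.
#' @param allow_n allow N bases?
#' @param what name used in error messages.
#' @return `x`, uppercased, invisibly usable.
#' @keywords internal
check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x))
    stop(sprintf("invalid_alphabet: %s contains characters outside {%s}",
                 what, paste(strsplit(alphabet, "")[[1]], collapse = ",")),
         call. = FALSE)
  x
}

#' @keywords internal
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string (IUPAC-aware)
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' 1-based positions of cytosines in a sequence (N never counts as C)
#' @keywords internal
c_positions_of <- function(sequence) {
  which(seq_chars(sequence) == "C")
}

# IUPAC code for a set of observed bases (used for consensus ties).
IUPAC_FROM_BASES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' @keywords internal
iupac_code <- function(bases) {
  bases <- sort(unique(bases[bases %in% DNA_BASES]))
  if (length(bases) == 0L) return("N")
  unname(IUPAC_FROM_BASES[paste(bases, collapse = "")])
}

#' Global pairwise identity of two equal-length or unequal sequences
#'
#' Needleman-Wunsch identity: matches / alignment length, using
#' [Biostrings::pairwiseAlignment()].
#' @keywords internal
global_identity <- function(a, b) {
  if (a == b) return(1)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  al1 <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  al2 <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  sum(al1 == al2) / length(al1)
}

#' Generate a random DNA sequence
#'
#' @param length sequence length in nt.
#' @param gc_fraction target GC content; C and G each get half of it.
#' @return character scalar.
#' @export
random_dna <- function(length, gc_fraction = 0.5) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = probs),
        collapse = "")
}
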