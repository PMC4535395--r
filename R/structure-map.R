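# Mapping sequence coordinates onto shared structural coordinate systems:
# the 72-position representative tRNA cloverleaf (anticodon fixed at 34-36)
# and anchor-based rRNA numbering via global pairwise alignment.

#' Map a tRNA sequence onto the 72-position representative structure
#'
#' tRNAs differ in length, so sites are compared across molecules on a
#' canonical 72-position coordinate system (classical numbering: acceptor
#' stem 1-7/66-72, anticodon 34-36, variable region after 45, T-arm 49-65).
#' The anticodon triplet is the anchor and always receives labels 34-36.
#' Upstream bases count back from label 33 (a shorter D-arm skips the
#' 5'-most labels; extra 5' bases are unmapped). Downstream of the
#' anticodon, the 24 acceptor-proximal bases take labels 49-72, the bases
#' immediately after the anticodon take labels 37 upward, and any overflow
#' between the two blocks (a long variable loop) is unmapped; a short
#' variable region skips the highest variable-region labels. Mapped labels
#' strictly increase along the sequence.
#'
#' When the anticodon occurs more than once, the occurrence whose placement
#' best fits the canonical architecture (33 nt upstream, 36 nt downstream)
#' wins; an exact tie is an error, never a silent choice.
#'
#' @param sequence mature tRNA sequence, 60-100 nt.
#' @param anticodon the 3-nt anticodon.
#' @return object of class `structural_map`: list with `mapping` (data.frame
#'   `seq_index`, `structural_position`) and `unmapped` (integer vector of
#'   sequence indices).
#' @export
assign_trna_structure <- function(sequence, anticodon) {
  sequence <- check_dna(sequence, what = "tRNA sequence")
  anticodon <- check_dna(anticodon, allow_n = FALSE, what = "anticodon")
  stopifnot(nchar(anticodon) == 3)
  if (nchar(sequence) < 60 || nchar(sequence) > 100)
    stop("tRNA sequence must be 60-100 nt", call. = FALSE)
  occ <- gregexpr(anticodon, sequence, fixed = TRUE)[[1]]
  if (occ[1] == -1L)
    stop("anticodon ", anticodon, " not found in sequence", call. = FALSE)
  occ <- as.integer(occ)
  if (length(occ) > 1L) {
    # architecture fit: distance from the canonical 33-nt upstream /
    # 36-nt downstream layout
    score <- abs((occ - 1L) - 33L) +
      abs((nchar(sequence) - (occ + 2L)) - 36L)
    best <- which(score == min(score))
    if (length(best) > 1L)
      stop("anticodon placement ambiguous: candidate starts at ",
           paste(occ[best], collapse = ", "), call. = FALSE)
    occ <- occ[best]
  }
  L <- nchar(sequence)
  u <- occ - 1L                  # upstream length
  d <- L - (occ + 2L)            # downstream length
  seq_index <- integer(0)
  label <- integer(0)
  unmapped <- integer(0)

  # upstream: last min(u, 33) bases take labels counting back from 33
  if (u > 33L) unmapped <- c(unmapped, seq_len(u - 33L))
  n_up <- min(u, 33L)
  if (n_up > 0L) {
    seq_index <- c(seq_index, seq(u - n_up + 1L, u))
    label <- c(label, seq(33L - n_up + 1L, 33L))
  }
  # anticodon -> 34-36
  seq_index <- c(seq_index, occ, occ + 1L, occ + 2L)
  label <- c(label, 34L, 35L, 36L)
  # downstream: acceptor-proximal 24 bases -> 49-72; leading bases -> 37+;
  # overflow between the blocks (variable loop) unmapped
  if (d > 0L) {
    first_ds <- occ + 3L
    n_tail <- min(d, 24L)
    tail_idx <- seq(L - n_tail + 1L, L)
    tail_lab <- seq(73L - n_tail, 72L)
    n_head <- max(0L, min(d - n_tail, 12L))
    if (n_head > 0L) {
      seq_index <- c(seq_index, seq(first_ds, length.out = n_head))
      label <- c(label, seq(37L, length.out = n_head))
    }
    overflow <- d - n_tail - n_head
    if (overflow > 0L)
      unmapped <- c(unmapped, seq(first_ds + n_head, length.out = overflow))
    seq_index <- c(seq_index, tail_idx)
    label <- c(label, tail_lab)
  }
  structure(list(mapping = data.frame(seq_index = seq_index,
                                      structural_position = label),
                 unmapped = sort(unmapped)),
            class = "structural_map")
}

#' @export
print.structural_map <- function(x, ...) {
  cat(sprintf("<structural_map> %d mapped, %d unmapped positions\n",
              nrow(x$mapping), length(x$unmapped)))
  invisible(x)
}

#' Structural label of a sequence position
#' @param map a [assign_trna_structure()] result.
#' @param seq_index 1-based sequence position(s).
#' @return structural label(s); `NA` for unmapped positions.
#' @export
structural_label <- function(map, seq_index) {
  map$mapping$structural_position[match(seq_index, map$mapping$seq_index)]
}

#' Lift positions of a species rRNA onto an anchor rRNA coordinate system
#'
#' Cross-species rRNA sites are numbered on the corresponding anchor
#' (Arabidopsis) reference. The species sequence is globally aligned to the
#' anchor (match +1, mismatch -1, gap open -5, gap extend -1); species
#' positions in match/mismatch columns map to the aligned anchor position,
#' gap columns are unmappable. The resulting map is strictly monotonic.
#'
#' @param species_seq,anchor_seq DNA sequences.
#' @return object of class `coordinate_lift`: list with `map` (data.frame
#'   `species_pos`, `anchor_pos`), `unmappable` (species positions in gap
#'   columns), `identity` (alignment identity), `low_identity` (flag,
#'   identity < 0.5 — the anchor may be the wrong subunit).
#' @export
lift_rrna_position <- function(species_seq, anchor_seq) {
  species_seq <- check_dna(species_seq, what = "species sequence")
  anchor_seq <- check_dna(anchor_seq, what = "anchor sequence")
  if (species_seq == anchor_seq) {
    n <- nchar(species_seq)
    return(structure(list(map = data.frame(species_pos = seq_len(n),
                                           anchor_pos = seq_len(n)),
                          unmappable = integer(0),
                          identity = 1, low_identity = FALSE),
                     class = "coordinate_lift"))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(species_seq), Biostrings::DNAString(anchor_seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  a_sp <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  a_an <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  sp_pos <- cumsum(a_sp != "-")
  an_pos <- cumsum(a_an != "-")
  match_col <- a_sp != "-" & a_an != "-"
  map <- data.frame(species_pos = sp_pos[match_col],
                    anchor_pos = an_pos[match_col])
  ident <- sum(a_sp == a_an & match_col) / length(a_sp)
  structure(list(map = map,
                 unmappable = setdiff(seq_len(nchar(species_seq)),
                                      map$species_pos),
                 identity = ident,
                 low_identity = ident < 0.5),
            class = "coordinate_lift")
}

#' Anchor position of a species rRNA position
#' @param lift a [lift_rrna_position()] result.
#' @param species_pos position(s) on the species sequence.
#' @return anchor position(s); `NA` when unmappable.
#' @export
lift_position <- function(lift, species_pos) {
  lift$map$anchor_pos[match(species_pos, lift$map$species_pos)]
}

#' @export
print.coordinate_lift <- function(x, ...) {
  cat(sprintf("<coordinate_lift> %d mapped, %d unmappable (identity %.1f%%%s)\n",
              nrow(x$map), length(x$unmappable), 100 * x$identity,
              if (x$low_identity) ", LOW" else ""))
  invisible(x)
}
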