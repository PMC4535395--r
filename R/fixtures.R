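# Bundled synthetic example sequences. These are constructed stand-ins with
# the documented architecture of the corresponding Arabidopsis molecules
# (they are NOT the database sequences): a 72-nt tRNA-Asp(GTC)-like
# consensus whose C38 sits inside an HpyCH4IV site, and a nuclear LSU
# 25S-like rRNA whose C2268 supports a HinfI dCAPS assay. They drive the
# worked examples, tests and the in-silico chop-assay validation.

#' Synthetic tRNA-Asp(GTC)-like consensus
#'
#' 72 nt with the canonical cloverleaf layout: anticodon GTC at positions
#' 34-36, an HpyCH4IV recognition site (ACGT) spanning 37-40 so that C38 is
#' the methylation-sensitive cytosine, and further cytosines at structural
#' positions 48, 49, 50 and 72. Synthetic: built to this architecture, not
#' taken from a database.
#'
#' @return list with `consensus_id`, `sequence`, `anticodon`,
#'   `methylated_positions` (the five structural m5C positions as sequence
#'   indices, which coincide here because the molecule matches the
#'   72-position representative structure exactly).
#' @export
synthetic_asp_trna <- function() {
  sequence <- paste0(
    "GGAGCGGTAGTTCAGTCGGTTAGAATACCTGCC",  # 1-33 (acceptor stem + D-arm)
    "GTC",                                # 34-36 anticodon
    "ACGT",                               # 37-40: C38 inside A^CGT
    "GGTTACACCCGGTTCGATTCCCGGTAGGGAGC")   # 41-72 (variable region + T-arm)
  list(consensus_id = "Asp-GTC", sequence = sequence, anticodon = "GTC",
       methylated_positions = c(38L, 48L, 49L, 50L, 72L))
}

#' Primers for the synthetic tRNA-Asp(GTC) methyl-chop assay
#'
#' Both primers match the bisulfite-converted template exactly (their
#' footprints contain no methylation-sensitive base), so the 72 bp product
#' covers the whole molecule and the HpyCH4IV site at C38 is the only
#' methylation-dependent cut.
#'
#' @return list with `fwd` and `rev` [pcr_primer()] objects.
#' @export
asp_chop_primers <- function() {
  conv <- gsub("C", "T", synthetic_asp_trna()$sequence, fixed = TRUE)
  list(fwd = pcr_primer(substr(conv, 1, 20), "AspF"),
       rev = pcr_primer(revcomp(substr(conv, 53, 72)), "AspR"))
}

#' Synthetic nuclear LSU 25S-like rRNA with a C2268 dCAPS site
#'
#' A deterministic 2400-nt synthetic sequence carrying a cytosine at
#' position 2268 embedded so that a forward dCAPS primer with a G mismatch
#' at position four from its 3' end creates a HinfI site (GANTC) in the
#' 155 bp PCR product only when C2268 is methylated (i.e. survives
#' bisulfite conversion as C). The amplicon spans positions 2236-2390.
#'
#' @return list with `rrna_id`, `sequence`, `site` (2268), `amplicon_span`.
#' @export
synthetic_lsu_rrna <- function() {
  sequence <- withr_seed(20150814L, random_dna(2400, 0.5))
  ch <- seq_chars(sequence)
  # designed dCAPS context: primer G mismatch lands on 2264; GANTC then
  # reads G(primer) A(2265) N(2266) T(2267) C(2268, only when methylated)
  ch[2264:2268] <- c("A", "A", "T", "T", "C")
  list(rrna_id = "nuclear-25S", sequence = paste(ch, collapse = ""),
       site = 2268L, amplicon_span = c(2236L, 2390L))
}

#' Primers for the synthetic 25S C2268 dCAPS assay
#'
#' The forward primer matches the converted template over positions
#' 2236-2267 except for a deliberate G at position four from the 3' end
#' (dCAPS mismatch); the reverse primer matches positions 2366-2390 (25 nt:
#' bisulfite-converted templates are effectively three-letter sequences, so
#' primers run long to stay unique). With
#' the mismatch the HinfI cut falls 29 bp into the 155 bp product
#' (fragments 29 + 126) when C2268 is methylated; without it the assay is
#' uninformative.
#'
#' @param dcaps include the G mismatch (default `TRUE`).
#' @return list with `fwd` and `rev` [pcr_primer()] objects.
#' @export
lsu_dcaps_primers <- function(dcaps = TRUE) {
  ref <- synthetic_lsu_rrna()
  conv <- gsub("C", "T", ref$sequence, fixed = TRUE)
  fwd_match <- substr(conv, 2236, 2267)
  fwd <- if (dcaps) dcaps_primer(fwd_match, 4, "G", "25S_F_dCAPS")
         else pcr_primer(fwd_match, "25S_F")
  list(fwd = fwd,
       rev = pcr_primer(revcomp(substr(conv, 2366, 2390)), "25S_R"))
}

#' Synthetic six-species tRNA panel with known conservation classes
#'
#' Six species share the [synthetic_asp_trna()] molecule; one species
#' ("Ct") carries a C-to-G transversion at structural position 50. The
#' methylation map embeds one site per conservation class: position 38
#' methylated in all six species (class 1), position 50 methylated in the
#' five species that retain the cytosine (class 2, SNP in the sixth), and
#' position 48 methylated in two species with the cytosine present but
#' unmethylated in the rest (class 3).
#'
#' @return list: per species (`At`, `Br`, `Td`, `No`, `Ct`, `Gb`) a list
#'   with `sequence`, `anticodon` and `methylation` (data.frame `id`,
#'   `position`, `fraction`), plus `expected_classes` (named by structural
#'   position).
#' @export
synthetic_species_panel <- function() {
  base <- synthetic_asp_trna()
  species <- c("At", "Br", "Td", "No", "Ct", "Gb")
  make_species <- function(sp) {
    seq <- base$sequence
    if (sp == "Ct") substr(seq, 50, 50) <- "G"
    meth <- data.frame(id = base$consensus_id,
                       position = c(38L, 50L, 48L),
                       fraction = c(0.90,
                                    if (sp == "Ct") NA else 0.85,
                                    switch(sp, Td = 0.35, Gb = 0.25, 0.0)),
                       stringsAsFactors = FALSE)
    meth <- meth[!is.na(meth$fraction) & meth$fraction > 0, , drop = FALSE]
    list(sequence = seq, anticodon = base$anticodon, methylation = meth)
  }
  panel <- setNames(lapply(species, make_species), species)
  panel$expected_classes <- c("38" = "class1", "50" = "class2",
                              "48" = "class3")
  panel
}
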