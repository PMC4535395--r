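# Reference construction: tRNA isodecoder consensus collapsing, rRNA
# reference sets, and in-silico bisulfite (C->T) conversion.

#' Construct a tRNA gene record table
#'
#' Plant genomes carry several hundred predicted tRNA genes across the
#' nuclear, chloroplast and mitochondrial genomes, often with many identical
#' or near-identical copies per isodecoder. This constructor validates the
#' per-gene inputs to consensus collapsing.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param genome one of `"nuclear"`, `"chloroplast"`, `"mitochondrial"` per gene.
#' @param aa amino-acid code (1- or 3-letter) per gene.
#' @param anticodon 3-nt anticodon over A/C/G/T, or `"XXX"` when undetermined.
#' @param sequence mature tRNA sequence, 5'->3', DNA alphabet, 60-100 nt.
#' @return data.frame with class `trna_genes`.
#' @export
trna_genes <- function(gene_id, genome, aa, anticodon, sequence) {
  n <- length(gene_id)
  stopifnot(length(sequence) == n)
  if (anyDuplicated(gene_id))
    stop("gene_id values must be unique", call. = FALSE)
  if (n == 0L) {
    out <- data.frame(gene_id = character(), genome = character(),
                      aa = character(), anticodon = character(),
                      sequence = character(), stringsAsFactors = FALSE)
    class(out) <- c("trna_genes", "data.frame")
    return(out)
  }
  genome <- rep_len(tolower(genome), n)
  if (!all(genome %in% GENOMES))
    stop("genome must be one of: ", paste(GENOMES, collapse = ", "),
         call. = FALSE)
  aa <- rep_len(as.character(aa), n)
  anticodon <- rep_len(toupper(anticodon), n)
  bad_ac <- nchar(anticodon) != 3L |
    (!grepl("^[ACGT]{3}$", anticodon) & anticodon != "XXX")
  if (any(bad_ac))
    stop("anticodon must be 3 nt over {A,C,G,T} or 'XXX': ",
         paste(gene_id[bad_ac], collapse = ", "), call. = FALSE)
  sequence <- vapply(seq_along(sequence), function(i)
    check_dna(sequence[i], what = paste0("sequence of ", gene_id[i])),
    character(1))
  out <- data.frame(gene_id = as.character(gene_id), genome = genome,
                    aa = aa, anticodon = anticodon,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("trna_genes", "data.frame")
  out
}

GENOMES <- c("nuclear", "chloroplast", "mitochondrial")

#' Read tRNA genes from FASTA plus a sidecar metadata TSV
#'
#' The TSV (columns `gene_id`, `genome`, `aa`, `anticodon`) carries the
#' genome of origin and isodecoder identity, avoiding FASTA-header dialect
#' dependence. FASTA names must match `gene_id`.
#'
#' @param fasta path to a FASTA of mature tRNA gene sequences.
#' @param meta_tsv path to the sidecar TSV.
#' @return a `trna_genes` table.
#' @export
read_trna_genes <- function(fasta, meta_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- read.delim(meta_tsv, stringsAsFactors = FALSE)
  need <- c("gene_id", "genome", "aa", "anticodon")
  if (!all(need %in% names(meta)))
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(meta$gene_id, ids)
  if (length(missing))
    stop("sequences missing from FASTA for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  trna_genes(meta$gene_id, meta$genome, meta$aa, meta$anticodon,
             as.character(seqs[match(meta$gene_id, ids)]))
}

#' Collapse tRNA genes into isodecoder consensus references
#'
#' Genes are grouped by (amino acid, anticodon) and clustered within each
#' group by single-linkage at a global-identity threshold. Each cluster
#' yields one consensus (per-position majority base; ties become IUPAC
#' ambiguity codes). The largest cluster in a group keeps the plain
#' `<aa>-<anticodon>` name; minority isodecoders are suffixed `-1`, `-2`, ...
#' in decreasing size order. The consensus `genomes` field is the union of
#' member genomes, so a sequence present in, say, both the nuclear and
#' chloroplast genomes is represented once with an ambiguous origin.
#'
#' @param genes a `trna_genes` table.
#' @param identity_threshold minimum global identity for two genes to be
#'   linked into the same cluster (default 0.95).
#' @return data.frame with columns `consensus_id`, `aa`, `anticodon`,
#'   `sequence`, `genomes` (comma-joined), `n_members`, `member_gene_ids`
#'   (comma-joined), `length`.
#' @export
collapse_isodecoders <- function(genes, identity_threshold = 0.95) {
  stopifnot(inherits(genes, "trna_genes") || is.data.frame(genes))
  if (!(identity_threshold > 0 && identity_threshold <= 1))
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  if (nrow(genes) == 0L) return(empty_consensus_table())
  n_frac <- vapply(genes$sequence,
                   function(s) mean(seq_chars(s) == "N"), numeric(1))
  if (any(n_frac > 0.10))
    stop("high_n_content: sequences with >10% N: ",
         paste(genes$gene_id[n_frac > 0.10], collapse = ", "), call. = FALSE)

  groups <- split(seq_len(nrow(genes)),
                  paste(genes$aa, genes$anticodon, sep = "-"))
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    clusters <- single_linkage_clusters(genes$sequence[idx],
                                        identity_threshold)
    # largest cluster first; ties broken by smallest member index for
    # determinism
    ord <- order(-vapply(clusters, length, integer(1)),
                 vapply(clusters, min, integer(1)))
    clusters <- clusters[ord]
    do.call(rbind, lapply(seq_along(clusters), function(k) {
      members <- idx[clusters[[k]]]
      cid <- if (k == 1L) gname else paste0(gname, "-", k - 1L)
      data.frame(
        consensus_id = cid,
        aa = genes$aa[members[1]],
        anticodon = genes$anticodon[members[1]],
        sequence = majority_consensus(genes$sequence[members]),
        genomes = paste(sort(unique(genes$genome[members])), collapse = ","),
        n_members = length(members),
        member_gene_ids = paste(genes$gene_id[members], collapse = ","),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$consensus_id), , drop = FALSE]
  rownames(out) <- NULL
  out$length <- nchar(out$sequence)
  out
}

empty_consensus_table <- function() {
  data.frame(consensus_id = character(), aa = character(),
             anticodon = character(), sequence = character(),
             genomes = character(), n_members = integer(),
             member_gene_ids = character(), length = integer(),
             stringsAsFactors = FALSE)
}

# Single-linkage clustering of sequences at >= threshold global identity.
# Returns a list of integer index vectors (a partition of seq_along(seqs)).
single_linkage_clusters <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1L) return(list(1L))
  # union-find over all pairs; identical strings short-circuit the alignment
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (global_identity(seqs[i], seqs[j]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# Per-position majority base over equal- or unequal-length member sequences;
# positions are taken per index (members of a cluster are >=95% identical so
# lengths rarely differ; shorter members simply do not vote past their end).
# Ties -> IUPAC ambiguity code. N never outvotes a real base.
majority_consensus <- function(seqs) {
  L <- max(nchar(seqs))
  mats <- lapply(seqs, function(s) c(seq_chars(s), rep(NA, L - nchar(s))))
  m <- do.call(rbind, mats)
  cons <- vapply(seq_len(L), function(p) {
    col <- m[, p]
    col <- col[!is.na(col) & col %in% DNA_BASES]
    if (length(col) == 0L) return("N")
    tab <- table(col)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) winners else iupac_code(winners)
  }, character(1))
  paste(cons, collapse = "")
}

#' Construct an rRNA reference table
#'
#' @param rrna_id identifier, e.g. `"nuclear-25S"`.
#' @param genome genome of origin per entry.
#' @param subunit `"LSU"` or `"SSU"` per entry.
#' @param sequence DNA sequence per entry.
#' @return data.frame with class `rrna_refs`.
#' @export
rrna_refs <- function(rrna_id, genome, subunit, sequence) {
  n <- length(rrna_id)
  stopifnot(n >= 1, length(sequence) == n)
  genome <- rep_len(tolower(genome), n)
  if (!all(genome %in% GENOMES))
    stop("genome must be one of: ", paste(GENOMES, collapse = ", "),
         call. = FALSE)
  subunit <- rep_len(toupper(subunit), n)
  if (!all(subunit %in% c("LSU", "SSU")))
    stop("subunit must be LSU or SSU", call. = FALSE)
  if (anyDuplicated(paste(rrna_id, genome)))
    stop("(rrna_id, genome) pairs must be unique", call. = FALSE)
  sequence <- vapply(seq_along(sequence), function(i)
    check_dna(sequence[i], what = paste0("sequence of ", rrna_id[i])),
    character(1))
  out <- data.frame(rrna_id = as.character(rrna_id), genome = genome,
                    subunit = subunit, sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("rrna_refs", "data.frame")
  out
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' Replaces every cytosine with thymine and records the original C
#' positions, mirroring full bisulfite conversion of an unmethylated
#' molecule. Reads from converted libraries are aligned against these
#' converted references so that unconverted (methylated) Cs do not count as
#' mismatches. N bases never count as cytosines.
#'
#' @param source_id identifier of the source sequence.
#' @param sequence DNA sequence over A/C/G/T/N.
#' @return an object of class `converted_ref`: list with `source_id`,
#'   `source_sequence`, `converted_sequence`, `c_positions` (sorted, 1-based).
#' @export
in_silico_convert <- function(source_id, sequence) {
  sequence <- check_dna(sequence, what = source_id)
  out <- list(source_id = source_id,
              source_sequence = sequence,
              converted_sequence = gsub("C", "T", sequence, fixed = TRUE),
              c_positions = c_positions_of(sequence))
  class(out) <- "converted_ref"
  out
}

#' @export
print.converted_ref <- function(x, ...) {
  cat(sprintf("<converted_ref> %s: %d nt, %d cytosines\n",
              x$source_id, nchar(x$source_sequence), length(x$c_positions)))
  invisible(x)
}

#' Restore the original sequence from a converted reference
#' @param x a `converted_ref`.
#' @return the source DNA sequence.
#' @export
restore_cytosines <- function(x) {
  stopifnot(inherits(x, "converted_ref"))
  ch <- seq_chars(x$converted_sequence)
  ch[x$c_positions] <- "C"
  paste(ch, collapse = "")
}

#' Build a reference set for alignment
#'
#' @param ids reference identifiers.
#' @param sequences DNA sequences.
#' @param category per-reference category used for mapping-rate summaries:
#'   `"tRNA"`, `"rRNA"` or `"spikein"`.
#' @return object of class `refset`: named list of `converted_ref` with a
#'   `category` attribute.
#' @export
refset <- function(ids, sequences, category = "tRNA") {
  stopifnot(length(ids) == length(sequences), !anyDuplicated(ids))
  if (length(ids) == 0L) stop("empty refset", call. = FALSE)
  category <- rep_len(category, length(ids))
  out <- Map(in_silico_convert, ids, sequences)
  names(out) <- ids
  attr(out, "category") <- setNames(category, ids)
  class(out) <- "refset"
  out
}

#' @export
print.refset <- function(x, ...) {
  cat(sprintf("<refset> %d references (%s)\n", length(x),
              paste(names(table(attr(x, "category"))), collapse = ", ")))
  invisible(x)
}

#' Derive a species-specific rRNA reference from RNA-seq reads
#'
#' For species without a deposited rRNA sequence, non-bisulfite RNA-seq
#' reads are aligned to the corresponding anchor (Arabidopsis) rRNA and a
#' consensus is taken so species-specific SNPs replace the anchor base.
#' Positions covered below `min_depth` retain the anchor base and are
#' flagged.
#'
#' @param reads data.frame with columns `read_id`, `sequence` (RNA-seq, not
#'   bisulfite converted).
#' @param anchor_id,anchor_sequence the anchor rRNA.
#' @param min_depth minimum coverage for a position to be re-called.
#' @param max_mismatch mismatch allowance when placing reads on the anchor.
#' @return list with `sequence` (the species consensus), `low_coverage`
#'   (positions kept from the anchor), `snps` (data.frame position,
#'   anchor_base, species_base).
#' @export
derive_species_rrna <- function(reads, anchor_id, anchor_sequence,
                                min_depth = 10, max_mismatch = 6) {
  anchor_sequence <- check_dna(anchor_sequence, what = anchor_id)
  if (nrow(reads) == 0L)
    stop("no reads provided for anchor ", anchor_id, call. = FALSE)
  aln <- align_plain_reads(reads, anchor_id, anchor_sequence,
                           max_mismatch = max_mismatch)
  if (nrow(aln) == 0L)
    stop("zero reads aligned to anchor ", anchor_id, call. = FALSE)
  L <- nchar(anchor_sequence)
  counts <- matrix(0, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  read_chars <- strsplit(toupper(reads$sequence), "", fixed = TRUE)
  names(read_chars) <- reads$read_id
  for (i in seq_len(nrow(aln))) {
    ch <- read_chars[[aln$read_id[i]]]
    pos <- seq(aln$start[i], length.out = length(ch))
    keep <- ch %in% DNA_BASES
    counts[cbind(match(ch[keep], DNA_BASES), pos[keep])] <-
      counts[cbind(match(ch[keep], DNA_BASES), pos[keep])] + 1
  }
  depth <- colSums(counts)
  anchor_chars <- seq_chars(anchor_sequence)
  called <- anchor_chars
  recall <- which(depth >= min_depth)
  if (length(recall)) {
    # majority base; ties keep the anchor base when it co-champions,
    # otherwise the lexicographically first champion (deterministic)
    called[recall] <- vapply(recall, function(p) {
      col <- counts[, p]
      champs <- DNA_BASES[col == max(col)]
      if (anchor_chars[p] %in% champs) anchor_chars[p] else champs[1]
    }, character(1))
  }
  snp <- which(called != anchor_chars)
  list(sequence = paste(called, collapse = ""),
       low_coverage = which(depth < min_depth),
       snps = data.frame(position = snp,
                         anchor_base = anchor_chars[snp],
                         species_base = called[snp],
                         stringsAsFactors = FALSE))
}

#' Write a reference directory (consensus FASTA, converted FASTA, manifest)
#'
#' @param consensus a consensus table from [collapse_isodecoders()], or any
#'   data.frame with `consensus_id`/`sequence` (plus optional `genomes`,
#'   `n_members`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_dir <- function(consensus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- consensus$consensus_id
  seqs <- Biostrings::DNAStringSet(setNames(consensus$sequence, ids))
  Biostrings::writeXStringSet(seqs, file.path(dir, "consensus.fasta"))
  conv <- Biostrings::DNAStringSet(
    setNames(gsub("C", "T", consensus$sequence, fixed = TRUE), ids))
  Biostrings::writeXStringSet(conv, file.path(dir, "consensus.converted.fasta"))
  manifest <- data.frame(
    consensus_id = ids,
    genomes = if ("genomes" %in% names(consensus)) consensus$genomes else NA,
    n_members = if ("n_members" %in% names(consensus)) consensus$n_members else NA,
    length = nchar(consensus$sequence))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
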