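# Shared test helpers: independent oracles and synthetic input generators.

# Pure-R brute-force minimal-mismatch aligner, independent of the compiled
# scanner. Scores every offset of every reference by direct character
# comparison (vectorised over offsets) and returns all champion alignments
# (global minimum <= max_mismatch; per reference the leftmost best offset),
# ordered by reference_id.
brute_force_align <- function(read, refs, max_mismatch = 2) {
  # refs: named character vector (converted reference sequences)
  rch <- strsplit(read, "")[[1]]
  l <- length(rch)
  per_ref <- lapply(sort(names(refs)), function(id) {
    fch <- strsplit(refs[[id]], "")[[1]]
    L <- length(fch)
    if (l > L) return(NULL)
    win <- matrix(fch[outer(0:(l - 1L), seq_len(L - l + 1L), "+")],
                  nrow = l)
    mm <- colSums(win != rch)
    data.frame(reference_id = id, start = which.min(mm),
               mismatches = min(mm), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per_ref)
  if (is.null(res)) return(res)
  best <- min(res$mismatches)
  if (best > max_mismatch)
    return(res[0, , drop = FALSE])
  res[res$mismatches == best, , drop = FALSE]
}

# Apply the brute-force oracle to a batch of reads in three-letter space.
brute_force_align_batch <- function(reads, refs_converted, max_mismatch = 2) {
  out <- lapply(seq_len(nrow(reads)), function(i) {
    hit <- brute_force_align(gsub("C", "T", toupper(reads$sequence[i])),
                             refs_converted, max_mismatch)
    if (is.null(hit) || nrow(hit) == 0L) return(NULL)
    hit$read_id <- reads$read_id[i]
    hit
  })
  do.call(rbind, out)
}

# Random tRNA-like sequence with the anticodon placed once at a realistic
# offset (canonical upstream arm ~33 nt, downstream ~36 nt). Re-draws the
# body until the anticodon occurs exactly once.
random_trna <- function(anticodon = "GTC", upstream = 33, downstream = 36) {
  repeat {
    up <- random_dna(upstream, 0.5)
    down <- random_dna(downstream, 0.5)
    seq <- paste0(up, anticodon, down)
    occ <- gregexpr(anticodon, seq, fixed = TRUE)[[1]]
    if (length(occ) == 1L && occ[1] == upstream + 1) return(seq)
  }
}

# A small synthetic reference panel: n random tRNA-length references with a
# guaranteed number of cytosines (>= min_c) each.
random_ref_panel <- function(n, length = 80, min_c = 10) {
  ids <- sprintf("ref%02d", seq_len(n))
  seqs <- vapply(ids, function(i) {
    repeat {
      s <- random_dna(length, 0.5)
      if (sum(strsplit(s, "")[[1]] == "C") >= min_c) return(s)
    }
  }, character(1))
  data.frame(id = ids, sequence = unname(seqs), category = "tRNA",
             stringsAsFactors = FALSE)
}
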