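# Consensus collapsing and in-silico conversion.

test_that("identical isodecoder genes collapse to one consensus", {
  asp <- synthetic_asp_trna()
  genes <- trna_genes(c("g1", "g2"), "nuclear", "Asp", "GTC",
                      c(asp$sequence, asp$sequence))
  cons <- collapse_isodecoders(genes)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_members, 2L)
  expect_equal(cons$genomes, "nuclear")
  expect_equal(cons$sequence, asp$sequence)
  expect_equal(cons$consensus_id, "Asp-GTC")
})

test_that("a sequence shared by two genomes yields one ambiguous-origin consensus", {
  asp <- synthetic_asp_trna()
  genes <- trna_genes(c("nuc1", "chl1"), c("nuclear", "chloroplast"),
                      "Asp", "GTC", c(asp$sequence, asp$sequence))
  cons <- collapse_isodecoders(genes)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$genomes, "chloroplast,nuclear")
})

test_that("a diverged minority isodecoder stays separate and is suffixed -1", {
  set.seed(10)
  base <- random_trna("GCC")
  # 8 substitutions over 72 nt: 64/72 = 88.9% identity, below 0.95
  minority <- base
  ch <- strsplit(minority, "")[[1]]
  flip <- c(2, 10, 20, 28, 45, 55, 60, 70)
  ch[flip] <- vapply(ch[flip], function(b) setdiff(c("A", "G", "T"), b)[1],
                     character(1))
  minority <- paste(ch, collapse = "")
  genes <- trna_genes(c("g1", "g2", "g3"), "nuclear", "Gly", "GCC",
                      c(base, base, minority))
  cons <- collapse_isodecoders(genes)
  # brute-force single-linkage oracle over the 3 pairs: only (g1,g2) link
  ident <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  expect_lt(ident(base, minority), 0.95)
  expect_equal(nrow(cons), 2L)
  expect_equal(cons$consensus_id, c("Gly-GCC", "Gly-GCC-1"))
  expect_equal(cons$n_members, c(2L, 1L))
  expect_equal(cons$member_gene_ids[2], "g3")
})

test_that("collapsing rejects degenerate input and handles empty input", {
  expect_equal(nrow(collapse_isodecoders(
    trna_genes(character(), character(), character(), character(),
               character()))), 0L)
  n_heavy <- paste0(strrep("N", 10), random_dna(62))
  genes <- trna_genes("g1", "nuclear", "Asp", "GTC", n_heavy)
  expect_error(collapse_isodecoders(genes), "high_n_content")
})

test_that("collapsing is idempotent and forms a partition", {
  set.seed(11)
  seqs <- c(replicate(3, random_trna("GTC")), replicate(2, random_trna("TTC")))
  genes <- trna_genes(sprintf("g%d", 1:5), "nuclear",
                      c("Asp", "Asp", "Asp", "Glu", "Glu"),
                      c("GTC", "GTC", "GTC", "TTC", "TTC"), seqs)
  cons <- collapse_isodecoders(genes)
  members <- unlist(strsplit(cons$member_gene_ids, ","))
  expect_setequal(members, genes$gene_id)       # every gene appears
  expect_false(anyDuplicated(members) > 0)      # exactly once
  # re-collapsing the consensus list changes nothing
  genes2 <- trna_genes(cons$consensus_id, "nuclear", cons$aa, cons$anticodon,
                       cons$sequence)
  cons2 <- collapse_isodecoders(genes2)
  expect_equal(cons2$sequence, cons$sequence)
  expect_equal(nrow(cons2), nrow(cons))
})

test_that("cluster count is non-increasing as the identity threshold drops", {
  set.seed(12)
  base <- random_trna("GTC")
  variant <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- vapply(ch[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                      character(1))
    paste(ch, collapse = "")
  }
  seqs <- c(base, variant(base, 2), variant(base, 6), variant(base, 15))
  genes <- trna_genes(sprintf("g%d", 1:4), "nuclear", "Asp", "GTC", seqs)
  counts <- vapply(c(0.99, 0.95, 0.90, 0.75, 0.50),
                   function(th) nrow(collapse_isodecoders(genes, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("in-silico conversion records cytosines and round-trips", {
  expect_equal(in_silico_convert("x", "ACGT")$converted_sequence, "ATGT")
  expect_equal(in_silico_convert("x", "ACGT")$c_positions, 2L)
  expect_equal(in_silico_convert("x", "AGTA")$c_positions, integer(0))
  expect_equal(in_silico_convert("x", "CCCC")$converted_sequence, "TTTT")
  expect_equal(in_silico_convert("x", "CCCC")$c_positions, 1:4)
  expect_error(in_silico_convert("x", "ACGU"), "invalid_alphabet")
  # N never counts as a cytosine
  expect_equal(in_silico_convert("x", "NCN")$c_positions, 2L)
  set.seed(21)
  for (i in 1:50) {
    s <- random_dna(sample(60:100, 1), runif(1, 0.2, 0.8))
    conv <- in_silico_convert("r", s)
    expect_false(grepl("C", conv$converted_sequence))
    expect_equal(nchar(conv$converted_sequence), nchar(s))
    expect_equal(restore_cytosines(conv), s)
  }
})

test_that("FASTA + sidecar TSV round-trip into a gene table", {
  asp <- synthetic_asp_trna()
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">g1", asp$sequence, ">g2", asp$sequence), fa)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("g1", "g2"),
                         genome = c("nuclear", "chloroplast"),
                         aa = "Asp", anticodon = "GTC"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- read_trna_genes(fa, tsv)
  expect_equal(genes$sequence, rep(asp$sequence, 2))
  expect_equal(genes$genome, c("nuclear", "chloroplast"))
})

test_that("species rRNA consensus recovers SNPs at covered positions", {
  set.seed(31)
  anchor <- random_dna(400, 0.5)
  mut_pos <- sort(sample(50:350, 5))
  ch <- strsplit(anchor, "")[[1]]
  ch[mut_pos] <- vapply(ch[mut_pos],
                        function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                        character(1))
  species <- paste(ch, collapse = "")
  cfg <- sim_config(data.frame(id = "sp", sequence = species,
                               category = "rRNA"),
                    n_reads = 2500, seq_error_rate = 0, seed = 5)
  sim <- simulate_rnaseq_reads(cfg)
  res <- derive_species_rrna(sim$reads, "anchor-LSU", anchor,
                             min_depth = 50)
  expect_equal(res$snps$position, mut_pos)
  expect_equal(res$sequence, species)

  # reads identical to the anchor reproduce the anchor
  cfg2 <- sim_config(data.frame(id = "a", sequence = anchor,
                                category = "rRNA"),
                     n_reads = 800, seq_error_rate = 0, seed = 6)
  sim2 <- simulate_rnaseq_reads(cfg2)
  res2 <- derive_species_rrna(sim2$reads, "anchor-LSU", anchor,
                              min_depth = 20)
  expect_equal(res2$sequence, anchor)
  expect_equal(nrow(res2$snps), 0L)

  expect_error(derive_species_rrna(sim2$reads[0, ], "anchor-LSU", anchor),
               "anchor-LSU")
})
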