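# Pileup arithmetic, conversion QC, threshold calling, differential report.

test_that("pileups count C/T per reference cytosine with fractional weights", {
  asp <- synthetic_asp_trna()
  refs <- refset("Asp-GTC", asp$sequence)
  conv <- gsub("C", "T", asp$sequence, fixed = TRUE)
  # unambiguous read keeping C38
  ch <- strsplit(substr(conv, 31, 60), "")[[1]]
  ch[8] <- "C"  # position 38
  reads <- data.frame(read_id = "q1", sequence = paste(ch, collapse = ""))
  aln <- align_reads(reads, refs)
  pile <- tally_pileup(aln, reads, refs)
  at38 <- pile[pile$position == 38, ]
  expect_equal(at38$n_C, 1)
  expect_equal(at38$n_T, 0)
  expect_equal(at38$methylation, 1)
  # every other covered C position shows T
  covered <- pile[pile$position >= 31 & pile$position <= 60 &
                    pile$position != 38, ]
  expect_true(all(covered$n_T == 1))

  # a read ambiguous between two references contributes 0.5 to each
  refs2 <- refset(c("a1", "a2"), rep(asp$sequence, 2))
  reads2 <- data.frame(read_id = "q1",
                       sequence = substr(conv, 31, 60))
  aln2 <- align_reads(reads2, refs2)
  pile2 <- tally_pileup(aln2, reads2, refs2)
  at38b <- pile2[pile2$position == 38, ]
  expect_equal(at38b$n_T, c(0.5, 0.5))

  expect_error(tally_pileup(data.frame(read_id = "q", reference_id = "zz",
                                       start = 1, weight = 1),
                            reads, refs), "unknown reference")
})

test_that("percent methylation follows the C/(C+T) formula", {
  expect_equal(percent_methylation(4, 6), 0.40)
  expect_equal(percent_methylation(10, 0), 1.0)
  expect_equal(percent_methylation(0, 10), 0.0)
  expect_true(is.na(percent_methylation(0, 0)))  # undefined, not 0
  expect_equal(percent_methylation(c(4, 0), c(6, 0)), c(0.4, NA))
})

test_that("pileup counts are conserved against the simulator truth", {
  set.seed(61)
  panel <- random_ref_panel(3, length = 80)
  refs <- refset(panel$id, panel$sequence)
  cfg <- sim_config(panel, n_reads = 400, seq_error_rate = 0, seed = 16)
  sim <- simulate_bisulfite_reads(cfg)
  aln <- align_reads(sim$reads, refs)
  pile <- tally_pileup(aln, sim$reads, refs)
  # sum over sites of all tallied bases = sum over champion alignments of
  # (C positions covered) x weight
  total_tallied <- sum(pile$n_C + pile$n_T + pile$n_other)
  cpos <- lapply(refs, function(r) r$c_positions)
  lens <- setNames(nchar(sim$reads$sequence), sim$reads$read_id)
  expected <- sum(vapply(seq_len(nrow(aln)), function(i) {
    cp <- cpos[[aln$reference_id[i]]]
    aln$weight[i] * sum(cp >= aln$start[i] &
                          cp <= aln$start[i] + lens[[aln$read_id[i]]] - 1)
  }, numeric(1)))
  expect_equal(total_tallied, expected)
})

test_that("conversion QC gates libraries at 98% on the spike-in", {
  ctrl <- make_spikein(1000, 0.5, seed = 17, control_id = "ctl")
  refs <- refset("ctl", ctrl$sequence, category = "spikein")
  run_qc <- function(e) {
    cfg <- sim_config(data.frame(id = "dummy",
                                 sequence = synthetic_asp_trna()$sequence,
                                 category = "tRNA"),
                      n_reads = 10000, conversion_efficiency = e,
                      spikein_fraction = 0.999, seq_error_rate = 0,
                      seed = 18)
    sim <- simulate_bisulfite_reads(cfg, ctrl)
    spike <- sim$truth_reads$source_id == "ctl"
    aln <- align_reads(sim$reads[spike, ], refs)
    qc_conversion(tally_pileup(aln, sim$reads[spike, ], refs))
  }
  qc95 <- run_qc(0.95)
  qc99 <- run_qc(0.99)
  expect_false(qc95$pass)
  expect_true(qc99$pass)
  expect_lt(abs(qc95$global_conversion - 0.95), 0.005)
  expect_lt(abs(qc99$global_conversion - 0.99), 0.005)
  # a failed library cannot be called
  expect_error(call_sites(data.frame(), qc = qc95), "failed conversion QC")
  # no covered control cytosines -> QC error
  expect_error(qc_conversion(data.frame(reference_id = "ctl", position = 1,
                                        n_C = 0, n_T = 0, coverage = 0)),
               "qc_error")
})

test_that("site calling applies the 5-read / 20% thresholds inclusively", {
  pile <- data.frame(reference_id = "r",
                     position = c(10, 20, 30, 40, 50),
                     n_C = c(4, 1.9, 1, 66, 5),
                     n_T = c(0, 8.1, 4, 34, 95),
                     n_other = 0)
  pile$coverage <- pile$n_C + pile$n_T
  pile$methylation <- percent_methylation(pile$n_C, pile$n_T)
  calls <- call_sites(pile, min_coverage = 5, min_methylation = 0.20)
  expect_equal(calls$status,
               c("no_call",        # coverage 4 despite 100% methylation
                 "unmethylated",   # 19% < 20%
                 "methylated",     # exactly 5 reads, exactly 20%
                 "methylated",     # 66%
                 "unmethylated"))  # 5%
  # spec example triple: (5, 0.20), (100, 0.66), (100, 0.05) -> exactly 2
  expect_equal(sum(calls$status[3:5] == "methylated"), 2L)
})

test_that("global cytosine abundance separates BS from non-BS libraries", {
  set.seed(62)
  panel <- random_ref_panel(3, length = 80)
  refs <- refset(panel$id, panel$sequence)
  # unconverted RNA-seq: equals reference C composition
  cfg_rna <- sim_config(panel, n_reads = 2000, seq_error_rate = 0, seed = 19)
  sim_rna <- simulate_rnaseq_reads(cfg_rna)
  aln_rna <- align_reads(sim_rna$reads, refs, convert_reads = FALSE)
  comp_ref <- mean(strsplit(paste(panel$sequence, collapse = ""), "")[[1]] == "C")
  expect_lt(abs(global_cytosine_abundance(aln_rna, sim_rna$reads, refs) -
                  comp_ref), 0.02)
  # converted library with sparse methylation stays below ~2%
  mm <- data.frame(id = panel$id[1],
                   position = refs[[panel$id[1]]]$c_positions[1],
                   fraction = 0.8)
  cfg_bs <- sim_config(panel, methylation_map = mm, n_reads = 2000,
                       conversion_efficiency = 0.99, seq_error_rate = 0,
                       seed = 20)
  sim_bs <- simulate_bisulfite_reads(cfg_bs)
  aln_bs <- align_reads(sim_bs$reads, refs)
  abundance <- global_cytosine_abundance(aln_bs, sim_bs$reads, refs)
  expect_lt(abundance, 0.02)
  expect_gt(abundance, 0)
})

test_that("differential report classifies lost, reduced and unchanged sites", {
  mk <- function(m, cov = 100) {
    pile <- data.frame(reference_id = "r", position = c(10, 20, 30, 40),
                       n_C = m * cov, n_T = (1 - m) * cov, n_other = 0,
                       coverage = cov, methylation = m)
    pile$coverage[4] <- 3  # no_call site in both genotypes
    call_sites(pile)
  }
  wt <- mk(c(0.66, 0.90, 0.50, 0.9))
  mut <- mk(c(0.02, 0.60, 0.45, 0.9))
  d <- differential_sites(wt, mut)
  expect_equal(d$change[d$position == 10], "lost")     # 66% -> 2%
  expect_equal(d$change[d$position == 20], "reduced")  # 90% -> 60%
  expect_equal(d$change[d$position == 30], "unchanged")
  expect_false(40 %in% d$position)  # no_call excluded
  # wild-type unmethylated sites are not compared
  expect_equal(nrow(d), 3L)
  expect_error(differential_sites(wt, mk(0.5)[0, ]),
               "different reference sets")
})

test_that("methylation matrix mirrors heatmap semantics (NA when no call)", {
  pile <- data.frame(reference_id = "r", position = c(5, 9),
                     n_C = c(8, 1), n_T = c(2, 1), n_other = 0,
                     coverage = c(10, 2), methylation = c(0.8, 0.5))
  calls <- call_sites(pile)
  m <- methylation_matrix(list(s1 = calls, s2 = calls))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["r:5", "s1"], 80)
  expect_true(is.na(m["r:9", "s2"]))  # coverage < 5 -> white/NA
})
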