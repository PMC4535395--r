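# Read simulator: conversion model, spike-in control, determinism.

test_that("spike-in control is self-consistent and degenerate cases fail", {
  sp <- make_spikein(1000, 0.5, seed = 1)
  expect_equal(sp$n_cytosines,
               sum(strsplit(sp$sequence, "")[[1]] == "C"))
  expect_error(make_spikein(80), ">= 100")
  # a C-free control is unusable for conversion QC
  sp0 <- make_spikein(500, gc_fraction = 0, seed = 1)
  expect_equal(sp0$n_cytosines, 0L)
  refs <- data.frame(id = "r1", sequence = random_trna(), category = "tRNA")
  cfg <- sim_config(refs, n_reads = 10, spikein_fraction = 0.5, seed = 1)
  expect_error(simulate_bisulfite_reads(cfg, sp0), "no cytosines")
})

test_that("fully methylated and fully unmethylated sites behave deterministically", {
  asp <- synthetic_asp_trna()
  refs <- data.frame(id = "Asp-GTC", sequence = asp$sequence,
                     category = "tRNA")
  # m = 1, no over-conversion, no error: every covering read keeps the C
  cfg <- sim_config(refs,
                    methylation_map = data.frame(id = "Asp-GTC",
                                                 position = 38,
                                                 fraction = 1),
                    n_reads = 300, conversion_efficiency = 1,
                    over_conversion = 0, seq_error_rate = 0, seed = 2)
  sim <- simulate_bisulfite_reads(cfg)
  covering <- sim$truth_reads$start <= 38 &
    sim$truth_reads$start + sim$truth_reads$length - 1 >= 38
  base38 <- substr(sim$reads$sequence[covering],
                   38 - sim$truth_reads$start[covering] + 1,
                   38 - sim$truth_reads$start[covering] + 1)
  expect_true(all(base38 == "C"))
  # m = 0 everywhere, perfect conversion: "results in no cytosines"
  cfg0 <- sim_config(refs, n_reads = 300, conversion_efficiency = 1,
                     over_conversion = 0, seq_error_rate = 0, seed = 3)
  sim0 <- simulate_bisulfite_reads(cfg0)
  expect_false(any(grepl("C", sim0$reads$sequence)))
})

test_that("empirical site methylation matches the binomial oracle", {
  asp <- synthetic_asp_trna()
  refs <- data.frame(id = "Asp-GTC", sequence = asp$sequence,
                     category = "tRNA")
  m <- 0.66
  cfg <- sim_config(refs,
                    methylation_map = data.frame(id = "Asp-GTC",
                                                 position = 38, fraction = m),
                    n_reads = 10000, conversion_efficiency = 1,
                    over_conversion = 0, seq_error_rate = 0,
                    read_length_range = c(72, 72), seed = 4)
  sim <- simulate_bisulfite_reads(cfg)
  base38 <- substr(sim$reads$sequence, 38, 38)
  n <- length(base38)
  frac <- mean(base38 == "C")
  expect_lt(abs(frac - m), 3 * sqrt(m * (1 - m) / n))
})

test_that("RNA-seq simulation preserves sequence and composition", {
  set.seed(41)
  refs <- random_ref_panel(2, length = 90)
  refs$weight <- c(9, 1)
  cfg <- sim_config(refs, n_reads = 5000, seq_error_rate = 0, seed = 5)
  sim <- simulate_rnaseq_reads(cfg)
  # error 0: every read is an exact substring of its source
  for (i in sample(nrow(sim$reads), 100)) {
    src <- refs$sequence[refs$id == sim$truth_reads$source_id[i]]
    expect_equal(sim$reads$sequence[i],
                 substr(src, sim$truth_reads$start[i],
                        sim$truth_reads$start[i] + sim$truth_reads$length[i] - 1))
  }
  # abundance weights 9:1 within 3 binomial SE
  p <- mean(sim$truth_reads$source_id == refs$id[1])
  expect_lt(abs(p - 0.9), 3 * sqrt(0.9 * 0.1 / nrow(sim$reads)))
  # global C composition of reads approximates the panel composition
  comp_reads <- mean(strsplit(paste(sim$reads$sequence, collapse = ""),
                              "")[[1]] == "C")
  comp_ref <- mean(strsplit(paste(refs$sequence, collapse = ""), "")[[1]] == "C")
  expect_lt(abs(comp_reads - comp_ref), 0.02)
})

test_that("identical seed and config give byte-identical output", {
  refs <- data.frame(id = "r", sequence = synthetic_asp_trna()$sequence,
                     category = "tRNA")
  ctrl <- make_spikein(500, 0.5, seed = 9)
  cfg <- sim_config(refs, n_reads = 500, spikein_fraction = 0.2, seed = 77)
  a <- simulate_bisulfite_reads(cfg, ctrl)
  b <- simulate_bisulfite_reads(cfg, ctrl)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth_reads, b$truth_reads)
  fq1 <- tempfile(); fq2 <- tempfile()
  write_fastq(a$reads, fq1); write_fastq(b$reads, fq2)
  expect_identical(readLines(fq1), readLines(fq2))
  expect_identical(read_fastq(fq1)$sequence, a$reads$sequence)
})

test_that("spike-in reads carry C only through the conversion-failure channel", {
  refs <- data.frame(id = "r", sequence = synthetic_asp_trna()$sequence,
                     category = "tRNA")
  ctrl <- make_spikein(800, 0.5, seed = 10, control_id = "ctl")
  cfg <- sim_config(refs, n_reads = 3000, conversion_efficiency = 1,
                    over_conversion = 0, seq_error_rate = 0,
                    spikein_fraction = 0.5, seed = 11)
  sim <- simulate_bisulfite_reads(cfg, ctrl)
  spike <- sim$reads$sequence[sim$truth_reads$source_id == "ctl"]
  expect_gt(length(spike), 0)
  expect_false(any(grepl("C", spike)))
  # the map may not touch control cytosines
  cfg_bad <- sim_config(refs, n_reads = 10, spikein_fraction = 0.5, seed = 1)
  cfg_bad$methylation_map <- data.frame(id = "ctl", position = 1,
                                        fraction = 0.5)
  expect_error(simulate_bisulfite_reads(cfg_bad, ctrl), "must not appear")
})

test_that("the simulator converges to the closed-form observed methylation", {
  asp <- synthetic_asp_trna()
  refs <- data.frame(id = "Asp-GTC", sequence = asp$sequence,
                     category = "tRNA")
  m <- 0.5; e <- 0.97; o <- 0.05
  cfg <- sim_config(refs,
                    methylation_map = data.frame(id = "Asp-GTC",
                                                 position = 48, fraction = m),
                    n_reads = 20000, conversion_efficiency = e,
                    over_conversion = o, seq_error_rate = 0,
                    read_length_range = c(72, 72), seed = 12)
  sim <- simulate_bisulfite_reads(cfg)
  obs <- mean(substr(sim$reads$sequence, 48, 48) == "C")
  expected <- expected_observed_methylation(m, e, o)
  expect_lt(abs(obs - expected),
            3 * sqrt(expected * (1 - expected) / nrow(sim$reads)))
})

test_that("invalid methylation map positions are rejected", {
  refs <- data.frame(id = "r", sequence = "ACGTACGTACGTACGTACGTACGTACGTACGT" ,
                     category = "tRNA")
  expect_error(sim_config(refs, methylation_map = data.frame(
    id = "r", position = 1, fraction = 0.5)), "not a cytosine")
  expect_error(sim_config(refs, methylation_map = data.frame(
    id = "zz", position = 2, fraction = 0.5)), "unknown id")
})
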