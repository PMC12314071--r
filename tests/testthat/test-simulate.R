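test_that("class bookkeeping and determinism of the genome generator", {
  cfg <- simulation_config(seed = 7, n_genes = 20,
                           fractions = c(both = 0.5, crm_only = 0.2,
                                         ypatch_only = 0.2, neither = 0.1))
  sim <- simulate_genome(cfg)
  expect_equal(sum(sim$truth$planted_both), 10)
  expect_equal(nrow(sim$truth), 20)
  expect_equal(names(sim$genome), sim$genes$gene_id)
  # same seed twice: byte-identical outputs
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$genome, sim2$genome)
  expect_identical(sim$truth, sim2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_genome(sim, d1); write_sim_genome(sim2, d2)
  for (f in c("genome.fa", "genes.gff3", "dhs.bed", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("gene too short for the plants errors by name", {
  expect_error(
    simulate_genome(simulation_config(seed = 1, n_genes = 2,
                                      gene_length_range = c(300, 400))),
    "too short"
  )
})

test_that("emitted files round-trip through the readers and agree with the truth", {
  cfg <- simulation_config(seed = 11, n_genes = 8)
  sim <- simulate_genome(cfg)
  dir <- withr::local_tempdir()
  write_sim_genome(sim, dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, sim$genome)
  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(
    as.data.frame(genes[order(genes$gene_id),
                        c("gene_id", "strand", "tss", "translational_start",
                          "utr3_end")]),
    as.data.frame(sim$genes[order(sim$genes$gene_id),
                            c("gene_id", "strand", "tss",
                              "translational_start", "utr3_end")])
  )
  dhs <- read_dhs(file.path(dir, "dhs.bed"))
  expect_equal(nrow(dhs), nrow(sim$dhs))
  # every emitted interval is within its chromosome
  len <- nchar(genome)[dhs$chrom]
  expect_true(all(dhs$start >= 1 & dhs$end <= len))
  # planted consensus strings really sit in the emitted sequence
  both <- sim$truth[sim$truth$planted_crm, ][1, ]
  crm_seq <- substring(genome[[both$gene_id]], both$crm_start, both$crm_end)
  cons <- crmscreen:::CRM_FAMILY_CONSENSUS
  found <- vapply(cons, function(cs) {
    grepl(cs, crm_seq, fixed = TRUE) || grepl(revcomp(cs), crm_seq,
                                              fixed = TRUE)
  }, TRUE)
  expect_true(all(found))
})

test_that("expression generator plants recoverable classes deterministically", {
  cfg <- simulation_config(seed = 13, n_genes = 30)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$de, b$de)
  # planted truth is recovered exactly by the filters
  expect_equal(bs_specific_filter(a$de),
               sort(a$truth$gene_id[a$truth$bs_specific]))
  suppressWarnings(
    expect_equal(expressed_genes(a$expr, a$samples),
                 sort(a$truth$gene_id[a$truth$expressed]))
  )
  # an all-zero TPM gene exists and fails expressed_genes
  zero_gene <- a$expr |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(total = sum(tpm)) |>
    dplyr::filter(total == 0)
  expect_gt(nrow(zero_gene), 0)
  expect_false(any(zero_gene$gene_id %in%
                     expressed_genes(a$expr, a$samples) |>
                     suppressWarnings()))
  # design: 7 stages, 3-4 replicates per stage and cell type
  reps <- a$samples |> dplyr::count(stage, cell_type)
  expect_true(all(reps$n %in% 3:4))
  expect_equal(sort(unique(a$samples$stage)), 1:7)
})

test_that("kinetics generator: noiseless rates are exact, duplicates identical", {
  cfg <- simulation_config(seed = 17, n_lines = 6)
  sk <- simulate_kinetics(cfg, sd = 0)
  # 20 cycles, 2 min apart
  one <- sk$kinetics[sk$kinetics$line_id == "line01" &
                       sk$kinetics$duplicate_id == 1, ]
  expect_equal(nrow(one), 20)
  expect_equal(unique(diff(one$time_min)), 2)
  expect_equal(nrow(sk$standards), 10)
  curve <- fit_standard_curve(sk$standards)
  rates <- gus_rate(sk$kinetics, curve, sk$lines)
  expect_equal(rates$rate,
               sk$truth$rate_per_mg[match(rates$line_id, sk$truth$line_id)],
               tolerance = 1e-10)
  # duplicates with sd = 0 have identical slopes
  slopes <- sk$kinetics |>
    dplyr::group_by(line_id, duplicate_id) |>
    dplyr::summarise(s = coef(lm(fluorescence ~ time_min))[2],
                     .groups = "drop") |>
    dplyr::group_by(line_id) |>
    dplyr::summarise(spread = diff(range(s)))
  expect_true(all(slopes$spread < 1e-10))
})

test_that("noisy kinetics recover rates within analytic standard errors", {
  cfg <- simulation_config(seed = 19, n_lines = 40, kinetic_sd = 30)
  sk <- simulate_kinetics(cfg)
  curve <- fit_standard_curve(sk$standards)
  rates <- gus_rate(sk$kinetics, curve, sk$lines)
  truth <- sk$truth$rate_per_mg[match(rates$line_id, sk$truth$line_id)]
  # analytic se of an OLS slope over t = 0,2,...,38 with sd = 30, averaged
  # over 2 duplicates, converted to rate units
  t <- seq(0, 38, by = 2)
  se_slope <- 30 / sqrt(sum((t - mean(t))^2)) / sqrt(2)
  se_rate <- se_slope / cfg$curve_slope / cfg$protein_mg
  z <- abs(rates$rate - truth) / se_rate
  expect_lt(mean(z > 3), 0.05)       # ~0.3% expected beyond 3 se
  expect_lt(mean(abs(rates$rate - truth)), 3 * se_rate)
})
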