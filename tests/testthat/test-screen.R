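mk_hit <- function(family, start, p, stop = start + 7L, region_id = 1L) {
  tibble::tibble(
    motif_id = paste0("syn_", family), family = family, sequence_name = "g",
    start = as.integer(start), stop = as.integer(stop), strand = "+",
    score = 10, p_value = p, matched_sequence = "NNNNNNNN",
    region_id = region_id
  )
}

six <- c("WRKY", "G2like", "MYBR_B", "DOF", "IDD", "DPBF")

test_that("per-family cutoffs are strict and family-specific", {
  fm <- setNames(six, paste0("syn_", six))
  hits <- dplyr::bind_rows(
    mk_hit("DOF", 10, 5e-4),    # needs < 1e-4: dropped
    mk_hit("WRKY", 50, 5e-4),   # needs < 1e-3: retained
    mk_hit("IDD", 90, 1e-4),    # exactly at the cutoff: dropped (strict <)
    mk_hit("DPBF", 130, 9e-5)   # retained
  )
  out <- label_and_filter_hits(hits, fm)
  expect_equal(sort(out$family), c("DPBF", "WRKY"))
  expect_equal(nrow(label_and_filter_hits(hits[0, ], fm)), 0)
})

test_that("hits without a family are dropped with a warning", {
  hits <- mk_hit("WRKY", 10, 1e-5)
  hits$motif_id <- "mystery"
  expect_warning(out <- label_and_filter_hits(hits, c(known = "WRKY")),
                 "without a family")
  expect_equal(nrow(out), 0)
})

test_that("six-family window rule is exact at the 300-bp boundary", {
  # six hits, first five tightly packed, the sixth placed so the total span
  # is exactly `span`: 299 and 300 call, 301 does not
  placed <- function(span) {
    dplyr::bind_rows(
      lapply(seq_along(six[-6]), function(i) {
        mk_hit(six[i], 1 + (i - 1) * 10, 1e-5)
      }),
      mk_hit(six[6], span - 7, 1e-5)  # stop = span
    )
  }
  expect_equal(nrow(call_crm_windows(placed(299))), 1)
  expect_equal(call_crm_windows(placed(300))$span_length, 300L)
  expect_equal(nrow(call_crm_windows(placed(301))), 0)
  # five families only: no call
  expect_equal(nrow(call_crm_windows(placed(299)[-1, ])), 0)
})

test_that("hits split across accessible intervals are never bridged", {
  h <- dplyr::bind_rows(lapply(seq_along(six), function(i) {
    mk_hit(six[i], 1 + (i - 1) * 10, 1e-5)
  }))
  expect_equal(nrow(call_crm_windows(h)), 1)
  h$region_id <- c(1L, 1L, 1L, 2L, 2L, 2L)  # same coordinates, two intervals
  expect_equal(nrow(call_crm_windows(h)), 0)
})

test_that("widening the window never removes a call", {
  withr::with_seed(211, {
    for (rep in 1:10) {
      h <- dplyr::bind_rows(lapply(six, function(f) {
        mk_hit(f, sample(1:400, 1), 1e-5)
      }))
      n200 <- nrow(call_crm_windows(h, window_bp = 200))
      n300 <- nrow(call_crm_windows(h, window_bp = 300))
      n500 <- nrow(call_crm_windows(h, window_bp = 500))
      expect_lte(n200, n300)
      expect_lte(n300, n500)
    }
  })
})

test_that("supporting hits are the lowest-p hit per family inside the window", {
  h <- dplyr::bind_rows(
    mk_hit("WRKY", 1, 1e-5), mk_hit("WRKY", 20, 1e-7),
    mk_hit("G2like", 40, 1e-5), mk_hit("MYBR_B", 60, 1e-5),
    mk_hit("DOF", 80, 1e-5), mk_hit("IDD", 100, 1e-5),
    mk_hit("DPBF", 120, 1e-5)
  )
  calls <- call_crm_windows(h)
  expect_equal(nrow(calls), 1)
  sup <- calls$supporting_hits[[1]]
  expect_equal(nrow(sup), 6)
  expect_equal(sup$p_value[sup$family == "WRKY"], 1e-7)
})

test_that("planted screen recovers truth; empty DHS kills every call", {
  cfg <- simulation_config(seed = 19, n_genes = 24)
  sim <- simulate_genome(cfg)
  lib <- builtin_motif_library("crm")
  res <- gene_screen(sim$genes, sim$genome, sim$dhs, lib,
                     y_patch_model = y_patch_pwm())
  cmp <- dplyr::inner_join(tidy(res), sim$truth, by = "gene_id")
  expect_equal(cmp$has_both, cmp$planted_both)
  expect_equal(cmp$has_crm, cmp$planted_crm)
  expect_equal(cmp$has_y_patch, cmp$planted_ypatch)
  # flags are internally consistent
  expect_equal(cmp$has_both, cmp$has_y_patch & cmp$has_crm)
  # empty DHS: no accessible sequence, no CRM calls anywhere
  empty_dhs <- sim$dhs[0, ]
  res0 <- gene_screen(sim$genes, sim$genome, empty_dhs, lib,
                      y_patch_model = y_patch_pwm())
  expect_false(any(tidy(res0)$has_crm))
})

test_that("plants outside accessible chromatin are not called", {
  cfg <- simulation_config(seed = 23, n_genes = 16,
                           dhs_mode = "exclude-plants")
  sim <- simulate_genome(cfg)
  res <- gene_screen(sim$genes, sim$genome, sim$dhs,
                     builtin_motif_library("crm"),
                     y_patch_model = y_patch_pwm())
  expect_false(any(tidy(res)$has_crm))
})

test_that("screen is deterministic and genes missing from the genome are skipped", {
  cfg <- simulation_config(seed = 29, n_genes = 10)
  sim <- simulate_genome(cfg)
  lib <- builtin_motif_library("crm")
  r1 <- gene_screen(sim$genes, sim$genome, sim$dhs, lib,
                    y_patch_model = y_patch_pwm())
  r2 <- gene_screen(sim$genes, sim$genome, sim$dhs, lib,
                    y_patch_model = y_patch_pwm())
  expect_identical(tidy(r1), tidy(r2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tidy(r1), f1); readr::write_tsv(tidy(r2), f2)
  expect_identical(readLines(f1), readLines(f2))
  genome_partial <- sim$genome[-1]
  expect_warning(
    r3 <- gene_screen(sim$genes, genome_partial, sim$dhs, lib,
                      y_patch_model = y_patch_pwm()),
    "skipping"
  )
  expect_equal(nrow(tidy(r3)), 9)
})

test_that("enrichment test matches the closed-form hypergeometric sum", {
  u <- sprintf("g%02d", 1:20)
  # balanced table: no association
  et0 <- enrichment_test(u[1:10], u[c(1:5, 11:15)], u)
  expect_equal(et0$odds_ratio, 1)
  expect_equal(et0$p_value, 1)
  # table (a=9, b=1, c=1, d=9): OR 81, p from the two-sided dhyper sum
  flag <- u[1:10]; class <- u[c(1:9, 11)]
  et <- enrichment_test(flag, class, u)
  expect_equal(et$odds_ratio, 81)
  dens <- dhyper(0:10, 10, 10, 10)
  p_expected <- sum(dens[dens <= dhyper(9, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(et$p_value, p_expected, tolerance = 1e-10)
  # degenerate: flag = universe -> OR undefined but flagged, not an error
  etd <- enrichment_test(u, u[1:10], u)
  expect_false(etd$odds_ratio_defined)
  expect_error(enrichment_test("a", "a", character(0)), "empty")
})

test_that("cross-tabulation ties screen flags to expression classes", {
  cfg <- simulation_config(seed = 31, n_genes = 20)
  sim <- simulate_genome(cfg)
  res <- gene_screen(sim$genes, sim$genome, sim$dhs,
                     builtin_motif_library("crm"),
                     y_patch_model = y_patch_pwm())
  classes <- list(planted_both = sim$truth$gene_id[sim$truth$planted_both])
  ct <- cross_tabulate(res, classes)
  row <- ct[ct$flag == "has_both" & ct$class == "planted_both", ]
  # has_both identifies exactly the planted class -> perfect overlap
  expect_equal(row$n_overlap, sum(sim$truth$planted_both))
  expect_equal(row$b, 0)
  expect_equal(row$c, 0)
})
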