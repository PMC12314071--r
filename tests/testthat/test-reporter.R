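test_that("standard curve fits exact lines exactly and validates input", {
  pts <- tibble::tibble(concentration = c(0, 1, 2),
                        fluorescence = c(0, 10, 20))
  sc <- fit_standard_curve(pts)
  expect_equal(sc$slope, 10)
  expect_equal(sc$intercept, 0)
  expect_equal(sc$r_squared, 1)
  expect_error(fit_standard_curve(pts[1, ]), "2 distinct")
  expect_error(
    fit_standard_curve(tibble::tibble(concentration = c(1, 1),
                                      fluorescence = c(5, 9))),
    "distinct"
  )
  # declining fluorescence: slope must be positive
  expect_error(
    fit_standard_curve(tibble::tibble(concentration = c(0, 1, 2),
                                      fluorescence = c(20, 10, 0))),
    "positive"
  )
})

test_that("noisy standard curve recovers the slope within 3 standard errors", {
  withr::with_seed(301, {
    conc <- seq(0, 9)
    slope <- 250
    fl <- 40 + slope * conc + rnorm(10, 0, 30)
    sc <- fit_standard_curve(tibble::tibble(concentration = conc,
                                            fluorescence = fl))
    se <- summary(sc$fit)$coefficients["concentration", "Std. Error"]
    expect_lt(abs(sc$slope - slope), 3 * se)
  })
})

mk_kinetics <- function(rates_by_dup, curve_slope = 100, intercept = 10,
                        line_id = "L1", construct_id = "C1") {
  t <- seq(0, 38, by = 2)
  dplyr::bind_rows(lapply(seq_along(rates_by_dup), function(d) {
    tibble::tibble(line_id = line_id, construct_id = construct_id,
                   duplicate_id = d, time_min = t,
                   fluorescence = intercept + curve_slope * rates_by_dup[d] * t)
  }))
}

test_that("GUS rate is the duplicate-averaged slope converted and protein-normalised", {
  curve <- fit_standard_curve(tibble::tibble(concentration = 0:9,
                                             fluorescence = 100 * (0:9)))
  kin <- mk_kinetics(c(2, 4))  # AU slopes 200 and 400 -> rates 2 and 4
  lines <- tibble::tibble(line_id = "L1", protein_mg = 0.5)
  out <- gus_rate(kin, curve, lines)
  expect_equal(out$rate, mean(c(2, 4)) / 0.5)   # (s1+s2)/2, per mg
  expect_equal(out$rate_per_second, out$rate / 60)
  expect_equal(out$n_duplicates, 2L)
  expect_error(gus_rate(kin, curve,
                        tibble::tibble(line_id = "L1", protein_mg = 0)),
               "positive")
  bad <- kin[kin$time_min < 5, ]  # 3 readings is fine; 2 is not
  expect_error(gus_rate(bad[bad$time_min < 3, ], curve, lines), ">= 3")
})

test_that("rate estimation is scale-equivariant in fluorescence units", {
  withr::with_seed(303, {
    t <- seq(0, 38, by = 2)
    fl <- 10 + 150 * t + rnorm(20, 0, 5)
    mk <- function(scale) {
      kin <- tibble::tibble(line_id = "L", construct_id = "C",
                            duplicate_id = 1, time_min = t,
                            fluorescence = fl * scale)
      curve <- fit_standard_curve(
        tibble::tibble(concentration = 0:9,
                       fluorescence = scale * 100 * (0:9)))
      gus_rate(kin, curve, tibble::tibble(line_id = "L", protein_mg = 1))$rate
    }
    expect_equal(mk(1), mk(7.5))
  })
})

test_that("LUC/GUS ratio is scale-invariant and log2 works", {
  expect_equal(luc_gus_ratio(100, 10), 10)
  expect_equal(luc_gus_ratio(100 * 3, 10 * 3), 10)
  expect_equal(luc_gus_ratio(80, 10, log2_transform = TRUE), 3)
  expect_error(luc_gus_ratio(100, 0), "positive")
})

test_that("BH adjustment matches the closed form and identical groups share a letter", {
  # closed form: (0.01, 0.02, 0.03) with m = 3 -> (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  withr::with_seed(307, {
    df <- tibble::tibble(
      construct_id = rep(c("A", "B"), each = 6),
      rate = rep(c(1.2, 3.4, 2.2, 4.1, 0.8, 2.9), 2)  # identical groups
    )
    cc <- compare_constructs(df, test = "wilcoxon")
    expect_equal(cc$pairwise$adj_p_value, 1)
    expect_equal(cc$letters$letters, c("a", "a"))
  })
})

test_that("a far-shifted group earns its own letter under both tests", {
  withr::with_seed(311, {
    df <- tibble::tibble(
      construct_id = rep(c("low1", "low2", "high"), each = 8),
      rate = c(rnorm(8, 1, 0.2), rnorm(8, 1.1, 0.2), rnorm(8, 50, 0.5))
    )
    for (tst in c("wilcoxon", "t")) {
      cc <- compare_constructs(df, test = tst)
      lt <- setNames(cc$letters$letters, cc$letters$group)
      expect_equal(lt[["low1"]], lt[["low2"]])
      expect_false(lt[["high"]] %in% c(lt[["low1"]], lt[["low2"]]))
    }
  })
})

test_that("letter sharing exactly reproduces the thresholded adjusted-p matrix", {
  withr::with_seed(313, {
    for (rep in 1:5) {
      k <- sample(3:5, 1)
      df <- tibble::tibble(
        construct_id = rep(sprintf("g%d", seq_len(k)), each = 6),
        rate = rnorm(6 * k, rep(sample(c(1, 1, 5, 20), k, TRUE),
                                each = 6), 0.5)
      )
      cc <- suppressWarnings(compare_constructs(df))
      lt <- setNames(strsplit(cc$letters$letters, ""), cc$letters$group)
      for (i in seq_len(nrow(cc$pairwise))) {
        g1 <- cc$pairwise$group1[i]; g2 <- cc$pairwise$group2[i]
        share <- length(intersect(lt[[g1]], lt[[g2]])) > 0
        expect_equal(share, cc$pairwise$adj_p_value[i] >= cc$alpha)
      }
    }
  })
})

test_that("size-1 groups are excluded with a warning", {
  df <- tibble::tibble(construct_id = c("A", "A", "A", "B", "B", "B", "C"),
                       rate = c(1, 2, 3, 10, 11, 12, 99))
  expect_warning(cc <- compare_constructs(df), "size 1")
  expect_equal(sort(cc$groups$group), c("A", "B"))
})

test_that("fold change is the ratio of group medians to the reference", {
  df <- tibble::tibble(construct_id = rep(c("ref", "up"), each = 5),
                       rate = c(1, 2, 2, 2, 3, 40, 50, 50, 50, 60))
  fc <- fold_change(df, "ref")
  expect_equal(fc$fold[fc$group == "ref"], 1)
  expect_equal(fc$fold[fc$group == "up"], 25)
  expect_error(fold_change(df, "nope"), "not found")
  zero <- tibble::tibble(construct_id = rep(c("z", "u"), each = 3),
                         rate = c(0, 0, 0, 1, 1, 1))
  expect_error(fold_change(zero, "z"), "positive")
})

test_that("wilcoxon path holds its size on null data after BH (single pair)", {
  withr::with_seed(317, {
    n_rep <- 400
    rejections <- 0
    for (i in seq_len(n_rep)) {
      df <- tibble::tibble(construct_id = rep(c("A", "B"), each = 8),
                           rate = rnorm(16))
      cc <- compare_constructs(df, test = "wilcoxon")
      if (cc$pairwise$adj_p_value < 0.05) rejections <- rejections + 1
    }
    # exact test at n = 8 + 8: the attainable size sits just below 0.05, so
    # allow the discreteness gap on top of binomial error
    se <- sqrt(0.05 * 0.95 / n_rep)
    expect_lt(abs(rejections / n_rep - 0.05), 3 * se + 0.01)
  })
})
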