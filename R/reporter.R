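#' Fit a 4-MU standard curve
#'
#' Ordinary least squares of fluorescence on 4-MU amount:
#' `fluorescence = slope * concentration + intercept`. At least two distinct
#' concentrations are required and the slope must come out positive (more
#' 4-MU, more fluorescence).
#'
#' @param points Tibble with columns `concentration` (nmol 4-MU) and
#'   `fluorescence` (arbitrary units).
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `points`, `n`. Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
fit_standard_curve <- function(points) {
  if (!all(c("concentration", "fluorescence") %in% names(points))) {
    abort("points needs columns concentration and fluorescence")
  }
  if (length(unique(points$concentration)) < 2) {
    abort("standard curve needs at least 2 distinct concentrations")
  }
  fit <- lm(fluorescence ~ concentration, data = points)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("standard curve slope must be positive")
  }
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((points$fluorescence - mean(points$fluorescence))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
         points = as_tibble(points), n = nrow(points), fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4g AU/nmol, intercept %.4g, r^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' GUS enzymatic rates from kinetic series
#'
#' Per duplicate reaction, the slope of fluorescence over time (OLS over all
#' cycles) is converted to nmol 4-MU per minute via the standard-curve slope;
#' duplicate rates are averaged per line and divided by the protein amount in
#' the reaction, giving nmol 4-MU/min/mg protein.
#'
#' @param kinetics Long tibble: `line_id`, `construct_id`, `duplicate_id`,
#'   `time_min`, `fluorescence`. Each series needs >= 3 readings with
#'   strictly increasing times.
#' @param curve A [fit_standard_curve()] object.
#' @param lines Tibble `line_id`, `protein_mg` (mg protein in the reaction;
#'   must be positive).
#' @return A tibble of activity measurements: `line_id`, `construct_id`,
#'   `rate` (nmol 4-MU/min/mg protein), `rate_per_second`, `n_duplicates`.
#' @export
gus_rate <- function(kinetics, curve, lines) {
  stopifnot(inherits(curve, "standard_curve"))
  need <- c("line_id", "construct_id", "duplicate_id", "time_min",
            "fluorescence")
  if (!all(need %in% names(kinetics))) {
    abort(sprintf("kinetics needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!all(c("line_id", "protein_mg") %in% names(lines))) {
    abort("lines needs columns line_id and protein_mg")
  }
  if (any(lines$protein_mg <= 0)) abort("protein_mg must be positive")
  slopes <- kinetics |>
    group_by(.data$line_id, .data$construct_id, .data$duplicate_id) |>
    group_modify(function(d, key) {
      if (nrow(d) < 3) abort("each kinetic series needs >= 3 readings")
      if (any(diff(d$time_min) <= 0)) {
        abort("times within a kinetic series must be strictly increasing")
      }
      tibble(au_per_min = unname(coef(lm(fluorescence ~ time_min,
                                         data = d))[2]))
    }) |>
    ungroup()
  out <- slopes |>
    group_by(.data$line_id, .data$construct_id) |>
    summarise(au_per_min = mean(.data$au_per_min),
              n_duplicates = n(), .groups = "drop") |>
    inner_join(lines[, c("line_id", "protein_mg")], by = "line_id") |>
    mutate(
      rate = .data$au_per_min / curve$slope / .data$protein_mg,
      rate_per_second = .data$rate / 60
    ) |>
    select("line_id", "construct_id", "rate", "rate_per_second",
           "n_duplicates")
  if (any(!is.finite(out$rate))) abort("non-finite GUS rate")
  out
}

#' LUC/GUS transactivation ratio
#'
#' Transcriptional activity normalised for transformation efficiency:
#' LUC luminescence divided by the rate of MUG turnover per second.
#' Optionally log2-transformed for downstream group comparisons.
#'
#' @param luc_luminescence Numeric vector of LUC readings.
#' @param gus_rate_per_second Matching numeric vector of GUS rates
#'   (per second; must be positive).
#' @param log2_transform Return log2 of the ratio.
#' @return Numeric vector of ratios (or their log2).
#' @export
luc_gus_ratio <- function(luc_luminescence, gus_rate_per_second,
                          log2_transform = FALSE) {
  if (any(gus_rate_per_second <= 0)) {
    abort("GUS rate must be positive to normalise LUC")
  }
  r <- luc_luminescence / gus_rate_per_second
  if (log2_transform) log2(r) else r
}

#' Pairwise group comparison with BH correction and compact letters
#'
#' All pairwise two-sided tests between constructs (Wilcoxon rank-sum or
#' Welch t), Benjamini-Hochberg correction over the pairwise family, and a
#' compact letter display in which two constructs share a letter exactly when
#' their adjusted p-value is >= `alpha`. Groups of size 1 are excluded with a
#' warning.
#'
#' @param measurements Tibble with a grouping column and a value column.
#' @param value Name of the value column; default `"rate"`.
#' @param group Name of the grouping column; default `"construct_id"`.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param alpha Significance level for the letter display; default 0.05.
#' @return An object of class `construct_comparison`: `pairwise` tibble
#'   (`group1`, `group2`, `statistic`, `p_value`, `adj_p_value`), `letters`
#'   tibble (`group`, `letters`), `groups` summary (n, median), `test`,
#'   `alpha`. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
compare_constructs <- function(measurements, value = "rate",
                               group = "construct_id",
                               test = c("wilcoxon", "t"), alpha = 0.05) {
  test <- match.arg(test)
  if (!all(c(value, group) %in% names(measurements))) {
    abort(sprintf("measurements needs columns '%s' and '%s'", group, value))
  }
  df <- tibble(group = as.character(measurements[[group]]),
               value = measurements[[value]])
  df <- df[is.finite(df$value), , drop = FALSE]
  sizes <- count(df, .data$group)
  tiny <- sizes$group[sizes$n < 2]
  if (length(tiny) > 0) {
    warn(sprintf("excluding group(s) of size 1: %s",
                 paste(tiny, collapse = ", ")))
    df <- df[!df$group %in% tiny, , drop = FALSE]
  }
  groups <- sort(unique(df$group))
  if (length(groups) < 2) abort("need at least 2 groups of size >= 2")
  pairs <- utils::combn(groups, 2)
  pw <- map(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- df$value[df$group == g1]
    y <- df$value[df$group == g2]
    ht <- if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    } else {
      t.test(x, y, alternative = "two.sided")
    }
    tibble(group1 = g1, group2 = g2,
           statistic = unname(ht$statistic), p_value = ht$p.value)
  }) |> bind_rows()
  pw$adj_p_value <- p.adjust(pw$p_value, method = "BH")
  letters <- compact_letter_display(groups, pw, alpha = alpha)
  summary <- df |>
    group_by(group) |>
    summarise(n = n(), median = median(.data$value), .groups = "drop")
  structure(
    list(pairwise = pw, letters = letters, groups = summary,
         test = test, alpha = alpha, data = df),
    class = "construct_comparison"
  )
}

# insert-and-absorb compact letter display: start with one column holding all
# groups; for each significant pair split every column containing both;
# absorb columns that became subsets; label columns a, b, c, ... in order of
# their first group
compact_letter_display <- function(groups, pairwise, alpha = 0.05) {
  cols <- list(groups)
  sig <- pairwise[pairwise$adj_p_value < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  ord <- order(map_int(cols, function(col) min(match(col, groups))))
  cols <- cols[ord]
  lab <- letters[seq_along(cols)]
  tibble(
    group = groups,
    letters = map_chr(groups, function(g) {
      paste(lab[map_lgl(cols, function(col) g %in% col)], collapse = "")
    })
  )
}

#' @export
print.construct_comparison <- function(x, ...) {
  cat(sprintf("<construct_comparison> %d groups, %s test, BH-adjusted, alpha = %g\n",
              nrow(x$groups), x$test, x$alpha))
  print(left_join(x$groups, x$letters, by = "group"))
  invisible(x)
}

#' Fold change of group medians against a reference construct
#'
#' @param measurements Tibble with grouping and value columns.
#' @param reference Reference construct id (median must be positive).
#' @param value,group Column names as in [compare_constructs()].
#' @return A tibble `group`, `median`, `fold` (median / reference median).
#' @export
fold_change <- function(measurements, reference, value = "rate",
                        group = "construct_id") {
  df <- tibble(group = as.character(measurements[[group]]),
               value = measurements[[value]])
  med <- df |>
    group_by(.data$group) |>
    summarise(median = median(.data$value), .groups = "drop")
  if (!reference %in% med$group) {
    abort(sprintf("reference construct '%s' not found", reference))
  }
  ref <- med$median[med$group == reference]
  if (ref <= 0) abort("reference median must be positive")
  mutate(med, fold = .data$median / ref)
}
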