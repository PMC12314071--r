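#' Motif landscape plot
#'
#' Positions of motif hits along a sequence, one row per family, segment
#' height by -log10 p-value — the standard way to eyeball the cis-regulatory
#' landscape of a promoter.
#'
#' @param hits Hit tibble (see [scan_sequence()]).
#' @param sequence_length Optional x-axis limit.
#' @return A ggplot object.
#' @export
plot_motif_landscape <- function(hits, sequence_length = NULL) {
  df <- hits |>
    mutate(family = ifelse(is.na(.data$family), "unassigned", .data$family),
           neglog10p = -log10(.data$p_value))
  p <- ggplot(df, aes(x = .data$start, xend = .data$stop,
                      y = .data$family, yend = .data$family,
                      colour = .data$neglog10p)) +
    geom_segment(linewidth = 3) +
    labs(x = "position (bp)", y = NULL, colour = expression(-log[10] * p)) +
    theme_minimal()
  if (!is.null(sequence_length)) p <- p + xlim(1, sequence_length)
  p
}

#' @describeIn gene_screen Bar chart of per-gene screen flags.
#' @param object A `crm_screen` object.
#' @param ... Unused.
#' @method autoplot crm_screen
#' @export
autoplot.crm_screen <- function(object, ...) {
  df <- object$per_gene |>
    summarise(
      `Y-patch` = sum(.data$has_y_patch),
      CRM = sum(.data$has_crm),
      both = sum(.data$has_both)
    ) |>
    pivot_longer(everything(), names_to = "flag", values_to = "genes")
  ggplot(df, aes(x = factor(.data$flag, levels = c("Y-patch", "CRM", "both")),
                 y = .data$genes)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "genes",
         title = sprintf("CRM screen over %d genes",
                         object$summary$n_genes)) +
    theme_minimal()
}

#' @describeIn fit_standard_curve Scatter of standards with the fitted line.
#' @param object A `standard_curve` object.
#' @param ... Unused.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot(object$points, aes(x = .data$concentration, y = .data$fluorescence)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "red") +
    labs(x = "4-MU (nmol)", y = "fluorescence (AU)",
         title = sprintf("standard curve: slope %.3g, r^2 %.4f",
                         object$slope, object$r_squared)) +
    theme_minimal()
}

#' @describeIn compare_constructs Boxplot with compact-letter labels.
#' @param object A `construct_comparison` object.
#' @param ... Unused.
#' @method autoplot construct_comparison
#' @export
autoplot.construct_comparison <- function(object, ...) {
  lab <- object$data |>
    group_by(.data$group) |>
    summarise(y = max(.data$value), .groups = "drop") |>
    left_join(object$letters, by = "group")
  ggplot(object$data, aes(x = .data$group, y = .data$value)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    geom_text(data = lab, aes(y = .data$y * 1.08, label = .data$letters),
              fontface = "bold") +
    labs(x = NULL, y = "activity",
         subtitle = sprintf("pairwise %s tests, BH-adjusted; groups sharing a letter: adj. p >= %g",
                            object$test, object$alpha)) +
    theme_minimal()
}
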