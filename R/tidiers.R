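#' Tidy a CRM screen result
#'
#' @param x A `crm_screen` object.
#' @param ... Unused.
#' @return The per-gene flag tibble.
#' @method tidy crm_screen
#' @export
tidy.crm_screen <- function(x, ...) x$per_gene

#' One-row summary of a CRM screen
#'
#' @param x A `crm_screen` object.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_y_patch`, `n_crm`, `n_both`.
#' @method glance crm_screen
#' @export
glance.crm_screen <- function(x, ...) as_tibble(x$summary)

#' Tidy a standard curve
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Tibble of terms (`intercept`, `slope`) and estimates.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = x$n)
}

#' Tidy a construct comparison
#'
#' @param x A `construct_comparison` object.
#' @param ... Unused.
#' @return The pairwise test tibble with BH-adjusted p-values.
#' @method tidy construct_comparison
#' @export
tidy.construct_comparison <- function(x, ...) x$pairwise

#' One-row summary of a construct comparison
#'
#' @param x A `construct_comparison` object.
#' @param ... Unused.
#' @return Tibble with `n_groups`, `n_pairs`, `test`, `alpha`.
#' @method glance construct_comparison
#' @export
glance.construct_comparison <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), n_pairs = nrow(x$pairwise),
         test = x$test, alpha = x$alpha)
}
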