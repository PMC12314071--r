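#' Expressed genes from a TPM table
#'
#' A gene is expressed when at least one developmental stage has at least
#' `min_samples` samples with TPM strictly above `tpm_min` (so TPM exactly at
#' the threshold does not count). Stages with fewer than `min_samples`
#' samples can never qualify and trigger a warning.
#'
#' @param expr Long TPM tibble: `gene_id`, `sample`, `tpm`.
#' @param samples Sample metadata tibble: `sample`, `cell_type`, `stage`,
#'   `replicate`.
#' @param tpm_min TPM threshold (strict); default 1.
#' @param min_samples Samples per stage required; default 3.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(expr, samples, tpm_min = 1, min_samples = 3) {
  need <- c("gene_id", "sample", "tpm")
  if (!all(need %in% names(expr))) {
    abort(sprintf("expr needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!all(c("sample", "stage") %in% names(samples))) {
    abort("samples needs columns sample and stage")
  }
  if (any(expr$tpm < 0, na.rm = TRUE)) abort("TPM must be non-negative")
  missing_meta <- setdiff(unique(expr$sample), samples$sample)
  if (length(missing_meta) > 0) {
    abort(sprintf("samples without metadata: %s",
                  paste(head(missing_meta, 5), collapse = ", ")))
  }
  stage_sizes <- count(samples, .data$stage)
  small <- stage_sizes$stage[stage_sizes$n < min_samples]
  if (length(small) > 0) {
    warn(sprintf("stage(s) with fewer than %d samples can never qualify: %s",
                 min_samples, paste(small, collapse = ", ")))
  }
  joined <- inner_join(expr, samples[, c("sample", "stage")], by = "sample")
  ok <- joined |>
    group_by(.data$gene_id, .data$stage) |>
    summarise(n_pass = sum(.data$tpm > tpm_min, na.rm = TRUE),
              .groups = "drop") |>
    filter(.data$n_pass >= min_samples)
  sort(unique(ok$gene_id))
}

#' Bundle-sheath-specific gene filter
#'
#' Conjunction of four conditions on the two contrasts, strict comparisons as
#' printed: `log2fc(BS/M) > 2`, `adjusted_p(BS/M) < 0.01`,
#' `fdr(BS/M) < 0.01`, `log2fc(BS/V) > -0.5`. Genes missing either contrast
#' or carrying missing values fail (conservative).
#'
#' @param de Long differential-expression tibble: `gene_id`, `contrast`
#'   (`"BS_M"`, `"BS_V"`), `log2fc`, `adjusted_p`, `fdr`.
#' @param log2fc_bs_m_min,adj_p_max,fdr_max,log2fc_bs_v_min Thresholds.
#' @return Character vector of passing gene ids.
#' @export
bs_specific_filter <- function(de, log2fc_bs_m_min = 2, adj_p_max = 0.01,
                               fdr_max = 0.01, log2fc_bs_v_min = -0.5) {
  need <- c("gene_id", "contrast", "log2fc", "adjusted_p", "fdr")
  if (!all(need %in% names(de))) {
    abort(sprintf("de needs columns: %s", paste(need, collapse = ", ")))
  }
  bad_p <- c(de$adjusted_p, de$fdr)
  if (any(bad_p < 0 | bad_p > 1, na.rm = TRUE)) {
    abort("adjusted_p and fdr must lie in [0, 1]")
  }
  wide <- de |>
    filter(.data$contrast %in% c("BS_M", "BS_V")) |>
    pivot_wider(id_cols = "gene_id", names_from = "contrast",
                values_from = c("log2fc", "adjusted_p", "fdr"))
  for (col in c("log2fc_BS_M", "adjusted_p_BS_M", "fdr_BS_M", "log2fc_BS_V")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  pass <- with(wide,
    !is.na(log2fc_BS_M) & log2fc_BS_M > log2fc_bs_m_min &
    !is.na(adjusted_p_BS_M) & adjusted_p_BS_M < adj_p_max &
    !is.na(fdr_BS_M) & fdr_BS_M < fdr_max &
    !is.na(log2fc_BS_V) & log2fc_BS_V > log2fc_bs_v_min
  )
  sort(wide$gene_id[pass])
}

#' Rank genes by co-expression with a target gene
#'
#' Pearson correlation with the target on the `log2(TPM + 1)` scale across
#' all samples, ranked descending; ties broken by gene id. Genes with zero
#' variance get `NA` correlation and sort last; a zero-variance target is an
#' error.
#'
#' @param expr Long TPM tibble: `gene_id`, `sample`, `tpm`.
#' @param target_gene Gene id present in `expr`.
#' @param transform Function applied to TPM before correlating; default
#'   `log2(TPM + 1)`.
#' @return A tibble `gene_id`, `correlation`, `rank` (target included, rank
#'   1).
#' @export
coexpression_rank <- function(expr, target_gene,
                              transform = function(x) log2(x + 1)) {
  wide <- expr |>
    mutate(value = transform(.data$tpm)) |>
    pivot_wider(id_cols = "gene_id", names_from = "sample",
                values_from = "value")
  if (!target_gene %in% wide$gene_id) {
    abort(sprintf("target gene '%s' not in expression table", target_gene))
  }
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  tv <- m[target_gene, ]
  if (sd(tv) == 0) abort("target gene has zero variance")
  cors <- suppressWarnings(apply(m, 1, function(x) {
    if (sd(x) == 0) NA_real_ else cor(x, tv)
  }))
  tibble(gene_id = names(cors), correlation = unname(cors)) |>
    arrange(desc(.data$correlation), .data$gene_id) |>
    mutate(rank = row_number())
}
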