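#' Default screen configuration
#'
#' Collects the tunable thresholds of the co-occurrence screen. Scan
#' threshold, per-family cutoffs, the 300-bp window and the region extents
#' follow the published screening procedure; the rest are package defaults.
#'
#' @param scan_p Loose scanning threshold applied to every motif; default
#'   1e-3 (hits are reported at `p <= scan_p`).
#' @param per_family_p Named vector of strict per-family cutoffs (retained at
#'   `p < cutoff`).
#' @param required_families Families a CRM call must contain.
#' @param window_bp Maximum span of one CRM call; default 300.
#' @param core_upstream Core-promoter extent upstream of the TSS; default 200.
#' @param crm_upstream Search-space extent upstream of the TSS; default 2000.
#' @param y_patch_p Y-patch threshold; default 4e-4.
#' @param pseudocount,background,granularity PWM construction parameters.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(scan_p = 1e-3,
                          per_family_p = c(WRKY = 1e-3, G2like = 1e-3,
                                           MYBR_B = 1e-4, DOF = 1e-4,
                                           IDD = 1e-4, DPBF = 1e-4),
                          required_families = names(per_family_p),
                          window_bp = 300,
                          core_upstream = 200, crm_upstream = 2000,
                          y_patch_p = 4e-4,
                          pseudocount = 0.1, background = rep(0.25, 4),
                          granularity = 1/1000) {
  structure(
    list(scan_p = scan_p, per_family_p = per_family_p,
         required_families = required_families, window_bp = window_bp,
         core_upstream = core_upstream, crm_upstream = crm_upstream,
         y_patch_p = y_patch_p, pseudocount = pseudocount,
         background = background, granularity = granularity),
    class = "screen_config"
  )
}

#' Label hits with families and apply per-family p-value cutoffs
#'
#' Each hit gets the family of its motif; hits whose motif has no family are
#' dropped with a warning, as are hits from families without a configured
#' cutoff. A retained hit must pass its family's cutoff strictly
#' (`p_value < cutoff`).
#'
#' @param hits Hit tibble from scanning at the loose threshold.
#' @param family_map Named vector motif_id -> family (hits already carrying a
#'   non-`NA` family keep it when `family_map` is `NULL`).
#' @param per_family_p Named vector of cutoffs per family.
#' @return Filtered hit tibble with a `family` column.
#' @export
label_and_filter_hits <- function(hits, family_map = NULL,
                                  per_family_p = c(WRKY = 1e-3, G2like = 1e-3,
                                                   MYBR_B = 1e-4, DOF = 1e-4,
                                                   IDD = 1e-4, DPBF = 1e-4)) {
  if (nrow(hits) == 0) return(empty_hits())
  if (!is.null(family_map)) {
    hits$family <- family_of(family_map, hits$motif_id)
  } else {
    hits$family[is.na(hits$family)] <- "unassigned"
  }
  unmapped <- hits$family == "unassigned"
  if (any(unmapped)) {
    warn(sprintf("dropping %d hit(s) from motifs without a family",
                 sum(unmapped)))
    hits <- hits[!unmapped, , drop = FALSE]
  }
  known <- hits$family %in% names(per_family_p)
  hits <- hits[known, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  hits[hits$p_value < unname(per_family_p[hits$family]), , drop = FALSE]
}

#' Call CRM windows from family-labelled hits of one gene
#'
#' A cis-regulatory module call exists where one passing hit per required
#' family can be chosen such that the chosen hits span at most `window_bp`
#' bases (max stop - min start + 1) and all lie within one contiguous
#' accessible interval. The hit table must carry a `region_id` column when
#' the search region has several intervals (hits are never bridged across
#' intervals); without one, all hits are assumed to share an interval.
#' Overlapping qualifying windows are merged into one call per locus, and
#' the minimal-span window at each locus is reported with the lowest-p
#' supporting hit per family inside it.
#'
#' @param hits Family-labelled hit tibble (genomic coordinates) for one gene.
#' @param required_families Character vector of families a call needs.
#' @param window_bp Maximum call span in bp; default 300.
#' @return A tibble of CRM calls: `window_start`, `window_end`,
#'   `span_length`, `families_present`, and a `supporting_hits` list column.
#' @export
call_crm_windows <- function(hits,
                             required_families = c("WRKY", "G2like", "MYBR_B",
                                                   "DOF", "IDD", "DPBF"),
                             window_bp = 300) {
  empty <- tibble(window_start = integer(0), window_end = integer(0),
                  span_length = integer(0), families_present = character(0),
                  supporting_hits = list())
  if (nrow(hits) == 0) return(empty)
  if (!"region_id" %in% names(hits)) hits$region_id <- 1L
  hits <- hits[hits$family %in% required_families, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)

  calls <- list()
  for (rid in unique(hits$region_id)) {
    h <- hits[hits$region_id == rid, , drop = FALSE] |>
      arrange(.data$start, .data$stop)
    if (!all(required_families %in% h$family)) next
    n <- nrow(h)
    windows <- list()
    for (i in seq_len(n)) {
      # anchor: h[i] is the leftmost selected hit; for each family take the
      # smallest achievable stop among hits starting at/after the anchor
      cand <- h[h$start >= h$start[i], , drop = FALSE]
      if (!all(required_families %in% cand$family)) break
      fam_stop <- cand |>
        group_by(.data$family) |>
        summarise(min_stop = min(.data$stop), .groups = "drop")
      max_stop <- max(fam_stop$min_stop)
      span <- max_stop - h$start[i] + 1L
      if (span <= window_bp) {
        windows[[length(windows) + 1L]] <-
          tibble(window_start = h$start[i], window_end = as.integer(max_stop),
                 span_length = as.integer(span))
      }
    }
    if (length(windows) == 0) next
    w <- bind_rows(windows)
    merged <- merge_intervals(tibble(start = w$window_start,
                                     end = w$window_end))
    for (k in seq_len(nrow(merged))) {
      inside <- w[w$window_start >= merged$start[k] &
                    w$window_end <= merged$end[k], , drop = FALSE]
      best <- inside[which.min(inside$span_length), , drop = FALSE]
      sup <- h[h$start >= best$window_start & h$stop <= best$window_end, ,
               drop = FALSE] |>
        filter(.data$family %in% required_families) |>
        group_by(.data$family) |>
        arrange(.data$p_value, .data$start, .by_group = TRUE) |>
        slice(1) |>
        ungroup()
      calls[[length(calls) + 1L]] <- tibble(
        window_start = best$window_start, window_end = best$window_end,
        span_length = best$span_length,
        families_present = paste(sort(unique(sup$family)), collapse = ","),
        supporting_hits = list(sup)
      )
    }
  }
  if (length(calls) == 0) return(empty)
  bind_rows(calls) |> arrange(.data$window_start)
}

#' Genome-wide Y-patch x CRM co-occurrence screen
#'
#' For every gene: (1) annotate the core promoter (TSS - 200 to the base
#' before the translational start, transcript orientation) for
#' orientation-correct Y-patches; (2) scan the accessible search space
#' (TSS - 2000 to the 3'UTR end, intersected with DHS intervals) with the
#' motif library at the loose threshold; (3) apply the per-family cutoffs and
#' call six-family windows of at most 300 bp within single accessible
#' intervals. Genes missing from the genome are skipped with a warning.
#'
#' @param genes Gene model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param dhs DHS tibble (`chrom`, `start`, `end`), or `NULL` for
#'   unrestricted search space.
#' @param library Motif library tibble (family labels required unless
#'   `family_map` given).
#' @param family_map Optional named vector motif_id -> family.
#' @param y_patch_model `pwm` for Y-patch detection (`NULL` = fallback rule).
#' @param config A [screen_config()].
#' @return An object of class `crm_screen`: list with `per_gene` (gene_id,
#'   has_y_patch, y_patch_count, has_crm, n_crm_calls, has_both), `crm_calls`
#'   (per-gene call table, genomic coordinates), `config` and `summary`
#'   counts. `tidy()` returns the per-gene table, `glance()` the counts.
#' @export
gene_screen <- function(genes, genome, dhs, library, family_map = NULL,
                        y_patch_model = NULL, config = screen_config()) {
  validate_gene_models(genes)
  present <- genes$chrom %in% names(genome)
  if (any(!present)) {
    warn(sprintf("skipping %d gene(s) on chromosomes absent from genome",
                 sum(!present)))
    genes <- genes[present, , drop = FALSE]
  }
  chrom_len <- nchar(genome)

  core <- annotate_core_promoters(
    genes, genome, y_patch_model = y_patch_model,
    y_patch_p = config$y_patch_p, upstream_len = config$core_upstream
  )

  search <- crm_search_region(genes, dhs, upstream_len = config$crm_upstream,
                              chrom_length = chrom_len)
  pwms <- library_pwms(library, pseudocount = config$pseudocount,
                       background = config$background,
                       granularity = config$granularity)
  if (!is.null(family_map)) {
    for (i in seq_along(pwms)) {
      pwms[[i]]$family <- family_of(family_map, pwms[[i]]$motif_id)
    }
  }
  pwms <- Filter(function(p) isTRUE(p$family %in% config$required_families),
                 pwms)
  scanners <- map(pwms, make_scanner, strands = "both")

  per_gene <- vector("list", nrow(genes))
  all_calls <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    regions <- search[search$gene_id == g$gene_id, , drop = FALSE]
    hits <- list()
    if (nrow(regions) > 0) {
      seqs <- substring(genome[regions$chrom], regions$start, regions$end)
      for (ri in seq_len(nrow(regions))) {
        for (scanner in scanners) {
          h <- scan_with_scanner(seqs[[ri]], scanner,
                                 p_threshold = config$scan_p,
                                 sequence_name = g$gene_id)
          if (nrow(h) > 0) {
            h$start <- h$start + regions$start[ri] - 1L
            h$stop <- h$stop + regions$start[ri] - 1L
            h$region_id <- ri
            hits[[length(hits) + 1L]] <- h
          }
        }
      }
    }
    hits <- if (length(hits) > 0) bind_rows(hits) else empty_hits()
    passing <- label_and_filter_hits(hits, family_map = NULL,
                                     per_family_p = config$per_family_p)
    calls <- call_crm_windows(passing,
                              required_families = config$required_families,
                              window_bp = config$window_bp)
    if (nrow(calls) > 0) {
      calls <- mutate(calls, gene_id = g$gene_id, .before = 1)
      all_calls[[length(all_calls) + 1L]] <- calls
    }
    yc <- core$y_patch_count[core$gene_id == g$gene_id]
    yc <- if (length(yc) == 0) 0L else yc[1]
    per_gene[[gi]] <- tibble(
      gene_id = g$gene_id,
      has_y_patch = yc > 0L,
      y_patch_count = yc,
      has_crm = nrow(calls) > 0L,
      n_crm_calls = nrow(calls)
    )
  }
  per_gene <- bind_rows(per_gene) |>
    mutate(has_both = .data$has_y_patch & .data$has_crm)
  crm_calls <- if (length(all_calls) > 0) bind_rows(all_calls) else
    tibble(gene_id = character(0), window_start = integer(0),
           window_end = integer(0), span_length = integer(0),
           families_present = character(0), supporting_hits = list())
  res <- structure(
    list(
      per_gene = per_gene,
      crm_calls = crm_calls,
      config = config,
      summary = list(
        n_genes = nrow(per_gene),
        n_y_patch = sum(per_gene$has_y_patch),
        n_crm = sum(per_gene$has_crm),
        n_both = sum(per_gene$has_both)
      )
    ),
    class = "crm_screen"
  )
  cs_log("screen: %d genes, %d with Y-patch, %d with CRM, %d with both",
         res$summary$n_genes, res$summary$n_y_patch,
         res$summary$n_crm, res$summary$n_both)
  res
}

#' @export
print.crm_screen <- function(x, ...) {
  cat(sprintf(
    "<crm_screen> %d genes: %d with core Y-patch, %d with CRM call, %d with both\n",
    x$summary$n_genes, x$summary$n_y_patch, x$summary$n_crm, x$summary$n_both
  ))
  invisible(x)
}

#' Enrichment of a gene flag within a gene class
#'
#' Builds the 2x2 table of `flag` x `class` over `universe` and tests
#' association with Fisher's exact two-sided test. The reported odds ratio is
#' the sample (cross-product) odds ratio; it is `Inf`/`NaN`-flagged for
#' degenerate tables rather than dropped.
#'
#' @param flag,class Gene-id character vectors (subsets of `universe`).
#' @param universe Character vector of all genes screened.
#' @return One-row tibble: counts `a` (flag & class), `b` (flag only), `c`
#'   (class only), `d` (neither), `odds_ratio`, `p_value`,
#'   `odds_ratio_defined`.
#' @export
enrichment_test <- function(flag, class, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  if (!all(flag %in% universe) || !all(class %in% universe)) {
    abort("flag and class must be subsets of the universe")
  }
  u <- unique(universe)
  f <- u %in% flag
  k <- u %in% class
  a <- sum(f & k); b <- sum(f & !k); c_ <- sum(!f & k); d <- sum(!f & !k)
  or <- (a * d) / (b * c_)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  tibble(a = a, b = b, c = c_, d = d,
         odds_ratio = or, p_value = p,
         odds_ratio_defined = is.finite(or))
}

#' Cross-tabulate screen flags against expression classes
#'
#' @param screen A `crm_screen` object.
#' @param classes Named list of gene-id vectors (e.g. expressed,
#'   bs_specific).
#' @return A tibble with one row per (flag, class) pair: overlap count and
#'   enrichment statistics over the screened universe.
#' @export
cross_tabulate <- function(screen, classes) {
  stopifnot(inherits(screen, "crm_screen"))
  pg <- screen$per_gene
  universe <- pg$gene_id
  flags <- list(
    has_y_patch = pg$gene_id[pg$has_y_patch],
    has_crm = pg$gene_id[pg$has_crm],
    has_both = pg$gene_id[pg$has_both]
  )
  rows <- list()
  for (fn in names(flags)) {
    for (cn in names(classes)) {
      cl <- intersect(classes[[cn]], universe)
      et <- enrichment_test(flags[[fn]], cl, universe)
      rows[[length(rows) + 1L]] <- mutate(
        et, flag = fn, class = cn, n_overlap = et$a, .before = 1
      )
    }
  }
  bind_rows(rows)
}
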