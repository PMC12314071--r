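#' Simulation configuration
#'
#' Fixes every knob of the synthetic-data generator. Defaults emulate the
#' study conditions the pipeline is built for: genes of 2-6 kb at 40% GC,
#' six-family CRM sextets planted within a bounded span inside accessible
#' chromatin, orientation-correct Y-patches in core promoters, a 7-stage
#' three-cell-type expression design with 3-4 replicates, and 2-min x
#' 20-cycle reporter kinetics.
#'
#' @param seed Integer seed; fixes all randomness (per-stage sub-streams are
#'   derived from it so the genome, expression and kinetics draws do not
#'   perturb one another).
#' @param n_genes Number of genes; default 100.
#' @param gene_length_range Gene span (TSS to 3'UTR end) range in bp.
#' @param gc Background GC fraction; default 0.4.
#' @param fractions Named fractions of genes receiving `both`, `crm_only`,
#'   `ypatch_only`, `neither`; must sum to 1.
#' @param crm_span_range Range of planted sextet spans in bp (max must stay
#'   at or below the caller's window).
#' @param family_consensus Named consensus strings planted per family.
#' @param dhs_mode `"cover-plants"` (DHS over each planted CRM plus a decoy),
#'   `"exclude-plants"` (DHS avoiding the plants) or `"whole-chromosome"`.
#' @param utr5_len 5'UTR length in bp.
#' @param upstream_flank,downstream_flank Intergenic context around each
#'   gene (each gene sits on its own chromosome).
#' @param n_stages,cell_types,replicates Expression design.
#' @param bs_log2fc_mean,bs_log2fc_sd BS/M effect size for planted
#'   bundle-sheath-specific genes (truncated above 2).
#' @param n_lines,true_rate_range,kinetic_sd,n_cycles,cycle_min Reporter
#'   kinetics design; `kinetic_sd` is the fluorescence noise SD (AU).
#' @param curve_slope,curve_intercept,protein_mg Standard curve (AU per nmol
#'   4-MU) and protein per reaction.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 100,
                              gene_length_range = c(2000, 6000), gc = 0.4,
                              fractions = c(both = 0.4, crm_only = 0.2,
                                            ypatch_only = 0.2, neither = 0.2),
                              crm_span_range = c(150, 290),
                              family_consensus = CRM_FAMILY_CONSENSUS,
                              dhs_mode = c("cover-plants", "exclude-plants",
                                           "whole-chromosome"),
                              utr5_len = 150, upstream_flank = 2500,
                              downstream_flank = 300,
                              n_stages = 7, cell_types = c("BS", "M", "V"),
                              replicates = c(4, 4, 4, 4, 3, 3, 3),
                              bs_log2fc_mean = 3, bs_log2fc_sd = 0.5,
                              n_lines = 12, true_rate_range = c(0.2, 5),
                              kinetic_sd = 20, n_cycles = 20, cycle_min = 2,
                              curve_slope = 1000, curve_intercept = 50,
                              protein_mg = 0.02) {
  dhs_mode <- match.arg(dhs_mode)
  if (abs(sum(fractions) - 1) > 1e-9) abort("class fractions must sum to 1")
  if (!all(c("both", "crm_only", "ypatch_only", "neither") %in%
           names(fractions))) {
    abort("fractions needs both, crm_only, ypatch_only, neither")
  }
  if (length(replicates) != n_stages) {
    abort("replicates must give one count per stage")
  }
  structure(
    list(seed = as.integer(seed), n_genes = n_genes,
         gene_length_range = gene_length_range, gc = gc,
         fractions = fractions, crm_span_range = crm_span_range,
         family_consensus = family_consensus, dhs_mode = dhs_mode,
         utr5_len = utr5_len, upstream_flank = upstream_flank,
         downstream_flank = downstream_flank,
         n_stages = n_stages, cell_types = cell_types,
         replicates = replicates,
         bs_log2fc_mean = bs_log2fc_mean, bs_log2fc_sd = bs_log2fc_sd,
         n_lines = n_lines, true_rate_range = true_rate_range,
         kinetic_sd = kinetic_sd, n_cycles = n_cycles, cycle_min = cycle_min,
         curve_slope = curve_slope, curve_intercept = curve_intercept,
         protein_mg = protein_mg),
    class = "sim_config"
  )
}

# per-stage sub-seed, kept below 2^31
sub_seed <- function(config, stage) {
  (config$seed * 101L + stage * 7919L) %% .Machine$integer.max
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# break any run of >= 12 pyrimidines by flipping its middle base to purine,
# so cores without a planted Y-patch carry none (keeps the truth table
# consistent with the emitted sequence)
scrub_pyrimidine_runs <- function(seq, max_run = 11) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  repeat {
    pyr <- x %in% c("C", "T")
    r <- rle(pyr)
    ends <- cumsum(r$lengths)
    long <- which(r$values & r$lengths > max_run)
    if (length(long) == 0) break
    for (k in long) {
      mid <- ends[k] - r$lengths[k] %/% 2
      x[mid] <- "G"
    }
  }
  paste(x, collapse = "")
}

random_y_patch <- function(len = 12) {
  y <- sample(c("C", "T"), len, replace = TRUE)
  y[sample(len, 1)] <- "C"  # guarantee at least one C
  paste(y, collapse = "")
}

#' Simulate a genome with planted CRMs and Y-patches
#'
#' Each gene sits on its own chromosome with intergenic flanks. Genes of
#' class `both` or `crm_only` carry one consensus string per required family,
#' on random strands, within a span no wider than the configured limit,
#' placed upstream of the TSS inside accessible chromatin; genes of class
#' `both` or `ypatch_only` additionally carry an orientation-correct
#' 12-base pyrimidine patch in the core promoter. Core promoters of genes
#' without a planted Y-patch are scrubbed of accidental pyrimidine runs so
#' the truth table stays consistent with the emitted sequence. Deterministic
#' per seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_genome`: `genome` (named sequences), `genes`
#'   (gene model tibble, plus `gene_start`/`gene_end`/`cds_end` for GFF3
#'   export), `dhs` (interval tibble), `truth` (per-gene planted flags and
#'   loci), `planted` (per-motif planted positions).
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config, 1L), {
    n <- config$n_genes
    classes <- rep(names(config$fractions),
                   times = round(config$fractions * n))
    if (length(classes) < n) {
      classes <- c(classes, rep("neither", n - length(classes)))
    }
    classes <- sample(classes[seq_len(n)])
    ids <- sprintf("gene%03d", seq_len(n))
    cons <- toupper(config$family_consensus)
    min_len <- config$utr5_len + 400
    if (min(config$gene_length_range) < min_len) {
      abort(sprintf("gene too short for plants: need >= %d bp", min_len))
    }

    genome <- character(n); names(genome) <- ids
    gene_rows <- vector("list", n)
    dhs_rows <- list()
    truth_rows <- vector("list", n)
    planted_rows <- list()

    for (i in seq_len(n)) {
      gid <- ids[i]
      strand <- sample(c("+", "-"), 1)
      glen <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2]), 1)
      chrom_len <- config$upstream_flank + glen + config$downstream_flank
      seq_fwd <- random_dna(chrom_len, config$gc)

      # transcript-orientation template: positions 1..chrom_len with the TSS
      # at upstream_flank + 1; edits happen here, then the chromosome is
      # written out as-is (+) or reverse-complemented (-)
      tss_t <- config$upstream_flank + 1L
      atg_t <- tss_t + config$utr5_len
      utr3_t <- tss_t + glen - 1L
      x <- seq_fwd

      core_s <- tss_t - 200L
      core_e <- atg_t - 1L
      core_seq <- substring(x, core_s, core_e)
      has_ypatch <- classes[i] %in% c("both", "ypatch_only")
      ypatch_t <- c(NA_integer_, NA_integer_)
      if (has_ypatch) {
        yp <- random_y_patch()
        off <- sample(20:(config$utr5_len + 150), 1)  # start within core
        ys <- core_s + off - 1L
        substr(x, ys, ys + nchar(yp) - 1L) <- yp
        ypatch_t <- c(ys, ys + nchar(yp) - 1L)
        # rebuild core around the plant without accidental second patches
        left <- substring(x, core_s, ys - 1L)
        right <- substring(x, ys + nchar(yp), core_e)
        substr(x, core_s, ys - 1L) <- scrub_pyrimidine_runs(left)
        substr(x, ys + nchar(yp), core_e) <- scrub_pyrimidine_runs(right)
      } else {
        substr(x, core_s, core_e) <- scrub_pyrimidine_runs(core_seq)
      }

      has_crm <- classes[i] %in% c("both", "crm_only")
      crm_t <- c(NA_integer_, NA_integer_)
      if (has_crm) {
        span <- sample(seq(config$crm_span_range[1],
                           config$crm_span_range[2]), 1)
        fams <- sample(names(cons))
        widths <- nchar(cons[fams])
        gap_total <- span - sum(widths)
        if (gap_total < 0) abort("crm span too small for consensus strings")
        cuts <- sort(sample(0:gap_total, length(fams) - 1, replace = TRUE))
        gaps <- diff(c(0, cuts, gap_total))[seq_len(length(fams) - 1)]
        # keep the sextet upstream of the core region (TSS-200) so it can
        # never overwrite a planted Y-patch, and inside the TSS-2000 span
        crm_start_t <- tss_t - sample((span + 220L):1800L, 1)
        pos <- crm_start_t
        for (k in seq_along(fams)) {
          s_str <- cons[[fams[k]]]
          if (sample(c(TRUE, FALSE), 1)) s_str <- revcomp(s_str)
          substr(x, pos, pos + nchar(s_str) - 1L) <- s_str
          planted_rows[[length(planted_rows) + 1L]] <- tibble(
            gene_id = gid, family = fams[k],
            start_t = pos, end_t = pos + nchar(s_str) - 1L
          )
          pos <- pos + nchar(s_str) + if (k < length(fams)) gaps[k] else 0L
        }
        crm_t <- c(crm_start_t, pos - 1L)
      }

      # map template coordinate to genomic (forward-strand) coordinate
      to_gen <- function(p) {
        if (strand == "+") as.integer(p) else as.integer(chrom_len - p + 1L)
      }
      genome[[gid]] <- if (strand == "+") x else revcomp(x)
      tss_g <- to_gen(tss_t); atg_g <- to_gen(atg_t); utr3_g <- to_gen(utr3_t)
      cds_end_t <- utr3_t - 100L  # 100-bp 3'UTR
      gene_rows[[i]] <- tibble(
        gene_id = gid, chrom = gid, strand = strand,
        tss = tss_g, translational_start = atg_g, utr3_end = utr3_g,
        gene_start = min(tss_g, utr3_g), gene_end = max(tss_g, utr3_g),
        cds_end = to_gen(cds_end_t)
      )
      crm_g <- sort(c(to_gen(crm_t[1]), to_gen(crm_t[2])))
      yp_g <- sort(c(to_gen(ypatch_t[1]), to_gen(ypatch_t[2])))
      if (!has_crm) crm_g <- c(NA_integer_, NA_integer_)
      if (!has_ypatch) yp_g <- c(NA_integer_, NA_integer_)

      if (config$dhs_mode == "whole-chromosome") {
        dhs_rows[[length(dhs_rows) + 1L]] <- tibble(
          chrom = gid, start = 1L, end = as.integer(chrom_len))
      } else if (config$dhs_mode == "cover-plants") {
        if (has_crm) {
          dhs_rows[[length(dhs_rows) + 1L]] <- tibble(
            chrom = gid,
            start = max(1L, crm_g[1] - 150L),
            end = min(as.integer(chrom_len), crm_g[2] + 150L))
        }
        # decoy interval in the gene body
        body_s <- min(atg_g, to_gen(cds_end_t))
        dhs_rows[[length(dhs_rows) + 1L]] <- tibble(
          chrom = gid, start = as.integer(body_s),
          end = as.integer(body_s + 400L))
      } else {  # exclude-plants: accessible gene body only, away from plants
        body_s <- min(atg_g, to_gen(cds_end_t))
        iv <- tibble(chrom = gid, start = as.integer(body_s),
                     end = as.integer(body_s + 400L))
        if (has_crm && iv$end >= crm_g[1] && iv$start <= crm_g[2]) {
          iv$start <- crm_g[2] + 50L
          iv$end <- iv$start + 400L
        }
        dhs_rows[[length(dhs_rows) + 1L]] <- iv
      }

      truth_rows[[i]] <- tibble(
        gene_id = gid, class = classes[i], strand = strand,
        planted_crm = has_crm, planted_ypatch = has_ypatch,
        planted_both = has_crm && has_ypatch,
        crm_start = crm_g[1], crm_end = crm_g[2],
        ypatch_start = yp_g[1], ypatch_end = yp_g[2]
      )
    }
    genes <- bind_rows(gene_rows)
    validate_gene_models(genes)
    out <- list(
      genome = genome,
      genes = genes,
      dhs = bind_rows(dhs_rows),
      truth = bind_rows(truth_rows),
      planted = if (length(planted_rows) > 0) bind_rows(planted_rows) else
        tibble(gene_id = character(0), family = character(0),
               start_t = integer(0), end_t = integer(0)),
      config = config
    )
    class(out) <- "sim_genome"
    out
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d genes (%s), dhs_mode %s, seed %d\n",
              nrow(x$genes),
              paste(sprintf("%s:%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", "),
              x$config$dhs_mode, x$config$seed))
  invisible(x)
}

#' Write a simulated genome to FASTA + GFF3 + BED + truth TSV
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_sim_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    bed = file.path(dir, "dhs.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(sim$genome, paths[["fasta"]])
  write_gene_models_gff3(sim$genes, paths[["gff3"]])
  write_dhs(sim$dhs, paths[["bed"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Simulate expression and differential-expression tables with known truth
#'
#' Builds a TPM table over the configured stages/cell types/replicates and a
#' two-contrast differential-expression table. A subset of genes is planted
#' as bundle-sheath specific: their BS/M log2 fold change is drawn from
#' Normal(mean, sd) truncated above 2, their adjusted p and FDR below the
#' 0.01 thresholds, and BS/V above -0.5; every other gene violates at least
#' one condition, including deliberate boundary cases sitting exactly on the
#' strict thresholds (log2FC = 2, TPM = 1). Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param truth Optional `sim_genome` truth tibble; genes of class `both`
#'   become the planted BS-specific set (plus a few others for contrast).
#'   Without it, gene ids are generated.
#' @return A list of class `sim_expression`: `expr` (long TPM), `samples`
#'   metadata, `de` (long DE stats), `truth` (per-gene `bs_specific`,
#'   `expressed` flags).
#' @export
simulate_expression <- function(config = simulation_config(), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config, 2L), {
    ids <- if (!is.null(truth)) truth$gene_id else
      sprintf("gene%03d", seq_len(config$n_genes))
    n <- length(ids)
    bs_specific <- if (!is.null(truth)) {
      truth$planted_both | (runif(n) < 0.05 & !truth$planted_both)
    } else {
      runif(n) < 0.25
    }
    # boundary + silent genes carved from the non-BS-specific pool
    expressed <- rep(TRUE, n)
    pool <- which(!bs_specific)
    silent <- pool[seq_len(min(5, length(pool)))]
    boundary_tpm <- pool[seq_len(min(7, length(pool)))[-seq_len(min(5, length(pool)))]]
    expressed[silent] <- FALSE
    expressed[boundary_tpm] <- FALSE  # TPM exactly 1 everywhere: not expressed

    samples <- tibble()
    for (st in seq_len(config$n_stages)) {
      for (ct in config$cell_types) {
        for (r in seq_len(config$replicates[st])) {
          samples <- bind_rows(samples, tibble(
            sample = sprintf("%s_S%d_R%d", ct, st, r),
            cell_type = ct, stage = st, replicate = r
          ))
        }
      }
    }

    base <- exp(rnorm(n, log(20), 1))
    expr <- vector("list", n)
    for (i in seq_len(n)) {
      # expressed genes are shifted 2 TPM up so every sample clears the
      # strict TPM > 1 rule; non-expressed ones are capped safely below it
      tpm <- if (expressed[i]) {
        2 + base[i] * exp(rnorm(nrow(samples), 0, 0.3))
      } else {
        0.2 * exp(rnorm(nrow(samples), 0, 0.3))
      }
      if (bs_specific[i]) {
        bs <- samples$cell_type == "BS"
        tpm[bs] <- tpm[bs] * 8
      }
      if (i %in% silent) tpm <- rep(0, nrow(samples))
      if (i %in% boundary_tpm) tpm <- rep(1, nrow(samples))
      expr[[i]] <- tibble(gene_id = ids[i], sample = samples$sample,
                          tpm = tpm)
    }
    expr <- bind_rows(expr)

    # DE stats: planted BS-specific genes pass all four conditions; others
    # violate at least one (some exactly on the boundary)
    truncated_above <- function(n, mean, sd, lower) {
      x <- rnorm(n, mean, sd)
      while (any(x <= lower)) x[x <= lower] <- rnorm(sum(x <= lower), mean, sd)
      x
    }
    l2fc_m <- numeric(n); adjp <- numeric(n); fdr <- numeric(n)
    l2fc_v <- numeric(n)
    nb <- sum(bs_specific)
    l2fc_m[bs_specific] <- truncated_above(nb, config$bs_log2fc_mean,
                                           config$bs_log2fc_sd, 2)
    adjp[bs_specific] <- runif(nb, 0, 0.009)
    fdr[bs_specific] <- runif(nb, 0, 0.009)
    l2fc_v[bs_specific] <- runif(nb, -0.4, 2)
    nn <- sum(!bs_specific)
    l2fc_m[!bs_specific] <- runif(nn, -2, 1.8)
    adjp[!bs_specific] <- runif(nn, 0, 1)
    fdr[!bs_specific] <- runif(nn, 0, 1)
    l2fc_v[!bs_specific] <- runif(nn, -2, 2)
    # boundary violations: strong everywhere except one exactly-at-threshold
    idx <- which(!bs_specific)
    if (length(idx) >= 2) {
      b1 <- idx[1]  # log2FC(BS/M) exactly 2: must fail the strict >
      l2fc_m[b1] <- 2; adjp[b1] <- 0.001; fdr[b1] <- 0.001; l2fc_v[b1] <- 1
      b2 <- idx[2]  # adjusted p exactly 0.01: must fail the strict <
      l2fc_m[b2] <- 3; adjp[b2] <- 0.01; fdr[b2] <- 0.001; l2fc_v[b2] <- 1
    }
    de <- bind_rows(
      tibble(gene_id = ids, contrast = "BS_M", log2fc = l2fc_m,
             adjusted_p = adjp, fdr = fdr),
      tibble(gene_id = ids, contrast = "BS_V", log2fc = l2fc_v,
             adjusted_p = runif(n, 0, 1), fdr = runif(n, 0, 1))
    )
    structure(
      list(expr = expr, samples = samples, de = de,
           truth = tibble(gene_id = ids, bs_specific = bs_specific,
                          expressed = expressed)),
      class = "sim_expression"
    )
  })
}

#' Simulate reporter kinetics with known rates
#'
#' Ten 4-MU standards spanning the dynamic range define the conversion
#' curve. Each line gets duplicate reactions read every `cycle_min` minutes
#' for `n_cycles` cycles; fluorescence follows
#' `intercept + slope * rate * t + Normal(0, sd)` where `rate` is the line's
#' true MUG turnover (nmol 4-MU/min). Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param sd Fluorescence noise SD; defaults to `config$kinetic_sd` (set 0
#'   for the noiseless check).
#' @return A list of class `sim_kinetics`: `standards`, `kinetics` (long
#'   series table), `lines` (`line_id`, `construct_id`, `protein_mg`),
#'   `truth` (`line_id`, true `rate` per reaction and per mg).
#' @export
simulate_kinetics <- function(config = simulation_config(),
                              sd = config$kinetic_sd) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config, 3L), {
    rates <- runif(config$n_lines, config$true_rate_range[1],
                   config$true_rate_range[2])
    if (any(rates <= 0)) abort("true rates must be positive")
    lines <- tibble(
      line_id = sprintf("line%02d", seq_len(config$n_lines)),
      construct_id = sprintf("construct%d",
                             rep_len(1:3, config$n_lines)),
      protein_mg = config$protein_mg
    )
    t_min <- seq(0, by = config$cycle_min, length.out = config$n_cycles)
    max_amount <- max(rates) * max(t_min)
    standards <- tibble(
      concentration = seq(0, max_amount, length.out = 10),
      fluorescence = config$curve_intercept +
        config$curve_slope * seq(0, max_amount, length.out = 10)
    )
    kin <- vector("list", config$n_lines * 2)
    j <- 0L
    for (i in seq_len(config$n_lines)) {
      for (dup in 1:2) {
        j <- j + 1L
        kin[[j]] <- tibble(
          line_id = lines$line_id[i],
          construct_id = lines$construct_id[i],
          duplicate_id = dup,
          time_min = t_min,
          fluorescence = config$curve_intercept +
            config$curve_slope * rates[i] * t_min +
            rnorm(length(t_min), 0, sd)
        )
      }
    }
    structure(
      list(standards = standards, kinetics = bind_rows(kin), lines = lines,
           truth = tibble(line_id = lines$line_id,
                          construct_id = lines$construct_id,
                          rate_nmol_min = rates,
                          rate_per_mg = rates / config$protein_mg)),
      class = "sim_kinetics"
    )
  })
}
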