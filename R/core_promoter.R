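#' Detect Y-patches in a core-promoter sequence
#'
#' The pyrimidine patch (Y-patch) is a TC-rich plant core-promoter element
#' that is orientation-specific: only hits in the same orientation as the
#' gene count, so the input must be the core-promoter sequence in gene
#' orientation and only the forward strand is scanned.
#'
#' Two detection modes are available. With a PWM (`y_patch_model`), windows
#' with occurrence p-value at or below `p_threshold` are reported. Without a
#' model, a documented fallback rule is applied: maximal runs built from
#' windows of length >= `rule_length` with pyrimidine fraction >=
#' `rule_pyrimidine_frac` and at least one C, merged over overlaps (those
#' hits carry `NA` score and p-value).
#'
#' @param core_sequence Core-promoter sequence in gene orientation.
#' @param y_patch_model A `pwm` object, or `NULL` to use the fallback rule
#'   (see [y_patch_pwm()] for the built-in synthetic model).
#' @param p_threshold P-value threshold for PWM mode; default 4e-4.
#' @param use_rule Allow the fallback rule when no model is given.
#' @param rule_length,rule_pyrimidine_frac Fallback-rule parameters.
#' @param sequence_name Name recorded in the hit table.
#' @return Hit tibble (forward strand only).
#' @export
detect_y_patch <- function(core_sequence, y_patch_model = NULL,
                           p_threshold = 4e-4, use_rule = TRUE,
                           rule_length = 8, rule_pyrimidine_frac = 0.8,
                           sequence_name = "core") {
  if (!is.null(y_patch_model)) {
    hits <- scan_sequence(core_sequence, y_patch_model,
                          p_threshold = p_threshold, strands = "forward",
                          sequence_name = sequence_name)
    hits$family <- "Ypatch"
    return(hits)
  }
  if (!use_rule) abort("no Y-patch model supplied and fallback rule disabled")
  x <- strsplit(toupper(core_sequence), "", fixed = TRUE)[[1]]
  n <- length(x)
  L <- as.integer(rule_length)
  if (n < L) return(empty_hits())
  pyr <- as.integer(x %in% c("C", "T"))
  isc <- as.integer(x == "C")
  cpyr <- c(0L, cumsum(pyr))
  cc <- c(0L, cumsum(isc))
  starts <- seq_len(n - L + 1L)
  frac <- (cpyr[starts + L] - cpyr[starts]) / L
  has_c <- (cc[starts + L] - cc[starts]) >= 1L
  ok <- which(frac >= rule_pyrimidine_frac & has_c)
  if (length(ok) == 0) return(empty_hits())
  merged <- merge_intervals(tibble(start = ok, end = ok + L - 1L))
  tibble(
    motif_id = "ypatch_rule", family = "Ypatch",
    sequence_name = sequence_name,
    start = as.integer(merged$start), stop = as.integer(merged$end),
    strand = "+",
    score = NA_real_, p_value = NA_real_,
    matched_sequence = substring(toupper(core_sequence),
                                 merged$start, merged$end)
  )
}

#' Detect TATA-box variants by exact hexamer match
#'
#' Reports every occurrence (overlaps included) of the configured TATA
#' hexamers in the given orientation; optionally adds PWM hits when a TATA
#' matrix is supplied.
#'
#' @param core_sequence Core-promoter sequence in gene orientation.
#' @param hexamers Exact-match strings; default `TATAAA` and `ATTAAA`.
#' @param tata_pwm Optional `pwm` for PWM-mode detection.
#' @param p_threshold P-value threshold for PWM mode.
#' @param sequence_name Name recorded in the hit table.
#' @return Hit tibble; exact matches carry `NA` score/p-value.
#' @export
detect_tata_variant <- function(core_sequence,
                                hexamers = c("TATAAA", "ATTAAA"),
                                tata_pwm = NULL, p_threshold = 1e-3,
                                sequence_name = "core") {
  seq_up <- toupper(core_sequence)
  out <- list()
  for (hx in hexamers) {
    pos <- gregexpr(paste0("(?=", hx, ")"), seq_up, perl = TRUE)[[1]]
    pos <- pos[pos > 0]
    if (length(pos) > 0) {
      out[[hx]] <- tibble(
        motif_id = hx, family = "TATA", sequence_name = sequence_name,
        start = as.integer(pos), stop = as.integer(pos + nchar(hx) - 1L),
        strand = "+", score = NA_real_, p_value = NA_real_,
        matched_sequence = hx
      )
    }
  }
  if (!is.null(tata_pwm)) {
    ph <- scan_sequence(core_sequence, tata_pwm, p_threshold = p_threshold,
                        strands = "forward", sequence_name = sequence_name)
    ph$family <- "TATA"
    out <- c(out, list(ph))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty_hits())
  arrange(res, .data$start, .data$motif_id)
}

#' Detect core-promoter elements (MTE, BREu, DCE-S-I)
#'
#' Scans the core-promoter sequence with every library motif belonging to the
#' requested families. Families absent from the library yield an empty hit
#' list with a warning.
#'
#' @param core_sequence Core-promoter sequence in gene orientation.
#' @param polII_motif_library Motif library tibble with family labels.
#' @param p_threshold Occurrence p-value threshold; default 1e-3.
#' @param families Families to annotate.
#' @param sequence_name Name recorded in hit tables.
#' @param strands Strands to scan; core elements are not orientation
#'   constrained, so both by default.
#' @return Named list (one hit tibble per family).
#' @export
detect_core_elements <- function(core_sequence, polII_motif_library,
                                 p_threshold = 1e-3,
                                 families = c("MTE", "BREu", "DCE_S_I"),
                                 sequence_name = "core",
                                 strands = "both") {
  out <- setNames(vector("list", length(families)), families)
  for (fam in families) {
    sub <- polII_motif_library[
      !is.na(polII_motif_library$family) & polII_motif_library$family == fam, ,
      drop = FALSE
    ]
    if (nrow(sub) == 0) {
      warn(sprintf("family '%s' absent from motif library", fam))
      out[[fam]] <- empty_hits()
      next
    }
    out[[fam]] <- scan_sequences(
      setNames(core_sequence, sequence_name), sub,
      p_threshold = p_threshold, strands = strands
    )
  }
  out
}

#' Count non-overlapping Y-patches
#'
#' Greedy leftmost collapse: hits are taken in start order and any hit
#' overlapping an already-accepted one is absorbed into it.
#'
#' @param hits Y-patch hit tibble.
#' @return Integer count.
#' @export
count_y_patches <- function(hits) {
  if (nrow(hits) == 0) return(0L)
  h <- arrange(hits, .data$start, .data$stop)
  n <- 0L
  last_stop <- -Inf
  for (i in seq_len(nrow(h))) {
    if (h$start[i] > last_stop) {
      n <- n + 1L
      last_stop <- h$stop[i]
    } else {
      last_stop <- max(last_stop, h$stop[i])
    }
  }
  n
}

#' Annotate core promoters of a set of genes
#'
#' Extracts each gene's core-promoter region (TSS - `upstream_len` to the
#' base before the translational start, transcript orientation), detects
#' Y-patches, TATA-box variants and the MTE/BREu/DCE-S-I elements, and
#' reports per-gene counts plus TATA positions relative to the translational
#' start (5' base of the hexamer; the A of ATG is +1).
#'
#' @param genes Gene model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param y_patch_model `pwm` for Y-patch detection (`NULL` = fallback rule).
#' @param polII_motif_library Optional library for MTE/BREu/DCE-S-I.
#' @param y_patch_p Y-patch p-value threshold; default 4e-4.
#' @param element_p Core-element threshold; default 1e-3.
#' @param upstream_len Core region extent upstream of the TSS; default 200.
#' @return A tibble: `gene_id`, `y_patch_count`, `n_tata`, `tata_positions`
#'   (comma-separated offsets), `n_mte`, `n_breu`, `n_dce_s_i`, and list
#'   columns `y_patch_hits`, `tata_hits` with per-gene hit tables (positions
#'   within the core sequence).
#' @export
annotate_core_promoters <- function(genes, genome, y_patch_model = NULL,
                                    polII_motif_library = NULL,
                                    y_patch_p = 4e-4, element_p = 1e-3,
                                    upstream_len = 200) {
  regions <- core_promoter_region(genes, upstream_len = upstream_len,
                                  chrom_length = nchar(genome))
  seqs <- region_sequences(regions, genome, orient = "gene")
  y_scanner <- if (!is.null(y_patch_model)) {
    make_scanner(y_patch_model, "forward")
  }
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    gid <- regions$gene_id[i]
    gene <- genes[genes$gene_id == gid, ][1, ]
    s <- seqs[[i]]
    yh <- if (!is.null(y_scanner)) {
      h <- scan_with_scanner(s, y_scanner, p_threshold = y_patch_p,
                             sequence_name = gid)
      h$family <- "Ypatch"
      h
    } else {
      detect_y_patch(s, NULL, p_threshold = y_patch_p, sequence_name = gid)
    }
    th <- detect_tata_variant(s, sequence_name = gid)
    # offset of the core sequence 5' end relative to the ATG
    core_5p <- if (gene$strand == "+") regions$start[i] else regions$end[i]
    off0 <- relative_position(core_5p, gene)
    tata_off <- if (nrow(th) > 0) off0 + th$start - 1L else integer(0)
    counts <- c(MTE = 0L, BREu = 0L, DCE_S_I = 0L)
    if (!is.null(polII_motif_library)) {
      eh <- detect_core_elements(s, polII_motif_library,
                                 p_threshold = element_p,
                                 sequence_name = gid)
      counts <- map_int(eh, nrow)[names(counts)]
    }
    rows[[i]] <- tibble(
      gene_id = gid,
      y_patch_count = count_y_patches(yh),
      n_tata = nrow(th),
      tata_positions = paste(tata_off, collapse = ","),
      n_mte = counts[["MTE"]], n_breu = counts[["BREu"]],
      n_dce_s_i = counts[["DCE_S_I"]],
      y_patch_hits = list(yh), tata_hits = list(th)
    )
  }
  bind_rows(rows)
}
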