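#' Build a position weight matrix with pseudocount and background
#'
#' Converts a count (or probability) matrix into a position weight matrix:
#' per-position base probabilities after pseudocount smoothing, and log-odds
#' scores in bits against a background base composition. Probability matrices
#' (every row summing to 1 within 1e-3) are first rescaled to pseudo-counts of
#' 100 so that the pseudocount has a comparable effect on both input kinds.
#'
#' The smoothing rule is
#' `prob[i, b] = (count[i, b] + pseudocount * background[b]) / (rowsum + pseudocount)`,
#' i.e. the pseudocount mass is distributed proportionally to the background.
#'
#' Log-odds are additionally discretised to an integer grid of `granularity`
#' bits per step; the same grid is used for window scores and for the exact
#' score distribution, so occurrence p-values are exact for the discretised
#' score.
#'
#' @param counts_or_probs Numeric L x 4 matrix over A, C, G, T: non-negative
#'   counts, or probabilities with unit row sums.
#' @param pseudocount Positive scalar, default 0.1.
#' @param background Length-4 positive vector summing to 1 (A, C, G, T order);
#'   default uniform.
#' @param motif_id Identifier carried into hits.
#' @param family Transcription-factor family label (or `NA`).
#' @param granularity Bits per discretisation step for the score grid,
#'   default 1/1000.
#' @return An object of class `pwm`: a list with elements `motif_id`, `family`,
#'   `length`, `probs`, `background`, `log_odds` (bits), `int_scores`
#'   (log-odds on the integer grid) and `granularity`.
#' @examples
#' m <- matrix(c(10, 0, 0, 0), nrow = 1)
#' p <- build_pwm(m, pseudocount = 0.1)
#' p$probs  # (10.025/10.1, 0.025/10.1, ...)
#' @export
build_pwm <- function(counts_or_probs, pseudocount = 0.1,
                      background = rep(0.25, 4), motif_id = "motif",
                      family = NA_character_, granularity = 1/1000) {
  m <- as.matrix(counts_or_probs)
  if (ncol(m) != 4) abort("motif matrix must have 4 columns (A, C, G, T)")
  if (nrow(m) < 1) abort("motif matrix must have at least one row")
  if (any(!is.finite(m)) || any(m < 0)) abort("motif matrix entries must be finite and non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) abort(sprintf("motif '%s': row %d sums to zero", motif_id, which(rs == 0)[1]))
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (length(background) != 4 || any(background <= 0)) {
    abort("background must be 4 positive values")
  }
  background <- background / sum(background)
  if (granularity <= 0) abort("granularity must be positive")

  if (all(abs(rs - 1) <= 1e-3)) {
    m <- m * 100  # probability input: rescale to pseudo-counts of 100
    rs <- rowSums(m)
  }
  probs <- (m + pseudocount * matrix(background, nrow(m), 4, byrow = TRUE)) /
    (rs + pseudocount)
  log_odds <- log2(sweep(probs, 2, background, "/"))
  structure(
    list(
      motif_id = motif_id, family = family, length = nrow(m),
      probs = probs, background = background,
      log_odds = log_odds,
      int_scores = matrix(as.integer(round(log_odds / granularity)),
                          nrow(m), 4),
      granularity = granularity
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (family %s), length %d, granularity %g bit\n",
              x$motif_id, x$family %||% NA, x$length, x$granularity))
  invisible(x)
}

# PWM for the reverse complement: reversed positions, complemented bases
reverse_complement_pwm <- function(pwm) {
  rev_idx <- pwm$length:1
  comp_idx <- 4:1  # A<->T, C<->G in A,C,G,T order
  out <- pwm
  out$probs <- pwm$probs[rev_idx, comp_idx, drop = FALSE]
  out$background <- pwm$background[comp_idx]
  out$log_odds <- pwm$log_odds[rev_idx, comp_idx, drop = FALSE]
  out$int_scores <- pwm$int_scores[rev_idx, comp_idx, drop = FALSE]
  out
}

#' Score a single window against a PWM
#'
#' Sum of per-position log-odds (bits). Windows containing characters outside
#' ACGT (for example N) get `NA`: they have no score and are skipped by the
#' scanner.
#'
#' @param pwm A [build_pwm()] object.
#' @param window A string of length `pwm$length` over ACGT.
#' @return Score in bits, or `NA` if the window contains N.
#' @export
score_window <- function(pwm, window) {
  x <- encode_dna(window)
  if (length(x) != pwm$length) {
    abort(sprintf("window length %d does not match motif length %d",
                  length(x), pwm$length))
  }
  if (anyNA(x)) return(NA_real_)
  sum(pwm$log_odds[cbind(seq_len(pwm$length), x)])
}

#' Exact distribution of PWM scores under the background model
#'
#' Dynamic programme: the per-position log-odds are discretised to an integer
#' grid (`granularity` bits per step) and the distribution of the total score
#' of a random background k-mer is built by position-wise convolution. The
#' survival function gives the occurrence p-value P(S >= s) used by
#' [scan_sequence()].
#'
#' @param pwm A [build_pwm()] object.
#' @param granularity Bits per step; defaults to the PWM's own grid.
#' @return An object of class `score_distribution`: list with `granularity`,
#'   integer score bounds `min_score`/`max_score`, `pmf` and `survival`
#'   vectors over the integer support.
#' @export
score_distribution <- function(pwm, granularity = pwm$granularity) {
  k <- pwm$int_scores
  if (granularity != pwm$granularity) {
    k <- matrix(as.integer(round(pwm$log_odds / granularity)), pwm$length, 4)
  }
  row_min <- apply(k, 1, min)
  row_max <- apply(k, 1, max)
  cur <- 1
  cur_min <- 0L
  for (i in seq_len(pwm$length)) {
    w <- numeric(length(cur) + row_max[i] - row_min[i])
    for (b in 1:4) {
      off <- k[i, b] - row_min[i]
      idx <- seq_along(cur) + off
      w[idx] <- w[idx] + cur * pwm$background[b]
    }
    cur <- w
    cur_min <- cur_min + row_min[i]
  }
  pmf <- cur
  surv <- rev(cumsum(rev(pmf)))
  surv <- pmin(surv, 1)
  structure(
    list(
      granularity = granularity,
      min_score = cur_min,
      max_score = cur_min + length(pmf) - 1L,
      pmf = pmf,
      survival = surv
    ),
    class = "score_distribution"
  )
}

# survival lookup for integer scores; scores below support -> 1, above -> 0
pvalue_int <- function(dist, s_int) {
  idx <- s_int - dist$min_score + 1L
  out <- rep(NA_real_, length(s_int))
  low <- !is.na(idx) & idx < 1L
  high <- !is.na(idx) & idx > length(dist$survival)
  ok <- !is.na(idx) & !low & !high
  out[low] <- 1
  out[high] <- 0
  out[ok] <- dist$survival[idx[ok]]
  out
}

#' Occurrence p-value of a PWM score
#'
#' P(S >= score) for a random background window, from the exact discretised
#' score distribution.
#'
#' @param pwm A [build_pwm()] object.
#' @param score Score(s) in bits.
#' @param dist Optional precomputed [score_distribution()].
#' @return Numeric vector of p-values in (0, 1].
#' @export
pwm_pvalue <- function(pwm, score, dist = NULL) {
  dist <- dist %||% score_distribution(pwm)
  pvalue_int(dist, as.integer(round(score / dist$granularity)))
}

# integer scores of all windows of x_int (encoded sequence) against k (L x 4);
# windows overlapping NA positions come back NA
window_scores_int <- function(x_int, k) {
  L <- nrow(k)
  n <- length(x_int)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  s <- rep(0L, nw)
  for (i in seq_len(L)) {
    kr <- k[i, ]
    s <- s + kr[x_int[i:(i + nw - 1L)]]
  }
  s
}

#' Scan a sequence for PWM occurrences
#'
#' Slides the motif over every window of the sequence (both strands by
#' default) and reports windows whose occurrence p-value is at or below the
#' threshold. Minus-strand matches are reported in forward-strand coordinates
#' with the matched sequence reverse-complemented. Windows containing N are
#' skipped. A sequence shorter than the motif yields an empty table.
#'
#' @param sequence A DNA string (ACGTN).
#' @param pwm A [build_pwm()] object.
#' @param p_threshold Occurrence p-value cutoff in (0, 1]; default 1e-3.
#' @param strands `"both"` (default) or `"forward"`.
#' @param sequence_name Name recorded in the hit table.
#' @return A tibble of hits: `motif_id`, `family`, `sequence_name`, `start`,
#'   `stop` (1-based inclusive, forward strand), `strand`, `score` (bits),
#'   `p_value`, `matched_sequence`.
#' @export
scan_sequence <- function(sequence, pwm, p_threshold = 1e-3,
                          strands = c("both", "forward"),
                          sequence_name = "seq") {
  strands <- match.arg(strands)
  scanner <- make_scanner(pwm, strands)
  scan_with_scanner(sequence, scanner, p_threshold, sequence_name)
}

# precompute per-strand matrices and score distributions so repeated scans
# (many sequences, one motif) skip the dynamic programme
make_scanner <- function(pwm, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  sc <- list(list(pwm = pwm, strand = "+", dist = score_distribution(pwm)))
  if (strands == "both") {
    rc <- reverse_complement_pwm(pwm)
    sc <- c(sc, list(list(pwm = rc, strand = "-",
                          dist = score_distribution(rc))))
  }
  sc
}

scan_with_scanner <- function(sequence, scanner, p_threshold = 1e-3,
                              sequence_name = "seq") {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort("p_threshold must be in (0, 1]")
  }
  pwm <- scanner[[1]]$pwm
  sequence <- toupper(sequence)
  x <- encode_dna(sequence)
  res <- vector("list", length(scanner))
  for (si in seq_along(scanner)) {
    sc <- scanner[[si]]
    dist <- sc$dist
    s_int <- window_scores_int(x, sc$pwm$int_scores)
    if (length(s_int) == 0) { res[[si]] <- empty_hits(); next }
    pv <- pvalue_int(dist, s_int)
    keep <- which(!is.na(pv) & pv <= p_threshold)
    if (length(keep) == 0) { res[[si]] <- empty_hits(); next }
    starts <- keep
    stops <- keep + pwm$length - 1L
    matched <- substring(sequence, starts, stops)
    if (sc$strand == "-") matched <- revcomp(matched)
    res[[si]] <- tibble(
      motif_id = pwm$motif_id,
      family = pwm$family,
      sequence_name = sequence_name,
      start = as.integer(starts), stop = as.integer(stops),
      strand = sc$strand,
      score = s_int[keep] * dist$granularity,
      p_value = pv[keep],
      matched_sequence = matched
    )
  }
  bind_rows(res) |> arrange(.data$start, .data$strand)
}

#' Scan many sequences with a motif library
#'
#' Convenience wrapper around [scan_sequence()]: score distributions are
#' computed once per motif and reused across sequences.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param library A motif library tibble (see [read_motifs()] /
#'   [motif_library()]).
#' @param p_threshold Occurrence p-value cutoff; default 1e-3.
#' @param strands `"both"` or `"forward"`.
#' @param pseudocount,background,granularity Passed to [build_pwm()].
#' @return A tibble of hits across all sequences and motifs.
#' @export
scan_sequences <- function(sequences, library, p_threshold = 1e-3,
                           strands = c("both", "forward"),
                           pseudocount = 0.1, background = rep(0.25, 4),
                           granularity = 1/1000) {
  strands <- match.arg(strands)
  pwms <- library_pwms(library, pseudocount = pseudocount,
                       background = background, granularity = granularity)
  out <- vector("list", length(pwms) * length(sequences))
  j <- 0L
  for (pwm in pwms) {
    scanner <- make_scanner(pwm, strands)
    for (nm in names(sequences)) {
      j <- j + 1L
      out[[j]] <- scan_with_scanner(sequences[[nm]], scanner,
                                    p_threshold = p_threshold,
                                    sequence_name = nm)
    }
  }
  hits <- bind_rows(out)
  cs_log("scanned %d sequence(s) x %d motif(s): %d hits",
         length(sequences), length(pwms), nrow(hits))
  hits
}

# build one pwm per library entry
library_pwms <- function(library, pseudocount = 0.1,
                         background = rep(0.25, 4), granularity = 1/1000) {
  pmap(
    list(library$motif_id, library$matrix, library$family),
    function(id, m, fam) {
      build_pwm(m, pseudocount = pseudocount, background = background,
                motif_id = id, family = fam, granularity = granularity)
    }
  )
}
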