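# Independent brute-force oracle: enumerate all 4^L windows, score with the
# PWM's integer matrix, weight by background. Returns a function p(s_int).
brute_force_survival <- function(pwm) {
  L <- pwm$length
  kmers <- as.matrix(do.call(expand.grid, rep(list(1:4), L)))
  scores <- integer(nrow(kmers))
  weights <- numeric(nrow(kmers)) + 1
  for (i in seq_len(L)) {
    scores <- scores + pwm$int_scores[i, kmers[, i]]
    weights <- weights * pwm$background[kmers[, i]]
  }
  function(s_int) vapply(s_int, function(q) sum(weights[scores >= q]), 0)
}

# brute-force scan: score every window of a sequence directly via
# score_window and the enumeration-based survival function
brute_force_scan <- function(sequence, pwm, p_threshold) {
  surv <- brute_force_survival(pwm)
  L <- pwm$length
  n <- nchar(sequence)
  if (n < L) return(integer(0))
  g <- pwm$granularity
  hits <- integer(0)
  for (j in seq_len(n - L + 1)) {
    w <- substr(sequence, j, j + L - 1)
    if (grepl("N", w)) next
    s_int <- sum(pwm$int_scores[cbind(seq_len(L),
                                      match(strsplit(w, "")[[1]],
                                            c("A", "C", "G", "T")))])
    if (surv(s_int) <= p_threshold) hits <- c(hits, j)
  }
  hits
}

random_pwm <- function(len, motif_id = "rnd", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build_pwm(matrix(sample(1:30, len * 4, replace = TRUE), len, 4),
            motif_id = motif_id)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# background sequence guaranteed free of pyrimidine runs that would read as
# a Y-patch in either orientation (breaks runs of >= 8 same-type bases)
mixed_background <- function(n) {
  x <- character(n)
  pool <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    x[i] <- sample(pool, 1)
    if (i >= 4) {
      recent <- x[(i - 3):i]
      if (all(recent %in% c("C", "T"))) x[i] <- sample(c("A", "G"), 1)
      if (all(recent %in% c("A", "G"))) x[i] <- sample(c("C", "T"), 1)
    }
  }
  paste(x, collapse = "")
}
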