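DNA_BASES <- c("A", "C", "G", "T")

# A=1, C=2, G=3, T=4; N (or anything else) -> NA so windows touching it drop out
encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Reverse-complement a DNA string
#'
#' Vectorised over its input; accepts A, C, G, T and N (case-insensitive).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements, upper-cased.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

cs_log <- function(fmt, ..., level = "INFO") {
  if (isTRUE(getOption("crmscreen.verbose", FALSE))) {
    message(sprintf("[crmscreen %s] %s", level, sprintf(fmt, ...)))
  }
}

# empty hit table shared by every detector so binds always line up
empty_hits <- function() {
  tibble(
    motif_id = character(0), family = character(0),
    sequence_name = character(0),
    start = integer(0), stop = integer(0), strand = character(0),
    score = double(0), p_value = double(0),
    matched_sequence = character(0)
  )
}

# merge overlapping/adjacent 1-based inclusive intervals in a tibble(start, end)
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- arrange(df, .data$start, .data$end)
  out_start <- df$start[1]
  out_end <- df$end[1]
  starts <- integer(0); ends <- integer(0)
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      if (df$start[i] <= out_end + 1L) {
        out_end <- max(out_end, df$end[i])
      } else {
        starts <- c(starts, out_start); ends <- c(ends, out_end)
        out_start <- df$start[i]; out_end <- df$end[i]
      }
    }
  }
  tibble(start = c(starts, out_start), end = c(ends, out_end))
}

# intersection of one interval [s, e] with a set of intervals (1-based inclusive)
clip_to_intervals <- function(s, e, intervals) {
  if (nrow(intervals) == 0 || e < s) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  hit <- intervals[intervals$end >= s & intervals$start <= e, , drop = FALSE]
  if (nrow(hit) == 0) return(tibble(start = integer(0), end = integer(0)))
  tibble(start = pmax(hit$start, s), end = pmin(hit$end, e)) |>
    arrange(.data$start)
}
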