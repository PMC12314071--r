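#' Read a FASTA file
#'
#' Sequences are upper-cased and validated against the ACGTN alphabet; record
#' names are the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(sprintf("empty FASTA file: %s", path))
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate sequence name in %s: %s",
                  path, nms[duplicated(nms)][1]))
  }
  seqs <- toupper(as.character(ss))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "sequence '%s' contains invalid character '%s' at position %d",
      nms[i], substr(seqs[i], bad[i], bad[i]), bad[i]
    ))
  }
  cs_log("read %d sequence(s) from %s", length(seqs), path)
  setNames(seqs, nms)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = width
  )
  invisible(path)
}

#' Read gene models from GFF3
#'
#' One model per gene, anchored on a primary mRNA (the longest, when a gene
#' has several). The TSS is the transcript 5' end, the translational start the
#' first CDS base in transcript orientation, and the 3'UTR end the transcript
#' 3' end. mRNAs without CDS are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param primary_transcript How to pick among multiple mRNAs per gene;
#'   currently only `"longest"`.
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand`, `tss`,
#'   `translational_start`, `utr3_end` (all 1-based genomic coordinates).
#' @export
read_gene_models <- function(path, primary_transcript = "longest") {
  stopifnot(primary_transcript == "longest")
  gr <- rtracklayer::import(path)
  ftype <- as.character(gr$type)
  mrna <- gr[ftype == "mRNA"]
  if (length(mrna) == 0) abort(sprintf("no mRNA features in %s", path))
  cds <- gr[ftype == "CDS"]
  cds_parent <- as.character(unlist(cds$Parent))
  mr <- tibble(
    transcript_id = as.character(mrna$ID),
    gene_id = map_chr(as.list(mrna$Parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }),
    chrom = as.character(GenomicRanges::seqnames(mrna)),
    strand = as.character(GenomicRanges::strand(mrna)),
    start = GenomicRanges::start(mrna),
    end = GenomicRanges::end(mrna)
  )
  mr$gene_id[is.na(mr$gene_id)] <- mr$transcript_id[is.na(mr$gene_id)]
  if (any(mr$start > mr$end)) abort("coordinate inversion in mRNA feature")
  has_cds <- mr$transcript_id %in% cds_parent
  if (any(!has_cds)) {
    warn(sprintf("skipping %d mRNA(s) without CDS: %s",
                 sum(!has_cds),
                 paste(head(mr$transcript_id[!has_cds], 5), collapse = ", ")))
    mr <- mr[has_cds, , drop = FALSE]
  }
  if (nrow(mr) == 0) abort("no mRNA with CDS found")
  atg <- map_dbl(seq_len(nrow(mr)), function(i) {
    ci <- cds[cds_parent == mr$transcript_id[i]]
    if (mr$strand[i] == "+") min(GenomicRanges::start(ci))
    else max(GenomicRanges::end(ci))
  })
  mr$translational_start <- as.integer(atg)
  mr$tss <- ifelse(mr$strand == "+", mr$start, mr$end)
  mr$utr3_end <- ifelse(mr$strand == "+", mr$end, mr$start)
  models <- mr |>
    mutate(len = .data$end - .data$start + 1L) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$len), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    transmute(
      gene_id = .data$gene_id, chrom = .data$chrom, strand = .data$strand,
      tss = as.integer(.data$tss),
      translational_start = .data$translational_start,
      utr3_end = as.integer(.data$utr3_end)
    ) |>
    arrange(.data$gene_id)
  validate_gene_models(models)
  cs_log("read %d gene model(s) from %s", nrow(models), path)
  models
}

validate_gene_models <- function(models) {
  need <- c("gene_id", "chrom", "strand", "tss", "translational_start", "utr3_end")
  if (!all(need %in% names(models))) {
    abort(sprintf("gene models must have columns: %s", paste(need, collapse = ", ")))
  }
  plus <- models$strand == "+"
  ok <- ifelse(plus,
               models$tss <= models$translational_start &
                 models$translational_start <= models$utr3_end,
               models$tss >= models$translational_start &
                 models$translational_start >= models$utr3_end)
  if (any(!ok)) {
    abort(sprintf("malformed gene model (TSS/ATG/3'UTR order): %s",
                  models$gene_id[!ok][1]))
  }
  invisible(models)
}

#' Read a motif library
#'
#' Supports the JASPAR PFM dialect (`>ID name` header followed by four
#' `A [ ... ]` style rows) and the MEME minimal dialect (`MOTIF` blocks with a
#' `letter-probability matrix` header). Matrices are stored as L x 4 (A, C, G,
#' T columns). Count matrices are kept exactly; probability matrices are
#' accepted when every row sums to 1 within 1e-3. A matrix mixing count-like
#' and probability-like rows is rejected.
#'
#' @param path Path to the motif file.
#' @param dialect `"jaspar_pfm"` or `"meme_minimal"`.
#' @param family_map Optional named vector mapping motif_id to family; unmapped
#'   motifs get family `"unassigned"`.
#' @return A motif library tibble: `motif_id`, `family`, `matrix` (list of
#'   L x 4 matrices).
#' @export
read_motifs <- function(path, dialect = c("jaspar_pfm", "meme_minimal"),
                        family_map = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lib <- switch(dialect,
    jaspar_pfm = parse_jaspar_pfm(lines),
    meme_minimal = parse_meme_minimal(lines)
  )
  if (!is.null(family_map)) {
    lib$family <- family_of(family_map, lib$motif_id)
  }
  validate_motif_library(lib)
  cs_log("read %d motif(s) from %s", nrow(lib), path)
  lib
}

parse_matrix_rows <- function(rows, where) {
  vals <- lapply(rows, function(r) {
    r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
    r <- gsub("[\\[\\]]", " ", r, perl = TRUE)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  })
  n <- unique(lengths(vals))
  if (length(n) != 1) abort(sprintf("%s: ragged matrix rows", where))
  m <- t(do.call(rbind, vals))  # rows were per-base; transpose to L x 4
  if (ncol(m) != 4) abort(sprintf("%s: matrix must have 4 base rows", where))
  if (any(is.na(m))) abort(sprintf("%s: non-numeric matrix entry", where))
  m
}

parse_jaspar_pfm <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort("no JASPAR records found")
  ends <- c(hdr[-1] - 1L, length(lines))
  entries <- map2(hdr, ends, function(h, e) {
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    rows <- lines[(h + 1):e]
    if (length(rows) != 4) {
      abort(sprintf("JASPAR record '%s': expected 4 base rows, got %d",
                    id, length(rows)))
    }
    list(motif_id = id, matrix = parse_matrix_rows(rows, id))
  })
  tibble(
    motif_id = map_chr(entries, "motif_id"),
    family = NA_character_,
    matrix = map(entries, "matrix")
  )
}

parse_meme_minimal <- function(lines) {
  mot <- grep("^MOTIF\\s", lines)
  if (length(mot) == 0) abort("no MEME MOTIF blocks found")
  entries <- map(seq_along(mot), function(i) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[mot[i]])), "\\s+")[[1]][1]
    to <- if (i < length(mot)) mot[i + 1] - 1L else length(lines)
    block <- lines[mot[i]:to]
    hdr <- grep("letter-probability matrix", block)
    if (length(hdr) != 1) {
      abort(sprintf("MEME motif '%s': missing letter-probability matrix", id))
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr]))
    rows <- block[(hdr + 1):(hdr + w)]
    m <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    if (ncol(m) != 4 || any(is.na(m))) {
      abort(sprintf("MEME motif '%s': matrix must be %d x 4 numeric", id, w))
    }
    list(motif_id = id, matrix = m)
  })
  tibble(
    motif_id = map_chr(entries, "motif_id"),
    family = NA_character_,
    matrix = map(entries, "matrix")
  )
}

#' Construct a motif library
#'
#' @param motif_id Character vector of unique identifiers.
#' @param matrix List of L x 4 numeric matrices (A, C, G, T columns).
#' @param family Character vector of family labels; `NA` becomes
#'   `"unassigned"` at use time.
#' @return A validated motif library tibble.
#' @export
motif_library <- function(motif_id, matrix, family = NA_character_) {
  lib <- tibble(motif_id = motif_id, family = family, matrix = matrix)
  validate_motif_library(lib)
  lib
}

validate_motif_library <- function(lib) {
  if (anyDuplicated(lib$motif_id)) {
    abort(sprintf("duplicate motif_id: %s",
                  lib$motif_id[duplicated(lib$motif_id)][1]))
  }
  for (i in seq_len(nrow(lib))) {
    m <- lib$matrix[[i]]
    id <- lib$motif_id[i]
    if (!is.matrix(m) || ncol(m) != 4) {
      abort(sprintf("motif '%s': matrix must have 4 columns", id))
    }
    if (nrow(m) < 1) abort(sprintf("motif '%s': empty matrix", id))
    if (any(m < 0) || any(!is.finite(m))) {
      abort(sprintf("motif '%s': entries must be finite and non-negative", id))
    }
    rs <- rowSums(m)
    if (any(rs == 0)) {
      abort(sprintf("motif '%s': row %d is all-zero", id, which(rs == 0)[1]))
    }
    prob_like <- abs(rs - 1) <= 1e-3
    if (any(prob_like) && !all(prob_like)) {
      abort(sprintf("motif '%s': rows mix counts and probabilities", id))
    }
  }
  invisible(lib)
}

#' Write a motif library in JASPAR PFM format
#'
#' @param library Motif library tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(library))) {
    m <- library$matrix[[i]]
    writeLines(sprintf(">%s", library$motif_id[i]), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(m[, b], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a motif-to-family map
#'
#' Tab-separated file with columns `motif_id` and `family`.
#'
#' @param path Path to the TSV.
#' @return Named character vector: family keyed by motif_id.
#' @export
read_family_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("motif_id", "family") %in% names(df))) {
    abort("family map needs columns motif_id and family")
  }
  setNames(df$family, df$motif_id)
}

#' Look up motif families in a family map
#'
#' The map is total: motifs absent from it get family `"unassigned"`.
#'
#' @param family_map Named character vector (family keyed by motif_id).
#' @param motif_ids Character vector of motif ids.
#' @return Character vector of family labels.
#' @export
family_of <- function(family_map, motif_ids) {
  fam <- unname(family_map[motif_ids])
  fam[is.na(fam)] <- "unassigned"
  fam
}

#' Read accessible-chromatin intervals from BED
#'
#' BED is 0-based half-open on disk; intervals come back 1-based inclusive.
#' Strand, if present, is ignored (accessibility is strand-less).
#'
#' @param path Path to a BED file (3+ columns).
#' @return A tibble: `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_dhs <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) |> arrange(.data$chrom, .data$start)
  cs_log("read %d DHS interval(s) from %s", nrow(out), path)
  out
}

#' Write DHS-style intervals to BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dhs <- function(intervals, path) {
  readr::write_tsv(
    tibble(chrom = intervals$chrom,
           start = intervals$start - 1L,   # back to BED 0-based half-open
           end = intervals$end),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write a motif hit table as TSV
#'
#' Deterministic sort by (sequence_name, start, motif_id, strand); columns
#' `motif_id`, `family`, `sequence_name`, `start`, `stop`, `strand`, `score`,
#' `p_value`, `matched_sequence`. Coordinates are 1-based inclusive on the
#' forward strand of the scanned sequence.
#'
#' @param hits Hit tibble (see [scan_sequence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("motif_id", "family", "sequence_name", "start", "stop",
            "strand", "score", "p_value", "matched_sequence")
  out <- hits |>
    select(all_of(cols)) |>
    arrange(.data$sequence_name, .data$start, .data$motif_id, .data$strand)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a motif hit table written by [write_hits_tsv()]
#'
#' @param path Path to the TSV.
#' @return Hit tibble.
#' @export
read_hits_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    motif_id = "c", family = "c", sequence_name = "c",
    start = "i", stop = "i", strand = "c",
    score = "d", p_value = "d", matched_sequence = "c"
  ), progress = FALSE)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, five_prime_UTR, CDS and three_prime_UTR features for
#' simple single-exon models, enough to round-trip through
#' [read_gene_models()]. Used by the synthetic-genome generator.
#'
#' @param models Gene model tibble (needs in addition `gene_start`,
#'   `gene_end` genomic bounds).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    lo <- min(g$gene_start, g$gene_end)
    hi <- max(g$gene_start, g$gene_end)
    tid <- paste0(g$gene_id, ".1")
    feat <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      sprintf("%s\tcrmscreen\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s, e, g$strand, attrs)
    }
    if (g$strand == "+") {
      utr5 <- c(g$tss, g$translational_start - 1L)
      cds <- c(g$translational_start, g$cds_end)
      utr3 <- c(g$cds_end + 1L, g$utr3_end)
    } else {
      utr5 <- c(g$translational_start + 1L, g$tss)
      cds <- c(g$cds_end, g$translational_start)
      utr3 <- c(g$utr3_end, g$cds_end - 1L)
    }
    lines <- c(
      lines,
      feat("gene", lo, hi, g$gene_id),
      feat("mRNA", lo, hi, tid, g$gene_id),
      if (utr5[2] >= utr5[1]) feat("five_prime_UTR", utr5[1], utr5[2],
                                   paste0(tid, ".utr5"), tid),
      feat("CDS", cds[1], cds[2], paste0(tid, ".cds"), tid),
      if (utr3[2] >= utr3[1]) feat("three_prime_UTR", utr3[1], utr3[2],
                                   paste0(tid, ".utr3"), tid)
    )
  }
  writeLines(lines, path)
  invisible(path)
}
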