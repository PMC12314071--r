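#' Core-promoter region of a gene
#'
#' The region running, in transcript orientation, from `upstream_len` bases
#' upstream of the TSS to the base immediately before the translational start
#' (the ATG base itself is excluded). Clipped at the chromosome start and,
#' when `chrom_length` is given, the chromosome end.
#'
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @param upstream_len Bases upstream of the TSS; default 200.
#' @param chrom_length Optional named vector of chromosome lengths for
#'   clipping on the minus strand.
#' @return A region tibble: `gene_id`, `purpose = "core"`, `chrom`, `start`,
#'   `end` (1-based inclusive genomic), `strand`. Genes whose region is empty
#'   are absent.
#' @export
core_promoter_region <- function(genes, upstream_len = 200,
                                 chrom_length = NULL) {
  validate_gene_models(genes)
  plus <- genes$strand == "+"
  if (any(plus & genes$translational_start < genes$tss) ||
      any(!plus & genes$translational_start > genes$tss)) {
    abort("malformed gene model: translational start upstream of TSS")
  }
  start <- ifelse(plus,
                  pmax(1L, genes$tss - as.integer(upstream_len)),
                  genes$translational_start + 1L)
  end <- ifelse(plus,
                genes$translational_start - 1L,
                genes$tss + as.integer(upstream_len))
  if (!is.null(chrom_length)) {
    end <- pmin(end, unname(chrom_length[genes$chrom]))
  }
  out <- tibble(
    gene_id = genes$gene_id, purpose = "core",
    chrom = genes$chrom,
    start = as.integer(start), end = as.integer(end),
    strand = genes$strand
  )
  out[out$end >= out$start, , drop = FALSE]
}

#' CRM search region of a gene
#'
#' The span from `upstream_len` bases upstream of the TSS (transcript
#' orientation) to the 3'UTR end, intersected with accessible-chromatin (DHS)
#' intervals. With `dhs = NULL` the unclipped span is returned as a single
#' interval. DHS intervals are treated as strand-less.
#'
#' @param genes Gene model tibble.
#' @param dhs DHS tibble (`chrom`, `start`, `end`, 1-based inclusive) or
#'   `NULL`.
#' @param upstream_len Bases upstream of the TSS; default 2000.
#' @param chrom_length Optional named vector of chromosome lengths.
#' @return A region tibble (`gene_id`, `purpose = "crm_search"`, `chrom`,
#'   `start`, `end`, `strand`); possibly several disjoint intervals per gene,
#'   possibly none.
#' @export
crm_search_region <- function(genes, dhs = NULL, upstream_len = 2000,
                              chrom_length = NULL) {
  validate_gene_models(genes)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      s <- max(1L, g$tss - as.integer(upstream_len))
      e <- g$utr3_end
    } else {
      s <- g$utr3_end
      e <- g$tss + as.integer(upstream_len)
    }
    if (!is.null(chrom_length)) e <- min(e, unname(chrom_length[g$chrom]))
    if (is.null(dhs)) {
      iv <- tibble(start = as.integer(s), end = as.integer(e))
    } else {
      dv <- dhs[dhs$chrom == g$chrom, c("start", "end"), drop = FALSE]
      iv <- clip_to_intervals(s, e, merge_intervals(dv))
    }
    if (nrow(iv) > 0) {
      out[[i]] <- tibble(
        gene_id = g$gene_id, purpose = "crm_search", chrom = g$chrom,
        start = as.integer(iv$start), end = as.integer(iv$end),
        strand = g$strand
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(gene_id = character(0), purpose = character(0),
                  chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0))
  }
  res
}

#' Signed offset relative to the translational start
#'
#' Promoter coordinate convention: the A of the ATG is +1, the base
#' immediately upstream is -1; there is no position 0. Strand-aware, so the
#' axis follows transcript orientation.
#'
#' @param genomic_pos Vector of genomic positions (1-based).
#' @param gene A single gene model (one-row tibble or list with `strand` and
#'   `translational_start`).
#' @return Integer vector of signed offsets.
#' @export
relative_position <- function(genomic_pos, gene) {
  d <- if (gene$strand == "+") {
    genomic_pos - gene$translational_start
  } else {
    gene$translational_start - genomic_pos
  }
  as.integer(ifelse(d >= 0, d + 1L, d))
}

#' Genomic position of a signed offset
#'
#' Inverse of [relative_position()].
#'
#' @param offset Signed offset vector (no zeros).
#' @param gene A single gene model.
#' @return Integer vector of genomic positions.
#' @export
genomic_position <- function(offset, gene) {
  if (any(offset == 0)) abort("offset 0 does not exist in this convention")
  d <- ifelse(offset > 0, offset - 1L, offset)
  out <- if (gene$strand == "+") {
    gene$translational_start + d
  } else {
    gene$translational_start - d
  }
  as.integer(out)
}

#' Extract region sequences in transcript orientation
#'
#' @param regions Region tibble (see [core_promoter_region()]).
#' @param genome Named character vector of chromosome sequences.
#' @param orient `"gene"` (reverse-complement minus-strand regions; default)
#'   or `"forward"` (genomic forward strand as-is).
#' @return Named character vector, one element per region row, named
#'   `gene_id` when each gene has one region or `gene_id:start-end` otherwise.
#' @export
region_sequences <- function(regions, genome, orient = c("gene", "forward")) {
  orient <- match.arg(orient)
  if (nrow(regions) == 0) return(character(0))
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing) > 0) {
    abort(sprintf("chromosome(s) absent from genome: %s",
                  paste(missing, collapse = ", ")))
  }
  seqs <- substring(genome[regions$chrom], regions$start, regions$end)
  if (orient == "gene") {
    minus <- regions$strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  }
  nm <- if (anyDuplicated(regions$gene_id)) {
    sprintf("%s:%d-%d", regions$gene_id, regions$start, regions$end)
  } else {
    regions$gene_id
  }
  setNames(unname(seqs), nm)
}
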