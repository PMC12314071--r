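# Consensus strings for the synthetic demonstration library. These are
# synthetic stand-ins built around the canonical core of each family's known
# binding site (W-box TTGACT for WRKY, GATTC for G2-like, AAC core for
# MYB-related, AAAG for DOF, TTTGTCG for IDD, the ACGT G-box/ABRE core for
# group-A bZIP/DPBF); they are NOT curated database matrices.
CRM_FAMILY_CONSENSUS <- c(
  WRKY   = "GTTGACTT",
  G2like = "AGATTCTC",
  MYBR_B = "GTAACTGC",
  DOF    = "CAAAGCGG",
  IDD    = "TTTGTCGC",
  DPBF   = "ACACGTGT"
)

CORE_ELEMENT_CONSENSUS <- c(
  MTE     = "CGAACGGA",
  BREu    = "GCGCGCCA",
  DCE_S_I = "CTTCGTGC"
)

# counts matrix strongly favouring the consensus base (dominant counts out of
# `total` per position)
consensus_counts <- function(consensus, dominant = 97, total = 100) {
  x <- encode_dna(consensus)
  if (anyNA(x)) abort("consensus must be over ACGT")
  m <- matrix((total - dominant) / 3, length(x), 4)
  m[cbind(seq_along(x), x)] <- dominant
  m
}

#' Built-in synthetic motif library
#'
#' A small demonstration library with one informative matrix per CRM family
#' (WRKY, G2like, MYBR_B, DOF, IDD, DPBF), the three core-promoter elements
#' (MTE, BREu, DCE_S_I) and a pyrimidine-patch (Ypatch) matrix. All matrices
#' are synthetic: they are built from plausible consensus cores so the
#' pipeline can be exercised with known ground truth, and are not substitutes
#' for curated database matrices, which users should supply via
#' [read_motifs()] for real screens.
#'
#' The Ypatch matrix has every position favouring C/T at probability 0.45
#' each, so at the standard threshold (p < 4e-4 under uniform background)
#' only fully pyrimidine windows score as hits.
#'
#' @param include Which groups to include: any of `"crm"`, `"core"`,
#'   `"ypatch"`.
#' @return A motif library tibble (`motif_id`, `family`, `matrix`).
#' @export
builtin_motif_library <- function(include = c("crm", "core", "ypatch")) {
  include <- match.arg(include, several.ok = TRUE)
  ids <- character(0); fams <- character(0); mats <- list()
  if ("crm" %in% include) {
    for (fam in names(CRM_FAMILY_CONSENSUS)) {
      ids <- c(ids, paste0("syn_", fam))
      fams <- c(fams, fam)
      mats <- c(mats, list(consensus_counts(CRM_FAMILY_CONSENSUS[[fam]])))
    }
  }
  if ("core" %in% include) {
    for (fam in names(CORE_ELEMENT_CONSENSUS)) {
      ids <- c(ids, paste0("syn_", fam))
      fams <- c(fams, fam)
      mats <- c(mats, list(consensus_counts(CORE_ELEMENT_CONSENSUS[[fam]])))
    }
  }
  if ("ypatch" %in% include) {
    ids <- c(ids, "syn_Ypatch")
    fams <- c(fams, "Ypatch")
    mats <- c(mats, list(y_patch_matrix()))
  }
  motif_library(ids, mats, fams)
}

# 12 positions, each 45% C / 45% T / 5% A / 5% G (as counts per 100)
y_patch_matrix <- function(length = 12) {
  matrix(rep(c(5, 45, 5, 45), length), length, 4, byrow = TRUE)
}

#' Built-in Y-patch position weight matrix
#'
#' @param pseudocount,background,granularity Passed to [build_pwm()].
#' @return A `pwm` object for the synthetic pyrimidine-patch model.
#' @export
y_patch_pwm <- function(pseudocount = 0.1, background = rep(0.25, 4),
                        granularity = 1/1000) {
  build_pwm(y_patch_matrix(), pseudocount = pseudocount,
            background = background, motif_id = "syn_Ypatch",
            family = "Ypatch", granularity = granularity)
}

#' Family map of the built-in library
#'
#' @return Named character vector: family keyed by motif_id.
#' @export
builtin_family_map <- function() {
  lib <- builtin_motif_library()
  setNames(lib$family, lib$motif_id)
}
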