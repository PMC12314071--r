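---
title: "Methods: screening cis-regulatory modules and core-promoter elements"
author: "crmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening cis-regulatory modules and core-promoter elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscreen)
library(dplyr)
```

## The problem

Cell-type-specific gene expression in plant leaves — for example, expression
restricted to the bundle sheath, the cell layer wrapping leaf veins — is often
driven by a compact cis-regulatory module (CRM): a short stretch of DNA bound
combinatorially by transcription factors from several families, working
together with a compatible core promoter. A recurring architecture couples a
distal CRM carrying binding sites for WRKY, G2-like, MYB-related, DOF, IDD and
group-A bZIP (DPBF) factors to a core promoter containing a pyrimidine
(Y-)patch, the TC-rich plant alternative to the TATA-box. `crmscreen`
implements the computational side of finding and quantifying such
architectures:

1. position-weight-matrix (PWM) scanning with exact occurrence p-values;
2. annotation of core-promoter elements (Y-patch, TATA variants, MTE, BREu,
   DCE-S-I);
3. a genome-wide co-occurrence screen for the six-family CRM inside
   accessible chromatin, crossed with the core-promoter Y-patch;
4. expression-class filters over cell-separated RNA-seq summary tables;
5. quantification of fluorometric reporter assays (MUG kinetics, LUC/GUS
   ratios) with pairwise group statistics and compact-letter displays;
6. a synthetic-data generator that plants all of the above with known ground
   truth.

## PWM model and exact p-values

A motif of length $L$ is a count (or probability) matrix over A, C, G, T.
With pseudocount $\alpha$ (default 0.1) distributed by the background
$b = (b_A, b_C, b_G, b_T)$ (default uniform), position probabilities are

$$p_{i\beta} = \frac{c_{i\beta} + \alpha\, b_\beta}{\sum_\gamma c_{i\gamma} + \alpha},$$

and scores are log-odds in bits, $s_{i\beta} = \log_2 (p_{i\beta} / b_\beta)$.
A window scores the sum of its per-position log-odds. Probability matrices
are first rescaled to pseudo-counts of 100 so the pseudocount acts
comparably on count and probability inputs — mixed motif sources are common
and the two kinds must not be smoothed differently.

The occurrence p-value of a score $s$ is $P(S \ge s)$ for a random background
window. We compute it exactly by dynamic programming: per-position scores are
discretised to a grid of 1/1000 bit (configurable) and the distribution of
the total is built by position-wise convolution of the four-point
per-position distributions. The **same** integer grid scores the windows
during scanning, so reported p-values are exact for the discretised score —
the test suite checks them against exhaustive enumeration of all $4^L$
windows, and the agreement is equality, not approximation. The residual
error against the continuous score is at most $L/2$ grid steps
($\approx 0.01$ bit for a 20-position motif), far below one count of
resolution in any curated matrix.

Scanning reports every window at or below the p-value threshold on both
strands by default (minus-strand hits in forward coordinates, matched
sequence reverse-complemented). Overlapping occurrences of the same motif are
all reported — no greedy masking — because downstream co-occurrence logic
picks its own best hit per family, and occurrence counts are then honest
lower-bound counts. Windows containing N are skipped rather than scored.
Default scan threshold is $10^{-3}$, matching the loose screening threshold
used throughout.

Calibration: on i.i.d. background the fraction of windows reported at
$p \le \alpha$ is within Monte-Carlo error of $\alpha$ (checked at
$\alpha = 10^{-2}, 10^{-3}$ on 100 kb).

## Regions and coordinates

All coordinates are 1-based inclusive, the GFF3 and R/Bioconductor
convention; BED input is converted on read. Promoter positions are reported
relative to the translational start with the A of ATG at +1 and the base
immediately upstream at −1 — **there is no position 0**. This matches the
convention in which a promoter runs, say, from −2571 to +42; an off-by-one
here corrupts every downstream report, so `relative_position()` /
`genomic_position()` are exact inverses and are property-tested as such.

Two regions anchor the screen, both in transcript orientation:

* **core promoter**: TSS − 200 to the base before the translational start
  (the ATG base itself is excluded — "to the translational start" is read
  exclusively; the choice is visible in one place,
  `core_promoter_region()`).
* **CRM search space**: TSS − 2000 to the 3'UTR end, intersected with
  accessible chromatin (DNase I hypersensitive sites). DHS intervals are
  strand-less, per BED convention.

Where a gene has several mRNAs the longest is the anchor (configurable
decision; annotations differ and no single choice is canonical).

## Core-promoter annotation

The **Y-patch** is orientation-specific: only hits in the gene's orientation
count, at $p < 4\times10^{-4}$. Curated Y-patch matrices are not generally
redistributable, so the model slot is pluggable: supply any PWM, use the
built-in synthetic pyrimidine-patch matrix (12 positions, C/T at 0.45 each —
at the default threshold under uniform background only fully pyrimidine
windows qualify, which makes planted-truth tests deterministic), or fall
back to a rule (windows of length ≥ 8 with pyrimidine fraction ≥ 0.8 and at
least one C, merged over overlaps). Replication of any published screen is
conditional on supplying that screen's matrix.

Y-patches per promoter are counted after greedy leftmost collapse of
overlapping hits — deterministic and order-independent, and the count is
what correlates with core-promoter strength in deletion experiments.

**TATA variants** are found by exact hexamer match (default TATAAA and
ATTAAA) because reported variants are exact strings; a PWM mode is optional.
Reported TATA positions are the 5' base of the hexamer relative to the ATG
(the centre would be an equally defensible convention; the 5' base is the
documented one here).

**MTE, BREu and DCE-S-I** are scanned from a user-supplied (or built-in
synthetic) PolII-element library at $p \le 10^{-3}$, unconstrained in
orientation.

## The co-occurrence screen

Hits from scanning at $10^{-3}$ are labelled by family and filtered with
per-family strict cutoffs: WRKY and G2-like at $p < 10^{-3}$; MYBR_B, DOF,
IDD and DPBF at $p < 10^{-4}$. A CRM call requires one passing hit per
family such that the selected hits span at most 300 bp and sit inside one
contiguous accessible interval (no bridging across DHS gaps — a CRM is a
physical module). The 300-bp rule is applied to all six families jointly;
read literally, the published phrasing attaches the window only to the
$10^{-4}$ families, but the joint reading matches the biology of one compact
module and is the default (`window_bp` and the cutoff table are
configurable, so the literal reading is one argument away). The window
algorithm anchors each hit as the leftmost selected hit and takes, per
family, the smallest achievable stop — exact, and checked at the 299/301
boundary. Only the Y-patch is orientation-constrained; CRM hits count on
either strand.

A gene is reported `has_both` when its core promoter has a Y-patch and its
accessible search space has a CRM call. Enrichment of screen flags within
expression classes uses Fisher's exact two-sided test (the natural choice
for a 2×2 gene-set table; the sample cross-product odds ratio is reported
alongside, flagged when undefined).

The exact genome-wide counts from any published screen depend on pinned
external inputs (genome build, DHS release, motif library release); with
those supplied the same functions perform that screen, and the package's own
guarantees are stated on planted synthetic truth instead: sensitivity ≥ 0.95
for `has_both` and zero false positives among genes carrying at most five
planted families, at defaults (observed: sensitivity 1.0, zero false
positives, on 100-gene genomes).

## Expression filters

From a TPM table with sample metadata, a gene is **expressed** when some
developmental stage has at least 3 samples with TPM strictly above 1 (TPM
exactly 1 fails, as do stages with fewer than 3 samples). The
**bundle-sheath-specific** filter is the conjunction, with strict
inequalities: log2FC(BS/M) > 2, adjusted p(BS/M) < 0.01, FDR(BS/M) < 0.01,
log2FC(BS/V) > −0.5. "Adjusted p" and "FDR" are deliberately two distinct
columns — the upstream analyses that produce them (DESeq2-style adjusted
p-values and edgeR-style FDR) are both required, and the differential
statistics are consumed, never recomputed. Missing values fail filters.
Co-expression with a target gene is ranked by Pearson correlation of
log2(TPM + 1), ties broken by gene id.

## Reporter quantification

MUG assay: fluorescence is read every 2 min for 20 cycles; each duplicate
reaction's slope (OLS over all cycles — no lag-phase trimming by default,
a trim being a judgement call best left explicit) is converted to nmol
4-MU/min via the slope of a ten-point 4-MU standard curve, duplicates are
averaged, and the result divided by mg protein: nmol 4-MU/min/mg protein.
LUC/GUS ratios divide LUC luminescence by the GUS rate **per second** (the
per-minute/per-second distinction is centralised in one field,
`rate_per_second`). The estimator is scale-equivariant: rescaling
fluorescence units cancels between kinetics and standards.

Group comparisons run all pairwise two-sided tests (Wilcoxon rank-sum for
rate data, Welch t for log2 LUC/GUS — both exposed), BH-correct over the
pairwise family, and render a compact letter display via insert-and-absorb;
two groups share a letter exactly when their adjusted p ≥ 0.05, an
equivalence the tests assert against the full adjusted-p matrix. `wilcox.test`
computes an exact null for small samples without ties and a corrected normal
approximation otherwise. Fold changes are ratios of group medians to a
reference construct's median.

## The synthetic-data generator

`simulate_genome()` puts each gene on its own chromosome (2–6 kb genes, 40%
GC i.i.d. background, both strands, 2.5 kb upstream flank). Genes are
assigned to classes — `both`, `crm_only`, `ypatch_only`, `neither` — and
receive accordingly: one consensus string per family (random strands,
random order, total span 150–290 bp, placed between TSS − 1800 and the edge
of the core region so plants can never collide) and/or a 12-base pyrimidine
patch in the core promoter. Accessibility tracks come in three modes:
covering the plants (plus a decoy interval), excluding them (negative
control: the screen must call nothing), or whole-chromosome.

Two generator choices matter for interpreting the tests. First, the planted
motifs are consensus strings of strongly informative synthetic matrices, so
their p-values sit safely below every cutoff — the recovery tests exercise
the screen's logic (regions, thresholds, windows, strands, accessibility),
not borderline scoring, which the oracle and calibration tests cover
instead. Second, core promoters of genes *without* a planted Y-patch are
scrubbed of accidental ≥ 12-base pyrimidine runs, and expressed genes' TPMs
are shifted clear of the threshold, so the emitted files are exactly
consistent with the truth table; without the scrub ~8% of cores would carry
a chance Y-patch and "planted truth" would be a misnomer. The corresponding
limitation is explicit: passing recovery tests demonstrates correctness of
the screening logic under the stated conditions, not performance on real
genomes, where motif matches are weak, backgrounds are structured
(a first-order background stresses this assumption), and truth is unknown.

Expression tables follow the 7-stage, three-cell-type (BS/M/V), 3–4-replicate
design; planted BS-specific genes draw log2FC(BS/M) from Normal(3, 0.5)
truncated above 2 with sub-threshold p and FDR, every other gene violates at
least one condition, and boundary genes sit exactly on the strict thresholds
(log2FC = 2, adjusted p = 0.01, TPM = 1) to pin the inequalities. Kinetics
follow fluorescence = intercept + slope·rate·t + Normal(0, sd); with sd = 0
recovered rates are exact to machine precision, and with noise the mean
absolute error stays within the analytic OLS slope standard error scaled to
rate units. All randomness derives from one seed through per-stage
sub-streams, so adding genes does not perturb the kinetics draws.

## Problem sizes and numerical choices

The shipped checks use 20 random PWMs of length ≤ 8 against full $4^L$
enumeration, 100 kb of background for calibration, 100-gene genomes for
recovery, 80-gene expression tables and 100 reporter lines — sizes at which
every guarantee above is measurable in seconds to a couple of minutes on one
CPU. Granularity 1/1000 bit; survival functions are monotone by
construction; degenerate inputs (empty DHS, missing families, size-1 groups,
zero-variance targets, zero GUS rates, reference median 0) are either
warnings with well-defined results or immediate errors, as documented on
each function.

## Known limitations

* The built-in motif and Y-patch matrices are synthetic stand-ins for
  demonstration and testing; real screens need curated matrices
  (`read_motifs()` accepts JASPAR PFM and MEME-minimal files).
* TSSs are taken from the annotation; no TSS discovery from read data.
* Differential-expression statistics are inputs, not computations; the
  package does not reimplement DESeq2/edgeR/Salmon, nor WGCNA-style network
  modules (a pre-filtered gene list can be supplied where cluster membership
  would have been used).
* The scanner's background is 0-order; higher-order backgrounds are out of
  scope, and p-values on strongly structured real sequence are
  correspondingly approximate in interpretation, though exact under the
  stated model.
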