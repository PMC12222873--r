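---
title: "Models and methods behind gamhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gamhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

Genome Architecture Mapping (GAM) infers chromatin contacts without
ligation: nuclei are cryosectioned into thin slabs, the genomic content of
each slab ("nuclear profile", NP) is sequenced, and contacts are read off
the co-segregation of genomic windows across the collection of slices. In
an F1 hybrid cell line the two parental genomes (here called CAST and S129)
differ at a high density of SNPs, so the reads that cover a SNP reveal
which chromosomal copy a detected window came from. `gamhap` implements the
window-calling and haplotype-phasing core of this workflow plus the
downstream haplotype-resolved analyses (QC, contact-matrix normalization,
TADs, compartments, compaction, allele-specific expression and peaks), and
a diploid nuclear-slicing simulator that provides ground truth for every
stage. Read alignment, SNP-splitting of reads, and peak calling are out of
scope: the package starts from per-window coverage tables and per-feature
allelic counts.

# Window calling and phasing

A GAM sample mixes true signal (windows present in the slice) with
scattered sequencing noise. Because truly present windows come from
contiguous chromatin stretches, signal windows cluster along the genome
while noise does not. The per-sample **optimal threshold** exploits this:
for each candidate coverage threshold $t$, windows with coverage $\ge t$
are called positive and we compute the fraction of positive windows that
have at least one adjacent positive window on the same chromosome; the
chosen $t$ is the lowest one maximizing this neighbour fraction
(`optimal_threshold()`). Ties are resolved towards the lowest $t$ by
construction. The candidate set defaults to the distinct observed nonzero
coverages, subsampled to at most 256 quantile-spaced values; passing
`candidates = 1:max(coverage)` reproduces an exhaustive scan exactly
(property-tested against a brute-force oracle).

Phasing applies the *same* threshold to the nucleotide coverage of
SNP-containing reads: a positive window is phased to CAST when its
CAST-SNP coverage is $\ge t$, to S129 symmetrically, and to *both* ("dual
phasing") when both pass. Dual-phased windows enter both haplotype tables
by default (`dual = "both"`); they are rare in practice and their rate is
reported, with `dual = "exclude"` available. This choice was genuinely
open — the source method reports dual phasing as rare without stating the
table membership — and "both" was chosen because dropping them biases
per-haplotype detection frequency downwards at dense loci.

# Quality control

`qc_samples()` computes per-sample orphan-window percentage (positive
windows with no adjacent positive), genome coverage, and read count, and
flags cross-contamination by the Jaccard index of positive-window sets
within a plate group (J > 0.4 excludes both members of a pair). A sample
passes with < 60% orphans, strictly more than 50,000 uniquely mapped reads
and no contamination flag.

`resolution_check()` asks whether enough NPs were collected for a window
size: raw co-segregation counts of all intrachromosomal pairs in a
distance stratum are Yeo–Johnson transformed (the transform's $\lambda$ is
fitted by Gaussian maximum likelihood on the counts — the source names the
transform but not $\lambda$), a Poisson reference with matching mean and
size receives the same transform, and Kendall's $\tau$ is computed between
the two sorted (quantile-aligned) vectors; $\tau \ge 0.95$ passes. Two
numerical choices matter here. First, the alignment rule: comparing
distributions requires pairing values, and quantile alignment is the
natural choice the source leaves implicit. Second, on sorted vectors no
pair is discordant, so $\tau_b$ reduces to a function of tie-run lengths;
we compute it with an $O(n)$ formula (validated against
`stats::cor(method = "kendall")`, which is $O(n^2)$ and would dominate the
calibration test).

`undersampling_mask()` removes over-collapsed windows: the window
detection frequency (WDF) track is smoothed by an 11-window centred moving
mean per chromosome (edge-truncated rather than NA-padded), the normalized
delta $ND = (raw - smoothed)/smoothed$ is thresholded at 5, the two
windows on each side of a hit are also removed, and windows with mean
mappability below 0.2 are dropped irrespective of WDF. When a window's
smoothed value is 0, ND is undefined and the window is excluded with the
ND reason. Each excluded window carries exactly one primary reason, with
priority ND > low-mappability > neighbour-of-ND.

# Contact matrices

Co-segregation counts (`cosegregation_matrix()`) are normalized by
pointwise mutual information (`npmi_matrix()`): with $p_i$ the detection
rate of window $i$ and $p_{ij}$ the co-detection rate,

$$\mathrm{NPMI}_{ij} = \frac{\ln\left(p_{ij} / (p_i p_j)\right)}{-\ln p_{ij}} \in [-1, 1].$$

Natural logarithms are used (NPMI is base-invariant). $p_{ij} = 0$ maps to
$-1$; $p_{ij} = p_i = p_j$ maps to $+1$; windows with zero marginal and
the diagonal are NA; a zero marginal with nonzero co-segregation raises a
data-integrity error.

`zscore_by_distance()` standardizes each diagonal (genomic distance
stratum) to mean 0 and *population* standard deviation 1 over its finite
entries; a zero-variance stratum maps to z = 0. A global-standardization
mode exists behind `per_distance = FALSE`. Allele-specific contacts are
pairs within 50 Mb, outside the mask, with $\Delta z = z_{CAST} -
z_{S129}$ beyond $\pm 1$ and NPMI above 0.3; the intensity filter applies
to the gaining haplotype's map by default, with `npmi_filter = "either"`
implementing the more permissive either-map reading (both readings appear
in the source; the gaining-map rule is the stricter and is the package
default). Strong contacts are per-haplotype selections with z > 2.0 and
NPMI > 0.3, deliberately uninformed by the other allele. Distance decay
uses per-diagonal means on the $\log_{10}$ axis smoothed by
`stats::ksmooth` with a Normal kernel of bandwidth 0.3, with slopes taken
as successive differences at 0.1-spaced breakpoints.

# TADs and compartments

`insulation_score()` implements the insulation-square method: for window
$i$ and square size $s$ bins, the mean matrix value over pairs $(a, b)$,
$a \in [i-s, i-1]$, $b \in [i+1, i+s]$, clipped at chromosome ends, NA
when more than half the square is missing; the normalized track is the
log2 ratio to the chromosome mean (which makes it invariant to global
matrix scaling). TAD borders (`call_tad_borders()`, 400-kb square) are
strict local minima widened by one bin on each side; plateaus of equal
minima take the leftmost window; minima flanked by missing values on both
sides are dropped.

`call_compartments()` follows the classical eigenvector route on a 100-kb
co-segregation matrix: observed over per-distance expected, Pearson
correlation matrix of the O/E columns, eigendecomposition, component 1 by
default (`select_pc = "by-gc"` scans components 1–3 for the best absolute
GC correlation), orientation such that positive values correlate
positively with GC content, then per-chromosome rescaling of positive
values to (0, 1] (compartment A) and negative values to [-1, 0)
(compartment B).

# Haplotype-resolved feature statistics

* **WDF** is the exact fraction of samples in which a window is positive;
  larger chromatin volume (decondensation) raises capture probability, so
  the differential CAST − S129 is a compaction-asymmetry proxy (positive =
  CAST more open).
* **ASE calling** excludes genes with fewer than 20 allelic reads, runs a
  two-sided exact binomial test against 0.5, corrects by
  Benjamini–Hochberg, and calls ASE at adjusted p ≤ 0.05, |log2FC| ≥ 1 and
  TPM ≥ 1; a zero denominator yields a signed infinite fold change that
  always satisfies the fold-change criterion (the monoallelic path).
* **ChIP peak phasing** uses |log2FC| > 2 with a 10-SNP-read floor.
* **ATAC peaks** use the reads-ratio D score $(CAST - S129)/(CAST +
  S129)$ per replicate and a read-relabeling permutation test on |D|; the
  null is Binomial(m, 1/2), so p-values for peaks with ≤ 15 reads are
  computed by exact enumeration and match an exhaustive oracle exactly.
  The source's filter text ("a D score between −0.3 and 0.3") contradicts
  the goal of detecting imbalance; the default requires |D| ≥ 0.3 in every
  replicate, and the literal inside-range rule is available via
  `rule = "literal"` rather than being silently chosen.
* **Promoter states** bootstrap the per-mark read threshold in one pass:
  provisional positives are defined by enriched-region overlap alone, the
  threshold is the 5th percentile (type-1, i.e. an observed value) of
  their TSS-window read counts, and final positives need both. States:
  Active = S5p⁺S7p⁺K27me3⁻, PRCa = S5p⁺S7p⁺K27me3⁺, PRC = K27me3⁺S7p⁻
  (S5p unconstrained, following the cited classification), Inactive
  otherwise.
* **Differential methylation** calls a CpG methylated above 50%, forms the
  methylated/unmethylated ratio in TSS ± 1000 bp promoters of genes longer
  than 2000 bp, and calls promoters whose |S129 − CAST| ratio difference
  exceeds the 95th percentile (two-tailed default; the literal one-tailed
  reading of "exceeded the 5th percentile" is available via
  `tail = "upper"`). Promoters with undefined ratio differences
  (infinite on both alleles) are excluded with a reason.
* **Circular permutation tests** rotate all features by one uniform offset
  per chromosome, wrapping at chromosome ends, preserving intra-chromosome
  spacing; on a single chromosome with a small rotation space the p-value
  is exact by enumeration, otherwise Monte Carlo with the
  $(1 + k)/(1 + n)$ estimator.

# The simulator: what it emulates, and what it does not

Each simulated cell carries one locus sphere per window per haplotype.
Only the coordinate perpendicular to the sectioning plane matters for
slab capture, so positions are scalar:

$$z_w = g[\mathrm{comp}(w)] + t[\mathrm{TAD}(w)] + \varepsilon_w,$$

with per-cell, per-haplotype draws $g \sim N(0, \sigma_{comp}^2)$ per
compartment label, $t \sim N(0, \sigma_{tad}^2)$ per TAD and
$\varepsilon \sim N(0, \sigma_{jit}^2)$ per window, clamped to the
nucleus. A slab of thickness $h$ placed uniformly across the diameter
captures a window when it intersects the locus sphere; for radius $r$ in
nucleus radius $R$ the capture probability is exactly $(2r + h)/(2R + h)$,
which the tests verify by Monte Carlo against the closed form.

Parameter defaults and their reasoning, chosen once:

| parameter | default | why |
|---|---|---|
| nucleus radius $R$ | 5000 nm | ~10 µm mESC nucleus; exposed because the true radius distribution is not stated for this line |
| slab thickness $h$ | 230 nm | cryosection thickness used in GAM |
| locus radius $r$ | 300 nm | puts single-slice capture at 8.1%, inside the 5–15% per-NP range |
| $\sigma_{comp}, \sigma_{tad}, \sigma_{jit}$ | 2200, 1000, 330 nm | fills the nucleus (total sd ≈ 2.4 µm), gives within-TAD NPMI ≈ 0.5 and visible compartment checkerboard, matching real GAM maps |
| SNP density | 1/124 bp | the hybrid line's autosomal density; ~400 SNPs per 50-kb window |
| read length | 75 bp | a read phases when it covers a SNP: P = 1 − exp(−snps·75/window), ≈ 0.45 per read, bracketing the observed ~37% read-phasing rate |
| depth | 40,000 nt | nucleotide coverage of a fully captured 50-kb window at 2–3 M reads per NP |
| slices per sample | 3 | the multiplexed 3NP collection mode |
| background / error rate | 0 | noiseless by default; raised only in threshold-calling tests |

Homologues are placed independently (matching the low dual-capture rates
seen by cryo-FISH); compartment runs are composed of whole TADs because
independent 100-kb compartment blocks would cut TADs into positionally
incoherent pieces and destroy the very structure being planted; planted
long-range contacts tie the full centre of one TAD to another on one
haplotype. All randomness flows through a single seeded generator; the
seed is recorded in the emitted metadata and the caller's RNG state is
restored.

What the simulator does **not** emulate: polymer connectivity between
adjacent TADs (adjacent TADs get independent centres, so real-data
distance decay is steeper at short range than simulated decay), mapping
bias, GC/mappability coverage artifacts, trans-chromosomal organization,
and slab-orientation anisotropy. A green planted-truth test therefore
establishes that the estimators recover block-level co-segregation
structure at realistic sampling depth — not that they are calibrated on
real sequencing artifacts, which is what the QC and masking stages are
for.

# Degenerate inputs and tie-breaking, in one place

* All-zero coverage samples raise an "unsuitable sample" error in
  threshold computation and are dropped (with a warning) by the table
  builder.
* Neighbour fraction at a threshold yielding zero positives is defined as
  0.
* `NPMI`: $p_{ij} = 0 \to -1$; perfect co-segregation $\to 1$; diagonal
  and zero-marginal windows NA.
* z-scores: zero-variance strata give 0, NA propagates.
* Border plateaus take the leftmost window; borders need at least one
  finite neighbour.
* Eigenvector orientation fails loudly when GC correlation is undefined;
  a constant matrix raises a degenerate-decomposition error.
* Isoform selection falls through its cascade only on exact ties and ends
  in a seeded uniform choice.

# Known limitations

The per-distance z-score treats structural spread as the noise scale, so
very short chromosomes (few pairs per diagonal) produce unstable calls;
the simulator's capture model ignores partial-window effects other than
slab overlap; and the CLI covers the core subcommands rather than every
exported function. The published genome-wide counts (thousands of ASE
genes, hundreds of haplotype-specific TAD borders, 18% compartment
discordance) depend on the full experimental dataset and are treated as
qualitative context; nothing in the package asserts them.
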