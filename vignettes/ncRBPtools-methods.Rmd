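---
title: "Methods and design of ncRBPtools"
author: "ncRBPtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ncRBPtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncRBPtools)
```

# Scope

ncRBPtools re-implements, as a tested and reusable pipeline, the
computational procedures used to characterize a non-canonical RNA-binding
protein (ncRBP) in acute myeloid leukaemia cell models: depletion scoring of
a pooled CRISPR knockout screen, construction and annotation of CLIP peaks
from single-nucleotide crosslink sites, an eCDF statistic quantifying
stabilization of CLIP target transcripts after knockdown, a minimal
differential-expression and translation-efficiency layer, biophysical curve
fits (binding isotherms, competition, mass photometry, enzyme activity),
and mRNA half-life estimation from actinomycin-D time courses. A seeded
synthetic-data generator produces every input class with known ground
truth, so the whole pipeline is testable without external sequencing data.

Deliberately out of scope: read alignment and quantification, HMM-based
crosslink-site calling (sites are this package's *input*), shrinkage-based
differential-expression frameworks, batch correction, enrichment analysis
and motif discovery.

# CRISPR screen scoring

Guide counts are normalized per sample to reads-per-100,000:
$\tilde c_{gs} = c_{gs} / \sum_g c_{gs} \times 10^5$, so normalized
abundances always total 100,000 within a sample. Depletion is scored as
$\log_2((\tilde c_{d4} + pc)/(\tilde c_{d20} + pc))$ per guide — replicates
averaged first, then guides averaged per gene — so positive scores mean
depletion over the screen. The pseudocount (default 0.5) keeps scores
finite for guides that drop out entirely; it is applied to normalized
abundances, mirroring common screen practice.

Hit selection applies three filters: *depleted* (gene score at least
$\log_2 5$, i.e. five-fold, in every AML line), *lineage-specific* (score
above 1 in each AML line and below 1 in the T-ALL counter-screen line),
and an analogous two-AML-line contrast at threshold 2.5. Lineage
specificity is implemented as "above the threshold in the focal line(s),
below the same threshold in the counter line"; a difference-of-scores rule
would also be defensible, but the per-axis reading matches the rectangular
selection regions of screen scatterplots and is the configurable default.
Core-fitness flagging is membership in a caller-supplied gene list.

# CLIP peak construction and annotation

Crosslink sites are width-1 stranded genomic positions. Sites on the same
chromosome and strand within 50 bp of each other (chained single linkage)
merge into one peak spanning the cluster; a cluster of one site is extended
*symmetrically* to a 50 bp peak. The merge distance is the only distance
the protocol names, so it is the default for both knobs and both are
arguments. Symmetric solo extension is the least biased geometry when the
protocol does not specify a direction; one-sided extension can be emulated
by post-processing. Coordinates are 0-based half-open on disk (BED) and
1-based closed in memory (GRanges); `rtracklayer` converts at the
boundary. Implementation note: interval merging is delegated to
`GenomicRanges::reduce()`; because two width-1 sites at distance $d$ have
an inter-range gap of $d - 1$, "sites within 50 bp" is `min.gapwidth = 50`.
The test-suite cross-checks this against a brute-force all-pairs
single-linkage oracle.

Cross-condition overlap (the Venn of the three metabolic conditions —
normal glucose, low glucose, galactose) clusters peaks from all conditions
by single linkage on same-strand overlap of at least 1 bp, then counts
clusters present in all three, exactly two, or one condition. No
reciprocal-overlap fraction is required. Counts are invariant to condition
relabeling, and the three categories partition the clusters.

Peak annotation assigns exactly one label per peak with precedence
5'UTR > CDS > 3'UTR > intron > lncRNA > other non-coding > intergenic,
using same-strand 1 bp overlap. The precedence puts the 5'UTR first —
the compartment of primary biological interest here — and prevents double
counting; the order is an argument. The 5'UTR metagene profile scales every
annotated 5'UTR to `n_bins` bins in transcript orientation (strand-aware)
and reports, per bin, the fraction of UTRs covered by at least one peak;
peak heights are not used because presence/absence is what the
corresponding figure logic needs and weighting is otherwise unspecified.

# Differential expression and translation efficiency

The package intentionally ships a *minimal* DE layer rather than wrapping a
GLM framework: the downstream stabilization and TE statistics only consume
per-gene log fold changes, and a transparent, dependency-light
normalization keeps the pipeline auditable. Size factors are
median-of-ratios (reference genes = nonzero in every sample; factor =
median of count/geometric-mean ratios). The LFC is computed from
size-factor-normalized group means with a 0.5 pseudocount; the p-value is
a Welch (unequal-variance) t-test on log2 normalized counts, adjusted by
Benjamini–Hochberg. This is *not* a substitute for dispersion-shrinkage
methods when genome-wide DE calling is the goal; it is adequate and
unbiased for rank-based downstream statistics. Samples from the three
metabolic conditions are pooled by knockdown status for the main contrast,
matching the study design this mirrors; per-condition contrasts remain
possible by subsetting.

Translation efficiency is the ratio of normalized ribosome-nascent-chain
(RNC) counts to normalized total counts per gene, compared between
knockdown and control as `delta_log2_te`; the test applies the same Welch
test to per-replicate log2 TE values, pairing RNC with total within
(group, condition, replicate). A GLM with an interaction term would be the
heavier alternative; the replicate-level log-TE contrast is implemented
and labelled as such. The qPCR path uses the standard relative
quantification $2^{-\Delta\Delta C_t}$ with 18S rRNA as the reference.

# Target stabilization (eCDF shift)

Given per-gene knockdown LFCs, a CLIP target set and a background set, the
comparison reports both medians, the difference of mean LFCs, both eCDF
curves, and a two-sided Wilcoxon rank-sum test. The background defaults to
*all* quantified genes; a seeded random non-target control set (genes
without a detected CLIP peak — the only coherent reading of a
"non-target" control for this assay) is reported as a second comparison,
never substituted for the background. The test is exact when the smaller
set has at most 25 observations and there are no ties, otherwise the
normal approximation with tie correction is used; the suite verifies
agreement with exhaustive permutation enumeration for small sets to 1e-12.
Sidedness defaults to two-sided since the direction is a finding, not an
assumption.

# Biophysical fits

*Binding isotherms.* The default model is the one-site hyperbola
$r([P]) = r_\mathrm{free} + (r_\mathrm{bound} - r_\mathrm{free})
\,[P]/(K_D + [P])$, appropriate because the labelled probe (2 nM) sits
far below the dissociation constants involved (~170–1300 nM); a quadratic
ligand-depletion model using the probe concentration is available by
argument, and the two agree to <1% in $K_D$ when probe ≤ $K_D/50$ (tested).
Fits use Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
$K_D > 0$ enforced by a bound; the starting $K_D$ is the concentration at
half-maximal response by interpolation. A response range below the noise
floor raises a "no binding signal" error rather than returning a
meaningless fit. No Hill coefficient is fitted by default (one-site
behaviour is the modelled regime). EMSA fraction-bound tables use the same
isotherm machinery; densitometry is upstream of this package.

*Competition.* A four-parameter logistic on log concentration; maximum
inhibition is $1 - \mathrm{lower}/\mathrm{upper}$. Flat or monotonically
increasing responses set a no-inhibition flag with `ic50 = NA` instead of
forcing a fit.

*Mass photometry.* Contrast-to-mass calibration is an ordinary
least-squares line through the standards (defaults documented as BSA
66.5 kDa and thyroglobulin 660 kDa monomer masses, overridable). The mass
histogram is reduced to oligomeric species by a one-dimensional Gaussian
mixture fitted by EM, written in the package so its numerical contract is
explicit: k-means++ initialization from a caller seed (bit-for-bit
reproducible), convergence at relative log-likelihood change < 1e-8 or 500
iterations, component means returned ascending, and `k = "auto"` chosen by
BIC over 1–4 components. The suite cross-checks means and log-likelihood
against an independent mixture implementation (`mclust`). Mass shifts
between conditions difference the matched components (nearest means).

*Enzyme activity.* The kinetic A450 trace and the NADH standard curve are
both fitted by least squares; activity = kinetic slope / standard-curve
slope / sample volume, in nmole NADH · min⁻¹ · mL⁻¹.

# mRNA stability

Decay curves (hourly, 0–8 h, normalized to t = 0 per replicate — the qPCR
readout is relative) are fitted by default with log-linear OLS of
ln(abundance) on time, $\lambda = -\mathrm{slope}$, half-life
$= \ln 2/\lambda$ with a delta-method standard error; a direct nonlinear
exponential fit is available and agrees to ≤0.1% on noiseless data
(tested). Replicates are pooled by fitting all points jointly. Non-decaying
series are flagged with an infinite half-life instead of a negative rate;
zero abundances switch the log-linear method to the nonlinear fit with a
warning. A model-free time-to-50% interpolation is provided as a companion
estimate; the single-exponential fit is primary. Condition comparisons
report the control/knockdown half-life ratio with a propagated
(delta-method) standard error.

# The synthetic-data generator

The generator defines the study conditions under which everything is
tested; its defaults are fixed once:

* **Screen**: 1045 candidate genes × 4 guides (the library design),
  2 × 10⁶ reads/sample (300–500× coverage), two AML lines and one T-ALL
  counter-screen line, day-4 and day-20 timepoints. Latent guide
  abundances are log-normal (sdlog 0.5) and counts multinomial at the
  configured depth. Depleted genes (default 10% of the library, in the AML
  lines only) lose 8-fold in relative abundance — comfortably past the
  5-fold selection threshold, since injecting an effect exactly at the
  decision boundary cannot be recovered by any caller. Depletion is
  modelled with *repopulation*: surviving cells expand to fill the
  culture, so the day-20 relative abundance of a depleted guide drops by
  exactly the configured fold and, with noise off, the gene score equals
  $\log_2 k$ to machine precision under the reads-per-100,000
  normalization. Without repopulation the normalization itself would
  induce a compositional offset on every gene.
* **Toy genome**: one transcript per gene, ~50 transcripts per chromosome,
  alternating strands; protein-coding transcripts carry 200 nt 5'UTR,
  600 nt CDS, 400 nt 3'UTR; 12% lncRNA and 8% other non-coding genes.
  Crosslink sites (default 1000 per condition × replicate, 3 metabolic
  conditions × 2 replicates) are placed on the designated target genes,
  in 5'UTRs with probability `utr5Enrichment` (default 0.5, the observed
  protein-coding share of hits) and otherwise across CDS/3'UTR/lncRNA.
* **Expression**: negative-binomial counts with a shared dispersion
  (default 0.05, typical for bulk RNA-seq cell-line replicates), log-normal
  baseline means (median 200 counts); target genes shift by
  `stabilizationLfc` (default −0.5, a moderate destabilization-on-knockdown
  effect) in knockdown samples, plus an optional TE shift on the RNC
  fraction.
* **Assays**: a 2-fold dilution titration centred on the true $K_D$
  (default 167 nM with plateaus 50→250 mP and 5 mP Gaussian noise,
  triplicate); mass events from the configured mixture (defaults at the
  measured monomer and tetramer masses, 38.5 and 148.3 kDa, sd 6 kDa —
  a realistic single-event spread for this instrument class, distinct from
  the sub-kDa standard errors of fitted peak positions); decay with
  half-lives 6 h (control) vs 2 h (knockdown) — the threefold difference —
  with 10% multiplicative log-normal noise and 4 replicates.

All randomness flows from one master seed through named substreams, so a
stage's output is reproducible in isolation and adding a stage never
perturbs another stage's draws; the generators also restore the caller's
RNG state.

What the generator does **not** emulate: read-level artefacts (PCR
duplicates, UMIs, mapping bias), sequence-motif-driven site placement,
overdispersion heterogeneity across genes, batch effects, and the
correlation structure of real replicates. Passing tests therefore
demonstrate that the *estimators and rules* recover known truth under the
stated noise models — not that any specific biological dataset would
reproduce.

# Workflow, sizes, and numerical choices

`runPipeline()` executes screen → CLIP → DE/TE → CDF (assays independent)
from one configuration, fails fast when a stage's dependency is disabled,
writes per-stage TSV/JSON with a provenance header (package version, seed,
config MD5) and a small self-contained HTML summary. The bundled demo
configuration uses 300 genes, 5 × 10⁵ screen reads and 500 sites per
sample — sizes chosen so a complete run takes seconds while every
statistic remains comfortably estimable; the full-scale defaults of
`simConfig()` remain available. The test suite runs the peak-merging
oracle at 200 intervals, the exact rank-sum comparison at set sizes ≤ 12
(where enumeration is cheap), and estimator-recovery checks at 20,000 mass
events and 1,000–10,000-site tracks.

Known limitations: the DE layer is deliberately simple (see above); the
screen model does not simulate infection multiplicity or guide-efficiency
variation; lineage specificity is a thresholding rule, not a statistical
test; the mixture EM assumes Gaussian components and can merge species
closer than ~2 sd; and the half-life ratio inherits the usual instability
of ratios of fitted rates when either arm is weakly decaying (flagged as
infinite rather than extrapolated).
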