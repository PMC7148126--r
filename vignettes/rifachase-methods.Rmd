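---
title: "Methods: decay kinetics, production rates, and the two-pool model"
author: "rifachase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay kinetics, production rates, and the two-pool model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifachase)
```

## Scope and data model

`rifachase` analyzes rifampin-chase qPCR experiments in fast-growing
bacteria: transcription is blocked at t = 0 and transcript abundance is
sampled over the following minutes. The raw datum is a threshold cycle
(C_T); −C_T is log2 abundance, which makes exponential decay linear and
turns half-life estimation into linear regression. All tables are plain
TSV with header-named columns; the `CtTable` class (a validated
`DataFrame`) enforces the schema (strain, gene, replicate, time_min, ct)
and finiteness before anything downstream runs.

## Relative quantification

Steady-state abundance uses the ΔC_T method against a reference gene
measured in the same strain and replicate:

$$\text{rel. abundance} = E^{(C_{T,\mathrm{ref}} - C_{T,\mathrm{target}})}$$

with amplification efficiency E = 2 by default (perfect doubling;
configurable, since primer efficiencies vary but are rarely reported).
ΔC_T is computed per replicate first and averaged on the log2 scale, so
the reported linear ratio is a geometric mean — the natural choice for a
log-scale measurement, and the convention assumed everywhere else in the
package. The sign convention (reference minus target) makes larger values
mean more abundant. Whether replicates should be averaged before or after
normalization is genuinely ambiguous in most protocols; we fix the
per-replicate-first, log2-scale convention and document it in the schema.

## Half-life estimation and biphasic segmentation

For a chase series, ordinary least squares is fit to −C_T versus time with
all replicates pooled into one regression (rather than averaging
per-replicate fits — pooling matches how such comparisons are usually
reported and gives the interaction test below its proper degrees of
freedom). The half-life is −1/slope minutes. A non-negative slope yields
an infinite-half-life sentinel rather than an error so pipelines survive
stable transcripts. The 95% CI of the half-life inverts the slope CI
endpoints, which is exact under the regression model and remains sensible
for very short half-lives where a delta-method interval would misbehave;
a slope CI endpoint crossing zero maps to an infinite bound.

Chase curves in mycobacteria are often biphasic: a fast initial phase
holding most of the RNA, then a much slower tail (minority species or a
rifampin artifact — the data cannot distinguish, and the package draws no
conclusion). `segmentBiphasic()` operationalizes the informal "use the
initial phase" rule as an automatic procedure:

1. exhaustive search over breakpoints in the sorted unique times, with at
   least `min_points_per_segment` (default 2) distinct times per segment;
2. two independent OLS segments; total SSE minimized;
3. the two-segment model is accepted only if an extra sum-of-squares
   F test (2 extra parameters) beats the single line at
   `significance_alpha` **and** the late segment decays more slowly;
4. the fast-pool fraction is `1 − 2^(a_slow,0 − a_fast,0)` from the two
   intercepts extrapolated to t = 0, clamped to [0, 1];
5. optionally, a significant split whose fast segment explains less than
   `min_fast_fraction` of t = 0 abundance is discarded in favor of the
   single line. `estimateHalfLife()` applies the configured threshold
   (default 0.9); `segmentBiphasic()` called directly applies none.

Step 5 encodes the experimental convention of using the initial phase for
headline half-lives only when it reflects the decay of at least ~90% of
the transcript pool. It also matters quantitatively: a tiny, rapidly lost
subpopulation inflates only the t = 0 point, and without the gate that
contamination masquerades as a "fast phase" whose slope does not describe
bulk decay (see the two-pool analysis below).

Two caveats the tests make explicit. On smooth two-exponential mixtures
the two-line model is misspecified in the transition region, so when the
slow phase is not fully resolved within the sampling window the
intercept-based fraction is biased downward (the package's brute-force
oracle tests freeze the exact values the SSE-optimal fit produces). And
because the chase observes total per-cell concentration, the fitted decay
rate is k + μ, not k alone; at the short half-lives this package targets
(k ≥ 100 μ) the distinction is below 1%.

Half-life comparisons between strains use a pooled regression with a
strain×time interaction restricted to each strain's fast-phase points;
the interaction's two-sided p is reported. (Whether such comparisons are
an interaction test or CI overlap is often left unstated in figure
legends; the interaction test is fixed here because it is calibrated —
the test suite verifies type-I error within [0.03, 0.07] at α = 0.05 over
1000 null simulations.)

## Production rate and translation efficiency

At steady state synthesis balances loss, so the production rate is
inferred as V_t = (k + μ)[mRNA] with k = ln2/t½ and μ = ln2/doubling
time. Because [mRNA] is relative, V_t is relative; only ratios within a
run are meaningful, which is why `relativeSummary()` reports construct
panels as percent-of-reference (a construct against itself is 100
everywhere, and percentages are invariant to common abundance scaling).
The default doubling time is 180 min — typical for a fast-growing
mycobacterium in rich medium — and is a documented package convention,
not a measured value; for transcripts with half-lives of a minute or two
the μ term moves V_t by well under 1%, and the logs report values both
with and without it. Translation efficiency is protein/[mRNA] at chase
time 0, in arbitrary units.

## The two-pool ("dark matter") model

The simulator formalizes the hypothesis that some transcripts are
degraded almost immediately unless captured by ribosomes. Synthesis at
rate α routes a fraction p into a translated pool (decay k_t) and 1−p
into a dark pool (decay k_d ≥ k_t); both dilute at μ; protein is made at
β per translated mRNA and removed by dilution only (fluorescent reporters
are stable on these time scales). Steady states are closed-form:

$$M_t = \frac{p\alpha}{k_t+\mu},\quad M_d = \frac{(1-p)\alpha}{k_d+\mu},
\quad P = \frac{\beta M_t}{\mu}$$

verified in the tests against numerical ODE integration (≤ 1e-6
relative) and by exact mass balance α = (k_t+μ)M_t + (k_d+μ)M_d. The
chase is a perfect instantaneous transcription block; "nearly
instantaneous" dark-pool decay is modeled as a finite large k_d (default
50× k_t) so curves stay well-defined. Noise enters only at the C_T
measurement layer (Gaussian in cycles), reflecting population-level qPCR
rather than molecule-count stochasticity; no parameter here is a claim
about any particular organism — magnitudes for p and k_d are simulator
inputs.

`apparentProductionRate()` quantifies the interpretive risk: it runs the
full measurement pipeline (steady-state abundance → chase → fast-phase
half-life → V_t) on simulated data and returns V̂_t/α. When k_d = k_t the
pools are indistinguishable and the ratio is 1 for any p; as k_d/k_t
grows the ratio falls monotonically to p. In words: if dark matter mRNA
exists, conventional abundance × decay arithmetic under-reports true
synthesis by exactly the dark share, while measured half-lives barely
move. The residual deviation from p at k_d = 100·k_t is under 0.015
across p ∈ [0.2, 1] with the default protocol (four time points, gated
segmentation), part of which is the inherent +μ/(k_t+μ) ≈ 0.8% offset
from dilution appearing both in the measured decay and as a separate term
in V_t.

## 5′ UTR annotation and Shine-Dalgarno scanning

Coordinates are 1-based inclusive genome positions with explicit strand.
The UTR length is the number of transcribed nucleotides strictly before
the start codon's first nucleotide, the TSS counting as transcribed
nucleotide 1; 0 means leaderless. This convention simultaneously
reproduces both standard anchors used in mycobacterial annotation work
(a 123-nt leader from a TSS at 100 and start at 223, and a 39-nt
downstream distance between two minus-strand GTG codons at 2827625 and
2827586). Classification is leaderless (0), ambiguous (1–14 nt; excluded
from leadered/leaderless contrasts because the initiation mechanism of
very short leaders is unclear), and leadered (≥ 15 nt). Distribution
summaries exclude leaderless genes by default and use 10-nt histogram
bins (a "mode near 40 nt" is inherently a binned statement).

The SD scan slides the anti-SD (default core `AGGAGG`, a stated
convention — the reverse complement of the 16S 3′ tail varies slightly
by species) ungapped across spacings of 4–20 nt upstream of the start
codon, reporting maximal per-position identity; ties break toward the
spacing closest to 7 nt, then toward the start codon. Identity equals
brute-force enumeration over all windows (property-tested on 1000 random
sequences).

## Synthetic data: what it does and does not emulate

`generatePanel()` produces the full measurement set for a construct panel
with known truth: steady-state and chase C_T tables (Gaussian C_T noise,
default SD 0.15 cycles — a plausible qPCR repeatability figure, exposed
in config), a stable reference gene equal across strains up to noise,
lognormal protein noise, and lognormal per-cell fluorescence (CV 0.35).
`generateAnnotationTable()` draws leadered UTR lengths from
gamma(shape 4, scale 10) + 12 nt — mode ≈ 42 nt, median ≈ 48 nt, the
skewed shape seen in mycobacterial TSS surveys — with a 14% leaderless
fraction. `generateProteomeTable()` draws log10 mRNA per leader class
around group medians (leaderless 0.3 log10 lower by default) and log10
protein along a shared slope with Gaussian residuals.

What passing tests show: the estimators recover known kinetic truth at
realistic noise, the statistics are calibrated under their nominal nulls,
and every generator output round-trips through the package's own readers.
What they do not show: real chases may violate the instantaneous-block
assumption (rifampin takes time to act and may itself perturb
degradation), C_T noise can be heteroskedastic near detection limits,
real UTR surveys carry TSS-mapping errors and multi-TSS genes (excluded
here by design), and proteome/transcriptome pairs have shared technical
covariates the generator omits. Synthetic recovery is necessary, not
sufficient, evidence about real data.

## Statistical battery

Spearman correlation (midranks, two-sided), ANCOVA slope-equality via a
group×abundance interaction on log10 scales (log-log because abundance
spans decades; the transformation is an explicit, configurable step),
Mann-Whitney (exact for small tie-free samples, normal approximation with
continuity correction otherwise), Kruskal-Wallis with Dunn's pairwise z
tests (tie-corrected, Bonferroni-family adjustment — the adjustment is a
stated choice, since figure legends rarely name one), and one-way ANOVA
with Tukey HSD. Dunn's procedure is implemented in the package on pooled
midranks; for two groups its z² equals the Kruskal-Wallis statistic,
which the tests exploit as an internal consistency check.

## Numerical conventions and test scales

Degenerate inputs: all-equal abundances give a flat single-phase fit with
warning; fewer distinct times than two segments require fall back to a
single phase; missing t = 0 in a chase is an error (the fast phase needs
its anchor). Ties in the SD scan and breakpoints follow the stated
deterministic rules, so every result is reproducible from (inputs,
config, seed).

Simulation sizes in the test suite and acceptance script were chosen to
give stable statistical verdicts at interactive runtimes: 200 seeds for
half-life recovery (±20% band at C_T noise 0.1), 1000 simulations for
each type-I calibration, a 5×5 (p × k_d/k_t) grid for the bias law, 1000
random instances for the SD-scan property, and 10,000 genes for the UTR
survey. The acceptance script reruns all of these from scratch under a
caller-supplied seed.

## Known limitations

- The production-rate inference attributes all loss to first-order decay
  plus dilution; regulated or zero-order degradation would bias V_t.
- Initiation, elongation and termination contributions to V_t are not
  separable from these data.
- The biphasic segmentation assumes at most two phases; three-component
  mixtures fold into whichever two-line fit minimizes SSE.
- The slow chase phase is reported but not interpreted: the data cannot
  distinguish a real slow pool from a rifampin artifact.
- Secondary-structure effects on 5′ UTR function are out of scope; only
  length, class, and SD match geometry are computed.
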