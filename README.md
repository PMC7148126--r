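# rifachase

Quantitative analysis of bacterial mRNA turnover from rifampin-chase qPCR,
written for experiments of the kind used to dissect how 5′ UTRs and leaderless
gene architecture shape expression in mycobacteria. Transcription is blocked
with rifampin, transcript abundance is sampled over a few minutes by qPCR, and
the package turns the resulting threshold-cycle (C_T) tables into half-lives,
predicted transcript production rates, and translation efficiencies — together
with the statistics used to compare reporter constructs, and a kinetic
simulator that makes the "dark matter mRNA" interpretation of such data
explicit and testable.

## The model

qPCR reports −C_T as log2 transcript abundance. For each strain and gene the
package fits

    −C_T(t) = a + s·t        (OLS over pooled replicates)
    t½ = −1/s

Chase curves in mycobacteria are frequently **biphasic**: a fast initial
exponential followed by a much slower tail. `segmentBiphasic()` searches all
breakpoints, fits two independent OLS segments, accepts the split only when an
extra-sum-of-squares F test beats the single line and the late segment decays
more slowly, and reports the fast-phase fit as the headline half-life. The
fast-pool fraction is estimated from the two intercepts extrapolated to t = 0
(1 − 2^(a_slow − a_fast)); by default the fast phase is only used as the
headline when it accounts for ≥ 90 % of the t = 0 abundance.

At steady state, synthesis balances loss to degradation and growth dilution,
so the **transcript production rate** is inferred as

    V_t = (k + μ)·[mRNA],   k = ln2 / t½,   μ = ln2 / doubling time

and **translation efficiency** is protein abundance / mRNA abundance (both in
relative units). The **two-pool simulator** formalizes the hypothesis that
newly made transcripts partition with probability *p* into a translated pool
(decay k_t) and otherwise into a rapidly degraded, effectively invisible pool
(decay k_d ≥ k_t): `apparentProductionRate()` runs the full measurement
pipeline on simulated data and shows that the inferred V_t underestimates true
synthesis by exactly the dark-pool share as k_d ≫ k_t.

## Worked example

Simulate two constructs — a reporter with a 1.5-min half-life and a variant
with a 0.6-min half-life at 6-fold lower steady-state abundance — then run the
analysis end to end:

```r
library(rifachase)
cfg <- pipelineConfig(ct_noise_sd = 0.1)
mu  <- growthRate(180)
cons <- list(
  "UTRtetO-yfp"        = TwoPoolParams(alpha = 10, p = 1,
                                       k_t = degradationConstant(1.5) - mu,
                                       mu = mu, beta = 5),
  "UTRtetO-sigA54-yfp" = TwoPoolParams(alpha = 10/6 * degradationConstant(0.6) /
                                         degradationConstant(1.5), p = 1,
                                       k_t = degradationConstant(0.6) - mu,
                                       mu = mu, beta = 5))
panel <- generatePanel(cons, cfg, seed = 42)

halfLife(estimateHalfLife(panel@chase_ct, "UTRtetO-yfp", "yfp", cfg))
#> 1.50 min
halfLife(estimateHalfLife(panel@chase_ct, "UTRtetO-sigA54-yfp", "yfp", cfg))
#> 0.591 min

a1 <- summarizeAbundance(panel@steady_ct, "UTRtetO-yfp", "yfp", "sigA")
a2 <- summarizeAbundance(panel@steady_ct, "UTRtetO-sigA54-yfp", "yfp", "sigA")
ref <- expressionSummary("UTRtetO-yfp", 100, a1$rel_abundance, 1.50)
tgt <- expressionSummary("UTRtetO-sigA54-yfp", 12, a2$rel_abundance, 0.591)
relativeSummary(tgt, ref)
#>               strain reference_strain protein_pct mrna_pct half_life_pct vt_pct
#> 1 UTRtetO-sigA54-yfp      UTRtetO-yfp          12     16.7          39.4     42
```

Reading the last row: the variant makes 12 % of the reference's protein from
16.7 % of its mRNA, that mRNA turns over 2.5× faster (39.4 % of the reference
half-life), and the inferred transcript production rate is 42 % of the
reference — i.e. a ~58 % reduction in predicted synthesis despite an identical
promoter. `compareHalfLives(panel@chase_ct, "yfp", ...)` confirms the decay
slopes differ (interaction p ≈ 1e-19 on this simulated panel).

A command-line wrapper covering the same steps
(`quantify`, `halflife`, `rates`, `simulate`, `annotate-utrs`, `correlate`,
`synth`) ships in `inst/scripts/rifachase`.

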