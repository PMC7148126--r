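#' @describeIn DecayFit-class half-life in minutes (`Inf` for stable fits)
#' @export
setMethod("halfLife", "DecayFit", function(object) object@half_life_min)

#' @describeIn DecayFit-class OLS slope in log2 units per minute
#' @export
setMethod("decaySlope", "DecayFit", function(object) object@slope)

#' @describeIn BiphasicFit-class headline (fast-phase) half-life in minutes
#' @export
setMethod("halfLife", "BiphasicFit", function(object) object@fast@half_life_min)

#' @describeIn BiphasicFit-class headline (fast-phase) slope
#' @export
setMethod("decaySlope", "BiphasicFit", function(object) object@fast@slope)

#' @describeIn BiphasicFit-class estimated fast-pool share of t = 0 abundance
#' @export
setMethod("fastFraction", "BiphasicFit", function(object) object@fast_fraction)

#' @describeIn BiphasicFit-class was the two-segment model accepted?
#' @export
setMethod("isBiphasic", "BiphasicFit", function(object) object@is_biphasic)

#' @describeIn BiphasicFit-class the fast-segment [DecayFit-class]
#' @export
setMethod("fastPhase", "BiphasicFit", function(object) object@fast)

#' @describeIn BiphasicFit-class the slow-segment [DecayFit-class] or NULL
#' @export
setMethod("slowPhase", "BiphasicFit", function(object) object@slow)

#' @describeIn SteadyState-class named vector of translated/dark/protein levels
#' @export
setMethod("poolAbundances", "SteadyState", function(object) {
  c(m_translated = object@m_translated,
    m_dark = object@m_dark,
    protein = object@protein)
})

#' @describeIn ChaseCurve-class the simulated [CtTable-class]
#' @export
setMethod("ctTable", "ChaseCurve", function(object) object@ct_table)

setMethod("show", "DecayFit", function(object) {
  hl <- object@half_life_min
  cat("DecayFit: slope ", signif(object@slope, 4), " log2/min, half-life ",
      if (is.finite(hl)) paste0(signif(hl, 4), " min") else "Inf (stable)",
      "\n", sep = "")
  if (!is.null(object@ci95_half_life))
    cat("  95% CI [", signif(object@ci95_half_life[1], 4), ", ",
        signif(object@ci95_half_life[2], 4), "] min\n", sep = "")
  cat("  r2 ", signif(object@r2, 3), ", n = ", object@n_points,
      ", times {", paste(object@times_used, collapse = ", "), "}\n", sep = "")
})

setMethod("show", "BiphasicFit", function(object) {
  cat(if (object@is_biphasic) "Biphasic" else "Single-phase",
      " decay fit\n", sep = "")
  cat("  fast: "); show(object@fast)
  if (object@is_biphasic) {
    cat("  slow: "); show(object@slow)
    cat("  fast fraction ", signif(object@fast_fraction, 3),
        ", breakpoint after time index ", object@breakpoint_index, "\n",
        sep = "")
  }
})

setMethod("show", "TwoPoolParams", function(object) {
  cat("TwoPoolParams: alpha ", object@alpha, "/min, p ", object@p,
      ", k_t ", object@k_t, "/min, k_d ", object@k_d,
      "/min, mu ", object@mu, "/min, beta ", object@beta, "\n", sep = "")
})

setMethod("show", "SteadyState", function(object) {
  cat("SteadyState: translated ", signif(object@m_translated, 5),
      ", dark ", signif(object@m_dark, 5),
      ", protein ", signif(object@protein, 5), "\n", sep = "")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n",
      "  reference_gene: ", object@reference_gene, "\n",
      "  doubling_time_min: ", object@doubling_time_min, "\n",
      "  chase_times_min: ", paste(object@chase_times_min, collapse = ", "),
      "\n",
      "  ct_noise_sd: ", object@ct_noise_sd, "\n",
      "  min_fast_fraction: ", object@min_fast_fraction, "\n",
      "  significance_alpha: ", object@significance_alpha, "\n",
      "  amplification_efficiency: ", object@amplification_efficiency, "\n",
      sep = "")
})
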