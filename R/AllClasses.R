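#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Pipeline configuration
#'
#' Holds every analysis constant that the underlying experimental design does
#' not itself determine: the reference gene used for normalization, the
#' culture doubling time (for the growth-dilution rate \eqn{\mu = \ln 2 /
#' \mathrm{doubling\ time}}), the rifampin-chase sampling times, the C_T
#' measurement noise, the minimum fast-pool fraction expected of a headline
#' half-life, and the significance level for model-selection F tests.
#'
#' @slot reference_gene character(1), gene used as the \eqn{\Delta C_T}
#'   normalizer (conventionally an endogenous stable sigma-factor transcript).
#' @slot doubling_time_min numeric(1), culture doubling time in minutes.
#' @slot chase_times_min numeric, chase sampling times (min), sorted, starting
#'   at 0.
#' @slot ct_noise_sd numeric(1), Gaussian SD of C_T measurement noise (cycles).
#' @slot min_fast_fraction numeric(1) in (0, 1], share of time-zero abundance
#'   the fast phase must explain for its half-life to be considered
#'   representative.
#' @slot significance_alpha numeric(1) in (0, 1), alpha for the biphasic
#'   extra-sum-of-squares F test.
#' @slot amplification_efficiency numeric(1) in (1, 2], qPCR per-cycle
#'   amplification factor.
#' @slot rng_seed integer(1), default seed for simulation helpers.
#' @seealso [pipelineConfig()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    reference_gene = "character",
    doubling_time_min = "numeric",
    chase_times_min = "numeric",
    ct_noise_sd = "numeric",
    min_fast_fraction = "numeric",
    significance_alpha = "numeric",
    amplification_efficiency = "numeric",
    rng_seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (length(object@doubling_time_min) != 1L || object@doubling_time_min <= 0)
    msg <- c(msg, "doubling_time_min must be a single positive number")
  tt <- object@chase_times_min
  if (length(tt) < 2L || is.unsorted(tt, strictly = TRUE) || tt[1L] != 0)
    msg <- c(msg, "chase_times_min must be strictly ascending and start at 0")
  if (object@ct_noise_sd < 0)
    msg <- c(msg, "ct_noise_sd must be >= 0")
  f <- object@min_fast_fraction
  if (length(f) != 1L || f <= 0 || f > 1)
    msg <- c(msg, "min_fast_fraction must be in (0, 1]")
  a <- object@significance_alpha
  if (length(a) != 1L || a <= 0 || a >= 1)
    msg <- c(msg, "significance_alpha must be in (0, 1)")
  e <- object@amplification_efficiency
  if (length(e) != 1L || e <= 1 || e > 2)
    msg <- c(msg, "amplification_efficiency must be in (1, 2]")
  if (length(msg)) msg else TRUE
})

#' qPCR threshold-cycle table
#'
#' A validated table of qPCR threshold-cycle (C_T) measurements, one row per
#' well: strain/construct, gene, biological replicate, chase time in minutes,
#' and C_T. \eqn{-C_T} is transcript abundance on a log2 scale, which is the
#' representation every downstream fit works on. Extends
#' [S4Vectors::DataFrame] so all the usual subsetting and coercion applies.
#'
#' @seealso [CtTable()], [readCtTable()], [estimateHalfLife()]
#' @exportClass CtTable
setClass("CtTable", contains = "DFrame")

.ct_required_cols <- c("strain", "gene", "replicate", "time_min", "ct")

setValidity("CtTable", function(object) {
  msg <- character()
  missing_cols <- setdiff(.ct_required_cols, colnames(object))
  if (length(missing_cols))
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (!is.numeric(object$ct) || any(!is.finite(object$ct)))
    msg <- c(msg, "ct must be finite numeric")
  if (!is.numeric(object$time_min) || any(object$time_min < 0))
    msg <- c(msg, "time_min must be numeric and >= 0")
  if (length(msg)) msg else TRUE
})

#' Single-phase exponential decay fit
#'
#' Ordinary least-squares fit of \eqn{-C_T} (log2 abundance) against chase
#' time. The half-life is \eqn{-1/\mathrm{slope}} minutes; a non-negative
#' slope yields an infinite half-life sentinel. The 95\% CI of the half-life
#' is obtained by inverting the slope CI endpoints.
#'
#' @slot slope numeric(1), log2 abundance units per minute (negative for
#'   decaying transcripts).
#' @slot intercept numeric(1), fitted log2 abundance at t = 0.
#' @slot half_life_min numeric(1), \eqn{-1/\mathrm{slope}}; `Inf` when
#'   slope >= 0.
#' @slot ci95_half_life numeric(2) or NULL, 95\% CI (min) for the half-life.
#' @slot r2 numeric(1), coefficient of determination.
#' @slot n_points integer(1), observations used.
#' @slot times_used numeric, distinct chase times entering the fit.
#' @seealso [fitSinglePhase()]
#' @exportClass DecayFit
setClass("DecayFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    half_life_min = "numeric",
    ci95_half_life = "numericOrNULL",
    r2 = "numeric",
    n_points = "integer",
    times_used = "numeric"
  )
)

setValidity("DecayFit", function(object) {
  msg <- character()
  s <- object@slope
  hl <- object@half_life_min
  if (is.finite(s) && s < 0 && abs(hl * (-s) - 1) > 1e-8)
    msg <- c(msg, "half_life_min must equal -1/slope for negative slopes")
  if (is.finite(s) && s >= 0 && is.finite(hl))
    msg <- c(msg, "non-negative slope requires infinite half-life sentinel")
  if (object@n_points < 2L)
    msg <- c(msg, "n_points must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Biphasic decay segmentation result
#'
#' Result of a two-segment piecewise-linear fit to a log2 decay curve.
#' When the two-segment model significantly beats a single line (extra
#' sum-of-squares F test) and the late segment decays more slowly, the curve
#' is classified biphasic; the fast (early) segment supplies the headline
#' half-life and `fast_fraction` estimates the share of time-zero abundance
#' belonging to the fast-decaying pool.
#'
#' @slot fast [DecayFit-class] for the early fast phase (the headline fit).
#' @slot slow [DecayFit-class] or NULL for the late slow phase.
#' @slot breakpoint_index integer(1), index into sorted unique times of the
#'   last time in the fast segment (`NA` for single-phase).
#' @slot fast_fraction numeric(1) in \[0, 1\], estimated fast-pool share of
#'   time-zero abundance (1 for single-phase curves).
#' @slot is_biphasic logical(1).
#' @slot f_p_value numeric(1), p of the extra-sum-of-squares F test (`NA`
#'   when no candidate breakpoint existed).
#' @seealso [segmentBiphasic()], [estimateHalfLife()]
#' @exportClass BiphasicFit
setClass("BiphasicFit",
  representation(
    fast = "DecayFit",
    slow = "ANY",
    breakpoint_index = "integer",
    fast_fraction = "numeric",
    is_biphasic = "logical",
    f_p_value = "numeric"
  )
)

setValidity("BiphasicFit", function(object) {
  msg <- character()
  ff <- object@fast_fraction
  if (ff < 0 || ff > 1)
    msg <- c(msg, "fast_fraction must lie in [0, 1]")
  if (!object@is_biphasic) {
    if (!is.null(object@slow))
      msg <- c(msg, "single-phase fits must have no slow segment")
    if (ff != 1)
      msg <- c(msg, "single-phase fits must have fast_fraction 1")
  } else {
    if (!is(object@slow, "DecayFit"))
      msg <- c(msg, "biphasic fits require a slow DecayFit")
    else if (object@fast@slope > object@slow@slope + 1e-12)
      msg <- c(msg, "fast segment must decay at least as quickly as slow")
  }
  if (length(msg)) msg else TRUE
})

#' Two-pool ("dark matter") kinetic model parameters
#'
#' Formalization of the hypothesis that newly synthesized transcripts
#' partition between a translated pool and a rapidly degraded, effectively
#' invisible pool. Transcripts are synthesized at rate `alpha`; a fraction
#' `p` enters the translated pool decaying at `k_t`, the rest a dark pool
#' decaying at `k_d >= k_t`; both pools are additionally diluted by growth
#' at `mu`; protein is produced at `beta` per translated mRNA per minute and
#' removed by dilution only.
#'
#' @slot alpha numeric(1), transcript synthesis rate (molecules/min).
#' @slot p numeric(1) in \[0, 1\], partition fraction into the translated pool.
#' @slot k_t numeric(1), translated-pool decay constant (1/min).
#' @slot k_d numeric(1), dark-pool decay constant (1/min), `k_d >= k_t`.
#' @slot mu numeric(1), growth rate (1/min).
#' @slot beta numeric(1), protein synthesis rate per translated mRNA
#'   (protein units/mRNA/min).
#' @seealso [TwoPoolParams()], [steadyState()], [simulateChase()]
#' @exportClass TwoPoolParams
setClass("TwoPoolParams",
  representation(
    alpha = "numeric",
    p = "numeric",
    k_t = "numeric",
    k_d = "numeric",
    mu = "numeric",
    beta = "numeric"
  )
)

setValidity("TwoPoolParams", function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (object@k_t < 0) msg <- c(msg, "k_t must be >= 0")
  if (object@k_d < object@k_t)
    msg <- c(msg, "dark pool must decay at least as fast as translated (k_d >= k_t)")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Steady state of the two-pool model
#'
#' Closed-form steady-state abundances: \eqn{M_t = p\alpha/(k_t+\mu)},
#' \eqn{M_d = (1-p)\alpha/(k_d+\mu)}, and protein
#' \eqn{P = \beta M_t/\mu} (undefined when \eqn{\mu = 0}).
#'
#' @slot m_translated numeric(1), translated-pool abundance (molecules).
#' @slot m_dark numeric(1), dark-pool abundance (molecules).
#' @slot protein numeric(1), steady-state protein (NA when mu = 0).
#' @seealso [steadyState()]
#' @exportClass SteadyState
setClass("SteadyState",
  representation(
    m_translated = "numeric",
    m_dark = "numeric",
    protein = "numeric"
  )
)

#' Simulated rifampin-chase curve
#'
#' Output of [simulateChase()]: the deterministic two-pool decay curve after
#' an instantaneous transcription block at t = 0, together with a noisy
#' [CtTable-class] rendering of it and the seed that produced the noise.
#'
#' @slot times numeric, chase sampling times (min).
#' @slot true_abundance numeric, noiseless total abundance at `times`.
#' @slot ct_table [CtTable-class] of simulated measurements.
#' @slot seed integer(1).
#' @exportClass ChaseCurve
setClass("ChaseCurve",
  representation(
    times = "numeric",
    true_abundance = "numeric",
    ct_table = "CtTable",
    seed = "integer"
  )
)

setValidity("ChaseCurve", function(object) {
  if (any(diff(object@true_abundance) > 1e-9))
    "true_abundance must be non-increasing after the transcription block"
  else TRUE
})
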