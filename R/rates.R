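#' Degradation rate constant from a half-life
#'
#' First-order decay: \eqn{k = \ln 2 / t_{1/2}} per minute. An infinite
#' half-life (stable transcript sentinel) maps to 0.
#'
#' @param half_life_min positive half-life in minutes (vectorized; `Inf`
#'   allowed).
#' @return rate constant(s), 1/min.
#' @examples
#' degradationConstant(1)     # ln 2
#' degradationConstant(Inf)   # 0
#' @export
degradationConstant <- function(half_life_min) {
  if (any(is.na(half_life_min)) || any(half_life_min <= 0))
    stop("half_life_min must be positive (Inf allowed)")
  ifelse(is.infinite(half_life_min), 0, log(2) / half_life_min)
}

#' Growth (dilution) rate from a doubling time
#'
#' \eqn{\mu = \ln 2 / \mathrm{doubling\ time}} per minute; an infinite
#' doubling time (non-growing culture) maps to 0.
#'
#' @param doubling_time_min positive doubling time in minutes (vectorized).
#' @return growth rate(s), 1/min.
#' @export
growthRate <- function(doubling_time_min) {
  if (any(is.na(doubling_time_min)) || any(doubling_time_min <= 0))
    stop("doubling_time_min must be positive (Inf allowed)")
  ifelse(is.infinite(doubling_time_min), 0, log(2) / doubling_time_min)
}

#' Steady-state transcript production rate
#'
#' At steady state, synthesis balances loss to degradation and growth
#' dilution: \eqn{V_t = k[\mathrm{mRNA}] + \mu[\mathrm{mRNA}]}. Because the
#' abundance is a relative qPCR value, \eqn{V_t} is relative too, meaningful
#' only in ratios within a run.
#'
#' @param mrna_abundance non-negative relative abundance (vectorized).
#' @param k degradation rate constant, 1/min.
#' @param mu growth rate, 1/min (default 0 for the dilution-free
#'   approximation, which differs from the full value by < 1\% whenever
#'   \eqn{k \ge 100\mu}).
#' @return production rate(s), relative units/min.
#' @examples
#' productionRate(1, degradationConstant(1.5), growthRate(180))
#' @export
productionRate <- function(mrna_abundance, k, mu = 0) {
  if (any(is.na(mrna_abundance)) || any(mrna_abundance < 0))
    stop("mrna_abundance must be >= 0")
  if (any(k < 0) || any(mu < 0))
    stop("rate constants must be >= 0")
  (k + mu) * mrna_abundance
}

#' Translation efficiency
#'
#' Protein abundance divided by mRNA abundance, in arbitrary units —
#' comparable only within a run.
#'
#' @param protein_abundance non-negative protein level(s), arbitrary units.
#' @param mrna_abundance strictly positive relative mRNA abundance(s).
#' @return efficiency value(s).
#' @export
translationEfficiency <- function(protein_abundance, mrna_abundance) {
  if (any(is.na(mrna_abundance)) || any(mrna_abundance <= 0))
    stop("mrna_abundance must be > 0")
  if (any(protein_abundance < 0))
    stop("protein_abundance must be >= 0")
  protein_abundance / mrna_abundance
}

#' Per-construct expression summary
#'
#' Bundles steady-state protein and mRNA abundance with the measured
#' half-life into the derived quantities: degradation constant, production
#' rate \eqn{V_t = (k+\mu)[\mathrm{mRNA}]}, and translation efficiency.
#'
#' @param strain label.
#' @param protein_abundance positive, arbitrary units.
#' @param mrna_abundance positive, relative units.
#' @param half_life_min positive minutes (Inf allowed).
#' @param doubling_time_min positive minutes; sets \eqn{\mu}.
#' @return one-row data.frame: `strain`, `protein_abundance`,
#'   `mrna_abundance`, `half_life_min`, `vt`, `translation_efficiency`.
#' @seealso [relativeSummary()]
#' @export
expressionSummary <- function(strain, protein_abundance, mrna_abundance,
                              half_life_min, doubling_time_min = 180) {
  stopifnot(protein_abundance > 0, mrna_abundance > 0)
  k <- degradationConstant(half_life_min)
  mu <- growthRate(doubling_time_min)
  data.frame(
    strain = strain,
    protein_abundance = protein_abundance,
    mrna_abundance = mrna_abundance,
    half_life_min = half_life_min,
    vt = productionRate(mrna_abundance, k, mu),
    translation_efficiency = translationEfficiency(protein_abundance,
                                                   mrna_abundance),
    stringsAsFactors = FALSE)
}

#' Percent-of-reference construct summary
#'
#' Expresses one construct's protein abundance, mRNA abundance, half-life
#' and production rate as percentages of a reference construct, the format
#' used to compare reporter variants against their parent construct. A
#' non-positive reference field yields NA for that percentage with a
#' warning; a construct compared against itself gives 100 everywhere.
#'
#' @param target,reference one-row data.frames from [expressionSummary()].
#' @return one-row data.frame: `strain`, `reference_strain`, `protein_pct`,
#'   `mrna_pct`, `half_life_pct`, `vt_pct`.
#' @examples
#' ref <- expressionSummary("yfp", 100, 1, 1.5)
#' tgt <- expressionSummary("sigA54-yfp", 11, 1/6, 0.6)
#' relativeSummary(tgt, ref)   # vt_pct ~ 41: a ~60% production-rate drop
#' @export
relativeSummary <- function(target, reference) {
  pct <- function(field) {
    r <- reference[[field]]
    if (!is.finite(r) || r <= 0) {
      warning(sprintf("reference %s is not positive; percentage undefined",
                      field))
      return(NA_real_)
    }
    100 * target[[field]] / r
  }
  data.frame(
    strain = target$strain,
    reference_strain = reference$strain,
    protein_pct = pct("protein_abundance"),
    mrna_pct = pct("mrna_abundance"),
    half_life_pct = pct("half_life_min"),
    vt_pct = pct("vt"),
    stringsAsFactors = FALSE)
}
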