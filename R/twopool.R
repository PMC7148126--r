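#' Construct two-pool kinetic parameters
#'
#' @param alpha transcript synthesis rate, molecules/min.
#' @param p partition fraction into the translated pool, \[0, 1\].
#' @param k_t translated-pool decay constant, 1/min.
#' @param k_d dark-pool decay constant, 1/min; defaults to 50 times `k_t`
#'   ("nearly instantaneous" decay modeled as a finite large rate so chase
#'   curves stay well defined).
#' @param mu growth rate, 1/min.
#' @param beta protein synthesis per translated mRNA, units/mRNA/min.
#' @return a [TwoPoolParams-class]
#' @examples
#' TwoPoolParams(alpha = 10, p = 0.9, k_t = log(2) / 1.5)
#' @export
TwoPoolParams <- function(alpha, p = 1, k_t, k_d = 50 * k_t,
                          mu = growthRate(180), beta = 1) {
  new("TwoPoolParams", alpha = as.numeric(alpha), p = as.numeric(p),
      k_t = as.numeric(k_t), k_d = as.numeric(k_d),
      mu = as.numeric(mu), beta = as.numeric(beta))
}

#' Closed-form steady state of the two-pool model
#'
#' Solves \eqn{dM_t/dt = p\alpha - (k_t+\mu)M_t},
#' \eqn{dM_d/dt = (1-p)\alpha - (k_d+\mu)M_d},
#' \eqn{dP/dt = \beta M_t - \mu P} at zero:
#' \eqn{M_t = p\alpha/(k_t+\mu)}, \eqn{M_d = (1-p)\alpha/(k_d+\mu)},
#' \eqn{P = \beta M_t/\mu}. With \eqn{\mu = 0} protein has no steady state
#' and is reported as NA. A pool with zero total removal rate but nonzero
#' input diverges and is an error.
#'
#' @param params a [TwoPoolParams-class].
#' @return a [SteadyState-class]
#' @examples
#' steadyState(TwoPoolParams(alpha = 10, p = 1, k_t = 1, mu = 0.01))
#' @export
steadyState <- function(params) {
  with_p <- function(inflow, removal)
    if (inflow == 0) 0 else if (removal == 0)
      stop("pool with synthesis but no removal diverges") else inflow / removal
  m_t <- with_p(params@p * params@alpha, params@k_t + params@mu)
  m_d <- with_p((1 - params@p) * params@alpha, params@k_d + params@mu)
  protein <- if (params@mu > 0) params@beta * m_t / params@mu
             else if (params@beta * m_t == 0) 0 else NA_real_
  new("SteadyState", m_translated = m_t, m_dark = m_d, protein = protein)
}

#' Simulate a rifampin chase under the two-pool model
#'
#' Transcription halts instantaneously at t = 0 from steady state; each pool
#' then decays exponentially at its decay constant plus growth dilution, so
#' total abundance is
#' \eqn{M(t) = M_t e^{-(k_t+\mu)t} + M_d e^{-(k_d+\mu)t}}. Abundance is
#' rendered as threshold cycles via
#' \eqn{C_T(t) = C_{T,0} - \log_2(M(t)/M(0))}, with i.i.d. Gaussian noise of
#' SD `ct_noise_sd` added to every measurement. Fully reproducible given the
#' seed.
#'
#' @param params a [TwoPoolParams-class].
#' @param times sampling times (min), including 0.
#' @param n_replicates biological replicates; default 3.
#' @param ct_noise_sd C_T noise SD (cycles); 0 for a noiseless curve.
#' @param seed integer seed.
#' @param ct0 baseline C_T at time zero (default 20).
#' @param strain,gene labels written into the output table.
#' @return a [ChaseCurve-class]
#' @export
simulateChase <- function(params, times = c(0, 1, 2, 4), n_replicates = 3L,
                          ct_noise_sd = 0, seed = 1L, ct0 = 20,
                          strain = "sim", gene = "yfp") {
  stopifnot(0 %in% times, ct_noise_sd >= 0, n_replicates >= 1L)
  times <- sort(unique(times))
  ss <- steadyState(params)
  m0 <- ss@m_translated + ss@m_dark
  if (m0 <= 0)
    stop("steady-state abundance is zero; nothing to chase")
  m_t <- ss@m_translated * exp(-(params@k_t + params@mu) * times)
  m_d <- ss@m_dark * exp(-(params@k_d + params@mu) * times)
  m_tot <- m_t + m_d
  ct_true <- ct0 - log2(m_tot / m0)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      time_min = times, KEEP.OUT.ATTRS = FALSE)
  seed <- as.integer(seed)
  noise <- if (ct_noise_sd > 0) {
    local_seed(stats::rnorm(nrow(grid), 0, ct_noise_sd), seed)
  } else rep(0, nrow(grid))
  tab <- CtTable(data.frame(
    strain = strain, gene = gene,
    replicate = grid$replicate, time_min = grid$time_min,
    ct = ct_true[match(grid$time_min, times)] + noise))
  new("ChaseCurve", times = times, true_abundance = m_tot,
      ct_table = tab, seed = seed)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(expr, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Bias of inferred production rates under two-pool kinetics
#'
#' Runs the full measurement pipeline on simulated data — steady state,
#' rifampin chase, fast-phase half-life via [segmentBiphasic()], then
#' \eqn{\hat V_t = (\hat k + \mu) M(0)} — and returns the ratio of the
#' inferred production rate to the true synthesis rate \eqn{\alpha}. When
#' the dark pool decays much faster than the translated pool
#' (\eqn{k_d \gg k_t}) the ratio converges to the partition fraction p:
#' measurements blind to the dark pool under-report synthesis by exactly the
#' share routed into it. When \eqn{k_d = k_t} the pools are
#' indistinguishable and the ratio is 1 for any p.
#'
#' The half-life step applies the configured `min_fast_fraction` rule: a
#' significant early segment is used as the headline decay rate only when
#' it explains at least that share of time-zero abundance, otherwise the
#' single-line fit over all chase points stands (see [segmentBiphasic()]).
#'
#' @param params a [TwoPoolParams-class].
#' @param times chase sampling times (min); defaults to the config's.
#' @param n_replicates replicates for the simulated chase.
#' @param ct_noise_sd measurement noise; default 0 (noiseless protocol).
#' @param seed integer seed (used only when `ct_noise_sd > 0`).
#' @param config a [PipelineConfig-class] supplying the F-test alpha and
#'   the minimum fast-pool fraction.
#' @param dense_times use a fine time grid over the chase window for the
#'   half-life fit instead of `times` (default FALSE, mirroring the
#'   four-point qPCR design).
#' @return numeric(1), \eqn{\hat V_t / \alpha}.
#' @export
apparentProductionRate <- function(params, times = config@chase_times_min,
                                   n_replicates = 3L, ct_noise_sd = 0,
                                   seed = 1L, config = pipelineConfig(),
                                   dense_times = FALSE) {
  if (params@alpha <= 0)
    stop("alpha must be positive to define a bias ratio")
  if (dense_times)
    times <- sort(unique(c(times, seq(min(times), max(times), length.out = 25))))
  ct0 <- 20
  chase <- simulateChase(params, times = times, n_replicates = n_replicates,
                         ct_noise_sd = ct_noise_sd, seed = seed, ct0 = ct0)
  df <- as.data.frame(chase@ct_table)
  fit <- segmentBiphasic(df$time_min, -df$ct,
                         alpha = config@significance_alpha,
                         min_fast_fraction = config@min_fast_fraction)
  k_hat <- degradationConstant(halfLife(fit))
  # abundance at t = 0 as the pipeline would measure it, in model units:
  # the simulated C_T encodes M(t)/M(0) relative to the ct0 baseline
  m0_hat <- chase@true_abundance[1L] *
    2^(ct0 - mean(df$ct[df$time_min == 0]))
  productionRate(m0_hat, k_hat, params@mu) / params@alpha
}
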