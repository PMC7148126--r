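#' Fit a single exponential decay phase
#'
#' Ordinary least-squares regression of \eqn{-C_T} (log2 abundance) on chase
#' time, pooling all replicate points. The half-life is defined as
#' \eqn{-1/\mathrm{slope}} minutes. Its 95\% CI comes from inverting the
#' slope's 95\% CI endpoints, which is exact under the regression model; a
#' CI endpoint at or above zero slope maps to an infinite half-life bound.
#' With no residual degrees of freedom (two points) the CI is NULL.
#'
#' @param times numeric chase times (min); at least two distinct values.
#' @param neg_ct numeric \eqn{-C_T} values, same length.
#' @return a [DecayFit-class]
#' @examples
#' fitSinglePhase(c(0, 1, 2), c(-20, -21, -22))   # halves every minute
#' @export
fitSinglePhase <- function(times, neg_ct) {
  stopifnot(length(times) == length(neg_ct),
            all(is.finite(times)), all(is.finite(neg_ct)))
  ut <- sort(unique(times))
  if (length(ut) < 2L)
    stop("at least two distinct time points are required")
  fit <- stats::lm(neg_ct ~ times)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((neg_ct - mean(neg_ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  ci <- NULL
  if (stats::df.residual(fit) >= 1L) {
    sci <- suppressWarnings(stats::confint(fit, "times", level = 0.95))
    if (all(is.finite(sci)))
      ci <- sort(vapply(c(sci[1L], sci[2L]), .slope_to_hl, numeric(1)))
  }
  if (slope >= 0)
    warning("non-negative decay slope; reporting infinite half-life")
  new("DecayFit",
      slope = slope, intercept = intercept,
      half_life_min = .slope_to_hl(slope),
      ci95_half_life = ci,
      r2 = r2, n_points = length(times), times_used = ut)
}

.slope_to_hl <- function(s) if (s < 0) -1 / s else Inf

#' Segment a decay curve into fast and slow exponential phases
#'
#' Exhaustive search over breakpoints in the sorted unique times: each
#' candidate splits the points into an early and a late segment, each fitted
#' by independent OLS. The best two-segment model (minimum total SSE) is
#' accepted as biphasic only when it beats the single straight line in an
#' extra sum-of-squares F test at `alpha` *and* the late segment decays more
#' slowly than the early one. The fast-pool fraction is estimated from the
#' two intercepts extrapolated to t = 0:
#' \eqn{1 - 2^{(a_{\mathrm{slow},0} - a_{\mathrm{fast},0})}}, clamped to
#' \[0, 1\]. Curves without enough distinct times for two segments fall back
#' to a single-phase fit with a warning.
#'
#' When `min_fast_fraction` is positive, a statistically significant split
#' whose fast segment explains less than that share of time-zero abundance
#' is rejected in favor of the single straight line: a "fast phase"
#' carrying a small minority of the RNA is measurement contamination (for
#' example a rapidly lost subpopulation inflating only the t = 0 point),
#' and its slope would not represent bulk decay. This mirrors the
#' experimental convention of restricting half-life fits to an initial
#' phase only when that phase accounts for at least ~90\% of the
#' transcript pool.
#'
#' @param times,neg_ct pooled chase points as in [fitSinglePhase()].
#' @param min_points_per_segment minimum distinct times per segment.
#' @param alpha significance level of the F test gating the biphasic call.
#' @param min_fast_fraction minimum fast-pool share for a biphasic call to
#'   be kept (default 0: keep any significant split).
#' @return a [BiphasicFit-class]; `fastPhase()` carries the headline
#'   half-life.
#' @examples
#' t <- rep(c(0, 1, 2, 4), each = 3)
#' y <- -20 - t                     # single exponential, no noise
#' isBiphasic(segmentBiphasic(t, y))
#' @export
segmentBiphasic <- function(times, neg_ct, min_points_per_segment = 2L,
                            alpha = 0.05, min_fast_fraction = 0) {
  stopifnot(length(times) == length(neg_ct))
  ut <- sort(unique(times))
  k <- length(ut)
  m <- as.integer(min_points_per_segment)
  single <- function(warn = NULL) {
    if (!is.null(warn)) warning(warn)
    new("BiphasicFit", fast = fitSinglePhase(times, neg_ct), slow = NULL,
        breakpoint_index = NA_integer_, fast_fraction = 1,
        is_biphasic = FALSE, f_p_value = NA_real_)
  }
  if (stats::var(neg_ct) < .Machine$double.eps)
    return(single("all abundances equal; returning flat single-phase fit"))
  if (k < 2L * m)
    return(single(sprintf(
      "%d distinct times cannot support two segments of >= %d; single-phase fit",
      k, m)))

  n <- length(times)
  sse_lm <- function(tt, yy) {
    f <- stats::lm.fit(cbind(1, tt), yy)
    sum(f$residuals^2)
  }
  sse_single <- sse_lm(times, neg_ct)

  best <- NULL
  for (b in seq.int(m, k - m)) {
    fast_idx <- times <= ut[b]
    sse2 <- sse_lm(times[fast_idx], neg_ct[fast_idx]) +
            sse_lm(times[!fast_idx], neg_ct[!fast_idx])
    if (is.null(best) || sse2 < best$sse) best <- list(b = b, sse = sse2)
  }
  # F test: 2 extra parameters for the second line
  df2 <- n - 4L
  p_f <- if (df2 < 1L) {
    NA_real_
  } else if (best$sse <= .Machine$double.eps * max(1, sse_single)) {
    if (sse_single - best$sse <= .Machine$double.eps) 1 else 0
  } else {
    fstat <- ((sse_single - best$sse) / 2) / (best$sse / df2)
    stats::pf(fstat, 2, df2, lower.tail = FALSE)
  }
  fast_idx <- times <= ut[best$b]
  fast_fit <- suppressWarnings(fitSinglePhase(times[fast_idx], neg_ct[fast_idx]))
  slow_fit <- suppressWarnings(fitSinglePhase(times[!fast_idx], neg_ct[!fast_idx]))
  accept <- !is.na(p_f) && p_f < alpha && slow_fit@slope > fast_fit@slope
  if (!accept)
    return(single())
  frac <- 1 - 2^(slow_fit@intercept - fast_fit@intercept)
  frac <- min(1, max(0, frac))
  if (frac < min_fast_fraction)
    return(single())
  new("BiphasicFit",
      fast = fast_fit, slow = slow_fit,
      breakpoint_index = as.integer(best$b),
      fast_fraction = frac,
      is_biphasic = TRUE, f_p_value = p_f)
}

#' Estimate an mRNA half-life from a chase table
#'
#' Assembles the \eqn{-C_T} time series for one strain/gene from a
#' rifampin-chase [CtTable-class] (replicates pooled into one regression; no
#' reference normalization is applied within a chase, since the slope of
#' \eqn{-C_T} already is the log2 decay rate) and applies
#' [segmentBiphasic()]. When the curve is biphasic only the initial fast
#' phase informs the headline half-life. The time-zero anchor is required.
#'
#' @param table a [CtTable-class] with chase measurements.
#' @param strain,gene labels selecting the series.
#' @param config a [PipelineConfig-class]; supplies the F-test alpha.
#' @param verbose emit a message describing points used and the breakpoint.
#' @return a [BiphasicFit-class]
#' @export
estimateHalfLife <- function(table, strain, gene, config = pipelineConfig(),
                             verbose = FALSE) {
  df <- as.data.frame(table)
  df <- df[df$strain == strain & df$gene == gene, , drop = FALSE]
  if (nrow(df) == 0L)
    stop(sprintf("no chase rows for strain %s, gene %s", strain, gene))
  if (!any(df$time_min == 0))
    stop("chase series lacks the required t = 0 anchor")
  fit <- segmentBiphasic(df$time_min, -df$ct,
                         alpha = config@significance_alpha,
                         min_fast_fraction = config@min_fast_fraction)
  if (verbose)
    message(sprintf(
      "%s/%s: %d points over times {%s}; %s; fast phase uses times <= %g",
      strain, gene, nrow(df),
      paste(sort(unique(df$time_min)), collapse = ", "),
      if (isBiphasic(fit)) "biphasic" else "single-phase",
      max(fit@fast@times_used)))
  fit
}

#' Compare decay slopes of two point sets
#'
#' Pooled regression of \eqn{-C_T} on time with a strain indicator and a
#' strain-by-time interaction; the interaction term's two-sided p-value
#' tests whether the two decay slopes (and hence half-lives) differ.
#'
#' @param times_a,neg_ct_a fast-phase points of strain A.
#' @param times_b,neg_ct_b fast-phase points of strain B.
#' @return a data.frame row: `slope_a`, `slope_b`, `difference`
#'   (slope_a - slope_b), `p_value`, `df`.
#' @seealso [compareHalfLives()]
#' @export
compareDecaySlopes <- function(times_a, neg_ct_a, times_b, neg_ct_b) {
  stopifnot(length(times_a) == length(neg_ct_a),
            length(times_b) == length(neg_ct_b))
  if (length(unique(times_a)) < 2L || length(unique(times_b)) < 2L)
    stop("each strain needs at least two distinct fast-phase times")
  dat <- data.frame(
    time = c(times_a, times_b),
    y = c(neg_ct_a, neg_ct_b),
    strain = factor(rep(c("A", "B"), c(length(times_a), length(times_b)))))
  fit <- stats::lm(y ~ time * strain, data = dat)
  if (stats::df.residual(fit) < 1L)
    stop("no residual degrees of freedom for the slope comparison")
  cf <- stats::summary.lm(fit)$coefficients
  slope_a <- cf["time", "Estimate"]
  inter <- cf["time:strainB", ]
  p <- unname(inter["Pr(>|t|)"])
  est <- unname(inter["Estimate"])
  if (!is.finite(est)) stop("degenerate design: interaction not estimable")
  # identical point clouds give a 0/0 t statistic; the difference is exactly 0
  if (is.nan(p)) p <- 1
  data.frame(slope_a = slope_a, slope_b = slope_a + est,
             difference = -est, p_value = p,
             df = stats::df.residual(fit))
}

#' Compare half-lives of two strains from a chase table
#'
#' Runs [estimateHalfLife()] for each strain to identify its fast phase,
#' restricts each strain to its fast-phase points, and tests slope equality
#' with [compareDecaySlopes()].
#'
#' @param table a [CtTable-class].
#' @param gene gene label shared by both strains.
#' @param strain_a,strain_b strain labels.
#' @param config a [PipelineConfig-class].
#' @return as [compareDecaySlopes()], with strain labels attached.
#' @export
compareHalfLives <- function(table, gene, strain_a, strain_b,
                             config = pipelineConfig()) {
  grab <- function(strain) {
    fit <- estimateHalfLife(table, strain, gene, config)
    df <- as.data.frame(table)
    df <- df[df$strain == strain & df$gene == gene, , drop = FALSE]
    df <- df[df$time_min <= max(fit@fast@times_used), , drop = FALSE]
    df
  }
  a <- grab(strain_a)
  b <- grab(strain_b)
  out <- compareDecaySlopes(a$time_min, -a$ct, b$time_min, -b$ct)
  out$strain_a <- strain_a
  out$strain_b <- strain_b
  out
}
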