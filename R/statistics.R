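#' Spearman correlation of paired abundances
#'
#' Rank-based correlation with midranks for ties and a two-sided p-value
#' (t approximation, the standard large-sample treatment), as used to relate
#' protein and mRNA abundance across genes.
#'
#' @param x,y equal-length finite numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
correlateAbundance <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Test equality of log-log regression slopes between two groups
#'
#' Fits a single linear model of log-protein on log-mRNA with a group main
#' effect and a group-by-abundance interaction; the interaction's two-sided
#' p-value tests whether the two groups share a regression slope (the
#' classic ANCOVA slope-homogeneity test). Abundances are expected already
#' log-transformed.
#'
#' @param log_mrna,log_protein numeric vectors (log10 scale conventionally).
#' @param group labels with exactly two levels, each n >= 3.
#' @return list with `slope_leadered`/`slope_leaderless` style per-group
#'   slopes (named by group level), `p_interaction`, `n`.
#' @export
slopeEquality <- function(log_mrna, log_protein, group) {
  group <- factor(group)
  stopifnot(length(log_mrna) == length(log_protein),
            length(group) == length(log_mrna))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(table(group) < 3L)) stop("each group needs n >= 3")
  for (lev in levels(group))
    if (stats::var(log_mrna[group == lev]) == 0)
      stop("constant log_mrna within a group: design is singular")
  fit <- stats::lm(log_protein ~ log_mrna * group)
  cf <- stats::summary.lm(fit)$coefficients
  int_row <- grep("^log_mrna:group", rownames(cf))
  p <- cf[int_row, "Pr(>|t|)"]
  if (is.nan(p)) p <- 1   # duplicated clouds: interaction exactly 0
  slopes <- c(cf["log_mrna", "Estimate"],
              cf["log_mrna", "Estimate"] + cf[int_row, "Estimate"])
  names(slopes) <- levels(group)
  list(slopes = slopes, p_interaction = unname(p), n = length(log_mrna))
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U with midranks for ties; exact enumeration when
#' both samples are small (combined n below `exact_threshold`) and tie-free,
#' normal approximation with continuity correction otherwise — the behavior
#' of [stats::wilcox.test()].
#'
#' @param a,b nonempty numeric vectors.
#' @param exact_threshold use the exact distribution when `length(a) +
#'   length(b)` is below this and there are no ties; default 50.
#' @return list with `statistic` (U for the first sample), `p_value`,
#'   `exact` (logical).
#' @export
rankSum <- function(a, b, exact_threshold = 50L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  use_exact <- (length(a) + length(b)) < exact_threshold &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

#' Multi-group comparison with post hoc pairwise tests
#'
#' Either the rank-based battery (Kruskal-Wallis omnibus followed by Dunn's
#' pairwise z tests on mean ranks with tie correction, Bonferroni-adjusted)
#' or the parametric one (one-way ANOVA followed by Tukey's honestly
#' significant difference test). Dunn's procedure is implemented here on
#' pooled midranks; the omnibus tests and Tukey HSD are delegated to
#' \pkg{stats}.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2);
#'   unnamed lists get `group1`, `group2`, ... labels.
#' @param flavor `"kruskal_dunn"` or `"anova_tukey"`.
#' @param p_adjust adjustment for Dunn pairwise p-values (a
#'   [stats::p.adjust()] method); default `"bonferroni"`.
#' @return list with `omnibus_stat`, `omnibus_p`, and `pairwise` (data.frame
#'   `group1`, `group2`, `p_adj`).
#' @export
multiGroupTest <- function(groups, flavor = c("kruskal_dunn", "anova_tukey"),
                           p_adjust = "bonferroni") {
  flavor <- match.arg(flavor)
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  if (flavor == "kruskal_dunn") {
    kw <- stats::kruskal.test(values, labels)
    pw <- .dunn_test(values, labels, p_adjust)
    list(omnibus_stat = unname(kw$statistic), omnibus_p = kw$p.value,
         pairwise = pw)
  } else {
    fit <- stats::aov(values ~ labels)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$labels
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pw <- data.frame(group1 = pairs[, 2L], group2 = pairs[, 1L],
                     p_adj = unname(tk[, "p adj"]),
                     stringsAsFactors = FALSE)
    list(omnibus_stat = an[["F value"]][1L], omnibus_p = an[["Pr(>F)"]][1L],
         pairwise = pw)
  }
}

# Dunn's pairwise z tests on pooled midranks with tie correction.
.dunn_test <- function(values, labels, p_adjust = "bonferroni") {
  n_tot <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lev <- levels(labels)
  combs <- utils::combn(lev, 2L)
  z <- apply(combs, 2L, function(pair) {
    i <- pair[1L]; j <- pair[2L]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    (mean_ranks[i] - mean_ranks[j]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
             z = as.numeric(z),
             p_adj = pmin(1, stats::p.adjust(p_raw, method = p_adjust)),
             stringsAsFactors = FALSE)
}
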