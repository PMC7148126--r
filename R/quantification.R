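#' Relative transcript abundance from a Delta-C_T pair
#'
#' Converts a target/reference threshold-cycle pair to a linear abundance
#' ratio: \eqn{E^{(C_{T,\mathrm{ref}} - C_{T,\mathrm{target}})}} where E is
#' the per-cycle amplification factor (2 for perfect doubling). Equal C_T
#' values give a ratio of 1; each extra target cycle divides the ratio by E.
#'
#' @param ct_target,ct_reference finite numeric threshold cycles (vectorized).
#' @param efficiency amplification factor per cycle, in (1, 2].
#' @return linear abundance ratio(s), strictly positive.
#' @examples
#' relativeAbundance(22, 20)        # two extra cycles: 4-fold less
#' relativeAbundance(18.5, 20)      # 2^1.5
#' @export
relativeAbundance <- function(ct_target, ct_reference, efficiency = 2.0) {
  if (length(efficiency) != 1L || !is.finite(efficiency) ||
      efficiency <= 1 || efficiency > 2)
    stop("efficiency must be a single value in (1, 2]")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("threshold cycles must be finite")
  efficiency^(ct_reference - ct_target)
}

#' Summarize replicate abundance for one strain/gene
#'
#' Computes per-replicate \eqn{\Delta C_T = C_{T,\mathrm{ref}} -
#' C_{T,\mathrm{target}}} at a single chase time (steady state is time 0),
#' then averages on the log2 scale — i.e. the reported linear ratio is the
#' geometric mean across replicates. Replicates lacking the reference gene
#' at that time are excluded with a warning.
#'
#' @param table a [CtTable-class].
#' @param strain,gene labels selecting the target measurements.
#' @param reference_gene label of the normalizer gene (same strain).
#' @param time_filter chase time (min) at which to summarize; default 0.
#' @param efficiency amplification factor per cycle.
#' @return a data.frame row: `strain`, `gene`, `rel_abundance`, `log2_rel`,
#'   `sd_log2` (NA for a single replicate), `n`.
#' @examples
#' tab <- CtTable(data.frame(
#'   strain = "wt", gene = rep(c("yfp", "sigA"), each = 3),
#'   replicate = rep(1:3, 2), time_min = 0,
#'   ct = c(19, 19, 19, 20, 20, 20)))
#' summarizeAbundance(tab, "wt", "yfp", "sigA")
#' @export
summarizeAbundance <- function(table, strain, gene, reference_gene,
                               time_filter = 0, efficiency = 2.0) {
  df <- as.data.frame(table)
  df <- df[df$strain == strain & df$time_min == time_filter, , drop = FALSE]
  tgt <- df[df$gene == gene, c("replicate", "ct")]
  ref <- df[df$gene == reference_gene, c("replicate", "ct")]
  if (nrow(tgt) == 0L)
    stop(sprintf("no %s measurements for strain %s at time %g",
                 gene, strain, time_filter))
  if (nrow(ref) == 0L) {
    warning(sprintf("replicate(s) %s lack reference gene %s and were excluded",
                    paste(unique(tgt$replicate), collapse = ", "),
                    reference_gene))
    stop("no replicate has both target and reference measurements")
  }
  # average duplicate wells within a replicate before pairing
  tgt <- stats::aggregate(ct ~ replicate, tgt, mean)
  ref <- stats::aggregate(ct ~ replicate, ref, mean)
  merged <- merge(tgt, ref, by = "replicate", suffixes = c("_t", "_r"))
  dropped <- setdiff(tgt$replicate, merged$replicate)
  if (length(dropped))
    warning(sprintf("replicate(s) %s lack reference gene %s and were excluded",
                    paste(dropped, collapse = ", "), reference_gene))
  if (nrow(merged) == 0L)
    stop("no replicate has both target and reference measurements")
  delta <- merged$ct_r - merged$ct_t           # larger = more abundant
  log2_per_rep <- delta * log2(efficiency)
  log2_rel <- mean(log2_per_rep)
  data.frame(strain = strain, gene = gene,
             rel_abundance = 2^log2_rel,
             log2_rel = log2_rel,
             sd_log2 = if (nrow(merged) > 1L) stats::sd(log2_per_rep) else NA_real_,
             n = nrow(merged),
             stringsAsFactors = FALSE)
}
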