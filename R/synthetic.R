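#' Synthetic reporter-construct panel
#'
#' Container for a complete simulated experiment: steady-state and chase
#' C_T tables, per-strain protein abundances, per-cell fluorescence, and
#' the generating parameters (`truth`), so any analysis can be checked
#' against known ground truth.
#'
#' @slot steady_ct [CtTable-class] of time-0 target + reference measurements.
#' @slot chase_ct [CtTable-class] of rifampin-chase measurements.
#' @slot protein_table data.frame `strain`, `protein_abundance`.
#' @slot cell_fluorescence data.frame `strain`, `cell`, `fluorescence`.
#' @slot truth list of per-construct [TwoPoolParams-class] plus generation
#'   settings.
#' @slot seed integer(1).
#' @seealso [generatePanel()]
#' @exportClass SyntheticPanel
setClass("SyntheticPanel",
  representation(
    steady_ct = "CtTable",
    chase_ct = "CtTable",
    protein_table = "data.frame",
    cell_fluorescence = "data.frame",
    truth = "list",
    seed = "integer"
  )
)

setMethod("show", "SyntheticPanel", function(object) {
  cat("SyntheticPanel: ", length(object@truth$constructs), " construct(s), ",
      nrow(object@chase_ct), " chase rows, seed ", object@seed, "\n", sep = "")
})

#' Generate a synthetic reporter panel
#'
#' Simulates the full measurement set for a panel of reporter constructs
#' with known two-pool kinetics: steady-state abundances from
#' [steadyState()], chase C_T tables from [simulateChase()], a stable
#' reference gene with equal abundance across strains (up to C_T noise),
#' protein abundances with lognormal noise, and per-cell fluorescence drawn
#' lognormally around the steady-state protein level. The target gene's C_T
#' is placed so that its Delta-C_T relative abundance equals the model's
#' steady-state total mRNA in model units.
#'
#' @param constructs named list of [TwoPoolParams-class], one per strain;
#'   names are strain labels and must be unique.
#' @param config a [PipelineConfig-class]; supplies chase times and C_T
#'   noise.
#' @param seed integer seed; identical seeds give identical panels.
#' @param n_replicates biological replicates (default 3).
#' @param protein_noise_sdlog lognormal sdlog of protein measurement noise.
#' @param fluorescence_cv per-cell fluorescence coefficient of variation.
#' @param n_cells cells per strain in the fluorescence table.
#' @param gene,ct_ref_base target gene label and reference-gene baseline C_T.
#' @return a [SyntheticPanel-class]
#' @examples
#' cfg <- pipelineConfig()
#' panel <- generatePanel(
#'   list(fast = TwoPoolParams(alpha = 6, p = 1, k_t = log(2) / 0.6),
#'        slow = TwoPoolParams(alpha = 6, p = 1, k_t = log(2) / 1.5)),
#'   cfg, seed = 42)
#' panel
#' @export
generatePanel <- function(constructs, config = pipelineConfig(), seed = 1L,
                          n_replicates = 3L, protein_noise_sdlog = 0.1,
                          fluorescence_cv = 0.35, n_cells = 200L,
                          gene = "yfp", ct_ref_base = 20) {
  if (is.null(names(constructs)) || anyDuplicated(names(constructs)))
    stop("constructs must be a uniquely named list")
  if (!all(vapply(constructs, is, logical(1), "TwoPoolParams")))
    stop("every construct must be a TwoPoolParams object")
  seed <- as.integer(seed)
  local_seed({
    sub_seeds <- sample.int(.Machine$integer.max - 1L, length(constructs))
    steady_rows <- list()
    chase_tabs <- list()
    protein_rows <- list()
    fluor_rows <- list()
    for (i in seq_along(constructs)) {
      lab <- names(constructs)[i]
      par <- constructs[[i]]
      ss <- steadyState(par)
      m_tot <- ss@m_translated + ss@m_dark
      ct0 <- ct_ref_base - log2(m_tot)
      reps <- seq_len(n_replicates)
      steady_rows[[i]] <- data.frame(
        strain = lab,
        gene = rep(c(gene, config@reference_gene), each = n_replicates),
        replicate = rep(reps, 2L),
        time_min = 0,
        ct = c(ct0 + stats::rnorm(n_replicates, 0, config@ct_noise_sd),
               ct_ref_base + stats::rnorm(n_replicates, 0, config@ct_noise_sd)))
      chase <- simulateChase(par, times = config@chase_times_min,
                             n_replicates = n_replicates,
                             ct_noise_sd = config@ct_noise_sd,
                             seed = sub_seeds[i], ct0 = ct0,
                             strain = lab, gene = gene)
      chase_tabs[[i]] <- as.data.frame(chase@ct_table)
      prot_true <- ss@protein
      protein_rows[[i]] <- data.frame(
        strain = lab,
        protein_abundance = prot_true *
          stats::rlnorm(1L, -protein_noise_sdlog^2 / 2, protein_noise_sdlog))
      sdlog <- sqrt(log(1 + fluorescence_cv^2))
      fluor_rows[[i]] <- data.frame(
        strain = lab, cell = seq_len(n_cells),
        fluorescence = stats::rlnorm(n_cells,
                                     log(prot_true) - sdlog^2 / 2, sdlog))
    }
    new("SyntheticPanel",
        steady_ct = CtTable(do.call(rbind, steady_rows)),
        chase_ct = CtTable(do.call(rbind, chase_tabs)),
        protein_table = do.call(rbind, protein_rows),
        cell_fluorescence = do.call(rbind, fluor_rows),
        truth = list(constructs = constructs, gene = gene,
                     ct_ref_base = ct_ref_base,
                     n_replicates = n_replicates, sub_seeds = sub_seeds),
        seed = seed)
  }, seed)
}

#' Generate a synthetic TSS/start-codon annotation table
#'
#' Emulates a skewed bacterial 5' UTR length distribution with a leaderless
#' fraction: a gene is leaderless with probability `leaderless_fraction`
#' (UTR 0 nt); otherwise its UTR length is gamma-distributed plus an
#' offset, rounded to an integer >= 1. Defaults (shape 4, scale 10, offset
#' 12 nt) put the mode near 42 nt and the median near 48 nt, the shape
#' typical of mycobacterial UTR surveys. Coordinates and strands are
#' synthesized consistently with the 1-based, strand-aware convention of
#' [utrLength()].
#'
#' @param n_genes number of genes.
#' @param leaderless_fraction probability of a 0-nt UTR; default 0.14.
#' @param shape,scale,offset gamma law for leadered UTR lengths (nt).
#' @param seed integer seed.
#' @return data.frame `gene`, `strand`, `tss`, `start_codon` (the schema of
#'   [readAnnotationTable()]).
#' @export
generateAnnotationTable <- function(n_genes, leaderless_fraction = 0.14,
                                    shape = 4, scale = 10, offset = 12,
                                    seed = 1L) {
  stopifnot(n_genes >= 1, leaderless_fraction >= 0, leaderless_fraction <= 1)
  if (shape <= 0 || scale <= 0 || offset < 0)
    stop("invalid length-law parameters")
  local_seed({
    leaderless <- stats::runif(n_genes) < leaderless_fraction
    len <- integer(n_genes)
    n_led <- sum(!leaderless)
    if (n_led > 0)
      len[!leaderless] <- pmax(1L, as.integer(round(
        stats::rgamma(n_led, shape = shape, scale = scale) + offset)))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- sample.int(5000000L, n_genes)
    data.frame(
      gene = sprintf("gene%05d", seq_len(n_genes)),
      strand = strand,
      tss = tss,
      start_codon = ifelse(strand == "+", tss + len, tss - len),
      stringsAsFactors = FALSE)
  }, as.integer(seed))
}

#' Generate a correlated mRNA/protein abundance table
#'
#' Emulates a transcriptome/proteome comparison across leader classes:
#' log10 mRNA abundance is Gaussian around a group-specific median, and
#' log10 protein follows a shared regression slope with group-specific
#' intercepts plus Gaussian noise. Defaults place the leaderless group
#' 0.3 log10 units (2-fold) below the leadered group in mRNA with equal
#' intercepts and slope 1.
#'
#' @param n_genes total genes.
#' @param group_fractions named proportions summing to 1; default
#'   `c(leadered = 0.86, leaderless = 0.14)`.
#' @param shared_slope regression slope of log10 protein on log10 mRNA.
#' @param group_medians named log10 mRNA medians per group.
#' @param group_intercepts named log10 protein intercepts per group.
#' @param mrna_sd log10 SD of mRNA abundance within a group.
#' @param noise_sd log10 SD of protein residual noise; must be > 0.
#' @param seed integer seed.
#' @return data.frame `gene`, `leader_class`, `log10_mrna`, `log10_protein`.
#' @export
generateProteomeTable <- function(n_genes = 400L,
                                  group_fractions = c(leadered = 0.86,
                                                      leaderless = 0.14),
                                  shared_slope = 1.0,
                                  group_medians = c(leadered = 2.0,
                                                    leaderless = 1.7),
                                  group_intercepts = c(leadered = 1.0,
                                                       leaderless = 1.0),
                                  mrna_sd = 0.5, noise_sd = 0.3, seed = 1L) {
  stopifnot(abs(sum(group_fractions) - 1) < 1e-8, noise_sd > 0, mrna_sd > 0)
  gnames <- names(group_fractions)
  stopifnot(!is.null(gnames), all(gnames %in% names(group_medians)),
            all(gnames %in% names(group_intercepts)))
  local_seed({
    cls <- sample(gnames, n_genes, replace = TRUE, prob = group_fractions)
    log10_mrna <- stats::rnorm(n_genes, group_medians[cls], mrna_sd)
    log10_protein <- shared_slope * log10_mrna + group_intercepts[cls] +
      stats::rnorm(n_genes, 0, noise_sd)
    data.frame(
      gene = sprintf("gene%05d", seq_len(n_genes)),
      leader_class = cls,
      log10_mrna = log10_mrna,
      log10_protein = log10_protein,
      stringsAsFactors = FALSE)
  }, as.integer(seed))
}
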