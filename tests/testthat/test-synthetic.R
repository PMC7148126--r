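test_that("panels are deterministic given the seed and schema-valid", {
  cfg <- pipelineConfig()
  cons <- list(a = TwoPoolParams(alpha = 6, p = 1, k_t = log(2) / 1.5),
               b = TwoPoolParams(alpha = 6, p = 1, k_t = log(2) / 0.6))
  p1 <- generatePanel(cons, cfg, seed = 7)
  p2 <- generatePanel(cons, cfg, seed = 7)
  expect_identical(as.data.frame(p1@chase_ct), as.data.frame(p2@chase_ct))
  expect_identical(p1@protein_table, p2@protein_table)
  p3 <- generatePanel(cons, cfg, seed = 8)
  expect_false(identical(as.data.frame(p1@chase_ct)$ct,
                         as.data.frame(p3@chase_ct)$ct))
  # generator output passes the reader's validation unchanged
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCtTable(p1@chase_ct, path)
  expect_s4_class(readCtTable(path), "CtTable")
  expect_error(generatePanel(setNames(cons, c("a", "a")), cfg), "uniquely")
})

test_that("reference gene is stable and equal across strains up to noise", {
  cfg <- pipelineConfig(ct_noise_sd = 0.05)
  cons <- list(lo = TwoPoolParams(alpha = 1, p = 1, k_t = 1),
               hi = TwoPoolParams(alpha = 100, p = 1, k_t = 1))
  panel <- generatePanel(cons, cfg, seed = 3)
  steady <- as.data.frame(panel@steady_ct)
  ref <- steady[steady$gene == cfg@reference_gene, ]
  expect_equal(diff(range(ref$ct)), 0, tolerance = 6 * 0.05)
  # target Ct differences encode the 100-fold abundance ratio
  tgt <- steady[steady$gene == "yfp", ]
  dct <- mean(tgt$ct[tgt$strain == "lo"]) - mean(tgt$ct[tgt$strain == "hi"])
  expect_equal(dct, log2(100), tolerance = 0.3)
})

test_that("pipeline round trip recovers known construct differences", {
  # noiseless: half-lives 1.5 vs 0.6 min, 6-fold abundance -> ~60% vt drop
  cfg <- pipelineConfig(ct_noise_sd = 1e-9)
  mu <- growthRate(cfg@doubling_time_min)
  # total chase decay rate is k_t + mu, so subtract mu to make the
  # *measured* half-lives land on 1.5 and 0.6 min exactly
  cons <- list(
    ref = TwoPoolParams(alpha = 1 * degradationConstant(1.5), p = 1,
                        k_t = degradationConstant(1.5) - mu, mu = mu),
    ext = TwoPoolParams(alpha = degradationConstant(0.6) / 6, p = 1,
                        k_t = degradationConstant(0.6) - mu, mu = mu))
  panel <- generatePanel(cons, cfg, seed = 5)
  hl <- vapply(names(cons), function(s)
    halfLife(estimateHalfLife(panel@chase_ct, s, "yfp", cfg)), numeric(1))
  expect_equal(unname(hl), c(1.5, 0.6), tolerance = 1e-4)
  ab <- vapply(names(cons), function(s)
    summarizeAbundance(panel@steady_ct, s, "yfp", "sigA")$rel_abundance,
    numeric(1))
  expect_equal(unname(ab[1] / ab[2]), 6, tolerance = 1e-4)
  vt <- productionRate(ab, degradationConstant(hl), mu)
  expect_equal(unname(vt["ext"] / vt["ref"]), 0.4146, tolerance = 1e-3)
})

test_that("panel of constructs differing only in partition shows the vt bias", {
  cfg <- pipelineConfig(ct_noise_sd = 1e-9)
  kt <- log(2) / 1.5
  cons <- list(
    full = TwoPoolParams(alpha = 10, p = 1, k_t = kt, k_d = 100 * kt),
    half = TwoPoolParams(alpha = 10, p = 0.5, k_t = kt, k_d = 100 * kt))
  panel <- generatePanel(cons, cfg, seed = 11)
  hl <- lapply(names(cons), function(s)
    estimateHalfLife(panel@chase_ct, s, "yfp", cfg))
  # measured half-lives indistinguishable...
  expect_equal(halfLife(hl[[1]]), halfLife(hl[[2]]), tolerance = 0.05)
  # ...but inferred production differs by the partition fraction
  ab <- vapply(names(cons), function(s)
    summarizeAbundance(panel@steady_ct, s, "yfp", "sigA")$rel_abundance,
    numeric(1))
  vt <- productionRate(ab, vapply(hl, function(f)
    degradationConstant(halfLife(f)), numeric(1)), growthRate(180))
  expect_equal(unname(vt[2] / vt[1]), 0.5, tolerance = 0.03)
})

test_that("annotation generator matches its nominal leaderless fraction and mode", {
  ann <- generateAnnotationTable(10000, leaderless_fraction = 0.14, seed = 2)
  out <- annotateUtrs(ann)
  frac <- mean(out$leader_class == "leaderless")
  expect_lt(abs(frac - 0.14), 0.01)
  d <- utrDistribution(out$utr_length)
  expect_equal(d$modal_bin, c(40, 50))
  # single leaderless gene edge case
  one <- generateAnnotationTable(1, leaderless_fraction = 1, seed = 1)
  expect_equal(annotateUtrs(one)$utr_length, 0L)
  expect_error(generateAnnotationTable(10, shape = -1), "length-law")
})

test_that("modal bin is stable across seeds at survey scale", {
  modal_ok <- vapply(1:20, function(s) {
    ann <- generateAnnotationTable(10000, seed = s)
    identical(utrDistribution(annotateUtrs(ann)$utr_length)$modal_bin,
              c(40, 50))
  }, logical(1))
  expect_gte(mean(modal_ok), 0.95)
})

test_that("proteome generator produces the designed group structure", {
  # low noise: within-group Spearman correlation approaches 1
  tight <- generateProteomeTable(300, noise_sd = 1e-4, seed = 4)
  for (cl in unique(tight$leader_class)) {
    d <- tight[tight$leader_class == cl, ]
    expect_gt(correlateAbundance(d$log10_mrna, d$log10_protein)$rho, 0.999)
  }
  # default -0.3 log10 leaderless offset is detectable by rank-sum
  # (>= 90% of this fixed seed set at p < 0.01)
  hits <- 0
  for (s in 1:200) {
    tab <- generateProteomeTable(400, seed = s)
    p <- rankSum(tab$log10_mrna[tab$leader_class == "leaderless"],
                 tab$log10_mrna[tab$leader_class == "leadered"])$p_value
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
  # equal slopes by construction: interaction test is null-calibrated
  set.seed(6)
  ps <- vapply(1:40, function(s) {
    tab <- generateProteomeTable(400, seed = s + 100)
    slopeEquality(tab$log10_mrna, tab$log10_protein,
                  tab$leader_class)$p_interaction
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.85)
  expect_identical(generateProteomeTable(50, seed = 9),
                   generateProteomeTable(50, seed = 9))
})
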