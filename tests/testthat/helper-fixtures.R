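# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# single-exponential chase C_T table: -C_T falls by 1/t_half per minute
make_chase_table <- function(t_half, times = c(0, 1, 2, 4), n_rep = 3,
                             noise_sd = 0, seed = 1, strain = "s1",
                             gene = "yfp", ct0 = 20) {
  grid <- expand.grid(replicate = seq_len(n_rep), time_min = times)
  set.seed(seed)
  ct <- ct0 + grid$time_min / t_half + rnorm(nrow(grid), 0, noise_sd)
  CtTable(data.frame(strain = strain, gene = gene,
                     replicate = grid$replicate,
                     time_min = grid$time_min, ct = ct))
}

# independent brute-force oracle for the two-segment fit: exhaustive SSE
# minimization over breakpoints with per-segment OLS via lm()
brute_force_segments <- function(times, y, min_pts = 2) {
  ut <- sort(unique(times))
  k <- length(ut)
  best <- NULL
  for (b in seq.int(min_pts, k - min_pts)) {
    fa <- times <= ut[b]
    f1 <- stats::lm(y[fa] ~ times[fa])
    f2 <- stats::lm(y[!fa] ~ times[!fa])
    sse <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(b = b, sse = sse,
                   fast_slope = unname(stats::coef(f1)[2]),
                   fast_int = unname(stats::coef(f1)[1]),
                   slow_int = unname(stats::coef(f2)[1]))
  }
  best
}

# brute-force oracle for the SD scan: enumerate every allowed spacing
brute_force_sd <- function(seq_chr, anti, window = c(4, 20)) {
  s_ch <- strsplit(tolower(seq_chr), "")[[1]]
  a_ch <- strsplit(tolower(anti), "")[[1]]
  n <- length(s_ch); L <- length(a_ch)
  best <- -1
  for (sp in window[1]:window[2]) {
    st <- n - sp - L + 1
    if (st < 1) next
    best <- max(best, mean(s_ch[st:(st + L - 1)] == a_ch))
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
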