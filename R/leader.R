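#' 5' UTR length from TSS and start-codon coordinates
#'
#' Number of transcribed nucleotides strictly before the first nucleotide of
#' the start codon, counting the TSS as transcribed nucleotide 1. On the
#' plus strand this is `start_codon - tss`; on the minus strand
#' `tss - start_codon`. Zero means the transcript is leaderless (its 5' end
#' coincides with the start codon). Coordinates are 1-based inclusive genome
#' positions; orderings impossible for the stated strand are errors.
#'
#' @param tss,start_codon 1-based genome coordinates (vectorized).
#' @param strand `"+"` or `"-"` (vectorized).
#' @return integer UTR length(s) in nt.
#' @examples
#' utrLength(100, 223, "+")            # 123-nt leader
#' utrLength(2827625, 2827586, "-")    # 39 nt downstream on the minus strand
#' @export
utrLength <- function(tss, start_codon, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  len <- ifelse(strand == "+", start_codon - tss, tss - start_codon)
  if (any(len < 0))
    stop("start codon lies upstream of the TSS for the stated strand")
  as.integer(len)
}

#' Classify leader status from a UTR length
#'
#' Three classes: `leaderless` (0 nt), `ambiguous` (1-14 nt, conventionally
#' excluded from leadered-vs-leaderless contrasts because their initiation
#' mechanism is unclear), and `leadered` (>= 15 nt).
#'
#' @param utr_length non-negative integer(s).
#' @return factor with levels `leaderless`, `ambiguous`, `leadered`.
#' @examples
#' classifyLeader(c(0, 14, 15))
#' @export
classifyLeader <- function(utr_length) {
  if (any(is.na(utr_length)) || any(utr_length < 0) ||
      any(utr_length != floor(utr_length)))
    stop("utr_length must be non-negative integers")
  cls <- ifelse(utr_length == 0, "leaderless",
         ifelse(utr_length <= 14, "ambiguous", "leadered"))
  factor(cls, levels = c("leaderless", "ambiguous", "leadered"))
}

#' Annotate UTR records
#'
#' Adds `utr_length` and `leader_class` columns to an annotation table read
#' by [readAnnotationTable()].
#'
#' @param annotation data.frame with `gene`, `strand`, `tss`, `start_codon`.
#' @return the table with `utr_length` (nt) and `leader_class` appended.
#' @export
annotateUtrs <- function(annotation) {
  annotation$utr_length <- utrLength(annotation$tss, annotation$start_codon,
                                     annotation$strand)
  annotation$leader_class <- classifyLeader(annotation$utr_length)
  annotation
}

#' Summarize a 5' UTR length distribution
#'
#' Median, histogram, and modal bin of a set of UTR lengths. Leaderless
#' genes (length 0) are excluded by default, matching the convention for
#' reporting median leader lengths; bins are `[0, w), [w, 2w), ...`.
#'
#' @param lengths non-negative integer UTR lengths.
#' @param bin_width histogram bin width in nt; default 10.
#' @param exclude_leaderless drop zero-length entries first (default TRUE).
#' @return list with `median`, `modal_bin` (numeric(2), `[lo, hi)` of the
#'   densest bin), `histogram` (data.frame `bin_lo`, `bin_hi`, `count`),
#'   and `n`.
#' @examples
#' utrDistribution(c(40, 48, 60))$median
#' @export
utrDistribution <- function(lengths, bin_width = 10,
                            exclude_leaderless = TRUE) {
  stopifnot(all(lengths >= 0), bin_width > 0)
  if (exclude_leaderless) lengths <- lengths[lengths > 0]
  if (length(lengths) == 0L)
    stop("no UTR lengths remain after excluding leaderless genes")
  bins <- floor(lengths / bin_width)
  counts <- table(bins)
  lo <- as.integer(names(counts)) * bin_width
  hist_df <- data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                        count = as.integer(counts))
  hist_df <- hist_df[order(hist_df$bin_lo), , drop = FALSE]
  rownames(hist_df) <- NULL
  modal <- hist_df[which.max(hist_df$count), ]
  list(median = stats::median(lengths),
       modal_bin = c(modal$bin_lo, modal$bin_hi),
       histogram = hist_df,
       n = length(lengths))
}

#' Scan an upstream sequence for a Shine-Dalgarno match
#'
#' Slides the anti-SD sequence (the reverse complement of the 16S rRNA 3'
#' tail; default the mycobacterial core `AGGAGG` by package convention)
#' ungapped across the region upstream of a start codon and reports the
#' best per-position identity. `spacing_nt` counts the nucleotides between
#' the 3' end of the matched window and the first nucleotide of the start
#' codon; the search is restricted to spacings in `window` (default 4-20
#' nt). Ties on identity are broken toward the spacing closest to
#' `canonical_spacing` (default 7 nt), then toward the start codon.
#'
#' @param upstream_seq character(1), 5'-to-3' sequence ending at the
#'   nucleotide immediately before the start codon; alphabet A/C/G/T/U.
#' @param anti_sd character(1), anti-SD sequence to match.
#' @param window integer(2), allowed spacing range (nt).
#' @param canonical_spacing preferred spacing for tie-breaking (nt).
#' @return list with `matched_seq`, `identity` (fraction in \[0, 1\]),
#'   `spacing_nt`, and `position` (offset of the match 5' end upstream of
#'   the start codon, nt).
#' @examples
#' sdScan(paste0("CCCCAGGAGGCCCCCCCC"), "AGGAGG")   # planted, spacing 8
#' @export
sdScan <- function(upstream_seq, anti_sd = "AGGAGG", window = c(4L, 20L),
                   canonical_spacing = 7L) {
  norm <- function(s) chartr("u", "t", tolower(s))
  seq_chars <- strsplit(norm(upstream_seq), "")[[1]]
  sd_chars <- strsplit(norm(anti_sd), "")[[1]]
  if (!all(c(seq_chars, sd_chars) %in% c("a", "c", "g", "t")))
    stop("sequences must use the A/C/G/T/U alphabet")
  n <- length(seq_chars)
  L <- length(sd_chars)
  if (n < L) stop("upstream sequence shorter than the anti-SD")
  spacings <- seq.int(window[1L], window[2L])
  # spacing s: match occupies positions (n - s - L + 1) .. (n - s)
  spacings <- spacings[n - spacings - L + 1L >= 1L]
  if (length(spacings) == 0L)
    stop("spacing window lies outside the upstream sequence")
  ident <- vapply(spacings, function(s) {
    start <- n - s - L + 1L
    mean(seq_chars[start:(start + L - 1L)] == sd_chars)
  }, numeric(1))
  best <- which(ident == max(ident))
  if (length(best) > 1L) {
    d <- abs(spacings[best] - canonical_spacing)
    best <- best[d == min(d)]
    if (length(best) > 1L) best <- best[which.min(spacings[best])]
  }
  s <- spacings[best]
  start <- n - s - L + 1L
  list(matched_seq = toupper(paste(seq_chars[start:(start + L - 1L)],
                                   collapse = "")),
       identity = ident[best],
       spacing_nt = as.integer(s),
       position = as.integer(s + L))
}
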