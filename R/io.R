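#' Build a pipeline configuration
#'
#' All constants that are conventions of the analysis rather than properties
#' of the data live here. Defaults: doubling time 180 min (typical of a
#' fast-growing mycobacterium under rich-medium conditions; a package
#' convention, adjust to your culture), chase sampling at 0/1/2/4 min,
#' C_T noise SD 0.15 cycles, minimum fast-pool fraction 0.9, F-test alpha
#' 0.05, perfect amplification efficiency 2.0.
#'
#' @param reference_gene character(1), normalizer gene label.
#' @param doubling_time_min positive numeric(1), minutes per doubling.
#' @param chase_times_min ascending numeric starting at 0, minutes.
#' @param ct_noise_sd non-negative numeric(1), C_T cycles.
#' @param min_fast_fraction numeric(1) in (0, 1].
#' @param significance_alpha numeric(1) in (0, 1).
#' @param amplification_efficiency numeric(1) in (1, 2].
#' @param rng_seed integer(1).
#' @param file optional path to a flat YAML document whose keys override the
#'   defaults above (explicit arguments override the file).
#' @return a [PipelineConfig-class]
#' @examples
#' cfg <- pipelineConfig(doubling_time_min = 150)
#' cfg
#' @export
pipelineConfig <- function(reference_gene = "sigA",
                           doubling_time_min = 180,
                           chase_times_min = c(0, 1, 2, 4),
                           ct_noise_sd = 0.15,
                           min_fast_fraction = 0.9,
                           significance_alpha = 0.05,
                           amplification_efficiency = 2.0,
                           rng_seed = 1L,
                           file = NULL) {
  if (!is.null(file)) {
    vals <- yaml::read_yaml(file)
    known <- c("reference_gene", "doubling_time_min", "chase_times_min",
               "ct_noise_sd", "min_fast_fraction", "significance_alpha",
               "amplification_efficiency", "rng_seed")
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    supplied <- names(match.call())[-1]
    for (key in setdiff(names(vals), supplied))
      assign(key, vals[[key]])
  }
  new("PipelineConfig",
      reference_gene = as.character(reference_gene),
      doubling_time_min = as.numeric(doubling_time_min),
      chase_times_min = as.numeric(chase_times_min),
      ct_noise_sd = as.numeric(ct_noise_sd),
      min_fast_fraction = as.numeric(min_fast_fraction),
      significance_alpha = as.numeric(significance_alpha),
      amplification_efficiency = as.numeric(amplification_efficiency),
      rng_seed = as.integer(rng_seed))
}

#' Construct a CtTable
#'
#' @param x a data.frame (or DataFrame) with columns `strain`, `gene`,
#'   `replicate`, `time_min`, `ct`; extra columns are kept.
#' @return a validated [CtTable-class]
#' @examples
#' CtTable(data.frame(strain = "wt", gene = "yfp", replicate = 1,
#'                    time_min = 0, ct = 20.1))
#' @export
CtTable <- function(x) {
  df <- as(as.data.frame(x), "DFrame")
  new("CtTable", df)
}

#' Read a qPCR threshold-cycle table
#'
#' Parses a delimited text file of C_T measurements. Columns are matched by
#' header name, not position. Non-numeric `ct` or `time_min` entries (for
#' example comma decimals) are reported as row-level parse errors rather than
#' silently coerced to NA.
#'
#' @param path file path.
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @return a [CtTable-class]
#' @seealso [writeCtTable()]
#' @export
readCtTable <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, quote = "\"")
  missing_cols <- setdiff(.ct_required_cols, colnames(raw))
  if (length(missing_cols))
    stop("C_T table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("time_min", "ct")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value \"%s\" at data row %d of %s",
                   col, raw[[col]][bad[1L]], bad[1L], path))
    if (anyNA(vals))
      stop(sprintf("missing '%s' value at data row %d of %s",
                   col, which(is.na(vals))[1L], path))
    raw[[col]] <- vals
  }
  CtTable(raw)
}

#' Write a CtTable to tab-delimited text
#'
#' Numeric fields are written with full precision (17 significant digits) so
#' that `readCtTable(writeCtTable(x))` round-trips exactly.
#'
#' @param x a [CtTable-class] (or coercible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("time_min", "ct"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS/start-codon annotation table
#'
#' Reads per-gene transcription start site and translation start coordinates
#' either from a TSV (columns `gene`, `strand`, `tss`, `start_codon`) or a
#' GFF3 file in which gene features carry a `tss` attribute (`start`/`end`
#' supply the translation start according to strand). Coordinates are 1-based
#' inclusive genome positions. Records whose start codon lies on the wrong
#' side of the TSS for their strand are dropped with a warning.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @return a data.frame with columns `gene`, `strand`, `tss`, `start_codon`.
#' @seealso [utrLength()], [annotateUtrs()]
#' @export
readAnnotationTable <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene", "strand", "tss", "start_codon")
    missing_cols <- setdiff(need, colnames(df))
    if (length(missing_cols))
      stop("annotation table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    df <- df[need]
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    tss_attr <- S4Vectors::mcols(gr)$tss
    if (is.null(tss_attr))
      stop("GFF3 gene features must carry a 'tss' attribute")
    strand_chr <- as.character(BiocGenerics::strand(gr))
    df <- data.frame(
      gene = if (!is.null(gr$ID)) gr$ID else gr$Name,
      strand = strand_chr,
      tss = as.integer(tss_attr),
      # translation start = first nt of the CDS in transcript orientation
      start_codon = ifelse(strand_chr == "+",
                           BiocGenerics::start(gr), BiocGenerics::end(gr)),
      stringsAsFactors = FALSE)
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  bad <- (df$strand == "+" & df$start_codon < df$tss) |
         (df$strand == "-" & df$start_codon > df$tss)
  if (any(bad)) {
    warning(sprintf(
      "%d record(s) excluded: start codon upstream of TSS for their strand (%s)",
      sum(bad), paste(utils::head(df$gene[bad], 5L), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
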