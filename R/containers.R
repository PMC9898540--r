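#' Construct a barcode count table
#'
#' A barcode count table is a `SummarizedExperiment` with one row per barcode,
#' one column per sorted sample, an integer `counts` assay, and the sample key
#' fields (`mouse`, `group`, `cell_type`, `timepoint`) in `colData`.
#'
#' @param counts Integer matrix, barcodes x samples; row names are barcode
#'   sequences, column names are sample keys (see [format_sample_key()]) unless
#'   `samples` is supplied.
#' @param samples Optional `data.frame` with columns `mouse`, `group`,
#'   `cell_type`, `timepoint` (one row per column of `counts`). When missing,
#'   sample metadata is parsed from `colnames(counts)`.
#' @return A `SummarizedExperiment` holding the validated counts.
#' @export
barcode_count_table <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) stop("no samples")
  if (nrow(counts) > 0L && is.null(rownames(counts))) {
    stop("counts must have barcode row names")
  }
  barcodes <- toupper(rownames(counts) %||% character(0L))
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcode: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  }
  if (any(grepl("[^A-Z0-9]", barcodes))) {
    stop("barcodes must be uppercase alphanumeric strings")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- barcodes
  if (is.null(samples)) {
    if (is.null(colnames(counts))) stop("counts must have sample column names")
    samples <- parse_sample_keys(colnames(counts))
  } else {
    samples <- as.data.frame(samples)
    stopifnot(nrow(samples) == ncol(counts))
    samples$sample_id <- format_sample_key(samples$mouse, samples$group,
                                           samples$cell_type, samples$timepoint)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample key: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  colnames(counts) <- samples$sample_id
  cd <- S4Vectors::DataFrame(mouse = samples$mouse, group = samples$group,
                             cell_type = samples$cell_type,
                             timepoint = samples$timepoint,
                             row.names = samples$sample_id)
  SummarizedExperiment::SummarizedExperiment(assays = list(counts = counts),
                                             colData = cd)
}

#' Construct a clonal abundance matrix
#'
#' The central object of the pipeline: per-clone abundance expressed as a
#' percentage of all white blood cells (%WBC), one row per barcode and one
#' column per (mouse, group, cell type, timepoint) sample.
#'
#' @param abundance Numeric matrix (barcodes x samples, %WBC, all entries
#'   >= 0); row/column naming as in [barcode_count_table()].
#' @param samples Optional sample `data.frame`, as in [barcode_count_table()].
#'   May additionally carry `pop_frac_wbc`, `donor_frac`, `gfp_frac` columns,
#'   which are kept in `colData` so per-sample conservation can be checked.
#' @return A `SummarizedExperiment` with an `abundance` assay.
#' @export
clonal_abundance_matrix <- function(abundance, samples = NULL) {
  abundance <- as.matrix(abundance)
  if (nrow(abundance) > 0L && is.null(rownames(abundance))) {
    stop("abundance must have barcode row names")
  }
  if (anyDuplicated(rownames(abundance))) stop("duplicate barcode")
  if (anyNA(abundance) || any(abundance < 0)) {
    stop("abundance must be non-negative and finite")
  }
  if (is.null(samples)) {
    samples <- parse_sample_keys(colnames(abundance))
  } else {
    samples <- as.data.frame(samples)
    stopifnot(nrow(samples) == ncol(abundance))
    if (is.null(samples$sample_id)) {
      samples$sample_id <- format_sample_key(samples$mouse, samples$group,
                                             samples$cell_type,
                                             samples$timepoint)
    }
  }
  colnames(abundance) <- samples$sample_id
  keep <- setdiff(names(samples), "sample_id")
  cd <- S4Vectors::DataFrame(samples[keep], row.names = samples$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
}

#' Clonal abundance in long format
#'
#' @param abundance A clonal abundance `SummarizedExperiment`.
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `cell_type`,
#'   `timepoint`, `abundance` (%WBC).
#' @export
abundance_long <- function(abundance) {
  m <- SummarizedExperiment::assay(abundance, "abundance")
  meta <- sample_meta(abundance)
  n_b <- nrow(m)
  data.frame(
    barcode = rep(rownames(m), times = ncol(m)),
    mouse = rep(meta$mouse, each = n_b),
    group = rep(meta$group, each = n_b),
    cell_type = rep(meta$cell_type, each = n_b),
    timepoint = rep(meta$timepoint, each = n_b),
    abundance = as.vector(m),
    stringsAsFactors = FALSE)
}
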