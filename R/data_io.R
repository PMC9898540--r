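#' Read a barcode count table from TSV
#'
#' Expects a tab-separated file whose first column holds barcode sequences and
#' whose remaining column headers are colon-delimited sample keys
#' (`mouse:group:cell_type:timepoint`).
#'
#' @param path Path to the TSV file.
#' @return A barcode count `SummarizedExperiment` (see
#'   [barcode_count_table()]).
#' @export
read_barcode_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("no samples")
  barcodes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("counts must be non-negative integers")
  rownames(mat) <- barcodes
  barcode_count_table(mat)
}

#' Write a barcode count table to TSV
#'
#' @param counts A barcode count `SummarizedExperiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_counts <- function(counts, path) {
  m <- SummarizedExperiment::assay(counts, "counts")
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

FLOW_COLUMNS <- c("mouse", "group", "cell_type", "timepoint",
                  "pop_frac_wbc", "donor_frac", "gfp_frac")

#' Read a flow-cytometry summary table
#'
#' One row per sample with the three FACS fractions entering the clonal
#' abundance formula: the population's share of white blood cells
#' (`pop_frac_wbc`), the donor-derived share of that population
#' (`donor_frac`), and the GFP+ (barcoded) share of donor cells (`gfp_frac`).
#' Columns whose values exceed 1 are interpreted as percentages and divided by
#' 100 with a warning, since instruments typically report percent while the
#' formula consumes fractions.
#'
#' @param path Path to a CSV file with columns `mouse`, `group`, `cell_type`,
#'   `timepoint`, `pop_frac_wbc`, `donor_frac`, `gfp_frac`.
#' @return A validated `data.frame` (class `flow_summary`).
#' @export
read_flow_summary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  flow_summary(df)
}

#' @rdname read_flow_summary
#' @param df A `data.frame` already holding the flow columns.
#' @export
flow_summary <- function(df) {
  missing_cols <- setdiff(FLOW_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(df$group %in% GROUPS), all(df$cell_type %in% CELL_TYPES))
  for (col in c("pop_frac_wbc", "donor_frac", "gfp_frac")) {
    x <- df[[col]]
    if (anyNA(x) || any(x < 0) || any(x > 100)) {
      stop("column '", col, "' must lie in [0, 1] (or [0, 100] as percent)")
    }
    if (any(x > 1)) {
      warning("column '", col, "' looks like percentages; dividing by 100")
      x <- x / 100
    }
    df[[col]] <- x
  }
  df$sample_id <- format_sample_key(df$mouse, df$group, df$cell_type,
                                    df$timepoint)
  if (anyDuplicated(df$sample_id)) stop("duplicate flow-summary row")
  class(df) <- c("flow_summary", "data.frame")
  df
}

#' Count whitelisted barcodes in toy sequencing reads
#'
#' Each read is scanned for the constant flank sequence; the fixed-length
#' window following the flank is matched against the whitelist under Hamming
#' distance (fixed-length lentiviral barcode libraries; no indels). A read is
#' assigned to the unique whitelist barcode within `max_mismatch`; reads with
#' no flank, no match, or two equally close matches are discarded.
#'
#' @param reads A `Biostrings::DNAStringSet`, a character vector of read
#'   sequences, or the path to a FASTQ file.
#' @param whitelist Character vector of equal-length barcode sequences.
#' @param flank Anchor sequence immediately 5' of the barcode.
#' @param max_mismatch Maximum Hamming distance for assignment (default 0).
#' @param sample Sample key string for the resulting one-column table.
#' @return A list with `counts` (single-sample barcode count
#'   `SummarizedExperiment` over the whitelist) and `discarded` (number of
#'   unassigned reads).
#' @export
count_barcodes_from_reads <- function(reads, whitelist, flank,
                                      max_mismatch = 0,
                                      sample = "toy:HSC:Gr:2.5") {
  if (length(whitelist) == 0L) stop("empty whitelist")
  whitelist <- toupper(whitelist)
  bl <- unique(nchar(whitelist))
  if (length(bl) != 1L) stop("whitelist barcodes must all have the same length")
  if (anyDuplicated(whitelist)) stop("duplicate whitelist barcode")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  reads <- toupper(as.character(reads))
  flank <- toupper(flank)

  # locate barcode window after the first flank occurrence
  pos <- regexpr(flank, reads, fixed = TRUE)
  start <- ifelse(pos > 0L, pos + nchar(flank), NA_integer_)
  window <- ifelse(!is.na(start) & (start + bl - 1L) <= nchar(reads),
                   substr(reads, start, start + bl - 1L), NA_character_)

  wl_chars <- do.call(rbind, strsplit(whitelist, ""))
  assign_one <- function(w) {
    if (is.na(w)) return(NA_integer_)
    d <- colSums(t(wl_chars) != strsplit(w, "")[[1L]])
    dmin <- min(d)
    if (dmin > max_mismatch || sum(d == dmin) > 1L) return(NA_integer_)
    which.min(d)
  }
  # distance computation per distinct window only
  uw <- unique(window)
  hit <- vapply(uw, assign_one, integer(1L))
  idx <- hit[match(window, uw)]

  tab <- tabulate(idx, nbins = length(whitelist))
  counts <- matrix(as.integer(tab), ncol = 1L,
                   dimnames = list(whitelist, sample))
  list(counts = barcode_count_table(counts),
       discarded = sum(is.na(idx)))
}

#' Write / read a clonal abundance matrix as long-format TSV
#'
#' Columns: `barcode`, `mouse`, `group`, `cell_type`, `timepoint`,
#' `abundance_pct_wbc`. Values are written with 12 significant digits so a
#' write/read round trip is lossless for practical purposes.
#'
#' @param abundance A clonal abundance `SummarizedExperiment`.
#' @param path File path.
#' @return `path` (writer) or the reconstructed `SummarizedExperiment`
#'   (reader).
#' @export
write_abundance <- function(abundance, path) {
  long <- abundance_long(abundance)
  long$abundance_pct_wbc <- sprintf("%.12g", long$abundance)
  long$abundance <- NULL
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(barcode = "character",
                                    mouse = "character"))
  if (nrow(long) == 0L) stop("no abundance rows in ", path)
  long$sample_id <- format_sample_key(long$mouse, long$group, long$cell_type,
                                      long$timepoint)
  samples <- unique(long[c("sample_id", "mouse", "group", "cell_type",
                           "timepoint")])
  barcodes <- unique(long$barcode)
  m <- matrix(0, nrow = length(barcodes), ncol = nrow(samples),
              dimnames = list(barcodes, samples$sample_id))
  m[cbind(match(long$barcode, barcodes),
          match(long$sample_id, samples$sample_id))] <- long$abundance_pct_wbc
  clonal_abundance_matrix(m, samples)
}
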