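#' @importFrom methods is
#' @importFrom stats prcomp pt rbeta rbinom rmultinom rnorm runif sd setNames var
#' @importFrom utils read.csv read.delim write.table
NULL

# Controlled vocabularies for the four sorted blood populations and the two
# transplantation groups. All samples in a run are keyed by
# (mouse, group, cell_type, timepoint).
CELL_TYPES <- c("Gr", "B", "CD4T", "CD8T")
GROUPS <- c("HSC", "HSC_MPP")
LYMPHOID_TYPES <- c("B", "CD4T", "CD8T")
MYELOID_TYPES <- "Gr"
DEFAULT_TIMEPOINTS <- c(2.5, 3.5, 5.5, 6.5)

#' Cell types and groups recognised by the pipeline
#'
#' `cell_types()` returns the four sorted peripheral-blood populations
#' (granulocytes, B cells, CD4 T cells, CD8 T cells); `sample_groups()` the
#' two transplantation arms (HSC only, HSC cotransplanted with MPP).
#'
#' @return Character vector of tokens used in sample keys.
#' @export
cell_types <- function() CELL_TYPES

#' @rdname cell_types
#' @export
sample_groups <- function() GROUPS

#' Build a sample identifier from its four components
#'
#' Sample identity is encoded as a single colon-delimited token
#' `"<mouse>:<group>:<cell_type>:<timepoint>"` so that a count table can be a
#' flat TSV whose column headers carry all metadata.
#'
#' @param mouse Mouse identifier (no colons).
#' @param group `"HSC"` or `"HSC_MPP"`.
#' @param cell_type One of [cell_types()].
#' @param timepoint Months post-transplantation (numeric).
#' @return Character vector of sample keys.
#' @export
format_sample_key <- function(mouse, group, cell_type, timepoint) {
  stopifnot(all(group %in% GROUPS), all(cell_type %in% CELL_TYPES))
  paste(mouse, group, cell_type, format(timepoint, trim = TRUE), sep = ":")
}

#' Parse colon-delimited sample keys
#'
#' @param keys Character vector of `"mouse:group:cell_type:timepoint"` tokens.
#' @return A `data.frame` with columns `sample_id`, `mouse`, `group`,
#'   `cell_type`, `timepoint`.
#' @export
parse_sample_keys <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed sample header(s): ", paste(keys[bad], collapse = ", "),
         " (expected 'mouse:group:cell_type:timepoint')")
  }
  m <- do.call(rbind, parts)
  tp <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(tp)) {
    stop("non-numeric timepoint in sample header(s): ",
         paste(keys[is.na(tp)], collapse = ", "))
  }
  if (!all(m[, 2L] %in% GROUPS)) {
    stop("unknown group token(s): ",
         paste(unique(m[!(m[, 2L] %in% GROUPS), 2L]), collapse = ", "))
  }
  if (!all(m[, 3L] %in% CELL_TYPES)) {
    stop("unknown cell-type token(s): ",
         paste(unique(m[!(m[, 3L] %in% CELL_TYPES), 3L]), collapse = ", "))
  }
  data.frame(sample_id = keys, mouse = m[, 1L], group = m[, 2L],
             cell_type = m[, 3L], timepoint = tp,
             stringsAsFactors = FALSE)
}

# colData of a counts/abundance experiment as a plain data.frame
sample_meta <- function(se) {
  df <- as.data.frame(SummarizedExperiment::colData(se))
  df$sample_id <- colnames(se)
  df
}
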