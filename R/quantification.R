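#' Convert barcode read counts to clonal abundance (%WBC)
#'
#' Implements the clonal abundance calculation
#' \deqn{A_{bs} = 100 \times f^{pop}_s \times f^{donor}_s \times f^{GFP}_s
#'   \times c_{bs} / \sum_b c_{bs}}
#' where the three fractions come from flow cytometry: the sorted population's
#' share of white blood cells, the donor-derived share of that population, and
#' the GFP+ share of donor cells. A clone's read share of a sample is thereby
#' anchored to an absolute scale, percent of all white blood cells.
#'
#' Samples with zero total reads yield all-zero abundance with a warning
#' (late-timepoint samples can legitimately drop out).
#'
#' @param counts Barcode count `SummarizedExperiment`
#'   (see [barcode_count_table()]).
#' @param flow A `flow_summary` data frame covering every sample in `counts`.
#' @return A clonal abundance `SummarizedExperiment`; `colData` keeps the
#'   three flow fractions used for each sample.
#' @export
compute_clonal_abundance <- function(counts, flow) {
  meta <- sample_meta(counts)
  idx <- match(meta$sample_id, flow$sample_id)
  if (anyNA(idx)) {
    stop("no flow-summary row for sample(s): ",
         paste(meta$sample_id[is.na(idx)], collapse = ", "))
  }
  flow <- flow[idx, , drop = FALSE]
  m <- SummarizedExperiment::assay(counts, "counts")
  totals <- colSums(m)
  if (any(totals == 0)) {
    warning("sample(s) with zero total reads yield zero abundance: ",
            paste(meta$sample_id[totals == 0], collapse = ", "))
  }
  scale <- 100 * flow$pop_frac_wbc * flow$donor_frac * flow$gfp_frac /
    ifelse(totals > 0, totals, 1)
  ab <- sweep(m, 2L, scale, `*`)
  samples <- cbind(meta[c("sample_id", "mouse", "group", "cell_type",
                          "timepoint")],
                   flow[c("pop_frac_wbc", "donor_frac", "gfp_frac")])
  clonal_abundance_matrix(ab, samples)
}

#' Remove single-sample spike artifacts
#'
#' A clone is discarded when, within one mouse, it exceeds `spike_threshold`
#' %WBC in exactly one (cell type, timepoint) sample and is absent
#' (abundance below `absence_threshold`) in every other sample of that mouse.
#' Such isolated spikes are PCR/sequencing artifacts or index hops rather
#' than genuine clones, which leave a footprint in more than one sample.
#' Removal is judged per mouse; the absence cutoff defaults to the 0.01 %WBC
#' measurability floor so that "absent" is the exact complement of
#' "measurable".
#'
#' @param abundance Clonal abundance `SummarizedExperiment`.
#' @param spike_threshold %WBC a lone sample must exceed (default 0.5).
#' @param absence_threshold %WBC below which a clone counts as absent
#'   (default 0.01).
#' @return A list with `abundance` (spike cells zeroed; barcodes whose entire
#'   signal was spurious dropped) and `removed`, a `data.frame` of
#'   (`barcode`, `mouse`) pairs that were discarded.
#' @export
filter_spurious_clones <- function(abundance, spike_threshold = 0.5,
                                   absence_threshold = 0.01) {
  stopifnot(spike_threshold >= 0, absence_threshold >= 0)
  m <- SummarizedExperiment::assay(abundance, "abundance")
  meta <- sample_meta(abundance)
  removed <- list()
  if (nrow(m)) {
    for (mouse in unique(meta$mouse)) {
      cols <- which(meta$mouse == mouse)
      sub <- m[, cols, drop = FALSE]
      spike <- sub > spike_threshold
      absent <- sub < absence_threshold
      drop <- rowSums(spike) == 1L & rowSums(!spike & !absent) == 0L
      if (any(drop)) {
        removed[[mouse]] <- data.frame(barcode = rownames(m)[drop],
                                       mouse = mouse,
                                       stringsAsFactors = FALSE)
        m[drop, cols] <- 0
      }
    }
  }
  removed <- if (length(removed)) {
    do.call(rbind, c(removed, list(make.row.names = FALSE)))
  } else {
    data.frame(barcode = character(), mouse = character(),
               stringsAsFactors = FALSE)
  }
  # drop barcodes whose signal was exclusively spurious
  empty <- rownames(m)[rowSums(m) == 0 & rownames(m) %in% removed$barcode]
  keep <- setdiff(rownames(m), empty)
  out <- abundance[keep, ]
  SummarizedExperiment::assay(out, "abundance") <- m[keep, , drop = FALSE]
  list(abundance = out, removed = removed)
}
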