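#' Classification parameters
#'
#' Thresholds governing every categorical call made on a clone:
#' \describe{
#'   \item{fold_threshold}{Relative copy-number fold above which a clone is
#'     lineage-biased; cot(22.5 degrees) = 2.4142, i.e. a 45-degree sector
#'     around the diagonal of the myeloid/lymphoid plane counts as balanced.}
#'   \item{detect_floor}{%WBC at or above which a clone measurably produces a
#'     cell type (0.01; "absent" is its strict complement).}
#'   \item{high_abundance_floor}{%WBC a clone must exceed (strictly) to count
#'     as a high-abundance producer (0.05).}
#'   \item{early_timepoint, late_timepoint}{Reference months for temporal and
#'     dynamics calls (2.5 and 6.5; blood production at 5.5 and 6.5 months is
#'     similar, so the last timepoint serves as the long-term reference).}
#'   \item{relative}{Compare lineages on relative copy numbers (lineage share
#'     normalised within mouse and timepoint, the default) or on raw %WBC.}
#' }
#'
#' @param fold_threshold Bias fold threshold (> 1).
#' @param detect_floor Measurability floor in %WBC (inclusive).
#' @param high_abundance_floor High-abundance cutoff in %WBC (exclusive).
#' @param early_timepoint,late_timepoint Reference timepoints in months.
#' @param relative Logical; normalise lineage abundances within mouse.
#' @return A list of class `bias_parameters`.
#' @export
bias_parameters <- function(fold_threshold = 1 / tan(22.5 * pi / 180),
                            detect_floor = 0.01,
                            high_abundance_floor = 0.05,
                            early_timepoint = 2.5,
                            late_timepoint = 6.5,
                            relative = TRUE) {
  stopifnot(fold_threshold > 1, detect_floor >= 0, high_abundance_floor >= 0)
  structure(list(fold_threshold = fold_threshold,
                 detect_floor = detect_floor,
                 high_abundance_floor = high_abundance_floor,
                 early_timepoint = early_timepoint,
                 late_timepoint = late_timepoint,
                 relative = relative),
            class = "bias_parameters")
}

# clone universe: (barcode, mouse) pairs carrying any signal in that mouse
clone_table <- function(long) {
  u <- unique(long[long$abundance > 0, c("barcode", "mouse", "group")])
  u <- u[order(u$mouse, u$barcode), , drop = FALSE]
  rownames(u) <- NULL
  u
}

clone_key <- function(barcode, mouse) paste(barcode, mouse, sep = "\r")

# clones x cell-type abundance matrix at one timepoint
ct_matrix_at <- function(long, clones, timepoint) {
  sub <- long[long$timepoint == timepoint, , drop = FALSE]
  ck <- clone_key(clones$barcode, clones$mouse)
  key <- clone_key(sub$barcode, sub$mouse)
  keep <- key %in% ck
  sub <- sub[keep, , drop = FALSE]
  m <- matrix(0, nrow(clones), length(CELL_TYPES),
              dimnames = list(ck, CELL_TYPES))
  m[cbind(match(key[keep], ck), match(sub$cell_type, CELL_TYPES))] <-
    sub$abundance
  m
}

#' Presence of measurable output per clone, cell type and timepoint
#'
#' A clone produces a cell type at a timepoint when its abundance is at or
#' above the detection floor (0.01 %WBC by default; the floor is inclusive so
#' that presence and absence partition all abundances).
#'
#' @param abundance Clonal abundance `SummarizedExperiment`.
#' @param params A [bias_parameters()] object.
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `cell_type`,
#'   `timepoint`, `abundance`, `present`.
#' @export
detect_produced_types <- function(abundance, params = bias_parameters()) {
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  keep <- clone_key(long$barcode, long$mouse) %in%
    clone_key(clones$barcode, clones$mouse)
  out <- long[keep, , drop = FALSE]
  out$present <- out$abundance >= params$detect_floor
  rownames(out) <- NULL
  out
}

#' Produced-cell-type combination of each clone at a timepoint
#'
#' CD4 T and CD8 T production is merged into a single T category, giving seven
#' possible non-empty combinations of \{Gr, B, T\}. Clones producing nothing
#' measurable at the timepoint get `NA` and are excluded from tallies.
#'
#' @inheritParams detect_produced_types
#' @param timepoint Months post-transplantation.
#' @return `data.frame` with columns `barcode`, `mouse`, `group`,
#'   `combination` (e.g. `"Gr+B+T"`).
#' @export
combination_labels <- function(abundance, params = bias_parameters(),
                               timepoint = params$early_timepoint) {
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  m <- ct_matrix_at(long, clones, timepoint) >= params$detect_floor
  present <- cbind(Gr = m[, "Gr"], B = m[, "B"],
                   T = m[, "CD4T"] | m[, "CD8T"])
  lab <- apply(present, 1L, function(p) {
    if (!any(p)) NA_character_ else paste(colnames(present)[p], collapse = "+")
  })
  data.frame(clones, combination = unname(lab), stringsAsFactors = FALSE)
}

#' Relative copy number of each clone in a lineage
#'
#' A clone's summed abundance over the lineage's cell types, normalised by the
#' summed abundance of all clones over those cell types in the same mouse and
#' timepoint. The normalisation makes myeloid and lymphoid compartments of
#' different absolute sizes comparable, so the bias fold rule is scale-free.
#'
#' @inheritParams combination_labels
#' @param lineage Character vector of cell types (subset of [cell_types()]).
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `rcn`.
#' @export
relative_copy_number <- function(abundance, lineage, timepoint) {
  stopifnot(length(lineage) > 0, all(lineage %in% CELL_TYPES))
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  m <- ct_matrix_at(long, clones, timepoint)
  own <- rowSums(m[, lineage, drop = FALSE])
  totals <- tapply(own, clones$mouse, sum)[clones$mouse]
  rcn <- ifelse(totals > 0, own / totals, 0)
  data.frame(clones, rcn = unname(rcn), stringsAsFactors = FALSE)
}

# shared engine for the myeloid/lymphoid and B/T bias rules
classify_bias_engine <- function(abundance, params, timepoint,
                                 lineage_a, lineage_b, labels) {
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  m <- ct_matrix_at(long, clones, timepoint)
  meas_a <- rowSums(m[, lineage_a, drop = FALSE] >= params$detect_floor) > 0
  meas_b <- rowSums(m[, lineage_b, drop = FALSE] >= params$detect_floor) > 0
  a <- rowSums(m[, lineage_a, drop = FALSE])
  b <- rowSums(m[, lineage_b, drop = FALSE])
  if (params$relative) {
    a <- a / pmax(tapply(a, clones$mouse, sum)[clones$mouse], .Machine$double.xmin)
    b <- b / pmax(tapply(b, clones$mouse, sum)[clones$mouse], .Machine$double.xmin)
  }
  thr <- params$fold_threshold
  lab <- rep(labels["none"], nrow(clones))
  lab[meas_a & !meas_b] <- labels["a_specialized"]
  lab[!meas_a & meas_b] <- labels["b_specialized"]
  both <- meas_a & meas_b
  lab[both] <- ifelse(a[both] > thr * b[both], labels["a_biased"],
                      ifelse(b[both] > thr * a[both], labels["b_biased"],
                             labels["balanced"]))
  data.frame(clones, timepoint = timepoint, label = unname(lab),
             stringsAsFactors = FALSE)
}

#' Myeloid/lymphoid lineage bias of each clone
#'
#' Specialisation takes precedence: a clone measurable (at or above the
#' detection floor) in only one lineage is `*_specialized`. Otherwise the
#' relative copy numbers m (granulocytes) and l (B + CD4 T + CD8 T) are
#' compared: `m > fold_threshold * l` is `myeloid_biased`,
#' `l > fold_threshold * m` is `lymphoid_biased`, anything else `balanced`.
#' Clones measurable in neither lineage are `undetected`.
#'
#' @inheritParams combination_labels
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `timepoint`,
#'   `lineage_bias`.
#' @export
classify_lineage_bias <- function(abundance, params = bias_parameters(),
                                  timepoint = params$late_timepoint) {
  out <- classify_bias_engine(
    abundance, params, timepoint,
    lineage_a = MYELOID_TYPES, lineage_b = LYMPHOID_TYPES,
    labels = c(a_specialized = "myeloid_specialized",
               b_specialized = "lymphoid_specialized",
               a_biased = "myeloid_biased", b_biased = "lymphoid_biased",
               balanced = "balanced", none = "undetected"))
  names(out)[names(out) == "label"] <- "lineage_bias"
  out
}

#' B-cell versus T-cell bias of each clone
#'
#' Same precedence and fold rule as [classify_lineage_bias()], applied to the
#' lymphoid compartment only: B cells versus T cells (CD4 T and CD8 T
#' combined). Clones measurable in neither are `not_applicable`.
#'
#' @inheritParams combination_labels
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `timepoint`,
#'   `bt_bias`.
#' @export
classify_bt_bias <- function(abundance, params = bias_parameters(),
                             timepoint = params$late_timepoint) {
  out <- classify_bias_engine(
    abundance, params, timepoint,
    lineage_a = "B", lineage_b = c("CD4T", "CD8T"),
    labels = c(a_specialized = "B_specialized",
               b_specialized = "T_specialized",
               a_biased = "B_biased", b_biased = "T_biased",
               balanced = "BT_balanced", none = "not_applicable"))
  names(out)[names(out) == "label"] <- "bt_bias"
  out
}

#' Flag high-abundance clones
#'
#' A clone is a high-abundance producer of a cell type at a timepoint when its
#' abundance is strictly above the high-abundance floor (0.05 %WBC).
#'
#' @inheritParams detect_produced_types
#' @return The presence table of [detect_produced_types()] with an extra
#'   logical column `high`.
#' @export
flag_high_abundance <- function(abundance, params = bias_parameters()) {
  out <- detect_produced_types(abundance, params)
  out$high <- out$abundance > params$high_abundance_floor
  out
}

#' Temporal category of each clone per cell type
#'
#' Based on measurable production at the early and late reference timepoints:
#' present at both is `persisted`, only early is `early`, only late is `late`,
#' neither is `neither`.
#'
#' @inheritParams detect_produced_types
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `cell_type`,
#'   `temporal`.
#' @export
classify_temporal <- function(abundance, params = bias_parameters()) {
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  pe <- ct_matrix_at(long, clones, params$early_timepoint) >=
    params$detect_floor
  pl <- ct_matrix_at(long, clones, params$late_timepoint) >=
    params$detect_floor
  out <- do.call(rbind, lapply(CELL_TYPES, function(ct) {
    lab <- ifelse(pe[, ct] & pl[, ct], "persisted",
                  ifelse(pe[, ct], "early",
                         ifelse(pl[, ct], "late", "neither")))
    data.frame(clones, cell_type = ct, temporal = unname(lab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expansion dynamics of persisted T-cell-producing clones
#'
#' For clones that persist in producing a T cell type, the ratio of late to
#' early production classifies them: above 1 is `expanded`, below 1
#' `shrunken`, exactly 1 `neither` (a measure-zero tie under continuous
#' noise). Clones not persisted for the cell type are `not_applicable`.
#'
#' @inheritParams detect_produced_types
#' @param cell_types_dyn T cell types to assess (kept separate, not merged).
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `cell_type`,
#'   `ratio`, `dynamics`.
#' @export
classify_dynamics <- function(abundance, params = bias_parameters(),
                              cell_types_dyn = c("CD4T", "CD8T")) {
  stopifnot(all(cell_types_dyn %in% CELL_TYPES))
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  me <- ct_matrix_at(long, clones, params$early_timepoint)
  ml <- ct_matrix_at(long, clones, params$late_timepoint)
  floor_ <- params$detect_floor
  out <- do.call(rbind, lapply(cell_types_dyn, function(ct) {
    persisted <- me[, ct] >= floor_ & ml[, ct] >= floor_
    ratio <- rep(NA_real_, nrow(clones))
    bad <- persisted & me[, ct] == 0
    if (any(bad)) {
      warning(sum(bad), " clone(s) with undefined late/early ratio excluded")
      persisted[bad] <- FALSE
    }
    ratio[persisted] <- ml[persisted, ct] / me[persisted, ct]
    lab <- rep("not_applicable", nrow(clones))
    lab[persisted] <- ifelse(ratio[persisted] > 1, "expanded",
                             ifelse(ratio[persisted] < 1, "shrunken",
                                    "neither"))
    data.frame(clones, cell_type = ct, ratio = unname(ratio),
               dynamics = unname(lab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fate at the late timepoint of clones detected early
#'
#' For every clone measurable at the early reference timepoint, tallies its
#' late-timepoint lineage category: `multilineage` (measurable in both
#' lineages), `myeloid_specialized`, `lymphoid_specialized`, or `undetected`.
#' Per mouse, the fractions over the four categories sum to 1.
#'
#' @inheritParams detect_produced_types
#' @return `data.frame` with columns `mouse`, `group`, `category`, `n`,
#'   `fraction`.
#' @export
early_late_overlap <- function(abundance, params = bias_parameters()) {
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  me <- ct_matrix_at(long, clones, params$early_timepoint)
  ml <- ct_matrix_at(long, clones, params$late_timepoint)
  floor_ <- params$detect_floor
  early_det <- rowSums(me >= floor_) > 0
  mye <- rowSums(ml[, MYELOID_TYPES, drop = FALSE] >= floor_) > 0
  lym <- rowSums(ml[, LYMPHOID_TYPES, drop = FALSE] >= floor_) > 0
  category <- ifelse(mye & lym, "multilineage",
                     ifelse(mye, "myeloid_specialized",
                            ifelse(lym, "lymphoid_specialized", "undetected")))
  cats <- c("multilineage", "myeloid_specialized", "lymphoid_specialized",
            "undetected")
  sub <- clones[early_det, , drop = FALSE]
  sub$category <- category[early_det]
  out <- do.call(rbind, lapply(split(sub, sub$mouse), function(d) {
    n <- table(factor(d$category, levels = cats))
    data.frame(mouse = d$mouse[1L], group = d$group[1L], category = cats,
               n = as.integer(n), fraction = as.numeric(n) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' All categorical labels for every clone, in long format
#'
#' Convenience wrapper running the complete classification suite: produced
#' cell-type combination, myeloid/lymphoid bias and B/T bias at both
#' reference timepoints, temporal category per cell type, expansion dynamics
#' for the T cell types, and the high-abundance flag per sample.
#'
#' @inheritParams detect_produced_types
#' @return `data.frame` with columns `barcode`, `mouse`, `group`, `axis`,
#'   `cell_type`, `timepoint`, `label`.
#' @export
classify_clones <- function(abundance, params = bias_parameters()) {
  rows <- list()
  for (tp in c(params$early_timepoint, params$late_timepoint)) {
    comb <- combination_labels(abundance, params, tp)
    rows[[length(rows) + 1L]] <- data.frame(
      comb[c("barcode", "mouse", "group")], axis = "combination",
      cell_type = NA_character_, timepoint = tp, label = comb$combination,
      stringsAsFactors = FALSE)
    lb <- classify_lineage_bias(abundance, params, tp)
    rows[[length(rows) + 1L]] <- data.frame(
      lb[c("barcode", "mouse", "group")], axis = "lineage_bias",
      cell_type = NA_character_, timepoint = tp, label = lb$lineage_bias,
      stringsAsFactors = FALSE)
    bt <- classify_bt_bias(abundance, params, tp)
    rows[[length(rows) + 1L]] <- data.frame(
      bt[c("barcode", "mouse", "group")], axis = "bt_bias",
      cell_type = NA_character_, timepoint = tp, label = bt$bt_bias,
      stringsAsFactors = FALSE)
  }
  tmp <- classify_temporal(abundance, params)
  rows[[length(rows) + 1L]] <- data.frame(
    tmp[c("barcode", "mouse", "group")], axis = "temporal",
    cell_type = tmp$cell_type, timepoint = NA_real_, label = tmp$temporal,
    stringsAsFactors = FALSE)
  dyn <- classify_dynamics(abundance, params)
  rows[[length(rows) + 1L]] <- data.frame(
    dyn[c("barcode", "mouse", "group")], axis = "dynamics",
    cell_type = dyn$cell_type, timepoint = NA_real_, label = dyn$dynamics,
    stringsAsFactors = FALSE)
  hi <- flag_high_abundance(abundance, params)
  rows[[length(rows) + 1L]] <- data.frame(
    hi[c("barcode", "mouse", "group")], axis = "high_abundance",
    cell_type = hi$cell_type, timepoint = hi$timepoint,
    label = ifelse(hi$high, "high", "not_high"), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
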