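#' One-tailed Welch (unequal variance) two-sample t test
#'
#' The test statistic is
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with Welch-Satterthwaite degrees of freedom, and the p value is the
#' one-tailed tail probability in the stated direction (`"greater"` tests
#' mean(a) > mean(b)). The direction is an explicit required argument and is
#' never inferred from the data, since silent direction inference invalidates
#' one-tailed p values. When both groups are constant with equal means the
#' test is undefined and p = 0.5 is returned by convention with a warning.
#'
#' @param a,b Numeric vectors, at least two values each.
#' @param alternative `"greater"` or `"less"`.
#' @return A list with elements `t`, `df`, `p`.
#' @export
welch_t_one_tailed <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (var(a) + var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means; p = 0.5 by convention")
      return(list(t = 0, df = length(a) + length(b) - 2, p = 0.5))
    }
    t <- sign(mean(a) - mean(b)) * Inf
    p <- if (alternative == "greater") as.numeric(t < 0) else as.numeric(t > 0)
    return(list(t = t, df = length(a) + length(b) - 2, p = p))
  }
  fit <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Shannon diversity of a clone abundance vector
#'
#' \eqn{H = -\sum_i p_i \log p_i} over the clone frequency shares
#' \eqn{p_i = a_i / \sum a}, in nats by default (the convention of the vegan
#' package, which performs the computation).
#'
#' @param abundances Non-negative clone abundances for one
#'   mouse/cell-type/timepoint sample; at least one must be positive.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Shannon index (scalar).
#' @export
shannon_index <- function(abundances, base = exp(1)) {
  if (anyNA(abundances) || any(abundances < 0)) {
    stop("abundances must be non-negative")
  }
  if (sum(abundances) == 0) stop("no detected clones")
  as.numeric(vegan::diversity(abundances, index = "shannon", base = base))
}

#' Shannon diversity for every sample of an abundance matrix
#'
#' @param abundance Clonal abundance `SummarizedExperiment`.
#' @param base Logarithm base (default nats).
#' @return `data.frame` with columns `mouse`, `group`, `cell_type`,
#'   `timepoint`, `n_clones` (clones with positive abundance) and `shannon`.
#'   Samples without any detected clone are skipped with a message.
#' @export
shannon_diversity <- function(abundance, base = exp(1)) {
  m <- SummarizedExperiment::assay(abundance, "abundance")
  meta <- sample_meta(abundance)
  ok <- colSums(m) > 0
  if (any(!ok)) {
    message(sum(!ok), " sample(s) without detected clones skipped")
  }
  data.frame(meta[ok, c("mouse", "group", "cell_type", "timepoint")],
             n_clones = colSums(m[, ok, drop = FALSE] > 0),
             shannon = apply(m[, ok, drop = FALSE], 2L, shannon_index,
                             base = base),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-mouse total abundance of one cell type at one timepoint
#'
#' The summed clonal abundance of a sorted population equals the
#' donor-derived, barcoded share of that population in %WBC, the natural
#' per-mouse metric for group comparisons.
#'
#' @param abundance Clonal abundance `SummarizedExperiment`.
#' @param cell_type One of [cell_types()].
#' @param timepoint Months post-transplantation.
#' @return `data.frame` with columns `mouse`, `group`, `value`.
#' @export
celltype_totals <- function(abundance, cell_type, timepoint) {
  stopifnot(cell_type %in% CELL_TYPES)
  m <- SummarizedExperiment::assay(abundance, "abundance")
  meta <- sample_meta(abundance)
  sel <- meta$cell_type == cell_type & meta$timepoint == timepoint
  data.frame(mouse = meta$mouse[sel], group = meta$group[sel],
             value = colSums(m[, sel, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a per-mouse metric between the two transplantation groups
#'
#' Wraps [welch_t_one_tailed()] with the mouse as the unit of replication (no
#' clone-level pseudo-replication). Reports group means with SEM and the
#' conventional significance tag: `"*"` for p <= 0.05, `"**"` for p < 0.01.
#' No multiple-testing correction is applied; callers running several
#' comparisons should report how many tests were run.
#'
#' @param values `data.frame` with columns `mouse`, `group`, `value`
#'   (one row per mouse, e.g. from [celltype_totals()]).
#' @param metric Name of the metric (bookkeeping only).
#' @param alternative `"greater"` or `"less"`, the tested direction for
#'   `groups[1]` relative to `groups[2]`; always stated explicitly.
#' @param groups Character vector of length 2 naming the groups to compare,
#'   in the order the alternative refers to.
#' @return A list of class `group_comparison`: `metric`, `groups`, `n`,
#'   `mean`, `sem`, `t`, `df`, `p`, `alternative`, `significance`.
#' @export
compare_groups <- function(values, metric = "metric",
                           alternative = c("greater", "less"),
                           groups = c("HSC_MPP", "HSC")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("mouse", "group", "value") %in% names(values)),
            length(groups) == 2L)
  a <- values$value[values$group == groups[1L]]
  b <- values$value[values$group == groups[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 mice")
  }
  res <- welch_t_one_tailed(a, b, alternative)
  sem <- function(x) sd(x) / sqrt(length(x))
  tag <- if (res$p < 0.01) "**" else if (res$p <= 0.05) "*" else ""
  structure(list(metric = metric, groups = groups,
                 n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)), sem = c(sem(a), sem(b)),
                 t = res$t, df = res$df, p = res$p,
                 alternative = alternative, significance = tag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (%s vs %s, one-tailed '%s')\n",
              x$metric, x$groups[1L], x$groups[2L], x$alternative))
  for (i in 1:2) {
    cat(sprintf("  %-8s n = %d  mean = %.4g +/- %.4g (SEM)\n",
                x$groups[i], x$n[i], x$mean[i], x$sem[i]))
  }
  cat(sprintf("  Welch t = %.4g, df = %.3g, p = %.4g %s\n",
              x$t, x$df, x$p, x$significance))
  invisible(x)
}
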