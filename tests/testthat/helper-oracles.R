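# Independent brute-force oracles: literal loops over the definitions,
# sharing no decision logic with the package implementation.

# Spike-filter rule re-checked clause by clause on one mouse's
# clone x cell matrix.
oracle_filter_decisions <- function(mat, spike = 0.5, absence = 0.01) {
  removed <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      if (mat[i, j] > spike) {
        others <- mat[i, -j]
        if (all(others < absence)) {
          # clause 2 holds for this candidate cell; clause 1 needs it unique
          if (sum(mat[i, ] > spike) == 1) removed[i] <- TRUE
        }
      }
    }
  }
  removed
}

# All five label axes, computed clone by clone from the long table.
oracle_labels <- function(abundance, params = bias_parameters()) {
  long <- abundance_long(abundance)
  long <- long[order(long$mouse, long$barcode), ]
  ids <- unique(long[long$abundance > 0, c("barcode", "mouse")])
  floor_ <- params$detect_floor
  thr <- params$fold_threshold
  tps <- c(params$early_timepoint, params$late_timepoint)

  get_ab <- function(b, m, ct, tp) {
    v <- long$abundance[long$barcode == b & long$mouse == m &
                          long$cell_type == ct & long$timepoint == tp]
    if (length(v) == 0) 0 else sum(v)
  }
  lineage_sum <- function(b, m, cts, tp) {
    s <- 0
    for (ct in cts) s <- s + get_ab(b, m, ct, tp)
    s
  }
  mouse_lineage_total <- function(m, cts, tp) {
    s <- 0
    for (i in seq_len(nrow(ids))) {
      if (ids$mouse[i] == m) {
        s <- s + lineage_sum(ids$barcode[i], ids$mouse[i], cts, tp)
      }
    }
    s
  }

  out <- list()
  for (i in seq_len(nrow(ids))) {
    b <- ids$barcode[i]; m <- ids$mouse[i]
    rec <- list(barcode = b, mouse = m)
    for (tp in tps) {
      tpn <- format(tp, trim = TRUE)
      # presence per cell type
      pres <- sapply(cell_types(), function(ct) get_ab(b, m, ct, tp) >= floor_)
      # combination with CD4T/CD8T merged into T
      got <- c("Gr"[pres["Gr"]], "B"[pres["B"]],
               "T"[pres["CD4T"] || pres["CD8T"]])
      rec[[paste0("combination_", tpn)]] <-
        if (length(got)) paste(got, collapse = "+") else NA_character_
      # myeloid / lymphoid bias with specialization precedence
      mye_meas <- pres["Gr"]
      lym_meas <- pres["B"] || pres["CD4T"] || pres["CD8T"]
      bias <- if (!mye_meas && !lym_meas) {
        "undetected"
      } else if (mye_meas && !lym_meas) {
        "myeloid_specialized"
      } else if (!mye_meas && lym_meas) {
        "lymphoid_specialized"
      } else {
        mm <- lineage_sum(b, m, "Gr", tp)
        ll <- lineage_sum(b, m, c("B", "CD4T", "CD8T"), tp)
        if (params$relative) {
          mm <- mm / mouse_lineage_total(m, "Gr", tp)
          ll <- ll / mouse_lineage_total(m, c("B", "CD4T", "CD8T"), tp)
        }
        if (mm > thr * ll) "myeloid_biased"
        else if (ll > thr * mm) "lymphoid_biased"
        else "balanced"
      }
      rec[[paste0("lineage_bias_", tpn)]] <- bias
      # B vs T bias
      b_meas <- pres["B"]
      t_meas <- pres["CD4T"] || pres["CD8T"]
      bt <- if (!b_meas && !t_meas) {
        "not_applicable"
      } else if (b_meas && !t_meas) {
        "B_specialized"
      } else if (!b_meas && t_meas) {
        "T_specialized"
      } else {
        bb <- lineage_sum(b, m, "B", tp)
        tt <- lineage_sum(b, m, c("CD4T", "CD8T"), tp)
        if (params$relative) {
          bb <- bb / mouse_lineage_total(m, "B", tp)
          tt <- tt / mouse_lineage_total(m, c("CD4T", "CD8T"), tp)
        }
        if (bb > thr * tt) "B_biased"
        else if (tt > thr * bb) "T_biased"
        else "BT_balanced"
      }
      rec[[paste0("bt_bias_", tpn)]] <- bt
    }
    # temporal and dynamics per cell type
    for (ct in cell_types()) {
      e <- get_ab(b, m, ct, params$early_timepoint) >= floor_
      l <- get_ab(b, m, ct, params$late_timepoint) >= floor_
      rec[[paste0("temporal_", ct)]] <-
        if (e && l) "persisted" else if (e) "early" else if (l) "late"
        else "neither"
    }
    for (ct in c("CD4T", "CD8T")) {
      e_ab <- get_ab(b, m, ct, params$early_timepoint)
      l_ab <- get_ab(b, m, ct, params$late_timepoint)
      rec[[paste0("dynamics_", ct)]] <-
        if (e_ab >= floor_ && l_ab >= floor_) {
          r <- l_ab / e_ab
          if (r > 1) "expanded" else if (r < 1) "shrunken" else "neither"
        } else "not_applicable"
    }
    out[[i]] <- rec
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Closed-form Welch statistic, df and one-tailed p.
oracle_welch <- function(a, b, alternative) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (alternative == "greater") pt(t, df, lower.tail = FALSE)
  else pt(t, df)
  list(t = t, df = df, p = p)
}

# Direct-summation Shannon index.
oracle_shannon <- function(x, base = exp(1)) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p)) / log(base)
}

# All set partitions of 1..n (for exhaustive modularity checks, n <= 8).
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Per-cluster majority tally of detection fractions, re-done literally.
oracle_term_categories <- function(det, assignments, early, late, middle) {
  ids <- sort(unique(assignments))
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    rows <- names(assignments)[assignments == ids[i]]
    f <- colSums(det[rows, , drop = FALSE]) / length(rows)
    best <- names(f)[which.max(f)]
    out[i] <- if (f[late] >= 0.5) "long_term"
    else if (f[early] >= 0.5) "short_term"
    else if (f[middle] >= 0.5) "middle_term"
    else if (best == late) "long_term"
    else if (best == early) "short_term"
    else "middle_term"
  }
  names(out) <- ids
  out
}
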