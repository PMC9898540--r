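#' Built-in clone archetypes
#'
#' Eight clone phenotypes spanning the behaviours a barcoded-HSC experiment
#' produces: a short-term multilineage burst, a middle-term clone, long-term
#' balanced / myeloid-specialized / lymphoid-specialized / T-biased /
#' B-biased clones, and a persisted clone with expanding T-cell output. Each
#' archetype carries its mean abundance (%WBC) per cell type and timepoint
#' and the class labels the classifiers are expected to recover, plus its
#' mixture weight in each transplantation group (the HSC+MPP mixture shifts
#' weight from short-term towards middle/long-term phenotypes).
#'
#' Means and weights were chosen so that every annotated label lies well away
#' from its classification threshold after the within-mouse relative
#' copy-number normalisation, for lognormal clone noise up to sigma = 0.3.
#' The flat-T B-biased archetype has no meaningful expansion truth (its
#' late/early ratio is exactly 1 noise-free), so its dynamics label is `NA`.
#'
#' @param timepoints Time grid in months (means are defined on the default
#'   grid 2.5, 3.5, 5.5, 6.5).
#' @return A list of archetype specifications (lists with `name`, `means`,
#'   `lineage_bias`, `bias_timepoint`, `dynamics`, `weight`).
#' @export
default_archetypes <- function(timepoints = DEFAULT_TIMEPOINTS) {
  A <- function(...) {
    matrix(c(...), nrow = 4L, byrow = TRUE,
           dimnames = list(CELL_TYPES, format(timepoints, trim = TRUE)))
  }
  spec <- function(name, means, lineage_bias, bias_timepoint, dynamics,
                   w_hsc, w_mpp) {
    list(name = name, means = means, lineage_bias = lineage_bias,
         bias_timepoint = bias_timepoint, dynamics = dynamics,
         weight = c(HSC = w_hsc, HSC_MPP = w_mpp))
  }
  list(
    spec("short_multilineage",
         A(.12, 0, 0, 0,
           .06, 0, 0, 0,
           .03, 0, 0, 0,
           .03, 0, 0, 0),
         "balanced", timepoints[1L], NA, .26, .18),
    spec("middle_term",
         A(0, 0, .12, 0,
           0, 0, .06, 0,
           0, 0, .03, 0,
           0, 0, .03, 0),
         "undetected", timepoints[4L], NA, .08, .10),
    spec("long_balanced",
         A(.10, .10, .10, .10,
           .08, .08, .08, .08,
           .10, .08, .04, .022,
           .10, .08, .04, .022),
         "balanced", timepoints[4L], "shrunken", .16, .16),
    spec("long_myeloid_specialized",
         A(.80, .80, .80, .80,
           0, 0, 0, 0,
           0, 0, 0, 0,
           0, 0, 0, 0),
         "myeloid_specialized", timepoints[4L], NA, .13, .12),
    spec("long_lymphoid_specialized",
         A(0, 0, 0, 0,
           .08, .08, .08, .08,
           .03, .04, .07, .09,
           .03, .04, .07, .09),
         "lymphoid_specialized", timepoints[4L], "expanded", .08, .08),
    spec("long_T_biased",
         A(0, 0, 0, 0,
           .03, .03, .03, .03,
           .06, .08, .13, .18,
           .06, .08, .13, .18),
         "lymphoid_specialized", timepoints[4L], "expanded", .06, .07),
    spec("persisted_expanding_T",
         A(.06, .06, .06, .06,
           .06, .06, .06, .06,
           .03, .05, .10, .15,
           .03, .05, .10, .15),
         "lymphoid_biased", timepoints[4L], "expanded", .06, .09),
    spec("long_B_biased",
         A(0, 0, 0, 0,
           .20, .20, .20, .20,
           .025, .025, .025, .025,
           .025, .025, .025, .025),
         "lymphoid_specialized", timepoints[4L], NA, .17, .20)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study design: 5 HSC-only and 7 HSC+MPP mice, about
#' 200 clones per mouse, four sorted populations at 2.5/3.5/5.5/6.5 months,
#' multiplicative lognormal clone noise on top of archetype means, multinomial
#' read sampling at 100,000 reads per sample, Beta-distributed measurement
#' noise on the flow fractions, a 2-fold increase of late (>= 5.5 months)
#' T-cell means in the HSC+MPP group, and a 2% rate of injected single-sample
#' spike artifacts (each exceeding 0.5 %WBC in exactly one sample and absent
#' elsewhere, satisfying the artifact filter's removal clause by
#' construction).
#'
#' @param n_mice Named integer vector, mice per group.
#' @param clones_per_mouse Clones per mouse.
#' @param archetypes Archetype list (see [default_archetypes()]).
#' @param sigma Lognormal noise SD on the log scale, applied per
#'   (clone, cell type, timepoint) cell.
#' @param depth Sequencing reads per sample.
#' @param flow_kappa Beta concentration for flow-fraction noise (`Inf` for
#'   noise-free fractions).
#' @param mpp_effect Multiplier on CD4T/CD8T means at timepoints >= 5.5
#'   months in the HSC+MPP group.
#' @param spike_rate Expected spike artifacts per clone.
#' @param timepoints Time grid (months).
#' @param barcode_length Length of the random barcodes.
#' @param donor_frac,gfp_frac Baseline donor and GFP fractions used to
#'   decompose each sample's total abundance into the three flow fractions.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_mice = c(HSC = 5L, HSC_MPP = 7L),
                              clones_per_mouse = 200L,
                              archetypes = default_archetypes(),
                              sigma = 0.5,
                              depth = 1e5,
                              flow_kappa = 200,
                              mpp_effect = 2.0,
                              spike_rate = 0.02,
                              timepoints = DEFAULT_TIMEPOINTS,
                              barcode_length = 27L,
                              donor_frac = 0.9,
                              gfp_frac = 0.5) {
  stopifnot(all(names(n_mice) %in% GROUPS), all(n_mice >= 0),
            clones_per_mouse > 0, sigma >= 0, depth > 0,
            spike_rate >= 0, spike_rate <= 1,
            donor_frac > 0, donor_frac <= 1, gfp_frac > 0, gfp_frac <= 1,
            flow_kappa > 0, mpp_effect > 0, barcode_length >= 8)
  for (a in archetypes) {
    if (all(a$means == 0)) stop("archetype '", a$name, "' has all-zero means")
    stopifnot(all(a$means >= 0), all(a$weight >= 0))
  }
  for (g in names(n_mice)) {
    w <- sum(vapply(archetypes, function(a) a$weight[[g]], numeric(1L)))
    if (abs(w - 1) > 1e-8) stop("archetype weights for ", g, " must sum to 1")
  }
  structure(list(n_mice = n_mice, clones_per_mouse = clones_per_mouse,
                 archetypes = archetypes, sigma = sigma, depth = depth,
                 flow_kappa = flow_kappa, mpp_effect = mpp_effect,
                 spike_rate = spike_rate, timepoints = timepoints,
                 barcode_length = barcode_length, donor_frac = donor_frac,
                 gfp_frac = gfp_frac),
            class = "simulation_config")
}

# n unique random fixed-length barcodes
random_barcodes <- function(n, len) {
  out <- character(0L)
  while (length(out) < n) {
    need <- n - length(out)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1L))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

# Beta-perturbed fraction with concentration kappa (Inf = exact)
beta_perturb <- function(x, kappa) {
  if (!is.finite(kappa)) return(x)
  ifelse(x <= 0, 0, ifelse(x >= 1, 1,
                           rbeta(length(x), kappa * x, kappa * (1 - x))))
}

#' Generate a complete in-silico barcoding experiment
#'
#' Per mouse, each clone draws an archetype from the group's mixture; its true
#' abundance in every (cell type, timepoint) cell is the archetype mean
#' (after the HSC+MPP late-T multiplier) times independent lognormal noise.
#' Spike artifacts are injected on top. Flow fractions are decomposed from
#' each sample's true total abundance (baseline donor and GFP fractions, the
#' population fraction absorbing the remainder) and perturbed with Beta
#' noise; read counts are multinomial draws from the clones' relative
#' abundances at the configured depth. Fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `clonetrace_sim`: `counts` (barcode count
#'   `SummarizedExperiment`), `flow` (`flow_summary`), and `truth` with
#'   `clones` (per-clone archetype, spike flag and annotated bias/dynamics
#'   classes), `temporal` (per clone and cell type) and `trajectories`
#'   (long-format true abundance before measurement noise).
#' @export
generate_dataset <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  tps <- config$timepoints
  tp_lab <- format(tps, trim = TRUE)
  n_ct <- length(CELL_TYPES)
  n_tp <- length(tps)
  arch <- config$archetypes
  w_mat <- vapply(arch, function(a) a$weight[GROUPS], numeric(length(GROUPS)))
  late <- tps >= 5.5

  mice <- unlist(lapply(names(config$n_mice), function(g) {
    if (config$n_mice[[g]] == 0) return(character(0L))
    setNames(rep(g, config$n_mice[[g]]),
             paste0(g, "_m", seq_len(config$n_mice[[g]])))
  }))
  if (config$depth < config$clones_per_mouse) {
    warning("sequencing depth below the number of clones per mouse")
  }

  clone_rows <- list()
  temporal_rows <- list()
  traj_rows <- list()
  mouse_mats <- list()

  for (mid in names(mice)) {
    grp <- mice[[mid]]
    n <- config$clones_per_mouse
    arch_idx <- sample.int(length(arch), n, replace = TRUE,
                           prob = w_mat[match(grp, GROUPS), ])
    # effective means per archetype for this group
    eff <- lapply(arch, function(a) {
      m <- a$means
      if (grp == "HSC_MPP") {
        m[c("CD4T", "CD8T"), late] <- m[c("CD4T", "CD8T"), late] *
          config$mpp_effect
      }
      m
    })
    means <- t(vapply(arch_idx, function(i) as.vector(eff[[i]]),
                      numeric(n_ct * n_tp)))
    noise <- matrix(exp(rnorm(n * n_ct * n_tp, 0, config$sigma)),
                    nrow = n)
    true_ab <- means * noise

    n_spike <- rbinom(1L, n, config$spike_rate)
    if (n_spike > 0) {
      spike_ab <- matrix(0, n_spike, n_ct * n_tp)
      cells <- sample.int(n_ct * n_tp, n_spike, replace = TRUE)
      spike_ab[cbind(seq_len(n_spike), cells)] <- runif(n_spike, 0.8, 2.0)
      true_ab <- rbind(true_ab, spike_ab)
    }
    bcs <- random_barcodes(n + n_spike, config$barcode_length)
    rownames(true_ab) <- bcs
    mouse_mats[[mid]] <- true_ab

    is_spike <- c(rep(FALSE, n), rep(TRUE, n_spike))
    arch_name <- c(vapply(arch_idx, function(i) arch[[i]]$name,
                          character(1L)),
                   rep("spike_artifact", n_spike))
    clone_rows[[mid]] <- data.frame(
      barcode = bcs, mouse = mid, group = grp, archetype = arch_name,
      is_spike = is_spike,
      lineage_bias = c(vapply(arch_idx,
                              function(i) arch[[i]]$lineage_bias,
                              character(1L)), rep(NA_character_, n_spike)),
      bias_timepoint = c(vapply(arch_idx,
                                function(i) arch[[i]]$bias_timepoint,
                                numeric(1L)), rep(NA_real_, n_spike)),
      dynamics = c(vapply(arch_idx,
                          function(i) as.character(arch[[i]]$dynamics),
                          character(1L)), rep(NA_character_, n_spike)),
      stringsAsFactors = FALSE)

    # temporal truth from the structural zero pattern of the means
    i_early <- which(tps == 2.5)
    i_late <- which(tps == 6.5)
    if (length(i_early) && length(i_late)) {
      pat <- lapply(seq_len(n), function(j) {
        m <- eff[[arch_idx[j]]]
        e <- m[, i_early] > 0
        l <- m[, i_late] > 0
        ifelse(e & l, "persisted", ifelse(e, "early",
                                          ifelse(l, "late", "neither")))
      })
      temporal_rows[[mid]] <- data.frame(
        barcode = rep(bcs[seq_len(n)], each = n_ct), mouse = mid,
        cell_type = rep(CELL_TYPES, n),
        temporal = unlist(pat), stringsAsFactors = FALSE)
    }

    traj_rows[[mid]] <- data.frame(
      barcode = rep(bcs, times = n_ct * n_tp), mouse = mid,
      cell_type = rep(rep(CELL_TYPES, each = nrow(true_ab)), n_tp),
      timepoint = rep(tps, each = nrow(true_ab) * n_ct),
      true_abundance = as.vector(true_ab), stringsAsFactors = FALSE)
  }

  all_barcodes <- unlist(lapply(mouse_mats, rownames), use.names = FALSE)
  # regenerate any cross-mouse collision (vanishingly rare at 27 bp)
  stopifnot(!anyDuplicated(all_barcodes))

  sample_grid <- do.call(rbind, lapply(names(mice), function(mid) {
    expand.grid(mouse = mid, cell_type = CELL_TYPES, timepoint = tps,
                stringsAsFactors = FALSE)
  }))
  sample_grid$group <- mice[sample_grid$mouse]

  counts <- matrix(0L, length(all_barcodes), nrow(sample_grid),
                   dimnames = list(all_barcodes, NULL))
  flow <- sample_grid
  flow$pop_frac_wbc <- NA_real_
  flow$donor_frac <- NA_real_
  flow$gfp_frac <- NA_real_

  for (s in seq_len(nrow(sample_grid))) {
    mid <- sample_grid$mouse[s]
    ct_i <- match(sample_grid$cell_type[s], CELL_TYPES)
    tp_i <- match(sample_grid$timepoint[s], tps)
    ab <- mouse_mats[[mid]][, (tp_i - 1L) * n_ct + ct_i]
    total <- sum(ab)
    donor <- config$donor_frac
    gfp <- config$gfp_frac
    pop <- total / (100 * donor * gfp)
    if (pop > 0.99) {
      warning("sample total abundance exceeds the representable range; ",
              "population fraction capped at 0.99")
      pop <- 0.99
    }
    flow$pop_frac_wbc[s] <- beta_perturb(pop, config$flow_kappa)
    flow$donor_frac[s] <- beta_perturb(donor, config$flow_kappa)
    flow$gfp_frac[s] <- beta_perturb(gfp, config$flow_kappa)
    if (total > 0) {
      reads <- rmultinom(1L, size = config$depth, prob = ab)
      counts[match(rownames(mouse_mats[[mid]]), all_barcodes), s] <- reads
    }
  }

  keys <- format_sample_key(sample_grid$mouse, sample_grid$group,
                            sample_grid$cell_type, sample_grid$timepoint)
  colnames(counts) <- keys
  counts_se <- barcode_count_table(counts)
  flow_df <- flow_summary(flow[c("mouse", "group", "cell_type", "timepoint",
                                 "pop_frac_wbc", "donor_frac", "gfp_frac")])
  truth <- list(
    clones = do.call(rbind, c(clone_rows, list(make.row.names = FALSE))),
    temporal = if (length(temporal_rows)) {
      do.call(rbind, c(temporal_rows, list(make.row.names = FALSE)))
    } else NULL,
    trajectories = do.call(rbind, c(traj_rows, list(make.row.names = FALSE))))
  structure(list(counts = counts_se, flow = flow_df, truth = truth,
                 config = config, seed = seed),
            class = "clonetrace_sim")
}

#' Emit toy FASTQ reads for a barcode count vector
#'
#' Writes `counts[b]` reads per barcode, each `flank + barcode + filler`,
#' with independent per-base substitution errors at `error_rate`. With
#' `error_rate = 0` a round trip through [count_barcodes_from_reads()]
#' recovers the counts exactly.
#'
#' @param counts Named integer vector of reads per barcode, or a
#'   single-sample barcode count `SummarizedExperiment`.
#' @param flank Constant anchor sequence placed 5' of the barcode.
#' @param error_rate Per-base substitution probability (at most 0.1).
#' @param seed Integer seed.
#' @param filler_length Random 3' filler bases per read.
#' @param fastq_path,whitelist_path Optional output files (FASTQ text and
#'   one-barcode-per-line whitelist).
#' @return A list with `reads` (character vector of sequences), `fastq`
#'   (character vector of FASTQ lines) and `whitelist`.
#' @export
generate_toy_reads <- function(counts, flank = "ACGTGACC", error_rate = 0,
                               seed = 1, filler_length = 8,
                               fastq_path = NULL, whitelist_path = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  if (is(counts, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(counts, "counts")
    stopifnot(ncol(m) == 1L)
    counts <- setNames(as.integer(m[, 1L]), rownames(m))
  }
  set.seed(seed)
  whitelist <- names(counts)
  bases <- c("A", "C", "G", "T")
  seqs <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) return(character(0L))
    vapply(seq_len(counts[i]), function(j) {
      filler <- paste(sample(bases, filler_length, replace = TRUE),
                      collapse = "")
      read <- paste0(flank, whitelist[i], filler)
      if (error_rate > 0) {
        chars <- strsplit(read, "")[[1L]]
        hit <- runif(length(chars)) < error_rate
        if (any(hit)) {
          chars[hit] <- vapply(chars[hit], function(b) {
            sample(setdiff(bases, b), 1L)
          }, character(1L))
          read <- paste(chars, collapse = "")
        }
      }
      read
    }, character(1L))
  }))
  fastq <- if (length(seqs)) {
    as.vector(rbind(paste0("@read_", seq_along(seqs)), seqs, "+",
                    strrep("I", nchar(seqs))))
  } else character(0L)
  if (!is.null(fastq_path)) writeLines(fastq, fastq_path)
  if (!is.null(whitelist_path)) writeLines(whitelist, whitelist_path)
  list(reads = seqs, fastq = fastq, whitelist = whitelist)
}

#' Score classifier label recovery against simulation ground truth
#'
#' Compares the classifier output on a (quantified, filtered) abundance
#' matrix with the generator's annotated classes, per label axis. Spike
#' artifacts are excluded; a non-spike clone missing from the abundance
#' matrix (e.g. removed by the artifact filter) counts as a mismatch.
#' Lineage bias is evaluated at each clone's annotated reference timepoint;
#' dynamics only for clones whose archetype has a defined expansion truth.
#'
#' @param sim A `clonetrace_sim` object.
#' @param abundance Clonal abundance `SummarizedExperiment` derived from it.
#' @param params A [bias_parameters()] object.
#' @return Named numeric vector of per-axis agreement fractions
#'   (`lineage_bias`, `temporal`, `dynamics`).
#' @export
label_recovery <- function(sim, abundance, params = bias_parameters()) {
  truth <- sim$truth$clones[!sim$truth$clones$is_spike, , drop = FALSE]
  key <- function(b, m, extra = NULL) {
    if (is.null(extra)) paste(b, m, sep = "\r") else paste(b, m, extra,
                                                           sep = "\r")
  }
  # lineage bias at each clone's annotated reference timepoint
  acc <- c(lineage_bias = NA_real_, temporal = NA_real_,
           dynamics = NA_real_)
  hits <- 0L
  tot <- 0L
  for (tp in unique(truth$bias_timepoint)) {
    sub <- truth[truth$bias_timepoint == tp, , drop = FALSE]
    called <- classify_lineage_bias(abundance, params, tp)
    m <- match(key(sub$barcode, sub$mouse),
               key(called$barcode, called$mouse))
    hits <- hits + sum(called$lineage_bias[m] == sub$lineage_bias,
                       na.rm = TRUE)
    tot <- tot + nrow(sub)
  }
  acc["lineage_bias"] <- hits / tot

  tt <- sim$truth$temporal
  called <- classify_temporal(abundance, params)
  m <- match(key(tt$barcode, tt$mouse, tt$cell_type),
             key(called$barcode, called$mouse, called$cell_type))
  acc["temporal"] <- sum(called$temporal[m] == tt$temporal, na.rm = TRUE) /
    nrow(tt)

  dyn_truth <- truth[!is.na(truth$dynamics) & truth$dynamics != "NA", ,
                     drop = FALSE]
  called <- classify_dynamics(abundance, params)
  hits <- 0L
  tot <- 0L
  for (ct in c("CD4T", "CD8T")) {
    sub <- called[called$cell_type == ct, , drop = FALSE]
    m <- match(key(dyn_truth$barcode, dyn_truth$mouse),
               key(sub$barcode, sub$mouse))
    hits <- hits + sum(sub$dynamics[m] == dyn_truth$dynamics, na.rm = TRUE)
    tot <- tot + nrow(dyn_truth)
  }
  acc["dynamics"] <- hits / tot
  acc
}
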