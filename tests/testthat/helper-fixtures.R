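# In-code fixtures: tiny abundance matrices and simulation configs used
# across the test files.

# Abundance experiment from a long specification; unspecified cells are 0.
# `values` is a data.frame with barcode, cell_type, timepoint, abundance and
# optional mouse/group columns.
toy_abundance <- function(values, mouse = "m1", group = "HSC",
                          timepoints = c(2.5, 6.5),
                          flow = NULL) {
  if (is.null(values$mouse)) values$mouse <- mouse
  if (is.null(values$group)) values$group <- group
  mice <- unique(values[c("mouse", "group")])
  grid <- do.call(rbind, lapply(seq_len(nrow(mice)), function(i) {
    expand.grid(mouse = mice$mouse[i], group = mice$group[i],
                cell_type = cell_types(), timepoint = timepoints,
                stringsAsFactors = FALSE)
  }))
  grid$sample_id <- format_sample_key(grid$mouse, grid$group, grid$cell_type,
                                      grid$timepoint)
  barcodes <- unique(values$barcode)
  m <- matrix(0, length(barcodes), nrow(grid),
              dimnames = list(barcodes, grid$sample_id))
  key <- format_sample_key(values$mouse, values$group, values$cell_type,
                           values$timepoint)
  m[cbind(match(values$barcode, barcodes), match(key, grid$sample_id))] <-
    values$abundance
  clonal_abundance_matrix(m, grid)
}

# Random single-mouse abundance experiment exercising all decision
# boundaries: zeros, sub-floor traces, mid-range values and rare spikes.
random_abundance <- function(n_clones, timepoints = c(2.5, 6.5),
                             mouse = "m1", group = "HSC") {
  n_cells <- 4L * length(timepoints)
  vals <- matrix(0, n_clones, n_cells)
  pick <- matrix(runif(n_clones * n_cells), n_clones)
  vals[pick > 0.45] <- runif(sum(pick > 0.45), 0, 0.08)
  vals[pick > 0.85] <- runif(sum(pick > 0.85), 0.002, 0.02)
  vals[pick > 0.97] <- runif(sum(pick > 0.97), 0.4, 0.8)
  rownames(vals) <- sprintf("BC%03d", seq_len(n_clones))
  grid <- expand.grid(mouse = mouse, group = group, cell_type = cell_types(),
                      timepoint = timepoints, stringsAsFactors = FALSE)
  colnames(vals) <- format_sample_key(grid$mouse, grid$group, grid$cell_type,
                                      grid$timepoint)
  clonal_abundance_matrix(vals, grid)
}

# Small full experiment for pipeline tests (fast to generate).
small_config <- function(...) {
  simulation_config(n_mice = c(HSC = 2L, HSC_MPP = 2L),
                    clones_per_mouse = 60L, ...)
}

# 3-archetype planted-structure configuration for cluster recovery:
# short-term, middle-term and long-term multilineage clones, equal design in
# both groups, multiplier off so exactly three structures exist.
planted3_config <- function(sigma = 0.3) {
  arch <- default_archetypes()[c(1, 2, 3)]
  w <- c(.4, .3, .3)
  for (i in seq_along(arch)) {
    arch[[i]]$weight <- c(HSC = w[i], HSC_MPP = w[i])
  }
  simulation_config(n_mice = c(HSC = 2L, HSC_MPP = 2L),
                    clones_per_mouse = 100L, archetypes = arch,
                    sigma = sigma, spike_rate = 0, mpp_effect = 1)
}

run_quantify <- function(sim) {
  suppressWarnings(compute_clonal_abundance(sim$counts, sim$flow))
}

clone_id <- function(barcode, mouse) paste(barcode, mouse, sep = "\r")
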