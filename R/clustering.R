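#' Build the clone trajectory feature matrix
#'
#' One row per clone (pooled over all mice and both groups), one column per
#' (cell type, timepoint) pair over the requested timepoints, holding
#' log2-normalised abundance `log2(abundance + pseudocount)`. The pseudocount
#' (default 1e-4 %WBC, two decades below the detection floor) keeps
#' undetected cells finite while well separated from detected ones. Clones
#' with zero abundance in every selected cell are dropped (count reported via
#' a message).
#'
#' Column order is fixed and documented: timepoints in the given order, cell
#' types Gr, B, CD4T, CD8T within each timepoint, named `<cell_type>_<tp>`.
#'
#' @param abundance Clonal abundance `SummarizedExperiment`.
#' @param timepoints Timepoints (months) to include; default 2.5, 5.5 and 6.5,
#'   the months analysed throughout (3.5-month samples are redundant with the
#'   adjacent bleeds).
#' @param pseudocount %WBC added before taking log2.
#' @return A list of class `feature_matrix` with `clones` (data frame:
#'   `barcode`, `mouse`, `group`) and `features` (numeric matrix).
#' @export
build_feature_matrix <- function(abundance, timepoints = c(2.5, 5.5, 6.5),
                                 pseudocount = 1e-4) {
  stopifnot(pseudocount > 0)
  meta <- sample_meta(abundance)
  unknown <- setdiff(timepoints, meta$timepoint)
  if (length(unknown)) {
    stop("unknown timepoint(s): ", paste(unknown, collapse = ", "))
  }
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  blocks <- lapply(timepoints, function(tp) {
    m <- ct_matrix_at(long, clones, tp)
    colnames(m) <- paste0(CELL_TYPES, "_", format(tp, trim = TRUE))
    m
  })
  raw <- do.call(cbind, blocks)
  keep <- rowSums(raw) > 0
  if (any(!keep)) {
    message(sum(!keep), " clone(s) undetected in all selected cells dropped")
  }
  features <- log2(raw[keep, , drop = FALSE] + pseudocount)
  structure(list(clones = clones[keep, , drop = FALSE], features = features),
            class = "feature_matrix")
}

#' Principal component scores of clone trajectories
#'
#' Features are centred and unit-variance scaled per column (constant columns
#' are centred only) before the decomposition. With 12 components on the 12
#' trajectory features this is a full-rank rotation that preserves pairwise
#' distances. Component signs are fixed deterministically by making each
#' component's largest-magnitude loading positive.
#'
#' @param features A `feature_matrix` (see [build_feature_matrix()]) or a
#'   plain numeric matrix.
#' @param n_components Number of components to keep (default 12).
#' @param scale. Unit-scale columns before the decomposition.
#' @return Score matrix (clones x `n_components`), components ordered by
#'   decreasing explained variance.
#' @export
run_pca <- function(features, n_components = 12, scale. = TRUE) {
  x <- if (inherits(features, "feature_matrix")) features$features else features
  if (nrow(x) < 2L) stop("need at least 2 clones for PCA")
  if (n_components > ncol(x)) {
    stop("n_components exceeds the number of features")
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  if (isTRUE(scale.)) {
    sds <- apply(x, 2L, sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2L, sds, `/`)
  }
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1L))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  rownames(scores) <- rownames(x)
  scores
}

#' Shared-nearest-neighbor graph over clones
#'
#' Nodes are clones; an edge joins i and j when either is among the other's k
#' nearest neighbours (Euclidean distance in score space). Edge weights are
#' the Jaccard overlap of the two neighbourhoods (each neighbourhood includes
#' the point itself, so k mutual duplicates get weight 1); zero-weight edges
#' are removed.
#'
#' @param scores Numeric matrix of PC scores (clones x components).
#' @param k Neighbourhood size; must satisfy `0 < k < nrow(scores)`.
#' @return An undirected weighted `igraph` graph with one vertex per clone.
#' @export
knn_graph <- function(scores, k = 20) {
  n <- nrow(scores)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of clones")
  d <- as.matrix(dist(scores))
  # k nearest excluding self; ties broken by row order for determinism
  nn_raw <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord[ord != i][seq_len(k)]
  }, integer(k))
  nn <- if (k == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)
  # neighbourhood sets including self, as 0/1 indicator matrix
  ind <- matrix(0L, n, n)
  ind[cbind(rep(seq_len(n), each = k), as.vector(t(nn)))] <- 1L
  diag(ind) <- 1L
  edges <- unique(rbind(
    cbind(rep(seq_len(n), each = k), as.vector(t(nn))),
    cbind(as.vector(t(nn)), rep(seq_len(n), each = k))))
  edges <- edges[edges[, 1L] < edges[, 2L], , drop = FALSE]
  inter <- rowSums(ind[edges[, 1L], , drop = FALSE] *
                     ind[edges[, 2L], , drop = FALSE])
  weight <- inter / (2L * (k + 1L) - inter)
  keep <- weight > 0
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- weight[keep]
  igraph::V(g)$name <- rownames(scores) %||% as.character(seq_len(n))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Louvain community detection on the clone graph
#'
#' Modularity-based (Louvain) community detection with a resolution parameter
#' scaling the null model; isolated vertices become singleton clusters.
#' Cluster ids are 0-based and relabelled by decreasing size (ties by first
#' appearance) so that cluster 0 is always the largest.
#'
#' @param graph An `igraph` graph from [knn_graph()].
#' @param resolution Louvain resolution (default 1.0).
#' @param seed Integer seed fixing the (stochastic) vertex sweep order.
#' @return Named integer vector of 0-based cluster assignments.
#' @export
cluster_graph <- function(graph, resolution = 1.0, seed = 17) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  rank <- rank(-as.numeric(sizes), ties.method = "first")
  relabel <- setNames(as.integer(rank - 1L), names(sizes))
  out <- relabel[as.character(memb)]
  names(out) <- igraph::V(graph)$name
  out
}

#' 2D embedding of clone scores for visualisation
#'
#' UMAP embedding of the PC scores, used for plotting only, never for cluster
#' assignment. Deterministic for a fixed seed (single-threaded optimisation,
#' PCA initialisation).
#'
#' @param scores Numeric matrix of PC scores.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (capped at `nrow - 1`).
#' @return Matrix (clones x 2) of embedding coordinates.
#' @export
embed_2d <- function(scores, seed = 17, n_neighbors = 15) {
  if (nrow(scores) < 3L) stop("need at least 3 clones to embed")
  set.seed(seed)
  coords <- uwot::umap(scores, n_neighbors = min(n_neighbors,
                                                 nrow(scores) - 1L),
                       init = "pca", n_threads = 1, n_sgd_threads = 1)
  rownames(coords) <- rownames(scores)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

#' Categorise clusters by reconstitution timing
#'
#' Per cluster, the fraction of member clones with measurable output (any
#' cell type at or above the detection floor) at each timepoint decides the
#' category by majority: detected at the late reference timepoint is
#' `long_term`; otherwise detected early is `short_term`; otherwise detected
#' at the middle timepoint is `middle_term`. Clusters with no majority
#' anywhere are labelled by their best-detected timepoint.
#'
#' @param abundance Clonal abundance `SummarizedExperiment`.
#' @param assignments Named 0-based cluster vector from [cluster_graph()];
#'   names are clone keys (`barcode\rmouse`) as produced by the pipeline.
#' @param params A [bias_parameters()] object.
#' @param timepoints Timepoints considered (default 2.5, 5.5, 6.5).
#' @return Named character vector: `long_term` / `middle_term` / `short_term`
#'   per cluster id.
#' @export
categorize_clusters <- function(abundance, assignments,
                                params = bias_parameters(),
                                timepoints = c(2.5, 5.5, 6.5)) {
  long <- abundance_long(abundance)
  clones <- clone_table(long)
  ck <- clone_key(clones$barcode, clones$mouse)
  if (!all(names(assignments) %in% ck)) {
    stop("assignments contain clones absent from the abundance matrix")
  }
  det <- vapply(timepoints, function(tp) {
    rowSums(ct_matrix_at(long, clones, tp) >= params$detect_floor) > 0
  }, logical(nrow(clones)))
  det <- matrix(det, nrow = nrow(clones))
  colnames(det) <- format(timepoints, trim = TRUE)
  rownames(det) <- ck
  det <- det[names(assignments), , drop = FALSE]
  early <- format(params$early_timepoint, trim = TRUE)
  late <- format(params$late_timepoint, trim = TRUE)
  middle <- setdiff(colnames(det), c(early, late))
  term_of <- function(rows) {
    f <- colMeans(det[rows, , drop = FALSE])
    if (f[late] >= 0.5) return("long_term")
    if (f[early] >= 0.5) return("short_term")
    if (length(middle) && max(f[middle]) >= 0.5) return("middle_term")
    best <- colnames(det)[which.max(f)]
    if (best == late) "long_term" else if (best == early) "short_term"
    else "middle_term"
  }
  ids <- sort(unique(assignments))
  out <- vapply(ids, function(cid) term_of(which(assignments == cid)),
                character(1L))
  names(out) <- ids
  out
}

#' Cluster clone trajectories end to end
#'
#' Pipeline wrapper: feature matrix, PCA, shared-nearest-neighbor graph,
#' Louvain communities, timing categories, and a 2D embedding for plotting.
#' `k` is capped at `ceiling(n/3)` so small data sets keep local structure.
#'
#' @inheritParams build_feature_matrix
#' @inheritParams cluster_graph
#' @param k Neighbourhood size before capping.
#' @param n_components Principal components retained.
#' @param params A [bias_parameters()] object (detection floor for the timing
#'   categories).
#' @param embed Compute the UMAP embedding (set `FALSE` to skip).
#' @return A list of class `cluster_result`: `clones` data frame with
#'   `cluster` and `term_category` columns, `scores`, `embedding` (or `NULL`),
#'   and `term_category` per cluster.
#' @export
cluster_clones <- function(abundance, k = 20, resolution = 1.0, seed = 17,
                           timepoints = c(2.5, 5.5, 6.5), pseudocount = 1e-4,
                           n_components = 12, params = bias_parameters(),
                           embed = TRUE) {
  fm <- build_feature_matrix(abundance, timepoints, pseudocount)
  rownames(fm$features) <- clone_key(fm$clones$barcode, fm$clones$mouse)
  scores <- run_pca(fm, n_components = min(n_components, ncol(fm$features)))
  n <- nrow(scores)
  k_eff <- max(1L, min(k, ceiling(n / 3)))
  g <- knn_graph(scores, k = k_eff)
  assignments <- cluster_graph(g, resolution = resolution, seed = seed)
  assignments <- assignments[rownames(scores)]
  terms <- categorize_clusters(abundance, assignments, params, timepoints)
  clones <- fm$clones
  clones$cluster <- unname(assignments)
  clones$term_category <- unname(terms[as.character(clones$cluster)])
  embedding <- if (isTRUE(embed)) embed_2d(scores, seed = seed) else NULL
  structure(list(clones = clones, scores = scores, embedding = embedding,
                 term_category = terms, k = k_eff, resolution = resolution,
                 seed = seed),
            class = "cluster_result")
}
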