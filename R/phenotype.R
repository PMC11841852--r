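#' Scale marker intensities for clustering
#'
#' Applies the multiplexed-imaging convention: `arcsinh(x / cofactor)` per
#' marker followed by a z-score across all cells. Zero-variance markers map to
#' all-zeros with a warning rather than NaN.
#'
#' @param cells A cell table, or a numeric cells-x-markers matrix.
#' @param cofactor arcsinh cofactor (default 5).
#' @return List: `scaled` (matrix), `center`, `scale` (per-marker parameters
#'   on the arcsinh scale), `cofactor`.
#' @export
scale_features <- function(cells, cofactor = 5) {
  X <- if (is.data.frame(cells)) {
    panel <- attr(cells, "panel")
    if (is.null(panel))
      tme_stop("tme_validation_error", "cell table lacks a marker panel attribute")
    as.matrix(cells[, unclass(panel), drop = FALSE])
  } else as.matrix(cells)
  if (nrow(X) == 0)
    tme_stop("tme_validation_error", "cannot scale an empty table")
  A <- asinh(X / cofactor)
  ctr <- colMeans(A)
  sdv <- apply(A, 2, sd)
  flat <- !is.finite(sdv) | sdv == 0
  if (any(flat)) {
    tme_warn("zero-variance marker(s) scaled to zero: %s",
             paste(colnames(A)[flat], collapse = ", "))
    sdv[flat] <- 1
    ctr[flat] <- if (nrow(A) > 0) A[1, flat] else 0
  }
  S <- sweep(sweep(A, 2, ctr), 2, sdv, "/")
  list(scaled = S, center = ctr, scale = sdv, cofactor = cofactor)
}

## undirected union kNN graph in scaled space
knn_graph <- function(S, k) {
  n <- nrow(S)
  nn <- RANN::nn2(S, k = k + 1L)$nn.idx[, -1, drop = FALSE]
  el <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  el <- unique(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Cluster cells on a kNN graph with the Leiden algorithm
#'
#' Builds the Euclidean k-nearest-neighbor graph of the scaled matrix and runs
#' Leiden community detection (modularity objective). Clustering operates on
#' the kNN graph, never on a 2-D embedding.
#'
#' @param scaled Cells-x-markers scaled matrix (see [scale_features()]).
#' @param k Neighbors per cell (default 30).
#' @param resolution Leiden resolution (default 0.25; modularity objective on
#'   an unweighted kNN graph, where resolutions near 1 over-partition
#'   geometric graphs).
#' @param seed Integer seed making the partition reproducible.
#' @return Integer vector of 0-based contiguous cluster labels.
#' @export
cluster_cells <- function(scaled, k = 30, resolution = 0.25, seed = 0) {
  n <- nrow(scaled)
  if (n < k + 1)
    tme_stop("tme_parameter_error", "need at least k+1 = %d cells, got %d",
             k + 1, n)
  g <- knn_graph(scaled, k)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 3)
  lab <- as.integer(igraph::membership(cl))
  ## relabel 0-based, ordered by decreasing cluster size (ties by first cell)
  sz <- sort(table(lab), decreasing = TRUE)
  match(lab, as.integer(names(sz))) - 1L
}

#' Mean scaled expression profile per cluster
#'
#' @param scaled Cells-x-markers scaled matrix.
#' @param labels Integer cluster labels (one per row of `scaled`).
#' @return Matrix, non-empty clusters x markers; rownames are cluster labels.
#' @export
compute_cluster_profiles <- function(scaled, labels) {
  if (length(labels) != nrow(scaled))
    tme_stop("tme_validation_error", "labels length must match rows of matrix")
  cl <- sort(unique(labels))
  out <- t(vapply(cl, function(c)
    colMeans(scaled[labels == c, , drop = FALSE]), numeric(ncol(scaled))))
  rownames(out) <- cl
  colnames(out) <- colnames(scaled)
  out
}

#' Annotate clusters against a marker signature
#'
#' Score of cluster c for type t is the mean of `signature(t, m) * profile(c,
#' m)` over the type's nonzero markers; each cluster gets the argmax type when
#' the best score reaches `min_score`, else "Unassigned". Ties go to
#' "Unassigned" with a warning.
#'
#' @param profiles Cluster-x-marker matrix ([compute_cluster_profiles()]).
#' @param signature A [signature_matrix] with markers among the profile
#'   columns.
#' @param min_score Minimum score to assign a type (default 0.1).
#' @return Named character vector: cluster label -> cell-type name.
#' @export
annotate_clusters <- function(profiles, signature, min_score = 0.1) {
  if (nrow(signature) == 0)
    tme_stop("tme_config_error", "empty signature")
  miss <- setdiff(colnames(signature), colnames(profiles))
  if (length(miss))
    tme_stop("tme_config_error", "signature markers not in profiles: %s",
             paste(miss, collapse = ", "))
  P <- profiles[, colnames(signature), drop = FALSE]
  S <- t(unclass(signature))                  # markers x types
  score <- P %*% S
  score <- sweep(score, 2, colSums(S != 0), "/")
  score[!is.finite(score)] <- -Inf
  ann <- vapply(seq_len(nrow(score)), function(i) {
    s <- score[i, ]
    top <- max(s)
    if (top < min_score) return("Unassigned")
    winners <- colnames(score)[s == top]
    if (length(winners) > 1) {
      tme_warn("cluster %s: tied annotation (%s); set to Unassigned",
               rownames(profiles)[i], paste(winners, collapse = ", "))
      return("Unassigned")
    }
    winners
  }, character(1))
  names(ann) <- rownames(profiles)
  ann
}

#' Per-cluster region-mixing entropy (batch-effect check)
#'
#' For each cluster, the Shannon entropy of its region composition normalised
#' by `log(#regions)`, so 1 means cells come evenly from all regions and 0
#' means a single-region cluster. Low values flag region-driven (batch-like)
#' clusters.
#'
#' @param labels Cluster labels (one per cell).
#' @param region_ids Region id per cell.
#' @param flag_below Threshold below which a cluster is flagged.
#' @return `data.frame(cluster, n_cells, entropy, flagged)`.
#' @export
region_mixing_entropy <- function(labels, region_ids, flag_below = 0.5) {
  regions <- unique(region_ids)
  if (length(regions) < 2)
    tme_stop("tme_parameter_error",
             "region mixing entropy needs >= 2 regions; skip this check for single-region data")
  cl <- sort(unique(labels))
  ent <- vapply(cl, function(c) {
    p <- table(region_ids[labels == c])
    p <- p / sum(p)
    -sum(p * log(p)) / log(length(regions))
  }, numeric(1))
  data.frame(cluster = cl,
             n_cells = as.vector(table(factor(labels, levels = cl))),
             entropy = ent,
             flagged = ent < flag_below)
}

#' 2-D UMAP embedding of the scaled matrix (visualisation only)
#'
#' The embedding is never used for clustering decisions; it exists for plots.
#'
#' @param scaled Cells-x-markers scaled matrix.
#' @param seed Integer seed (embedding is deterministic given it).
#' @param n_neighbors UMAP neighborhood size.
#' @return Cells-x-2 numeric matrix.
#' @export
embed_umap <- function(scaled, seed = 0, n_neighbors = 15) {
  if (nrow(scaled) < 10)
    tme_stop("tme_parameter_error", "need at least 10 cells to embed")
  if (!requireNamespace("uwot", quietly = TRUE))
    tme_stop("tme_config_error", "package 'uwot' is required for embed_umap")
  set.seed(seed)
  uwot::umap(scaled, n_neighbors = min(n_neighbors, nrow(scaled) - 1),
             n_threads = 1, n_sgd_threads = 1, batch = TRUE)
}

#' Phenotype a cell table
#'
#' The full phenotyping chain: arcsinh + z-score scaling, kNN-graph Leiden
#' clustering, cluster expression profiles, and signature-based annotation.
#'
#' @inheritParams scale_features
#' @inheritParams cluster_cells
#' @inheritParams annotate_clusters
#' @param signature A [signature_matrix].
#' @return An object of class `phenotype_model`: list with `labels` (per-cell
#'   cluster), `annotation` (cluster -> type), `cell_types` (per-cell type),
#'   `profiles`, scaling parameters and the call parameters. The input table
#'   with a `cell_type` column is in `$cells`.
#' @export
phenotype <- function(cells, signature, cofactor = 5, k = 30,
                      resolution = 0.25, seed = 0, min_score = 0.1) {
  sc <- scale_features(cells, cofactor)
  labels <- cluster_cells(sc$scaled, k = k, resolution = resolution, seed = seed)
  profiles <- compute_cluster_profiles(sc$scaled, labels)
  ann <- annotate_clusters(profiles, signature, min_score = min_score)
  types <- unname(ann[as.character(labels)])
  out_cells <- cells
  out_cells$cell_type <- types
  structure(list(labels = labels, annotation = ann, cell_types = types,
                 profiles = profiles, center = sc$center, scale = sc$scale,
                 cells = out_cells,
                 params = list(cofactor = cofactor, k = k,
                               resolution = resolution, seed = seed,
                               min_score = min_score)),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Phenotype model:", length(x$labels), "cells,",
      nrow(x$profiles), "clusters\n")
  cat("  k =", x$params$k, " resolution =", x$params$resolution,
      " cofactor =", x$params$cofactor, "\n")
  tab <- sort(table(x$cell_types), decreasing = TRUE)
  cat("  cell types:\n")
  for (nm in names(tab))
    cat(sprintf("    %-24s %6d (%5.1f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / length(x$cell_types)))
  invisible(x)
}

#' Heatmap of cluster expression profiles
#'
#' Base-graphics image of the cluster-by-marker mean scaled expression, the
#' standard diagnostic for checking that cluster annotations make sense.
#'
#' @param x A `phenotype_model`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.phenotype_model <- function(x, ...) {
  p <- x$profiles
  lab <- sprintf("%s: %s", rownames(p), x$annotation[rownames(p)])
  op <- graphics::par(mar = c(7, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(p)), seq_len(nrow(p)), t(p),
                  col = grDevices::hcl.colors(50, "Blue-Red 2"),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Cluster expression profiles", ...)
  graphics::axis(1, seq_len(ncol(p)), colnames(p), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(p)), lab, las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' @export
summary.phenotype_model <- function(object, ...) {
  ann <- object$annotation
  tab <- data.frame(cluster = names(ann),
                    n_cells = as.vector(table(factor(object$labels,
                                                     levels = names(ann)))),
                    cell_type = unname(ann))
  tab$share <- tab$n_cells / sum(tab$n_cells)
  tab
}
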