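# Shared fixtures and independent oracles, built in code at test time.

toy_panel <- function() marker_panel(c("m1", "m2"))

# minimal valid cell table (n cells, 2 markers), optionally typed
toy_cells <- function(n = 3, region = "r1", type = NULL) {
  df <- data.frame(cell_id = paste0(region, "_c", seq_len(n)),
                   region_id = region,
                   x = seq_len(n) * 10, y = rep(5, n),
                   m1 = seq_len(n), m2 = rev(seq_len(n)))
  if (!is.null(type)) df$cell_type <- type
  as_cell_table(df, toy_panel())
}

toy_meta <- function(regions = "r1", samples = regions,
                     patients = samples, groups = "WT") {
  as_sample_metadata(data.frame(region_id = regions, sample_id = samples,
                                patient_id = patients, group = groups))
}

# cell table from bare coordinates + types, one region
xy_cells <- function(x, y, type, region = "r1") {
  df <- data.frame(cell_id = sprintf("%s_c%03d", region, seq_along(x)),
                   region_id = region, x = x, y = y,
                   m1 = 1, m2 = 1, cell_type = type)
  as_cell_table(df, toy_panel())
}

# simulate a small typed cohort using ground-truth types (phenotyping skipped)
truth_cohort <- function(config) {
  sim <- simulate_cohort(config, intensities = FALSE)
  cells <- join_cells_metadata(sim$cells, sim$meta)
  cells$cell_type <- sim$truth$cell_types
  list(cells = cells, meta = sim$meta, truth = sim$truth)
}

# Oracle: rasterized-Voronoi adjacency at a fixed pixel resolution.
# Cannot see facets shorter than the pixel scale; tests pair it with a
# facet-length bound for implementation-only edges.
raster_voronoi_pairs <- function(x, y, pad, res = 0.25) {
  gx <- seq(min(x) - pad, max(x) + pad, by = res)
  gy <- seq(min(y) - pad, max(y) + pad, by = res)
  g <- as.matrix(expand.grid(gx, gy))
  own <- RANN::nn2(cbind(x, y), g, k = 1)$nn.idx[, 1]
  m <- matrix(own, nrow = length(gx))
  e <- rbind(cbind(as.vector(m[-nrow(m), ]), as.vector(m[-1, ])),
             cbind(as.vector(m[, -ncol(m)]), as.vector(m[, -1])))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# Exact oracle: clipped-Voronoi facet length of pair (i, j) computed on the
# perpendicular bisector. Every other site k excludes a half-line of the
# bisector (the constraint |p-k|^2 > |p-i|^2 is linear in the bisector
# parameter), and the clipping window bounds it; the facet is the remaining
# interval. Independent of the tessellation library.
bisector_facet_length <- function(x, y, i, j, rw) {
  m <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2)
  d <- c(-(y[j] - y[i]), x[j] - x[i])
  d <- d / sqrt(sum(d^2))
  lo <- -Inf; hi <- Inf
  clip1 <- function(a, b, lo, hi) {
    # a * t + b > 0
    if (abs(a) < 1e-300) { if (b <= 0) return(c(1, 0)) else return(c(lo, hi)) }
    if (a > 0) c(max(lo, -b / a), hi) else c(lo, min(hi, -b / a))
  }
  for (w in list(c(1, 0, -rw[1]), c(-1, 0, rw[2]), c(0, 1, -rw[3]),
                 c(0, -1, rw[4]))) {
    # w1 * px + w2 * py + w3 > 0
    v <- clip1(w[1] * d[1] + w[2] * d[2], w[1] * m[1] + w[2] * m[2] + w[3],
               lo, hi)
    lo <- v[1]; hi <- v[2]
  }
  for (k in seq_along(x)) {
    if (k == i || k == j) next
    a <- 2 * (d[1] * (x[i] - x[k]) + d[2] * (y[i] - y[k]))
    b <- 2 * (m[1] * (x[i] - x[k]) + m[2] * (y[i] - y[k])) +
      x[k]^2 + y[k]^2 - x[i]^2 - y[i]^2
    v <- clip1(a, b, lo, hi)
    lo <- v[1]; hi <- v[2]
    if (lo >= hi) return(0)
  }
  max(hi - lo, 0)
}

# all adjacent pairs by the exact bisector oracle
bisector_adjacency <- function(x, y, rw) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bisector_facet_length(x, y, i, j, rw) > 0)
      out[[length(out) + 1L]] <- c(i, j)
  }
  do.call(rbind, out)
}

# contact-graph edges as sorted index pairs relative to `cells` row order
graph_pairs <- function(graph, cells) {
  i <- match(graph$edges$cell_a, cells$cell_id)
  j <- match(graph$edges$cell_b, cells$cell_id)
  cbind(pmin(i, j), pmax(i, j))
}

pair_key <- function(p) paste(p[, 1], p[, 2])

# Oracle: brute-force nearest-neighbor cross-type distance
bf_nn_dist <- function(fx, fy, tx, ty, exclude_self = FALSE) {
  vapply(seq_along(fx), function(i) {
    d <- sqrt((tx - fx[i])^2 + (ty - fy[i])^2)
    if (exclude_self) d <- d[-i]
    min(d)
  }, numeric(1))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
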