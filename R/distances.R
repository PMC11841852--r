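#' Per-cell nearest-neighbor cross-type distances
#'
#' For every cell of `from_type`, the Euclidean distance to the closest
#' `to_type` cell in the same region (itself excluded for same-type queries).
#' Distances are only computed within a region: tissue-microarray cores are
#' physically separate, so cross-region distances are meaningless. From-cells
#' in a region without any eligible target emit no rows rather than a sentinel
#' value.
#'
#' @param cells Typed cell table (may span several regions; needs `cell_id`,
#'   `region_id`, `x`, `y`, `cell_type`).
#' @param from_type,to_type Cell-type names.
#' @return `data.frame(cell_id, region_id, from_type, to_type, nn_distance)`.
#' @export
nn_cross_distance <- function(cells, from_type, to_type) {
  if (!"cell_type" %in% names(cells))
    tme_stop("tme_validation_error", "cells must carry a cell_type column")
  rows <- list()
  for (r in unique(cells$region_id)) {
    reg <- cells[cells$region_id == r, , drop = FALSE]
    fr <- reg[reg$cell_type == from_type, , drop = FALSE]
    to <- reg[reg$cell_type == to_type, , drop = FALSE]
    if (nrow(fr) == 0 || nrow(to) == 0) next
    same <- from_type == to_type
    if (same && nrow(to) < 2) next
    k <- if (same) 2L else 1L
    nn <- RANN::nn2(as.matrix(to[, c("x", "y")]),
                    as.matrix(fr[, c("x", "y")]),
                    k = min(k, nrow(to)))
    if (same) {
      ## nearest other cell: drop the self match (index, not distance, decides)
      self <- match(fr$cell_id, to$cell_id)
      d <- vapply(seq_len(nrow(fr)), function(i) {
        idx <- nn$nn.idx[i, ]
        dd <- nn$nn.dists[i, ]
        pick <- which(idx != self[i])[1]
        dd[pick]
      }, numeric(1))
    } else {
      d <- nn$nn.dists[, 1]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = fr$cell_id, region_id = r,
      from_type = from_type, to_type = to_type, nn_distance = d)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(), region_id = character(),
                      from_type = character(), to_type = character(),
                      nn_distance = numeric())
  rownames(out) <- NULL
  out
}

#' All-pairs nearest-neighbor distance table
#'
#' @param cells Typed cell table.
#' @param pairs Optional `data.frame(from_type, to_type)`; default all ordered
#'   pairs of observed types (including same-type).
#' @return Row-bound [nn_cross_distance()] tables.
#' @export
nn_distance_table <- function(cells, pairs = NULL) {
  if (is.null(pairs)) {
    ty <- sort(unique(cells$cell_type))
    pairs <- expand.grid(from_type = ty, to_type = ty,
                         stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    nn_cross_distance(cells, pairs$from_type[i], pairs$to_type[i])))
}

#' Per-sample weighted mean nearest-neighbor distances
#'
#' All per-cell distances of a sample's regions are pooled, which equals a
#' mean of region means weighted by per-region from-cell counts.
#'
#' @param distances A [nn_cross_distance()]/[nn_distance_table()] result.
#' @param meta Sample metadata.
#' @return `data.frame(sample_id, from_type, to_type, weighted_mean,
#'   n_from_cells)`.
#' @export
summarize_sample <- function(distances, meta) {
  orphan <- setdiff(unique(distances$region_id), meta$region_id)
  if (length(orphan))
    tme_stop("tme_integrity_error", "regions missing from metadata: %s",
             paste(orphan, collapse = ", "))
  distances$sample_id <- setNames(meta$sample_id,
                                  meta$region_id)[distances$region_id]
  if (nrow(distances) == 0)
    return(data.frame(sample_id = character(), from_type = character(),
                      to_type = character(), weighted_mean = numeric(),
                      n_from_cells = integer()))
  agg <- aggregate(nn_distance ~ sample_id + from_type + to_type,
                   data = distances,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(sample_id = agg$sample_id, from_type = agg$from_type,
                    to_type = agg$to_type,
                    weighted_mean = agg$nn_distance[, "mean"],
                    n_from_cells = as.integer(agg$nn_distance[, "n"]))
  out[order(out$sample_id, out$from_type, out$to_type), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Group-level mean-distance heatmap data
#'
#' Unweighted mean over samples within each group (each sample counts once),
#' per (from, to) pair; pairs missing in a group stay missing.
#'
#' @param summaries A [summarize_sample()] result.
#' @param meta Sample metadata.
#' @return `data.frame(group, from_type, to_type, mean_distance, n_samples)`.
#' @export
group_distance_heatmap <- function(summaries, meta) {
  s2g <- unique(as.data.frame(meta)[, c("sample_id", "group")])
  summaries$group <- setNames(s2g$group, s2g$sample_id)[summaries$sample_id]
  agg <- aggregate(weighted_mean ~ group + from_type + to_type,
                   data = summaries,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(group = agg$group, from_type = agg$from_type,
                    to_type = agg$to_type,
                    mean_distance = agg$weighted_mean[, "mean"],
                    n_samples = as.integer(agg$weighted_mean[, "n"]))
  out[order(out$group, out$from_type, out$to_type), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Compare nearest-neighbor distances across groups
#'
#' Per (from, to) pair, a one-way ANOVA with Tukey post hoc contrasts on the
#' per-sample weighted means (the sample is the unit). A per-cell mode exists
#' behind `unit = "cell"` but is anti-conservative: per-cell units treat
#' thousands of correlated cells as independent observations.
#'
#' @param summaries A [summarize_sample()] result (`unit = "sample"`), or a
#'   raw distance table joined to samples (`unit = "cell"`).
#' @param meta Sample metadata.
#' @param pairs `data.frame(from_type, to_type)`.
#' @param unit `"sample"` (default) or `"cell"`.
#' @return Long result table as in [compare_groups()] plus the pair columns.
#' @export
compare_distances <- function(summaries, meta, pairs,
                              unit = c("sample", "cell")) {
  unit <- match.arg(unit)
  s2g <- unique(as.data.frame(meta)[, c("sample_id", "group")])
  r2g <- setNames(meta$group, meta$region_id)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    fr <- pairs$from_type[i]; to <- pairs$to_type[i]
    sub <- summaries[summaries$from_type == fr & summaries$to_type == to, ]
    if (unit == "cell") {
      ## anti-conservative: every cell treated as an independent observation
      gr <- r2g[sub$region_id]
      gl <- split(sub$nn_distance, gr)
      ok <- length(gl) >= 2 && all(vapply(gl, length, 0L) >= 2)
      if (!ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          from_type = fr, to_type = to, scheme = "three-group", contrast = NA,
          mean_group = NA_real_, mean_rest = NA_real_, statistic = NA_real_,
          df = NA_real_, anova.p = NA_real_, p.value = NA_real_,
          note = "insufficient data")
        next
      }
      res <- anova_tukey(gl)
      for (j in seq_len(nrow(res$tukey))) {
        rows[[length(rows) + 1L]] <- data.frame(
          from_type = fr, to_type = to, scheme = "three-group",
          contrast = paste(res$tukey$group1[j], "vs", res$tukey$group2[j]),
          mean_group = mean(gl[[res$tukey$group1[j]]]),
          mean_rest = mean(gl[[res$tukey$group2[j]]]),
          statistic = res$F, df = res$df[2], anova.p = res$p.value,
          p.value = res$tukey$p.adj[j], note = "ok")
      }
      next
    }
    v <- setNames(sub$weighted_mean, sub$sample_id)
    gr <- setNames(s2g$group, s2g$sample_id)[names(v)]
    if (any(table(factor(gr, levels = unique(s2g$group))) < 2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        from_type = fr, to_type = to, scheme = "three-group", contrast = NA,
        mean_group = NA_real_, mean_rest = NA_real_, statistic = NA_real_,
        df = NA_real_, anova.p = NA_real_, p.value = NA_real_,
        note = "insufficient data")
      next
    }
    m <- matrix(v, ncol = 1, dimnames = list(names(v), "pair"))
    res <- compare_groups(m, meta, scheme = "three-group")
    res$from_type <- fr; res$to_type <- to; res$note <- "ok"
    rows[[length(rows) + 1L]] <-
      res[, c("from_type", "to_type", "scheme", "contrast", "mean_group",
              "mean_rest", "statistic", "df", "anova.p", "p.value", "note")]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Network-plot export of cell-type proximities
#'
#' Nodes are cell types sized by frequency; edges carry the symmetrised mean
#' of the two directed mean distances (both directed values are recorded).
#' Catch-all "Other" types are excluded from the plot data by default.
#'
#' @param summaries A [summarize_sample()] result restricted to (or averaged
#'   over) one unit, or a [group_distance_heatmap()] slice with column
#'   `mean_distance`.
#' @param composition Named frequency vector over cell types for the unit.
#' @param unit Label stored in the export.
#' @param exclude Types excluded from the network (default `"Other"`).
#' @return List (`unit`, `nodes`, `edges`) for a force-layout renderer.
#' @export
network_export <- function(summaries, composition, unit = "all",
                           exclude = "Other") {
  df <- as.data.frame(summaries)
  val <- if ("mean_distance" %in% names(df)) "mean_distance" else "weighted_mean"
  df <- df[!(df$from_type %in% exclude) & !(df$to_type %in% exclude), ]
  composition <- composition[!(names(composition) %in% exclude)]
  composition <- composition[composition > 0]
  nodes <- data.frame(type = names(composition),
                      frequency = as.vector(composition))
  df <- df[df$from_type %in% nodes$type & df$to_type %in% nodes$type, ]
  key <- paste(pmin(df$from_type, df$to_type),
               pmax(df$from_type, df$to_type), sep = "\r")
  edges <- do.call(rbind, lapply(unique(key), function(k) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    fwd <- df[[val]][df$from_type == ab[1] & df$to_type == ab[2]]
    rev <- df[[val]][df$from_type == ab[2] & df$to_type == ab[1]]
    data.frame(type_a = ab[1], type_b = ab[2],
               mean_distance = mean(c(fwd, rev)),
               dist_a_to_b = if (length(fwd)) mean(fwd) else NA_real_,
               dist_b_to_a = if (length(rev)) mean(rev) else NA_real_)
  }))
  if (is.null(edges))
    edges <- data.frame(type_a = character(), type_b = character(),
                        mean_distance = numeric(), dist_a_to_b = numeric(),
                        dist_b_to_a = numeric())
  rownames(edges) <- NULL
  list(unit = unit, nodes = nodes, edges = edges)
}
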