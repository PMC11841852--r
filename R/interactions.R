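#' Build the Voronoi-contact graph of one region
#'
#' Two cells are in contact when their Voronoi cells share a facet after the
#' tessellation is clipped to the region bounding box padded by `pad`, and
#' their centroid distance is at most `2 * cap` (the Voronoi expansion of each
#' cell is capped at `cap` micrometres, roughly a cell radius scale, so sparse
#' regions do not produce spurious long-range contacts). The edge set is a
#' subgraph of the Delaunay triangulation.
#'
#' @param cells Cell table rows of a single region (columns `cell_id`, `x`,
#'   `y`).
#' @param cap Contact radius cap in micrometres (default 15, i.e. max 30 um
#'   centroid separation); `Inf` disables the distance filter.
#' @param pad Clipping pad around the bounding box; defaults to `cap` when
#'   finite, else 15.
#' @param jitter_seed Seed for the deterministic 0.01 um jitter that resolves
#'   duplicate coordinates.
#' @return Object of class `contact_graph`: list with `region_id`, `edges`
#'   (`data.frame(cell_a, cell_b, distance, facet_length)`), `n_cells`, `cap`,
#'   `pad`.
#' @export
build_contact_graph <- function(cells, cap = 15, pad = NULL,
                                jitter_seed = 0) {
  region_id <- if ("region_id" %in% names(cells) && nrow(cells) > 0)
    unique(cells$region_id) else NA_character_
  if (length(region_id) > 1)
    tme_stop("tme_validation_error",
             "build_contact_graph expects a single region, got: %s",
             paste(region_id, collapse = ", "))
  empty <- data.frame(cell_a = character(), cell_b = character(),
                      distance = numeric(), facet_length = numeric())
  if (nrow(cells) < 2) {
    tme_warn("region %s has fewer than 2 cells; empty contact graph", region_id)
    return(structure(list(region_id = region_id, edges = empty,
                          cell_ids = cells$cell_id,
                          n_cells = nrow(cells), cap = cap, pad = pad),
                     class = "contact_graph"))
  }
  x <- cells$x; y <- cells$y
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    tme_warn("region %s: %d duplicate coordinate(s) jittered by 0.01 um",
             region_id, sum(dup))
    set.seed(jitter_seed)
    x[dup] <- x[dup] + rnorm(sum(dup), 0, 0.01)
    y[dup] <- y[dup] + rnorm(sum(dup), 0, 0.01)
  }
  if (is.null(pad)) pad <- if (is.finite(cap)) cap else 15
  rw <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  dd <- deldir::deldir(x, y, rw = rw, suppressMsge = TRUE)
  ds <- dd$dirsgs
  flen <- sqrt((ds$x1 - ds$x2)^2 + (ds$y1 - ds$y2)^2)
  keep <- flen > 0
  i <- pmin(ds$ind1, ds$ind2)[keep]
  j <- pmax(ds$ind1, ds$ind2)[keep]
  fl <- flen[keep]
  ## deldir can emit a facet in several clipped segments; keep one per pair
  key <- paste(i, j)
  first <- !duplicated(key)
  agg_len <- tapply(fl, key, sum)
  i <- i[first]; j <- j[first]
  fl <- as.vector(agg_len[paste(i, j)])
  d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  ok <- d <= 2 * cap
  edges <- data.frame(cell_a = cells$cell_id[i[ok]],
                      cell_b = cells$cell_id[j[ok]],
                      distance = d[ok], facet_length = fl[ok])
  o <- order(edges$cell_a, edges$cell_b)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(region_id = region_id, edges = edges,
                 cell_ids = cells$cell_id, n_cells = nrow(cells),
                 cap = cap, pad = pad),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("Contact graph for region", x$region_id, ":", x$n_cells, "cells,",
      nrow(x$edges), "edges (cap", x$cap, "um)\n")
  invisible(x)
}

#' Type-to-type interaction counts from a contact graph
#'
#' `count(A, B)` is the number of type-A cells with at least one type-B
#' contact (each from-cell counted once per to-type, so the count never
#' exceeds the denominator); `denom(A)` is the number of type-A cells in the
#' region, contacted or not. Same-type pairs use neighbors other than the cell
#' itself (the graph has no self-edges).
#'
#' @param graph A [build_contact_graph()] result.
#' @param cell_types Named character vector: cell_id -> type, covering every
#'   cell of the graph's region (a cohort-wide vector is fine; only the
#'   region's cells enter the counts and denominators).
#' @param types Type universe for the matrix dimensions (default: types seen
#'   in the region).
#' @return List: `counts` (from x to matrix), `denom` (named vector).
#' @export
interaction_counts <- function(graph, cell_types, types = NULL) {
  ids <- graph$cell_ids
  miss <- setdiff(ids, names(cell_types))
  if (length(miss))
    tme_stop("tme_validation_error", "untyped cell(s) in graph: %s",
             paste(head(miss, 5L), collapse = ", "))
  region_types <- cell_types[ids]
  if (is.null(types)) types <- sort(unique(region_types))
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(from = types, to = types))
  denom <- table(factor(region_types, levels = types))
  e <- graph$edges
  if (nrow(e) > 0) {
    nbr <- data.frame(cell = c(e$cell_a, e$cell_b),
                      other = c(e$cell_b, e$cell_a))
    nbr$from_type <- cell_types[nbr$cell]
    nbr$to_type <- cell_types[nbr$other]
    hit <- unique(nbr[, c("cell", "from_type", "to_type")])
    tab <- table(factor(hit$from_type, levels = types),
                 factor(hit$to_type, levels = types))
    counts <- counts + unclass(tab)
  }
  list(counts = counts, denom = as.vector(denom) |> setNames(types))
}

#' Aggregate region interaction counts into per-sample proportions
#'
#' Counts and denominators are summed over all regions of a sample, then the
#' proportion is the pooled ratio (never the mean of per-region proportions).
#' From-types absent from a sample yield no rows (missing, not zero).
#'
#' @param region_counts Named list: region_id -> [interaction_counts()] result.
#' @param meta Sample metadata covering every region.
#' @return Long `data.frame(sample_id, from_type, to_type, count, denom,
#'   proportion)`.
#' @export
aggregate_interactions <- function(region_counts, meta) {
  orphan <- setdiff(names(region_counts), meta$region_id)
  if (length(orphan))
    tme_stop("tme_integrity_error", "regions missing from metadata: %s",
             paste(orphan, collapse = ", "))
  r2s <- setNames(meta$sample_id, meta$region_id)
  types <- sort(unique(unlist(lapply(region_counts,
                                     function(r) rownames(r$counts)))))
  rows <- list()
  for (s in unique(r2s[names(region_counts)])) {
    regs <- names(region_counts)[r2s[names(region_counts)] == s]
    cnt <- matrix(0, length(types), length(types),
                  dimnames = list(types, types))
    den <- setNames(numeric(length(types)), types)
    for (r in regs) {
      rc <- region_counts[[r]]
      cnt[rownames(rc$counts), colnames(rc$counts)] <-
        cnt[rownames(rc$counts), colnames(rc$counts)] + rc$counts
      den[names(rc$denom)] <- den[names(rc$denom)] + rc$denom
    }
    for (a in types[den > 0]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, from_type = a, to_type = types,
        count = cnt[a, ], denom = den[[a]],
        proportion = cnt[a, ] / den[[a]])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), from_type = character(),
                      to_type = character(), count = numeric(),
                      denom = numeric(), proportion = numeric())
  rownames(out) <- NULL
  out
}

#' Chord-diagram export of an interaction matrix
#'
#' Nodes carry the unit's type frequencies (from the interaction
#' denominators); arcs carry the pairwise interaction strength, the mean of
#' the two directed proportions.
#'
#' @param interactions Long table from [aggregate_interactions()].
#' @param unit A `sample_id` present in the table, or `NULL` if the table has
#'   a single unit.
#' @return List (`unit`, `nodes`, `arcs`) ready for JSON serialisation, e.g.
#'   `jsonlite::write_json(x, path, auto_unbox = TRUE)`.
#' @export
chord_export <- function(interactions, unit = NULL) {
  df <- as.data.frame(interactions)
  if (!is.null(unit)) df <- df[df$sample_id == unit, , drop = FALSE]
  else if (length(unique(df$sample_id)) > 1)
    tme_stop("tme_validation_error", "multiple units present; pass `unit`")
  if (nrow(df) == 0)
    return(list(unit = unit, nodes = data.frame(type = character(),
                                                frequency = numeric()),
                arcs = data.frame(type_a = character(), type_b = character(),
                                  strength = numeric())))
  den <- unique(df[, c("from_type", "denom")])
  nodes <- data.frame(type = den$from_type,
                      frequency = den$denom / sum(den$denom))
  prop <- df[!is.na(df$proportion), c("from_type", "to_type", "proportion")]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ks <- unique(key(prop$from_type, prop$to_type))
  arcs <- do.call(rbind, lapply(ks, function(k) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    vals <- prop$proportion[(prop$from_type == ab[1] & prop$to_type == ab[2]) |
                            (prop$from_type == ab[2] & prop$to_type == ab[1])]
    data.frame(type_a = ab[1], type_b = ab[2], strength = mean(vals))
  }))
  rownames(arcs) <- NULL
  list(unit = unit %||% unique(df$sample_id), nodes = nodes, arcs = arcs)
}

#' Compare per-sample interaction proportions across groups
#'
#' Applies the composition test machinery to the per-sample proportion of a
#' chosen (from, to) pair. Samples where the from-type is absent have no
#' defined proportion and are excluded; groups left with fewer than 2 defined
#' samples flag the pair as insufficient data.
#'
#' @param interactions Long table from [aggregate_interactions()].
#' @param meta Sample metadata.
#' @param pairs `data.frame(from_type, to_type)` of pairs to test.
#' @param scheme,group See [compare_groups()].
#' @return Long result table with a `note` column (`"ok"` or
#'   `"insufficient data"`).
#' @export
compare_interactions <- function(interactions, meta, pairs,
                                 scheme = c("one-vs-rest", "three-group"),
                                 group = "FGFR2") {
  scheme <- match.arg(scheme)
  s2g <- unique(as.data.frame(meta)[, c("sample_id", "group")])
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    fr <- pairs$from_type[i]; to <- pairs$to_type[i]
    sub <- interactions[interactions$from_type == fr &
                        interactions$to_type == to &
                        !is.na(interactions$proportion), , drop = FALSE]
    v <- setNames(sub$proportion, sub$sample_id)
    gr <- setNames(s2g$group, s2g$sample_id)[names(v)]
    enough <- if (scheme == "one-vs-rest")
      sum(gr == group) >= 2 && sum(gr != group) >= 2
    else all(table(factor(gr, levels = unique(s2g$group))) >= 2)
    if (!enough) {
      rows[[length(rows) + 1L]] <- data.frame(
        from_type = fr, to_type = to, scheme = scheme, contrast = NA,
        mean_group = NA_real_, mean_rest = NA_real_, statistic = NA_real_,
        df = NA_real_, anova.p = NA_real_, p.value = NA_real_,
        note = "insufficient data")
      next
    }
    m <- matrix(v, ncol = 1, dimnames = list(names(v), "pair"))
    res <- compare_groups(m, meta, scheme = scheme, group = group)
    if (nrow(res) == 0) next
    res$from_type <- fr; res$to_type <- to; res$note <- "ok"
    res$cell_type <- NULL
    rows[[length(rows) + 1L]] <-
      res[, c("from_type", "to_type", "scheme", "contrast", "mean_group",
              "mean_rest", "statistic", "df", "anova.p", "p.value", "note")]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}
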