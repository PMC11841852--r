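#' Per-sample cell-type composition
#'
#' All regions (cores) of a sample are pooled before proportions are computed:
#' the sample, not the core, is the statistical unit. The immune-only level
#' restricts the denominator to the immune type set.
#'
#' @param cells Typed, metadata-joined cell table (must carry `cell_type` and
#'   `sample_id`; see [join_cells_metadata()] and [phenotype()]).
#' @param level `"all"` or `"immune"`.
#' @param immune Character vector of immune type names (used when
#'   `level = "immune"`).
#' @return Matrix of proportions, samples x cell types, each row summing to 1;
#'   samples with zero cells at the chosen level are dropped with a warning.
#' @export
compute_composition <- function(cells, level = c("all", "immune"),
                                immune = immune_types(default_signature())) {
  level <- match.arg(level)
  if (!all(c("cell_type", "sample_id") %in% names(cells)))
    tme_stop("tme_validation_error",
             "cells must carry cell_type and sample_id columns")
  df <- cells
  if (level == "immune") df <- df[df$cell_type %in% immune, , drop = FALSE]
  all_samples <- unique(cells$sample_id)
  tab <- table(factor(df$sample_id, levels = all_samples), df$cell_type)
  tot <- rowSums(tab)
  empty <- tot == 0
  if (any(empty)) {
    tme_warn("dropping %d sample(s) with zero cells at level '%s': %s",
             sum(empty), level, paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
    tot <- tot[!empty]
  }
  out <- sweep(unclass(tab), 1, tot, "/")
  attr(out, "level") <- level
  out
}

#' Welch's unpaired two-sample t test
#'
#' Standard Welch statistic with Welch-Satterthwaite fractional degrees of
#' freedom and a two-sided p from the t distribution.
#'
#' @param x,y Numeric vectors of per-sample values, each of length >= 2.
#' @return List: `statistic` (t), `df`, `p.value`, `means` (group means).
#' @export
welch_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    tme_stop("tme_degenerate_error", "each group needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    tme_stop("tme_degenerate_error", "zero variance in both groups")
  sx <- vx / length(x); sy <- vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p.value = p, means = c(mean(x), mean(y)))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA; all-pairs post hoc comparisons via the
#' Tukey-Kramer studentized-range statistic on the pooled mean squared error.
#'
#' @param groups Named list of numeric vectors (one per group, each n >= 2).
#' @return List: `F`, `df` (c(between, within)), `p.value`, and `tukey` -- a
#'   data.frame with one row per pair (`group1`, `group2`, `diff`, `p.adj`).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2)
    tme_stop("tme_degenerate_error", "need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    tme_stop("tme_degenerate_error", "every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  N <- sum(ns)
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- N - k
  mse <- ssw / df2
  if (ssb == 0 && ssw == 0) {
    Fst <- 0; p <- 1
  } else {
    Fst <- (ssb / df1) / mse
    p <- pf(Fst, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(names(groups), 2)
  tk <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  tk$diff <- means[tk$group2] - means[tk$group1]
  se <- sqrt(mse / 2 * (1 / ns[tk$group1] + 1 / ns[tk$group2]))
  q <- abs(tk$diff) / se
  tk$p.adj <- ifelse(se == 0, ifelse(tk$diff == 0, 1, 0),
                     ptukey(q, nmeans = k, df = df2, lower.tail = FALSE))
  rownames(tk) <- NULL
  list(F = Fst, df = c(df1, df2), p.value = p, tukey = tk)
}

#' Compare cell-type shares (or any per-sample quantity) across groups
#'
#' Scheme `"one-vs-rest"` runs Welch's t test of the named group against all
#' other samples pooled, per cell type; `"three-group"` runs one-way ANOVA with
#' Tukey HSD per cell type. P values are reported raw (a
#' Benjamini-Hochberg-adjusted column is appended but carries no flags).
#'
#' @param comp Samples-x-types proportion matrix ([compute_composition()]), or
#'   any samples-x-variables matrix with sample rownames.
#' @param meta Sample metadata.
#' @param scheme `"one-vs-rest"` or `"three-group"`.
#' @param group Focal group for `"one-vs-rest"` (default `"FGFR2"`).
#' @return Long `data.frame`: one row per cell type (and, for three-group, per
#'   Tukey pair) with means, statistic, df, `p.value` and `p.bh`.
#' @export
compare_groups <- function(comp, meta, scheme = c("one-vs-rest", "three-group"),
                           group = "FGFR2") {
  scheme <- match.arg(scheme)
  s2g <- unique(as.data.frame(meta)[, c("sample_id", "group")])
  gr <- setNames(s2g$group, s2g$sample_id)[rownames(comp)]
  if (anyNA(gr))
    tme_stop("tme_integrity_error", "samples missing from metadata: %s",
             paste(rownames(comp)[is.na(gr)], collapse = ", "))
  rows <- list()
  for (ty in colnames(comp)) {
    v <- comp[, ty]
    if (scheme == "one-vs-rest") {
      res <- tryCatch(welch_two_sample(v[gr == group], v[gr != group]),
                      tme_degenerate_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ty, scheme = scheme, contrast = paste0(group, " vs rest"),
        mean_group = res$means[1], mean_rest = res$means[2],
        statistic = res$statistic, df = res$df, anova.p = NA_real_,
        p.value = res$p.value)
    } else {
      gl <- split(v, gr)
      res <- tryCatch(anova_tukey(gl), tme_degenerate_error = function(e) NULL)
      if (is.null(res)) next
      for (i in seq_len(nrow(res$tukey))) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ty, scheme = scheme,
          contrast = paste(res$tukey$group1[i], "vs", res$tukey$group2[i]),
          mean_group = mean(gl[[res$tukey$group1[i]]]),
          mean_rest = mean(gl[[res$tukey$group2[i]]]),
          statistic = res$F, df = res$df[2], anova.p = res$p.value,
          p.value = res$tukey$p.adj[i])
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p.bh <- p.adjust(out$p.value, "BH")
  rownames(out) <- NULL
  out
}
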