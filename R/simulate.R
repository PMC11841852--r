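#' Configure a synthetic tissue-microarray cohort
#'
#' The generator emulates the study design the analysis assumes: patients in
#' three molecular groups, each contributing one biopsy sample represented by
#' 1-3 circular 0.6 mm cores; cells placed in each core with tumor-nest
#' clustering (Thomas process), optional planted spatial attraction between
#' chosen type pairs, and log-normal marker intensities driven by a
#' signature matrix.
#'
#' @param n_patients Named integer vector: patients per group. Default
#'   `c(FGFR2 = 7, IDH1 = 9, WT = 8)`, the study cohort.
#' @param cores_per_patient Probabilities over 1, 2 and 3 cores per patient.
#'   Core counts are allocated deterministically by largest-remainder quota so
#'   the default `c(12, 10, 2)/24` yields exactly the study design (12 + 20 +
#'   6 = 38 regions over 24 patients).
#' @param core_diameter_um Core diameter in micrometres (default 600).
#' @param cells_per_core Mean cells per core; realized counts are Poisson.
#' @param composition Either a single named proportion vector over cell types
#'   (shared by all groups) or a named list with one vector per group. Each
#'   vector must be non-negative and sum to 1 within 1e-9.
#' @param dirichlet_conc Concentration of the per-sample Dirichlet draw around
#'   the group composition (biological overdispersion); `Inf` disables it.
#' @param nest_spec List: `types` (cell types laid out as Thomas clusters),
#'   `parents_per_core` (mean Poisson parent count), `sigma_nest`
#'   (offspring dispersion, um).
#' @param attraction_spec List of planted attractions, each a list with
#'   `from`, `to`, `rho` (probability in \[0,1\] that a from-cell is placed
#'   near a to-cell), `sigma` (Gaussian offset SD, um) and optional `group`
#'   (restrict the attraction to one molecular group; `NULL` = all).
#' @param signature A [signature_matrix] whose rownames are the cell types.
#' @param delta Log-scale mean shift applied per signature entry (+1 up, -1
#'   down) when sampling intensities.
#' @param sigma_noise Log-scale Gaussian noise SD for intensities.
#' @param base_log Baseline log-intensity.
#' @param min_dist Minimum inter-cell spacing (um), enforced by resampling so
#'   coincident points cannot break the Voronoi dual.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = c(FGFR2 = 7, IDH1 = 9, WT = 8),
                              cores_per_patient = c(12, 10, 2) / 24,
                              core_diameter_um = 600,
                              cells_per_core = 1500,
                              composition = NULL,
                              dirichlet_conc = 150,
                              nest_spec = list(types = "Tumor",
                                               parents_per_core = 8,
                                               sigma_nest = 30),
                              attraction_spec = list(),
                              signature = default_signature(),
                              delta = 2,
                              sigma_noise = 0.5,
                              base_log = 1.5,
                              min_dist = 2,
                              seed = 1) {
  if (is.null(names(n_patients)) || any(n_patients < 1))
    tme_stop("tme_config_error", "n_patients must be a named vector of counts >= 1")
  if (length(cores_per_patient) != 3 || any(cores_per_patient < 0) ||
      abs(sum(cores_per_patient) - 1) > 1e-9)
    tme_stop("tme_config_error", "cores_per_patient must be 3 probabilities summing to 1")
  if (core_diameter_um <= 0)
    tme_stop("tme_config_error", "core_diameter_um must be positive")
  types <- rownames(signature)
  if (is.null(composition))
    composition <- icca_composition(signature)
  if (!is.list(composition))
    composition <- setNames(rep(list(composition), length(n_patients)),
                            names(n_patients))
  missing_g <- setdiff(names(n_patients), names(composition))
  if (length(missing_g))
    tme_stop("tme_config_error", "composition missing for group(s): %s",
             paste(missing_g, collapse = ", "))
  for (g in names(n_patients)) {
    p <- composition[[g]]
    if (is.null(names(p)) || !setequal(names(p), types))
      tme_stop("tme_config_error",
               "composition for group %s must be named over the signature's cell types", g)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      tme_stop("tme_config_error",
               "composition for group %s must be non-negative and sum to 1", g)
    composition[[g]] <- p[types]
  }
  for (a in attraction_spec) {
    if (!all(c("from", "to", "rho", "sigma") %in% names(a)))
      tme_stop("tme_config_error", "attraction entries need from, to, rho, sigma")
    if (a$rho < 0 || a$rho > 1 || a$sigma <= 0)
      tme_stop("tme_config_error", "attraction needs rho in [0,1] and sigma > 0")
    for (ty in c(a$from, a$to)) {
      if (!ty %in% types)
        tme_stop("tme_config_error", "attraction references unknown type: %s", ty)
      gs <- if (is.null(a$group)) names(n_patients) else a$group
      if (any(vapply(gs, function(g) composition[[g]][[ty]], 0) <= 0))
        tme_stop("tme_config_error",
                 "attraction references a type with zero expected count: %s", ty)
    }
  }
  if (sigma_noise < 0 || min_dist < 0 || cells_per_core <= 0)
    tme_stop("tme_config_error", "cells_per_core must be positive; sigma_noise, min_dist non-negative")
  structure(list(n_patients = n_patients,
                 cores_per_patient = cores_per_patient,
                 core_diameter_um = core_diameter_um,
                 cells_per_core = cells_per_core,
                 composition = composition,
                 dirichlet_conc = dirichlet_conc,
                 nest_spec = nest_spec,
                 attraction_spec = attraction_spec,
                 signature = signature,
                 delta = delta, sigma_noise = sigma_noise,
                 base_log = base_log, min_dist = min_dist, seed = seed),
            class = "simulation_config")
}

#' Default cohort-level composition for a packaged signature
#'
#' Proportions chosen to mirror the published cohort-level breakdown (tumor
#' cells ~45%, fibroblasts ~16%, immune cells ~24% of the TME with macrophages
#' the most prevalent immune type, then granulocytes).
#'
#' @param signature A packaged [signature_matrix].
#' @return Named proportion vector over the signature's cell types.
#' @export
icca_composition <- function(signature = default_signature()) {
  types <- rownames(signature)
  if (length(types) == 6) {
    p <- c("Tumor" = 0.45, "Fibroblast" = 0.16, "CD4 T cell" = 0.08,
           "CD8 T cell" = 0.06, "Macrophage" = 0.14, "Granulocyte" = 0.11)
  } else {
    p <- c("Tumor" = 0.451, "Fibroblast" = 0.164, "Endothelial" = 0.055,
           "Nerve" = 0.013, "PanCK+Vimentin+ mixed" = 0.040,
           "HLA-DR+ other" = 0.025, "Other" = 0.010,
           "B cell" = 0.016, "CD4 T cell" = 0.040, "CD8 T cell" = 0.018,
           "Granulocyte" = 0.068, "Macrophage CD68+CD163-" = 0.055,
           "Macrophage CD68+CD163+" = 0.035, "Mast cell" = 0.010)
  }
  if (!setequal(names(p), types))
    tme_stop("tme_config_error",
             "no default composition for this signature; supply one explicitly")
  p <- p[types]
  p / sum(p)
}

## largest-remainder quota: deterministic integer allocation of n patients to
## the 1/2/3-core classes so the default study design is reproduced exactly
quota_alloc <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

## uniform points in a disc of radius r centred at origin
runif_disc <- function(n, r) {
  th <- runif(n, 0, 2 * pi)
  rad <- r * sqrt(runif(n))
  cbind(x = rad * cos(th), y = rad * sin(th))
}

#' Place cells of each type inside one circular core
#'
#' Nest types are laid out as Thomas clusters (Poisson parents in the disc,
#' Gaussian offspring resampled until inside); attracted from-types are placed,
#' with probability `rho`, at a Gaussian offset from a uniformly chosen
#' already-placed to-type cell; all remaining types are uniform in the disc.
#' A minimum spacing is enforced by resampling the later-placed point of any
#' violating pair with its own mechanism.
#'
#' @param n_by_type Named integer vector of cell counts per type.
#' @param diameter Core diameter (um).
#' @param nest_spec,attraction_spec,min_dist See [simulation_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return `data.frame(x, y, type)` with all points inside the disc.
#' @export
place_cells <- function(n_by_type, diameter,
                        nest_spec = list(types = character(), parents_per_core = 8,
                                         sigma_nest = 30),
                        attraction_spec = list(), min_dist = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- diameter / 2
  all_types <- names(n_by_type)
  for (a in attraction_spec) {
    if (!all(c(a$from, a$to) %in% all_types))
      tme_stop("tme_config_error",
               "attraction references a type with zero expected count: %s",
               paste(setdiff(c(a$from, a$to), all_types), collapse = ", "))
  }
  n_by_type <- n_by_type[n_by_type > 0]
  from_types <- intersect(vapply(attraction_spec, `[[`, "", "from"),
                          names(n_by_type))
  first_types <- setdiff(names(n_by_type), from_types)

  ## columns: x, y, type plus the resampling mechanism (anchor + sd; NA = uniform)
  pts <- list()
  add <- function(x, y, type, ax = NA_real_, ay = NA_real_, asd = NA_real_) {
    pts[[length(pts) + 1L]] <<- data.frame(x = x, y = y, type = type,
                                           ax = ax, ay = ay, asd = asd)
  }
  gauss_in_disc <- function(cx, cy, sd) {
    repeat {
      p <- c(cx + rnorm(1, 0, sd), cy + rnorm(1, 0, sd))
      if (sum(p^2) <= r^2) return(p)
    }
  }

  for (ty in first_types) {
    n <- n_by_type[[ty]]
    if (ty %in% (nest_spec$types %||% character())) {
      np <- max(1L, rpois(1, nest_spec$parents_per_core))
      par <- runif_disc(np, r)
      pid <- sample.int(np, n, replace = TRUE)
      xy <- t(vapply(seq_len(n), function(i)
        gauss_in_disc(par[pid[i], 1], par[pid[i], 2], nest_spec$sigma_nest),
        numeric(2)))
      add(xy[, 1], xy[, 2], ty, par[pid, 1], par[pid, 2], nest_spec$sigma_nest)
    } else {
      xy <- runif_disc(n, r)
      add(xy[, 1], xy[, 2], ty)
    }
  }
  placed <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(), y = numeric(), type = character(),
               ax = numeric(), ay = numeric(), asd = numeric())

  for (ty in from_types) {
    a <- attraction_spec[[match(ty, vapply(attraction_spec, `[[`, "", "from"))]]
    n <- n_by_type[[ty]]
    targets <- placed[placed$type == a$to, c("x", "y"), drop = FALSE]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (nrow(targets) > 0 && runif(1) < a$rho) {
        j <- sample.int(nrow(targets), 1)
        p <- gauss_in_disc(targets$x[j], targets$y[j], a$sigma)
        rows[[i]] <- data.frame(x = p[1], y = p[2], type = ty,
                                ax = targets$x[j], ay = targets$y[j],
                                asd = a$sigma)
      } else {
        xy <- runif_disc(1, r)
        rows[[i]] <- data.frame(x = xy[1], y = xy[2], type = ty,
                                ax = NA_real_, ay = NA_real_, asd = NA_real_)
      }
    }
    placed <- rbind(placed, do.call(rbind, rows))
  }

  ## enforce minimum spacing: the later point of a close pair is re-placed
  if (min_dist > 0 && nrow(placed) > 1) {
    for (iter in 1:50) {
      nn <- RANN::nn2(placed[, c("x", "y")], k = min(6L, nrow(placed)))
      viol <- rep(FALSE, nrow(placed))
      for (i in seq_len(nrow(placed))) {
        close <- nn$nn.idx[i, -1][nn$nn.dists[i, -1] < min_dist]
        if (any(close < i)) viol[i] <- TRUE
      }
      if (!any(viol)) break
      for (i in which(viol)) {
        if (is.na(placed$asd[i])) {
          xy <- runif_disc(1, r)
        } else {
          xy <- gauss_in_disc(placed$ax[i], placed$ay[i], placed$asd[i])
        }
        placed$x[i] <- xy[1]; placed$y[i] <- xy[2]
      }
    }
  }
  rownames(placed) <- NULL
  placed[, c("x", "y", "type")]
}

#' Sample marker intensities for ground-truth cell types
#'
#' Log-intensity is `base_log + delta * signature entry + N(0, sigma_noise)`,
#' exponentiated, so intensities are strictly positive and expected-positive
#' markers are shifted up, expected-negative ones down.
#'
#' @param true_types Character vector of per-cell types (rows of `signature`).
#' @param signature A [signature_matrix].
#' @inheritParams simulation_config
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric matrix, cells x markers.
#' @export
sample_marker_intensities <- function(true_types, signature, delta = 2,
                                      sigma_noise = 0.5, base_log = 1.5,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(unique(true_types), rownames(signature))
  if (length(bad))
    tme_stop("tme_config_error", "unknown cell type(s): %s",
             paste(bad, collapse = ", "))
  n <- length(true_types)
  m <- ncol(signature)
  lg <- base_log + delta * unclass(signature)[true_types, , drop = FALSE]
  if (sigma_noise > 0) lg <- lg + matrix(rnorm(n * m, 0, sigma_noise), n, m)
  out <- exp(lg)
  dimnames(out) <- list(NULL, colnames(signature))
  out
}

#' Simulate a complete tissue-microarray cohort
#'
#' @param config A [simulation_config()].
#' @param intensities If `FALSE`, marker intensity sampling is skipped (cells
#'   carry zero intensity columns); useful when only ground-truth types are
#'   needed, e.g. statistical calibration runs.
#' @return List with `cells` (cell table, intensity columns over the signature
#'   markers), `meta` (sample metadata) and `truth` (list: `cell_types` =
#'   per-cell true type aligned with `cells`, `composition` = per-group mean
#'   vectors, `attractions` = planted attraction list).
#' @export
simulate_cohort <- function(config, intensities = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- names(config$n_patients)
  types <- rownames(config$signature)

  ## patients interleaved across groups, then largest-remainder core counts
  pat <- data.frame(patient_id = character(), group = character())
  idx <- lapply(config$n_patients, seq_len)
  for (i in seq_len(max(config$n_patients))) {
    for (g in groups) {
      if (i <= config$n_patients[[g]])
        pat <- rbind(pat, data.frame(patient_id = sprintf("%s_%02d", g, i),
                                     group = g))
    }
  }
  ncls <- quota_alloc(nrow(pat), config$cores_per_patient)
  cores <- rep(c(1L, 2L, 3L), times = ncls)[seq_len(nrow(pat))]
  pat$n_cores <- cores

  meta <- do.call(rbind, lapply(seq_len(nrow(pat)), function(i) {
    data.frame(region_id = sprintf("R%02d_%d", i, seq_len(pat$n_cores[i])),
               sample_id = sprintf("S%02d", i),
               patient_id = pat$patient_id[i],
               group = pat$group[i])
  }))
  meta <- as_sample_metadata(meta, groups = groups)

  ## one Dirichlet composition draw per sample, shared by its cores
  samp <- unique(meta[, c("sample_id", "group")])
  samp_comp <- lapply(seq_len(nrow(samp)), function(i) {
    mu <- config$composition[[samp$group[i]]]
    if (is.finite(config$dirichlet_conc)) {
      p <- rdirichlet1(config$dirichlet_conc * mu)
      names(p) <- names(mu)
      p
    } else mu
  })
  names(samp_comp) <- samp$sample_id

  region_tabs <- vector("list", nrow(meta))
  for (ri in seq_len(nrow(meta))) {
    g <- meta$group[ri]
    p <- samp_comp[[meta$sample_id[ri]]]
    n <- rpois(1, config$cells_per_core)
    cnt <- as.vector(rmultinom(1, n, p))
    names(cnt) <- names(p)
    attr_g <- Filter(function(a) is.null(a$group) || a$group == g,
                     config$attraction_spec)
    placed <- place_cells(cnt, config$core_diameter_um,
                          nest_spec = config$nest_spec,
                          attraction_spec = attr_g,
                          min_dist = config$min_dist, seed = NULL)
    if (nrow(placed) == 0) next
    region_tabs[[ri]] <- data.frame(
      cell_id = sprintf("%s_c%05d", meta$region_id[ri], seq_len(nrow(placed))),
      region_id = meta$region_id[ri],
      x = placed$x, y = placed$y,
      true_type = placed$type)
  }
  cells <- do.call(rbind, region_tabs)
  rownames(cells) <- NULL

  panel <- marker_panel(colnames(config$signature))
  if (intensities) {
    im <- sample_marker_intensities(cells$true_type, config$signature,
                                    delta = config$delta,
                                    sigma_noise = config$sigma_noise,
                                    base_log = config$base_log, seed = NULL)
  } else {
    im <- matrix(0, nrow(cells), length(panel),
                 dimnames = list(NULL, unclass(panel)))
  }
  truth <- list(cell_types = cells$true_type,
                composition = config$composition,
                attractions = config$attraction_spec)
  cells <- cbind(cells[, c("cell_id", "region_id", "x", "y")],
                 as.data.frame(im, check.names = FALSE))
  cells <- as_cell_table(cells, panel)
  list(cells = cells, meta = meta, truth = truth)
}

#' A study-like cohort configuration with planted group differences
#'
#' Convenience wrapper configuring the generator to resemble the study's
#' findings: the FGFR2 group is enriched for granulocytes (and depleted of CD8
#' T cells) with a planted granulocyte-to-tumor spatial attraction; the IDH1
#' group carries extra fibroblasts. Sizes are scaled by `cells_per_core` for
#' desk-scale runs.
#'
#' @param cells_per_core Mean cells per core.
#' @param granulocyte_shift Added granulocyte proportion in the FGFR2 group.
#' @param rho,sigma_attr Attraction strength and offset SD (um) for the FGFR2
#'   granulocyte-tumor attraction.
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
icca_like_config <- function(cells_per_core = 400, granulocyte_shift = 0.12,
                             rho = 0.8, sigma_attr = 10, seed = 1) {
  sig <- default_signature()
  base <- icca_composition(sig)
  fg <- base
  fg["Granulocyte"] <- fg["Granulocyte"] + granulocyte_shift
  fg["CD8 T cell"] <- max(fg["CD8 T cell"] - 0.04, 0.005)
  fg <- fg / sum(fg)
  id <- base
  id["Fibroblast"] <- id["Fibroblast"] + 0.08
  id <- id / sum(id)
  simulation_config(
    composition = list(FGFR2 = fg, IDH1 = id, WT = base),
    cells_per_core = cells_per_core,
    attraction_spec = list(list(from = "Granulocyte", to = "Tumor",
                                rho = rho, sigma = sigma_attr,
                                group = "FGFR2")),
    signature = sig, seed = seed)
}
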