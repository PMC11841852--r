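#' Configure an end-to-end pipeline run
#'
#' Either `simulation` (a [simulation_config()]) or both `cells_path` and
#' `meta_path` must be given. Every stage parameter is recorded in the output
#' manifest so a run is reproducible from it.
#'
#' @param simulation Optional [simulation_config()] for synthetic input.
#' @param cells_path,meta_path CSV inputs when not simulating.
#' @param signature A [signature_matrix].
#' @param cofactor,k,resolution,seed,min_score Phenotyping parameters.
#' @param immune Immune type set for immune-level composition.
#' @param cap Voronoi contact-radius cap (um).
#' @param pairs `data.frame(from_type, to_type)` for interaction/distance
#'   comparisons; `NULL` = all ordered type pairs.
#' @param scheme,focal_group Comparison scheme (see [compare_groups()]).
#' @param out_dir Report directory (created if missing).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, cells_path = NULL,
                            meta_path = NULL, signature = default_signature(),
                            cofactor = 5, k = 30, resolution = 0.25, seed = 0,
                            min_score = 0.1,
                            immune = immune_types(signature),
                            cap = 15, pairs = NULL,
                            scheme = "one-vs-rest", focal_group = "FGFR2",
                            out_dir = tempfile("tme_run_")) {
  if (is.null(simulation) && (is.null(cells_path) || is.null(meta_path)))
    tme_stop("tme_config_error",
             "either a simulation config or cells_path + meta_path is required")
  types <- rownames(signature)
  if (!is.null(pairs)) {
    bad <- setdiff(unique(c(pairs$from_type, pairs$to_type)), types)
    if (length(bad))
      tme_stop("tme_config_error", "pair list references unknown type(s): %s",
               paste(bad, collapse = ", "))
  }
  bad_imm <- setdiff(immune, types)
  if (length(bad_imm))
    tme_stop("tme_config_error", "immune set references unknown type(s): %s",
             paste(bad_imm, collapse = ", "))
  structure(list(simulation = simulation, cells_path = cells_path,
                 meta_path = meta_path, signature = signature,
                 cofactor = cofactor, k = k, resolution = resolution,
                 seed = seed, min_score = min_score, immune = immune,
                 cap = cap, pairs = pairs, scheme = scheme,
                 focal_group = focal_group, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror [pipeline_config()] arguments; a `simulation` block mirrors
#' [simulation_config()] (with `composition` as a per-group mapping and
#' `signature: default` or a CSV path).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sig <- y$signature %||% "default"
  signature <- if (identical(sig, "default")) default_signature()
    else if (identical(sig, "icca")) icca_signature()
    else read_signature(sig)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    args <- s[intersect(names(s),
                        names(formals(simulation_config)))]
    if (!is.null(args$composition))
      args$composition <- lapply(args$composition, unlist)
    if (!is.null(args$n_patients)) args$n_patients <- unlist(args$n_patients)
    if (!is.null(args$cores_per_patient))
      args$cores_per_patient <- unlist(args$cores_per_patient)
    args$signature <- signature
    sim <- do.call(simulation_config, args)
  }
  args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("simulation", "signature")))]
  if (!is.null(args$pairs)) args$pairs <- do.call(rbind, lapply(
    args$pairs, function(p) data.frame(from_type = p$from, to_type = p$to)))
  args$simulation <- sim
  args$signature <- signature
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> phenotype -> composition + group comparisons -> Voronoi
#' interactions + chord exports -> nearest-neighbor distances + network
#' exports, writing every stage output, a JSON manifest and a markdown report
#' into `config$out_dir`. Identical config and seeds give identical outputs.
#' A failing stage aborts with the stage named; partial outputs are kept next
#' to a `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf("[%s] %s", stage, sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  on_fail <- function(e) {
    writeLines(c(paste("failed at stage:", stage), conditionMessage(e)),
               file.path(out, "FAILED"))
    tme_stop("tme_pipeline_error", "pipeline failed at stage '%s': %s",
             stage, conditionMessage(e))
  }
  tryCatch({
    t_start <- Sys.time()
    stage <- "input"
    if (!is.null(config$simulation)) {
      sim <- simulate_cohort(config$simulation)
      cells <- sim$cells; meta <- sim$meta
      write_results(data.frame(cell_id = cells$cell_id,
                               true_type = sim$truth$cell_types),
                    file.path(out, "truth.csv"))
      note("simulated %d cells over %d regions", nrow(cells), nrow(meta))
    } else {
      panel <- marker_panel(colnames(config$signature))
      cells <- read_cell_table(config$cells_path, panel)
      meta <- read_sample_metadata(config$meta_path)
      note("loaded %d cells over %d regions", nrow(cells), nrow(meta))
    }
    cells <- join_cells_metadata(cells, meta)

    stage <- "phenotype"
    ph <- phenotype(cells, config$signature, cofactor = config$cofactor,
                    k = config$k, resolution = config$resolution,
                    seed = config$seed, min_score = config$min_score)
    typed <- ph$cells
    write_results(typed, file.path(out, "cells_typed.csv"))
    write_results(cbind(cluster = rownames(ph$profiles),
                        as.data.frame(ph$profiles)),
                  file.path(out, "profiles.csv"))
    if (length(unique(typed$region_id)) >= 2)
      write_results(region_mixing_entropy(ph$labels, typed$region_id),
                    file.path(out, "entropy.csv"))
    note("%d clusters -> %d cell types", nrow(ph$profiles),
         length(unique(ph$cell_types)))

    stage <- "composition"
    comp_all <- compute_composition(typed, "all", config$immune)
    comp_imm <- compute_composition(typed, "immune", config$immune)
    write_results(cbind(sample_id = rownames(comp_all),
                        as.data.frame(comp_all)),
                  file.path(out, "composition_all.csv"))
    write_results(cbind(sample_id = rownames(comp_imm),
                        as.data.frame(comp_imm)),
                  file.path(out, "composition_immune.csv"))
    cmp <- compare_groups(comp_all, meta, scheme = config$scheme,
                          group = config$focal_group)
    write_results(cmp, file.path(out, "comparisons_composition.csv"))
    note("%d composition comparisons, %d at p<0.05", nrow(cmp),
         sum(cmp$p.value < 0.05, na.rm = TRUE))

    stage <- "interactions"
    ct <- setNames(typed$cell_type, typed$cell_id)
    graphs <- lapply(split(typed, typed$region_id), build_contact_graph,
                     cap = config$cap)
    edges <- do.call(rbind, lapply(graphs, function(g)
      if (nrow(g$edges)) cbind(region_id = g$region_id, g$edges) else NULL))
    if (!is.null(edges))
      write_results(edges, file.path(out, "edges.csv"))
    rc <- lapply(graphs, interaction_counts, cell_types = ct,
                 types = rownames(config$signature))
    inter <- aggregate_interactions(rc, meta)
    write_results(inter, file.path(out, "interactions_sample.csv"))
    gmeta <- meta; gmeta$sample_id <- gmeta$group
    inter_g <- aggregate_interactions(rc, gmeta)
    for (g in unique(meta$group)) {
      ch <- chord_export(inter_g, unit = g)
      jsonlite::write_json(ch, file.path(out, sprintf("chord_%s.json", g)),
                           auto_unbox = TRUE, digits = NA)
    }
    pair_df <- config$pairs %||% {
      ty <- rownames(config$signature)
      expand.grid(from_type = ty, to_type = ty, stringsAsFactors = FALSE)
    }
    cmp_int <- compare_interactions(inter, meta, pair_df,
                                    scheme = config$scheme,
                                    group = config$focal_group)
    write_results(cmp_int, file.path(out, "comparisons_interactions.csv"))
    note("interaction matrices for %d samples", length(unique(inter$sample_id)))

    stage <- "distances"
    dist_tab <- nn_distance_table(typed, config$pairs)
    summ <- summarize_sample(dist_tab, meta)
    write_results(summ, file.path(out, "sample_summaries.csv"))
    heat <- group_distance_heatmap(summ, meta)
    write_results(heat, file.path(out, "group_heatmap.csv"))
    cmp_d <- compare_distances(summ, meta, unique(
      summ[, c("from_type", "to_type")]))
    write_results(cmp_d, file.path(out, "comparisons_distances.csv"))
    for (g in unique(meta$group)) {
      gcells <- typed[typed$group == g, ]
      freq <- table(gcells$cell_type) / nrow(gcells)
      net <- network_export(heat[heat$group == g, ],
                            setNames(as.vector(freq), names(freq)), unit = g)
      jsonlite::write_json(net, file.path(out, sprintf("network_%s.json", g)),
                           auto_unbox = TRUE, digits = NA)
    }
    note("distance summaries for %d pairs",
         nrow(unique(summ[, c("from_type", "to_type")])))

    stage <- "report"
    manifest <- list(
      package_version = as.character(utils::packageVersion("tmespatial")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      simulation_seed = if (!is.null(config$simulation))
        config$simulation$seed else NULL,
      parameters = config[c("cofactor", "k", "resolution", "min_score",
                            "cap", "scheme", "focal_group", "immune")],
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    sig_rows <- cmp[!is.na(cmp$p.value) & cmp$p.value < 0.05, , drop = FALSE]
    report <- c(
      "# Spatial TME analysis report", "",
      sprintf("Cells: %d; regions: %d; samples: %d; groups: %s",
              nrow(typed), length(unique(typed$region_id)),
              length(unique(meta$sample_id)),
              paste(sort(unique(meta$group)), collapse = ", ")), "",
      "## Mean composition (all cells)", "",
      paste0("- ", colnames(comp_all), ": ",
             sprintf("%.1f%%", 100 * colMeans(comp_all))), "",
      "## Significant composition comparisons (p < 0.05, raw)", "",
      if (nrow(sig_rows)) paste0("- ", sig_rows$cell_type, " (",
                                 sig_rows$contrast, "): p = ",
                                 signif(sig_rows$p.value, 3))
      else "- none", "",
      "## Warnings/log", "", paste0("- ", log_lines))
    writeLines(report, file.path(out, "report.md"))
    invisible(out)
  }, error = function(e) {
    if (inherits(e, "tme_pipeline_error")) stop(e)
    on_fail(e)
  })
}
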