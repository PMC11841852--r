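#' Read and validate a segmented single-cell table
#'
#' The cell table is the pipeline's central input: one row per segmented cell
#' with its centroid (micrometres, per-region frame) and one intensity column
#' per panel marker. Extra columns are tolerated (platform exports vary) but
#' warned about and dropped.
#'
#' @param path CSV file with header columns `cell_id`, `region_id`, `x`, `y`
#'   and one column per panel marker.
#' @param panel A [marker_panel].
#' @return A validated cell table: `data.frame` with columns `cell_id`,
#'   `region_id`, `x`, `y`, the panel markers, and (if present in the file)
#'   `cell_type`; the panel is stored in `attr(, "panel")`.
#' @export
read_cell_table <- function(path, panel) {
  df <- read.csv(path, check.names = FALSE)
  as_cell_table(df, panel)
}

#' Validate a data frame as a cell table
#'
#' @param df Data frame in the [read_cell_table] schema.
#' @inheritParams read_cell_table
#' @export
as_cell_table <- function(df, panel) {
  required <- c("cell_id", "region_id", "x", "y")
  missing <- setdiff(c(required, unclass(panel)), names(df))
  if (length(missing))
    tme_stop("tme_schema_error", "cell table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  keep <- c(required, unclass(panel), intersect("cell_type", names(df)))
  extra <- setdiff(names(df), keep)
  if (length(extra))
    tme_warn("ignoring %d unrecognised column(s): %s",
             length(extra), paste(extra, collapse = ", "))
  df <- df[, keep, drop = FALSE]

  if (anyDuplicated(df$cell_id))
    tme_stop("tme_validation_error", "duplicate cell_id(s): %s",
             paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  bad_xy <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad_xy))
    tme_stop("tme_validation_error",
             "non-finite coordinate at row(s): %s",
             paste(head(bad_xy, 5L), collapse = ", "))
  im <- as.matrix(df[, unclass(panel), drop = FALSE])
  if (!is.numeric(im) || anyNA(im) || any(!is.finite(im)))
    tme_stop("tme_validation_error", "non-numeric or missing marker intensity")
  neg <- which(rowSums(im < 0) > 0)
  if (length(neg))
    tme_stop("tme_validation_error", "negative intensity at row(s): %s",
             paste(head(neg, 5L), collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  df$region_id <- as.character(df$region_id)
  attr(df, "panel") <- panel
  df
}

#' Read and validate region-to-sample-to-patient metadata
#'
#' Maps each tissue-microarray region (core) to its sample, patient and
#' molecular group; optional additional columns carry clinical bins (age bin,
#' stage, overall-survival bin, sex, surgery, prior treatment).
#'
#' @param path CSV with columns `region_id`, `sample_id`, `patient_id`,
#'   `group`, plus optional clinical columns.
#' @param groups Allowed group labels (character); defaults to the three
#'   molecular subgroups `FGFR2`, `IDH1`, `WT`.
#' @param aliases Optional named character vector mapping alternative labels to
#'   canonical ones (e.g. `c(Other = "WT")`).
#' @return A validated `data.frame` of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path, groups = c("FGFR2", "IDH1", "WT"),
                                 aliases = NULL) {
  as_sample_metadata(read.csv(path, check.names = FALSE), groups, aliases)
}

#' @rdname read_sample_metadata
#' @param df Data frame in the metadata schema.
#' @export
as_sample_metadata <- function(df, groups = c("FGFR2", "IDH1", "WT"),
                               aliases = NULL) {
  required <- c("region_id", "sample_id", "patient_id", "group")
  missing <- setdiff(required, names(df))
  if (length(missing))
    tme_stop("tme_schema_error", "metadata missing column(s): %s",
             paste(missing, collapse = ", "))
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (!is.null(aliases)) {
    hit <- df$group %in% names(aliases)
    df$group[hit] <- aliases[df$group[hit]]
  }
  if (anyDuplicated(df$region_id))
    tme_stop("tme_integrity_error", "region_id mapped more than once: %s",
             paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), groups)
  if (length(bad))
    tme_stop("tme_validation_error", "unknown group label(s): %s",
             paste(bad, collapse = ", "))
  s2p <- unique(df[, c("sample_id", "patient_id")])
  if (anyDuplicated(s2p$sample_id))
    tme_stop("tme_integrity_error", "sample mapped to more than one patient: %s",
             paste(s2p$sample_id[duplicated(s2p$sample_id)], collapse = ", "))
  p2g <- unique(df[, c("patient_id", "group")])
  if (anyDuplicated(p2g$patient_id))
    tme_stop("tme_integrity_error", "patient assigned to more than one group: %s",
             paste(p2g$patient_id[duplicated(p2g$patient_id)], collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Annotate cells with sample, patient and group
#'
#' @param cells A cell table ([read_cell_table]).
#' @param meta Sample metadata ([read_sample_metadata]).
#' @return `cells` with `sample_id`, `patient_id` and `group` columns appended.
#' @export
join_cells_metadata <- function(cells, meta) {
  orphan <- setdiff(unique(cells$region_id), meta$region_id)
  if (length(orphan))
    tme_stop("tme_integrity_error",
             "region_id(s) absent from metadata: %s",
             paste(orphan, collapse = ", "))
  i <- match(cells$region_id, meta$region_id)
  cells$sample_id <- meta$sample_id[i]
  cells$patient_id <- meta$patient_id[i]
  cells$group <- meta$group[i]
  cells
}

#' Write a tabular result to CSV
#'
#' All pipeline outputs are plain long-format tables; writing then re-reading
#' reproduces the table to 12 significant digits.
#'
#' @param table A data frame.
#' @param path Output CSV path (directory must exist).
#' @export
write_results <- function(table, path) {
  if (!dir.exists(dirname(path)))
    tme_stop("tme_io_error", "output directory does not exist: %s", dirname(path))
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path, check.names = FALSE)
}
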