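#' Construct a marker panel
#'
#' A marker panel is the ordered set of antibody markers measured per cell.
#' Intensity columns of a cell table are validated against it.
#'
#' @param markers Character vector of unique, non-empty marker names.
#' @return An object of class `marker_panel` (a character vector with a class
#'   attribute).
#' @examples
#' marker_panel(c("PanCK", "CD45", "CD8"))
#' @export
marker_panel <- function(markers) {
  markers <- as.character(markers)
  if (length(markers) < 1L)
    tme_stop("tme_config_error", "a marker panel needs at least one marker")
  if (anyNA(markers) || any(!nzchar(markers)))
    tme_stop("tme_config_error", "marker names must be non-empty")
  if (anyDuplicated(markers))
    tme_stop("tme_config_error", "duplicate marker names: %s",
             paste(unique(markers[duplicated(markers)]), collapse = ", "))
  structure(markers, class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel with", length(x), "markers:\n")
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' The 38-marker antibody panel used for intrahepatic cholangiocarcinoma TMAs
#'
#' The full panel covering structural, lymphoid, myeloid and tumor markers,
#' as used on formalin-fixed paraffin-embedded tissue-microarray cores.
#'
#' @return A [marker_panel] of 38 markers.
#' @export
icca_panel <- function() {
  marker_panel(c(
    "AXL", "CD107a", "CD117", "CD11b", "CD134", "CD14", "CD141", "CD15",
    "CD163", "CD183", "CD197", "CD20", "CD21", "CD31", "CD34", "CD3e",
    "CD4", "CD45", "CD45RA", "CD45RO", "CD56", "CD68", "CD8", "GATA3",
    "GranzymeB", "HLA-DR", "ICOS", "IDH1", "PD1", "PDL1", "PGP9.5",
    "PanCK", "Podoplanin", "SPP1", "Siglec8", "Tbet", "Vimentin", "aSMA"
  ))
}

#' Construct a cell-type marker signature matrix
#'
#' Rows are cell types, columns markers; entries are +1 (expected positive),
#' -1 (expected negative) or 0 (uninformative). Used to annotate clusters by
#' their mean scaled expression profile.
#'
#' @param mat Numeric matrix with cell-type rownames and marker colnames,
#'   entries in \{-1, 0, +1\}.
#' @param panel Optional [marker_panel]; if given, signature markers must be a
#'   subset of it.
#' @return A validated matrix of class `signature_matrix`.
#' @export
signature_matrix <- function(mat, panel = NULL) {
  mat <- as.matrix(mat)
  if (length(mat) == 0L || is.null(rownames(mat)) || is.null(colnames(mat)))
    tme_stop("tme_config_error",
             "signature must be a non-empty matrix with cell-type rownames and marker colnames")
  if (anyDuplicated(rownames(mat)))
    tme_stop("tme_config_error", "duplicate cell-type names in signature")
  if (!all(mat %in% c(-1, 0, 1)))
    tme_stop("tme_config_error", "signature entries must be -1, 0 or +1")
  if (any(rowSums(mat != 0) == 0L))
    tme_stop("tme_config_error", "signature rows with no nonzero entry: %s",
             paste(rownames(mat)[rowSums(mat != 0) == 0L], collapse = ", "))
  if (!is.null(panel)) {
    bad <- setdiff(colnames(mat), unclass(panel))
    if (length(bad))
      tme_stop("tme_config_error", "signature markers not in panel: %s",
               paste(bad, collapse = ", "))
  }
  class(mat) <- c("signature_matrix", "matrix", "array")
  mat
}

#' Read a signature matrix from CSV
#'
#' Expects the first column to hold cell-type names and the remaining columns
#' one marker each, with entries -1/0/+1.
#'
#' @inheritParams signature_matrix
#' @param path Path to a CSV file.
#' @return A `signature_matrix`.
#' @export
read_signature <- function(path, panel = NULL) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signature_matrix(m, panel)
}

## small builder used by the packaged signatures
sig_build <- function(types, markers, pos, neg) {
  m <- matrix(0, length(types), length(markers),
              dimnames = list(types, markers))
  for (ty in names(pos)) m[ty, pos[[ty]]] <- 1
  for (ty in names(neg)) m[ty, neg[[ty]]] <- -1
  signature_matrix(m)
}

#' Reduced 12-marker, 6-type signature
#'
#' A compact signature over the major compartments (tumor, fibroblast, CD4 and
#' CD8 T cells, macrophage, granulocyte), the default for simulations and
#' worked examples.
#'
#' @return A `signature_matrix` (6 types x 12 markers).
#' @export
default_signature <- function() {
  markers <- c("PanCK", "Vimentin", "aSMA", "CD45", "CD3e", "CD4", "CD8",
               "CD68", "CD163", "CD11b", "CD15", "CD31")
  sig_build(
    c("Tumor", "Fibroblast", "CD4 T cell", "CD8 T cell",
      "Macrophage", "Granulocyte"),
    markers,
    pos = list(
      "Tumor"       = "PanCK",
      "Fibroblast"  = c("aSMA", "Vimentin"),
      "CD4 T cell"  = c("CD45", "CD3e", "CD4"),
      "CD8 T cell"  = c("CD45", "CD3e", "CD8"),
      "Macrophage"  = c("CD45", "CD68", "CD11b"),
      "Granulocyte" = c("CD45", "CD11b", "CD15")
    ),
    neg = list(
      "Tumor"       = c("CD45", "Vimentin"),
      "Fibroblast"  = c("CD45", "PanCK"),
      "CD4 T cell"  = c("CD8", "PanCK"),
      "CD8 T cell"  = c("CD4", "PanCK"),
      "Macrophage"  = c("CD3e", "PanCK"),
      "Granulocyte" = c("CD68", "PanCK")
    )
  )
}

#' Full 14-type signature over the 38-marker panel
#'
#' Covers the 14 cell types resolved in the cholangiocarcinoma TMA cohort:
#' 7 immune subtypes (B cells, CD4+ and CD8+ T cells, CD11b+/CD15+
#' granulocytes, CD68+/CD163- and CD68+/CD163+ macrophages, CD117+ mast cells)
#' plus tumor, fibroblast, endothelial, nerve cells, two explicit catch-all
#' types (HLA-DR+ other; PanCK+/Vimentin+ mixed) and Other. The exact
#' type-to-marker logic is a package design choice: the platform heatmap it
#' mirrors does not print one.
#'
#' @return A `signature_matrix` (14 types x 38 markers, zero columns included).
#' @export
icca_signature <- function() {
  markers <- unclass(icca_panel())
  sig_build(
    c("Tumor", "Fibroblast", "Endothelial", "Nerve",
      "PanCK+Vimentin+ mixed", "HLA-DR+ other", "Other",
      "B cell", "CD4 T cell", "CD8 T cell", "Granulocyte",
      "Macrophage CD68+CD163-", "Macrophage CD68+CD163+", "Mast cell"),
    markers,
    pos = list(
      "Tumor"                  = "PanCK",
      "Fibroblast"             = c("aSMA", "Vimentin", "Podoplanin"),
      "Endothelial"            = c("CD31", "CD34"),
      "Nerve"                  = "PGP9.5",
      "PanCK+Vimentin+ mixed"  = c("PanCK", "Vimentin"),
      "HLA-DR+ other"          = "HLA-DR",
      "B cell"                 = c("CD20", "CD21", "CD45"),
      "CD4 T cell"             = c("CD3e", "CD4", "CD45"),
      "CD8 T cell"             = c("CD3e", "CD8", "CD45"),
      "Granulocyte"            = c("CD11b", "CD15", "CD45"),
      "Macrophage CD68+CD163-" = c("CD68", "CD14", "CD45"),
      "Macrophage CD68+CD163+" = c("CD68", "CD163", "CD14", "CD45"),
      "Mast cell"              = c("CD117", "Siglec8", "CD45")
    ),
    neg = list(
      "Tumor"                  = c("CD45", "Vimentin", "aSMA"),
      "Fibroblast"             = c("CD45", "PanCK"),
      "Endothelial"            = c("CD45", "PanCK"),
      "Nerve"                  = c("CD45", "PanCK"),
      "PanCK+Vimentin+ mixed"  = "CD45",
      "HLA-DR+ other"          = c("CD68", "CD20", "CD3e", "PanCK"),
      "Other"                  = c("CD45", "PanCK", "Vimentin", "aSMA",
                                   "CD31", "PGP9.5"),
      "B cell"                 = c("CD3e", "PanCK"),
      "CD4 T cell"             = c("CD8", "PanCK"),
      "CD8 T cell"             = c("CD4", "PanCK"),
      "Granulocyte"            = c("CD68", "CD3e", "PanCK"),
      "Macrophage CD68+CD163-" = c("CD163", "CD3e", "PanCK"),
      "Macrophage CD68+CD163+" = c("CD3e", "PanCK"),
      "Mast cell"              = c("CD3e", "CD68", "PanCK")
    )
  )
}

#' Immune cell-type names
#'
#' The immune subset used for immune-only composition denominators.
#'
#' @param signature A `signature_matrix`; the immune subset is returned for the
#'   packaged signatures, or guessed by name for custom ones.
#' @return Character vector of immune type names present in `signature`.
#' @export
immune_types <- function(signature = icca_signature()) {
  full <- c("B cell", "CD4 T cell", "CD8 T cell", "Granulocyte",
            "Macrophage", "Macrophage CD68+CD163-", "Macrophage CD68+CD163+",
            "Mast cell")
  intersect(rownames(signature), full)
}
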