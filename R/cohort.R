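#' Summarise a cohort's clinical bins by group
#'
#' Patient-level counts and percentages per categorical field, the standard
#' demographics table: for each field value, the count of patients per group
#' and the percentage of that group (denominator = group size), rounded to one
#' decimal.
#'
#' @param meta Sample metadata with per-patient clinical columns.
#' @param fields Character vector of clinical columns to tabulate; defaults to
#'   every column beyond the id/group core.
#' @return Long `data.frame(field, value, group, n, pct)`.
#' @export
cohort_summary <- function(meta,
                           fields = setdiff(names(meta),
                                            c("region_id", "sample_id",
                                              "patient_id", "group"))) {
  df <- as.data.frame(meta)
  pat <- unique(df[, c("patient_id", "group", intersect(fields, names(df))),
                   drop = FALSE])
  if (anyDuplicated(pat$patient_id))
    tme_stop("tme_integrity_error",
             "inconsistent clinical values within a patient")
  gsize <- table(pat$group)
  rows <- list()
  for (f in fields) {
    for (v in unique(pat[[f]])) {
      for (g in names(gsize)) {
        n <- sum(pat$group == g & pat[[f]] == v)
        rows[[length(rows) + 1L]] <- data.frame(
          field = f, value = as.character(v), group = g, n = n,
          pct = round(100 * n / gsize[[g]], 1))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall group shares of a cohort
#'
#' @param meta Sample metadata.
#' @return `data.frame(group, n, pct)` over patients, percentages to 1 decimal.
#' @export
group_shares <- function(meta) {
  pat <- unique(as.data.frame(meta)[, c("patient_id", "group")])
  tab <- table(pat$group)
  data.frame(group = names(tab), n = as.vector(tab),
             pct = round(100 * as.vector(tab) / sum(tab), 1))
}

#' Reconstructed 24-patient cholangiocarcinoma cohort metadata (synthetic)
#'
#' Rebuilds a published-style demographic table in code: 7 FGFR2-altered, 9
#' IDH1-mutant and 8 wild-type patients with the printed per-bin counts for
#' age, sex, stage at diagnosis, overall-survival bin, surgical resection and
#' prior treatment, plus the tissue-microarray core design (12 patients with 1
#' core, 10 with 2, 2 with 3 = 38 regions). Which patients fall in which bin
#' jointly, and which carry multiple cores, is not published; those assignments
#' are deterministic package choices, so only the per-bin marginals are
#' faithful.
#'
#' @return A `sample_metadata` data frame (38 region rows) with clinical
#'   columns `age_bin`, `sex`, `stage`, `os_bin`, `surgery`, `prior_treatment`.
#' @export
icca_cohort_metadata <- function() {
  fill <- function(counts) rep(names(counts), times = counts)
  pat <- data.frame(
    patient_id = sprintf("P%02d", 1:24),
    group = c(rep("FGFR2", 7), rep("IDH1", 9), rep("WT", 8)),
    age_bin = c(fill(c("20-40" = 1, "41-60" = 5, "61-80" = 1)),
                fill(c("20-40" = 1, "41-60" = 4, "61-80" = 4)),
                fill(c("20-40" = 1, "41-60" = 4, "61-80" = 3))),
    sex = c(fill(c(M = 5, F = 2)), fill(c(M = 4, F = 5)), fill(c(M = 4, F = 4))),
    stage = c(fill(c(Resectable = 3, `Borderline Resectable` = 1,
                     `Locally Advanced` = 1, Metastatic = 2)),
              fill(c(Resectable = 4, `Locally Advanced` = 2, Metastatic = 3)),
              fill(c(Resectable = 2, `Locally Advanced` = 4, Metastatic = 2))),
    os_bin = c(fill(c("0-2" = 3, "2-4" = 3, "4+" = 1)),
               fill(c("0-2" = 4, "2-4" = 4, "4+" = 1)),
               fill(c("0-2" = 3, "2-4" = 3, "4+" = 2))),
    surgery = c(fill(c(Yes = 6, No = 1)), fill(c(Yes = 6, No = 3)),
                fill(c(Yes = 6, No = 2))),
    prior_treatment = c(fill(c(Yes = 1, No = 6)), fill(c(No = 9)),
                        fill(c(Yes = 1, No = 7))))
  ## core design: 12 x 1, 10 x 2, 2 x 3 cores, assigned by patient order
  n_cores <- rep(c(1L, 2L, 3L), times = c(12L, 10L, 2L))
  meta <- do.call(rbind, lapply(1:24, function(i) {
    k <- seq_len(n_cores[i])
    cbind(data.frame(region_id = sprintf("R%02d_%d", i, k),
                     sample_id = sprintf("S%02d", i)),
          pat[rep(i, length(k)), , drop = FALSE])
  }))
  rownames(meta) <- NULL
  as_sample_metadata(meta)
}
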