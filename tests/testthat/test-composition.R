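test_that("composition pools a sample's regions before taking proportions", {
  cells <- rbind(xy_cells(1:4, rep(1, 4), c("A", "A", "A", "B"), "r1"))
  cells$sample_id <- "s1"
  comp <- compute_composition(cells, "all")
  expect_equal(unname(comp["s1", c("A", "B")]), c(0.75, 0.25))

  # two regions (A:1,B:1) and (A:3,B:3) pool to (0.5, 0.5)
  c2 <- rbind(xy_cells(1:2, c(1, 1), c("A", "B"), "r1"),
              xy_cells(1:6, rep(1, 6), rep(c("A", "B"), 3), "r2"))
  c2$sample_id <- "s1"
  comp2 <- compute_composition(c2, "all")
  expect_equal(unname(comp2["s1", c("A", "B")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(comp2)), 1)
})

test_that("immune-only and all-cells levels are mutually consistent", {
  cfg <- simulation_config(n_patients = c(FGFR2 = 2, IDH1 = 2, WT = 2),
                           cores_per_patient = c(0, 1, 0),
                           cells_per_core = 300, seed = 5)
  co <- truth_cohort(cfg)
  imm <- immune_types(default_signature())
  all_lvl <- compute_composition(co$cells, "all", imm)
  imm_lvl <- compute_composition(co$cells, "immune", imm)
  imm_share <- rowSums(all_lvl[, intersect(colnames(all_lvl), imm)])
  for (ty in colnames(imm_lvl)) {
    expect_equal(imm_lvl[, ty] * imm_share[rownames(imm_lvl)],
                 all_lvl[rownames(imm_lvl), ty], tolerance = 1e-9)
  }
})

test_that("Welch test matches the reference implementation and its identities", {
  # identical groups: t = 0, p = 1 exactly
  r <- welch_two_sample(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_identical(r$statistic, 0)
  expect_identical(r$p.value, 1)

  # cross-check against stats::t.test on 50 random datasets
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    ref <- stats::t.test(x, y)
    got <- welch_two_sample(x, y)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
  }

  # symmetry: swapping negates t, preserves p
  a <- welch_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))
  b <- welch_two_sample(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p.value, b$p.value)

  expect_error(welch_two_sample(c(0, 0), c(1, 1)),
               class = "tme_degenerate_error")
  expect_error(welch_two_sample(1, c(1, 2)), class = "tme_degenerate_error")
})

test_that("ANOVA + Tukey matches aov/TukeyHSD and its identities", {
  # identical groups: F = 0, p = 1, all Tukey p = 1
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anova_tukey(g)
  expect_identical(r$F, 0)
  expect_identical(r$p.value, 1)
  expect_true(all(r$tukey$p.adj == 1))

  # distinct third group: its two contrasts significant, the null one not
  g2 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  r2 <- anova_tukey(g2)
  pa <- setNames(r2$tukey$p.adj,
                 paste(r2$tukey$group1, r2$tukey$group2))
  expect_lt(pa[["a c"]], 0.05)
  expect_lt(pa[["b c"]], 0.05)
  expect_gt(pa[["a b"]], 0.05)

  # reference cross-check on 50 random unbalanced datasets
  set.seed(7)
  for (i in 1:50) {
    gl <- lapply(1:3, function(j) rnorm(sample(3:8, 1), mean = j * runif(1)))
    names(gl) <- c("a", "b", "c")
    got <- anova_tukey(gl)
    df <- data.frame(y = unlist(gl),
                     g = factor(rep(names(gl), lengths(gl))))
    fit <- stats::aov(y ~ g, data = df)
    ref_f <- summary(fit)[[1]]
    expect_equal(got$F, ref_f[["F value"]][1], tolerance = 1e-8)
    expect_equal(got$p.value, ref_f[["Pr(>F)"]][1], tolerance = 1e-8)
    ref_t <- stats::TukeyHSD(fit)$g
    key <- paste(got$tukey$group2, got$tukey$group1, sep = "-")
    expect_equal(unname(got$tukey$p.adj), unname(ref_t[key, "p adj"]),
                 tolerance = 1e-8)
    expect_equal(unname(got$tukey$diff), unname(ref_t[key, "diff"]),
                 tolerance = 1e-8)
  }

  # two groups: F equals the square of the pooled-variance t statistic
  x <- c(1, 3, 5, 7); y <- c(2, 3, 8)
  r3 <- anova_tukey(list(a = x, b = y))
  t_pooled <- stats::t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(r3$F, unname(t_pooled^2), tolerance = 1e-10)

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))),
               class = "tme_degenerate_error")
})

test_that("group comparison table covers both schemes", {
  comp <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), ncol = 1,
                 dimnames = list(paste0("s", 1:6), "A"))
  meta <- toy_meta(paste0("r", 1:6), paste0("s", 1:6), paste0("p", 1:6),
                   rep(c("FGFR2", "IDH1", "WT"), each = 2))
  ovr <- compare_groups(comp, meta, "one-vs-rest", "FGFR2")
  expect_equal(nrow(ovr), 1)           # single cell type -> one row
  expect_equal(ovr$cell_type, "A")
  tg <- compare_groups(comp, meta, "three-group")
  expect_equal(nrow(tg), 3)            # three Tukey pairs
  expect_true(all(tg$p.value >= 0 & tg$p.value <= 1))
})

test_that("cohort summary reproduces the demographic-table arithmetic", {
  meta <- icca_cohort_metadata()
  gs <- group_shares(meta)
  expect_equal(gs$pct[gs$group == "FGFR2"], 29.2)   # 7 / 24
  expect_equal(gs$pct[gs$group == "IDH1"], 37.5)    # 9 / 24
  cs <- cohort_summary(meta)
  a <- cs[cs$field == "age_bin" & cs$value == "41-60", ]
  expect_equal(a$pct[a$group == "FGFR2"], 71.4)     # 5 / 7
  expect_equal(a$n[a$group == "FGFR2"], 5)
  expect_equal(a$pct[a$group == "IDH1"], 44.4)      # 4 / 9
  expect_equal(a$pct[a$group == "WT"], 50.0)        # 4 / 8

  # single-patient group: 100% in its bins
  m1 <- as_sample_metadata(data.frame(region_id = "r1", sample_id = "s1",
                                      patient_id = "p1", group = "WT",
                                      sex = "F"))
  cs1 <- cohort_summary(m1, "sex")
  expect_equal(cs1$pct[cs1$group == "WT"], 100.0)
})
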