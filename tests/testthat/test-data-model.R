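test_that("cell table round-trips through CSV and validates its schema", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(cell_id = c("a", "b", "c"), region_id = "r1",
                   x = c(0, 1.5, 3), y = c(0, 0.5, 1),
                   m1 = c(0.1, 2, 3), m2 = c(5, 0, 1))
  write.csv(df, path, row.names = FALSE)
  ct <- read_cell_table(path, panel)
  expect_equal(nrow(ct), 3)
  expect_equal(ct$cell_id, df$cell_id)          # row order preserved
  expect_equal(as.matrix(ct[, c("m1", "m2")]), as.matrix(df[, c("m1", "m2")]))

  # missing required column named in the error
  write.csv(df[, setdiff(names(df), "y")], path, row.names = FALSE)
  expect_error(read_cell_table(path, panel), "y", class = "tme_schema_error")

  # negative intensity cites the row
  bad <- df; bad$m1[2] <- -1
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_cell_table(path, panel), "2", class = "tme_validation_error")

  # duplicates and non-finite coordinates are typed errors
  dup <- df; dup$cell_id[2] <- "a"
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_cell_table(path, panel), class = "tme_validation_error")
  expect_error(as_cell_table(transform(df, x = c(0, NaN, 3)), panel),
               class = "tme_validation_error")

  # extra columns are warned about and dropped
  extra <- cbind(df, junk = 1)
  expect_warning(ct2 <- as_cell_table(extra, panel), "junk")
  expect_false("junk" %in% names(ct2))
})

test_that("sample metadata validates mappings and group labels", {
  m <- toy_meta(regions = c("r1", "r2", "r3"), samples = c("s1", "s1", "s2"),
                patients = c("p1", "p1", "p2"), groups = c("WT", "WT", "IDH1"))
  expect_s3_class(m, "sample_metadata")

  expect_error(as_sample_metadata(
    data.frame(region_id = c("r1", "r1"), sample_id = c("s1", "s2"),
               patient_id = "p1", group = "WT")),
    "r1", class = "tme_integrity_error")
  expect_error(as_sample_metadata(
    data.frame(region_id = "r1", sample_id = "s1", patient_id = "p1",
               group = "MUTANT")),
    class = "tme_validation_error")
  # alias map folds alternative labels onto canonical ones
  m2 <- as_sample_metadata(
    data.frame(region_id = "r1", sample_id = "s1", patient_id = "p1",
               group = "Other"), aliases = c(Other = "WT"))
  expect_equal(m2$group, "WT")
})

test_that("metadata reproduces the 38-region TMA design", {
  # 24 patients: 12 with one core, 10 with two, 2 with three
  cores <- rep(c(1, 2, 3), times = c(12, 10, 2))
  df <- do.call(rbind, lapply(1:24, function(i)
    data.frame(region_id = sprintf("r%d_%d", i, seq_len(cores[i])),
               sample_id = paste0("s", i), patient_id = paste0("p", i),
               group = c("FGFR2", "IDH1", "WT")[1 + (i %% 3)])))
  m <- as_sample_metadata(df)
  expect_equal(nrow(m), 38)
  expect_equal(length(unique(m$patient_id)), 24)
})

test_that("joining annotates every cell and flags orphans", {
  cells <- rbind(toy_cells(2, "r1"), toy_cells(2, "r2"))
  cells <- as_cell_table(cells, toy_panel())
  meta <- toy_meta(c("r1", "r2", "r3"), c("s1", "s1", "s2"),
                   c("p1", "p1", "p2"), c("WT", "WT", "FGFR2"))
  j <- join_cells_metadata(cells, meta)
  expect_true(all(j$sample_id == "s1"))
  expect_true(all(j$group == "WT"))

  orphan <- toy_cells(2, "r9")
  expect_error(join_cells_metadata(orphan, meta), "r9",
               class = "tme_integrity_error")

  empty <- toy_cells(3)[0, ]
  expect_equal(nrow(join_cells_metadata(empty, meta)), 0)
})

test_that("marker panels and signatures validate and round-trip", {
  expect_length(icca_panel(), 38)
  expect_error(marker_panel(c("a", "a")), class = "tme_config_error")
  expect_error(marker_panel(character()), class = "tme_config_error")

  sig <- icca_signature()
  expect_equal(nrow(sig), 14)
  expect_length(immune_types(sig), 7)
  expect_true(all(rowSums(sig != 0) >= 1))
  expect_true(all(colnames(sig) %in% unclass(icca_panel())))

  # rows with no informative marker are rejected
  expect_error(signature_matrix(rbind(A = c(m1 = 1), B = c(m1 = 0))),
               class = "tme_config_error")
  expect_error(signature_matrix(rbind(A = c(m1 = 2))),
               class = "tme_config_error")
  expect_error(signature_matrix(rbind(A = c(zz = 1)), panel = toy_panel()),
               class = "tme_config_error")

  path <- withr::local_tempfile(fileext = ".csv")
  df <- cbind(data.frame(cell_type = rownames(sig)),
              as.data.frame(unclass(sig), check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  back <- read_signature(path, icca_panel())
  expect_equal(unclass(back), unclass(sig))

  # the full signature annotates noiseless per-type profiles onto themselves
  X <- sample_marker_intensities(rownames(sig), sig, delta = 2,
                                 sigma_noise = 0, seed = 1)
  expect_warning(prof <- scale_features(X)$scaled, "zero-variance")
  rownames(prof) <- rownames(sig)
  ann <- annotate_clusters(prof, sig)
  expect_equal(unname(ann), rownames(sig))
})

test_that("result tables round-trip through write_results at 12 digits", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(sample_id = c("s1", "s2"), from_type = "A", to_type = "B",
                    proportion = c(2 / 3, 1 / 7), count = c(4L, 1L))
  write_results(tab, path)
  back <- read_results(path)
  expect_equal(back$proportion, tab$proportion, tolerance = 1e-11)
  expect_equal(back$count, tab$count)
  expect_identical(names(back), names(tab))

  # empty table -> header only
  write_results(tab[0, ], path)
  expect_equal(nrow(read_results(path)), 0)

  expect_error(write_results(tab, file.path(tempdir(), "no_such_dir", "x.csv")),
               class = "tme_io_error")
})
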