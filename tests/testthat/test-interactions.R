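test_that("contact needs Delaunay adjacency within the distance cap", {
  two <- xy_cells(c(0, 10), c(0, 0), c("A", "B"))
  g <- build_contact_graph(two, cap = 30)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$distance, 10)

  far <- xy_cells(c(0, 100), c(0, 0), c("A", "B"))
  g2 <- build_contact_graph(far, cap = 30)    # 100 > 2 * 30
  expect_equal(nrow(g2$edges), 0)

  expect_warning(g3 <- build_contact_graph(two[1, ], cap = 30), "fewer than 2")
  expect_equal(nrow(g3$edges), 0)

  dup <- xy_cells(c(0, 0, 10), c(0, 0, 0), c("A", "A", "B"))
  expect_warning(g4 <- build_contact_graph(dup, cap = 30), "jitter")
  expect_equal(g4$n_cells, 3)
})

test_that("contact graph is a symmetric subgraph of the Delaunay triangulation", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    cells <- xy_cells(runif(n, 0, 200), runif(n, 0, 200),
                      sample(c("A", "B"), n, TRUE))
    g <- build_contact_graph(cells, cap = 15)
    expect_true(all(g$edges$cell_a != g$edges$cell_b))   # no self-edges
    expect_true(all(g$edges$distance <= 30))
    # subgraph of the full Delaunay edge set
    dd <- deldir::deldir(cells$x, cells$y, suppressMsge = TRUE)$delsgs
    del <- pair_key(unique(cbind(pmin(dd$ind1, dd$ind2),
                                 pmax(dd$ind1, dd$ind2))))
    expect_true(all(pair_key(graph_pairs(g, cells)) %in% del))
    # edge set monotone non-decreasing in cap
    e_small <- pair_key(graph_pairs(build_contact_graph(cells, cap = 8), cells))
    e_big <- pair_key(graph_pairs(g, cells))
    expect_true(all(e_small %in% e_big))
  }
})

test_that("uncapped adjacency matches the raster and exact bisector oracles", {
  # the pixel raster cannot resolve facets shorter than a pixel (and can flip
  # adjacency at near-degenerate vertices); every disagreement must be
  # certified sub-pixel by the exact bisector oracle
  for (s in 1:6) {
    set.seed(100 + s)
    n <- sample(30:50, 1)
    cells <- xy_cells(runif(n, 0, 200), runif(n, 0, 200), rep("A", n))
    g <- build_contact_graph(cells, cap = Inf, pad = 15)
    impl <- pair_key(graph_pairs(g, cells))
    rw <- c(min(cells$x) - 15, max(cells$x) + 15,
            min(cells$y) - 15, max(cells$y) + 15)
    exact <- pair_key(bisector_adjacency(cells$x, cells$y, rw))
    expect_true(setequal(impl, exact))
    oracle <- pair_key(raster_voronoi_pairs(cells$x, cells$y, pad = 15))
    for (e in setdiff(impl, oracle)) {      # raster missed a short facet
      ij <- as.integer(strsplit(e, " ")[[1]])
      expect_lt(bisector_facet_length(cells$x, cells$y, ij[1], ij[2], rw),
                0.25 * sqrt(2))
    }
    expect_true(all(setdiff(oracle, impl) %in% setdiff(oracle, exact)))
  }
})

test_that("interaction counts are cell-level, bounded by denominators", {
  # triangle A-B-A, all pairwise adjacent (exhaustively enumerable):
  # count(A,B) = 2, count(B,A) = 1, count(A,A) = 2
  tri <- xy_cells(c(0, 10, 5), c(0, 0, 8), c("A", "B", "A"))
  g <- build_contact_graph(tri, cap = 30)
  expect_equal(nrow(g$edges), 3)
  ic <- interaction_counts(g, setNames(tri$cell_type, tri$cell_id))
  expect_equal(ic$counts["A", "B"], 2L)
  expect_equal(ic$counts["B", "A"], 1L)
  expect_equal(ic$counts["A", "A"], 2L)
  expect_equal(unname(ic$denom[c("A", "B")]), c(2L, 1L))
  expect_true(all(ic$counts <= matrix(ic$denom, 2, 2)))

  # no type-B cells: count(A,B) = 0 for all A
  ic2 <- interaction_counts(g, setNames(rep("A", 3), tri$cell_id),
                            types = c("A", "B"))
  expect_true(all(ic2$counts[, "B"] == 0))
  # fully connected same-type square: count(A,A) = 4
  sq <- xy_cells(c(0, 10, 0, 10), c(0, 0, 10, 10), rep("A", 4))
  g3 <- build_contact_graph(sq, cap = 30)
  ic3 <- interaction_counts(g3, setNames(sq$cell_type, sq$cell_id))
  expect_equal(ic3$counts["A", "A"], 4L)
})

test_that("sample aggregation pools counts, never averages proportions", {
  rc <- list(
    r1 = list(counts = matrix(1L, 1, 1, dimnames = list("A", "A")),
              denom = c(A = 2)),
    r2 = list(counts = matrix(3L, 1, 1, dimnames = list("A", "A")),
              denom = c(A = 4)))
  meta <- toy_meta(c("r1", "r2"), c("s1", "s1"), c("p1", "p1"),
                   c("WT", "WT"))
  agg <- aggregate_interactions(rc, meta)
  expect_equal(agg$proportion, 4 / 6)   # not mean(0.5, 0.75)

  # single-region sample equals the region-level proportion
  agg1 <- aggregate_interactions(rc["r1"], meta[meta$region_id == "r1", ])
  expect_equal(agg1$proportion, 0.5)

  # a sample with zero from-cells of a type has no row for it
  rc$r1$denom <- c(A = 0); rc$r1$counts[] <- 0L
  rc$r2$denom <- c(A = 0); rc$r2$counts[] <- 0L
  agg0 <- aggregate_interactions(rc, meta)
  expect_equal(nrow(agg0), 0)
})

test_that("chord export averages the two directions and carries frequencies", {
  df <- data.frame(sample_id = "s1",
                   from_type = c("A", "A", "B", "B"),
                   to_type = c("A", "B", "A", "B"),
                   count = c(0, 4, 6, 0), denom = c(10, 10, 10, 10),
                   proportion = c(0, 0.4, 0.6, 0))
  ch <- chord_export(df, "s1")
  arc <- ch$arcs[ch$arcs$type_a == "A" & ch$arcs$type_b == "B", ]
  expect_equal(arc$strength, 0.5)
  expect_equal(ch$nodes$frequency, c(0.5, 0.5))
  empty <- chord_export(df[0, ], "s1")
  expect_equal(nrow(empty$arcs), 0)
})

test_that("interaction comparisons flag pairs with insufficient data", {
  cfg <- icca_like_config(cells_per_core = 150, seed = 2)
  co <- truth_cohort(cfg)
  graphs <- lapply(split(co$cells, co$cells$region_id), build_contact_graph,
                   cap = 15)
  ct <- setNames(co$cells$cell_type, co$cells$cell_id)
  rc <- lapply(graphs, interaction_counts, cell_types = ct,
               types = rownames(default_signature()))
  inter <- aggregate_interactions(rc, co$meta)
  expect_true(all(inter$proportion >= 0 & inter$proportion <= 1, na.rm = TRUE))
  expect_equal(inter$proportion, inter$count / inter$denom)

  pairs <- data.frame(from_type = c("Granulocyte", "Granulocyte"),
                      to_type = c("Tumor", "NoSuchType"))
  res <- compare_interactions(inter, co$meta, pairs, "one-vs-rest", "FGFR2")
  ok <- res[res$to_type == "Tumor", ]
  expect_equal(ok$note, "ok")
  expect_lt(ok$p.value, 0.05)          # planted FGFR2 attraction detected
  expect_gt(ok$mean_group, ok$mean_rest)
  expect_equal(res$note[res$to_type == "NoSuchType"], "insufficient data")
})
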