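test_that("Delaunay nearest neighbors respect the geometry of a square", {
  cc <- fake_called(paste0("c", 1:4), rep("A", 4), "A",
                    x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  g <- build_graph(cc)
  expect_true(g$delaunay)
  expect_equal(g$nn$distance, rep(1, 4))  # sides, not the diagonal
  # Delaunay edge set is symmetric with no self loops
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
})

test_that("collinear points fall back to direct nearest-neighbor search", {
  cc <- fake_called(paste0("c", 1:3), rep("A", 3), "A",
                    x = c(0, 1, 3), y = c(0, 0, 0))
  expect_warning(g <- build_graph(cc), "collinear|triangulation")
  expect_false(g$delaunay)
  expect_equal(g$nn$nn_index, c(2, 1, 2))
  expect_equal(g$nn$distance, c(1, 1, 2))
})

test_that("graph nearest neighbors match the brute-force oracle", {
  set.seed(55)
  for (n in c(50, 500)) {
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    cc <- fake_called(paste0("c", 1:n), rep("A", n), "A", x = x, y = y)
    g <- build_graph(cc)
    orc <- nn_oracle(x, y)
    expect_identical(g$nn$nn_index, orc$index)
    expect_equal(g$nn$distance, orc$distance, tolerance = 1e-12)
  }
})

test_that("voronoi tiles are returned clipped to the window", {
  set.seed(2)
  n <- 40
  cc <- fake_called(paste0("c", 1:n), rep("A", n), "A",
                    x = runif(n, 0, 100), y = runif(n, 0, 100))
  clip <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  g <- build_graph(cc, clip = clip, compute_voronoi = TRUE)
  expect_length(g$voronoi, n)
  areas <- vapply(g$voronoi, polygon_area, numeric(1))
  # tiles tessellate the clip window
  expect_equal(sum(areas), 100 * 100, tolerance = 0.01)
  expect_true(all(vapply(g$voronoi, function(p)
    all(p[, 1] >= -1e-6 & p[, 1] <= 100 + 1e-6), logical(1))))
})

test_that("duplicate coordinates are rejected", {
  cc <- fake_called(c("a", "b", "c"), rep("A", 3), "A",
                    x = c(0, 0, 1), y = c(0, 0, 1))
  expect_error(build_graph(cc), "duplicate")
})

test_that("nearest-neighbor composition rows are percentages summing to 100", {
  # alternating two-type 1-D lattice: every nearest neighbor is the other type
  n <- 20
  cc <- fake_called(paste0("c", 1:n), rep(c("A", "B"), n / 2), c("A", "B"),
                    x = seq_len(n), y = rep(0, n))
  g <- suppressWarnings(build_graph(cc))
  comp <- nn_composition(g, setNames(cc$called_type, cc$cell_id))
  expect_equal(unname(comp["A", "B"]), 100)
  expect_equal(unname(comp["B", "A"]), 100)
  # single-type map: all mass on the diagonal
  cc2 <- fake_called(paste0("c", 1:4), rep("A", 4), "A",
                     x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  comp2 <- nn_composition(build_graph(cc2),
                          setNames(cc2$called_type, cc2$cell_id))
  expect_equal(unname(comp2["A", "A"]), 100)
  # absent type flagged
  comp3 <- suppressWarnings(nn_composition(
    build_graph(cc2), setNames(cc2$called_type, cc2$cell_id),
    types = c("A", "Z")))
  expect_true(all(is.na(comp3["Z", ])))
  expect_identical(attr(comp3, "undefined"), "Z")
})

test_that("well-mixed labels split nearest neighbors evenly", {
  set.seed(23)
  n <- 2000
  cc <- fake_called(paste0("c", 1:n),
                    sample(rep(c("A", "B"), n / 2)), c("A", "B"),
                    x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  g <- build_graph(cc)
  comp <- nn_composition(g, setNames(cc$called_type, cc$cell_id))
  expect_true(all(abs(comp - 50) <= 5))
  expect_equal(unname(rowSums(comp)), c(100, 100))
})

test_that("mean distance to the most prevalent neighbor follows the map", {
  # regular grid, one type: every nearest neighbor sits one spacing away
  gr <- expand.grid(x = seq(0, 180, by = 20), y = seq(0, 180, by = 20))
  cc <- fake_called(paste0("c", seq_len(nrow(gr))), rep("A", nrow(gr)),
                    "A", x = gr$x, y = gr$y)
  nnd <- nn_mean_distance(build_graph(cc),
                          setNames(cc$called_type, cc$cell_id))
  expect_equal(nnd$mean_distance, 20)
  expect_identical(nnd$nn_type, "A")
  # two tight clusters of different types 1000 um apart
  set.seed(4)
  ax <- runif(30, 0, 50); ay <- runif(30, 0, 50)
  bx <- runif(30, 1000, 1050); by <- runif(30, 0, 50)
  cc2 <- fake_called(paste0("c", 1:60), rep(c("A", "B"), each = 30),
                     c("A", "B"), x = c(ax, bx), y = c(ay, by))
  nnd2 <- nn_mean_distance(build_graph(cc2),
                           setNames(cc2$called_type, cc2$cell_id))
  expect_identical(nnd2$nn_type, c("A", "B"))  # homotypic within clusters
  expect_true(all(nnd2$mean_distance < 50))
})

test_that("permutation enrichment flags planted segregation, not null maps", {
  set.seed(61)
  # segregated blocks
  n <- 150
  cc <- fake_called(paste0("c", 1:(2 * n)), rep(c("A", "B"), each = n),
                    c("A", "B"),
                    x = c(runif(n, 0, 400), runif(n, 600, 1000)),
                    y = runif(2 * n, 0, 400))
  g <- build_graph(cc)
  labs <- setNames(cc$called_type, cc$cell_id)
  enr <- enrichment_test(g, labs, n_permutations = 1000, seed = 5)
  expect_gt(enr$z["A", "A"], 3)
  expect_gt(enr$z["B", "B"], 3)
  expect_lt(enr$p["A", "A"], 0.01)
  expect_lt(enr$p["B", "B"], 0.01)
  # determinism
  enr2 <- enrichment_test(g, labs, n_permutations = 1000, seed = 5)
  expect_identical(enr$p, enr2$p)
  expect_identical(enr$z, enr2$z)
})

test_that("single-type maps give a degenerate null with p = 1", {
  set.seed(7)
  cc <- fake_called(paste0("c", 1:30), rep("A", 30), "A",
                    x = runif(30), y = runif(30))
  g <- build_graph(cc)
  enr <- enrichment_test(g, setNames(cc$called_type, cc$cell_id),
                         n_permutations = 100, seed = 1)
  expect_equal(unname(enr$observed["A", "A"]), 30)
  expect_equal(unname(enr$null_mean["A", "A"]), 30)
  expect_true(is.na(enr$z["A", "A"]))
  expect_equal(unname(enr$p["A", "A"]), 1)
})

test_that("edge-count enrichment is symmetric in the type pair", {
  set.seed(15)
  n <- 300
  cc <- fake_called(paste0("c", 1:n),
                    sample(c("A", "B", "C"), n, TRUE), c("A", "B", "C"),
                    x = runif(n, 0, 500), y = runif(n, 0, 500))
  g <- build_graph(cc)
  enr <- enrichment_test(g, setNames(cc$called_type, cc$cell_id),
                         n_permutations = 200, seed = 2,
                         statistic = "edge_count")
  expect_equal(unname(enr$observed), unname(t(enr$observed)))
  z <- unname(enr$z); z[is.na(z)] <- 0
  expect_equal(z, t(z), tolerance = 1e-12)
})

test_that("clustered labels strengthen homotypic z-scores monotonically", {
  # planted clusters with decreasing scatter around 8 cluster centres
  set.seed(33)
  centres <- expand.grid(x = c(200, 600, 1000, 1400), y = c(300, 900))
  zmean <- vapply(c(Inf, 200, 50), function(sig) {
    mean(vapply(1:3, function(s) {
      set.seed(100 + s)
      n_per <- 60
      lab <- rep(c("A", "B"), each = 4 * n_per)
      cid <- rep(seq_len(8), each = n_per)
      if (is.finite(sig)) {
        x <- centres$x[cid] + rnorm(8 * n_per, 0, sig)
        y <- centres$y[cid] + rnorm(8 * n_per, 0, sig)
      } else {
        x <- runif(8 * n_per, 0, 1600); y <- runif(8 * n_per, 0, 1200)
      }
      cc <- fake_called(paste0("c", seq_along(x)), lab, c("A", "B"),
                        x = x, y = y)
      g <- build_graph(cc)
      enr <- enrichment_test(g, setNames(lab, cc$cell_id),
                             n_permutations = 200, seed = s)
      mean(diag(enr$z), na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(zmean) > 0))
})
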