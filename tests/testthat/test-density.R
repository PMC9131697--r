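square_poly <- function(side) cbind(x = c(0, side, side, 0),
                                    y = c(0, 0, side, side))

test_that("kernel maps are unimodal for one cell and symmetric for two", {
  poly <- square_poly(1000)
  m <- kde_map(432, 581, poly, bandwidth = 80, spacing = 20)
  peak <- which(m$z == max(m$z, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(m$x[peak[1]], 440)  # nearest grid node to the cell
  expect_equal(m$y[peak[2]], 580)
  m2 <- kde_map(c(200, 800), c(500, 500), poly, bandwidth = 40,
                spacing = 20)
  v1 <- m2$z[m2$x == 200, m2$y == 500]
  v2 <- m2$z[m2$x == 800, m2$y == 500]
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(max(m2$z, na.rm = TRUE), v1, tolerance = 1e-9)
})

test_that("kernel maps agree with the classical bivariate KDE", {
  set.seed(3)
  poly <- square_poly(1000)
  x <- runif(200, 0, 1000); y <- runif(200, 0, 1000)
  m <- kde_map(x, y, poly, bandwidth = 75, spacing = 250)
  ref <- MASS::kde2d(x, y, h = 4 * 75, n = length(m$x),
                     lims = c(range(m$x), range(m$y)))
  expect_equal(m$z / length(x), ref$z, tolerance = 1e-10)
})

test_that("kernel mass within the polygon matches the cell count", {
  set.seed(9)
  poly <- square_poly(2000)
  n <- 400
  # keep cells > 4 sigma from the boundary so kernel mass stays inside
  x <- runif(n, 300, 1700); y <- runif(n, 300, 1700)
  m <- kde_map(x, y, poly, bandwidth = 50, spacing = 20)
  integral <- sum(m$z, na.rm = TRUE) * m$spacing^2
  expect_lt(abs(integral - n) / n, 0.02)
})

test_that("uniform point patterns produce flat interior density", {
  set.seed(41)
  poly <- square_poly(2000)
  x <- runif(5000, 0, 2000); y <- runif(5000, 0, 2000)
  m <- kde_map(x, y, poly, bandwidth = 100, spacing = 20)
  interior <- m$z[m$x >= 400 & m$x <= 1600, m$y >= 400 & m$y <= 1600]
  expect_lt(sd(interior) / mean(interior), 0.2)
})

test_that("section normalization scales the global maximum to exactly 1", {
  poly <- square_poly(500)
  a <- kde_map(250, 250, poly, bandwidth = 50, spacing = 25)
  b <- a; b$z <- a$z / 2
  out <- normalize_section(list(A = a, B = b))
  expect_identical(max(vapply(out, function(l) max(l$z, na.rm = TRUE),
                              numeric(1))), 1)
  expect_equal(max(out$B$z, na.rm = TRUE), 0.5, tolerance = 1e-12)
  single <- normalize_section(a)
  expect_identical(max(single$z, na.rm = TRUE), 1)
  zero <- a; zero$z[] <- 0
  expect_error(normalize_section(list(zero)), "zero")
  empty <- kde_map(numeric(0), numeric(0), poly, 50, 25)
  expect_true(empty$flagged)
  expect_true(all(empty$z[!is.na(empty$z)] == 0))
})

test_that("depth profiles localize mass and conserve counts", {
  axis <- list(from = c(500, 1000), to = c(500, 0))  # pia at top
  breaks <- c(0.10, 0.35, 0.50, 0.75)
  cc <- fake_called(paste0("c", 1:50), rep("A", 50), c("A", "B"),
                    x = rep(500, 50), y = rep(200, 50))  # depth 0.8
  dp <- depth_profile(cc, axis, breaks)
  expect_identical(colnames(dp$occupancy),
                   c("I", "II/III", "IV", "V", "VI"))
  expect_identical(names(which.max(dp$occupancy["A", ])), "VI")
  peak_depth <- dp$depth[which.max(dp$profile[, "A"])]
  expect_gt(peak_depth, 0.75)
  # occupancy sums to the cell count (reflection conserves mass)
  expect_equal(sum(dp$occupancy["A", ]), 50, tolerance = 1e-6)
  expect_equal(sum(dp$occupancy["B", ]), 0)
})

test_that("uniform depths occupy layers proportionally to their widths", {
  set.seed(6)
  n <- 10000
  axis <- list(from = c(0, 1000), to = c(0, 0))
  breaks <- c(0.10, 0.35, 0.50, 0.75)
  cc <- fake_called(paste0("c", 1:n), rep("A", n), "A",
                    x = rep(0, n), y = runif(n, 0, 1000))
  dp <- depth_profile(cc, axis, breaks)
  widths <- diff(c(0, breaks, 1))
  expect_true(all(abs(dp$occupancy["A", ] / n - widths) < 0.02))
})

test_that("planted infragranular bias is recovered in layer occupancies", {
  set.seed(8)
  n <- 1000
  deep <- runif(0.8 * n, 0.6, 1); sup <- runif(0.2 * n, 0, 0.6)
  axis <- list(from = c(0, 1000), to = c(0, 0))
  cc <- fake_called(paste0("c", 1:n), rep("A", n), "A",
                    x = rep(0, n), y = 1000 * (1 - c(deep, sup)))
  dp <- depth_profile(cc, axis, c(0.10, 0.35, 0.50, 0.75))
  infra <- sum(dp$occupancy["A", c("V", "VI")])
  supra <- sum(dp$occupancy["A", c("I", "II/III", "IV")])
  expect_gt(infra, supra)
})

test_that("depth profiles are invariant to rigid transforms of the section", {
  set.seed(14)
  n <- 300
  x <- runif(n, 0, 400); y <- runif(n, 0, 1000)
  axis <- list(from = c(200, 1000), to = c(200, 0))
  cc <- fake_called(paste0("c", 1:n), sample(c("A", "B"), n, TRUE),
                    c("A", "B"), x = x, y = y)
  dp <- depth_profile(cc, axis, c(0.2, 0.5, 0.8))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy2 <- cbind(x, y) %*% t(R) + matrix(c(123, -456), n, 2, byrow = TRUE)
  ax2 <- list(from = as.numeric(R %*% axis$from + c(123, -456)),
              to = as.numeric(R %*% axis$to + c(123, -456)))
  cc2 <- cc; cc2$x <- xy2[, 1]; cc2$y <- xy2[, 2]
  dp2 <- depth_profile(cc2, ax2, c(0.2, 0.5, 0.8))
  expect_equal(dp2$profile, dp$profile, tolerance = 1e-9)
  expect_equal(dp2$occupancy, dp$occupancy, tolerance = 1e-9)
})

test_that("cells beyond the depth axis are clipped with a warning", {
  axis <- list(from = c(0, 100), to = c(0, 0))
  cc <- fake_called(paste0("c", 1:10), rep("A", 10), "A",
                    x = rep(0, 10), y = c(rep(50, 4), rep(-40, 6)))
  expect_warning(dp <- depth_profile(cc, axis), "outside")
  expect_equal(sum(dp$occupancy), 10, tolerance = 1e-6)
})

test_that("area occurrences separate planted area preferences", {
  lay <- make_layout("brain_coronal", scale = 1000)
  # all A in M2, all B in S1
  m2 <- colMeans(lay$areas$M2); s1 <- colMeans(lay$areas$S1)
  cc <- fake_called(paste0("c", 1:20), rep(c("A", "B"), each = 10),
                    c("A", "B"),
                    x = c(rep(m2[1], 10), rep(s1[1], 10)),
                    y = c(rep(m2[2], 10), rep(s1[2], 10)))
  ao <- area_occurrence(cc, lay$areas[c("S1", "M2")])
  expect_equal(ao$occurrence[ao$area == "M2" & ao$type == "A"], 100)
  expect_equal(ao$occurrence[ao$area == "S1" & ao$type == "A"], 0)
  expect_warning(area_occurrence(cc, lay$areas["Cg2"]), "no cells")
})

test_that("planted medial gradients reach significance across sections", {
  lay <- make_layout("brain_coronal", scale = 1000)
  set.seed(19)
  make_section <- function(s, p_m2, p_s1) {
    pick <- function(poly, n, p) {
      bx <- range(poly[, 1]); by <- range(poly[, 2])
      data.frame(x = runif(n, bx[1], bx[2]), y = runif(n, by[1], by[2]),
                 type = sample(c("OPC", "MOL5"), n, TRUE,
                               prob = c(p, 1 - p)))
    }
    d <- rbind(pick(lay$areas$M2, 250, p_m2), pick(lay$areas$S1, 250, p_s1))
    cc <- fake_called(sprintf("s%d_c%d", s, seq_len(nrow(d))), d$type,
                      c("OPC", "MOL5"), x = d$x, y = d$y)
    ao <- area_occurrence(cc, lay$areas[c("S1", "M2")])
    data.frame(sample = paste0("sec", s), ao)
  }
  # planted: OPC fraction 20 points higher in M2 than S1
  sections <- do.call(rbind, lapply(1:4, make_section, p_m2 = 0.5,
                                    p_s1 = 0.3))
  opc <- sections[sections$type == "OPC", ]
  res <- compare_groups(data.frame(type = "OPC", group = opc$area,
                                   value = opc$occurrence))
  expect_lt(res$p_adj, 0.05)
  means <- tapply(opc$occurrence, opc$area, mean)
  expect_gt(means[["M2"]], means[["S1"]])
  # specificity: no planted difference, mostly no significant contrast
  hits <- vapply(1:20, function(r) {
    secs <- do.call(rbind, lapply(1:4, make_section, p_m2 = 0.4,
                                  p_s1 = 0.4))
    o <- secs[secs$type == "OPC", ]
    compare_groups(data.frame(type = "OPC", group = o$area,
                              value = o$occurrence))$p_adj < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})
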