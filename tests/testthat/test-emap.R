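test_that("emap files round-trip and malformed rows are reported by line", {
  pts <- cbind(runif(20, 0, 10), runif(20, 0, 10), 0)
  map <- emap(pts, runif(20, 0.1, 3.5), runif(20, 0, 60))
  path <- tempfile(fileext = ".tsv")
  write_emap(map, path)
  m2 <- read_emap(path)
  expect_equal(m2$points, map$points, tolerance = 1e-12)
  expect_equal(m2$voltage, map$voltage, tolerance = 1e-12)
  expect_equal(m2$lat, map$lat, tolerance = 1e-12)

  ln <- readLines(path)
  ln[5] <- "1.0\t2.0\tnot_a_number\t0.5\t10"
  writeLines(ln, path)
  expect_error(read_emap(path), "line 5")

  expect_error(emap(pts, rep(-1, 20), rep(0, 20)), ">= 0")
})

test_that("rigid alignment recovers a known transform (Procrustes oracle)", {
  set.seed(42)
  pts <- cbind(runif(60, 0, 20), runif(60, 0, 20), runif(60, 0, 5))
  map <- emap(pts, runif(60, 0.1, 3), runif(60, 0, 50))

  # identity landmarks: nothing moves
  al0 <- rigid_align(map, pts[1:5, ], pts[1:5, ])
  expect_lt(attr(al0, "rms_residual_mm"), 1e-9)
  expect_equal(al0$points, pts, tolerance = 1e-9)

  ang <- pi / 6
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- emap(pts %*% t(R) + matrix(rep(c(4, -7, 2), each = 60), ncol = 3),
                map$voltage, map$lat)
  lmk <- c(1, 9, 22, 35, 51)
  al <- rigid_align(moved, moved$points[lmk, ], pts[lmk, ])
  expect_lt(attr(al, "rms_residual_mm"), 1e-6)
  expect_lt(max(abs(al$points - pts)), 1e-6)

  # cross-check the recovered rotation against vegan's Procrustes solution
  pro <- vegan::procrustes(pts[lmk, ], moved$points[lmk, ], scale = FALSE)
  expect_equal(attr(al, "rotation"), t(pro$rotation), tolerance = 1e-8)

  expect_error(rigid_align(moved, moved$points[1:2, ], pts[1:2, ]),
               "at least 3")
  col <- cbind(1:5, 2 * (1:5), 0)
  expect_error(rigid_align(moved, col, col), "collinear")
})

test_that("IDW interpolation honors exact hits, symmetry and bounds", {
  m <- generate_sheet_mesh(10, 10, 500)

  const <- emap(m$nodes[c(10, 50, 90, 130), ] + 0.2, rep(1.8, 4), rep(5, 4))
  f <- idw_interpolate(const, m, "voltage")
  expect_true(all(abs(f$values[f$covered] - 1.8) < 1e-9))

  hit <- emap(rbind(m$nodes[33, ], m$nodes[77, ] + c(0.3, 0, 0)),
              c(1.8, 0.4), c(0, 0))
  fh <- idw_interpolate(hit, m, "voltage")
  expect_equal(fh$values[33], 1.8)

  # node equidistant from a 1 mV and a 3 mV sample reads 2 mV
  node <- which(abs(m$nodes[, 1] - 5) < 0.26 & abs(m$nodes[, 2] - 5) < 0.25)[1]
  p <- m$nodes[node, ]
  two <- emap(rbind(p + c(2, 0, 0), p - c(2, 0, 0)), c(1, 3), c(0, 0))
  ft <- idw_interpolate(two, m, "voltage")
  expect_equal(ft$values[node], 2, tolerance = 1e-9)

  # output bounded by in-radius sample range; uncovered nodes get 5 mV
  set.seed(1)
  rnd <- emap(cbind(runif(30, 0, 4), runif(30, 0, 4), 0),
              runif(30, 0.2, 3), runif(30, 0, 40))
  fr <- idw_interpolate(rnd, m, "voltage", radius = 3)
  expect_true(all(fr$values[fr$covered] >= min(rnd$voltage) - 1e-9))
  expect_true(all(fr$values[fr$covered] <= max(rnd$voltage) + 1e-9))
  expect_true(any(!fr$covered))
  expect_true(all(fr$values[!fr$covered] == 5))
})

test_that("the fibrosis probability curve matches its published form", {
  expect_equal(fibrosis_probability(0), 0.998)
  expect_lt(abs(fibrosis_probability(1.74)), 0.01)
  expect_equal(fibrosis_probability(0.5), 0.3055, tolerance = 1e-6)
  expect_equal(fibrosis_probability(-0.1), 1)
  expect_equal(fibrosis_probability(2.5), 0)

  grid <- seq(-0.5, 3, by = 0.005)
  p <- fibrosis_probability(grid)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  # effective continuity at the 1.74 mV threshold
  expect_lt(abs(fibrosis_probability(1.74 - 1e-9) -
                  fibrosis_probability(1.74 + 1e-9)), 0.01)
})

test_that("stochastic fibrosis assignment concentrates at the Eq. probability", {
  m <- generate_sheet_mesh(50, 40, 500)
  n <- nrow(m$nodes)
  expect_gte(n, 9000)

  hi <- assign_fibrosis(m, rep(5, n))
  expect_equal(attr(hi, "fibrosis_fraction"), 0)
  lo <- assign_fibrosis(m, rep(-0.1, n))
  expect_equal(attr(lo, "fibrosis_fraction"), 1)

  for (v in c(0.3, 0.5, 1.0)) {
    p <- fibrosis_probability(v)
    f <- attr(assign_fibrosis(m, rep(v, n), fibrosis_model(7)),
              "fibrosis_fraction")
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(f - p), 3 * se)
  }

  a <- assign_fibrosis(m, rep(0.5, n), fibrosis_model(123))
  b <- assign_fibrosis(m, rep(0.5, n), fibrosis_model(123))
  expect_identical(a$fibrosis, b$fibrosis)
})

test_that("map agreement statistics match hand computations", {
  id <- map_agreement(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(id$pearson_r, 1)
  expect_equal(id$rmse, 0)

  anti <- map_agreement(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(anti$pearson_r, -1)

  h <- map_agreement(c(1, 2, 3), c(1, 2, 4))
  expect_equal(h$rmse, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(h$percent_rmse, 100 * (1 / sqrt(3)) / 2, tolerance = 1e-12)

  regions <- c(1L, 1L, 1L, 2L)
  expect_warning(out <- map_agreement(c(1, 2, 3, 4), c(1, 2, 3, 4), regions),
                 "region 2")
  expect_equal(out$region, c("overall", "1"))
})

test_that("synthetic maps are reproducible and recover their truth fields", {
  m <- sheet20()
  s1 <- generate_synthetic_emap(m, n_points = 400, seed = 5)
  s2 <- generate_synthetic_emap(m, n_points = 400, seed = 5)
  expect_identical(s1$map$points, s2$map$points)
  expect_identical(s1$map$voltage, s2$map$voltage)
  expect_true(min(s1$truth_voltage) >= 0.1 - 1e-9 &&
                max(s1$truth_voltage) <= 3.5 + 1e-9)

  s0 <- generate_synthetic_emap(m, n_points = 500, seed = 5,
                                noise_sd_voltage = 0, noise_sd_lat = 0)
  fv <- idw_interpolate(s0$map, m, "voltage")
  expect_gt(cor(fv$values[fv$covered], s0$truth_voltage[fv$covered]), 0.95)

  expect_error(generate_synthetic_emap(m, n_points = 1e6), "exceeds")
})
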