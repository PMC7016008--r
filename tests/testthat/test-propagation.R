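test_that("the diffusion operator is conservative and matches hand assembly", {
  m <- coarse_strip()
  op <- build_diffusion(m, conductivity_set(), c(2, 4))
  n <- nrow(m$nodes)
  # zero row sums: a uniform potential produces no diffusion current
  expect_lt(max(abs(op$K %*% rep(1, n))), 1e-10)
  expect_lt(max(abs(op$L %*% rep(1, n))), 1e-10)
  expect_lt(max(abs(op$K - Matrix::t(op$K))), 1e-10)
  # total diffusion current vanishes for any field (no-flux boundary)
  set.seed(2)
  u <- rnorm(n)
  expect_lt(abs(sum(op$mass * as.numeric(op$L %*% u))) /
              sum(abs(op$mass * as.numeric(op$L %*% u))), 1e-8)

  # isotropic limit: the operator is invariant under fiber rotation
  iso <- conductivity_set(0.1, 0.1, 0.1, 0.1)
  op1 <- build_diffusion(m, iso, c(1, 1))
  m45 <- assign_fiber_field(m, "uniform", direction = c(1, 1, 0))
  op2 <- build_diffusion(m45, iso, c(1, 1))
  expect_lt(max(abs(op1$K - op2$K)), 1e-10)

  # two-triangle unit strip against the known P1 stiffness stencil
  us <- unit_strip()
  opu <- build_diffusion(us, iso, c(10, 10)) # D = 1 everywhere
  K_oracle <- rbind(c(1, -0.5, -0.5, 0),
                    c(-0.5, 1, 0, -0.5),
                    c(-0.5, 0, 1, -0.5),
                    c(0, -0.5, -0.5, 1))
  expect_equal(as.matrix(opu$K), K_oracle, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(build_diffusion(atrial_mesh(us$nodes, us$triangles),
                               conductivity_set()), "fiber")
  expect_error(conductivity_set(sigma_L_normal = 0.01), "transverse")
})

test_that("quiescent tissue stays at rest and runs are deterministic", {
  m <- generate_sheet_mesh(8, 6, 800)
  op <- build_diffusion(m, conductivity_set(), c(2, 4))
  silent <- make_pacing_protocol(1, 0, amplitude = 0)
  # neutral tissue sits at the published resting state (the AF profile
  # settles to a slightly hyperpolarized rest of its own)
  res <- run_monodomain(m, op, silent, scaling = neutral_profile(),
                        duration = 1000, output_interval = 10)
  expect_lt(max(abs(res$vm - res$vm[1, 1])), 1)

  stim <- make_pacing_protocol(which(m$nodes[, 1] < 0.9), 5,
                               amplitude = -8000)
  r1 <- run_monodomain(m, op, stim, duration = 40)
  r2 <- run_monodomain(m, op, stim, duration = 40)
  expect_identical(r1$vm, r2$vm)
  expect_error(run_monodomain(m, op, stim, duration = 0), "duration")
  op_other <- build_diffusion(sheet20(), conductivity_set(), c(2, 4))
  expect_error(run_monodomain(m, op_other, stim, duration = 10),
               "not built on this mesh")
})

test_that("LAT extraction is kinematically exact on a planar wave", {
  m <- sheet20()
  pw <- make_plane_wave_movie(m, speed = 0.5, cl = 600, duration = 600)
  lm <- extract_lat(pw)
  fit <- stats::lm(lm$lat ~ m$nodes[, 1])
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(1 / unname(stats::coef(fit)[2]), 0.5, tolerance = 0.02)
  # the earliest-activation node lies on the stimulated edge
  expect_lt(m$nodes[lm$eas_node, 1], 1)

  # sub-threshold stimulus: nothing activates
  ms <- generate_sheet_mesh(6, 4, 800)
  ops <- build_diffusion(ms, conductivity_set(), c(2, 4))
  weak <- make_pacing_protocol(which(ms$nodes[, 1] < 0.9), 0,
                               amplitude = -100)
  rw <- run_monodomain(ms, ops, weak, duration = 30)
  expect_error(extract_lat(rw), "no node activates")
})

test_that("CV measurement divides surface distance by activation delay", {
  m <- sheet20()
  lat <- as.numeric(m$nodes[, 1]) / 0.5 # exactly 0.5 m/s along x
  lm <- structure(list(lat = lat, eas_node = which.min(lat),
                       activated = rep(TRUE, length(lat)), reference = 0),
                  class = "lat_map")
  row <- which(abs(m$nodes[, 2] - 10) < 0.25)
  a <- row[which.min(abs(m$nodes[row, 1] - 5))]
  b <- row[which.min(abs(m$nodes[row, 1] - 15))]
  out <- measure_cv(lm, m, a, b)
  expect_equal(out$mean_cv, 0.5, tolerance = 0.04) # geodesic discretization
  expect_error(measure_cv(lm, m, a, a), "non-positive")
})

test_that("ramp protocols span the stated pacing duration", {
  p <- make_ramp_protocol(1L)
  on <- p$events$time
  expect_equal(on[1], 0)
  expect_false(is.unsorted(on))
  expect_equal(utils::tail(on, 1) + 120, 6530) # last cycle ends at total
  gaps <- diff(on)
  expect_true(all(gaps >= 120 - 1e-9))
  expect_equal(sort(unique(utils::head(gaps, 32))),
               seq(130, 200, by = 10)) # the stepped-down ramp

  p2 <- make_ramp_protocol(1L, cl_start = 200, cl_end = 200, total = 1000)
  expect_equal(p2$events$time, c(0, 200, 400, 600, 800))

  expect_error(make_ramp_protocol(1L, cl_start = 120, cl_end = 200),
               "cl_end")
  expect_error(make_ramp_protocol(1L, total = 100), "too short")
})

test_that("induction detection demands sustained post-pacing activity", {
  m <- sheet20()
  prot <- make_pacing_protocol(1L, 0, duration = 2)
  # quiescent tissue: not induced
  quiet <- constant_result(nrow(m$nodes), -80, 6200, 10)
  expect_false(detect_induction(quiet, prot, window = 6000)$induced)
  # a maintained spiral: induced
  sp <- make_spiral_movie(m, frequency = 6, duration = 6200,
                          output_interval = 10)
  det <- detect_induction(sp, prot, window = 6000)
  expect_true(det$induced)
  expect_equal(unname(det$window), c(2, 6002))
  # a movie ending too soon after pacing is an error
  short <- make_spiral_movie(m, frequency = 6, duration = 2000,
                             output_interval = 10)
  expect_error(detect_induction(short, prot, window = 6000), "too short")
})

test_that("planar CV scales as sqrt(D) and fibrosis slows conduction", {
  # sqrt(D) law at the calibration-grade resolution (coarser meshes sit in
  # the discrete-propagation regime where the continuum law bends)
  mfine <- generate_sheet_mesh(30, 6, 235)
  cond <- conductivity_set()
  cvf1 <- atrialwave:::planar_cv(mfine,
                                 build_diffusion(mfine, cond, c(1.94, 2.9)),
                                 af_remodeling_profile(), duration = 60)
  cvf4 <- atrialwave:::planar_cv(mfine,
                                 build_diffusion(mfine, cond,
                                                 4 * c(1.94, 2.9)),
                                 af_remodeling_profile(), duration = 40)
  expect_lt(abs(cvf4 / cvf1 - 2), 0.1)

  m <- coarse_strip()
  cv1 <- atrialwave:::planar_cv(m, build_diffusion(m, cond, c(1.9, 2.9)),
                                af_remodeling_profile(), x1 = 5, x2 = 15,
                                duration = 70)
  mf <- m
  mf$fibrosis <- rep(TRUE, nrow(m$nodes))
  cvf <- atrialwave:::planar_cv(mf, build_diffusion(mf, cond, c(1.9, 2.9)),
                                af_remodeling_profile(), x1 = 5, x2 = 15,
                                duration = 140)
  expect_lt(cvf, cv1)

  # transverse direction: fibers across the strip
  mt <- assign_fiber_field(m, "uniform", direction = c(0, 1, 0))
  cvt <- atrialwave:::planar_cv(mt, build_diffusion(mt, cond, c(1.9, 2.9)),
                                af_remodeling_profile(), x1 = 5, x2 = 15,
                                duration = 100)
  expect_lt(cvt, cv1)
  mtf <- mt
  mtf$fibrosis <- rep(TRUE, nrow(mt$nodes))
  cvtf <- atrialwave:::planar_cv(mtf, build_diffusion(mtf, cond, c(1.9, 2.9)),
                                 af_remodeling_profile(), x1 = 5, x2 = 15,
                                 duration = 220)
  expect_lt(cvtf, cvt)
})

test_that("diffusion tuning is a fixed point at scale 1", {
  m <- generate_sheet_mesh(25, 8, 500)
  cond <- conductivity_set()
  kappa <- c(1.9, 2.9)
  eas <- which.min(rowSums(sweep(m$nodes, 2, c(0, 4, 0))^2))
  prot <- make_pacing_protocol(stim_site_disk(m, eas, 1.2), 0,
                               amplitude = -8000)
  targets <- vapply(list(c(10, 3), c(15, 5), c(20, 4)), function(p)
    which.min(rowSums(sweep(m$nodes, 2, c(p, 0))^2)), integer(1))
  op <- build_diffusion(m, cond, kappa)
  res <- run_monodomain(m, op, prot, duration = 60, output_interval = 1)
  lm <- extract_lat(res)
  clin <- lm$lat[targets] - min(lm$lat, na.rm = TRUE)
  sc <- tune_diffusion(m, cond, kappa, prot, targets, clin, duration = 60)
  expect_lt(abs(sc - 1), 0.02)
  expect_lt(max(abs(attr(sc, "residuals_ms"))), 2)

  expect_error(tune_diffusion(m, cond, kappa, prot, targets, c(0, 0, 0)),
               "must be > 0")
})
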