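make_tone_result <- function(freqs_hz, amps, n_nodes = 25, duration = 6000,
                             dt = 10) {
  times <- seq(0, duration - dt, by = dt)
  vm <- matrix(0, n_nodes, length(times))
  for (i in seq_len(n_nodes)) {
    for (k in seq_along(freqs_hz)) {
      vm[i, ] <- vm[i, ] + amps[k] * sin(2 * pi * freqs_hz[k] * times / 1000 +
                                           i / 3)
    }
  }
  wrap_result(vm - 80, times)
}

test_that("dominant frequency finds the strongest band-limited peak", {
  pure <- make_tone_result(6, 1)
  df <- compute_df_map(pure)
  expect_true(all(abs(df$df_hz - 6) < 1e-9))

  # larger-amplitude tone wins the periodogram
  mix <- make_tone_result(c(4, 8), c(1, 2))
  dfm <- compute_df_map(mix)
  expect_true(all(abs(dfm$df_hz - 8) < 1e-9))

  # constant trace has no defined DF; short windows are rejected
  con <- constant_result(10)
  dfc <- compute_df_map(con)
  expect_true(all(is.na(dfc$df_hz)))
  expect_error(compute_df_map(pure, window = c(0, 500)), "1 s")
})

test_that("DF equals a brute-force trigonometric periodogram scan", {
  set.seed(31)
  times <- seq(0, 5990, by = 10)
  n <- 12
  vm <- matrix(0, n, length(times))
  for (i in seq_len(n)) {
    f3 <- sample(seq(1.5, 15, by = 0.5), 3)
    a3 <- runif(3, 0.3, 2)
    vm[i, ] <- colSums(a3 * t(sapply(f3, function(f)
      sin(2 * pi * f * times / 1000 + runif(1, 0, 6)))))
  }
  res <- wrap_result(vm - 80, times)
  df <- compute_df_map(res, band = c(1, 20))

  # oracle: direct projection onto the tapered Fourier basis per frequency
  nt <- length(times)
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(nt) / (nt + 1)))
  freqs <- (0:(nt - 1)) / (nt * 0.01)
  inband <- freqs[freqs >= 1 & freqs <= 20]
  for (i in seq_len(n)) {
    x <- (vm[i, ] - mean(vm[i, ])) * taper
    pow <- vapply(inband, function(f) {
      ang <- 2 * pi * f * (seq_len(nt) - 1) * 0.01
      sum(x * cos(ang))^2 + sum(x * sin(ang))^2
    }, numeric(1))
    expect_equal(df$df_hz[i], inband[which.max(pow)])
  }
})

test_that("top-DF selection counts, ties and bounds behave", {
  dfmap <- structure(list(df_hz = seq(1, 10, length.out = 100),
                          peak_power = rep(1, 100)), class = "df_map")
  top <- top_df_region(dfmap, 0.05)
  expect_length(top$nodes, 5)
  expect_equal(top$peak_node, 100)
  expect_true(all(top$nodes %in% 96:100))

  all_eq <- structure(list(df_hz = rep(5, 50), peak_power = rep(2, 50)),
                      class = "df_map")
  expect_warning(t2 <- top_df_region(all_eq, 0.1), "tie")
  expect_length(t2$nodes, 50)

  expect_length(top_df_region(dfmap, 1)$nodes, 100)
  expect_error(top_df_region(dfmap, 0), "fraction")
  expect_error(top_df_region(dfmap, 1.2), "fraction")

  # boundary ties broken by peak power
  dfp <- structure(list(df_hz = c(rep(10, 3), rep(5, 97)),
                        peak_power = c(3, 2, 1, rep(0, 97))),
                   class = "df_map")
  t3 <- top_df_region(dfp, 0.02)
  expect_equal(sort(t3$nodes), c(1, 2))
})

test_that("analytic-signal phase advances 2*pi per cycle and is scale-free", {
  times <- seq(0, 2990, by = 10)
  v <- sin(2 * pi * 5 * times / 1000)
  res <- wrap_result(rbind(v, 3 * v, deparse.level = 0) - 70, times)
  ph <- compute_phase(res)
  unwrapped <- ph$phase[1, ] + c(0, cumsum(round(-diff(ph$phase[1, ]) /
                                                   (2 * pi)))) * 2 * pi
  drift <- diff(unwrapped) / diff(times) # rad/ms
  core <- 30:260 # away from window edges
  expect_lt(max(abs(drift[core] - 2 * pi * 5 / 1000)), 0.002)
  dwrap <- ((ph$phase[1, ] - ph$phase[2, ] + pi) %% (2 * pi)) - pi
  expect_lt(max(abs(dwrap)), 1e-9)

  con <- constant_result(3)
  pc <- compute_phase(con)
  expect_true(all(is.na(pc$phase)))
})

test_that("face winding numbers localize phase singularities", {
  m <- sheet20()
  # analytic vortex at a generic position inside a face
  x0 <- 10.13; y0 <- 10.07
  th <- atan2(m$nodes[, 2] - y0, m$nodes[, 1] - x0)
  pf <- structure(list(phase = cbind(th, th), times = c(0, 10)),
                  class = "phase_field")
  ev <- detect_ps(pf, m, 1)
  expect_equal(nrow(ev), 1)
  expect_lt(sqrt((ev$x - x0)^2 + (ev$y - y0)^2), 0.5)
  expect_equal(ev$chirality, 1L)

  # reversed field flips chirality; uniform phase has none
  pf2 <- structure(list(phase = cbind(-th), times = 0), class = "phase_field")
  expect_equal(detect_ps(pf2, m, 1)$chirality, -1L)
  pf3 <- structure(list(phase = matrix(1, nrow(m$nodes), 1), times = 0),
                   class = "phase_field")
  expect_equal(nrow(detect_ps(pf3, m, 1)), 0)

  # topological charge conservation on a closed surface
  sph <- generate_sphere_mesh(10, 2)
  ths <- atan2(sph$nodes[, 2], sph$nodes[, 1])
  pfs <- structure(list(phase = cbind(ths), times = 0),
                   class = "phase_field")
  evs <- detect_ps(pfs, sph, 1)
  expect_gt(nrow(evs), 0)
  expect_equal(sum(evs$chirality), 0)
})

test_that("PS detection on spiral fixtures recovers the true tip", {
  m <- sheet20()
  sp <- make_spiral_movie(m, frequency = 6, duration = 600,
                          output_interval = 10)
  ph <- compute_phase(sp)
  edge_len <- mesh_statistics(m)$mean_spacing_um / 1000
  frames <- 10:50
  ev <- detect_ps_series(ph, m, frames)
  tr <- link_trajectories(ev, max_step = 5)
  ls <- vapply(tr$trajectories, attr, numeric(1), "lifespan_ms")
  main <- tr$trajectories[[which.max(ls)]]
  err <- sqrt((main$x - 10)^2 + (main$y - 10)^2)
  expect_lt(max(err), 2 * edge_len)
  expect_true(all(main$chirality == 1))

  spr <- make_spiral_movie(m, frequency = -6, duration = 600,
                           output_interval = 10)
  evr <- detect_ps(compute_phase(spr), m, 30)
  expect_true(all(evr$chirality == -1))
})

test_that("trajectory linking respects step bound, chirality and gaps", {
  mk <- function(t, x, y, ch) data.frame(time = t, face = 1L, x = x, y = y,
                                         z = 0, chirality = ch)
  # stationary PS over 10 frames: one trajectory spanning the window
  ev <- do.call(rbind, lapply(1:10, function(k) mk(10 * k, 5, 5, 1L)))
  tr <- link_trajectories(ev, max_step = 5)
  expect_length(tr$trajectories, 1)
  expect_equal(attr(tr$trajectories[[1]], "lifespan_ms"), 90)

  # two simultaneous PSs farther apart than the step bound stay separate
  ev2 <- do.call(rbind, lapply(1:5, function(k)
    rbind(mk(10 * k, 0, 0, 1L), mk(10 * k, 15, 0, 1L))))
  expect_length(link_trajectories(ev2, max_step = 5)$trajectories, 2)

  # drift below the bound stays linked; opposite chirality never links
  ev3 <- do.call(rbind, lapply(1:8, function(k) mk(10 * k, 0.8 * k, 0, 1L)))
  expect_length(link_trajectories(ev3, max_step = 2)$trajectories, 1)
  ev4 <- rbind(mk(10, 5, 5, 1L), mk(20, 5, 5, -1L))
  expect_length(link_trajectories(ev4, max_step = 5)$trajectories, 2)
})

test_that("mother-rotor classification applies lifespan and confinement", {
  mk_traj <- function(times, xs, ys) {
    data.frame(time = times, face = 1L, x = xs, y = ys, z = 0,
               chirality = 1L)
  }
  crit <- mother_rotor_criterion(80) # confinement diameter 40 mm
  expect_equal(crit$confinement_diameter_mm, 40)

  stat6 <- mk_traj(seq(0, 6000, by = 50), 5, 5)
  expect_true(classify_mother_rotor(stat6, crit))

  # meander over a 60-mm-diameter circle violates confinement
  tt <- seq(0, 6000, by = 50)
  wide <- mk_traj(tt, 30 + 30 * cos(tt / 300), 30 + 30 * sin(tt / 300))
  expect_false(classify_mother_rotor(wide, crit))

  stat3 <- mk_traj(seq(0, 3000, by = 50), 5, 5)
  expect_false(classify_mother_rotor(stat3, crit))

  expect_error(classify_mother_rotor(stat6[0, ], crit), "empty")
  expect_error(mother_rotor_criterion(-1), "wavelength")
})

test_that("minimal enclosing circle matches a brute-force oracle", {
  set.seed(99)
  brute_mec <- function(Q) {
    # smallest circle through all pairs/triples that contains every point
    best <- list(radius = Inf)
    n <- nrow(Q)
    check <- function(ctr, r) {
      if (r < best$radius - 1e-12 &&
          all(sqrt(rowSums(sweep(Q, 2, ctr)^2)) <= r + 1e-9)) {
        best <<- list(center = ctr, radius = r)
      }
    }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ctr <- (Q[i, ] + Q[j, ]) / 2
      check(ctr, sqrt(sum((Q[i, ] - ctr)^2)))
    }
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- Q[i, ]; b <- Q[j, ]; cc <- Q[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
               sum(cc^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
               sum(cc^2) * (b[1] - a[1])) / d
      check(c(ux, uy), sqrt(sum((a - c(ux, uy))^2)))
    }
    best
  }
  for (rep in 1:5) {
    Q <- cbind(runif(18, -5, 5), runif(18, -5, 5))
    mine <- min_enclosing_circle(cbind(Q, 0))
    oracle <- brute_mec(Q)
    expect_equal(mine$radius, oracle$radius, tolerance = 1e-8)
    d <- sqrt(rowSums(sweep(Q, 2, mine$center[1:2])^2))
    expect_true(all(d <= mine$radius + 1e-8))
  }
})
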