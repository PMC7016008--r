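# a compact source: one interior node raised to +20 mV, neighbors at rest
bump_result <- function(mesh, node, frames = 3) {
  vm <- matrix(-80, nrow(mesh$nodes), frames)
  vm[node, ] <- 20
  wrap_result(vm, seq(0, by = 1, length.out = frames))
}

center_node <- function(mesh) {
  ctr <- colMeans(mesh$nodes)
  which.min(rowSums(sweep(mesh$nodes, 2, ctr)^2))
}

test_that("unipolar electrograms obey uniformity, linearity and scaling", {
  m <- generate_sheet_mesh(10, 10, 500)
  el <- c(5, 5, 3)

  # spatially uniform vm produces zero potential at all times
  u0 <- unipolar_egm(constant_result(nrow(m$nodes), -80, 20, 1), m, el)
  expect_lt(max(abs(u0$potential)), 1e-12)

  # superposition: phi(a + b) = phi(a) + phi(b) (vm as deviation field)
  set.seed(4)
  times <- 0:20
  A <- matrix(rnorm(nrow(m$nodes) * length(times)), nrow(m$nodes))
  B <- matrix(rnorm(nrow(m$nodes) * length(times)), nrow(m$nodes))
  pa <- unipolar_egm(wrap_result(A, times), m, el)$potential
  pb <- unipolar_egm(wrap_result(B, times), m, el)$potential
  pab <- unipolar_egm(wrap_result(A + B, times), m, el)$potential
  expect_equal(pab, pa + pb, tolerance = 1e-10)

  # doubling sigma_i/sigma_e doubles the potential
  src <- bump_result(m, center_node(m))
  p1 <- unipolar_egm(src, m, el, egm_model(sigma_i = 0.4))$potential
  p2 <- unipolar_egm(src, m, el, egm_model(sigma_i = 0.8))$potential
  expect_equal(p2, 2 * p1, tolerance = 1e-12)

  expect_error(unipolar_egm(src, m, c(5, 5, 0.1)), "clearance")
})

test_that("the dipole kernel is antisymmetric across the source", {
  # single activated element with a uniform gradient g (along +y):
  # mirroring the electrode across the plane through the centroid
  # perpendicular to g flips the sign of phi (dipole antisymmetry)
  tri <- atrial_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0)),
                     rbind(c(1, 2, 3)))
  src1 <- wrap_result(matrix(c(-80, -80, 20), 3, 2), c(0, 1))
  ctr <- colMeans(tri$nodes)
  eA <- ctr + c(0, 3, 1.5)
  eB <- ctr + c(0, -3, 1.5)
  pa <- unipolar_egm(src1, tri, eA)$potential[1]
  pb <- unipolar_egm(src1, tri, eB)$potential[1]
  expect_equal(pa, -pb, tolerance = 1e-12)
  expect_gt(abs(pa), 0)

  # far-field decay is faster than 1/distance beyond a few source sizes
  m <- generate_sheet_mesh(10, 10, 500)
  nd <- center_node(m)
  src <- bump_result(m, nd)
  p0 <- m$nodes[nd, ]
  ds <- c(5, 10, 20, 40)
  amp <- vapply(ds, function(d)
    abs(unipolar_egm(src, m, p0 + c(0.7, 0.3, d))$potential[1]), numeric(1))
  expect_true(all(diff(amp) < 0))
  for (k in seq_len(length(ds) - 1)) {
    expect_lt(amp[k + 1] / amp[k], ds[k] / ds[k + 1])
  }
})

test_that("bipolar electrograms difference the two poles", {
  m <- generate_sheet_mesh(10, 10, 500)
  pw <- make_plane_wave_movie(m, speed = 0.5, cl = 600, duration = 100,
                              output_interval = 1)
  ctr <- c(5, 5, 2)

  bi <- bipolar_egm(pw, m, ctr, orientation = c(1, 0, 0))
  rev <- bipolar_egm(pw, m, ctr, orientation = c(-1, 0, 0))
  expect_equal(bi$potential, -rev$potential, tolerance = 1e-12)
  expect_gt(diff(range(bi$potential)), 0)

  # shrinking pole spacing shrinks the bipolar amplitude toward zero
  amp <- vapply(c(1, 0.3, 0.1, 0.03), function(s)
    diff(range(bipolar_egm(pw, m, ctr, c(1, 0, 0), spacing = s)$potential)),
    numeric(1))
  expect_true(all(diff(amp) < 0))
  expect_lt(amp[4], 0.05 * amp[1])

  # poles placed symmetrically about a symmetric source cancel exactly
  tri <- atrial_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0)),
                     rbind(c(1, 2, 3)))
  mv <- wrap_result(matrix(c(-80, -80, 20), 3, 2), c(0, 1))
  bs <- bipolar_egm(mv, tri, c(1, 0.5, 1.5), orientation = c(1, 0, 0))
  expect_lt(max(abs(bs$potential)), 1e-12)
})

test_that("morphology similarity is a segment-averaged cosine", {
  t <- seq(0, 2 * pi, length.out = 400)
  s <- sin(t); cc <- cos(t)
  expect_equal(morphology_similarity(s, s), 1)
  expect_equal(morphology_similarity(s, 5 * s), 1)
  expect_equal(morphology_similarity(s, -s), -1)
  expect_lt(abs(morphology_similarity(s[-400], cc[-400])), 0.02)
  expect_error(morphology_similarity(s, 0 * s), "zero-norm")
  expect_error(morphology_similarity(s, s[-1]), "equal length")

  # per-segment averaging: identical in one beat, inverted in the other
  tm <- seq(0, 399)
  a <- rep(sin(seq(0, 2 * pi, length.out = 200)), 2)
  b <- c(sin(seq(0, 2 * pi, length.out = 200)),
         -sin(seq(0, 2 * pi, length.out = 200)))
  sim <- morphology_similarity(a, b, times = tm, breaks = 199.5)
  expect_equal(sim, 0, tolerance = 1e-9)
})
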