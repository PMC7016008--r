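test_that("remodeling profiles encode the stated multiplicative factors", {
  n <- neutral_profile()
  expect_true(all(unclass(n) == 1))

  af <- af_remodeling_profile()
  expect_equal(unname(af["f_K1"]), 2.0)
  expect_equal(unname(af["f_NCX"]), 1.4)
  expect_equal(unname(af["f_Na"]), 0.9)
  expect_equal(unname(af["f_to"]), 0.3)
  expect_equal(unname(af["f_CaL"]), 0.5)
  expect_equal(unname(af["f_Kur"]), 0.5)

  fib <- fibrosis_remodeling_profile()
  expect_equal(unname(fib["f_K1"]), 0.5)
  expect_equal(unname(fib["f_CaL"]), 0.5)
  expect_equal(unname(fib["f_Na"]), 0.6)
  expect_equal(unname(fib["f_to"]), 1)

  # composition is multiplicative and neutral is the identity
  expect_equal(compose_profiles(n, n), n)
  expect_equal(compose_profiles(n, af), af)
  fib_af <- fibrosis_remodeling_profile(af)
  expect_equal(unname(fib_af["f_K1"]), 1.0)
  expect_equal(unname(fib_af["f_CaL"]), 0.25)
  expect_equal(unname(fib_af["f_Na"]), 0.54)
  # applying the fibrotic multipliers twice is not idempotent
  expect_false(isTRUE(all.equal(fibrosis_remodeling_profile(fib), fib)))
})

test_that("resting state is stationary, stimulus depolarizes, scaling is linear", {
  y0 <- crn_resting_state()
  d0 <- crn_derivatives(y0)
  expect_lt(max(abs(d0)), 5e-3)

  d_stim <- crn_derivatives(y0, i_stim = -2000)
  expect_gt(d_stim["vm"], 1)

  expect_error(crn_derivatives(replace(y0, 1, NaN)), "non-finite")

  # doubling f_K1 exactly doubles I_K1 at fixed state
  c1 <- crn_currents(y0, neutral_profile())
  prof2 <- compose_profiles(neutral_profile(),
                            new_channel_scaling(c(2, 1, 1, 1, 1, 1)))
  c2 <- crn_currents(y0, prof2)
  expect_equal(c2[["i_K1"]], 2 * c1[["i_K1"]])
  expect_equal(c2[["i_Kr"]], c1[["i_Kr"]])
})

test_that("single-cell integration is bounded, stable and deterministic", {
  # zero duration leaves the state untouched
  tr0 <- integrate_cell(duration = 0)
  expect_length(tr0$times, 0)
  expect_equal(tr0$state, crn_resting_state())

  # 10 s quiescent: vm drifts by less than 1 mV
  trq <- integrate_cell(duration = 10000, out_dt = 10)
  expect_lt(max(abs(trq$vm - crn_resting_state()["vm"])), 1)

  # one paced beat: same call twice gives identical traces; final state has
  # all gates in [0, 1] and positive concentrations
  tr1 <- integrate_cell(stim_times = 0, duration = 400)
  tr2 <- integrate_cell(stim_times = 0, duration = 400)
  expect_identical(tr1$vm, tr2$vm)
  gates <- tr1$state[2:16]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(tr1$state[17:21] > 0))
  expect_true(all(tr1$vm >= -100 & tr1$vm <= 60))

  expect_error(integrate_cell(duration = 100, dt_min = 0.001),
               "dt bounds")
})

test_that("AP morphology matches an independently coded CRN oracle", {
  oracle <- crn_oracle_beat(neutral_profile(), duration = 600,
                            out_dt = 0.05)
  mine <- integrate_cell(stim_times = 0, duration = 600, dt_max = 0.02,
                         out_dt = 0.05)
  vi <- stats::approx(mine$times, mine$vm, xout = oracle$times, rule = 2)$y
  act_time <- function(tt, vv) tt[which.max(diff(vv))]
  t_act <- act_time(oracle$times, oracle$vm)
  # upstroke timing agrees to within 50 us ...
  expect_lt(abs(act_time(mine$times, mine$vm) - t_act), 0.05)
  # ... and amplitudes agree to < 2 mV outside a 3-ms window around the
  # 300 mV/ms upstroke, where a ~10-us lateral solver offset already moves
  # vm by several mV
  outside <- abs(oracle$times - t_act) > 3
  expect_lt(max(abs(vi[outside] - oracle$vm[outside])), 2)
  expect_lt(abs(max(vi) - max(oracle$vm)), 2)
  apd_o <- compute_apd90(list(times = oracle$times, vm = oracle$vm,
                              stim_times = 0))
  apd_m <- compute_apd90(mine)
  expect_lt(abs(apd_o - apd_m), 2)
})

test_that("APD90 of a synthetic triangular AP matches the closed form", {
  # rest -80 mV, instant rise to +20 at t = 10, linear fall over 200 ms:
  # 90% of the 100 mV recovered at 0.9 x 200 ms after activation
  times <- seq(0, 300, by = 0.25)
  vm <- rep(-80, length(times))
  act <- times >= 10 & times <= 210
  vm[act] <- 20 - 100 * (times[act] - 10) / 200
  tr <- list(times = times, vm = vm, stim_times = 10)
  expect_equal(compute_apd90(tr), 180, tolerance = 0.01)

  flat <- list(times = times, vm = rep(-80, length(times)), stim_times = 10)
  expect_error(compute_apd90(flat), "upstroke")
})
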