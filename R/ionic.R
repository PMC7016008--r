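#' Ion-channel scaling profiles
#'
#' A scaling profile is a named numeric vector of multiplicative factors
#' applied to six targeted membrane currents of the Courtemanche-Ramirez-
#' Nattel (CRN) atrial myocyte model: `f_K1` (inward rectifier), `f_NCX`
#' (Na+/Ca2+ exchanger), `f_Na` (fast sodium), `f_to` (transient outward),
#' `f_CaL` (L-type calcium) and `f_Kur` (ultrarapid delayed rectifier).
#' All other CRN currents are implicitly scaled by 1.
#'
#' @return A `channel_scaling` object (named numeric of length 6).
#' @examples
#' neutral_profile()
#' af_remodeling_profile()
#' @export
neutral_profile <- function() {
  new_channel_scaling(c(f_K1 = 1, f_NCX = 1, f_Na = 1, f_to = 1,
                        f_CaL = 1, f_Kur = 1))
}

new_channel_scaling <- function(x) {
  stopifnot(is.numeric(x), length(x) == 6)
  nm <- c("f_K1", "f_NCX", "f_Na", "f_to", "f_CaL", "f_Kur")
  if (is.null(names(x))) names(x) <- nm else x <- x[nm]
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all scaling factors must be finite and > 0")
  }
  structure(x, class = "channel_scaling")
}

#' @describeIn neutral_profile Chronic-AF electrical remodeling: I_K1 +100%,
#'   I_NCX +40%, I_Na -10%, I_to -70%, I_CaL -50%, I_Kur -50%.
#' @export
af_remodeling_profile <- function() {
  new_channel_scaling(c(f_K1 = 2.0, f_NCX = 1.4, f_Na = 0.9, f_to = 0.3,
                        f_CaL = 0.5, f_Kur = 0.5))
}

#' @describeIn neutral_profile Fibrotic-tissue remodeling applied on top of a
#'   base profile: I_K1 -50%, I_CaL -50%, I_Na -40% (factors multiply).
#' @param base base `channel_scaling` the fibrotic multipliers are applied to.
#' @export
fibrosis_remodeling_profile <- function(base = neutral_profile()) {
  compose_profiles(base, new_channel_scaling(
    c(f_K1 = 0.5, f_NCX = 1, f_Na = 0.6, f_to = 1, f_CaL = 0.5, f_Kur = 1)))
}

#' @describeIn neutral_profile Multiplicative composition of two profiles.
#' @param a,b profiles to compose.
#' @export
compose_profiles <- function(a, b) {
  new_channel_scaling(unclass(a) * unclass(b))
}

#' @export
print.channel_scaling <- function(x, ...) {
  cat("<channel_scaling>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' CRN resting state
#'
#' The published resting steady state of the CRN model: membrane potential,
#' 15 gating variables and 5 ionic concentration pools (21 variables).
#'
#' @return Named numeric vector of length 21 (`vm` in mV, gates
#'   dimensionless, concentrations in mM).
#' @export
crn_resting_state <- function() {
  y <- crn_resting_state_cpp()
  names(y) <- crn_state_names()
  y
}

#' @rdname crn_resting_state
#' @export
crn_state_names <- function() {
  c("vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "f_Ca", "u", "v", "w", "Na_i", "K_i", "Ca_i",
    "Ca_up", "Ca_rel")
}

#' CRN state time-derivatives
#'
#' Evaluates d(state)/dt of the full CRN model with a channel scaling
#' profile applied. The stimulus current is in pA; negative values
#' depolarize the membrane.
#'
#' @param state numeric(21) CRN state (see [crn_resting_state()]).
#' @param scaling a `channel_scaling` profile.
#' @param i_stim stimulus current, pA.
#' @return Named numeric(21) of time-derivatives (mV/ms, 1/ms, mM/ms).
#' @export
crn_derivatives <- function(state, scaling = neutral_profile(), i_stim = 0) {
  if (any(!is.finite(state))) stop("non-finite state")
  d <- crn_rates_cpp(as.numeric(state), as.numeric(scaling), i_stim)
  names(d) <- crn_state_names()
  d
}

#' Scaled CRN membrane currents at a fixed state
#'
#' @inheritParams crn_derivatives
#' @return Named numeric vector of the 12 membrane currents, pA.
#' @export
crn_currents <- function(state, scaling = neutral_profile()) {
  crn_currents_cpp(as.numeric(state), as.numeric(scaling))
}

#' Integrate a single CRN cell
#'
#' Rush-Larsen (gates) / forward-Euler (voltage and concentrations)
#' integration with the adaptive time step rule used throughout the tissue
#' solver: `dt_min` while any membrane is in its upstroke
#' (|dvm/dt| > 1 mV/ms), `dt_max` otherwise.
#'
#' @param initial numeric(21) initial state; defaults to the resting state.
#' @param scaling `channel_scaling` profile.
#' @param stim_times onset times of rectangular stimulus pulses, ms.
#' @param stim_duration pulse width, ms (default 2).
#' @param stim_amplitude pulse amplitude, pA (default -2000, about twice the
#'   diastolic threshold; negative = depolarizing).
#' @param duration total integration time, ms.
#' @param dt_min,dt_max adaptive time-step bounds, ms (0.01 and 0.1).
#' @param out_dt trace output interval, ms.
#' @return An `ap_trace` object: `times`, `vm`, `stim_times`, and the final
#'   `state` (for warm restarts).
#' @export
integrate_cell <- function(initial = crn_resting_state(),
                           scaling = neutral_profile(),
                           stim_times = numeric(),
                           stim_duration = 2,
                           stim_amplitude = -2000,
                           duration,
                           dt_min = 0.01, dt_max = 0.1,
                           out_dt = 0.5) {
  if (dt_min < 0.01 - 1e-12 || dt_max > 0.1 + 1e-12 || dt_min > dt_max) {
    stop("adaptive dt bounds must satisfy 0.01 <= dt_min <= dt_max <= 0.1 ms")
  }
  if (duration < 0) stop("duration must be >= 0")
  res <- integrate_cell_cpp(as.numeric(initial), as.numeric(scaling),
                            as.numeric(stim_times), stim_duration,
                            stim_amplitude, duration, dt_min, dt_max,
                            out_dt, 1.0)
  state <- res$state
  names(state) <- crn_state_names()
  structure(list(times = res$times, vm = res$vm,
                 stim_times = as.numeric(stim_times), state = state),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples over %.1f ms, %d stimuli\n",
              length(x$times), if (length(x$times)) max(x$times) else 0,
              length(x$stim_times)))
  invisible(x)
}

#' Action potential duration at 90% repolarization
#'
#' APD90 is measured from the activation time (maximum dvm/dt within the
#' beat) to the time vm recovers 90% of the way from the beat's peak back to
#' the pre-beat diastolic level, with linear interpolation between samples.
#'
#' @param trace an `ap_trace` (or list with `times`, `vm`, `stim_times`).
#' @param beat_index which beat to measure, 1-based; defaults to the last
#'   detected beat.
#' @return APD90 in ms.
#' @export
compute_apd90 <- function(trace, beat_index = NULL) {
  times <- trace$times
  vm <- trace$vm
  if (length(times) < 3) stop("trace too short for APD measurement")
  dv <- diff(vm) / diff(times)
  # beat boundaries: prefer stimulus marks, else detect upstrokes
  if (length(trace$stim_times)) {
    onsets <- trace$stim_times
  } else {
    cross <- which(vm[-length(vm)] < -40 & vm[-1] >= -40)
    if (!length(cross)) stop("no upstroke found in trace")
    # merge crossings closer than 50 ms (same beat)
    tc <- times[cross]
    onsets <- tc[c(TRUE, diff(tc) > 50)] - 5
  }
  onsets <- sort(onsets)
  if (is.null(beat_index)) beat_index <- length(onsets)
  if (beat_index < 1 || beat_index > length(onsets)) {
    stop("requested beat not present in trace")
  }
  t0 <- onsets[beat_index]
  t1 <- if (beat_index < length(onsets)) onsets[beat_index + 1] else max(times)
  # open the window one sample early so an upstroke right at the mark is kept
  margin <- 2 * stats::median(diff(times))
  in_beat <- which(times >= t0 - margin & times <= t1)
  if (length(in_beat) < 3) stop("requested beat not present in trace")
  # diastolic level just before the beat
  pre <- which(times < t0 - margin)
  v_rest <- if (length(pre)) vm[max(pre)] else vm[in_beat[1]]
  seg_t <- times[in_beat]
  seg_v <- vm[in_beat]
  dvseg <- diff(seg_v) / diff(seg_t)
  if (max(dvseg) <= 1) stop("no upstroke found in trace")
  i_act <- which.max(dvseg)
  t_act <- seg_t[i_act + 1]
  v_peak <- max(seg_v[i_act:length(seg_v)])
  v90 <- v_peak - 0.9 * (v_peak - v_rest)
  after <- which(seg_t > t_act)
  idx <- after[which(seg_v[after] <= v90)]
  if (!length(idx)) stop("repolarization to APD90 level not reached before next beat")
  k <- idx[1]
  # linear interpolation between sample k-1 and k
  tA <- seg_t[k - 1]; tB <- seg_t[k]
  vA <- seg_v[k - 1]; vB <- seg_v[k]
  t90 <- if (vA == vB) tB else tA + (vA - v90) / (vA - vB) * (tB - tA)
  t90 - t_act
}
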