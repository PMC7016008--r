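#' Tissue conductivities
#'
#' The four base conductivities of the model: longitudinal/transverse for
#' non-fibrotic and fibrotic tissue. Units S/m. Longitudinal must be at
#' least transverse within each tissue class.
#'
#' @param sigma_L_normal,sigma_L_fibrotic,sigma_T_normal,sigma_T_fibrotic
#'   conductivities, S/m.
#' @return A `conductivity_set` list.
#' @export
conductivity_set <- function(sigma_L_normal = 0.1264,
                             sigma_L_fibrotic = 0.0546,
                             sigma_T_normal = 0.0252,
                             sigma_T_fibrotic = 0.0068) {
  x <- list(sigma_L_normal = sigma_L_normal,
            sigma_L_fibrotic = sigma_L_fibrotic,
            sigma_T_normal = sigma_T_normal,
            sigma_T_fibrotic = sigma_T_fibrotic)
  if (any(unlist(x) <= 0)) stop("conductivities must be > 0")
  if (sigma_L_normal < sigma_T_normal ||
      sigma_L_fibrotic < sigma_T_fibrotic) {
    stop("longitudinal conductivity must be >= transverse")
  }
  structure(x, class = "conductivity_set")
}

#' Build the fiber-anisotropic diffusion operator
#'
#' Linear-triangle stiffness-style assembly of \eqn{\nabla\cdot(D\nabla)}
#' over the mesh surface, with the per-element diffusion tensor
#' \eqn{D = \kappa_L \sigma_L f f^T + \kappa_T \sigma_T t t^T} restricted
#' to the element's tangent plane (f = element fiber direction, t = the
#' in-plane perpendicular). \eqn{\sigma_L,\sigma_T} are chosen by the
#' element's fibrosis status (majority vote of its three nodes), and the
#' calibration constants \eqn{\kappa_L,\kappa_T} convert conductivity
#' (S/m) to a surface diffusivity (mm^2/ms); see [calibrate_conduction()].
#' Boundaries are zero-flux; rows of the operator sum to zero.
#'
#' @param mesh an `atrial_mesh` with fibers (and fibrosis flags).
#' @param conductivities a [conductivity_set()].
#' @param kappa length-2 numeric `c(kappa_L, kappa_T)` calibration scales.
#' @return A `diffusion_operator`: sparse operator `L` (dV/dt units 1/ms),
#'   stiffness `K`, lumped mass vector, and the inputs used.
#' @export
build_diffusion <- function(mesh, conductivities = conductivity_set(),
                            kappa = c(kappa_L = 1, kappa_T = 1)) {
  if (is.null(mesh$fiber)) stop("mesh has no fiber field")
  eg <- element_gradients(mesh)
  tr <- mesh$triangles
  m <- nrow(tr)
  # element fiber: mean of node fibers projected into the element plane
  ef <- (mesh$fiber[tr[, 1], , drop = FALSE] +
         mesh$fiber[tr[, 2], , drop = FALSE] +
         mesh$fiber[tr[, 3], , drop = FALSE]) / 3
  nrm <- eg$normal
  ef <- ef - nrm * rowSums(ef * nrm)
  efn <- sqrt(rowSums(ef^2))
  if (any(efn < 1e-9)) {
    stop("element fiber degenerate (opposing node fibers) in ",
         sum(efn < 1e-9), " elements")
  }
  ef <- ef / efn
  # in-plane transverse direction
  et <- cbind(nrm[, 2] * ef[, 3] - nrm[, 3] * ef[, 2],
              nrm[, 3] * ef[, 1] - nrm[, 1] * ef[, 3],
              nrm[, 1] * ef[, 2] - nrm[, 2] * ef[, 1])
  fib_elem <- (mesh$fibrosis[tr[, 1]] + mesh$fibrosis[tr[, 2]] +
               mesh$fibrosis[tr[, 3]]) >= 2
  dL <- kappa[1] * ifelse(fib_elem, conductivities$sigma_L_fibrotic,
                          conductivities$sigma_L_normal)
  dT <- kappa[2] * ifelse(fib_elem, conductivities$sigma_T_fibrotic,
                          conductivities$sigma_T_normal)
  # K[i,j] = sum_e A_e * grad_i' D grad_j
  gl <- list(eg$g1, eg$g2, eg$g3)
  ii <- jj <- xx <- vector("list", 9)
  k <- 1
  for (a in 1:3) {
    ga_f <- rowSums(gl[[a]] * ef)
    ga_t <- rowSums(gl[[a]] * et)
    for (b in 1:3) {
      gb_f <- rowSums(gl[[b]] * ef)
      gb_t <- rowSums(gl[[b]] * et)
      ii[[k]] <- tr[, a]
      jj[[k]] <- tr[, b]
      xx[[k]] <- eg$area * (dL * ga_f * gb_f + dT * ga_t * gb_t)
      k <- k + 1
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = rep(nrow(mesh$nodes), 2))
  mass <- numeric(nrow(mesh$nodes))
  for (a in 1:3) {
    s <- rowsum(eg$area / 3, tr[, a])
    mass[as.integer(rownames(s))] <- mass[as.integer(rownames(s))] + s
  }
  L <- methods::as(-Matrix::Diagonal(x = 1 / mass) %*% K, "CsparseMatrix")
  structure(list(L = L, K = K, mass = mass, kappa = kappa,
                 conductivities = conductivities,
                 n_nodes = nrow(mesh$nodes)),
            class = "diffusion_operator")
}

#' Pacing protocols
#'
#' A pacing protocol is a stimulus node set plus a list of rectangular
#' current pulses (onset, duration, amplitude). `stim_site_disk` selects
#' all nodes within a Euclidean radius of a seed node.
#'
#' @param site integer vector of stimulated node indices.
#' @param times pulse onset times, ms (non-negative, sorted internally).
#' @param duration pulse width, ms.
#' @param amplitude pulse amplitude, pA (negative = depolarizing).
#' @param label free-text protocol label.
#' @return A `pacing_protocol`.
#' @export
make_pacing_protocol <- function(site, times, duration = 2,
                                 amplitude = -2000, label = "custom") {
  if (!length(site)) stop("empty stimulus site")
  if (any(times < 0)) stop("event times must be non-negative")
  structure(list(site = as.integer(site),
                 events = data.frame(time = sort(as.numeric(times)),
                                     duration = duration,
                                     amplitude = amplitude),
                 label = label),
            class = "pacing_protocol")
}

#' @rdname make_pacing_protocol
#' @param mesh an `atrial_mesh`.
#' @param center_node seed node index.
#' @param radius disk radius, mm.
#' @export
stim_site_disk <- function(mesh, center_node, radius = 1) {
  d <- sqrt(rowSums(sweep(mesh$nodes, 2, mesh$nodes[center_node, ])^2))
  which(d <= radius)
}

#' Ramp pacing protocol for AF induction
#'
#' Stepped-down cycle lengths from `cl_start` to `cl_end` (default 200 to
#' 120 ms in 10-ms steps, `beats_per_step` beats each), continuing at
#' `cl_end` until the pacing train spans `total` ms (default 6,530). Any
#' remainder that does not divide into whole `cl_end` cycles is absorbed
#' into the final inter-beat interval, so the last cycle always ends
#' exactly at `total`.
#'
#' @inheritParams make_pacing_protocol
#' @param cl_start,cl_end first and last cycle length, ms.
#' @param total total pacing duration, ms.
#' @param cl_step cycle-length decrement per step, ms.
#' @param beats_per_step beats delivered at each cycle length.
#' @return A `pacing_protocol` with attribute `total` (= `total`).
#' @export
make_ramp_protocol <- function(site, cl_start = 200, cl_end = 120,
                               total = 6530, cl_step = 10,
                               beats_per_step = 4, duration = 2,
                               amplitude = -2000) {
  if (cl_end > cl_start) stop("cl_end must be <= cl_start")
  if (cl_start <= 0 || cl_end <= 0) stop("cycle lengths must be > 0")
  if (cl_start > total) stop("total too short for even one cycle")
  cls <- seq(cl_start, cl_end, by = -cl_step)
  intervals <- rep(utils::head(cls, -1), each = beats_per_step)
  onsets <- numeric(0)
  t <- 0
  k <- 1
  repeat {
    cl <- if (k <= length(intervals)) intervals[k] else cl_end
    if (t + cl > total + 1e-9) break
    onsets <- c(onsets, t)
    t <- t + cl
    k <- k + 1
  }
  if (!length(onsets)) stop("total too short for even one cycle")
  last_required <- total - cl_end
  if (abs(utils::tail(onsets, 1) - last_required) > 1e-9) {
    onsets <- onsets[onsets <= last_required - cl_end + 1e-9]
    onsets <- c(onsets, last_required)
  }
  p <- make_pacing_protocol(site, onsets, duration = duration,
                            amplitude = amplitude,
                            label = sprintf("ramp-%g-%g", cl_start, cl_end))
  attr(p, "total") <- total
  p
}

#' Run the monodomain simulation
#'
#' Operator-splitting integration of the monodomain reaction-diffusion
#' system on the mesh: reaction via the CRN model (Rush-Larsen gates,
#' forward-Euler voltage and concentrations), diffusion via explicit
#' sub-stepped updates of the assembled operator. The global time step
#' adapts between `dt_min` and `dt_max`: fine while any node's |dvm/dt|
#' exceeds 1 mV/ms, coarse otherwise. Per-node channel scaling is the base
#' profile, with fibrotic nodes additionally fibrosis-remodeled.
#' Deterministic: identical inputs give identical movies.
#'
#' @param mesh an `atrial_mesh` (with fibers, fibrosis flags).
#' @param operator a [build_diffusion()] operator for this mesh.
#' @param protocol a `pacing_protocol`, or a list of them (their events are
#'   merged; each protocol keeps its own site).
#' @param scaling base `channel_scaling` (default [af_remodeling_profile()]).
#' @param duration simulated time, ms.
#' @param output_interval movie sampling interval, ms (>= 1 recommended).
#' @param dt_min,dt_max adaptive time-step bounds, ms.
#' @param initial_states optional n x 21 matrix of initial CRN states (for
#'   warm restarts); default: resting state everywhere.
#' @return A `simulation_result`: `vm` (n x T movie, mV), `times` (ms),
#'   `final_states`, `protocol`, `n_steps`, `wall_time_s`.
#' @export
run_monodomain <- function(mesh, operator, protocol,
                           scaling = af_remodeling_profile(),
                           duration, output_interval = 1,
                           dt_min = 0.01, dt_max = 0.1,
                           initial_states = NULL) {
  if (!inherits(operator, "diffusion_operator") ||
      operator$n_nodes != nrow(mesh$nodes)) {
    stop("operator was not built on this mesh")
  }
  if (duration <= 0) stop("duration must be > 0")
  n <- nrow(mesh$nodes)
  if (is.null(initial_states)) {
    initial_states <- matrix(rep(crn_resting_state(), each = n), nrow = n)
  }
  fac <- matrix(rep(as.numeric(scaling), each = n), nrow = n)
  if (any(mesh$fibrosis)) {
    fibfac <- as.numeric(fibrosis_remodeling_profile(scaling))
    fac[mesh$fibrosis, ] <- matrix(rep(fibfac, each = sum(mesh$fibrosis)),
                                   ncol = 6)
  }
  protocols <- if (inherits(protocol, "pacing_protocol")) list(protocol)
               else protocol
  ev_start <- ev_dur <- ev_amp <- numeric(0)
  ev_nodes <- list()
  for (p in protocols) {
    stopifnot(inherits(p, "pacing_protocol"))
    if (any(p$site < 1 | p$site > n)) stop("stimulus site outside the mesh")
    ev_start <- c(ev_start, p$events$time)
    ev_dur <- c(ev_dur, p$events$duration)
    ev_amp <- c(ev_amp, p$events$amplitude)
    ev_nodes <- c(ev_nodes, rep(list(p$site - 1L), nrow(p$events)))
  }
  Lc <- operator$L
  t0 <- proc.time()[3]
  res <- run_monodomain_cpp(initial_states, fac,
                            Lc@p, Lc@i, Lc@x,
                            ev_start, ev_dur, ev_amp, ev_nodes,
                            duration, dt_min, dt_max, output_interval, 1.0)
  structure(list(vm = res$vm, times = res$times,
                 final_states = res$states,
                 protocol = protocols,
                 output_interval = output_interval,
                 n_steps = res$n_steps,
                 wall_time_s = unname(proc.time()[3] - t0)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d nodes x %d frames (%.0f ms at %g ms)",
              nrow(x$vm), ncol(x$vm), max(x$times), x$output_interval))
  if (!is.null(x$wall_time_s)) cat(sprintf(", %.1f s wall", x$wall_time_s))
  cat("\n")
  invisible(x)
}

#' Extract a local activation time map
#'
#' Per-node first time vm crosses `threshold` (default -40 mV) with
#' positive slope at or after `after`, linearly interpolated between movie
#' frames. Non-activated nodes are NA.
#'
#' @param result a `simulation_result`.
#' @param after reference time (stimulus onset), ms.
#' @param threshold crossing threshold, mV.
#' @return A `lat_map`: list(lat, eas_node, activated).
#' @export
extract_lat <- function(result, after = 0, threshold = -40) {
  tt <- result$times
  sel <- which(tt >= after)
  if (length(sel) < 2) stop("result does not contain the requested event")
  vm <- result$vm[, sel, drop = FALSE]
  ts <- tt[sel]
  n <- nrow(vm)
  lat <- rep(NA_real_, n)
  below <- vm[, -ncol(vm), drop = FALSE] < threshold
  above <- vm[, -1, drop = FALSE] >= threshold
  for (i in seq_len(n)) {
    k <- which(below[i, ] & above[i, ])
    if (length(k)) {
      k <- k[1]
      v0 <- vm[i, k]; v1 <- vm[i, k + 1]
      lat[i] <- ts[k] + (threshold - v0) / (v1 - v0) * (ts[k + 1] - ts[k])
    }
  }
  if (all(is.na(lat))) stop("no node activates after t = ", after)
  structure(list(lat = lat, eas_node = which.min(lat),
                 activated = !is.na(lat), reference = after),
            class = "lat_map")
}

#' Conduction velocity from a LAT map
#'
#' CV to each target is the on-surface (geodesic) distance from the
#' earliest-activation site divided by the activation-time difference;
#' mm/ms equals m/s.
#'
#' @param latmap a `lat_map`.
#' @param mesh the mesh the LAT map lives on.
#' @param eas earliest-activation-site node index.
#' @param targets integer vector of target nodes.
#' @return list(cv = per-target m/s, mean_cv, distance_mm, dt_ms).
#' @export
measure_cv <- function(latmap, mesh, eas, targets) {
  if (any(is.na(latmap$lat[c(eas, targets)]))) {
    stop("EAS or target node did not activate")
  }
  d <- geodesic_distance(mesh, eas, targets)
  dt <- latmap$lat[targets] - latmap$lat[eas]
  if (any(dt <= 0)) {
    stop("non-positive activation-time difference for target(s) ",
         paste(targets[dt <= 0], collapse = ", "))
  }
  cv <- d / dt # mm/ms = m/s
  list(cv = cv, mean_cv = mean(cv), distance_mm = d, dt_ms = dt)
}

# planar-wave CV on a calibration sheet: stimulate the left edge, measure
# between the midline nodes nearest x = x1 and x = x2
planar_cv <- function(mesh, operator, scaling, x1 = 10, x2 = 20,
                      duration, dt_max = 0.1) {
  edge <- which(mesh$nodes[, 1] <= min(mesh$nodes[, 1]) + 0.5)
  prot <- make_pacing_protocol(edge, 0, amplitude = -8000, label = "S1-edge")
  res <- run_monodomain(mesh, operator, prot, scaling = scaling,
                        duration = duration, output_interval = 0.5,
                        dt_max = dt_max)
  lm <- extract_lat(res)
  ymid <- stats::median(mesh$nodes[, 2])
  row <- which(abs(mesh$nodes[, 2] - ymid) < 1e-6)
  if (length(row) < 2) {
    row <- which(abs(mesh$nodes[, 2] - ymid) <
                   min(abs(mesh$nodes[, 2] - ymid)) + 1e-6)
  }
  nA <- row[which.min(abs(mesh$nodes[row, 1] - x1))]
  nB <- row[which.min(abs(mesh$nodes[row, 1] - x2))]
  if (is.na(lm$lat[nA]) || is.na(lm$lat[nB])) return(NA_real_)
  measure_cv(lm, mesh, nA, nB)$mean_cv
}

#' Calibrate the conductivity-to-diffusivity conversion
#'
#' The model's observable conduction velocities are fixed by matching
#' planar-wave CV on uniform non-fibrotic AF-remodeled test sheets to the
#' target longitudinal and transverse CVs (defaults 0.707 and 0.486 m/s).
#' The two calibration scales \eqn{\kappa_L,\kappa_T} (mm^2/ms per S/m)
#' are found independently by a fixed-point iteration accelerated by the
#' continuum law CV \eqn{\propto\sqrt{D}}; they are then frozen for all
#' runs (patient-level tuning scales both at the same rate, see
#' [tune_diffusion()]).
#'
#' @param conductivities a [conductivity_set()].
#' @param spacing_um sheet mesh resolution, um.
#' @param sheet_width,sheet_height test-sheet dimensions, mm.
#' @param scaling base `channel_scaling` of the calibration tissue.
#' @param cv_targets `c(longitudinal, transverse)` m/s.
#' @param tol relative CV tolerance (default 0.01, the repeatability of the
#'   planar CV probe itself).
#' @param max_eval maximum CV evaluations per direction.
#' @param verbose print per-iteration CVs.
#' @return `c(kappa_L, kappa_T)` with attribute `achieved_cv`.
#' @export
calibrate_conduction <- function(conductivities = conductivity_set(),
                                 spacing_um = 235,
                                 sheet_width = 30, sheet_height = 10,
                                 scaling = af_remodeling_profile(),
                                 cv_targets = c(0.707, 0.486),
                                 tol = 0.01, max_eval = 8,
                                 verbose = FALSE) {
  mesh_L <- generate_sheet_mesh(sheet_width, sheet_height, spacing_um)
  mesh_T <- assign_fiber_field(mesh_L, "uniform", direction = c(0, 1, 0))
  calibrate_dir <- function(longitudinal, kappa0, kappa_other) {
    # fibers along x for the longitudinal test (wave along fibers),
    # along y for the transverse test (the wave still runs along x);
    # the other direction's kappa is held at its current estimate so the
    # discrete stencil sees the same cross coupling as production runs
    mesh <- if (longitudinal) mesh_L else mesh_T
    target <- if (longitudinal) cv_targets[1] else cv_targets[2]
    kappa <- kappa0
    cvs <- numeric(0)
    for (it in seq_len(max_eval)) {
      kap <- if (longitudinal) c(kappa, kappa_other) else c(kappa_other, kappa)
      op <- build_diffusion(mesh, conductivities, kap)
      dur <- 15 + 22 / (0.6 * target)
      cv <- planar_cv(mesh, op, scaling, duration = dur)
      if (is.na(cv)) { # wave too slow to reach the far probe: push kappa up
        kappa <- kappa * 4
        next
      }
      cvs <- c(cvs, cv)
      if (verbose) {
        message(sprintf("  %s: kappa=%.4f cv=%.4f m/s",
                        if (longitudinal) "L" else "T", kappa, cv))
      }
      if (abs(cv - target) <= tol * target) {
        return(list(kappa = kappa, cv = cv))
      }
      kappa <- kappa * (target / cv)^2
    }
    stop(sprintf(
      "calibration failed to converge (achieved CV range %.3f-%.3f m/s)",
      if (length(cvs)) min(cvs) else NA, if (length(cvs)) max(cvs) else NA))
  }
  sig <- conductivities
  # initial guesses from typical atrial diffusivities (D ~ 0.4 / 0.2 mm^2/ms)
  kL0 <- 0.4 / sig$sigma_L_normal
  kT0 <- 0.2 / sig$sigma_T_normal
  # two passes: each direction is re-tuned with the other's latest value,
  # since the triangular stencil weakly couples the two axes
  L <- calibrate_dir(TRUE, kL0, kT0)
  T_ <- calibrate_dir(FALSE, kT0, L$kappa)
  L <- calibrate_dir(TRUE, L$kappa, T_$kappa)
  T_ <- calibrate_dir(FALSE, T_$kappa, L$kappa)
  out <- c(kappa_L = L$kappa, kappa_T = T_$kappa)
  attr(out, "achieved_cv") <- c(longitudinal = L$cv, transverse = T_$cv)
  out
}

#' Patient-level diffusion tuning against clinical conduction times
#'
#' Finds one multiplicative factor applied to both \eqn{\kappa_L} and
#' \eqn{\kappa_T} (longitudinal and transverse scaled at the same rate) so
#' that the mean simulated conduction time from the earliest-activation
#' site to the target nodes matches the clinical mean within `tol`.
#' Uses the CV \eqn{\propto\sqrt{D}} law for the update, so convergence
#' takes a handful of simulations.
#'
#' @param mesh an `atrial_mesh` with fibers and fibrosis.
#' @param conductivities a [conductivity_set()].
#' @param kappa calibrated `c(kappa_L, kappa_T)`.
#' @param protocol pacing protocol defining the EAS stimulus.
#' @param targets target node indices.
#' @param clinical_times clinical conduction times to the targets, ms.
#' @param scaling base `channel_scaling`.
#' @param duration per-iteration simulation length, ms.
#' @param tol relative tolerance on the mean conduction time.
#' @param max_iter iteration cap (error on non-convergence, reporting the
#'   best factor).
#' @return The scale factor, with attributes `residuals_ms` (per-target)
#'   and `virtual_times_ms`.
#' @export
tune_diffusion <- function(mesh, conductivities, kappa, protocol, targets,
                           clinical_times, scaling = af_remodeling_profile(),
                           duration = 60, tol = 0.02, max_iter = 30) {
  if (!length(targets) || length(clinical_times) != length(targets)) {
    stop("need one clinical conduction time per target")
  }
  if (all(clinical_times <= 0)) stop("clinical conduction times must be > 0")
  scale <- 1
  best <- NULL
  for (it in seq_len(max_iter)) {
    op <- build_diffusion(mesh, conductivities, kappa * scale)
    res <- run_monodomain(mesh, op, protocol, scaling = scaling,
                          duration = duration, output_interval = 1)
    lm <- extract_lat(res)
    if (any(is.na(lm$lat[targets]))) {
      scale <- scale * 2 # wave too slow to reach all targets
      next
    }
    virt <- lm$lat[targets] - min(lm$lat, na.rm = TRUE)
    err <- mean(virt) / mean(clinical_times) - 1
    if (is.null(best) || abs(err) < abs(best$err)) {
      best <- list(scale = scale, err = err, virt = virt)
    }
    if (abs(err) <= tol) {
      out <- scale
      attr(out, "virtual_times_ms") <- virt
      attr(out, "residuals_ms") <- virt - clinical_times
      return(out)
    }
    # times ~ 1/CV ~ 1/sqrt(scale)
    scale <- scale * (mean(virt) / mean(clinical_times))^2
  }
  stop(sprintf(
    "tune_diffusion did not converge in %d iterations (best factor %.3f, mean-time error %.1f%%)",
    max_iter, best$scale, 100 * best$err))
}

#' Detect sustained AF after pacing
#'
#' The episode counts as induced when activation (some node crossing
#' `threshold` upward) continues through the whole post-pacing analysis
#' window with no electrically silent gap longer than `max_gap` ms.
#'
#' @param result a `simulation_result` extending at least `window` ms past
#'   the last stimulus.
#' @param protocol the pacing protocol that was applied.
#' @param window analysis window length, ms (default 6000).
#' @param max_gap longest tolerated silent gap, ms.
#' @param threshold activation threshold, mV.
#' @return list(induced, window = c(start, end), activation_times).
#' @export
detect_induction <- function(result, protocol, window = 6000,
                             max_gap = 500, threshold = -40) {
  protocols <- if (inherits(protocol, "pacing_protocol")) list(protocol)
               else protocol
  t_end <- max(vapply(protocols, function(p)
    max(p$events$time + p$events$duration), numeric(1)))
  if (max(result$times) < t_end + window - 1e-6) {
    stop(sprintf("result too short: need %g ms past the last stimulus",
                 window))
  }
  sel <- which(result$times >= t_end & result$times <= t_end + window)
  vm <- result$vm[, sel, drop = FALSE]
  ts <- result$times[sel]
  up <- vm[, -ncol(vm), drop = FALSE] < threshold &
        vm[, -1, drop = FALSE] >= threshold
  act <- ts[-1][colSums(up) > 0]
  gaps <- diff(c(t_end, act, t_end + window))
  list(induced = length(act) > 0 && max(gaps) <= max_gap,
       window = c(start = t_end, end = t_end + window),
       activation_times = act)
}
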