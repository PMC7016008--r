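#' Stereotyped action-potential template
#'
#' Piecewise atrial AP waveform used by the movie fixtures: resting at
#' -80 mV, a 1-ms linear upstroke to +20 mV, then a raised-cosine
#' repolarization shaped so that 90% of the amplitude is recovered exactly
#' `apd90` ms after activation. Lets the analysis modules be tested
#' without running the ionic solver.
#'
#' @param t_since_activation time since local activation, ms (vectorized;
#'   negative = not yet activated).
#' @param apd90 action potential duration at 90% repolarization, ms.
#' @return Membrane potential, mV.
#' @export
ap_template <- function(t_since_activation, apd90 = 150) {
  t <- t_since_activation
  v <- rep(-80, length(t))
  up <- which(t >= 0 & t < 1)
  v[up] <- -80 + 100 * t[up]
  # raised cosine from +20 back to -80; 90% recovered at t = apd90:
  # 0.5*(1+cos(pi*x90)) = 0.1  =>  x90 = acos(-0.8)/pi
  x90 <- acos(-0.8) / pi
  Tfull <- (apd90 - 1) / x90
  rep_idx <- which(t >= 1)
  x <- pmin((t[rep_idx] - 1) / Tfull, 1)
  v[rep_idx] <- -80 + 100 * 0.5 * (1 + cos(pi * x))
  v
}

#' Plane-wave membrane-potential movie
#'
#' A stereotyped AP waveform translated across the mesh at constant speed:
#' node activation times are (p . direction)/speed per beat, so the
#' extracted LAT map is exactly linear in distance and [measure_cv()]
#' recovers `speed`. Used for wavelength measurement (CV at a 600-ms
#' cycle length) and as a kinematic oracle.
#'
#' @param mesh an `atrial_mesh`.
#' @param direction length-3 propagation direction.
#' @param speed conduction speed, m/s (= mm/ms).
#' @param cl cycle length between beats, ms.
#' @param duration movie length, ms (> 0).
#' @param apd90 template APD90, ms.
#' @param output_interval frame interval, ms.
#' @return A `simulation_result` with attribute `true_lat` (first-beat
#'   activation times).
#' @export
make_plane_wave_movie <- function(mesh, direction = c(1, 0, 0), speed = 0.5,
                                  cl = 600, duration = 1000, apd90 = 150,
                                  output_interval = 1) {
  if (speed <= 0 || cl <= 0) stop("speed and cl must be > 0")
  if (duration <= 0) stop("empty movie: duration must be > 0")
  u <- direction / sqrt(sum(direction^2))
  proj <- as.numeric(mesh$nodes %*% u)
  lat0 <- (proj - min(proj)) / speed
  times <- seq(0, duration, by = output_interval)
  n <- nrow(mesh$nodes)
  vm <- matrix(-80, n, length(times))
  for (k in seq_along(times)) {
    tk <- times[k]
    # most recent beat per node
    beat <- floor((tk - lat0) / cl)
    tsa <- tk - lat0 - beat * cl
    tsa[beat < 0] <- -1
    vm[, k] <- ap_template(tsa, apd90)
  }
  structure(list(vm = vm, times = times, final_states = NULL,
                 protocol = list(), output_interval = output_interval,
                 n_steps = 0, wall_time_s = 0,
                 true_lat = lat0),
            class = "simulation_result")
}

#' Spiral-wave membrane-potential movie with known tip path
#'
#' Rigidly rotating (optionally drifting) Archimedean spiral on a flat
#' sheet: vm = raised-cosine carrier of the spiral phase
#' \eqn{\theta = atan2(y-y_c, x-x_c) - \omega t + 2\pi r/\lambda}. The
#' phase singularity sits exactly at the (drifting) core, giving a
#' ground-truth tip path for PS detection and mother-rotor tests.
#'
#' @param mesh a flat `atrial_mesh` (z = const).
#' @param core length-2 or -3 initial core position, mm.
#' @param frequency rotation frequency, Hz; its sign sets the chirality
#'   reported by the phase-winding detector (+1 for positive).
#' @param drift length-2 drift velocity, mm/s.
#' @param wavelength_mm spatial arm spacing of the spiral, mm.
#' @param duration movie length, ms.
#' @param output_interval frame interval, ms.
#' @return A `simulation_result` with attribute `true_tip` (data.frame
#'   time, x, y) and `chirality`.
#' @export
make_spiral_movie <- function(mesh, core = NULL, frequency = 6,
                              drift = c(0, 0), wavelength_mm = 40,
                              duration = 1000, output_interval = 10) {
  if (diff(range(mesh$nodes[, 3])) > 1e-6) {
    stop("spiral fixture requires a flat (z = const) sheet")
  }
  if (is.null(core)) {
    core <- c(mean(range(mesh$nodes[, 1])), mean(range(mesh$nodes[, 2])))
  }
  core <- core[1:2]
  omega <- 2 * pi * frequency / 1000 # rad/ms
  times <- seq(0, duration, by = output_interval)
  n <- nrow(mesh$nodes)
  vm <- matrix(0, n, length(times))
  tip <- matrix(0, length(times), 2)
  for (k in seq_along(times)) {
    tk <- times[k]
    ck <- core + drift * tk / 1000
    tip[k, ] <- ck
    dx <- mesh$nodes[, 1] - ck[1]
    dy <- mesh$nodes[, 2] - ck[2]
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) + omega * tk + 2 * pi * r / wavelength_mm
    vm[, k] <- -55 + 45 * cos(th)
  }
  structure(list(vm = vm, times = times, final_states = NULL,
                 protocol = list(), output_interval = output_interval,
                 n_steps = 0, wall_time_s = 0,
                 true_tip = data.frame(time = times, x = tip[, 1],
                                       y = tip[, 2]),
                 chirality = if (frequency >= 0) 1L else -1L),
            class = "simulation_result")
}

#' Partition a mesh into contiguous regions
#'
#' Labels every node 1..n_regions by equal-count quantile bins of the
#' first principal coordinate (strips). On a sheet each region is a
#' connected band; the labels partition the node set.
#'
#' @param mesh an `atrial_mesh`.
#' @param n_regions number of regions (>= 1, <= node count).
#' @return The mesh with `region` set.
#' @export
make_labeled_regions <- function(mesh, n_regions = 10) {
  n <- nrow(mesh$nodes)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (n_regions > n) stop("n_regions exceeds the node count")
  ctr <- sweep(mesh$nodes, 2, colMeans(mesh$nodes))
  pc1 <- ctr %*% svd(ctr, nu = 0, nv = 1)$v[, 1]
  ranks <- rank(pc1, ties.method = "first")
  mesh$region <- as.integer(ceiling(ranks / n * n_regions))
  mesh
}

#' Declarative fixture specification
#'
#' Small key-value text files describing a fixture (`kind` plus
#' parameters and a seed), so test inputs are reproducible from the spec
#' alone. `read_fixture_spec` parses `key: value` lines;
#' `build_fixture` materializes the fixture.
#'
#' @param path spec file path.
#' @return `read_fixture_spec`: named list (numbers parsed);
#'   `build_fixture`: the fixture object.
#' @export
read_fixture_spec <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, ":", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2) stop("malformed fixture spec line: ", p[[1]])
    key <- trimws(p[[1]])
    val <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    out[[key]] <- if (any(is.na(num))) val else num
  }
  out
}

#' @rdname read_fixture_spec
#' @param spec a parsed fixture spec (named list).
#' @export
build_fixture <- function(spec) {
  kind <- spec$kind
  if (is.null(kind)) stop("fixture spec lacks a 'kind'")
  get_or <- function(nm, default) if (!is.null(spec[[nm]])) spec[[nm]] else default
  switch(kind,
    sheet = generate_sheet_mesh(get_or("width", 20), get_or("height", 20),
                                get_or("spacing", 500)),
    sphere = generate_sphere_mesh(get_or("radius", 10),
                                  get_or("subdivisions", 3)),
    "labeled-sheet" = make_labeled_regions(
      generate_sheet_mesh(get_or("width", 20), get_or("height", 20),
                          get_or("spacing", 500)),
      get_or("n_regions", 10)),
    "plane-wave" = make_plane_wave_movie(
      build_fixture(list(kind = "sheet", width = get_or("width", 20),
                         height = get_or("height", 20),
                         spacing = get_or("spacing", 500))),
      speed = get_or("speed", 0.5), cl = get_or("cl", 600),
      duration = get_or("duration", 1000)),
    spiral = make_spiral_movie(
      build_fixture(list(kind = "sheet", width = get_or("width", 40),
                         height = get_or("height", 40),
                         spacing = get_or("spacing", 800))),
      frequency = get_or("frequency", 6),
      duration = get_or("duration", 1000)),
    emap = {
      mesh <- build_fixture(list(kind = "sheet", width = get_or("width", 20),
                                 height = get_or("height", 20),
                                 spacing = get_or("spacing", 500)))
      generate_synthetic_emap(mesh, n_points = get_or("n_points", 500),
                              seed = get_or("seed", 1))
    },
    stop("unknown fixture kind: ", kind))
}
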