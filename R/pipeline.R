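#' Run configuration
#'
#' A flat, human-editable `key = value` configuration covering every stage
#' of a study: mesh source, electro-anatomical map source, interpolation,
#' fibrosis seed, fiber rule, conduction constants, pacing protocol and
#' analysis settings. Every physical constant of the model appears here
#' with its default, so each is overridable per run. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the default keys (see `default_run_config()`).
#' @return A `run_config` (named list).
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
default_run_config <- function() {
  list(
    mesh.path = "",
    mesh.width_mm = 30, mesh.height_mm = 30, mesh.spacing_um = 500,
    emap.path = "",
    emap.n_points = 500, emap.speed_mps = 0.7,
    emap.voltage_min_mv = 0.1, emap.voltage_max_mv = 3.5,
    emap.noise_sd_voltage_mv = 0.05, emap.noise_sd_lat_ms = 1,
    idw.radius_mm = 10, idw.power = 2,
    fibers.rule = "from_lat_gradient",
    conduction.sigma_L_normal = 0.1264, conduction.sigma_L_fibrotic = 0.0546,
    conduction.sigma_T_normal = 0.0252, conduction.sigma_T_fibrotic = 0.0068,
    conduction.kappa_L = NA_real_, conduction.kappa_T = NA_real_,
    conduction.tune = 1, conduction.n_targets = 5,
    pacing.cl_start_ms = 200, pacing.cl_end_ms = 120,
    pacing.total_ms = 6530, pacing.site_radius_mm = 2,
    pacing.amplitude_pa = -4000,
    analysis.window_ms = 6000, analysis.df_low_hz = 1,
    analysis.df_high_hz = 20, analysis.top_fraction = 0.05,
    analysis.frame_ms = 10, analysis.max_step_mm = 5,
    analysis.n_regions = 10,
    run.seed = 1, run.label = "study", run.output_dir = ""
  )
}

#' @rdname run_config
#' @param path config file path (`key = value` lines, `#` comments).
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  over <- list()
  for (l in ln) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    over[[key]] <- if (is.na(num) && !identical(val, "NA")) val else num
  }
  do.call(run_config, over)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  ln <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(ln, path)
  invisible(path)
}

stage_log <- function(report, stage, t0, ...) {
  dt <- proc.time()[3] - t0
  message(sprintf("[%s] %-12s %6.1f s  %s", format(Sys.time(), "%H:%M:%S"),
                  stage, dt, paste(..., collapse = " ")))
  report$stages[[stage]] <- list(seconds = unname(dt), note = paste(...))
  report
}

#' Run a full personalized-AF study
#'
#' End-to-end orchestration: load or synthesize the mesh and the
#' electro-anatomical map; interpolate voltage and LAT onto the mesh
#' (IDW); assign fibrosis stochastically from the voltage field; set
#' fibers from the LAT gradient; calibrate (or accept) the
#' conductivity-to-diffusivity constants and tune them to the map's
#' conduction times; induce AF by ramp pacing; and, if activity sustains
#' through the post-pacing window, compute the DF map, the top-DF region,
#' PS trajectories and mother-rotor verdicts. Non-induction is reported,
#' not an error. Deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @return A `wave_dynamics_report` (also written to
#'   `run.output_dir` when set): fibrosis fraction, induction verdict,
#'   DF summary, PS counts, per-region tables and provenance.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(label = config$run.label, stages = list(),
                 provenance = list(
                   seed = config$run.seed,
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("atrialwave"))))
  t0 <- proc.time()[3]

  # --- geometry ---
  mesh <- if (nzchar(config$mesh.path)) {
    load_mesh(config$mesh.path)
  } else {
    generate_sheet_mesh(config$mesh.width_mm, config$mesh.height_mm,
                        config$mesh.spacing_um)
  }
  mesh <- make_labeled_regions(mesh, config$analysis.n_regions)
  st <- mesh_statistics(mesh)
  report <- stage_log(report, "mesh", t0,
                      sprintf("%d nodes, %.0f um spacing", st$n_nodes,
                              st$mean_spacing_um))

  # --- electro-anatomical map ---
  t0 <- proc.time()[3]
  if (nzchar(config$emap.path)) {
    map <- read_emap(config$emap.path)
  } else {
    syn <- generate_synthetic_emap(
      mesh, n_points = config$emap.n_points, speed = config$emap.speed_mps,
      voltage_range = c(config$emap.voltage_min_mv,
                        config$emap.voltage_max_mv),
      noise_sd_voltage = config$emap.noise_sd_voltage_mv,
      noise_sd_lat = config$emap.noise_sd_lat_ms, seed = config$run.seed)
    map <- syn$map
  }
  report <- stage_log(report, "emap", t0, sprintf("%d points",
                                                  nrow(map$points)))

  # --- interpolation ---
  t0 <- proc.time()[3]
  vfield <- idw_interpolate(map, mesh, "voltage",
                            radius = config$idw.radius_mm,
                            power = config$idw.power)
  lfield <- idw_interpolate(map, mesh, "lat",
                            radius = config$idw.radius_mm,
                            power = config$idw.power,
                            uncovered_value = NA_real_)
  report <- stage_log(report, "interpolate", t0,
                      sprintf("%.1f%% coverage", 100 * mean(vfield$covered)))

  # --- fibrosis ---
  t0 <- proc.time()[3]
  mesh <- assign_fibrosis(mesh, vfield, fibrosis_model(config$run.seed))
  report$fibrosis_fraction <- attr(mesh, "fibrosis_fraction")
  report <- stage_log(report, "fibrosis", t0,
                      sprintf("%.1f%% fibrotic",
                              100 * report$fibrosis_fraction))

  # --- fibers ---
  t0 <- proc.time()[3]
  lat_for_fibers <- lfield$values
  if (anyNA(lat_for_fibers)) {
    lat_for_fibers[is.na(lat_for_fibers)] <-
      mean(lat_for_fibers, na.rm = TRUE)
  }
  mesh <- switch(config$fibers.rule,
    from_lat_gradient = assign_fiber_field(mesh, "from_lat_gradient",
                                           lat = lat_for_fibers),
    uniform = assign_fiber_field(mesh, "uniform", direction = c(1, 0, 0)),
    stop("unknown fibers.rule: ", config$fibers.rule))
  report <- stage_log(report, "fibers", t0, config$fibers.rule)

  # --- conduction constants ---
  t0 <- proc.time()[3]
  cond <- conductivity_set(config$conduction.sigma_L_normal,
                           config$conduction.sigma_L_fibrotic,
                           config$conduction.sigma_T_normal,
                           config$conduction.sigma_T_fibrotic)
  if (is.na(config$conduction.kappa_L) || is.na(config$conduction.kappa_T)) {
    kappa <- calibrate_conduction(cond,
                                  spacing_um = config$mesh.spacing_um)
  } else {
    kappa <- c(kappa_L = config$conduction.kappa_L,
               kappa_T = config$conduction.kappa_T)
  }
  report$kappa <- unname(kappa[1:2])

  # earliest-activation site and pacing site: covered node with minimal LAT
  cov_idx <- which(lfield$covered)
  eas <- cov_idx[which.min(lfield$values[cov_idx])]
  site <- stim_site_disk(mesh, eas, config$pacing.site_radius_mm)
  scale <- 1
  if (config$conduction.tune > 0) {
    targets <- pick_spread_targets(mesh, eas, config$conduction.n_targets,
                                   cov_idx)
    clin <- lfield$values[targets] - lfield$values[eas]
    keep <- clin > 0
    if (sum(keep) >= 1) {
      prot <- make_pacing_protocol(site, 0,
                                   amplitude = config$pacing.amplitude_pa,
                                   label = "S1-tune")
      dur <- min(1.5 * max(clin[keep]) + 30, 400)
      scale <- as.numeric(tune_diffusion(mesh, cond, kappa, prot,
                                         targets[keep], clin[keep],
                                         duration = dur))
    }
  }
  report$diffusion_scale <- scale
  kappa_run <- kappa * scale
  op <- build_diffusion(mesh, cond, kappa_run)
  report <- stage_log(report, "conduction", t0,
                      sprintf("kappa=(%.3f, %.3f) x %.3f", kappa[1],
                              kappa[2], scale))

  # --- AF induction ---
  t0 <- proc.time()[3]
  ramp <- make_ramp_protocol(site, cl_start = config$pacing.cl_start_ms,
                             cl_end = config$pacing.cl_end_ms,
                             total = config$pacing.total_ms,
                             amplitude = config$pacing.amplitude_pa)
  duration <- config$pacing.total_ms + config$analysis.window_ms + 10
  res <- run_monodomain(mesh, op, ramp, duration = duration,
                        output_interval = config$analysis.frame_ms)
  ind <- detect_induction(res, ramp, window = config$analysis.window_ms)
  report$induced <- ind$induced
  report$analysis_window_ms <- unname(ind$window)
  report <- stage_log(report, "induction", t0,
                      if (ind$induced) "AF sustained" else "not induced")

  # --- wave-dynamics analysis ---
  if (ind$induced) {
    t0 <- proc.time()[3]
    win <- ind$window
    dfmap <- compute_df_map(res, window = win,
                            band = c(config$analysis.df_low_hz,
                                     config$analysis.df_high_hz))
    top <- top_df_region(dfmap, config$analysis.top_fraction)
    phase <- compute_phase(res, window = win)
    events <- detect_ps_series(phase, mesh)
    trajs <- link_trajectories(events, config$analysis.max_step_mm, mesh)
    # wavelength from a 600-ms-CL plane wave at the tuned conduction speed
    pw_mesh <- generate_sheet_mesh(20, 6, 500)
    pw_op <- build_diffusion(pw_mesh, cond, kappa_run)
    cv600 <- planar_cv(pw_mesh, pw_op, af_remodeling_profile(),
                       x1 = 5, x2 = 15, duration = 80)
    wl <- wavelength_from_cv(cv600)
    crit <- mother_rotor_criterion(wl)
    verdicts <- vapply(trajs$trajectories, classify_mother_rotor,
                       logical(1), criterion = crit)
    report$df <- list(peak_node = top$peak_node,
                      peak_df_hz = dfmap$df_hz[top$peak_node],
                      top_nodes = top$nodes,
                      mean_df_hz = mean(dfmap$df_hz, na.rm = TRUE))
    report$ps <- list(n_events = nrow(events),
                      n_trajectories = length(trajs$trajectories),
                      region_counts = trajs$region_counts,
                      mother_rotor = verdicts,
                      wavelength_mm = wl)
    report$per_region <- per_region_table(mesh, dfmap, trajs)
    report$dfmap <- dfmap
    report$trajectories <- trajs
    report <- stage_log(report, "wavedynamics", t0,
                        sprintf("%d PS events, %d trajectories",
                                nrow(events), length(trajs$trajectories)))
  }

  report <- structure(report, class = "wave_dynamics_report")
  if (nzchar(config$run.output_dir)) {
    write_report(report, config, mesh, res, config$run.output_dir)
  }
  report
}

pick_spread_targets <- function(mesh, eas, n, candidates) {
  d <- geodesic_distance(mesh, eas, candidates)
  ord <- candidates[order(d)]
  qs <- unique(round(seq(0.5, 0.95, length.out = n) * length(ord)))
  ord[pmax(qs, 1)]
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small deterministic polynomial hash (no external digest dependency)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 16777213
  sprintf("%06x", h)
}

per_region_table <- function(mesh, dfmap, trajs) {
  regs <- sort(unique(mesh$region[mesh$region != 0]))
  fib <- vapply(regs, function(r) mean(mesh$fibrosis[mesh$region == r]),
                numeric(1))
  df <- vapply(regs, function(r)
    mean(dfmap$df_hz[mesh$region == r], na.rm = TRUE), numeric(1))
  ps <- rep(0, length(regs))
  if (!is.null(trajs$region_counts)) {
    ps[match(names(trajs$region_counts), as.character(regs))] <-
      as.numeric(trajs$region_counts)
  }
  data.frame(region = regs, fibrosis_fraction = fib, mean_df_hz = df,
             ps_events = ps)
}

#' @export
print.wave_dynamics_report <- function(x, ...) {
  cat(sprintf("<wave_dynamics_report> '%s'\n", x$label))
  cat(sprintf("  fibrosis fraction : %.1f%%\n", 100 * x$fibrosis_fraction))
  cat(sprintf("  AF induced        : %s\n", x$induced))
  if (isTRUE(x$induced)) {
    cat(sprintf("  peak DF           : %.2f Hz at node %d\n",
                x$df$peak_df_hz, x$df$peak_node))
    cat(sprintf("  top-DF region     : %d nodes\n", length(x$df$top_nodes)))
    cat(sprintf("  PS                : %d events, %d trajectories\n",
                x$ps$n_events, x$ps$n_trajectories))
    cat(sprintf("  mother rotors     : %d\n", sum(x$ps$mother_rotor)))
  }
  cat(sprintf("  provenance        : seed %d, config %s\n",
              x$provenance$seed, x$provenance$config_hash))
  invisible(x)
}

write_report <- function(report, config, mesh, result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(dir, "config.txt"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  json <- report[c("label", "fibrosis_fraction", "induced",
                   "analysis_window_ms", "kappa", "diffusion_scale")]
  json$provenance <- report$provenance
  if (isTRUE(report$induced)) {
    json$df <- report$df[c("peak_node", "peak_df_hz", "mean_df_hz")]
    json$ps <- report$ps[c("n_events", "n_trajectories", "wavelength_mm")]
    json$ps$n_mother_rotors <- sum(report$ps$mother_rotor)
    json$per_region <- report$per_region
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fields <- list(fibrosis = as.numeric(mesh$fibrosis),
                 region = as.numeric(mesh$region))
  if (!is.null(report$dfmap)) fields$df_hz <- report$dfmap$df_hz
  save_mesh_with_fields(mesh, file.path(dir, "maps.vtk"), fields)
  if (!is.null(report$trajectories)) {
    tj <- report$trajectories$trajectories
    if (length(tj)) {
      tab <- do.call(rbind, lapply(seq_along(tj), function(i)
        cbind(trajectory = i, tj[[i]])))
      utils::write.table(tab, file.path(dir, "ps_trajectories.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' Save / load a membrane-potential movie as delimited text
#'
#' Plain TSV with one row per output frame (first column time in ms, then
#' one column per node). Self-contained enough for the analysis CLI.
#'
#' @param result a `simulation_result`.
#' @param path file path.
#' @return `save_result` returns `path` invisibly; `load_result` a
#'   `simulation_result`.
#' @export
save_result <- function(result, path) {
  m <- cbind(time_ms = result$times, t(result$vm))
  colnames(m) <- c("time_ms", paste0("n", seq_len(nrow(result$vm))))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  structure(list(vm = t(m[, -1, drop = FALSE]), times = m[, 1],
                 final_states = NULL, protocol = list(),
                 output_interval = stats::median(diff(m[, 1])),
                 n_steps = 0, wall_time_s = 0),
            class = "simulation_result")
}
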