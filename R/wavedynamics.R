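#' Dominant-frequency map
#'
#' Per-node periodogram of the de-meaned, Hann-tapered membrane potential
#' over the analysis window; the dominant frequency (DF) is the frequency
#' of highest spectral power within `band`. Frequency resolution is
#' 1/window. Nodes with no signal (constant vm) are NA.
#'
#' @param result a `simulation_result` (sampling interval <= 10 ms).
#' @param window `c(start, end)` ms; default: the full recording (must be
#'   >= 1000 ms).
#' @param band frequency band searched, Hz.
#' @return A `df_map`: list(df_hz, peak_power, window_ms, band_hz).
#' @export
compute_df_map <- function(result, window = NULL, band = c(1, 20)) {
  tt <- result$times
  if (is.null(window)) window <- range(tt)
  sel <- which(tt >= window[1] & tt <= window[2])
  if (length(sel) < 2) stop("analysis window is outside the recording")
  span <- diff(range(tt[sel]))
  if (span < 1000) stop("analysis window must be at least 1 s")
  dt_s <- stats::median(diff(tt[sel])) / 1000
  if (dt_s > 0.010 + 1e-9) stop("sampling interval must be <= 10 ms")
  X <- t(result$vm[, sel, drop = FALSE]) # time x nodes
  nt <- nrow(X)
  X <- sweep(X, 2, colMeans(X))
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(nt) / (nt + 1))) # Hann
  X <- X * taper
  P <- Mod(stats::mvfft(X))^2
  freq <- (seq_len(nt) - 1) / (nt * dt_s)
  inband <- which(freq >= band[1] & freq <= band[2])
  Pb <- P[inband, , drop = FALSE]
  idx <- apply(Pb, 2, which.max)
  df <- freq[inband][idx]
  pk <- Pb[cbind(idx, seq_len(ncol(Pb)))]
  silent <- apply(result$vm[, sel, drop = FALSE], 1, stats::sd) < 1e-9
  df[silent] <- NA_real_
  pk[silent] <- NA_real_
  structure(list(df_hz = df, peak_power = pk,
                 window_ms = c(tt[sel][1], max(tt[sel])), band_hz = band),
            class = "df_map")
}

#' Highest-DF region
#'
#' Nodes at or above the (1 - fraction) quantile of the DF map (default
#' the top 5%). Boundary ties are broken by peak spectral power; if the
#' tie cannot be broken (equal powers) all tied nodes are kept with a
#' warning. Also returns the single peak node of the DF map.
#'
#' @param dfmap a `df_map` (>= 20 defined nodes).
#' @param fraction fraction of nodes to keep, in (0, 1].
#' @return list(nodes, peak_node, threshold_hz).
#' @export
top_df_region <- function(dfmap, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  df <- dfmap$df_hz
  pw <- dfmap$peak_power
  def <- which(!is.na(df))
  if (length(def) < 20) stop("DF map defined on fewer than 20 nodes")
  k <- ceiling(fraction * length(def))
  ord <- def[order(-df[def], -pw[def])]
  thr <- df[ord[k]]
  cand <- def[df[def] >= thr]
  if (length(cand) > k) {
    boundary <- cand[df[cand] == thr]
    keep_above <- cand[df[cand] > thr]
    need <- k - length(keep_above)
    bord <- boundary[order(-pw[boundary])]
    if (need < length(boundary) &&
        length(unique(pw[boundary])) == 1) {
      warning("DF ties at the selection boundary cannot be broken; ",
              "returning all ", length(cand), " tied nodes")
      sel <- cand
    } else {
      sel <- c(keep_above, bord[seq_len(need)])
    }
  } else {
    sel <- cand
  }
  peak <- def[order(-df[def], -pw[def])][1]
  list(nodes = sort(sel), peak_node = peak, threshold_hz = thr)
}

#' Instantaneous phase field
#'
#' Analytic-signal (Hilbert-transform) phase of each node's de-meaned
#' membrane potential over the analysis window. The phase of a periodic
#' action potential advances by 2*pi per cycle; amplitude scaling leaves
#' it unchanged. Silent nodes are flagged undefined (NA).
#'
#' @inheritParams compute_df_map
#' @return A `phase_field`: list(phase = node x frame matrix in
#'   (-pi, pi], times).
#' @export
compute_phase <- function(result, window = NULL) {
  tt <- result$times
  if (is.null(window)) window <- range(tt)
  sel <- which(tt >= window[1] & tt <= window[2])
  if (length(sel) < 4) stop("analysis window too short for phase")
  X <- t(result$vm[, sel, drop = FALSE])
  nt <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  X <- sweep(X, 2, colMeans(X))
  # analytic signal: zero negative frequencies, double positive ones
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[c(1, nt / 2 + 1)] <- 1
    h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nt + 1) / 2)] <- 2
  }
  A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / nt
  ph <- t(Arg(A))
  ph[sds < 1e-9, ] <- NA_real_
  structure(list(phase = ph, times = tt[sel]), class = "phase_field")
}

wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Phase-singularity detection by face winding number
#'
#' For each mesh face, sums the wrapped phase differences around the
#' oriented node cycle; a winding of +/-2*pi marks a phase singularity
#' (the rotor tip, where phase is undefined) at the face centroid, with
#' chirality the sign of the winding. Faces touching undefined-phase
#' nodes are skipped.
#'
#' @param phase a `phase_field`.
#' @param mesh the mesh the field lives on.
#' @param frame frame index into the phase field.
#' @return data.frame(time, face, x, y, z, chirality); zero rows if no PS.
#' @export
detect_ps <- function(phase, mesh, frame) {
  ph <- phase$phase[, frame]
  tr <- mesh$triangles
  p1 <- ph[tr[, 1]]; p2 <- ph[tr[, 2]]; p3 <- ph[tr[, 3]]
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3))
  w <- wrap_phase(p2 - p1) + wrap_phase(p3 - p2) + wrap_phase(p1 - p3)
  wind <- round(w / (2 * pi))
  hit <- which(ok & wind != 0)
  tg <- triangle_geometry(mesh)
  data.frame(time = rep(phase$times[frame], length(hit)), face = hit,
             x = tg$centroid[hit, 1], y = tg$centroid[hit, 2],
             z = tg$centroid[hit, 3],
             chirality = as.integer(sign(wind[hit])))
}

#' @rdname detect_ps
#' @param frames frame indices (default all).
#' @return `detect_ps_series`: one data.frame over all frames.
#' @export
detect_ps_series <- function(phase, mesh, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(phase$times)
  out <- lapply(frames, function(f) detect_ps(phase, mesh, f))
  do.call(rbind, out)
}

#' Link phase-singularity events into trajectories
#'
#' Greedy nearest-neighbor linking of same-chirality PS events across
#' consecutive frames under a maximum step length. Unmatched events start
#' new trajectories; trajectories with no match end.
#'
#' @param events data.frame from [detect_ps_series()].
#' @param max_step largest tip displacement linked between consecutive
#'   frames, mm.
#' @param mesh optional mesh with region labels, for per-region PS counts
#'   (region of the nearest node to each event).
#' @param merge_radius same-frame, same-chirality detections closer than
#'   this (mm) are merged into one event before linking — a single tip
#'   sitting near a shared edge can light up two adjacent faces.
#' @return A `ps_trajectories` object: list of trajectories (each a
#'   data.frame with lifespan and displacement attributes), plus
#'   `region_counts` (events per region) when a labeled mesh is given.
#' @export
link_trajectories <- function(events, max_step = 5, mesh = NULL,
                              merge_radius = 1) {
  if (!is.null(events) && nrow(events) && merge_radius > 0) {
    events <- merge_coincident_ps(events, merge_radius)
  }
  trajs <- list()
  active <- list() # list of (idx into trajs, last row)
  if (!is.null(events) && nrow(events)) {
    for (t_now in unique(events$time)) {
      ev <- events[events$time == t_now, , drop = FALSE]
      used_ev <- rep(FALSE, nrow(ev))
      next_active <- list()
      if (length(active)) {
        # all candidate pairs sorted by distance, matched greedily
        cand <- NULL
        for (ai in seq_along(active)) {
          last <- active[[ai]]$last
          d <- sqrt((ev$x - last$x)^2 + (ev$y - last$y)^2 +
                    (ev$z - last$z)^2)
          okc <- which(d <= max_step & ev$chirality == last$chirality)
          if (length(okc)) {
            cand <- rbind(cand, data.frame(ai = ai, ei = okc, d = d[okc]))
          }
        }
        if (!is.null(cand)) {
          cand <- cand[order(cand$d), , drop = FALSE]
          used_a <- rep(FALSE, length(active))
          for (r in seq_len(nrow(cand))) {
            ai <- cand$ai[r]; ei <- cand$ei[r]
            if (used_a[ai] || used_ev[ei]) next
            used_a[ai] <- TRUE
            used_ev[ei] <- TRUE
            ti <- active[[ai]]$traj
            trajs[[ti]] <- rbind(trajs[[ti]], ev[ei, ])
            next_active[[length(next_active) + 1]] <-
              list(traj = ti, last = ev[ei, ])
          }
        }
      }
      for (ei in which(!used_ev)) {
        trajs[[length(trajs) + 1]] <- ev[ei, ]
        next_active[[length(next_active) + 1]] <-
          list(traj = length(trajs), last = ev[ei, ])
      }
      active <- next_active
    }
  }
  trajs <- lapply(trajs, function(tj) {
    rownames(tj) <- NULL
    attr(tj, "lifespan_ms") <- diff(range(tj$time))
    P <- as.matrix(tj[, c("x", "y", "z")])
    attr(tj, "max_displacement_mm") <-
      if (nrow(P) > 1) max(stats::dist(P)) else 0
    tj
  })
  region_counts <- NULL
  if (!is.null(mesh) && !is.null(events) && nrow(events) &&
      any(mesh$region != 0)) {
    near <- vapply(seq_len(nrow(events)), function(r) {
      d2 <- (mesh$nodes[, 1] - events$x[r])^2 +
            (mesh$nodes[, 2] - events$y[r])^2 +
            (mesh$nodes[, 3] - events$z[r])^2
      which.min(d2)
    }, integer(1))
    rg <- mesh$region[near]
    region_counts <- table(factor(rg, levels = sort(unique(
      mesh$region[mesh$region != 0]))))
  }
  structure(list(trajectories = trajs, region_counts = region_counts,
                 max_step = max_step),
            class = "ps_trajectories")
}

# single-linkage clustering of same-frame same-chirality events; each
# cluster is replaced by its centroid (face of the first member kept)
merge_coincident_ps <- function(events, radius) {
  out <- NULL
  for (t_now in unique(events$time)) {
    ev <- events[events$time == t_now, , drop = FALSE]
    for (ch in unique(ev$chirality)) {
      e <- ev[ev$chirality == ch, , drop = FALSE]
      k <- nrow(e)
      grp <- seq_len(k)
      if (k > 1) {
        d <- as.matrix(stats::dist(e[, c("x", "y", "z")]))
        for (i in seq_len(k - 1)) {
          for (j in (i + 1):k) {
            if (d[i, j] <= radius) grp[grp == grp[j]] <- grp[i]
          }
        }
      }
      for (g in unique(grp)) {
        sel <- e[grp == g, , drop = FALSE]
        rep1 <- sel[1, , drop = FALSE]
        rep1$x <- mean(sel$x); rep1$y <- mean(sel$y); rep1$z <- mean(sel$z)
        out <- rbind(out, rep1)
      }
    }
  }
  rownames(out) <- NULL
  out[order(out$time), , drop = FALSE]
}

#' @export
print.ps_trajectories <- function(x, ...) {
  ls <- vapply(x$trajectories, attr, numeric(1), "lifespan_ms")
  cat(sprintf("<ps_trajectories> %d trajectories, lifespans %.0f-%.0f ms\n",
              length(x$trajectories),
              if (length(ls)) min(ls) else 0, if (length(ls)) max(ls) else 0))
  invisible(x)
}

#' Mother-rotor criterion and classification
#'
#' A trajectory qualifies as a mother rotor when its tip stays within a
#' circle of diameter half the cardiac wavelength for longer than 5 s.
#' The wavelength is CV x 600 ms, measured from a planar wave paced at a
#' 600-ms cycle length. Confinement uses the exact minimal enclosing
#' circle of the tip path (computed in the path's best-fit plane).
#'
#' @param wavelength_mm cardiac wavelength, mm.
#' @param min_lifespan_ms minimum lifespan, ms (default 5000).
#' @return `mother_rotor_criterion` list with the derived confinement
#'   diameter (= wavelength / 2).
#' @export
mother_rotor_criterion <- function(wavelength_mm, min_lifespan_ms = 5000) {
  if (wavelength_mm <= 0) stop("wavelength must be > 0")
  structure(list(wavelength_mm = wavelength_mm,
                 confinement_diameter_mm = wavelength_mm / 2,
                 min_lifespan_ms = min_lifespan_ms),
            class = "mother_rotor_criterion")
}

#' @rdname mother_rotor_criterion
#' @param cv_600 planar CV at a 600-ms cycle length, m/s.
#' @export
wavelength_from_cv <- function(cv_600) {
  cv_600 * 600 # (mm/ms) x ms = mm
}

#' @rdname mother_rotor_criterion
#' @param traj one trajectory data.frame (from [link_trajectories()]).
#' @param criterion a `mother_rotor_criterion`.
#' @return `classify_mother_rotor`: TRUE iff lifespan exceeds the minimum
#'   and the minimal enclosing circle diameter is at most
#'   `confinement_diameter_mm`.
#' @export
classify_mother_rotor <- function(traj, criterion) {
  if (is.null(traj) || !nrow(traj)) stop("empty trajectory")
  lifespan <- diff(range(traj$time))
  if (lifespan <= criterion$min_lifespan_ms) return(FALSE)
  P <- as.matrix(traj[, c("x", "y", "z")])
  mec <- min_enclosing_circle(P)
  2 * mec$radius <= criterion$confinement_diameter_mm
}

#' Minimal enclosing circle of a point set
#'
#' Exact smallest enclosing circle (Welzl's algorithm) of 3-D points
#' projected onto their best-fit (principal) plane. For trajectories on a
#' flat sheet this is the exact planar circle.
#'
#' @param points k x 3 matrix.
#' @return list(center (3-D, on the plane), radius).
#' @export
min_enclosing_circle <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) == 0) stop("no points")
  ctr <- colMeans(P)
  P0 <- sweep(P, 2, ctr)
  if (nrow(P) == 1) return(list(center = ctr, radius = 0))
  sv <- svd(P0, nu = 0, nv = 3)
  B <- sv$v[, 1:2, drop = FALSE]
  Q <- P0 %*% B # 2-D coordinates in the best-fit plane
  mec <- welzl_mec(Q)
  list(center = ctr + as.numeric(B %*% mec$center), radius = mec$radius)
}

# Welzl's move-to-front minimal enclosing circle in 2-D (iterative
# restatement: grow the circle whenever a point falls outside).
welzl_mec <- function(Q) {
  circ2 <- function(a, b) {
    list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      # collinear: take the widest pair
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  inside <- function(circ, p, eps = 1e-9) {
    sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
  }
  n <- nrow(Q)
  if (n == 1) return(list(center = Q[1, ], radius = 0))
  c_now <- circ2(Q[1, ], Q[2, ])
  if (n == 2) return(c_now)
  for (i in 3:n) {
    if (inside(c_now, Q[i, ])) next
    # circle through Q[i] and points before it
    c_now <- circ2(Q[1, ], Q[i, ])
    for (j in 2:(i - 1)) {
      if (inside(c_now, Q[j, ])) next
      c_now <- circ2(Q[i, ], Q[j, ])
      for (k in seq_len(j - 1)) {
        if (inside(c_now, Q[k, ])) next
        c_now <- circ3(Q[i, ], Q[j, ], Q[k, ])
      }
    }
  }
  c_now
}
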