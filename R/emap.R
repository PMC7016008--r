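#' Electro-anatomical map
#'
#' A sparse set of catheter-acquired point samples over the atrial surface:
#' 3-D coordinates (mm), bipolar peak-to-peak voltage (mV) and local
#' activation time (ms) relative to the pacing reference.
#'
#' @param points n x 3 matrix of coordinates, mm.
#' @param voltage numeric(n) bipolar voltage, mV (non-negative).
#' @param lat numeric(n) local activation time, ms.
#' @param pacing_cycle_length pacing cycle length during acquisition, ms.
#' @return An `emap` object.
#' @export
emap <- function(points, voltage, lat, pacing_cycle_length = 500) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1) {
    stop("points must be an n x 3 matrix with n >= 1")
  }
  if (length(voltage) != nrow(points) || length(lat) != nrow(points)) {
    stop("voltage and lat must have one value per point")
  }
  if (any(!is.finite(voltage)) || any(voltage < 0)) {
    stop("voltages must be finite and >= 0")
  }
  if (any(!is.finite(lat))) stop("LATs must be finite")
  structure(list(points = unname(points), voltage = as.numeric(voltage),
                 lat = as.numeric(lat),
                 pacing_cycle_length = pacing_cycle_length),
            class = "emap")
}

#' @export
print.emap <- function(x, ...) {
  cat(sprintf(paste0("<emap> %d points, voltage %.2f-%.2f mV, ",
                     "LAT %.1f-%.1f ms, paced at CL %g ms\n"),
              nrow(x$points), min(x$voltage), max(x$voltage),
              min(x$lat), max(x$lat), x$pacing_cycle_length))
  invisible(x)
}

#' Read / write an electro-anatomical map as delimited text
#'
#' Tab-separated text with header columns `x_mm`, `y_mm`, `z_mm`,
#' `voltage_mV`, `lat_ms`. Malformed rows are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @param map an `emap`.
#' @param pacing_cycle_length cycle length recorded with the map, ms.
#' @return `read_emap` returns an `emap`; `write_emap` returns `path`
#'   invisibly.
#' @export
read_emap <- function(path, pacing_cycle_length = 500) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- strsplit(trimws(ln[1]), "[\t,;[:space:]]+")[[1]]
  need <- c("x_mm", "y_mm", "z_mm", "voltage_mV", "lat_ms")
  if (!all(need %in% hdr)) {
    stop("emap file must have header columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_along(ln)[-1], function(i) {
    v <- suppressWarnings(
      as.numeric(strsplit(trimws(ln[i]), "[\t,;[:space:]]+")[[1]]))
    if (length(v) != length(hdr) || any(is.na(v))) {
      stop("malformed emap row at line ", i, " of ", path)
    }
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- hdr
  emap(m[, c("x_mm", "y_mm", "z_mm"), drop = FALSE], m[, "voltage_mV"],
       m[, "lat_ms"], pacing_cycle_length = pacing_cycle_length)
}

#' @rdname read_emap
#' @export
write_emap <- function(map, path) {
  stopifnot(inherits(map, "emap"))
  df <- data.frame(x_mm = map$points[, 1], y_mm = map$points[, 2],
                   z_mm = map$points[, 3], voltage_mV = map$voltage,
                   lat_ms = map$lat)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rigid landmark alignment of a map onto a mesh
#'
#' Least-squares rigid transform (rotation + translation, no scaling)
#' mapping the map's landmark points onto the corresponding mesh points,
#' solved in closed form via SVD (Kabsch), then applied to all map points.
#'
#' @param map an `emap`.
#' @param map_landmarks k x 3 matrix of landmark coordinates in map space.
#' @param mesh_landmarks k x 3 matrix of the same landmarks in mesh space.
#' @return The transformed `emap`, with attributes `rotation`,
#'   `translation` and `rms_residual_mm`.
#' @export
rigid_align <- function(map, map_landmarks, mesh_landmarks) {
  A <- as.matrix(map_landmarks)
  B <- as.matrix(mesh_landmarks)
  if (nrow(A) < 3 || nrow(B) != nrow(A)) {
    stop("at least 3 landmark pairs are required")
  }
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # collinear landmarks leave the rotation about their axis undetermined
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2) {
    stop("landmarks are collinear; the rigid transform is not determined")
  }
  s <- svd(t(A0) %*% B0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cb - as.numeric(R %*% ca)
  transform <- function(P) sweep(P %*% t(R), 2, t_vec, `+`)
  resid <- sqrt(mean(rowSums((transform(A) - B)^2)))
  out <- map
  out$points <- transform(map$points)
  attr(out, "rotation") <- R
  attr(out, "translation") <- t_vec
  attr(out, "rms_residual_mm") <- resid
  out
}

#' Inverse-distance-weighted interpolation onto mesh nodes
#'
#' Each node value is the IDW average of all map samples within `radius`
#' (default 10 mm): \eqn{\sum w_i v_i / \sum w_i} with
#' \eqn{w_i = 1/d_i^{power}}. A node coincident with a sample (within 1e-6
#' mm) takes that sample's value exactly. Nodes with no sample in radius
#' are flagged uncovered and receive `uncovered_value`.
#'
#' @param map an `emap`.
#' @param mesh an `atrial_mesh`.
#' @param field `"voltage"` or `"lat"`.
#' @param radius search radius, mm.
#' @param power IDW exponent.
#' @param uncovered_value value given to uncovered nodes (default 5 mV:
#'   healthy, above the fibrosis threshold, so sparse coverage never
#'   fabricates low-voltage tissue; uncovered nodes are excluded from
#'   agreement statistics via the coverage mask).
#' @return A `node_field`: list(values, covered).
#' @export
idw_interpolate <- function(map, mesh, field = c("voltage", "lat"),
                            radius = 10, power = 2, uncovered_value = 5) {
  field <- match.arg(field)
  if (radius <= 0) stop("radius must be > 0")
  if (!nrow(map$points)) stop("empty map")
  v <- map[[field]]
  nodes <- mesh$nodes
  n <- nrow(nodes)
  vals <- rep(uncovered_value, n)
  covered <- rep(FALSE, n)
  eps <- 1e-6
  # process nodes in blocks to bound the distance-matrix size
  block <- max(1L, floor(2e6 / nrow(map$points)))
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    d2 <- outer(rowSums(nodes[idx, , drop = FALSE]^2),
                rowSums(map$points^2), `+`) -
          2 * nodes[idx, , drop = FALSE] %*% t(map$points)
    d <- sqrt(pmax(d2, 0))
    inr <- d <= radius
    hit <- d < eps
    for (r in seq_along(idx)) {
      i <- idx[r]
      if (any(hit[r, ])) {
        vals[i] <- v[which(hit[r, ])[1]]
        covered[i] <- TRUE
      } else if (any(inr[r, ])) {
        w <- 1 / d[r, inr[r, ]]^power
        vals[i] <- sum(w * v[inr[r, ]]) / sum(w)
        covered[i] <- TRUE
      }
    }
  }
  structure(list(values = vals, covered = covered, field = field),
            class = "node_field")
}

#' Fibrosis probability from bipolar voltage
#'
#' Piecewise cubic mapping from bipolar voltage X (mV) to the probability
#' that a node is fibrotic: 1 below 0 mV, 0 above 1.74 mV, and between them
#' the percent-scale polynomial
#' \eqn{-40 X^3 + 155 X^2 - 206 X + 99.8} divided by 100 and clamped to
#' \[0, 1\]. Monotone non-increasing; effectively continuous at both
#' boundaries (the polynomial is 99.8% at 0 and <1% at 1.74).
#'
#' @param x bipolar voltage(s), mV.
#' @return Probability in \[0, 1\], vectorized over `x`.
#' @export
fibrosis_probability <- function(x) {
  if (any(!is.finite(x))) stop("voltage must be finite")
  p <- (-40.0 * x^3 + 155 * x^2 - 206 * x + 99.8) / 100
  p <- pmin(pmax(p, 0), 1)
  p[x < 0] <- 1
  p[x > 1.74] <- 0
  p
}

#' Fibrosis model parameters
#'
#' Bundles the voltage threshold, the percent-scale polynomial coefficients
#' and the RNG seed used for stochastic fibrosis assignment.
#'
#' @param seed integer seed for the Bernoulli draws.
#' @return A `fibrosis_model` list.
#' @export
fibrosis_model <- function(seed = 1L) {
  structure(list(threshold = 1.74,
                 coefficients = c(-40.0, 155, -206, 99.8),
                 seed = as.integer(seed)),
            class = "fibrosis_model")
}

#' Stochastic fibrosis assignment from a voltage field
#'
#' Each node is flagged fibrotic with probability
#' [fibrosis_probability()] of its interpolated voltage, by comparing an
#' independent uniform random number per node against the probability.
#' Seeded and reproducible.
#'
#' @param mesh an `atrial_mesh`.
#' @param voltage_field a `node_field` of voltages (or numeric(n)).
#' @param model a [fibrosis_model()].
#' @return The mesh with `fibrosis` set; attribute `fibrosis_fraction`
#'   holds the global fibrotic fraction.
#' @export
assign_fibrosis <- function(mesh, voltage_field, model = fibrosis_model()) {
  v <- if (inherits(voltage_field, "node_field")) voltage_field$values
       else as.numeric(voltage_field)
  if (length(v) != nrow(mesh$nodes)) {
    stop("voltage field must cover every mesh node")
  }
  p <- fibrosis_probability(v)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(model$seed)
  u <- stats::runif(length(p))
  mesh$fibrosis <- u < p
  attr(mesh, "fibrosis_fraction") <- mean(mesh$fibrosis)
  mesh
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Agreement statistics between two node fields
#'
#' Pearson correlation, RMSE and %RMSE between two fields on the same mesh,
#' overall and per region label. Only nodes covered in both fields are
#' compared. %RMSE is 100 x RMSE / mean(|a|), with the first argument
#' playing the role of the clinical (reference) field.
#'
#' @param a,b `node_field`s or numeric vectors on the same mesh.
#' @param regions integer region label per node (0 = unlabeled); `NULL` for
#'   overall statistics only.
#' @return data.frame with columns `region` ("overall" or the label),
#'   `n`, `pearson_r`, `rmse`, `percent_rmse`.
#' @export
map_agreement <- function(a, b, regions = NULL) {
  av <- if (inherits(a, "node_field")) a$values else as.numeric(a)
  bv <- if (inherits(b, "node_field")) b$values else as.numeric(b)
  if (length(av) != length(bv)) stop("fields must be on the same mesh")
  cov <- rep(TRUE, length(av))
  if (inherits(a, "node_field")) cov <- cov & a$covered
  if (inherits(b, "node_field")) cov <- cov & b$covered
  stat1 <- function(x, y) {
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
         else stats::cor(x, y)
    rmse <- sqrt(mean((x - y)^2))
    c(pearson_r = r, rmse = rmse,
      percent_rmse = 100 * rmse / mean(abs(x)))
  }
  out <- data.frame(region = "overall", n = sum(cov),
                    t(stat1(av[cov], bv[cov])))
  if (!is.null(regions)) {
    for (rg in sort(unique(regions[regions != 0]))) {
      sel <- cov & regions == rg
      if (sum(sel) < 2) {
        warning("region ", rg, " has < 2 covered nodes; skipped")
        next
      }
      out <- rbind(out, data.frame(region = as.character(rg), n = sum(sel),
                                   t(stat1(av[sel], bv[sel]))))
    }
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic electro-anatomical map
#'
#' Emulates a >500-point catheter acquisition on a mesh: a spatially smooth
#' voltage truth field spanning approximately `voltage_range`
#' (the clinically observed bipolar range), a LAT truth field spreading at
#' constant speed from a single earliest-activation site, point samples
#' drawn without replacement from mesh nodes, jittered up to 0.5 mm
#' off-surface, with additive Gaussian noise. The truth fields are
#' returned for recovery tests.
#'
#' @param mesh an `atrial_mesh`.
#' @param n_points number of samples (>= 1, <= node count).
#' @param eas_node earliest-activation-site node; default: node nearest the
#'   first mesh corner.
#' @param speed conduction speed of the LAT truth field, m/s.
#' @param voltage_range approximate range of the smooth voltage truth, mV.
#' @param noise_sd_voltage,noise_sd_lat additive Gaussian noise SDs
#'   (mV, ms).
#' @param seed integer seed; same seed, same map.
#' @return list(map, truth_voltage, truth_lat, eas_node, sample_nodes).
#' @export
generate_synthetic_emap <- function(mesh, n_points = 500, eas_node = 1L,
                                    speed = 0.7,
                                    voltage_range = c(0.1, 3.5),
                                    noise_sd_voltage = 0.05,
                                    noise_sd_lat = 1, seed = 1L) {
  n <- nrow(mesh$nodes)
  if (n_points > n) stop("n_points exceeds the mesh node count")
  if (n_points < 1) stop("n_points must be >= 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # smooth voltage truth: superposition of long-wavelength harmonics
  P <- mesh$nodes
  ext <- max(apply(P, 2, function(x) diff(range(x))), 1e-6)
  raw <- rep(0, n)
  for (k in 1:4) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    wl <- ext / k
    ph <- stats::runif(1, 0, 2 * pi)
    raw <- raw + (1 / k) * sin(2 * pi * (P %*% dir) / wl + ph)
  }
  raw <- (raw - min(raw)) / max(diff(range(raw)), 1e-12)
  truth_v <- voltage_range[1] + raw * diff(voltage_range)
  truth_lat <- geodesic_distance(mesh, eas_node, seq_len(n)) / speed
  sample_nodes <- sort(sample.int(n, n_points))
  nn <- node_normals(mesh)
  jitter <- stats::runif(n_points, -0.5, 0.5)
  pts <- mesh$nodes[sample_nodes, , drop = FALSE] +
    nn[sample_nodes, , drop = FALSE] * jitter
  v <- pmax(truth_v[sample_nodes] +
              stats::rnorm(n_points, 0, noise_sd_voltage), 0)
  lat <- truth_lat[sample_nodes] + stats::rnorm(n_points, 0, noise_sd_lat)
  list(map = emap(pts, v, lat),
       truth_voltage = as.numeric(truth_v),
       truth_lat = as.numeric(truth_lat),
       eas_node = eas_node, sample_nodes = sample_nodes)
}
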