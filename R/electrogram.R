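#' Electrogram forward model
#'
#' Infinite-medium volume-conductor parameters for computing extracellular
#' potentials from the transmembrane potential gradient: the ratio of
#' intracellular to extracellular conductivity scales the amplitude, and a
#' nominal wall thickness turns the monolayer's element areas into source
#' volumes. Electrodes must keep a minimum clearance off the surface (the
#' singular self-element is excluded geometrically, as catheter electrodes
#' sit off-wall).
#'
#' @param sigma_i,sigma_e intracellular / extracellular conductivities
#'   (only their ratio matters up to overall scale).
#' @param thickness nominal atrial wall thickness, mm.
#' @param clearance minimum electrode-to-surface distance, mm.
#' @return An `egm_model` list.
#' @export
egm_model <- function(sigma_i = 0.4, sigma_e = 1.0, thickness = 2,
                      clearance = 0.5) {
  if (sigma_i <= 0 || sigma_e <= 0) stop("conductivities must be > 0")
  structure(list(sigma_i = sigma_i, sigma_e = sigma_e,
                 thickness = thickness, clearance = clearance),
            class = "egm_model")
}

# per-node weights w such that phi_e(t) = w . vm(, t):
# phi_e = -(1/4pi)(si/se) sum_e [grad vm_e . (r' - c_e)/|r' - c_e|^3] A_e th
egm_weights <- function(mesh, electrode, model) {
  if (length(electrode) != 3) stop("electrode must be a 3-D position")
  dmin <- min(sqrt(rowSums(sweep(mesh$nodes, 2, electrode)^2)))
  if (dmin < model$clearance) {
    stop(sprintf("electrode is %.2f mm from the surface; clearance is %g mm",
                 dmin, model$clearance))
  }
  eg <- element_gradients(mesh)
  r <- sweep(-eg$centroid, 2, electrode, `+`) # r' - c_e
  rn3 <- (rowSums(r^2))^(3 / 2)
  kvec <- r / rn3
  scale <- -(1 / (4 * pi)) * (model$sigma_i / model$sigma_e) *
    eg$area * model$thickness
  tr <- mesh$triangles
  w <- numeric(nrow(mesh$nodes))
  for (a in 1:3) {
    ga <- switch(a, eg$g1, eg$g2, eg$g3)
    contrib <- scale * rowSums(ga * kvec)
    s <- rowsum(contrib, tr[, a])
    w[as.integer(rownames(s))] <- w[as.integer(rownames(s))] + s
  }
  w
}

#' Unipolar extracellular electrogram
#'
#' Forward-computes the extracellular potential at an electrode from a
#' membrane-potential movie: each triangle contributes its P1 surface
#' gradient of vm dotted with the dipole kernel
#' \eqn{\nabla(1/|r'-r_c|)}, weighted by its source volume
#' (area x wall thickness) and scaled by
#' \eqn{-\sigma_i/(4\pi\sigma_e)}. A spatially uniform vm yields zero.
#'
#' @param result a `simulation_result`.
#' @param mesh the mesh it was computed on.
#' @param electrode 3-D electrode position, mm.
#' @param model an [egm_model()].
#' @return An `electrogram`: list(times, potential, electrode).
#' @export
unipolar_egm <- function(result, mesh, electrode, model = egm_model()) {
  w <- egm_weights(mesh, electrode, model)
  structure(list(times = result$times,
                 potential = as.numeric(w %*% result$vm),
                 electrode = electrode, type = "unipolar"),
            class = "electrogram")
}

#' Bipolar electrogram
#'
#' Difference of the two unipolar electrograms at `center +/- spacing/2`
#' along `orientation` (default pole spacing 1 mm).
#'
#' @inheritParams unipolar_egm
#' @param center bipole center position, mm.
#' @param orientation length-3 direction of the bipole axis.
#' @param spacing inter-pole distance, mm.
#' @return An `electrogram` with `type = "bipolar"`.
#' @export
bipolar_egm <- function(result, mesh, center, orientation, spacing = 1,
                        model = egm_model()) {
  u <- orientation / sqrt(sum(orientation^2))
  p1 <- center + u * spacing / 2
  p2 <- center - u * spacing / 2
  e1 <- unipolar_egm(result, mesh, p1, model)
  e2 <- unipolar_egm(result, mesh, p2, model)
  structure(list(times = result$times,
                 potential = e1$potential - e2$potential,
                 electrode = rbind(p1, p2), spacing = spacing,
                 type = "bipolar"),
            class = "electrogram")
}

#' @export
print.electrogram <- function(x, ...) {
  cat(sprintf("<electrogram> %s, %d samples, amplitude %.3g\n",
              x$type, length(x$times), diff(range(x$potential))))
  invisible(x)
}

#' Write an electrogram as a delimited time/value table
#' @param egm an `electrogram`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_electrogram <- function(egm, path) {
  utils::write.table(data.frame(time_ms = egm$times,
                                potential = egm$potential),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Electrogram morphology similarity
#'
#' Mean inner product of the unit-normalized signal vectors, per aligned
#' segment: with no segmentation this is the cosine similarity of the two
#' whole signals; with `breaks` (segment boundary times, e.g. detected
#' local activations) each segment is resampled to a common length,
#' normalized, and the per-segment inner products are averaged.
#' Scale-invariant; in \[-1, 1\].
#'
#' @param a,b numeric signal vectors on a common time grid, or
#'   `electrogram` objects.
#' @param times sample times (required when `breaks` is given and `a`,`b`
#'   are plain vectors).
#' @param breaks segment boundary times, ms.
#' @param resample_n per-segment resampling length.
#' @return Similarity in \[-1, 1\].
#' @export
morphology_similarity <- function(a, b, times = NULL, breaks = NULL,
                                  resample_n = 100) {
  if (inherits(a, "electrogram")) { times <- a$times; a <- a$potential }
  if (inherits(b, "electrogram")) b <- b$potential
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2) {
    stop("signals must have equal length >= 2")
  }
  cosim <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) stop("zero-norm signal segment")
    sum(x * y) / (nx * ny)
  }
  if (is.null(breaks)) return(cosim(a, b))
  if (is.null(times)) stop("breaks require sample times")
  bounds <- sort(unique(c(min(times), breaks, max(times))))
  sims <- numeric(0)
  for (s in seq_len(length(bounds) - 1)) {
    sel <- which(times >= bounds[s] & times <= bounds[s + 1])
    if (length(sel) < 2) next
    grid <- seq(times[sel[1]], times[sel[length(sel)]],
                length.out = resample_n)
    ra <- stats::approx(times[sel], a[sel], xout = grid)$y
    rb <- stats::approx(times[sel], b[sel], xout = grid)$y
    sims <- c(sims, cosim(ra, rb))
  }
  if (!length(sims)) stop("no usable segments")
  mean(sims)
}
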