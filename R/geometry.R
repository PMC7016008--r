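#' Atrial surface mesh
#'
#' An `atrial_mesh` is a triangulated surface with optional per-node
#' attributes: `fiber` (unit tangent vector, the local myocyte axis),
#' `fibrosis` (logical flag) and `region` (integer label, 0 = unlabeled).
#' Coordinates are in mm throughout; node indices are 1-based.
#'
#' @param nodes n x 3 numeric matrix of coordinates, mm.
#' @param triangles m x 3 integer matrix of node indices (1-based).
#' @param fiber optional n x 3 matrix of per-node unit tangent vectors.
#' @param fibrosis optional logical(n).
#' @param region optional integer(n).
#' @return An `atrial_mesh` object.
#' @export
atrial_mesh <- function(nodes, triangles, fiber = NULL, fibrosis = NULL,
                        region = NULL) {
  nodes <- as.matrix(nodes)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 matrix")
  if (ncol(triangles) != 3) stop("triangles must be an m x 3 matrix")
  n <- nrow(nodes)
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("triangle indices reference nodes outside 1..", n)
  }
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3])) {
    stop("degenerate triangle (repeated node index)")
  }
  if (is.null(fibrosis)) fibrosis <- rep(FALSE, n)
  if (is.null(region)) region <- rep(0L, n)
  stopifnot(length(fibrosis) == n, length(region) == n)
  m <- structure(list(nodes = unname(nodes), triangles = unname(triangles),
                      fiber = if (!is.null(fiber)) unname(as.matrix(fiber)),
                      fibrosis = as.logical(fibrosis),
                      region = as.integer(region)),
                 class = "atrial_mesh")
  if (!is.null(fiber)) {
    if (!all(dim(m$fiber) == c(n, 3))) stop("fiber must be an n x 3 matrix")
    validate_fiber_field(m)
  }
  m
}

#' @export
print.atrial_mesh <- function(x, ...) {
  st <- mesh_statistics(x)
  cat(sprintf(paste0("<atrial_mesh> %d nodes, %d triangles, mean spacing ",
                     "%.1f um%s%s\n"),
              nrow(x$nodes), nrow(x$triangles), st$mean_spacing_um,
              if (!is.null(x$fiber)) ", fibers" else "",
              if (any(x$fibrosis)) sprintf(", %.1f%% fibrotic",
                                           100 * mean(x$fibrosis)) else ""))
  invisible(x)
}

# unit row vectors; zero rows left as zero
normalize_rows <- function(v) {
  nr <- sqrt(rowSums(v^2))
  nr[nr == 0] <- 1
  v / nr
}

#' Per-triangle geometry: unit normals, areas and centroids
#' @param mesh an `atrial_mesh`.
#' @return list with `normal` (m x 3), `area` (m), `centroid` (m x 3).
#' @keywords internal
triangle_geometry <- function(mesh) {
  tr <- mesh$triangles
  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 < 1e-12)) stop("zero-area triangle in mesh")
  list(normal = cr / area2, area = area2 / 2, centroid = (p1 + p2 + p3) / 3)
}

#' Per-node outward normals (area-weighted average of incident triangles)
#' @inheritParams triangle_geometry
#' @return n x 3 matrix of unit normals.
#' @export
node_normals <- function(mesh) {
  tg <- triangle_geometry(mesh)
  n <- nrow(mesh$nodes)
  w <- tg$normal * tg$area
  # area-weighted accumulation over the three corners
  acc <- matrix(0, n, 3)
  for (k in 1:3) {
    idx <- mesh$triangles[, k]
    for (d in 1:3) {
      s <- rowsum(w[, d], idx)
      acc[as.integer(rownames(s)), d] <- acc[as.integer(rownames(s)), d] + s
    }
  }
  normalize_rows(acc)
}

validate_fiber_field <- function(mesh, tol_norm = 1e-6, tol_tang = 1e-3) {
  nr <- sqrt(rowSums(mesh$fiber^2))
  if (any(abs(nr - 1) > tol_norm)) {
    stop("fiber vectors must have unit norm (max deviation ",
         signif(max(abs(nr - 1)), 3), ")")
  }
  nn <- node_normals(mesh)
  dp <- abs(rowSums(mesh$fiber * nn))
  if (any(dp > tol_tang)) {
    stop("fiber vectors must be tangent to the surface (max |fiber.normal| = ",
         signif(max(dp), 3), ")")
  }
  invisible(TRUE)
}

#' Unique edges of a mesh
#' @inheritParams triangle_geometry
#' @return 2-column integer matrix, each row an undirected edge (i < j).
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mesh spacing statistics
#'
#' Node count plus the mean and standard deviation of the adjacent-node
#' (edge) distance in micrometres — the resolution statistic the solver's
#' stability and calibration are tied to.
#'
#' @inheritParams triangle_geometry
#' @return list(n_nodes, mean_spacing_um, sd_spacing_um).
#' @export
mesh_statistics <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                     mesh$nodes[e[, 2], , drop = FALSE])^2))
  list(n_nodes = nrow(mesh$nodes),
       mean_spacing_um = mean(d) * 1000,
       sd_spacing_um = stats::sd(d) * 1000)
}

#' Generate a flat triangulated sheet
#'
#' Near-equilateral triangulation of a rectangle in the z = 0 plane, used as
#' the desk-scale stand-in for the CT-derived atrial surface. Default fibers
#' run along the width (x) axis.
#'
#' @param width,height sheet dimensions, mm.
#' @param target_spacing desired mean adjacent-node distance, um.
#' @return An `atrial_mesh` with uniform `fiber = (1,0,0)`.
#' @export
generate_sheet_mesh <- function(width, height, target_spacing = 235) {
  if (width <= 0 || height <= 0 || target_spacing <= 0) {
    stop("width, height and target_spacing must be > 0")
  }
  s <- target_spacing / 1000 # mm
  if (s > min(width, height)) {
    stop("target_spacing (", target_spacing, " um) exceeds the sheet size")
  }
  dy <- s * sqrt(3) / 2
  nx <- max(2L, round(width / s) + 1L)
  ny <- max(2L, round(height / dy) + 1L)
  xs <- seq(0, width, length.out = nx)
  ys <- seq(0, height, length.out = ny)
  dx <- xs[2] - xs[1]
  nodes <- matrix(0, nx * ny, 3)
  for (r in seq_len(ny)) {
    off <- if (r %% 2 == 0) dx / 2 else 0
    x <- xs + off
    x[x > width] <- width
    rows <- ((r - 1) * nx + 1):(r * nx)
    nodes[rows, 1] <- x
    nodes[rows, 2] <- ys[r]
  }
  tris <- vector("list", ny - 1)
  for (r in seq_len(ny - 1)) {
    a <- (r - 1) * nx + seq_len(nx - 1) # this row
    b <- a + 1
    c <- a + nx                          # row above
    d <- c + 1
    if (r %% 2 == 1) {
      tris[[r]] <- rbind(cbind(a, b, c), cbind(b, d, c))
    } else {
      tris[[r]] <- rbind(cbind(a, b, d), cbind(a, d, c))
    }
  }
  tri <- do.call(rbind, tris)
  fiber <- matrix(rep(c(1, 0, 0), each = nx * ny), ncol = 3)
  atrial_mesh(nodes, tri, fiber = fiber)
}

#' Generate an icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; used for closed-surface
#' property checks (topological charge conservation, geodesic closure).
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0-4).
#' @return An `atrial_mesh` (no fibers).
#' @export
generate_sphere_mesh <- function(radius = 10, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- normalize_rows(v)
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- (vlist[[i]] + vlist[[j]]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1]] <<- p
      mid_cache[[key]] <- length(vlist)
      length(vlist)
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  atrial_mesh(v * radius, f)
}

# weighted edge graph for geodesics: mesh edges plus, for every interior
# edge, a shortcut between the two opposite vertices of its adjacent
# triangles (chord length); errors bounded at the mesh densities used here
geodesic_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  tr <- mesh$triangles
  # map each undirected edge to the opposite vertices of its triangles
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edge_ids <- c(ekey(tr[, 1], tr[, 2]), ekey(tr[, 2], tr[, 3]),
                ekey(tr[, 3], tr[, 1]))
  opp <- c(tr[, 3], tr[, 1], tr[, 2])
  sp <- split(opp, edge_ids)
  two <- sp[lengths(sp) == 2]
  if (length(two)) {
    shortcut <- do.call(rbind, unname(two))
    shortcut <- shortcut[shortcut[, 1] != shortcut[, 2], , drop = FALSE]
    e <- rbind(e, cbind(pmin(shortcut[, 1], shortcut[, 2]),
                        pmax(shortcut[, 1], shortcut[, 2])))
    e <- unique(e)
  }
  w <- sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                     mesh$nodes[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$nodes)) {
    g <- igraph::add_vertices(g, nrow(mesh$nodes) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- w
  g
}

#' On-surface (geodesic) distance
#'
#' Shortest on-surface path length from a source node to target nodes,
#' computed by Dijkstra on the mesh edge graph augmented with
#' triangle-diagonal shortcuts. On a flat sheet this equals the Euclidean
#' distance to within a few percent.
#'
#' @inheritParams triangle_geometry
#' @param source source node index.
#' @param targets integer vector of target node indices.
#' @return numeric vector of distances, mm.
#' @export
geodesic_distance <- function(mesh, source, targets) {
  g <- geodesic_graph(mesh)
  d <- igraph::distances(g, v = source, to = targets)[1, ]
  if (any(!is.finite(d))) {
    stop("unreachable target nodes (disconnected component): ",
         paste(targets[!is.finite(d)], collapse = ", "))
  }
  unname(d)
}

#' Assign a fiber field to a mesh
#'
#' Three synthetic fiber rules stand in for atlas-based fiber tracking:
#' `uniform` (a constant direction projected to the tangent plane),
#' `circular` (perpendicular to the radius from a center, i.e. concentric),
#' and `from_lat_gradient` (parallel to the surface gradient of a local
#' activation time field — the direction of fastest apparent conduction —
#' smoothed over one ring of neighbors). The last rule is how clinical
#' activation maps inform the fiber direction.
#'
#' @inheritParams triangle_geometry
#' @param rule `"uniform"`, `"circular"` or `"from_lat_gradient"`.
#' @param direction length-3 vector for `uniform`.
#' @param center length-3 point for `circular`.
#' @param lat numeric(n) activation times for `from_lat_gradient`, ms.
#' @return The mesh with `fiber` set (unit, tangent).
#' @export
assign_fiber_field <- function(mesh,
                               rule = c("uniform", "circular",
                                        "from_lat_gradient"),
                               direction = c(1, 0, 0), center = NULL,
                               lat = NULL) {
  rule <- match.arg(rule)
  n <- nrow(mesh$nodes)
  nn <- node_normals(mesh)
  raw <- switch(rule,
    uniform = {
      if (length(direction) != 3 || all(direction == 0)) {
        stop("uniform rule needs a nonzero length-3 direction")
      }
      matrix(rep(direction, each = n), ncol = 3)
    },
    circular = {
      if (is.null(center) || length(center) != 3) {
        stop("circular rule needs a length-3 center")
      }
      r <- sweep(mesh$nodes, 2, center)
      cbind(nn[, 2] * r[, 3] - nn[, 3] * r[, 2],
            nn[, 3] * r[, 1] - nn[, 1] * r[, 3],
            nn[, 1] * r[, 2] - nn[, 2] * r[, 1])
    },
    from_lat_gradient = {
      if (is.null(lat) || length(lat) != n) {
        stop("from_lat_gradient needs a LAT value per node")
      }
      node_gradient(mesh, lat)
    })
  # project to tangent plane
  raw <- raw - nn * rowSums(raw * nn)
  nr <- sqrt(rowSums(raw^2))
  bad <- which(nr < 1e-9)
  raw <- normalize_rows(raw)
  # fall back to the one-ring neighbor average at degenerate nodes, then
  # smooth the from_lat_gradient field by one ring
  adj <- node_adjacency_list(mesh)
  fill_from_neighbors <- function(vecs, idx) {
    for (i in idx) {
      v <- colSums(vecs[adj[[i]], , drop = FALSE])
      v <- v - nn[i, ] * sum(v * nn[i, ])
      if (sqrt(sum(v^2)) < 1e-9) next
      vecs[i, ] <- v / sqrt(sum(v^2))
    }
    vecs
  }
  if (length(bad)) {
    if (length(bad) > n / 2) stop("fully degenerate fiber field")
    raw[bad, ] <- 0
    raw <- fill_from_neighbors(raw, bad)
    still <- which(sqrt(rowSums(raw^2)) < 1e-9)
    if (length(still)) raw <- fill_from_neighbors(raw, still)
    # isolated singular points (e.g. the poles of a circular field on a
    # closed surface) get an arbitrary tangent direction
    still <- which(sqrt(rowSums(raw^2)) < 1e-9)
    for (i in still) {
      for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        v <- axis - nn[i, ] * sum(axis * nn[i, ])
        if (sqrt(sum(v^2)) > 1e-6) {
          raw[i, ] <- v / sqrt(sum(v^2))
          break
        }
      }
    }
  }
  if (rule == "from_lat_gradient") {
    sm <- raw
    for (i in seq_len(n)) {
      ring <- c(i, adj[[i]])
      # align neighbor vectors with the node's own before averaging
      vi <- raw[i, ]
      vs <- raw[ring, , drop = FALSE]
      flip <- sign(vs %*% vi)
      flip[flip == 0] <- 1
      v <- colSums(vs * as.numeric(flip))
      v <- v - nn[i, ] * sum(v * nn[i, ])
      if (sqrt(sum(v^2)) > 1e-9) sm[i, ] <- v / sqrt(sum(v^2))
    }
    raw <- sm
  }
  if (any(sqrt(rowSums(raw^2)) < 0.5)) stop("fully degenerate fiber field")
  mesh$fiber <- normalize_rows(raw)
  validate_fiber_field(mesh)
  mesh
}

node_adjacency_list <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$nodes)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = 1:n))
  unname(adj)
}

#' Per-node surface gradient of a scalar field
#'
#' Area-weighted average of per-triangle P1 gradients over each node's
#' incident triangles.
#'
#' @inheritParams triangle_geometry
#' @param values numeric(n) scalar field.
#' @return n x 3 matrix of gradient vectors (tangent to the surface).
#' @export
node_gradient <- function(mesh, values) {
  tg <- triangle_geometry(mesh)
  grads <- element_gradients(mesh) # list of m x 3 basis gradient matrices
  tr <- mesh$triangles
  gx <- grads$g1 * values[tr[, 1]] + grads$g2 * values[tr[, 2]] +
        grads$g3 * values[tr[, 3]]
  n <- nrow(mesh$nodes)
  acc <- matrix(0, n, 3)
  wsum <- numeric(n)
  w <- tg$area
  for (k in 1:3) {
    idx <- tr[, k]
    for (d in 1:3) {
      s <- rowsum(gx[, d] * w, idx)
      acc[as.integer(rownames(s)), d] <- acc[as.integer(rownames(s)), d] + s
    }
    sw <- rowsum(w, idx)
    wsum[as.integer(rownames(sw))] <- wsum[as.integer(rownames(sw))] + sw
  }
  acc / pmax(wsum, 1e-12)
}

# P1 basis-function gradients per triangle: for vertex i opposite edge e_i,
# grad phi_i = (n x e_i) / (2A) with e_i oriented so grad phi_i points
# toward vertex i.
element_gradients <- function(mesh) {
  tr <- mesh$triangles
  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  tg <- triangle_geometry(mesh)
  nrm <- tg$normal
  cross_rows <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  inv2A <- 1 / (2 * tg$area)
  list(g1 = cross_rows(nrm, p3 - p2) * inv2A,
       g2 = cross_rows(nrm, p1 - p3) * inv2A,
       g3 = cross_rows(nrm, p2 - p1) * inv2A,
       area = tg$area, normal = nrm, centroid = tg$centroid)
}
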