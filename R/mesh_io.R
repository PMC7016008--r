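#' Read and write surface meshes
#'
#' ASCII readers/writers for three standard surface-mesh formats: PLY, OFF
#' and legacy VTK POLYDATA. PLY and VTK carry the per-node attributes
#' (fiber vector, fibrosis flag, region label); OFF stores geometry only.
#' Round-tripping a mesh through PLY or VTK preserves nodes and triangles
#' to full double precision.
#'
#' @param path file path.
#' @param format `"ply"`, `"off"` or `"vtk"`; inferred from the file
#'   extension when `NULL`.
#' @param mesh an `atrial_mesh`.
#' @return `load_mesh` returns an `atrial_mesh`; `save_mesh` returns `path`
#'   invisibly.
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- resolve_mesh_format(path, format)
  switch(format,
         ply = read_ply(path),
         off = read_off(path),
         vtk = read_vtk(path))
}

#' @rdname load_mesh
#' @export
save_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "atrial_mesh"))
  format <- resolve_mesh_format(path, format)
  switch(format,
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         vtk = write_vtk(mesh, path))
  invisible(path)
}

resolve_mesh_format <- function(path, format) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- tolower(format)
  if (!format %in% c("ply", "off", "vtk")) {
    stop("unknown mesh format '", format, "' (supported: ply, off, vtk)")
  }
  format
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$nodes, 1,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1,
                   function(r) paste(c(3L, r), collapse = " ")), con)
}

read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("malformed OFF file: ", path)
  hdr <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  if (length(ln) < 2 + nv + nf) stop("truncated OFF file: ", path)
  nodes <- t(vapply(ln[3:(2 + nv)],
                    function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3]),
                    numeric(3)))
  faces <- t(vapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 3) stop("non-triangular face in OFF file: ", path)
    v[2:4]
  }, integer(3)))
  atrial_mesh(unname(nodes), unname(faces) + 1L)
}

write_ply <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  has_fiber <- !is.null(mesh$fiber)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (has_fiber) {
    hdr <- c(hdr, "property double fiber_x", "property double fiber_y",
             "property double fiber_z")
  }
  hdr <- c(hdr, "property uchar fibrosis", "property int region",
           sprintf("element face %d", nrow(mesh$triangles)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vmat <- mesh$nodes
  if (has_fiber) vmat <- cbind(vmat, mesh$fiber)
  vlines <- apply(vmat, 1, function(r) paste(fmt_num(r), collapse = " "))
  vlines <- paste(vlines, as.integer(mesh$fibrosis), mesh$region)
  writeLines(vlines, con)
  writeLines(apply(mesh$triangles - 1L, 1,
                   function(r) paste(c(3L, r), collapse = " ")), con)
}

read_ply <- function(path) {
  ln <- readLines(path)
  if (trimws(ln[1]) != "ply") stop("malformed PLY file: ", path)
  if (!grepl("ascii", ln[2])) stop("only ascii PLY is supported: ", path)
  end <- which(trimws(ln) == "end_header")[1]
  if (is.na(end)) stop("malformed PLY file (no end_header): ", path)
  hdr <- trimws(ln[1:end])
  props <- character()
  nv <- nf <- NA_integer_
  cur <- ""
  for (h in hdr) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nv <- as.integer(tok[3])
      if (cur == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" && tok[2] != "list") {
      props <- c(props, tok[3])
    }
  }
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- ln[(end + 1):length(ln)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY file: ", path)
  vmat <- t(vapply(body[seq_len(nv)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  }, numeric(length(props))))
  colnames(vmat) <- props
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stop("PLY file lacks x/y/z coordinates: ", path)
  faces <- t(vapply(body[nv + seq_len(nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 3) stop("non-triangular face in PLY file: ", path)
    v[2:4]
  }, integer(3)))
  fiber <- NULL
  if (all(c("fiber_x", "fiber_y", "fiber_z") %in% props)) {
    fiber <- unname(vmat[, c("fiber_x", "fiber_y", "fiber_z"), drop = FALSE])
  }
  fibrosis <- if ("fibrosis" %in% props) as.logical(vmat[, "fibrosis"])
  region <- if ("region" %in% props) as.integer(vmat[, "region"])
  atrial_mesh(unname(vmat[, need, drop = FALSE]), unname(faces) + 1L,
              fiber = fiber, fibrosis = fibrosis, region = region)
}

write_vtk <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "atrialwave surface mesh",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(apply(mesh$triangles - 1L, 1,
                   function(r) paste(c(3L, r), collapse = " ")), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS fibrosis int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$fibrosis)), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$region), con)
  if (!is.null(mesh$fiber)) {
    writeLines("VECTORS fiber double", con)
    writeLines(apply(mesh$fiber, 1,
                     function(r) paste(fmt_num(r), collapse = " ")), con)
  }
}

read_vtk <- function(path) {
  ln <- readLines(path)
  tln <- trimws(ln)
  ip <- grep("^POINTS\\s", tln)[1]
  if (is.na(ip)) stop("malformed VTK file (no POINTS): ", path)
  nv <- as.integer(strsplit(tln[ip], "\\s+")[[1]][2])
  # points may wrap across lines: collect numbers until 3*nv are read
  vals <- numeric(0)
  k <- ip + 1
  while (length(vals) < 3 * nv && k <= length(ln)) {
    vals <- c(vals, as.numeric(strsplit(tln[k], "\\s+")[[1]]))
    k <- k + 1
  }
  if (length(vals) < 3 * nv) stop("truncated VTK POINTS block: ", path)
  nodes <- matrix(vals[1:(3 * nv)], ncol = 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS\\s", tln)[1]
  if (is.na(ipoly)) stop("malformed VTK file (no POLYGONS): ", path)
  nf <- as.integer(strsplit(tln[ipoly], "\\s+")[[1]][2])
  fvals <- integer(0)
  k <- ipoly + 1
  while (length(fvals) < 4 * nf && k <= length(ln)) {
    fvals <- c(fvals, as.integer(strsplit(tln[k], "\\s+")[[1]]))
    k <- k + 1
  }
  fm <- matrix(fvals[1:(4 * nf)], ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular polygon in VTK file: ", path)
  faces <- fm[, 2:4, drop = FALSE] + 1L
  read_scalar <- function(name) {
    i <- grep(sprintf("^SCALARS %s ", name), tln)[1]
    if (is.na(i)) return(NULL)
    vals <- numeric(0)
    k <- i + 2 # skip LOOKUP_TABLE
    while (length(vals) < nv && k <= length(ln)) {
      vals <- c(vals, as.numeric(strsplit(tln[k], "\\s+")[[1]]))
      k <- k + 1
    }
    vals[1:nv]
  }
  fibrosis <- read_scalar("fibrosis")
  region <- read_scalar("region")
  fiber <- NULL
  iv <- grep("^VECTORS fiber ", tln)[1]
  if (!is.na(iv)) {
    vals <- numeric(0)
    k <- iv + 1
    while (length(vals) < 3 * nv && k <= length(ln)) {
      vals <- c(vals, as.numeric(strsplit(tln[k], "\\s+")[[1]]))
      k <- k + 1
    }
    fiber <- matrix(vals[1:(3 * nv)], ncol = 3, byrow = TRUE)
  }
  atrial_mesh(nodes, faces, fiber = fiber,
              fibrosis = if (!is.null(fibrosis)) as.logical(fibrosis),
              region = if (!is.null(region)) as.integer(region))
}

#' Write per-node scalar fields as VTK attributes
#'
#' Saves the mesh as legacy VTK POLYDATA with additional named per-node
#' scalar arrays (e.g. a DF map or voltage field) for visualization.
#'
#' @inheritParams load_mesh
#' @param mesh an `atrial_mesh`.
#' @param fields named list of numeric(n) fields.
#' @return `path`, invisibly.
#' @export
save_mesh_with_fields <- function(mesh, path, fields = list()) {
  write_vtk(mesh, path)
  if (!length(fields)) return(invisible(path))
  con <- file(path, "a")
  on.exit(close(con))
  for (nm in names(fields)) {
    v <- fields[[nm]]
    stopifnot(length(v) == nrow(mesh$nodes))
    v[!is.finite(v)] <- -1
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt_num(v), con)
  }
  invisible(path)
}
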