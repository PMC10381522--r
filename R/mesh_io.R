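# Mesh file I/O: STL (ASCII + binary), PLY (ASCII + binary little-endian),
# OBJ (triangles). STL is triangle soup, so loading welds duplicate vertices
# before any topology query.

#' Load a triangulated surface mesh
#'
#' Reads STL, PLY, or OBJ, converts coordinates to millimetres, welds
#' duplicate vertices, drops degenerate faces, and repairs winding to a
#' consistent outward orientation.
#'
#' @param path file path; format inferred from the extension
#'   (`.stl`, `.ply`, `.obj`).
#' @param unit unit of the file's coordinates, `"mm"` or `"um"`. Mesh files
#'   carry no unit metadata; if the argument is missing, `"mm"` is assumed
#'   with a warning.
#' @param weld_tol vertex merge tolerance in mm (default 1e-6).
#' @return A [surface_mesh()] in mm with provenance recorded.
#' @export
load_mesh <- function(path, unit = c("mm", "um"), weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(unit))
    warning("no unit given; assuming coordinates are in mm", call. = FALSE)
  unit <- match.arg(unit)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                stl = read_stl(path),
                ply = read_ply(path),
                obj = read_obj(path),
                stop("unsupported mesh format: .", ext, call. = FALSE))
  V <- raw$vertices
  F <- raw$faces
  if (is.null(V) || nrow(V) == 0 || is.null(F) || nrow(F) == 0)
    stop("empty mesh in ", path, call. = FALSE)
  if (unit == "um") V <- V * 0.001
  w <- weld_vertices(V, F, tol = weld_tol)
  mesh <- surface_mesh(w$vertices, w$faces,
                       provenance = paste0(basename(path), " (", unit, ")"),
                       check = TRUE)
  orient_mesh(mesh)
}

#' Write a mesh to STL, PLY, or OBJ
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; format from extension.
#' @param binary write binary STL / binary little-endian PLY (default `TRUE`
#'   for STL, `FALSE` for PLY/OBJ text formats).
#' @param quality optional per-vertex scalar written as a PLY `quality`
#'   property.
#' @param color optional n x 3 integer matrix (0-255) of per-vertex RGB,
#'   PLY only.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = NULL, quality = NULL, color = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = isTRUE(binary) || is.null(binary)),
         ply = write_ply(mesh, path, binary = isTRUE(binary),
                         quality = quality, color = color),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: .", ext, call. = FALSE))
  invisible(path)
}

# --- STL ---------------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.info(path)$size
  close(con)
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    sz == 84 + 50 * as.numeric(ntri)
  if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84)
  rec <- readBin(con, "raw", 50 * ntri)
  m <- matrix(rec, nrow = 50)
  tri <- vapply(seq_len(ntri), function(i) {
    readBin(m[13:48, i], "numeric", 9, size = 4, endian = "little")
  }, numeric(9))
  V <- matrix(as.vector(tri), ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0) stop("no vertices in ASCII STL ", path, call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  V <- do.call(rbind, nums)
  if (nrow(V) %% 3 != 0) stop("malformed ASCII STL ", path, call. = FALSE)
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices
  F <- mesh$faces
  N <- face_normals(V, F)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(c(N[i, ], t(V[F[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid enamelmap", con)
    for (i in seq_len(nrow(F))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2],
                         N[i, 3]), con)
      writeLines("  outer loop", con)
      writeLines(sprintf("    vertex %.9g %.9g %.9g", V[F[i, ], 1],
                         V[F[i, ], 2], V[F[i, ], 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid enamelmap", con)
  }
  invisible(path)
}

# --- PLY ---------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) stop("truncated PLY header", call. = FALSE)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  fmt <- strsplit(trimws(fmt), "\\s+")[[1]][1]
  # parse element/property declarations in order
  elems <- list()
  cur <- NULL
  for (ln in hdr) {
    p <- strsplit(trimws(ln), "\\s+")[[1]]
    if (p[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = p[2], count = as.integer(p[3]), props = list())
    } else if (p[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1]] <-
        if (p[2] == "list") list(list = TRUE, ctype = p[3], vtype = p[4],
                                 name = p[5])
        else list(list = FALSE, vtype = p[2], name = p[3])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (fmt == "ascii") read_ply_ascii(con, elems)
  else if (fmt == "binary_little_endian") read_ply_binary(con, elems)
  else stop("unsupported PLY format: ", fmt, call. = FALSE)
}

ply_type_size <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stop("unknown PLY type ", t, call. = FALSE))
}
ply_type_what <- function(t) {
  if (t %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
}

read_ply_ascii <- function(con, elems) {
  out <- list()
  for (el in elems) {
    lns <- readLines(con, el$count)
    toks <- strsplit(trimws(lns), "\\s+")
    if (el$name == "vertex") {
      nm <- vapply(el$props, `[[`, "", "name")
      M <- do.call(rbind, lapply(toks, as.numeric))
      colnames(M) <- nm
      out$vertex <- M
    } else if (el$name == "face") {
      out$face <- lapply(toks, function(tk) as.integer(tk[-1]) + 1L)
    }
  }
  finish_ply(out)
}

read_ply_binary <- function(con, elems) {
  out <- list()
  for (el in elems) {
    if (el$name == "vertex") {
      nm <- vapply(el$props, `[[`, "", "name")
      M <- matrix(NA_real_, nrow = el$count, ncol = length(nm),
                  dimnames = list(NULL, nm))
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          pr <- el$props[[j]]
          sz <- ply_type_size(pr$vtype)
          M[i, j] <- readBin(con, ply_type_what(pr$vtype), 1, size = sz,
                             endian = "little",
                             signed = !(pr$vtype %in% c("uchar", "uint8",
                                                        "ushort", "uint16")))
        }
      }
      out$vertex <- M
    } else if (el$name == "face") {
      pr <- el$props[[1]]
      fl <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        n <- readBin(con, ply_type_what(pr$ctype), 1,
                     size = ply_type_size(pr$ctype), endian = "little",
                     signed = !(pr$ctype %in% c("uchar", "uint8")))
        idx <- readBin(con, ply_type_what(pr$vtype), n,
                       size = ply_type_size(pr$vtype), endian = "little")
        fl[[i]] <- as.integer(idx) + 1L
      }
      out$face <- fl
    } else {
      # skip unknown fixed-size element
      sz <- sum(vapply(el$props, function(p) ply_type_size(p$vtype), 0L))
      readBin(con, "raw", el$count * sz)
    }
  }
  finish_ply(out)
}

finish_ply <- function(out) {
  M <- out$vertex
  V <- M[, c("x", "y", "z"), drop = FALSE]
  F <- NULL
  if (!is.null(out$face)) {
    ns <- lengths(out$face)
    if (any(ns != 3))
      stop("PLY contains non-triangular faces", call. = FALSE)
    F <- matrix(unlist(out$face), ncol = 3, byrow = TRUE)
  }
  extra <- setdiff(colnames(M), c("x", "y", "z"))
  attrs <- if (length(extra)) M[, extra, drop = FALSE] else NULL
  list(vertices = V, faces = F, vertex_attributes = attrs)
}

write_ply <- function(mesh, path, binary = FALSE, quality = NULL,
                      color = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(V)
  if (!is.null(quality) && length(quality) != n)
    stop("quality length must match vertex count", call. = FALSE)
  if (!is.null(color) && (!is.matrix(color) || nrow(color) != n))
    stop("color must be an n x 3 matrix", call. = FALSE)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment enamelmap",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  if (!is.null(quality)) hdr <- c(hdr, "property float quality")
  if (!is.null(color))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    for (i in seq_len(n)) {
      writeBin(as.numeric(V[i, ]), con, size = 4, endian = "little")
      if (!is.null(quality))
        writeBin(as.numeric(quality[i]), con, size = 4, endian = "little")
      if (!is.null(color))
        writeBin(as.raw(color[i, ]), con)
    }
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    vl <- sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    if (!is.null(quality)) vl <- paste(vl, sprintf("%.9g", quality))
    if (!is.null(color))
      vl <- paste(vl, color[, 1], color[, 2], color[, 3])
    fl <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

# --- OBJ ---------------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(p) as.numeric(p[2:4])))
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- vapply(p[-1], function(tok) as.integer(strsplit(tok, "/")[[1]][1]),
                  0L)
    if (length(idx) != 3)
      stop("OBJ contains non-triangular faces", call. = FALSE)
    idx
  }))
  list(vertices = V, faces = F)
}

write_obj <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  invisible(path)
}

# --- welding & winding -------------------------------------------------------

# Merge vertices within `tol` by snapping to a grid of pitch `tol`.
weld_vertices <- function(V, F, tol = 1e-6) {
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  Vw <- V[first, , drop = FALSE]
  Fw <- matrix(map[F], ncol = 3)
  # drop collapsed faces
  keep <- Fw[, 1] != Fw[, 2] & Fw[, 2] != Fw[, 3] & Fw[, 1] != Fw[, 3]
  Fw <- Fw[keep, , drop = FALSE]
  keep2 <- face_areas(Vw, Fw) >= 1e-12
  list(vertices = Vw, faces = Fw[keep2, , drop = FALSE])
}

# Make winding consistent by propagation over the face adjacency graph,
# then orient components outward: the component of largest |signed volume|
# positive, components nested inside it negative (inner surface of a shell).
orient_mesh <- function(mesh) {
  F <- mesh$faces
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  o <- order(key)
  ks <- key[o]
  dup <- which(ks[-1] == ks[-length(ks)])
  if (length(dup)) {
    f1 <- he$face[o][dup]
    f2 <- he$face[o][dup + 1]
    same_dir <- he$from[o][dup] == he$from[o][dup + 1]
    g <- igraph::graph_from_edgelist(cbind(f1, f2), directed = FALSE)
    if (igraph::vcount(g) < nrow(F))
      g <- igraph::add_vertices(g, nrow(F) - igraph::vcount(g))
    igraph::E(g)$flip <- same_dir  # shared edge traversed same way => one must flip
    flip <- rep(NA, nrow(F))
    comp <- igraph::components(g)$membership
    adj <- igraph::as_adj_edge_list(g)
    ends <- igraph::ends(g, igraph::E(g))
    eflip <- igraph::E(g)$flip
    for (root in which(!duplicated(comp))) {
      flip[root] <- FALSE
      queue <- root
      while (length(queue)) {
        fcur <- queue[1]
        queue <- queue[-1]
        for (e in adj[[fcur]]) {
          nb <- if (ends[e, 1] == fcur) ends[e, 2] else ends[e, 1]
          want <- xor(flip[fcur], eflip[e])
          if (is.na(flip[nb])) {
            flip[nb] <- want
            queue <- c(queue, nb)
          }
        }
      }
    }
    flip[is.na(flip)] <- FALSE
    if (any(flip)) F[flip, ] <- F[flip, c(1, 3, 2)]
  } else {
    comp <- rep(1L, nrow(F))
  }
  # per-component outward orientation
  mesh$faces <- F
  vols <- vapply(split(seq_len(nrow(F)), comp), function(idx) {
    sub <- mesh
    sub$faces <- F[idx, , drop = FALSE]
    mesh_volume(sub)
  }, 0)
  main <- which.max(abs(vols))
  comps <- sort(unique(comp))
  bbox_of <- function(ci) {
    vv <- unique(as.vector(F[comp == comps[ci], ]))
    apply(mesh$vertices[vv, , drop = FALSE], 2, range)
  }
  main_bb <- bbox_of(main)
  for (ci in seq_along(comps)) {
    want_pos <- TRUE
    if (ci != main) {
      bb <- bbox_of(ci)
      nested <- all(bb[1, ] >= main_bb[1, ] - 1e-9) &&
        all(bb[2, ] <= main_bb[2, ] + 1e-9)
      if (nested) want_pos <- FALSE
    }
    if ((vols[ci] < 0) == want_pos) {
      idx <- which(comp == comps[ci])
      F[idx, ] <- F[idx, c(1, 3, 2)]
    }
  }
  mesh$faces <- F
  mesh
}

# --- validation --------------------------------------------------------------

#' Validate a mesh
#'
#' Side-effect-free report: watertightness, boundary loops, total area,
#' signed enclosed volume (divergence theorem), non-manifold edges, Euler
#' characteristic.
#'
#' @param mesh a [surface_mesh()].
#' @return A list of class `mesh_validation`.
#' @export
validate_mesh <- function(mesh) {
  F <- mesh$faces
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  tab <- table(key)
  n_bound <- sum(tab == 1)
  n_nonman <- sum(tab > 2)
  loops <- if (n_bound > 0) boundary_loops(mesh) else list()
  nV <- length(unique(as.vector(F)))
  nE <- length(tab)
  nF <- nrow(F)
  structure(list(
    watertight = n_bound == 0 && n_nonman == 0,
    n_boundary_edges = n_bound,
    n_boundary_loops = length(loops),
    n_nonmanifold_edges = n_nonman,
    area = mesh_area(mesh),
    volume = mesh_volume(mesh),
    euler_characteristic = nV - nE + nF
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(paste0("<mesh_validation> watertight=%s, boundary loops=%d, ",
                     "area=%.6g mm^2, volume=%.6g mm^3, chi=%d\n"),
              x$watertight, x$n_boundary_loops, x$area, x$volume,
              x$euler_characteristic))
  invisible(x)
}

#' Fill small boundary holes
#'
#' Triangulates shut every boundary loop whose perimeter is below a
#' threshold, by a fan around the loop centroid. Larger openings (such as the
#' cervical rim of a single-surface model) are left open and reported.
#'
#' @param mesh a [surface_mesh()].
#' @param max_perimeter maximum fillable loop perimeter, mm. Default 10% of
#'   the bounding-box diagonal.
#' @return List with elements `mesh` (repaired), `n_filled`, and
#'   `open_loops` (perimeters of loops left open).
#' @export
fill_holes <- function(mesh, max_perimeter = NULL) {
  nm <- nonmanifold_edges(mesh$faces)
  if (nrow(nm) > 0)
    stop(sprintf("non-manifold edge between vertices %d and %d; cannot repair",
                 nm[1, 1], nm[1, 2]), call. = FALSE)
  if (is.null(max_perimeter)) {
    bb <- apply(mesh$vertices, 2, range)
    max_perimeter <- 0.1 * sqrt(sum((bb[2, ] - bb[1, ])^2))
  }
  loops <- boundary_loops(mesh)
  if (length(loops) == 0)
    return(list(mesh = mesh, n_filled = 0L, open_loops = numeric(0)))
  V <- mesh$vertices
  F <- mesh$faces
  n_filled <- 0L
  open_per <- numeric(0)
  for (lp in loops) {
    P <- V[lp, , drop = FALSE]
    per <- sum(sqrt(rowSums((P - P[c(2:nrow(P), 1), , drop = FALSE])^2)))
    if (per >= max_perimeter) {
      open_per <- c(open_per, per)
      next
    }
    centre <- colMeans(P)
    V <- rbind(V, centre)
    ci <- nrow(V)
    k <- length(lp)
    # boundary half-edges run (lp[i] -> lp[i+1]) in face winding; the filling
    # fan must traverse them the opposite way to keep orientation consistent
    newF <- cbind(lp[c(2:k, 1)], lp, rep(ci, k))
    F <- rbind(F, newF)
    n_filled <- n_filled + 1L
  }
  out <- mesh
  out$vertices <- V
  out$faces <- F
  list(mesh = out, n_filled = n_filled, open_loops = open_per)
}
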