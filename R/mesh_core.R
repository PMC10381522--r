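#' Triangulated surface mesh
#'
#' The universal geometric carrier of the package: vertex coordinates in
#' millimetres and triangle faces as 1-based vertex index triples with
#' consistent outward winding.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param provenance free-text source tag.
#' @param check validate invariants (finite coordinates, index range,
#'   non-degenerate faces)? Default `TRUE`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, provenance = "", check = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (check) {
    if (nrow(vertices) == 0 || nrow(faces) == 0)
      stop("empty mesh: no vertices or faces", call. = FALSE)
    if (any(!is.finite(vertices)))
      stop("non-finite vertex coordinates", call. = FALSE)
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face references an out-of-range vertex index", call. = FALSE)
    a <- face_areas(vertices, faces)
    if (any(a < 1e-12))
      stop(sprintf("%d degenerate faces (area < 1e-12 mm^2)", sum(a < 1e-12)),
           call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)[1]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

# --- low-level triangle quantities (vectorized over faces) ------------------

face_cross <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_areas <- function(V, F) {
  cr <- face_cross(V, F)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(V, F) {
  cr <- face_cross(V, F)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

face_centroids <- function(V, F) {
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return Numeric scalar.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Signed enclosed volume of a mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes against the origin;
#' meaningful for watertight meshes, sign follows winding.
#' @param mesh a `surface_mesh`.
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  cr <- face_cross(V, F)
  sum(rowSums(a * cr)) / 6
}

# --- edge topology -----------------------------------------------------------

# Undirected edge key for vertex pair (i, j); safe as a double for < 9e7 verts.
edge_key <- function(i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  lo * 1e8 + hi
}

# All 3m directed half-edges with their face of origin.
half_edges <- function(F) {
  m <- nrow(F)
  data.frame(from = c(F[, 1], F[, 2], F[, 3]),
             to   = c(F[, 2], F[, 3], F[, 1]),
             face = rep(seq_len(m), 3))
}

# Per undirected edge: incidence count and (up to two) adjacent faces.
edge_incidence <- function(F) {
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  cnt <- table(key)
  list(he = he, key = key, count = cnt)
}

# Boundary half-edges: undirected edges used by exactly one face, in the
# direction they appear in that face (so loops inherit the surface winding).
boundary_half_edges <- function(F) {
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  tab <- table(key)
  single <- names(tab)[tab == 1]
  he[key %in% as.numeric(single), , drop = FALSE]
}

# Chain directed edges (from, to) into ordered loops / open chains.
# Returns a list of records `list(v = vertex sequence, closed = flag)`;
# closed loops do not repeat the first vertex at the end.
chain_edges <- function(from, to) {
  n <- length(from)
  if (n == 0) return(list())
  used <- rep(FALSE, n)
  out <- split(seq_len(n), from)
  pick <- function(v) {
    ids <- out[[as.character(v)]]
    if (is.null(ids)) return(NA_integer_)
    ids <- ids[!used[ids]]
    if (length(ids) == 0) NA_integer_ else ids[1]
  }
  trace_from <- function(v0) {
    path <- v0
    repeat {
      e <- pick(path[length(path)])
      if (is.na(e)) return(list(v = path, closed = FALSE))
      used[e] <<- TRUE
      nv <- to[e]
      if (nv == path[1]) return(list(v = path, closed = TRUE))
      path <- c(path, nv)
    }
  }
  res <- list()
  starts <- setdiff(unique(from), unique(to))
  for (s in starts)
    while (!is.na(pick(s))) res[[length(res) + 1]] <- trace_from(s)
  while (any(!used))
    res[[length(res) + 1]] <- trace_from(from[which(!used)[1]])
  res
}

# Ordered boundary loops as lists of vertex index vectors.
boundary_loops <- function(mesh) {
  be <- boundary_half_edges(mesh$faces)
  if (nrow(be) == 0) return(list())
  res <- chain_edges(be$from, be$to)
  lapply(res, `[[`, "v")
}

# Face adjacency graph: undirected igraph, vertices = faces, edges between
# faces sharing a mesh edge. Edge attribute "elen" = shared edge length.
face_adjacency <- function(mesh) {
  F <- mesh$faces
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  o <- order(key)
  key <- key[o]
  face <- he$face[o]
  from <- he$from[o]
  to <- he$to[o]
  dup <- which(key[-1] == key[-length(key)])
  if (length(dup) == 0) {
    g <- igraph::make_empty_graph(n = nrow(F), directed = FALSE)
    return(g)
  }
  f1 <- face[dup]
  f2 <- face[dup + 1]
  elen <- sqrt(rowSums((mesh$vertices[from[dup], , drop = FALSE] -
                          mesh$vertices[to[dup], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(f1, f2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(F) - igraph::vcount(g)))
  igraph::E(g)$elen <- elen
  g
}

# Non-manifold edges (incidence > 2). Returns matrix of vertex pairs.
nonmanifold_edges <- function(F) {
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  tab <- table(key)
  bad <- as.numeric(names(tab)[tab > 2])
  if (length(bad) == 0) return(matrix(integer(0), ncol = 2))
  cbind(floor(bad / 1e8), bad %% 1e8)
}

# --- rigid transforms --------------------------------------------------------

# Active rotation p' = R p + t applied to points stored as rows.
transform_points <- function(P, R = diag(3), t = c(0, 0, 0)) {
  sweep(P %*% t(R), 2, -as.numeric(t))
}

translate_mesh <- function(mesh, t) {
  mesh$vertices <- sweep(mesh$vertices, 2, -as.numeric(t))
  mesh
}
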