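# Enamel-cap segmentation: partition the cap mesh into the outer enamel
# surface (OES) and the enamel-dentine junction (EDJ) from face positions and
# normal directions, and extract their shared cervical borderline.

#' Enamel cap: mesh plus outer/inner partition and cervical edge
#'
#' @param mesh a [surface_mesh()].
#' @param outer_faces,inner_faces integer face-index sets (OES / EDJ); must
#'   partition the faces.
#' @param cervical_edge optional [contour3d()] of the cervical borderline.
#' @param mass_center area-weighted surface centroid (recorded, not applied).
#' @return An object of class `enamel_cap`.
#' @export
enamel_cap <- function(mesh, outer_faces, inner_faces, cervical_edge = NULL,
                       mass_center = c(0, 0, 0)) {
  outer_faces <- sort(unique(as.integer(outer_faces)))
  inner_faces <- sort(unique(as.integer(inner_faces)))
  nf <- nrow(mesh$faces)
  if (length(intersect(outer_faces, inner_faces)) > 0)
    stop("outer and inner face sets overlap", call. = FALSE)
  if (length(outer_faces) + length(inner_faces) != nf)
    stop("outer and inner face sets must partition the mesh faces",
         call. = FALSE)
  structure(list(mesh = mesh, outer_faces = outer_faces,
                 inner_faces = inner_faces, cervical_edge = cervical_edge,
                 mass_center = as.numeric(mass_center)),
            class = "enamel_cap")
}

#' @export
print.enamel_cap <- function(x, ...) {
  cat(sprintf("<enamel_cap> %d OES + %d EDJ faces, %d vertices\n",
              length(x$outer_faces), length(x$inner_faces),
              nrow(x$mesh$vertices)))
  invisible(x)
}

#' Ordered 3D contour
#'
#' @param points k x 3 matrix of ordered points (mm).
#' @param closed is the contour a closed loop?
#' @return An object of class `contour3d`.
#' @export
contour3d <- function(points, closed = TRUE) {
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  # drop consecutive duplicates
  if (nrow(points) > 1) {
    d <- sqrt(rowSums((points - points[c(2:nrow(points), 1), ,
                                       drop = FALSE])^2))
    keep <- if (closed) d > 1e-12 else c(d[-length(d)] > 1e-12, TRUE)
    points <- points[keep, , drop = FALSE]
  }
  if (closed && nrow(points) < 3)
    stop("a closed contour needs at least 3 distinct points", call. = FALSE)
  structure(list(points = points, closed = isTRUE(closed)),
            class = "contour3d")
}

#' Arc length of a contour (mm)
#' @param contour a [contour3d()].
#' @return Numeric scalar.
#' @export
contour_length <- function(contour) {
  P <- contour$points
  if (nrow(P) < 2) return(0)
  seg <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  len <- sum(sqrt(rowSums(seg^2)))
  if (contour$closed)
    len <- len + sqrt(sum((P[1, ] - P[nrow(P), ])^2))
  len
}

#' @export
print.contour3d <- function(x, ...) {
  cat(sprintf("<contour3d> %d points, %s, length %.4g mm\n", nrow(x$points),
              if (x$closed) "closed" else "open", contour_length(x)))
  invisible(x)
}

#' Translate a mesh so its area-weighted surface centroid is at the origin
#'
#' @param mesh a [surface_mesh()].
#' @return List with `mesh` (translated) and `mass_center` (original
#'   centroid).
#' @export
center_at_mass <- function(mesh) {
  a <- face_areas(mesh$vertices, mesh$faces)
  if (sum(a) <= 0) stop("zero total surface area", call. = FALSE)
  cen <- face_centroids(mesh$vertices, mesh$faces)
  com <- unname(colSums(cen * a) / sum(a))
  list(mesh = translate_mesh(mesh, -com), mass_center = com)
}

#' Partition an enamel-cap mesh into outer (OES) and inner (EDJ) surfaces
#'
#' Two-pass classification from the triangle position and normal direction:
#' each face is seeded outer or inner by the sign of the dot product between
#' its outward normal and the ray from the surface mass centre to the face
#' centroid; labels are then refined over edge-connected components, keeping
#' the two largest components and absorbing smaller ones into the neighbour
#' with the longest shared border.
#'
#' @param mesh a [surface_mesh()], centred via [center_at_mass()].
#' @param tie_cos faces whose |cosine| to the radial direction is below this
#'   are left to the refinement pass.
#' @return An [enamel_cap()] with the cervical edge populated.
#' @export
classify_surfaces <- function(mesh, tie_cos = 1e-3) {
  cen <- face_centroids(mesh$vertices, mesh$faces)
  nrm <- face_normals(mesh$vertices, mesh$faces)
  a <- face_areas(mesh$vertices, mesh$faces)
  com <- colSums(cen * a) / sum(a)
  rad <- sweep(cen, 2, com)
  rn <- sqrt(rowSums(rad^2))
  rn[rn == 0] <- 1
  cosang <- rowSums(nrm * rad) / rn
  lab <- ifelse(cosang > tie_cos, 1L, ifelse(cosang < -tie_cos, 2L, 0L))
  g <- face_adjacency(mesh)
  ends <- igraph::ends(g, igraph::E(g))
  elen <- igraph::E(g)$elen
  # resolve ties by neighbour majority (two sweeps suffice in practice)
  for (sweep_i in 1:3) {
    idx <- which(lab == 0L)
    if (!length(idx)) break
    for (f in idx) {
      nb <- c(ends[ends[, 1] == f, 2], ends[ends[, 2] == f, 1])
      nl <- lab[nb]
      if (any(nl > 0L))
        lab[f] <- as.integer(names(which.max(table(nl[nl > 0L]))))
    }
  }
  lab[lab == 0L] <- 1L
  ncomp_mesh <- igraph::components(g)$no
  if (ncomp_mesh > 2) {
    sizes <- sort(table(igraph::components(g)$membership), decreasing = TRUE)
    stop("ambiguous topology: mesh has ", ncomp_mesh,
         " disconnected shells of sizes ", paste(sizes, collapse = ", "),
         call. = FALSE)
  }
  # component refinement: absorb all but the two largest same-label
  # components into the neighbour with the longest shared border
  keep_edge <- lab[ends[, 1]] == lab[ends[, 2]]
  gsub <- igraph::subgraph_from_edges(g, igraph::E(g)[keep_edge],
                                      delete.vertices = FALSE)
  comp <- igraph::components(gsub)$membership
  repeat {
    sizes <- tapply(a, comp, sum)
    if (length(sizes) <= 2) break
    cc <- as.integer(names(sizes)[order(sizes)[1]])
    eb <- which(xor(comp[ends[, 1]] == cc, comp[ends[, 2]] == cc))
    if (!length(eb)) {
      comp[comp == cc] <- as.integer(names(sizes)[which.max(sizes)])
      next
    }
    other <- ifelse(comp[ends[eb, 1]] == cc, comp[ends[eb, 2]],
                    comp[ends[eb, 1]])
    blen <- tapply(elen[eb], other, sum)
    comp[comp == cc] <- as.integer(names(which.max(blen)))
  }
  comps <- unique(comp)
  if (length(comps) < 2)
    stop(paste0("no internal surface found: classification produced a ",
                "single class"), call. = FALSE)
  # outer class = component whose area-weighted radial cosine is larger
  score <- vapply(comps, function(cc) {
    idx <- comp == cc
    sum(a[idx] * cosang[idx]) / sum(a[idx])
  }, 0)
  outer_faces <- which(comp == comps[which.max(score)])
  inner_faces <- which(comp == comps[which.min(score)])
  # both classes must be edge-connected
  for (cls in list(outer_faces, inner_faces)) {
    sub <- igraph::induced_subgraph(g, cls)
    ncomp <- igraph::components(sub)$no
    if (ncomp > 1) {
      sizes <- sort(table(igraph::components(sub)$membership),
                    decreasing = TRUE)
      stop("ambiguous topology: a surface class splits into ", ncomp,
           " components of sizes ", paste(sizes, collapse = ", "),
           call. = FALSE)
    }
  }
  cap <- enamel_cap(mesh, outer_faces, inner_faces, mass_center = com)
  cap$cervical_edge <- tryCatch(extract_cervical_edge(cap),
                                error = function(e) NULL)
  cap
}

#' Extract the cervical edge of an enamel cap
#'
#' The borderline between the OES and EDJ classes: for a closed cap, the set
#' of mesh edges with one face of each class; for an open-rim cap, the mesh
#' boundary loop. Returned as a single closed loop ordered by edge adjacency,
#' traversed counter-clockwise about the crown direction.
#'
#' @param cap an [enamel_cap()].
#' @return A closed [contour3d()].
#' @export
extract_cervical_edge <- function(cap) {
  mesh <- cap$mesh
  F <- mesh$faces
  cls <- integer(nrow(F))
  cls[cap$outer_faces] <- 1L
  cls[cap$inner_faces] <- 2L
  he <- half_edges(F)
  key <- edge_key(he$from, he$to)
  o <- order(key)
  ks <- key[o]
  dup <- which(ks[-1] == ks[-length(ks)])
  f1 <- he$face[o][dup]
  f2 <- he$face[o][dup + 1]
  mixed <- which(cls[f1] != cls[f2])
  if (length(mixed) >= 3) {
    # orient each borderline edge as it appears in its OUTER face, so the
    # chained loop inherits the outer-surface winding
    eo <- o[dup][mixed]
    ei <- o[dup + 1][mixed]
    use <- ifelse(cls[he$face[eo]] == 1L, eo, ei)
    res <- chain_edges(he$from[use], he$to[use])
  } else {
    be <- boundary_half_edges(F)
    if (nrow(be) == 0)
      stop(paste0("no cervical edge: classes share no border and the mesh ",
                  "has no boundary"), call. = FALSE)
    res <- chain_edges(be$from, be$to)
  }
  closed <- vapply(res, `[[`, TRUE, "closed")
  res <- res[closed]
  if (length(res) == 0)
    stop("cervical edge chaining produced no closed loop", call. = FALSE)
  if (length(res) > 1) {
    lens <- vapply(res, function(r) {
      P <- mesh$vertices[r$v, , drop = FALSE]
      sum(sqrt(rowSums((P - P[c(2:nrow(P), 1), , drop = FALSE])^2)))
    }, 0)
    stop("multiple cervical boundary loops (lengths ",
         paste(sprintf("%.3g", sort(lens, decreasing = TRUE)),
               collapse = ", "), " mm)", call. = FALSE)
  }
  P <- mesh$vertices[res[[1]]$v, , drop = FALSE]
  orient_loop_ccw(contour3d(P, closed = TRUE), cap)
}

# Orient a closed loop counter-clockwise about the crown (occlusal) axis:
# the plane normal signed toward the side holding the larger cap area.
orient_loop_ccw <- function(contour, cap = NULL) {
  P <- contour$points
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Q), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (!is.null(cap)) {
    cen <- face_centroids(cap$mesh$vertices, cap$mesh$faces)
    a <- face_areas(cap$mesh$vertices, cap$mesh$faces)
    side <- sign(sweep(cen, 2, ctr) %*% nrm)
    if (sum(a * side) < 0) nrm <- -nrm
  } else if (nrm[3] < 0) nrm <- -nrm
  # signed area of the projection onto the plane with normal nrm
  basis <- svd(diag(3) - tcrossprod(nrm))$u[, 1:2]
  uv <- Q %*% basis
  if (det(cbind(basis, nrm)) < 0) uv[, 2] <- -uv[, 2]
  k <- nrow(uv)
  s <- sum(uv[, 1] * uv[c(2:k, 1), 2] - uv[c(2:k, 1), 1] * uv[, 2]) / 2
  if (s < 0) contour$points <- P[k:1, , drop = FALSE]
  contour
}

#' Per-face class labels of a cap (1 = OES, 2 = EDJ)
#' @param cap an [enamel_cap()].
#' @return Integer vector over faces.
#' @export
cap_face_classes <- function(cap) {
  cls <- integer(nrow(cap$mesh$faces))
  cls[cap$outer_faces] <- 1L
  cls[cap$inner_faces] <- 2L
  cls
}

#' OES or EDJ submesh of a cap
#' @param cap an [enamel_cap()].
#' @param which `"oes"` or `"edj"`.
#' @return List with `mesh` (the submesh) and `vertex_map` (submesh vertex id
#'   -> cap vertex id).
#' @export
cap_submesh <- function(cap, which = c("oes", "edj")) {
  which <- match.arg(which)
  fidx <- if (which == "oes") cap$outer_faces else cap$inner_faces
  F <- cap$mesh$faces[fidx, , drop = FALSE]
  vids <- sort(unique(as.vector(F)))
  remap <- integer(nrow(cap$mesh$vertices))
  remap[vids] <- seq_along(vids)
  mesh <- surface_mesh(cap$mesh$vertices[vids, , drop = FALSE],
                       matrix(remap[F], ncol = 3),
                       provenance = paste0(cap$mesh$provenance, ":", which),
                       check = FALSE)
  list(mesh = mesh, vertex_map = vids)
}
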