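# Tooth coordinate frame: origin at the cervical-edge centroid, z toward the
# occlusal side (plane normal of the cervical edge), x along the mesio-distal
# principal axis, y bucco-lingual. Each tooth is oriented in its own frame,
# with no reference to external geometry.

#' Tooth coordinate frame
#'
#' @param origin 3D point (mm).
#' @param x_axis,y_axis,z_axis orthonormal right-handed axes
#'   (mesio-distal, bucco-lingual, occluso-cervical; +z occlusal).
#' @return An object of class `tooth_frame`.
#' @export
tooth_frame <- function(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                        y_axis = c(0, 1, 0), z_axis = c(0, 0, 1)) {
  R <- cbind(as.numeric(x_axis), as.numeric(y_axis), as.numeric(z_axis))
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("axes are not orthonormal", call. = FALSE)
  if (det(R) < 0)
    stop("axes are not right-handed (x cross y must equal z)", call. = FALSE)
  structure(list(origin = as.numeric(origin), x_axis = R[, 1],
                 y_axis = R[, 2], z_axis = R[, 3]),
            class = "tooth_frame")
}

#' @export
print.tooth_frame <- function(x, ...) {
  cat("<tooth_frame>\n")
  cat(sprintf("  origin: % .4f % .4f % .4f\n", x$origin[1], x$origin[2],
              x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: % .6f % .6f % .6f\n", ax, x[[ax]][1], x[[ax]][2],
                x[[ax]][3]))
  invisible(x)
}

# arc-length weights of contour points (half the two adjacent segments)
contour_weights <- function(contour) {
  P <- contour$points
  k <- nrow(P)
  nxt <- sqrt(rowSums((P[c(2:k, 1), , drop = FALSE] - P)^2))
  prv <- nxt[c(k, 1:(k - 1))]
  if (!contour$closed) {
    nxt[k] <- 0
    prv[1] <- 0
  }
  (nxt + prv) / 2
}

#' Build a tooth frame from the cervical edge
#'
#' Origin at the arc-length-weighted centroid of the edge points; z along the
#' total-least-squares plane normal, signed toward the crown (the side
#' holding the larger share of cap surface area when a cap is supplied);
#' x along the major principal axis of the edge points projected into the
#' plane; y completes the right-handed frame.
#'
#' @param edge closed [contour3d()] with at least 10 points.
#' @param cap optional [enamel_cap()] used to pick the occlusal direction and
#'   the principal-axis sign.
#' @return A [tooth_frame()].
#' @export
frame_from_cervical_edge <- function(edge, cap = NULL) {
  P <- edge$points
  if (!edge$closed || nrow(P) < 10)
    stop("need a closed cervical edge with at least 10 points", call. = FALSE)
  w <- contour_weights(edge)
  origin <- colSums(P * w) / sum(w)
  Q <- sweep(P, 2, origin)
  M <- crossprod(Q * sqrt(w / sum(w)))
  ev <- eigen(M, symmetric = TRUE)
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1e-300))
    stop("degenerate cervical edge: points are collinear", call. = FALSE)
  z <- ev$vectors[, 3]
  if (!is.null(cap)) {
    cen <- face_centroids(cap$mesh$vertices, cap$mesh$faces)
    a <- face_areas(cap$mesh$vertices, cap$mesh$faces)
    if (sum(a * sign(sweep(cen, 2, origin) %*% z)) < 0) z <- -z
  } else if (z[3] < 0) z <- -z
  x <- principal_axis_in_plane(P, w, origin, z)
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  tooth_frame(origin, x, y / sqrt(sum(y^2)), z)
}

# Major principal axis of weighted contour points projected into the plane
# (origin, normal z), with the deterministic sign rule: +x toward the contour
# half contributing the larger enclosed area; within 1%, toward the first
# contour point.
principal_axis_in_plane <- function(P, w, origin, z) {
  Q <- sweep(P, 2, origin)
  Qp <- Q - outer(as.vector(Q %*% z), z)
  M <- crossprod(Qp * sqrt(w / sum(w)))
  ev <- eigen(M, symmetric = TRUE)
  x <- ev$vectors[, 1]
  x <- x - sum(x * z) * z
  x <- x / sqrt(sum(x^2))
  k <- nrow(P)
  nxtQ <- Qp[c(2:k, 1), , drop = FALSE]
  crossP <- cbind(Qp[, 2] * nxtQ[, 3] - Qp[, 3] * nxtQ[, 2],
                  Qp[, 3] * nxtQ[, 1] - Qp[, 1] * nxtQ[, 3],
                  Qp[, 1] * nxtQ[, 2] - Qp[, 2] * nxtQ[, 1])
  tri_a <- abs(crossP %*% z) / 2   # sector area per segment
  side <- sign((Qp + nxtQ) %*% x)
  apos <- sum(tri_a[side > 0])
  aneg <- sum(tri_a[side < 0])
  tot <- apos + aneg
  if (tot > 0 && abs(apos - aneg) / tot > 0.01) {
    if (apos < aneg) x <- -x
  } else if (sum(Qp[1, ] * x) < 0) x <- -x
  x
}

#' Re-align the mesio-distal axis to the occlusal contour
#'
#' Keeps origin and z; x is recomputed as the major principal axis of the
#' occlusal contour projected into the cervical plane, then the frame is
#' re-orthonormalised.
#'
#' @param frame a [tooth_frame()].
#' @param occlusal_contour a [contour3d()] with at least 10 points, in the
#'   same coordinates as `frame`.
#' @return A [tooth_frame()].
#' @export
refine_frame_with_occlusal <- function(frame, occlusal_contour) {
  P <- occlusal_contour$points
  if (nrow(P) < 10)
    stop("occlusal contour too short (< 10 points)", call. = FALSE)
  w <- contour_weights(occlusal_contour)
  z <- frame$z_axis
  x <- principal_axis_in_plane(P, w, frame$origin, z)
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  tooth_frame(frame$origin, x, y / sqrt(sum(y^2)), z)
}

#' Transform geometry into frame coordinates
#'
#' Rigid map `p -> R^T (p - origin)` taking world coordinates into the tooth
#' frame (x mesio-distal, y bucco-lingual, z occlusal). Areas and volumes are
#' unchanged.
#'
#' @param x a [surface_mesh()], [contour3d()], [enamel_cap()], or k x 3
#'   matrix.
#' @param frame a [tooth_frame()].
#' @return Object of the same class in frame coordinates.
#' @export
apply_frame <- function(x, frame) UseMethod("apply_frame")

frame_rotation <- function(frame)
  cbind(frame$x_axis, frame$y_axis, frame$z_axis)

#' @export
apply_frame.matrix <- function(x, frame) {
  out <- sweep(x, 2, frame$origin) %*% frame_rotation(frame)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
apply_frame.surface_mesh <- function(x, frame) {
  x$vertices <- apply_frame(x$vertices, frame)
  x
}

#' @export
apply_frame.contour3d <- function(x, frame) {
  x$points <- apply_frame(x$points, frame)
  x
}

#' @export
apply_frame.enamel_cap <- function(x, frame) {
  x$mesh <- apply_frame(x$mesh, frame)
  if (!is.null(x$cervical_edge))
    x$cervical_edge <- apply_frame(x$cervical_edge, frame)
  x$mass_center <- as.vector(apply_frame(matrix(x$mass_center, 1), frame))
  x
}

#' Serialize / read a frame as JSON
#' @param frame a [tooth_frame()].
#' @param path output path.
#' @return `path` (write) or a [tooth_frame()] (read).
#' @export
write_frame <- function(frame, path) {
  jsonlite::write_json(list(origin = frame$origin, x_axis = frame$x_axis,
                            y_axis = frame$y_axis, z_axis = frame$z_axis),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tooth_frame(j$origin, j$x_axis, j$y_axis, j$z_axis)
}
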