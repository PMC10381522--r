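# Topographic enamel-thickness mapping: per-OES-vertex nearest distance to
# the EDJ surface, exported as a colour-mapped PLY model.

#' Per-vertex enamel thickness on the outer enamel surface
#'
#' For every OES vertex, the unsigned distance to the nearest point of the
#' EDJ face set (point-to-triangle, candidate-filtered in compiled code).
#' The alternative `"ray"` method casts along -z instead and is bounded below
#' by the nearest-point distance.
#'
#' @param cap an [enamel_cap()] with both surface classes populated.
#' @param method `"nearest"` (cloud-to-mesh, default) or `"ray"`.
#' @return A list of class `thickness_field`: `values` (mm, one per OES
#'   vertex), `vertex_ids` (cap mesh vertex indices), `stats`
#'   (min/max/mean/median).
#' @export
thickness_field <- function(cap, method = c("nearest", "ray")) {
  method <- match.arg(method)
  if (length(cap$inner_faces) == 0)
    stop("empty EDJ face set", call. = FALSE)
  oes <- cap_submesh(cap, "oes")
  edj <- cap_submesh(cap, "edj")
  P <- oes$mesh$vertices
  if (method == "nearest") {
    vals <- cpp_point_mesh_distance(P, edj$mesh$vertices, edj$mesh$faces)
  } else {
    rc <- cpp_raycast_down(P, edj$mesh$vertices, edj$mesh$faces)
    vals <- abs(P[, 3] - rc$z)
    vals[!rc$hit] <- NA_real_
  }
  structure(list(values = as.numeric(vals), vertex_ids = oes$vertex_map,
                 method = method,
                 stats = list(min = min(vals, na.rm = TRUE),
                              max = max(vals, na.rm = TRUE),
                              mean = mean(vals, na.rm = TRUE),
                              median = median(vals, na.rm = TRUE))),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<thickness_field> %d vertices (%s): min %.4g, ",
                     "mean %.4g, median %.4g, max %.4g mm\n"),
              length(x$values), x$method, s$min, s$mean, s$median, s$max))
  invisible(x)
}

#' Map scalars to colormap RGB
#'
#' @param values numeric vector.
#' @param range clamp range `c(lo, hi)`; values outside are clamped to the
#'   endpoints. Default `[0, 99th percentile]` to avoid outlier washout.
#' @param colormap a palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @return n x 3 integer matrix of RGB in 0-255.
#' @export
thickness_colors <- function(values, range = NULL, colormap = "viridis") {
  if (is.null(range))
    range <- c(0, as.numeric(quantile(values, 0.99, na.rm = TRUE)))
  if (diff(range) <= 0) range <- range + c(0, 1e-9)
  v <- pmin(pmax(values, range[1]), range[2])
  pal <- hcl.colors(256, colormap)
  idx <- 1 + round(255 * (v - range[1]) / diff(range))
  idx[!is.finite(idx)] <- 1
  t(col2rgb(pal[idx]))
}

#' Export a colour-mapped thickness model
#'
#' Writes the OES submesh as PLY with a per-vertex `quality` scalar (the
#' thickness, mm) and RGB colours from the colormap over `[min, max]` or a
#' user range.
#'
#' @param cap an [enamel_cap()] (its OES submesh is exported), or a
#'   [surface_mesh()] whose vertices match the field.
#' @param field a [thickness_field()].
#' @param path output `.ply` path.
#' @param range optional colour range `c(lo, hi)` in mm.
#' @param colormap palette name (default `"viridis"`).
#' @param binary write binary little-endian PLY?
#' @return `path`, invisibly.
#' @export
export_colored <- function(cap, field, path, range = NULL,
                           colormap = "viridis", binary = FALSE) {
  mesh <- if (inherits(cap, "enamel_cap")) cap_submesh(cap, "oes")$mesh
          else cap
  if (length(field$values) != nrow(mesh$vertices))
    stop("field length does not match mesh vertex count", call. = FALSE)
  if (is.null(range)) range <- c(field$stats$min, field$stats$max)
  col <- thickness_colors(field$values, range = range, colormap = colormap)
  write_ply(mesh, path, binary = binary, quality = field$values, color = col)
  invisible(path)
}

#' Write a thickness field as CSV (`vertex_id, thickness_mm`)
#' @param field a [thickness_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thickness_csv <- function(field, path) {
  write.csv(data.frame(vertex_id = field$vertex_ids,
                       thickness_mm = field$values),
            path, row.names = FALSE)
  invisible(path)
}
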