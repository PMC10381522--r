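# Occlusal topography: discrete curvature, occlusal-contour delineation on
# the OES, projection onto the EDJ, the bucco-lingual section series, and the
# mesio-distal midline of per-section deepest points.
#
# All operations expect the cap in tooth-frame coordinates (+z occlusal,
# x mesio-distal); passing `frame` transforms the inputs first.

#' Discrete mean curvature per vertex
#'
#' Cotangent-Laplacian mean curvature with barycentric vertex areas, signed
#' positive on convex (cusp-like) regions. Units 1/mm. Boundary and isolated
#' vertices are flagged and set to 0.
#'
#' @param mesh a [surface_mesh()].
#' @return List of class `curvature_field` with `values` (per vertex, 1/mm)
#'   and `boundary` (logical flags).
#' @export
vertex_curvature <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(V)
  cot_at <- function(p, q, r) {
    # cotangent of the angle at p in triangle (p, q, r)
    u <- V[q, , drop = FALSE] - V[p, , drop = FALSE]
    v <- V[r, , drop = FALSE] - V[p, , drop = FALSE]
    dotuv <- rowSums(u * v)
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    dotuv / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  c1 <- cot_at(F[, 1], F[, 2], F[, 3])
  c2 <- cot_at(F[, 2], F[, 3], F[, 1])
  c3 <- cot_at(F[, 3], F[, 1], F[, 2])
  from <- c(F[, 2], F[, 3], F[, 3], F[, 1], F[, 1], F[, 2])
  to   <- c(F[, 3], F[, 2], F[, 1], F[, 3], F[, 2], F[, 1])
  wgt  <- c(c1, c1, c2, c2, c3, c3)
  dK <- (V[from, , drop = FALSE] - V[to, , drop = FALSE]) * wgt
  K <- rowsum(dK, from, reorder = FALSE)
  Kfull <- matrix(0, n, 3)
  Kfull[as.integer(rownames(K)), ] <- K
  area <- face_areas(V, F)
  av <- rowsum(rep(area / 3, 3), as.vector(F), reorder = FALSE)
  A <- numeric(n)
  A[as.integer(rownames(av))] <- av
  KN <- Kfull / pmax(2 * A, 1e-300)
  # vertex normals (area-weighted)
  fn <- face_normals(V, F) * area
  nv <- rowsum(rbind(fn, fn, fn), as.vector(F), reorder = FALSE)
  N <- matrix(0, n, 3)
  N[as.integer(rownames(nv)), ] <- nv
  nl <- sqrt(rowSums(N^2))
  nl[nl == 0] <- 1
  N <- N / nl
  # project the mean-curvature normal onto the outward vertex normal;
  # convex (cusp-like) regions positive
  H <- rowSums(KN * N) / 2
  be <- boundary_half_edges(F)
  boundary <- rep(FALSE, n)
  boundary[unique(c(be$from, be$to))] <- TRUE
  isolated <- A == 0
  H[boundary | isolated | !is.finite(H)] <- 0
  structure(list(values = H, boundary = boundary, normals = N),
            class = "curvature_field")
}

# Undirected vertex graph of a mesh with edge lengths; extra weights allowed.
mesh_vertex_graph <- function(mesh, vertex_cost = NULL) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  w <- if (is.null(vertex_cost)) len
       else len * (vertex_cost[e[, 1]] + vertex_cost[e[, 2]]) / 2
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  igraph::E(g)$weight <- w
  g
}

#' Delineate the occlusal contour on the outer enamel surface
#'
#' Finds the closed loop following the marginal-ridge crest around the
#' occlusal basin. Cusp apices are detected as separated curvature maxima
#' high on the crown; a crest candidate is picked per angular sector around
#' the apex midpoint (the outermost convex crest, scored by
#' `max(0, curvature) * radius^2`), and consecutive candidates are joined by
#' minimal-cost paths on the OES graph with edge cost
#' `length / (eps + max(0, curvature))`. If `overrides` are given they are
#' snapped to the nearest OES vertices and joined along geodesics instead.
#'
#' @param cap an [enamel_cap()] in tooth-frame coordinates.
#' @param frame optional [tooth_frame()] applied first.
#' @param curvature optional [vertex_curvature()] field of `cap$mesh`.
#' @param overrides optional k x 3 matrix of user contour points.
#' @param n_bins angular sectors used for crest candidates.
#' @param min_height_frac crest candidates are restricted to vertices above
#'   this fraction of the OES height range.
#' @param eps curvature floor in the edge cost, 1/mm.
#' @return A closed [contour3d()] whose points are OES vertices.
#' @export
occlusal_contour_oes <- function(cap, frame = NULL, curvature = NULL,
                                 overrides = NULL, n_bins = 96,
                                 min_height_frac = 0.45, eps = 1e-3) {
  if (!is.null(frame)) cap <- apply_frame(cap, frame)
  sub <- cap_submesh(cap, "oes")
  mesh <- sub$mesh
  if (is.null(curvature)) {
    H <- vertex_curvature(mesh)$values
  } else {
    H <- curvature$values[sub$vertex_map]
  }
  V <- mesh$vertices
  cost <- 1 / (eps + pmax(0, H))
  g <- mesh_vertex_graph(mesh, vertex_cost = cost)
  if (!is.null(overrides)) {
    overrides <- matrix(as.numeric(overrides), ncol = 3)
    ids <- apply(overrides, 1, function(p)
      which.min(colSums((t(V) - p)^2)))
    glen <- mesh_vertex_graph(mesh)
    path <- integer(0)
    k <- length(ids)
    for (i in seq_len(k)) {
      a <- ids[i]
      b <- ids[if (i == k) 1 else i + 1]
      sp <- igraph::shortest_paths(glen, a, b, output = "vpath")$vpath[[1]]
      path <- c(path, as.integer(sp)[-length(sp)])
    }
    return(orient_loop_ccw(contour3d(V[path, , drop = FALSE], closed = TRUE),
                           cap))
  }
  zr <- range(V[, 3])
  hi <- which(H > quantile(H, 0.85) & V[, 3] > zr[1] + 0.6 * diff(zr))
  if (length(hi) < 2)
    stop(paste0("occlusal contour failure: fewer than 2 curvature maxima ",
                "found; supply override points"), call. = FALSE)
  bb <- apply(V[, 1:2, drop = FALSE], 2, range)
  min_sep <- 0.2 * sqrt(sum((bb[2, ] - bb[1, ])^2))
  ord <- hi[order(V[hi, 3], decreasing = TRUE)]
  apexes <- ord[1]
  for (v in ord[-1]) {
    if (length(apexes) >= 4) break
    if (min(sqrt(colSums((t(V[apexes, 1:2, drop = FALSE]) -
                            V[v, 1:2])^2))) > min_sep)
      apexes <- c(apexes, v)
  }
  if (length(apexes) < 2)
    stop(paste0("occlusal contour failure: could not separate 2 cusp ",
                "apices; supply override points"), call. = FALSE)
  ctr <- colMeans(V[apexes, 1:2, drop = FALSE])
  cand <- which(V[, 3] > zr[1] + min_height_frac * diff(zr))
  dx <- V[cand, 1] - ctr[1]
  dy <- V[cand, 2] - ctr[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  r2 <- dx^2 + dy^2
  score <- pmax(0, H[cand]) * r2
  bin <- pmin(floor(ang / (2 * pi) * n_bins) + 1, n_bins)
  winners <- integer(0)
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    if (!length(idx)) next
    winners <- c(winners, cand[idx[which.max(score[idx])]])
  }
  if (length(winners) < 3)
    stop("occlusal contour failure: crest band empty; supply override points",
         call. = FALSE)
  path <- integer(0)
  k <- length(winners)
  for (i in seq_len(k)) {
    a <- winners[i]
    b <- winners[if (i == k) 1 else i + 1]
    if (a == b) next
    sp <- igraph::shortest_paths(g, a, b, output = "vpath")$vpath[[1]]
    path <- c(path, as.integer(sp)[-length(sp)])
  }
  path <- path[c(TRUE, diff(path) != 0)]
  out <- orient_loop_ccw(contour3d(V[path, , drop = FALSE], closed = TRUE),
                         cap)
  attr(out, "apexes") <- V[apexes, , drop = FALSE]
  out
}

#' Project a contour onto the EDJ surface
#'
#' Casts each contour point along -z onto the EDJ face set and takes the
#' nearest intersection below; points with no intersection are interpolated
#' from their neighbours and flagged.
#'
#' @param contour a [contour3d()].
#' @param cap an [enamel_cap()] in final orientation.
#' @param frame optional [tooth_frame()] applied to both first.
#' @param max_fail_frac error if more than this fraction of points fails to
#'   project (default 0.2).
#' @return A [contour3d()] with the same point count and closed flag;
#'   attribute `"failed"` lists interpolated point indices.
#' @export
project_contour_to_edj <- function(contour, cap, frame = NULL,
                                   max_fail_frac = 0.2) {
  if (!is.null(frame)) {
    cap <- apply_frame(cap, frame)
    contour <- apply_frame(contour, frame)
  }
  sub <- cap_submesh(cap, "edj")
  P <- contour$points
  rc <- cpp_raycast_down(P, sub$mesh$vertices, sub$mesh$faces)
  ok <- rc$hit
  if (mean(!ok) > max_fail_frac)
    stop(sprintf("projection failure: %d of %d contour points missed the EDJ",
                 sum(!ok), length(ok)), call. = FALSE)
  out <- cbind(P[, 1], P[, 2], rc$z)
  if (any(!ok)) {
    k <- nrow(P)
    good <- which(ok)
    for (i in which(!ok)) {
      if (contour$closed) {
        dfwd <- (good - i) %% k
        dbwd <- (i - good) %% k
        a <- good[which.min(dbwd)]
        b <- good[which.min(dfwd)]
      } else {
        a <- max(good[good < i], good[1])
        b <- min(good[good > i], good[length(good)])
      }
      wa <- abs(i - b); wb <- abs(i - a)
      if (wa + wb == 0) { wa <- 1; wb <- 1 }
      out[i, 3] <- (out[a, 3] * wa + out[b, 3] * wb) / (wa + wb)
    }
  }
  res <- contour3d(out, closed = contour$closed)
  attr(res, "failed") <- which(!ok)
  res
}

#' Bucco-lingual section series
#'
#' Cuts the cap with `n` planes normal to the mesio-distal (x) axis,
#' uniformly spaced (bin midpoints) over the occlusal contour's x-extent, or
#' over the whole crown when no contour is given. Each section's
#' mesh-plane intersection is assembled into closed polygons in the (y, z)
#' plane, with every polygon edge labelled OES or EDJ from its face class.
#'
#' @param cap an [enamel_cap()] in tooth-frame coordinates.
#' @param n number of sections (default 80).
#' @param frame optional [tooth_frame()] applied first.
#' @param contour optional occlusal [contour3d()] bounding the x-extent.
#' @param span `"occlusal"` (contour x-extent) or `"crown"` (full mesh).
#' @return List of `planar_section` objects (possibly with empty loop sets).
#' @export
section_series <- function(cap, n = 80, frame = NULL, contour = NULL,
                           span = c("occlusal", "crown")) {
  span <- match.arg(span)
  if (n < 3) stop("need at least 3 sections", call. = FALSE)
  if (!is.null(frame)) {
    cap <- apply_frame(cap, frame)
    if (!is.null(contour)) contour <- apply_frame(contour, frame)
  }
  mesh <- cap$mesh
  xr <- if (span == "occlusal" && !is.null(contour))
    range(contour$points[, 1]) else range(mesh$vertices[, 1])
  dx <- diff(xr) / n
  xs <- xr[1] + (seq_len(n) - 0.5) * dx
  cls <- cap_face_classes(cap)
  lapply(xs, function(x0)
    plane_section(mesh, x0, cls, spacing = dx))
}

# Intersect a mesh with the plane x = x0. Crossing points are computed once
# per mesh edge, so chains match exactly across adjacent faces.
plane_section <- function(mesh, x0, face_class, spacing = NA_real_) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- V[, 1] - x0
  # nudge off exact vertex hits for a clean transversal cut
  if (any(abs(d) < 1e-12)) {
    x0 <- x0 + 1e-9 * max(1, diff(range(V[, 1])))
    d <- V[, 1] - x0
  }
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ekey <- edge_key(e[, 1], e[, 2])
  uk <- !duplicated(ekey)
  eu <- e[uk, , drop = FALSE]
  eid <- match(ekey, ekey[uk])            # 3m -> edge id
  face_edges <- matrix(eid, ncol = 3)     # per face, its 3 edge ids
  crossing <- (d[eu[, 1]] > 0) != (d[eu[, 2]] > 0)
  if (!any(crossing))
    return(structure(list(x = x0, loops = list(), spacing = spacing),
                     class = "planar_section"))
  t <- d[eu[, 1]] / (d[eu[, 1]] - d[eu[, 2]])
  py <- V[eu[, 1], 2] + t * (V[eu[, 2], 2] - V[eu[, 1], 2])
  pz <- V[eu[, 1], 3] + t * (V[eu[, 2], 3] - V[eu[, 1], 3])
  fcross <- matrix(crossing[face_edges], ncol = 3)
  nface <- rowSums(fcross)
  fsel <- which(nface == 2)
  if (!length(fsel))
    return(structure(list(x = x0, loops = list(), spacing = spacing),
                     class = "planar_section"))
  seg_e <- t(vapply(fsel, function(f) face_edges[f, fcross[f, ]],
                    integer(2)))
  seg_class <- face_class[fsel]
  # chain segments: nodes are crossing-edge ids, links are faces
  loops <- chain_section_segments(seg_e, seg_class, py, pz)
  structure(list(x = x0, loops = loops, spacing = spacing),
            class = "planar_section")
}

chain_section_segments <- function(seg_e, seg_class, py, pz) {
  nseg <- nrow(seg_e)
  used <- rep(FALSE, nseg)
  # map edge id -> segments touching it (at most 2 on a manifold mesh)
  touch <- split(rep(seq_len(nseg), 2), c(seg_e[, 1], seg_e[, 2]))
  # open chains must start from a degree-1 crossing edge, otherwise a walk
  # started mid-chain splits it in two
  deg1 <- as.numeric(names(touch)[lengths(touch) == 1])
  starts <- unique(unlist(touch[as.character(deg1)], use.names = FALSE))
  loops <- list()
  for (s0 in c(starts, seq_len(nseg))) {
    if (used[s0]) next
    if (s0 %in% starts) {
      # begin at the chain's free end
      e1 <- seg_e[s0, ]
      free <- e1[e1 %in% deg1][1]
      if (!is.na(free) && seg_e[s0, 1] != free)
        seg_e[s0, ] <- rev(seg_e[s0, ])
    }
    used[s0] <- TRUE
    epath <- c(seg_e[s0, 1], seg_e[s0, 2])
    cpath <- seg_class[s0]
    closed <- FALSE
    repeat {
      tail_e <- epath[length(epath)]
      nxt <- touch[[as.character(tail_e)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      s <- nxt[1]
      used[s] <- TRUE
      other <- if (seg_e[s, 1] == tail_e) seg_e[s, 2] else seg_e[s, 1]
      cpath <- c(cpath, seg_class[s])
      if (other == epath[1]) { closed <- TRUE; break }
      epath <- c(epath, other)
    }
    pts <- cbind(y = py[epath], z = pz[epath])
    area <- NA_real_
    if (closed && nrow(pts) >= 3) {
      k <- nrow(pts)
      area <- sum(pts[, 1] * pts[c(2:k, 1), 2] -
                    pts[c(2:k, 1), 1] * pts[, 2]) / 2
      if (area < 0) {  # orient counter-clockwise in (y, z)
        pts <- pts[k:1, , drop = FALSE]
        cpath <- rev(cpath)
        area <- -area
      }
    }
    loops[[length(loops) + 1]] <-
      list(points = pts, seg_class = cpath, closed = closed, area = area)
  }
  loops
}

#' Midline of per-section deepest occlusal points
#'
#' For each section, the deepest OES point: the minimum-z vertex of the OES
#' chain restricted to the occlusal contour's y-range at that x. Ties within
#' 1e-6 mm resolve to the candidate closest to the previous section's
#' midline y (first section: closest to y = 0). With `pit_filter`,
#' candidates whose mean curvature falls below the `pit_percentile` quantile
#' of the section's candidates are suppressed before the search. Override
#' entries replace automatic points verbatim.
#'
#' @param sections list from [section_series()].
#' @param occlusal_oes closed occlusal [contour3d()] bounding the search.
#' @param overrides optional data.frame `(section_index, y, z)`.
#' @param pit_filter suppress low-curvature (pit) candidates?
#' @param pit_percentile quantile for the pit filter (default 0.1).
#' @param margin_frac fraction of the y-interval excluded at each end, so
#'   points on the marginal-ridge crest itself (the contour crossings) are
#'   not mistaken for basin points (default 0.05).
#' @param cap,curvature cap and [vertex_curvature()] field of `cap$mesh`,
#'   needed when `pit_filter = TRUE`.
#' @return An open, x-monotone [contour3d()]; attribute `"skipped"` lists
#'   sections with no usable candidates.
#' @export
midline_from_sections <- function(sections, occlusal_oes, overrides = NULL,
                                  pit_filter = FALSE, pit_percentile = 0.1,
                                  cap = NULL, curvature = NULL,
                                  margin_frac = 0.05) {
  CP <- occlusal_oes$points
  k <- nrow(CP)
  nxt <- c(2:k, 1)
  ov <- NULL
  if (!is.null(overrides)) {
    ov <- as.data.frame(overrides)
    names(ov)[1:3] <- c("section_index", "y", "z")
  }
  oesV <- NULL
  Hoes <- NULL
  if (pit_filter) {
    if (is.null(cap) || is.null(curvature))
      stop("pit_filter needs `cap` and `curvature`", call. = FALSE)
    sub <- cap_submesh(cap, "oes")
    oesV <- sub$mesh$vertices
    Hoes <- curvature$values[sub$vertex_map]
  }
  pts <- matrix(NA_real_, 0, 3)
  skipped <- integer(0)
  prev_y <- 0
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    if (!is.null(ov) && si %in% ov$section_index) {
      row <- ov[ov$section_index == si, ][1, ]
      pts <- rbind(pts, c(sec$x, row$y, row$z))
      prev_y <- row$y
      next
    }
    # occlusal-contour y-range at this x
    cross <- (CP[, 1] - sec$x) * (CP[nxt, 1] - sec$x) < 0
    if (!any(cross)) { skipped <- c(skipped, si); next }
    tt <- (sec$x - CP[cross, 1]) / (CP[nxt, , drop = FALSE][cross, 1] -
                                      CP[cross, 1])
    yc <- CP[cross, 2] + tt * (CP[nxt, , drop = FALSE][cross, 2] -
                                 CP[cross, 2])
    yr <- range(yc)
    yr <- yr + c(1, -1) * margin_frac * diff(yr)
    cand <- NULL
    for (lp in sec$loops) {
      if (nrow(lp$points) < 2) next
      np <- nrow(lp$points)
      on_oes <- rep(FALSE, np)
      idx <- which(lp$seg_class == 1L)
      if (length(idx)) {
        ends2 <- idx + 1
        if (isTRUE(lp$closed)) ends2[ends2 > np] <- 1L
        else ends2 <- ends2[ends2 <= np]
        on_oes[idx[idx <= np]] <- TRUE
        on_oes[ends2] <- TRUE
      }
      sel <- on_oes & lp$points[, 1] >= yr[1] & lp$points[, 1] <= yr[2]
      if (any(sel)) cand <- rbind(cand, lp$points[sel, , drop = FALSE])
    }
    if (is.null(cand) || nrow(cand) == 0) { skipped <- c(skipped, si); next }
    if (pit_filter && nrow(cand) >= 5) {
      Hc <- vapply(seq_len(nrow(cand)), function(i) {
        d2 <- (oesV[, 1] - sec$x)^2 + (oesV[, 2] - cand[i, 1])^2 +
          (oesV[, 3] - cand[i, 2])^2
        Hoes[which.min(d2)]
      }, 0)
      keep <- Hc >= quantile(Hc, pit_percentile)
      if (any(keep)) cand <- cand[keep, , drop = FALSE]
    }
    zmin <- min(cand[, 2])
    tied <- which(cand[, 2] < zmin + 1e-6)
    best <- tied[which.min(abs(cand[tied, 1] - prev_y))]
    pts <- rbind(pts, c(sec$x, cand[best, 1], cand[best, 2]))
    prev_y <- cand[best, 1]
  }
  if (nrow(pts) < 2)
    stop("midline failed: fewer than 2 usable sections", call. = FALSE)
  out <- contour3d(pts, closed = FALSE)
  attr(out, "skipped") <- skipped
  out
}
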