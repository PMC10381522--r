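# Synthetic enamel-cap fixtures with analytic ground truth. The generators
# emulate the study material -- two-cusp (bucco-lingual) molar crowns built as
# offset shells of known uniform thickness, optionally with wear facets and
# punched perforations -- so every pipeline stage can be tested without scan
# data.

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-way subdivision passes (20 * 4^k faces).
#' @param center sphere centre.
#' @return A [surface_mesh()] with outward winding.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nV <- nrow(V)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (V[i, ] + V[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1]] <<- p
      id <- nV + length(newV)
      assign(key, id, envir = mid_cache)
      id
    }
    newF <- matrix(0L, nrow = 4 * nrow(F), ncol = 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  V <- sweep(V * radius, 2, -as.numeric(center))
  surface_mesh(V, F, provenance = sprintf("icosphere R=%g", radius))
}

# UV-grid spherical cap: rings of constant polar angle theta in (0, theta_max],
# nphi sectors, fan at the pole (theta = 0 on +z). radius_fun(theta) gives the
# radial distance of each ring. Returns vertices, faces (outward winding) and
# the rim ring vertex ids.
uv_cap <- function(radius_fun, theta_max, n_theta, n_phi) {
  thetas <- seq(0, theta_max, length.out = n_theta + 1)[-1]
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  rpole <- radius_fun(0)
  V <- matrix(c(0, 0, rpole), ncol = 3)
  for (th in thetas) {
    r <- radius_fun(th)
    V <- rbind(V, cbind(r * sin(th) * cos(phis), r * sin(th) * sin(phis),
                        r * cos(th)))
  }
  ring <- function(i) 1 + (i - 1) * n_phi + seq_len(n_phi)  # i in 1..n_theta
  F <- NULL
  r1 <- ring(1)
  F <- cbind(1, r1, r1[c(2:n_phi, 1)])
  for (i in seq_len(n_theta - 1)) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- a[c(2:n_phi, 1)]; b2 <- b[c(2:n_phi, 1)]
    F <- rbind(F, cbind(a, b, b2), cbind(a, b2, a2))
  }
  list(vertices = V, faces = F, rim = ring(n_theta))
}

#' Concentric or cervically joined sphere-shell enamel cap
#'
#' With `cap_angle = pi` (default) the fixture is a closed concentric shell:
#' an outward-wound outer sphere of radius `R` and an inward-wound inner
#' sphere of radius `r`, with closed-form ground truth (areas `4*pi*R^2` and
#' `4*pi*r^2`, volume `4/3*pi*(R^3 - r^3)`, thickness `R - r`). With
#' `cap_angle < pi` the fixture is a spherical enamel cap whose inner (EDJ)
#' surface is the radial offset `R - t(theta)`, with the thickness tapering to
#' zero at the cervical rim so both surfaces share the rim ring -- the
#' geometry of a real enamel cap, with quadrature ground truth.
#'
#' @param R outer radius, mm.
#' @param r inner radius, mm (`R - r` is the nominal enamel thickness).
#' @param resolution target edge length, mm.
#' @param cap_angle polar angle of the cervical margin, radians.
#' @param taper_start fraction of `cap_angle` beyond which the thickness
#'   tapers to zero (cap variant only).
#' @return List with `cap` (an [enamel_cap()]) and `truth` (ground-truth
#'   labels and closed-form or quadrature areas, volume, thickness).
#' @export
make_sphere_shell <- function(R, r, resolution = 0.05, cap_angle = pi,
                              taper_start = 0.8) {
  if (!(R > r && r > 0)) stop("need R > r > 0", call. = FALSE)
  t <- R - r
  if (cap_angle >= pi) {
    lvl <- max(1, ceiling(log2(1.05146 * R / resolution)))
    lvl <- min(lvl, 6)
    outer <- icosphere(R, lvl)
    inner <- icosphere(r, lvl)
    inner$faces <- inner$faces[, c(1, 3, 2)]  # inward orientation
    nVo <- nrow(outer$vertices)
    nFo <- nrow(outer$faces)
    V <- rbind(outer$vertices, inner$vertices)
    F <- rbind(outer$faces, inner$faces + nVo)
    mesh <- surface_mesh(V, F, provenance = sprintf(
      "sphere shell R=%g r=%g", R, r))
    truth <- list(
      outer_faces = seq_len(nFo),
      inner_faces = nFo + seq_len(nrow(inner$faces)),
      area_oes = 4 * pi * R^2, area_edj = 4 * pi * r^2,
      volume = 4 / 3 * pi * (R^3 - r^3), thickness = t,
      rim_length = NA_real_)
  } else {
    n_theta <- max(8, ceiling(R * cap_angle / resolution))
    n_phi <- max(12, ceiling(2 * pi * R * sin(cap_angle) / resolution))
    taper <- function(th) {
      s <- (th / cap_angle - taper_start) / (1 - taper_start)
      s <- pmin(1, pmax(0, s))
      1 - s^2 * (3 - 2 * s)  # smoothstep 1 -> 0
    }
    r_in <- function(th) R - t * taper(th)
    oes <- uv_cap(function(th) rep(R, length(th)), cap_angle, n_theta, n_phi)
    edj <- uv_cap(r_in, cap_angle, n_theta, n_phi)
    # drop the EDJ rim ring (radius R there) and reuse the OES rim vertices
    nVo <- nrow(oes$vertices)
    keep <- setdiff(seq_len(nrow(edj$vertices)), edj$rim)
    remap <- integer(nrow(edj$vertices))
    remap[keep] <- nVo + seq_along(keep)
    remap[edj$rim] <- oes$rim
    Fe <- matrix(remap[edj$faces], ncol = 3)[, c(1, 3, 2), drop = FALSE]
    V <- rbind(oes$vertices, edj$vertices[keep, , drop = FALSE])
    F <- rbind(oes$faces, Fe)
    mesh <- surface_mesh(V, F, provenance = sprintf(
      "sphere cap shell R=%g r=%g angle=%g", R, r, cap_angle))
    # quadrature truth on the analytic profiles
    th <- seq(0, cap_angle, length.out = 20001)
    ri <- r_in(th)
    dri <- c(diff(ri) / diff(th), 0)
    dri[length(dri)] <- dri[length(dri) - 1]
    area_oes <- 2 * pi * R^2 * (1 - cos(cap_angle))
    integ <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(th))
    # surface of revolution: 2*pi * integral of ring radius * arc element
    area_edj <- 2 * pi * integ(ri * sin(th) * sqrt(ri^2 + dri^2))
    volume <- 2 * pi / 3 * integ((R^3 - ri^3) * sin(th))
    truth <- list(
      outer_faces = seq_len(nrow(oes$faces)),
      inner_faces = nrow(oes$faces) + seq_len(nrow(Fe)),
      area_oes = area_oes, area_edj = area_edj, volume = volume,
      thickness = t, rim_length = 2 * pi * R * sin(cap_angle))
  }
  cap <- enamel_cap(mesh, truth$outer_faces, truth$inner_faces)
  list(cap = cap, truth = truth)
}

# --- two-cusp crown ----------------------------------------------------------

#' Specification of a synthetic two-cusp crown
#'
#' Defaults emulate a primate lower-molar crown at realistic scale: an
#' elliptical footprint of 11 x 9 mm, a flat-topped dome with steep cervical
#' walls, two Gaussian cusps placed buccally and lingually, and a mesio-distal
#' central groove along `y = 0` (the analytic valley locus). The enamel-dentine
#' junction is the inward offset of the outer surface along the analytic
#' surface normal by `thickness`, tapering to zero at the cervical rim so the
#' cap closes there.
#'
#' @param semi_axes footprint semi-axes (mesio-distal, bucco-lingual), mm.
#' @param wall_height crown height at the pole of the dome term, mm.
#' @param dome_exponent superellipse-like exponent of the dome profile;
#'   larger values flatten the occlusal table and steepen the walls.
#' @param cusp_centers 2 x 2 matrix of cusp centre (x, y) positions, mm.
#' @param cusp_height,cusp_width Gaussian cusp height and s.d., mm.
#' @param valley_depth,valley_width central-groove depth and s.d., mm.
#' @param thickness uniform enamel thickness, mm.
#' @param taper_start normalised radius beyond which enamel tapers to zero.
#' @param resolution target mesh edge length, mm.
#' @param wear_depth planar wear-facet depth from the highest point, mm
#'   (0 = unworn).
#' @param n_pits,pit_radius number and radius of punched perforations.
#' @param seed integer seed controlling pit placement.
#' @return A list of class `tooth_spec`.
#' @export
tooth_spec <- function(semi_axes = c(5.5, 4.5), wall_height = 4,
                       dome_exponent = 16,
                       cusp_centers = rbind(c(0, 2.2), c(0, -2.2)),
                       cusp_height = 1.2, cusp_width = 1.5,
                       valley_depth = 0.8, valley_width = 0.9,
                       thickness = 0.5, taper_start = 0.85,
                       resolution = 0.25, wear_depth = 0, n_pits = 0L,
                       pit_radius = 0.2, seed = 1234L) {
  stopifnot(thickness > 0 || identical(thickness, 0),
            resolution > 0, all(semi_axes > 0))
  structure(as.list(environment()), class = "tooth_spec")
}

# Height field and analytic gradient of the crown outer surface.
crown_field <- function(spec) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  H <- spec$wall_height; m <- spec$dome_exponent
  cc <- spec$cusp_centers; h <- spec$cusp_height; s2 <- spec$cusp_width^2
  dv <- spec$valley_depth; sv2 <- spec$valley_width^2
  f <- function(x, y) {
    rho <- sqrt((x / a)^2 + (y / b)^2)
    dome <- H * (1 - rho^m)
    g <- 1 - rho^m
    z <- dome - dv * exp(-y^2 / (2 * sv2)) * g
    for (i in seq_len(nrow(cc)))
      z <- z + h * exp(-((x - cc[i, 1])^2 + (y - cc[i, 2])^2) / (2 * s2))
    z
  }
  grad <- function(x, y) {
    rho <- pmax(sqrt((x / a)^2 + (y / b)^2), 1e-12)
    rm1 <- rho^(m - 1)
    drdx <- x / (a^2 * rho)
    drdy <- y / (b^2 * rho)
    E <- exp(-y^2 / (2 * sv2))
    fx <- -H * m * rm1 * drdx + dv * E * m * rm1 * drdx
    fy <- -H * m * rm1 * drdy + dv * E * m * rm1 * drdy +
      dv * (1 - rho^m) * (y / sv2) * E
    for (i in seq_len(nrow(cc))) {
      Ei <- exp(-((x - cc[i, 1])^2 + (y - cc[i, 2])^2) / (2 * s2))
      fx <- fx - h * (x - cc[i, 1]) / s2 * Ei
      fy <- fy - h * (y - cc[i, 2]) / s2 * Ei
    }
    cbind(fx, fy)
  }
  list(f = f, grad = grad)
}

# OES and EDJ points for polar parameters (rho, phi); EDJ is the inward
# analytic-normal offset with cervical taper.
crown_surfaces <- function(spec) {
  fld <- crown_field(spec)
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  t0 <- spec$thickness; ts <- spec$taper_start
  taper <- function(rho) {
    s <- pmin(1, pmax(0, (rho - ts) / (1 - ts)))
    1 - s^2 * (3 - 2 * s)
  }
  oes <- function(rho, phi) {
    x <- a * rho * cos(phi)
    y <- b * rho * sin(phi)
    cbind(x, y, fld$f(x, y))
  }
  edj <- function(rho, phi) {
    p <- oes(rho, phi)
    g <- fld$grad(p[, 1], p[, 2])
    w <- sqrt(1 + g[, 1]^2 + g[, 2]^2)
    n <- cbind(-g[, 1], -g[, 2], 1) / w
    p - t0 * taper(rho) * n
  }
  list(oes = oes, edj = edj, taper = taper, field = fld)
}

# Non-uniform radial rings so that steps along the steep wall stay close to
# the target resolution.
crown_rings <- function(spec) {
  fld <- crown_field(spec)
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  rr <- seq(0, 1, length.out = 4001)
  zz <- fld$f(a * rr, rep(0, length(rr)))
  ds <- sqrt((diff(rr) * (a + b) / 2)^2 + diff(zz)^2)
  s <- c(0, cumsum(ds))
  n_r <- max(8, ceiling(s[length(s)] / spec$resolution))
  starget <- seq(0, s[length(s)], length.out = n_r + 1)
  rho <- approx(s, rr, xout = starget)$y
  rho[1] <- 0
  rho[length(rho)] <- 1
  unique(rho)
}

#' Generate a two-cusp enamel-cap crown with ground truth
#'
#' Builds the outer enamel surface as a parametric height field over an
#' elliptical footprint (flat-topped dome, two Gaussian cusps, central
#' groove), offsets it inward along the analytic normal to create the EDJ,
#' and closes the cap at the cervical rim where the enamel tapers to zero.
#' Deterministic for a fixed spec.
#'
#' @param spec a [tooth_spec()].
#' @return List with `cap` (an [enamel_cap()]) and `truth`: ground-truth face
#'   labels, apex positions, valley locus, quadrature areas and enamel volume,
#'   and the spec.
#' @export
make_two_cusp_crown <- function(spec = tooth_spec()) {
  srf <- crown_surfaces(spec)
  # self-intersection screen: offset must stay below the minimal radius of
  # curvature of the cusp/groove terms
  min_rcurv <- min(spec$cusp_width^2 / spec$cusp_height,
                   spec$valley_width^2 / max(spec$valley_depth, 1e-9))
  if (spec$thickness >= min_rcurv)
    stop(sprintf(paste0("thickness %.3g mm exceeds local feature size ",
                        "%.3g mm; inward offset would self-intersect"),
                 spec$thickness, min_rcurv), call. = FALSE)
  rho <- crown_rings(spec)
  n_r <- length(rho) - 1
  n_phi <- max(12, ceiling(2 * pi * mean(spec$semi_axes) / spec$resolution))
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid_pts <- function(fun) {
    P <- fun(0, 0)
    for (i in seq_len(n_r))
      P <- rbind(P, fun(rep(rho[i + 1], n_phi), phis))
    P
  }
  Vo <- grid_pts(srf$oes)
  ring <- function(i) 1 + (i - 1) * n_phi + seq_len(n_phi)
  Fo <- cbind(1, ring(1), ring(1)[c(2:n_phi, 1)])
  for (i in seq_len(n_r - 1)) {
    aa <- ring(i); bb <- ring(i + 1)
    a2 <- aa[c(2:n_phi, 1)]; b2 <- bb[c(2:n_phi, 1)]
    Fo <- rbind(Fo, cbind(aa, bb, b2), cbind(aa, b2, a2))
  }
  # OES height field winding gives +z (outward) orientation
  Ve <- grid_pts(srf$edj)
  rim <- ring(n_r)
  nVo <- nrow(Vo)
  keep <- setdiff(seq_len(nrow(Ve)), rim)
  remap <- integer(nrow(Ve))
  remap[keep] <- nVo + seq_along(keep)
  remap[rim] <- rim  # shared cervical ring
  Fe <- matrix(remap[Fo], ncol = 3)[, c(1, 3, 2), drop = FALSE]
  V <- rbind(Vo, Ve[keep, , drop = FALSE])
  F <- rbind(Fo, Fe)
  mesh <- surface_mesh(V, F, provenance = "synthetic two-cusp crown")
  outer_faces <- seq_len(nrow(Fo))
  inner_faces <- nrow(Fo) + seq_len(nrow(Fe))
  cap <- enamel_cap(mesh, outer_faces, inner_faces)
  truth <- list(outer_faces = outer_faces, inner_faces = inner_faces,
                apexes = crown_apexes(spec), valley_y = 0,
                spec = spec)
  truth <- c(truth, crown_truth_quadrature(spec))
  cap0 <- cap
  if (spec$wear_depth > 0 || spec$n_pits > 0)
    cap <- apply_wear_and_pits(cap, wear_depth = spec$wear_depth,
                               n_pits = spec$n_pits,
                               pit_radius = spec$pit_radius,
                               seed = spec$seed)$cap
  list(cap = cap, truth = truth, pristine = cap0)
}

# Numeric apex positions: refine from the cusp centres on a local fine grid.
crown_apexes <- function(spec) {
  fld <- crown_field(spec)
  out <- matrix(NA_real_, nrow = nrow(spec$cusp_centers), ncol = 3)
  for (i in seq_len(nrow(spec$cusp_centers))) {
    cx <- spec$cusp_centers[i, 1]; cy <- spec$cusp_centers[i, 2]
    gx <- seq(cx - 1, cx + 1, length.out = 201)
    gy <- seq(cy - 1, cy + 1, length.out = 201)
    G <- expand.grid(x = gx, y = gy)
    z <- fld$f(G$x, G$y)
    k <- which.max(z)
    out[i, ] <- c(G$x[k], G$y[k], z[k])
  }
  out
}

# Quadrature ground truth for areas and enamel volume on the analytic
# surfaces, independent of the generated mesh resolution.
crown_truth_quadrature <- function(spec, n_r = 320, n_phi = 720) {
  srf <- crown_surfaces(spec)
  rho <- seq(0, 1, length.out = n_r + 1)
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  build <- function(fun) {
    P <- fun(0, 0)
    for (i in seq_len(n_r))
      P <- rbind(P, fun(rep(rho[i + 1], n_phi), phis))
    ring <- function(i) 1 + (i - 1) * n_phi + seq_len(n_phi)
    F <- cbind(1, ring(1), ring(1)[c(2:n_phi, 1)])
    for (i in seq_len(n_r - 1)) {
      aa <- ring(i); bb <- ring(i + 1)
      a2 <- aa[c(2:n_phi, 1)]; b2 <- bb[c(2:n_phi, 1)]
      F <- rbind(F, cbind(aa, bb, b2), cbind(aa, b2, a2))
    }
    list(V = P, F = F)
  }
  oes <- build(srf$oes)
  edj <- build(srf$edj)
  m_o <- structure(list(vertices = oes$V, faces = oes$F), class = "surface_mesh")
  m_e <- structure(list(vertices = edj$V,
                        faces = edj$F[, c(1, 3, 2), drop = FALSE]),
                   class = "surface_mesh")
  # the two open parametric surfaces share the rim curve, so their divergence
  # sums combine to the enclosed enamel volume
  list(area_oes = mesh_area(m_o), area_edj = mesh_area(m_e),
       volume = mesh_volume(m_o) + mesh_volume(m_e))
}

#' Apply wear facets and perforations to a synthetic cap
#'
#' Wear truncates the crown above `zmax - wear_depth` (a horizontal facet,
#' possibly exposing the EDJ where the cut passes below it); perforations
#' punch small holes into the OES to exercise hole filling and the
#' pit-robust midline.
#'
#' @param cap an [enamel_cap()].
#' @param wear_depth facet depth from the highest OES point, mm.
#' @param n_pits number of perforations.
#' @param pit_radius perforation radius, mm.
#' @param seed integer seed for pit placement.
#' @return List with `cap` (modified), `exposed_vertices` (OES vertex ids
#'   where wear reached the EDJ), `pit_centers`.
#' @export
apply_wear_and_pits <- function(cap, wear_depth = 0, n_pits = 0L,
                                pit_radius = 0.2, seed = 1234L) {
  mesh <- cap$mesh
  V <- mesh$vertices
  F <- mesh$faces
  outer_faces <- cap$outer_faces
  inner_faces <- cap$inner_faces
  oes_v <- sort(unique(as.vector(F[outer_faces, ])))
  edj_v <- sort(unique(as.vector(F[inner_faces, ])))
  exposed <- integer(0)
  if (wear_depth > 0) {
    zmax <- max(V[oes_v, 3])
    zcut <- zmax - wear_depth
    if (zcut <= min(V[oes_v, 3]))
      stop("wear facet would remove the whole crown", call. = FALSE)
    hit <- oes_v[V[oes_v, 3] > zcut]
    V[hit, 3] <- zcut
    # wear through the enamel: clamp to the EDJ where the cut dips below it
    edj_only <- setdiff(edj_v, oes_v)
    if (length(hit) && length(edj_only)) {
      Q <- V[hit, , drop = FALSE]
      Q[, 3] <- max(V[, 3]) + 1
      rc <- cpp_raycast_down(Q, V, matrix(F[inner_faces, ], ncol = 3))
      zed <- rc$z
      expose <- which(rc$hit & V[hit, 3] < zed)
      if (length(expose)) {
        V[hit[expose], 3] <- zed[expose]
        exposed <- hit[expose]
      }
    }
    mesh$vertices <- V
  }
  pit_centers <- NULL
  if (n_pits > 0) {
    set.seed(as.integer(seed))
    cen <- face_centroids(V, F)
    # candidate pit sites: OES faces on the occlusal table, clear of the rim
    bb <- apply(V, 2, range)
    zlim <- bb[1, 3] + 0.6 * (bb[2, 3] - bb[1, 3])
    cand <- outer_faces[cen[outer_faces, 3] > zlim]
    chosen <- integer(0)
    pts <- matrix(NA_real_, 0, 3)
    guard <- 0
    while (length(chosen) < n_pits && guard < 1000) {
      guard <- guard + 1
      f <- cand[sample.int(length(cand), 1)]
      p <- cen[f, ]
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, p)^2))) > 4 * pit_radius) {
        chosen <- c(chosen, f)
        pts <- rbind(pts, p)
      }
    }
    if (length(chosen) < n_pits)
      warning("placed only ", length(chosen), " of ", n_pits, " pits")
    drop <- integer(0)
    for (i in seq_along(chosen)) {
      d <- sqrt(rowSums(sweep(cen, 2, pts[i, ])^2))
      drop <- union(drop, intersect(which(d < pit_radius), outer_faces))
    }
    if (length(drop)) {
      keep <- setdiff(seq_len(nrow(F)), drop)
      old2new <- integer(nrow(F))
      old2new[keep] <- seq_along(keep)
      F <- F[keep, , drop = FALSE]
      outer_faces <- old2new[setdiff(outer_faces, drop)]
      inner_faces <- old2new[setdiff(inner_faces, drop)]
      mesh$faces <- F
      mesh$vertices <- V
    }
    pit_centers <- pts
  }
  mesh$vertices <- V
  mesh$faces <- F
  out <- enamel_cap(mesh, outer_faces, inner_faces,
                    mass_center = cap$mass_center)
  list(cap = out, exposed_vertices = exposed, pit_centers = pit_centers)
}
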