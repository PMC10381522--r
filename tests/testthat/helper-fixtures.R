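# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# unit cube with outward winding
fx_cube <- function(origin = c(0, 0, 0)) {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  V <- sweep(V, 2, -as.numeric(origin))
  F <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(V, F, provenance = "unit cube")
}

# rectangular grid plate at height z0 (lx x ly, n cells per side);
# winding gives +z normals
fx_plate <- function(lx = 2, ly = 3, z0 = 0, n = 12) {
  xs <- seq(0, lx, length.out = n + 1)
  ys <- seq(0, ly, length.out = n + 1)
  G <- as.matrix(expand.grid(x = xs, y = ys))
  V <- cbind(G, z0)
  id <- function(i, j) (j - 1) * (n + 1) + i
  F <- NULL
  for (j in seq_len(n)) for (i in seq_len(n))
    F <- rbind(F, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  list(V = V, F = F)
}

# two parallel plates as an enamel cap: OES at z = gap, EDJ at z = 0
fx_plate_cap <- function(lx = 2, ly = 3, gap = 0.5, n = 12) {
  top <- fx_plate(lx, ly, gap, n)
  bot <- fx_plate(lx, ly, 0, n)
  nv <- nrow(top$V)
  mesh <- surface_mesh(rbind(top$V, bot$V),
                       rbind(top$F, bot$F[, c(1, 3, 2)] + nv),
                       provenance = "parallel plates", check = TRUE)
  enamel_cap(mesh, seq_len(nrow(top$F)),
             nrow(top$F) + seq_len(nrow(bot$F)))
}

# open cylinder surface of radius R about the x axis, length L
fx_cylinder <- function(R = 2, L = 10, m = 64, nx = 40) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  xs <- seq(0, L, length.out = nx + 1)
  V <- NULL
  for (x in xs) V <- rbind(V, cbind(x, R * cos(th), R * sin(th)))
  id <- function(i, j) (i - 1) * m + ((j - 1) %% m) + 1
  F <- NULL
  for (i in seq_len(nx)) for (j in seq_len(m))
    F <- rbind(F, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  mesh <- surface_mesh(V, F, provenance = "cylinder")
  # make the winding outward (normals along the radial direction)
  n <- enamelmap:::face_normals(mesh$vertices, mesh$faces)
  cen <- enamelmap:::face_centroids(mesh$vertices, mesh$faces)
  if (mean(rowSums(n * cbind(0, cen[, 2], cen[, 3]))) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# extruded half-annulus enamel band: OES arc radius R, EDJ arc radius r,
# length L along x; watertight; connectors and endcaps carry the EDJ label
fx_prism_cap <- function(R = 1.1, r = 1.0, L = 8, m = 64, nx = 40) {
  th <- seq(0, pi, length.out = m + 1)
  xs <- seq(0, L, length.out = nx + 1)
  nring <- 2 * (m + 1)
  V <- NULL
  for (x in xs)
    V <- rbind(V, cbind(x, R * cos(th), R * sin(th)),
               cbind(x, r * cos(th), r * sin(th)))
  O <- function(i, j) (i - 1) * nring + j
  I <- function(i, j) (i - 1) * nring + (m + 1) + j
  Fo <- NULL; Fi <- NULL; Fw <- NULL
  for (i in seq_len(nx)) {
    for (j in seq_len(m)) {
      Fo <- rbind(Fo, c(O(i, j), O(i + 1, j), O(i + 1, j + 1)),
                  c(O(i, j), O(i + 1, j + 1), O(i, j + 1)))
      Fi <- rbind(Fi, c(I(i, j), I(i, j + 1), I(i + 1, j + 1)),
                  c(I(i, j), I(i + 1, j + 1), I(i + 1, j)))
    }
    Fw <- rbind(Fw,
      c(O(i, 1), I(i, 1), I(i + 1, 1)), c(O(i, 1), I(i + 1, 1), O(i + 1, 1)),
      c(O(i, m + 1), O(i + 1, m + 1), I(i + 1, m + 1)),
      c(O(i, m + 1), I(i + 1, m + 1), I(i, m + 1)))
  }
  for (j in seq_len(m))
    Fw <- rbind(Fw,
      c(O(1, j), O(1, j + 1), I(1, j + 1)), c(O(1, j), I(1, j + 1), I(1, j)),
      c(O(nx + 1, j), I(nx + 1, j), I(nx + 1, j + 1)),
      c(O(nx + 1, j), I(nx + 1, j + 1), O(nx + 1, j + 1)))
  mesh <- enamelmap:::orient_mesh(
    surface_mesh(V, rbind(Fo, Fi, Fw), provenance = "prism band"))
  enamel_cap(mesh, seq_len(nrow(Fo)),
             nrow(Fo) + seq_len(nrow(Fi) + nrow(Fw)))
}

# synthetic rectangular-band planar section: OES top chain at z = th,
# EDJ bottom chain at z = 0, width w; closing sides labelled 0 (cervical)
fx_rect_section <- function(w = 10, th = 0.5, n = 20) {
  ys <- seq(0, w, length.out = n + 1)
  top <- cbind(y = ys, z = th)
  bot <- cbind(y = rev(ys), z = 0)
  pts <- rbind(top, bot)
  seg_class <- c(rep(1L, n),   # along top
                 0L,           # right side (y = w)
                 rep(2L, n),   # along bottom
                 0L)           # left side closes the loop
  lp <- list(points = pts, seg_class = seg_class, closed = TRUE,
             area = w * th)
  structure(list(x = 0, loops = list(lp), spacing = NA_real_),
            class = "planar_section")
}

# synthetic half-annulus section (outer R, inner r), radial closers class 0
fx_annulus_section <- function(R = 1.1, r = 1.0, m = 400) {
  th <- seq(0, pi, length.out = m + 1)
  outer <- cbind(y = R * cos(th), z = R * sin(th))
  inner <- cbind(y = r * cos(rev(th)), z = r * sin(rev(th)))
  pts <- rbind(outer, inner)
  seg_class <- c(rep(1L, m), 0L, rep(2L, m), 0L)
  lp <- list(points = pts, seg_class = seg_class, closed = TRUE,
             area = pi * (R^2 - r^2) / 2)
  structure(list(x = 0, loops = list(lp), spacing = NA_real_),
            class = "planar_section")
}

# rotation matrices
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))
rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                           c(0, sin(a), cos(a)))

rigid_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(R) +
    matrix(t, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# cached heavyweight fixtures ------------------------------------------------

fx_shell <- function() fixture("shell", function()
  make_sphere_shell(1.1, 1.0, resolution = 0.05))

fx_hemi_shell <- function() fixture("hemi_shell", function()
  make_sphere_shell(2, 1.8, resolution = 0.08, cap_angle = pi / 2))

fx_crown <- function() fixture("crown", function()
  make_two_cusp_crown(tooth_spec(resolution = 0.25)))

fx_crown_pitted <- function() fixture("crown_pitted", function()
  make_two_cusp_crown(tooth_spec(resolution = 0.25, n_pits = 5,
                                 pit_radius = 0.2, seed = 11)))

fx_prism <- function() fixture("prism", fx_prism_cap)

# labels-vs-truth accuracy of a classification against generator truth
label_accuracy <- function(cap, truth) {
  nf <- nrow(cap$mesh$faces)
  got <- seq_len(nf) %in% cap$outer_faces
  want <- seq_len(nf) %in% truth$outer_faces
  mean(got == want)
}
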