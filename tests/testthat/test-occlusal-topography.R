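test_that("discrete mean curvature matches sphere, plane and cylinder", {
  s <- icosphere(5, 4)
  H <- vertex_curvature(s)$values
  # the 12 pentavalent seed vertices play the role of the poles: the
  # barycentric vertex area is least accurate there
  deg <- tabulate(as.vector(s$faces))
  regular <- deg == 6
  expect_lt(max(abs(H[regular] - 0.2)) / 0.2, 0.05)
  expect_lt(abs(median(H) - 0.2) / 0.2, 0.01)
  # flat plate interior ~ 0
  pl <- fx_plate(2, 2, 0, 16)
  pm <- surface_mesh(pl$V, pl$F)
  cf <- vertex_curvature(pm)
  interior <- !cf$boundary
  expect_true(any(interior))
  expect_lt(max(abs(cf$values[interior])), 1e-3)
  # cylinder radius 2 interior ~ 1/(2R) = 0.25
  cyl <- fx_cylinder(R = 2, L = 10, m = 64, nx = 40)
  cc <- vertex_curvature(cyl)
  mid <- !cc$boundary & abs(cyl$vertices[, 1] - 5) < 2
  expect_lt(max(abs(cc$values[mid] - 0.25)) / 0.25, 0.05)
})

test_that("occlusal contour is a closed OES loop enclosing both cusp apices", {
  fx <- fx_crown()
  cap <- fx$cap
  occ <- occlusal_contour_oes(cap)
  expect_true(occ$closed)
  # all points are OES vertices
  oes <- cap_submesh(cap, "oes")$mesh$vertices
  for (i in seq_len(nrow(occ$points))) {
    d <- min(colSums((t(oes) - occ$points[i, ])^2))
    expect_lt(d, 1e-18)
  }
  # encloses both apex (x, y) projections
  ap <- fx$truth$apexes
  inside <- enamelmap:::point_in_polygon(ap[, 1], ap[, 2],
                                         occ$points[, 1], occ$points[, 2])
  expect_true(all(inside))
})

test_that("override points pass through (snapped and joined on the OES)", {
  fx <- fx_crown()
  cap <- fx$cap
  oes <- cap_submesh(cap, "oes")$mesh
  # an analytic ring at 80% of the footprint, snapped to the OES
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  srf <- enamelmap:::crown_surfaces(fx$truth$spec)
  ring <- srf$oes(rep(0.8, length(th)), th)
  occ <- occlusal_contour_oes(cap, overrides = ring)
  expect_true(occ$closed)
  # returned contour stays within one mesh-edge length of the override ring
  med_edge <- fx$truth$spec$resolution
  for (i in seq_len(nrow(occ$points))) {
    d <- sqrt(min(colSums((t(ring) - occ$points[i, ])^2)))
    expect_lt(d, 2 * med_edge)
  }
})

test_that("contour projection onto the EDJ preserves x,y and drops by the gap", {
  cap <- fx_plate_cap(gap = 0.5)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(1 + 0.5 * cos(th), 1.5 + 0.8 * sin(th), 0.5)
  ct <- contour3d(ring, closed = TRUE)
  pr <- project_contour_to_edj(ct, cap)
  expect_true(pr$closed)
  expect_equal(nrow(pr$points), nrow(ct$points))
  expect_equal(pr$points[, 1:2], ct$points[, 1:2])
  expect_equal(pr$points[, 3], rep(0, nrow(ring)), tolerance = 1e-9)
  # a point above an EDJ vertex lands on that vertex
  vq <- contour3d(rbind(c(0.5, 0.5, 0.5), c(1, 0.5, 0.5), c(0.75, 1, 0.5)),
                  closed = TRUE)
  prv <- project_contour_to_edj(vq, cap)
  expect_equal(prv$points[, 3], c(0, 0, 0), tolerance = 1e-12)
  # points far off the EDJ fail and trigger the projection error
  far <- contour3d(cbind(seq(10, 12, length.out = 12), 0, 1), closed = FALSE)
  expect_error(project_contour_to_edj(far, cap), "projection failure")
})

test_that("sections of the unit cube are unit squares; empty planes allowed", {
  cube <- fx_cube()
  capc <- enamel_cap(cube, 1:6, 7:12)
  secs <- section_series(capc, n = 3, span = "crown")
  expect_length(secs, 3)
  for (s in secs) {
    expect_length(s$loops, 1)
    expect_true(s$loops[[1]]$closed)
    expect_equal(s$loops[[1]]$area, 1, tolerance = 1e-9)
  }
  off <- enamelmap:::plane_section(cube, 5, cap_face_classes(capc))
  expect_length(off$loops, 0)
})

test_that("section areas integrate to the enclosed shell volume", {
  fx <- fx_crown()
  secs <- section_series(fx$cap, n = 80, span = "crown")
  vol <- sum(vapply(secs, function(s)
    sum(vapply(s$loops, function(lp) lp$area, 0)) * s$spacing, 0))
  expect_equal(vol, mesh_volume(fx$cap$mesh), tolerance = 0.02)
})

test_that("sectioning is equivariant under rigid motion of the cap", {
  fx <- fx_crown()
  secs <- section_series(fx$cap, n = 10, span = "crown")
  cap2 <- fx$cap
  cap2$mesh <- rigid_mesh(cap2$mesh, diag(3), c(7, 0, 0))
  secs2 <- section_series(cap2, n = 10, span = "crown")
  a1 <- vapply(secs, function(s) sum(vapply(s$loops, `[[`, 0, "area")), 0)
  a2 <- vapply(secs2, function(s) sum(vapply(s$loops, `[[`, 0, "area")), 0)
  expect_equal(a2, a1, tolerance = 1e-9)
})

test_that("the midline tracks the analytic valley and is x-monotone on the OES", {
  fx <- fx_crown()
  cap <- fx$cap
  occ <- occlusal_contour_oes(cap)
  secs <- section_series(cap, n = 80, contour = occ)
  mid <- midline_from_sections(secs, occ)
  expect_false(mid$closed)
  expect_equal(nrow(mid$points), 80)
  # valley locus at y = 0, tolerance 2 mesh-edge lengths
  expect_lt(max(abs(mid$points[, 2] - fx$truth$valley_y)),
            2 * fx$truth$spec$resolution)
  expect_true(all(diff(mid$points[, 1]) > 0))
})

test_that("midline overrides replace the automatic points verbatim", {
  fx <- fx_crown()
  occ <- occlusal_contour_oes(fx$cap)
  secs <- section_series(fx$cap, n = 20, contour = occ)
  ov <- data.frame(section_index = 10, y = 0.333, z = 4.2)
  mid <- midline_from_sections(secs, occ, overrides = ov)
  expect_equal(mid$points[10, 2:3], c(y = 0.333, z = 4.2))
})

test_that("symmetric sections give the deepest point on the symmetry line", {
  cap <- fx_prism()
  rect <- contour3d(rbind(c(0.5, -0.9, 2), c(7.5, -0.9, 2),
                          c(7.5, 0.9, 2), c(0.5, 0.9, 2)), closed = TRUE)
  secs <- section_series(cap, n = 5, contour = rect)
  # the band's lowest OES ordinate within |y|<=0.9 is at |y| = 0.9 on both
  # sides; the tie-break keeps the point nearest the previous midline y
  mid <- midline_from_sections(secs, rect)
  expect_true(all(abs(diff(mid$points[, 2])) < 0.1))
})
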