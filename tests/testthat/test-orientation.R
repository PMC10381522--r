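circle_contour <- function(R = 8, center = c(3, 4, 5), n = 360,
                           Rm = diag(3)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  P <- cbind(R * cos(th), R * sin(th), 0) %*% t(Rm)
  contour3d(sweep(P, 2, -center), closed = TRUE)
}

ellipse_contour <- function(a = 9.5, b = 8.3, angle = 0, n = 720,
                            center = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  P <- cbind(a * cos(th), b * sin(th), 0) %*% t(rot_z(angle))
  contour3d(sweep(P, 2, -center), closed = TRUE)
}

test_that("frame from a planar circle recovers centre and plane normal", {
  fr <- frame_from_cervical_edge(circle_contour())
  expect_equal(fr$origin, c(3, 4, 5), tolerance = 1e-9)
  expect_equal(abs(fr$z_axis[3]), 1, tolerance = 1e-9)
  R <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  expect_gt(det(R), 0)
})

test_that("the mesio-distal axis follows the rotated ellipse major axis", {
  for (ang in c(0, pi / 6, 1.2)) {
    fr <- frame_from_cervical_edge(ellipse_contour(angle = ang))
    want <- c(cos(ang), sin(ang), 0)
    misalign <- acos(min(1, abs(sum(fr$x_axis * want))))
    expect_lt(misalign, 1e-6)
  }
})

test_that("re-deriving the frame after transforming is the identity", {
  edge <- ellipse_contour(angle = 0.6, center = c(1, -2, 3))
  fr <- frame_from_cervical_edge(edge)
  edge2 <- apply_frame(edge, fr)
  fr2 <- frame_from_cervical_edge(edge2)
  expect_equal(fr2$origin, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(abs(fr2$x_axis[1]), 1, tolerance = 1e-6)
  expect_equal(abs(fr2$z_axis[3]), 1, tolerance = 1e-6)
})

test_that("degenerate (collinear) edges are rejected", {
  P <- cbind(seq_len(20), 2 * seq_len(20), 3 * seq_len(20))
  expect_error(frame_from_cervical_edge(contour3d(P, closed = TRUE)),
               "collinear|degenerate")
})

test_that("occlusal refinement re-aligns x, keeps origin and z", {
  base <- frame_from_cervical_edge(ellipse_contour())
  # coaxial occlusal contour: unchanged axes
  same <- refine_frame_with_occlusal(base, ellipse_contour(a = 7, b = 6))
  expect_equal(abs(sum(same$x_axis * base$x_axis)), 1, tolerance = 1e-9)
  # occlusal rotated 10 degrees: x follows it
  rot10 <- refine_frame_with_occlusal(base,
                                      ellipse_contour(a = 7, b = 6,
                                                      angle = pi / 18))
  want <- c(cos(pi / 18), sin(pi / 18), 0)
  expect_lt(acos(min(1, abs(sum(rot10$x_axis * want)))), 1e-6)
  expect_equal(rot10$origin, base$origin)
  expect_equal(rot10$z_axis, base$z_axis)
  # mirrored contour: right-handedness preserved
  occ <- ellipse_contour(a = 7, b = 6)
  occ$points[, 2] <- -occ$points[, 2]
  mir <- refine_frame_with_occlusal(base, occ)
  R <- cbind(mir$x_axis, mir$y_axis, mir$z_axis)
  expect_gt(det(R), 0)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
})

test_that("apply_frame is rigid: areas, volumes and known rotations", {
  cube <- fx_cube()
  idf <- tooth_frame()
  expect_equal(apply_frame(cube, idf)$vertices, cube$vertices)
  fr <- tooth_frame(origin = c(0, 0, 0),
                    x_axis = c(0, 1, 0), y_axis = c(-1, 0, 0),
                    z_axis = c(0, 0, 1))
  rot <- apply_frame(cube, fr)
  expect_equal(mesh_volume(rot), 1, tolerance = 1e-12)
  expect_equal(sort(round(rot$vertices[, 1], 9)), sort(cube$vertices[, 2]))
  cr <- fx_crown()$cap$mesh
  fr2 <- frame_from_cervical_edge(circle_contour(Rm = rot_x(0.4)))
  moved <- apply_frame(cr, fr2)
  expect_equal(mesh_area(moved), mesh_area(cr), tolerance = 1e-9)
  expect_equal(abs(mesh_volume(moved)), abs(mesh_volume(cr)),
               tolerance = 1e-9)
})

test_that("canonical pose is recovered after arbitrary rigid displacement", {
  fx <- fx_crown()
  cm <- center_at_mass(fx$cap$mesh)
  cap0 <- classify_surfaces(cm$mesh)
  fr0 <- frame_from_cervical_edge(extract_cervical_edge(cap0), cap0)
  canon <- apply_frame(cap0$mesh, fr0)
  disp <- rigid_mesh(cm$mesh, rot_z(0.8) %*% rot_x(-0.3), c(4, 9, -2))
  cap1 <- classify_surfaces(center_at_mass(disp)$mesh)
  fr1 <- frame_from_cervical_edge(extract_cervical_edge(cap1), cap1)
  back <- apply_frame(cap1$mesh, fr1)
  # same pose up to the deterministic in-plane sign conventions
  d_direct <- max(abs(back$vertices - canon$vertices))
  flip <- back
  flip$vertices[, 1] <- -flip$vertices[, 1]
  flip$vertices[, 2] <- -flip$vertices[, 2]
  expect_lt(min(d_direct, max(abs(flip$vertices - canon$vertices))), 1e-6)
})

test_that("z axis points to the crown side (more cap area above the plane)", {
  fx <- fx_crown()
  cap <- classify_surfaces(center_at_mass(fx$cap$mesh)$mesh)
  fr <- frame_from_cervical_edge(extract_cervical_edge(cap), cap)
  oriented <- apply_frame(cap$mesh, fr)
  a <- enamelmap:::face_areas(oriented$vertices, oriented$faces)
  cen <- enamelmap:::face_centroids(oriented$vertices, oriented$faces)
  expect_gt(sum(a[cen[, 3] > 0]), sum(a[cen[, 3] < 0]))
})

test_that("frames serialize to JSON and back", {
  fr <- frame_from_cervical_edge(ellipse_contour(angle = 0.3,
                                                 center = c(2, 1, -4)))
  p <- withr::local_tempfile(fileext = ".json")
  write_frame(fr, p)
  fr2 <- read_frame(p)
  expect_equal(fr2$origin, fr$origin)
  expect_equal(fr2$x_axis, fr$x_axis)
  expect_equal(fr2$z_axis, fr$z_axis)
})
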