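test_that("sphere shells carry closed-form truth and valid geometry", {
  fx <- fx_shell()
  expect_equal(fx$truth$volume, 4 / 3 * pi * (1.1^3 - 1), tolerance = 1e-12)
  expect_equal(fx$truth$volume, 1.3864, tolerance = 1e-4)
  expect_equal(fx$truth$thickness, 0.1)
  v <- validate_mesh(fx$cap$mesh)
  expect_true(v$watertight)
  expect_equal(v$volume, fx$truth$volume, tolerance = 0.005)
  expect_equal(patch_area(cap_submesh(fx$cap, "oes")$mesh),
               4 * pi * 1.1^2, tolerance = 0.005 * 4 * pi * 1.1^2)
  expect_error(make_sphere_shell(1, 1.1), "R > r")
  expect_error(make_sphere_shell(1, 1), "R > r")
})

test_that("very thin shells remain valid and recoverable", {
  fx <- make_sphere_shell(1 + 1e-3, 1, resolution = 0.1)
  cap <- classify_surfaces(center_at_mass(fx$cap$mesh)$mesh)
  expect_gte(label_accuracy(cap, fx$truth), 0.99)
})

test_that("the two-cusp crown is deterministic, symmetric and watertight", {
  spec <- tooth_spec(resolution = 0.35)
  a <- make_two_cusp_crown(spec)
  b <- make_two_cusp_crown(spec)
  expect_identical(a$cap$mesh$vertices, b$cap$mesh$vertices)
  expect_identical(a$cap$mesh$faces, b$cap$mesh$faces)
  v <- validate_mesh(a$cap$mesh)
  expect_true(v$watertight)
  # mirror symmetry about y = 0 within resolution
  Vm <- a$cap$mesh$vertices
  flip <- cbind(Vm[, 1], -Vm[, 2], Vm[, 3])
  d <- enamelmap:::cpp_point_mesh_distance(flip[seq(1, nrow(flip), by = 7), ],
                                           Vm, a$cap$mesh$faces)
  expect_lt(max(d), spec$resolution)
})

test_that("crown mesh volume converges to the quadrature ground truth", {
  fx <- fx_crown()
  expect_equal(mesh_volume(fx$cap$mesh), fx$truth$volume, tolerance = 0.02)
  expect_equal(mesh_area(fx$cap$mesh),
               fx$truth$area_oes + fx$truth$area_edj, tolerance = 0.02)
  # refinement shrinks the volume error (first-order convergence or better)
  coarse <- make_two_cusp_crown(tooth_spec(resolution = 0.5))
  e_coarse <- abs(mesh_volume(coarse$cap$mesh) - coarse$truth$volume)
  e_fine <- abs(mesh_volume(fx$cap$mesh) - fx$truth$volume)
  expect_lt(e_fine, e_coarse)
})

test_that("offsets that exceed local feature size are rejected", {
  expect_error(make_two_cusp_crown(tooth_spec(thickness = 3)),
               "self-intersect")
})

test_that("wear truncates cusps and can expose the EDJ", {
  fx <- fx_crown()
  same <- apply_wear_and_pits(fx$cap, wear_depth = 0, n_pits = 0)
  expect_identical(same$cap$mesh$vertices, fx$cap$mesh$vertices)
  zmax <- max(fx$cap$mesh$vertices[, 3])
  worn <- apply_wear_and_pits(fx$cap, wear_depth = 0.3)
  expect_equal(max(worn$cap$mesh$vertices[, 3]), zmax - 0.3,
               tolerance = 1e-9)
  expect_length(worn$exposed_vertices, 0)
  deep <- apply_wear_and_pits(fx$cap, wear_depth = 0.8)
  expect_gt(length(deep$exposed_vertices), 0)
  expect_error(apply_wear_and_pits(fx$cap, wear_depth = 10), "whole crown")
})

test_that("each pit punches exactly one extra boundary loop, reproducibly", {
  spec1 <- tooth_spec(resolution = 0.25, n_pits = 1, pit_radius = 0.2)
  one <- make_two_cusp_crown(spec1)
  v <- validate_mesh(one$cap$mesh)
  expect_equal(v$n_boundary_loops, 1)
  five <- fx_crown_pitted()
  expect_equal(validate_mesh(five$cap$mesh)$n_boundary_loops, 5)
  again <- make_two_cusp_crown(tooth_spec(resolution = 0.25, n_pits = 5,
                                          pit_radius = 0.2, seed = 11))
  expect_identical(again$cap$mesh$faces, five$cap$mesh$faces)
})
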