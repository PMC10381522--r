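test_that("a minimal single-triangle STL loads with unit conversion", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t",
               "facet normal 0 0 1", "  outer loop",
               "    vertex 0 0 0", "    vertex 1000 0 0",
               "    vertex 0 1000 0",
               "  endloop", "endfacet", "endsolid t"), p)
  m_mm <- load_mesh(p, unit = "mm")
  expect_equal(nrow(m_mm$vertices), 3)
  expect_equal(nrow(m_mm$faces), 1)
  m_um <- load_mesh(p, unit = "um")
  expect_equal(sort(m_um$vertices[, 1]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(max(abs(m_um$vertices)), 1)
})

test_that("validate reports cube area, volume, watertightness and winding", {
  cube <- fx_cube()
  v <- validate_mesh(cube)
  expect_true(v$watertight)
  expect_equal(v$n_boundary_loops, 0)
  expect_equal(v$area, 6, tolerance = 1e-12)
  expect_equal(v$volume, 1, tolerance = 1e-12)
  inv <- cube
  inv$faces <- inv$faces[, c(1, 3, 2)]
  expect_equal(validate_mesh(inv)$volume, -1, tolerance = 1e-12)
  # open hemisphere: one boundary loop
  s <- icosphere(1, 3)
  s$faces <- s$faces[enamelmap:::face_centroids(s$vertices, s$faces)[, 3] > 0, ]
  vh <- validate_mesh(s)
  expect_false(vh$watertight)
  expect_equal(vh$n_boundary_loops, 1)
})

test_that("volume is invariant under rigid motion", {
  cube <- fx_cube()
  m2 <- rigid_mesh(cube, rot_z(0.7) %*% rot_x(1.1), c(5, -3, 2))
  expect_equal(mesh_volume(m2), mesh_volume(cube), tolerance = 1e-9)
  sh <- fx_shell()$cap$mesh
  sh2 <- rigid_mesh(sh, rot_x(0.3), c(-1, 2, 0.5))
  expect_equal(mesh_volume(sh2), mesh_volume(sh), tolerance = 1e-9)
})

test_that("load/save round trips preserve geometry per format", {
  cr <- fx_crown()
  mesh <- cr$cap$mesh
  for (ext in c("stl", "ply", "obj")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    save_mesh(mesh, p)
    m2 <- load_mesh(p, unit = "mm")
    expect_equal(nrow(m2$faces), nrow(mesh$faces), label = ext)
    # volume summarizes vertex + topology fidelity (STL stores float32)
    expect_equal(mesh_volume(m2), mesh_volume(mesh), tolerance = 1e-5,
                 label = ext)
  }
  # ascii STL round trip keeps coordinates to 1e-6
  p <- withr::local_tempfile(fileext = ".stl")
  save_mesh(fx_cube(), p, binary = FALSE)
  m3 <- load_mesh(p, unit = "mm")
  expect_equal(mesh_volume(m3), 1, tolerance = 1e-6)
  expect_equal(nrow(m3$vertices), 8)
})

test_that("binary PLY round-trips per-vertex quality and colour", {
  cube <- fx_cube()
  q <- seq_len(8) / 10
  col <- matrix(rep(c(10L, 128L, 250L), each = 8), 8, 3)
  for (bin in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".ply")
    enamelmap:::write_ply(cube, p, binary = bin, quality = q, color = col)
    r <- enamelmap:::read_ply(p)
    expect_equal(as.numeric(r$vertex_attributes[, "quality"]), q,
                 tolerance = 1e-6)
    expect_equal(as.integer(r$vertex_attributes[, "red"]), rep(10L, 8))
  }
})

test_that("fill_holes closes small holes, leaves large openings, never drops faces", {
  cube <- fx_cube()
  expect_equal(fill_holes(cube)$n_filled, 0)
  # cube missing one face's 2 triangles -> watertight, volume 1
  m <- cube
  m$faces <- m$faces[-c(1, 2), ]
  fh <- fill_holes(m, max_perimeter = 10)
  expect_equal(fh$n_filled, 1)
  expect_true(validate_mesh(fh$mesh)$watertight)
  expect_equal(mesh_volume(fh$mesh), 1, tolerance = 1e-12)
  expect_gte(nrow(fh$mesh$faces), nrow(m$faces))
  # sphere with a polar cap removed -> filled, Euler characteristic 2
  s <- icosphere(1, 3)
  s$faces <- s$faces[enamelmap:::face_centroids(s$vertices,
                                                s$faces)[, 3] < 0.93, ]
  fh2 <- fill_holes(s, max_perimeter = 10)
  expect_equal(fh2$n_filled, 1)
  v <- validate_mesh(fh2$mesh)
  expect_true(v$watertight)
  expect_equal(v$euler_characteristic, 2)
  # a loop above the threshold stays open and is reported
  fh3 <- fill_holes(s, max_perimeter = 1e-3)
  expect_equal(fh3$n_filled, 0)
  expect_length(fh3$open_loops, 1)
})

test_that("winding repair recovers outward orientation from scrambled input", {
  cube <- fx_cube()
  scram <- cube
  set.seed(42)
  fl <- sample(nrow(scram$faces), 6)
  scram$faces[fl, ] <- scram$faces[fl, c(1, 3, 2)]
  fixed <- enamelmap:::orient_mesh(scram)
  expect_equal(mesh_volume(fixed), 1, tolerance = 1e-12)
  # nested shell: inner component oriented inward (enamel volume positive)
  sh <- fx_shell()
  expect_gt(mesh_volume(enamelmap:::orient_mesh(sh$cap$mesh)), 0)
})

test_that("degenerate and malformed meshes are rejected", {
  expect_error(surface_mesh(matrix(0, 0, 3), matrix(1L, 0, 3)), "empty")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 4))), "out-of-range")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            rbind(c(1, 2, 3))), "degenerate")
  expect_error(load_mesh(withr::local_tempfile(fileext = ".xyz")),
               "not found")
})
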