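test_that("center_at_mass reports the area-weighted surface centroid", {
  off <- fx_cube(origin = c(5, 5, 5))
  cm <- center_at_mass(off)
  expect_equal(cm$mass_center, c(5.5, 5.5, 5.5), tolerance = 1e-12)
  expect_equal(unname(colMeans(cm$mesh$vertices)), c(0, 0, 0),
               tolerance = 1e-12)
  # already centred: identity
  cm2 <- center_at_mass(cm$mesh)
  expect_equal(cm2$mass_center, c(0, 0, 0), tolerance = 1e-12)
  # two spheres of area A and 4A at x = 0 and x = 10: centroid x = 8
  s1 <- icosphere(1, 3, center = c(0, 0, 0))
  s2 <- icosphere(2, 3, center = c(10, 0, 0))
  both <- surface_mesh(rbind(s1$vertices, s2$vertices),
                       rbind(s1$faces, s2$faces + nrow(s1$vertices)))
  expect_equal(center_at_mass(both)$mass_center[1], 8, tolerance = 1e-3)
})

test_that("classify_surfaces recovers generator labels on shells and crowns", {
  for (fx in list(fx_shell(), fx_hemi_shell(), fx_crown())) {
    cm <- center_at_mass(fx$cap$mesh)
    cap <- classify_surfaces(cm$mesh)
    expect_gte(label_accuracy(cap, fx$truth), 0.99)
    # partition property holds exactly
    expect_equal(sort(c(cap$outer_faces, cap$inner_faces)),
                 seq_len(nrow(cap$mesh$faces)))
  }
})

test_that("classification accuracy holds across shell thicknesses", {
  for (t in c(0.05, 0.3, 1.0)) {
    fx <- make_sphere_shell(2, 2 - t, resolution = 0.12)
    cap <- classify_surfaces(center_at_mass(fx$cap$mesh)$mesh)
    expect_gte(label_accuracy(cap, fx$truth), 0.99)
  }
})

test_that("a single closed surface raises the no-internal-surface error", {
  s <- icosphere(1, 3)
  expect_error(classify_surfaces(center_at_mass(s)$mesh),
               "no internal surface")
})

test_that("classification commutes with rigid motion", {
  fx <- fx_crown()
  cm <- center_at_mass(fx$cap$mesh)
  base <- classify_surfaces(cm$mesh)
  rot <- rigid_mesh(cm$mesh, rot_z(1.1) %*% rot_x(0.5))
  moved <- classify_surfaces(rot)
  expect_equal(moved$outer_faces, base$outer_faces)
  expect_equal(moved$inner_faces, base$inner_faces)
})

test_that("cervical edge is the exact class border, a single ordered loop", {
  fx <- fx_hemi_shell()
  cap <- classify_surfaces(center_at_mass(fx$cap$mesh)$mesh)
  edge <- extract_cervical_edge(cap)
  expect_true(edge$closed)
  # hemispherical shell meeting at the equator, R = 2: length ~ 2*pi*R
  expect_equal(contour_length(edge), 2 * pi * 2, tolerance = 0.01)
  # each returned point sits on a mesh edge bordered by one face per class
  cls <- cap_face_classes(cap)
  he <- enamelmap:::half_edges(cap$mesh$faces)
  key <- enamelmap:::edge_key(he$from, he$to)
  o <- order(key); ks <- key[o]
  dup <- which(ks[-1] == ks[-length(ks)])
  mixed <- cls[he$face[o][dup]] != cls[he$face[o][dup + 1]]
  nb <- length(unique(c(he$from[o][dup][mixed], he$to[o][dup][mixed])))
  expect_equal(nrow(edge$points), nb)
})

test_that("the crown cervical edge is one loop that moves rigidly with the cap", {
  fx <- fx_crown()
  cap <- classify_surfaces(center_at_mass(fx$cap$mesh)$mesh)
  e1 <- extract_cervical_edge(cap)
  expect_true(e1$closed)
  shift <- c(3, -2, 7)
  cap2 <- cap
  cap2$mesh <- rigid_mesh(cap$mesh, diag(3), shift)
  e2 <- extract_cervical_edge(cap2)
  expect_equal(sweep(e2$points, 2, shift), e1$points, tolerance = 1e-12)
})
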