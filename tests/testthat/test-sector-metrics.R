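test_that("saet3d implements the averaged-area thickness exactly", {
  # worked example with the study's occlusal sector magnitudes
  m <- saet3d(SV = 170.60, SAedj = 227.46, SAoes = 249.96)
  expect_equal(m$SAA, (227.46 + 249.96) / 2, tolerance = 1e-12)
  expect_equal(m$SAA, 238.71, tolerance = 1e-12)
  expect_equal(m$SAET3D, 170.60 / 238.71, tolerance = 1e-12)
  expect_equal(m$SAET3D, 0.7147, tolerance = 1e-4)
  # equal areas reduce to the classical denominator
  m2 <- saet3d(10, 25, 25, classical = TRUE)
  expect_equal(m2$SAA, 25)
  expect_equal(m2$SAET3D, m2$AET)
  expect_error(saet3d(-1, 2, 3), "positive")
  expect_error(saet3d(1, 0, 3), "positive")
})

test_that("saet3d and saet2d equal independent recomputation on random inputs", {
  set.seed(99)
  for (i in 1:200) {
    v <- exp(stats::runif(3, -2, 5))
    m <- saet3d(v[1], v[2], v[3])
    expect_identical(m$SAA, (v[2] + v[3]) / 2)
    expect_identical(m$SAET3D, v[1] / ((v[2] + v[3]) / 2))
  }
})

test_that("thin spherical shells recover their thickness from Eq-level areas", {
  # closed form: SAET3D = (2/3)(R^3 - r^3)/(R^2 + r^2)
  for (t in c(0.02, 0.1, 0.2)) {
    R <- 1 + t; r <- 1
    SV <- 4 / 3 * pi * (R^3 - r^3)
    m <- saet3d(SV, 4 * pi * r^2, 4 * pi * R^2)
    closed <- (2 / 3) * (R^3 - r^3) / (R^2 + r^2)
    expect_equal(m$SAET3D, closed, tolerance = 1e-12)
    expect_lt(abs(m$SAET3D - t) / t, 0.02 * (t / 0.1) + 0.02)
  }
})

test_that("patch_area matches square, hemisphere and rigid invariance", {
  sq <- fx_plate(1, 1, 0, 1)
  expect_equal(patch_area(surface_mesh(sq$V, sq$F)), 1, tolerance = 1e-12)
  hemi <- cap_submesh(fx_hemi_shell()$cap, "oes")$mesh
  expect_equal(patch_area(hemi), 8 * pi, tolerance = 0.01 * 8 * pi)
  hemi2 <- rigid_mesh(hemi, rot_x(0.9), c(1, 2, 3))
  expect_equal(patch_area(hemi2), patch_area(hemi), tolerance = 1e-9)
})

test_that("sector_volume integrates parallel plates exactly", {
  cap <- fx_plate_cap(lx = 2, ly = 3, gap = 0.5)
  oes <- cap_submesh(cap, "oes")
  V <- oes$mesh$vertices
  F <- oes$mesh$faces
  patch <- structure(list(triangles = cbind(V[F[, 1], ], V[F[, 2], ],
                                            V[F[, 3], ])),
                     class = "sector_patch")
  expect_equal(sector_volume(patch, cap), 3, tolerance = 1e-9)
})

test_that("sector segmentation splits symmetric crowns evenly and additively", {
  fx <- fx_crown()
  cap <- fx$cap
  occ <- occlusal_contour_oes(cap)
  occ_edj <- project_contour_to_edj(occ, cap)
  secs <- section_series(cap, n = 80, contour = occ)
  mid <- midline_from_sections(secs, occ)
  mid_edj <- project_contour_to_edj(mid, cap)
  sect <- segment_sectors(cap, occ, occ_edj, mid, mid_edj)
  Ab <- patch_area(sect$oes$buccal_inner_slope)
  Al <- patch_area(sect$oes$lingual_inner_slope)
  At <- patch_area(sect$oes$occlusal_total)
  # mirror symmetry about y = 0
  expect_lt(abs(Ab - Al) / At, 0.005)
  # exact partition of the area inside the contour
  expect_equal(Ab + Al, At, tolerance = 1e-9)
  Vb <- sector_volume(sect$oes$buccal_inner_slope, cap)
  Vl <- sector_volume(sect$oes$lingual_inner_slope, cap)
  Vt <- sector_volume(sect$oes$occlusal_total, cap)
  expect_lt(abs(Vb - Vl) / Vt, 0.005)
  expect_lt(abs(Vb + Vl - Vt) / Vt, 0.001)
  expect_error(segment_sectors(cap, contour3d(occ$points, closed = FALSE),
                               occ_edj, mid, mid_edj), "closed")
})

test_that("hemisphere cap splits into equal sectors under equator + meridian", {
  fx <- fx_hemi_shell()
  cap <- fx$cap
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  equator <- contour3d(cbind(2.001 * cos(th), 2.001 * sin(th), 0),
                       closed = TRUE)
  meridian <- contour3d(cbind(seq(-2.1, 2.1, length.out = 50), 0, 0),
                        closed = FALSE)
  sect <- segment_sectors(cap, equator, equator, meridian, meridian)
  half <- patch_area(cap_submesh(cap, "oes")$mesh) / 2
  expect_equal(patch_area(sect$oes$buccal_inner_slope), half,
               tolerance = 0.01 * half)
  expect_equal(patch_area(sect$oes$lingual_inner_slope), half,
               tolerance = 0.01 * half)
})

test_that("saet2d reproduces the rectangle and half-annulus closed forms", {
  sec <- fx_rect_section(w = 10, th = 0.5)
  m <- saet2d(sec, midline_y = 5, contour_y = c(0, 10))
  tot <- m$occlusal_total
  expect_equal(tot$SA, 5, tolerance = 1e-9)
  expect_equal(tot$SCLoes, 10, tolerance = 1e-9)
  expect_equal(tot$SCLedj, 10, tolerance = 1e-9)
  expect_equal(tot$SACL, 10, tolerance = 1e-9)
  expect_equal(tot$SAET2D, 0.5, tolerance = 1e-9)
  ann <- fx_annulus_section(R = 1.1, r = 1.0, m = 2000)
  ma <- saet2d(ann, midline_y = 0, contour_y = c(-1.1, 1.1))
  expect_equal(ma$occlusal_total$SA, pi * (1.1^2 - 1) / 2, tolerance = 1e-4)
  expect_equal(ma$occlusal_total$SACL, pi * (1.1 + 1) / 2, tolerance = 1e-4)
  expect_equal(ma$occlusal_total$SAET2D, 0.1, tolerance = 1e-3)
  # union SAET2D lies between the sub-sector values
  vals <- c(ma$buccal_inner_slope$SAET2D, ma$lingual_inner_slope$SAET2D)
  expect_gte(ma$occlusal_total$SAET2D, min(vals) - 1e-12)
  expect_lte(ma$occlusal_total$SAET2D, max(vals) + 1e-12)
  expect_error(saet2d(sec, midline_y = 5, contour_y = c(20, 30)),
               "degenerate")
})

test_that("build_report reproduces the percentage layout and flags leaks", {
  # symmetric sectors: 50.00 / 50.00
  occ <- saet3d(10, 20, 22)
  half <- saet3d(5, 10, 11, "buccal_inner_slope")
  halfl <- saet3d(5, 10, 11, "lingual_inner_slope")
  rep1 <- build_report(list(occlusal_total = occ,
                            buccal_inner_slope = half,
                            lingual_inner_slope = halfl))
  expect_true(rep1$conservation_ok)
  expect_equal(rep1$table$buccal_pct, c(50, 50, 50, 100))
  expect_error(build_report(list(occlusal_total = occ)), "missing sector")
  # percentage rounding is half-up at 2 decimals
  expect_equal(enamelmap:::round_half_up(54.8968), 54.90)
  expect_equal(enamelmap:::round_half_up(101.7310), 101.73)
  expect_equal(enamelmap:::round_half_up(2.005), 2.01)
  expect_equal(enamelmap:::round_half_up(2.004999), 2.00)
})

test_that("reports serialize to CSV and JSON", {
  occ <- saet3d(10, 20, 22)
  repx <- build_report(list(
    occlusal_total = occ,
    buccal_inner_slope = saet3d(6, 11, 12, "buccal_inner_slope"),
    lingual_inner_slope = saet3d(4, 9, 10, "lingual_inner_slope")))
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_report(repx, pc)
  write_report(repx, pj)
  back <- read.csv(pc)
  expect_equal(nrow(back), 4)
  expect_equal(back$occlusal[3], 10)
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(nrow(j$table), 4)
})
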