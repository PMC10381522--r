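# Sector segmentation and the modified average enamel thickness parameters.
#
# The occlusal enamel is bounded by the occlusal contour (on the OES, and its
# projection on the EDJ) and split by the midline into the buccal and lingual
# inner-slope sectors. Per sector: enamel volume SV, EDJ area SAedj, OES area
# SAoes, and the modified 3D average enamel thickness
#   SAET3D = SV / SAA,   SAA = (SAedj + SAoes) / 2;
# in a bucco-lingual section: enamel area SA, contour lengths SCLedj/SCLoes,
#   SAET2D = SA / SACL,  SACL = (SCLedj + SCLoes) / 2.

# exact half-up rounding (Table-style percentages)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# vectorized ray-crossing point-in-polygon (polygon closed implicitly)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# region code for points: 0 outside contour, 1 buccal (y > midline),
# 2 lingual (y < midline)
sector_code <- function(x, y, contour_xy, midline_fun) {
  inside <- point_in_polygon(x, y, contour_xy[, 1], contour_xy[, 2])
  ym <- midline_fun(x)
  ifelse(!inside, 0L, ifelse(y > ym, 1L, 2L))
}

# 4-way midpoint subdivision of triangles given as k x 9 (A, B, C) rows
subdivide_tris <- function(T9) {
  A <- T9[, 1:3, drop = FALSE]
  B <- T9[, 4:6, drop = FALSE]
  C <- T9[, 7:9, drop = FALSE]
  AB <- (A + B) / 2
  BC <- (B + C) / 2
  CA <- (C + A) / 2
  rbind(cbind(A, AB, CA), cbind(AB, B, BC), cbind(CA, BC, C),
        cbind(AB, BC, CA))
}

tri9_area <- function(T9) {
  u <- T9[, 4:6, drop = FALSE] - T9[, 1:3, drop = FALSE]
  v <- T9[, 7:9, drop = FALSE] - T9[, 1:3, drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Segment the enamel cap into occlusal sectors
#'
#' OES faces inside the occlusal contour are split by the midline into the
#' buccal (`y > midline`) and lingual (`y < midline`) inner-slope patches,
#' and likewise for the EDJ with the projected contours. Faces straddling a
#' boundary are partitioned by recursive midpoint subdivision with
#' centroid-rule assignment of the fragments, so sector areas are exactly
#' additive.
#'
#' @param cap an [enamel_cap()] in tooth-frame coordinates.
#' @param occlusal_oes,occlusal_edj closed occlusal contours on the two
#'   surfaces (the EDJ one is the -z projection, sharing x,y).
#' @param midline_oes,midline_edj open x-monotone midlines.
#' @param depth subdivision depth for straddling faces (4^depth fragments).
#' @return List with `oes` and `edj`, each a list of patches
#'   `occlusal_total`, `buccal_inner_slope`, `lingual_inner_slope`.
#' @export
segment_sectors <- function(cap, occlusal_oes, occlusal_edj, midline_oes,
                            midline_edj, depth = 3) {
  for (ct in list(occlusal_oes, occlusal_edj))
    if (!ct$closed)
      stop("occlusal contour must be closed for sector segmentation",
           call. = FALSE)
  mk_midfun <- function(ml) {
    P <- ml$points
    function(x) approx(P[, 1], P[, 2], xout = x, rule = 2)$y
  }
  one_surface <- function(which, contour, midfun) {
    sub <- cap_submesh(cap, which)
    V <- sub$mesh$vertices
    F <- sub$mesh$faces
    cxy <- contour$points[, 1:2, drop = FALSE]
    vcode <- sector_code(V[, 1], V[, 2], cxy, midfun)
    fcode <- matrix(vcode[F], ncol = 3)
    same <- fcode[, 1] == fcode[, 2] & fcode[, 2] == fcode[, 3]
    whole <- list(`0` = which(same & fcode[, 1] == 0L),
                  `1` = which(same & fcode[, 1] == 1L),
                  `2` = which(same & fcode[, 1] == 2L))
    strad <- which(!same)
    frags <- list(`0` = NULL, `1` = NULL, `2` = NULL)
    if (length(strad)) {
      T9 <- cbind(V[F[strad, 1], , drop = FALSE],
                  V[F[strad, 2], , drop = FALSE],
                  V[F[strad, 3], , drop = FALSE])
      for (d in seq_len(depth)) T9 <- subdivide_tris(T9)
      cen <- (T9[, 1:3, drop = FALSE] + T9[, 4:6, drop = FALSE] +
                T9[, 7:9, drop = FALSE]) / 3
      code <- sector_code(cen[, 1], cen[, 2], cxy, midfun)
      for (cc in c(0L, 1L, 2L))
        frags[[as.character(cc)]] <- T9[code == cc, , drop = FALSE]
    }
    patch <- function(codes) {
      fids <- unlist(whole[as.character(codes)], use.names = FALSE)
      fr <- do.call(rbind, frags[as.character(codes)])
      T9w <- if (length(fids))
        cbind(V[F[fids, 1], , drop = FALSE], V[F[fids, 2], , drop = FALSE],
              V[F[fids, 3], , drop = FALSE]) else NULL
      tris <- rbind(T9w, fr)
      structure(list(triangles = tris, surface = which,
                     n_whole = length(fids), n_frag = NROW(fr)),
                class = "sector_patch")
    }
    list(occlusal_total = patch(c(1L, 2L)),
         buccal_inner_slope = patch(1L),
         lingual_inner_slope = patch(2L))
  }
  list(oes = one_surface("oes", occlusal_oes, mk_midfun(midline_oes)),
       edj = one_surface("edj", occlusal_edj, mk_midfun(midline_edj)))
}

#' Surface area of a sector patch (mm^2)
#'
#' @param patch a `sector_patch` from [segment_sectors()], or a
#'   [surface_mesh()], or a face-index subset with `mesh`.
#' @param mesh optional [surface_mesh()] when `patch` is a face-index vector.
#' @return Numeric scalar; 0 with a warning for an empty patch.
#' @export
patch_area <- function(patch, mesh = NULL) {
  if (inherits(patch, "surface_mesh"))
    return(mesh_area(patch))
  if (is.numeric(patch) && !is.null(mesh))
    return(sum(face_areas(mesh$vertices,
                          mesh$faces[as.integer(patch), , drop = FALSE])))
  tris <- patch$triangles
  if (is.null(tris) || nrow(tris) == 0) {
    warning("empty patch: area 0")
    return(0)
  }
  sum(tri9_area(tris))
}

#' Enamel volume of a sector (mm^3)
#'
#' Integrates prismatic columns between the OES patch and the EDJ surface:
#' for each patch triangle, the xy-projected area times the mean vertical
#' enamel depth `z_OES - z_EDJ` at its corners (EDJ sampled by -z ray
#' casting). Exactly additive over disjoint patches.
#'
#' @param oes_patch a `sector_patch` on the OES.
#' @param cap the [enamel_cap()] providing the EDJ surface.
#' @return Numeric scalar (mm^3).
#' @export
sector_volume <- function(oes_patch, cap) {
  tris <- oes_patch$triangles
  if (is.null(tris) || nrow(tris) == 0) {
    warning("empty patch: volume 0")
    return(0)
  }
  sub <- cap_submesh(cap, "edj")
  P <- rbind(tris[, 1:3, drop = FALSE], tris[, 4:6, drop = FALSE],
             tris[, 7:9, drop = FALSE])
  rc <- cpp_raycast_down(P, sub$mesh$vertices, sub$mesh$faces)
  depthv <- P[, 3] - rc$z
  depthv[!rc$hit | !is.finite(depthv)] <- 0
  depthv[depthv < 0] <- 0
  k <- nrow(tris)
  dmean <- (depthv[seq_len(k)] + depthv[k + seq_len(k)] +
              depthv[2 * k + seq_len(k)]) / 3
  # xy-projected (plan) area per triangle
  ax <- tris[, 1]; ay <- tris[, 2]
  bx <- tris[, 4]; by <- tris[, 5]
  cx <- tris[, 7]; cy <- tris[, 8]
  plan <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  sum(plan * dmean)
}

#' Sector average enamel thickness, 3D mode
#'
#' `SAA = (SAedj + SAoes) / 2` and `SAET3D = SV / SAA`, the modified
#' average-thickness parameter whose denominator averages the two bounding
#' surfaces of the worn enamel cap. Optionally also reports the classical
#' EDJ-only parameter `AET = SV / SAedj`.
#'
#' @param SV sector enamel volume, mm^3.
#' @param SAedj,SAoes sector EDJ and OES areas, mm^2.
#' @param sector_id one of `"occlusal_total"`, `"buccal_inner_slope"`,
#'   `"lingual_inner_slope"`.
#' @param classical also include the classical EDJ-denominator thickness?
#' @return A list of class `sector_measurement_3d`.
#' @export
saet3d <- function(SV, SAedj, SAoes,
                   sector_id = c("occlusal_total", "buccal_inner_slope",
                                 "lingual_inner_slope"),
                   classical = FALSE) {
  sector_id <- match.arg(sector_id)
  if (!all(is.finite(c(SV, SAedj, SAoes))) || SV <= 0 || SAedj <= 0 ||
      SAoes <= 0)
    stop("SV, SAedj and SAoes must all be positive", call. = FALSE)
  SAA <- (SAedj + SAoes) / 2
  out <- list(sector_id = sector_id, SV = SV, SAedj = SAedj, SAoes = SAoes,
              SAA = SAA, SAET3D = SV / SAA)
  if (classical) out$AET <- SV / SAedj
  structure(out, class = "sector_measurement_3d")
}

#' @export
print.sector_measurement_3d <- function(x, ...) {
  cat(sprintf(paste0("<sector_measurement_3d> %s: SV=%.4g mm^3, ",
                     "SAedj=%.4g, SAoes=%.4g, SAA=%.4g mm^2, ",
                     "SAET3D=%.4g mm\n"),
              x$sector_id, x$SV, x$SAedj, x$SAoes, x$SAA, x$SAET3D))
  invisible(x)
}

# Sutherland-Hodgman clip of a closed polygon (k x 2) to the slab
# lo <= y <= hi; returns the clipped polygon (possibly with zero-width
# bridges, which do not affect the area).
polygon_clip_slab <- function(pts, lo, hi) {
  clip_half <- function(P, bound, keep_ge) {
    if (is.null(P) || nrow(P) < 3) return(NULL)
    n <- nrow(P)
    out <- matrix(NA_real_, 0, 2)
    for (i in seq_len(n)) {
      a <- P[i, ]
      b <- P[if (i == n) 1 else i + 1, ]
      ain <- if (keep_ge) a[1] >= bound else a[1] <= bound
      bin <- if (keep_ge) b[1] >= bound else b[1] <= bound
      if (ain) out <- rbind(out, a)
      if (xor(ain, bin)) {
        t <- (bound - a[1]) / (b[1] - a[1])
        out <- rbind(out, a + t * (b - a))
      }
    }
    if (nrow(out) < 3) NULL else out
  }
  clip_half(clip_half(pts, lo, TRUE), hi, FALSE)
}

polygon_area2 <- function(P) {
  if (is.null(P) || nrow(P) < 3) return(0)
  k <- nrow(P)
  abs(sum(P[, 1] * P[c(2:k, 1), 2] - P[c(2:k, 1), 1] * P[, 2]) / 2)
}

# length of the class-`cls` segments of a section loop clipped to the slab
chain_length_in_slab <- function(lp, cls, lo, hi) {
  P <- lp$points
  n <- nrow(P)
  if (n < 2) return(0)
  nseg <- length(lp$seg_class)
  total <- 0
  for (i in seq_len(nseg)) {
    if (lp$seg_class[i] != cls) next
    a <- P[i, ]
    b <- P[if (i == n) 1 else i + 1, ]
    ys <- sort(c(a[1], b[1]))
    if (ys[2] < lo || ys[1] > hi) next
    if (abs(b[1] - a[1]) < 1e-300) {
      if (a[1] > lo && a[1] < hi) total <- total + sqrt(sum((b - a)^2))
      next
    }
    t0 <- max(0, min(1, (lo - a[1]) / (b[1] - a[1])))
    t1 <- max(0, min(1, (hi - a[1]) / (b[1] - a[1])))
    tt <- sort(c(t0, t1))
    total <- total + (tt[2] - tt[1]) * sqrt(sum((b - a)^2))
  }
  total
}

#' Sector average enamel thickness in a bucco-lingual section (2D mode)
#'
#' For each sector slab between the midline ordinate and the occlusal
#' contour crossings: enamel cross-section area `SA` (clipped section
#' polygon), OES and EDJ contour lengths `SCLoes`/`SCLedj` (clipped labelled
#' chains), `SACL = (SCLedj + SCLoes)/2` and `SAET2D = SA / SACL`.
#'
#' @param section a `planar_section` from [section_series()].
#' @param midline_y midline ordinate of this section, mm.
#' @param contour_y occlusal-contour crossing ordinates `c(lingual, buccal)`
#'   (min, max), mm.
#' @return List of class-`sector_measurement_2d` records for
#'   `occlusal_total`, `buccal_inner_slope`, `lingual_inner_slope`.
#' @export
saet2d <- function(section, midline_y, contour_y) {
  contour_y <- sort(as.numeric(contour_y))
  slabs <- list(occlusal_total = c(contour_y[1], contour_y[2]),
                buccal_inner_slope = c(midline_y, contour_y[2]),
                lingual_inner_slope = c(contour_y[1], midline_y))
  out <- lapply(names(slabs), function(nm) {
    sl <- slabs[[nm]]
    SA <- 0
    SCLoes <- 0
    SCLedj <- 0
    for (lp in section$loops) {
      if (isTRUE(lp$closed))
        SA <- SA + polygon_area2(polygon_clip_slab(lp$points, sl[1], sl[2]))
      SCLoes <- SCLoes + chain_length_in_slab(lp, 1L, sl[1], sl[2])
      SCLedj <- SCLedj + chain_length_in_slab(lp, 2L, sl[1], sl[2])
    }
    if (SA < 1e-9)
      stop("degenerate sector '", nm, "': cross-section area < 1e-9",
           call. = FALSE)
    SACL <- (SCLedj + SCLoes) / 2
    structure(list(sector_id = nm, SA = SA, SCLoes = SCLoes,
                   SCLedj = SCLedj, SACL = SACL, SAET2D = SA / SACL),
              class = "sector_measurement_2d")
  })
  names(out) <- names(slabs)
  out
}

#' Assemble the per-tooth report
#'
#' Lays out OES area, EDJ area, enamel volume and SAET3D for the occlusal
#' total and the two inner-slope sectors, with each slope expressed as a
#' percentage of the occlusal value (thickness relative to occlusal SAET3D),
#' rounded half-up to 2 decimals.
#'
#' @param measurements named list with `occlusal_total`,
#'   `buccal_inner_slope`, `lingual_inner_slope`
#'   [saet3d()] records.
#' @param tooth label for the report.
#' @return A list of class `tooth_report` with a `table` data.frame and a
#'   `conservation_ok` flag (buccal% + lingual% within 0.01 of 100 for areas
#'   and volume).
#' @export
build_report <- function(measurements, tooth = "tooth") {
  need <- c("occlusal_total", "buccal_inner_slope", "lingual_inner_slope")
  if (!all(need %in% names(measurements)))
    stop("missing sector(s): ",
         paste(setdiff(need, names(measurements)), collapse = ", "),
         call. = FALSE)
  occ <- measurements$occlusal_total
  bu <- measurements$buccal_inner_slope
  li <- measurements$lingual_inner_slope
  quant <- c(SAoes = "Outer enamel surface area, mm2",
             SAedj = "Enamel-dentine junction area, mm2",
             SV = "Enamel volume, mm3",
             SAET3D = "Three-dimensional average enamel thickness, mm")
  rows <- lapply(names(quant), function(q) {
    vo <- occ[[q]]; vb <- bu[[q]]; vl <- li[[q]]
    data.frame(quantity = quant[[q]], parameter = q,
               occlusal = vo, buccal = vb, lingual = vl,
               buccal_pct = round_half_up(100 * vb / vo),
               lingual_pct = round_half_up(100 * vl / vo))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cons <- tab$parameter != "SAET3D"
  conservation_ok <- all(abs(tab$buccal_pct[cons] + tab$lingual_pct[cons] -
                               100) <= 0.01 + 1e-9)
  structure(list(tooth = tooth, measurements = measurements, table = tab,
                 conservation_ok = conservation_ok),
            class = "tooth_report")
}

#' @export
print.tooth_report <- function(x, ...) {
  cat(sprintf("<tooth_report> %s\n", x$tooth))
  print(x$table, digits = 6)
  if (!x$conservation_ok)
    cat("note: buccal% + lingual% deviates from 100.00 by more than 0.01\n")
  invisible(x)
}

#' Write a tooth report as CSV or JSON
#' @param report a `tooth_report`.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.csv(report$table, path, row.names = FALSE)
  } else if (ext == "json") {
    tab <- report$table
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(v) signif(v, 6))
    jsonlite::write_json(list(tooth = report$tooth, table = tab,
                              conservation_ok = report$conservation_ok),
                         path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", pretty = TRUE)
  } else stop("unsupported report format: .", ext, call. = FALSE)
  invisible(path)
}
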