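# End-to-end orchestration: load/repair -> centre -> segment -> orient ->
# curvature -> occlusal contour -> sections -> midline -> projections ->
# sector metrics -> thickness map -> report.

#' Pipeline configuration
#'
#' @param unit input mesh unit (`"mm"` or `"um"`).
#' @param n_sections bucco-lingual sections (default 80).
#' @param span section span, `"occlusal"` or `"crown"`.
#' @param pit_filter enable the pit-robust midline filter?
#' @param contour_overrides optional k x 3 matrix (or CSV path `x,y,z`) of
#'   occlusal-contour override points, in tooth-frame coordinates.
#' @param midline_overrides optional data.frame (or CSV path)
#'   `section_index,y,z`.
#' @param frame_override optional [tooth_frame()] (or JSON path) taking
#'   precedence over the automatic orientation.
#' @param thickness_method `"nearest"` or `"ray"`.
#' @param seed integer seed recorded in the run config.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(unit = "mm", n_sections = 80,
                            span = c("occlusal", "crown"),
                            pit_filter = FALSE, contour_overrides = NULL,
                            midline_overrides = NULL, frame_override = NULL,
                            thickness_method = "nearest", seed = 1L) {
  span <- match.arg(span)
  if (n_sections < 3) stop("n_sections must be at least 3", call. = FALSE)
  if (is.character(contour_overrides))
    contour_overrides <- as.matrix(read.csv(contour_overrides))
  if (is.character(midline_overrides))
    midline_overrides <- read.csv(midline_overrides)
  if (is.character(frame_override))
    frame_override <- read_frame(frame_override)
  structure(list(unit = unit, n_sections = as.integer(n_sections),
                 span = span, pit_filter = isTRUE(pit_filter),
                 contour_overrides = contour_overrides,
                 midline_overrides = midline_overrides,
                 frame_override = frame_override,
                 thickness_method = thickness_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full enamel-thickness measurement pipeline
#'
#' Stages: mesh load and hole filling, centring at the surface mass centre,
#' OES/EDJ segmentation, cervical-edge extraction, tooth-frame orientation
#' (refined by the occlusal contour), curvature analysis, occlusal-contour
#' delineation and projection onto the EDJ, the bucco-lingual section series
#' and midline, sector segmentation, the SAET3D report, and the topographic
#' thickness map. Deterministic: identical input and config reproduce
#' identical outputs.
#'
#' @param input path to a mesh file, a [surface_mesh()], or an
#'   [enamel_cap()] (skips loading/segmentation).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, all stage artifacts
#'   are written there with stable filenames.
#' @param verbose log stage progress?
#' @return List of class `pipeline_result` with `cap`, `frame`,
#'   `cervical_edge`, `occlusal_oes`, `occlusal_edj`, `midline_oes`,
#'   `midline_edj`, `sections`, `sectors`, `measurements`, `report`,
#'   `thickness`, `log`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  t0 <- Sys.time()
  logline <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    logline <<- c(logline, msg)
    if (verbose) message(msg)
  }
  stage <- function(name, expr, hint = NULL) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s%s", name,
                   conditionMessage(e),
                   if (is.null(hint)) "" else paste0(" (hint: ", hint, ")")),
           call. = FALSE)
    })
  }
  # --- load / segment --------------------------------------------------------
  if (inherits(input, "enamel_cap")) {
    cap <- input
    say("input: enamel cap in memory (%d faces)", nrow(cap$mesh$faces))
  } else {
    mesh <- if (inherits(input, "surface_mesh")) input
            else stage("load", load_mesh(input, unit = config$unit))
    say("loaded mesh: %d vertices, %d faces", nrow(mesh$vertices),
        nrow(mesh$faces))
    fh <- stage("fill_holes", fill_holes(mesh))
    if (fh$n_filled > 0)
      say("filled %d perforation(s); %d larger opening(s) left",
          fh$n_filled, length(fh$open_loops))
    cm <- stage("center", center_at_mass(fh$mesh))
    say("mass centre at (%.3f, %.3f, %.3f) mm", cm$mass_center[1],
        cm$mass_center[2], cm$mass_center[3])
    cap <- stage("classify", classify_surfaces(cm$mesh),
                 hint = "input must contain both OES and EDJ sheets")
    cap$mass_center <- cm$mass_center
    say("segmented: %d OES / %d EDJ faces", length(cap$outer_faces),
        length(cap$inner_faces))
  }
  # --- orientation -----------------------------------------------------------
  if (!is.null(config$frame_override)) {
    frame <- config$frame_override
    say("using frame override")
  } else {
    edge <- stage("cervical_edge",
                  if (!is.null(cap$cervical_edge)) cap$cervical_edge
                  else extract_cervical_edge(cap))
    frame <- stage("frame", frame_from_cervical_edge(edge, cap))
    say("preliminary frame from cervical edge (%d points)",
        nrow(edge$points))
  }
  cap <- apply_frame(cap, frame)
  # --- curvature + occlusal contour ------------------------------------------
  curv <- stage("curvature", vertex_curvature(cap$mesh))
  occ <- stage("occlusal_contour",
               occlusal_contour_oes(cap, curvature = curv,
                                    overrides = config$contour_overrides),
               hint = "supply contour_overrides")
  say("occlusal contour: %d points, length %.2f mm", nrow(occ$points),
      contour_length(occ))
  # refine the mesio-distal axis on the occlusal contour, then re-orient
  refined <- stage("refine_frame", refine_frame_with_occlusal(
    tooth_frame(), occ))
  cap <- apply_frame(cap, refined)
  occ <- apply_frame(occ, refined)
  frame <- compose_frames(frame, refined)
  occ_edj <- stage("project_contour", project_contour_to_edj(occ, cap))
  # --- sections + midline ----------------------------------------------------
  secs <- stage("sections", section_series(cap, n = config$n_sections,
                                           contour = occ, span = config$span))
  say("%d sections over x in [%.2f, %.2f] mm", length(secs),
      secs[[1]]$x, secs[[length(secs)]]$x)
  mid <- stage("midline", midline_from_sections(
    secs, occ, overrides = config$midline_overrides,
    pit_filter = config$pit_filter, cap = cap, curvature = curv))
  mid_edj <- stage("project_midline", project_contour_to_edj(mid, cap))
  say("midline: %d points, %d section(s) skipped", nrow(mid$points),
      length(attr(mid, "skipped")))
  # --- sectors + metrics -----------------------------------------------------
  sect <- stage("sectors", segment_sectors(cap, occ, occ_edj, mid, mid_edj))
  meas <- stage("metrics", {
    ms <- lapply(c("occlusal_total", "buccal_inner_slope",
                   "lingual_inner_slope"), function(sid) {
      saet3d(SV = sector_volume(sect$oes[[sid]], cap),
             SAedj = patch_area(sect$edj[[sid]]),
             SAoes = patch_area(sect$oes[[sid]]),
             sector_id = sid)
    })
    names(ms) <- c("occlusal_total", "buccal_inner_slope",
                   "lingual_inner_slope")
    ms
  })
  report <- stage("report", build_report(meas, tooth = if (is.character(input))
    basename(input) else "synthetic"))
  say("SAET3D occlusal %.4f, buccal %.4f, lingual %.4f mm",
      meas$occlusal_total$SAET3D, meas$buccal_inner_slope$SAET3D,
      meas$lingual_inner_slope$SAET3D)
  # --- thickness map ---------------------------------------------------------
  thick <- stage("thickness", thickness_field(cap,
                                              method = config$thickness_method))
  say("thickness field: mean %.4f, max %.4f mm", thick$stats$mean,
      thick$stats$max)
  res <- structure(list(cap = cap, frame = frame, cervical_edge =
                          cap$cervical_edge,
                        occlusal_oes = occ, occlusal_edj = occ_edj,
                        midline_oes = mid, midline_edj = mid_edj,
                        sections = secs, sectors = sect,
                        measurements = meas, report = report,
                        thickness = thick, config = config, log = logline),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

# sequential composition of two frames (second applied in the coordinates
# produced by the first): p2 = R2^T (R1^T (p - o1) - o2)
compose_frames <- function(first, second) {
  R1 <- frame_rotation(first)
  R2 <- frame_rotation(second)
  R <- R1 %*% R2
  origin <- first$origin + as.vector(R1 %*% second$origin)
  tooth_frame(origin, R[, 1], R[, 2], R[, 3])
}

write_contour_csv <- function(contour, path) {
  write.csv(data.frame(x = contour$points[, 1], y = contour$points[, 2],
                       z = contour$points[, 3]),
            path, row.names = FALSE)
}

write_sections_csv <- function(sections, path) {
  rows <- list()
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    for (li in seq_along(sec$loops)) {
      lp <- sec$loops[[li]]
      n <- nrow(lp$points)
      cls <- lp$seg_class
      length(cls) <- n
      rows[[length(rows) + 1]] <-
        data.frame(section = si, section_x = sec$x, loop = li,
                   y = lp$points[, 1], z = lp$points[, 2],
                   seg_class = cls)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_frame(res$frame, fp("frame.json"))
  if (!is.null(res$cervical_edge))
    write_contour_csv(res$cervical_edge, fp("cervical_edge.csv"))
  write_contour_csv(res$occlusal_oes, fp("occlusal_contour_oes.csv"))
  write_contour_csv(res$occlusal_edj, fp("occlusal_contour_edj.csv"))
  write_contour_csv(res$midline_oes, fp("midline_oes.csv"))
  write_contour_csv(res$midline_edj, fp("midline_edj.csv"))
  write_sections_csv(res$sections, fp("sections.csv"))
  write_report(res$report, fp("report.json"))
  write_report(res$report, fp("report.csv"))
  export_colored(res$cap, res$thickness, fp("thickness_map.ply"))
  write_thickness_csv(res$thickness, fp("thickness.csv"))
  # per-face class labels of the cap
  cls <- cap_face_classes(res$cap)
  write.csv(data.frame(face = seq_along(cls), class = cls),
            fp("face_classes.csv"), row.names = FALSE)
  cfg <- res$config
  cfg$frame_override <- NULL
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], fp("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, fp("log.txt"))
  invisible(out_dir)
}
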