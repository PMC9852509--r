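# Shared fixtures and independent oracles.

# The worked limb: femoral head at the origin, horizontal plateau of
# width 70 at depth 400, ankle deviated 20 mm medially (2.86 deg
# varus), vertical cortices inset 2 mm from the plateau edges.
worked_limb <- function(ankle_x = 20) {
  hto_limb(
    femoral_head_center = c(0, 0),
    plateau_medial_edge = c(35, 400),
    plateau_lateral_edge = c(-35, 400),
    ankle_center = c(ankle_x, 800),
    medial_cortex = cbind(c(33, 33), c(400, 800)),
    lateral_cortex = cbind(c(-33, -33), c(400, 800)),
    patient_id = "worked"
  )
}

straight_limb <- function() worked_limb(ankle_x = 0)

# Raw landmark document for the worked limb in pixel units; scale px/mm
# and side are configurable, left sides are written mirrored (x -> -x)
# as they appear on the film.
worked_limb_doc <- function(px_per_mm = 2, side = "right",
                            drop = NULL, origin_px = c(500, 100)) {
  s <- if (side == "left") -1 else 1
  px <- function(x, y) c(s * x, y) * px_per_mm + origin_px
  pl <- function(x) list(px(x, 400), px(x, 800))
  doc <- list(
    schema_version = 1, patient_id = "worked", side = side, timepoint = "pre",
    calibration = list(marker_a = px(0, 0), marker_b = px(0, 100),
                       known_distance_mm = 100),
    landmarks = list(femoral_head_center = px(0, 0),
                     plateau_medial_edge = px(35, 400),
                     plateau_lateral_edge = px(-35, 400),
                     ankle_center = px(20, 800)),
    polylines = list(medial_cortex = pl(33), lateral_cortex = pl(-33))
  )
  if (!is.null(drop)) doc$landmarks[[drop]] <- NULL
  doc
}

write_limb_json <- function(doc) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# Independent oracle for circle/line intersection: dense sampling of
# the signed distance-to-circle along the line, sign changes refined
# by uniroot.  Deliberately knows nothing about the closed form.
circle_line_oracle <- function(center, radius, a, b, span = 10) {
  d <- (b - a) / sqrt(sum((b - a)^2))
  f <- function(t) sqrt(sum((a + t * d - center)^2)) - radius
  reach <- sqrt(sum((a - center)^2)) + (1 + span) * radius
  ts <- seq(-reach, reach, length.out = 20001)
  fv <- vapply(ts, f, 0)
  roots <- c()
  for (i in seq_len(length(ts) - 1)) {
    if (fv[i] == 0) roots <- c(roots, ts[i])
    else if (fv[i] * fv[i + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(ts[i], ts[i + 1]),
                                       tol = 1e-12)$root)
  }
  pts <- lapply(roots, function(t) a + t * d)
  pts[order(vapply(pts, `[[`, 0, 2L))]
}

# Random non-degenerate geometry for property tests.
random_point <- function(lim = 100) frontal_point(runif(1, -lim, lim),
                                                  runif(1, -lim, lim))
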