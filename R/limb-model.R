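# Landmark data model for one limb on a standing whole-leg AP
# radiograph, pixel-to-mm calibration, and the frontal-plane alignment
# measures (WBL ratio, mFTA, mMPTA).

#' Assemble the landmark set of one limb
#'
#' Bundles the digitized frontal-plane landmarks of a limb in the
#' canonical frame (mm, +x medial, +y distal, femoral head centre at
#' the origin by convention after [load_landmarks()]).  The knee
#' centre used by the mechanical axes is derived as the midpoint of
#' the two plateau edges.
#'
#' @param femoral_head_center,plateau_medial_edge,plateau_lateral_edge,ankle_center
#'   Frontal points (mm).
#' @param medial_cortex,lateral_cortex Cortex contours as [polyline()]s,
#'   proximal to distal.
#' @param side `"left"` or `"right"` (metadata; coordinates are always
#'   canonical).
#' @param patient_id Free-text identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param validate Check the anatomical invariants (default `TRUE`):
#'   medial plateau edge medial (+x) of the lateral edge, landmarks
#'   ordered proximal to distal, cortices starting at or proximal to
#'   their plateau edge and extending at least 60 mm distally.
#' @return An object of class `"hto_limb"`.
#' @export
hto_limb <- function(femoral_head_center, plateau_medial_edge,
                     plateau_lateral_edge, ankle_center,
                     medial_cortex, lateral_cortex,
                     side = c("right", "left"), patient_id = "anon",
                     timepoint = c("pre", "post"), validate = TRUE) {
  side <- match.arg(side)
  timepoint <- match.arg(timepoint)
  limb <- structure(list(
    femoral_head_center = as_point(femoral_head_center, "femoral_head_center"),
    plateau_medial_edge = as_point(plateau_medial_edge, "plateau_medial_edge"),
    plateau_lateral_edge = as_point(plateau_lateral_edge, "plateau_lateral_edge"),
    ankle_center = as_point(ankle_center, "ankle_center"),
    medial_cortex = polyline(medial_cortex, validate = validate),
    lateral_cortex = polyline(lateral_cortex, validate = validate),
    side = side, patient_id = as.character(patient_id), timepoint = timepoint
  ), class = "hto_limb")
  if (validate) validate_limb(limb)
  limb
}

validate_limb <- function(limb) {
  with(limb, {
    if (plateau_medial_edge[["x"]] <= plateau_lateral_edge[["x"]])
      stop("invalid limb: plateau_medial_edge must be medial (+x) of plateau_lateral_edge",
           call. = FALSE)
    if (!(ankle_center[["y"]] > plateau_medial_edge[["y"]] &&
          plateau_medial_edge[["y"]] > femoral_head_center[["y"]]))
      stop("invalid limb: expected femoral_head_center, plateau, ankle_center ordered proximal to distal",
           call. = FALSE)
    for (nm in c("medial_cortex", "lateral_cortex")) {
      pl <- limb[[nm]]
      edge <- if (nm == "medial_cortex") plateau_medial_edge else plateau_lateral_edge
      if (min(pl[, "y"]) > edge[["y"]] + 1e-9)
        stop(sprintf("invalid limb: %s must start at or proximal to the plateau", nm),
             call. = FALSE)
      if (max(pl[, "y"]) < edge[["y"]] + 60)
        stop(sprintf("invalid limb: %s must extend at least 60 mm distal to the plateau", nm),
             call. = FALSE)
    }
  })
  invisible(limb)
}

#' Knee centre of a limb
#'
#' Midpoint of the two tibial plateau edges; serves as the knee-side
#' endpoint of both the femoral and the tibial mechanical axis.
#'
#' @param limb An [hto_limb()].
#' @return A frontal point.
#' @export
knee_center <- function(limb) {
  p <- (limb$plateau_medial_edge + limb$plateau_lateral_edge) / 2
  frontal_point(p[["x"]], p[["y"]])
}

#' @export
print.hto_limb <- function(x, ...) {
  cat(sprintf("<hto_limb> patient %s, %s limb, %soperative\n",
              x$patient_id, x$side, x$timepoint))
  cat(sprintf("  femoral head (%.1f, %.1f)  plateau (%.1f..%.1f, y %.1f)  ankle (%.1f, %.1f)\n",
              x$femoral_head_center[["x"]], x$femoral_head_center[["y"]],
              x$plateau_lateral_edge[["x"]], x$plateau_medial_edge[["x"]],
              x$plateau_medial_edge[["y"]],
              x$ankle_center[["x"]], x$ankle_center[["y"]]))
  invisible(x)
}

# ---- landmark file I/O -----------------------------------------------------

required_landmarks <- c("femoral_head_center", "plateau_medial_edge",
                        "plateau_lateral_edge", "ankle_center")

#' Load a landmark file
#'
#' Reads the versioned JSON landmark format (all coordinates in
#' pixels), calibrates pixels to millimetres from the marker pair of
#' known separation, mirrors left limbs (`x -> -x`) into the canonical
#' +x-medial orientation so one code path serves both sides, and
#' translates the origin to the femoral head centre.
#'
#' The file layout is
#' \preformatted{
#' {"schema_version": 1, "patient_id": "...", "side": "left|right",
#'  "timepoint": "pre|post",
#'  "calibration": {"marker_a": [x,y], "marker_b": [x,y],
#'                  "known_distance_mm": 50},
#'  "landmarks": {"femoral_head_center": [x,y],
#'                "plateau_medial_edge": [x,y],
#'                "plateau_lateral_edge": [x,y],
#'                "ankle_center": [x,y]},
#'  "polylines": {"medial_cortex": [[x,y], ...],
#'                "lateral_cortex": [[x,y], ...]}}
#' }
#' with pixel `y` increasing distally (image rows run cranio-caudal).
#'
#' @param path Path to a landmark JSON file.
#' @return An [hto_limb()] in canonical millimetre coordinates.
#' @export
load_landmarks <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("schema_version", "patient_id", "side", "timepoint",
                  "calibration", "landmarks", "polylines"))
    if (is.null(doc[[field]]))
      stop(sprintf("landmark file invalid: missing '%s'", field), call. = FALSE)
  if (doc$schema_version != 1)
    stop(sprintf("landmark file invalid: unsupported schema_version %s",
                 doc$schema_version), call. = FALSE)
  cal <- doc$calibration
  for (field in c("marker_a", "marker_b", "known_distance_mm"))
    if (is.null(cal[[field]]))
      stop(sprintf("landmark file invalid: missing 'calibration.%s'", field),
           call. = FALSE)
  ma <- as_point(cal$marker_a, "calibration.marker_a")
  mb <- as_point(cal$marker_b, "calibration.marker_b")
  if (all(ma == mb))
    stop("landmark file invalid: calibration markers coincide", call. = FALSE)
  if (!is.finite(cal$known_distance_mm) || cal$known_distance_mm <= 0)
    stop("landmark file invalid: 'calibration.known_distance_mm' must be positive",
         call. = FALSE)
  scale <- cal$known_distance_mm / pt_dist(ma, mb)

  for (nm in required_landmarks)
    if (is.null(doc$landmarks[[nm]]))
      stop(sprintf("landmark file invalid: missing landmark '%s'", nm),
           call. = FALSE)
  for (nm in c("medial_cortex", "lateral_cortex"))
    if (is.null(doc$polylines[[nm]]))
      stop(sprintf("landmark file invalid: missing polyline '%s'", nm),
           call. = FALSE)

  mirror <- identical(doc$side, "left")
  tx <- function(p) {
    p <- as.numeric(p) * scale
    if (mirror) p[1L] <- -p[1L]
    p
  }
  pts <- lapply(doc$landmarks[required_landmarks], tx)
  origin <- pts$femoral_head_center
  pts <- lapply(pts, function(p) p - origin)
  tx_pl <- function(m) {
    m <- as.matrix(m) * scale
    if (mirror) m[, 1L] <- -m[, 1L]
    sweep(m, 2L, origin)
  }
  hto_limb(
    femoral_head_center = pts$femoral_head_center,
    plateau_medial_edge = pts$plateau_medial_edge,
    plateau_lateral_edge = pts$plateau_lateral_edge,
    ankle_center = pts$ankle_center,
    medial_cortex = tx_pl(doc$polylines$medial_cortex),
    lateral_cortex = tx_pl(doc$polylines$lateral_cortex),
    side = doc$side, patient_id = doc$patient_id, timepoint = doc$timepoint
  )
}

#' Write a limb to a landmark file
#'
#' Serializes a canonical-frame limb to the JSON landmark format with
#' an identity calibration (markers 100 px = 100 mm apart), so the file
#' round-trips through [load_landmarks()].  Left limbs are written in
#' image orientation (x negated) because the loader mirrors them back.
#'
#' @param limb An [hto_limb()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(limb, path) {
  sgn <- if (limb$side == "left") -1 else 1
  as_px <- function(p) c(sgn * p[["x"]], p[["y"]])
  pl_px <- function(m) {
    m <- unclass(m)
    lapply(seq_len(nrow(m)), function(i) c(sgn * m[i, 1L], m[i, 2L]))
  }
  doc <- list(
    schema_version = 1,
    patient_id = limb$patient_id,
    side = limb$side,
    timepoint = limb$timepoint,
    calibration = list(marker_a = c(0, 0), marker_b = c(100, 0),
                       known_distance_mm = 100),
    landmarks = lapply(limb[required_landmarks], as_px),
    polylines = list(medial_cortex = pl_px(limb$medial_cortex),
                     lateral_cortex = pl_px(limb$lateral_cortex))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- alignment measures ----------------------------------------------------

#' Weight-bearing-line ratio
#'
#' Where a line crosses the tibial plateau, as a percentage of plateau
#' width counted from the medial edge: 0 at the medial edge, 100 at
#' the lateral edge.  The crossing is taken on the *infinite* line
#' through the two plateau edges, so lines passing medial of the
#' plateau give negative ratios and lateral ones give values above
#' 100 (severe varus knees genuinely measure below 0).
#'
#' @param limb An [hto_limb()].
#' @param line_through A list or pair of two points defining the line
#'   (default: the actual weight-bearing line, femoral head centre to
#'   ankle centre).
#' @return The ratio in percent.
#' @export
wbl_ratio <- function(limb,
                      line_through = list(limb$femoral_head_center,
                                          limb$ankle_center)) {
  a <- as_point(line_through[[1L]], "line point")
  b <- as_point(line_through[[2L]], "line point")
  m <- limb$plateau_medial_edge
  l <- limb$plateau_lateral_edge
  x <- line_line_intersection(a, b, m, l)
  w <- l - m
  100 * sum((x - m) * w) / sum(w * w)
}

#' Mechanical femorotibial angle (mFTA)
#'
#' Deviation from a straight (180 degree) mechanical axis, measured at
#' the knee centre between the femoral axis (knee centre to femoral
#' head) and the tibial axis (knee centre to ankle centre).  Signed:
#' positive when the ankle deviates medially relative to the femoral
#' mechanical axis (varus), negative for valgus, 0 for a collinear
#' limb.
#'
#' @param limb An [hto_limb()].
#' @return Signed degrees.
#' @export
measure_mfta <- function(limb) {
  f <- limb$femoral_head_center
  k <- knee_center(limb)
  c1 <- limb$ankle_center
  if (pt_dist(f, k) == 0 || pt_dist(k, c1) == 0)
    stop("degenerate limb: coincident landmarks for mFTA", call. = FALSE)
  dev <- 180 - angle_at_vertex(k, f, c1)
  # side of the ankle relative to the femoral axis F->K extended:
  # medial (+x-ward) deviation is varus
  d <- k - f
  v <- c1 - f
  cross <- d[["x"]] * v[["y"]] - d[["y"]] * v[["x"]]
  if (cross == 0) 0 else dev * (if (cross < 0) 1 else -1)
}

#' Mechanical medial proximal tibial angle (mMPTA)
#'
#' The medial-side angle between the tibial plateau joint line and the
#' tibial mechanical axis (knee centre to ankle centre), in degrees;
#' about 87--90 in a normal knee.
#'
#' @param limb An [hto_limb()].
#' @return Degrees in `(0, 180)`.
#' @export
measure_mpta <- function(limb) {
  k <- knee_center(limb)
  m <- limb$plateau_medial_edge
  c1 <- limb$ankle_center
  if (pt_dist(limb$plateau_medial_edge, limb$plateau_lateral_edge) == 0 ||
      pt_dist(k, c1) == 0)
    stop("degenerate limb: coincident landmarks for mMPTA", call. = FALSE)
  angle_at_vertex(k, m, c1)
}

#' All alignment measures of a limb
#'
#' Bundles the WBL ratio (along the actual weight-bearing line,
#' femoral head centre to ankle centre), the signed mFTA and the
#' mMPTA.
#'
#' @param limb An [hto_limb()].
#' @return An object of class `"hto_measures"`: a list with elements
#'   `wbl_ratio` (percent), `mfta` (signed degrees, varus positive)
#'   and `mpta` (degrees).
#' @export
measure_all <- function(limb) {
  m <- list(wbl_ratio = wbl_ratio(limb),
            mfta = measure_mfta(limb),
            mpta = measure_mpta(limb))
  if (!(m$mpta > 0 && m$mpta < 180))
    stop("degenerate limb: mMPTA outside (0, 180)", call. = FALSE)
  structure(m, class = "hto_measures")
}

#' @export
print.hto_measures <- function(x, ...) {
  lab <- if (x$mfta >= 0) sprintf("varus %.1f°", x$mfta)
         else sprintf("valgus %.1f°", -x$mfta)
  cat(sprintf("WBL ratio %.1f%%  mFTA %s  mMPTA %.1f°\n",
              x$wbl_ratio, lab, x$mpta))
  invisible(x)
}
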