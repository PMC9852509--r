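# The five-step concentric-circle planning construction for medial
# open-wedge HTO:
#   1. target weight-bearing line L1 from the femoral head through the
#      target point O on the plateau;
#   2. lateral hinge H, 15 mm distal to the lateral plateau and 8 mm
#      medial to the lateral cortex;
#   3. osteotomy site S, where the 40-mm circle about the medial
#      plateau edge meets the medial cortex;
#   4. correction angle theta at H between the ankle centre C1 and the
#      image I of the ankle on L1 (circle about H through C1);
#   5. correction gap, the chord PG of theta at radius |HS|.

#' Planning parameters
#'
#' Tunable constants of the concentric-circle construction.  Defaults
#' are the standard values: target crossing at 50 % of the plateau,
#' hinge 15 mm distal to the lateral plateau and 8 mm medial to the
#' lateral cortex, 40-mm osteotomy circle about the medial plateau
#' edge, 0.9-mm saw blade added to the planned gap for the
#' intraoperative tape length, and an acceptable postoperative band of
#' the target ratio plus or minus 5 percentage points.
#'
#' @param target_ratio Target WBL crossing in percent of plateau width
#'   from the medial edge, or `"fujisawa"` for the classical 62.5 %
#'   overcorrection point.
#' @param hinge_distal_offset mm distal to the lateral plateau edge.
#' @param hinge_medial_offset mm medial (horizontal) from the lateral
#'   cortex.
#' @param osteotomy_radius mm; radius of the circle about the medial
#'   plateau edge that locates the osteotomy site.
#' @param blade_thickness mm; saw-blade thickness added to the planned
#'   gap.
#' @param acceptable_halfwidth Percentage points; half-width of the
#'   acceptable postoperative WBL band around `target_ratio`.
#' @return An object of class `"hto_params"`.
#' @export
#' @examples
#' plan_parameters()
#' plan_parameters(target_ratio = "fujisawa")
plan_parameters <- function(target_ratio = 50,
                            hinge_distal_offset = 15,
                            hinge_medial_offset = 8,
                            osteotomy_radius = 40,
                            blade_thickness = 0.9,
                            acceptable_halfwidth = 5) {
  if (identical(target_ratio, "fujisawa")) target_ratio <- 62.5
  target_ratio <- as.numeric(target_ratio)
  stopifnot(is.finite(target_ratio), target_ratio > 0, target_ratio < 100,
            hinge_distal_offset > 0, hinge_medial_offset > 0,
            osteotomy_radius > 0, blade_thickness > 0,
            acceptable_halfwidth > 0)
  structure(list(target_ratio = target_ratio,
                 hinge_distal_offset = hinge_distal_offset,
                 hinge_medial_offset = hinge_medial_offset,
                 osteotomy_radius = osteotomy_radius,
                 blade_thickness = blade_thickness,
                 acceptable_halfwidth = acceptable_halfwidth),
            class = "hto_params")
}

#' Target weight-bearing line
#'
#' Step 1: place the target point `O` at `target_ratio` percent of the
#' plateau width from the medial edge and draw the line `L1` from the
#' femoral head centre through `O`, extended distally.
#'
#' @param limb An [hto_limb()].
#' @param params [plan_parameters()].
#' @return A list with `O` (frontal point) and `L1`, a list of two
#'   points (femoral head centre, O) defining the infinite line.
#' @export
target_wbl_line <- function(limb, params = plan_parameters()) {
  m <- limb$plateau_medial_edge
  l <- limb$plateau_lateral_edge
  o <- m + (params$target_ratio / 100) * (l - m)
  o <- frontal_point(o[["x"]], o[["y"]])
  list(O = o, L1 = list(limb$femoral_head_center, o))
}

#' Locate the lateral hinge point
#'
#' Step 2: the hinge `H` sits `hinge_distal_offset` mm distal to the
#' lateral plateau edge, and `hinge_medial_offset` mm medial
#' (horizontally) of the lateral cortex at that depth.
#'
#' @inheritParams target_wbl_line
#' @return The hinge point `H`.
#' @export
locate_hinge <- function(limb, params = plan_parameters()) {
  y <- limb$plateau_lateral_edge[["y"]] + params$hinge_distal_offset
  x_cortex <- polyline_x_at(limb$lateral_cortex, y, name = "lateral cortex")
  frontal_point(x_cortex + params$hinge_medial_offset, y)
}

#' Locate the osteotomy site
#'
#' Step 3: the osteotomy site `S` is the distal intersection of the
#' circle of radius `osteotomy_radius` about the medial plateau edge
#' with the medial cortex.
#'
#' @inheritParams target_wbl_line
#' @return The osteotomy site `S`.
#' @export
locate_osteotomy_site <- function(limb, params = plan_parameters()) {
  circle_polyline_intersection(limb$plateau_medial_edge,
                               params$osteotomy_radius,
                               limb$medial_cortex,
                               branch = "distal", name = "medial cortex")
}

#' Correction angle at the hinge
#'
#' Step 4: the circle about the hinge `H` through the ankle centre
#' `C1` cuts the target line `L1` at the ankle image `I` (distal
#' branch); the correction angle is the angle `C1-H-I`.
#'
#' @param limb An [hto_limb()].
#' @param H Hinge point from [locate_hinge()].
#' @param L1 Target line from [target_wbl_line()] (list of two points).
#' @return A list with `theta` (degrees, `>= 0`) and `I`.
#' @export
correction_angle <- function(limb, H, L1) {
  c1 <- limb$ankle_center
  r <- pt_dist(H, c1)
  pts <- circle_line_intersections(H, r, L1[[1L]], L1[[2L]])
  # distal branch: the crossing at ankle depth, not the proximal one
  pts <- Filter(function(p) p[["y"]] > knee_center(limb)[["y"]], pts)
  if (length(pts) == 0L)
    stop(sprintf(paste0("target unreachable: the hinge circle through the ankle ",
                        "does not meet the target line distally ",
                        "(limb mFTA %.2f deg)"), measure_mfta(limb)),
         call. = FALSE)
  i <- pts[[which.max(vapply(pts, `[[`, 0, "y"))]]
  theta <- if (pt_dist(c1, i) == 0) 0 else angle_at_vertex(H, c1, i)
  list(theta = theta, I = i)
}

#' Correction gap (chord construction)
#'
#' Step 5: the circle about the hinge through the osteotomy site `S`
#' cuts the ray to the ankle centre at `P` and the ray to the ankle
#' image at `G`; the planned correction gap is the distance `PG`,
#' i.e. the chord of the correction angle at radius `|HS|`.  The
#' intraoperative gap adds the saw-blade thickness (the length of the
#' tape cut in theatre).
#'
#' @param H Hinge point.
#' @param S Osteotomy site.
#' @param C1 Ankle centre.
#' @param I Ankle image on the target line.
#' @param params [plan_parameters()].
#' @return A list with `gap`, `intraoperative_gap` (mm) and the chord
#'   endpoints `P`, `G`.
#' @export
correction_gap <- function(H, S, C1, I, params = plan_parameters()) {
  r <- pt_dist(H, S)
  on_ray <- function(q) {
    v <- q - H
    p <- H + r * v / pt_dist(H, q)
    frontal_point(p[["x"]], p[["y"]])
  }
  p <- on_ray(C1)
  g <- on_ray(I)
  gap <- pt_dist(p, g)
  list(gap = gap, intraoperative_gap = gap + params$blade_thickness,
       P = p, G = g)
}

#' Build the full osteotomy plan
#'
#' Composes the five construction steps into an `"hto_plan"`.  Only
#' varus limbs (weight-bearing line medial of the target point) are
#' plannable with a medial opening wedge; a limb already on target
#' yields a valid zero-angle plan flagged *no correction needed*, and
#' a valgus limb (WBL lateral of target) is an error.  Gaps above
#' 15 mm are flagged `graft_recommended` (structural bone graft is
#' conventional for such openings); the flag is informational.
#'
#' @inheritParams target_wbl_line
#' @return An object of class `"hto_plan"`: a list with the target
#'   point `O`, target line `L1`, hinge `H`, osteotomy site `S`, ankle
#'   image `I`, chord endpoints `P` and `G`, `theta` (degrees),
#'   `rotation` (signed degrees, the rigid rotation taking the ankle
#'   centre onto `I`), `gap` and `intraoperative_gap` (mm), the radii
#'   `radius_ankle` and `radius_osteotomy` (mm), and the flags
#'   `no_correction_needed` and `graft_recommended`.
#' @export
make_plan <- function(limb, params = plan_parameters()) {
  validate_limb(limb)
  preop_ratio <- wbl_ratio(limb)
  if (preop_ratio > params$target_ratio + 1e-9)
    stop(sprintf(paste0("target unreachable by medial opening wedge: ",
                        "preoperative WBL ratio %.1f%% is already lateral ",
                        "of the %.1f%% target"),
                 preop_ratio, params$target_ratio), call. = FALSE)
  tw <- target_wbl_line(limb, params)
  H <- tryCatch(locate_hinge(limb, params),
                error = function(e) stop("hinge construction failed: ",
                                         conditionMessage(e), call. = FALSE))
  S <- tryCatch(locate_osteotomy_site(limb, params),
                error = function(e) stop("osteotomy-site construction failed: ",
                                         conditionMessage(e), call. = FALSE))
  ca <- correction_angle(limb, H, tw$L1)
  cg <- correction_gap(H, S, limb$ankle_center, ca$I, params)
  structure(list(
    O = tw$O, L1 = tw$L1, H = H, S = S, I = ca$I,
    P = cg$P, G = cg$G,
    theta = ca$theta,
    rotation = signed_angle_at_vertex(H, limb$ankle_center, ca$I),
    gap = cg$gap,
    intraoperative_gap = cg$intraoperative_gap,
    radius_ankle = pt_dist(H, limb$ankle_center),
    radius_osteotomy = pt_dist(H, S),
    no_correction_needed = ca$theta < 1e-9,
    graft_recommended = cg$gap > 15,
    params = params
  ), class = "hto_plan")
}

#' @export
print.hto_plan <- function(x, ...) {
  cat("<hto_plan>\n")
  cat(sprintf("  hinge H            (%.2f, %.2f) mm\n", x$H[["x"]], x$H[["y"]]))
  cat(sprintf("  osteotomy site S   (%.2f, %.2f) mm\n", x$S[["x"]], x$S[["y"]]))
  cat(sprintf("  correction angle   %.2f deg\n", x$theta))
  cat(sprintf("  correction gap     %.2f mm\n", x$gap))
  cat(sprintf("  intraoperative gap %.2f mm (incl. %.1f mm blade)\n",
              x$intraoperative_gap, x$params$blade_thickness))
  if (x$no_correction_needed) cat("  note: no correction needed\n")
  if (x$graft_recommended) cat("  note: gap > 15 mm, structural graft recommended\n")
  invisible(x)
}

#' Classify a postoperative correction
#'
#' Classifies a postoperative WBL ratio against the acceptable band
#' `target_ratio` plus or minus `acceptable_halfwidth`: strictly below
#' the band is under-correction, strictly above is over-correction,
#' and the boundaries count as acceptable.
#'
#' @param postop_ratio Postoperative WBL ratio(s) in percent
#'   (vectorized).
#' @param params [plan_parameters()].
#' @return A character vector with levels `"under"`, `"acceptable"`,
#'   `"over"`.
#' @export
#' @examples
#' classify_correction(c(41.8, 49.3, 58.1))
classify_correction <- function(postop_ratio, params = plan_parameters()) {
  lo <- params$target_ratio - params$acceptable_halfwidth
  hi <- params$target_ratio + params$acceptable_halfwidth
  ifelse(postop_ratio < lo, "under",
         ifelse(postop_ratio > hi, "over", "acceptable"))
}
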