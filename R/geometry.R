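# Exact 2D primitives in the canonical frontal frame:
# millimetres, +x medial, +y distal.  Points are length-2 numeric
# vectors c(x, y); polylines are n x 2 matrices ordered proximal to
# distal (y strictly increasing).

#' Construct a frontal-plane point
#'
#' A point in the canonical frontal radiographic frame: millimetres,
#' `+x` medial, `+y` distal.  All construction points of the planner
#' (femoral head centre, hinge, osteotomy site, chord endpoints, ...)
#' are `frontal_point`s.
#'
#' @param x,y Coordinates in millimetres; must be finite.
#' @return A named numeric vector `c(x, y)`.
#' @export
#' @examples
#' frontal_point(-25, 415)
frontal_point <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != 1L || length(y) != 1L || !is.finite(x) || !is.finite(y))
    stop("frontal_point coordinates must be single finite numbers", call. = FALSE)
  c(x = x, y = y)
}

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p)))
    stop(sprintf("%s must be two finite coordinates", what), call. = FALSE)
  c(x = p[1L], y = p[2L])
}

pt_dist <- function(a, b) sqrt(sum((a - b)^2))

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Construct a polyline (bone cortex contour)
#'
#' An ordered proximal-to-distal sequence of frontal-plane points with
#' strictly increasing depth `y`, so the contour is single-valued in
#' depth.  Used for the medial and lateral tibial cortex.
#'
#' @param coords A matrix or data frame with two columns (x, y) in mm,
#'   or a list of length-2 points.
#' @param validate Check the ordering invariant (default `TRUE`).
#' @return An n x 2 numeric matrix with columns `x`, `y` and class
#'   `"hto_polyline"`.
#' @export
#' @examples
#' polyline(cbind(x = c(33, 33), y = c(400, 800)))
polyline <- function(coords, validate = TRUE) {
  if (is.list(coords) && !is.data.frame(coords))
    coords <- do.call(rbind, lapply(coords, as.numeric))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("a polyline needs two coordinate columns (x, y)", call. = FALSE)
  colnames(coords) <- c("x", "y")
  if (validate) {
    if (nrow(coords) < 2L)
      stop("a polyline needs at least 2 points", call. = FALSE)
    if (!all(is.finite(coords)))
      stop("polyline coordinates must be finite", call. = FALSE)
    if (any(diff(coords[, "y"]) <= 0))
      stop("polyline y must increase strictly from proximal to distal",
           call. = FALSE)
  }
  structure(coords, class = c("hto_polyline", class(coords)))
}

#' Intersect a circle with an infinite line
#'
#' Solves for the 0, 1 or 2 points where the circle of given centre and
#' radius meets the infinite line through `a` and `b`.  This is the
#' primitive behind the planner's concentric-circle constructions
#' (e.g. the circle about the hinge through the ankle centre, cut by
#' the target weight-bearing line).
#'
#' @param center Circle centre (frontal point, mm).
#' @param radius Circle radius in mm, `> 0`.
#' @param a,b Two distinct points defining the infinite line.
#' @return A list of 0--2 points ordered by increasing `y`
#'   (proximal first).  No intersection is an empty list, not an error.
#' @export
#' @examples
#' circle_line_intersections(frontal_point(0, 0), 1,
#'                           frontal_point(0, -5), frontal_point(0, 5))
circle_line_intersections <- function(center, radius, a, b) {
  center <- as_point(center, "center"); a <- as_point(a, "a"); b <- as_point(b, "b")
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be a positive length", call. = FALSE)
  d <- b - a
  if (all(d == 0))
    stop("degenerate line: a and b coincide", call. = FALSE)
  # |a + t d - c|^2 = r^2, quadratic in t
  f <- a - center
  A <- sum(d * d)
  B <- 2 * sum(d * f)
  C <- sum(f * f) - radius^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(list())
  s <- sqrt(disc)
  ts <- if (s == 0) (-B / (2 * A)) else c((-B - s) / (2 * A), (-B + s) / (2 * A))
  pts <- lapply(ts, function(t) a + t * d)
  pts <- pts[order(vapply(pts, `[[`, 0, "y"))]
  lapply(pts, function(p) frontal_point(p[["x"]], p[["y"]]))
}

#' Intersect two infinite lines
#'
#' @param a1,a2 Two distinct points on the first line.
#' @param b1,b2 Two distinct points on the second line.
#' @return The intersection point; an error for parallel lines.
#' @export
line_line_intersection <- function(a1, a2, b1, b2) {
  a1 <- as_point(a1); a2 <- as_point(a2); b1 <- as_point(b1); b2 <- as_point(b2)
  u <- a2 - a1; v <- b2 - b1
  if (all(u == 0) || all(v == 0))
    stop("degenerate line: coincident defining points", call. = FALSE)
  den <- u[["x"]] * v[["y"]] - u[["y"]] * v[["x"]]
  scale <- max(abs(c(u, v)))
  if (abs(den) <= 1e-12 * scale^2)
    stop("lines are parallel: no unique intersection", call. = FALSE)
  w <- b1 - a1
  t <- (w[["x"]] * v[["y"]] - w[["y"]] * v[["x"]]) / den
  p <- a1 + t * u
  frontal_point(p[["x"]], p[["y"]])
}

#' Unsigned angle at a vertex
#'
#' The angle in degrees, in `[0, 180]`, between the rays
#' `vertex -> p1` and `vertex -> p2`.  This is how the planner reads
#' off the correction angle at the hinge between the ankle-centre ray
#' and the target-line ray.
#'
#' @param vertex Apex of the angle.
#' @param p1,p2 Points defining the two rays; must differ from `vertex`.
#' @return Angle in degrees.
#' @export
#' @examples
#' angle_at_vertex(frontal_point(0, 0), frontal_point(1, 0), frontal_point(0, 1))
angle_at_vertex <- function(vertex, p1, p2) {
  vertex <- as_point(vertex, "vertex")
  u <- as_point(p1, "p1") - vertex
  w <- as_point(p2, "p2") - vertex
  if (all(u == 0) || all(w == 0))
    stop("zero-length ray: point coincides with the vertex", call. = FALSE)
  # atan2 form is stable for tiny and near-straight angles
  cross <- u[["x"]] * w[["y"]] - u[["y"]] * w[["x"]]
  dot <- sum(u * w)
  rad2deg(atan2(abs(cross), dot))
}

#' Signed angle from one ray to another
#'
#' Counter-clockwise-positive angle in degrees, in `(-180, 180]`, from
#' ray `vertex -> p1` to ray `vertex -> p2` in the canonical frame.
#' Used to orient the opening-wedge rotation.
#'
#' @inheritParams angle_at_vertex
#' @return Signed angle in degrees.
#' @export
signed_angle_at_vertex <- function(vertex, p1, p2) {
  vertex <- as_point(vertex, "vertex")
  u <- as_point(p1, "p1") - vertex
  w <- as_point(p2, "p2") - vertex
  if (all(u == 0) || all(w == 0))
    stop("zero-length ray: point coincides with the vertex", call. = FALSE)
  rad2deg(atan2(u[["x"]] * w[["y"]] - u[["y"]] * w[["x"]], sum(u * w)))
}

#' Rotate a point about a centre
#'
#' Rigid rotation, counter-clockwise for positive angles in the
#' canonical frame.  Realizes the opening-wedge rotation of the distal
#' limb about the lateral hinge.
#'
#' @param p Point to rotate.
#' @param center Centre of rotation.
#' @param angle Signed angle in degrees.
#' @return The rotated point.
#' @export
#' @examples
#' rotate_about(frontal_point(1, 0), frontal_point(0, 0), 90)
rotate_about <- function(p, center, angle) {
  p <- as_point(p, "p"); center <- as_point(center, "center")
  a <- deg2rad(angle)
  v <- p - center
  frontal_point(center[["x"]] + cos(a) * v[["x"]] - sin(a) * v[["y"]],
                center[["y"]] + sin(a) * v[["x"]] + cos(a) * v[["y"]])
}

#' Chord length subtended by an angle
#'
#' Length of the chord of a circle of the given radius subtending the
#' given central angle: `2 * radius * sin(angle / 2)`.  The predicted
#' correction gap is the chord of the correction angle at the
#' hinge-to-osteotomy-site radius.
#'
#' @param radius Radius in mm, `>= 0`.
#' @param angle Central angle in degrees, in `[0, 180]`.
#' @return Chord length in mm.
#' @export
#' @examples
#' chord_length(63.14, 2.97)
chord_length <- function(radius, angle) {
  if (!is.finite(radius) || radius < 0)
    stop("radius must be non-negative", call. = FALSE)
  if (!is.finite(angle) || angle < 0 || angle > 180)
    stop("angle must lie in [0, 180] degrees", call. = FALSE)
  2 * radius * sin(deg2rad(angle) / 2)
}

#' Intersect a circle with a polyline and select a branch
#'
#' Intersects the circle with every segment of the polyline and returns
#' the single crossing with smallest (`"proximal"`) or largest
#' (`"distal"`) depth `y`.  The planner uses this to drop the
#' 40-mm circle about the medial plateau edge onto the medial cortex,
#' which marks the osteotomy site.
#'
#' @param center Circle centre.
#' @param radius Circle radius in mm, `> 0`.
#' @param pl A [polyline()].
#' @param branch `"proximal"` or `"distal"`: which crossing to return.
#' @param name Label used in the error message when the construction
#'   fails (no crossing).
#' @return The selected intersection point.
#' @export
circle_polyline_intersection <- function(center, radius, pl,
                                         branch = c("distal", "proximal"),
                                         name = "polyline") {
  branch <- match.arg(branch)
  center <- as_point(center, "center")
  if (!is.finite(radius) || radius <= 0)
    stop(sprintf("construction failed: non-positive circle radius against %s", name),
         call. = FALSE)
  pl <- unclass(pl)
  hits <- list()
  for (i in seq_len(nrow(pl) - 1L)) {
    a <- c(x = pl[i, 1L], y = pl[i, 2L])
    b <- c(x = pl[i + 1L, 1L], y = pl[i + 1L, 2L])
    cand <- circle_line_intersections(center, radius, a, b)
    seg <- b - a
    len2 <- sum(seg * seg)
    for (p in cand) {
      t <- sum((p - a) * seg) / len2
      if (t >= -1e-12 && t <= 1 + 1e-12) hits[[length(hits) + 1L]] <- p
    }
  }
  if (length(hits) == 0L)
    stop(sprintf("construction failed: circle does not intersect %s", name),
         call. = FALSE)
  ys <- vapply(hits, `[[`, 0, "y")
  hits[[if (branch == "proximal") which.min(ys) else which.max(ys)]]
}

#' Interpolated x-coordinate of a polyline at a given depth
#'
#' Linear interpolation of the cortex contour at depth `y`; used to
#' read the lateral cortex position at the hinge depth.
#'
#' @param pl A [polyline()].
#' @param y Depth in mm; must lie within the polyline's depth range.
#' @param name Label for error messages.
#' @return The interpolated x in mm.
#' @export
polyline_x_at <- function(pl, y, name = "polyline") {
  pl <- unclass(pl)
  ys <- pl[, 2L]
  if (y < min(ys) - 1e-9 || y > max(ys) + 1e-9)
    stop(sprintf("construction failed: %s does not cover depth y = %g mm", name, y),
         call. = FALSE)
  stats::approx(ys, pl[, 1L], xout = y, rule = 1)$y
}
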