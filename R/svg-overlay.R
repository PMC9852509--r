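# Minimal SVG writer for plan overlays.  The output is plain SVG 1.1
# markup: cortex contours, the target weight-bearing line, the two
# planning circles, and the labelled construction points.

svg_num <- function(x) formatC(x, format = "fg", digits = 6)

#' Write an SVG overlay of a plan
#'
#' Draws the limb (cortex contours, plateau, mechanical axis
#' landmarks) together with the plan's construction: the target line
#' L1, the hinge circle through the ankle centre, the osteotomy
#' circle, and the labelled points H, S, I, O, P, G.  Coordinates are
#' the canonical millimetre frame, 1 SVG user unit = 1 mm, with x
#' flipped so that medial appears on the left as on an AP radiograph
#' of a right limb.
#'
#' @param limb The planned [hto_limb()].
#' @param plan The [make_plan()] result.
#' @param path Output path for the `.svg` file.
#' @return `path`, invisibly.
#' @export
plan_svg <- function(limb, plan, path) {
  pts <- rbind(limb$femoral_head_center, limb$plateau_medial_edge,
               limb$plateau_lateral_edge, limb$ankle_center,
               unclass(limb$medial_cortex), unclass(limb$lateral_cortex),
               plan$H, plan$S, plan$I, plan$O)
  pad <- 30
  xr <- range(-pts[, 1L]) + c(-pad, pad)   # mirror x for display
  yr <- range(pts[, 2L]) + c(-pad, pad)
  X <- function(p) -p[[1L]] - xr[1L]
  Y <- function(p) p[[2L]] - yr[1L]
  line <- function(a, b, col, w = 0.8, dash = NULL)
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
            svg_num(X(a)), svg_num(Y(a)), svg_num(X(b)), svg_num(Y(b)), col, w,
            if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash))
  circ <- function(c, r, col)
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="0.6"/>',
            svg_num(X(c)), svg_num(Y(c)), svg_num(r), col)
  dot <- function(p, label, col = "black") c(
    sprintf('<circle cx="%s" cy="%s" r="1.6" fill="%s"/>',
            svg_num(X(p)), svg_num(Y(p)), col),
    sprintf('<text x="%s" y="%s" font-size="9" fill="%s">%s</text>',
            svg_num(X(p) + 3), svg_num(Y(p) - 3), col, label))
  poly <- function(m, col) {
    m <- unclass(m)
    sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="1"/>',
            paste(sprintf("%s,%s", svg_num(-m[, 1L] - xr[1L]),
                          svg_num(m[, 2L] - yr[1L])), collapse = " "), col)
  }
  # extend L1 a little beyond the ankle image for display
  l1_end <- plan$L1[[1L]] + 1.1 * (plan$I - plan$L1[[1L]])
  body <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%smm" height="%smm" viewBox="0 0 %s %s">',
            svg_num(diff(xr)), svg_num(diff(yr)), svg_num(diff(xr)), svg_num(diff(yr))),
    '<rect width="100%" height="100%" fill="white"/>',
    poly(limb$medial_cortex, "#777777"),
    poly(limb$lateral_cortex, "#777777"),
    line(limb$plateau_medial_edge, limb$plateau_lateral_edge, "#333333", 1.2),
    line(limb$femoral_head_center, l1_end, "#1f77b4", 0.8, dash = "4 2"),
    line(plan$H, limb$ankle_center, "#2ca02c", 0.6),
    line(plan$H, plan$I, "#2ca02c", 0.6),
    line(plan$P, plan$G, "#d62728", 1.2),
    circ(plan$H, plan$radius_ankle, "#9467bd"),
    circ(plan$H, plan$radius_osteotomy, "#9467bd"),
    circ(limb$plateau_medial_edge, plan$params$osteotomy_radius, "#8c564b"),
    dot(limb$femoral_head_center, "F"),
    dot(limb$ankle_center, "C1"),
    dot(limb$plateau_medial_edge, "M"),
    dot(plan$O, "O", "#1f77b4"),
    dot(plan$H, "H", "#2ca02c"),
    dot(plan$S, "S", "#d62728"),
    dot(plan$I, "I", "#1f77b4"),
    dot(plan$P, "P", "#d62728"),
    dot(plan$G, "G", "#d62728"),
    sprintf('<text x="5" y="12" font-size="10">theta = %.2f deg, gap = %.2f mm (intraop %.2f mm)</text>',
            plan$theta, plan$gap, plan$intraoperative_gap),
    '</svg>')
  writeLines(body, path)
  invisible(path)
}
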