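# Synthetic limb generator, landmark-noise model, simulated execution
# of a plan (rigid rotation of the distal segment about the hinge) and
# Monte-Carlo accuracy studies.

#' Specification of a synthetic limb
#'
#' Parameters of the frontal-plane stick-and-contour limb generator.
#' The varus deformity is placed entirely in the proximal tibia (an
#' MPTA deficit), matching the indication for high tibial osteotomy:
#' the femoral axis is vertical, the plateau horizontal, and the ankle
#' deviates medially by `tibia_length * tan(varus_angle)`.  Lengths
#' are craniocaudal extents in mm.
#'
#' @param femur_length Femoral head centre to knee centre, mm.
#' @param tibia_length Knee centre to ankle centre (vertical extent), mm.
#' @param plateau_width Tibial plateau width, mm.
#' @param varus_angle Tibial mechanical-axis deviation in degrees,
#'   `0 <= varus_angle < 15` (the HTO indication covers varus below
#'   15 degrees).
#' @param cortex_inset Horizontal distance from each plateau edge to
#'   its cortex line, mm.
#' @param cortex_flare Dimensionless metaphyseal taper: extra outward
#'   cortex offset per mm of proximity to the plateau over the top
#'   40 mm (0 = straight cortices).
#' @param noise_sigma Isotropic Gaussian landmark noise, mm per
#'   coordinate (0 = exact landmarks).
#' @param seed Integer RNG seed for the noise; required when
#'   `noise_sigma > 0`.
#' @return An object of class `"hto_limb_spec"`.
#' @export
synthetic_limb_spec <- function(femur_length = 400, tibia_length = 400,
                                plateau_width = 70, varus_angle = 6.4,
                                cortex_inset = 2, cortex_flare = 0,
                                noise_sigma = 0, seed = NULL) {
  stopifnot(femur_length > 0, tibia_length > 0, plateau_width > 0,
            cortex_inset >= 0, cortex_inset < plateau_width / 2,
            cortex_flare >= 0, noise_sigma >= 0)
  if (!is.finite(varus_angle) || varus_angle < 0 || varus_angle >= 15)
    stop("varus_angle must lie in [0, 15) degrees", call. = FALSE)
  if (noise_sigma > 0 && is.null(seed))
    stop("a seed is required when noise_sigma > 0", call. = FALSE)
  structure(list(femur_length = femur_length, tibia_length = tibia_length,
                 plateau_width = plateau_width, varus_angle = varus_angle,
                 cortex_inset = cortex_inset, cortex_flare = cortex_flare,
                 noise_sigma = noise_sigma, seed = seed),
            class = "hto_limb_spec")
}

flare_zone_mm <- 40

#' Generate a synthetic limb
#'
#' Builds a canonical-frame limb from a [synthetic_limb_spec()]:
#' femoral head at the origin, vertical femur, horizontal plateau of
#' the given width, ankle deviated medially by
#' `tibia_length * tan(varus_angle)`, and cortex polylines inset from
#' the plateau edges with optional metaphyseal flare.  A noiseless
#' limb measures back exactly: `mFTA = varus_angle`,
#' `mMPTA = 90 - varus_angle`.  With `noise_sigma > 0` each landmark
#' is perturbed by independent isotropic Gaussian noise and each
#' cortex polyline by a single rigid Gaussian offset; deterministic
#' given the seed.
#'
#' @param spec A [synthetic_limb_spec()].
#' @param patient_id,side,timepoint Metadata for the generated limb.
#' @return An [hto_limb()].
#' @export
#' @examples
#' measure_all(generate_limb(synthetic_limb_spec(varus_angle = 0)))
generate_limb <- function(spec, patient_id = "synthetic", side = "right",
                          timepoint = "pre") {
  stopifnot(inherits(spec, "hto_limb_spec"))
  half <- spec$plateau_width / 2
  y_knee <- spec$femur_length
  y_ankle <- spec$femur_length + spec$tibia_length
  ankle_x <- spec$tibia_length * tan(deg2rad(spec$varus_angle))

  cortex <- function(sign) {
    x0 <- sign * (half - spec$cortex_inset)
    depths <- sort(unique(c(seq(0, flare_zone_mm, by = 10),
                            seq(flare_zone_mm, spec$tibia_length, by = 25),
                            spec$tibia_length)))
    xs <- x0 + sign * spec$cortex_flare * pmax(flare_zone_mm - depths, 0)
    cbind(x = xs, y = y_knee + depths)
  }

  limb <- hto_limb(
    femoral_head_center = c(0, 0),
    plateau_medial_edge = c(half, y_knee),
    plateau_lateral_edge = c(-half, y_knee),
    ankle_center = c(ankle_x, y_ankle),
    medial_cortex = cortex(+1),
    lateral_cortex = cortex(-1),
    side = side, patient_id = patient_id, timepoint = timepoint
  )
  if (spec$noise_sigma > 0)
    limb <- add_landmark_noise(limb, spec$noise_sigma, seed = spec$seed)
  limb
}

#' Perturb a limb with landmark-placement noise
#'
#' Emulates observer digitization error: each of the four point
#' landmarks receives independent isotropic Gaussian noise of the
#' given standard deviation per coordinate, and each cortex polyline
#' is shifted rigidly by a single Gaussian offset (a rigid shift
#' cannot self-intersect the contour).
#'
#' @param limb An [hto_limb()].
#' @param sigma Noise standard deviation in mm per coordinate.
#' @param seed Optional integer seed; when `NULL` the current RNG
#'   state is used.
#' @return A perturbed [hto_limb()] (not revalidated: noise may
#'   slightly violate the anatomical orderings).
#' @export
add_landmark_noise <- function(limb, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(limb)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  for (nm in required_landmarks)
    limb[[nm]] <- limb[[nm]] + stats::rnorm(2L, 0, sigma)
  for (nm in c("medial_cortex", "lateral_cortex")) {
    off <- stats::rnorm(2L, 0, sigma)
    m <- sweep(unclass(limb[[nm]]), 2L, -off)
    # keep the contour anchored at the (perturbed) plateau depth so the
    # noisy copy still satisfies the anatomical invariants and remains
    # plannable
    edge <- if (nm == "medial_cortex") limb$plateau_medial_edge
            else limb$plateau_lateral_edge
    m[1L, 2L] <- min(m[1L, 2L], edge[["y"]])
    limb[[nm]] <- polyline(m, validate = FALSE)
  }
  limb
}

#' Execute a plan virtually
#'
#' Applies the opening-wedge correction as a rigid rotation of the
#' distal segment about the hinge: every landmark distal to the
#' horizontal osteotomy plane through `S` (the ankle centre and the
#' distal cortex points) rotates by the plan's signed correction
#' rotation; proximal landmarks are unchanged and the timepoint is set
#' to `"post"`.  For a plan built on the same limb the rotated ankle
#' centre lands exactly on the ankle image `I`, so the postoperative
#' weight-bearing line passes through the target point.
#'
#' @param limb The limb to correct.
#' @param plan An [make_plan()] result (normally built from this limb,
#'   or from a noisy copy of it in simulation studies).
#' @return The corrected [hto_limb()].
#' @export
apply_osteotomy <- function(limb, plan) {
  stopifnot(inherits(plan, "hto_plan"))
  xr <- range(limb$plateau_medial_edge[["x"]], limb$plateau_lateral_edge[["x"]],
              limb$medial_cortex[, "x"], limb$lateral_cortex[, "x"])
  yr <- range(limb$femoral_head_center[["y"]], limb$ankle_center[["y"]])
  pad <- 25
  if (plan$H[["x"]] < xr[1L] - pad || plan$H[["x"]] > xr[2L] + pad ||
      plan$H[["y"]] < yr[1L] - pad || plan$H[["y"]] > yr[2L] + pad)
    stop("plan/limb mismatch: hinge lies outside the limb bounds", call. = FALSE)
  y_cut <- plan$S[["y"]]
  rot <- function(p) rotate_about(p, plan$H, plan$rotation)
  if (limb$ankle_center[["y"]] > y_cut)
    limb$ankle_center <- rot(limb$ankle_center)
  for (nm in c("medial_cortex", "lateral_cortex")) {
    m <- unclass(limb[[nm]])
    distal <- m[, "y"] > y_cut
    if (any(distal))
      m[distal, ] <- t(apply(m[distal, , drop = FALSE], 1L, rot))
    limb[[nm]] <- polyline(m, validate = FALSE)
  }
  limb$timepoint <- "post"
  limb
}

rep_seed <- function(seed, i) (as.double(seed) * 48271 + i * 9973) %% 2147483629

#' Monte-Carlo accuracy of the planning pipeline under landmark noise
#'
#' For each replicate: generate the noiseless true limb from `spec`;
#' plan on an independently noise-perturbed copy (planning error);
#' execute that plan on the true limb; measure the postoperative WBL
#' ratio on a second noise-perturbed copy (measurement error); and
#' classify the correction.  Replicates whose plan construction fails
#' are counted in `n_failed` and excluded from the fractions, never
#' silently dropped.  Each replicate draws from its own RNG stream
#' derived from `(seed, replicate)`, so results do not depend on
#' replicate ordering and are exactly reproducible.
#'
#' @param spec A [synthetic_limb_spec()] (its own `noise_sigma` is
#'   ignored here; the study noise is `noise_sigma` below).
#' @param params [plan_parameters()].
#' @param n Number of replicates.
#' @param noise_sigma Landmark noise s.d. in mm (default 1.5, a
#'   realistic observer digitization error on whole-leg films).
#' @param seed Integer master seed.
#' @param varus_range Optional length-2 vector: draw each replicate's
#'   varus angle uniformly from this range instead of `spec$varus_angle`.
#' @return An object of class `"hto_sim"`: list with `n`, `n_failed`,
#'   `postop_ratios`, `theta`, `gap`, `classes`, the fractions
#'   `fraction_under`, `fraction_acceptable`, `fraction_over` (of
#'   successful replicates), `mean_theta` and `mean_gap`.
#' @export
monte_carlo_accuracy <- function(spec, params = plan_parameters(), n = 100,
                                 noise_sigma = 1.5, seed = 1,
                                 varus_range = NULL) {
  stopifnot(inherits(spec, "hto_limb_spec"), n >= 1, noise_sigma >= 0)
  ratios <- thetas <- gaps <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    set.seed(rep_seed(seed, i))
    varus <- if (is.null(varus_range)) spec$varus_angle
             else stats::runif(1L, varus_range[1L], varus_range[2L])
    spec_i <- spec
    spec_i$varus_angle <- varus
    spec_i$noise_sigma <- 0
    truth <- generate_limb(spec_i, patient_id = sprintf("mc%05d", i))
    planned_on <- add_landmark_noise(truth, noise_sigma)
    plan <- tryCatch(make_plan(planned_on, params), error = function(e) NULL)
    if (is.null(plan)) { failed[i] <- TRUE; next }
    post <- apply_osteotomy(truth, plan)
    measured_on <- add_landmark_noise(post, noise_sigma)
    ratios[i] <- wbl_ratio(measured_on)
    thetas[i] <- plan$theta
    gaps[i] <- plan$gap
  }
  ok <- !failed
  classes <- classify_correction(ratios[ok], params)
  structure(list(
    n = n, n_failed = sum(failed),
    postop_ratios = ratios[ok], theta = thetas[ok], gap = gaps[ok],
    classes = classes,
    fraction_under = mean(classes == "under"),
    fraction_acceptable = mean(classes == "acceptable"),
    fraction_over = mean(classes == "over"),
    mean_theta = mean(thetas[ok]), mean_gap = mean(gaps[ok]),
    noise_sigma = noise_sigma, seed = seed
  ), class = "hto_sim")
}

#' @export
print.hto_sim <- function(x, ...) {
  cat(sprintf("<hto_sim> n = %d (%d failed), landmark noise sigma = %.2f mm\n",
              x$n, x$n_failed, x$noise_sigma))
  cat(sprintf("  under %.1f%%  acceptable %.1f%%  over %.1f%%\n",
              100 * x$fraction_under, 100 * x$fraction_acceptable,
              100 * x$fraction_over))
  cat(sprintf("  mean correction angle %.2f deg, mean gap %.2f mm\n",
              x$mean_theta, x$mean_gap))
  invisible(x)
}
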