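test_that("circle_line_intersections handles the unit-circle cases and errors", {
  o <- frontal_point(0, 0)
  hits <- circle_line_intersections(o, 1, frontal_point(0, -5), frontal_point(0, 5))
  expect_length(hits, 2L)
  expect_equal(hits[[1]], frontal_point(0, -1))
  expect_equal(hits[[2]], frontal_point(0, 1))

  expect_length(circle_line_intersections(o, 1, frontal_point(2, -5),
                                          frontal_point(2, 5)), 0L)
  expect_error(circle_line_intersections(o, 1, frontal_point(1, 1),
                                         frontal_point(1, 1)), "degenerate")
  expect_error(circle_line_intersections(o, 0, frontal_point(0, -1),
                                         frontal_point(0, 1)), "radius")
})

test_that("the hinge-circle / target-line crossing matches the closed-form oracle", {
  h <- frontal_point(-25, 415)
  r <- sqrt(45^2 + 385^2)              # hinge-to-ankle distance of the worked limb
  hits <- circle_line_intersections(h, r, frontal_point(0, 0), frontal_point(0, 1))
  expect_length(hits, 2L)
  distal <- hits[[2]]
  # oracle: solve (0 + 25)^2 + (y - 415)^2 = r^2 for the distal branch
  expect_equal(distal[["y"]], 415 + sqrt(r^2 - 625), tolerance = 1e-12)
  expect_equal(distal[["y"]], 801.813909, tolerance = 1e-6)
  expect_equal(distal[["x"]], 0)
})

test_that("angle_at_vertex matches hand trigonometry and rejects zero rays", {
  o <- frontal_point(0, 0)
  expect_equal(angle_at_vertex(o, frontal_point(1, 0), frontal_point(0, 1)), 90)
  expect_equal(angle_at_vertex(o, frontal_point(1, 0), frontal_point(1, 0)), 0)
  # worked-example correction angle: difference of two arctangents
  got <- angle_at_vertex(frontal_point(-25, 415), frontal_point(20, 800),
                         frontal_point(0, 801.813909))
  oracle <- (atan(45 / 385) - atan(25 / 386.813909)) * 180 / pi
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(got, 2.96874, tolerance = 1e-4)
  expect_error(angle_at_vertex(o, o, frontal_point(1, 0)), "zero-length")
})

test_that("angle_at_vertex is symmetric and rigid-motion invariant", {
  set.seed(11)
  for (i in 1:50) {
    v <- random_point(); p1 <- random_point(); p2 <- random_point()
    if (all(p1 == v) || all(p2 == v)) next
    a <- angle_at_vertex(v, p1, p2)
    expect_gte(a, 0); expect_lte(a, 180)
    expect_equal(angle_at_vertex(v, p2, p1), a, tolerance = 1e-12)
    # rigid motion: rotate all three about a random centre, then translate
    c0 <- random_point(); ang <- runif(1, -180, 180); sh <- c(x = 1.5, y = -7)
    mv <- function(p) rotate_about(p, c0, ang) + sh
    expect_equal(angle_at_vertex(mv(v), mv(p1), mv(p2)), a, tolerance = 1e-9)
  }
})

test_that("rotate_about is an isometry with the expected orientation", {
  expect_equal(rotate_about(frontal_point(1, 0), frontal_point(0, 0), 90),
               frontal_point(0, 1), tolerance = 1e-12)
  p <- frontal_point(3, -4)
  expect_equal(rotate_about(p, p, 123.4), p)

  # the rotation that maps the worked ankle onto the target line
  h <- frontal_point(-25, 415)
  ankle <- frontal_point(20, 800)
  i <- frontal_point(0, 415 + sqrt(45^2 + 385^2 - 625))
  theta <- signed_angle_at_vertex(h, ankle, i)
  expect_equal(rotate_about(ankle, h, theta), i, tolerance = 1e-9)

  set.seed(12)
  for (k in 1:25) {
    c0 <- random_point(); ang <- runif(1, -180, 180)
    pts <- replicate(4, random_point(), simplify = FALSE)
    rot <- lapply(pts, rotate_about, center = c0, angle = ang)
    for (a in 1:3) for (b in (a + 1):4) {
      d0 <- sqrt(sum((pts[[a]] - pts[[b]])^2))
      d1 <- sqrt(sum((rot[[a]] - rot[[b]])^2))
      expect_equal(d1, d0, tolerance = 1e-9)
    }
    # radius preservation
    expect_equal(sqrt(sum((rot[[1]] - c0)^2)), sqrt(sum((pts[[1]] - c0)^2)),
                 tolerance = 1e-9)
  }
})

test_that("chord_length matches its closed form and the rotation construction", {
  expect_equal(chord_length(63.14, 0), 0)
  expect_equal(chord_length(63.14, 180), 126.28)
  expect_equal(chord_length(63.14, 2.97), 2 * 63.14 * sin(2.97 / 2 * pi / 180))
  expect_equal(chord_length(63.14, 2.97), 3.27, tolerance = 1e-2)
  expect_error(chord_length(-1, 10), "radius")
  expect_error(chord_length(1, 181), "angle")

  # oracle equivalence: chord = distance between rotate_about(q, c, +/- theta/2)
  set.seed(13)
  for (k in 1:100) {
    c0 <- random_point()
    r <- runif(1, 0.1, 200); theta <- runif(1, 0, 180)
    dir <- runif(1, 0, 2 * pi)
    q <- c0 + r * c(x = cos(dir), y = sin(dir))
    p1 <- rotate_about(q, c0, theta / 2)
    p2 <- rotate_about(q, c0, -theta / 2)
    expect_equal(chord_length(r, theta), sqrt(sum((p1 - p2)^2)),
                 tolerance = 1e-9)
  }
})

test_that("circle_polyline_intersection selects branches and fails loudly", {
  cortex <- polyline(cbind(c(33, 33), c(390, 600)))
  center <- frontal_point(35, 400)
  s <- circle_polyline_intersection(center, 40, cortex, branch = "distal")
  # oracle: (33 - 35)^2 + (y - 400)^2 = 1600 solved by hand
  expect_equal(s[["y"]], 400 + sqrt(1596), tolerance = 1e-12)
  expect_equal(s[["y"]], 439.95, tolerance = 1e-2)
  expect_equal(s[["x"]], 33)
  # the proximal crossing (y = 400 - sqrt(1596)) lies above the short
  # cortex's span, so extend the contour to reach it
  long <- polyline(cbind(c(33, 33), c(300, 600)))
  p <- circle_polyline_intersection(center, 40, long, branch = "proximal")
  expect_equal(p[["y"]], 400 - sqrt(1596), tolerance = 1e-12)

  expect_error(circle_polyline_intersection(frontal_point(33, 500), 0, cortex,
                                            name = "medial cortex"),
               "construction failed.*medial cortex")
  far <- polyline(cbind(c(100, 100), c(390, 600)))
  expect_error(circle_polyline_intersection(center, 40, far,
                                            name = "medial cortex"),
               "construction failed.*medial cortex")
})

test_that("every returned intersection satisfies the circle equation to 1e-9 relative", {
  set.seed(14)
  for (k in 1:100) {
    c0 <- random_point(); r <- runif(1, 0.5, 150)
    a <- random_point(); b <- random_point()
    if (all(a == b)) next
    for (p in circle_line_intersections(c0, r, a, b)) {
      expect_equal(sqrt(sum((p - c0)^2)) / r, 1, tolerance = 1e-9)
      # and on the line: cross product of (p - a) with (b - a) vanishes
      u <- p - a; v <- b - a
      expect_lt(abs(u[["x"]] * v[["y"]] - u[["y"]] * v[["x"]]) /
                  (sqrt(sum(v^2)) * max(r, 1)), 1e-9)
    }
  }
})

test_that("polyline enforces ordering and length invariants", {
  expect_error(polyline(cbind(1, 1)), "at least 2")
  expect_error(polyline(cbind(c(0, 0), c(5, 5))), "strictly")
  expect_error(polyline(cbind(c(0, 0), c(5, 4))), "strictly")
  pl <- polyline(cbind(c(0, 1, 2), c(0, 10, 30)))
  expect_equal(polyline_x_at(pl, 20), 1.5)
  expect_error(polyline_x_at(pl, 31, name = "lateral cortex"),
               "construction failed.*lateral cortex")
})
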