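make_lm <- function(points, side = "right", measured = 25, true = 25) {
  radiograph_landmarks(points, side = side, marker_measured = measured,
                       marker_true = true)
}

test_that("magnification correction scales about the origin and is idempotent", {
  pts <- rbind(p4 = c(110, 220), p19 = c(-40, 10))
  lm <- make_lm(pts, measured = 27.5, true = 25)
  corr <- correct_magnification(lm)
  expect_equal(unname(corr$points["p4", ]), c(100, 200))
  expect_equal(attr(corr, "scale"), 25 / 27.5)
  # re-application is the identity after the marker update
  corr2 <- correct_magnification(corr)
  expect_equal(corr2$points, corr$points)
  # measured == true leaves points unchanged
  same <- correct_magnification(make_lm(pts))
  expect_equal(same$points, lm$points)
  expect_error(make_lm(pts, measured = -1), "marker")
})

test_that("lateral margin line is the internal bisector of angle 7-4-11", {
  l1 <- lateral_margin_line(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(l1$direction, c(sqrt(2) / 2, sqrt(2) / 2))
  l2 <- lateral_margin_line(c(0, 0), c(2, 0), c(2, 2))
  expect_equal(atan2(l2$direction[2], l2$direction[1]), 22.5 * pi / 180,
               tolerance = 1e-12)
  expect_error(lateral_margin_line(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
  expect_error(lateral_margin_line(c(0, 0), c(1, 1), c(2, 2)), "degenerate")
})

test_that("bisector makes equal angles with both rays (1000 seeded configs)", {
  with_seed(4821, {
    worst <- 0
    for (i in 1:1000) {
      p4 <- runif(2, -50, 50)
      a1 <- runif(1, 0, 2 * pi)
      a2 <- a1 + runif(1, 0.1, pi - 0.1)   # nondegenerate angle
      p7 <- p4 + runif(1, 1, 60) * c(cos(a1), sin(a1))
      p11 <- p4 + runif(1, 1, 60) * c(cos(a2), sin(a2))
      dir <- lateral_margin_line(p4, p7, p11)$direction
      u1 <- (p7 - p4) / sqrt(sum((p7 - p4)^2))
      u2 <- (p11 - p4) / sqrt(sum((p11 - p4)^2))
      worst <- max(worst, abs(acos(min(1, sum(dir * u1))) -
                                acos(min(1, sum(dir * u2)))))
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("medial margin line runs from p5 through the exact midpoint W", {
  m <- medial_margin_line(p5 = c(1, 5), p6 = c(0, 0), p18 = c(2, 0))
  expect_equal(m$W, c(1, 0))
  expect_equal(m$line$direction, c(0, -1))
  # midpoint of coincident points
  m2 <- medial_margin_line(p5 = c(0, 0), p6 = c(3, 4), p18 = c(3, 4))
  expect_equal(m2$W, c(3, 4))
  expect_error(medial_margin_line(p5 = c(1, 0), p6 = c(0, 0), p18 = c(2, 0)),
               "degenerate")
})

test_that("CE angle is signed by the lateral sense of each side", {
  # p4 straight superior of the head centre
  expect_equal(ce_angle(c(0, 0), c(0, 10), "right"), 0)
  # equal superior and lateral offsets -> 45 degrees (lateral = -x on the right)
  expect_equal(ce_angle(c(0, 0), c(-7, 7), "right"), 45)
  expect_equal(ce_angle(c(0, 0), c(7, 7), "left"), 45)
  # medial deviation is negative
  expect_lt(ce_angle(c(0, 0), c(5, 20), "right"), 0)
  expect_error(ce_angle(c(1, 1), c(1, 1), "right"), "degenerate")
})

test_that("constructions are equivariant under rigid motions", {
  with_seed(99, {
    p4 <- c(-14, 22); p7 <- c(24, -18); p11 <- c(-6, -21)
    p5 <- c(12, 24); p6 <- c(22, 0); p18 <- c(25, -20)
    ang <- 0.7; R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    t_vec <- c(13, -8)
    mv <- function(p) as.numeric(R %*% p + t_vec)
    lat0 <- lateral_margin_line(p4, p7, p11)
    lat1 <- lateral_margin_line(mv(p4), mv(p7), mv(p11))
    expect_equal(lat1$anchor, mv(lat0$anchor), tolerance = 1e-12)
    expect_equal(lat1$direction, as.numeric(R %*% lat0$direction),
                 tolerance = 1e-12)
    med0 <- medial_margin_line(p5, p6, p18)
    med1 <- medial_margin_line(mv(p5), mv(p6), mv(p18))
    expect_equal(med1$W, mv(med0$W), tolerance = 1e-12)
    expect_equal(med1$line$direction, as.numeric(R %*% med0$line$direction),
                 tolerance = 1e-12)
  })
})

test_that("full boundary construction passes through its defining points", {
  fem <- generate_femur_surface(femur_params(), n_lat = 24, n_lon = 32)
  r <- generate_radiograph(fem$truth, magnification = 1.1, noise_sd = 0)
  lm <- correct_magnification(r$landmarks)
  bc <- build_boundary_construction(lm)
  d_point_line <- function(line, p) {
    rel <- p - line$anchor
    abs(line$direction[1] * rel[2] - line$direction[2] * rel[1])
  }
  expect_lt(d_point_line(bc$lateral_line, lm$points["p4", ]), 1e-9)
  expect_lt(d_point_line(bc$lateral_line, bc$lateral_line$anchor), 1e-9)
  expect_lt(d_point_line(bc$medial_line, lm$points["p5", ]), 1e-9)
  expect_lt(d_point_line(bc$medial_line, bc$W), 1e-9)
  expect_equal(bc$W, (lm$points["p6", ] + lm$points["p18", ]) / 2)
})

test_that("mirrored landmark sets give mirrored constructions and equal CE", {
  fem <- generate_femur_surface(femur_params(), n_lat = 24, n_lon = 32)
  r <- generate_radiograph(fem$truth, noise_sd = 0)
  lm <- correct_magnification(r$landmarks)
  bc <- build_boundary_construction(lm)
  lm_m <- mirror_landmarks(lm, x0 = 10)
  bc_m <- build_boundary_construction(lm_m)
  expect_equal(bc_m$ce_deg, bc$ce_deg, tolerance = 1e-9)
  expect_equal(bc_m$head_center[1], 20 - bc$head_center[1])
  expect_equal(bc_m$lateral_line$direction[1],
               -bc$lateral_line$direction[1], tolerance = 1e-12)
  expect_equal(bc_m$lateral_line$direction[2],
               bc$lateral_line$direction[2], tolerance = 1e-12)
  expect_equal(abs(bc_m$center_distance_lateral),
               abs(bc$center_distance_lateral), tolerance = 1e-9)
})

test_that("missing landmarks produce a structured error naming the point", {
  fem <- generate_femur_surface(femur_params(), n_lat = 24, n_lon = 32)
  r <- generate_radiograph(fem$truth, noise_sd = 0)
  lm <- r$landmarks
  lm$points <- lm$points[rownames(lm$points) != "p18", ]
  expect_error(build_boundary_construction(lm), "p18")
})

test_that("head-circle fit cross-checks the head-centre landmark", {
  fem <- generate_femur_surface(femur_params(head_radius = 23), n_lat = 24,
                                n_lon = 32)
  r <- generate_radiograph(fem$truth, noise_sd = 0)
  fit <- fit_head_circle(r$landmarks)
  expect_equal(fit$radius, 23, tolerance = 1e-9)
  expect_equal(fit$center, unname(r$landmarks$points["p19", ]),
               tolerance = 1e-9)
})
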