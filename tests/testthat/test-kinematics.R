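cfg <- analysis_config()

test_that("likelihood masking is strict-below and per keypoint", {
  tr <- make_track(matrix(c(0, 0, 1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE),
                   matrix(c(0, 1, 1, 2, 2, 3, 3, 4), ncol = 2, byrow = TRUE),
                   matrix(c(0, 2, 1, 3, 2, 4, 3, 5), ncol = 2, byrow = TRUE))
  same <- mask_low_likelihood(tr, 0.9)
  expect_equal(same$frames, tr$frames)

  tr$frames$nose_p <- c(1, 0.89, 0.9, 1)
  m <- mask_low_likelihood(tr, 0.9)
  expect_true(is.na(m$frames$nose_x[2]))
  expect_false(is.na(m$frames$nose_x[3]))   # exactly 0.9 is kept
  yaw <- head_yaw(m)
  expect_false(yaw$valid[2])
  expect_true(yaw$valid[3])
})

test_that("body angle follows the stated sign convention", {
  # mouse at (100, 100) aimed straight at a port to the east: 0 degrees
  aimed <- make_track(nose = matrix(c(120, 100), 1),
                      neck = matrix(c(110, 100), 1),
                      body = matrix(c(90, 100), 1))
  expect_equal(body_angle(aimed, c(300, 100), cfg)$deg, 0, tolerance = 1e-9)

  # port straight up-screen, mouse aimed east = 90 deg clockwise on screen
  up <- make_track(nose = matrix(c(120, 100), 1),
                   neck = matrix(c(110, 100), 1),
                   body = matrix(c(90, 100), 1))
  expect_equal(body_angle(up, c(100, 0), cfg)$deg, 90, tolerance = 1e-9)
  # ... and a port down-screen gives -90 (counter-clockwise)
  expect_equal(body_angle(up, c(100, 200), cfg)$deg, -90, tolerance = 1e-9)

  # literal backward heading vector flips the aimed case to 180
  lit <- analysis_config(literal_body_vector = TRUE)
  expect_equal(abs(body_angle(aimed, c(300, 100), lit)$deg), 180,
               tolerance = 1e-9)

  # coincident neck and body: degenerate frame
  degen <- make_track(nose = matrix(c(1, 0), 1), neck = matrix(c(0, 0), 1),
                      body = matrix(c(0, 0), 1))
  expect_false(body_angle(degen, c(10, 0), cfg)$valid[1])
})

test_that("head yaw is left-positive in the egocentric frame", {
  # facing up-screen (image y decreases ahead), nose straight: 0 degrees
  straight <- make_track(nose = matrix(c(100, 80), 1),
                         neck = matrix(c(100, 90), 1),
                         body = matrix(c(100, 100), 1))
  expect_equal(head_yaw(straight)$deg, 0, tolerance = 1e-9)

  # nose displaced to the animal's left (screen west when facing up)
  left <- make_track(nose = matrix(c(95, 81), 1),
                     neck = matrix(c(100, 90), 1),
                     body = matrix(c(100, 100), 1))
  expect_gt(head_yaw(left)$deg, 0)
  right <- make_track(nose = matrix(c(105, 81), 1),
                      neck = matrix(c(100, 90), 1),
                      body = matrix(c(100, 100), 1))
  expect_lt(head_yaw(right)$deg, 0)

  # nose on the neck: degenerate
  degen <- make_track(nose = matrix(c(100, 90), 1),
                      neck = matrix(c(100, 90), 1),
                      body = matrix(c(100, 100), 1))
  expect_false(head_yaw(degen)$valid[1])
})

test_that("angles match an independent atan2 oracle on random scenes", {
  set.seed(12)
  for (rep in 1:50) {
    pts <- matrix(runif(8, 0, 500), ncol = 2)
    nose <- pts[1, ]; neck <- pts[2, ]; body <- pts[3, ]; port <- pts[4, ]
    tr <- make_track(matrix(nose, 1), matrix(neck, 1), matrix(body, 1))
    # oracle in the mathematical frame (negate y), angle from target to
    # heading, clockwise-on-screen positive
    tomath <- function(v) c(v[1], -v[2])
    ang <- function(a, b) {   # signed angle a -> b, CCW positive
      atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * 180 / pi
    }
    m <- (neck + body) / 2
    h <- tomath(m - body)
    p <- tomath(port - m)
    expect_equal(body_angle(tr, port, cfg)$deg, -ang(p, h),
                 tolerance = 1e-9)
    hd <- tomath(nose - neck)
    fw <- tomath(neck - body)
    expect_equal(head_yaw(tr)$deg, ang(fw, hd), tolerance = 1e-9)
  }
})

test_that("speed converts frame displacement to px/s and keeps gaps", {
  n <- 60L
  still <- make_track(matrix(10, n, 2), matrix(20, n, 2), matrix(30, n, 2))
  sp <- speed(still, smoothing_window = 0.2)
  expect_equal(max(abs(sp$values[-1, 1])), 0)

  move <- make_track(matrix(10, n, 2), matrix(20, n, 2),
                     cbind(2 * seq_len(n), rep(5, n)))
  sp2 <- speed(move, smoothing_window = 0.2)
  expect_equal(unique(round(sp2$values[-1, 1], 9)), 60)

  gap <- move
  gap$frames$body_p[30] <- 0.1
  sp3 <- speed(mask_low_likelihood(gap, 0.9), smoothing_window = 0.2)
  expect_true(is.na(sp3$values[30, 1]))
  expect_false(anyNA(sp3$values[c(20, 40), 1]))
})

test_that("zero crossings count sign changes with interpolation", {
  fps <- 30
  t <- seq(0, 10 - 1 / fps, by = 1 / fps)
  yaw <- angle_series(t, 10 * sin(2 * pi * 1 * t))
  cr <- zero_crossings(yaw)
  expect_gte(length(cr), 19L)
  expect_lte(length(cr), 21L)
  # crossing times sit near the half-period marks
  expect_lt(max(abs(cr - round(cr * 2) / 2)), 1 / fps)

  expect_length(zero_crossings(angle_series(t, rep(5, length(t)))), 0L)

  # a sign change across an invalid gap is not counted
  y <- c(5, 4, NA, -4, -5)
  g <- angle_series((0:4) / fps, y, valid = !is.na(y))
  expect_length(zero_crossings(g), 0L)

  # an exact zero adopts the following sign
  z <- angle_series((0:2) / fps, c(2, 0, -3))
  expect_length(zero_crossings(z), 1L)
})

test_that("angles are invariant to rotation/translation, negated by mirror", {
  set.seed(99)
  rot <- function(xy, th, img = TRUE) {
    # rotation on screen (image coordinates)
    s <- if (img) -1 else 1
    cbind(cos(th) * xy[, 1] - s * sin(th) * xy[, 2],
          s * sin(th) * xy[, 1] + cos(th) * xy[, 2])
  }
  for (rep in 1:20) {
    pts <- matrix(runif(8, -100, 100), ncol = 2)
    tr <- make_track(pts[1, , drop = FALSE], pts[2, , drop = FALSE],
                     pts[3, , drop = FALSE])
    port <- pts[4, ]
    b0 <- body_angle(tr, port, cfg)$deg
    y0 <- head_yaw(tr)$deg
    th <- runif(1, 0, 2 * pi)
    shift <- runif(2, -50, 50)
    tp <- rot(pts, th)
    tp <- sweep(tp, 2L, shift, "+")
    tr2 <- make_track(tp[1, , drop = FALSE], tp[2, , drop = FALSE],
                      tp[3, , drop = FALSE])
    expect_equal(body_angle(tr2, tp[4, ], cfg)$deg, b0, tolerance = 1e-6)
    expect_equal(head_yaw(tr2)$deg, y0, tolerance = 1e-6)

    mir <- cbind(-pts[, 1], pts[, 2])
    tr3 <- make_track(mir[1, , drop = FALSE], mir[2, , drop = FALSE],
                      mir[3, , drop = FALSE])
    expect_equal(body_angle(tr3, mir[4, ], cfg)$deg, -b0, tolerance = 1e-6)
    expect_equal(head_yaw(tr3)$deg, -y0, tolerance = 1e-6)
  }
})
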