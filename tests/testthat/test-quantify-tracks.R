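simple_track <- function(df, ...) kinetochore_track(df, ...)

static_pair <- function(times = seq(-8, 12, 4), y = 5, dk = 1) {
  do.call(rbind, lapply(times, function(t)
    data.frame(time_s = t, object_id = c("sister1", "sister2"),
               x_um = c(-dk / 2, dk / 2), y_um = y)))
}

test_that("contour angles match known lines", {
  expect_equal(angle_from_contour(rbind(c(0, 0), c(1, 0), c(2, 0))), 0)
  expect_equal(angle_from_contour(rbind(c(0, 0), c(1, 1), c(2, 2))), 45)
  expect_error(angle_from_contour(rbind(c(1, 1), c(1, 1), c(1, 1))),
               "degenerate")
  expect_error(angle_from_contour(rbind(c(0, 0), c(1, 1))), "3 contour")
  # noisy points from a known 65.5-degree line: unbiased within the CI
  set.seed(12)
  ang <- replicate(300, {
    x <- c(0, 0.25, 0.5) * cos(65.5 * pi / 180)
    y <- c(0, 0.25, 0.5) * sin(65.5 * pi / 180)
    angle_from_contour(cbind(x + rnorm(3, 0, 0.02),
                             y + rnorm(3, 0, 0.02)))
  })
  expect_lt(abs(mean(ang) - 65.5), 3 * sd(ang) / sqrt(300) + 0.5)
})

test_that("sister tilt measures the pair orientation", {
  tr <- simple_track(static_pair())
  expect_equal(sister_tilt(tr, 0), 0)
  vert <- data.frame(time_s = 0, object_id = c("sister1", "sister2"),
                     x_um = 0, y_um = c(0, 1))
  tr2 <- kinetochore_track(vert)
  expect_equal(sister_tilt(tr2, 0), 90)
  co <- data.frame(time_s = 0, object_id = c("sister1", "sister2"),
                   x_um = 1, y_um = 1)
  expect_error(sister_tilt(kinetochore_track(co), 0), "coincide")
})

test_that("static sisters show zero relaxation and displacement", {
  tr <- simple_track(static_pair())
  expect_equal(interkinetochore_distance(tr, 0), 1)
  expect_equal(kk_relaxation(tr), 0)
  expect_equal(perpendicular_displacement(tr, "sister1", 8), 0)
})

test_that("pure along-axis motion has no perpendicular component", {
  df <- do.call(rbind, lapply(seq(-4, 8, 4), function(t)
    data.frame(time_s = t, object_id = c("sister1", "sister2"),
               x_um = c(-0.5, 0.5) + 0.1 * t, y_um = 5)))
  tr <- kinetochore_track(df)
  expect_equal(perpendicular_displacement(tr, "sister1", 8), 0)
})

test_that("outward motion is positive on either side of the axis", {
  mk <- function(y0, dy) {
    df <- rbind(
      data.frame(time_s = 0, object_id = c("sister1", "sister2"),
                 x_um = c(-0.5, 0.5), y_um = y0),
      data.frame(time_s = 4, object_id = c("sister1", "sister2"),
                 x_um = c(-0.5, 0.5), y_um = y0 + dy))
    kinetochore_track(df)
  }
  expect_equal(perpendicular_displacement(mk(5, 0.3), "sister1", 4), 0.3)
  # below the axis, moving further down is also "outward"
  expect_equal(perpendicular_displacement(mk(-5, -0.3), "sister1", 4), 0.3)
})

test_that("geometric measures are invariant under rigid transforms", {
  set.seed(5)
  geo <- ref_geometry()
  tr <- generate_cut_response(cut_response_params(), geo, stub_length_um = 1,
                              n_cells = 1, seed = 5)[[1]]
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(3, -2)
  df2 <- as.data.frame(tr)
  xy <- as.matrix(df2[, c("x_um", "y_um")]) %*% t(R)
  df2$x_um <- xy[, 1] + shift[1]; df2$y_um <- xy[, 2] + shift[2]
  ax <- R %*% attr(tr, "axis_direction")
  o2 <- as.vector(R %*% attr(tr, "axis_origin") + shift)
  tr2 <- kinetochore_track(df2, axis_origin = o2, axis_direction = as.vector(ax),
                           t_cut_s = 0, frame_interval_s = 4)
  expect_equal(kk_relaxation(tr2), kk_relaxation(tr), tolerance = 1e-10)
  expect_equal(sister_tilt(tr2, 4), sister_tilt(tr, 4), tolerance = 1e-8)
  expect_equal(interkinetochore_distance(tr2, 8),
               interkinetochore_distance(tr, 8), tolerance = 1e-10)
  expect_equal(stub_length(tr2), stub_length(tr), tolerance = 1e-10)
  expect_equal(perpendicular_displacement(tr2, "sister1", 8),
               perpendicular_displacement(tr, "sister1", 8),
               tolerance = 1e-8)
})

test_that("stub length is the kinetochore-to-tip distance", {
  df <- rbind(static_pair(times = c(-4, 0)),
              data.frame(time_s = 4, object_id = c("sister1", "sister2",
                                                   "stub_tip"),
                         x_um = c(-0.5, 0.5, -1.5), y_um = 5))
  tr <- kinetochore_track(df)
  expect_equal(stub_length(tr), 1)
  df2 <- df; df2$x_um[df2$object_id == "stub_tip"] <- -0.5
  expect_equal(stub_length(kinetochore_track(df2)), 0)
  expect_error(stub_length(simple_track(static_pair())), "stub_tip")
})

test_that("frame matching tolerates one frame interval and no more", {
  tr <- simple_track(static_pair(times = c(-4, 0, 4, 8)))
  expect_equal(interkinetochore_distance(tr, 5), 1)  # nearest frame 4
  expect_error(interkinetochore_distance(tr, 20), "no frame")
  expect_error(kinetochore_track(data.frame(time_s = c(0, 0),
                                            object_id = "sister1",
                                            x_um = 0, y_um = 0)),
               "strictly increasing")
})
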