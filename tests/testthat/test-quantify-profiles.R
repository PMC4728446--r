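gaussian_profile <- function(amp, sd, centre = 2, bg = 0, span = 4,
                             step = 0.081, noise = 0, background = NULL) {
  x <- seq(0, span, by = step)
  y <- bg + amp * exp(-(x - centre)^2 / (2 * sd^2))
  if (noise > 0) y <- y + rnorm(length(x), 0, noise)
  intensity_profile(x, y, background = background)
}

test_that("background subtraction removes the cytoplasmic offset", {
  flat <- intensity_profile(seq(0, 2, 0.1), rep(10, 21), background = 10)
  expect_equal(subtract_background(flat)$intensity, rep(0, 21))
  g <- gaussian_profile(1, 0.15, bg = 5, background = 5)
  pure <- gaussian_profile(1, 0.15, bg = 0)
  expect_equal(subtract_background(g)$intensity, pure$intensity)
  # flank-based estimate on a synthetic two-peak scan removes the offset
  set.seed(4)
  noisy <- gaussian_profile(50, 0.15, bg = 20, noise = 2)
  sub <- subtract_background(noisy, use_flanks = TRUE)
  flanks <- sub$intensity[c(1:8, (nrow(sub) - 7):nrow(sub))]
  expect_lt(abs(mean(flanks)), 2 * 2 / sqrt(length(flanks)) + 0.5)
  expect_error(subtract_background(gaussian_profile(1, 0.2),
                                   use_flanks = FALSE),
               "no background")
})

test_that("peak areas match the Gaussian integral and scale linearly", {
  g <- gaussian_profile(1, 0.15)
  a <- peak_area(g, window_center_um = 2, window_width_um = 2)
  expect_equal(a, 0.15 * sqrt(2 * pi), tolerance = 0.01)
  # linear in amplitude
  g7 <- gaussian_profile(7, 0.15)
  expect_equal(peak_area(g7, 2, 2), 7 * a, tolerance = 1e-6)
  # all-zero profile integrates to zero
  z <- intensity_profile(seq(0, 4, 0.081), numeric(50))
  expect_identical(peak_area(z, 2, 1), 0)
  expect_error(peak_area(g, 0.1, 2), "window exceeds")
})

test_that("peak area recovers the generator's analytic value", {
  set.seed(9)
  pp <- profile_params()
  sim <- generate_intensity_profile(pp, target_ratio_r = 0.45)
  area <- peak_area(subtract_background(sim$bridge),
                    window_center_um = 2, window_width_um = 1.2)
  expect_lt(abs(area / sim$truth$area_bridge - 1), 0.05)
})

test_that("intensity ratio converts to bridge fraction and MT count", {
  expect_equal(bridge_fraction(0.45), 0.45 / 0.55)
  expect_equal(round(100 * bridge_fraction(0.45)), 82)
  expect_identical(bridge_fraction(0), 0)
  expect_equal(bridge_fraction(0.5), 1)
  expect_error(bridge_fraction(1), "must lie in")
  expect_error(bridge_fraction(-0.1), "must lie in")
  expect_equal(as.integer(estimate_bridge_mt_number(0.45, 17)), 14L)
  expect_equal(as.integer(estimate_bridge_mt_number(0.20, 24)), 6L)
  expect_equal(as.integer(estimate_bridge_mt_number(0.5, 10)), 10L)
  expect_equal(attr(estimate_bridge_mt_number(0.45, 17), "raw"),
               17 * 0.45 / 0.55)
})

test_that("bridge fraction round-trips and count is monotone", {
  rs <- seq(0.05, 0.9, by = 0.05)
  f <- bridge_fraction(rs)
  expect_equal(f / (1 + f), rs, tolerance = 1e-14)
  raw <- sapply(rs, function(r) attr(estimate_bridge_mt_number(r, 17), "raw"))
  expect_true(all(diff(raw) > 0))
  ns <- sapply(c(5, 10, 20, 40), function(nk)
    attr(estimate_bridge_mt_number(0.3, nk), "raw"))
  expect_true(all(diff(ns) > 0))
})

test_that("peak-to-peak distance gives a signed d_bk", {
  b <- gaussian_profile(30, 0.15, centre = 2.0)
  k <- gaussian_profile(40, 0.15, centre = 2.24)
  expect_equal(dbk_from_profiles(b, k), 0.24, tolerance = 0.082)
  expect_equal(dbk_from_profiles(k, b), -dbk_from_profiles(b, k))
  expect_equal(dbk_from_profiles(b, b), 0)
  set.seed(2)
  flat <- intensity_profile(seq(0, 4, 0.081),
                            rnorm(50, 0, 1))
  expect_error(dbk_from_profiles(flat, k), "no peak")
})

test_that("comet rates are counts over time, per direction", {
  ev <- data.frame(direction = rep(c("toward", "away"), c(19, 6)))
  r <- comet_rate(ev, duration_min = 10)
  expect_equal(unname(r["toward"]), 1.9)
  expect_equal(unname(r["away"]), 0.6)
  expect_equal(comet_rate(0, 5), 0)
  expect_equal(unname(comet_rate(ev, 10, direction = "toward")), 1.9)
  expect_error(comet_rate(ev, 0), "positive")
})
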