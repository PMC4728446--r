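test_that("identical seeds reproduce identical outputs", {
  p <- geometry_population_params("hela")
  expect_identical(sample_geometry(p, 5, seed = 42),
                   sample_geometry(p, 5, seed = 42))
  expect_identical(generate_intensity_profile(profile_params(), 0.45,
                                              seed = 42),
                   generate_intensity_profile(profile_params(), 0.45,
                                              seed = 42))
  geo <- ref_geometry()
  expect_identical(generate_cut_response(cut_response_params(), geo,
                                         n_cells = 3, seed = 42),
                   generate_cut_response(cut_response_params(), geo,
                                         n_cells = 3, seed = 42))
  expect_identical(generate_comet_events(duration_min = 30, seed = 42),
                   generate_comet_events(duration_min = 30, seed = 42))
})

test_that("geometry sampling reproduces the population statistics", {
  p <- geometry_population_params("hela")
  s <- sample_geometry(p, 400, seed = 1)
  L <- sapply(s$geometries, `[[`, "L_um")
  expect_lt(abs(mean(L) - 11.1), 2 * 1.2 / sqrt(400))
  th0 <- sapply(s$geometries, `[[`, "theta0_deg")
  expect_lt(abs(mean(th0) - 65.5), 2 * 8.8 / sqrt(400) + 0.3)
  # invariants hold for every sample
  for (g in s$geometries) {
    expect_true(g$theta0_deg > 0 && g$theta0_deg < 90)
    expect_true(g$hk_um > 0 && g$L_um > 0)
    expect_true(g$xk_um > 0 && g$xk_um <= g$L_um / 2)
  }
  # degenerate spread pins every draw at the mean
  p0 <- p
  for (nm in c("n_b", "theta0_deg", "thetak_deg", "dbk_um", "dk_um",
               "L_um", "hk_um")) p0[[nm]][2] <- 0
  s0 <- sample_geometry(p0, 3, seed = 1)
  expect_true(all(sapply(s0$geometries, `[[`, "L_um") == 11.1))
  expect_true(all(s0$n_b == 14))
})

test_that("noise-free profiles return the programmed intensity ratio", {
  pp <- profile_params(noise_sd = 0)
  sim <- generate_intensity_profile(pp, target_ratio_r = 0.45)
  ib <- peak_area(subtract_background(sim$bridge), 2, 0.6 * 2)
  ibk <- peak_area(subtract_background(sim$kfibre), 2, 1.0 * 2)
  r <- ib / ibk
  expect_lt(abs(r - 0.45), 0.005)
  # amplitude rescaling leaves the ratio untouched
  pp2 <- profile_params(amplitude_bridge = 100, noise_sd = 0)
  sim2 <- generate_intensity_profile(pp2, target_ratio_r = 0.45)
  ib2 <- peak_area(subtract_background(sim2$bridge), 2, 1.2)
  ibk2 <- peak_area(subtract_background(sim2$kfibre), 2, 2.0)
  expect_equal(ib2 / ibk2, r, tolerance = 1e-6)
})

test_that("noisy profile replicates estimate the bridging MT count", {
  set.seed(33)
  pp <- profile_params()
  nb <- replicate(100, {
    sim <- generate_intensity_profile(pp, target_ratio_r = 0.45)
    ib <- peak_area(subtract_background(sim$bridge), 2, 1.2)
    ibk <- peak_area(subtract_background(sim$kfibre), 2, 2.0)
    as.integer(estimate_bridge_mt_number(min(max(ib / ibk, 0), 0.99), 17))
  })
  expect_lt(abs(mean(nb) - 14), 1)
})

test_that("contour observations lie on the solved shape and recover angles", {
  truth <- symmetric_truth(Fk = 280, xj = 4.3)
  obs <- generate_contour_observation(truth$shape, spacing_um = 0.25)
  # noise-free points interpolate the contour
  p <- truth$shape$rods$p
  yy <- approx(p$x_um, p$y_um, xout = obs$x_um[obs$x_um <= truth$xj])$y
  expect_lt(max(abs(yy - obs$y_um[obs$x_um <= truth$xj])), 2e-3)
  # the first three points reproduce the pole angle up to discretisation
  a0 <- angle_from_contour(as.matrix(obs[1:3, c("x_um", "y_um")]))
  expect_lt(abs(a0 - 64), 2.5)
  # 50 nm noise: unbiased over replicates
  set.seed(8)
  angs <- replicate(200, {
    o <- generate_contour_observation(truth$shape, 0.25, noise_sd_um = 0.05)
    angle_from_contour(as.matrix(o[1:3, c("x_um", "y_um")]))
  })
  expect_lt(abs(mean(angs) - a0), 3 * sd(angs) / sqrt(200) + 1)
  expect_error(generate_contour_observation(truth$shape, spacing_um = 50),
               "spacing")
})

test_that("noise-free single-cell kinematics follow the programmed course", {
  geo <- ref_geometry()
  par0 <- cut_response_params(peak_disp_sd_um = 0, time_to_peak_s = 12,
                              time_to_peak_sd_s = 0, relax_sd_um = 0,
                              tilt4_sd_deg = c("3" = 0, "14" = 0, "23" = 0),
                              noise_sd_um = 0)
  tr <- generate_cut_response(par0, geo, stub_length_um = 0.3,
                              n_cells = 1, seed = 1)[[1]]
  # peak displacement equals the configured mean at the configured frame
  expect_equal(perpendicular_displacement(tr, "sister1", 12), 0.32,
               tolerance = 1e-9)
  expect_lt(perpendicular_displacement(tr, "sister1", 4), 0.32)
  # relaxation at 4 s equals the short-stub logistic value
  expect_equal(kk_relaxation(tr), expected_relaxation(0.3, par0),
               tolerance = 1e-9)
  # tilt at 4 s equals the class mean
  expect_equal(sister_tilt(tr, 4), 4.0, tolerance = 1e-6)
  # stub is placed at the programmed length
  expect_equal(stub_length(tr), 0.3, tolerance = 1e-9)
})

test_that("measured responses track the generator's manifest truth", {
  geo <- ref_geometry()
  trs <- generate_cut_response(cut_response_params(), geo, n_cells = 40,
                               seed = 99)
  relax_err <- sapply(trs, function(tr)
    kk_relaxation(tr) - attr(tr, "truth")$relaxation_um)
  # measurement error is only tracking noise (sd 25 nm per coordinate)
  expect_lt(abs(mean(relax_err)), 3 * 0.05 / sqrt(40))
  stub_err <- sapply(trs, function(tr)
    stub_length(tr) - attr(tr, "truth")$stub_length_um)
  expect_lt(abs(mean(stub_err)), 0.03)
  tilt_err <- sapply(trs, function(tr)
    sister_tilt(tr, 4) - attr(tr, "truth")$tilt4_deg)
  expect_lt(abs(mean(tilt_err)), 1.5)
})

test_that("relaxation is larger for cuts closer to the kinetochore", {
  geo <- ref_geometry()
  near <- generate_cut_response(cut_response_params(), geo,
                                stub_length_um = 0.3, n_cells = 60,
                                seed = 7)
  far <- generate_cut_response(cut_response_params(), geo,
                               stub_length_um = 2.0, n_cells = 60,
                               seed = 8)
  m_near <- mean(sapply(near, kk_relaxation))
  m_far <- mean(sapply(far, kk_relaxation))
  expect_gt(m_near, m_far)
})

test_that("comet event streams have the programmed rates and speeds", {
  expect_equal(nrow(generate_comet_events(c(toward = 0), 100, seed = 1)), 0)
  ev <- generate_comet_events(c(toward = 1.9, away = 0.6), 1000, seed = 3)
  r <- comet_rate(ev, 1000)
  expect_lt(abs(r[["toward"]] - 1.9), 2 * sqrt(1.9 / 1000))
  expect_lt(abs(r[["away"]] - 0.6), 2 * sqrt(0.6 / 1000))
  expect_lt(abs(mean(ev$velocity_um_min) - 13.1), 0.1)
  expect_true(all(diff(ev$time_min) >= 0))
})
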