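test_that("zero loads give a straight rod at the initial slope", {
  arch <- ref_architecture()
  slope <- tan(64 * pi / 180)
  r <- integrate_rod("p", 0, 4.3, 0, slope, spindle_loads(0, 0), arch, 5)
  expect_equal(r$y_um, r$x_um * slope, tolerance = 1e-12)
  expect_equal(r$slope, rep(slope, nrow(r)), tolerance = 1e-12)
})

test_that("midpoint integrator matches an adaptive high-order solver", {
  # oracle: deSolve lsoda at tight tolerances on the same ODE
  library(deSolve)
  arch <- ref_architecture()
  loads <- raw_loads(33, 280)   # signed coefficients of the reference solve
  hk <- 5
  cases <- list(
    list(rod = "p", x0 = 0, x1 = 4.3, y0 = 0, v0 = tan(64 * pi / 180)),
    list(rod = "k", x0 = 4.3, x1 = 5.05, y0 = 4.85, v0 = 0.35),
    list(rod = "b", x0 = 4.3, x1 = 5.55, y0 = 4.85, v0 = 0.35))
  for (cs in cases) {
    kappa <- switch(cs$rod, p = arch$kappa_p, k = arch$kappa_k,
                    b = arch$kappa_b)
    f <- function(x, st, parms) {
      M <- bending_moment(cs$rod, st[1], loads, hk)
      list(c(st[2], M / kappa * (1 + st[2]^2)^1.5))
    }
    ora <- deSolve::ode(c(y = cs$y0, v = cs$v0), c(cs$x0, cs$x1), f, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-12)
    mine <- integrate_rod(cs$rod, cs$x0, cs$x1, cs$y0, cs$v0, loads, arch, hk)
    expect_lt(abs(mine$y_um[nrow(mine)] / ora[2, "y"] - 1), 1e-3)
    expect_lt(abs(mine$slope[nrow(mine)] - ora[2, "v"]) /
                max(abs(ora[2, "v"]), 0.1), 1e-3)
  }
})

test_that("halving the step changes the endpoint by less than 0.5%", {
  arch <- ref_architecture()
  loads <- raw_loads(33, 280)
  a <- integrate_rod("p", 0, 4.3, 0, tan(64 * pi / 180), loads, arch, 5,
                     n_steps = 50)
  b <- integrate_rod("p", 0, 4.3, 0, tan(64 * pi / 180), loads, arch, 5,
                     n_steps = 100)
  expect_lt(abs(a$y_um[nrow(a)] / b$y_um[nrow(b)] - 1), 0.005)
})

test_that("degenerate and near-vertical rods raise informative errors", {
  arch0 <- fibre_architecture(17, 0)
  expect_error(
    integrate_rod("b", 0, 1, 0, 0, raw_loads(10, 100), arch0, 5),
    "degenerate rod")
  # a rigidity-free moment-free rod is fine (straight line)
  r <- integrate_rod("b", 0, 1, 2, 0.5, spindle_loads(0, 0), arch0, 5)
  expect_equal(r$y_um[nrow(r)], 2.5)
  # absurd moment drives the slope past the parameterisation bound
  expect_error(
    integrate_rod("p", 0, 10, 0, 2, raw_loads(-5000, 0),
                  ref_architecture(), 5),
    "parameterization breakdown")
})

test_that("compiled endpoint kernel agrees with the trajectory integrator", {
  arch <- ref_architecture()
  loads <- raw_loads(40, 350)
  r <- integrate_rod("p", 0, 4.0, 0, tan(60 * pi / 180), loads, arch, 5)
  fast <- bridgefibre:::.rod_endpoint(loads$F0_pN / arch$kappa_p,
                                      loads$M0_pN_um / arch$kappa_p,
                                      4.0, 0, tan(60 * pi / 180), 50)
  expect_equal(r$y_um[nrow(r)], fast[1], tolerance = 1e-12)
  expect_equal(r$slope[nrow(r)], fast[2], tolerance = 1e-12)
})
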