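#' Control parameters for the force-balance solver
#'
#' @param tol_pos Convergence tolerance on the kinetochore-height residual
#'   (micrometres), default 1e-3.
#' @param tol_ang Convergence tolerance on the angle/slope residuals
#'   (radians), default 1e-3.
#' @param max_iter Maximum damped-Newton iterations per start, default 60.
#' @param n_steps Integration steps per rod, default 50.
#' @param slope_branch Sign of the imposed kinetochore end slope: `+1`
#'   (default) constrains `y'(xk) = +tan(thetak)`, the branch on which the
#'   k-fibre is still rising at the kinetochore and the bridging fibre passes
#'   beneath it; `-1` selects the descending branch.
#' @param multistart List with numeric vectors `Fk` (pN) and `dxj`
#'   (distance of the junction start value below `xk`, micrometres) defining
#'   the grid of starting points; the pole force is not a free start value
#'   because it is eliminated through the symmetry condition at every
#'   evaluation.
#' @param sigma_hk Measurement scale of the half-width (micrometres) used to
#'   weight the height residual in the least-squares fallback, default 0.7.
#' @param sigma_theta_deg Measurement scale of the kinetochore angle
#'   (degrees) used to weight the angle residual in the fallback, default
#'   10.1.
#' @param check_roots If `TRUE`, run every start to convergence and warn when
#'   distinct roots are found.
#' @return A list of class `"solver_control"`.
#' @export
solver_control <- function(tol_pos = 1e-3, tol_ang = 1e-3, max_iter = 60,
                           n_steps = 50, slope_branch = 1,
                           multistart = list(Fk = c(100, 300, 500),
                                             dxj = c(0.5, 1.0, 1.5)),
                           sigma_hk = 0.7, sigma_theta_deg = 10.1,
                           check_roots = FALSE) {
  stopifnot(slope_branch %in% c(-1, 1))
  structure(list(tol_pos = tol_pos, tol_ang = tol_ang, max_iter = max_iter,
                 n_steps = n_steps, slope_branch = slope_branch,
                 multistart = multistart, sigma_hk = sigma_hk,
                 sigma_theta_deg = sigma_theta_deg,
                 check_roots = check_roots),
            class = "solver_control")
}

# pole force satisfying the midplane-symmetry condition for given (Fk, xj);
# warm-started around `near` when available
.F0_symmetry_root <- function(Fk, xj, M0, geometry, architecture, n_steps,
                              near = NA_real_, F0_range = c(0.5, 250)) {
  g <- function(F0) .mid_slope_of_F0(F0, Fk, xj, M0, geometry, architecture,
                                     n_steps)
  if (is.finite(near)) {
    lo <- max(F0_range[1], 0.7 * near); hi <- min(F0_range[2], 1.4 * near)
    vlo <- suppressWarnings(g(lo)); vhi <- suppressWarnings(g(hi))
    if (is.finite(vlo) && is.finite(vhi) && sign(vlo) != sign(vhi))
      return(suppressWarnings(
        stats::uniroot(g, c(lo, hi), tol = 1e-10)$root))
  }
  roots <- .scan_roots(g, F0_range[1], F0_range[2], max_grid = 800)
  if (length(roots) == 0) return(NA_real_)
  if (is.finite(near)) roots[which.min(abs(roots - near))] else roots[1]
}

# residuals (hk mismatch [um], end-angle mismatch [rad]) on the symmetry
# manifold; F0 is eliminated via its 1-D root; state carries the warm start
.fb_residuals2 <- function(par, geometry, architecture, M0, control,
                           near = NA_real_) {
  xk <- geometry$xk_um
  xj <- min(max(par[2], 1e-2), min(xk, geometry$L_um / 2) - 1e-6)
  F0 <- .F0_symmetry_root(par[1], xj, M0, geometry, architecture,
                          control$n_steps, near = near)
  if (!is.finite(F0)) return(list(r = rep(1e3, 2), F0 = NA_real_))
  f <- .forward_fast(F0, par[1], xj, M0, geometry, architecture,
                     control$n_steps)
  if (is.null(f)) return(list(r = rep(1e3, 2), F0 = F0))
  list(r = c(f$hk_model - geometry$hk_um,
             atan(f$slope_k) -
               control$slope_branch * geometry$thetak_deg * pi / 180),
       F0 = F0, mid = f$mid)
}

# damped (optionally weighted) Newton on (Fk, xj) with F0 eliminated
.fb_newton <- function(par, geometry, architecture, M0, control,
                       weights = c(1, 1)) {
  xk <- geometry$xk_um
  xj_hi <- min(xk, geometry$L_um / 2) - 1e-6
  clamp <- function(p) c(max(p[1], 1), min(max(p[2], 1e-2), xj_hi))
  par <- clamp(par)
  ev <- .fb_residuals2(par, geometry, architecture, M0, control)
  r <- ev$r; F0 <- ev$F0
  for (it in seq_len(control$max_iter)) {
    if (abs(r[1]) < control$tol_pos && abs(r[2]) < control$tol_ang)
      return(list(par = par, F0 = F0, residuals = r, mid = ev$mid,
                  iterations = it, converged = TRUE))
    J <- matrix(0, 2, 2)
    dp <- c(max(1e-4 * abs(par[1]), 0.1), 1e-5)
    for (j in 1:2) {
      p2 <- par; p2[j] <- p2[j] + dp[j]
      J[, j] <- (.fb_residuals2(p2, geometry, architecture, M0, control,
                                near = F0)$r - r) / dp[j]
    }
    Jw <- J * weights; rw <- r * weights
    step <- tryCatch(qr.solve(Jw, -rw), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(list(par = par, F0 = F0, residuals = r, mid = ev$mid,
                  iterations = it, converged = FALSE))
    # cap the Fk step: the angle residual is nearly flat in Fk and raw
    # Newton steps along that direction can be enormous
    if (abs(step[1]) > 0.7 * max(abs(par[1]), 50))
      step <- step * 0.7 * max(abs(par[1]), 50) / abs(step[1])
    lam <- 1; improved <- FALSE
    while (lam >= 1 / 8192) {
      p2 <- clamp(par + lam * step)
      ev2 <- .fb_residuals2(p2, geometry, architecture, M0, control,
                            near = F0)
      # require a non-negligible decrease: in the nearly flat Fk valley the
      # line search otherwise drifts for many iterations without progress
      if (sum((ev2$r * weights)^2) <
          sum(rw^2) * (1 - 1e-6) - 1e-14) { improved <- TRUE; break }
      lam <- lam / 2
    }
    if (!improved)
      return(list(par = par, F0 = F0, residuals = r, mid = ev$mid,
                  iterations = it, converged = FALSE))
    par <- p2; ev <- ev2; r <- ev$r; F0 <- ev$F0
  }
  list(par = par, F0 = F0, residuals = r, mid = ev$mid,
       iterations = control$max_iter,
       converged = abs(r[1]) < control$tol_pos && abs(r[2]) < control$tol_ang)
}

#' Infer pole force, kinetochore tension and junction position
#'
#' Inverse solve of the three-rod model: finds the loads `(F0, Fk)` and the
#' junction abscissa `xj` such that the forward shape satisfies the three
#' constraints (i) reflection symmetry at the midplane, `y_b'(L/2) = 0`,
#' (ii) the kinetochore height, `y_k(xk) = hk`, and (iii) the measured
#' k-fibre angle at the kinetochore, `|atan y_k'(xk)| = thetak`. The pole
#' moment `M0` is fixed (default 0); it has a contribution complementary to
#' `F0` and is never treated as a simultaneous free parameter.
#'
#' A damped Newton iteration is run from a grid of starting points. If no
#' start reaches the exact tolerances — with measured (rather than
#' model-generated) constraints the three conditions are generally not
#' simultaneously attainable, and the kinetochore tension is only weakly
#' identified — the solver falls back to damped Gauss-Newton on residuals
#' weighted by the measurement scales in `control` (symmetry held tight,
#' height and angle weighted by their population s.d.), returning the
#' best-fit point with `converged = FALSE` and the residuals as diagnostics.
#'
#' @param geometry A [spindle_geometry()] object (constraints `hk_um`,
#'   `thetak_deg` are taken from it).
#' @param architecture A [fibre_architecture()] object.
#' @param M0_pN_um Fixed pole moment, default 0.
#' @param control A [solver_control()] object.
#' @return An object of class `"force_balance"`: list with `loads`
#'   ([spindle_loads()]), `xj_um`, `junction_distance_um` (`xk - xj`),
#'   `shape` (the solved [forward_spindle_shape()]), `residuals` (named:
#'   `mid_slope`, `hk_um`, `thetak_rad`), `converged`, `iterations`,
#'   `n_starts_tried`, and `weighted` (`TRUE` when the least-squares
#'   fallback produced the result).
#' @examples
#' \donttest{
#' geo <- spindle_geometry(64, 13.7, 11.1, 5.0, 5.05)
#' arch <- fibre_architecture(17, 14)
#' fb <- solve_force_balance(geo, arch)
#' fb$loads$F0_pN
#' }
#' @export
solve_force_balance <- function(geometry, architecture, M0_pN_um = 0,
                                control = solver_control()) {
  stopifnot(inherits(geometry, "spindle_geometry"),
            inherits(architecture, "fibre_architecture"))
  xk <- geometry$xk_um
  ms <- control$multistart
  starts <- expand.grid(Fk = ms$Fk, dxj = ms$dxj, KEEP.OUT.ATTRS = FALSE)
  starts$xj <- pmax(xk - starts$dxj, 0.05)
  # residuals are weighted by the measurement spreads throughout; an exact
  # root (residuals below tolerance) is unaffected by the weighting, and
  # when no root exists the same runs provide the least-squares fit
  w <- c(1 / control$sigma_hk, 1 / (control$sigma_theta_deg * pi / 180))
  roots <- list(); fits <- list(); best <- NULL; tried <- 0L
  for (i in seq_len(nrow(starts))) {
    tried <- tried + 1L
    fit <- .fb_newton(c(starts$Fk[i], starts$xj[i]),
                      geometry, architecture, M0_pN_um, control, weights = w)
    fits[[i]] <- fit
    if (fit$converged) {
      roots[[length(roots) + 1L]] <- fit
      if (is.null(best)) best <- fit
      if (!control$check_roots) break
    }
  }
  weighted <- FALSE
  if (is.null(best)) {
    sse <- vapply(fits, function(f) sum((f$residuals * w)^2), numeric(1))
    best <- fits[[which.min(sse)]]
    weighted <- TRUE
  } else if (control$check_roots && length(roots) > 1L) {
    pars <- do.call(rbind, lapply(roots, function(f) c(f$F0, f$par)))
    spread <- apply(pars, 2, function(v) diff(range(v)))
    rel <- spread / pmax(abs(pars[1, ]), 1)
    if (any(rel > 0.02))
      warning("multiple distinct roots found across restarts; ",
              "reporting the first", call. = FALSE)
  }
  xj <- min(max(best$par[2], 1e-2), min(xk, geometry$L_um / 2) - 1e-6)
  shape <- forward_spindle_shape(geometry, architecture,
                                 spindle_loads(best$F0, best$par[1],
                                               M0_pN_um),
                                 xj, control$n_steps)
  structure(
    list(loads = spindle_loads(best$F0, best$par[1], M0_pN_um),
         xj_um = xj, junction_distance_um = xk - xj,
         shape = shape,
         residuals = c(mid_slope = shape$mid_slope,
                       hk_um = best$residuals[1],
                       thetak_rad = best$residuals[2]),
         converged = best$converged, weighted = weighted,
         iterations = best$iterations, n_starts_tried = tried,
         control = control),
    class = "force_balance")
}

#' @export
print.force_balance <- function(x, ...) {
  cat("Force balance of the three-rod spindle model\n")
  cat(sprintf("  F0 = %.2f pN, Fk = %.1f pN, xj = %.3f um (xk - xj = %.3f um)\n",
              x$loads$F0_pN, x$loads$Fk_pN, x$xj_um, x$junction_distance_um))
  cat(sprintf("  residuals: mid slope %+.2e, hk %+.3f um, thetak %+.3f deg\n",
              x$residuals[1], x$residuals[2], x$residuals[3] * 180 / pi))
  cat(sprintf("  converged: %s%s (%d iterations)\n", x$converged,
              if (x$weighted) " [weighted least-squares fit]" else "",
              x$iterations))
  invisible(x)
}

# lean scalar midpoint integrator for the affine-moment rod ODE
# kappa*y'' = (A*y + B)*(1+y'^2)^{3/2}; returns c(y, v) at x_end or NULL on
# parameterisation breakdown; compiled kernel
.rod_endpoint <- function(A, B, x_len, y, v, n_steps,
                          max_slope = tan(89 * pi / 180)) {
  out <- .rod_endpoint_cpp(A, B, x_len, y, v, as.integer(n_steps), max_slope)
  if (!is.finite(out[1])) return(NULL)
  out
}

# scalar outputs of the three-rod forward model (signed internal loads are
# derived from the reported ones); any breakdown yields NULL
.forward_fast <- function(F0, Fk, xj, M0, geometry, architecture, n_steps,
                          rods = c("p", "k", "b")) {
  a0 <- -F0; ak <- Fk; m0 <- -M0
  hk <- geometry$hk_um
  p <- .rod_endpoint(a0 / architecture$kappa_p, m0 / architecture$kappa_p,
                     xj, 0, tan(geometry$theta0_deg * pi / 180), n_steps)
  if (is.null(p)) return(NULL)
  out <- list(hj = p[1], vj = p[2])
  if ("k" %in% rods) {
    k <- .rod_endpoint(-ak / architecture$kappa_k,
                       ak * hk / architecture$kappa_k,
                       geometry$xk_um - xj, p[1], p[2], n_steps)
    if (is.null(k)) return(NULL)
    out$hk_model <- k[1]; out$slope_k <- k[2]
  }
  if ("b" %in% rods) {
    b <- .rod_endpoint((ak + a0) / architecture$kappa_b,
                       (-ak * hk + m0) / architecture$kappa_b,
                       geometry$L_um / 2 - xj, p[1], p[2], n_steps)
    if (is.null(b)) return(NULL)
    out$h <- b[1]; out$mid <- b[2]
  }
  out
}

# midplane slope of the bridge for given pole force, rods p and b only
.mid_slope_of_F0 <- function(F0, Fk, xj, M0, geometry, architecture, n_steps) {
  f <- .forward_fast(F0, Fk, xj, M0, geometry, architecture, n_steps,
                     rods = c("p", "b"))
  if (is.null(f)) NA_real_ else f$mid
}

# all sign-change roots of a scalar function on a grid, NA-tolerant; the
# domain where g is defined can be a narrow window between integrator
# blow-ups (thin bridges), so refine progressively when nothing brackets
.scan_roots <- function(g, lower, upper, n_grid = 200, max_grid = 6400) {
  repeat {
    xs <- seq(lower, upper, length.out = n_grid)
    vs <- vapply(xs, function(x) suppressWarnings(g(x)), numeric(1))
    roots <- numeric(0)
    for (i in seq_along(xs)[-1]) {
      if (is.finite(vs[i - 1]) && is.finite(vs[i]) &&
          sign(vs[i - 1]) != sign(vs[i]))
        roots <- c(roots,
                   suppressWarnings(
                     stats::uniroot(g, c(xs[i - 1], xs[i]),
                                    tol = 1e-10)$root))
    }
    if (length(roots) > 0 || n_grid >= max_grid) return(roots)
    fin <- which(is.finite(vs))
    if (length(fin) == 0) {
      n_grid <- n_grid * 4
      next
    }
    # refine around the finite window only
    lo_i <- max(min(fin) - 1L, 1L); hi_i <- min(max(fin) + 1L, length(xs))
    lower <- xs[lo_i]; upper <- xs[hi_i]
    n_grid <- min(n_grid * 4, max_grid)
  }
}

#' Pole force as a function of bridging-fibre thickness
#'
#' For each bridging-fibre microtubule count `n_b`, solves the
#' single-unknown problem: find the pole force `F0` such that the bridge is
#' symmetric at the midplane, `y_b'(L/2) = 0`, with the kinetochore tension
#' `Fk`, the junction position `xj` and the pole moment `M0` held fixed. The
#' kinetochore angle and height are outputs here, not constraints. When
#' several symmetry roots exist the one closest to the previous `n_b` value
#' is kept (continuity of the sweep).
#'
#' `n_b = 0` is the singular limit of a rigidity-free bridge: there the
#' bridge carries no bending moment, so its height locks to the zero of the
#' bridge moment and the surviving condition is that rod p must deliver the
#' junction at exactly that height, which is again a one-dimensional root
#' problem for `F0`.
#'
#' @param nb_values Integer vector of bridging-fibre microtubule counts
#'   (>= 0).
#' @param geometry A [spindle_geometry()] object (only `theta0_deg`, `L_um`,
#'   `hk_um` enter).
#' @param Fk_pN Fixed kinetochore tension (pN).
#' @param xj_um Fixed junction abscissa (micrometres).
#' @param n_k k-fibre microtubule count, default 17.
#' @param kappa0_pN_um2 Single-microtubule rigidity, default 30.
#' @param M0_pN_um Fixed pole moment, default 0.
#' @param n_steps Steps per rod, default 50.
#' @param F0_range Search interval for the pole force (pN).
#' @return Data frame with columns `n_b`, `F0_pN`, `hk_model_um`,
#'   `thetak_model_deg`, `h_um` (kinetochore height/angle and midplane
#'   height are `NA` for `n_b = 0`).
#' @examples
#' \donttest{
#' geo <- spindle_geometry(64, 13.7, 11.1, 5.0, 5.05)
#' sweep_pole_force(c(5, 14, 23), geo, Fk_pN = 280, xj_um = 4.3)
#' }
#' @export
sweep_pole_force <- function(nb_values, geometry, Fk_pN, xj_um,
                             n_k = 17, kappa0_pN_um2 = 30, M0_pN_um = 0,
                             n_steps = 50, F0_range = c(0.5, 250)) {
  stopifnot(all(nb_values >= 0))
  out <- data.frame(n_b = nb_values, F0_pN = NA_real_,
                    hk_model_um = NA_real_, thetak_model_deg = NA_real_,
                    h_um = NA_real_)
  prev <- NA_real_
  for (i in seq_along(nb_values)) {
    nb <- nb_values[i]
    if (nb == 0) {
      # rigidity-free bridge: junction height must sit at the zero of the
      # bridge moment, hj = (ak*hk - m0)/(ak + a0) in signed coefficients
      arch0 <- fibre_architecture(n_k, 0, kappa0_pN_um2)
      g <- function(F0) {
        sl <- .signed_loads(spindle_loads(F0, Fk_pN, M0_pN_um))
        denom <- sl$ak + sl$a0
        if (abs(denom) < 1e-12) return(NA_real_)
        ystar <- (sl$ak * geometry$hk_um - sl$m0) / denom
        raw <- spindle_loads(sl$a0, sl$ak, sl$m0)
        p <- tryCatch(
          integrate_rod("p", 0, xj_um, 0,
                        tan(geometry$theta0_deg * pi / 180),
                        raw, arch0, geometry$hk_um, n_steps),
          error = function(e) NULL)
        if (is.null(p)) return(NA_real_)
        p$y_um[nrow(p)] - ystar
      }
      roots <- .scan_roots(g, F0_range[1], F0_range[2])
    } else {
      arch <- fibre_architecture(n_k, nb, kappa0_pN_um2)
      g <- function(F0) .mid_slope_of_F0(F0, Fk_pN, xj_um, M0_pN_um,
                                         geometry, arch, n_steps)
      roots <- .scan_roots(g, F0_range[1], F0_range[2])
    }
    if (length(roots) == 0) next
    F0 <- if (is.finite(prev)) roots[which.min(abs(roots - prev))] else
      roots[1]
    out$F0_pN[i] <- F0
    prev <- F0
    if (nb > 0) {
      sh <- tryCatch(
        forward_spindle_shape(geometry, fibre_architecture(n_k, nb,
                                                           kappa0_pN_um2),
                              spindle_loads(F0, Fk_pN, M0_pN_um), xj_um,
                              n_steps),
        error = function(e) NULL)
      if (!is.null(sh)) {
        out$hk_model_um[i] <- sh$hk_model_um
        out$thetak_model_deg[i] <- sh$thetak_model_deg
        out$h_um[i] <- sh$h_um
      }
    }
  }
  out
}
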