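#' Bending moment of a rod at height y
#'
#' The three rods of the half-spindle model carry bending moments that are
#' affine in the height `y` above the long axis:
#' \deqn{M_p = m_0 + a_0 y, \quad M_k = -a_k (y - h_k), \quad
#'       M_b = (a_k + a_0) y - a_k h_k + m_0,}
#' where `a0`, `ak`, `m0` are the signed load coefficients of the pole force,
#' kinetochore force and pole moment. The identity `M_b = M_p - M_k` holds
#' for all `y` and any loads. This function evaluates the moment with the
#' coefficients taken directly from `loads` (coefficients `a0 = F0`,
#' `ak = Fk`, `m0 = M0`); the sign mapping between reported anchor forces and
#' these coefficients is applied by the higher-level functions, see
#' [forward_spindle_shape()].
#'
#' @param rod_id One of `"p"` (pole to junction), `"k"` (junction to
#'   kinetochore), `"b"` (junction to midplane).
#' @param y_um Height above the spindle long axis (micrometres); vectorised.
#' @param loads A [spindle_loads()] object (used here as raw coefficients).
#' @param hk_um Kinetochore height (micrometres).
#' @return Bending moment(s) in pN um.
#' @examples
#' l <- spindle_loads(F0_pN = 33, Fk_pN = 280)
#' bending_moment("p", 0, l, hk_um = 5)    # = M0 = 0
#' bending_moment("k", 5, l, hk_um = 5)    # = 0 at the kinetochore height
#' @export
bending_moment <- function(rod_id, y_um, loads, hk_um) {
  if (!is.character(rod_id) || length(rod_id) != 1L ||
      !rod_id %in% c("p", "k", "b"))
    stop("unknown rod_id: must be one of \"p\", \"k\", \"b\"", call. = FALSE)
  stopifnot(is.numeric(y_um), is.finite(hk_um))
  F0 <- loads$F0_pN; Fk <- loads$Fk_pN; M0 <- loads$M0_pN_um
  switch(rod_id,
         p = M0 + F0 * y_um,
         k = -Fk * (y_um - hk_um),
         b = (Fk + F0) * y_um - Fk * hk_um + M0)
}

#' Integrate one elastic rod with the fixed-step midpoint method
#'
#' Solves the Cartesian Euler-Bernoulli equation
#' \deqn{\kappa\, y'' = M(y)\,(1 + y'^2)^{3/2}}
#' for a single rod over `[x_start, x_end]`, where `M(y)` is the affine
#' bending moment of [bending_moment()] with the coefficients in `loads`.
#' The integrator is the explicit midpoint rule (second-order Runge-Kutta)
#' with a fixed step `(x_end - x_start) / n_steps`; the default of 50 steps
#' per rod is the reference discretisation of the model.
#'
#' @param rod_id Rod identifier, see [bending_moment()].
#' @param x_start,x_end Integration interval (micrometres), `x_end > x_start`.
#' @param y_start Height at `x_start` (micrometres).
#' @param slope_start Slope dy/dx at `x_start`.
#' @param loads A [spindle_loads()] object holding the signed moment
#'   coefficients.
#' @param architecture A [fibre_architecture()] object; supplies the rod
#'   rigidity.
#' @param hk_um Kinetochore height (micrometres).
#' @param n_steps Number of integration steps (>= 2), default 50.
#' @param max_slope Slope magnitude at which the graph parameterisation is
#'   declared broken (near-vertical rod); default `tan(89 deg)`.
#' @return A data frame with columns `x_um`, `y_um`, `slope` sampled at the
#'   `n_steps + 1` grid nodes.
#' @examples
#' arch <- fibre_architecture(17, 14)
#' # zero loads: straight line at the initial slope
#' r <- integrate_rod("p", 0, 4, 0, tan(64 * pi / 180),
#'                    spindle_loads(0, 0), arch, hk_um = 5)
#' all.equal(r$y_um, r$x_um * tan(64 * pi / 180))
#' @export
integrate_rod <- function(rod_id, x_start, x_end, y_start, slope_start,
                          loads, architecture, hk_um, n_steps = 50,
                          max_slope = tan(89 * pi / 180)) {
  if (!(x_end > x_start)) stop("x_end must exceed x_start", call. = FALSE)
  if (n_steps < 2) stop("n_steps must be at least 2", call. = FALSE)
  kappa <- switch(rod_id,
                  p = architecture$kappa_p,
                  k = architecture$kappa_k,
                  b = architecture$kappa_b,
                  stop("unknown rod_id: must be one of \"p\", \"k\", \"b\"",
                       call. = FALSE))
  F0 <- loads$F0_pN; Fk <- loads$Fk_pN; M0 <- loads$M0_pN_um
  # affine moment M(y) = A*y + B per rod
  AB <- switch(rod_id,
               p = c(F0, M0),
               k = c(-Fk, Fk * hk_um),
               b = c(Fk + F0, -Fk * hk_um + M0))
  if (kappa <= 0) {
    if (abs(AB[1]) > 0 || abs(AB[2]) > 0)
      stop("degenerate rod: zero rigidity with non-zero bending moment",
           call. = FALSE)
    # moment-free zero-rigidity rod: straight line
    x <- seq(x_start, x_end, length.out = n_steps + 1)
    return(data.frame(x_um = x, y_um = y_start + slope_start * (x - x_start),
                      slope = rep(slope_start, n_steps + 1)))
  }
  A <- AB[1] / kappa; B <- AB[2] / kappa
  h <- (x_end - x_start) / n_steps
  x <- numeric(n_steps + 1); yv <- numeric(n_steps + 1); vv <- numeric(n_steps + 1)
  x[1] <- x_start; yv[1] <- y_start; vv[1] <- slope_start
  y <- y_start; v <- slope_start
  for (i in seq_len(n_steps)) {
    a1 <- (A * y + B) * (1 + v * v)^1.5
    ym <- y + 0.5 * h * v
    vm <- v + 0.5 * h * a1
    a2 <- (A * ym + B) * (1 + vm * vm)^1.5
    y <- y + h * vm
    v <- v + h * a2
    if (!is.finite(y) || !is.finite(v) || abs(v) > max_slope)
      stop(sprintf(
        "parameterization breakdown on rod %s near x = %.3f um (|slope| > %.0f)",
        rod_id, x_start + i * h, max_slope), call. = FALSE)
    x[i + 1] <- x_start + i * h; yv[i + 1] <- y; vv[i + 1] <- v
  }
  data.frame(x_um = x, y_um = yv, slope = vv)
}

#' Forward solution of the three-rod spindle shape
#'
#' Integrates rod p from the pole `(0, 0)` with slope `tan(theta0)` to the
#' junction at `x = xj_um`, then rods k (to the kinetochore abscissa) and b
#' (to the midplane `L/2`) from the junction with continuous position and
#' slope ("clamped and tangential" junction). The reported loads follow the
#' anchor-force convention of [spindle_loads()]; internally the pole force
#' and pole moment enter the bending moments with reversed sign (see the
#' methods vignette).
#'
#' @param geometry A [spindle_geometry()] object.
#' @param architecture A [fibre_architecture()] object.
#' @param loads A [spindle_loads()] object (anchor-force convention).
#' @param xj_um Junction abscissa, `0 < xj_um < min(xk_um, L/2)`.
#' @param n_steps Steps per rod for the midpoint integrator (default 50).
#' @return An object of class `"spindle_shape"`: list with `rods` (named list
#'   of data frames `p`, `k`, `b` with `x_um`, `y_um`, `slope`), junction
#'   coordinates `xj_um`, `hj_um`, junction slope `slope_j`, midplane height
#'   `h_um` and slope `mid_slope`, and the model-implied kinetochore height
#'   `hk_model_um` and angle `thetak_model_deg` (unsigned).
#' @examples
#' geo <- spindle_geometry(64, 13.7, 11.1, 5.0, 5.05)
#' arch <- fibre_architecture(17, 14)
#' sh <- forward_spindle_shape(geo, arch, spindle_loads(38, 500), 4.55)
#' sh$hk_model_um
#' @export
forward_spindle_shape <- function(geometry, architecture, loads, xj_um,
                                  n_steps = 50) {
  xk <- geometry$xk_um; L <- geometry$L_um
  if (!(xj_um > 0 && xj_um < min(xk, L / 2)))
    stop("xj_um must lie in (0, min(xk_um, L/2))", call. = FALSE)
  sl <- .signed_loads(loads)
  raw <- spindle_loads(sl$a0, sl$ak, sl$m0)
  hk <- geometry$hk_um
  rod_p <- integrate_rod("p", 0, xj_um, 0, tan(geometry$theta0_deg * pi / 180),
                         raw, architecture, hk, n_steps)
  np <- nrow(rod_p)
  hj <- rod_p$y_um[np]; vj <- rod_p$slope[np]
  rod_k <- integrate_rod("k", xj_um, xk, hj, vj, raw, architecture, hk, n_steps)
  rod_b <- integrate_rod("b", xj_um, L / 2, hj, vj, raw, architecture, hk,
                         n_steps)
  nk <- nrow(rod_k); nb <- nrow(rod_b)
  structure(
    list(rods = list(p = rod_p, k = rod_k, b = rod_b),
         xj_um = xj_um, hj_um = hj, slope_j = vj,
         h_um = rod_b$y_um[nb], mid_slope = rod_b$slope[nb],
         hk_model_um = rod_k$y_um[nk],
         slope_k_end = rod_k$slope[nk],
         thetak_model_deg = abs(atan(rod_k$slope[nk])) * 180 / pi,
         L_um = L, n_steps = n_steps,
         loads = loads, geometry = geometry, architecture = architecture),
    class = "spindle_shape")
}

#' @export
print.spindle_shape <- function(x, ...) {
  cat("Three-rod spindle shape (half-spindle):\n")
  cat(sprintf("  junction at (%.3f, %.3f) um, slope %.3f\n",
              x$xj_um, x$hj_um, x$slope_j))
  cat(sprintf("  kinetochore end: y = %.3f um, angle %.2f deg (slope %+.3f)\n",
              x$hk_model_um, x$thetak_model_deg, x$slope_k_end))
  cat(sprintf("  midplane: h = %.3f um, slope %+.4f\n", x$h_um, x$mid_slope))
  invisible(x)
}

#' Mirror a half-spindle shape about the midplane
#'
#' Builds the full pole-to-pole contour from a half-spindle shape by
#' reflection about `x = L/2`: each rod contributes its own points plus the
#' image `(L - x, y)`. The k-fibre contour (rods p + k) and the bridging
#' fibre contour (rods p + b plus mirror) are returned as a single tidy data
#' frame.
#'
#' @param shape A `"spindle_shape"` from [forward_spindle_shape()].
#' @param L_um Pole-to-pole length; defaults to the length stored in `shape`.
#' @return Data frame with columns `rod_id` (`"p"`, `"k"`, `"b"`, `"b'"`,
#'   `"k'"`, `"p'"`; primes are mirror images), `x_um`, `y_um`, `slope`.
#' @examples
#' geo <- spindle_geometry(64, 13.7, 11.1, 5.0, 5.05)
#' arch <- fibre_architecture(17, 14)
#' sh <- forward_spindle_shape(geo, arch, spindle_loads(38, 500), 4.55)
#' full <- mirror_full_spindle(sh)
#' range(full$x_um)   # 0 .. L
#' @export
mirror_full_spindle <- function(shape, L_um = shape$L_um) {
  stopifnot(inherits(shape, "spindle_shape"))
  half <- do.call(rbind, lapply(names(shape$rods), function(id) {
    r <- shape$rods[[id]]
    data.frame(rod_id = id, x_um = r$x_um, y_um = r$y_um, slope = r$slope)
  }))
  if (max(half$x_um) > L_um / 2 + 1e-9)
    stop("shape extends beyond L/2; cannot mirror", call. = FALSE)
  mirror <- half[rev(seq_len(nrow(half))), ]
  mirror$x_um <- L_um - mirror$x_um
  mirror$slope <- -mirror$slope
  mirror$rod_id <- paste0(mirror$rod_id, "'")
  rbind(half, mirror)
}

#' Predicted outcome of severing a k-fibre
#'
#' After laser ablation the k-fibre stub that remains attached to the
#' kinetochore either retains or loses its lateral connection to the bridging
#' fibre, depending on where the cut fell relative to the junction: the
#' connection (and hence interkinetochore tension) survives only when the
#' stub is strictly longer than the kinetochore-to-junction distance.
#' Equality is classified as `"tension_lost"`: connection requires overlap
#' strictly beyond the junction.
#'
#' @param stub_length_um Length of the k-fibre stub (micrometres, >= 0);
#'   vectorised.
#' @param junction_distance_um Distance from kinetochore to junction
#'   (micrometres, >= 0).
#' @return Character vector, `"tension_retained"` or `"tension_lost"`.
#' @examples
#' predict_cut_outcome(2.0, 0.75)   # retained
#' predict_cut_outcome(0.3, 0.75)   # lost
#' @export
predict_cut_outcome <- function(stub_length_um, junction_distance_um) {
  if (any(stub_length_um < 0) || any(junction_distance_um < 0))
    stop("lengths must be non-negative", call. = FALSE)
  ifelse(stub_length_um > junction_distance_um,
         "tension_retained", "tension_lost")
}
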