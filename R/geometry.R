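#' Spindle geometry of one half-spindle
#'
#' Bundles the measured shape parameters of a metaphase half-spindle: the
#' angles of the k-fibre to the spindle long axis near the pole and near the
#' kinetochore, the pole-to-pole length, the half-width (height of the
#' outermost kinetochore above the long axis), and the horizontal kinetochore
#' position measured from the pole. The interkinetochore distance and the
#' kinetochore-to-bridging-fibre distance are optional: they are not needed by
#' the beam model itself but are carried along for bookkeeping and for the
#' synthetic-data generator.
#'
#' Coordinates put the spindle pole at the origin with the long axis along
#' `x` and heights `y >= 0`; the system midplane is at `x = L/2`.
#'
#' @param theta0_deg Angle of the k-fibre to the long axis near the pole
#'   (degrees, in (0, 90)).
#' @param thetak_deg Angle of the k-fibre to the long axis at the kinetochore
#'   (degrees, in \[0, 90)).
#' @param L_um Pole-to-pole spindle length (micrometres).
#' @param hk_um Spindle half-width: height of the outermost kinetochore above
#'   the long axis (micrometres).
#' @param xk_um Horizontal kinetochore position from the pole (micrometres,
#'   in (0, L/2\]).
#' @param dk_um Optional interkinetochore distance (micrometres).
#' @param dbk_um Optional signed kinetochore-to-bridging-fibre distance
#'   (micrometres; positive when the kinetochore lies on the outer side of
#'   the bridging fibre).
#' @return An object of class `"spindle_geometry"`.
#' @examples
#' spindle_geometry(theta0_deg = 64, thetak_deg = 13.7, L_um = 11.1,
#'                  hk_um = 5.0, xk_um = 5.05)
#' @export
spindle_geometry <- function(theta0_deg, thetak_deg, L_um, hk_um, xk_um,
                             dk_um = NA_real_, dbk_um = NA_real_) {
  stopifnot(is.numeric(theta0_deg), is.numeric(thetak_deg), is.numeric(L_um),
            is.numeric(hk_um), is.numeric(xk_um))
  if (!(theta0_deg > 0 && theta0_deg < 90))
    stop("theta0_deg must lie in (0, 90) degrees", call. = FALSE)
  if (!(thetak_deg >= 0 && thetak_deg < 90))
    stop("thetak_deg must lie in [0, 90) degrees", call. = FALSE)
  if (!(L_um > 0)) stop("L_um must be positive", call. = FALSE)
  if (!(hk_um > 0)) stop("hk_um must be positive", call. = FALSE)
  if (!(xk_um > 0 && xk_um <= L_um / 2))
    stop("xk_um must lie in (0, L_um/2]", call. = FALSE)
  structure(
    list(theta0_deg = theta0_deg, thetak_deg = thetak_deg, L_um = L_um,
         hk_um = hk_um, xk_um = xk_um, dk_um = dk_um, dbk_um = dbk_um),
    class = "spindle_geometry")
}

#' @export
print.spindle_geometry <- function(x, ...) {
  cat("Spindle geometry (half-spindle):\n")
  cat(sprintf("  theta0 = %.1f deg, thetak = %.1f deg\n",
              x$theta0_deg, x$thetak_deg))
  cat(sprintf("  L = %.2f um, hk = %.2f um, xk = %.2f um\n",
              x$L_um, x$hk_um, x$xk_um))
  if (is.finite(x$dk_um)) cat(sprintf("  dk = %.2f um\n", x$dk_um))
  if (is.finite(x$dbk_um)) cat(sprintf("  dbk = %.2f um\n", x$dbk_um))
  invisible(x)
}

#' Fibre architecture: microtubule counts and flexural rigidities
#'
#' The model treats each fibre as a bundle of `n` microtubules whose flexural
#' rigidity is additive, `kappa_i = n_i * kappa0`, appropriate when
#' microtubules can slide past each other as the bundle bends. The pole rod
#' contains both the k-fibre and bridging-fibre microtubules,
#' `n_p = n_k + n_b`, so `kappa_p = kappa_k + kappa_b`. For a fully
#' crosslinked bundle (no sliding) rigidity scales with the square of the
#' count; that alternative is exposed via `coupling = "crosslinked"` but is
#' not the default and is not used by the calibrated defaults.
#'
#' @param n_k Number of microtubules in the k-fibre (positive).
#' @param n_b Number of microtubules in the bridging fibre (non-negative).
#' @param kappa0_pN_um2 Flexural rigidity of one microtubule (pN um^2);
#'   default 30.
#' @param coupling `"sliding"` (rigidity proportional to count, default) or
#'   `"crosslinked"` (proportional to count squared).
#' @return An object of class `"fibre_architecture"` with fields `n_k`,
#'   `n_b`, `n_p`, `kappa0_pN_um2`, `kappa_k`, `kappa_b`, `kappa_p`.
#' @examples
#' fibre_architecture(n_k = 17, n_b = 14)
#' @export
fibre_architecture <- function(n_k, n_b, kappa0_pN_um2 = 30,
                               coupling = c("sliding", "crosslinked")) {
  coupling <- match.arg(coupling)
  stopifnot(is.numeric(n_k), is.numeric(n_b), is.numeric(kappa0_pN_um2))
  if (!(n_k > 0)) stop("n_k must be positive", call. = FALSE)
  if (n_b < 0) stop("n_b must be non-negative", call. = FALSE)
  if (!(kappa0_pN_um2 > 0)) stop("kappa0_pN_um2 must be positive", call. = FALSE)
  pow <- if (coupling == "sliding") 1 else 2
  structure(
    list(n_k = n_k, n_b = n_b, n_p = n_k + n_b,
         kappa0_pN_um2 = kappa0_pN_um2, coupling = coupling,
         kappa_k = n_k^pow * kappa0_pN_um2,
         kappa_b = n_b^pow * kappa0_pN_um2,
         kappa_p = if (coupling == "sliding")
           (n_k + n_b) * kappa0_pN_um2 else (n_k^2 + n_b^2) * kappa0_pN_um2),
    class = "fibre_architecture")
}

#' @export
print.fibre_architecture <- function(x, ...) {
  cat(sprintf("Fibre architecture (%s coupling):\n", x$coupling))
  cat(sprintf("  n_k = %g, n_b = %g, n_p = %g; kappa0 = %g pN um^2\n",
              x$n_k, x$n_b, x$n_p, x$kappa0_pN_um2))
  cat(sprintf("  kappa_k = %g, kappa_b = %g, kappa_p = %g pN um^2\n",
              x$kappa_k, x$kappa_b, x$kappa_p))
  invisible(x)
}

#' Boundary loads on the three-rod system
#'
#' Forces and pole moment parameterising the bending moments of the rods.
#' `F0_pN` is the force at the spindle pole (positive = the fibre system
#' presses the pole inward, toward the spindle centre) and `Fk_pN` the
#' tension at the kinetochore (positive = the kinetochore is pulled toward
#' the pole by the k-fibre, i.e. the interkinetochore link is under tension).
#' `M0_pN_um` is the clamping moment at the pole; it trades off against
#' `F0_pN` and is fixed to zero by default in all solves.
#'
#' See `vignette("bridging-fibre-force-balance")` for the exact sign
#' convention with which these loads enter the rod bending moments.
#'
#' @param F0_pN Force at the spindle pole (pN).
#' @param Fk_pN Tension at the kinetochore (pN).
#' @param M0_pN_um Bending moment at the pole (pN um), default 0.
#' @return An object of class `"spindle_loads"`.
#' @examples
#' spindle_loads(F0_pN = 33, Fk_pN = 280)
#' @export
spindle_loads <- function(F0_pN, Fk_pN, M0_pN_um = 0) {
  stopifnot(is.numeric(F0_pN), is.numeric(Fk_pN), is.numeric(M0_pN_um))
  structure(list(F0_pN = F0_pN, Fk_pN = Fk_pN, M0_pN_um = M0_pN_um),
            class = "spindle_loads")
}

#' @export
print.spindle_loads <- function(x, ...) {
  cat(sprintf("Loads: F0 = %.3g pN, Fk = %.3g pN, M0 = %.3g pN um\n",
              x$F0_pN, x$Fk_pN, x$M0_pN_um))
  invisible(x)
}

# internal: signed moment coefficients used by the integrator.
# Reported loads are forces exerted by the fibre system on its anchors;
# in the rod bending moments the pole force enters with opposite sign to
# the kinetochore force (see vignette).
.signed_loads <- function(loads) {
  list(a0 = -loads$F0_pN, ak = loads$Fk_pN, m0 = -loads$M0_pN_um)
}
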