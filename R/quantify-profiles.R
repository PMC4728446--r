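#' Construct a fluorescence line-scan intensity profile
#'
#' A 1-D intensity profile taken along a scan line across a fibre, as
#' produced by drawing a line perpendicular to a k-fibre (or between sister
#' kinetochores, for the bridging fibre) in a tubulin image. Positions must
#' be strictly increasing.
#'
#' @param position_um Strictly increasing sample positions (micrometres).
#' @param intensity Intensities (arbitrary units), same length.
#' @param background Optional scalar cytoplasmic background estimate.
#' @return A data frame of class `"intensity_profile"` with columns
#'   `position_um`, `intensity`, and attributes `background` and
#'   `background_subtracted`.
#' @export
intensity_profile <- function(position_um, intensity, background = NULL) {
  stopifnot(is.numeric(position_um), is.numeric(intensity))
  if (length(position_um) != length(intensity))
    stop("position_um and intensity must have the same length", call. = FALSE)
  if (any(diff(position_um) <= 0))
    stop("position_um must be strictly increasing", call. = FALSE)
  out <- data.frame(position_um = position_um, intensity = intensity)
  attr(out, "background") <- background
  attr(out, "background_subtracted") <- FALSE
  class(out) <- c("intensity_profile", "data.frame")
  out
}

# mean of the outer flank samples (fraction of span at each end)
.flank_values <- function(profile, flank_fraction = 0.2) {
  n <- nrow(profile)
  k <- max(2L, floor(n * flank_fraction / 2))
  profile$intensity[c(seq_len(k), seq.int(n - k + 1L, n))]
}

#' Subtract the cytoplasmic background from a profile
#'
#' Shifts the intensities down by the mean cytoplasmic background. The
#' background is taken from, in order of precedence: the `background`
#' argument, the profile's stored background, or the mean of the flank
#' samples (the outer `flank_fraction` of the scan at each end) when
#' `use_flanks = TRUE`. Values are not clipped at zero.
#'
#' @param profile An [intensity_profile()].
#' @param background Optional scalar background.
#' @param use_flanks If `TRUE` (default), estimate the background from the
#'   profile flanks when no explicit value is available.
#' @param flank_fraction Fraction of samples treated as flank, default 0.2.
#' @return The profile with shifted intensities; attribute
#'   `background_subtracted` set to `TRUE`.
#' @export
subtract_background <- function(profile, background = NULL, use_flanks = TRUE,
                                flank_fraction = 0.2) {
  stopifnot(inherits(profile, "intensity_profile"))
  bg <- background
  if (is.null(bg)) bg <- attr(profile, "background", exact = TRUE)
  if (is.null(bg)) {
    if (!use_flanks)
      stop("no background available: supply `background` or a flank region",
           call. = FALSE)
    bg <- mean(.flank_values(profile, flank_fraction))
  }
  profile$intensity <- profile$intensity - bg
  attr(profile, "background") <- bg
  attr(profile, "background_subtracted") <- TRUE
  profile
}

# trapezoid integral of a sampled profile over [a, b] with linear
# interpolation at the window edges
.trapz_window <- function(x, y, a, b) {
  f <- stats::approxfun(x, y, rule = 2)
  xs <- c(a, x[x > a & x < b], b)
  ys <- f(xs)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

# indices of strict local maxima of v (plateau-free definition)
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Area under an intensity peak
#'
#' Integrates (trapezoid rule) a background-subtracted profile over a window
#' of width `window_width_um` centred on the selected peak. The peak is the
#' local maximum nearest `window_center_um` whose prominence above zero
#' exceeds `min_prominence` (default: twice the standard deviation of the
#' flank samples). If no qualifying peak exists the window is centred on
#' `window_center_um` itself, so a flat zero profile integrates to zero.
#' Typical window widths at the base of the peak are 0.6 um for the bridging
#' fibre and 1 um for the k-fibre.
#'
#' @param profile A background-subtracted [intensity_profile()].
#' @param window_center_um Centre of the search window (micrometres),
#'   typically the midpoint between sister kinetochores.
#' @param window_width_um Width of the integration window (micrometres).
#' @param min_prominence Minimum peak height; default `2 * sd(flanks)`.
#' @return Peak area (a.u. times micrometres).
#' @export
peak_area <- function(profile, window_center_um, window_width_um,
                      min_prominence = NULL) {
  stopifnot(inherits(profile, "intensity_profile"),
            window_width_um > 0)
  x <- profile$position_um; y <- profile$intensity
  half <- window_width_um / 2
  if (window_center_um - half < x[1] - 1e-9 ||
      window_center_um + half > x[length(x)] + 1e-9)
    stop("integration window exceeds the profile span", call. = FALSE)
  if (is.null(min_prominence))
    min_prominence <- 2 * stats::sd(.flank_values(profile))
  if (!is.finite(min_prominence)) min_prominence <- 0
  in_win <- which(x >= window_center_um - half & x <= window_center_um + half)
  lm <- .local_maxima(y)
  lm <- lm[lm %in% in_win & y[lm] >= min_prominence]
  centre <- if (length(lm) > 0)
    x[lm[which.min(abs(x[lm] - window_center_um))]] else window_center_um
  a <- max(centre - half, x[1]); b <- min(centre + half, x[length(x)])
  .trapz_window(x, y, a, b)
}

#' Convert a bridging-fibre intensity ratio to a bridge-to-k-fibre ratio
#'
#' The scan between sister kinetochores measures the bridging-fibre signal
#' `I_b`; the scan across the k-fibre near a kinetochore measures the sum
#' `I_bk = I_k + I_b` because the bridging fibre runs alongside the k-fibre
#' there. Given `r = I_b / I_bk`, the ratio of bridging-fibre to k-fibre
#' signal (and hence of microtubule numbers) is
#' \deqn{I_b / I_k = r / (1 - r).}
#'
#' @param r Ratio `I_b / I_bk`, in `[0, 1)`; vectorised.
#' @return `r / (1 - r)`.
#' @examples
#' bridge_fraction(0.45)   # ~0.82
#' @export
bridge_fraction <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 1))
    stop("r = I_b/I_bk must lie in [0, 1)", call. = FALSE)
  r / (1 - r)
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate the number of microtubules in the bridging fibre
#'
#' Scales the bridge-to-k-fibre intensity ratio by the known number of
#' k-fibre microtubules: `n_b = round(n_k * r / (1 - r))`, rounding half
#' away from zero. The unrounded value is attached as attribute `"raw"`.
#'
#' @param r Ratio `I_b / I_bk`, in `[0, 1)`.
#' @param n_k Number of k-fibre microtubules (> 0).
#' @return Integer estimate of `n_b`, with attribute `raw`.
#' @examples
#' estimate_bridge_mt_number(0.45, 17)   # 14
#' estimate_bridge_mt_number(0.20, 24)   # 6
#' @export
estimate_bridge_mt_number <- function(r, n_k) {
  if (any(n_k <= 0)) stop("n_k must be positive", call. = FALSE)
  raw <- n_k * bridge_fraction(r)
  out <- as.integer(.round_half_away(raw))
  attr(out, "raw") <- raw
  out
}

#' Signed distance between bridging-fibre and kinetochore profile peaks
#'
#' The distance between the kinetochore and the bridging fibre, `d_bk`, is
#' measured as the distance between the peaks of the two intensity profiles
#' taken along the same scan line. The sign convention follows the scan
#' orientation: with positions increasing outward (away from the spindle
#' long axis), the result is positive when the kinetochore peak lies on the
#' outer side of the bridging-fibre peak.
#'
#' @param bridge_profile,kinetochore_profile Background-subtracted
#'   [intensity_profile()]s along the same line.
#' @param min_prominence Minimum peak height above the noise floor; default
#'   `2 * sd(flanks)` per profile.
#' @return Signed peak distance (micrometres): kinetochore peak position
#'   minus bridge peak position.
#' @export
dbk_from_profiles <- function(bridge_profile, kinetochore_profile,
                              min_prominence = NULL) {
  peak_pos <- function(profile) {
    x <- profile$position_um; y <- profile$intensity
    thr <- min_prominence
    if (is.null(thr)) thr <- 2 * stats::sd(.flank_values(profile))
    if (!is.finite(thr)) thr <- 0
    lm <- .local_maxima(y)
    lm <- lm[y[lm] >= thr & y[lm] > 0]
    if (length(lm) == 0)
      stop("no peak above the noise floor in profile", call. = FALSE)
    x[lm[which.max(y[lm])]]
  }
  peak_pos(kinetochore_profile) - peak_pos(bridge_profile)
}

#' Event rate of microtubule plus-end comets
#'
#' Converts counts of directed plus-end comet crossing events (for example,
#' comets traversing the region between sister kinetochores) into rates per
#' minute, per direction class.
#'
#' @param events Data frame with at least a `direction` column (one row per
#'   event), or a non-negative count (scalar) when `direction` is not
#'   needed.
#' @param duration_min Observation time (minutes, > 0).
#' @param direction Optional direction class to select; default all classes.
#' @return Named numeric vector of rates (events per minute), or a single
#'   rate when `events` is a count or `direction` is given.
#' @examples
#' comet_rate(data.frame(direction = rep(c("toward", "away"), c(19, 6))), 10)
#' @export
comet_rate <- function(events, duration_min, direction = NULL) {
  if (!(duration_min > 0)) stop("duration_min must be positive", call. = FALSE)
  if (is.numeric(events) && length(events) == 1L)
    return(events / duration_min)
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    if (!is.null(direction)) return(stats::setNames(0, direction))
    return(numeric(0))
  }
  tab <- table(events$direction)
  rates <- as.numeric(tab) / duration_min
  names(rates) <- names(tab)
  if (!is.null(direction)) {
    r <- rates[direction]
    r[is.na(r)] <- 0
    names(r) <- direction
    return(r)
  }
  rates
}
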