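#' Population parameters of spindle geometry
#'
#' Mean and standard deviation of the measured spindle-shape parameters for
#' the two cell types, together with truncation bounds keeping samples
#' physical (angles inside (0, 90) degrees, lengths positive). These are the
#' population statistics the synthetic generator is calibrated to.
#'
#' @param cell_type `"hela"` or `"ptk1"`.
#' @return A list of class `"geometry_population_params"`: per parameter a
#'   vector `c(mean, sd)`, plus `bounds`, a named list of `c(lower, upper)`.
#' @export
geometry_population_params <- function(cell_type = c("hela", "ptk1")) {
  cell_type <- match.arg(cell_type)
  p <- switch(cell_type,
    hela = list(n_b = c(14, 2), theta0_deg = c(65.5, 8.8),
                thetak_deg = c(13.7, 10.1), dbk_um = c(0.24, 0.15),
                dk_um = c(1.05, 0.32), L_um = c(11.1, 1.2),
                hk_um = c(5.0, 0.7)),
    ptk1 = list(n_b = c(6, 1), theta0_deg = c(52.6, 8.4),
                thetak_deg = c(21.2, 10.2), dbk_um = c(0.20, 0.10),
                dk_um = c(1.92, 0.54), L_um = c(11.8, 1.7),
                hk_um = c(4.0, 0.6)))
  p$bounds <- list(n_b = c(1, Inf), theta0_deg = c(5, 85),
                   thetak_deg = c(0, 85), dbk_um = c(-Inf, Inf),
                   dk_um = c(0.1, Inf), L_um = c(4, Inf),
                   hk_um = c(0.5, Inf))
  p$cell_type <- cell_type
  class(p) <- "geometry_population_params"
  p
}

# truncated-normal sampler (rejection; exact for sd = 0)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  if (stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd) < 1e-6)
    stop("infeasible truncation bounds for mean ", mean, ", sd ", sd,
         call. = FALSE)
  out <- numeric(n); filled <- 0L
  while (filled < n) {
    draw <- stats::rnorm(n - filled, mean, sd)
    keep <- draw[draw >= lower & draw <= upper]
    if (length(keep) > 0) {
      out[(filled + 1L):(filled + length(keep))] <- keep
      filled <- filled + length(keep)
    }
  }
  out
}

#' Sample spindle geometries from the population distributions
#'
#' Draws per-cell geometry parameters as independent truncated normals with
#' the population means and standard deviations, and derives the horizontal
#' kinetochore position as `x_k = L/2 - d_k/2` (outermost kinetochore pair
#' symmetric about the midplane) unless the draw would violate the geometry
#' invariants.
#'
#' @param params A [geometry_population_params()] object.
#' @param n_cells Number of cells to draw (>= 1).
#' @param seed Optional integer seed.
#' @return A list with `geometries` (list of [spindle_geometry()]), `n_b`
#'   (integer vector of bridging-fibre counts), and `params`.
#' @export
sample_geometry <- function(params, n_cells, seed = NULL) {
  stopifnot(inherits(params, "geometry_population_params"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- params$bounds
  draw <- function(name) .rtnorm(n_cells, params[[name]][1], params[[name]][2],
                                 b[[name]][1], b[[name]][2])
  theta0 <- draw("theta0_deg"); thetak <- draw("thetak_deg")
  L <- draw("L_um"); hk <- draw("hk_um"); dk <- draw("dk_um")
  dbk <- draw("dbk_um")
  n_b <- as.integer(round(.rtnorm(n_cells, params$n_b[1], params$n_b[2],
                                  b$n_b[1], b$n_b[2])))
  xk <- pmin(pmax(L / 2 - dk / 2, 0.1), L / 2)
  geoms <- lapply(seq_len(n_cells), function(i)
    spindle_geometry(theta0[i], thetak[i], L[i], hk[i], xk[i], dk[i], dbk[i]))
  list(geometries = geoms, n_b = n_b, params = params)
}

#' Parameters of the post-ablation cut response
#'
#' Population parameters of the kinematic response to severing a k-fibre,
#' calibrated to the measured cohort statistics: an outward perpendicular
#' excursion of the sister kinetochores peaking at 0.32 um about 11 s after
#' the cut followed by a partial return, an interkinetochore relaxation at
#' 4 s whose magnitude depends on stub length through a logistic step
#' centred at the 1 um transition, and a sister tilt at 4 s that grows with
#' the bridging-fibre thickness. Between-cell spreads are the reported
#' s.e.m. values scaled by the square root of the cohort size.
#'
#' @param peak_disp_um Mean peak perpendicular displacement (um).
#' @param peak_disp_sd_um Between-cell s.d. of the peak (um).
#' @param time_to_peak_s Mean time to peak (s).
#' @param time_to_peak_sd_s Between-cell s.d. of the time to peak (s).
#' @param return_timescale_s Exponential time constant of the return phase.
#' @param relax_short_um,relax_long_um Relaxation plateaus for short and
#'   long stubs (um).
#' @param relax_sd_um Between-cell s.d. of the relaxation (um).
#' @param transition_um Stub length at the relaxation transition (um).
#' @param transition_steepness_um Logistic steepness of the transition (um).
#' @param tilt4_deg Named vector: mean sister tilt 4 s after the cut per
#'   bridging-fibre class (degrees), names are n_b values.
#' @param tilt4_sd_deg Named vector of between-cell s.d. per class.
#' @param noise_sd_um Per-frame isotropic positional noise s.d. (um).
#' @param frame_interval_s Acquisition interval (s).
#' @return A list of class `"cut_response_params"`.
#' @export
cut_response_params <- function(peak_disp_um = 0.32,
                                peak_disp_sd_um = 0.04 * sqrt(52),
                                time_to_peak_s = 11,
                                time_to_peak_sd_s = 2,
                                return_timescale_s = 15,
                                relax_short_um = 0.25, relax_long_um = 0.05,
                                relax_sd_um = 0.06 * sqrt(52),
                                transition_um = 1.0,
                                transition_steepness_um = 0.2,
                                tilt4_deg = c("3" = 2.9, "14" = 4.0,
                                              "23" = 15.9),
                                tilt4_sd_deg = c("3" = 4.8, "14" = 3.4,
                                                 "23" = 10.1),
                                noise_sd_um = 0.025, frame_interval_s = 4) {
  structure(list(peak_disp_um = peak_disp_um,
                 peak_disp_sd_um = peak_disp_sd_um,
                 time_to_peak_s = time_to_peak_s,
                 time_to_peak_sd_s = time_to_peak_sd_s,
                 return_timescale_s = return_timescale_s,
                 relax_short_um = relax_short_um,
                 relax_long_um = relax_long_um, relax_sd_um = relax_sd_um,
                 transition_um = transition_um,
                 transition_steepness_um = transition_steepness_um,
                 tilt4_deg = tilt4_deg, tilt4_sd_deg = tilt4_sd_deg,
                 noise_sd_um = noise_sd_um,
                 frame_interval_s = frame_interval_s),
            class = "cut_response_params")
}

#' Mean interkinetochore relaxation as a function of stub length
#'
#' Logistic step between the short-stub and long-stub plateaus, centred at
#' the transition length: cuts closer to the kinetochore (short stubs, below
#' the junction distance) release the tension and relax more.
#'
#' @param stub_length_um Stub length(s) in micrometres.
#' @param params A [cut_response_params()] object.
#' @return Expected relaxation (um).
#' @export
expected_relaxation <- function(stub_length_um,
                                params = cut_response_params()) {
  lo <- params$relax_long_um; hi <- params$relax_short_um
  lo + (hi - lo) /
    (1 + exp((stub_length_um - params$transition_um) /
             params$transition_steepness_um))
}

#' Simulate post-ablation kinetochore tracks
#'
#' Generates per-cell kinetochore tracks with the piecewise kinematics of
#' the cut response: before the cut the sisters sit at their baseline
#' positions; afterwards the pair moves outward (linear rise to a
#' cell-specific peak, then exponential return), the interkinetochore
#' distance contracts linearly over 4 s to its relaxed value (stub-length
#' dependent, see [expected_relaxation()]), and the sister axis tilts,
#' ramping over 4 s to the cell's tilt. A stub tip is placed at the
#' programmed stub length from the proximal sister. Frame-rate sampling and
#' isotropic Gaussian positional noise are applied last.
#'
#' @param params A [cut_response_params()] object.
#' @param geometry A [spindle_geometry()] giving the baseline `hk_um` and
#'   `dk_um`; `dk_um` must be finite.
#' @param stub_length_um Programmed stub length(s): scalar, vector of length
#'   `n_cells`, or `NULL` to draw from a log-normal with median at the
#'   transition length.
#' @param n_cells Number of cells.
#' @param n_b Bridging-fibre class for the tilt response (must match a name
#'   of `params$tilt4_deg`), default 14.
#' @param t_max_s Last frame time (s), default 40.
#' @param seed Optional integer seed.
#' @return A list of [kinetochore_track()]s; each carries an attribute
#'   `truth` with the cell's programmed peak displacement, time to peak,
#'   relaxation, tilt and stub length (the generator's oracle).
#' @export
generate_cut_response <- function(params = cut_response_params(),
                                  geometry, stub_length_um = NULL,
                                  n_cells = 1, n_b = 14, t_max_s = 40,
                                  seed = NULL) {
  stopifnot(inherits(params, "cut_response_params"),
            inherits(geometry, "spindle_geometry"))
  if (!is.finite(geometry$dk_um))
    stop("geometry must carry a finite dk_um", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cls <- as.character(n_b)
  if (!cls %in% names(params$tilt4_deg))
    stop("no tilt calibration for n_b = ", n_b, call. = FALSE)
  if (is.null(stub_length_um))
    stub_length_um <- stats::rlnorm(n_cells,
                                    meanlog = log(params$transition_um),
                                    sdlog = 0.5)
  stub_length_um <- rep_len(stub_length_um, n_cells)
  dt <- params$frame_interval_s
  times <- seq(-2 * dt, t_max_s, by = dt)
  hk <- geometry$hk_um; dk0 <- geometry$dk_um
  lapply(seq_len(n_cells), function(i) {
    A <- stats::rnorm(1, params$peak_disp_um, params$peak_disp_sd_um)
    Tp <- .rtnorm(1, params$time_to_peak_s, params$time_to_peak_sd_s,
                  lower = dt / 2)
    R <- stats::rnorm(1, expected_relaxation(stub_length_um[i], params),
                      params$relax_sd_um)
    tilt <- .rtnorm(1, params$tilt4_deg[[cls]], params$tilt4_sd_deg[[cls]],
                    lower = 0, upper = 80)
    rows <- lapply(times, function(t) {
      D <- if (t <= 0) 0 else if (t <= Tp) A * t / Tp else
        A * exp(-(t - Tp) / params$return_timescale_s)
      ramp <- if (t <= 0) 0 else min(t / 4, 1)
      dk <- dk0 - R * ramp
      phi <- tilt * ramp * pi / 180
      # the programmed excursion D(t) is the perpendicular displacement of
      # the proximal sister; tilt is differential outward motion, so the
      # distal sister trails by dk*sin(phi)
      ctr <- c(0, hk + D - (dk / 2) * sin(phi))
      u <- c(cos(phi), -sin(phi))
      s1 <- ctr - (dk / 2) * u
      s2 <- ctr + (dk / 2) * u
      out <- data.frame(
        time_s = t, object_id = c("sister1", "sister2"),
        x_um = c(s1[1], s2[1]), y_um = c(s1[2], s2[2]))
      if (t > 0) {
        tip <- s1 - stub_length_um[i] * u
        out <- rbind(out, data.frame(time_s = t, object_id = "stub_tip",
                                     x_um = tip[1], y_um = tip[2]))
      }
      out
    })
    df <- do.call(rbind, rows)
    df$x_um <- df$x_um + stats::rnorm(nrow(df), 0, params$noise_sd_um)
    df$y_um <- df$y_um + stats::rnorm(nrow(df), 0, params$noise_sd_um)
    tr <- kinetochore_track(df, axis_origin = c(0, 0),
                            axis_direction = c(1, 0), t_cut_s = 0,
                            frame_interval_s = dt)
    attr(tr, "truth") <- list(peak_disp_um = A, time_to_peak_s = Tp,
                              relaxation_um = R, tilt4_deg = tilt,
                              stub_length_um = stub_length_um[i])
    tr
  })
}

#' Parameters of synthetic intensity line profiles
#'
#' @param amplitude_bridge Peak amplitude of the bridging-fibre Gaussian
#'   (a.u.).
#' @param width_bridge_um,width_kfibre_um Peak widths at the base (um); the
#'   Gaussian s.d. is a quarter of the base width.
#' @param background Cytoplasmic background level (a.u.).
#' @param noise_sd Additive Gaussian noise s.d. (a.u.).
#' @param step_um Sampling step (um), default 0.081 (the pixel size).
#' @param span_um Length of each scan line (um).
#' @return A list of class `"profile_params"`.
#' @export
profile_params <- function(amplitude_bridge = 50, width_bridge_um = 0.6,
                           width_kfibre_um = 1.0, background = 20,
                           noise_sd = 2, step_um = 0.081, span_um = 4) {
  stopifnot(width_bridge_um > 0, width_kfibre_um > 0, step_um > 0)
  structure(list(amplitude_bridge = amplitude_bridge,
                 width_bridge_um = width_bridge_um,
                 width_kfibre_um = width_kfibre_um,
                 background = background, noise_sd = noise_sd,
                 step_um = step_um, span_um = span_um),
            class = "profile_params")
}

#' Simulate a bridging-fibre / k-fibre intensity profile pair
#'
#' Generates the two line scans of the intensity-ratio measurement: the
#' bridge scan (between sister kinetochores, signal `I_b`) and the k-fibre
#' scan (across the k-fibre near a kinetochore, signal `I_bk = I_b + I_k`).
#' Both are Gaussian peaks on a flat background with additive noise; the
#' analytic peak areas satisfy `I_b / I_bk = target_ratio_r` exactly.
#'
#' @param params A [profile_params()] object.
#' @param target_ratio_r Target `I_b / I_bk` in (0, 1).
#' @param seed Optional integer seed.
#' @return List with `bridge` and `kfibre` ([intensity_profile()]s, each
#'   with the true background stored) and `truth` (analytic areas and the
#'   target ratio).
#' @export
generate_intensity_profile <- function(params = profile_params(),
                                       target_ratio_r, seed = NULL) {
  stopifnot(inherits(params, "profile_params"),
            target_ratio_r > 0, target_ratio_r < 1)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, params$span_um, by = params$step_um)
  mid <- params$span_um / 2
  sd_b <- params$width_bridge_um / 4
  sd_k <- params$width_kfibre_um / 4
  area_b <- params$amplitude_bridge * sd_b * sqrt(2 * pi)
  area_bk <- area_b / target_ratio_r
  amp_k <- area_bk / (sd_k * sqrt(2 * pi))
  mk <- function(amp, sd) {
    y <- params$background + amp * exp(-(x - mid)^2 / (2 * sd^2)) +
      stats::rnorm(length(x), 0, params$noise_sd)
    intensity_profile(x, y, background = params$background)
  }
  list(bridge = mk(params$amplitude_bridge, sd_b),
       kfibre = mk(amp_k, sd_k),
       truth = list(area_bridge = area_b, area_bk = area_bk,
                    ratio_r = target_ratio_r, centre_um = mid))
}

#' Sample a noisy contour observation from a solved shape
#'
#' Resamples the pole-to-kinetochore contour (rods p then k) of a forward
#' shape at fixed arc-length spacing — emulating manual contour tracking
#' with points every ~250 nm — and adds isotropic Gaussian noise.
#'
#' @param shape A `"spindle_shape"` from [forward_spindle_shape()].
#' @param spacing_um Arc-length spacing between points, default 0.25.
#' @param noise_sd_um Isotropic positional noise s.d., default 0.
#' @param seed Optional integer seed.
#' @return Data frame with `s_um` (arc length), `x_um`, `y_um`.
#' @export
generate_contour_observation <- function(shape, spacing_um = 0.25,
                                         noise_sd_um = 0, seed = NULL) {
  stopifnot(inherits(shape, "spindle_shape"), spacing_um > 0)
  if (!is.null(seed)) set.seed(seed)
  pts <- rbind(shape$rods$p[, c("x_um", "y_um")],
               shape$rods$k[-1, c("x_um", "y_um")])
  seg <- sqrt(diff(pts$x_um)^2 + diff(pts$y_um)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (spacing_um > total)
    stop("spacing exceeds the contour length", call. = FALSE)
  si <- seq(0, total, by = spacing_um)
  out <- data.frame(
    s_um = si,
    x_um = stats::approx(s, pts$x_um, xout = si)$y,
    y_um = stats::approx(s, pts$y_um, xout = si)$y)
  if (noise_sd_um > 0) {
    out$x_um <- out$x_um + stats::rnorm(nrow(out), 0, noise_sd_um)
    out$y_um <- out$y_um + stats::rnorm(nrow(out), 0, noise_sd_um)
  }
  out
}

#' Simulate plus-end comet crossing events
#'
#' Homogeneous Poisson events per direction class with Gaussian velocities,
#' emulating plus-end comets traversing the bridging fibre.
#'
#' @param rates_per_min Named numeric vector of event rates, e.g.
#'   `c(toward = 1.9, away = 0.6)`.
#' @param duration_min Observation duration (minutes).
#' @param velocity_mean_um_min,velocity_sd_um_min Comet velocity
#'   distribution, defaults 13.1 and 1.1.
#' @param seed Optional integer seed.
#' @return Data frame with `time_min`, `direction`, `velocity_um_min`,
#'   sorted by time.
#' @export
generate_comet_events <- function(rates_per_min = c(toward = 1.9,
                                                    away = 0.6),
                                  duration_min,
                                  velocity_mean_um_min = 13.1,
                                  velocity_sd_um_min = 1.1, seed = NULL) {
  stopifnot(all(rates_per_min >= 0), duration_min > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(names(rates_per_min), function(dir) {
    n <- stats::rpois(1, rates_per_min[[dir]] * duration_min)
    if (n == 0) return(NULL)
    data.frame(time_min = sort(stats::runif(n, 0, duration_min)),
               direction = dir,
               velocity_um_min = stats::rnorm(n, velocity_mean_um_min,
                                              velocity_sd_um_min))
  }))
  if (is.null(out))
    out <- data.frame(time_min = numeric(0), direction = character(0),
                      velocity_um_min = numeric(0))
  out[order(out$time_min), , drop = FALSE]
}
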