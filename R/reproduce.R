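#' Reference inputs of the three-rod force-balance analysis
#'
#' The fixed parameter set used throughout the reference analysis: HeLa
#' geometry (pole angle 64 degrees, spindle length 11.1 um, kinetochore at
#' 5.05 um and height 5.0 um, kinetochore angle 13.7 degrees), 17 k-fibre
#' and 14 bridging microtubules, single-microtubule rigidity 30 pN um^2.
#'
#' @return List with `geometry` ([spindle_geometry()]) and `architecture`
#'   ([fibre_architecture()]).
#' @export
reference_inputs <- function() {
  list(geometry = spindle_geometry(theta0_deg = 64, thetak_deg = 13.7,
                                   L_um = 11.1, hk_um = 5.0, xk_um = 5.05,
                                   dk_um = 1.05, dbk_um = 0.24),
       architecture = fibre_architecture(n_k = 17, n_b = 14,
                                         kappa0_pN_um2 = 30))
}

#' Run the full reference analysis end to end
#'
#' Executes the main computations of the package against their reference
#' values and writes a JSON and a Markdown report: (i) the inverse
#' force-balance solve on the reference geometry; (ii) the pole-force sweep
#' against bridging-fibre thickness for the three fixed parameter sets;
#' (iii) the microtubule-count worked examples; (iv) summaries of a
#' synthetic laser-ablation cohort. Failures in one stage are recorded and
#' the remaining stages still run.
#'
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param n_cells Cohort size of the synthetic stage, default 100.
#' @param nb_grid Bridging-fibre counts for the sweep stage.
#' @param seed Integer seed for the synthetic stage, default 1.
#' @return A list of class `"reproduction_report"` with one entry per
#'   stage: computed values, reference values, tolerances and pass flags.
#' @export
reproduce_analysis <- function(out_dir = NULL, n_cells = 100,
                               nb_grid = c(2, 6, 10, 14, 18, 23, 30),
                               seed = 1) {
  ref <- reference_inputs()
  report <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      list(error = conditionMessage(e)))
    report[[name]] <<- res
    invisible(res)
  }

  stage("force_balance", {
    fb <- solve_force_balance(ref$geometry, ref$architecture)
    vals <- c(junction_distance_um = fb$junction_distance_um,
              F0_pN = fb$loads$F0_pN, Fk_pN = fb$loads$Fk_pN)
    refs <- c(junction_distance_um = 0.75, F0_pN = 33, Fk_pN = 280)
    list(values = vals, reference = refs, tolerance_rel = 0.15,
         pass = as.list(abs(vals / refs - 1) <= 0.15),
         converged = fb$converged, weighted = fb$weighted,
         residuals = fb$residuals)
  })

  stage("pole_force_sweep", {
    sets <- list(black = c(Fk = 280, xj = 4.3),
                 pink = c(Fk = 180, xj = 4.8),
                 green = c(Fk = 380, xj = 3.8))
    sweeps <- lapply(sets, function(s)
      sweep_pole_force(nb_grid, ref$geometry, Fk_pN = s[["Fk"]],
                       xj_um = s[["xj"]]))
    F0_at_14 <- sweeps$black$F0_pN[match(14, sweeps$black$n_b)]
    mono <- vapply(sweeps, function(sw) all(diff(sw$F0_pN) > 0), logical(1))
    list(F0_at_nb14_pN = F0_at_14, reference_F0_pN = 33,
         tolerance_rel = 0.15,
         pass = list(F0_at_nb14 = is.finite(F0_at_14) &&
                       abs(F0_at_14 / 33 - 1) <= 0.15,
                     monotone_all_sets = all(mono)),
         monotone = as.list(mono), sweeps = sweeps)
  })

  stage("mt_counts", {
    frac <- 100 * bridge_fraction(0.45)
    hela <- estimate_bridge_mt_number(0.45, 17)
    ptk1 <- estimate_bridge_mt_number(0.20, 24)
    list(values = c(bridge_fraction_pct = frac, n_b_hela = hela,
                    n_b_ptk1 = ptk1),
         reference = c(bridge_fraction_pct = 82, n_b_hela = 14,
                       n_b_ptk1 = 6),
         pass = list(bridge_fraction_pct = round(frac) == 82,
                     n_b_hela = hela == 14L, n_b_ptk1 = ptk1 == 6L))
  })

  stage("synthetic_cohort", {
    geo <- ref$geometry
    tracks <- generate_cut_response(cut_response_params(), geo,
                                    n_cells = n_cells, seed = seed)
    dt <- cut_response_params()$frame_interval_s
    tt <- sort(unique(tracks[[1]]$time_s[tracks[[1]]$time_s > 0]))
    disp <- vapply(tracks, function(tr)
      vapply(tt, function(t)
        perpendicular_displacement(tr, "sister1", t), numeric(1)),
      numeric(length(tt)))
    peak <- apply(disp, 2, max)
    t_peak <- tt[which.max(rowMeans(disp))]   # timing of the cohort mean
    relax <- vapply(tracks, kk_relaxation, numeric(1))
    list(n_cells = n_cells, seed = seed,
         mean_peak_disp_um = mean(peak),
         se_peak_disp_um = stats::sd(peak) / sqrt(n_cells),
         time_of_mean_peak_s = t_peak,
         mean_relaxation_um = mean(relax),
         se_relaxation_um = stats::sd(relax) / sqrt(n_cells),
         reference = c(peak_disp_um = 0.32, time_to_peak_s = 11,
                       relaxation_um = 0.15),
         pass = list(
           peak_disp = abs(mean(peak) - 0.32) <=
             2 * stats::sd(peak) / sqrt(n_cells),
           time_to_peak = abs(t_peak - 11) <= dt,
           relaxation = abs(mean(relax) - 0.15) <=
             2 * stats::sd(relax) / sqrt(n_cells)))
  })

  class(report) <- "reproduction_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(.report_markdown(report), file.path(out_dir, "report.md"))
  }
  report
}

.report_json <- function(report) {
  lapply(report, function(st) {
    st$sweeps <- NULL    # tables go to the markdown report
    st
  })
}

.report_markdown <- function(report) {
  lines <- c("# Reference analysis report", "")
  for (name in names(report)) {
    st <- report[[name]]
    lines <- c(lines, paste0("## ", name), "")
    if (!is.null(st$error)) {
      lines <- c(lines, paste0("stage failed: ", st$error), "")
      next
    }
    if (!is.null(st$values)) {
      for (k in names(st$values))
        lines <- c(lines, sprintf("- %s: %.4g (reference %.4g)", k,
                                  st$values[[k]], st$reference[[k]]))
    }
    if (!is.null(st$pass)) {
      for (k in names(st$pass))
        lines <- c(lines, sprintf("- check %s: %s", k,
                                  if (isTRUE(st$pass[[k]])) "pass" else
                                    "FAIL"))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(.report_markdown(x), sep = "\n")
  invisible(x)
}
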