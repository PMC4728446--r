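#' Read an intensity profile from CSV
#'
#' Expects columns `position_um` and `intensity`; an optional `background`
#' column (constant) is used as the background estimate.
#'
#' @param path Path to a CSV file.
#' @return An [intensity_profile()].
#' @export
read_intensity_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(df)))
    stop("profile CSV needs columns position_um, intensity", call. = FALSE)
  bg <- if ("background" %in% names(df)) df$background[1] else NULL
  intensity_profile(df$position_um, df$intensity, background = bg)
}

#' Write an intensity profile to CSV
#' @param profile An [intensity_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("position_um", "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a kinetochore track from CSV
#'
#' Expects columns `time_s`, `object_id`, `x_um`, `y_um`. Axis and cut time
#' are supplied as arguments (they are acquisition metadata, not rows).
#'
#' @param path Path to a CSV file.
#' @inheritParams kinetochore_track
#' @return A [kinetochore_track()].
#' @export
read_kinetochore_track <- function(path, axis_origin = c(0, 0),
                                   axis_direction = c(1, 0), t_cut_s = 0,
                                   frame_interval_s = NULL) {
  df <- utils::read.csv(path)
  kinetochore_track(df, axis_origin, axis_direction, t_cut_s,
                    frame_interval_s)
}

#' Write a kinetochore track to CSV
#' @param track A [kinetochore_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetochore_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Export a solved spindle shape as tidy CSV
#'
#' One row per sampled contour point, columns `rod_id`, `x_um`, `y_um`,
#' `slope`.
#'
#' @param shape A `"spindle_shape"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_csv <- function(shape, path) {
  stopifnot(inherits(shape, "spindle_shape"))
  df <- do.call(rbind, lapply(names(shape$rods), function(id)
    cbind(rod_id = id, shape$rods[[id]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate an input file against the package schemas
#'
#' Checks a CSV input (intensity profile or kinetochore track, detected from
#' the header unless `type` is given) for schema and invariant violations,
#' reporting row-level diagnostics instead of failing at first error.
#'
#' @param path Path to the file.
#' @param type `"auto"` (default), `"profile"` or `"track"`.
#' @return A list of class `"input_diagnostics"`: `ok` (logical), `type`,
#'   and `messages` (character vector of problems; empty when valid).
#' @export
validate_inputs <- function(path, type = c("auto", "profile", "track")) {
  type <- match.arg(type)
  msgs <- character(0)
  if (!file.exists(path))
    return(structure(list(ok = FALSE, type = type,
                          messages = paste0("file not found: ", path)),
                     class = "input_diagnostics"))
  df <- tryCatch(utils::read.csv(path), error = function(e) NULL)
  if (is.null(df))
    return(structure(list(ok = FALSE, type = type,
                          messages = "file is not readable as CSV"),
                     class = "input_diagnostics"))
  if (type == "auto") {
    type <- if (all(c("position_um", "intensity") %in% names(df))) "profile"
    else if (all(c("time_s", "object_id") %in% names(df))) "track"
    else {
      return(structure(list(ok = FALSE, type = "unknown",
                            messages = paste0(
                              "cannot identify schema from header: ",
                              paste(names(df), collapse = ", "))),
                       class = "input_diagnostics"))
    }
  }
  check_num <- function(col) {
    if (!col %in% names(df)) {
      msgs <<- c(msgs, paste0("missing column: ", col)); return(FALSE)
    }
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      msgs <<- c(msgs, paste0("column ", col, ": non-numeric value at row ",
                              paste(utils::head(bad, 5), collapse = ", ")))
    length(bad) == 0
  }
  if (type == "profile") {
    ok_p <- check_num("position_um"); check_num("intensity")
    if (ok_p) {
      bad <- which(diff(df$position_um) <= 0)
      if (length(bad) > 0)
        msgs <- c(msgs, paste0("position_um not strictly increasing at row ",
                               paste(utils::head(bad + 1, 5), collapse = ", ")))
    }
  } else {
    ok_t <- check_num("time_s"); check_num("x_um"); check_num("y_um")
    if (!"object_id" %in% names(df))
      msgs <- c(msgs, "missing column: object_id")
    else if (ok_t) {
      for (id in unique(df$object_id)) {
        tt <- df$time_s[df$object_id == id]
        bad <- which(diff(tt) <= 0)
        if (length(bad) > 0)
          msgs <- c(msgs, sprintf(
            "object '%s': time_s not strictly increasing at row %s", id,
            paste(utils::head(bad + 1, 5), collapse = ", ")))
      }
    }
  }
  structure(list(ok = length(msgs) == 0, type = type, messages = msgs),
            class = "input_diagnostics")
}

#' @export
print.input_diagnostics <- function(x, ...) {
  cat(sprintf("Input validation (%s): %s\n", x$type,
              if (x$ok) "OK" else "FAILED"))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with the blocks `geometry`,
#' `architecture`, `loads`, `solver`, `generator`, plus scalar keys `seed`,
#' `out_dir` and `verbosity`. Unknown top-level keys are rejected.
#'
#' @param path Path to a YAML or JSON file.
#' @return A named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  }
  known <- c("geometry", "architecture", "loads", "solver", "generator",
             "seed", "out_dir", "verbosity")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  cfg
}
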