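#' Read and write the package's delimited sensor formats
#'
#' Accelerometer CSV: columns `t_s, ax_g, ay_g, az_g`. Heart-rate CSV:
#' `t_s, hr_bpm`. Cohort CSV: one row per participant with id, class and all
#' assessment fields; [write_cohort_csv()] drops list-columns and writes a
#' JSON sidecar recording the generating configuration (including the seed)
#' next to the table.
#'
#' @param x The tibble to write.
#' @param path File path.
#' @param rate_hz,interval_s Nominal sampling metadata restored as attributes
#'   on read.
#' @param config Optional [cohort_config()] recorded in the sidecar.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name sensor_io
NULL

#' @rdname sensor_io
#' @export
write_accel_csv <- function(x, path) {
  require_columns(x, c("t_s", "ax_g", "ay_g", "az_g"), "accelerometer stream")
  utils::write.csv(as.data.frame(x)[, c("t_s", "ax_g", "ay_g", "az_g")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname sensor_io
#' @export
read_accel_csv <- function(path, rate_hz = NULL) {
  x <- as_tibble(utils::read.csv(path))
  require_columns(x, c("t_s", "ax_g", "ay_g", "az_g"), "accelerometer CSV")
  if (!is.null(rate_hz)) attr(x, "rate_hz") <- rate_hz
  class(x) <- c("fs_accel", class(x))
  x
}

#' @rdname sensor_io
#' @export
write_hr_csv <- function(x, path) {
  require_columns(x, c("t_s", "hr_bpm"), "heart-rate stream")
  utils::write.csv(as.data.frame(x)[, c("t_s", "hr_bpm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname sensor_io
#' @export
read_hr_csv <- function(path, interval_s = NULL) {
  x <- as_tibble(utils::read.csv(path))
  require_columns(x, c("t_s", "hr_bpm"), "heart-rate CSV")
  if (!is.null(interval_s)) attr(x, "interval_s") <- interval_s
  class(x) <- c("fs_hr", class(x))
  x
}

#' @rdname sensor_io
#' @export
write_cohort_csv <- function(x, path, config = NULL) {
  keep <- !vapply(x, is.list, logical(1))
  utils::write.csv(as.data.frame(x)[, keep, drop = FALSE], path,
                   row.names = FALSE)
  if (!is.null(config)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort_config("jsonlite is required to write the config sidecar")
    }
    sidecar <- sub("\\.csv$", "", path)
    jsonlite::write_json(
      unclass(config), paste0(sidecar, "_config.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(path)
}

#' @rdname sensor_io
#' @export
read_cohort_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path))
  if ("frailty_class" %in% names(x)) {
    x$frailty_class <- factor(x$frailty_class, levels = frailty_levels())
  }
  x
}
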