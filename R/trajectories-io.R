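#' Write / read trajectory tables as CSV
#'
#' One row per (subject, maneuver, roi, frame) with pelvic-frame position,
#' displacement kinematics and tracking diagnostics. The round trip is
#' lossless to at least 6 decimals. Malformed files (non-numeric values in
#' numeric columns) raise a parse error reporting the offending row.
#'
#' @param records Tibble with columns `subject`, `maneuver`, `roi`,
#'   `frame`, `t_s`, `x_mm`, `y_mm`, `theta_deg`, `dx_mm`, `dy_mm`,
#'   `dmag_mm`, `phi_deg`, `n_points_tracked`.
#' @param path CSV file path.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns the tibble.
#' @export
write_trajectories <- function(records, path) {
  cols <- trajectory_columns()
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0)
    abort_arg(sprintf("Trajectory table missing column(s): %s.",
                      paste(miss, collapse = ", ")), "urokin_argument_error")
  readr::write_csv(records[cols], path)
  invisible(path)
}

trajectory_columns <- function() {
  c("subject", "maneuver", "roi", "frame", "t_s", "x_mm", "y_mm",
    "theta_deg", "dx_mm", "dy_mm", "dmag_mm", "phi_deg",
    "n_points_tracked")
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path))
    abort_arg(sprintf("Trajectory file '%s' does not exist.", path),
              "urokin_io_error")
  spec <- readr::cols(
    subject = readr::col_character(), maneuver = readr::col_character(),
    roi = readr::col_character(), frame = readr::col_integer(),
    t_s = readr::col_double(), x_mm = readr::col_double(),
    y_mm = readr::col_double(), theta_deg = readr::col_double(),
    dx_mm = readr::col_double(), dy_mm = readr::col_double(),
    dmag_mm = readr::col_double(), phi_deg = readr::col_double(),
    n_points_tracked = readr::col_integer())
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE))
  pb <- readr::problems(tbl)
  if (nrow(pb) > 0)
    abort_arg(sprintf("Malformed trajectory CSV at line %d: expected %s.",
                      pb$row[1], pb$expected[1]),
              "urokin_parse_error")
  miss <- setdiff(trajectory_columns(), names(tbl))
  if (length(miss) > 0)
    abort_arg(sprintf("Trajectory CSV missing column(s): %s.",
                      paste(miss, collapse = ", ")), "urokin_parse_error")
  tbl
}
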