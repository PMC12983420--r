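#' Per-frame displacement kinematics of one segment
#'
#' Converts a pelvic-coordinate pose series into displacements from the
#' rest frame: anterior-posterior `dx_mm` (posterior positive),
#' superior-inferior `dy_mm` (superior positive), rotation `dtheta_deg`,
#' displacement-vector magnitude `dmag_mm` and direction `phi_deg`
#' (`atan2(dy, dx)` in degrees, so pure inferior motion is -90). The
#' direction is flagged unreliable (`phi_unreliable`) when the magnitude is
#' below `phi_min_mm`, because near-rest motion makes the angle numerically
#' meaningless; flagged values are excluded from direction averages
#' downstream.
#'
#' @param pelvic_poses Tibble with `frame`, `x_mm`, `y_mm`, `theta_deg`
#'   (from [to_pelvic()] or ground truth).
#' @param rest_frame_index Index (0-based frame id) of the rest frame;
#'   default 0, i.e. time zero of the loop.
#' @param phi_min_mm Magnitude below which `phi_deg` is flagged
#'   unreliable (default 0.1 mm).
#' @return A `kinematic_record` tibble: `frame`, `dx_mm`, `dy_mm`,
#'   `dtheta_deg`, `dmag_mm`, `phi_deg`, `phi_unreliable`.
#' @examples
#' poses <- tibble::tibble(frame = 0:2, x_mm = c(0, 3, 3),
#'                         y_mm = c(0, 4, -6), theta_deg = 0)
#' displacement_series(poses)
#' @export
displacement_series <- function(pelvic_poses, rest_frame_index = 0,
                                phi_min_mm = 0.1) {
  if (nrow(pelvic_poses) == 0)
    abort_arg("Empty pose series.", "urokin_argument_error")
  i0 <- match(rest_frame_index, pelvic_poses$frame)
  if (is.na(i0))
    abort_arg(sprintf("Rest frame %d not present in the series.",
                      rest_frame_index), "urokin_argument_error")
  dx <- pelvic_poses$x_mm - pelvic_poses$x_mm[i0]
  dy <- pelvic_poses$y_mm - pelvic_poses$y_mm[i0]
  dth <- pelvic_poses$theta_deg - pelvic_poses$theta_deg[i0]
  dmag <- sqrt(dx^2 + dy^2)
  phi <- deg_atan2(dy, dx)
  structure(tibble::tibble(frame = pelvic_poses$frame, dx_mm = dx,
                           dy_mm = dy, dtheta_deg = dth, dmag_mm = dmag,
                           phi_deg = phi,
                           phi_unreliable = dmag < phi_min_mm),
            rest_frame_index = rest_frame_index,
            class = c("kinematic_record", "tbl_df", "tbl", "data.frame"))
}

#' Signed urethral kink angle
#'
#' The kink angle of the proximal-mid-distal chain: the angle between the
#' proximal-to-mid and mid-to-distal segment vectors, signed by their 2D
#' cross product in the pelvic frame. Collinear origins give 0; the sign
#' convention is positive when the chain bends so the mid segment is convex
#' toward anterior (cross product `(mid - prox) x (dist - mid) > 0`), which
#' distinguishes convex from concave kinking and flips under mirror
#' reflection. The angle is invariant under global rotation and
#' translation of the three points.
#'
#' @param prox_xy,mid_xy,dist_xy Length-2 numeric `(x, y)` positions, or
#'   equal-length 2-column matrices for a vectorised call.
#' @return Signed angle(s) in degrees, in `(-180, 180]`.
#' @examples
#' kink_angle(c(0, 2), c(0, 1), c(1, 1))  # right-angle bend
#' @export
kink_angle <- function(prox_xy, mid_xy, dist_xy) {
  p <- matrix(as.numeric(prox_xy), ncol = 2,
              nrow = if (is.matrix(prox_xy)) nrow(prox_xy) else 1)
  m <- matrix(as.numeric(mid_xy), ncol = 2,
              nrow = if (is.matrix(mid_xy)) nrow(mid_xy) else 1)
  d <- matrix(as.numeric(dist_xy), ncol = 2,
              nrow = if (is.matrix(dist_xy)) nrow(dist_xy) else 1)
  v1 <- m - p
  v2 <- d - m
  l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2))
  if (any(l1 < 1e-9) || any(l2 < 1e-9))
    abort_arg("Coincident adjacent segment origins: kink angle undefined.",
              "urokin_degenerate_geometry_error")
  cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  dot <- rowSums(v1 * v2)
  deg_atan2(cross, dot)
}

#' Relative mobility of adjacent urethral segments
#'
#' Difference in displacement magnitude between the lower (more distal)
#' and upper (more proximal) of two adjacent segments, normalised by their
#' rest-frame separation along the superior-inferior axis. Negative values
#' indicate greater motion in the more proximal segment. The rest-frame
#' (not per-frame) distance is used so the measure is a pure function of
#' the displacements.
#'
#' @param dmag_upper_mm,dmag_lower_mm Displacement magnitudes (mm) of the
#'   upper and lower segments, typically at the maximum-excursion frame.
#' @param rest_distance_y_mm Rest-frame `|y_upper - y_lower|` in mm (> 0).
#' @return Relative mobility in mm/mm.
#' @examples
#' relative_mobility(6, 3, 10)  # proximal moves more: negative
#' @export
relative_mobility <- function(dmag_upper_mm, dmag_lower_mm,
                              rest_distance_y_mm) {
  if (any(rest_distance_y_mm <= 0))
    abort_arg("`rest_distance_y_mm` must be > 0.",
              "urokin_degenerate_geometry_error")
  (dmag_lower_mm - dmag_upper_mm) / rest_distance_y_mm
}

#' Maximum-excursion frame
#'
#' Finds the frame maximising the excursion statistic over a kinematic
#' record (default: the displacement magnitude). Ties are broken by the
#' earliest frame.
#'
#' @param record A `kinematic_record` (or any tibble with `frame` and the
#'   statistic column).
#' @param statistic Column name to maximise (default `"dmag_mm"`).
#' @return A list with `frame` (0-based id) and `value`.
#' @export
max_excursion <- function(record, statistic = "dmag_mm") {
  if (nrow(record) == 0)
    abort_arg("Empty kinematic record.", "urokin_argument_error")
  v <- record[[statistic]]
  i <- which.max(v)  # which.max returns the first maximum: earliest frame
  list(frame = record$frame[i], value = v[i])
}

#' Select the greatest-excursion trial among repetitions
#'
#' Given maneuver results for repeated trials of the same maneuver,
#' returns the one whose maximum-excursion statistic is largest (ties:
#' lowest trial index), mirroring the acquisition rule of analysing the
#' trial with the greatest urethral excursion.
#'
#' @param results List of maneuver-result objects, each with a
#'   `max_excursion_mm` element (as produced by [subject_metrics()]).
#' @return The chosen element of `results`, with attribute `trial_index`.
#' @export
select_trial <- function(results) {
  if (length(results) == 0)
    abort_arg("No trials supplied.", "urokin_argument_error")
  stat <- vapply(results, function(r) r$max_excursion_mm, numeric(1))
  i <- which.max(stat)
  structure(results[[i]], trial_index = i)
}

#' Segment-level metrics for one subject-maneuver
#'
#' Assembles the full kinematic read-out from per-segment pelvic pose
#' series: per-frame displacement records, the maximum-excursion frame
#' (statistic configurable; default the proximal segment's displacement
#' magnitude, i.e. bladder-neck excursion), displacement vector components
#' at that frame per segment, kink angle at rest and at maximum excursion,
#' and relative segmental mobility.
#'
#' @param pelvic Named list (`proximal`, `mid`, `distal`) of pelvic pose
#'   tibbles (`frame`, `x_mm`, `y_mm`, `theta_deg`).
#' @param rest_frame_index Rest frame id (default 0).
#' @param excursion_roi Segment whose displacement magnitude defines
#'   maximum excursion: `"proximal"` (default), `"mid"`, `"distal"`, or
#'   `"mean"` for the across-segment mean.
#' @return A list of class `maneuver_result` with elements `metrics` (a
#'   tibble, one row per segment), `records` (per-frame kinematic
#'   records), `relations` (per-frame kink angle series),
#'   `max_frame`, `max_excursion_mm`, `omega_rest_deg`, `omega_max_deg`,
#'   `r_prox_mid`, `r_mid_dist`.
#' @export
subject_metrics <- function(pelvic, rest_frame_index = 0,
                            excursion_roi = "proximal") {
  rois <- intersect(URETHRA_ROIS, names(pelvic))
  if (length(rois) == 0)
    abort_arg("No urethral pose series supplied.", "urokin_argument_error")
  if (!excursion_roi %in% c(rois, "mean"))
    abort_arg(sprintf("Excursion segment '%s' was not tracked.",
                      excursion_roi), "urokin_argument_error")
  records <- lapply(pelvic[rois], displacement_series,
                    rest_frame_index = rest_frame_index)
  stat_tbl <- if (excursion_roi == "mean") {
    tibble::tibble(frame = records[[1]]$frame,
                   dmag_mm = Reduce(`+`, lapply(records, `[[`, "dmag_mm")) /
                     length(records))
  } else records[[excursion_roi]]
  mx <- max_excursion(stat_tbl)
  i_max <- match(mx$frame, records[[1]]$frame)
  i_rest <- match(rest_frame_index, records[[1]]$frame)

  # chain metrics need all three segments; with a subset they are NA
  full_chain <- all(URETHRA_ROIS %in% rois)
  omega_rest <- omega_max <- NA_real_
  r_pm <- r_md <- NA_real_
  omega_series <- rep(NA_real_, nrow(records[[1]]))
  if (full_chain) {
    pos_at <- function(i) lapply(pelvic[URETHRA_ROIS], function(p)
      c(p$x_mm[i], p$y_mm[i]))
    omega_rest <- do.call(kink_angle, unname(pos_at(i_rest)))
    omega_max <- do.call(kink_angle, unname(pos_at(i_max)))
    omega_series <- kink_angle(
      cbind(pelvic$proximal$x_mm, pelvic$proximal$y_mm),
      cbind(pelvic$mid$x_mm, pelvic$mid$y_mm),
      cbind(pelvic$distal$x_mm, pelvic$distal$y_mm))
    ydist <- function(a, b)
      abs(pelvic[[a]]$y_mm[i_rest] - pelvic[[b]]$y_mm[i_rest])
    r_pm <- relative_mobility(records$proximal$dmag_mm[i_max],
                              records$mid$dmag_mm[i_max],
                              ydist("proximal", "mid"))
    r_md <- relative_mobility(records$mid$dmag_mm[i_max],
                              records$distal$dmag_mm[i_max],
                              ydist("mid", "distal"))
  }

  metrics <- dplyr::bind_rows(lapply(rois, function(lab) {
    r <- records[[lab]]
    tibble::tibble(roi = lab, dx_mm = r$dx_mm[i_max], dy_mm = r$dy_mm[i_max],
                   dtheta_deg = r$dtheta_deg[i_max],
                   dmag_mm = r$dmag_mm[i_max], phi_deg = r$phi_deg[i_max],
                   phi_unreliable = r$phi_unreliable[i_max])
  }))
  metrics$omega_rest_deg <- omega_rest
  metrics$omega_max_deg <- omega_max
  metrics$r_prox_mid <- r_pm
  metrics$r_mid_dist <- r_md
  metrics$max_frame <- mx$frame

  structure(list(metrics = metrics, records = records,
                 relations = tibble::tibble(frame = records[[1]]$frame,
                                            omega_deg = omega_series),
                 max_frame = mx$frame, max_excursion_mm = mx$value,
                 omega_rest_deg = omega_rest, omega_max_deg = omega_max,
                 r_prox_mid = r_pm, r_mid_dist = r_md),
            class = "maneuver_result")
}
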