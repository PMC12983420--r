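#' Construct the pubis-anchored coordinate frame per frame
#'
#' Builds, for every frame of the loop, the anatomical coordinate system in
#' which urethral motion is reported: origin at the inferior pubic point
#' (IPP), x-axis tangent to the inferior pubic margin pointing posteriorly
#' (from the IPP toward the annotated tangent point), y-axis perpendicular
#' pointing superiorly. The frame-0 axes come from the annotation; every
#' subsequent frame's origin and axes are obtained by applying the tracked
#' rigid pose of the pubis, so the frame moves with the probe-pubis motion
#' and measuring in it removes that confounder.
#'
#' @param pubis_pose_series A `pose_series` from [track_roi()] for the
#'   pubis ROI.
#' @param annotation The [roi_annotation()] (supplies IPP and tangent).
#' @param pixel_spacing_mm Isotropic pixel spacing in mm/px.
#' @return A `pelvic_frame` object: tibble with per-frame `frame`,
#'   `ipp_x_px`, `ipp_y_px`, `ex_x`, `ex_y`, `ey_x`, `ey_y` (unit axes in
#'   image coordinates) and `pubis_theta_deg`, with attribute
#'   `pixel_spacing_mm`.
#' @export
construct_frame <- function(pubis_pose_series, annotation,
                            pixel_spacing_mm) {
  stopifnot(inherits(annotation, "roi_annotation"))
  axes <- annotation_axes(annotation)
  rigids <- attr(pubis_pose_series, "rigid")
  nf <- nrow(pubis_pose_series)
  ipp <- matrix(NA_real_, nf, 2)
  ex <- matrix(NA_real_, nf, 2)
  ey <- matrix(NA_real_, nf, 2)
  for (t in seq_len(nf)) {
    A <- rigids[[t]]
    ipp[t, ] <- as.numeric(rigid_apply(A, matrix(annotation$ipp_px, 1)))
    ex[t, ] <- as.numeric(A$R %*% axes$x)
    ey[t, ] <- as.numeric(A$R %*% axes$y)
  }
  out <- tibble::tibble(frame = pubis_pose_series$frame,
                        ipp_x_px = ipp[, 1], ipp_y_px = ipp[, 2],
                        ex_x = ex[, 1], ex_y = ex[, 2],
                        ey_x = ey[, 1], ey_y = ey[, 2],
                        pubis_theta_deg = pubis_pose_series$theta_deg)
  structure(out, pixel_spacing_mm = pixel_spacing_mm,
            class = c("pelvic_frame", class(out)))
}

#' Express an ROI pose series in pelvic coordinates
#'
#' Projects the tracked ROI origin onto the per-frame pelvic axes and
#' scales to millimetres; orientation is the ROI rotation minus the pubis
#' rotation. The raster row direction points inferiorly, so this
#' projection is where the single sign flip to the superior-positive
#' anatomical y-axis happens (the pelvic y-axis unit vector already points
#' superiorly in image coordinates), and rotation is negated so that
#' positive pelvic rotation is counter-clockwise with y up.
#'
#' @param pose_series A `pose_series` from [track_roi()].
#' @param frame A `pelvic_frame` from [construct_frame()].
#' @return A tibble with columns `frame`, `x_mm`, `y_mm`, `theta_deg`
#'   (pelvic coordinates) plus the tracking diagnostics carried over.
#' @export
to_pelvic <- function(pose_series, frame) {
  stopifnot(inherits(frame, "pelvic_frame"))
  if (nrow(pose_series) != nrow(frame))
    abort_arg("Pose series and pelvic frame must have equal lengths.",
              "urokin_argument_error")
  spacing <- attr(frame, "pixel_spacing_mm")
  vx <- pose_series$x_px - frame$ipp_x_px
  vy <- pose_series$y_px - frame$ipp_y_px
  x_mm <- (vx * frame$ex_x + vy * frame$ex_y) * spacing
  y_mm <- (vx * frame$ey_x + vy * frame$ey_y) * spacing
  theta <- -(pose_series$theta_deg - frame$pubis_theta_deg)
  tibble::tibble(
    frame = pose_series$frame,
    x_mm = x_mm,
    y_mm = y_mm,
    theta_deg = theta,
    n_points_tracked = pose_series$n_points_tracked,
    mean_fb_error_px = pose_series$mean_fb_error_px,
    reseeded = pose_series$reseeded)
}
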