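#' Smooth sinusoidal probe-motion series
#'
#' Generates a global rigid probe-pubis motion confounder: sinusoidal
#' translation along a fixed direction plus a small sinusoidal rotation
#' about the frame centre. Amplitude 0 yields a static probe.
#'
#' @param n_frames Number of frames.
#' @param frame_rate_hz Frame rate in Hz.
#' @param amplitude_px Peak translation in pixels.
#' @param period_s Oscillation period in seconds.
#' @param direction_deg Translation direction in image coordinates
#'   (degrees; 0 = +x/rightward).
#' @param rotation_amplitude_deg Peak rotation in degrees.
#' @param phase Phase offset in radians.
#' @return A tibble with columns `frame`, `tx_px`, `ty_px`, `rot_deg`.
#' @export
probe_motion_series <- function(n_frames, frame_rate_hz = 30,
                                amplitude_px = 4, period_s = 2.5,
                                direction_deg = 20,
                                rotation_amplitude_deg = 1, phase = 0) {
  t <- (seq_len(n_frames) - 1) / frame_rate_hz
  s <- sin(2 * pi * t / period_s + phase) - sin(phase)  # zero at frame 0
  d <- direction_deg * pi / 180
  tibble::tibble(frame = seq_len(n_frames) - 1L,
                 tx_px = amplitude_px * s * cos(d),
                 ty_px = amplitude_px * s * sin(d),
                 rot_deg = rotation_amplitude_deg * s)
}

zero_probe_motion <- function(n_frames) {
  tibble::tibble(frame = seq_len(n_frames) - 1L, tx_px = 0, ty_px = 0,
                 rot_deg = 0)
}

#' Render a synthetic speckle cine with known ground truth
#'
#' Rigidly warps each annotated ROI patch of a speckle texture along its
#' prescribed pelvic-frame trajectory, composes that with a global probe
#' motion applied to the whole frame, blends patch edges with a
#' cosine-tapered margin to avoid seam artifacts, and adds zero-mean
#' Gaussian noise. The pubis patch moves with the probe motion only. The
#' returned ground truth holds the probe-motion-free pelvic-frame pose of
#' every ROI per frame, which is what the tracking + frame-correction
#' pipeline should recover.
#'
#' @param texture Background speckle image (H x W matrix in `[0, 1]`), e.g.
#'   from [generate_speckle_field()].
#' @param annotation An [roi_annotation()] within the texture bounds.
#' @param trajectories Named list (`proximal`, `mid`, `distal`) of tibbles
#'   as returned by [maneuver_trajectory()] (equal frame counts).
#' @param probe_motion Optional tibble from [probe_motion_series()]; `NULL`
#'   means a static probe.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units; default 0.02).
#' @param seed Integer seed for the noise; rendering is bitwise
#'   reproducible for fixed inputs and seed.
#' @param frame_rate_hz,pixel_spacing_mm Acquisition metadata for the
#'   resulting [cine_loop()] (defaults 30 Hz, 0.2 mm/px).
#' @param pad_rigid_px Rigid margin around each rectangle that moves with
#'   it (keeps feature windows on rigidly-moving texture).
#' @param taper_px Width of the cosine blend from patch to background.
#' @return A list with elements `cine` (a [cine_loop()]) and `truth`
#'   (list with `trajectories`: tibble `frame, roi, x_mm, y_mm, theta_deg`
#'   in pelvic coordinates, and `probe`: the probe-motion tibble).
#' @export
render_cine <- function(texture, annotation, trajectories,
                        probe_motion = NULL, noise_sd = 0.02, seed = 1,
                        frame_rate_hz = 30, pixel_spacing_mm = 0.2,
                        pad_rigid_px = 16, taper_px = 8) {
  stopifnot(is.matrix(texture), inherits(annotation, "roi_annotation"))
  H <- nrow(texture); W <- ncol(texture)
  check_annotation_bounds(annotation, c(H, W))
  miss <- setdiff(URETHRA_ROIS, names(trajectories))
  if (length(miss) > 0)
    abort_arg(sprintf("`trajectories` missing segment(s): %s.",
                      paste(miss, collapse = ", ")), "urokin_argument_error")
  nf <- nrow(trajectories[[URETHRA_ROIS[1]]])
  if (!all(vapply(trajectories[URETHRA_ROIS], nrow, 1L) == nf))
    abort_arg("All trajectories must have the same frame count.",
              "urokin_argument_error")
  if (is.null(probe_motion)) probe_motion <- zero_probe_motion(nf)
  if (nrow(probe_motion) != nf)
    abort_arg("`probe_motion` must match the trajectory frame count.",
              "urokin_argument_error")
  axes <- annotation_axes(annotation)
  centre <- c((W - 1) / 2, (H - 1) / 2)

  frames <- vector("list", nf)
  with_seed(seed, {
    for (t in seq_len(nf)) {
      g <- rigid(probe_motion$rot_deg[t],
                 t = c(probe_motion$tx_px[t], probe_motion$ty_px[t]))
      # probe rotation acts about the frame centre
      g$t <- g$t + centre - as.numeric(g$R %*% centre)
      frame <- warp_by_rigid(texture, g, H, W)
      for (lab in ALL_ROIS) {
        l <- local_transform(annotation, lab, trajectories, t, axes,
                             pixel_spacing_mm)
        if (is.null(l)) next  # pubis with no local motion: already in frame
        m <- rigid_compose(g, l)
        frame <- paste_patch(frame, texture, annotation$rois[[lab]], m, g,
                             lab, t - 1L, pad_rigid_px, taper_px)
      }
      # pubis moves with the probe only, but still check it stays in frame
      check_rect_in_frame(rigid_apply(g, rect_corners(annotation$rois$pubis)),
                          H, W, "pubis", t - 1L)
      frames[[t]] <- add_noise_clip_cpp(frame, noise_sd)
    }
  })

  rest <- rest_pelvic_positions(annotation, pixel_spacing_mm)
  truth <- dplyr::bind_rows(lapply(ALL_ROIS, function(lab) {
    if (lab == "pubis") {
      tibble::tibble(frame = probe_motion$frame, roi = lab,
                     x_mm = rest[[lab]][1], y_mm = rest[[lab]][2],
                     theta_deg = 0)
    } else {
      tr <- trajectories[[lab]]
      tibble::tibble(frame = tr$frame, roi = lab,
                     x_mm = rest[[lab]][1] + tr$dx_mm,
                     y_mm = rest[[lab]][2] + tr$dy_mm,
                     theta_deg = tr$dtheta_deg)
    }
  }))
  list(cine = cine_loop(frames, frame_rate_hz, pixel_spacing_mm,
                        source = "synthetic"),
       truth = list(trajectories = truth, probe = probe_motion))
}

# Pelvic-frame rest position (mm) of each ROI origin.
rest_pelvic_positions <- function(annotation, pixel_spacing_mm) {
  axes <- annotation_axes(annotation)
  out <- lapply(annotation$rois, function(r) {
    v <- rect_origin(r) - annotation$ipp_px
    c(sum(v * axes$x), sum(v * axes$y)) * pixel_spacing_mm
  })
  out
}

# Local (probe-free) rigid transform of one ROI at frame t (1-based).
# Returns NULL for the pubis (identity; it is rendered by the global warp).
local_transform <- function(annotation, lab, trajectories, t, axes,
                            spacing) {
  if (lab == "pubis") return(NULL)
  tr <- trajectories[[lab]]
  d_px <- (tr$dx_mm[t] * axes$x + tr$dy_mm[t] * axes$y) / spacing
  # anatomical rotation is counter-clockwise with y up; in raster image
  # coordinates (y down) the same physical rotation has opposite sign
  ang_img <- -tr$dtheta_deg[t]
  o0 <- rect_origin(annotation$rois[[lab]])
  l <- rigid(ang_img)
  l$t <- o0 + d_px - as.numeric(l$R %*% o0)
  l
}

warp_by_rigid <- function(img, tr, out_h, out_w) {
  inv <- rigid_invert(tr)
  warp_affine_cpp(img, out_h, out_w,
                  c(inv$R[1, 1], inv$R[1, 2], inv$t[1],
                    inv$R[2, 1], inv$R[2, 2], inv$t[2]))
}

check_rect_in_frame <- function(corners, H, W, lab, frame0) {
  if (min(corners[, 1]) < 0 || max(corners[, 1]) > W - 1 ||
      min(corners[, 2]) < 0 || max(corners[, 2]) > H - 1)
    abort_arg(sprintf("ROI '%s' exits the frame bounds at frame %d.",
                      lab, frame0), "urokin_bounds_error")
  invisible(NULL)
}

# Blend the rigidly-moved ROI patch into `frame`. `m` maps rest texture
# coordinates to the current frame; weights are 1 over rect +/- pad_rigid,
# cosine-taper to 0 over the next taper_px, evaluated in rest coordinates.
paste_patch <- function(frame, texture, rect, m, g, lab, frame0,
                        pad_rigid, taper) {
  H <- nrow(frame); W <- ncol(frame)
  check_rect_in_frame(rigid_apply(m, rect_corners(rect)), H, W, lab, frame0)
  ext <- pad_rigid + taper
  xr <- c(rect[1] - ext, rect[1] + rect[3] + ext)
  yr <- c(rect[2] - rect[4] - ext, rect[2] + ext)
  ext_corners <- cbind(c(xr[1], xr[2], xr[2], xr[1]),
                       c(yr[1], yr[1], yr[2], yr[2]))
  moved <- rigid_apply(m, ext_corners)
  cx <- floor(max(0, min(moved[, 1]))):ceiling(min(W - 1, max(moved[, 1])))
  cy <- floor(max(0, min(moved[, 2]))):ceiling(min(H - 1, max(moved[, 2])))
  if (length(cx) == 0 || length(cy) == 0) return(frame)
  qx <- rep(cx, times = length(cy))
  qy <- rep(cy, each = length(cx))
  inv <- rigid_invert(m)
  px <- inv$R[1, 1] * qx + inv$R[1, 2] * qy + inv$t[1]
  py <- inv$R[2, 1] * qx + inv$R[2, 2] * qy + inv$t[2]
  # distance outside the rigid core, in rest coordinates
  dxo <- pmax(0, (rect[1] - pad_rigid) - px, px - (rect[1] + rect[3] + pad_rigid))
  dyo <- pmax(0, (rect[2] - rect[4] - pad_rigid) - py, py - (rect[2] + pad_rigid))
  d <- pmax(dxo, dyo)
  w <- 0.5 * (1 + cos(pi * pmin(d, taper) / taper))
  keep <- w > 0
  if (!any(keep)) return(frame)
  val <- sample_bilinear_cpp(texture, px[keep], py[keep])
  idx <- cbind(qy[keep] + 1L, qx[keep] + 1L)
  frame[idx] <- w[keep] * val + (1 - w[keep]) * frame[idx]
  frame
}
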