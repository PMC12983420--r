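#' Tracker settings
#'
#' Parameters of the sparse feature tracker: Shi-Tomasi corner detection
#' followed by pyramidal Lucas-Kanade optical flow with a forward-backward
#' validity check and robust rigid pose estimation.
#'
#' @param quality_level Corners are kept when their minimum-eigenvalue
#'   response exceeds `quality_level` times the strongest response in the
#'   ROI (default 0.01).
#' @param min_distance_px Minimum mutual distance between corners (px).
#' @param max_features Maximum number of corners retained per ROI.
#' @param win_half_px Half-width of the Lucas-Kanade window (window size
#'   `2 * win_half_px + 1`, default 10 i.e. 21 px).
#' @param pyramid_levels Number of pyramid levels (default 3).
#' @param max_iter,eps Iteration cap and convergence threshold (px) of the
#'   flow refinement.
#' @param fb_tol_px Forward-backward error tolerance: a point is valid iff
#'   tracking it forward then backward returns within this distance of its
#'   start (default 1 px).
#' @param min_ncc Appearance check: minimum zero-mean normalized
#'   cross-correlation between the reference window and its matched window
#'   (default 0.5); rejects coincidental matches on decorrelated texture.
#' @param min_points Minimum valid correspondences required for a pose
#'   (default 10).
#' @param reseed_fraction Re-detect features when the tracked fraction
#'   falls below this value (default 0.5).
#' @param ransac_iter,ransac_tol_px RANSAC iterations and inlier threshold
#'   for the rigid fit (defaults 64 and 2 px).
#' @return A list of class `track_settings`.
#' @export
track_settings <- function(quality_level = 0.01, min_distance_px = 3,
                           max_features = 80, win_half_px = 10,
                           pyramid_levels = 3, max_iter = 30, eps = 0.01,
                           fb_tol_px = 1.0, min_ncc = 0.5,
                           min_points = 10,
                           reseed_fraction = 0.5, ransac_iter = 64,
                           ransac_tol_px = 2.0) {
  s <- as.list(environment())
  for (nm in c("quality_level", "min_distance_px", "max_features",
               "win_half_px", "pyramid_levels", "fb_tol_px", "min_points"))
    assert_scalar_num(s[[nm]], nm, positive = TRUE)
  structure(s, class = "track_settings")
}

#' Detect trackable corner features inside an ROI
#'
#' Shi-Tomasi (minimum eigenvalue of the local structure tensor) corner
#' detection restricted to an annotated rectangle, with non-maximum
#' suppression and a minimum mutual distance. Deterministic for fixed
#' input.
#'
#' @param frame H x W intensity matrix in `[0, 1]`.
#' @param rect Rectangle `c(origin_x, origin_y, width, height)` with a
#'   bottom-left origin (see [roi_annotation()]).
#' @param settings A [track_settings()].
#' @param label ROI name used in error messages.
#' @return A tibble with columns `x`, `y` (0-based px) and `quality`,
#'   ordered by decreasing quality.
#' @export
detect_features <- function(frame, rect, settings = track_settings(),
                            label = "roi") {
  H <- nrow(frame); W <- ncol(frame)
  x0 <- max(0, floor(rect[1])); x1 <- min(W - 1, ceiling(rect[1] + rect[3]))
  y0 <- max(0, floor(rect[2] - rect[4])); y1 <- min(H - 1, ceiling(rect[2]))
  if (x1 - x0 < 4 || y1 - y0 < 4)
    abort_arg(sprintf("ROI '%s' is too small for feature detection.", label),
              "urokin_argument_error")
  sub <- frame[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  resp <- shi_tomasi_response(sub)
  mx <- max(resp)
  if (mx <= 1e-12)
    abort_arg(sprintf("ROI '%s' has too little texture for tracking.", label),
              "urokin_low_texture_error")
  thr <- settings$quality_level * mx
  # 3 x 3 non-maximum suppression
  nms <- resp >= shift_max3(resp) & resp >= thr
  idx <- which(nms, arr.ind = TRUE)
  if (nrow(idx) == 0)
    abort_arg(sprintf("ROI '%s' has too little texture for tracking.", label),
              "urokin_low_texture_error")
  q <- resp[idx]
  ord <- order(q, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; q <- q[ord]
  # greedy min-distance filter on an occupancy grid
  keep <- greedy_min_dist(idx[, 2], idx[, 1], settings$min_distance_px,
                          settings$max_features)
  pts <- tibble::tibble(x = x0 + idx[keep, 2] - 1, y = y0 + idx[keep, 1] - 1,
                        quality = q[keep])
  if (nrow(pts) < settings$min_points)
    abort_arg(sprintf(
      "ROI '%s': only %d trackable features found (need >= %d).",
      label, nrow(pts), settings$min_points), "urokin_low_texture_error")
  pts
}

shi_tomasi_response <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  a <- box_sum(gx * gx); b <- box_sum(gx * gy); c_ <- box_sum(gy * gy)
  # minimum eigenvalue of [[a, b], [b, c]]
  lam <- (a + c_) / 2 - sqrt(((a - c_) / 2)^2 + b^2)
  lam[c(1:2, H - 1:0), ] <- 0
  lam[, c(1:2, W - 1:0)] <- 0
  lam
}

# 3x3 box sum via 2D cumulative sums.
box_sum <- function(m, h = 1L) {
  H <- nrow(m); W <- ncol(m)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  P <- matrix(0, H + 1, W + 1)
  P[2:(H + 1), 2:(W + 1)] <- cs
  r0 <- pmax(seq_len(H) - h, 1); r1 <- pmin(seq_len(H) + h, H)
  c0 <- pmax(seq_len(W) - h, 1); c1 <- pmin(seq_len(W) + h, W)
  P[r1 + 1, c1 + 1, drop = FALSE] - P[r0, c1 + 1, drop = FALSE] -
    P[r1 + 1, c0, drop = FALSE] + P[r0, c0, drop = FALSE]
}

shift_max3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(-Inf, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(H, H + dr)
    rd <- rs - dr
    cs <- max(1, 1 + dc):min(W, W + dc)
    cd <- cs - dc
    out[rd, cd] <- pmax(out[rd, cd], m[rs, cs])
  }
  out
}

greedy_min_dist <- function(x, y, min_dist, max_n) {
  keep <- integer(0)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_along(x)) {
    if (length(keep) >= max_n) break
    if (length(keep) == 0 ||
        min((kx - x[i])^2 + (ky - y[i])^2) >= min_dist^2) {
      keep <- c(keep, i)
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  keep
}

# Coerce a points argument (tibble/data.frame with x,y or bare 2-column
# matrix) to an n x 2 numeric matrix.
as_xy_matrix <- function(points) {
  if (is.matrix(points) && is.null(colnames(points)))
    return(matrix(as.numeric(points), ncol = 2))
  m <- as.data.frame(points)
  as.matrix(m[, c("x", "y")])
}

#' Sparse optical-flow step between two frames
#'
#' Tracks a point set from `frame_a` to `frame_b` with iterative pyramidal
#' Lucas-Kanade flow and validates each point by the forward-backward
#' criterion: a point is valid iff its backward-tracked position lies
#' within `fb_tol_px` of its origin.
#'
#' @param frame_a,frame_b Same-size intensity matrices.
#' @param points Tibble or matrix with `x`, `y` columns (0-based px).
#' @param settings A [track_settings()].
#' @return A list with `points` (tibble `x`, `y` of moved points),
#'   `valid` (logical), and `fb_error_px` (numeric, `Inf` where tracking
#'   failed outright).
#' @export
flow_step <- function(frame_a, frame_b, points,
                      settings = track_settings()) {
  if (!identical(dim(frame_a), dim(frame_b)))
    abort_arg("Frames must have identical dimensions.",
              "urokin_argument_error")
  pts <- as_xy_matrix(points)
  if (nrow(pts) < 1)
    abort_arg("At least one input point is required.",
              "urokin_argument_error")
  pa <- build_pyramid_cpp(frame_a, settings$pyramid_levels)
  pb <- build_pyramid_cpp(frame_b, settings$pyramid_levels)
  flow_step_pyr(pa, pb, pts, settings)
}

flow_step_pyr <- function(pyr_a, pyr_b, pts, settings) {
  fw <- lk_track_cpp(pyr_a, pyr_b, pts, settings$win_half_px,
                     settings$max_iter, settings$eps)
  bw <- lk_track_cpp(pyr_b, pyr_a, fw$points, settings$win_half_px,
                     settings$max_iter, settings$eps)
  fb <- sqrt(rowSums((bw$points - pts)^2))
  fb[fw$status == 0 | bw$status == 0] <- Inf
  valid <- is.finite(fb) & fb <= settings$fb_tol_px &
    fw$ncc >= settings$min_ncc
  if (!any(valid))
    abort_arg("Optical flow lost all points between frames.",
              "urokin_tracking_loss_error")
  list(points = tibble::tibble(x = fw$points[, 1], y = fw$points[, 2]),
       valid = valid, fb_error_px = fb)
}

# Closed-form least-squares rigid fit (rotation + translation, no scale):
# cur ~ R ref + t. Returns list(R, t, theta_deg, rms).
fit_rigid_ls <- function(ref, cur) {
  mr <- unname(colMeans(ref)); mc <- unname(colMeans(cur))
  A <- sweep(ref, 2, mr); B <- sweep(cur, 2, mc)
  Hm <- t(A) %*% B
  sv <- svd(Hm)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t_ <- mc - as.numeric(R %*% mr)
  pred <- sweep(ref %*% t(R), 2, t_, `+`)
  rms <- sqrt(mean(rowSums((cur - pred)^2)))
  list(R = R, t = t_, theta_deg = deg_atan2(R[2, 1], R[1, 1]), rms = rms)
}

#' Robust rigid pose from point correspondences
#'
#' Estimates the rotation + translation (no scale) mapping reference points
#' to current points, with RANSAC outlier rejection followed by a
#' least-squares refit on the inliers. The minimal sample is a point pair;
#' candidate pairs are drawn from a deterministic internal generator so the
#' estimate is reproducible without touching the session RNG.
#'
#' @param points_ref,points_cur Tibbles/matrices with `x`, `y` columns.
#' @param validity Logical vector of correspondences to use (default all).
#' @param settings A [track_settings()] (uses `min_points`, `ransac_iter`,
#'   `ransac_tol_px`).
#' @param seed Integer seed of the deterministic sampler.
#' @return A list with `tx_px`, `ty_px` (translation), `dtheta_deg`
#'   (rotation, image convention), `R` (2 x 2), `inliers` (logical over all
#'   input correspondences) and `rms_px` (inlier residual).
#' @export
estimate_rigid_pose <- function(points_ref, points_cur, validity = NULL,
                                settings = track_settings(), seed = 1) {
  ref <- as_xy_matrix(points_ref)
  cur <- as_xy_matrix(points_cur)
  stopifnot(nrow(ref) == nrow(cur))
  validity <- validity %||% rep(TRUE, nrow(ref))
  use <- which(validity)
  if (length(use) < settings$min_points)
    abort_arg(sprintf("Only %d valid correspondences (need >= %d).",
                      length(use), settings$min_points),
              "urokin_degenerate_pose_error")
  r <- ref[use, , drop = FALSE]; c_ <- cur[use, , drop = FALSE]
  n <- nrow(r)
  tol2 <- settings$ransac_tol_px^2
  # common case: the direct least-squares fit has no outliers at all, and
  # RANSAC would select every point anyway
  fit0 <- fit_rigid_ls(r, c_)
  pred0 <- sweep(r %*% t(fit0$R), 2, fit0$t, `+`)
  if (all(rowSums((c_ - pred0)^2) <= tol2)) {
    inliers <- logical(nrow(ref))
    inliers[use] <- TRUE
    return(list(tx_px = fit0$t[1], ty_px = fit0$t[2],
                dtheta_deg = fit0$theta_deg, R = fit0$R, t = fit0$t,
                inliers = inliers, rms_px = fit0$rms))
  }
  rng <- local_rng(seed * 2654435761 %% 2^31 + n)
  best <- logical(n); best_n <- -1L
  for (k in seq_len(settings$ransac_iter)) {
    i <- 1L + as.integer(floor(rng() * n))
    j <- 1L + as.integer(floor(rng() * n))
    if (i == j || i > n || j > n) next
    v0 <- r[j, ] - r[i, ]; v1 <- c_[j, ] - c_[i, ]
    l0 <- sqrt(sum(v0^2))
    if (l0 < 1e-9) next
    ang <- deg_atan2(v1[2], v1[1]) - deg_atan2(v0[2], v0[1])
    R <- rot2(ang)
    t_ <- c_[i, ] - as.numeric(R %*% r[i, ])
    pred <- sweep(r %*% t(R), 2, t_, `+`)
    resid2 <- rowSums((c_ - pred)^2)
    inl <- resid2 <= tol2
    if (sum(inl) > best_n) { best <- inl; best_n <- sum(inl) }
  }
  if (best_n < settings$min_points)
    abort_arg("Too few inliers for a rigid pose after outlier rejection.",
              "urokin_degenerate_pose_error")
  # refit on inliers, twice, re-selecting inliers in between
  for (pass in 1:2) {
    fit <- fit_rigid_ls(r[best, , drop = FALSE], c_[best, , drop = FALSE])
    pred <- sweep(r %*% t(fit$R), 2, fit$t, `+`)
    best <- rowSums((c_ - pred)^2) <= tol2
    if (sum(best) < settings$min_points)
      abort_arg("Too few inliers for a rigid pose after outlier rejection.",
                "urokin_degenerate_pose_error")
  }
  fit <- fit_rigid_ls(r[best, , drop = FALSE], c_[best, , drop = FALSE])
  inliers <- logical(nrow(ref))
  inliers[use[best]] <- TRUE
  list(tx_px = fit$t[1], ty_px = fit$t[2], dtheta_deg = fit$theta_deg,
       R = fit$R, t = fit$t, inliers = inliers, rms_px = fit$rms)
}

#' Track one ROI through a cine loop
#'
#' Frame-to-frame feature tracking with per-step rigid pose estimation,
#' composed into a cumulative pose for every frame. When the tracked
#' fraction of features drops below `reseed_fraction`, features are
#' re-detected inside the current (moved) ROI and tracking continues with
#' pose continuity preserved. Frame-to-frame (rather than frame-0-to-t)
#' tracking is used because speckle decorrelates over long intervals;
#' drift is bounded by the validation suite rather than assumed away.
#'
#' @param cine A [cine_loop()].
#' @param annotation An [roi_annotation()].
#' @param roi ROI label to track (one of `proximal`, `mid`, `distal`,
#'   `pubis`).
#' @param settings A [track_settings()].
#' @return A `pose_series` tibble with columns `frame`, `x_px`, `y_px`
#'   (ROI origin), `theta_deg` (cumulative rotation, image convention),
#'   `n_points_tracked`, `mean_fb_error_px`, `reseeded`, and attributes
#'   `roi`, `rigid` (list of per-frame cumulative transforms).
#' @export
track_roi <- function(cine, annotation, roi, settings = track_settings()) {
  track_rois(cine, annotation, roi, settings)[[roi]]
}

# Track several ROIs in one pass over the cine so the per-frame image
# pyramids are built once and shared between ROIs.
track_rois <- function(cine, annotation, rois, settings = track_settings()) {
  stopifnot(inherits(cine, "cine_loop"), inherits(annotation, "roi_annotation"))
  miss <- setdiff(rois, names(annotation$rois))
  if (length(miss) > 0)
    abort_arg(sprintf("No annotation for ROI '%s'.", miss[1]),
              "urokin_argument_error")
  check_annotation_bounds(annotation, frame_size(cine))
  nf <- n_frames(cine)
  lev <- settings$pyramid_levels

  st <- lapply(setNames(rois, rois), function(roi) {
    rect <- annotation$rois[[roi]]
    feats <- detect_features(cine$frames[[1]], rect, settings, label = roi)
    out <- tibble::tibble(frame = 0:(nf - 1), x_px = NA_real_,
                          y_px = NA_real_, theta_deg = NA_real_,
                          n_points_tracked = NA_integer_,
                          mean_fb_error_px = NA_real_, reseeded = FALSE)
    origin <- rect_origin(rect)
    out$x_px[1] <- origin[1]; out$y_px[1] <- origin[2]
    out$theta_deg[1] <- 0
    out$n_points_tracked[1] <- nrow(feats)
    out$mean_fb_error_px[1] <- 0
    rigids <- vector("list", nf)
    rigids[[1]] <- rigid(0)
    list(roi = roi, rect = rect, origin = origin, out = out,
         rigids = rigids, pts = as_xy_matrix(feats), A = rigid(0),
         n_seed = nrow(feats))
  })

  pyr_prev <- build_pyramid_cpp(cine$frames[[1]], lev)
  for (t in 2:nf) {
    pyr_cur <- build_pyramid_cpp(cine$frames[[t]], lev)
    for (roi in rois) {
      s <- st[[roi]]
      step <- tryCatch(
        flow_step_pyr(pyr_prev, pyr_cur, s$pts, settings),
        urokin_tracking_loss_error = function(e) NULL)
      if (is.null(step) || sum(step$valid) < settings$min_points) {
        # attempt recovery: re-seed inside the last known pose and retry
        s$pts <- reseed_features(cine$frames[[t - 1]], s$rect, s$A, settings,
                                 roi, t - 2L)
        step <- tryCatch(
          flow_step_pyr(pyr_prev, pyr_cur, s$pts, settings),
          urokin_tracking_loss_error = function(e) NULL)
        if (is.null(step) || sum(step$valid) < settings$min_points)
          abort_arg(sprintf(
            "Unrecoverable tracking loss for ROI '%s' at frame %d.",
            roi, t - 1), "urokin_tracking_loss_error")
        s$out$reseeded[t] <- TRUE
        s$n_seed <- nrow(s$pts)
      }
      pose <- estimate_rigid_pose(s$pts, as_xy_matrix(step$points),
                                  step$valid, settings,
                                  seed = roi_seed(roi))
      dA <- list(R = pose$R, t = pose$t, theta_deg = pose$dtheta_deg)
      s$A <- rigid_compose(dA, s$A)
      p <- as.numeric(rigid_apply(s$A, matrix(s$origin, 1)))
      s$out$x_px[t] <- p[1]; s$out$y_px[t] <- p[2]
      s$out$theta_deg[t] <- s$A$theta_deg
      keep <- step$valid & pose$inliers
      s$out$n_points_tracked[t] <- sum(keep)
      s$out$mean_fb_error_px[t] <- mean(step$fb_error_px[step$valid])
      s$rigids[[t]] <- s$A
      s$pts <- as_xy_matrix(step$points)[keep, , drop = FALSE]
      if (nrow(s$pts) < max(settings$min_points,
                            ceiling(settings$reseed_fraction * s$n_seed))) {
        s$pts <- reseed_features(cine$frames[[t]], s$rect, s$A, settings,
                                 roi, t - 1L)
        s$out$reseeded[t] <- TRUE
        s$n_seed <- nrow(s$pts)
      }
      st[[roi]] <- s
    }
    pyr_prev <- pyr_cur
  }
  lapply(st, function(s)
    structure(s$out, roi = s$roi, rigid = s$rigids,
              class = c("pose_series", class(s$out))))
}

roi_seed <- function(roi) {
  sum(utf8ToInt(roi) * seq_along(utf8ToInt(roi))) + 17L
}

# Re-detect features inside the ROI rectangle moved by cumulative pose A.
reseed_features <- function(frame, rect, A, settings, roi, frame0) {
  corners <- rigid_apply(A, rect_corners(rect))
  bb <- c(min(corners[, 1]), max(corners[, 2]),
          max(corners[, 1]) - min(corners[, 1]),
          max(corners[, 2]) - min(corners[, 2]))
  f <- tryCatch(
    detect_features(frame, bb, settings, label = roi),
    urokin_low_texture_error = function(e) NULL)
  if (is.null(f))
    abort_arg(sprintf(
      "Unrecoverable tracking loss for ROI '%s' at frame %d (re-seed failed).",
      roi, frame0), "urokin_tracking_loss_error")
  pts <- as.matrix(f[, c("x", "y")])
  # keep points inside the moved rectangle (not just its bounding box)
  inv <- rigid_invert(A)
  back <- rigid_apply(inv, pts)
  inside <- back[, 1] >= rect[1] & back[, 1] <= rect[1] + rect[3] &
            back[, 2] >= rect[2] - rect[4] & back[, 2] <= rect[2]
  if (sum(inside) >= settings$min_points) pts <- pts[inside, , drop = FALSE]
  pts
}
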