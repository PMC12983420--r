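test_that("feature detection needs texture and is deterministic", {
  flat <- matrix(0.5, 128, 128)
  err <- expect_error(
    detect_features(flat, c(30, 90, 40, 40), label = "mid"),
    class = "urokin_low_texture_error")
  expect_match(conditionMessage(err), "mid")

  tex <- generate_speckle_field(128, 128, 3, seed = 5)
  f1 <- detect_features(tex, c(30, 90, 40, 40))
  f2 <- detect_features(tex, c(30, 90, 40, 40))
  expect_identical(f1, f2)
  expect_gte(nrow(f1), 10)
  # all points inside the rectangle
  expect_true(all(f1$x >= 30 & f1$x <= 70 & f1$y >= 50 & f1$y <= 90))
  # minimum mutual distance respected
  dmin <- min(dist(cbind(f1$x, f1$y)))
  expect_gte(dmin, 3)
})

test_that("optical flow recovers identity and integer translations", {
  tex <- generate_speckle_field(256, 256, 3, seed = 5)
  f <- detect_features(tex, c(100, 150, 50, 50))
  st <- flow_step(tex, tex, f)
  expect_true(all(st$valid))
  expect_lt(max(abs(st$points$x - f$x)), 0.1)
  expect_lt(max(abs(st$points$y - f$y)), 0.1)

  shifted <- cbind(tex[, 1:3], tex[, 1:(256 - 3)])  # content moves +3 px in x
  st2 <- flow_step(tex, shifted, f)
  expect_equal(mean(st2$points$x - f$x), 3, tolerance = 0.2)
  expect_equal(mean(st2$points$y - f$y), 0, tolerance = 0.2)

  noise <- generate_speckle_field(256, 256, 1, seed = 99)
  expect_error(flow_step(tex, noise, f),
               class = "urokin_tracking_loss_error")
})

test_that("rigid pose estimation matches the closed-form Procrustes oracle", {
  tex <- generate_speckle_field(256, 256, 3, seed = 5)
  pts <- urokin:::as_xy_matrix(detect_features(tex, c(100, 150, 50, 50)))

  # identity
  pose0 <- estimate_rigid_pose(pts, pts)
  expect_equal(pose0$dtheta_deg, 0, tolerance = 1e-9)
  expect_equal(c(pose0$tx_px, pose0$ty_px), c(0, 0), tolerance = 1e-9)

  # rotation about the centroid + translation, noiseless: exact recovery
  ctr <- unname(colMeans(pts))
  ang <- 10 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  cur <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + c(2, -1), "+")
  pose <- estimate_rigid_pose(pts, cur)
  expect_equal(pose$dtheta_deg, 10, tolerance = 1e-6)
  moved <- urokin:::rigid_apply(list(R = pose$R, t = pose$t),
                                matrix(ctr, 1))
  expect_equal(as.numeric(moved), ctr + c(2, -1), tolerance = 1e-6)

  # independent closed-form oracle (no RANSAC): plain SVD Procrustes
  oracle <- function(A, B) {
    ma <- colMeans(A); mb <- colMeans(B)
    H <- t(sweep(A, 2, ma)) %*% sweep(B, 2, mb)
    sv <- svd(H)
    Rr <- sv$v %*% diag(c(1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    atan2(Rr[2, 1], Rr[1, 1]) * 180 / pi
  }
  expect_equal(pose$dtheta_deg, oracle(pts, cur), tolerance = 1e-9)

  # 20% gross outliers: rejected, pose still within 0.1 px / 0.1 deg
  set.seed(2)
  idx <- sample(nrow(cur), floor(0.2 * nrow(cur)))
  cur2 <- cur
  cur2[idx, ] <- cur2[idx, ] + 50
  pose2 <- estimate_rigid_pose(pts, cur2)
  expect_false(any(which(pose2$inliers) %in% idx))
  expect_equal(pose2$dtheta_deg, 10, tolerance = 0.1)
  moved2 <- urokin:::rigid_apply(list(R = pose2$R, t = pose2$t),
                                 matrix(ctr, 1))
  expect_equal(as.numeric(moved2), ctr + c(2, -1), tolerance = 0.1)

  expect_error(estimate_rigid_pose(pts[1:5, ], cur[1:5, ]),
               class = "urokin_degenerate_pose_error")
})

test_that("static cines yield static poses for every ROI", {
  ann <- default_annotation()
  tex <- generate_speckle_field(384, 384, 3, seed = 4)
  sim <- render_cine(tex, ann, zero_trajectories(10), noise_sd = 0.01,
                     seed = 1)
  for (roi in c("proximal", "pubis")) {
    ps <- track_roi(sim$cine, ann, roi)
    expect_lt(max(abs(ps$x_px - ps$x_px[1])), 0.2)
    expect_lt(max(abs(ps$y_px - ps$y_px[1])), 0.2)
    expect_lt(max(abs(ps$theta_deg)), 0.2)
  }
})

test_that("recovered poses are equivariant to global translation and rotation", {
  tex <- generate_speckle_field(384, 384, 3, seed = 6)
  ann <- default_annotation()
  # integer global shift of every frame by (u, v)
  u <- 4L; v <- 3L
  shift_int <- function(m, du, dv) {
    H <- nrow(m); W <- ncol(m)
    out <- m
    out[(1 + dv):H, (1 + du):W] <- m[1:(H - dv), 1:(W - du)]
    out
  }
  cine0 <- cine_loop(list(tex, tex), 30, 0.2)
  cine1 <- cine_loop(list(tex, shift_int(tex, u, v)), 30, 0.2)
  p0 <- track_roi(cine0, ann, "mid")
  p1 <- track_roi(cine1, ann, "mid")
  expect_equal(p1$x_px[2] - p0$x_px[2], u, tolerance = 0.2)
  expect_equal(p1$y_px[2] - p0$y_px[2], v, tolerance = 0.2)

  # rigid global rotation about the frame centre
  for (alpha in c(5, 15)) {
    g <- urokin:::rigid(alpha)
    ctr <- c(383 / 2, 383 / 2)
    g$t <- ctr - as.numeric(g$R %*% ctr)
    rot <- urokin:::warp_by_rigid(tex, g, 384, 384)
    cine <- cine_loop(list(tex, rot), 30, 0.2)
    ps <- track_roi(cine, ann, "pubis")
    expect_equal(ps$theta_deg[2], alpha, tolerance = 0.5)
  }
})

test_that("tracking follows known motion within the accuracy contract", {
  sc <- cough_scene(seed = 21, probe = FALSE)
  res <- run_subject(sc$cine, sc$annotation, subject = "acc",
                     maneuver = "cough")
  rms <- truth_rms(res$trajectories, sc$truth)
  expect_lte(rms$pos_mm / sc$cine$pixel_spacing_mm, 0.5)  # px
  expect_lte(rms$theta_deg, 1.0)
})
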