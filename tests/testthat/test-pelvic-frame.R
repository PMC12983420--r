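# Build a synthetic pubis pose series from a list of rigid transforms.
fake_pose_series <- function(transforms, origin = c(100, 160)) {
  nf <- length(transforms)
  pos <- t(vapply(transforms, function(A)
    as.numeric(urokin:::rigid_apply(A, matrix(origin, 1))), numeric(2)))
  out <- tibble::tibble(frame = seq_len(nf) - 1L, x_px = pos[, 1],
                        y_px = pos[, 2],
                        theta_deg = vapply(transforms, `[[`, numeric(1),
                                           "theta_deg"),
                        n_points_tracked = 40L, mean_fb_error_px = 0,
                        reseeded = FALSE)
  structure(out, roi = "pubis", rigid = transforms,
            class = c("pose_series", class(out)))
}

test_that("the pelvic frame transports rigidly with the pubis", {
  ann <- default_annotation()
  id <- urokin:::rigid(0)
  shift <- urokin:::rigid(0, c(5, 0))
  rot5 <- urokin:::rigid(5)

  fr <- construct_frame(fake_pose_series(list(id, id, id)), ann, 0.2)
  expect_true(all(fr$ipp_x_px == fr$ipp_x_px[1]))
  expect_true(all(fr$ex_x == fr$ex_x[1] & fr$ey_y == fr$ey_y[1]))
  # frame-0 axes match the annotation
  ax <- urokin:::annotation_axes(ann)
  expect_equal(c(fr$ex_x[1], fr$ex_y[1]), ax$x)
  expect_equal(c(fr$ey_x[1], fr$ey_y[1]), ax$y)
  # axes orthonormal
  expect_equal(fr$ex_x^2 + fr$ex_y^2, rep(1, 3))
  expect_equal(fr$ex_x * fr$ey_x + fr$ex_y * fr$ey_y, rep(0, 3))

  fr2 <- construct_frame(fake_pose_series(list(id, shift)), ann, 0.2)
  expect_equal(fr2$ipp_x_px[2] - fr2$ipp_x_px[1], 5)
  expect_equal(fr2$ipp_y_px[2] - fr2$ipp_y_px[1], 0)
  expect_equal(fr2$ex_x[2], fr2$ex_x[1])

  fr3 <- construct_frame(fake_pose_series(list(id, rot5)), ann, 0.2)
  a0 <- atan2(fr3$ex_y[1], fr3$ex_x[1]) * 180 / pi
  a1 <- atan2(fr3$ex_y[2], fr3$ex_x[2]) * 180 / pi
  expect_equal(a1 - a0, 5, tolerance = 1e-9)

  bad <- ann
  bad$tangent_px <- bad$ipp_px
  expect_error(urokin:::annotation_axes(bad),
               class = "urokin_degenerate_axis_error")
})

test_that("pelvic projection applies the axis conventions once", {
  ann <- default_annotation()
  ax <- urokin:::annotation_axes(ann)
  id <- urokin:::rigid(0)
  fr <- construct_frame(fake_pose_series(list(id, id)), ann, 0.2)

  mk_roi_series <- function(p) tibble::tibble(
    frame = 0:1, x_px = p[1], y_px = p[2], theta_deg = 0,
    n_points_tracked = 40L, mean_fb_error_px = 0, reseeded = FALSE)

  # ROI at the IPP: origin of the pelvic frame
  at_ipp <- to_pelvic(mk_roi_series(ann$ipp_px), fr)
  expect_equal(c(at_ipp$x_mm[1], at_ipp$y_mm[1]), c(0, 0))

  # 10 px posterior along the tangent at 0.2 mm/px: (2, 0) mm
  post <- to_pelvic(mk_roi_series(ann$ipp_px + 10 * ax$x), fr)
  expect_equal(c(post$x_mm[1], post$y_mm[1]), c(2, 0), tolerance = 1e-9)

  # 10 px straight up in image rows from the IPP: positive (superior) y
  up <- to_pelvic(mk_roi_series(ann$ipp_px + c(0, -10)), fr)
  expect_gt(up$y_mm[1], 0)

  expect_error(to_pelvic(mk_roi_series(c(0, 0))[1, ], fr),
               class = "urokin_argument_error")
})

test_that("pelvic coordinates are invariant to probe motion end-to-end", {
  sc_off <- cough_scene(seed = 31, probe = FALSE)
  sc_on <- cough_scene(seed = 31, probe = TRUE)
  res_off <- run_subject(sc_off$cine, sc_off$annotation)
  res_on <- run_subject(sc_on$cine, sc_on$annotation)
  d <- merge(res_on$trajectories, res_off$trajectories,
             by = c("frame", "roi"))
  rms <- sqrt(mean((d$x_mm.x - d$x_mm.y)^2 + (d$y_mm.x - d$y_mm.y)^2))
  expect_lte(rms, 0.3)  # mm
})

test_that("inter-segment distances agree between image and pelvic frames", {
  sc <- cough_scene(seed = 41)
  poses <- urokin:::track_rois(sc$cine, sc$annotation,
                               c("proximal", "mid", "pubis"))
  fr <- construct_frame(poses$pubis, sc$annotation,
                        sc$cine$pixel_spacing_mm)
  pp <- to_pelvic(poses$proximal, fr)
  pm <- to_pelvic(poses$mid, fr)
  d_img <- sqrt((poses$proximal$x_px - poses$mid$x_px)^2 +
                (poses$proximal$y_px - poses$mid$y_px)^2) *
    sc$cine$pixel_spacing_mm
  d_pel <- sqrt((pp$x_mm - pm$x_mm)^2 + (pp$y_mm - pm$y_mm)^2)
  expect_equal(d_pel, d_img, tolerance = 1e-9)
})
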