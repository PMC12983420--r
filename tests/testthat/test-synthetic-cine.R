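test_that("speckle fields are seeded, bounded and corner-rich", {
  a <- generate_speckle_field(256, 256, 3, seed = 7)
  b <- generate_speckle_field(256, 256, 3, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_speckle_field(256, 256, 3, seed = 8)))
  expect_gte(min(a), 0)
  expect_lte(max(a), 1)
  # any 40 x 40 window must supply >= 50 trackable corners
  for (x0 in c(30, 108, 200)) {
    f <- detect_features(a, c(x0, x0 + 39, 40, 40),
                         track_settings(max_features = 500))
    expect_gte(nrow(f), 50)
  }
  expect_error(generate_speckle_field(32, 256, 3, seed = 1),
               class = "urokin_argument_error")
  expect_error(generate_speckle_field(-1, 256, 3, seed = 1),
               class = "urokin_argument_error")
})

test_that("maneuver trajectories honour their amplitude and shape contracts", {
  # null motion
  tpl0 <- motion_template("cough",
                          amplitudes_mm = list(proximal = c(0, 0),
                                               mid = c(0, 0),
                                               distal = c(0, 0)),
                          rotation_deg = 0, prelift_mm = 0)
  tr0 <- maneuver_trajectory(tpl0, "proximal")
  expect_true(all(tr0$dx_mm == 0 & tr0$dy_mm == 0 & tr0$dtheta_deg == 0))

  # cough: peak |d| = |(2, -6)| = 6.3246 within 1%, spike within the rise
  # time, rest at both ends
  tpl <- cough_template()
  tr <- maneuver_trajectory(tpl, "proximal")
  expect_equal(nrow(tr), round(tpl$duration_s * tpl$frame_rate_hz))
  expect_equal(max(tr$dmag_mm), sqrt(2^2 + 6^2), tolerance = 0.01)
  t_peak <- tr$t_s[which.max(tr$dmag_mm)]
  t_onset <- tpl$prelift_lead_s + 0.15
  expect_lte(t_peak, t_onset + tpl$rise_s + 1 / tpl$frame_rate_hz)
  expect_equal(tr$dmag_mm[1], 0)
  expect_lt(tail(tr$dmag_mm, 1), 0.05)
  # anticipatory pre-lift: superior motion before the main descent
  pre <- tr$dy_mm[tr$t_s < t_onset]
  expect_gt(max(pre), 0.2)

  # valsalva: sustained plateau >= 50% of peak for >= 25% of the duration
  tplv <- motion_template("valsalva",
                          amplitudes_mm = list(proximal = c(4, -9),
                                               mid = c(0, -6),
                                               distal = c(-2, -3)))
  trv <- maneuver_trajectory(tplv, "proximal")
  expect_gte(mean(trv$dmag_mm >= 0.5 * max(trv$dmag_mm)), 0.25)

  # pmc: dx crosses zero exactly once (posterior then anterior), ends at rest
  tplp <- motion_template("pmc",
                          amplitudes_mm = list(proximal = c(1.5, 3),
                                               mid = c(1, 2.5),
                                               distal = c(0.5, 2)))
  trp <- maneuver_trajectory(tplp, "proximal")
  sgn <- sign(trp$dx_mm[trp$dx_mm != 0])
  expect_equal(sum(diff(sgn) != 0), 1)
  expect_gt(sgn[1], 0)
  expect_lt(tail(sgn, 1), 0)
  expect_lt(tail(trp$dmag_mm, 1), 0.05)
  expect_equal(max(trp$dmag_mm), sqrt(1.5^2 + 3^2), tolerance = 1e-6)

  expect_error(maneuver_trajectory(tpl, "bladder"),
               class = "urokin_argument_error")
})

test_that("doubling template amplitudes doubles peak displacement exactly", {
  for (mv in c("cough", "valsalva", "pmc")) {
    a1 <- list(proximal = c(2, -5), mid = c(1, -4), distal = c(-1, -3))
    a2 <- lapply(a1, `*`, 2)
    tr1 <- maneuver_trajectory(motion_template(mv, amplitudes_mm = a1,
                                               prelift_mm = 0), "proximal")
    tr2 <- maneuver_trajectory(motion_template(mv, amplitudes_mm = a2,
                                               prelift_mm = 0), "proximal")
    expect_equal(max(tr2$dmag_mm), 2 * max(tr1$dmag_mm), tolerance = 1e-12)
  }
})

test_that("rendering is deterministic and static scenes stay static", {
  ann <- default_annotation()
  tex <- generate_speckle_field(384, 384, 3, seed = 4)
  zt <- zero_trajectories(8)
  sim <- render_cine(tex, ann, zt, noise_sd = 0, seed = 1)
  for (k in 2:8)
    expect_equal(sim$cine$frames[[k]], sim$cine$frames[[1]])
  sim2 <- render_cine(tex, ann, zt, noise_sd = 0.02, seed = 9)
  sim3 <- render_cine(tex, ann, zt, noise_sd = 0.02, seed = 9)
  expect_identical(sim2$cine$frames, sim3$cine$frames)
  expect_false(identical(
    sim2$cine$frames[[1]],
    render_cine(tex, ann, zt, noise_sd = 0.02, seed = 10)$cine$frames[[1]]))
})

test_that("ground truth is probe-motion-free by construction", {
  ann <- default_annotation()
  tex <- generate_speckle_field(384, 384, 3, seed = 4)
  tpl <- cough_template(duration_s = 0.5)
  trajs <- lapply(setNames(nm = urethra_rois),
                  function(r) maneuver_trajectory(tpl, r))
  pm <- probe_motion_series(nrow(trajs$proximal), amplitude_px = 5)
  with_probe <- render_cine(tex, ann, trajs, probe_motion = pm, seed = 2)
  without <- render_cine(tex, ann, trajs, probe_motion = NULL, seed = 2)
  expect_equal(with_probe$truth$trajectories, without$truth$trajectories)
  # probe translation alone leaves pelvic-frame truth at rest
  only_probe <- render_cine(tex, ann, zero_trajectories(nrow(pm)),
                            probe_motion = pm, seed = 2)
  tt <- only_probe$truth$trajectories
  for (roi in urethra_rois) {
    x <- tt$x_mm[tt$roi == roi]
    expect_true(all(x == x[1]))
  }
})

test_that("a trajectory that exits the frame is rejected with roi and frame", {
  ann <- default_annotation()
  tex <- generate_speckle_field(384, 384, 3, seed = 4)
  tpl <- motion_template("cough",
                         amplitudes_mm = list(proximal = c(80, -40),
                                              mid = c(0, -1),
                                              distal = c(0, -1)))
  trajs <- lapply(setNames(nm = urethra_rois),
                  function(r) maneuver_trajectory(tpl, r))
  err <- expect_error(render_cine(tex, ann, trajs, seed = 1),
                      class = "urokin_bounds_error")
  expect_match(conditionMessage(err), "proximal")
  expect_match(conditionMessage(err), "frame")
})

test_that("cohort generation is seeded and respects group distributions", {
  spec0 <- cohort_spec(n_control = 2, n_sui = 2, maneuvers = "cough",
                       frame_size_px = 256, sd_scale = 0,
                       probe_amplitude_px = c(0, 0), seed = 3)
  ch <- make_cohort(spec0)
  expect_equal(nrow(ch), 4)
  # degenerate SD = 0: within-group subjects share identical true motion
  tr1 <- ch$truth[[which(ch$subject == "ctrl01")]]$trajectories
  tr2 <- ch$truth[[which(ch$subject == "ctrl02")]]$trajectories
  expect_equal(tr1, tr2)
  # control and sui differ (different group means)
  trs <- ch$truth[[which(ch$subject == "sui01")]]$trajectories
  expect_false(isTRUE(all.equal(tr1, trs)))

  spec1 <- cohort_spec(n_control = 2, n_sui = 2, maneuvers = "cough",
                       frame_size_px = 256, seed = 3)
  spec2 <- cohort_spec(n_control = 2, n_sui = 2, maneuvers = "cough",
                       frame_size_px = 256, seed = 4)
  c1 <- make_cohort(spec1)
  c1b <- make_cohort(spec1)
  c2 <- make_cohort(spec2)
  expect_identical(c1$truth[[1]]$trajectories, c1b$truth[[1]]$trajectories)
  expect_false(isTRUE(all.equal(c1$truth[[1]]$trajectories,
                                c2$truth[[1]]$trajectories)))
  expect_error(cohort_spec(n_control = 1, n_sui = 2),
               class = "urokin_argument_error")
})
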