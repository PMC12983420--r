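test_that("displacement series follow the axis and magnitude conventions", {
  poses <- tibble::tibble(frame = 0:3, x_mm = c(1, 1, 4, 1),
                          y_mm = c(2, 2, 6, -4), theta_deg = c(0, 0, 3, 0))
  rec <- displacement_series(poses)
  expect_equal(rec$dx_mm[1], 0)
  expect_equal(rec$dmag_mm[1], 0)
  # 3-4-5 triangle
  expect_equal(rec$dmag_mm[3], 5)
  expect_equal(rec$phi_deg[3], atan2(4, 3) * 180 / pi, tolerance = 1e-9)
  # pure inferior motion: phi = -90
  expect_equal(rec$dx_mm[4], 0)
  expect_equal(rec$dy_mm[4], -6)
  expect_equal(rec$phi_deg[4], -90)
  # identities at machine precision
  expect_equal(rec$dmag_mm^2, rec$dx_mm^2 + rec$dy_mm^2, tolerance = 1e-14)
  # phi is scale-invariant
  poses2 <- dplyr::mutate(poses, x_mm = 2 * x_mm - 1, y_mm = 2 * y_mm - 2)
  rec2 <- displacement_series(poses2)
  expect_equal(rec2$phi_deg[3:4], rec$phi_deg[3:4], tolerance = 1e-12)
  # low-magnitude direction flag
  tiny <- displacement_series(tibble::tibble(frame = 0:1,
                                             x_mm = c(0, 0.05),
                                             y_mm = 0, theta_deg = 0))
  expect_true(tiny$phi_unreliable[2])
  expect_error(displacement_series(poses[0, ]),
               class = "urokin_argument_error")
})

test_that("kink angle is signed, geometric and mirror-consistent", {
  expect_equal(kink_angle(c(0, 2), c(0, 1), c(0, 0)), 0)
  expect_equal(abs(kink_angle(c(0, 2), c(0, 1), c(1, 1))), 90)

  p <- c(0, 2); m <- c(0.2, 1); d <- c(0, 0)
  w <- kink_angle(p, m, d)
  # rotation invariance
  R <- urokin:::rot2(30)
  rot <- function(v) as.numeric(R %*% v)
  expect_equal(kink_angle(rot(p), rot(m), rot(d)), w, tolerance = 1e-9)
  # translation invariance
  expect_equal(kink_angle(p + 5, m + 5, d + 5), w, tolerance = 1e-12)
  # mirror reflection flips the sign
  mir <- function(v) c(-v[1], v[2])
  expect_equal(kink_angle(mir(p), mir(m), mir(d)), -w, tolerance = 1e-12)

  expect_error(kink_angle(c(0, 1), c(0, 1), c(1, 1)),
               class = "urokin_degenerate_geometry_error")
})

test_that("relative mobility has the proximal-dominant sign convention", {
  expect_equal(relative_mobility(3, 3, 10), 0)
  expect_equal(relative_mobility(6, 3, 10), -0.3)
  expect_equal(relative_mobility(6, 3, 20), -0.15)
  expect_error(relative_mobility(6, 3, 0),
               class = "urokin_degenerate_geometry_error")
})

test_that("maximum excursion and trial selection break ties earliest", {
  ramp <- tibble::tibble(frame = 0:4, dmag_mm = c(0, 1, 2, 3, 4))
  expect_equal(max_excursion(ramp)$frame, 4)
  peak <- tibble::tibble(frame = 0:4, dmag_mm = c(0, 1, 5, 1, 0))
  expect_equal(max_excursion(peak)$frame, 2)
  ties <- tibble::tibble(frame = 0:4, dmag_mm = c(0, 3, 1, 3, 0))
  expect_equal(max_excursion(ties)$frame, 1)
  expect_error(max_excursion(ramp[0, ]), class = "urokin_argument_error")

  trials <- list(list(max_excursion_mm = 4), list(max_excursion_mm = 6),
                 list(max_excursion_mm = 5))
  expect_equal(attr(select_trial(trials), "trial_index"), 2)
  expect_equal(attr(select_trial(trials[1]), "trial_index"), 1)
  tied <- list(list(max_excursion_mm = 6), list(max_excursion_mm = 6))
  expect_equal(attr(select_trial(tied), "trial_index"), 1)
  expect_error(select_trial(list()), class = "urokin_argument_error")
})

test_that("subject metrics assemble segment and chain quantities", {
  nf <- 5
  mk <- function(x0, y0, dx, dy) tibble::tibble(
    frame = 0:(nf - 1), x_mm = x0 + dx * (0:(nf - 1)) / (nf - 1),
    y_mm = y0 + dy * (0:(nf - 1)) / (nf - 1), theta_deg = 0)
  pelvic <- list(proximal = mk(18, 16, 3, -4),  # dmag 5 at final frame
                 mid = mk(17, 7, 0, -2),
                 distal = mk(16, -2, 0, -1))
  res <- subject_metrics(pelvic)
  expect_equal(res$max_frame, nf - 1)
  expect_equal(res$max_excursion_mm, 5)
  m <- res$metrics
  expect_equal(m$dmag_mm[m$roi == "proximal"], 5)
  # proximal moves more than mid: negative relative mobility, rest
  # y-distance 9 mm
  expect_equal(res$r_prox_mid, (2 - 5) / 9, tolerance = 1e-12)
  # kinematics from simulator ground truth: metric code adds no error
  sc_truth <- cough_template()
  tr <- maneuver_trajectory(sc_truth, "proximal")
  rec <- displacement_series(
    tibble::tibble(frame = tr$frame, x_mm = 10 + tr$dx_mm,
                   y_mm = 5 + tr$dy_mm, theta_deg = tr$dtheta_deg))
  expect_equal(rec$dmag_mm, tr$dmag_mm, tolerance = 1e-12)
})
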