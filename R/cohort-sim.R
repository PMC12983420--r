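#' Specify a synthetic cohort
#'
#' Defines group sizes and the per-group distributions of maneuver
#' amplitudes from which synthetic subjects are drawn. By default the
#' per-cell displacement-magnitude and direction distributions are taken
#' from [reference_displacement_summary()], so simulated cohorts carry the
#' reference study's group effect sizes (e.g. proximal Valsalva magnitude
#' control 5.98 +/- 2.01 mm vs. SUI 10.64 +/- 3.69 mm, n = 10/11).
#'
#' Per subject and cell, a magnitude is drawn from a normal distribution
#' truncated at 0 (magnitudes are nonnegative) and a direction from an
#' untruncated normal; the segment amplitude vector is
#' `m * (cos(phi), sin(phi))`. Setting all SDs to 0 (see `sd_scale`)
#' collapses each group onto its mean.
#'
#' @param n_control,n_sui Group sizes (each >= 2).
#' @param amplitudes Tibble in the format of
#'   [reference_displacement_summary()] giving mean/SD per maneuver, roi,
#'   group and metric.
#' @param maneuvers Maneuvers to simulate (default all three).
#' @param rotation_mean_deg,rotation_sd_deg Distribution of the segment
#'   rotation amplitude (degrees; uncalibrated, modest by default).
#' @param probe_amplitude_px Range (`c(min, max)`) of the per-subject
#'   probe-motion translation amplitude; `c(0, 0)` disables probe motion.
#' @param noise_sd Rendering noise SD.
#' @param frame_size_px,pixel_spacing_mm,frame_rate_hz Scene geometry and
#'   acquisition defaults (384 px, 0.2 mm/px, 30 Hz).
#' @param sd_scale Multiplier on all amplitude SDs (0 gives degenerate
#'   within-group identical subjects).
#' @param seed Integer seed; cohort draws are deterministic per seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 10, n_sui = 11,
                        amplitudes = reference_displacement_summary(),
                        maneuvers = MANEUVERS,
                        rotation_mean_deg = 4, rotation_sd_deg = 1.5,
                        probe_amplitude_px = c(2, 6), noise_sd = 0.02,
                        frame_size_px = 384, pixel_spacing_mm = 0.2,
                        frame_rate_hz = 30, sd_scale = 1, seed = 1) {
  if (n_control < 2 || n_sui < 2)
    abort_arg("Each group needs at least 2 subjects.",
              "urokin_argument_error")
  if (any(amplitudes$sd < 0))
    abort_arg("Amplitude SDs must be >= 0.", "urokin_argument_error")
  structure(as.list(environment()), class = "cohort_spec")
}

# Draw one subject's per-maneuver, per-segment amplitudes (deterministic
# given the RNG state).
draw_subject_params <- function(spec, group) {
  amp <- spec$amplitudes
  cells <- lapply(spec$maneuvers, function(mv) {
    per_roi <- lapply(URETHRA_ROIS, function(r) {
      row_m <- amp[amp$maneuver == mv & amp$roi == r & amp$group == group &
                     amp$metric == "magnitude", ]
      row_d <- amp[amp$maneuver == mv & amp$roi == r & amp$group == group &
                     amp$metric == "direction", ]
      m <- rnorm_trunc0(1, row_m$mean, row_m$sd * spec$sd_scale)
      phi <- rnorm(1, row_d$mean, row_d$sd * spec$sd_scale) * pi / 180
      c(m * cos(phi), m * sin(phi))
    })
    names(per_roi) <- URETHRA_ROIS
    rot <- rnorm_trunc0(1, spec$rotation_mean_deg,
                        spec$rotation_sd_deg * spec$sd_scale)
    list(amplitudes_mm = per_roi, rotation_deg = rot)
  })
  names(cells) <- spec$maneuvers
  probe <- list(
    amplitude_px = runif(1, spec$probe_amplitude_px[1],
                         spec$probe_amplitude_px[2]),
    period_s = runif(1, 1.8, 3.2),
    direction_deg = runif(1, 0, 360),
    rotation_amplitude_deg = runif(1, 0.4, 1.5))
  list(cells = cells, probe = probe)
}

# Normal draw truncated at 0 by rejection (means here are several SDs
# above 0, so rejection is cheap and exact).
rnorm_trunc0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  for (k in seq_len(100)) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(x, 0)
}

# Render one subject-maneuver cine from drawn parameters.
simulate_subject_cine <- function(spec, params, maneuver, texture,
                                  annotation, seed, probe_on = TRUE) {
  cell <- params$cells[[maneuver]]
  tpl <- motion_template(maneuver, amplitudes_mm = cell$amplitudes_mm,
                         rotation_deg = cell$rotation_deg,
                         frame_rate_hz = spec$frame_rate_hz)
  trajs <- lapply(setNames(URETHRA_ROIS, URETHRA_ROIS),
                  function(r) maneuver_trajectory(tpl, r))
  nf <- nrow(trajs$proximal)
  probe <- if (probe_on && spec$probe_amplitude_px[2] > 0) {
    probe_motion_series(nf, spec$frame_rate_hz,
                        amplitude_px = params$probe$amplitude_px,
                        period_s = params$probe$period_s,
                        direction_deg = params$probe$direction_deg,
                        rotation_amplitude_deg =
                          params$probe$rotation_amplitude_deg)
  } else NULL
  render_cine(texture, annotation, trajs, probe_motion = probe,
              noise_sd = spec$noise_sd, seed = seed,
              frame_rate_hz = spec$frame_rate_hz,
              pixel_spacing_mm = spec$pixel_spacing_mm)
}

#' Generate a full synthetic cohort
#'
#' Draws every subject's amplitude parameters from the group
#' distributions of a [cohort_spec()] and renders one cine per subject and
#' maneuver, with per-subject speckle texture and probe motion.
#' Deterministic for a fixed spec seed. Note that the rendered frames are
#' kept in memory: for full-size cohorts prefer [run_cohort()], which
#' generates and analyses subject by subject.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject-maneuver: `subject`, `group`,
#'   `maneuver` and list-columns `cine`, `annotation`, `truth`, `params`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- cohort_manifest(spec)
  out <- with_seed(spec$seed, {
    ann <- default_annotation(spec$frame_size_px, spec$frame_size_px)
    params <- draw_cohort_params(spec)
    lapply(seq_len(nrow(rows)), function(i) {
      sub <- rows$subject[i]
      tex <- generate_speckle_field(spec$frame_size_px, spec$frame_size_px,
                                    seed = subject_seed(spec$seed, sub, 0))
      sim <- simulate_subject_cine(spec, params[[sub]], rows$maneuver[i],
                                   tex, ann,
                                   seed = subject_seed(spec$seed, sub,
                                                       match(rows$maneuver[i],
                                                             MANEUVERS)))
      list(cine = sim$cine, annotation = ann, truth = sim$truth)
    })
  })
  rows$cine <- lapply(out, `[[`, "cine")
  rows$annotation <- lapply(out, `[[`, "annotation")
  rows$truth <- lapply(out, `[[`, "truth")
  rows
}

cohort_manifest <- function(spec) {
  subjects <- c(sprintf("ctrl%02d", seq_len(spec$n_control)),
                sprintf("sui%02d", seq_len(spec$n_sui)))
  groups <- rep(c("control", "sui"), c(spec$n_control, spec$n_sui))
  tidyr::expand_grid(
    tibble::tibble(subject = subjects, group = groups),
    maneuver = spec$maneuvers)
}

# Draw all subjects' parameters in a fixed order (independent of which
# cines are later rendered) so subject draws are stable.
draw_cohort_params <- function(spec) {
  manifest <- unique(cohort_manifest(spec)[c("subject", "group")])
  params <- lapply(seq_len(nrow(manifest)), function(i)
    draw_subject_params(spec, manifest$group[i]))
  names(params) <- manifest$subject
  params
}

subject_seed <- function(seed, subject, k) {
  h <- sum(utf8ToInt(subject) * (seq_along(utf8ToInt(subject)) + 3))
  (abs(seed) * 1009 + h * 31 + k) %% 2000000011
}
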