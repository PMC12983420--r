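# Shared fixtures: small synthetic scenes built in code at test time.

urethra_rois <- c("proximal", "mid", "distal")

# Zero-motion trajectory list for a given frame count.
zero_trajectories <- function(n_frames, frame_rate_hz = 30) {
  lapply(setNames(nm = urethra_rois), function(r)
    tibble::tibble(frame = seq_len(n_frames) - 1L,
                   t_s = (seq_len(n_frames) - 1) / frame_rate_hz,
                   dx_mm = 0, dy_mm = 0, dtheta_deg = 0, dmag_mm = 0))
}

# A short cough scene at the default geometry; moderate amplitudes.
cough_template <- function(...) {
  motion_template("cough",
                  amplitudes_mm = list(proximal = c(2, -6), mid = c(0, -4),
                                       distal = c(-1, -3)),
                  rotation_deg = 4, ...)
}

cough_scene <- function(seed = 11, probe = FALSE, noise_sd = 0.02) {
  ann <- default_annotation()
  tex <- generate_speckle_field(384, 384, 3, seed = seed)
  tpl <- cough_template()
  trajs <- lapply(setNames(nm = urethra_rois),
                  function(r) maneuver_trajectory(tpl, r))
  pm <- if (probe)
    probe_motion_series(nrow(trajs$proximal), amplitude_px = 5,
                        rotation_amplitude_deg = 1.2)
  else NULL
  sim <- render_cine(tex, ann, trajs, probe_motion = pm,
                     noise_sd = noise_sd, seed = seed + 1)
  c(sim, list(annotation = ann, texture = tex, trajectories = trajs))
}

# RMS position error (mm) of pipeline trajectories vs. rendered truth.
truth_rms <- function(trajectories, truth) {
  cmp <- merge(trajectories, truth$trajectories, by = c("frame", "roi"))
  list(
    pos_mm = sqrt(mean((cmp$x_mm.x - cmp$x_mm.y)^2 +
                       (cmp$y_mm.x - cmp$y_mm.y)^2)),
    theta_deg = sqrt(mean((cmp$theta_deg.x - cmp$theta_deg.y)^2)))
}

# Long null metric table (no group effect) for ANOVA / contrast checks.
null_metric_table <- function(n_control = 10, n_sui = 11,
                              maneuvers = c("cough", "valsalva", "pmc")) {
  subjects <- c(sprintf("c%02d", seq_len(n_control)),
                sprintf("s%02d", seq_len(n_sui)))
  groups <- rep(c("control", "sui"), c(n_control, n_sui))
  tidyr::expand_grid(tibble::tibble(subject = subjects, group = groups),
                     maneuver = maneuvers) |>
    dplyr::mutate(roi = "proximal", metric = "dmag_mm",
                  value = rnorm(dplyr::n(), mean = 5, sd = 2))
}

# Independent brute-force sums-of-squares oracle for the balanced
# two-way mixed (one between, one within) design.
mixed_anova_oracle <- function(data) {
  y <- data$value
  grand <- mean(y)
  E <- length(unique(data$maneuver))
  G <- length(unique(data$group))
  N <- length(unique(data$subject))
  subj_means <- tapply(y, data$subject, mean)
  grp_of_subj <- tapply(data$group, data$subject, function(g) g[1])
  grp_means <- tapply(y, data$group, mean)
  n_g <- table(grp_of_subj)
  evt_means <- tapply(y, data$maneuver, mean)
  cell_means <- tapply(y, list(data$group, data$maneuver), mean)

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- E * sum((subj_means - grand)^2)
  ss_group <- E * sum(n_g * (grp_means[names(n_g)] - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_event <- N * sum((evt_means - grand)^2)
  ss_cells <- 0
  for (g in rownames(cell_means)) for (e in colnames(cell_means))
    ss_cells <- ss_cells + n_g[[g]] * (cell_means[g, e] - grand)^2
  ss_inter <- ss_cells - ss_group - ss_event
  ss_within <- ss_total - ss_between_subj
  ss_err <- ss_within - ss_event - ss_inter

  df_group <- G - 1; df_subj <- N - G
  df_event <- E - 1; df_inter <- (G - 1) * (E - 1)
  df_err <- (N - G) * (E - 1)
  tibble::tibble(
    effect = c("group", "maneuver", "group:maneuver"),
    F = c((ss_group / df_group) / (ss_subj_err / df_subj),
          (ss_event / df_event) / (ss_err / df_err),
          (ss_inter / df_inter) / (ss_err / df_err)))
}
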