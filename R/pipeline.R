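#' Analyse one subject's cine loop
#'
#' The single-subject pipeline: track the four annotated ROIs through the
#' loop, build the pubis-anchored frame, express the urethral segments in
#' pelvic coordinates, and compute the kinematic metrics. Deterministic
#' for fixed inputs.
#'
#' @param cine A [cine_loop()].
#' @param annotation An [roi_annotation()] (validated against the frame
#'   bounds before any tracking starts).
#' @param settings A [track_settings()].
#' @param subject,maneuver Labels attached to the output rows.
#' @param rest_frame_index Rest frame id (default 0).
#' @param excursion_roi Segment defining maximum excursion (see
#'   [subject_metrics()]).
#' @param rois Urethral segments to track and report (default all three;
#'   the pubis is always tracked for the coordinate frame). Chain metrics
#'   (kink angle, relative mobility) are NA unless all three are tracked.
#' @return A list with `trajectories` (long tibble, one row per roi-frame,
#'   ready for [write_trajectories()]), `metrics` (one row per segment),
#'   `result` (the full `maneuver_result`), and `log` (per-ROI tracked
#'   fraction, residuals and re-seed counts).
#' @export
run_subject <- function(cine, annotation, settings = track_settings(),
                        subject = "s01", maneuver = "unspecified",
                        rest_frame_index = 0, excursion_roi = "proximal",
                        rois = URETHRA_ROIS) {
  stopifnot(inherits(cine, "cine_loop"))
  rois <- intersect(URETHRA_ROIS, rois)
  check_annotation_bounds(annotation, frame_size(cine))

  poses <- track_rois(cine, annotation, c(rois, "pubis"), settings)
  frame <- construct_frame(poses$pubis, annotation, cine$pixel_spacing_mm)
  pelvic <- lapply(poses[rois], to_pelvic, frame = frame)
  res <- subject_metrics(pelvic, rest_frame_index = rest_frame_index,
                         excursion_roi = excursion_roi)

  traj <- dplyr::bind_rows(lapply(rois, function(lab) {
    p <- pelvic[[lab]]; r <- res$records[[lab]]
    tibble::tibble(subject = subject, maneuver = maneuver, roi = lab,
                   frame = as.integer(p$frame),
                   t_s = p$frame / cine$frame_rate_hz,
                   x_mm = p$x_mm, y_mm = p$y_mm, theta_deg = p$theta_deg,
                   dx_mm = r$dx_mm, dy_mm = r$dy_mm, dmag_mm = r$dmag_mm,
                   phi_deg = r$phi_deg,
                   n_points_tracked = as.integer(p$n_points_tracked))
  }))
  metrics <- dplyr::mutate(res$metrics, subject = subject,
                           maneuver = maneuver, .before = 1)
  log <- dplyr::bind_rows(lapply(c(rois, "pubis"), function(lab) {
    p <- poses[[lab]]
    tibble::tibble(subject = subject, maneuver = maneuver, roi = lab,
                   mean_tracked = mean(p$n_points_tracked),
                   mean_fb_error_px = mean(p$mean_fb_error_px),
                   n_reseeds = sum(p$reseeded))
  }))
  list(trajectories = traj, metrics = metrics, result = res, log = log)
}

#' Convert per-subject metrics into a long cohort table
#'
#' @param metrics Row-bound `metrics` tibbles from [run_subject()], with
#'   a `group` column attached.
#' @param metrics_keep Metric columns to pivot into the long table.
#' @return Long tibble `subject`, `group`, `maneuver`, `roi`, `metric`,
#'   `value`.
#' @export
cohort_table <- function(metrics,
                         metrics_keep = c("dmag_mm", "phi_deg", "dx_mm",
                                          "dy_mm", "dtheta_deg",
                                          "omega_max_deg", "r_prox_mid",
                                          "r_mid_dist")) {
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(metrics_keep), names_to = "metric",
                        values_to = "value") |>
    dplyr::select(dplyr::all_of(c("subject", "group", "maneuver", "roi",
                                  "metric", "value"))) |>
    dplyr::filter(!is.na(.data$value))
}

#' Simulate and analyse a whole synthetic cohort
#'
#' For each subject and maneuver in the [cohort_spec()], renders the
#' synthetic cine (subject by subject, so memory stays bounded), runs the
#' tracking pipeline, and aggregates per-subject metrics into cohort-level
#' summaries and statistics: a group-by-maneuver summary table, a mixed
#' repeated-measures ANOVA per ROI on the displacement magnitude, and the
#' default Bonferroni-corrected pairwise contrasts per ROI. A subject
#' whose tracking fails is recorded and skipped with a warning; the run
#' aborts only if fewer than 2 subjects per group survive.
#'
#' @param spec A [cohort_spec()].
#' @param settings A [track_settings()].
#' @param keep_trajectories Keep per-frame trajectories in the result
#'   (default FALSE to save memory).
#' @param rois Urethral segments to track (see [run_subject()]); ANOVA and
#'   contrasts are computed for the tracked segments only.
#' @return An object of class `cohort_result`: list with `metrics`
#'   (per-subject), `table` (long [cohort_table()]), `summary`
#'   ([cohort_summary()]), `anova` (named list per ROI, dmag), `contrasts`
#'   (named list per ROI), `failures` (tibble), and `trajectories` when
#'   requested.
#' @export
run_cohort <- function(spec, settings = track_settings(),
                       keep_trajectories = FALSE, rois = URETHRA_ROIS) {
  rois <- intersect(URETHRA_ROIS, rois)
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- cohort_manifest(spec)
  ann <- default_annotation(spec$frame_size_px, spec$frame_size_px)
  params <- with_seed(spec$seed, draw_cohort_params(spec))

  metrics <- list(); trajs <- list(); fails <- list()
  for (sub in unique(rows$subject)) {
    grp <- rows$group[match(sub, rows$subject)]
    tex <- generate_speckle_field(spec$frame_size_px, spec$frame_size_px,
                                  seed = subject_seed(spec$seed, sub, 0))
    for (mv in spec$maneuvers) {
      res <- tryCatch({
        sim <- simulate_subject_cine(spec, params[[sub]], mv, tex, ann,
                                     seed = subject_seed(spec$seed, sub,
                                                         match(mv, MANEUVERS)))
        run_subject(sim$cine, ann, settings, subject = sub, maneuver = mv,
                    rois = rois)
      }, urokin_error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("Subject %s (%s) failed: %s; skipped.", sub, mv,
                        conditionMessage(res)), call. = FALSE)
        fails[[length(fails) + 1]] <-
          tibble::tibble(subject = sub, maneuver = mv,
                         error = conditionMessage(res))
        next
      }
      metrics[[length(metrics) + 1]] <- dplyr::mutate(res$metrics,
                                                      group = grp)
      if (keep_trajectories) trajs[[length(trajs) + 1]] <- res$trajectories
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  failures <- dplyr::bind_rows(fails)
  complete <- metrics |>
    dplyr::distinct(.data$subject, .data$group, .data$maneuver) |>
    dplyr::count(.data$subject, .data$group) |>
    dplyr::filter(.data$n == length(spec$maneuvers))
  for (g in GROUPS) {
    if (sum(complete$group == g) < 2)
      abort_arg(sprintf(
        "Fewer than 2 complete subjects in group '%s' after failures.", g),
        "urokin_cohort_error")
  }
  metrics <- metrics[metrics$subject %in% complete$subject, ]
  tab <- cohort_table(metrics)
  summ <- cohort_summary(tab)
  dmag <- tab[tab$metric == "dmag_mm", ]
  anova <- lapply(setNames(rois, rois), function(r)
    if (length(spec$maneuvers) > 1) rm_anova_2x3(dmag, roi = r) else NULL)
  ctr <- default_contrasts(spec$maneuvers)
  if (!all(c("cough", "valsalva") %in% spec$maneuvers))
    ctr <- ctr[ctr$type == "independent", ]
  contrasts <- lapply(setNames(rois, rois), function(r)
    pairwise_compare(dmag[dmag$roi == r, ], ctr))
  structure(list(metrics = metrics, table = tab, summary = summ,
                 anova = anova, contrasts = contrasts, failures = failures,
                 trajectories = if (keep_trajectories)
                   dplyr::bind_rows(trajs) else NULL,
                 spec = spec),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects x %d maneuvers (%d failures)\n",
              length(unique(x$metrics$subject)),
              length(x$spec$maneuvers), nrow(x$failures)))
  cat("Summary cells:", nrow(x$summary), "\n")
  invisible(x)
}
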