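#' Maneuver motion template
#'
#' Parameterises the ground-truth motion of the three urethral segments for
#' one maneuver. Amplitudes are pelvic-frame displacements in mm (`dx`
#' posterior-positive, `dy` superior-positive) at peak excursion, one pair
#' per segment, plus a rigid rotation amplitude in degrees. Waveform shapes
#' follow the qualitative maneuver signatures seen on dynamic transperineal
#' ultrasound:
#'
#' * **cough** — a rapid spike-and-rebound raised-cosine pulse (default
#'   rise 0.15 s, rebound 0.35 s), optionally preceded by a small superior
#'   anticipatory pre-lift (the preprogrammed pelvic-floor "preflex");
#' * **valsalva** — a slow smoothstep ramp (1.5 s) to a sustained plateau
#'   (2 s) followed by a partial release, emulating viscoelastic creep;
#' * **pmc** — a superior raised-cosine lift whose anterior-posterior
#'   component first goes posterior (`dx > 0`) then reverses and drifts
#'   anterior (`dx < 0`) before returning to rest.
#'
#' Exact waveform timings are not published for this method; the defaults
#' are plausible physiological values and every one is a parameter.
#'
#' @param maneuver One of `"cough"`, `"valsalva"`, `"pmc"`.
#' @param amplitudes_mm Named list (`proximal`, `mid`, `distal`) of
#'   `c(dx, dy)` peak displacements in mm.
#' @param rotation_deg Named numeric vector (or single value recycled) of
#'   peak segment rotation in degrees.
#' @param duration_s Total maneuver duration in seconds.
#' @param frame_rate_hz Sampling rate (default 30 Hz, the typical cine
#'   frame rate).
#' @param rise_s,hold_s,rebound_s Waveform timing parameters in seconds
#'   (their meaning depends on the maneuver; see Details).
#' @param prelift_mm Anticipatory superior pre-lift amplitude in mm
#'   (cough only; 0 disables).
#' @param prelift_lead_s Lead time of the pre-lift before the main pulse
#'   onset, in seconds.
#' @param pmc_reversal Fraction (0-1) of the anterior-posterior amplitude
#'   used for the initial posterior pulse of a PMC; 0 disables the
#'   direction reversal.
#' @return An object of class `motion_template`.
#' @examples
#' tpl <- motion_template("cough",
#'   amplitudes_mm = list(proximal = c(2, -6), mid = c(0, -4), distal = c(-1, -3)))
#' traj <- maneuver_trajectory(tpl, "proximal")
#' max(traj$dmag_mm)
#' @export
motion_template <- function(maneuver = c("cough", "valsalva", "pmc"),
                            amplitudes_mm = list(proximal = c(2, -5),
                                                 mid = c(0, -4),
                                                 distal = c(-1, -3)),
                            rotation_deg = 4,
                            duration_s = NULL,
                            frame_rate_hz = 30,
                            rise_s = NULL, hold_s = NULL, rebound_s = NULL,
                            prelift_mm = 0.5, prelift_lead_s = 0.2,
                            pmc_reversal = 0.35) {
  maneuver <- match.arg(maneuver)
  defaults <- switch(maneuver,
    cough    = list(duration_s = 2.0, rise_s = 0.15, hold_s = 0, rebound_s = 0.35),
    valsalva = list(duration_s = 4.5, rise_s = 1.5, hold_s = 2.0, rebound_s = 1.0),
    pmc      = list(duration_s = 3.0, rise_s = 0.6, hold_s = 0.8, rebound_s = 0.9))
  duration_s <- duration_s %||% defaults$duration_s
  rise_s <- rise_s %||% defaults$rise_s
  hold_s <- hold_s %||% defaults$hold_s
  rebound_s <- rebound_s %||% defaults$rebound_s
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  miss <- setdiff(URETHRA_ROIS, names(amplitudes_mm))
  if (length(miss) > 0)
    abort_arg(sprintf("`amplitudes_mm` missing segment(s): %s.",
                      paste(miss, collapse = ", ")), "urokin_argument_error")
  if (length(rotation_deg) == 1)
    rotation_deg <- setNames(rep(rotation_deg, 3), URETHRA_ROIS)
  structure(list(maneuver = maneuver, amplitudes_mm = amplitudes_mm,
                 rotation_deg = rotation_deg, duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz, rise_s = rise_s,
                 hold_s = hold_s, rebound_s = rebound_s,
                 prelift_mm = prelift_mm, prelift_lead_s = prelift_lead_s,
                 pmc_reversal = pmc_reversal),
            class = "motion_template")
}

# Raised-cosine pulse: 0 before t0, rises over `rise` to 1, falls over
# `fall` back to 0, with an optional hold at 1 in between.
raised_cosine_pulse <- function(t, t0, rise, hold, fall) {
  out <- numeric(length(t))
  up <- t >= t0 & t < t0 + rise
  out[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / rise))
  flat <- t >= t0 + rise & t < t0 + rise + hold
  out[flat] <- 1
  dn <- t >= t0 + rise + hold & t < t0 + rise + hold + fall
  out[dn] <- 0.5 * (1 + cos(pi * (t[dn] - t0 - rise - hold) / fall))
  out
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Unit main waveform for each maneuver; peak value 1.
template_waveform <- function(tpl, t) {
  T <- tpl$duration_s
  switch(tpl$maneuver,
    cough = {
      t0 <- tpl$prelift_lead_s + 0.15  # pulse onset after the pre-lift
      raised_cosine_pulse(t, t0, tpl$rise_s, tpl$hold_s, tpl$rebound_s)
    },
    valsalva = {
      ramp <- smoothstep(t / tpl$rise_s)
      rel_t0 <- tpl$rise_s + tpl$hold_s
      # partial release toward a creep residual of 25% of peak
      rel <- ifelse(t <= rel_t0, 1,
                    0.25 + 0.75 * (1 - smoothstep((t - rel_t0) / tpl$rebound_s)))
      ramp * rel
    },
    pmc = raised_cosine_pulse(t, 0.1, tpl$rise_s, tpl$hold_s,
                              min(tpl$rebound_s, T - 0.1 - tpl$rise_s - tpl$hold_s)))
}

# PMC anterior-posterior waveform: positive half-sine then negative
# half-sine, one zero crossing, back to rest at the end. Peak magnitude 1.
pmc_x_waveform <- function(t, T, reversal) {
  u <- pmin(pmax(t / T, 0), 1)
  # positive half-sine on [0, 0.5), negative half-sine on [0.5, 1]:
  # one zero crossing, rest at both ends
  ifelse(u < 0.5, reversal * sin(2 * pi * u), -sin(2 * pi * (u - 0.5)))
}

#' Ground-truth trajectory for one urethral segment
#'
#' Evaluates a [motion_template()] for one segment, returning the per-frame
#' pelvic-frame displacement from rest. The series starts at `(0, 0, 0)` at
#' frame 0 and its peak displacement magnitude equals the template's
#' amplitude `|(dx, dy)|` (the PMC composite waveform is normalised so this
#' holds for every maneuver).
#'
#' @param template A [motion_template()].
#' @param roi_label One of `"proximal"`, `"mid"`, `"distal"`.
#' @return A tibble with columns `frame`, `t_s`, `dx_mm`, `dy_mm`,
#'   `dtheta_deg`, `dmag_mm`.
#' @export
maneuver_trajectory <- function(template, roi_label) {
  stopifnot(inherits(template, "motion_template"))
  if (!roi_label %in% URETHRA_ROIS)
    abort_arg(sprintf("Unknown roi_label '%s' (expected one of %s).",
                      roi_label, paste(URETHRA_ROIS, collapse = ", ")),
              "urokin_argument_error")
  n <- round(template$duration_s * template$frame_rate_hz)
  t <- (seq_len(n) - 1) / template$frame_rate_hz
  amp <- as.numeric(template$amplitudes_mm[[roi_label]])
  rot <- template$rotation_deg[[roi_label]]
  w <- template_waveform(template, t)
  dx <- amp[1] * w
  dy <- amp[2] * w
  if (template$maneuver == "cough" && template$prelift_mm != 0) {
    # anticipatory superior pre-lift, finished before the main rise begins
    wp <- raised_cosine_pulse(t, 0.02, template$prelift_lead_s / 2, 0,
                              template$prelift_lead_s / 2 + 0.1)
    dy <- dy + template$prelift_mm * wp
  }
  if (template$maneuver == "pmc" && template$pmc_reversal > 0) {
    # normalise time by the last sample so dx lands exactly at rest
    dx <- amp[1] * pmc_x_waveform(t, max(t), template$pmc_reversal)
  }
  dth <- rot * w
  dmag <- sqrt(dx^2 + dy^2)
  target <- sqrt(sum(amp^2))
  peak <- max(dmag)
  if (template$maneuver == "pmc" && peak > 0 && target > 0) {
    sc <- target / peak
    dx <- dx * sc; dy <- dy * sc; dmag <- dmag * sc
  }
  tibble::tibble(frame = seq_len(n) - 1L, t_s = t, dx_mm = dx, dy_mm = dy,
                 dtheta_deg = dth, dmag_mm = sqrt(dx^2 + dy^2))
}
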