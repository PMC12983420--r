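# Internal helpers shared across modules.

abort_arg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "urokin_error"))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_arg(sprintf("`%s` must be a finite numeric scalar.", name),
              "urokin_argument_error")
  if (positive && x <= 0)
    abort_arg(sprintf("`%s` must be > 0 (got %g).", name, x),
              "urokin_argument_error")
  invisible(x)
}

# 2x2 rotation matrix for an angle in degrees, acting on (x = col, y = row)
# image coordinates. Positive angles are counter-clockwise in (x, y); with
# raster rows increasing downward this appears clockwise on screen.
rot2 <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

deg_atan2 <- function(y, x) atan2(y, x) * 180 / pi

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(theta) {
  w <- (theta + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# Half-up integer rounding (used for reported integer percentages so that
# ties never round to even).
round_half_up <- function(x) floor(x + 0.5)

# Rigid transform as list(R = 2x2, t = length-2): x -> R x + t.
rigid <- function(theta_deg = 0, t = c(0, 0)) {
  list(R = rot2(theta_deg), t = as.numeric(t), theta_deg = theta_deg)
}

rigid_apply <- function(tr, pts) {
  # pts: n x 2 matrix (x, y)
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(tr$R), 2, tr$t, `+`)
}

rigid_compose <- function(outer, inner) {
  # (outer o inner)(x) = outer(inner(x))
  list(R = outer$R %*% inner$R,
       t = as.numeric(outer$R %*% inner$t) + outer$t,
       theta_deg = outer$theta_deg + inner$theta_deg)
}

rigid_invert <- function(tr) {
  Rt <- t(tr$R)
  list(R = Rt, t = as.numeric(-Rt %*% tr$t), theta_deg = -tr$theta_deg)
}

# Deterministic small PRNG (xorshift32) used where reproducibility must not
# disturb the user's global RNG stream (e.g. RANSAC sampling).
local_rng <- function(seed) {
  state <- as.integer(abs(seed) %% 2147483647)
  if (is.na(state) || state == 0L) state <- 246353424L
  function() {
    x <- state
    x <- bitwXor(x, bitwShiftL(x, 13L))
    x <- bitwXor(x, bitwShiftR(x, 17L))
    x <- bitwXor(x, bitwShiftL(x, 5L))
    state <<- x
    (x / 2^32) + 0.5  # uniform in [0, 1)
  }
}
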