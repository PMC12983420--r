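#' Generate a synthetic speckle texture
#'
#' Produces a grayscale image that mimics the granular interference texture
#' of B-mode ultrasound well enough for corner detection and optical-flow
#' tracking: low-pass-filtered white noise, rescaled to `[0, 1]`. The
#' autocorrelation length of the grain is approximately `grain_scale_px`.
#' Acoustic realism (beamforming, depth-dependent resolution) is a non-goal;
#' what matters for validating the tracker is a deterministic, corner-rich
#' field.
#'
#' @param height_px,width_px Image dimensions in pixels (>= 64).
#' @param grain_scale_px Speckle grain scale in pixels (>= 1); the standard
#'   deviation of the Gaussian low-pass filter applied to white noise.
#' @param seed Integer seed; the output is bitwise-reproducible for a fixed
#'   seed and does not disturb the caller's RNG state.
#' @return A `height_px` x `width_px` numeric matrix with values in `[0, 1]`.
#' @examples
#' tex <- generate_speckle_field(128, 128, grain_scale_px = 3, seed = 1)
#' range(tex)
#' @export
generate_speckle_field <- function(height_px, width_px, grain_scale_px = 3,
                                   seed = 1) {
  assert_scalar_num(height_px, "height_px", positive = TRUE)
  assert_scalar_num(width_px, "width_px", positive = TRUE)
  if (height_px < 64 || width_px < 64)
    abort_arg("Image dimensions must be at least 64 px.",
              "urokin_argument_error")
  assert_scalar_num(grain_scale_px, "grain_scale_px", positive = TRUE)
  if (grain_scale_px < 1)
    abort_arg("`grain_scale_px` must be >= 1.", "urokin_argument_error")

  noise <- with_seed(seed, matrix(rnorm(height_px * width_px),
                                  nrow = height_px, ncol = width_px))
  # blurred white noise has 1/e autocorrelation distance 2*sigma, so
  # sigma = grain/2 makes the grain scale the correlation length
  sm <- gauss_blur(noise, sigma = grain_scale_px / 2)
  rng <- range(sm)
  if (diff(rng) == 0) return(matrix(0.5, height_px, width_px))
  (sm - rng[1]) / diff(rng)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Separable Gaussian blur with reflecting edges; kernel truncated at 3 sigma.
gauss_blur <- function(mat, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(m, n) {
    top <- m[n:1, , drop = FALSE]
    bot <- m[nrow(m):(nrow(m) - n + 1), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_cols <- function(m) {
    # filter each column with kernel k (stats::filter handles matrices
    # column-wise); reflect-pad so borders stay defined
    p <- pad_reflect(m, half)
    f <- stats::filter(p, k, sides = 2)
    f[(half + 1):(half + nrow(m)), , drop = FALSE]
  }
  t(conv_cols(t(conv_cols(mat))))
}
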