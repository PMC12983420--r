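#' Reference cohort summary of urethral displacement
#'
#' Published group-level summary statistics of the urethral displacement
#' vector (magnitude in mm and direction in degrees) by segment, group and
#' maneuver from a 21-subject pilot transperineal-ultrasound cohort
#' (10 continent controls, 11 women with stress urinary incontinence).
#' These printed values serve two purposes in the package: they calibrate
#' the synthetic cohort generator's group effect sizes, and they provide
#' fixed inputs for arithmetic self-checks (CV and SEM reproduction).
#'
#' @return A tibble with columns `maneuver`, `roi`, `group`, `metric`
#'   (`"magnitude"` mm or `"direction"` deg), `mean`, `sd`, `range`,
#'   `cv_percent` (the printed integer CV).
#' @examples
#' ref <- reference_displacement_summary()
#' subset(ref, maneuver == "valsalva" & roi == "proximal" & metric == "magnitude")
#' @export
reference_displacement_summary <- function() {
  g <- rep(c("control", "sui"), 9)
  roi <- rep(rep(c("proximal", "mid", "distal"), each = 2), 3)
  man <- rep(c("cough", "valsalva", "pmc"), each = 6)
  mag <- tibble::tibble(
    maneuver = man, roi = roi, group = g, metric = "magnitude",
    mean = c(4.88, 6.59, 4.13, 3.88, 3.98, 3.65,
             5.98, 10.64, 4.97, 6.50, 4.94, 3.77,
             4.46, 3.43, 2.81, 1.93, 2.29, 1.72),
    sd = c(1.64, 1.61, 1.52, 1.22, 1.42, 1.32,
           2.01, 3.69, 2.06, 1.99, 2.06, 1.38,
           4.01, 2.58, 2.82, 1.22, 1.32, 1.35),
    range = c(5.56, 4.89, 4.37, 4.12, 3.95, 4.33,
              5.64, 10.91, 5.62, 6.52, 5.95, 4.63,
              11.95, 9.39, 9.19, 3.38, 3.62, 3.77),
    cv_percent = c(34L, 24L, 37L, 31L, 36L, 36L,
                   34L, 35L, 41L, 31L, 42L, 37L,
                   90L, 75L, 101L, 64L, 58L, 79L))
  dir <- tibble::tibble(
    maneuver = man, roi = roi, group = g, metric = "direction",
    mean = c(-79.55, -83.65, -90.14, -95.26, -117.56, -128.03,
             -67.08, -75.16, -92.64, -79.73, -121.68, -128.79,
             134.06, 131.66, 145.42, 115.97, 61.67, 85.45),
    sd = c(18.39, 10.34, 8.55, 25.55, 17.49, 22.75,
           18.56, 24.52, 16.79, 32.86, 30.73, 26.19,
           25.17, 7.66, 10.69, 16.90, 43.04, 49.28),
    range = c(43.38, 28.88, 23.81, 87.78, 49.94, 72.73,
              60.64, 61.48, 50.94, 87.93, 97.41, 89.40,
              64.58, 22.04, 29.77, 52.99, 113.79, 161.15),
    cv_percent = c(23L, 12L, 9L, 27L, 15L, 18L,
                   28L, 33L, 18L, 41L, 25L, 20L,
                   19L, 6L, 7L, 15L, 70L, 58L))
  dplyr::bind_rows(mag, dir)
}
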