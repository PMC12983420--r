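#' Basic inter-subject summary statistics
#'
#' Summarises a vector of per-subject metric values the way cohort tables
#' report them: n, mean, sample standard deviation (n - 1 denominator),
#' standard error of the mean, range (max - min) and coefficient of
#' variation in percent (`100 * sd / |mean|`).
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return A one-row tibble: `n`, `mean`, `sd`, `sem`, `range`,
#'   `cv_percent`.
#' @examples
#' summary_stats(c(2, 4, 6))
#' @export
summary_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2)
    abort_arg("At least 2 finite values are required.",
              "urokin_argument_error")
  m <- mean(values)
  s <- sd(values)
  tibble::tibble(n = n, mean = m, sd = s, sem = s / sqrt(n),
                 range = max(values) - min(values),
                 cv_percent = if (m == 0) NA_real_ else 100 * s / abs(m))
}

#' Coefficient of variation as a reported integer percent
#'
#' `round(100 * sd / |mean|)` with half-up rounding, matching how CV is
#' printed in cohort summary tables. The absolute mean is used so that
#' direction metrics with negative means still report a positive CV;
#' circular statistics are deliberately not used because reported CVs for
#' angular means are plain `SD/|mean|` ratios.
#'
#' @param mean,sd Summary values (mean must be nonzero; `sd = 0` gives 0).
#' @return Integer percent (vectorised).
#' @examples
#' coefficient_of_variation(4.88, 1.64)  # 34
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean == 0))
    abort_arg("CV is undefined for a zero mean.", "urokin_argument_error")
  as.integer(round_half_up(100 * sd / abs(mean)))
}

#' Two-by-three mixed repeated-measures ANOVA
#'
#' The cohort comparison design: group (control vs. SUI) as the
#' between-subject factor and maneuver (cough, Valsalva, PMC) as the
#' within-subject factor, fitted separately per ROI and metric. Sums of
#' squares follow the standard two-way mixed decomposition
#' (`stats::aov` with a subject error stratum); no sphericity correction
#' is applied, which is recorded in the result. Missing cells raise an
#' error rather than being silently imputed. If an effect's sum of squares
#' is exactly zero (degenerate variance structure), its F is reported as 0
#' with p = 1.
#'
#' @param data Long-format tibble with columns `subject`, `group`,
#'   `maneuver`, `value` (use [cohort_table()] selectors to get here).
#' @param roi,metric Optional filters applied when `data` carries `roi` /
#'   `metric` columns.
#' @return An object of class `rm_anova` with a `table` tibble
#'   (`effect`, `df`, `df_error`, `ss`, `ms`, `F`, `p`) covering the
#'   group, maneuver and interaction effects. Use [tidy()] / [glance()].
#' @export
rm_anova_2x3 <- function(data, roi = NULL, metric = NULL) {
  if (!is.null(roi) && "roi" %in% names(data))
    data <- data[data$roi == roi, ]
  if (!is.null(metric) && "metric" %in% names(data))
    data <- data[data$metric == metric, ]
  need <- c("subject", "group", "maneuver", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    abort_arg(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")),
              "urokin_argument_error")
  data <- data[need]
  events <- sort(unique(data$maneuver))
  counts <- table(data$subject, data$maneuver)
  if (any(counts != 1))
    abort_arg(paste0("Every subject needs exactly one value per maneuver; ",
                     "missing or duplicated cells found."),
              "urokin_missing_data_error")
  df <- data.frame(subject = factor(data$subject),
                   group = factor(data$group),
                   event = factor(data$maneuver),
                   value = as.numeric(data$value))
  if (nlevels(df$group) < 2)
    abort_arg("Both groups must be present.", "urokin_argument_error")

  fit <- stats::aov(value ~ group * event + Error(subject), data = df)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))
  pick <- function(tab, rn, eff) as.numeric(tab[match(eff, rn), ])
  b_grp <- pick(between, rn_b, "group")
  b_res <- pick(between, rn_b, "Residuals")
  w_evt <- pick(within, rn_w, "event")
  w_int <- pick(within, rn_w, "group:event")
  w_res <- pick(within, rn_w, "Residuals")

  ss_scale <- sum(abs(c(b_grp[2], b_res[2], w_evt[2], w_int[2], w_res[2])))
  row <- function(effect, eff, res) {
    ss <- eff[2]; df1 <- eff[1]; df2 <- res[1]
    ms <- ss / df1; mse <- res[2] / res[1]
    if (ss <= 1e-12 * max(ss_scale, 1)) {
      Fv <- 0; p <- 1
    } else {
      Fv <- ms / mse
      p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    tibble::tibble(effect = effect, df = df1, df_error = df2, ss = ss,
                   ms = ms, F = Fv, p = p)
  }
  tab <- dplyr::bind_rows(row("group", b_grp, b_res),
                          row("maneuver", w_evt, w_res),
                          row("group:maneuver", w_int, w_res))
  structure(list(table = tab, n_subjects = nlevels(df$subject),
                 events = levels(df$event), roi = roi, metric = metric,
                 sphericity_correction = "none"),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mixed 2 x %d repeated-measures ANOVA (%d subjects%s)\n",
              length(x$events), x$n_subjects,
              if (!is.null(x$roi)) paste0(", ROI ", x$roi) else ""))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Declare the default pairwise contrast family
#'
#' The targeted comparisons run after the omnibus ANOVA: independent
#' t-tests of control vs. SUI at each maneuver, and paired t-tests of
#' cough vs. Valsalva within each group — a family of five contrasts that
#' the Bonferroni correction is applied over.
#'
#' @param maneuvers Maneuver labels tested between groups.
#' @return A tibble describing the contrasts, for [pairwise_compare()].
#' @export
default_contrasts <- function(maneuvers = MANEUVERS) {
  dplyr::bind_rows(
    tibble::tibble(contrast = paste0("control_vs_sui@", maneuvers),
                   type = "independent", maneuver = maneuvers,
                   group = NA_character_),
    tibble::tibble(contrast = paste0("cough_vs_valsalva@", GROUPS),
                   type = "paired", maneuver = NA_character_,
                   group = GROUPS))
}

#' Targeted pairwise comparisons with Bonferroni correction
#'
#' Runs the declared contrast family on a long metric table: two-sided
#' pooled-variance independent t-tests (control vs. SUI at a maneuver) and
#' paired t-tests (cough vs. Valsalva within a group). The Bonferroni
#' family is exactly the set of contrasts declared in the call:
#' `p_bonferroni = min(1, m * p_raw)` with `m = nrow(contrasts)`.
#'
#' @param data Long tibble with `subject`, `group`, `maneuver`, `value`.
#' @param contrasts Contrast declaration, e.g. [default_contrasts()].
#' @return A tibble: `contrast`, `type`, `estimate`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`.
#' @export
pairwise_compare <- function(data, contrasts = default_contrasts()) {
  if (nrow(contrasts) == 0)
    abort_arg("Empty contrast list.", "urokin_argument_error")
  m <- nrow(contrasts)
  one <- function(i) {
    ct <- contrasts[i, ]
    if (ct$type == "independent") {
      d <- data[data$maneuver == ct$maneuver, ]
      a <- d$value[d$group == "control"]
      b <- d$value[d$group == "sui"]
      if (length(a) < 2 || length(b) < 2)
        abort_arg(sprintf("Contrast '%s': need n >= 2 per arm.", ct$contrast),
                  "urokin_argument_error")
      est <- mean(a) - mean(b)
      tt <- if (est == 0 && sd(c(a, b)) == 0)
        list(statistic = c(t = 0), parameter = c(df = length(a) +
                                                   length(b) - 2),
             p.value = 1)
      else stats::t.test(a, b, var.equal = TRUE)
    } else {
      d <- data[data$group == ct$group &
                  data$maneuver %in% c("cough", "valsalva"), ]
      w <- tidyr::pivot_wider(d[c("subject", "maneuver", "value")],
                              names_from = "maneuver",
                              values_from = "value")
      if (!all(c("cough", "valsalva") %in% names(w)) ||
          any(is.na(w$cough)) || any(is.na(w$valsalva)) || nrow(w) < 2)
        abort_arg(sprintf("Contrast '%s': incomplete pairs.", ct$contrast),
                  "urokin_argument_error")
      est <- mean(w$cough - w$valsalva)
      tt <- if (est == 0 && sd(w$cough - w$valsalva) == 0)
        list(statistic = c(t = 0), parameter = c(df = nrow(w) - 1),
             p.value = 1)
      else stats::t.test(w$cough, w$valsalva, paired = TRUE)
    }
    tibble::tibble(contrast = ct$contrast, type = ct$type, estimate = est,
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_bonferroni = min(1, m * tt$p.value))
  }
  dplyr::bind_rows(lapply(seq_len(m), one))
}

#' Cohort summary in the style of a group-by-maneuver table
#'
#' Per (maneuver, roi, group, metric) cell: n, mean, SD, SEM, range and
#' integer CV percent.
#'
#' @param cohort_table Long tibble with `subject`, `group`, `maneuver`,
#'   `roi`, `metric`, `value`.
#' @return A tibble with one row per cell.
#' @export
cohort_summary <- function(cohort_table) {
  cohort_table |>
    dplyr::group_by(.data$maneuver, .data$roi, .data$group, .data$metric) |>
    dplyr::summarise(stats = list(summary_stats(.data$value)),
                     .groups = "drop") |>
    tidyr::unnest("stats") |>
    dplyr::mutate(cv_percent = ifelse(
      is.na(.data$cv_percent), NA_integer_,
      as.integer(round_half_up(.data$cv_percent))))
}
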