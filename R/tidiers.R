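#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed repeated-measures ANOVA
#'
#' @param x An `rm_anova` from [rm_anova_2x3()].
#' @param ... Unused.
#' @return A tibble with one row per effect: `effect`, `df`, `df_error`,
#'   `ss`, `ms`, `F`, `p`.
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname tidy.rm_anova
#' @return For `glance`: a one-row tibble with `n_subjects`, `n_events`,
#'   `sphericity_correction`.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_events = length(x$events),
                 sphericity_correction = x$sphericity_correction)
}

#' Tidy a cohort analysis result
#'
#' @param x A `cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return The long per-subject metric table.
#' @export
tidy.cohort_result <- function(x, ...) x$table

#' @rdname tidy.cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$metrics$subject)),
    n_control = length(unique(x$metrics$subject[x$metrics$group == "control"])),
    n_sui = length(unique(x$metrics$subject[x$metrics$group == "sui"])),
    n_maneuvers = length(x$spec$maneuvers),
    n_failures = nrow(x$failures))
}
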