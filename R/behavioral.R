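#' Summarize trial-level behavior into per-subject asymmetries
#'
#' Computes, for each subject and cued side, the accuracy (proportion of
#' correct trials) and the mean response time, then the behavioral
#' asymmetry `BA = (right - left) / (right + left)` separately for
#' accuracy and RT. By default RT is averaged over correct trials only;
#' set `rt_correct_only = FALSE` to include error trials.
#'
#' @param trials Trial table with columns `subject_id`, `cue_side`
#'   (`"left"`/`"right"`), `correct` (0/1), `rt`.
#' @param rt_correct_only Restrict RT means to correct trials.
#' @return A tibble, one row per subject: `subject_id`, `acc_right`,
#'   `acc_left`, `rt_right`, `rt_left`, `ba_acc`, `ba_rt`.
#' @export
#' @examples
#' tr <- tidyr::expand_grid(subject_id = "S1",
#'                          cue_side = c("left", "right"), i = 1:20) |>
#'   dplyr::mutate(correct = 1, rt = 0.5)
#' summarize_behavior(tr)$ba_acc  # 0
summarize_behavior <- function(trials, rt_correct_only = TRUE) {
  need <- c("subject_id", "cue_side", "correct", "rt")
  stopifnot(all(need %in% names(trials)))
  sides <- trials |>
    dplyr::group_by(.data$subject_id, .data$cue_side) |>
    dplyr::summarise(
      acc = mean(.data$correct),
      rt = if (rt_correct_only) mean(.data$rt[.data$correct == 1]) else
        mean(.data$rt),
      n = dplyr::n(), .groups = "drop")
  counts <- table(sides$subject_id)
  if (any(counts != 2)) {
    abort(sprintf("Subject(s) missing trials on one cue side: %s",
                  paste(names(counts)[counts != 2], collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(sides[, c("subject_id", "cue_side", "acc", "rt")],
                             names_from = "cue_side",
                             values_from = c("acc", "rt"))
  if (any(wide$acc_right <= 0 | wide$acc_left <= 0)) {
    abort("A subject has zero accuracy on one side; BA is undefined.")
  }
  if (any(!is.finite(wide$rt_right) | !is.finite(wide$rt_left))) {
    abort("A subject has no usable RT trials on one side.")
  }
  wide |>
    dplyr::mutate(
      ba_acc = behavioral_asymmetry(.data$acc_right, .data$acc_left),
      ba_rt = behavioral_asymmetry(.data$rt_right, .data$rt_left)
    ) |>
    dplyr::select("subject_id", "acc_right", "acc_left", "rt_right",
                  "rt_left", "ba_acc", "ba_rt")
}

#' Refit the winning structural model on behavioral asymmetry
#'
#' Runs the winning GLM with a behavioral asymmetry score as the response
#' and the selected structures' LV values as regressors; called once for
#' accuracy asymmetry and once for RT asymmetry in the full pipeline.
#'
#' @param data Data frame with the BA column and LV columns.
#' @param response `"ba_acc"` or `"ba_rt"` (any BA column name).
#' @param regressors Structure columns; default the winning set
#'   thalamus, caudate nucleus, globus pallidus.
#' @return A `hemilat_ols` fit.
#' @export
fit_behavior_glm <- function(data, response = "ba_acc",
                             regressors = c("Th", "CN", "GP")) {
  fit_ols(data, response, regressors)
}
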