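#' Read and validate a volume table
#'
#' Reads a CSV with header `subject_id,structure,hemisphere,voxels`,
#' checking structure labels, hemisphere labels, duplicate rows and voxel
#' positivity.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_volume_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Volume table not found: %s", path))
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "structure", "hemisphere", "voxels")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("Volume table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(tab$structure), subcortical_structures())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown structure label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!all(tab$hemisphere %in% c("left", "right"))) {
    abort("Hemisphere labels must be 'left' or 'right'.")
  }
  dup <- duplicated(tab[, c("subject_id", "structure", "hemisphere")])
  if (any(dup)) {
    abort(sprintf("Duplicate (subject, structure, hemisphere) row at line %d.",
                  which(dup)[1] + 1L))
  }
  bad <- which(tab$voxels <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Nonpositive voxel count at data row %d (subject %s).",
                  bad[1], tab$subject_id[bad[1]]))
  }
  tab[, need]
}

#' Write a volume table CSV
#'
#' @param volumes Tibble with the four required columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(volumes, path) {
  write.csv(volumes[, c("subject_id", "structure", "hemisphere", "voxels")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param epochs Load the per-subject epoch files as well.
#' @return A cohort list as produced by [generate_cohort()] (without the
#'   generator config).
#' @export
read_cohort <- function(dir, epochs = TRUE) {
  volumes <- read_volume_table(file.path(dir, "volumes.csv"))
  behavior <- tibble::as_tibble(
    read.csv(file.path(dir, "behavior.csv"), stringsAsFactors = FALSE))
  ep <- NULL
  if (epochs) {
    subjects <- unique(volumes$subject_id)
    paths <- file.path(dir, "epochs", paste0(subjects, ".rds"))
    absent <- !file.exists(paths)
    if (any(absent)) {
      abort(sprintf("Missing epoch file(s) for subject(s): %s",
                    paste(subjects[absent], collapse = ", ")))
    }
    ep <- lapply(paths, readRDS)
    names(ep) <- subjects
  }
  list(volumes = volumes, epochs = ep, behavior = behavior)
}

#' Analysis parameters for the end-to-end pipeline
#'
#' @param freqs TFR frequency grid in Hz.
#' @param band Alpha band for the indices, Hz (closed interval).
#' @param window Pre-target analysis window in seconds (closed interval).
#' @param n_roi_pairs Number of ROI mirror pairs.
#' @param candidates Candidate structures for the model search.
#' @param criterion Selection criterion, `"aic"` or `"bic"`.
#' @param key_regressors Structures used in the condition-wise MMR and the
#'   behavioral refits; `NULL` (default) uses the search winner.
#' @param rt_correct_only Restrict RT means to correct trials.
#' @return A list of class `hemilat_analysis_config`.
#' @export
analysis_config <- function(freqs = 2:30, band = c(8, 13),
                            window = c(-0.850, 0), n_roi_pairs = 5,
                            candidates = subcortical_structures(),
                            criterion = "aic", key_regressors = NULL,
                            rt_correct_only = TRUE) {
  structure(list(freqs = freqs, band = band, window = window,
                 n_roi_pairs = n_roi_pairs, candidates = candidates,
                 criterion = criterion, key_regressors = key_regressors,
                 rt_correct_only = rt_correct_only),
            class = "hemilat_analysis_config")
}

#' Run the full structure-function pipeline
#'
#' Executes every stage on a cohort: time-frequency power and planar
#' combination, per-subject MI maps, group ROI selection, overall and
#' condition-wise HLM(alpha), LV computation, exhaustive model search with
#' the winning-model fit, condition-wise multivariate regression with
#' nested and per-regressor tests, and the behavioral-asymmetry refits.
#'
#' @param cohort In-memory cohort list (see [generate_cohort()]) or a
#'   directory written by [write_cohort()].
#' @param params An [analysis_config()].
#' @param verbose Print stage progress.
#' @return A `hemilat_report` list: `laterality`, `roi`, `group_mi`,
#'   `lv_tests`, `hlm_normality`, `search`, `winning_fit`, `vif`, `mmr`,
#'   `behavior_fits`, `provenance`.
#' @export
run_pipeline <- function(cohort, params = analysis_config(),
                         verbose = FALSE) {
  stopifnot(inherits(params, "hemilat_analysis_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(fmt, ...))
  }
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(force(code), error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
    say("stage %-12s %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  lat <- stage("laterality", cohort_laterality(
    cohort, freqs = params$freqs, band = params$band,
    window = params$window, n_roi_pairs = params$n_roi_pairs,
    rt_correct_only = params$rt_correct_only))
  d <- lat$laterality

  lv_tests <- stage("lv_tests", purrr::map_dfr(params$candidates, function(s) {
    dplyr::mutate(one_sample_test(d[[s]]), structure = s, .before = 1)
  }))
  hlm_norm <- stage("normality", normality_check(d$hlm))
  search <- stage("model_search", model_search(
    d, response = "hlm", candidates = params$candidates,
    criterion = params$criterion))
  key <- params$key_regressors
  if (is.null(key)) key <- search$winner
  vif_tab <- if (length(key) >= 2) vif(d, key) else NULL
  mmr_res <- stage("mmr", mmr_condition_analysis(
    d, key_regressors = key, all_regressors = params$candidates))
  beh <- NULL
  if (!is.null(cohort$behavior)) {
    beh <- stage("behavior", list(
      acc = fit_behavior_glm(d, "ba_acc", key),
      rt = fit_behavior_glm(d, "ba_rt", key)))
  }
  provenance <- list(
    package_version = as.character(utils::packageVersion("hemilat")),
    analysis_params = unclass(params),
    config_hash = rlang::hash(list(unclass(params), d)),
    n_subjects = nrow(d),
    timestamp = NULL  # deliberately unset: reports must be byte-reproducible
  )
  structure(list(laterality = d, roi = lat$roi, group_mi = lat$group_mi,
                 lv_tests = lv_tests, hlm_normality = hlm_norm,
                 search = search, winning_fit = search$fit, vif = vif_tab,
                 mmr = mmr_res, behavior_fits = beh,
                 provenance = provenance),
            class = "hemilat_report")
}

#' @export
print.hemilat_report <- function(x, ...) {
  cat(sprintf("<hemilat_report> %d subjects\n", nrow(x$laterality)))
  cat(sprintf("  winning model (%s): %s\n", toupper(x$search$criterion),
              paste(x$search$winner, collapse = " + ")))
  g <- glance(x$winning_fit)
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g, adj R^2 = %.3f\n",
              g$df, g$df.residual, g$statistic, g$p.value, g$adj.r.squared))
  invisible(x)
}

#' Serialize a pipeline report to JSON and CSV
#'
#' Writes `report.json` (laterality table, search table, coefficient and
#' test tables, provenance) plus `laterality.csv` and `model_search.csv`
#' into `dir`. Output is a pure function of the report, so identical
#' configurations and seeds produce byte-identical files.
#'
#' @param report A `hemilat_report`.
#' @param dir Output directory (created if needed).
#' @return Path of the JSON report, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hemilat_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$laterality, file.path(dir, "laterality.csv"),
            row.names = FALSE)
  write.csv(report$search$table, file.path(dir, "model_search.csv"),
            row.names = FALSE)
  payload <- list(
    laterality = as.data.frame(report$laterality),
    lv_tests = as.data.frame(report$lv_tests),
    hlm_normality = as.data.frame(report$hlm_normality),
    roi = list(n_pairs = report$roi$n_pairs,
               right_sensors = report$roi$right_sensors,
               left_sensors = report$roi$left_sensors),
    model_search = as.data.frame(report$search$table),
    winning_model = list(
      regressors = report$search$winner,
      coefficients = as.data.frame(tidy(report$winning_fit)),
      summary = as.data.frame(glance(report$winning_fit))),
    vif = if (is.null(report$vif)) NULL else as.data.frame(report$vif),
    mmr = list(
      coefficients = as.data.frame(tidy(report$mmr$fit)),
      full_vs_reduced = as.data.frame(report$mmr$full_vs_reduced),
      key_vs_null = as.data.frame(report$mmr$key_vs_null),
      per_regressor = as.data.frame(report$mmr$per_regressor)),
    behavior = if (is.null(report$behavior_fits)) NULL else list(
      acc = as.data.frame(tidy(report$behavior_fits$acc)),
      rt = as.data.frame(tidy(report$behavior_fits$rt))),
    provenance = report$provenance
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
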