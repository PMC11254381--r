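#' Alpha-band modulation index MI(alpha) per sensor
#'
#' For each sensor, `MI = (P_attRight - P_attLeft) / (P_attRight +
#' P_attLeft)`, where the two inputs are trial-averaged band power maps for
#' attend-right and attend-left trials (see [band_window_average()]).
#' Positive MI means more alpha power when attention is directed rightward;
#' on right-hemisphere sensors this contrasts ipsi- versus contralateral
#' attention, and inversely on the left.
#'
#' @param power_att_right,power_att_left Tibbles with sensor metadata and a
#'   `power` column, on the same sensors.
#' @return A tibble with the sensor metadata plus an `mi` column.
#' @export
#' @examples
#' r <- tibble::tibble(location = "R01", hemisphere = "right",
#'                     pair_id = 1, power = 2)
#' l <- dplyr::mutate(r, power = 1)
#' modulation_index(r, l)$mi  # 1/3
modulation_index <- function(power_att_right, power_att_left) {
  key <- intersect(c("channel", "location", "hemisphere", "pair_id",
                     "planar_channel_index"),
                   intersect(names(power_att_right), names(power_att_left)))
  if (!setequal(power_att_right[[key[1]]], power_att_left[[key[1]]])) {
    abort("The two power maps must cover the same sensors.")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(power_att_right, p_right = "power"),
    dplyr::select(power_att_left, dplyr::all_of(key[1]), p_left = "power"),
    by = key[1]
  )
  bad <- joined$p_right <= 0 | joined$p_left <= 0
  if (any(bad)) {
    abort(sprintf("Nonpositive power at sensor(s): %s",
                  paste(joined[[key[1]]][bad], collapse = ", ")))
  }
  joined |>
    dplyr::mutate(mi = (.data$p_right - .data$p_left) /
                    (.data$p_right + .data$p_left)) |>
    dplyr::select(-"p_right", -"p_left")
}

#' Compute a subject's MI(alpha) sensor map from a TFR
#'
#' Convenience wrapper: averages planar-combined power over the alpha band
#' and pre-target window separately for attend-right and attend-left
#' trials (optionally restricted to one condition), then forms the
#' modulation index per sensor.
#'
#' @param tfr A planar-combined `tfr_power`.
#' @param band,window Passed to [band_window_average()].
#' @param condition Optional condition label to restrict trials to.
#' @return A tibble of per-location MI values.
#' @export
mi_map <- function(tfr, band = c(8, 13), window = c(-0.850, 0),
                   condition = NULL) {
  stopifnot(inherits(tfr, "tfr_power"))
  tm <- tfr$trial_meta
  keep <- if (is.null(condition)) rep(TRUE, nrow(tm)) else
    tm$condition == condition
  sel_r <- keep & tm$cue_side == "right"
  sel_l <- keep & tm$cue_side == "left"
  if (!any(sel_r) || !any(sel_l)) {
    abort(sprintf("Missing cue side%s.", if (is.null(condition)) "" else
      sprintf(" in condition %s", condition)))
  }
  modulation_index(band_window_average(tfr, band, window, trials = sel_r),
                   band_window_average(tfr, band, window, trials = sel_l))
}

#' Select the region-of-interest sensor pairs
#'
#' At the group level, the MI of each left-hemisphere sensor is subtracted
#' from its right-hemisphere mirror partner; pairs are sorted by that
#' difference in decreasing order (ties broken by ascending `pair_id`) and
#' the top `n_pairs` pairs are selected — with the default 5 pairs this
#' yields 10 sensors, symmetrically distributed over the two hemispheres.
#'
#' @param group_mi A tibble of per-location MI values (columns `location`,
#'   `hemisphere`, `pair_id`, `mi`), typically the unweighted mean over
#'   subjects of per-subject [mi_map()]s.
#' @param n_pairs Number of mirror pairs to select.
#' @return An object of class `hemilat_roi`: list with `n_pairs`, `pairs`
#'   (tibble `pair_id`, `diff`, ordered as selected), `right_sensors`,
#'   `left_sensors`.
#' @export
select_roi <- function(group_mi, n_pairs = 5) {
  need <- c("location", "hemisphere", "pair_id", "mi")
  stopifnot(all(need %in% names(group_mi)))
  wide <- tidyr::pivot_wider(group_mi[, need], names_from = "hemisphere",
                             values_from = c("mi", "location"))
  if (!all(c("mi_left", "mi_right") %in% names(wide)) ||
      any(is.na(wide$mi_left)) || any(is.na(wide$mi_right))) {
    abort("Every sensor must have a mirror partner in the other hemisphere.")
  }
  if (n_pairs > nrow(wide)) {
    abort(sprintf("Requested %d pairs but only %d are available.",
                  n_pairs, nrow(wide)))
  }
  wide <- wide |>
    dplyr::mutate(diff = .data$mi_right - .data$mi_left) |>
    dplyr::arrange(dplyr::desc(.data$diff), .data$pair_id)
  sel <- wide[seq_len(n_pairs), ]
  structure(list(n_pairs = as.integer(n_pairs),
                 pairs = dplyr::select(sel, "pair_id", "diff"),
                 right_sensors = sel$location_right,
                 left_sensors = sel$location_left),
            class = "hemilat_roi")
}

#' @export
print.hemilat_roi <- function(x, ...) {
  cat(sprintf("<hemilat_roi> %d mirror pairs (%d sensors)\n", x$n_pairs,
              2 * x$n_pairs))
  print(x$pairs)
  invisible(x)
}

#' Hemispheric lateralization modulation HLM(alpha)
#'
#' The mean MI over the right-hemisphere ROI sensors plus the mean MI over
#' the left-hemisphere ROI sensors. Because right-hemisphere MI is positive
#' and left-hemisphere MI negative under symmetric attentional modulation,
#' the two means largely cancel; the residual sum is the subject's
#' hemispheric imbalance, in (-2, 2). Negative values indicate stronger
#' modulation of alpha power over the left hemisphere.
#'
#' @param mi A per-location MI tibble (e.g. from [mi_map()]).
#' @param roi A `hemilat_roi` from [select_roi()].
#' @return A single numeric HLM(alpha) value.
#' @export
hlm <- function(mi, roi) {
  stopifnot(inherits(roi, "hemilat_roi"))
  need <- c(roi$right_sensors, roi$left_sensors)
  missing <- setdiff(need, mi$location)
  if (length(missing) > 0) {
    abort(sprintf("ROI sensor(s) absent from the MI map: %s",
                  paste(missing, collapse = ", ")))
  }
  mean(mi$mi[match(roi$right_sensors, mi$location)]) +
    mean(mi$mi[match(roi$left_sensors, mi$location)])
}

#' Condition-wise HLM(alpha)
#'
#' Recomputes the band/window-averaged power per cue side within each task
#' condition's trials, forms the per-sensor MI, and evaluates HLM(alpha) on
#' a fixed, previously selected ROI.
#'
#' @param tfr A planar-combined `tfr_power` with `condition` in its trial
#'   metadata.
#' @param roi A `hemilat_roi`.
#' @param band,window Passed to [band_window_average()].
#' @return A tibble with columns `condition` and `hlm`.
#' @export
condition_hlm <- function(tfr, roi, band = c(8, 13), window = c(-0.850, 0)) {
  conds <- sort(unique(tfr$trial_meta$condition))
  purrr::map_dfr(conds, function(cc) {
    tibble::tibble(condition = cc,
                   hlm = hlm(mi_map(tfr, band, window, condition = cc), roi))
  })
}

#' Lateralization volume index LV per structure
#'
#' For each subject and structure, `LV = (V_right - V_left) / (V_right +
#' V_left)` from the hemispheric voxel counts. LV ranges over (-1, 1);
#' positive values indicate rightward volumetric asymmetry. The
#' normalization implicitly controls for individual differences in overall
#' brain volume.
#'
#' @param volumes Long volume table: `subject_id`, `structure`,
#'   `hemisphere` (`"left"`/`"right"`), `voxels`.
#' @return A tibble `subject_id`, `structure`, `lv`.
#' @export
#' @examples
#' v <- tibble::tibble(subject_id = "S1", structure = "Th",
#'                     hemisphere = c("right", "left"),
#'                     voxels = c(4040, 3960))
#' lateralization_volume(v)$lv  # 0.01
lateralization_volume <- function(volumes) {
  need <- c("subject_id", "structure", "hemisphere", "voxels")
  stopifnot(all(need %in% names(volumes)))
  if (any(volumes$voxels <= 0)) {
    bad <- which(volumes$voxels <= 0)[1]
    abort(sprintf("Nonpositive voxel count for subject %s, structure %s.",
                  volumes$subject_id[bad], volumes$structure[bad]))
  }
  wide <- tidyr::pivot_wider(volumes[, need], names_from = "hemisphere",
                             values_from = "voxels")
  if (!all(c("left", "right") %in% names(wide)) ||
      any(is.na(wide$left)) || any(is.na(wide$right))) {
    abort("Each (subject, structure) needs both a left and a right row.")
  }
  wide |>
    dplyr::mutate(lv = (.data$right - .data$left) /
                    (.data$right + .data$left)) |>
    dplyr::select("subject_id", "structure", "lv")
}

#' Pivot a long LV table to one row per subject
#'
#' @param lv_long Tibble from [lateralization_volume()].
#' @return A tibble `subject_id` plus one LV column per structure, in
#'   canonical structure order.
#' @export
lv_wide <- function(lv_long) {
  out <- tidyr::pivot_wider(lv_long, names_from = "structure",
                            values_from = "lv")
  dplyr::select(out, "subject_id",
                dplyr::all_of(intersect(subcortical_structures(),
                                        names(out))))
}

#' Behavioral asymmetry BA
#'
#' Normalized right-minus-left difference `(x_right - x_left) / (x_right +
#' x_left)` of a positive performance metric (accuracy or response time)
#' split by attended side. Bounded in (-1, 1) for positive inputs.
#'
#' @param metric_att_right,metric_att_left Positive numeric vectors.
#' @return Numeric vector of asymmetries.
#' @export
#' @examples
#' behavioral_asymmetry(0.85, 0.75)  # 0.0625
behavioral_asymmetry <- function(metric_att_right, metric_att_left) {
  if (any(metric_att_right <= 0) || any(metric_att_left <= 0)) {
    abort("Behavioral metrics must be positive on both sides.")
  }
  (metric_att_right - metric_att_left) /
    (metric_att_right + metric_att_left)
}

#' Per-subject laterality indices for a whole cohort
#'
#' Runs the sensor-level pipeline for every subject: TFR, planar
#' combination, per-subject MI map, group-level ROI selection (unweighted
#' mean MI map across subjects), then overall and condition-wise
#' HLM(alpha), joined with the LV table and, when behavior is available,
#' behavioral asymmetries.
#'
#' @param cohort A cohort list (see [generate_cohort()]) with `epochs`,
#'   `volumes` and optionally `behavior`.
#' @param freqs Frequencies for the TFR stage.
#' @param band,window Alpha band and pre-target window for the indices.
#' @param n_roi_pairs Number of ROI mirror pairs.
#' @param rt_correct_only Passed to [summarize_behavior()].
#' @return A list with `laterality` (tibble, one row per subject: `hlm`,
#'   `hlm_c1..4`, LV columns, and `ba_acc`/`ba_rt` if behavior present),
#'   `roi`, `group_mi`, `mi_maps`.
#' @export
cohort_laterality <- function(cohort, freqs = 2:30, band = c(8, 13),
                              window = c(-0.850, 0), n_roi_pairs = 5,
                              rt_correct_only = TRUE) {
  if (is.null(cohort$epochs)) {
    abort("The cohort has no epochs; generate it with `epochs = TRUE`.")
  }
  # one subject at a time: keep only the (small) MI maps, not the TFRs
  maps <- list()
  cond_maps <- list()
  for (sid in names(cohort$epochs)) {
    tfr <- combine_planar(compute_tfr(cohort$epochs[[sid]], freqs = freqs))
    maps[[sid]] <- mi_map(tfr, band = band, window = window)
    conds <- sort(unique(tfr$trial_meta$condition))
    cond_maps[[sid]] <- purrr::map_dfr(conds, function(cc) {
      dplyr::mutate(mi_map(tfr, band = band, window = window,
                           condition = cc),
                    condition = cc)
    })
    rm(tfr)
  }
  group_mi <- dplyr::bind_rows(maps, .id = "subject_id") |>
    dplyr::group_by(.data$location, .data$hemisphere, .data$pair_id) |>
    dplyr::summarise(mi = mean(.data$mi), .groups = "drop")
  roi <- select_roi(group_mi, n_pairs = n_roi_pairs)
  per_subj <- purrr::map_dfr(names(maps), function(sid) {
    ch <- vapply(1:4, function(cc) {
      hlm(cond_maps[[sid]][cond_maps[[sid]]$condition == cc, ], roi)
    }, numeric(1))
    tibble::tibble(subject_id = sid,
                   hlm = hlm(maps[[sid]], roi),
                   hlm_c1 = ch[1], hlm_c2 = ch[2], hlm_c3 = ch[3],
                   hlm_c4 = ch[4])
  })
  lat <- dplyr::left_join(per_subj,
                          lv_wide(lateralization_volume(cohort$volumes)),
                          by = "subject_id")
  if (!is.null(cohort$behavior)) {
    beh <- summarize_behavior(cohort$behavior,
                              rt_correct_only = rt_correct_only)
    lat <- dplyr::left_join(lat,
                            beh[, c("subject_id", "ba_acc", "ba_rt")],
                            by = "subject_id")
  }
  list(laterality = lat, roi = roi, group_mi = group_mi, mi_maps = maps)
}
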