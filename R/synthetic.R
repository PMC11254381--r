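#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set describing a simulated covert spatial
#' attention experiment: a cohort of subjects with lateralized subcortical
#' volumes, sensor-level oscillatory epochs whose alpha-band (8-13 Hz)
#' lateralization is linearly coupled to the volume asymmetries, and
#' trial-level behavior.
#'
#' The defaults mirror the study design the package models: 33 subjects,
#' 2 x 256 trials split evenly over four target-load/distractor-salience
#' conditions (128 per condition), and per-structure lateralization volume
#' (LV) distributions matching the reported group statistics for thalamus,
#' caudate nucleus, putamen and nucleus accumbens. The default coupling
#' coefficients `c(Th = -2.19, CN = 0.92, GP = 0.51)` are the winning-model
#' estimates, and `hlm_noise_sd` is calibrated so the mean adjusted R^2 of the
#' three-regressor fit on cohorts of 33 subjects is about 0.38.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_trials_per_condition Trials per condition (must be even so cue
#'   sides balance exactly); 128 reproduces the 512-trial session.
#' @param sampling_rate Sampling rate in Hz. 250 Hz keeps simulation cheap
#'   while leaving the alpha band far below Nyquist.
#' @param epoch_window Numeric length-2, epoch start/end in seconds relative
#'   to target onset.
#' @param n_sensor_pairs Number of left/right mirror-symmetric sensor
#'   locations per hemisphere. Each location carries two planar channels.
#' @param n_roi_true Number of leading sensor pairs carrying the full
#'   modulation target; remaining pairs carry `offroi_fraction` of it,
#'   giving the spatial contrast that ROI selection needs.
#' @param offroi_fraction Fraction of the modulation target applied to
#'   non-hotspot pairs.
#' @param alpha_freq Alpha oscillation frequency in Hz.
#' @param base_alpha_amplitude Baseline alpha amplitude (arbitrary units).
#' @param modulation_depth Common attentional modulation magnitude `m`: the
#'   hemisphere-symmetric part of the per-sensor modulation index. Must
#'   satisfy `|m| + |HLM|/2 < 1` for all subjects.
#' @param noise_amplitude Standard deviation of the 1/f broadband noise
#'   added to every channel (same units as the alpha amplitude).
#' @param coupling_beta0 Intercept of the LV -> HLM(alpha) coupling.
#' @param coupling_betas Named numeric vector of per-structure coupling
#'   coefficients; names must be a subset of [subcortical_structures()].
#' @param hlm_noise_sd Standard deviation of the subject-level residual
#'   epsilon in the coupling model.
#' @param condition_sd Standard deviation of independent Gaussian
#'   perturbations turning the overall HLM target into four per-condition
#'   targets.
#' @param condition_betas Optional 7 x 4 matrix (rows named by structure)
#'   of condition-specific coupling coefficients. When supplied, each
#'   condition's HLM target uses its own column and the overall target is
#'   their mean; `condition_sd` is ignored.
#' @param volume_asym_params Data frame with columns `structure`,
#'   `lv_mean`, `lv_sd`, `total_voxels` for all seven structures.
#' @param behavior_params List with `base_accuracy`, `acc_side_bias`
#'   (right minus left accuracy difference), `rt_meanlog`, `rt_sdlog`,
#'   `rt_side_shift` (right minus left shift of the log-RT location).
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return A list of class `hemilat_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 4, n_trials_per_condition = 8,
#'                         n_sensor_pairs = 4)
#' cfg$coupling_betas
generator_config <- function(n_subjects = 33,
                             n_trials_per_condition = 128,
                             sampling_rate = 250,
                             epoch_window = c(-1.5, 0.5),
                             n_sensor_pairs = 10,
                             n_roi_true = 5,
                             offroi_fraction = 0.25,
                             alpha_freq = 10,
                             base_alpha_amplitude = 1,
                             modulation_depth = 0.1,
                             noise_amplitude = 0.5,
                             coupling_beta0 = 0,
                             coupling_betas = c(Th = -2.19, CN = 0.92, GP = 0.51),
                             hlm_noise_sd = 0.050,
                             condition_sd = 0.02,
                             condition_betas = NULL,
                             volume_asym_params = default_volume_params(),
                             behavior_params = list(base_accuracy = 0.8,
                                                    acc_side_bias = 0,
                                                    rt_meanlog = log(0.5),
                                                    rt_sdlog = 0.2,
                                                    rt_side_shift = 0),
                             seed = 1L) {
  structures <- subcortical_structures()
  stopifnot(is.numeric(epoch_window), length(epoch_window) == 2)
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (n_trials_per_condition < 1) {
    abort("`n_trials_per_condition` must be at least 1.")
  }
  if (n_trials_per_condition %% 2 != 0) {
    abort("`n_trials_per_condition` must be even so cue sides balance.")
  }
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (epoch_window[1] >= epoch_window[2]) {
    abort("`epoch_window` start must precede its end.")
  }
  if (abs(modulation_depth) >= 1) {
    abort("`modulation_depth` must satisfy |m| < 1.")
  }
  if (n_roi_true > n_sensor_pairs) {
    abort("`n_roi_true` cannot exceed `n_sensor_pairs`.")
  }
  vp <- tibble::as_tibble(volume_asym_params)
  needed <- c("structure", "lv_mean", "lv_sd", "total_voxels")
  if (!all(needed %in% names(vp)) || !setequal(vp$structure, structures)) {
    abort("`volume_asym_params` must cover all seven structures.")
  }
  if (any(vp$total_voxels <= 0)) abort("Volume scales must be positive.")
  if (!all(names(coupling_betas) %in% structures)) {
    abort("`coupling_betas` names must be subcortical structure labels.")
  }
  betas <- setNames(numeric(length(structures)), structures)
  betas[names(coupling_betas)] <- coupling_betas
  if (!is.null(condition_betas)) {
    condition_betas <- as.matrix(condition_betas)
    if (!identical(dim(condition_betas), c(7L, 4L)) ||
        !setequal(rownames(condition_betas), structures)) {
      abort("`condition_betas` must be a 7 x 4 matrix with structure rownames.")
    }
    condition_betas <- condition_betas[structures, , drop = FALSE]
  }
  bp <- behavior_params
  if (bp$base_accuracy <= 0 || bp$base_accuracy >= 1) {
    abort("`base_accuracy` must lie in (0, 1).")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_condition = as.integer(n_trials_per_condition),
         sampling_rate = sampling_rate,
         epoch_window = epoch_window,
         n_sensor_pairs = as.integer(n_sensor_pairs),
         n_roi_true = as.integer(n_roi_true),
         offroi_fraction = offroi_fraction,
         alpha_freq = alpha_freq,
         base_alpha_amplitude = base_alpha_amplitude,
         modulation_depth = modulation_depth,
         noise_amplitude = noise_amplitude,
         coupling_beta0 = coupling_beta0,
         coupling_betas = betas,
         hlm_noise_sd = hlm_noise_sd,
         condition_sd = condition_sd,
         condition_betas = condition_betas,
         volume_asym_params = vp[match(structures, vp$structure), ],
         behavior_params = bp,
         seed = as.integer(seed)),
    class = "hemilat_config"
  )
}

#' Default lateralization-volume distribution parameters
#'
#' Per-structure mean and standard deviation of the lateralization volume
#' index LV and a total-volume scale in voxels (1 mm^3 voxels, anatomically
#' plausible sizes). Thalamus, caudate nucleus, putamen and nucleus
#' accumbens use the reported group statistics; globus pallidus,
#' hippocampus and amygdala, for which no asymmetry was detected, default
#' to zero-mean LV with a comparable spread.
#'
#' @return A tibble with columns `structure`, `lv_mean`, `lv_sd`,
#'   `total_voxels`.
#' @export
default_volume_params <- function() {
  tibble::tibble(
    structure = subcortical_structures(),
    lv_mean = c(-0.0123, 0.0115, -0.0149, 0, 0, 0, -0.1141),
    lv_sd = c(0.0121, 0.0285, 0.0285, 0.03, 0.02, 0.03, 0.0746),
    total_voxels = c(15000, 7500, 10000, 3500, 7700, 3400, 1200)
  )
}

#' Simulate subcortical volume tables with known asymmetry
#'
#' Draws a lateralization volume index `LV ~ Normal(lv_mean, lv_sd)` for
#' every subject and structure, then splits the structure's total volume so
#' that `V_right = V_total (1 + LV) / 2` and `V_left = V_total (1 - LV) / 2`.
#' By construction, computing `(V_right - V_left) / (V_right + V_left)` on
#' the returned table recovers the drawn LV exactly.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list with `volumes` (long tibble: `subject_id`, `structure`,
#'   `hemisphere`, `voxels`) and `lv` (wide tibble: `subject_id` plus one
#'   column per structure holding the drawn LV).
#' @export
#' @examples
#' gv <- generate_volumes(generator_config(n_subjects = 2), seed = 1)
#' nrow(gv$volumes)  # 2 subjects x 7 structures x 2 hemispheres
generate_volumes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "hemilat_config"))
  vp <- config$volume_asym_params
  n <- config$n_subjects
  with_seed(seed, {
    lv_mat <- matrix(vapply(seq_len(nrow(vp)), function(i) {
      lv <- rnorm(n, vp$lv_mean[i], vp$lv_sd[i])
      bad <- abs(lv) >= 1
      while (any(bad)) {  # resample pathological draws; |LV| >= 1 is unphysical
        lv[bad] <- rnorm(sum(bad), vp$lv_mean[i], vp$lv_sd[i])
        bad <- abs(lv) >= 1
      }
      lv
    }, numeric(n)), nrow = n)
    colnames(lv_mat) <- vp$structure
    subject_id <- sprintf("S%03d", seq_len(n))
    lv <- tibble::as_tibble(lv_mat) |>
      dplyr::mutate(subject_id = subject_id, .before = 1)
    volumes <- tidyr::expand_grid(subject_id = subject_id,
                                  structure = vp$structure) |>
      dplyr::left_join(vp[, c("structure", "total_voxels")], by = "structure") |>
      dplyr::mutate(lv = as.vector(t(lv_mat))) |>
      tidyr::expand_grid(hemisphere = c("left", "right")) |>
      dplyr::mutate(
        voxels = ifelse(.data$hemisphere == "right",
                        .data$total_voxels * (1 + .data$lv) / 2,
                        .data$total_voxels * (1 - .data$lv) / 2)
      ) |>
      dplyr::select("subject_id", "structure", "hemisphere", "voxels")
    if (any(volumes$voxels <= 0)) abort("Generated a nonpositive volume.")
    list(volumes = volumes, lv = lv)
  })
}

#' Draw ground-truth HLM(alpha) targets from the coupling model
#'
#' Applies the generative coupling `HLM = beta0 + sum_s beta_s LV_s +
#' epsilon`, `epsilon ~ Normal(0, hlm_noise_sd)`, to a wide LV table, and
#' derives per-condition targets. In the default mode each condition target
#' is the overall target plus an independent `Normal(0, condition_sd)`
#' perturbation; when `config$condition_betas` is set, each condition has
#' its own coefficient vector and the overall target is the condition mean.
#'
#' @param lv Wide LV tibble as returned by [generate_volumes()].
#' @param config A [generator_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble with `subject_id`, `hlm`, `hlm_c1` ... `hlm_c4`;
#'   the coupling parameters are attached as attribute `"coupling"`.
#' @export
draw_hlm_targets <- function(lv, config, seed = NULL) {
  stopifnot(inherits(config, "hemilat_config"))
  structures <- subcortical_structures()
  lv_mat <- as.matrix(lv[, structures])
  n <- nrow(lv_mat)
  with_seed(seed, {
    if (is.null(config$condition_betas)) {
      hlm <- config$coupling_beta0 + drop(lv_mat %*% config$coupling_betas) +
        rnorm(n, 0, config$hlm_noise_sd)
      cond <- hlm + matrix(rnorm(4 * n, 0, config$condition_sd), n, 4)
    } else {
      cond <- config$coupling_beta0 + lv_mat %*% config$condition_betas +
        matrix(rnorm(4 * n, 0, config$hlm_noise_sd), n, 4)
      hlm <- rowMeans(cond)
    }
    out <- tibble::tibble(subject_id = lv$subject_id, hlm = hlm,
                          hlm_c1 = cond[, 1], hlm_c2 = cond[, 2],
                          hlm_c3 = cond[, 3], hlm_c4 = cond[, 4])
    attr(out, "coupling") <- list(beta0 = config$coupling_beta0,
                                  betas = config$coupling_betas,
                                  condition_betas = config$condition_betas,
                                  hlm_noise_sd = config$hlm_noise_sd)
    out
  })
}

# Hann taper, symmetric (zero at both endpoints).
hanning_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# Broadband noise with a 1/f power spectrum, unit standard deviation.
one_over_f_noise <- function(n_samples, n_series) {
  white <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  spec <- stats::mvfft(white)
  # amplitude ~ 1/sqrt(f) so power ~ 1/f; mirrored so the inverse is real
  k <- seq_len(n_samples) - 1
  freq <- pmin(k, n_samples - k)
  scale <- ifelse(freq == 0, 0, 1 / sqrt(freq))
  shaped <- Re(stats::mvfft(spec * scale, inverse = TRUE)) / n_samples
  sds <- apply(shaped, 2, sd)
  sweep(shaped, 2, ifelse(sds > 0, sds, 1), "/")
}

#' Synthesize sensor-level epochs for one subject
#'
#' Builds a `trials x channels x samples` array of amplitude-modulated
#' alpha oscillations plus 1/f broadband noise for a mirror-symmetric
#' planar-gradiometer array. Alpha amplitude depends on cue side,
#' hemisphere, condition and sensor so that the *expected* per-sensor
#' modulation index at hotspot locations equals `+m + HLM_c/2` on the right
#' and `-m + HLM_c/2` on the left for condition `c` (off-hotspot locations
#' carry `offroi_fraction` of those targets). Summed over the two ROI
#' hemisphere means this makes the expected HLM(alpha) equal the subject's
#' target. Attend-right and attend-left powers are set to `P0 (1 + MI)` and
#' `P0 (1 - MI)` so the implied power ratio is `(1 + MI) / (1 - MI)`.
#'
#' @param subject_truth One row of the tibble from [draw_hlm_targets()].
#' @param config A [generator_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An `epoch_set`: list with `data` (array trials x channels x
#'   samples), `trial_meta`, `sensor_meta`, `sampling_rate`, `time`.
#' @export
generate_epochs <- function(subject_truth, config, seed = NULL) {
  stopifnot(inherits(config, "hemilat_config"))
  m <- config$modulation_depth
  targets <- unlist(subject_truth[paste0("hlm_c", 1:4)])
  if (any(abs(targets) / 2 + abs(m) >= 1)) {
    abort("Condition HLM target too large: |HLM|/2 + |m| must be < 1.")
  }
  fs <- config$sampling_rate
  time <- seq(config$epoch_window[1], config$epoch_window[2], by = 1 / fs)
  n_samp <- length(time)
  n_pairs <- config$n_sensor_pairs
  n_cond_trials <- config$n_trials_per_condition
  n_trials <- 4L * n_cond_trials

  trial_meta <- tibble::tibble(
    trial = seq_len(n_trials),
    condition = rep(1:4, each = n_cond_trials),
    cue_side = rep(rep(c("left", "right"), each = n_cond_trials / 2), 4)
  )
  sensor_meta <- tidyr::expand_grid(
    hemisphere = c("left", "right"),
    pair_id = seq_len(n_pairs),
    planar_channel_index = 1:2
  ) |>
    dplyr::mutate(
      location = sprintf("%s%02d", ifelse(.data$hemisphere == "left", "L", "R"),
                         .data$pair_id),
      channel = sprintf("%s_%d", .data$location, .data$planar_channel_index)
    ) |>
    dplyr::select("channel", "location", "hemisphere", "pair_id",
                  "planar_channel_index")
  n_chan <- nrow(sensor_meta)

  # Per-location target MI by condition and hemisphere, with the hotspot /
  # off-hotspot spatial profile.
  spatial <- ifelse(sensor_meta$pair_id <= config$n_roi_true, 1,
                    config$offroi_fraction)
  hemi_sign <- ifelse(sensor_meta$hemisphere == "right", 1, -1)

  with_seed(seed, {
    data <- array(0, dim = c(n_trials, n_chan, n_samp))
    for (tr in seq_len(n_trials)) {
      h_c <- targets[trial_meta$condition[tr]]
      mi <- spatial * (hemi_sign * m + h_c / 2)
      if (any(abs(mi) >= 1)) abort("Implied power ratio is nonpositive.")
      cue_sign <- if (trial_meta$cue_side[tr] == "right") 1 else -1
      amp <- config$base_alpha_amplitude * sqrt(1 + cue_sign * mi) / sqrt(2)
      phase <- runif(n_chan, 0, 2 * pi)
      osc <- outer(amp, rep(1, n_samp)) *
        sin(2 * pi * config$alpha_freq * outer(rep(1, n_chan), time) + phase)
      if (config$noise_amplitude > 0) {
        osc <- osc + config$noise_amplitude *
          t(one_over_f_noise(n_samp, n_chan))
      }
      data[tr, , ] <- osc
    }
    structure(list(data = data, trial_meta = trial_meta,
                   sensor_meta = sensor_meta, sampling_rate = fs,
                   time = time),
              class = "epoch_set")
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate))
  cat(sprintf("  time %g..%g s; %d sensor locations (%d pairs)\n",
              min(x$time), max(x$time), nrow(x$sensor_meta) / 2,
              max(x$sensor_meta$pair_id)))
  invisible(x)
}

#' Simulate trial-level behavior for a cohort
#'
#' Draws per-trial correctness from a side-dependent Bernoulli probability
#' (`base_accuracy +/- acc_side_bias / 2`) and response times from a
#' log-normal whose location shifts by `+/- rt_side_shift / 2` with the
#' cued side. Trial structure (conditions, cue sides) matches the epoch
#' generator.
#'
#' @param truth Tibble from [draw_hlm_targets()] (one row per subject).
#' @param config A [generator_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble with `subject_id`, `trial`, `condition`, `cue_side`,
#'   `correct`, `rt`.
#' @export
generate_behavior <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "hemilat_config"))
  bp <- config$behavior_params
  p_right <- bp$base_accuracy + bp$acc_side_bias / 2
  p_left <- bp$base_accuracy - bp$acc_side_bias / 2
  if (p_right <= 0 || p_right >= 1 || p_left <= 0 || p_left >= 1) {
    abort("Side-specific accuracy probabilities must lie in (0, 1).")
  }
  n_cond_trials <- config$n_trials_per_condition
  base <- tibble::tibble(
    trial = seq_len(4L * n_cond_trials),
    condition = rep(1:4, each = n_cond_trials),
    cue_side = rep(rep(c("left", "right"), each = n_cond_trials / 2), 4)
  )
  with_seed(seed, {
    purrr::map_dfr(truth$subject_id, function(sid) {
      tab <- dplyr::mutate(base, subject_id = sid, .before = 1)
      p <- ifelse(tab$cue_side == "right", p_right, p_left)
      shift <- ifelse(tab$cue_side == "right", 1, -1) * bp$rt_side_shift / 2
      tab$correct <- rbinom(nrow(tab), 1, p)
      tab$rt <- rlnorm(nrow(tab), bp$rt_meanlog + shift, bp$rt_sdlog)
      tab
    })
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the volume, coupling, epoch and behavior generators under a single
#' seed, returning everything in memory and optionally writing it to disk
#' (`volumes.csv`, `behavior.csv`, `ground_truth.json`, and one epoch file
#' per subject under `epochs/`).
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; created if missing.
#' @param epochs If `FALSE`, skip the (comparatively expensive) epoch
#'   simulation; volume, coupling and behavior outputs are still produced.
#'   Useful for purely statistical simulations that consume HLM targets
#'   directly.
#' @return Invisibly (if `dir` is given) or visibly, a list with elements
#'   `volumes`, `lv`, `truth`, `epochs` (list of `epoch_set` or `NULL`),
#'   `behavior`, `config`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_trials_per_condition = 4,
#'                         n_sensor_pairs = 3, seed = 7)
#' cohort <- generate_cohort(cfg)
#' names(cohort)
generate_cohort <- function(config, dir = NULL, epochs = TRUE) {
  stopifnot(inherits(config, "hemilat_config"))
  cohort <- with_seed(config$seed, {
    gv <- generate_volumes(config, seed = NULL)
    truth <- draw_hlm_targets(gv$lv, config, seed = NULL)
    ep <- NULL
    if (epochs) {
      ep <- lapply(seq_len(nrow(truth)), function(i) {
        generate_epochs(truth[i, ], config, seed = NULL)
      })
      names(ep) <- truth$subject_id
    }
    behavior <- generate_behavior(truth, config, seed = NULL)
    list(volumes = gv$volumes, lv = gv$lv, truth = truth, epochs = ep,
         behavior = behavior, config = config)
  })
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    return(invisible(cohort))
  }
  cohort
}

#' Write a synthetic cohort to disk
#'
#' @param cohort List returned by [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume_table(cohort$volumes, file.path(dir, "volumes.csv"))
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  truth <- cohort$truth
  coupling <- attr(truth, "coupling")
  coupling$betas <- as.list(coupling$betas)
  gt <- list(
    coupling = coupling,
    seed = cohort$config$seed,
    lv = cohort$lv,
    targets = as.data.frame(truth)
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cohort$epochs)) {
    epdir <- file.path(dir, "epochs")
    if (!dir.exists(epdir)) dir.create(epdir)
    for (sid in names(cohort$epochs)) {
      saveRDS(cohort$epochs[[sid]], file.path(epdir, paste0(sid, ".rds")))
    }
  }
  invisible(dir)
}

#' Export an epoch set as a long-format delimited table
#'
#' Interoperability export: one row per (trial, channel, sample), columns
#' `trial`, `channel`, `time`, `value`. Large for realistic sizes; meant
#' for small excerpts and cross-language checks.
#'
#' @param epochs An `epoch_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_epochs_long <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  long <- tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(epochs$sensor_meta$channel, each = d[1]), times = d[3]),
    time = rep(epochs$time, each = d[1] * d[2]),
    value = as.vector(epochs$data)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
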