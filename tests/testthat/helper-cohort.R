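# Small generator configurations used across the suite. Epoch-level tests
# keep sensor counts and trial counts low; purely statistical tests skip
# epoch synthesis entirely (epochs = FALSE).

tiny_config <- function(...) {
  generator_config(n_subjects = 3, n_trials_per_condition = 8,
                   n_sensor_pairs = 4, n_roi_true = 2,
                   noise_amplitude = 0.2, seed = 42, ...)
}

# One-subject ground-truth row with equal condition targets.
flat_truth <- function(hlm = 0.02) {
  tibble::tibble(subject_id = "S001", hlm = hlm, hlm_c1 = hlm,
                 hlm_c2 = hlm, hlm_c3 = hlm, hlm_c4 = hlm)
}

# Direct single-window discrete Fourier oracle for the TFR: demean the
# segment, taper, zero-pad to the next power of two, take |FFT|^2 at the
# bin nearest f. Uses stats::fft(), independent of the kernel-based
# implementation under test.
oracle_window_power <- function(x, fs, f, center_idx, n_cycles = 3) {
  L <- max(2L, round(n_cycles / f * fs))
  half_lo <- (L - 1L) %/% 2L
  i0 <- center_idx - half_lo
  seg <- x[i0:(i0 + L - 1L)]
  seg <- seg - mean(seg)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  n_pad <- 2^ceiling(log2(L))
  bin <- round(f * n_pad / fs)
  sp <- stats::fft(c(seg * w, rep(0, n_pad - L)))[bin + 1]
  Mod(sp * 2 / sum(w))^2
}

# Null-coupling statistical cohort: LV draws plus HLM targets with all
# coupling coefficients zero; no epochs.
null_stat_cohort <- function(n = 33, seed = NULL, hlm_noise_sd = 0.050) {
  cfg <- generator_config(n_subjects = n, coupling_betas = c(Th = 0),
                          coupling_beta0 = 0, hlm_noise_sd = hlm_noise_sd)
  gv <- generate_volumes(cfg, seed = seed)
  targets <- draw_hlm_targets(gv$lv, cfg, seed = NULL)
  dplyr::left_join(targets, gv$lv, by = "subject_id")
}

# Coupled statistical cohort using the winning-model coefficients.
coupled_stat_cohort <- function(n = 33, seed = NULL, hlm_noise_sd = 0.050,
                                betas = c(Th = -2.19, CN = 0.92, GP = 0.51)) {
  cfg <- generator_config(n_subjects = n, coupling_betas = betas,
                          hlm_noise_sd = hlm_noise_sd)
  gv <- generate_volumes(cfg, seed = seed)
  targets <- draw_hlm_targets(gv$lv, cfg, seed = NULL)
  dplyr::left_join(targets, gv$lv, by = "subject_id")
}
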