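#' Sliding-window Hanning-taper time-frequency power
#'
#' Estimates power for each trial, channel, frequency and center time with
#' a fixed number of oscillation cycles per analysis window: at frequency
#' `f` the window spans `n_cycles / f` seconds (e.g. 300 ms at 10 Hz for 3
#' cycles). Each windowed segment is demeaned, multiplied by a Hanning
#' taper, zero-padded to the next power of two, Fourier transformed, and
#' the squared magnitude at the padded-FFT bin nearest `f` is recorded,
#' scaled by `2 / sum(taper)` so that power sits on an amplitude-squared
#' scale comparable across window lengths.
#' Center times advance on a `time_step` grid (snapped to the nearest
#' sample); a frequency's value is missing (`NA`) at centers where its full
#' window does not fit inside the epoch.
#'
#' @param epochs An `epoch_set` (see [generate_epochs()]).
#' @param freqs Frequencies of interest in Hz; default 2-30 Hz in 1 Hz
#'   steps.
#' @param n_cycles Cycles per analysis window.
#' @param time_step Spacing of output center times in seconds.
#' @return A `tfr_power` object: list with `power` (array trials x
#'   channels x frequencies x times), `freqs`, `times`, `sensor_meta`,
#'   `sampling_rate`, `combined` flag.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 1, n_trials_per_condition = 2,
#'                         n_sensor_pairs = 2, seed = 3)
#' co <- generate_cohort(cfg)
#' tfr <- compute_tfr(co$epochs[[1]], freqs = 8:13)
#' dim(tfr$power)
compute_tfr <- function(epochs, freqs = 2:30, n_cycles = 3,
                        time_step = 0.010) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_trials <- d[1]; n_chan <- d[2]; n_samp <- d[3]
  if (n_trials < 1) abort("Cannot compute a TFR from an empty trial set.")
  fs <- epochs$sampling_rate
  time <- epochs$time
  centers <- seq(time[1], time[n_samp], by = time_step)
  center_idx <- vapply(centers, function(tc) which.min(abs(time - tc)),
                       integer(1))
  n_t <- length(centers)
  n_f <- length(freqs)

  # flatten trials x channels into rows for one matrix product per window
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_samp)
  power <- array(NA_real_, dim = c(n_trials, n_chan, n_f, n_t))
  for (fi in seq_len(n_f)) {
    f <- freqs[fi]
    win_len <- max(2L, round(n_cycles / f * fs))
    if (win_len > n_samp) {
      warn(sprintf("Window for %g Hz (%d samples) never fits the epoch.",
                   f, win_len))
      next
    }
    taper <- hanning_taper(win_len)
    n_pad <- 2^ceiling(log2(win_len))
    bin <- round(f * n_pad / fs)
    theta <- 2 * pi * bin * (seq_len(win_len) - 1) / n_pad
    kc <- taper * cos(theta)
    ks <- -taper * sin(theta)
    # fold per-window demeaning into the kernels:
    # (x - mean(x)) . k == x . (k - mean-of-k-spread), see sum identity
    # and normalize by the taper mass so a unit sinusoid at the bin has
    # power ~1 regardless of window length
    K <- cbind(kc - sum(kc) / win_len, ks - sum(ks) / win_len) *
      (2 / sum(taper))
    half_lo <- (win_len - 1L) %/% 2L
    half_hi <- win_len - 1L - half_lo
    for (ti in seq_len(n_t)) {
      i0 <- center_idx[ti] - half_lo
      i1 <- center_idx[ti] + half_hi
      if (i0 < 1 || i1 > n_samp) next
      pr <- crossprod(X[i0:i1, , drop = FALSE], K)
      power[, , fi, ti] <- matrix(pr[, 1]^2 + pr[, 2]^2, n_trials, n_chan)
    }
  }
  structure(list(power = power, freqs = freqs, times = centers,
                 trial_meta = epochs$trial_meta,
                 sensor_meta = epochs$sensor_meta,
                 sampling_rate = fs, combined = FALSE),
            class = "tfr_power")
}

#' @export
print.tfr_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_power>%s %d trials x %d %s x %d freqs (%g-%g Hz) x %d times\n",
    if (x$combined) " [planar-combined]" else "", d[1], d[2],
    if (x$combined) "locations" else "channels", d[3], min(x$freqs),
    max(x$freqs), d[4]))
  invisible(x)
}

#' Combine planar-gradiometer channel pairs by summing power
#'
#' Sums the power of the two orthogonal planar channels at each sensor
#' location, halving the channel dimension. Location-level metadata
#' (hemisphere, mirror `pair_id`) is preserved.
#'
#' @param tfr A `tfr_power` from [compute_tfr()].
#' @return A `tfr_power` with one combined sensor per location.
#' @export
combine_planar <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_power"))
  if (tfr$combined) abort("Planar channels have already been combined.")
  sm <- tfr$sensor_meta
  locs <- unique(sm$location)
  counts <- table(sm$location)
  if (any(counts != 2)) {
    abort(sprintf("Location(s) without exactly two planar channels: %s",
                  paste(names(counts)[counts != 2], collapse = ", ")))
  }
  d <- dim(tfr$power)
  out <- array(NA_real_, dim = c(d[1], length(locs), d[3], d[4]))
  for (li in seq_along(locs)) {
    idx <- which(sm$location == locs[li])
    out[, li, , ] <- tfr$power[, idx[1], , ] + tfr$power[, idx[2], , ]
  }
  meta <- sm |>
    dplyr::distinct(.data$location, .data$hemisphere, .data$pair_id) |>
    dplyr::slice(match(locs, .data$location))
  structure(list(power = out, freqs = tfr$freqs, times = tfr$times,
                 trial_meta = tfr$trial_meta, sensor_meta = meta,
                 sampling_rate = tfr$sampling_rate, combined = TRUE),
            class = "tfr_power")
}

#' Average TFR power over a frequency band, time window and trial set
#'
#' Means the power over the selected trials, the grid frequencies inside
#' the closed `band`, and the center times inside the closed `window`,
#' yielding one scalar per sensor. Cells that are missing because a
#' frequency's window did not fit near the epoch edge are excluded from
#' the mean.
#'
#' @param tfr A `tfr_power` (raw or planar-combined).
#' @param band Closed frequency interval in Hz; default the 8-13 Hz alpha
#'   band.
#' @param window Closed time interval in seconds; default the -850-0 ms
#'   pre-target interval.
#' @param trials Optional integer or logical trial selector; default all.
#' @return A tibble with the sensor metadata plus a `power` column.
#' @export
band_window_average <- function(tfr, band = c(8, 13), window = c(-0.850, 0),
                                trials = NULL) {
  stopifnot(inherits(tfr, "tfr_power"))
  d <- dim(tfr$power)
  sel_tr <- if (is.null(trials)) seq_len(d[1]) else seq_len(d[1])[trials]
  if (length(sel_tr) == 0) abort("Trial selection is empty.")
  f_in <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (length(f_in) == 0) abort("Band does not intersect the frequency grid.")
  t_in <- which(tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9)
  if (length(t_in) == 0) abort("Window lies outside the TFR time axis.")
  sub <- tfr$power[sel_tr, , f_in, t_in, drop = FALSE]
  val <- apply(sub, 2, mean, na.rm = TRUE)
  if (any(!is.finite(val))) {
    abort("A sensor has no valid power values in the requested band/window.")
  }
  dplyr::mutate(tfr$sensor_meta, power = val)
}
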