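# Hand-built epoch set around a deterministic signal matrix:
# trials x channels x samples, with standard paired sensor metadata.
make_epochs <- function(signal, fs = 250, t0 = -1.5) {
  n_chan <- dim(signal)[2]
  stopifnot(n_chan %% 4 == 0)
  n_pairs <- n_chan / 4
  sm <- tidyr::expand_grid(hemisphere = c("left", "right"),
                           pair_id = seq_len(n_pairs),
                           planar_channel_index = 1:2) |>
    dplyr::mutate(
      location = sprintf("%s%02d",
                         ifelse(hemisphere == "left", "L", "R"), pair_id),
      channel = sprintf("%s_%d", location, planar_channel_index)) |>
    dplyr::select(channel, location, hemisphere, pair_id,
                  planar_channel_index)
  n_tr <- dim(signal)[1]
  tm <- tibble::tibble(trial = seq_len(n_tr),
                       condition = rep_len(1:4, n_tr),
                       cue_side = rep_len(c("left", "right"), n_tr))
  structure(list(data = signal, trial_meta = tm, sensor_meta = sm,
                 sampling_rate = fs,
                 time = t0 + (seq_len(dim(signal)[3]) - 1) / fs),
            class = "epoch_set")
}

test_that("per-window power matches a direct tapered Fourier oracle", {
  fs <- 250
  n_samp <- 501
  set.seed(31)
  sig <- array(rnorm(2 * 4 * n_samp), dim = c(2, 4, n_samp))
  ep <- make_epochs(sig, fs = fs)
  freqs <- c(3, 7, 10, 21)
  tfr <- compute_tfr(ep, freqs = freqs)
  # reconstruct the implementation's center grid, then spot-check cells
  centers <- seq(ep$time[1], ep$time[n_samp], by = 0.010)
  for (fi in seq_along(freqs)) {
    for (ti in c(100, 120, 140)) {  # interior centers where all windows fit
      ci <- which.min(abs(ep$time - centers[ti]))
      want <- oracle_window_power(sig[2, 3, ], fs, freqs[fi], ci)
      got <- tfr$power[2, 3, fi, ti]
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("a noiseless alpha sinusoid peaks at its own frequency", {
  fs <- 250
  t <- seq(-1.5, 0.5, by = 1 / fs)
  sig <- aperm(array(sin(2 * pi * 10 * t), dim = c(length(t), 1, 4)),
               c(2, 3, 1))
  ep <- make_epochs(sig, fs = fs)
  tfr <- compute_tfr(ep, freqs = 2:30)
  spectrum <- vapply(seq_along(tfr$freqs), function(fi) {
    mean(tfr$power[1, 1, fi, ], na.rm = TRUE)
  }, numeric(1))
  expect_equal(tfr$freqs[which.max(spectrum)], 10)
})

test_that("constant input has (numerically) zero power after demeaning", {
  sig <- array(3.7, dim = c(1, 4, 501))
  ep <- make_epochs(sig)
  tfr <- compute_tfr(ep, freqs = c(5, 10, 20))
  expect_lt(max(tfr$power, na.rm = TRUE), 1e-20)
})

test_that("power scales quadratically with signal amplitude", {
  set.seed(8)
  sig <- array(rnorm(2 * 4 * 501), dim = c(2, 4, 501))
  ep1 <- make_epochs(sig)
  ep3 <- make_epochs(3 * sig)
  t1 <- compute_tfr(ep1, freqs = c(6, 11))
  t3 <- compute_tfr(ep3, freqs = c(6, 11))
  expect_equal(t3$power, 9 * t1$power, tolerance = 1e-10)
})

test_that("windows that do not fit yield missing values, never numbers", {
  # 2 Hz with 3 cycles needs 1.5 s; near the epoch edges it cannot fit
  sig <- array(rnorm(1 * 4 * 501), dim = c(1, 4, 501))
  ep <- make_epochs(sig)
  tfr <- compute_tfr(ep, freqs = c(2, 10))
  p2 <- tfr$power[1, 1, 1, ]
  expect_true(any(is.na(p2)))
  expect_true(any(!is.na(p2)))
  # the short 10 Hz window fits everywhere well inside the epoch
  interior <- tfr$times > -1.2 & tfr$times < 0.2
  expect_true(all(!is.na(tfr$power[1, 1, 2, interior])))
  # an entirely too-long window is flagged as missing with a warning
  short <- make_epochs(array(rnorm(4 * 100), dim = c(1, 4, 100)))
  expect_warning(t_short <- compute_tfr(short, freqs = c(2, 20)), "never fits")
  expect_true(all(is.na(t_short$power[1, 1, 1, ])))
})

test_that("planar combination sums channel pairs and is order-invariant", {
  set.seed(12)
  sig <- array(rnorm(2 * 8 * 501), dim = c(2, 8, 501))
  ep <- make_epochs(sig)
  tfr <- compute_tfr(ep, freqs = c(10, 15))
  comb <- combine_planar(tfr)
  sm <- tfr$sensor_meta
  loc <- comb$sensor_meta$location[1]
  idx <- which(sm$location == loc)
  expect_equal(comb$power[, 1, , ],
               tfr$power[, idx[1], , ] + tfr$power[, idx[2], , ],
               tolerance = 1e-12)
  # swapping the two channels of every location changes nothing
  swap <- order(sm$location, -sm$planar_channel_index)
  ep2 <- ep
  ep2$data <- ep$data[, swap, , drop = FALSE]
  ep2$sensor_meta <- sm[swap, ]
  comb2 <- combine_planar(compute_tfr(ep2, freqs = c(10, 15)))
  expect_equal(comb2$power[, match(comb$sensor_meta$location,
                                   comb2$sensor_meta$location), , ],
               comb$power, tolerance = 1e-12)
  # a zero channel leaves the partner's power unchanged
  ep3 <- ep
  ep3$data[, which(sm$location == loc)[2], ] <- 0
  comb3 <- combine_planar(compute_tfr(ep3, freqs = c(10, 15)))
  expect_equal(comb3$power[, 1, , ], tfr$power[, idx[1], , ],
               tolerance = 1e-12)
  # ill-formed pairing is rejected
  ep_bad <- ep
  ep_bad$sensor_meta$location[1] <- "L99"
  expect_error(combine_planar(compute_tfr(ep_bad, freqs = 10)),
               "two planar")
})

test_that("band/window averaging selects closed intervals on both grids", {
  # hand-made combined TFR where power encodes the frequency value
  freqs <- 2:30
  times <- seq(-1.4, 0.4, by = 0.01)
  power <- array(rep(freqs, each = 2 * 3),
                 dim = c(2, 3, length(freqs), length(times)))
  sm <- tibble::tibble(location = c("L01", "L02", "R01"),
                       hemisphere = c("left", "left", "right"),
                       pair_id = c(1, 2, 1))
  tfr <- structure(list(power = power, freqs = freqs, times = times,
                        trial_meta = tibble::tibble(trial = 1:2),
                        sensor_meta = sm, sampling_rate = 250,
                        combined = TRUE),
                   class = "tfr_power")
  out <- band_window_average(tfr, band = c(8, 13), window = c(-0.85, 0))
  expect_equal(out$power, rep(mean(8:13), 3))  # exactly 6 bins, inclusive
  # constant power is returned unchanged
  tfr$power[] <- 4.2
  expect_equal(band_window_average(tfr)$power, rep(4.2, 3))
  expect_error(band_window_average(tfr, trials = integer(0)), "empty")
  expect_error(band_window_average(tfr, window = c(5, 6)), "outside")
  expect_error(band_window_average(tfr, band = c(40, 50)), "intersect")
})
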