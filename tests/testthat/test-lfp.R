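test_that("invalid LFP configurations are rejected", {
  expect_error(lfp_sim_config(stim_band_power_gain = -1),
               class = "sa_config_error")
  expect_error(lfp_sim_config(n_pulses = 0), class = "sa_config_error")
  expect_error(lfp_sim_config(erp_latency = 1000), class = "sa_config_error")
  expect_error(lfp_sim_config(duration = 100), class = "sa_config_error")
})

test_that("noiseless pulsed simulation plants one deflection per epoch", {
  cfg <- lfp_sim_config(fs = 1000, duration = 300,
                        light_mode = "pulsed_1hz_5ms", noise_amplitude = 0,
                        erp_amplitude = 50, erp_latency = 20, seed = 1)
  tr <- simulate_lfp_trace(cfg)
  fs <- tr$fs
  for (p in tr$light$pulse_onsets[c(1, 60, 120)]) {
    seg <- tr$signal[(round(p * fs) + 1):(round(p * fs) + fs)]
    expect_equal(max(abs(seg)), 50)
    expect_equal(which.max(abs(seg)), round(0.020 * fs) + 1)
  }
  # exactly one deflection: outside +/- 4 sigma of the peak the epoch is ~0
  seg <- tr$signal[(round(60 * fs) + 1):(round(60 * fs) + fs)]
  expect_true(all(abs(seg[(round(0.06 * fs)):fs]) < 1e-6))
})

test_that("a pure tone is localised to its frequency bin and power scales
           quadratically with amplitude", {
  fs <- 250
  x <- sin(2 * pi * 10 * (0:(30 * fs - 1)) / fs)
  sp1 <- morlet_spectrogram(lfp_trace(x, fs), time_step = 0.1)
  sp2 <- morlet_spectrogram(lfp_trace(2 * x, fs), time_step = 0.1)
  m1 <- apply(ifelse(sp1$valid, sp1$power, NA), 1, mean, na.rm = TRUE)
  expect_lte(abs(sp1$freqs[which.max(m1)] - 10), 0.1)
  m2 <- apply(ifelse(sp2$valid, sp2$power, NA), 1, mean, na.rm = TRUE)
  expect_equal(m2[which.max(m1)] / m1[which.max(m1)], 4, tolerance = 1e-6)
})

test_that("wavelet power per sample is duration invariant for an in-band tone", {
  fs <- 250
  pow_at <- function(dur) {
    x <- sin(2 * pi * 8 * (0:(dur * fs - 1)) / fs)
    sp <- morlet_spectrogram(lfp_trace(x, fs), freqs = 8, time_step = 0.1)
    mean(sp$power[1, sp$valid[1, ]])
  }
  expect_equal(pow_at(30), pow_at(60), tolerance = 0.02)
})

test_that("spectrogram masks edges and warns when the trace is too short", {
  fs <- 250
  x <- rnorm(5 * fs)
  expect_warning(sp <- morlet_spectrogram(lfp_trace(x, fs), time_step = 0.05),
                 "wavelet support")
  expect_false(any(sp$valid[sp$freqs < 3, ]))
  expect_true(any(sp$valid[sp$freqs == 15, ]))
})

test_that("spectrogram matches the naive convolution oracle", {
  set.seed(13)
  fs <- 250
  x <- rnorm(10 * fs)
  freqs <- c(4, 7, 10.5, 15)
  sp <- morlet_spectrogram(lfp_trace(x, fs), freqs = freqs, time_step = 0.05)
  for (j in seq_along(freqs)) {
    ok <- which(sp$valid[j, ])
    expect_gt(length(ok), 10)
    for (k in ok[seq(1, length(ok), by = 7)]) {
      t_idx <- round(sp$times[k] * fs) + 1
      oracle <- Mod(oracle_morlet_coef(x, fs, freqs[j], t_idx))^2
      expect_equal(sp$power[j, k], oracle, tolerance = 1e-6)
    }
  }
})

test_that("baseline normalisation zeroes the baseline and recovers ratios", {
  fs <- 250
  set.seed(21)
  # stationary noise: mean ratio near zero everywhere
  x <- rnorm(240 * fs)
  sp <- morlet_spectrogram(lfp_trace(x, fs), freqs = seq(5, 10, 0.5),
                           time_step = 0.1)
  nb <- normalize_to_baseline(sp, c(0, 60))
  r_base <- band_power_ratio(nb, band = c(5, 10), stim_window = c(0, 60))
  r_rest <- band_power_ratio(nb, band = c(5, 10), stim_window = c(60, 180))
  expect_equal(as.numeric(r_base), 0, tolerance = 1e-9)  # zeroed exactly
  expect_lt(abs(r_rest), 0.2)
  # doubled power in the stim window: ratio 1 exactly
  sp2 <- sp
  stim_cols <- sp$times >= 60 & sp$times < 180
  sp2$power[, stim_cols] <- 2 * sp2$power[, stim_cols]
  nb2 <- normalize_to_baseline(sp2, c(0, 60))
  expect_equal(as.numeric(band_power_ratio(nb2, band = c(5, 10),
                                           stim_window = c(60, 180))),
               2 * (as.numeric(r_rest) + 1) - 1, tolerance = 1e-9)
  # zero baseline power masks the row
  sp3 <- sp
  sp3$power[2, ] <- 0
  nb3 <- normalize_to_baseline(sp3, c(0, 60))
  expect_false(any(nb3$valid[2, ]))
})

test_that("band restriction separates an out-of-band from an in-band effect", {
  fs <- 250
  set.seed(31)
  n <- 240 * fs
  x <- rnorm(n)
  carrier <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  on <- (0:(n - 1)) / fs >= 60 & (0:(n - 1)) / fs < 180
  x <- x + 3 * carrier * on
  sp <- morlet_spectrogram(lfp_trace(x, fs),
                           freqs = c(seq(1, 2, 0.1), seq(9, 11, 0.1)),
                           time_step = 0.1)
  nb <- normalize_to_baseline(sp, c(0, 60))
  low <- band_power_ratio(nb, band = c(1, 2), stim_window = c(70, 170))
  full <- band_power_ratio(nb, band = c(9, 11), stim_window = c(70, 170))
  expect_lt(abs(low), 0.5)
  expect_gt(full, 5)
})

test_that("ERP peaks match a per-trial max-abs oracle and respect the window", {
  cfg <- lfp_sim_config(fs = 1000, duration = 300,
                        light_mode = "pulsed_1hz_5ms", noise_amplitude = 5,
                        noise_exponent = 0, erp_amplitude = 50,
                        erp_latency = 20, seed = 17)
  tr <- simulate_lfp_trace(cfg)
  e <- erp_peak_amplitude(tr)
  expect_equal(e$n_trials, 120L)
  expect_false(e$low_n)
  fs <- tr$fs
  nw <- round(0.05 * fs)
  for (k in c(1, 37, 120)) {
    p <- e$per_trial$pulse_onset[k]
    oi <- round(p * fs) + 1
    base <- mean(tr$signal[(oi - nw):(oi - 1)])
    expect_equal(e$per_trial$peak[k],
                 max(abs(tr$signal[oi:(oi + nw - 1)] - base)))
  }
  # deflection planted beyond the 50 ms window leaves only the noise floor
  late <- simulate_lfp_trace(lfp_sim_config(fs = 1000, duration = 300,
                                            light_mode = "pulsed_1hz_5ms",
                                            noise_amplitude = 5,
                                            noise_exponent = 0,
                                            erp_amplitude = 50,
                                            erp_latency = 60, seed = 17))
  e_late <- erp_peak_amplitude(late)
  expect_lt(e_late$mean_peak, 25)
})

test_that("decimation preserves the in-band content", {
  fs <- 2000
  x <- sin(2 * pi * 10 * (0:(30 * fs - 1)) / fs)
  tr <- decimate_lfp(lfp_trace(x, fs), 500)
  expect_equal(tr$fs, 500)
  expect_equal(length(tr$signal), 30 * 500)
  mid <- tr$signal[2000:13000]
  expect_equal(max(mid), 1, tolerance = 0.02)
  expect_gt(cor(mid, sin(2 * pi * 10 * (1999:12999) / 500)), 0.999)
})
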