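test_that("vm simulator constructs the planted light-evoked plateau", {
  cfg <- vm_sim_config(fs = 2000, cell_class = "non_spiking", noise_sd = 0,
                       evoked_depolarization = 8, light_mode = "constant",
                       evoked_rise_tau = 0.5, seed = 1)
  v <- simulate_vm_trace(cfg)
  fs <- v$fs
  # before onset: exactly resting
  expect_equal(v$vm[1:(60 * fs)], rep(-40, 60 * fs))
  # at plateau (rise tau 0.5 s, check 30 s in): resting + 8
  expect_equal(v$vm[(90 * fs):(120 * fs)],
               rep(-32, 30 * fs + 1), tolerance = 1e-6)
})

test_that("without light the windowed mean stays at rest within noise", {
  cfg <- vm_sim_config(fs = 2000, duration = 180, cell_class = "non_spiking",
                       noise_sd = 2, light_mode = "none", seed = 4)
  v <- simulate_vm_trace(cfg)
  n <- 60 * v$fs
  for (w in 0:2) {
    m <- mean(v$vm[(w * n + 1):((w + 1) * n)])
    expect_lt(abs(m - (-40)), 3 * 2 / sqrt(n))
  }
})

test_that("a too-short recording for the light epoch is a configuration error", {
  expect_error(vm_sim_config(duration = 100, light_onset = 60,
                             light_duration = 120),
               class = "sa_config_error")
})

test_that("spike detection recovers planted spikes and enforces refractoriness", {
  # flat trace: no spikes
  flat <- structure(list(fs = 10000, vm = rep(-40, 20000),
                         light = list(mode = "none")), class = "vm_trace")
  expect_equal(nrow(detect_spikes(flat)), 0L)
  # seven planted template spikes recovered at their times within 0.2 ms
  fs <- 10000
  vm <- rep(-40, 5 * fs) + rnorm(5 * fs, sd = 0.5)
  tmpl <- sleeparousal:::spike_template(fs)
  planted <- c(0.5, 1.1, 1.7, 2.4, 3.0, 3.9, 4.5)
  for (ts in planted) {
    i0 <- round(ts * fs) + 1
    idx <- i0 + seq_along(tmpl) - 1
    vm[idx] <- vm[idx] + tmpl
  }
  set.seed(7)
  tr <- structure(list(fs = fs, vm = vm, light = list(mode = "none")),
                  class = "vm_trace")
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 7L)
  peak_offset <- (which.max(tmpl) - 1) / fs
  expect_equal(sp$peak_time, planted + peak_offset, tolerance = 2e-4)
  # two planted peaks 1 ms apart merge under the 2 ms refractory
  vm2 <- rep(-40, fs)
  for (ts in c(0.5, 0.501)) {
    i0 <- round(ts * fs) + 1
    vm2[i0 + seq_along(tmpl) - 1] <- vm2[i0 + seq_along(tmpl) - 1] + tmpl
  }
  tr2 <- structure(list(fs = fs, vm = vm2, light = list(mode = "none")),
                   class = "vm_trace")
  expect_equal(nrow(detect_spikes(tr2)), 1L)
  # sub-kHz sampling cannot resolve spikes
  slow <- structure(list(fs = 500, vm = rep(-40, 1000),
                         light = list(mode = "none")), class = "vm_trace")
  expect_error(detect_spikes(slow), class = "sa_config_error")
})

test_that("burst grouping keys on failure to return to rest", {
  fs <- 10000
  tmpl <- sleeparousal:::spike_template(fs)
  # two spikes with the potential held 10 mV above rest between them: burst
  vm <- rep(-40, fs)
  vm[4000:4600] <- -30
  for (ts in c(0.405, 0.44)) {
    i0 <- round(ts * fs) + 1
    vm[i0 + seq_along(tmpl) - 1] <- vm[i0 + seq_along(tmpl) - 1] + tmpl
  }
  tr <- structure(list(fs = fs, vm = vm, light = list(mode = "none")),
                  class = "vm_trace")
  cl <- classify_cell(tr, resting = -40)
  expect_equal(cl$label, "burst")
  expect_equal(cl$n_burst, 1L)
  # same two spikes returning to rest in between: two singles
  vm2 <- rep(-40, fs)
  for (ts in c(0.405, 0.44)) {
    i0 <- round(ts * fs) + 1
    vm2[i0 + seq_along(tmpl) - 1] <- vm2[i0 + seq_along(tmpl) - 1] + tmpl
  }
  tr2 <- structure(list(fs = fs, vm = vm2, light = list(mode = "none")),
                   class = "vm_trace")
  cl2 <- classify_cell(tr2, resting = -40)
  expect_equal(cl2$label, "single")
  expect_equal(cl2$n_single, 2L)
})

test_that("classification covers non-spiking, mixtures and offset invariance", {
  # zero spikes across +10..+150 pA steps: non-spiking
  quiet <- structure(list(fs = 10000, vm = rep(-42, 30000),
                          light = list(mode = "none")), class = "vm_trace")
  steps <- data.frame(step_pA = seq(10, 150, by = 10), n_spikes = 0)
  expect_equal(classify_cell(quiet, step_protocol = steps)$label, "non_spiking")
  # no spikes and no step data: indeterminate, flagged
  cl <- classify_cell(quiet)
  expect_equal(cl$label, "indeterminate")
  expect_true(cl$indeterminate)
  # planted mixture recovered with evidence counts
  sim <- simulate_vm_trace(vm_sim_config(cell_class = "single_and_burst",
                                         light_mode = "none", duration = 120,
                                         noise_sd = 1, seed = 6))
  cl3 <- classify_cell(sim)
  expect_equal(cl3$label, "single_and_burst")
  expect_equal(cl3$n_single, length(sim$ground_truth$spike_times$single))
  expect_equal(cl3$n_burst, length(sim$ground_truth$volleys))
  # adding a constant offset changes nothing (criteria relative to rest)
  shifted <- sim
  shifted$vm <- sim$vm + 7
  cl4 <- classify_cell(shifted)
  expect_equal(cl4$label, cl3$label)
  expect_equal(cl4$n_burst, cl3$n_burst)
})

test_that("constant-light dVm windows equal brute-force slice means", {
  cfg <- vm_sim_config(fs = 2000, cell_class = "non_spiking", noise_sd = 1,
                       evoked_depolarization = 8, seed = 11)
  v <- simulate_vm_trace(cfg)
  s <- vm_response_constant(v)
  fs <- v$fs
  expect_equal(s$pre_mean, mean(v$vm[1:(60 * fs)]))
  expect_equal(s$stim_mean, mean(v$vm[(60 * fs + 1):(120 * fs)]))
  expect_equal(s$post_mean, mean(v$vm[(240 * fs + 1):(300 * fs)]))
  expect_equal(s$dvm_stim, s$stim_mean - s$pre_mean)
  # noiseless plateau: +8 during, ~0 after
  v0 <- simulate_vm_trace(vm_sim_config(fs = 2000, cell_class = "non_spiking",
                                        noise_sd = 0, evoked_depolarization = 8,
                                        evoked_rise_tau = 0.2, seed = 1))
  s0 <- vm_response_constant(v0)
  expect_equal(s0$dvm_stim, 8, tolerance = 0.03)
  expect_equal(s0$dvm_post, 0, tolerance = 0.01)
  # no light effect: dVm ~ 0
  vn <- simulate_vm_trace(vm_sim_config(fs = 2000, cell_class = "non_spiking",
                                        noise_sd = 1, evoked_depolarization = 0,
                                        seed = 3))
  expect_lt(abs(vm_response_constant(vn)$dvm_stim), 0.05)
})

test_that("the pulse composite averages epochs and reports the first 100 ms", {
  cfg <- vm_sim_config(fs = 2000, cell_class = "non_spiking", noise_sd = 0,
                       light_mode = "pulsed_1hz_5ms",
                       evoked_depolarization = 3, seed = 2)
  v <- simulate_vm_trace(cfg)
  comp <- composite_pulse_vm(v)
  expect_equal(comp$n_pulses, 120L)
  # identical noiseless responses: composite equals a single epoch
  fs <- v$fs
  i0 <- round(v$light$pulse_onsets[5] * fs) + 1
  expect_equal(comp$composite, v$vm[i0:(i0 + fs - 1)], tolerance = 1e-9)
  # bump normalisation: first-100-ms mean sits at rest + planted value
  expect_equal(comp$first100ms_mean, -40 + 3, tolerance = 1e-6)
  expect_equal(vm_response_pulsed(v)$dvm_stim, 3, tolerance = 1e-6)
  # fewer than two complete epochs is an error
  expect_error(composite_pulse_vm(v, pulse_onsets = 179.5),
               class = "sa_insufficient_data_error")
})

test_that("secondary spikes are counted in the 100-500 ms window only", {
  base <- vm_sim_config(fs = 10000, cell_class = "single",
                        light_mode = "pulsed_1hz_5ms", noise_sd = 0.5,
                        evoked_depolarization = 3, spont_single_rate = 0,
                        secondary_spike_prob = 1, seed = 9)
  v <- simulate_vm_trace(base)
  ss <- detect_secondary_spikes(v)
  expect_equal(ss$n_evoked, 120L)
  expect_equal(ss$reliability, 1.0)
  # planted probability zero: reliability zero
  none <- simulate_vm_trace(vm_sim_config(fs = 10000, cell_class = "single",
                                          light_mode = "pulsed_1hz_5ms",
                                          noise_sd = 0.5,
                                          evoked_depolarization = 3,
                                          spont_single_rate = 0,
                                          secondary_spike_prob = 0, seed = 9))
  expect_equal(detect_secondary_spikes(none)$reliability, 0.0)
  # spikes outside the window do not count: shift detection window instead
  shifted <- detect_secondary_spikes(v, window_ms = c(500, 900))
  expect_equal(shifted$reliability, 0.0)
})

test_that("burst ISI is the first-to-second peak interval", {
  expect_equal(burst_isi(c(1.0, 1.01875, 1.0375)), 18.75)
  expect_equal(burst_isi(c(2.0, 2.010)), 10)
  expect_true(is.na(burst_isi(3)))
  # random planted ISIs equal the first-difference oracle
  set.seed(5)
  for (k in 1:20) {
    t1 <- runif(1, 0, 10)
    isi <- runif(1, 5, 40) / 1000
    expect_equal(burst_isi(c(t1, t1 + isi)), isi * 1000)
  }
})

test_that("the simulator plants the stated intra-burst interval", {
  sim <- simulate_vm_trace(vm_sim_config(cell_class = "burst",
                                         light_mode = "none", duration = 60,
                                         noise_sd = 1, burst_isi = 18.75,
                                         spont_burst_rate = 0.15, seed = 4))
  sp <- detect_spikes(sim)
  rest <- estimate_resting_vm(sim, sp)
  grp <- group_bursts(sim, sp, rest)
  isis <- vapply(split(sp$peak_time, grp), function(v) burst_isi(sort(v)),
                 numeric(1))
  isis <- isis[!is.na(isis)]
  expect_gt(length(isis), 2)
  # 0.1 ms sampling resolution at 10 kHz
  expect_true(all(abs(isis - 18.75) <= 0.2))
})
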