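test_that("speed derivation matches the finite-difference definition", {
  # constant position -> all zero
  tr <- compute_speed(activity_trace(rep(10, 100)))
  expect_equal(tr$speed, rep(0, 100))
  # steady 2 mm per 1 s frame -> 2 mm/s after the first frame
  tr <- compute_speed(activity_trace(seq(0, by = 2, length.out = 30),
                                     tube_length = 100))
  expect_equal(tr$speed, c(0, rep(2, 29)))
  # random walk equals the elementwise |dx|/dt oracle
  set.seed(11)
  x <- pmin(abs(cumsum(rnorm(500))), 65)
  tr <- compute_speed(activity_trace(x))
  expect_equal(tr$speed, c(0, abs(diff(x)) * 1))
})

test_that("non-uniform time grids are rejected as a format error", {
  df <- data.frame(t_s = c(0, 1, 2, 4), x_mm = c(1, 2, 3, 4))
  expect_error(as_activity_trace(df), class = "sa_format_error")
})

test_that("sleep bouts are maximal immobility runs of >= 5 min", {
  # 60 min of zero speed -> one bout of 3600 s
  b <- detect_sleep_bouts(trace_from_speed(rep(0, 3600)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$end_s - b$start_s, 3600)
  # 4 min quiet / 1 moving frame / 4 min quiet -> no bout reaches 300 s
  b <- detect_sleep_bouts(trace_from_speed(c(rep(0, 240), 5, rep(0, 240))))
  expect_equal(nrow(b), 0L)
  # exactly 300 s counts (>= criterion)
  b <- detect_sleep_bouts(trace_from_speed(c(rep(5, 10), rep(0, 300), rep(5, 10))))
  expect_equal(nrow(b), 1L)
  expect_equal(b$end_s - b$start_s, 300)
})

test_that("bout detection equals the brute-force run scan on random activity", {
  for (seed in 1:10) {
    set.seed(seed)
    # correlated binary activity so runs straddle the 300 s criterion
    state <- numeric(7200)
    p <- 0.006
    state[1] <- rbinom(1, 1, 0.5)
    flips <- runif(7199) < p
    state[2:7200] <- (state[1] + cumsum(flips)) %% 2
    speed <- state * runif(7200, 0.6, 3)
    tr <- trace_from_speed(speed)
    expect_equal(
      detect_sleep_bouts(tr)[, c("start_s", "end_s")],
      oracle_bouts(compute_speed(tr)$speed, 1),
      ignore_attr = TRUE
    )
  }
})

test_that("hourly sleep splits bouts at hour boundaries and rescales exclusions", {
  # one 30-min bout inside hour 2
  bouts <- data.frame(fly_id = 1, start_s = 2 * 3600 + 600,
                      end_s = 2 * 3600 + 2400)
  s <- summarize_sleep(bouts, total_s = 6 * 3600)
  expect_equal(s$hourly$min_per_hr, c(0, 0, 30, 0, 0, 0))
  # 50-min bout starting at minute 40 of hour 0 -> 20 + 30 split
  bouts <- data.frame(fly_id = 1, start_s = 2400, end_s = 2400 + 3000)
  s <- summarize_sleep(bouts, total_s = 2 * 3600)
  expect_equal(s$hourly$min_per_hr, c(20, 30))
  # an hour fully excluded is missing, not zero
  s <- summarize_sleep(bouts, total_s = 2 * 3600,
                       exclusion_windows = data.frame(start_s = 3600,
                                                      end_s = 7200))
  expect_equal(s$hourly$min_per_hr[1], 20)
  expect_true(is.na(s$hourly$min_per_hr[2]))
  # exclusion removed from numerator and denominator, value rescaled
  bouts <- data.frame(fly_id = 1, start_s = 0, end_s = 1800)
  s <- summarize_sleep(bouts, total_s = 3600,
                       exclusion_windows = data.frame(start_s = 0, end_s = 900))
  expect_equal(s$hourly$min_per_hr, 60 * 900 / 2700)
})

test_that("hourly sleep equals a second-resolution interval oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n_bouts <- 12
    starts <- sort(runif(n_bouts, 0, 5.5 * 3600))
    ends <- starts + runif(n_bouts, 300, 1500)
    # enforce non-overlap and whole-second endpoints (the oracle grid)
    starts <- round(starts); ends <- round(pmin(ends, 6 * 3600))
    keep <- c(TRUE, starts[-1] >= head(ends, -1))
    bouts <- data.frame(fly_id = 1, start_s = starts[keep], end_s = ends[keep])
    excl <- data.frame(start_s = c(1800, 4 * 3600 + 900),
                       end_s = c(2700, 4 * 3600 + 1800))
    s <- summarize_sleep(bouts, total_s = 6 * 3600, exclusion_windows = excl)
    expect_equal(s$hourly$min_per_hr, oracle_hourly_sleep(bouts, excl, 6),
                 tolerance = 1e-9)
  }
})

test_that("stimulus-locked mean reduces to the aligned trace and the
           per-timepoint arithmetic mean", {
  sched <- data.frame(stim_id = 1:2, onset_s = c(600, 2400), light_on = FALSE)
  set.seed(3)
  sp1 <- c(0, runif(3599, 0, 2))
  tr1 <- trace_from_speed(sp1)
  # single fly, single trial: curve equals that fly's aligned speed
  cv <- stimulus_locked_mean(tr1, sched[1, ])
  sp_derived <- compute_speed(tr1)$speed
  expect_equal(cv$speed, sp_derived[(601 - 120):(601 + 900)])
  # two identical flies: the mean is idempotent
  tr2 <- tr1; tr2$fly_id <- 2L
  cv2 <- stimulus_locked_mean(list(tr1, tr2), sched[1, ])
  expect_equal(cv2$speed, cv$speed)
  expect_equal(attr(cv2, "n_trials"), 2L)
  # many flies: equals the direct per-timepoint mean oracle
  trs <- lapply(1:8, function(i) {
    set.seed(100 + i)
    trace_from_speed(c(0, runif(3599, 0, 2)), fly_id = i)
  })
  cv3 <- stimulus_locked_mean(trs, sched)
  oracle <- Reduce(`+`, lapply(trs, function(tr) {
    s <- compute_speed(tr)$speed
    s[(601 - 120):(601 + 900)] + s[(2401 - 120):(2401 + 900)]
  })) / (2 * length(trs))
  expect_equal(cv3$speed, oracle)
  # filtering away everything raises an empty-selection error
  expect_error(
    stimulus_locked_mean(tr1, sched, include = data.frame(fly_id = 99,
                                                          stim_id = 1)),
    class = "sa_empty_selection_error")
})

test_that("response-peak fit recovers planted kernels analytically", {
  # noiseless curve from the fitted family: <= 1% relative error on the peak
  truth <- kernel_peak(2, 2, 60)
  fit <- fit_response_peak(curve_from_kernel(B = 0.5, A = 2, rise = 2, decay = 60))
  expect_true(fit$converged)
  expect_lt(abs(fit$peak_mm_s - truth$peak) / truth$peak, 0.01)
  # doubling A doubles the peak (family is linear in A)
  fit2 <- fit_response_peak(curve_from_kernel(B = 0.5, A = 4, rise = 2, decay = 60))
  expect_equal(fit2$peak_mm_s / fit$peak_mm_s, 2, tolerance = 0.01)
  # flat curve at baseline -> zero peak
  fit0 <- fit_response_peak(curve_from_kernel(B = 0.7, A = 0, rise = 2, decay = 60))
  expect_equal(fit0$peak_mm_s, 0, tolerance = 1e-6)
})

test_that("responder calls implement the 3 mm / 1 min displacement rule", {
  onset <- 600
  # 0.1 mm per frame for 60 frames -> 6 mm, responder
  sp <- rep(0, 3600); sp[(onset + 2):(onset + 61)] <- 0.1
  call <- call_responder(trace_from_speed(sp), onset)
  expect_equal(call$displacement_mm, 6)
  expect_true(call$responder)
  expect_true(call$immobile_at_stim)
  # 2.9 mm total -> non-responder; threshold is a step function
  sp2 <- rep(0, 3600); sp2[(onset + 2):(onset + 30)] <- 0.1
  call2 <- call_responder(trace_from_speed(sp2), onset)
  expect_equal(call2$displacement_mm, 2.9, tolerance = 1e-9)
  expect_false(call2$responder)
  sp3 <- sp2; sp3[onset + 31] <- 0.1001
  expect_true(call_responder(trace_from_speed(sp3), onset)$responder)
  # truncated windows are excluded, not defaulted
  expect_null(call_responder(trace_from_speed(rep(0, 3600)), 30))
  expect_null(call_responder(trace_from_speed(rep(0, 3600)), 3580))
  # awake flag from movement in the prior minute
  sp4 <- rep(0, 3600); sp4[onset - 10] <- 2
  call4 <- call_responder(trace_from_speed(sp4), onset)
  expect_true(call4$moved_prior_min)
  expect_false(call4$immobile_at_stim)
})

test_that("sleep intensity is the exact responder fraction among immobile flies", {
  calls <- data.frame(immobile_at_stim = rep(TRUE, 10),
                      responder = c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(as.numeric(sleep_intensity(calls)), 0.4)
  # zero immobile flies: missing, not zero
  expect_true(is.na(sleep_intensity(calls[0, ])))
  # awake calls are a contract violation
  calls$immobile_at_stim[1] <- FALSE
  expect_error(sleep_intensity(calls), class = "sa_contract_error")
})

test_that("immobility bins are half-open 5-min intervals with an overflow bin", {
  calls <- data.frame(
    immobile_at_stim = TRUE,
    immobility_age_s = c(16 * 60, 5 * 60, 299, 31 * 60),
    responder = c(TRUE, FALSE, TRUE, FALSE))
  tab <- intensity_by_inactivity_bin(calls)
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$n[tab$bin_lo_min == 15], 1L)  # 16 min -> [15, 20)
  expect_equal(tab$n[tab$bin_lo_min == 5], 1L)   # exactly 5.0 min -> [5, 10)
  expect_equal(tab$n[tab$bin_lo_min == 0], 1L)   # 299 s -> [0, 5)
  expect_equal(tab$n[is.infinite(tab$bin_hi_min)], 1L)  # >= 30 min overflow
  expect_equal(tab$fraction[tab$bin_lo_min == 15], 1)
})

test_that("awake responsiveness composes the filter with the shared pipeline", {
  sched <- data.frame(stim_id = 1:2, onset_s = c(600, 2400), light_on = FALSE)
  # cohort in which every fly always moves: filter changes nothing
  trs <- lapply(1:4, function(i) {
    set.seed(200 + i)
    trace_from_speed(c(0, runif(3599, 0.6, 2)), fly_id = i)
  })
  awake <- awake_peak_responsiveness(trs, sched)
  unfiltered <- fit_response_peak(stimulus_locked_mean(trs, sched))
  expect_equal(awake$peak_mm_s, unfiltered$peak_mm_s)
  # all-immobile cohort: empty selection
  still <- lapply(1:3, function(i) trace_from_speed(rep(0, 3600), fly_id = i))
  expect_error(awake_peak_responsiveness(still, sched),
               class = "sa_empty_selection_error")
  # mixed cohort equals composing the operations manually
  mixed <- c(trs[1:2], still[1])
  calls <- call_responders(mixed, sched)
  inc <- calls[calls$moved_prior_min, c("fly_id", "stim_id")]
  manual <- fit_response_peak(stimulus_locked_mean(mixed, sched, include = inc))
  expect_equal(awake_peak_responsiveness(mixed, sched)$peak_mm_s,
               manual$peak_mm_s)
})
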