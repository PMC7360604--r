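# Pupil preprocessing: each operation against hand or brute-force oracles,
# then pipeline-level invariants.

test_that("average_eyes follows the single-eye fallback contract", {
  expect_equal(average_eyes(3.0, 5.0), 4.0)
  expect_equal(average_eyes(NA_real_, 4.2), 4.2)
  expect_true(is.na(average_eyes(NA_real_, NA_real_)))
  expect_equal(average_eyes(c(3, NA, NA), c(5, 4.2, NA)), c(4, 4.2, NA))
  expect_true(is.na(average_eyes(NA_real_, 4.2, strict = TRUE)))
  expect_error(average_eyes(1:3, 1:2), "length mismatch")
})

test_that("FIR smoother has unit DC gain, zero phase, and the designed stopband", {
  h <- fir_lowpass_coefs(30, 6, 31)
  expect_equal(sum(h), 1)
  expect_equal(h, rev(h))                       # symmetric -> linear phase
  # constant series passes unchanged, including segment edges
  expect_equal(smooth_fir(rep(4, 50), 30), rep(4, 50))
  # 10 Hz sinusoid at fs = 30 Hz: attenuation bounded by |H(10)| (oracle:
  # evaluate the designed filter's frequency response directly)
  f <- 10
  n <- 0:299
  x <- sin(2 * pi * f * n / 30)
  y <- smooth_fir(x, 30)
  gain <- abs(sum(h * exp(-2i * pi * (f / 30) * seq_along(h))))
  core <- 31:270                                # avoid renormalised edges
  expect_lte(max(abs(y[core])), gain * 1.0 + 1e-6)
  expect_lt(max(abs(y[core])), 0.1)             # well into the stopband
  # missing samples stay missing; valid neighbours unaffected by NA runs
  x2 <- c(rep(4, 20), NA, NA, rep(4, 20))
  y2 <- smooth_fir(x2, 30)
  expect_true(all(is.na(y2[21:22])))
  expect_equal(y2[-(21:22)], rep(4, 40))
  expect_error(smooth_fir(1:10, 10, cutoff_hz = 6), "Nyquist")
})

test_that("segment_trials yields picture windows of 150 samples at 30 Hz", {
  dt <- 1000 / 30
  t_ms <- (0:400) * dt
  x <- rep(4, length(t_ms))
  events <- data.frame(trial = 1:2, condition = c("view_neutral", "reappraisal"),
                       pic_ms = c(30 * dt, 340 * dt))
  traces <- segment_trials(t_ms, x, events)
  expect_length(traces, nrow(events))           # conservation
  tr <- traces[[1]]
  expect_equal(tr$status, "valid")
  expect_equal(sum(tr$t_rel_ms >= 0 & tr$t_rel_ms < 5000), 150)
  expect_equal(sum(tr$t_rel_ms >= -300 & tr$t_rel_ms < 0), 9)
  # second trial's window runs past the recording end -> too_short
  expect_equal(traces[[2]]$status, "discarded")
  expect_equal(traces[[2]]$discard_reason, "too_short")
})

test_that("range filter discards infeasible trials with inclusive bounds", {
  tr <- stressreg:::new_trial_trace(1, "view_neutral", (0:9) * 33, rep(4, 10))
  expect_equal(apply_range_filter(tr)$status, "valid")
  tr95 <- tr; tr95$diameter_mm[5] <- 9.5
  out <- apply_range_filter(tr95)
  expect_equal(out$status, "discarded")
  expect_equal(out$discard_reason, "out_of_range")
  tr15 <- tr; tr15$diameter_mm[5] <- 1.5        # boundary value is kept
  expect_equal(apply_range_filter(tr15)$status, "valid")
  tr90 <- tr; tr90$diameter_mm[5] <- 9.0
  expect_equal(apply_range_filter(tr90)$status, "valid")
})

test_that("dilation-speed filter matches the brute-force oracle on the toy trace", {
  t <- toy_trace_times()
  x <- toy_trace_values()
  d_oracle <- brute_speeds(t, x)
  expect_equal(stressreg:::dilation_speed(t, x), d_oracle)
  thr <- brute_mad_threshold(d_oracle, 16)
  tr <- stressreg:::new_trial_trace(1, "view_neutral", t, x)
  out <- flag_dilation_speed_outliers(tr, k = 16)
  expect_equal(which(is.na(out$diameter_mm)), which(d_oracle > thr))
  expect_true(6 %in% which(is.na(out$diameter_mm)))       # the 3 mm spike goes
  # constant trace: all speeds zero, MAD zero -> nothing flagged
  trc <- stressreg:::new_trial_trace(1, "view_neutral", t, rep(4, 10))
  expect_equal(flag_dilation_speed_outliers(trc, k = 16)$diameter_mm, rep(4, 10))
  # monotonicity: never fewer missing samples afterwards
  for (seed in 1:5) {
    xs <- stressreg:::with_seed(seed, {
      v <- 4 + cumsum(rnorm(30, 0, 0.05)); v[sample(30, 3)] <- NA; v
    })
    trs <- stressreg:::new_trial_trace(1, "view_neutral", (0:29) * 1000 / 30, xs)
    outs <- flag_dilation_speed_outliers(trs, k = 6)
    expect_gte(sum(is.na(outs$diameter_mm)), sum(is.na(xs)))
  }
  expect_error(flag_dilation_speed_outliers(tr, k = 5), "\\[6, 30\\]")
  expect_error(flag_dilation_speed_outliers(tr, k = 31), "\\[6, 30\\]")
})

test_that("gap handling: 100 ms gaps interpolate, longer gaps discard", {
  t <- (0:29) * 1000 / 30
  x <- 2 + 0.05 * (0:29)
  # 3 consecutive missing samples = 100 ms at 30 Hz -> kept and interpolated
  x3 <- x; x3[10:12] <- NA
  tr <- stressreg:::new_trial_trace(1, "view_neutral", t, x3)
  out <- handle_gaps(tr, max_gap_ms = 100, sampling_rate = 30)
  expect_equal(out$status, "valid")
  expect_equal(out$diameter_mm, x, tolerance = 1e-12)     # linear signal: exact
  # 4 consecutive missing (~133 ms) -> discarded
  x4 <- x; x4[10:13] <- NA
  out4 <- handle_gaps(stressreg:::new_trial_trace(1, "v", t, x4), 100, 30)
  expect_equal(out4$discard_reason, "long_gap")
  # single missing between 2.0 and 4.0 -> 3.0
  xg <- c(2, NA, 4)
  outg <- handle_gaps(stressreg:::new_trial_trace(1, "v", (0:2) * 1000 / 30, xg), 100, 30)
  expect_equal(outg$diameter_mm[2], 3.0)
  # leading gap cannot be interpolated
  xl <- x; xl[1] <- NA
  outl <- handle_gaps(stressreg:::new_trial_trace(1, "v", t, xl), 100, 30)
  expect_equal(outl$discard_reason, "long_gap")
})

test_that("baseline correction zeroes the pre-onset window and is idempotent", {
  dt <- 1000 / 30
  t <- seq(-300, 5000, by = dt)
  x <- ifelse(t < 0, 4.0, 4.0 + 0.5)
  tr <- stressreg:::new_trial_trace(1, "view_negative", t, x)
  out <- baseline_correct(tr)
  expect_true(out$corrected)
  expect_equal(out$baseline_value, 4.0)
  expect_equal(mean(out$diameter_mm[t >= -300 & t < 0]), 0)
  expect_equal(unique(out$diameter_mm[t >= 0]), 0.5)
  twice <- baseline_correct(out)
  expect_equal(twice$diameter_mm, out$diameter_mm)
  expect_equal(twice$baseline_value, 4.0)
  # (4.5, 5.0) with baseline mean 4.0 -> (0.5, 1.0)
  t2 <- c(seq(-300, -dt, by = dt), 0, dt)
  x2 <- c(rep(4, 9), 4.5, 5.0)
  out2 <- baseline_correct(stressreg:::new_trial_trace(1, "v", t2, x2))
  expect_equal(out2$diameter_mm[10:11], c(0.5, 1.0))
})

test_that("AUCg matches closed forms and the brute-force trapezoid", {
  dt <- 1000 / 30
  t <- seq(-300, 5000, by = dt)
  mk <- function(vals) {
    tr <- stressreg:::new_trial_trace(1, "v", t, vals)
    tr$corrected <- TRUE
    tr
  }
  expect_equal(compute_aucg(mk(rep(1, length(t)))), 3.0)  # 1 mm x 3 s
  expect_equal(compute_aucg(mk(rep(0, length(t)))), 0.0)
  # linear ramp 0 -> 1 across the window: closed form 1.5 mm*s
  ramp <- pmin(pmax((t - 2000) / 3000, 0), 1)
  expect_equal(compute_aucg(mk(ramp)), 1.5)
  # negative dilation subtracts (signed integral)
  expect_equal(compute_aucg(mk(rep(-0.5, length(t)))), -1.5)
  # arbitrary polyline equals an independently coded trapezoid
  set.seed(4)
  vals <- cumsum(rnorm(length(t), 0, 0.05))
  expect_equal(compute_aucg(mk(vals)), brute_trapezoid(t, vals, 2000, 5000),
               tolerance = 1e-12)
  # off-grid window edges are interpolated so the span is exactly 3 s
  t_off <- seq(-300, 5100, by = dt) + 7.3
  tro <- stressreg:::new_trial_trace(1, "v", t_off, rep(1, length(t_off)))
  tro$corrected <- TRUE
  expect_equal(compute_aucg(tro), 3.0)
  uncorrected <- stressreg:::new_trial_trace(1, "v", t, rep(1, length(t)))
  expect_error(compute_aucg(uncorrected), "corrected")
})

test_that("aggregate_condition applies the min_valid threshold", {
  trials <- data.frame(
    condition = rep("reappraisal", 10),
    status = c(rep("valid", 4), rep("discarded", 6)),
    aucg = c(1, 3, 2, 2, rep(NA, 6))
  )
  out <- aggregate_condition(trials, min_valid = 5)
  row <- out[out$condition == "reappraisal", ]
  expect_equal(row$n_valid, 4L)
  expect_true(is.na(row$mean_aucg))             # below threshold -> missing
  trials$status <- "valid"
  trials$aucg <- rep(2, 10)
  out2 <- aggregate_condition(trials, min_valid = 5)
  row2 <- out2[out2$condition == "reappraisal", ]
  expect_equal(row2$mean_aucg, 2.0)
  expect_equal(row2$n_valid, 10L)
  expect_equal(aggregate_condition(
    data.frame(condition = c("intensify", "intensify"),
               status = "valid", aucg = c(1, 3)),
    min_valid = 2)$mean_aucg[3], 2.0)
})

test_that("ln transform shifts only when needed and reports the shift", {
  pos <- ln_shift_transform(c(1, 2, 4))
  expect_equal(pos$shift, 0)
  expect_equal(pos$values, log(c(1, 2, 4)))
  mixed <- ln_shift_transform(c(-0.5, 1, 2))
  expect_equal(mixed$shift, 1.5)
  expect_equal(mixed$values, log(c(-0.5, 1, 2) + 1.5))
})

test_that("pipeline on artifact-free traces discards nothing and matches the generating curve", {
  cfg <- study_config(n_per_cell = 2, seed = 5,
                      artifact_params = no_artifact_params())
  st <- simulate_study(cfg)
  pp <- preprocess_pupil(st$pupil$samples, st$pupil$events, pupil_params())
  expect_equal(sum(pp$trials$status != "valid"), 0)
  # per-condition mean AUCg ~ closed-form integral of the generating curve
  dt <- 1000 / 30
  base_t <- seq(-300, -dt, by = dt)
  for (pid in st$roster$id[1:3]) {
    tt <- st$truth$participants[[match(pid, st$roster$id)]]$trial_truth
    got <- pp$trials[pp$trials$participant == pid, ]
    expected <- vapply(seq_len(nrow(tt)), function(i) {
      f <- function(t) pupil_trial_curve(t, tt$tonic[i], tt$arousal_amp[i],
                                         tt$effort_amp[i])
      stats::integrate(function(t) f(t) - mean(f(base_t)), 2000, 5000)$value / 1000
    }, 0)
    expect_equal(mean(got$aucg), mean(expected), tolerance = 0.03)
    expect_lt(max(abs(got$aucg - expected)), 0.3)
  }
})

test_that("adding artifacts never increases the number of valid trials", {
  clean <- simulate_study(study_config(n_per_cell = 2, seed = 31,
                                       artifact_params = no_artifact_params()))
  dirty <- simulate_study(study_config(n_per_cell = 2, seed = 31))
  # identical clean signal stream: only artifact injection differs
  par <- pupil_params()
  n_valid <- function(st) {
    pp <- preprocess_pupil(st$pupil$samples, st$pupil$events, par)
    sum(pp$trials$status == "valid")
  }
  expect_lte(n_valid(dirty), n_valid(clean))
})

test_that("every trial ends as exactly one of valid or discarded-with-reason", {
  st <- simulate_study(tiny_config(seed = 13))
  pp <- preprocess_pupil(st$pupil$samples, st$pupil$events, pupil_params())
  expect_equal(nrow(pp$trials), nrow(st$pupil$events))    # conservation
  valid <- pp$trials$status == "valid"
  expect_true(all(pp$trials$discard_reason[valid] == "none"))
  expect_true(all(pp$trials$discard_reason[!valid] %in%
                    c("out_of_range", "long_gap", "too_short")))
  expect_true(all(!is.na(pp$trials$aucg[valid])))
  expect_true(all(is.na(pp$trials$aucg[!valid])))
})

test_that("per-participant speed thresholding is available and comparable", {
  st <- simulate_study(tiny_config(seed = 17))
  pp_trial <- preprocess_pupil(st$pupil$samples, st$pupil$events,
                               pupil_params(speed_scope = "trial"))
  pp_part <- preprocess_pupil(st$pupil$samples, st$pupil$events,
                              pupil_params(speed_scope = "participant"))
  expect_equal(nrow(pp_part$trials), nrow(pp_trial$trials))
  expect_true(sum(pp_part$trials$status == "valid") > 0)
})
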