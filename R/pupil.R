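# Pupillometry preprocessing: binocular averaging, FIR smoothing, event-locked
# segmentation, artifact filters, baseline correction and AUCg.
#
# Pipeline order (see methods vignette): average eyes -> smooth -> segment ->
# range filter -> dilation-speed filter -> gap handling -> baseline
# correction -> AUCg -> per-condition aggregation.

#' Preprocessing parameters for the pupil pipeline
#'
#' @param sampling_rate nominal sampling rate, Hz.
#' @param cutoff_hz FIR low-pass cutoff (default 6 Hz).
#' @param fir_taps odd FIR tap count (default 31).
#' @param range_lo,range_hi feasible pupil diameter bounds in mm (inclusive;
#'   default 1.5–9).
#' @param mad_k dilation-speed threshold multiplier, in raw median absolute
#'   deviations; must lie in \[6, 30\] (default 16, the midpoint).
#' @param max_gap_ms longest interpolatable gap; gaps strictly longer discard
#'   the trial (default 100 ms).
#' @param baseline_ms pre-picture baseline window length (default 300 ms).
#' @param aucg_window AUCg integration window in ms after picture onset
#'   (default 2000–5000).
#' @param min_valid minimum valid trials per condition for a participant cell
#'   to enter the analysis (default 5 of 10).
#' @param strict_eyes if `TRUE`, a sample is missing unless both eyes are
#'   present; default uses the single available eye.
#' @param speed_scope `"trial"` (threshold per trace) or `"participant"`
#'   (one pooled threshold across a participant's trials).
#' @return A validated parameter list.
#' @export
pupil_params <- function(sampling_rate = 30, cutoff_hz = 6, fir_taps = 31,
                         range_lo = 1.5, range_hi = 9, mad_k = 16,
                         max_gap_ms = 100, baseline_ms = 300,
                         aucg_window = c(2000, 5000), min_valid = 5,
                         strict_eyes = FALSE,
                         speed_scope = c("trial", "participant")) {
  if (mad_k < 6 || mad_k > 30) {
    stopf("configuration error: 'mad_k' must lie in [6, 30], got %s", mad_k)
  }
  if (cutoff_hz >= sampling_rate / 2) {
    stopf("configuration error: 'cutoff_hz' must be below the Nyquist rate %s Hz",
          sampling_rate / 2)
  }
  list(sampling_rate = sampling_rate, cutoff_hz = cutoff_hz,
       fir_taps = as.integer(fir_taps), range_lo = range_lo,
       range_hi = range_hi, mad_k = mad_k, max_gap_ms = max_gap_ms,
       baseline_ms = baseline_ms, aucg_window = aucg_window,
       min_valid = min_valid, strict_eyes = strict_eyes,
       speed_scope = match.arg(speed_scope))
}

#' Average the two eyes into a monocular series
#'
#' Elementwise mean where both eyes are present; by default falls back to the
#' single available eye when one is missing (set `strict = TRUE` to require
#' both); missing where both are missing.
#'
#' @param left,right numeric vectors (mm) of equal length, `NA` = missing.
#' @param strict require both eyes per sample.
#' @return Monocular diameter series.
#' @export
average_eyes <- function(left, right, strict = FALSE) {
  if (length(left) != length(right)) {
    stopf("average_eyes: length mismatch (%d vs %d)", length(left), length(right))
  }
  if (strict) {
    return((left + right) / 2)
  }
  out <- (left + right) / 2
  only_l <- !is.na(left) & is.na(right)
  only_r <- is.na(left) & !is.na(right)
  out[only_l] <- left[only_l]
  out[only_r] <- right[only_r]
  out
}

#' Linear-phase FIR low-pass coefficients
#'
#' Windowed-sinc (Hamming) design with unit DC gain; exported so the filter's
#' frequency response can be evaluated independently.
#'
#' @inheritParams pupil_params
#' @param taps odd number of taps.
#' @return Numeric vector of `taps` coefficients summing to 1.
#' @export
fir_lowpass_coefs <- function(sampling_rate, cutoff_hz = 6, taps = 31) {
  if (cutoff_hz >= sampling_rate / 2) {
    stopf("FIR design error: cutoff %s Hz is at or above Nyquist (%s Hz)",
          cutoff_hz, sampling_rate / 2)
  }
  if (taps %% 2 == 0) stopf("FIR design error: 'taps' must be odd")
  m <- (taps - 1) / 2
  n <- seq(-m, m)
  fc <- cutoff_hz / sampling_rate            # normalised cutoff (cycles/sample)
  h <- 2 * fc * ifelse(n == 0, 1, sin(2 * pi * fc * n) / (2 * pi * fc * n))
  w <- 0.54 + 0.46 * cos(pi * n / m)         # Hamming window
  h <- h * w
  h / sum(h)
}

# Split indices into maximal runs that are non-missing and time-contiguous
# (time step <= 1.5 x nominal period), so smoothing never bridges blink gaps
# or inter-trial jumps.
contiguous_segments <- function(x, t_ms, sampling_rate) {
  ok <- !is.na(x)
  if (!any(ok)) return(list())
  dt_max <- 1.5 * sample_period_ms(sampling_rate)
  brk <- c(FALSE, diff(t_ms) > dt_max)
  grp <- cumsum(!ok | brk)
  idx <- which(ok)
  split(idx, grp[idx])
}

#' Zero-phase FIR smoothing of a pupil series
#'
#' Applies the [fir_lowpass_coefs()] kernel symmetrically about each sample
#' (zero phase shift, unit DC gain) within each contiguous valid segment;
#' kernel weights falling outside a segment are dropped and the remainder
#' renormalised, so edges keep unit DC gain. Missing samples stay missing.
#'
#' @param x diameter series (mm), `NA` = missing.
#' @param sampling_rate Hz; must exceed twice the cutoff.
#' @param cutoff_hz low-pass cutoff (default 6 Hz).
#' @param taps odd tap count (default 31).
#' @param t_ms optional sample times used to avoid smoothing across
#'   time-discontiguous spans; defaults to a uniform grid.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_fir <- function(x, sampling_rate, cutoff_hz = 6, taps = 31, t_ms = NULL) {
  h <- fir_lowpass_coefs(sampling_rate, cutoff_hz, taps)
  m <- (taps - 1) / 2
  if (is.null(t_ms)) t_ms <- seq_along(x) * sample_period_ms(sampling_rate)
  out <- rep(NA_real_, length(x))
  for (seg in contiguous_segments(x, t_ms, sampling_rate)) {
    xs <- x[seg]
    ns <- length(xs)
    xp <- c(rep(NA_real_, m), xs, rep(NA_real_, m))
    core <- vapply(seq_len(ns), function(i) {
      win <- xp[i:(i + 2 * m)]
      keep <- !is.na(win)
      sum(win[keep] * h[keep]) / sum(h[keep])
    }, 0)
    out[seg] <- core
  }
  out
}

new_trial_trace <- function(trial, condition, t_rel_ms, diameter_mm,
                            status = "valid", reason = "none") {
  structure(list(trial = trial, condition = condition, t_rel_ms = t_rel_ms,
                 diameter_mm = diameter_mm, status = status,
                 discard_reason = reason, baseline_value = NA_real_,
                 corrected = FALSE),
            class = "trial_trace")
}

discard_trace <- function(trace, reason) {
  trace$status <- "discarded"
  trace$discard_reason <- reason
  trace
}

#' @export
print.trial_trace <- function(x, ...) {
  cat(sprintf("<trial_trace> trial %s (%s): %d samples, %s%s%s\n",
              x$trial, x$condition, length(x$t_rel_ms), x$status,
              if (x$status == "discarded") paste0(" [", x$discard_reason, "]") else "",
              if (x$corrected) sprintf(", corrected (baseline %.3f mm)",
                                       x$baseline_value) else ""))
  invisible(x)
}

#' Cut a continuous recording into event-locked trial traces
#'
#' One trace per event row, spanning the baseline window before picture onset
#' through picture offset (`picture_ms` after onset, inclusive). Trials whose
#' window is not fully covered by the recording are kept but discarded with
#' reason `too_short`.
#'
#' @param t_ms,diameter_mm continuous sample times (strictly increasing) and
#'   monocular diameters.
#' @param events data frame with columns `trial`, `condition`, `pic_ms`.
#' @param baseline_ms,picture_ms window extents (defaults 300 / 5000 ms).
#' @return List of `trial_trace` objects, one per event row.
#' @export
segment_trials <- function(t_ms, diameter_mm, events,
                           baseline_ms = 300, picture_ms = 5000) {
  if (is.null(events) || nrow(events) == 0) stopf("segment_trials: no events")
  if (any(diff(t_ms) <= 0)) stopf("segment_trials: sample times must be strictly increasing")
  eps <- 1e-6   # guards window edges against float error in the time grid
  lapply(seq_len(nrow(events)), function(i) {
    onset <- events$pic_ms[i]
    lo <- onset - baseline_ms
    hi <- onset + picture_ms
    keep <- t_ms >= lo - eps & t_ms <= hi + eps
    trace <- new_trial_trace(events$trial[i], events$condition[i],
                             round(t_ms[keep] - onset, 6), diameter_mm[keep])
    if (lo < min(t_ms) || hi > max(t_ms) || !any(keep)) {
      trace <- discard_trace(trace, "too_short")
    }
    trace
  })
}

#' Discard trials with physiologically infeasible pupil sizes
#'
#' Any non-missing sample outside the inclusive `[lo, hi]` mm band discards
#' the whole trial with reason `out_of_range`.
#'
#' @param trace a `trial_trace`.
#' @param lo,hi feasible diameter bounds (defaults 1.5 and 9 mm).
#' @return The (possibly discarded) trace.
#' @export
apply_range_filter <- function(trace, lo = 1.5, hi = 9) {
  if (trace$status == "discarded") return(trace)
  x <- trace$diameter_mm
  if (any(x < lo | x > hi, na.rm = TRUE)) {
    trace <- discard_trace(trace, "out_of_range")
  }
  trace
}

# Per-sample dilation speed (mm/s): the larger absolute slope towards the two
# adjacent neighbours, using only non-missing neighbours.
dilation_speed <- function(t_rel_ms, x) {
  n <- length(x)
  slope <- function(i, j) {
    if (j < 1 || j > n || is.na(x[i]) || is.na(x[j])) return(NA_real_)
    abs(x[i] - x[j]) / abs(t_rel_ms[i] - t_rel_ms[j]) * 1000
  }
  vapply(seq_len(n), function(i) {
    s <- c(slope(i, i - 1L), slope(i, i + 1L))
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  }, 0)
}

#' Remove dilation-speed outliers from a trial trace
#'
#' Flags samples whose dilation speed exceeds `median(d) + k * MAD(d)` and
#' sets them missing (they are then treated as gaps). Speeds are the larger
#' absolute slope towards the two adjacent non-missing neighbours; the MAD is
#' the raw median absolute deviation (no consistency constant). If the MAD is
#' zero no sample is flagged. The admissible multiplier range is 6–30.
#'
#' @param trace a `trial_trace`.
#' @param k MAD multiplier in \[6, 30\] (default 16).
#' @param threshold optional externally supplied threshold (mm/s), e.g. a
#'   per-participant pooled value; overrides the per-trace computation.
#' @return Trace with outlier samples set missing.
#' @export
flag_dilation_speed_outliers <- function(trace, k = 16, threshold = NULL) {
  if (k < 6 || k > 30) {
    stopf("configuration error: MAD multiplier 'k' must lie in [6, 30], got %s", k)
  }
  if (trace$status == "discarded") return(trace)
  d <- dilation_speed(trace$t_rel_ms, trace$diameter_mm)
  if (is.null(threshold)) {
    med <- median(d, na.rm = TRUE)
    mad_raw <- median(abs(d - med), na.rm = TRUE)
    if (is.na(med) || is.na(mad_raw) || mad_raw == 0) return(trace)
    threshold <- med + k * mad_raw
  }
  trace$diameter_mm[!is.na(d) & d > threshold] <- NA_real_
  trace
}

# Pooled speed threshold across a participant's traces (speed_scope =
# "participant"): median + k * raw MAD over all per-sample speeds.
pooled_speed_threshold <- function(traces, k) {
  d <- unlist(lapply(traces, function(tr) {
    if (tr$status == "discarded") return(numeric(0))
    dilation_speed(tr$t_rel_ms, tr$diameter_mm)
  }))
  med <- median(d, na.rm = TRUE)
  mad_raw <- median(abs(d - med), na.rm = TRUE)
  if (is.na(med) || is.na(mad_raw) || mad_raw == 0) return(Inf)
  med + k * mad_raw
}

#' Discard major blink gaps, interpolate minor ones
#'
#' A gap is a run of consecutive missing samples; its duration is the run
#' length times the sample period. Gaps strictly longer than `max_gap_ms`
#' (major blinks) discard the trial with reason `long_gap`, as do leading or
#' trailing gaps (no flanking samples to interpolate from). Remaining gaps
#' are filled by linear interpolation between the flanking valid samples.
#'
#' @param trace a `trial_trace` (speed filter already applied).
#' @param max_gap_ms longest interpolatable gap (default 100 ms; a 100 ms gap
#'   is kept, anything longer is not).
#' @param sampling_rate Hz, for converting run lengths to durations.
#' @return Gap-free trace, or a discarded one.
#' @export
handle_gaps <- function(trace, max_gap_ms = 100, sampling_rate = 30) {
  if (trace$status == "discarded") return(trace)
  x <- trace$diameter_mm
  miss <- is.na(x)
  if (!any(miss)) return(trace)
  if (all(miss)) return(discard_trace(trace, "long_gap"))
  runs <- rle(miss)
  if (runs$values[1] || runs$values[length(runs$values)]) {
    return(discard_trace(trace, "long_gap"))      # leading/trailing gap
  }
  gap_ms <- runs$lengths[runs$values] * sample_period_ms(sampling_rate)
  if (any(gap_ms > max_gap_ms)) {
    return(discard_trace(trace, "long_gap"))
  }
  ok <- !miss
  trace$diameter_mm <- approx(trace$t_rel_ms[ok], x[ok],
                              xout = trace$t_rel_ms, method = "linear")$y
  trace
}

#' Subtract the pre-picture baseline from a trial trace
#'
#' The baseline is the mean diameter over the `baseline_ms` window before
#' picture onset (`[-baseline_ms, 0)` ms); it is stored on the trace and
#' subtracted from the whole series, turning it into a dilation trace whose
#' baseline-window mean is zero. Idempotent.
#'
#' @param trace a gap-free `trial_trace`.
#' @param baseline_ms baseline window length (default 300 ms).
#' @return Corrected trace (`corrected = TRUE`), or one discarded with reason
#'   `long_gap` when no valid baseline sample exists.
#' @export
baseline_correct <- function(trace, baseline_ms = 300) {
  if (trace$status == "discarded") return(trace)
  in_base <- trace$t_rel_ms >= -baseline_ms & trace$t_rel_ms < 0
  base_vals <- trace$diameter_mm[in_base]
  base_vals <- base_vals[!is.na(base_vals)]
  if (length(base_vals) == 0) return(discard_trace(trace, "long_gap"))
  b <- mean(base_vals)
  trace$diameter_mm <- trace$diameter_mm - b
  trace$baseline_value <- if (trace$corrected) trace$baseline_value else b
  trace$corrected <- TRUE
  trace
}

#' Area under the curve with respect to ground
#'
#' Signed trapezoidal integral of the baseline-corrected dilation over the
#' analysis window (default 2–5 s after picture onset), relative to the
#' post-correction zero line ("ground"). When no sample falls exactly on a
#' window edge, the edge value is linearly interpolated so the integral
#' covers the window exactly.
#'
#' @param trace a corrected `trial_trace`.
#' @param window integration window in ms (default `c(2000, 5000)`).
#' @return AUCg in mm·s.
#' @export
compute_aucg <- function(trace, window = c(2000, 5000)) {
  if (!isTRUE(trace$corrected)) stopf("compute_aucg: trace is not baseline-corrected")
  t <- trace$t_rel_ms
  x <- trace$diameter_mm
  inside <- t >= window[1] & t <= window[2]
  if (any(is.na(x[inside]))) stopf("compute_aucg: missing samples in the AUCg window")
  tt <- t[inside]
  xx <- x[inside]
  for (edge in window) {
    if (!any(tt == edge) && min(t) <= edge && max(t) >= edge) {
      v <- approx(t, x, xout = edge)$y
      tt <- c(tt, edge)
      xx <- c(xx, v)
    }
  }
  o <- order(tt)
  tt <- tt[o]
  xx <- xx[o]
  if (length(tt) < 2) stopf("compute_aucg: not enough samples in the window")
  sum(diff(tt) * (head(xx, -1) + tail(xx, -1)) / 2) / 1000
}

#' Aggregate trial AUCg values to per-condition means
#'
#' @param trials data frame with columns `condition`, `status`, `aucg` (one
#'   participant's trials).
#' @param min_valid minimum valid trials for a condition mean (default 5).
#' @param conditions condition vocabulary (defaults to [er_conditions()]).
#' @return Data frame with `condition`, `mean_aucg`, `n_valid`.
#' @export
aggregate_condition <- function(trials, min_valid = 5,
                                conditions = er_conditions()) {
  out <- data.frame(condition = conditions, mean_aucg = NA_real_,
                    n_valid = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(conditions)) {
    ok <- trials$condition == conditions[i] & trials$status == "valid" &
      !is.na(trials$aucg)
    out$n_valid[i] <- sum(ok)
    if (sum(ok) >= min_valid) out$mean_aucg[i] <- mean(trials$aucg[ok])
  }
  out
}

#' Natural-log transform with automatic positivity shift
#'
#' `ln(x + shift)` where `shift = 1 - min(x)` over the analysis set whenever
#' any value is non-positive (AUCg can be negative), else 0. The shift used is
#' returned so runs are auditable.
#'
#' @param x numeric vector (NAs preserved).
#' @return List with `values` and `shift`.
#' @export
ln_shift_transform <- function(x) {
  finite <- x[!is.na(x)]
  shift <- if (length(finite) && min(finite) <= 0) 1 - min(finite) else 0
  list(values = log(x + shift), shift = shift)
}

#' Run the full pupil preprocessing chain for a set of participants
#'
#' Averages eyes, smooths, segments per participant, applies the range and
#' dilation-speed filters, handles blink gaps, baseline-corrects, integrates
#' AUCg and aggregates per condition.
#'
#' @param samples data frame `participant, t_ms, left_mm, right_mm`.
#' @param events data frame `participant, trial, condition, pic_ms`.
#' @param params a [pupil_params()] list.
#' @return List with `trials` (per-trial QC table: participant, trial,
#'   condition, status, discard_reason, baseline, aucg) and `condition_auc`
#'   (participant x condition table with `mean_aucg`, `n_valid`, `ln_aucg`,
#'   plus attribute `ln_shift`).
#' @export
preprocess_pupil <- function(samples, events, params = pupil_params()) {
  qc <- list()
  cond_rows <- list()
  for (pid in unique(events$participant)) {
    s <- samples[samples$participant == pid, ]
    e <- events[events$participant == pid, ]
    mono <- average_eyes(s$left_mm, s$right_mm, strict = params$strict_eyes)
    mono <- smooth_fir(mono, params$sampling_rate, params$cutoff_hz,
                       params$fir_taps, t_ms = s$t_ms)
    traces <- segment_trials(s$t_ms, mono, e,
                             baseline_ms = params$baseline_ms)
    traces <- lapply(traces, apply_range_filter,
                     lo = params$range_lo, hi = params$range_hi)
    if (params$speed_scope == "participant") {
      thr <- pooled_speed_threshold(traces, params$mad_k)
      traces <- lapply(traces, flag_dilation_speed_outliers,
                       k = params$mad_k, threshold = thr)
    } else {
      traces <- lapply(traces, flag_dilation_speed_outliers, k = params$mad_k)
    }
    traces <- lapply(traces, handle_gaps, max_gap_ms = params$max_gap_ms,
                     sampling_rate = params$sampling_rate)
    traces <- lapply(traces, baseline_correct, baseline_ms = params$baseline_ms)
    aucg <- vapply(traces, function(tr) {
      if (tr$status == "valid") compute_aucg(tr, params$aucg_window) else NA_real_
    }, 0)
    qc[[pid]] <- data.frame(
      participant = pid,
      trial = vapply(traces, `[[`, 0, "trial"),
      condition = vapply(traces, `[[`, "", "condition"),
      status = vapply(traces, `[[`, "", "status"),
      discard_reason = vapply(traces, `[[`, "", "discard_reason"),
      baseline = vapply(traces, `[[`, 0, "baseline_value"),
      aucg = aucg,
      stringsAsFactors = FALSE
    )
    agg <- aggregate_condition(qc[[pid]], min_valid = params$min_valid)
    agg <- cbind(participant = pid, agg, stringsAsFactors = FALSE)
    cond_rows[[pid]] <- agg
  }
  trials <- do.call(rbind, qc)
  condition_auc <- do.call(rbind, cond_rows)
  rownames(trials) <- rownames(condition_auc) <- NULL
  ln <- ln_shift_transform(condition_auc$mean_aucg)
  condition_auc$ln_aucg <- ln$values
  attr(condition_auc, "ln_shift") <- ln$shift
  list(trials = trials, condition_auc = condition_auc)
}
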