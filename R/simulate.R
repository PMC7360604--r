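# Synthetic-study generator.
#
# Every draw flows from config$seed through per-participant, per-table
# sub-streams (see sub_seed()): the clean pupil signal and the artifact
# process use separate streams, so changing artifact rates never changes the
# underlying clean traces.

das_negative_factors <- function() {
  c("sadness", "anger", "disgust", "contempt", "fear", "shame", "guilt")
}
das_positive_factors <- function() c("joy", "surprise", "interest")

#' Deterministic generating pupil curve for one trial
#'
#' The noise-free dilation model: a tonic level plus two additive components —
#' an emotional-arousal ramp (logistic, rising from picture onset and
#' plateauing by ~2 s, so the 2–5 s AUCg window sits on the plateau) and a
#' cognitive-effort ramp whose onset is delayed by 500 ms (the regulation
#' instruction takes effect late). Used both by the generator and by
#' truth-based oracle tests.
#'
#' @param t_rel_ms time relative to picture onset (ms).
#' @param tonic tonic pupil diameter (mm).
#' @param arousal_amp,effort_amp component amplitudes (mm).
#' @return Pupil diameter in mm at each `t_rel_ms`.
#' @export
pupil_trial_curve <- function(t_rel_ms, tonic, arousal_amp, effort_amp) {
  tonic +
    arousal_amp * stats::plogis((t_rel_ms - 1000) / 250) +
    effort_amp * stats::plogis((t_rel_ms - 1500) / 250)
}

# Trial geometry on the sample grid; all counts derived from the configured
# timing so that picture onset and offset are exact samples.
trial_geometry <- function(config) {
  dt <- sample_period_ms(config$sampling_rate)
  tm <- config$timing
  n_pre <- ceiling((tm$cue_ms + tm$fixation_ms) / dt)      # samples before pic
  n_pic <- round(tm$picture_ms / dt)                       # picture span
  total_ms <- tm$cue_ms + tm$fixation_ms + tm$picture_ms + tm$rating_ms + tm$iti_ms
  stride <- ceiling(total_ms / dt)                         # samples per trial slot
  list(dt = dt, n_pre = n_pre, n_pic = n_pic, n_samples = n_pre + n_pic + 1L,
       stride = stride)
}

effort_amplitude <- function(participant, condition, pupil_params) {
  amp <- pupil_params$effort_amp[[condition]]
  if (condition == "reappraisal" &&
      participant$stress_group == "stress" &&
      participant$hormone_group == "MALE") {
    amp <- amp + pupil_params$sm_reappraisal_effort
  }
  amp
}

#' Simulate one raw event-locked pupil trial
#'
#' Draws a binocular pupil trace covering instructional cue, fixation and
#' picture presentation for one trial, from the current RNG state. The clean
#' signal is [pupil_trial_curve()] (clamped to the physiological band), to
#' which per-eye Gaussian noise, blink gaps (lognormal duration, both eyes),
#' single-eye dropouts, dilation-speed spikes and out-of-range runs are added
#' according to `config$artifact_params`.
#'
#' @param participant list with `id`, `stress_group`, `hormone_group`.
#' @param condition one of [er_conditions()].
#' @param config a [study_config()].
#' @param tonic optional participant tonic level (mm); drawn if `NULL`.
#' @return List with `t_rel_ms` (relative to picture onset), `left_mm`,
#'   `right_mm`, and `truth` (tonic/arousal/effort actually used).
#' @export
simulate_pupil_trial <- function(participant, condition, config, tonic = NULL) {
  if (!condition %in% config$conditions) {
    stopf("unknown condition '%s'", condition)
  }
  geo <- trial_geometry(config)
  pp <- config$effect_params$pupil
  ap <- config$artifact_params
  t_rel <- (seq_len(geo$n_samples) - 1 - geo$n_pre) * geo$dt
  if (is.null(tonic)) tonic <- rnorm(1, pp$tonic_mean, pp$tonic_sd)
  trial_tonic <- tonic + rnorm(1, 0, pp$trial_tonic_sd)
  a_amp <- pp$arousal_amp[[condition]]
  e_amp <- effort_amplitude(participant, condition, pp)
  clean <- pupil_trial_curve(t_rel, trial_tonic, a_amp, e_amp)
  clean <- pmin(pmax(clean, pp$band[1]), pp$band[2])

  n <- geo$n_samples
  dur_s <- (n - 1) * geo$dt / 1000
  left <- clean + rnorm(n, 0, ap$noise_sd)
  right <- clean + rnorm(n, 0, ap$noise_sd)

  # blinks: runs of missing samples in both eyes
  n_blink <- rpois(1, ap$blink_rate_hz * dur_s)
  if (n_blink > 0) {
    starts <- runif(n_blink, min(t_rel), max(t_rel))
    durs <- rlnorm(n_blink, ap$blink_meanlog, ap$blink_sdlog) * 1000
    for (b in seq_len(n_blink)) {
      hit <- t_rel >= starts[b] & t_rel < starts[b] + durs[b]
      left[hit] <- NA_real_
      right[hit] <- NA_real_
    }
  }
  # single-eye dropouts
  n_drop <- rpois(1, ap$eye_dropout_rate_hz * dur_s)
  if (n_drop > 0) {
    starts <- runif(n_drop, min(t_rel), max(t_rel))
    eyes <- sample(c("L", "R"), n_drop, replace = TRUE)
    for (b in seq_len(n_drop)) {
      hit <- t_rel >= starts[b] & t_rel < starts[b] + ap$eye_dropout_ms
      if (eyes[b] == "L") left[hit] <- NA_real_ else right[hit] <- NA_real_
    }
  }
  # isolated speed spikes
  n_spike <- rpois(1, ap$spike_rate_hz * dur_s)
  if (n_spike > 0) {
    idx <- sample.int(n, min(n_spike, n))
    sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
    left[idx] <- left[idx] + sgn * ap$spike_mm
    right[idx] <- right[idx] + sgn * ap$spike_mm
  }
  # out-of-range run (e.g. partial lid occlusion measured as tiny pupil)
  if (runif(1) < ap$range_rate) {
    start <- sample.int(n - 3L, 1)
    idx <- start:(start + 2L)
    left[idx] <- 0.8
    right[idx] <- 0.8
  }
  list(t_rel_ms = t_rel, left_mm = left, right_mm = right,
       truth = list(tonic = trial_tonic, arousal_amp = a_amp,
                    effort_amp = e_amp))
}

#' Simulate one participant's saliva time course
#'
#' Four samples per analyte (baseline, +2, +15, +45 min after stressor
#' offset). Each participant draws a baseline-to-peak delta from the
#' configured stress x hormone cell mean/SD; positive deltas produce a peaked
#' time course (cortisol peaking at +15 min, alpha-amylase immediately after
#' the stressor at +2), negative deltas a monotone decline — in both cases
#' the post-baseline maximum minus baseline equals the drawn delta, so the
#' delta-summary stage recovers the generating means. Concentrations are
#' floored at a small positive value.
#'
#' @inheritParams simulate_pupil_trial
#' @return Data frame with columns `participant`, `timepoint`,
#'   `cortisol_nmoll`, `saa_ul`.
#' @export
simulate_saliva <- function(participant, config) {
  sp <- config$effect_params$saliva
  g <- participant$stress_group
  h <- participant$hormone_group
  tp <- c("baseline", "+2", "+15", "+45")

  base_c <- max(rnorm(1, sp$cortisol_baseline_mean, sp$cortisol_baseline_sd),
                sp$floor[["cortisol"]] + 1)
  base_a <- max(rnorm(1, sp$saa_baseline_mean, sp$saa_baseline_sd),
                sp$floor[["saa"]] + 1)
  d_c <- rnorm(1, sp$cortisol_delta_mean[[g]][[h]], sp$cortisol_delta_sd[[g]][[h]])
  d_a <- rnorm(1, sp$saa_delta_mean[[g]][[h]], sp$saa_delta_sd[[g]][[h]])

  w_c <- if (d_c >= 0) sp$cortisol_peak else sp$decline
  w_a <- if (d_a >= 0) sp$saa_peak else sp$decline
  cort <- c(base_c, base_c + d_c * w_c) + rnorm(4, 0, sp$noise_sd[["cortisol"]])
  saa <- c(base_a, base_a + d_a * w_a) + rnorm(4, 0, sp$noise_sd[["saa"]])
  data.frame(
    participant = participant$id,
    timepoint = tp,
    cortisol_nmoll = pmax(cort, sp$floor[["cortisol"]]),
    saa_ul = pmax(saa, sp$floor[["saa"]]),
    stringsAsFactors = FALSE
  )
}

#' Simulate one participant's trial ratings and DAS time course
#'
#' Per-trial arousal and valence (9-point) and regulation success (5-point)
#' are Gaussian draws around condition means (plus a participant shift and,
#' for stressed males in the reappraisal condition, the configured effect
#' shifts), then rounded and clamped to the scale. The Differential Affect
#' Scale series has 10 factor columns on a 1–5 scale at baseline, +2 and +45,
#' with the configured negative-affect spike at +2 for stressed groups.
#'
#' @inheritParams simulate_pupil_trial
#' @param trial_conditions character vector giving the condition of each trial
#'   in presentation order.
#' @return List with `ratings` (data frame: participant, trial, condition,
#'   arousal, valence, success) and `das` (data frame: participant, timepoint,
#'   one column per affect factor).
#' @export
simulate_ratings_and_das <- function(participant, config,
                                     trial_conditions = NULL) {
  rp <- config$effect_params$ratings
  if (is.null(trial_conditions)) {
    trial_conditions <- rep(config$conditions, each = config$trials_per_condition)
  }
  n <- length(trial_conditions)
  sm <- participant$stress_group == "stress" &&
    participant$hormone_group == "MALE"
  shift <- function(scale_shift) {
    ifelse(sm & trial_conditions == "reappraisal", scale_shift, 0)
  }
  draw <- function(means, scale_shift, lo, hi) {
    subj <- rnorm(1, 0, rp$subject_sd)
    x <- means[trial_conditions] + subj + shift(scale_shift) +
      rnorm(n, 0, rp$trial_sd)
    pmin(pmax(round(x), lo), hi)
  }
  ratings <- data.frame(
    participant = participant$id,
    trial = seq_len(n),
    condition = trial_conditions,
    arousal = as.integer(draw(rp$arousal_mean, rp$sm_reappraisal_arousal, 1, 9)),
    valence = as.integer(draw(rp$valence_mean, rp$sm_reappraisal_valence, 1, 9)),
    success = as.integer(draw(rp$success_mean, rp$sm_reappraisal_success, 1, 5)),
    stringsAsFactors = FALSE
  )

  dp <- config$effect_params$das
  g <- participant$stress_group
  h <- participant$hormone_group
  delta <- rnorm(1, dp$delta_mean[[g]][[h]], dp$delta_sd[[g]][[h]])
  w <- c(0, if (delta >= 0) dp$peak else dp$decline)   # baseline, +2, +45
  tp <- c("baseline", "+2", "+45")
  das <- data.frame(participant = participant$id, timepoint = tp,
                    stringsAsFactors = FALSE)
  for (f in das_negative_factors()) {
    das[[f]] <- pmin(pmax(dp$neg_base_mean + delta * w + rnorm(3, 0, dp$factor_sd), 1), 5)
  }
  for (f in das_positive_factors()) {
    das[[f]] <- pmin(pmax(dp$pos_base_mean + rnorm(3, 0, dp$factor_sd), 1), 5)
  }
  list(ratings = ratings, das = das)
}

# Condition order per paradigm structure: trials arranged in blocks of five
# per condition, each condition once per half in random order.
draw_trial_conditions <- function(config) {
  per_block <- config$trials_per_condition / 2
  if (per_block == floor(per_block)) {
    halves <- c(sample(config$conditions), sample(config$conditions))
    rep(halves, each = per_block)
  } else {
    sample(rep(config$conditions, each = config$trials_per_condition))
  }
}

#' Simulate a complete synthetic study
#'
#' Generates a full dataset for the 2 (stress vs control) x 3 (MALE, FELU,
#' FEOC) between-subjects design with `n_per_cell` participants per cell and
#' five within-subject emotion regulation conditions: continuous binocular
#' pupil recordings with event markers, saliva series, DAS series and
#' per-trial ratings, plus the generating ground truth for recovery tests.
#' Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return A `stressreg_study` list with elements `roster`, `pupil`
#'   (`$samples`, `$events`), `saliva`, `das`, `ratings`, `truth`, `config`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "stressreg_config")) {
    stopf("configuration error: 'config' must come from study_config()")
  }
  cells <- expand.grid(hormone_group = hormone_groups(),
                       stress_group = stress_groups(),
                       stringsAsFactors = FALSE)
  roster <- cells[rep(seq_len(nrow(cells)), each = config$n_per_cell), ]
  roster$id <- sprintf("P%03d", seq_len(nrow(roster)))
  roster <- roster[, c("id", "stress_group", "hormone_group")]
  rownames(roster) <- NULL

  geo <- trial_geometry(config)
  n_trials <- length(config$conditions) * config$trials_per_condition

  pupil_samples <- vector("list", nrow(roster))
  pupil_events <- vector("list", nrow(roster))
  saliva <- vector("list", nrow(roster))
  das <- vector("list", nrow(roster))
  ratings <- vector("list", nrow(roster))
  truth_participants <- vector("list", nrow(roster))

  for (i in seq_len(nrow(roster))) {
    p <- as.list(roster[i, ])
    cond_order <- with_seed(sub_seed(config$seed, i, 4L),
                            draw_trial_conditions(config))

    if ("pupil" %in% config$include) {
      tonic <- with_seed(sub_seed(config$seed, i, 1L),
                         rnorm(1, config$effect_params$pupil$tonic_mean,
                               config$effect_params$pupil$tonic_sd))
      trials <- with_seed(sub_seed(config$seed, i, 2L), {
        lapply(seq_len(n_trials), function(j) {
          simulate_pupil_trial(p, cond_order[j], config, tonic = tonic)
        })
      })
      t0 <- (seq_len(n_trials) - 1) * geo$stride * geo$dt
      pupil_samples[[i]] <- data.frame(
        participant = p$id,
        t_ms = unlist(lapply(seq_len(n_trials), function(j) {
          t0[j] + geo$n_pre * geo$dt + trials[[j]]$t_rel_ms
        })),
        left_mm = unlist(lapply(trials, `[[`, "left_mm")),
        right_mm = unlist(lapply(trials, `[[`, "right_mm")),
        stringsAsFactors = FALSE
      )
      pupil_events[[i]] <- data.frame(
        participant = p$id,
        trial = seq_len(n_trials),
        condition = cond_order,
        cue_ms = t0,
        fix_ms = t0 + config$timing$cue_ms,
        pic_ms = t0 + geo$n_pre * geo$dt,
        stringsAsFactors = FALSE
      )
      truth_participants[[i]] <- list(
        id = p$id, tonic = tonic,
        trial_truth = data.frame(
          trial = seq_len(n_trials), condition = cond_order,
          tonic = vapply(trials, function(x) x$truth$tonic, 0),
          arousal_amp = vapply(trials, function(x) x$truth$arousal_amp, 0),
          effort_amp = vapply(trials, function(x) x$truth$effort_amp, 0)
        )
      )
    }
    if ("saliva" %in% config$include) {
      saliva[[i]] <- with_seed(sub_seed(config$seed, i, 3L),
                               simulate_saliva(p, config))
    }
    if ("das" %in% config$include || "ratings" %in% config$include) {
      rd <- with_seed(sub_seed(config$seed, i, 5L),
                      simulate_ratings_and_das(p, config, cond_order))
      if ("ratings" %in% config$include) ratings[[i]] <- rd$ratings
      if ("das" %in% config$include) das[[i]] <- rd$das
    }
  }

  bind <- function(lst) if (all(vapply(lst, is.null, TRUE))) NULL else do.call(rbind, lst)
  study <- list(
    roster = roster,
    pupil = if ("pupil" %in% config$include) {
      list(samples = bind(pupil_samples), events = bind(pupil_events))
    } else NULL,
    saliva = bind(saliva),
    das = bind(das),
    ratings = bind(ratings),
    truth = list(effect_params = config$effect_params,
                 participants = truth_participants),
    config = config
  )
  class(study) <- "stressreg_study"
  study
}

#' @export
print.stressreg_study <- function(x, ...) {
  cat("<stressreg_study>", nrow(x$roster), "participants;",
      length(x$config$conditions), "conditions x",
      x$config$trials_per_condition, "trials; tables:",
      paste(x$config$include, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read the study tables as delimited text
#'
#' Writes the five analysis input tables (pupil samples, events, saliva, DAS,
#' ratings) plus the roster as UTF-8 tab-separated files with a header row and
#' "." decimal mark, and the generating parameters as `truth.json`.
#'
#' @param study a `stressreg_study`.
#' @param dir output directory (created if missing).
#' @return `write_study_tables()` returns the directory invisibly;
#'   `read_study_tables()` returns a list of data frames with the same names.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  }
  tsv(study$roster, "roster")
  tsv(study$pupil$samples, "pupil_samples")
  tsv(study$pupil$events, "events")
  tsv(study$saliva, "saliva")
  tsv(study$das, "das")
  tsv(study$ratings, "ratings")
  jsonlite::write_json(study$truth$effect_params,
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study_tables
#' @export
read_study_tables <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (file.exists(path)) {
      utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    } else NULL
  }
  out <- list(roster = rd("roster"),
              pupil = list(samples = rd("pupil_samples"), events = rd("events")),
              saliva = rd("saliva"), das = rd("das"), ratings = rd("ratings"))
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) out$truth <- jsonlite::read_json(truth_path)
  out
}
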