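#' Emotion regulation condition and group vocabularies
#'
#' The five within-subject conditions of the emotion regulation paradigm (two
#' passive viewing conditions plus three regulation strategies), the two
#' between-subject stress groups, and the three sex-hormone groups (males,
#' free-cycling females in the luteal phase, females taking oral
#' contraceptives).
#'
#' @return Character vector of labels, in canonical order.
#' @export
er_conditions <- function() {
  c("view_neutral", "view_negative", "intensify", "reappraisal", "distraction")
}

#' @rdname er_conditions
#' @export
stress_groups <- function() c("stress", "control")

#' @rdname er_conditions
#' @export
hormone_groups <- function() c("MALE", "FELU", "FEOC")

# 30 Hz sample period in ms.
sample_period_ms <- function(sampling_rate) 1000 / sampling_rate

#' Default generating parameters for the synthetic study
#'
#' Effect parameters encode the study world the generator emulates: per-condition
#' rating means with a stressed-male reappraisal shift, a two-component pupil
#' dilation model (emotional arousal + cognitive regulatory effort), salivary
#' cortisol peaking 15 min after stressor offset with group-specific
#' baseline-to-peak deltas (MALE 13.96, FELU 4.55, FEOC 4.48 nmol/l; controls
#' slightly declining), alpha-amylase peaking immediately post stressor, and a
#' negative-affect spike at +2 min for stressed groups.
#'
#' @return Nested list of generating parameters; see the methods vignette for
#'   units and rationale.
#' @export
default_effect_params <- function() {
  conds <- er_conditions()
  list(
    ratings = list(
      # 9-point arousal/valence, 5-point success; means ordered
      # intensify > view_negative > reappraisal/distraction > view_neutral
      # for arousal and reversed for valence.
      arousal_mean = setNames(c(2.2, 5.4, 6.3, 4.4, 4.2), conds),
      valence_mean = setNames(c(5.5, 3.0, 2.4, 4.1, 4.0), conds),
      success_mean = setNames(c(3.4, 3.3, 3.8, 3.0, 3.1), conds),
      subject_sd = 0.5,   # between-participant shift, shared across conditions
      trial_sd = 1.2,     # per-trial noise before rounding/clamping
      # additive shifts applied to stressed males in the reappraisal condition
      sm_reappraisal_arousal = -0.8,
      sm_reappraisal_valence = 0.8,
      sm_reappraisal_success = 0.8
    ),
    pupil = list(
      tonic_mean = 4.5, tonic_sd = 0.3,  # mm, between participants
      trial_tonic_sd = 0.1,              # mm, trial-to-trial jitter
      # emotional-arousal ramp amplitude (mm) per condition
      arousal_amp = setNames(c(0.05, 0.30, 0.40, 0.30, 0.15), conds),
      # cognitive-effort component amplitude (mm); zero for passive viewing
      effort_amp = setNames(c(0.00, 0.00, 0.25, 0.20, 0.15), conds),
      sm_reappraisal_effort = 0.15,      # extra effort for stressed males
      band = c(1.6, 8.9)                 # clean-signal physiological band, mm
    ),
    saliva = list(
      cortisol_baseline_mean = 8, cortisol_baseline_sd = 2,    # nmol/l
      saa_baseline_mean = 60, saa_baseline_sd = 15,            # U/l
      # baseline-to-peak delta means/SDs per stress x hormone cell;
      # SDs are Table-style SEMs scaled to n ~ 20 per cell
      cortisol_delta_mean = list(
        stress = c(MALE = 13.96, FELU = 4.55, FEOC = 4.48),
        control = c(MALE = -1.61, FELU = -0.43, FEOC = -1.01)
      ),
      cortisol_delta_sd = list(
        stress = c(MALE = 8.36, FELU = 4.74, FEOC = 4.79),
        control = c(MALE = 8.14, FELU = 5.99, FEOC = 5.19)
      ),
      saa_delta_mean = list(
        stress = c(MALE = 115.98, FELU = 102.85, FEOC = 116.92),
        control = c(MALE = 22.86, FELU = -1.91, FEOC = 67.84)
      ),
      saa_delta_sd = list(
        stress = c(MALE = 95.2, FELU = 118.6, FEOC = 119.1),
        control = c(MALE = 55.0, FELU = 115.6, FEOC = 122.3)
      ),
      # post-baseline profile weights at +2, +15, +45 relative to the
      # participant's drawn delta: `peak` shapes are used when the delta is
      # positive (responder; max weight 1 at the analyte's peak time),
      # `decline` when it is negative (monotone decline whose smallest drop
      # is the delta) — either way max(post) - baseline recovers the delta.
      cortisol_peak = c(0.3, 1.0, 0.55),
      saa_peak = c(1.0, 0.45, 0.15),
      decline = c(1.0, 1.3, 1.6),
      noise_sd = c(cortisol = 0.3, saa = 3),   # measurement noise
      floor = c(cortisol = 0.5, saa = 1)       # concentrations stay positive
    ),
    das = list(
      neg_base_mean = 1.6, pos_base_mean = 2.5, factor_sd = 0.35,
      delta_mean = list(stress = c(MALE = 0.51, FELU = 0.60, FEOC = 0.35),
                        control = c(MALE = -0.12, FELU = -0.13, FEOC = -0.07)),
      delta_sd = list(stress = c(MALE = 0.58, FELU = 0.63, FEOC = 0.40),
                      control = c(MALE = 0.58, FELU = 0.63, FEOC = 0.45)),
      # negative-affect profile weights at +2 and +45 (same sign convention
      # as the saliva profiles: spike at +2 for positive deltas)
      peak = c(1.0, 0.1),
      decline = c(1.0, 1.3)
    )
  )
}

#' @rdname default_effect_params
#' @export
default_artifact_params <- function() {
  list(
    blink_rate_hz = 0.10,         # blinks per second of recording
    blink_meanlog = log(0.120),   # lognormal blink duration, median 120 ms
    blink_sdlog = 0.5,
    spike_rate_hz = 0.02,         # isolated dilation-speed spikes per second
    spike_mm = 1.5,
    range_rate = 0.01,            # per-trial probability of an out-of-range run
    eye_dropout_rate_hz = 0.05,   # single-eye tracking losses per second
    eye_dropout_ms = 100,
    noise_sd = 0.05               # Gaussian sample noise, mm
  )
}

#' Artifact parameters that disable every artifact source
#'
#' Zeroes blinks, spikes, out-of-range runs and eye dropouts while keeping
#' Gaussian measurement noise (set `noise_sd = 0` yourself for fully
#' deterministic traces — note that on a noise-free smooth trace the
#' dilation-speed MAD statistics collapse towards zero and the genuine
#' dilation ramp itself would be flagged; see the methods vignette).
#'
#' @rdname default_effect_params
#' @export
no_artifact_params <- function() {
  p <- default_artifact_params()
  p$blink_rate_hz <- 0
  p$spike_rate_hz <- 0
  p$range_rate <- 0
  p$eye_dropout_rate_hz <- 0
  p
}

#' Build a synthetic-study configuration
#'
#' Assembles and validates the full parameter set for [simulate_study()]:
#' design sizes, the trial timing of the emotion regulation paradigm (750 ms
#' instructional cue, 2,500 ms fixation, 5,000 ms picture, three 5,000 ms
#' rating screens, 2,000 ms inter-trial interval), generating effect
#' parameters and artifact rates.
#'
#' Event onsets are quantised to the sample grid (see the methods vignette), so
#' that picture onset, the baseline-window edge and the AUCg window edges fall
#' exactly on samples.
#'
#' @param n_per_cell participants per stress x hormone cell (>= 2).
#' @param sampling_rate pupil sampling rate in Hz (default 30).
#' @param trials_per_condition trials per within-subject condition (default 10).
#' @param effect_params generating means/SDs; see [default_effect_params()].
#' @param artifact_params blink/spike/noise rates; see
#'   [default_artifact_params()].
#' @param seed integer seed governing all randomness of the study.
#' @param include character subset of `c("pupil", "saliva", "das", "ratings")`
#'   selecting which tables to simulate (all by default).
#' @return A `stressreg_config` list.
#' @export
study_config <- function(n_per_cell = 20,
                         sampling_rate = 30,
                         trials_per_condition = 10,
                         effect_params = default_effect_params(),
                         artifact_params = default_artifact_params(),
                         seed = 1L,
                         include = c("pupil", "saliva", "das", "ratings")) {
  check_number(n_per_cell, "n_per_cell", lo = 2)
  check_number(sampling_rate, "sampling_rate", lo = .Machine$double.eps)
  check_number(trials_per_condition, "trials_per_condition", lo = 1)
  check_number(seed, "seed")
  include <- match.arg(include, several.ok = TRUE)
  sds <- c(
    effect_params$ratings$subject_sd, effect_params$ratings$trial_sd,
    effect_params$pupil$tonic_sd, effect_params$pupil$trial_tonic_sd,
    unlist(effect_params$saliva$cortisol_delta_sd),
    unlist(effect_params$saliva$saa_delta_sd),
    effect_params$saliva$noise_sd, effect_params$das$factor_sd,
    unlist(effect_params$das$delta_sd),
    artifact_params$noise_sd
  )
  if (any(sds < 0)) stopf("configuration error: 'effect_params/artifact_params' SDs must be >= 0")
  cfg <- list(
    n_per_cell = as.integer(n_per_cell),
    sampling_rate = sampling_rate,
    conditions = er_conditions(),
    trials_per_condition = as.integer(trials_per_condition),
    timing = list(cue_ms = 750, fixation_ms = 2500, picture_ms = 5000,
                  rating_ms = 3 * 5000, iti_ms = 2000),
    effect_params = effect_params,
    artifact_params = artifact_params,
    seed = as.integer(seed),
    include = include
  )
  class(cfg) <- "stressreg_config"
  cfg
}

#' Null-effect configuration for type-I error studies
#'
#' Same design as [study_config()] but with every systematic group difference
#' removed: no stressed-male reappraisal shifts (ratings or pupil effort), and
#' saliva/DAS deltas identical across stress and hormone groups.
#'
#' @param ... passed to [study_config()].
#' @export
null_study_config <- function(...) {
  cfg <- study_config(...)
  ep <- cfg$effect_params
  ep$ratings$sm_reappraisal_arousal <- 0
  ep$ratings$sm_reappraisal_valence <- 0
  ep$ratings$sm_reappraisal_success <- 0
  ep$pupil$sm_reappraisal_effort <- 0
  flat <- function(x) {
    x$stress[] <- mean(c(x$stress, x$control))
    x$control[] <- mean(c(x$stress, x$control))
    x
  }
  ep$saliva$cortisol_delta_mean <- flat(ep$saliva$cortisol_delta_mean)
  ep$saliva$saa_delta_mean <- flat(ep$saliva$saa_delta_mean)
  ep$das$delta_mean <- flat(ep$das$delta_mean)
  cfg$effect_params <- ep
  cfg
}
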