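# Pipeline orchestration: simulate -> preprocess -> summarise -> test, with a
# reconciled run report.

#' Per-participant, per-condition rating means
#'
#' @param ratings trial-level ratings table.
#' @param dv one of `"arousal"`, `"valence"`, `"success"`.
#' @return Long data frame `participant, condition, value`.
#' @export
condition_means <- function(ratings, dv = "arousal") {
  agg <- aggregate(ratings[[dv]],
                   by = list(participant = ratings$participant,
                             condition = ratings$condition),
                   FUN = mean)
  names(agg)[3] <- dv
  agg[order(agg$participant, agg$condition), , drop = FALSE]
}

# Attach roster group columns to a participant-keyed table.
with_groups <- function(df, roster, key = "participant") {
  merge(df, roster, by.x = key, by.y = "id", all.x = TRUE)
}

#' The stressed-male reappraisal stress contrast
#'
#' Welch t test of stress vs control among male participants on the
#' reappraisal-condition value of `dv` — the focal follow-up contrast of the
#' stress x sex-hormone x condition pathway.
#'
#' @param cell_means long table (`participant, condition, <dv>`), e.g. from
#'   [condition_means()].
#' @param roster participant roster with group columns.
#' @param dv value column name.
#' @return List with `t`, `df`, `p`, and per-group ns.
#' @export
reappraisal_stress_contrast <- function(cell_means, roster, dv) {
  dat <- with_groups(cell_means[cell_means$condition == "reappraisal", ], roster)
  dat <- dat[dat$hormone_group == "MALE" & !is.na(dat[[dv]]), ]
  x <- dat[[dv]][dat$stress_group == "stress"]
  y <- dat[[dv]][dat$stress_group == "control"]
  if (length(x) < 2 || length(y) < 2) {
    stopf("reappraisal_stress_contrast: fewer than 2 males in a stress cell")
  }
  res <- welch_t_raw(x, y)
  c(res, list(n_stress = length(x), n_control = length(y)))
}

# Saliva / DAS long tables for the time-course ANOVAs.
saliva_long <- function(saliva, analyte = c("cortisol_nmoll", "saa_ul")) {
  analyte <- match.arg(analyte)
  data.frame(participant = saliva$participant, timepoint = saliva$timepoint,
             value = saliva[[analyte]], stringsAsFactors = FALSE)
}

das_long <- function(das) {
  score <- vapply(seq_len(nrow(das)), function(i) {
    das_negative_affect(das[i, das_negative_factors()])
  }, 0)
  data.frame(participant = das$participant, timepoint = das$timepoint,
             value = score, stringsAsFactors = FALSE)
}

#' Statistical analysis stage
#'
#' Runs the inferential layer on a set of study tables: mixed-design ANOVAs
#' (stress x sex hormone between, condition within) for each rating scale and
#' for pupil AUCg; time-course ANOVAs for cortisol, alpha-amylase and DAS
#' negative affect; the stressed-male reappraisal contrast per rating scale;
#' and Pearson correlations of delta cortisol with male reappraisal success.
#'
#' @param tables list with `roster`, `ratings`, `saliva`, `das`, and
#'   optionally `condition_auc` (from [preprocess_pupil()]).
#' @param alpha significance level.
#' @param gg_policy passed to [mixed_anova()].
#' @return List of ANOVA tables, contrasts and correlations.
#' @export
analyze_study <- function(tables, alpha = 0.05, gg_policy = "mauchly") {
  roster <- tables$roster
  between <- c("stress_group", "hormone_group")
  out <- list(anova = list(), contrasts = list(), correlations = list(),
              notes = character(0))
  # a tiny or heavily filtered dataset can make single models unestimable
  # (e.g. < 2 participants left in a cell); record that instead of aborting
  try_fit <- function(name, expr) {
    res <- tryCatch(suppressWarnings(expr), error = function(e) {
      out$notes <<- c(out$notes, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
    res
  }

  if (!is.null(tables$ratings)) {
    for (dv in c("arousal", "valence", "success")) {
      cm <- condition_means(tables$ratings, dv)
      long <- with_groups(cm, roster)
      out$anova[[dv]] <- try_fit(dv, mixed_anova(
        long, dv = dv, within = "condition", between = between,
        gg_policy = gg_policy))
      out$contrasts[[dv]] <- try_fit(paste0(dv, " contrast"),
                                     reappraisal_stress_contrast(cm, roster, dv))
    }
  }
  if (!is.null(tables$condition_auc)) {
    long <- with_groups(tables$condition_auc, roster)
    out$anova$pupil_aucg <- try_fit("pupil_aucg", mixed_anova(
      long, dv = "mean_aucg", within = "condition", between = between,
      gg_policy = gg_policy))
  }
  if (!is.null(tables$saliva)) {
    for (an in c("cortisol_nmoll", "saa_ul")) {
      long <- with_groups(saliva_long(tables$saliva, an), roster)
      nm <- if (an == "cortisol_nmoll") "cortisol" else "saa"
      out$anova[[nm]] <- try_fit(nm, mixed_anova(
        long, dv = "value", within = "timepoint", between = between,
        gg_policy = gg_policy))
    }
  }
  if (!is.null(tables$das)) {
    long <- with_groups(das_long(tables$das), roster)
    out$anova$das <- try_fit("das", mixed_anova(
      long, dv = "value", within = "timepoint", between = between,
      gg_policy = gg_policy))
  }
  if (!is.null(tables$saliva) && !is.null(tables$ratings)) {
    deltas <- saliva_delta_table(tables$saliva, roster = roster)
    males <- deltas[deltas$hormone_group == "MALE", ]
    succ <- condition_means(tables$ratings, "success")
    for (cond in er_conditions()[-1]) {
      sc <- succ[succ$condition == cond, ]
      mm <- merge(males, sc, by = "participant")
      if (nrow(mm) >= 3 && sd(mm$delta_cortisol) > 0 && sd(mm$success) > 0) {
        out$correlations[[paste0("delta_cortisol_x_success_", cond)]] <-
          pearson_corr(mm$delta_cortisol, mm$success)
      }
    }
  }
  out$alpha <- alpha
  out
}

# Filter every table of a study/table list down to a participant subset.
filter_tables <- function(tables, ids) {
  keep <- function(df) {
    if (is.null(df)) return(NULL)
    df[df$participant %in% ids, , drop = FALSE]
  }
  list(
    roster = tables$roster[tables$roster$id %in% ids, , drop = FALSE],
    ratings = keep(tables$ratings),
    saliva = keep(tables$saliva),
    das = keep(tables$das),
    condition_auc = keep(tables$condition_auc),
    pupil = if (is.null(tables$pupil)) NULL else {
      list(samples = keep(tables$pupil$samples),
           events = keep(tables$pupil$events))
    }
  )
}

#' Run the full pipeline
#'
#' Simulates (or loads) a study, preprocesses the pupil data, computes the
#' endocrine/affect summaries and runs the statistical analysis, returning a
#' reconciled run report. Deterministic given the configuration seed.
#'
#' @param config a [study_config()] (used when `input_dir` is `NULL`).
#' @param input_dir directory of study tables from [write_study_tables()];
#'   overrides `config`-driven simulation.
#' @param out_dir optional directory: all intermediate tables and the report
#'   (JSON) are written there as delimited text.
#' @param params [pupil_params()] for the preprocessing stage.
#' @param alpha significance level.
#' @param subset optional named list (e.g.
#'   `list(stress_group = "control")`) restricting the statistical stage to
#'   matching participants.
#' @return A `stressreg_report` list: stage record counts, discard
#'   reconciliation, parameter echo, summaries and statistical output.
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, out_dir = NULL,
                         params = pupil_params(), alpha = 0.05,
                         subset = NULL) {
  if (is.null(config) && is.null(input_dir)) {
    stopf("run_pipeline: need a config (simulation) or an input_dir")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # --- stage 1: obtain data ----------------------------------------------
  if (!is.null(input_dir)) {
    tables <- read_study_tables(input_dir)
    seed <- NA_integer_
  } else {
    study <- simulate_study(config)
    tables <- study[c("roster", "pupil", "saliva", "das", "ratings")]
    seed <- config$seed
    if (!is.null(out_dir)) write_study_tables(study, file.path(out_dir, "input"))
  }
  report <- list(
    package_version = as.character(utils::packageVersion("stressreg")),
    seed = seed,
    alpha = alpha,
    params = params,
    n_participants = nrow(tables$roster),
    stages = list()
  )

  # --- stage 2: pupil preprocessing --------------------------------------
  if (!is.null(tables$pupil) && !is.null(tables$pupil$samples) &&
      nrow(tables$pupil$samples) > 0) {
    pp <- preprocess_pupil(tables$pupil$samples, tables$pupil$events, params)
    tables$condition_auc <- pp$condition_auc
    reasons <- table(factor(pp$trials$discard_reason,
                            levels = c("none", "out_of_range", "long_gap",
                                       "too_short")))
    report$stages$pupil <- list(
      n_trials = nrow(pp$trials),
      n_valid = sum(pp$trials$status == "valid"),
      discarded_by_reason = as.list(reasons[names(reasons) != "none"]),
      ln_shift = attr(pp$condition_auc, "ln_shift")
    )
    stopifnot(report$stages$pupil$n_valid +
                sum(unlist(report$stages$pupil$discarded_by_reason)) ==
                report$stages$pupil$n_trials)
    if (!is.null(out_dir)) {
      utils::write.table(pp$trials, file.path(out_dir, "pupil_trials_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pp$condition_auc,
                         file.path(out_dir, "condition_aucg.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- stage 3: endocrine / affect summaries -----------------------------
  if (!is.null(tables$saliva) && nrow(tables$saliva) > 0) {
    deltas <- saliva_delta_table(tables$saliva, das = tables$das,
                                 roster = tables$roster)
    summ <- group_summary(deltas)
    report$deltas_summary <- summ
    report$summary_t <- summary_t_tests(summ)
    report$stages$summarize <- list(n_participants = nrow(deltas))
    if (!is.null(out_dir)) {
      utils::write.table(deltas, file.path(out_dir, "deltas.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summ, file.path(out_dir, "delta_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- stage 4: statistics ----------------------------------------------
  stat_tables <- tables
  if (!is.null(subset)) {
    ids <- tables$roster$id
    for (field in names(subset)) {
      ids <- intersect(ids, tables$roster$id[tables$roster[[field]] %in%
                                               subset[[field]]])
    }
    if (length(ids) == 0) stopf("run_pipeline: empty participant subset")
    stat_tables <- filter_tables(tables, ids)
    report$subset <- subset
    report$n_participants_analyzed <- length(ids)
  } else {
    report$n_participants_analyzed <- nrow(tables$roster)
  }
  report$stats <- analyze_study(stat_tables, alpha = alpha)

  if (!is.null(out_dir)) {
    writable <- report
    writable$stats$anova <- lapply(report$stats$anova, as.data.frame)
    jsonlite::write_json(writable, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  class(report) <- "stressreg_report"
  report
}

#' Re-run the statistical stage on a participant subset
#'
#' Same pipeline on the participants matched by `selector` (e.g. only the
#' control group, in which case the stress factor drops out of the ANOVA
#' model automatically).
#'
#' @param config a [study_config()].
#' @param selector named list of group filters, e.g.
#'   `list(stress_group = "control")` or `list(hormone_group = "MALE")`.
#' @param ... passed to [run_pipeline()].
#' @return A `stressreg_report`.
#' @export
subset_analysis <- function(config, selector, ...) {
  run_pipeline(config = config, subset = selector, ...)
}

#' @export
print.stressreg_report <- function(x, ...) {
  cat("<stressreg_report> seed", x$seed, "-",
      x$n_participants, "participants (",
      x$n_participants_analyzed, "analyzed )\n")
  if (!is.null(x$stages$pupil)) {
    cat(sprintf("pupil: %d/%d trials valid\n",
                x$stages$pupil$n_valid, x$stages$pupil$n_trials))
  }
  for (nm in names(x$stats$anova)) {
    if (is.null(x$stats$anova[[nm]])) next
    cat("\n==", nm, "==\n")
    print(x$stats$anova[[nm]])
  }
  if (length(x$stats$notes)) {
    cat("\nnotes:\n")
    for (n in x$stats$notes) cat(" -", n, "\n")
  }
  invisible(x)
}
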