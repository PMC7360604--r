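# Endocrine and affect summaries: baseline-to-peak deltas, DAS negative
# affect scores, and t tests computed from published summary statistics.

#' Baseline-to-peak response delta
#'
#' The stress-response magnitude of an analyte time course: the maximum over
#' all post-baseline samples minus the baseline sample (signed — negative if
#' every post-baseline value lies below baseline). A fixed-timepoint variant
#' is available via `peak_at`.
#'
#' @param values analyte concentrations, baseline first.
#' @param timepoints optional labels aligned with `values`; the first is
#'   treated as baseline unless a `"baseline"` label is present.
#' @param peak_at optional timepoint label: use that sample as the peak
#'   instead of the post-baseline maximum.
#' @return The delta, in the analyte's units.
#' @export
delta_response <- function(values, timepoints = NULL, peak_at = NULL) {
  if (!is.null(timepoints)) {
    if (length(timepoints) != length(values)) {
      stopf("delta_response: 'timepoints' and 'values' lengths differ")
    }
    b <- if ("baseline" %in% timepoints) which(timepoints == "baseline")[1] else 1L
  } else {
    b <- 1L
  }
  baseline <- values[b]
  if (is.na(baseline)) stopf("delta_response: missing baseline sample")
  post <- values[-b]
  if (!is.null(peak_at)) {
    if (is.null(timepoints) || !peak_at %in% timepoints) {
      stopf("delta_response: peak timepoint '%s' not found", peak_at)
    }
    return(values[which(timepoints == peak_at)[1]] - baseline)
  }
  post <- post[!is.na(post)]
  if (length(post) == 0) stopf("delta_response: no post-baseline samples")
  max(post) - baseline
}

#' DAS negative-affect summary score
#'
#' Mean of the seven negative affect factors of the Differential Affect Scale
#' (sadness, anger, disgust, contempt, fear, shame, guilt; 1–5 scale);
#' positive factors are ignored.
#'
#' @param factors named numeric vector or one-row data frame of factor values.
#' @return Negative-affect score in \[1, 5\].
#' @export
das_negative_affect <- function(factors) {
  factors <- unlist(factors)
  needed <- das_negative_factors()
  missing_f <- setdiff(needed, names(factors))
  if (length(missing_f)) {
    stopf("das_negative_affect: missing factor(s): %s",
          paste(missing_f, collapse = ", "))
  }
  vals <- as.numeric(factors[needed])
  if (any(is.na(vals))) {
    stopf("das_negative_affect: missing factor(s): %s",
          paste(needed[is.na(vals)], collapse = ", "))
  }
  mean(vals)
}

#' Welch t statistic from group summary statistics
#'
#' Two-sample t statistic computed from per-group mean, SEM and (optionally)
#' n: `t = (m_a - m_b) / sqrt(sem_a^2 + sem_b^2)`, with Welch–Satterthwaite
#' degrees of freedom when both ns are supplied. Sign convention: first group
#' minus second.
#'
#' @param a,b lists or named vectors with `mean`, `sem` and optionally `n`.
#' @return List with `t` and `df` (`df` is `NA` when either n is missing).
#' @export
welch_t_from_summary <- function(a, b) {
  a <- as.list(a)
  b <- as.list(b)
  if ((a$sem %||% NA) == 0 && (b$sem %||% NA) == 0) {
    stopf("welch_t_from_summary: both SEMs are zero; t undefined")
  }
  se2 <- a$sem^2 + b$sem^2
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- NA_real_
  if (!is.null(a$n) && !is.null(b$n) && !is.na(a$n) && !is.na(b$n)) {
    df <- se2^2 / (a$sem^4 / (a$n - 1) + b$sem^4 / (b$n - 1))
  }
  list(t = t, df = df)
}

#' Per-participant endocrine and affect deltas
#'
#' Computes baseline-to-peak deltas for cortisol, alpha-amylase and DAS
#' negative affect from the study tables.
#'
#' @param saliva saliva table (`participant, timepoint, cortisol_nmoll,
#'   saa_ul`).
#' @param das DAS table (`participant, timepoint`, factor columns); optional.
#' @param roster participant roster (adds group columns when given).
#' @return Data frame with one row per participant: `delta_cortisol`,
#'   `delta_saa` and (if `das` given) `delta_das`.
#' @export
saliva_delta_table <- function(saliva, das = NULL, roster = NULL) {
  ids <- unique(saliva$participant)
  rows <- lapply(ids, function(pid) {
    s <- saliva[saliva$participant == pid, ]
    data.frame(
      participant = pid,
      delta_cortisol = delta_response(s$cortisol_nmoll, s$timepoint),
      delta_saa = delta_response(s$saa_ul, s$timepoint),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(das)) {
    neg <- vapply(ids, function(pid) {
      d <- das[das$participant == pid, ]
      scores <- vapply(seq_len(nrow(d)), function(i) {
        das_negative_affect(d[i, das_negative_factors()])
      }, 0)
      delta_response(scores, d$timepoint)
    }, 0)
    out$delta_das <- neg[match(out$participant, ids)]
  }
  if (!is.null(roster)) {
    out <- merge(roster, out, by.x = "id", by.y = "participant")
    names(out)[names(out) == "id"] <- "participant"
  }
  out
}

#' Group summary table (mean, SEM, n) of delta responses
#'
#' Mirrors the familiar "baseline-to-peak differences per stress x hormone
#' cell" table layout.
#'
#' @param deltas output of [saliva_delta_table()] including group columns.
#' @param variables delta columns to summarise.
#' @return Long data frame: `stress_group, hormone_group, variable, mean,
#'   sem, n`.
#' @export
group_summary <- function(deltas,
                          variables = intersect(
                            c("delta_cortisol", "delta_saa", "delta_das"),
                            names(deltas))) {
  rows <- list()
  for (sg in unique(deltas$stress_group)) {
    for (hg in unique(deltas$hormone_group)) {
      cell <- deltas[deltas$stress_group == sg & deltas$hormone_group == hg, ]
      for (v in variables) {
        x <- cell[[v]]
        x <- x[!is.na(x)]
        rows[[length(rows) + 1L]] <- data.frame(
          stress_group = sg, hormone_group = hg, variable = v,
          mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Published stress-response summary cells
#'
#' The printed group summary (mean ± SEM of baseline-to-peak deltas per
#' stress x hormone cell) used as input to [welch_t_from_summary()]: cortisol
#' (nmol/l), alpha-amylase (U/l) and DAS negative affect.
#'
#' @return Data frame with `stress_group, hormone_group, variable, mean, sem`.
#' @export
reference_delta_summary <- function() {
  data.frame(
    stress_group = rep(c("stress", "control"), each = 9),
    hormone_group = rep(rep(c("MALE", "FELU", "FEOC"), each = 3), 2),
    variable = rep(c("delta_cortisol", "delta_saa", "delta_das"), 6),
    mean = c(13.96, 115.98, 0.51,
             4.55, 102.85, 0.60,
             4.48, 116.92, 0.35,
             -1.61, 22.86, -0.12,
             -0.43, -1.91, -0.13,
             -1.01, 67.84, -0.07),
    sem = c(1.87, 21.29, 0.13,
            1.06, 26.51, 0.14,
            1.07, 26.64, 0.09,
            1.82, 12.29, 0.13,
            1.34, 25.84, 0.14,
            1.16, 27.34, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Stress-vs-control t statistics per hormone group from summary cells
#'
#' Applies [welch_t_from_summary()] with the (control, stress) argument order
#' to each hormone group and variable of a summary table, so a positive
#' stress response yields a negative t.
#'
#' @param summary a table in the [reference_delta_summary()] layout.
#' @return Data frame `hormone_group, variable, t, df`.
#' @export
summary_t_tests <- function(summary = reference_delta_summary()) {
  rows <- list()
  for (hg in unique(summary$hormone_group)) {
    for (v in unique(summary$variable)) {
      ctrl <- summary[summary$stress_group == "control" &
                        summary$hormone_group == hg & summary$variable == v, ]
      strs <- summary[summary$stress_group == "stress" &
                        summary$hormone_group == hg & summary$variable == v, ]
      if (nrow(ctrl) != 1 || nrow(strs) != 1) next
      res <- welch_t_from_summary(
        list(mean = ctrl$mean, sem = ctrl$sem, n = ctrl$n %||% NULL),
        list(mean = strs$mean, sem = strs$sem, n = strs$n %||% NULL)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        hormone_group = hg, variable = v, t = res$t, df = res$df,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
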