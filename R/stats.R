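# Post-hoc contrasts, assumption checks, correlations and difference scores.

# Welch two-sample t on raw values; degenerate inputs (zero variance and zero
# mean difference) yield t = 0, p = 1 rather than an error.
welch_t_raw <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- var(x)
  vy <- var(y)
  se2 <- vx / nx + vy / ny
  num <- mean(x) - mean(y)
  if (se2 == 0) {
    if (num == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(num) * Inf, df = nx + ny - 2, p = 0))
  }
  t <- num / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

paired_t_raw <- function(x, y) {
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

#' Bonferroni-corrected post-hoc t tests
#'
#' Runs the family of pairwise contrasts and multiplies each raw p-value by
#' the family size (capped at 1). Between-group contrasts use Welch's
#' unequal-variance t; within-subject contrasts use a paired t on
#' subject-aligned values.
#'
#' @param cells named list of numeric vectors (for paired contrasts the two
#'   vectors must be aligned by subject and of equal length).
#' @param family list of contrasts, each a list with `a` and `b` (cell
#'   names), optional `label`, and `paired` (default `FALSE`).
#' @param alpha family-wise significance level (default 0.05).
#' @return Data frame with `contrast`, `t`, `df`, `p_raw`, `p_bonferroni`,
#'   `alpha_adjusted` (`alpha / m`); contrasts with fewer than 2 observations
#'   in a cell are skipped with a warning.
#' @export
bonferroni_posthoc <- function(cells, family, alpha = 0.05) {
  if (length(family) == 0) stopf("bonferroni_posthoc: empty contrast family")
  m <- length(family)
  rows <- list()
  for (ct in family) {
    label <- ct$label %||% paste(ct$a, "vs", ct$b)
    x <- cells[[ct$a]]
    y <- cells[[ct$b]]
    paired <- isTRUE(ct$paired)
    if (paired) {
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]
      y <- y[keep]
    } else {
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
    }
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("bonferroni_posthoc: skipping '%s' (cell with n < 2)", label))
      next
    }
    res <- if (paired) paired_t_raw(x, y) else welch_t_raw(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = label, paired = paired, t = res$t, df = res$df,
      p_raw = res$p, p_bonferroni = min(1, m * res$p),
      alpha_adjusted = alpha / m, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(contrast = character(0), paired = logical(0),
                      t = numeric(0), df = numeric(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), alpha_adjusted = numeric(0)))
  }
  do.call(rbind, rows)
}

# Lilliefors-style Kolmogorov-Smirnov statistic: sup distance between the
# sample ECDF and the normal with estimated mean/sd.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- (sort(x) - mean(x)) / sd(x)
  p_hat <- stats::pnorm(z)
  max(seq_len(n) / n - p_hat, p_hat - (seq_len(n) - 1) / n)
}

#' Normality (Lilliefors-corrected KS) and variance-homogeneity checks
#'
#' Kolmogorov-Smirnov normality test with parameters estimated from the data;
#' the null distribution of the statistic is obtained by Monte Carlo (the
#' naive KS p-value is badly conservative with estimated parameters). When
#' `groups` is supplied, Levene's test (centre = mean) of variance
#' homogeneity is run across cells. A log-transform is recommended when
#' normality is rejected at `alpha`; if values are not all positive a shift
#' is flagged as required.
#'
#' @param x numeric values.
#' @param groups optional cell labels for Levene's test.
#' @param alpha significance level (default 0.05).
#' @param n_mc Monte Carlo replicates for the KS null (default 1000).
#' @param mc_seed internal seed making the Monte Carlo p-value reproducible.
#' @return List: `ks_stat`, `ks_p`, `levene_F`, `levene_p`,
#'   `log_transform_recommended`, `shift_required`, `n`.
#' @export
assumption_checks <- function(x, groups = NULL, alpha = 0.05, n_mc = 1000,
                              mc_seed = 42L) {
  x_ok <- x[!is.na(x)]
  n <- length(x_ok)
  if (n < 4) stopf("assumption_checks: need at least 4 observations")
  d_obs <- lilliefors_stat(x_ok)
  d_null <- with_seed(mc_seed, {
    vapply(seq_len(n_mc), function(i) lilliefors_stat(rnorm(n)), 0)
  })
  ks_p <- (sum(d_null >= d_obs) + 1) / (n_mc + 1)

  levene_F <- NA_real_
  levene_p <- NA_real_
  if (!is.null(groups)) {
    g <- factor(groups[!is.na(x)])
    z <- abs(x_ok - ave(x_ok, g))
    gm <- mean(z)
    ssb <- sum(tapply(z, g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum((z - ave(z, g))^2)
    df1 <- nlevels(g) - 1
    df2 <- n - nlevels(g)
    if (ssw == 0) {
      levene_F <- 0
      levene_p <- 1
    } else {
      levene_F <- (ssb / df1) / (ssw / df2)
      levene_p <- pf(levene_F, df1, df2, lower.tail = FALSE)
    }
  }
  reject <- ks_p < alpha
  list(ks_stat = d_obs, ks_p = ks_p, levene_F = levene_F, levene_p = levene_p,
       log_transform_recommended = reject && all(x_ok > 0),
       shift_required = reject && any(x_ok <= 0), n = n)
}

#' Pearson product-moment correlation
#'
#' Pearson r with the two-sided t-approximation p-value, on complete pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("pearson_corr: length mismatch")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("pearson_corr: need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stopf("pearson_corr: zero variance; correlation undefined")
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Difference scores against a reference within-subject condition
#'
#' Per participant, subtracts the reference-condition value from each other
#' condition's value and removes the reference level, producing a long table
#' ready for a difference-score ANOVA (a robustness check that systematic
#' differences in the reference condition do not drive condition effects).
#' Participants missing the reference value are dropped with a warning.
#'
#' @param data long table with subject, within-factor and value columns.
#' @param dv value column name.
#' @param reference reference condition (default `"view_negative"`).
#' @param within,subject column names.
#' @return Long data frame like `data` without the reference level, values
#'   replaced by differences.
#' @export
difference_scores <- function(data, dv, reference = "view_negative",
                              within = "condition", subject = "participant") {
  if (!reference %in% data[[within]]) {
    stopf("difference_scores: reference level '%s' not present", reference)
  }
  ref <- data[data[[within]] == reference, c(subject, dv)]
  names(ref)[2] <- ".ref"
  out <- data[data[[within]] != reference, , drop = FALSE]
  idx <- match(out[[subject]], ref[[subject]])
  dropped <- unique(out[[subject]][is.na(idx)])
  if (length(dropped)) {
    warning(sprintf("difference_scores: dropping %d participant(s) without a reference value",
                    length(dropped)))
    out <- out[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  out[[dv]] <- out[[dv]] - ref$.ref[idx]
  rownames(out) <- NULL
  out
}
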