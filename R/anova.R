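# Mixed-design (split-plot) repeated-measures ANOVA with Greenhouse-Geisser
# correction, Mauchly's sphericity test and partial eta squared.
#
# The decomposition follows the classical univariate approach: the
# between-subjects stratum is the ANOVA of sqrt(k)-scaled participant means;
# the within stratum projects each participant's k within-level scores onto
# an orthonormal contrast basis and accumulates Type III sums of squares
# (sum-to-zero coding, marginal SS) across contrast variates, so unbalanced
# between-subject cells are handled the way SPSS-style GLM does.

# Type III sums of squares for every term of X (columns grouped by `assign`;
# 0 = intercept), via the general-linear-hypothesis form
# SS(term) = b' [ (X'X)^{-1}_{term,term} ]^{-1} b.
type3_ss <- function(X, y, assign) {
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  ss <- vapply(unique(assign), function(tt) {
    idx <- which(assign == tt)
    b <- beta[idx]
    drop(crossprod(b, solve(XtXi[idx, idx, drop = FALSE], b)))
  }, 0)
  names(ss) <- as.character(unique(assign))
  list(ss = ss, rss = sum(res^2), residuals = res,
       df_res = nrow(X) - ncol(X))
}

# Sum-to-zero between-subjects design matrix for the given factors (full
# factorial). Returns the matrix, term labels, and per-column term assignment.
between_design <- function(bdat, between) {
  if (length(between) == 0) {
    X <- matrix(1, nrow(bdat), 1)
    return(list(X = X, assign = 0L, labels = character(0)))
  }
  for (b in between) bdat[[b]] <- factor(bdat[[b]])
  f <- as.formula(paste("~", paste(between, collapse = " * ")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- model.matrix(f, data = bdat)
  list(X = X, assign = attr(X, "assign"),
       labels = attr(terms(f), "term.labels"))
}

# Orthonormal basis of the space orthogonal to the unit vector (k x (k-1)).
orthonormal_contrasts <- function(k) {
  qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
}

#' Greenhouse-Geisser epsilon from a within-level covariance matrix
#'
#' Epsilon-hat computed from the double-centred k x k covariance of the
#' within-level scores, clipped to its admissible range
#' `[1/(k-1), 1]`.
#'
#' @param within_cov k x k sample covariance matrix of the within-level
#'   scores (k >= 2, from >= 2 participants).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(within_cov) {
  within_cov <- as.matrix(within_cov)
  k <- nrow(within_cov)
  if (k < 2 || ncol(within_cov) != k) {
    stopf("gg_epsilon: 'within_cov' must be a square matrix with k >= 2")
  }
  lower <- 1 / (k - 1)
  C <- diag(k) - 1 / k
  D <- C %*% within_cov %*% C
  denom <- (k - 1) * sum(D^2)
  if (!is.finite(denom) || denom <= 0) {
    warning("gg_epsilon: degenerate covariance; returning lower bound")
    return(lower)
  }
  eps <- sum(diag(D))^2 / denom
  min(max(eps, lower), 1)
}

#' Mauchly's test of sphericity
#'
#' Likelihood-ratio test that the covariance of orthonormal contrasts of the
#' within-level scores is spherical, with the standard chi-square
#' approximation. Not applicable for k < 3 (sphericity cannot be violated
#' with two levels).
#'
#' @param within_cov k x k covariance matrix of within-level scores.
#' @param n effective sample size behind the covariance (error degrees of
#'   freedom + 1; the participant count for a single group).
#' @return List with `W`, `p`, `df` (all `NA` with `applicable = FALSE` when
#'   k < 3).
#' @export
mauchly_test <- function(within_cov, n) {
  within_cov <- as.matrix(within_cov)
  k <- nrow(within_cov)
  if (k < 3) {
    return(list(W = NA_real_, p = NA_real_, df = NA_real_, applicable = FALSE))
  }
  M <- orthonormal_contrasts(k)
  S <- t(M) %*% within_cov %*% M
  p_ <- k - 1
  W <- det(S) / (sum(diag(S)) / p_)^p_
  W <- min(max(W, .Machine$double.xmin), 1)
  d <- (n - 1) - (2 * p_^2 + p_ + 2) / (6 * p_)
  chisq <- -d * log(W)
  df <- p_ * (p_ + 1) / 2 - 1
  list(W = W, p = pchisq(chisq, df, lower.tail = FALSE), df = df,
       applicable = TRUE)
}

#' Mixed-design repeated-measures ANOVA
#'
#' Split-plot decomposition for one within-subject factor crossed with up to
#' two (or zero) between-subject factors: between-subject main effects and
#' interaction are tested against the between-subjects error; the within main
#' effect and its interactions with the between factors against the within
#' error. Greenhouse-Geisser epsilon, Mauchly's W and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) are reported for every effect;
#' GG-corrected dfs/p-values apply to all within-involved effects.
#'
#' Participants missing any within level are dropped listwise with a warning.
#' Between factors with fewer than two observed levels are dropped from the
#' model (e.g. a control-only subset removes the stress factor).
#'
#' @param data long-format data frame.
#' @param dv name of the value column.
#' @param within name of the within-subject factor column.
#' @param between character vector of between-subject factor columns.
#' @param subject name of the participant id column.
#' @param gg_policy `"mauchly"` (default: report GG-corrected p as the
#'   headline p when Mauchly rejects at 0.05), `"always"`, or `"never"`.
#' @return A `stressreg_anova` data frame: one row per effect with `ss`,
#'   `ss_error`, `df1`, `df2`, `F`, `p`, `epsilon`, `df1_gg`, `df2_gg`,
#'   `p_gg`, `pes` (partial eta squared) and `p_reported`; Mauchly results
#'   and the dropped-participant count are attached as attributes.
#' @export
mixed_anova <- function(data, dv, within = "condition",
                        between = c("stress_group", "hormone_group"),
                        subject = "participant",
                        gg_policy = c("mauchly", "always", "never")) {
  gg_policy <- match.arg(gg_policy)
  for (col in c(dv, within, subject)) {
    if (!col %in% names(data)) stopf("mixed_anova: column '%s' not found", col)
  }
  between <- between[between %in% names(data)]
  data <- data[!is.na(data[[dv]]), ]

  lev <- unique(as.character(data[[within]]))
  if (all(lev %in% er_conditions())) {
    lev <- er_conditions()[er_conditions() %in% lev]
  } else {
    lev <- sort(lev)
  }
  k <- length(lev)
  if (k < 2) stopf("mixed_anova: within factor needs >= 2 levels")

  ids <- unique(as.character(data[[subject]]))
  Y <- matrix(NA_real_, length(ids), k, dimnames = list(ids, lev))
  Y[cbind(match(as.character(data[[subject]]), ids),
          match(as.character(data[[within]]), lev))] <- data[[dv]]
  complete <- rowSums(is.na(Y)) == 0
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    warning(sprintf("mixed_anova: dropping %d participant(s) with incomplete within-factor data",
                    n_dropped))
  }
  Y <- Y[complete, , drop = FALSE]
  ids <- rownames(Y)
  n <- nrow(Y)
  if (n < 4) stopf("mixed_anova: too few complete participants (%d)", n)

  bdat <- unique(data[, c(subject, between), drop = FALSE])
  bdat <- bdat[match(ids, as.character(bdat[[subject]])), , drop = FALSE]
  # drop single-level between factors (e.g. after subsetting)
  keep_b <- vapply(between, function(b) length(unique(bdat[[b]])) >= 2, TRUE)
  between <- between[keep_b]
  if (length(between)) {
    cell <- interaction(bdat[between], drop = TRUE)
    if (any(table(cell) < 2)) stopf("mixed_anova: a between-subjects cell has fewer than 2 participants")
  }
  des <- between_design(bdat, between)
  X <- des$X
  g <- ncol(X)            # number of between-cell parameters

  # --- between-subjects stratum: ANOVA of sqrt(k) * participant means -----
  u <- sqrt(k) * rowMeans(Y)
  fit_b <- type3_ss(X, u, des$assign)
  ss_err_b <- fit_b$rss
  df_err_b <- n - g

  # --- within stratum: orthonormal contrast variates ----------------------
  M <- orthonormal_contrasts(k)
  Z <- Y %*% M
  term_ids <- unique(des$assign)
  ss_w <- setNames(numeric(length(term_ids)), as.character(term_ids))
  rss_w <- 0
  R <- matrix(0, n, k - 1)
  for (j in seq_len(k - 1)) {
    fit_j <- type3_ss(X, Z[, j], des$assign)
    ss_w <- ss_w + fit_j$ss[names(ss_w)]
    rss_w <- rss_w + fit_j$rss
    R[, j] <- fit_j$residuals
  }
  df_err_w <- (k - 1) * (n - g)

  # pooled error covariance of contrast variates -> epsilon & Mauchly
  S <- crossprod(R) / (n - g)
  eps <- sum(diag(S))^2 / ((k - 1) * sum(S^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  if (k == 2) eps <- 1
  mau <- if (k >= 3) {
    p_ <- k - 1
    W <- det(S) / (sum(diag(S)) / p_)^p_
    W <- min(max(W, .Machine$double.xmin), 1)
    d <- (n - g) - (2 * p_^2 + p_ + 2) / (6 * p_)
    df_m <- p_ * (p_ + 1) / 2 - 1
    list(W = W, p = pchisq(-d * log(W), df_m, lower.tail = FALSE),
         df = df_m, applicable = TRUE)
  } else {
    list(W = NA_real_, p = NA_real_, df = NA_real_, applicable = FALSE)
  }

  term_df <- vapply(term_ids, function(tt) sum(des$assign == tt), 0L)
  names(term_df) <- as.character(term_ids)

  rows <- list()
  add_row <- function(effect, ss, df1, ss_err, df2, stratum) {
    mse <- ss_err / df2
    Fv <- (ss / df1) / mse
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
    within_involved <- stratum == "within"
    e <- if (within_involved) eps else NA_real_
    df1_gg <- if (within_involved) df1 * eps else df1
    df2_gg <- if (within_involved) df2 * eps else df2
    p_gg <- if (within_involved) pf(Fv, df1_gg, df2_gg, lower.tail = FALSE) else p
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, stratum = stratum, ss = ss, ss_error = ss_err,
      df1 = df1, df2 = df2, F = Fv, p = p, epsilon = e,
      df1_gg = df1_gg, df2_gg = df2_gg, p_gg = p_gg,
      pes = ss / (ss + ss_err), stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(des$labels)) {
    tid <- as.character(i)
    add_row(des$labels[i], fit_b$ss[[tid]], term_df[[tid]],
            ss_err_b, df_err_b, "between")
  }
  add_row(within, ss_w[["0"]], k - 1, rss_w, df_err_w, "within")
  for (i in seq_along(des$labels)) {
    tid <- as.character(i)
    add_row(paste(des$labels[i], within, sep = ":"),
            ss_w[[tid]], (k - 1) * term_df[[tid]], rss_w, df_err_w, "within")
  }
  tab <- do.call(rbind, rows)

  sphericity_violated <- isTRUE(mau$applicable) && !is.na(mau$p) && mau$p < 0.05
  apply_gg <- switch(gg_policy,
                     always = TRUE,
                     never = FALSE,
                     mauchly = sphericity_violated)
  tab$p_reported <- ifelse(tab$stratum == "within" & apply_gg, tab$p_gg, tab$p)

  attr(tab, "mauchly") <- mau
  attr(tab, "epsilon") <- eps
  attr(tab, "sphericity_violated") <- sphericity_violated
  attr(tab, "gg_applied") <- apply_gg
  attr(tab, "n_subjects") <- n
  attr(tab, "n_dropped") <- n_dropped
  attr(tab, "within_levels") <- lev
  class(tab) <- c("stressreg_anova", "data.frame")
  tab
}

#' @export
print.stressreg_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA (%d participants, %d dropped; GG %s)\n",
              attr(x, "n_subjects"), attr(x, "n_dropped"),
              if (attr(x, "gg_applied")) "applied" else "not applied"))
  mau <- attr(x, "mauchly")
  if (isTRUE(mau$applicable)) {
    cat(sprintf("Mauchly W = %.4f, p = %.4g (epsilon = %.4f)\n",
                mau$W, mau$p, attr(x, "epsilon")))
  }
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 5)
  df$ss_error <- signif(df$ss_error, 5)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  df$p_reported <- signif(df$p_reported, 3)
  df$pes <- round(df$pes, 3)
  print(df[, c("effect", "df1", "df2", "F", "p", "p_reported", "pes")],
        row.names = FALSE)
  invisible(x)
}
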