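# Independent oracles and shared fixtures. Everything here is deliberately
# written without reusing package internals (loops instead of vectorised
# code), so agreement is meaningful.

DT_MS <- 1000 / 30

# Hand-checkable 10-sample trace: gently varying around 4 mm with a single
# 3 mm spike at sample 6. Small jitter keeps the speed MAD strictly positive
# (on an exactly flat trace the MAD is zero and nothing may be flagged).
toy_trace_values <- function() {
  c(4.00, 4.02, 3.98, 4.01, 3.99, 7.00, 4.02, 3.98, 4.00, 4.01)
}
toy_trace_times <- function() (0:9) * DT_MS

# Brute-force dilation speeds: larger absolute slope towards adjacent
# non-missing neighbours, mm/s.
brute_speeds <- function(t, x) {
  n <- length(x)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    cand <- c()
    if (i > 1 && !is.na(x[i - 1])) {
      cand <- c(cand, abs(x[i] - x[i - 1]) / (t[i] - t[i - 1]) * 1000)
    }
    if (i < n && !is.na(x[i + 1])) {
      cand <- c(cand, abs(x[i + 1] - x[i]) / (t[i + 1] - t[i]) * 1000)
    }
    if (length(cand)) d[i] <- max(cand)
  }
  d
}

brute_mad_threshold <- function(d, k) {
  dd <- sort(d[!is.na(d)])
  med <- stats::median(dd)
  mad_raw <- stats::median(abs(dd - med))
  med + k * mad_raw
}

# Brute-force trapezoid on an explicit (t, x) polyline, over [a, b] (ms),
# interpolating the edge values; returns mm*s.
brute_trapezoid <- function(t, x, a, b) {
  grid <- sort(unique(c(t[t > a & t < b], a, b)))
  vals <- stats::approx(t, x, xout = grid)$y
  total <- 0
  for (i in seq_len(length(grid) - 1)) {
    total <- total + (grid[i + 1] - grid[i]) * (vals[i] + vals[i + 1]) / 2
  }
  total / 1000
}

# Split-plot RM-ANOVA oracle via stats::aov with an Error() stratum; valid
# for balanced designs (where Type I == Type III). Returns per-effect SS/df/F.
aov_mixed_oracle <- function(data, dv, within, between, subject) {
  data[[within]] <- factor(data[[within]])
  data[[subject]] <- factor(data[[subject]])
  for (b in between) data[[b]] <- factor(data[[b]])
  rhs <- paste(c(paste(between, collapse = "*"), within), collapse = "*")
  if (length(between) == 0) rhs <- within
  f <- stats::as.formula(paste(dv, "~", rhs,
                               "+ Error(", subject, "/", within, ")"))
  fit <- summary(stats::aov(f, data = data))
  tabs <- lapply(fit, function(s) as.data.frame(s[[1]]))
  out <- list()
  for (tb in tabs) {
    rn <- trimws(rownames(tb))
    err <- tb[rn == "Residuals", , drop = FALSE]
    for (i in which(rn != "Residuals")) {
      out[[rn[i]]] <- list(ss = tb[i, "Sum Sq"], df1 = tb[i, "Df"],
                           ss_error = err[1, "Sum Sq"], df2 = err[1, "Df"],
                           F = tb[i, "F value"], p = tb[i, "Pr(>F)"])
    }
  }
  out
}

# Literal single-group fixture with frozen reference values computed once
# with an independent implementation (pingouin 0.6.1: rm_anova, sphericity,
# epsilon) during development.
rm_fixture <- function() {
  Y <- matrix(c(5.1, 6.3, 7.0, 6.1,
                4.2, 5.9, 6.8, 5.0,
                5.5, 5.2, 7.7, 6.6,
                3.9, 6.1, 6.0, 5.8,
                6.0, 7.2, 8.1, 7.4,
                4.8, 5.5, 6.9, 5.2,
                5.3, 6.8, 7.3, 6.9,
                4.6, 5.0, 6.2, 5.5),
              nrow = 8, byrow = TRUE)
  data.frame(
    participant = rep(paste0("S", 1:8), times = 4),
    cond = rep(paste0("c", 1:4), each = 8),
    y = as.vector(Y)
  )
}

rm_fixture_reference <- function() {
  list(ss = 17.2759375, ss_error = 4.0215625,
       F = 30.070790271194, p = 8.623237183515e-08,
       p_gg = 1.486991715535e-05,
       epsilon = 0.626931827330, W = 0.252193149919)
}

# Tiny study configs used across tests.
tiny_config <- function(seed = 1, ...) {
  study_config(n_per_cell = 2, seed = seed, ...)
}

# A small balanced 2x2x(3) integer-valued design (deterministic literal).
toy_mixed_data <- function() {
  set.seed(20240901)
  n <- 4
  subj <- paste0("S", 1:(n * 4))
  grp <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                     stringsAsFactors = FALSE)[rep(1:4, each = n), ]
  d <- expand.grid(participant = subj, cond = c("c1", "c2", "c3"),
                   stringsAsFactors = FALSE)
  idx <- match(d$participant, subj)
  d$A <- grp$A[idx]
  d$B <- grp$B[idx]
  d$y <- as.numeric(sample(1:20, nrow(d), replace = TRUE))
  d
}
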