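# Internal helpers: seeded RNG scoping and argument checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps all package-level randomness insulated
# from (and invisible to) user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  expr
}

# Deterministic sub-seed for participant `i`, table `table_code` (1..5), from a
# top-level seed. Stays below 2^31 - 1; unique per (seed mod 1e5, i, code) for
# i < 10,000 and code < 10.
sub_seed <- function(seed, i, table_code) {
  (as.integer(seed) %% 100000L) * 100000L + i * 10L + table_code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stopf("configuration error: '%s' must be a number in [%s, %s]",
          name, format(lo), format(hi))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
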