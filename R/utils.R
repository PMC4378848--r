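# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# argument checkers; `name` appears verbatim in the error so callers can see
# which field of a spec was violated
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower))
    stopf("`%s` must be %s %s (got %g)", name,
          if (strict_lower) ">" else ">=", format(lower), x)
  if (x > upper || (strict_upper && x >= upper))
    stopf("`%s` must be %s %s (got %g)", name,
          if (strict_upper) "<" else "<=", format(upper), x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stopf("`%s` must be a single integer", name)
  if (x < lower) stopf("`%s` must be >= %d (got %d)", name, lower, as.integer(x))
  invisible(as.integer(x))
}

# evaluate `code` with a fixed RNG stream, restoring caller RNG state after;
# all generator randomness flows through this (no global state leaks)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# centered moving average preserving length (shrinking window at edges)
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# OLS slope + intercept + R^2, returned as a list (avoids lm() overhead in
# tight loops and keeps the regression explicit)
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stopf("degenerate regression: no spread in x")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# shift a matrix by (di, dj) padding with `fill`
shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr); rj <- seq_len(nc)
  si <- ri - di; sj <- rj - dj
  keep_i <- si >= 1 & si <= nr
  keep_j <- sj >= 1 & sj <= nc
  out[ri[keep_i], rj[keep_j]] <- m[si[keep_i], sj[keep_j]]
  out
}

# shift with edge replication (clamped indices); for derivative stencils,
# where zero padding would fabricate boundary structure
shift_mat_rep <- function(m, di, dj) {
  si <- pmin(pmax(seq_len(nrow(m)) - di, 1L), nrow(m))
  sj <- pmin(pmax(seq_len(ncol(m)) - dj, 1L), ncol(m))
  m[si, sj, drop = FALSE]
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
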