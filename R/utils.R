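#' @keywords internal
"_PACKAGE"

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
# All generators are pure functions of (config, seed); they must not disturb
# the global RNG stream.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

# Centered rolling mean / sd over a window of `k` points (k odd recommended).
# NA-padded at the edges. O(n) via cumulative sums.
roll_mean <- function(x, k) {
  n <- length(x)
  if (k > n) return(rep(NA_real_, n))
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  half <- (k - 1L) %/% 2L
  idx <- seq_len(n - k + 1L)
  means <- (cs[idx + k] - cs[idx]) / k
  out[idx + half] <- means
  out
}

roll_sd <- function(x, k) {
  n <- length(x)
  if (k > n) return(rep(NA_real_, n))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  out <- rep(NA_real_, n)
  half <- (k - 1L) %/% 2L
  idx <- seq_len(n - k + 1L)
  s <- cs[idx + k] - cs[idx]
  s2 <- cs2[idx + k] - cs2[idx]
  v <- (s2 - s^2 / k) / (k - 1)
  v[v < 0] <- 0
  out[idx + half] <- sqrt(v)
  out
}

# Linear interpolation of NA runs no longer than `max_gap` points; longer
# runs (and leading/trailing NAs) stay NA.
fill_gaps <- function(x, max_gap) {
  n <- length(x)
  if (!anyNA(x) || n < 2L) return(x)
  obs <- which(!is.na(x))
  if (length(obs) < 2L) return(x)
  filled <- stats::approx(obs, x[obs], xout = seq_len(n), rule = 1)$y
  # revert runs longer than max_gap
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths > max_gap)) {
    filled[starts[i]:ends[i]] <- NA_real_
  }
  filled
}

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
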