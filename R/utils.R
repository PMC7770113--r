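# Internal helpers shared across modules.

# Reference pressure convention: digital full-scale amplitude 1.0 corresponds to
# 94 dB SPL (1 Pa RMS against p0 = 20 uPa). All dB SPL computations in the
# package go through these two helpers.
FULL_SCALE_DB_SPL <- 94

#' Measure the sound pressure level of a sample vector
#'
#' Computes RMS level in dB SPL under the package's digital-to-pascal
#' convention (full-scale amplitude 1.0 = 94 dB SPL, i.e. 1 Pa RMS).
#'
#' @param samples Numeric vector of dimensionless pressure samples.
#' @return Level in dB SPL (scalar).
#' @export
measureLevel <- function(samples) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  r <- sqrt(mean(samples^2))
  if (r == 0) return(-Inf)
  FULL_SCALE_DB_SPL + 20 * log10(r)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a reproducible child seed (< 2^31) from a master seed and a tag.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_len(nchar(as.character(tag)))) %% 65521
  as.integer(((as.numeric(seed) %% 1048573) * 2039 + h * 31 + 17) %% 2147483629)
}

# Largest-remainder apportionment of n items into parts with given fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Moving average with window k (odd), edges padded by replication.
movingAverage <- function(x, k = 3L) {
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  half <- k %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + n)]
}
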