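# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a per-stream random seed from one global seed
#'
#' One global integer seed drives every stochastic stage through a fixed
#' substream scheme, so adding a stream never perturbs the draws of another.
#' Streams are named; each name maps to a fixed offset. The derived seed is
#' kept within the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stream Stream name, one of `"segments"`, `"expression"`,
#'   `"survival"`, `"mutations"`, `"peptides"`, `"clusters"`, `"resample"`,
#'   `"nmf"`, `"permutation"`.
#' @return An integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stream) {
  offsets <- c(segments = 101L, expression = 211L, survival = 307L,
               mutations = 401L, peptides = 503L, clusters = 601L,
               resample = 701L, nmf = 809L, permutation = 907L)
  if (!stream %in% names(offsets)) stopf("unknown random stream '%s'", stream)
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]]) %% 2147483647)
}

# Round half-up to `digits` decimals (reporting convention for percentages;
# base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Spearman rho and two-sided p for one pair, average ranks for ties.
# p from the t approximation t = rho*sqrt((n-2)/(1-rho^2)); |rho| = 1 -> p = 0.
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(rank(x[ok]), rank(y[ok]))
  if (is.na(r)) return(c(rho = NA_real_, p = NA_real_, n = n))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = r, p = p, n = n)
}

# Matrix z-score by row across samples; zero-variance rows map to 0.
row_zscore <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  z <- sweep(sweep(m, 1L, mu, "-"), 1L, ifelse(sd > 0, sd, 1), "/")
  z[sd == 0 | !is.finite(sd), ] <- 0
  z
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
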