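# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive enumeration / per-base loops, not the code
# paths they verify.

# Per-base mean log2 ratio of the segments covering an interval.
per_base_mean <- function(seg_start, seg_end, seg_ratio, start, end) {
  vals <- rep(NA_real_, end - start + 1)
  for (i in seq_along(seg_start)) {
    lo <- max(seg_start[i], start)
    hi <- min(seg_end[i], end)
    if (lo <= hi) vals[(lo:hi) - start + 1] <- seg_ratio[i]
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Benjamini-Hochberg step-up by definition.
bh_brute_force <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Exact two-sample Wilcoxon p by enumerating all group assignments.
wilcoxon_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Direct ssGSEA running-sum for one sample and one set (no cumsum tricks).
ssgsea_oracle <- function(values, set, alpha) {
  n <- length(values)
  r <- rank(values)
  ord <- order(values, decreasing = TRUE)
  member <- names(values)[ord] %in% set
  w <- abs(r[ord])^alpha
  p_in <- p_out <- 0
  es <- 0
  w_tot <- sum(w[member])
  for (i in seq_len(n)) {
    if (member[i]) p_in <- p_in + w[i] / w_tot
    else p_out <- p_out + 1 / (n - sum(member))
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Exhaustive k-medoids: best total distance over all medoid subsets.
exhaustive_medoid_cost <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(dm[, med, drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

pam_partition_cost <- function(d, labels) {
  dm <- as.matrix(d)
  sum(vapply(split(seq_len(nrow(dm)), labels), function(idx) {
    sub <- dm[idx, idx, drop = FALSE]
    min(colSums(sub))
  }, numeric(1)))
}

# Nelson-Aalen log-rank scores computed independently via survival::survfit.
logrank_scores_oracle <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  ch <- cumsum(fit$n.event / fit$n.risk)   # Nelson-Aalen at fit$time
  chaz_at <- stats::stepfun(fit$time, c(0, ch))
  event - chaz_at(time)
}

# Exhaustive maximally-selected statistic scan with naive per-threshold sums.
cutpoint_oracle <- function(time, event, marker, minprop = 0.1) {
  a <- logrank_scores_oracle(time, event)
  n <- length(marker)
  abar <- mean(a)
  ssq <- sum((a - abar)^2)
  cand <- sort(unique(marker))
  cand <- cand[-length(cand)]
  best <- NULL
  for (mu in cand) {
    m <- sum(marker <= mu)
    if (m < ceiling(minprop * n) || m > n - ceiling(minprop * n)) next
    S <- sum(a[marker <= mu])
    v <- m * (n - m) / (n * (n - 1)) * ssq
    stat <- abs(S - m * abar) / sqrt(v)
    if (is.null(best) || stat > best$stat + 1e-12)
      best <- list(cut = mu, stat = stat)
  }
  best
}

# Hand log-rank chi-squared: sum of (O - E) over event times, variance by
# the hypergeometric formula, for two groups.
logrank_chisq_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Adjusted Rand index via mclust when available (independent of the package).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  stop("mclust required for ARI")
}
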