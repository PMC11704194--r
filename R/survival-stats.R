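# Survival machinery: Kaplan-Meier / log-rank, univariate Cox, maximally
# selected rank-statistic cutpoints (with an optional permutation-adjusted
# p value), and group differential-abundance tests with BH control.

check_survival <- function(survival) {
  stopifnot(all(c("sample", "os_time", "os_event") %in% names(survival)))
  if (any(survival$os_time <= 0)) stopf("survival times must be positive")
  if (!all(survival$os_event %in% c(0, 1))) stopf("os_event must be 0/1")
  survival
}

#' Kaplan-Meier curves and the log-rank test
#'
#' Product-limit survival estimates per group and the standard log-rank
#' chi-squared statistic with k - 1 degrees of freedom.
#'
#' @param survival Survival data.frame (`sample`, `os_time`, `os_event`).
#' @param groups Group labels, either a named vector (names = samples) or
#'   aligned with the rows of `survival`.
#' @return List: `fit` (a [survival::survfit] object), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(survival, groups) {
  check_survival(survival)
  g <- align_groups(groups, survival$sample)
  if (length(unique(g)) < 2) stopf("need >= 2 groups")
  ev_per_group <- tapply(survival$os_event, g, sum)
  if (any(ev_per_group == 0))
    warnf("group(s) with zero events: %s",
          paste(names(ev_per_group)[ev_per_group == 0], collapse = ", "))
  d <- data.frame(time = survival$os_time, event = survival$os_event,
                  group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1L
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling. The coefficient equals
#' ln(HR); the confidence interval and p value are Wald-based.
#'
#' @param survival Survival data.frame.
#' @param covariate Numeric or two-level covariate, named by sample or
#'   aligned with `survival` rows.
#' @param conf_level Wald CI level.
#' @return List: `coef` (= ln HR), `hr`, `ci` (length-2), `se`, `p`.
#' @export
cox_univariate <- function(survival, covariate, conf_level = 0.95) {
  check_survival(survival)
  x <- align_groups(covariate, survival$sample)
  if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x)) - 1
  x <- as.numeric(x)
  if (length(unique(x[!is.na(x)])) < 2) stopf("covariate does not vary")
  if (nrow(survival) < 3 || sum(survival$os_event) < 1)
    stopf("degenerate survival data: need >= 3 subjects and >= 1 event")
  d <- data.frame(time = survival$os_time, event = survival$os_event, x = x)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, data = d,
                    ties = "efron"),
    warning = function(w) stopf("Cox fit did not converge cleanly: %s",
                                conditionMessage(w)),
    error = function(e) stopf("Cox fit failed: %s", conditionMessage(e)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(coef = beta, hr = exp(beta),
       ci = exp(beta + c(-1, 1) * zq * se), se = se,
       p = 2 * stats::pnorm(-abs(beta / se)))
}

# Log-rank scores a_i = event_i - NelsonAalen(t_i); their cumulative sums
# over marker-ordered subjects give the maximally selected rank statistic.
logrank_scores <- function(time, event) {
  u <- sort(unique(time[event == 1]))
  nj <- vapply(u, function(t) sum(time >= t), numeric(1))
  dj <- vapply(u, function(t) sum(time == t & event == 1), numeric(1))
  haz <- cumsum(dj / nj)
  cumhaz_at <- function(t) {
    idx <- findInterval(t, u)
    ifelse(idx == 0, 0, haz[pmax(idx, 1)])
  }
  event - cumhaz_at(time)
}

# Standardized statistics for every admissible split position of scores
# ordered by marker: T_m = |S_m - m*abar| / sqrt(m(n-m)/(n(n-1)) * ssq).
maxstat_stats <- function(a_ordered, admissible_m) {
  n <- length(a_ordered)
  abar <- mean(a_ordered)
  ssq <- sum((a_ordered - abar)^2)
  S <- cumsum(a_ordered)[admissible_m]
  v <- admissible_m * (n - admissible_m) / (n * (n - 1)) * ssq
  abs(S - admissible_m * abar) / sqrt(v)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans all admissible cutpoints of a continuous marker (both resulting
#' groups at least `minprop` of the cohort) and selects the one maximizing
#' the standardized log-rank statistic; ties resolve to the lower cutpoint.
#' The reported naive log-rank p at the selected cutpoint does not account
#' for the selection and is anti-conservative; `n_perm > 0` additionally
#' reports a permutation-adjusted p (the fraction of marker permutations
#' whose own maximal statistic reaches the observed one).
#'
#' @param survival Survival data.frame.
#' @param marker Continuous marker, named by sample or aligned with rows.
#' @param minprop Minimum group proportion.
#' @param n_perm Permutations for the adjusted p (0 = skip).
#' @param seed Seed for the permutation stream.
#' @return List: `cutpoint`, `statistic`, `groups` (`"low"`/`"high"`),
#'   `logrank_p` (naive), `perm_p` (or `NA`).
#' @export
optimal_cutpoint <- function(survival, marker, minprop = 0.1, n_perm = 0,
                             seed = 1) {
  check_survival(survival)
  x <- align_groups(marker, survival$sample)
  x <- as.numeric(x)
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  # admissible split after position m: x <= xs[m], requiring a value change
  lo <- ceiling(minprop * n)
  hi <- n - ceiling(minprop * n)
  cand_m <- seq_len(n - 1)
  cand_m <- cand_m[cand_m >= lo & cand_m <= hi & xs[cand_m] < xs[cand_m + 1]]
  if (!length(cand_m))
    stopf("no admissible cutpoint (marker constant or minprop too large)")
  a <- logrank_scores(survival$os_time, survival$os_event)
  a_ord <- a[ord]
  stat <- maxstat_stats(a_ord, cand_m)
  best <- which.max(stat)            # which.max takes the first (lower) tie
  cut <- xs[cand_m[best]]
  grp <- ifelse(x <= cut, "low", "high")
  d <- data.frame(time = survival$os_time, event = survival$os_event,
                  group = grp)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  naive_p <- stats::pchisq(sd_$chisq, 1, lower.tail = FALSE)
  perm_p <- NA_real_
  if (n_perm > 0) {
    set.seed(substream_seed(seed, "permutation"))
    obs <- stat[best]
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      mx <- max(maxstat_stats(sample(a), cand_m))
      if (mx >= obs) exceed <- exceed + 1L
    }
    perm_p <- (1 + exceed) / (n_perm + 1)
  }
  list(cutpoint = cut, statistic = unname(stat[best]), groups = grp,
       logrank_p = naive_p, perm_p = perm_p)
}

#' Differential abundance between sample groups
#'
#' Per-feature two-group (Wilcoxon rank-sum or Student t) or multi-group
#' (Kruskal-Wallis or one-way ANOVA) tests with BH adjustment across
#' features. Fold changes are ratios of group means on the unlogged scale,
#' with imputed cells excluded; features with fewer than `min_values`
#' non-imputed values in any group are skipped.
#'
#' @param x Abundance [omics_matrix()] or matrix (features x samples).
#' @param groups Named list of sample-id vectors (>= 2 groups). The fold
#'   change is `mean(first) / mean(second)` and is only computed for
#'   two-group designs.
#' @param test `"wilcoxon"`, `"student_t"` (two groups), `"kruskal"` or
#'   `"anova"` (any number).
#' @param fc_threshold,p_threshold Thresholds for the `direction` flags
#'   (`"up"` / `"down"` / `"ns"`); the p threshold applies to the BH q.
#' @param min_values Minimum non-imputed values per group and feature.
#' @return Data.frame: `feature`, `fold_change`, `statistic`, `p`, `q`,
#'   `direction`.
#' @export
differential_abundance <- function(x, groups,
                                   test = c("wilcoxon", "student_t",
                                            "kruskal", "anova"),
                                   fc_threshold = 2, p_threshold = 0.05,
                                   min_values = 3) {
  test <- match.arg(test)
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (test %in% c("wilcoxon", "student_t") && length(groups) != 2)
    stopf("%s requires exactly 2 groups", test)
  m <- unclass(x)
  m[imputed_mask(if (inherits(x, "omics_matrix")) x else
    omics_matrix(m, layer = "any"))] <- NA
  idx <- lapply(groups, function(g) match(intersect(g, colnames(m)),
                                          colnames(m)))
  rows <- lapply(rownames(m), function(f) {
    vals <- lapply(idx, function(i) {
      v <- m[f, i]
      v[!is.na(v)]
    })
    if (any(vapply(vals, length, integer(1)) < min_values)) return(NULL)
    fc <- if (length(vals) == 2) mean(vals[[1]]) / mean(vals[[2]])
          else NA_real_
    res <- switch(test,
      wilcoxon = {
        h <- suppressWarnings(stats::wilcox.test(vals[[1]], vals[[2]]))
        c(h$statistic, h$p.value)
      },
      student_t = {
        h <- stats::t.test(vals[[1]], vals[[2]])
        c(h$statistic, h$p.value)
      },
      kruskal = {
        h <- stats::kruskal.test(vals)
        c(h$statistic, h$p.value)
      },
      anova = {
        v <- unlist(vals)
        g <- factor(rep(seq_along(vals), vapply(vals, length, integer(1))))
        h <- summary(stats::aov(v ~ g))[[1]]
        c(h[["F value"]][1], h[["Pr(>F)"]][1])
      })
    data.frame(feature = f, fold_change = fc, statistic = unname(res[1]),
               p = unname(res[2]), stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped)
    message(skipped, " feature(s) skipped (insufficient non-imputed values)")
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no testable feature")
  out$q <- stats::p.adjust(out$p, "BH")
  out$direction <- "ns"
  sig <- !is.na(out$q) & out$q < p_threshold
  out$direction[sig & !is.na(out$fold_change) &
                  out$fold_change >= fc_threshold] <- "up"
  out$direction[sig & !is.na(out$fold_change) &
                  out$fold_change <= 1 / fc_threshold] <- "down"
  rownames(out) <- NULL
  out
}

# Accept either a named vector (matched by sample id) or a vector aligned
# with the sample order.
align_groups <- function(groups, samples) {
  if (!is.null(names(groups)) && all(samples %in% names(groups)))
    return(groups[samples])
  if (length(groups) != length(samples))
    stopf("groups must be named by sample or aligned with the table")
  groups
}
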