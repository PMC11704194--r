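sim_survival <- function(n, hr_group = NULL, seed = 1, baseline = 0.02,
                         censor_max = 120) {
  set.seed(seed)
  g <- if (is.null(hr_group)) rep(1, n) else hr_group
  t_ev <- rexp(n, baseline * g)
  t_c <- runif(n, 0, censor_max)
  data.frame(sample = paste0("S", seq_len(n)), os_time = pmin(t_ev, t_c),
             os_event = as.integer(t_ev <= t_c), stringsAsFactors = FALSE)
}

test_that("identical groups give a null log-rank test", {
  sv <- sim_survival(30, seed = 2)
  dup <- rbind(sv, transform(sv, sample = paste0("T", 1:30)))
  res <- km_logrank(dup, rep(c("a", "b"), each = 30))
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
})

test_that("the log-rank statistic matches a hand observed-minus-expected oracle", {
  sv <- data.frame(sample = paste0("S", 1:6),
                   os_time = c(3, 5, 7, 2, 8, 11),
                   os_event = c(1, 1, 0, 1, 1, 1))
  g <- rep(c("a", "b"), each = 3)
  res <- km_logrank(sv, g)
  expect_equal(res$chisq,
               logrank_chisq_oracle(sv$os_time, sv$os_event, g),
               tolerance = 1e-10)
  expect_identical(res$df, 1L)
  # planted hazard ratio is detected at n = 200
  ps <- sapply(1:5, function(s) {
    grp <- rep(c(1, 2), each = 100)
    sv2 <- sim_survival(200, hr_group = grp, seed = s)
    km_logrank(sv2, ifelse(grp == 1, "lo", "hi"))$p
  })
  expect_lt(median(ps), 0.05)
})

test_that("log-rank is invariant to order-preserving time transforms", {
  sv <- sim_survival(50, hr_group = rep(c(1, 2), 25), seed = 3)
  g <- rep(c("a", "b"), 25)
  a <- km_logrank(sv, g)
  sv2 <- transform(sv, os_time = os_time^1.5 + 1)
  b <- km_logrank(sv2, g)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
})

test_that("univariate Cox recovers a planted log hazard ratio", {
  set.seed(44)
  x <- rnorm(500)
  t_ev <- rexp(500, 0.02 * exp(0.7 * x))
  t_c <- runif(500, 0, 150)
  sv <- data.frame(sample = paste0("S", 1:500), os_time = pmin(t_ev, t_c),
                   os_event = as.integer(t_ev <= t_c))
  fit <- cox_univariate(sv, x)
  expect_lt(abs(fit$coef - 0.7), 0.15)
  expect_equal(fit$coef, log(fit$hr), tolerance = 1e-12)
  expect_true(fit$ci[1] < fit$hr & fit$hr < fit$ci[2])
})

test_that("Cox null coverage and degenerate inputs behave", {
  cover <- sapply(1:20, function(s) {
    sv <- sim_survival(80, seed = 400 + s)
    set.seed(s)
    fit <- cox_univariate(sv, rnorm(80))
    fit$ci[1] <= 1 && 1 <= fit$ci[2]
  })
  expect_gte(sum(cover), 16)   # ~95% nominal over 20 replicates
  sv2 <- data.frame(sample = c("a", "b"), os_time = c(1, 2),
                    os_event = c(1, 0))
  expect_error(cox_univariate(sv2, c(0, 1)), "degenerate")
  sv3 <- sim_survival(30, seed = 1)
  expect_error(cox_univariate(sv3, rep(2, 30)), "vary")
})

test_that("the optimal cutpoint equals an exhaustive scan and errors when inadmissible", {
  for (s in 1:5) {
    sv <- sim_survival(20, seed = 50 + s)
    set.seed(s)
    marker <- rnorm(20)
    got <- optimal_cutpoint(sv, marker, minprop = 0.1)
    want <- cutpoint_oracle(sv$os_time, sv$os_event, marker, minprop = 0.1)
    expect_equal(got$cutpoint, want$cut, tolerance = 1e-12)
    expect_equal(got$statistic, want$stat, tolerance = 1e-10)
  }
  sv <- sim_survival(20, seed = 1)
  expect_error(optimal_cutpoint(sv, rep(1, 20)), "admissible")
})

test_that("a near-indicator marker is cut exactly between the planted groups", {
  grp <- rep(c(0, 1), each = 40)
  sv <- sim_survival(80, hr_group = 1 + 2 * grp, seed = 7)
  set.seed(8)
  marker <- grp + rnorm(80, 0, 0.01)
  got <- optimal_cutpoint(sv, marker)
  expect_identical(unname(got$groups == "high"), grp == 1)
})

test_that("ties in the maximal statistic resolve to the lower cutpoint", {
  # symmetric marker, no events differences: duplicate-scan sanity via oracle
  sv <- sim_survival(12, seed = 9)
  marker <- rep(1:4, each = 3)
  got <- optimal_cutpoint(sv, marker, minprop = 0.1)
  want <- cutpoint_oracle(sv$os_time, sv$os_event, marker, minprop = 0.1)
  expect_equal(got$cutpoint, want$cut)
})

test_that("differential abundance flags planted shifts and matches exact Wilcoxon", {
  # identical groups: p ~ 1, no survivors
  m <- matrix(rep(rnorm(20, 8), 10), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("S", 1:10)))
  m <- 2^m
  grp <- list(a = paste0("S", 1:5), b = paste0("S", 6:10))
  out <- differential_abundance(omics_matrix(m, layer = "p"), grp,
                                test = "wilcoxon", fc_threshold = 1.5)
  expect_true(all(out$direction == "ns"))
  expect_true(all(out$fold_change == 1))

  # 4-value toy: exact p equals the permutation enumeration
  m2 <- matrix(2^c(1.2, 3.4, 2.2, 4.1), 1, 4,
               dimnames = list("f1", paste0("S", 1:4)))
  out2 <- differential_abundance(omics_matrix(m2, layer = "p"),
                                 list(a = c("S1", "S2"), b = c("S3", "S4")),
                                 test = "wilcoxon", min_values = 2)
  expect_equal(out2$p, wilcoxon_enumeration(c(1.2, 3.4), c(2.2, 4.1)),
               tolerance = 1e-12)

  # planted two-fold shift on 20 of 200 features
  set.seed(15)
  base <- matrix(rnorm(200 * 30, 8, 0.3), 200, 30,
                 dimnames = list(paste0("f", 1:200), paste0("S", 1:30)))
  base[1:20, 1:15] <- base[1:20, 1:15] + 1
  out3 <- differential_abundance(omics_matrix(2^base, layer = "p"),
                                 list(a = paste0("S", 1:15),
                                      b = paste0("S", 16:30)),
                                 test = "wilcoxon", fc_threshold = 1.5)
  up <- out3$feature[out3$direction == "up"]
  expect_gte(length(intersect(up, paste0("f", 1:20))), 18)
  expect_lte(length(setdiff(up, paste0("f", 1:20))), 2)
})

test_that("imputed cells are excluded and sparse features skipped", {
  m <- matrix(2^rnorm(40, 8), 4, 10,
              dimnames = list(paste0("f", 1:4), paste0("S", 1:10)))
  mask <- matrix(FALSE, 4, 10, dimnames = dimnames(m))
  mask[1, 1:8] <- TRUE   # f1 has too few real values in group a
  x <- omics_matrix(m, layer = "p", imputed = mask)
  expect_message(
    out <- differential_abundance(x, list(a = paste0("S", 1:5),
                                          b = paste0("S", 6:10)),
                                  test = "student_t"),
    "skipped")
  expect_false("f1" %in% out$feature)
})

test_that("kruskal and anova handle more than two groups", {
  set.seed(16)
  m <- matrix(rnorm(300, 8), 10, 30,
              dimnames = list(paste0("f", 1:10), paste0("S", 1:30)))
  m[1, 21:30] <- m[1, 21:30] + 3
  grp <- list(a = paste0("S", 1:10), b = paste0("S", 11:20),
              c = paste0("S", 21:30))
  for (tt in c("kruskal", "anova")) {
    out <- differential_abundance(omics_matrix(2^m, layer = "p"), grp,
                                  test = tt)
    expect_lt(out$p[out$feature == "f1"], 0.001)
    expect_true(all(is.na(out$fold_change)))
  }
  expect_error(differential_abundance(omics_matrix(2^m, layer = "p"), grp,
                                      test = "wilcoxon"), "exactly 2")
})
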