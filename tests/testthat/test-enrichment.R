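toy_expr <- function() {
  m <- matrix(c(10, 8, 6, 4, 2,
                1, 5, 9, 3, 7), 5,
              dimnames = list(paste0("g", 1:5), c("A", "B")))
  omics_matrix(m, layer = "protein")
}

test_that("ssGSEA equals the hand running-sum oracle on small toys", {
  x <- toy_expr()
  sets <- list(top = c("g1", "g2"), spread = c("g1", "g5"))
  sc <- ssgsea(x, sets, alpha = 0.25, min_size = 2, normalize = FALSE)
  for (s in colnames(x)) for (nm in names(sets)) {
    expect_equal(unclass(sc)[nm, s],
                 ssgsea_oracle(setNames(unclass(x)[, s], rownames(x)),
                               sets[[nm]], alpha = 0.25),
                 tolerance = 1e-12)
  }
  # 10-gene random toys
  set.seed(77)
  for (r in 1:5) {
    m <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("f", 1:10), "S"))
    st <- list(s1 = sample(rownames(m), 4))
    sc <- ssgsea(omics_matrix(m, layer = "x"), st, min_size = 2,
                 normalize = FALSE)
    expect_equal(unclass(sc)["s1", "S"],
                 ssgsea_oracle(setNames(m[, 1], rownames(m)), st$s1, 0.25),
                 tolerance = 1e-12)
  }
})

test_that("a set occupying the top ranks attains the maximal score of its size", {
  m <- matrix(c(9, 8, 7, 6, 5, 4), 6, 1,
              dimnames = list(paste0("f", 1:6), "S"))
  combos <- combn(rownames(m), 2, simplify = FALSE)
  sets <- setNames(combos, vapply(combos, paste, "", collapse = "_"))
  sc <- unclass(ssgsea(omics_matrix(m, layer = "x"), sets, min_size = 2,
                       normalize = FALSE))[, "S"]
  expect_identical(names(which.max(sc)), "f1_f2")
})

test_that("ssGSEA is invariant to strictly monotone transforms", {
  x <- toy_expr()
  sets <- list(a = c("g1", "g3", "g5"))
  a <- ssgsea(x, sets, min_size = 2, normalize = FALSE)
  b <- ssgsea(omics_matrix(exp(unclass(x)), layer = "protein"), sets,
              min_size = 2, normalize = FALSE)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("with alpha = 0, reversing the ranking negates the score", {
  set.seed(4)
  m <- matrix(rnorm(9), 9, 1, dimnames = list(paste0("f", 1:9), "S"))
  sets <- list(s = c("f2", "f5", "f7"))
  a <- unclass(ssgsea(omics_matrix(m, layer = "x"), sets, alpha = 0,
                      min_size = 2, normalize = FALSE))["s", "S"]
  b <- unclass(ssgsea(omics_matrix(-m, layer = "x"), sets, alpha = 0,
                      min_size = 2, normalize = FALSE))["s", "S"]
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("TF activity handles single-target fallback and planted programs", {
  set.seed(10)
  m <- matrix(rnorm(100, 8), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("S", 1:10)))
  x <- omics_matrix(m, layer = "mrna")
  expect_warning(act <- tf_activity(x, list(FOXC2 = "g3")), "min_size")
  z <- (m["g3", ] - mean(m["g3", ])) / sd(m["g3", ])
  expect_equal(unname(unclass(act)["FOXC2", ]), unname(z), tolerance = 1e-12)
  expect_equal(cor(unclass(act)["FOXC2", ], m["g3", ], method = "spearman"), 1)
  expect_message(tf_activity(x, list(ok = paste0("g", 1:9), none = "zzz"),
                             min_size = 2), "none")

  # planted up-regulated target program is highest in the planted cluster
  spec <- cohort_spec(n_samples = 45, n_genes = 120, mutation_rate = 5,
                      kinase_spec = list(), seed = 12)
  co <- generate_cohort(spec)
  prog <- spec$cluster_spec[[1]]$program
  suppressWarnings(act2 <- tf_activity(co$mrna, list(TF1 = prog)))
  means <- tapply(unclass(act2)["TF1", ], co$truth$clusters, mean)
  expect_identical(names(which.max(means)), "C1")
})

test_that("shuffled targets carry no planted signal", {
  rhos <- sapply(1:5, function(s) {
    spec <- cohort_spec(n_samples = 40, n_genes = 120, mutation_rate = 5,
                        kinase_spec = list(), seed = 100 + s)
    co <- generate_cohort(spec)
    set.seed(s)
    fake <- sample(setdiff(rownames(co$mrna),
                           unlist(lapply(spec$cluster_spec, `[[`, "program"))),
                   20)
    act <- tf_activity(co$mrna, list(TF = fake))
    truth <- as.integer(co$truth$clusters == "C1")
    abs(cor(unclass(act)["TF", ], truth, method = "spearman"))
  })
  expect_lt(median(rhos), 0.2)
})

test_that("MGPS is the mean of per-gene z-scores with degenerate genes as zero", {
  m <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("S", 1:3)))
  expect_equal(unname(mgps(omics_matrix(m, layer = "p"), paste0("g", 1:4))),
               rep(0, 3))
  set.seed(6)
  m2 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("g", 1:8), paste0("S", 1:5)))
  got <- mgps(omics_matrix(m2, layer = "p"), paste0("g", 1:8))
  oracle <- colMeans(t(apply(m2, 1, function(v) (v - mean(v)) / sd(v))))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(mgps(omics_matrix(m2, layer = "p"), "absent"), "no cell-cycle")
})

test_that("immune/stromal scores rank a planted immune-high group first", {
  set.seed(9)
  m <- matrix(rnorm(600, 8), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("S", 1:20)))
  immune <- paste0("g", 1:6); stromal <- paste0("g", 7:12)
  grpA <- paste0("S", 1:10)
  m[immune, grpA] <- m[immune, grpA] + 2
  sc <- immune_stromal_scores(omics_matrix(m, layer = "protein"),
                              immune, stromal)
  expect_gt(min(sc$immune[sc$sample %in% grpA]),
            max(sc$immune[!sc$sample %in% grpA]))
  expect_equal(sc$combined, sc$immune + sc$stromal)
  # identical samples give identical scores
  m2 <- m[, c(1, 1, 1)]
  colnames(m2) <- paste0("S", 1:3)
  sc2 <- immune_stromal_scores(omics_matrix(m2, layer = "p"), immune, stromal)
  expect_equal(sc2$immune, rep(sc2$immune[1], 3))
  expect_error(immune_stromal_scores(omics_matrix(m, layer = "p"),
                                     immune, "zzz"), "stromal")
})

test_that("over-representation p equals the hypergeometric enumeration", {
  universe <- paste0("g", 1:20)
  sets <- list(s = paste0("g", 1:5))
  out <- overrepresentation(paste0("g", 1:5), universe, sets)
  # oracle: P(X >= 5) with X ~ Hypergeom(5 in set, 15 out, 5 drawn)
  expect_equal(out$p, sum(dhyper(5, 5, 15, 5)), tolerance = 1e-12)
  out2 <- overrepresentation(paste0("g", 10:14), universe, sets)
  expect_equal(out2$p, 1 - phyper(-1, 5, 15, 5), tolerance = 1e-12)
  expect_error(overrepresentation("zzz", universe, sets), "universe")

  set.seed(14)
  ps <- replicate(200, {
    overrepresentation(sample(universe, 5), universe, sets)$p
  })
  # discrete but roughly uniform: severe enrichment should be rare
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("planted cluster programs separate clusters by score (AUROC)", {
  aurocs <- sapply(1:5, function(s) {
    spec <- cohort_spec(n_samples = 40, n_genes = 120, mutation_rate = 5,
                        kinase_spec = list(), seed = 200 + s)
    co <- generate_cohort(spec)
    prog <- spec$cluster_spec[[1]]$program
    sc <- ssgsea(co$protein, list(p1 = prog), min_size = 5)
    pos <- unclass(sc)["p1", co$truth$clusters == "C1"]
    neg <- unclass(sc)["p1", co$truth$clusters != "C1"]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  })
  expect_gt(min(aurocs), 0.95)
})
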