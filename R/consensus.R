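# Resampling-based consensus clustering: PAM on Spearman distance over
# subsampled cohorts, consensus matrices per k, CDF / delta-area / mean
# silhouette diagnostics and final labels from hierarchical clustering of
# the consensus.

#' Consensus clustering with PAM on Spearman distance
#'
#' Features are first filtered to the top `top_var_fraction` most variable
#' (variance by default, MAD optionally). Per repetition,
#' `ceiling(pItem * n)` samples are drawn without replacement and
#' partitioned by PAM with distance 1 - Spearman correlation between sample
#' profiles; the same subsamples are reused across all k. The consensus
#' entry of a sample pair is its co-clustering count divided by its
#' co-sampling count. Final labels per k come from average-linkage
#' hierarchical clustering of 1 - consensus; the CDF of upper-triangle
#' consensus values, the relative delta-area of its AUC, and the mean
#' silhouette width on 1 - consensus guide the choice of k (`chosen_k`
#' maximizes mean silhouette).
#'
#' @param x Abundance [omics_matrix()] or matrix (features x samples);
#'   expression ranks drive the Spearman distance so any monotone scale
#'   works.
#' @param k_range Cluster numbers to evaluate.
#' @param reps Number of subsampling repetitions.
#' @param pItem Sample subsampling proportion.
#' @param pFeature Feature subsampling proportion (1 = no feature
#'   resampling).
#' @param top_var_fraction Fraction of most-variable features retained.
#' @param var_stat `"variance"` or `"mad"` for the feature filter.
#' @param seed Seed for the resampling stream.
#' @return A `consensus_result`: `consensus` (list of matrices per k),
#'   `labels` (list per k), `cdf`, `auc`, `delta_area`, `silhouette`,
#'   `chosen_k`, `k_range`.
#' @export
consensus_cluster <- function(x, k_range = 2:5, reps = 200, pItem = 0.8,
                              pFeature = 1.0, top_var_fraction = 0.5,
                              var_stat = c("variance", "mad"), seed = 1) {
  var_stat <- match.arg(var_stat)
  m <- unclass(x)
  n <- ncol(m)
  if (n < 3 * max(k_range))
    stopf("need at least 3 * max(k) = %d samples, got %d", 3 * max(k_range), n)
  disp <- if (var_stat == "variance") apply(m, 1L, stats::var)
          else apply(m, 1L, stats::mad)
  keep <- order(disp, decreasing = TRUE)[seq_len(max(2L,
            ceiling(top_var_fraction * nrow(m))))]
  m <- m[keep, , drop = FALSE]

  set.seed(substream_seed(seed, "resample"))
  n_sub <- ceiling(pItem * n)
  subsamples <- lapply(seq_len(reps), function(r) sort(sample.int(n, n_sub)))
  feat_subs <- lapply(seq_len(reps), function(r) {
    if (pFeature >= 1) seq_len(nrow(m))
    else sort(sample.int(nrow(m), ceiling(pFeature * nrow(m))))
  })

  co_sampled <- matrix(0, n, n)
  for (idx in subsamples) co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
  if (any(co_sampled[upper.tri(co_sampled)] == 0))
    stopf(paste("some sample pairs were never co-sampled;",
                "increase reps or pItem"))

  consensus <- list()
  labels <- list()
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (k in k_range) {
    co_cluster <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- subsamples[[r]]
      sub <- m[feat_subs[[r]], idx, drop = FALSE]
      d <- spearman_distance(sub)
      # degenerate repetition: effectively identical samples cannot support
      # k groups; treat as one cluster rather than an arbitrary split
      cl <- if (max(d) < 1e-12) rep(1L, ncol(sub))
            else cluster::pam(d, k = k, diss = TRUE, cluster.only = TRUE)
      for (g in split(seq_along(idx), cl)) {
        gi <- idx[g]
        co_cluster[gi, gi] <- co_cluster[gi, gi] + 1
      }
    }
    cons <- co_cluster / co_sampled
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(x), colnames(x))
    consensus[[as.character(k)]] <- cons
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    lab <- stats::cutree(hc, k = k)
    labels[[as.character(k)]] <- lab
    sw <- tryCatch(cluster::silhouette(lab, stats::as.dist(1 - cons)),
                   error = function(e) NULL)
    sil[as.character(k)] <- if (is.matrix(sw)) mean(sw[, "sil_width"])
                            else NA_real_
  }

  grid <- seq(0, 1, length.out = 101)
  cdf <- sapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    stats::ecdf(v)(grid)
  })
  auc <- apply(cdf, 2L, function(y) sum(diff(grid) * (utils::head(y, -1) +
                                                       utils::tail(y, -1)) / 2))
  delta_area <- diff(c(0, auc)) / c(1, utils::head(auc, -1))
  names(delta_area) <- names(auc)
  if (all(is.na(sil))) {
    warnf("degenerate clustering (no valid silhouette); chosen_k set to %d",
          min(k_range))
    chosen_k <- as.integer(min(k_range))
  } else {
    chosen_k <- as.integer(names(which.max(sil)))
  }
  structure(list(consensus = consensus, labels = labels,
                 cdf = cdf, cdf_grid = grid, auc = auc,
                 delta_area = delta_area, silhouette = sil,
                 chosen_k = chosen_k, k_range = k_range,
                 features_used = rownames(m)),
            class = "consensus_result")
}

# 1 - Spearman correlation between sample profiles, as a dist object.
spearman_distance <- function(m) {
  rc <- apply(m, 2L, rank)
  stats::as.dist(1 - stats::cor(rc))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k in {%s}; chosen k = %d\n",
              paste(x$k_range, collapse = ", "), x$chosen_k))
  cat("  mean silhouette:",
      paste(sprintf("k=%s %.3f", names(x$silhouette), x$silhouette),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  graphics::matplot(x$cdf_grid, x$cdf, type = "l", lty = 1,
                    xlab = "consensus value", ylab = "CDF",
                    main = "Consensus CDF per k", ...)
  graphics::legend("bottomright", legend = paste0("k=", colnames(x$cdf)),
                   lty = 1, col = seq_len(ncol(x$cdf)))
  invisible(x)
}

#' Association of cluster labels with clinical variables
#'
#' Categorical variables are tested by Fisher's exact test when any
#' expected cell count is below 5 (chi-squared otherwise); continuous
#' variables by Kruskal-Wallis. Single-level variables are skipped.
#'
#' @param labels Named vector of cluster labels (names = samples).
#' @param clinical Data.frame with a `sample` column plus variables.
#' @param fisher_expected_max Expected-count threshold below which Fisher's
#'   exact test replaces the chi-squared test.
#' @return Data.frame: `variable`, `test`, `p`.
#' @export
cluster_association <- function(labels, clinical, fisher_expected_max = 5) {
  stopifnot("sample" %in% names(clinical))
  cl <- clinical[match(names(labels), clinical$sample), , drop = FALSE]
  vars <- setdiff(names(cl), "sample")
  rows <- lapply(vars, function(v) {
    x <- cl[[v]]
    if (length(unique(x[!is.na(x)])) < 2) return(NULL)
    if (is.numeric(x) && length(unique(x)) > 8) {
      p <- stats::kruskal.test(x, factor(labels))$p.value
      test <- "kruskal-wallis"
    } else {
      tab <- table(factor(labels), factor(x))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < fisher_expected_max)) {
        p <- stats::fisher.test(tab, simulate.p.value = (length(tab) > 30),
                                B = 1e4)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab)$p.value
        test <- "chi-squared"
      }
    }
    data.frame(variable = v, test = test, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
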