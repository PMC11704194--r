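# Single-sample enrichment machinery: the ssGSEA engine and the scores
# built on it (pathway, TF activity, proliferation, immune/stromal,
# cell-type), plus the hypergeometric over-representation test.

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per sample, features are ranked by abundance (descending, average ranks
#' for ties). The enrichment score of a set is the sum over the ranked list
#' of the difference between the weighted in-set empirical CDF (weights
#' |rank statistic|^alpha, the rank statistic being the feature's rank) and
#' the unweighted out-of-set ECDF. Scores are rank-based, hence invariant
#' to any strictly monotone transform of a sample's abundances. Optionally
#' all scores are normalized by the cohort-wide max - min enrichment score.
#'
#' @param x Abundance [omics_matrix()] or matrix (features x samples).
#' @param sets Named list of feature sets; members absent from `x` are
#'   dropped, sets falling below `min_size` are removed.
#' @param alpha Rank weighting exponent.
#' @param min_size Minimum surviving set size.
#' @param normalize Divide all scores by max(ES) - min(ES) over the cohort.
#' @return A `score_matrix`: sets x samples matrix with attributes
#'   `method = "ssgsea"`, `alpha`, `normalized`.
#' @export
ssgsea <- function(x, sets, alpha = 0.25, min_size = 10, normalize = TRUE) {
  m <- unclass(x)
  sets <- lapply(sets, function(s) unique(intersect(s, rownames(m))))
  sets <- sets[vapply(sets, length, integer(1)) >= min_size]
  if (!length(sets)) stopf("no gene set with >= %d members in the matrix",
                           min_size)
  n <- nrow(m)
  es <- matrix(NA_real_, length(sets), ncol(m),
               dimnames = list(names(sets), colnames(m)))
  set_idx <- lapply(sets, function(s) match(s, rownames(m)))
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j])                      # high abundance -> high rank
    ord <- order(m[, j], decreasing = TRUE)
    w <- abs(r[ord])^alpha
    inset <- matrix(FALSE, n, 1)
    for (si in seq_along(set_idx)) {
      member <- logical(n)
      member[match(set_idx[[si]], ord)] <- TRUE
      win <- w * member
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!member) / (n - sum(member))
      es[si, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  structure(es, method = "ssgsea", alpha = alpha, normalized = normalize,
            class = c("score_matrix", class(es)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s: %d sets x %d samples\n",
              attr(x, "method") %||% "score", nrow(x), ncol(x)))
  invisible(x)
}

#' Transcription-factor activity from target-gene expression
#'
#' Activity is the ssGSEA score of the TF's target set on the expression
#' matrix. Target sets smaller than `min_size` (after intersection) are
#' scored with a warning; single-target TFs fall back to the target's
#' standardized (z-scored across samples) abundance. TFs with no mapped
#' target are skipped.
#'
#' @param expr Expression [omics_matrix()].
#' @param tf_targets Named list: TF -> character vector of target genes.
#' @inheritParams ssgsea
#' @return A `score_matrix` (TFs x samples).
#' @export
tf_activity <- function(expr, tf_targets, alpha = 0.25, min_size = 10) {
  m <- unclass(expr)
  tf_targets <- lapply(tf_targets, function(s) unique(intersect(s, rownames(m))))
  sizes <- vapply(tf_targets, length, integer(1))
  if (any(sizes == 0)) {
    message("skipping TF(s) with no mapped target: ",
            paste(names(tf_targets)[sizes == 0], collapse = ", "))
    tf_targets <- tf_targets[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  if (!length(tf_targets)) stopf("no TF with mapped targets")
  small <- sizes < min_size
  if (any(small))
    warnf("TF target set(s) below min_size scored anyway: %s",
          paste(names(tf_targets)[small], collapse = ", "))
  out <- matrix(NA_real_, length(tf_targets), ncol(m),
                dimnames = list(names(tf_targets), colnames(m)))
  multi <- names(tf_targets)[sizes > 1]
  if (length(multi)) {
    sc <- ssgsea(expr, tf_targets[multi], alpha = alpha, min_size = 2,
                 normalize = TRUE)
    out[rownames(sc), ] <- unclass(sc)
  }
  single <- names(tf_targets)[sizes == 1]
  for (tf in single)
    out[tf, ] <- row_zscore(m[tf_targets[[tf]], , drop = FALSE])
  structure(out, method = "ssgsea+z", alpha = alpha, normalized = TRUE,
            class = c("score_matrix", class(out)))
}

#' Multi-gene proliferation score (MGPS)
#'
#' The mean standardized abundance of the cell-cycle-regulated genes in
#' each sample: each gene is z-scored across samples (zero-variance genes
#' contribute 0), then averaged per sample.
#'
#' @param expr Expression [omics_matrix()].
#' @param cell_cycle_genes Character vector of cell-cycle-regulated genes.
#' @return Named numeric vector, one score per sample.
#' @export
mgps <- function(expr, cell_cycle_genes) {
  m <- unclass(expr)
  present <- intersect(cell_cycle_genes, rownames(m))
  if (!length(present)) stopf("no cell-cycle gene present in the matrix")
  colMeans(row_zscore(m[present, , drop = FALSE]))
}

#' Immune and stromal signature scores
#'
#' ssGSEA scores of an immune and a stromal signature; the combined score
#' is their sum. (Tumor purity is deliberately not derived.)
#'
#' @param expr Expression [omics_matrix()].
#' @param immune_set,stromal_set Character vectors of signature genes.
#' @inheritParams ssgsea
#' @return Data.frame: `sample`, `immune`, `stromal`, `combined`.
#' @export
immune_stromal_scores <- function(expr, immune_set, stromal_set,
                                  alpha = 0.25, min_size = 2) {
  m <- unclass(expr)
  if (!length(intersect(immune_set, rownames(m))))
    stopf("immune signature has no overlap with the matrix")
  if (!length(intersect(stromal_set, rownames(m))))
    stopf("stromal signature has no overlap with the matrix")
  sc <- ssgsea(expr, list(immune = immune_set, stromal = stromal_set),
               alpha = alpha, min_size = min_size, normalize = TRUE)
  data.frame(sample = colnames(sc), immune = sc["immune", ],
             stromal = sc["stromal", ],
             combined = sc["immune", ] + sc["stromal", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-type signature scores
#'
#' ssGSEA score per cell-type signature (no spillover compensation between
#' related cell types is attempted).
#'
#' @param expr Expression [omics_matrix()].
#' @param signatures Named list of cell-type signatures.
#' @inheritParams ssgsea
#' @return A `score_matrix` (cell types x samples).
#' @export
cell_type_scores <- function(expr, signatures, alpha = 0.25, min_size = 2) {
  ssgsea(expr, signatures, alpha = alpha, min_size = min_size,
         normalize = TRUE)
}

#' Over-representation test for gene sets
#'
#' One-sided hypergeometric upper-tail p per set (the probability of at
#' least the observed overlap between the hit list and the set within the
#' universe), BH-adjusted across sets.
#'
#' @param hits Character vector of hit genes (must be within `universe`).
#' @param universe Character vector, the tested gene universe.
#' @param sets Named list of gene sets (intersected with the universe).
#' @return Data.frame: `set`, `set_size`, `overlap`, `p`, `q`.
#' @export
overrepresentation <- function(hits, universe, sets) {
  hits <- unique(hits)
  universe <- unique(universe)
  bad <- setdiff(hits, universe)
  if (length(bad))
    stopf("hit gene(s) outside the universe: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(hits, s))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(hits), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}
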