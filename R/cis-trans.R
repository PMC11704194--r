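# The CNV -> mRNA / protein / phosphoprotein correlation ledger: Spearman
# correlations per (copy-number feature, target feature) pair, BH control
# per (layer, mode) family, cis/trans classification and cross-layer
# overlaps of significant cis genes.

#' Correlate a copy-number layer against an abundance layer
#'
#' Spearman correlation (average ranks for ties) with a two-sided p value
#' for copy-number / abundance pairs, computed on pairwise-complete,
#' non-imputed cells. `mode = "cis_only"` restricts to same-gene pairs
#' (gene-level copy number against that gene's own feature); `mode = "all"`
#' computes every pair, labelling same-gene pairs `cis` and the rest
#' `trans`. BH adjustment is applied within each (layer, mode) family.
#'
#' @param cnv Gene-level copy-number [omics_matrix()] (genes x samples).
#' @param target Abundance [omics_matrix()]; its layer tag labels the
#'   ledger. Phosphosite matrices may be collapsed to protein level first
#'   (see [collapse_phospho()]).
#' @param mode `"cis_only"` or `"all"`.
#' @param min_pairs Minimum complete sample pairs; pairs with fewer are
#'   skipped.
#' @param target_gene Optional map from target feature to gene symbol
#'   (named character); defaults to the feature name itself.
#' @return An `effect_ledger` data.frame: `cnv_gene`, `feature`, `gene`,
#'   `layer`, `mode`, `rho`, `n`, `p`, `q`.
#' @export
correlate_layers <- function(cnv, target, mode = c("cis_only", "all"),
                             min_pairs = 10, target_gene = NULL) {
  mode <- match.arg(mode)
  layer <- attr(target, "layer") %||% "abundance"
  shared <- intersect(colnames(cnv), colnames(target))
  if (!length(shared)) stopf("no shared samples between layers")
  cn <- unclass(cnv)[, shared, drop = FALSE]
  tg <- unclass(target)[, shared, drop = FALSE]
  tg[imputed_mask(target)[, shared, drop = FALSE]] <- NA
  genes_of <- target_gene %||%
    stats::setNames(rownames(tg), rownames(tg))
  if (mode == "cis_only") {
    feats <- rownames(tg)[genes_of[rownames(tg)] %in% rownames(cn)]
    pairs <- cbind(genes_of[feats], feats)
  } else {
    pairs <- as.matrix(expand.grid(cnv_gene = rownames(cn),
                                   feature = rownames(tg),
                                   stringsAsFactors = FALSE))
  }
  if (!nrow(pairs)) stopf("no computable pairs")
  res <- matrix(NA_real_, nrow(pairs), 3,
                dimnames = list(NULL, c("rho", "p", "n")))
  for (i in seq_len(nrow(pairs))) {
    st <- spearman_test(cn[pairs[i, 1], ], tg[pairs[i, 2], ])
    if (st["n"] >= min_pairs) res[i, ] <- st[c("rho", "p", "n")]
  }
  skipped <- is.na(res[, "p"])
  out <- data.frame(cnv_gene = pairs[, 1], feature = pairs[, 2],
                    gene = unname(genes_of[pairs[, 2]]), layer = layer,
                    mode = ifelse(pairs[, 1] == genes_of[pairs[, 2]],
                                  "cis", "trans"),
                    rho = res[, "rho"], n = res[, "n"], p = res[, "p"],
                    stringsAsFactors = FALSE)[!skipped, , drop = FALSE]
  if (any(skipped))
    message(sum(skipped), " pair(s) skipped (fewer than ", min_pairs,
            " complete sample pairs)")
  out$q <- NA_real_
  for (md in unique(out$mode))
    out$q[out$mode == md] <- stats::p.adjust(out$p[out$mode == md], "BH")
  rownames(out) <- NULL
  class(out) <- c("effect_ledger", class(out))
  out
}

#' Collapse a phosphosite matrix to protein level
#'
#' Each protein is represented by its most abundant site (largest mean
#' abundance over non-imputed cells), the convention used when correlating
#' copy number against "phosphoprotein" abundance.
#'
#' @param phospho Phosphosite [omics_matrix()], features named
#'   `PROT_S123`-style.
#' @return A protein-level [omics_matrix()] (layer `"phosphoprotein"`).
#' @export
collapse_phospho <- function(phospho) {
  prot <- sub("_[STY][0-9]+[a-zx0-9]*$", "", rownames(phospho))
  vals <- unclass(phospho)
  vals_na <- vals
  vals_na[imputed_mask(phospho)] <- NA
  keep <- vapply(split(seq_len(nrow(vals)), prot), function(idx)
    idx[which.max(rowMeans(vals_na[idx, , drop = FALSE], na.rm = TRUE))],
    integer(1))
  m <- vals[keep, , drop = FALSE]
  msk <- imputed_mask(phospho)[keep, , drop = FALSE]
  rownames(m) <- rownames(msk) <- names(keep)
  omics_matrix(m, layer = "phosphoprotein",
               normalized = isTRUE(attr(phospho, "normalized")),
               imputed = msk)
}

#' Overlap of significant cis genes across omics layers
#'
#' Counts genes with a significant cis effect in each combination of
#' layers (Venn-style), optionally restricted to a cancer-associated gene
#' list.
#'
#' @param ledgers Named list of `effect_ledger`s (one per layer).
#' @param threshold Significance threshold.
#' @param use Column the threshold applies to (`"p"` raw or `"q"` adjusted).
#' @param cag Optional character vector restricting the gene universe.
#' @return List with `counts` (named by layer combinations such as
#'   `"mrna+protein"`) and `genes` (the gene sets).
#' @export
cis_overlap <- function(ledgers, threshold = 0.05, use = c("p", "q"),
                        cag = NULL) {
  use <- match.arg(use)
  sig <- lapply(ledgers, function(l) {
    l <- l[l$mode == "cis" & !is.na(l[[use]]) & l[[use]] < threshold, ]
    g <- unique(l$gene)
    if (!is.null(cag)) g <- intersect(g, cag)
    g
  })
  layers <- names(sig)
  combos <- unlist(lapply(seq_along(layers), function(k)
    utils::combn(layers, k, simplify = FALSE)), recursive = FALSE)
  genes <- lapply(combos, function(cm) {
    inn <- Reduce(intersect, sig[cm])
    outl <- setdiff(layers, cm)
    if (length(outl)) inn <- setdiff(inn, unique(unlist(sig[outl])))
    inn
  })
  names(genes) <- vapply(combos, paste, character(1), collapse = "+")
  list(counts = vapply(genes, length, integer(1)), genes = genes,
       per_layer = vapply(sig, length, integer(1)))
}
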