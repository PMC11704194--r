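# Label-free quantification: peptide intensities -> iBAQ -> FOT, the
# missing-value policy, and phosphosite localization filtering.

# All fully tryptic peptides of a protein sequence (cleave C-terminal of
# K/R, not before P), within a length window.
tryptic_peptides <- function(sequence, min_len = 7, max_len = 30) {
  if (!nzchar(sequence)) return(character(0))
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- unique(bounds)
  peps <- substring(sequence, utils::head(bounds, -1) + 1L,
                    utils::tail(bounds, -1))
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

#' Count theoretically observable tryptic peptides
#'
#' Fully tryptic digestion (cleavage C-terminal of K/R, suppressed before
#' proline), no missed cleavages by default, counting peptides whose length
#' falls in `[min_len, max_len]`. This count is the iBAQ denominator.
#'
#' @param sequence Protein sequence (20-letter amino-acid alphabet).
#' @param min_len,max_len Peptide length window.
#' @param missed_cleavages Number of allowed missed cleavages (0 counts only
#'   fully cleaved peptides).
#' @return Integer count.
#' @export
observable_peptides <- function(sequence, min_len = 7, max_len = 30,
                                missed_cleavages = 0) {
  if (is.na(sequence) || !nzchar(sequence)) {
    warnf("empty protein sequence; observable peptide count is 0")
    return(0L)
  }
  base <- tryptic_peptides(sequence, min_len = 1, max_len = .Machine$integer.max)
  if (!length(base)) return(0L)
  count <- 0L
  for (mc in 0:missed_cleavages) {
    if (mc + 1 > length(base)) break
    lens <- vapply(seq_len(length(base) - mc), function(i)
      sum(nchar(base[i:(i + mc)])), integer(1))
    count <- count + sum(lens >= min_len & lens <= max_len)
  }
  count
}

#' iBAQ protein quantification from a peptide intensity table
#'
#' Intensity-based absolute quantification: per protein and sample, the sum
#' of its peptide XIC intensities divided by the protein's count of
#' theoretically observable tryptic peptides.
#'
#' @param peptides Data.frame with columns `sample`, `protein`, `peptide`,
#'   `intensity` (non-negative). Peptides shorter than `min_pep_len`
#'   residues are removed before aggregation.
#' @param observable Named integer vector of observable-peptide counts per
#'   protein (e.g. from [observable_peptides()] over a FASTA). Proteins
#'   absent from this table, or with count < 1, are excluded with a warning.
#' @param min_pep_len Minimum peptide length retained.
#' @return An [omics_matrix()] of iBAQ values (proteins x samples).
#' @export
ibaq <- function(peptides, observable, min_pep_len = 7) {
  stopifnot(all(c("sample", "protein", "peptide", "intensity") %in%
                  names(peptides)))
  if (any(peptides$intensity < 0, na.rm = TRUE))
    stopf("peptide intensities must be non-negative")
  peptides <- peptides[nchar(peptides$peptide) >= min_pep_len, , drop = FALSE]
  known <- names(observable)[!is.na(observable) & observable >= 1]
  dropped <- setdiff(unique(peptides$protein), known)
  if (length(dropped))
    warnf("excluding %d protein(s) without an observable-peptide count: %s",
          length(dropped), paste(utils::head(dropped, 3), collapse = ", "))
  peptides <- peptides[peptides$protein %in% known, , drop = FALSE]
  if (!nrow(peptides)) stopf("no quantifiable peptides left")
  sums <- tapply(peptides$intensity,
                 list(protein = peptides$protein, sample = peptides$sample),
                 sum, default = NA_real_)
  m <- sums / as.numeric(observable[rownames(sums)])
  omics_matrix(unclass(m), layer = "protein")
}

#' FOT normalization (fraction of total, x 1e6)
#'
#' Each protein's iBAQ is divided by the column (sample) total over all
#' quantified proteins of that sample and scaled by `scale` (1e6 by
#' default), so every column sums to `scale` before imputation. Missing
#' values are then imputed with `impute_value` and recorded in the
#' imputation mask carried by the returned matrix.
#'
#' @param x An iBAQ [omics_matrix()] (or bare matrix), `NA` = not quantified.
#' @param scale Post-normalization column total.
#' @param impute_value Value substituted for missing cells after scaling
#'   (`NULL` to skip imputation).
#' @return A normalized [omics_matrix()] with an imputation mask.
#' @export
fot_normalize <- function(x, scale = 1e6, impute_value = 1e-5) {
  m <- as_bare_matrix(if (inherits(x, "omics_matrix")) x else
    omics_matrix(x, layer = "protein"))
  totals <- colSums(m, na.rm = TRUE)
  zero <- totals <= 0
  if (any(zero))
    stopf("sample(s) with no quantified signal: %s",
          paste(colnames(m)[zero], collapse = ", "))
  m <- sweep(m, 2L, totals, "/") * scale
  mask <- is.na(m)
  if (!is.null(impute_value)) m[mask] <- impute_value
  omics_matrix(m, layer = attr(x, "layer") %||% "protein",
               normalized = TRUE, imputed = mask)
}

#' Filter phosphosites by localization probability
#'
#' Keeps records whose localization probability is strictly greater than
#' `min_prob` (sites at exactly the threshold are removed).
#'
#' @param records Data.frame with columns `protein`, `residue` (S/T/Y),
#'   `position`, `probability` plus any abundance columns.
#' @param min_prob Localization probability threshold.
#' @return The surviving records, with a `residue_counts` attribute
#'   reporting survivors per residue.
#' @export
filter_phosphosites <- function(records, min_prob = 0.75) {
  stopifnot(all(c("residue", "probability") %in% names(records)))
  if (any(records$probability < 0 | records$probability > 1, na.rm = TRUE))
    stopf("localization probabilities must lie in [0, 1]")
  keep <- !is.na(records$probability) & records$probability > min_prob
  out <- records[keep, , drop = FALSE]
  attr(out, "residue_counts") <-
    table(factor(out$residue, levels = c("S", "T", "Y")))
  out
}

#' Residue distribution of phosphosites
#'
#' Counts and percentages for serine, threonine and tyrosine sites.
#' Percentages are `100 * count / total`, rounded half-up to one decimal.
#'
#' @param x Either a character vector of residues, a data.frame with a
#'   `residue` column, or a named numeric vector of counts
#'   (`c(S=, T=, Y=)`).
#' @return A data.frame with `residue`, `count`, `percent`. With empty
#'   input, counts are zero and `percent` is `NA` (flagged undefined).
#' @export
residue_distribution <- function(x) {
  if (is.data.frame(x)) x <- x$residue
  if (is.numeric(x)) {
    counts <- x[c("S", "T", "Y")]
    names(counts) <- c("S", "T", "Y")
    counts[is.na(counts)] <- 0
  } else {
    bad <- setdiff(unique(x), c("S", "T", "Y"))
    if (length(bad)) stopf("unknown residue(s): %s", paste(bad, collapse = ", "))
    counts <- table(factor(x, levels = c("S", "T", "Y")))
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * as.numeric(counts) / total, 1)
         else rep(NA_real_, 3)
  data.frame(residue = c("S", "T", "Y"), count = as.numeric(counts),
             percent = pct, stringsAsFactors = FALSE)
}

#' Spearman correlation between two abundance profiles
#'
#' Pairwise Spearman over the shared features of two columns or matrices,
#' excluding imputed cells (per the imputation masks) by default. Used for
#' replicate / QC-standard agreement.
#'
#' @param a,b Numeric vectors (named by feature) or single-column matrices.
#' @param exclude_imputed Drop cells flagged imputed in either input.
#' @return Spearman's rho.
#' @export
qc_correlation <- function(a, b, exclude_imputed = TRUE) {
  va <- extract_profile(a)
  vb <- extract_profile(b)
  shared <- intersect(names(va$value), names(vb$value))
  if (exclude_imputed)
    shared <- shared[!(va$imputed[shared] | vb$imputed[shared])]
  if (length(shared) < 3) stopf("fewer than 3 shared features")
  stats::cor(va$value[shared], vb$value[shared], method = "spearman",
             use = "complete.obs")
}

extract_profile <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 1) stopf("expected a vector or single-column matrix")
    imp <- imputed_mask(if (inherits(x, "omics_matrix")) x else
      omics_matrix(x, layer = "any"))[, 1]
    list(value = stats::setNames(x[, 1], rownames(x)), imputed = imp)
  } else {
    if (is.null(names(x))) stopf("profiles must be named by feature")
    list(value = x,
         imputed = stats::setNames(rep(FALSE, length(x)), names(x)))
  }
}
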