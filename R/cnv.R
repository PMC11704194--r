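# Copy-number and mutation genomics: gene-level copy ratios from segment
# tables, length-weighted arm scores, amplification/deletion calls, tumor
# mutational burden, 96-context matrices, NMF signature extraction and
# Fisher co-occurrence tests.
#
# Genomic coordinates are 1-based inclusive in all I/O (SEG convention);
# overlap lengths are computed as end - start + 1 on the intersected
# interval.

overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

check_chroms <- function(segments, genes) {
  bad <- setdiff(unique(segments$chrom), unique(genes$chrom))
  if (length(bad))
    stopf("segment chromosome(s) not in the gene model: %s",
          paste(bad, collapse = ", "))
}

#' Gene-level copy number from segments
#'
#' Each gene x sample cell is the length-weighted mean of the log2 copy
#' ratios of the segments overlapping the gene body (weights = overlapped
#' bases). Genes with no overlapping segment in a sample are `NA`.
#'
#' @param segments Segment data.frame (`sample`, `chrom`, `start`, `end`,
#'   `log2ratio`), coordinates 1-based inclusive.
#' @param genes Gene model data.frame (`gene`, `chrom`, `start`, `end`,
#'   `arm`).
#' @return An [omics_matrix()] (layer `"cnv"`), genes x samples.
#' @export
gene_copy_number <- function(segments, genes) {
  check_chroms(segments, genes)
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, nrow(genes), length(samples),
              dimnames = list(genes$gene, samples))
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    for (si in split(seq_len(nrow(s)), s$sample)) {
      seg <- s[si, , drop = FALSE]
      smp <- seg$sample[1]
      for (gi in seq_len(nrow(g))) {
        ol <- overlap_len(g$start[gi], g$end[gi], seg$start, seg$end)
        w <- ol > 0
        if (any(w))
          m[g$gene[gi], smp] <- sum(ol[w] * seg$log2ratio[w]) / sum(ol[w])
      }
    }
  }
  omics_matrix(m, layer = "cnv")
}

#' Length-weighted arm-level copy-number scores
#'
#' For every chromosome arm, the segment log2 copy ratios overlapping the
#' arm are combined with each segment weighted by its overlapped length,
#' normalized by the total overlapped length — a length-weighted mean, so
#' arm scores stay on the log2-ratio scale and the same amplification /
#' deletion cutoff applies. Samples with no segment on an arm are `NA`.
#'
#' @inheritParams gene_copy_number
#' @param arm_bounds Optional data.frame (`arm`, `chrom`, `start`, `end`);
#'   derived from the span of the gene model per arm when omitted.
#' @param normalize Divide by total overlapped length (default). With
#'   `FALSE` the raw length-weighted sum is returned (lengths in Mb).
#' @return An [omics_matrix()] (layer `"arm_cnv"`), arms x samples.
#' @export
arm_score <- function(segments, genes, arm_bounds = NULL, normalize = TRUE) {
  if (is.null(arm_bounds)) {
    arm_bounds <- do.call(rbind, lapply(split(genes, genes$arm), function(g)
      data.frame(arm = g$arm[1], chrom = g$chrom[1], start = min(g$start),
                 end = max(g$end), stringsAsFactors = FALSE)))
    arm_bounds <- arm_bounds[order(match(arm_bounds$arm, unique(genes$arm))), ]
  }
  if (!nrow(segments)) {
    warnf("empty segment table; all arm scores missing")
    return(omics_matrix(matrix(NA_real_, nrow(arm_bounds), 1,
                               dimnames = list(arm_bounds$arm, "none")),
                        layer = "arm_cnv"))
  }
  check_chroms(segments, genes)
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, nrow(arm_bounds), length(samples),
              dimnames = list(arm_bounds$arm, samples))
  for (ai in seq_len(nrow(arm_bounds))) {
    b <- arm_bounds[ai, ]
    s <- segments[segments$chrom == b$chrom, , drop = FALSE]
    if (!nrow(s)) next
    ol <- overlap_len(b$start, b$end, s$start, s$end)
    s <- s[ol > 0, , drop = FALSE]
    ol <- ol[ol > 0]
    if (!nrow(s)) next
    for (si in split(seq_len(nrow(s)), s$sample)) {
      wsum <- sum(ol[si] * s$log2ratio[si])
      m[b$arm, s$sample[si[1]]] <-
        if (normalize) wsum / sum(ol[si]) else wsum / 1e6
    }
  }
  omics_matrix(m, layer = "arm_cnv")
}

#' Call amplifications and deletions from log2 copy ratios
#'
#' A symmetric log2-ratio cutoff (1 by default) defines the calls:
#' `"amplified"` when value >= cutoff, `"deleted"` when value <= -cutoff,
#' otherwise `"neutral"`. The boundary is inclusive, so ties resolve toward
#' the called state.
#'
#' @param values Numeric matrix (or [omics_matrix()]) of log2 copy ratios.
#' @param cutoff Positive finite cutoff.
#' @return A character matrix of the same shape with values
#'   `"amplified"`, `"neutral"`, `"deleted"` (`NA` preserved).
#' @export
call_amp_del <- function(values, cutoff = 1) {
  if (!is.finite(cutoff) || cutoff <= 0) stopf("cutoff must be finite and > 0")
  v <- unclass(values)
  out <- ifelse(v >= cutoff, "amplified",
                ifelse(v <= -cutoff, "deleted", "neutral"))
  dimnames(out) <- dimnames(v)
  out
}

#' Tumor mutational burden
#'
#' Somatic mutations per megabase of captured coding sequence: all base
#' substitutions and indels are counted, synonymous (silent) alterations
#' included.
#'
#' @param mutations Mutation data.frame (see [read_maf()]).
#' @param coding_mb Size of the captured coding region in Mb (> 0).
#' @param samples Optional sample universe, so samples with zero mutations
#'   report TMB 0.
#' @return Named numeric vector of TMB per sample.
#' @export
tmb <- function(mutations, coding_mb, samples = NULL) {
  if (!is.numeric(coding_mb) || coding_mb <= 0)
    stopf("coding_mb must be positive")
  counts <- table(mutations$Tumor_Sample_Barcode)
  universe <- samples %||% names(counts)
  out <- stats::setNames(rep(0, length(universe)), universe)
  out[names(counts)] <- as.numeric(counts)
  out / coding_mb
}

#' 96-context mutation count matrix
#'
#' Single-nucleotide variants are tallied into the 96 pyrimidine-centred
#' trinucleotide contexts (see [sbs96_contexts()]). Purine-reference records
#' are reverse-complemented into the pyrimidine convention, so the matrix is
#' invariant to the strand on which a variant is reported. Non-SNV records
#' are ignored; column sums equal per-sample SNV counts.
#'
#' @param mutations Mutation data.frame with `Reference_Allele`,
#'   `Tumor_Seq_Allele2`, `Context` (ref-centred trinucleotide) and
#'   `Variant_Type`.
#' @param samples Optional sample universe for the columns.
#' @return A 96 x samples integer matrix in conventional row order.
#' @export
context_matrix <- function(mutations, samples = NULL) {
  ctx_levels <- sbs96_contexts()
  samples <- samples %||% unique(mutations$Tumor_Sample_Barcode)
  m <- matrix(0L, 96, length(samples), dimnames = list(ctx_levels, samples))
  snv <- mutations[mutations$Variant_Type %in% c("SNP", "SNV"), , drop = FALSE]
  if (!nrow(snv)) return(m)
  ref <- toupper(snv$Reference_Allele)
  alt <- toupper(snv$Tumor_Seq_Allele2)
  tri <- toupper(snv$Context)
  bad <- which(!ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T") |
                 is.na(tri) | nchar(tri) != 3 |
                 !grepl("^[ACGT]{3}$", ifelse(is.na(tri), "NNN", tri)))
  if (length(bad))
    stopf("unknown base symbol in SNV record(s) at row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  if (any(substr(tri, 2, 2) != ref))
    stopf("context middle base disagrees with the reference allele at row(s): %s",
          paste(utils::head(which(substr(tri, 2, 2) != ref), 5), collapse = ", "))
  flip <- ref %in% c("A", "G")
  ref[flip] <- revcomp(ref[flip])
  alt[flip] <- revcomp(alt[flip])
  tri[flip] <- revcomp(tri[flip])
  lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
  tab <- table(factor(lab, levels = ctx_levels),
               factor(snv$Tumor_Sample_Barcode, levels = samples))
  m[] <- as.integer(tab)
  m
}

#' Extract mutational signatures by NMF and match them to a reference
#'
#' Factorizes the 96 x samples context matrix `V ~ W H` with multiplicative
#' updates under the Frobenius objective (best of `n_restarts` seeded
#' restarts), column-normalizes the signature profiles `W`, scales the
#' exposures `H` accordingly, and matches each extracted signature to its
#' maximum-cosine reference profile.
#'
#' @param contexts 96 x samples count matrix.
#' @param k Number of signatures (>= 1, <= min(96, samples kept)).
#' @param reference 96 x R reference profile matrix (e.g.
#'   [reference_signatures()]).
#' @param n_restarts Random restarts; the fit with the lowest reconstruction
#'   error wins.
#' @param max_iter,tol Multiplicative-update iteration cap and relative
#'   objective-change tolerance.
#' @param seed Seed for the restarts.
#' @return A `signature_fit`: `profiles` (96 x k, columns sum to 1),
#'   `exposures` (k x samples, non-negative), `matches` (per signature:
#'   best reference and cosine), `objective` trace of the winning run.
#' @export
extract_signatures <- function(contexts, k, reference = reference_signatures(2),
                               n_restarts = 10, max_iter = 2000, tol = 1e-6,
                               seed = 1) {
  V <- unclass(contexts)
  zero <- colSums(V) == 0
  if (any(zero)) {
    warnf("dropping %d sample(s) with zero SNVs", sum(zero))
    V <- V[, !zero, drop = FALSE]
  }
  if (k < 1 || k > min(96, ncol(V)))
    stopf("k must lie in [1, min(96, samples)]")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(substream_seed(seed, "nmf") + r)
    fit <- nmf_mu(V, k, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  scale <- colSums(best$W)
  W <- sweep(best$W, 2L, scale, "/")
  H <- sweep(best$H, 1L, scale, "*")
  rownames(W) <- rownames(V)
  colnames(W) <- rownames(H) <- paste0("Sig", seq_len(k))
  colnames(H) <- colnames(V)
  cos <- t(apply(W, 2L, function(w)
    apply(reference, 2L, cosine_similarity, a = w)))
  matches <- data.frame(signature = colnames(W),
                        reference = colnames(reference)[max.col(cos)],
                        cosine = cos[cbind(seq_len(k), max.col(cos))],
                        stringsAsFactors = FALSE)
  structure(list(profiles = W, exposures = H, matches = matches,
                 cosines = cos, objective = best$trace, error = best$error),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("<signature_fit> %d signatures x %d samples, rel. error %.4g\n",
              nrow(x$exposures), ncol(x$exposures),
              x$error))
  print(x$matches)
  invisible(x)
}

# Multiplicative-update NMF for the Frobenius objective; returns the run's
# relative-error trace. Reconstruction error is ||V - WH||_F / ||V||_F.
nmf_mu <- function(V, k, max_iter = 2000, tol = 1e-6) {
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  vnorm <- sqrt(sum(V^2))
  err_prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((V - W %*% H)^2)) / vnorm
    trace <- c(trace, err)
    if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps))
      break
    err_prev <- err
  }
  list(W = W, H = H, error = err, trace = trace)
}

#' Pairwise co-occurrence / mutual exclusivity by Fisher's exact test
#'
#' For each event pair the 2x2 sample table is tested two-sided; direction
#' is `"co-occurring"` when the sample odds ratio exceeds 1, otherwise
#' `"exclusive"`. Degenerate margins (an event present in all or no
#' samples) yield p = 1 and are flagged.
#'
#' @param events Logical/0-1 matrix, events in rows, samples in columns.
#' @param pairs Optional 2-column matrix/data.frame of event-name pairs;
#'   all pairs when omitted.
#' @return Data.frame: `event_a`, `event_b`, `n_both`, `odds_ratio`, `p`,
#'   `q` (BH), `direction`, `degenerate`.
#' @export
cooccurrence <- function(events, pairs = NULL) {
  ev <- unclass(events) > 0
  if (is.null(rownames(ev))) rownames(ev) <- paste0("E", seq_len(nrow(ev)))
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(nrow(ev))), arr.ind = TRUE)
    pairs <- cbind(rownames(ev)[idx[, 1]], rownames(ev)[idx[, 2]])
  }
  pairs <- as.matrix(pairs)
  res <- apply(pairs, 1L, function(pr) {
    a <- ev[pr[1], ]; b <- ev[pr[2], ]
    tab <- table(factor(a, levels = c(TRUE, FALSE)),
                 factor(b, levels = c(TRUE, FALSE)))
    degen <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degen) {
      p <- 1; or <- NA_real_
    } else {
      p <- stats::fisher.test(tab)$p.value
      or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    }
    c(n_both = sum(a & b), or = or, p = p, degen = as.numeric(degen))
  })
  out <- data.frame(event_a = pairs[, 1], event_b = pairs[, 2],
                    n_both = res["n_both", ], odds_ratio = res["or", ],
                    p = res["p", ], q = stats::p.adjust(res["p", ], "BH"),
                    degenerate = res["degen", ] > 0,
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(is.na(out$odds_ratio), NA_character_,
                          ifelse(out$odds_ratio > 1, "co-occurring",
                                 "exclusive"))
  rownames(out) <- NULL
  out
}
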