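# Kinase-substrate enrichment analysis (KSEA): kinase activity z-scores
# from the collective phosphorylation status of mapped substrate sites.

#' KSEA kinase activity scores
#'
#' Per sample and kinase, the activity z-score is
#' \deqn{z = (\bar{s} - \bar{p}) \sqrt{m} / \delta}
#' where \eqn{\bar{s}} is the mean log2 abundance of the kinase's m mapped
#' substrate sites, \eqn{\bar{p}} the mean over all sites of the sample and
#' \eqn{\delta} the SD over all sites of the sample. With
#' `mode = "fold_change"` site abundances are first converted to log2 fold
#' changes against the cohort mean of the site, so z reflects differential
#' phosphorylation rather than absolute abundance. A two-sided normal p
#' accompanies each z. Kinases with fewer than `min_substrates` mapped
#' sites are dropped.
#'
#' Aggregation is by site (kinase-substrate *site* relationships); a site
#' shared by several kinases contributes to each of them.
#'
#' @param phospho Phosphosite [omics_matrix()] with site ids matching the
#'   map's `substrate_site` (`PROT_S123`); values on the linear scale are
#'   log2-transformed internally (`log2_input = FALSE`).
#' @param map Kinase-substrate data.frame (see [read_kinase_substrate()])
#'   or a named list kinase -> site ids.
#' @param min_substrates Minimum mapped sites per kinase.
#' @param mode `"abundance"` (mean log2 abundance) or `"fold_change"`
#'   (log2 FC vs the cohort mean per site).
#' @param log2_input Set `TRUE` when `phospho` is already log2-scaled.
#' @return A `ksea_result`: `z` (kinases x samples), `p` (same shape),
#'   `n_substrates` per kinase.
#' @export
ksea_scores <- function(phospho, map, min_substrates = 3,
                        mode = c("abundance", "fold_change"),
                        log2_input = FALSE) {
  mode <- match.arg(mode)
  m <- unclass(phospho)
  if (!log2_input) m <- log2(pmax(m, .Machine$double.xmin))
  if (mode == "fold_change") m <- m - rowMeans(m)
  if (is.data.frame(map))
    map <- split(map$substrate_site, map$kinase)
  map <- lapply(map, function(s) unique(intersect(s, rownames(m))))
  sizes <- vapply(map, length, integer(1))
  if (all(sizes == 0)) stopf("no kinase has a mappable substrate site")
  map <- map[sizes >= min_substrates]
  if (!length(map))
    stopf("no kinase with >= %d mapped substrate sites", min_substrates)
  p_bar <- colMeans(m)
  delta <- apply(m, 2L, stats::sd)
  z <- do.call(rbind, lapply(map, function(sites) {
    s_bar <- colMeans(m[sites, , drop = FALSE])
    (s_bar - p_bar) * sqrt(length(sites)) / delta
  }))
  dimnames(z) <- list(names(map), colnames(m))
  pval <- 2 * stats::pnorm(-abs(z))
  structure(list(z = z, p = pval,
                 n_substrates = vapply(map, length, integer(1)),
                 mode = mode),
            class = "ksea_result")
}

#' @export
print.ksea_result <- function(x, ...) {
  cat(sprintf("<ksea_result> %d kinases x %d samples (mode: %s)\n",
              nrow(x$z), ncol(x$z), x$mode))
  invisible(x)
}

#' Link kinase activity to overall survival
#'
#' For every kinase, the activity is dichotomized at the maximally selected
#' rank-statistic cutpoint and the two groups compared by Kaplan-Meier /
#' log-rank, with the hazard ratio (high vs low) from a univariate Cox fit.
#' Kinases without an admissible cutpoint (e.g. constant activity) are
#' flagged and returned with `NA` statistics.
#'
#' @param activity A `ksea_result` or kinases x samples matrix.
#' @param survival Survival data.frame (`sample`, `os_time`, `os_event`).
#' @param minprop Minimum group proportion for the cutpoint scan.
#' @return Data.frame: `kinase`, `cutpoint`, `hr`, `logrank_p`, `flagged`.
#' @export
activity_survival_link <- function(activity, survival, minprop = 0.1) {
  z <- if (inherits(activity, "ksea_result")) activity$z else unclass(activity)
  shared <- intersect(colnames(z), survival$sample)
  if (length(shared) < 20) stopf("need >= 20 shared samples")
  sv <- survival[match(shared, survival$sample), ]
  rows <- lapply(rownames(z), function(kin) {
    marker <- z[kin, shared]
    cp <- tryCatch(optimal_cutpoint(sv, marker, minprop = minprop),
                   error = function(e) NULL)
    if (is.null(cp))
      return(data.frame(kinase = kin, cutpoint = NA_real_, hr = NA_real_,
                        logrank_p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    high <- as.integer(marker > cp$cutpoint)
    cox <- cox_univariate(sv, high)
    data.frame(kinase = kin, cutpoint = cp$cutpoint, hr = cox$hr,
               logrank_p = cp$logrank_p, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
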