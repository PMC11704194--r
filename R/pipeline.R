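# Pipeline orchestration: a validated configuration drives the stages
# (simulate -> CNV genomics -> quantification -> cis/trans ledger ->
# enrichment scores -> KSEA -> consensus clustering -> survival) with
# plain-file handoff between stages, one structured log line per stage and
# a markdown report. Outputs are idempotent given identical config + seed.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "protegrate_out",
    cohort = list(n_samples = 200L, n_genes = 2000L, noise_sd = 0.5),
    thresholds = list(amp_del_cutoff = 1, phospho_min_prob = 0.75,
                      fc_threshold = 1.5, p_threshold = 0.05,
                      alpha = 0.25, min_size = 10, minprop = 0.1),
    clustering = list(k_min = 2L, k_max = 5L, reps = 200L, pItem = 0.8,
                      pFeature = 1.0, top_var_fraction = 0.5),
    signatures = list(k = 2L, n_restarts = 10L),
    tmb = list(coding_mb = 31.6),
    stages = list(simulate = TRUE, cnv = TRUE, quant = TRUE,
                  cistrans = TRUE, score = TRUE, ksea = TRUE,
                  cluster = TRUE, survival = TRUE))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys at every
#' level (typo safety), materializes defaults for everything omitted and
#' range-checks the thresholds.
#'
#' @param config Path to a YAML file or a nested list.
#' @return The normalized config (all defaults filled in), invisibly
#'   classed `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- default_pipeline_config()
  merged <- merge_config(defaults, config, path = "")
  th <- merged$thresholds
  if (th$amp_del_cutoff <= 0) stopf("amp_del_cutoff must be > 0")
  if (th$phospho_min_prob < 0 || th$phospho_min_prob > 1)
    stopf("phospho_min_prob must lie in [0, 1]")
  if (th$p_threshold <= 0 || th$p_threshold >= 1)
    stopf("p_threshold must lie in (0, 1)")
  if (th$minprop <= 0 || th$minprop >= 0.5)
    stopf("minprop must lie in (0, 0.5)")
  if (merged$clustering$pItem <= 0 || merged$clustering$pItem > 1)
    stopf("pItem must lie in (0, 1]")
  if (merged$clustering$k_min < 2 ||
      merged$clustering$k_max < merged$clustering$k_min)
    stopf("clustering k range invalid")
  structure(merged, class = "pipeline_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" under '", path, "'") else "",
          paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, if (nzchar(path)) ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

# Small polynomial hash of the serialized config for provenance lines.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(config)),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_write <- function(d, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protegrate config=%s seed=%d", hash, seed), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the integrated proteogenomic pipeline on a synthetic cohort
#'
#' Sequences the package's stages end to end: cohort simulation, gene/arm
#' copy-number summaries with amplification/deletion calls and TMB,
#' mutational-signature extraction, FOT quantification, the cis-effect
#' ledger across mRNA / protein / phosphoprotein, pathway scores on the
#' planted programs, KSEA kinase activities, consensus clustering of the
#' proteome, and survival contrasts of the recovered clusters. Every stage
#' writes its table under `config$out_dir` with a provenance header
#' (config hash + seed) and logs one structured line.
#'
#' @param config A [validate_config()] result, path, or list.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(stage, ...) {
    if (!quiet)
      message(sprintf("[protegrate] stage=%s %s", stage,
                      paste(sprintf("%s=%s", names(list(...)),
                                    unlist(list(...))), collapse = " ")))
  }
  out <- list(config = cfg, hash = hash, paths = character(0))
  emit <- function(name, d) {
    p <- file.path(cfg$out_dir, name)
    provenance_write(d, p, hash, cfg$seed)
    out$paths[[name]] <<- p
  }

  ## simulate
  spec <- cohort_spec(n_samples = cfg$cohort$n_samples,
                      n_genes = cfg$cohort$n_genes,
                      noise_sd = cfg$cohort$noise_sd, seed = cfg$seed)
  cohort <- generate_cohort(spec)
  if (isTRUE(cfg$stages$simulate)) {
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"), overwrite = TRUE)
    log_line("simulate", samples = spec$n_samples, genes = spec$n_genes)
  }
  out$cohort <- cohort

  ## cnv genomics
  if (isTRUE(cfg$stages$cnv)) {
    gcn <- gene_copy_number(cohort$segments, cohort$gene_model)
    arms <- arm_score(cohort$segments, cohort$gene_model)
    calls <- call_amp_del(arms, cutoff = cfg$thresholds$amp_del_cutoff)
    burden <- tmb(cohort$mutations, coding_mb = cfg$tmb$coding_mb,
                  samples = colnames(gcn))
    ctx <- context_matrix(cohort$mutations, samples = colnames(gcn))
    sig <- extract_signatures(ctx, k = cfg$signatures$k,
                              reference = cohort$signatures,
                              n_restarts = cfg$signatures$n_restarts,
                              seed = cfg$seed)
    emit("arm_scores.tsv", data.frame(arm = rownames(arms),
                                      unclass(arms), check.names = FALSE))
    emit("arm_calls.tsv", data.frame(arm = rownames(calls),
                                     calls, check.names = FALSE))
    emit("tmb.tsv", data.frame(sample = names(burden), tmb = burden))
    emit("signature_matches.tsv", sig$matches)
    out$gene_cn <- gcn; out$arm_scores <- arms; out$signature_fit <- sig
    log_line("cnv", arms = nrow(arms), signatures = cfg$signatures$k)
  } else {
    gcn <- gene_copy_number(cohort$segments, cohort$gene_model)
    out$gene_cn <- gcn
  }

  ## quantification
  if (isTRUE(cfg$stages$quant)) {
    counts <- vapply(cohort$protein_seqs, observable_peptides, integer(1))
    ib <- ibaq(cohort$peptides, counts)
    fot <- fot_normalize(ib)
    emit("fot_subset.tsv", data.frame(protein = rownames(fot),
                                      unclass(fot), check.names = FALSE))
    out$fot <- fot
    log_line("quant", proteins = nrow(fot))
  }

  ## cis/trans ledger
  if (isTRUE(cfg$stages$cistrans)) {
    ledgers <- list(
      mrna = correlate_layers(gcn, cohort$mrna, mode = "cis_only"),
      protein = correlate_layers(gcn, cohort$protein, mode = "cis_only"),
      phosphoprotein = correlate_layers(gcn, collapse_phospho(cohort$phospho),
                                        mode = "cis_only"))
    ledger <- do.call(rbind, ledgers)
    emit("cis_ledger.tsv", ledger)
    out$ledgers <- ledgers
    out$cis_venn <- cis_overlap(ledgers, threshold = cfg$thresholds$p_threshold)
    log_line("cistrans", pairs = nrow(ledger),
             sig = sum(ledger$p < cfg$thresholds$p_threshold, na.rm = TRUE))
  }

  ## enrichment scores
  if (isTRUE(cfg$stages$score)) {
    programs <- lapply(spec$cluster_spec, `[[`, "program")
    names(programs) <- vapply(spec$cluster_spec, `[[`, character(1), "cluster")
    sc <- ssgsea(cohort$protein, programs, alpha = cfg$thresholds$alpha,
                 min_size = cfg$thresholds$min_size)
    emit("pathway_scores.tsv", data.frame(set = rownames(sc), unclass(sc),
                                          check.names = FALSE))
    out$pathway_scores <- sc
    log_line("score", sets = nrow(sc))
  }

  ## ksea
  if (isTRUE(cfg$stages$ksea)) {
    kmap <- lapply(spec$kinase_spec, `[[`, "sites")
    names(kmap) <- vapply(spec$kinase_spec, `[[`, character(1), "kinase")
    ks <- ksea_scores(cohort$phospho, kmap)
    emit("kinase_activity.tsv", data.frame(kinase = rownames(ks$z),
                                           ks$z, check.names = FALSE))
    out$ksea <- ks
    log_line("ksea", kinases = nrow(ks$z))
  }

  ## consensus clustering
  if (isTRUE(cfg$stages$cluster)) {
    cc <- consensus_cluster(cohort$protein,
                            k_range = cfg$clustering$k_min:cfg$clustering$k_max,
                            reps = cfg$clustering$reps,
                            pItem = cfg$clustering$pItem,
                            pFeature = cfg$clustering$pFeature,
                            top_var_fraction = cfg$clustering$top_var_fraction,
                            seed = cfg$seed)
    lab <- cc$labels[[as.character(cc$chosen_k)]]
    emit("cluster_labels.tsv", data.frame(sample = names(lab), cluster = lab))
    out$clustering <- cc
    log_line("cluster", chosen_k = cc$chosen_k)
  }

  ## survival
  if (isTRUE(cfg$stages$survival)) {
    grp <- if (!is.null(out$clustering))
      out$clustering$labels[[as.character(out$clustering$chosen_k)]]
    else cohort$truth$clusters
    km <- km_logrank(cohort$survival, grp)
    srows <- data.frame(contrast = "clusters", chisq = km$chisq,
                        df = km$df, p = km$p)
    emit("survival_tests.tsv", srows)
    out$km <- km
    log_line("survival", logrank_p = signif(km$p, 3))
  }

  ## report
  rpt <- c("# protegrate pipeline report", "",
           sprintf("- config hash: `%s`", hash),
           sprintf("- seed: %d", cfg$seed),
           sprintf("- cohort: %d samples x %d genes (noise_sd = %.3g)",
                   cfg$cohort$n_samples, cfg$cohort$n_genes,
                   cfg$cohort$noise_sd),
           sprintf("- stages run: %s",
                   paste(names(Filter(isTRUE, cfg$stages)), collapse = ", ")),
           if (!is.null(out$clustering))
             sprintf("- consensus clustering chose k = %d",
                     out$clustering$chosen_k),
           if (!is.null(out$km))
             sprintf("- log-rank over clusters: chisq = %.2f, p = %.3g",
                     out$km$chisq, out$km$p))
  writeLines(rpt[!vapply(rpt, is.null, logical(1))],
             file.path(cfg$out_dir, "report.md"))
  invisible(out)
}
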