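# Synthetic multi-omics cohort generator with known ground truth.
#
# The generator plants the statistical structure the downstream stages are
# designed to detect: arm-level losses and focal amplifications/deletions in
# the copy-number segments, dosage (cis) coupling between a gene's copy
# ratio and its mRNA/protein abundance, cluster-specific proteomic programs,
# kinase-driven phosphosite shifts, trinucleotide mutation spectra drawn
# from reference signature mixtures, and survival hazards tied to planted
# labels. All randomness flows through one global seed via a fixed
# substream scheme (see substream_seed), so adding a stream never perturbs
# the draws of another.

#' The 96 trinucleotide mutation contexts in conventional order
#'
#' Six pyrimidine-centred base substitutions (C>A, C>G, C>T, T>A, T>C, T>G),
#' each within 16 combinations of 5' and 3' neighbour bases, ordered
#' substitution-major then alphabetically by flanks: `A[C>A]A`, `A[C>A]C`,
#' ..., `T[T>G]T`.
#'
#' @return Character vector of 96 context labels.
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))
  }))
}

#' Synthetic reference mutational-signature profiles
#'
#' Deterministic, well-separated 96-context profiles used as the reference
#' catalogue for signature extraction tests and for the synthetic cohort's
#' mutation spectra. These are synthetic stand-ins built in code (reference
#' catalogues such as COSMIC are not redistributed here); each profile
#' concentrates its mass on one substitution class with a flank preference,
#' so pairwise cosine similarities are low.
#'
#' @param n Number of signatures (2 to 6).
#' @return A 96 x n column-stochastic matrix with context rownames.
#' @export
reference_signatures <- function(n = 2) {
  if (n < 1 || n > 6) stopf("n must be between 1 and 6")
  ctx <- sbs96_contexts()
  subs_block <- rep(1:6, each = 16)
  # one dominant substitution class per signature, peaked at one 3' flank
  peak3 <- c("G", "A", "T", "C", "G", "A")
  profiles <- sapply(seq_len(n), function(k) {
    w <- rep(0.02, 96)
    block <- which(subs_block == k)
    w[block] <- 0.5
    w[block[substr(ctx[block], 7, 7) == peak3[k]]] <- 3
    w / sum(w)
  })
  rownames(profiles) <- ctx
  colnames(profiles) <- paste0("SIG_", LETTERS[seq_len(n)])
  profiles
}

#' Build a synthetic gene model
#'
#' Genes are laid out evenly along chromosome arms; each arm spans 50 Mb
#' (p arm first half of the chromosome, q arm second half), genes are 20 kb
#' long. Coordinates are 1-based inclusive.
#'
#' @param n_genes Number of genes.
#' @param arms Arm labels, e.g. `c("1p","1q","4q")`.
#' @return A data.frame with `gene`, `chrom`, `start`, `end`, `arm`.
#' @export
synthetic_gene_model <- function(n_genes,
                                 arms = c("1p", "1q", "4p", "4q",
                                          "9p", "9q", "17p", "17q")) {
  arm_len <- 5e7
  per_arm <- rep(n_genes %/% length(arms), length(arms))
  extra <- n_genes %% length(arms)
  if (extra > 0) per_arm[seq_len(extra)] <- per_arm[seq_len(extra)] + 1L
  rows <- lapply(seq_along(arms), function(i) {
    a <- arms[i]
    chrom <- sub("[pq]$", "", a)
    offset <- if (grepl("q$", a)) arm_len else 0
    k <- per_arm[i]
    if (k == 0) return(NULL)
    spacing <- floor((arm_len - 3e4) / k)
    start <- offset + 1e4 + (seq_len(k) - 1L) * spacing
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + 2e4 - 1L), arm = a,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d <- d[order(match(d$arm, arms), d$start), ]
  d <- data.frame(gene = sprintf("G%04d", seq_len(nrow(d))), d,
                  stringsAsFactors = FALSE)
  rownames(d) <- d$gene
  d
}

#' Specify a synthetic multi-omics cohort
#'
#' Defaults describe the cohort used throughout the package's tests: 200
#' tumors over 2,000 genes with one recurrent arm loss (4q, 35% of samples),
#' one focal deletion and one focal amplification, 20 dosage-coupled (cis)
#' genes on the lost arm, three proteomic clusters with disjoint 50-gene
#' programs, two planted kinases driving 10 substrate phosphosites each,
#' a two-signature mutation spectrum and cluster-dependent survival hazards.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param arm_events List of `list(arm=, fraction=, shift=)`: fraction of
#'   samples carrying the event and the mean log2 copy-ratio shift.
#' @param focal_events List of `list(locus=, genes=, fraction=, shift=)`;
#'   `genes` is a character vector of member genes.
#' @param cis_genes `data.frame(gene, slope)` of dosage-coupled genes; the
#'   log2 abundance of a cis gene gains `slope * copy_ratio`.
#' @param cluster_spec List of `list(cluster=, fraction=, program=, shift=)`;
#'   `program` is a gene vector up-shifted by `shift` log2 units in that
#'   cluster's samples.
#' @param kinase_spec List of `list(kinase=, sites=, activity=)`; `sites`
#'   are phosphosite ids (`GENE_S123`), `activity` a named numeric of
#'   log2 shifts per cluster label.
#' @param signature_mix Named weights over the columns of
#'   [reference_signatures()]; must sum to 1. Per-sample exposures are drawn
#'   from a Dirichlet distribution with mean `signature_mix` and
#'   concentration `signature_concentration` (weights of exactly 0 stay 0).
#' @param signature_concentration Dirichlet concentration for per-sample
#'   signature exposures.
#' @param mutation_rate Expected somatic mutations per sample (Poisson).
#' @param indel_fraction Fraction of mutations emitted as small indels
#'   (no trinucleotide context).
#' @param survival_spec `list(baseline_hazard=, hr=, censor_max=)`:
#'   exponential baseline hazard per month, named hazard ratios per cluster
#'   label, and the administrative censoring horizon (months).
#' @param n_background_sites Number of phosphosites not driven by any
#'   planted kinase.
#' @param noise_sd Residual SD on the log2 scale (> 0).
#' @param arm_noise_sd SD of per-sample arm-level copy-ratio baseline noise.
#' @param seed Global integer seed.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_samples = 200, n_genes = 2000,
                        arm_events = NULL, focal_events = NULL,
                        cis_genes = NULL, cluster_spec = NULL,
                        kinase_spec = NULL,
                        signature_mix = c(SIG_A = 0.7, SIG_B = 0.3),
                        signature_concentration = 15,
                        mutation_rate = 100, indel_fraction = 0.05,
                        survival_spec = NULL, n_background_sites = 150,
                        noise_sd = 0.5, arm_noise_sd = 0.1, seed = 1) {
  if (n_samples < 1 || n_genes < 8) stopf("cohort too small")
  genes <- synthetic_gene_model(n_genes)
  if (is.null(arm_events))
    arm_events <- list(list(arm = "4q", fraction = 0.35, shift = -1.2))
  if (is.null(focal_events)) {
    g9p <- genes$gene[genes$arm == "9p"]
    g17q <- genes$gene[genes$arm == "17q"]
    focal_events <- list(
      list(locus = "9p_del", genes = utils::head(g9p, 5), fraction = 0.3,
           shift = -1.3),
      list(locus = "17q_amp", genes = utils::head(g17q, 5), fraction = 0.25,
           shift = 1.3))
  }
  if (is.null(cis_genes)) {
    if (length(arm_events) > 0) {
      pool <- genes$gene[genes$arm == arm_events[[1]]$arm]
      cis_genes <- data.frame(gene = utils::head(pool, 20), slope = 1.5,
                              stringsAsFactors = FALSE)
    } else {
      cis_genes <- data.frame(gene = character(), slope = numeric())
    }
  }
  if (is.null(cluster_spec)) {
    pool <- genes$gene[genes$arm %in% c("1p", "1q", "9q")]
    n_prog <- min(50, length(pool) %/% 3)
    cluster_spec <- list(
      list(cluster = "C1", fraction = 0.3,
           program = pool[seq_len(n_prog)], shift = 1),
      list(cluster = "C2", fraction = 0.4,
           program = pool[n_prog + seq_len(n_prog)], shift = 1),
      list(cluster = "C3", fraction = 0.3,
           program = pool[2 * n_prog + seq_len(n_prog)], shift = 1))
  }
  if (is.null(kinase_spec)) {
    labs <- vapply(cluster_spec, `[[`, character(1), "cluster")
    host <- genes$gene[genes$arm == "17p"]
    act1 <- stats::setNames(rep(0, length(labs)), labs)
    if (length(labs)) act1[1] <- 1
    act2 <- stats::setNames(rep(0, length(labs)), labs)
    if (length(labs) > 1) act2[2] <- 0.5
    kinase_spec <- list(
      list(kinase = "KIN_A",
           sites = paste0(utils::head(host, 10), "_S", 11:20), activity = act1),
      list(kinase = "KIN_B",
           sites = paste0(utils::head(host[-(1:10)], 10), "_S", 21:30),
           activity = act2))
  }
  if (is.null(survival_spec)) {
    labs <- vapply(cluster_spec, `[[`, character(1), "cluster")
    hr <- stats::setNames(rep(1, length(labs)), labs)
    if (length(labs) > 1) hr[2] <- 2
    survival_spec <- list(baseline_hazard = 0.015, hr = hr, censor_max = 120)
  }
  spec <- structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    genes = genes, arm_events = arm_events, focal_events = focal_events,
    cis_genes = cis_genes, cluster_spec = cluster_spec,
    kinase_spec = kinase_spec, signature_mix = signature_mix,
    signature_concentration = signature_concentration,
    mutation_rate = mutation_rate, indel_fraction = indel_fraction,
    survival_spec = survival_spec, n_background_sites = n_background_sites,
    noise_sd = noise_sd, arm_noise_sd = arm_noise_sd,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$noise_sd <= 0) stopf("noise_sd must be positive")
  fr <- vapply(spec$arm_events, `[[`, numeric(1), "fraction")
  if (any(fr < 0 | fr > 1)) stopf("arm event fractions must lie in [0, 1]")
  fr <- vapply(spec$focal_events, `[[`, numeric(1), "fraction")
  if (any(fr < 0 | fr > 1)) stopf("focal event fractions must lie in [0, 1]")
  cf <- vapply(spec$cluster_spec, `[[`, numeric(1), "fraction")
  if (length(cf) && sum(cf) > 1 + 1e-8)
    stopf("cluster fractions sum to %.3f > 1", sum(cf))
  if (abs(sum(spec$signature_mix) - 1) > 1e-8)
    stopf("signature mixture weights must sum to 1")
  if (length(spec$signature_mix) < 1 ||
      length(spec$signature_mix) > 6)
    stopf("signature_mix must cover 1 to 6 reference signatures")
  focal_genes <- unlist(lapply(spec$focal_events, `[[`, "genes"))
  dup <- unique(focal_genes[duplicated(focal_genes)])
  if (length(dup))
    stopf("focal loci overlap on gene(s): %s", paste(dup, collapse = ", "))
  missing_g <- setdiff(c(spec$cis_genes$gene, focal_genes,
                         unlist(lapply(spec$cluster_spec, `[[`, "program"))),
                       spec$genes$gene)
  if (length(missing_g))
    stopf("planted genes not in gene universe: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d samples x %d genes | %d arm events, ",
                     "%d focal events, %d cis genes, %d clusters, ",
                     "%d kinases | noise_sd=%.2g seed=%d\n"),
              x$n_samples, x$n_genes, length(x$arm_events),
              length(x$focal_events), nrow(x$cis_genes),
              length(x$cluster_spec), length(x$kinase_spec),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic multi-omics cohort
#'
#' Produces copy-number segments, a mutation table, mRNA / protein /
#' phosphosite abundance matrices, a peptide-level intensity table, a
#' survival table and the ground truth behind all of them. Deterministic
#' under a fixed `spec$seed`.
#'
#' Abundances are generated on the log2 scale (baseline + planted effects +
#' Gaussian noise) and exponentiated to positive FOT-like values in the
#' emitted matrices; rank-based downstream statistics are unaffected.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list: `segments`, `mutations`, `mrna`,
#'   `protein`, `phospho` (each an [omics_matrix()]), `peptides`,
#'   `protein_seqs`, `survival`, `gene_model`, `signatures` (the reference
#'   profiles used) and `truth` (cluster labels, carrier flags, cis genes,
#'   kinase activities, signature exposures, gene copy ratios).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  genes <- spec$genes
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  arms <- unique(genes$arm)

  ## --- cluster labels ------------------------------------------------
  set.seed(substream_seed(spec$seed, "clusters"))
  if (length(spec$cluster_spec)) {
    labs <- vapply(spec$cluster_spec, `[[`, character(1), "cluster")
    fr <- vapply(spec$cluster_spec, `[[`, numeric(1), "fraction")
    counts <- floor(fr * n)
    short <- n - sum(counts)
    if (short > 0) counts[order(fr, decreasing = TRUE)[seq_len(short)]] <-
        counts[order(fr, decreasing = TRUE)[seq_len(short)]] + 1L
    clusters <- sample(rep(labs, counts))
  } else {
    clusters <- rep("C1", n)
  }
  names(clusters) <- samples

  ## --- segments and gene copy ratios ---------------------------------
  set.seed(substream_seed(spec$seed, "segments"))
  arm_carrier <- matrix(FALSE, length(spec$arm_events), n,
                        dimnames = list(vapply(spec$arm_events, `[[`,
                                               character(1), "arm"), samples))
  for (i in seq_along(spec$arm_events))
    arm_carrier[i, ] <- stats::runif(n) < spec$arm_events[[i]]$fraction
  focal_carrier <- matrix(FALSE, length(spec$focal_events), n,
                          dimnames = list(vapply(spec$focal_events, `[[`,
                                                 character(1), "locus"),
                                          samples))
  for (i in seq_along(spec$focal_events))
    focal_carrier[i, ] <- stats::runif(n) < spec$focal_events[[i]]$fraction

  arm_shift <- stats::setNames(rep(0, length(arms)), arms)
  for (ev in spec$arm_events) arm_shift[ev$arm] <- ev$shift
  arm_bounds <- do.call(rbind, lapply(arms, function(a) {
    g <- genes[genes$arm == a, ]
    data.frame(arm = a, chrom = g$chrom[1], start = min(g$start) - 1e4,
               end = max(g$end) + 1e4, stringsAsFactors = FALSE)
  }))
  # per-sample per-arm baseline log2 ratio
  arm_base <- matrix(stats::rnorm(length(arms) * n, 0, spec$arm_noise_sd),
                     length(arms), n, dimnames = list(arms, samples))
  for (i in seq_along(spec$arm_events)) {
    a <- spec$arm_events[[i]]$arm
    arm_base[a, arm_carrier[i, ]] <- arm_base[a, arm_carrier[i, ]] +
      spec$arm_events[[i]]$shift
  }
  focal_bounds <- lapply(spec$focal_events, function(ev) {
    g <- genes[genes$gene %in% ev$genes, ]
    list(locus = ev$locus, arm = g$arm[1], chrom = g$chrom[1],
         start = min(g$start), end = max(g$end), shift = ev$shift,
         genes = ev$genes)
  })

  seg_rows <- vector("list", n)
  for (s in seq_len(n)) {
    rows <- list()
    for (ai in seq_along(arms)) {
      a <- arms[ai]
      b <- arm_bounds[arm_bounds$arm == a, ]
      r <- arm_base[a, s]
      cuts <- list(c(b$start, b$end, r))
      for (fi in seq_along(focal_bounds)) {
        fb <- focal_bounds[[fi]]
        if (fb$arm == a && focal_carrier[fi, s]) {
          # split the arm segment around the focal interval
          base <- cuts[[length(cuts)]]
          cuts <- list()
          if (fb$start > b$start)
            cuts[[length(cuts) + 1]] <- c(b$start, fb$start - 1, r)
          cuts[[length(cuts) + 1]] <- c(fb$start, fb$end, r + fb$shift)
          if (fb$end < b$end)
            cuts[[length(cuts) + 1]] <- c(fb$end + 1, b$end, r)
        }
      }
      for (cc in cuts)
        rows[[length(rows) + 1]] <- data.frame(
          sample = samples[s], chrom = b$chrom, start = cc[1], end = cc[2],
          num_mark = max(10L, as.integer((cc[2] - cc[1]) / 1e5)),
          log2ratio = cc[3], stringsAsFactors = FALSE)
    }
    seg_rows[[s]] <- do.call(rbind, rows)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  # true gene-level copy ratio (by construction)
  gene_cn <- arm_base[genes$arm, , drop = FALSE]
  rownames(gene_cn) <- genes$gene
  for (fi in seq_along(focal_bounds)) {
    fb <- focal_bounds[[fi]]
    gene_cn[fb$genes, focal_carrier[fi, ]] <-
      gene_cn[fb$genes, focal_carrier[fi, ], drop = FALSE] + fb$shift
  }

  ## --- expression (mRNA, protein, phosphosites) ----------------------
  set.seed(substream_seed(spec$seed, "expression"))
  baseline <- stats::setNames(stats::rnorm(spec$n_genes, 8, 1), genes$gene)
  systematic <- matrix(baseline, spec$n_genes, n,
                       dimnames = list(genes$gene, samples))
  if (nrow(spec$cis_genes)) {
    cg <- spec$cis_genes
    systematic[cg$gene, ] <- systematic[cg$gene, , drop = FALSE] +
      cg$slope * gene_cn[cg$gene, , drop = FALSE]
  }
  for (cs in spec$cluster_spec) {
    member <- clusters == cs$cluster
    systematic[cs$program, member] <- systematic[cs$program, member] + cs$shift
  }
  mrna_log <- systematic + matrix(stats::rnorm(length(systematic), 0,
                                               spec$noise_sd),
                                  nrow(systematic))
  prot_log <- systematic + matrix(stats::rnorm(length(systematic), 0,
                                               spec$noise_sd),
                                  nrow(systematic))

  # phosphosites: planted kinase substrates + background sites
  kin_sites <- unlist(lapply(spec$kinase_spec, `[[`, "sites"))
  bg_host <- sample(genes$gene, spec$n_background_sites, replace = TRUE)
  bg_sites <- paste0(bg_host, "_S", sample(1:500, spec$n_background_sites,
                                           replace = TRUE))
  bg_sites <- make.unique(bg_sites, sep = "x")
  site_ids <- c(kin_sites, bg_sites)
  site_base <- stats::rnorm(length(site_ids), 6, 1)
  phos_log <- matrix(site_base, length(site_ids), n,
                     dimnames = list(site_ids, samples))
  kin_activity <- matrix(0, length(spec$kinase_spec), n,
                         dimnames = list(vapply(spec$kinase_spec, `[[`,
                                                character(1), "kinase"),
                                         samples))
  for (ki in seq_along(spec$kinase_spec)) {
    ks <- spec$kinase_spec[[ki]]
    act <- ks$activity[clusters]
    act[is.na(act)] <- 0
    kin_activity[ki, ] <- act
    phos_log[ks$sites, ] <- sweep(phos_log[ks$sites, , drop = FALSE], 2L,
                                  act, "+")
  }
  # substrate proteins also inherit a dampened cis of their host protein
  phos_log <- phos_log + matrix(stats::rnorm(length(phos_log), 0,
                                             spec$noise_sd), nrow(phos_log))

  ## --- peptides -------------------------------------------------------
  set.seed(substream_seed(spec$seed, "peptides"))
  n_pep_prot <- min(30L, spec$n_genes)
  pep_prot <- genes$gene[seq_len(n_pep_prot)]
  protein_seqs <- stats::setNames(vapply(pep_prot, function(g)
    random_tryptic_sequence(), character(1)), pep_prot)
  pep_rows <- lapply(pep_prot, function(g) {
    peps <- tryptic_peptides(protein_seqs[[g]], min_len = 7, max_len = 30)
    k <- length(peps)
    w <- stats::runif(k)
    w <- w / sum(w)
    lin <- 2^prot_log[g, ]
    data.frame(sample = rep(samples, each = k),
               protein = g, peptide = rep(peps, n),
               intensity = as.vector(outer(w * k, lin)),
               stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, pep_rows)
  rownames(peptides) <- NULL

  ## --- mutations ------------------------------------------------------
  set.seed(substream_seed(spec$seed, "mutations"))
  sigs <- reference_signatures(length(spec$signature_mix))
  mix <- spec$signature_mix
  if (is.null(names(mix))) names(mix) <- colnames(sigs)
  k <- length(mix)
  expo <- sapply(seq_len(n), function(i) {
    g <- stats::rgamma(k, shape = spec$signature_concentration * mix)
    if (sum(g) == 0) g <- mix
    g / sum(g)
  })
  dimnames(expo) <- list(names(mix), samples)
  ctx <- sbs96_contexts()
  mut_rows <- lapply(seq_len(n), function(i) {
    m <- stats::rpois(1, spec$mutation_rate)
    if (m == 0) return(NULL)
    n_indel <- stats::rbinom(1, m, spec$indel_fraction)
    n_snv <- m - n_indel
    rows <- list()
    if (n_snv > 0) {
      sig_of <- sample(seq_len(k), n_snv, replace = TRUE, prob = expo[, i])
      ctx_idx <- vapply(sig_of, function(s)
        sample.int(96, 1, prob = sigs[, s]), integer(1))
      lab <- ctx[ctx_idx]
      ref <- substr(lab, 3, 3)
      alt <- substr(lab, 5, 5)
      tri <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
      # scramble strand representation for half the records
      flip <- stats::runif(n_snv) < 0.5
      ref[flip] <- revcomp(ref[flip])
      alt[flip] <- revcomp(alt[flip])
      tri[flip] <- revcomp(tri[flip])
      gi <- sample.int(nrow(genes), n_snv, replace = TRUE)
      rows$snv <- data.frame(
        Tumor_Sample_Barcode = samples[i], Hugo_Symbol = genes$gene[gi],
        Chromosome = genes$chrom[gi],
        Start_Position = genes$start[gi] +
          sample.int(2e4, n_snv, replace = TRUE) - 1L,
        Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
        Variant_Classification = sample(c("Missense_Mutation", "Silent"),
                                        n_snv, replace = TRUE,
                                        prob = c(0.8, 0.2)),
        Variant_Type = "SNP", Context = tri, stringsAsFactors = FALSE)
    }
    if (n_indel > 0) {
      gi <- sample.int(nrow(genes), n_indel, replace = TRUE)
      rows$indel <- data.frame(
        Tumor_Sample_Barcode = samples[i], Hugo_Symbol = genes$gene[gi],
        Chromosome = genes$chrom[gi],
        Start_Position = genes$start[gi] +
          sample.int(2e4, n_indel, replace = TRUE) - 1L,
        Reference_Allele = "A", Tumor_Seq_Allele2 = "-",
        Variant_Classification = "Frame_Shift_Del", Variant_Type = "DEL",
        Context = NA_character_, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  mutations <- do.call(rbind, mut_rows)
  rownames(mutations) <- NULL

  ## --- survival -------------------------------------------------------
  set.seed(substream_seed(spec$seed, "survival"))
  sv <- spec$survival_spec
  hr <- sv$hr[clusters]
  hr[is.na(hr)] <- 1
  t_event <- stats::rexp(n, rate = sv$baseline_hazard * hr)
  t_cens <- stats::runif(n, 0, sv$censor_max)
  survival <- data.frame(sample = samples,
                         os_time = pmin(t_event, t_cens),
                         os_event = as.integer(t_event <= t_cens),
                         cluster = unname(clusters),
                         stringsAsFactors = FALSE)

  structure(list(
    segments = segments, mutations = mutations,
    mrna = omics_matrix(2^mrna_log, layer = "mrna"),
    protein = omics_matrix(2^prot_log, layer = "protein"),
    phospho = omics_matrix(2^phos_log, layer = "phosphosite"),
    peptides = peptides, protein_seqs = protein_seqs,
    survival = survival, gene_model = genes, signatures = sigs,
    truth = list(clusters = clusters, arm_carriers = arm_carrier,
                 focal_carriers = focal_carrier,
                 cis_genes = spec$cis_genes, kinase_activity = kin_activity,
                 exposures = expo, gene_cn = gene_cn),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d samples | %d segments, ",
                     "%d mutations, %d proteins, %d phosphosites\n"),
              x$spec$n_samples, nrow(x$segments),
              if (is.null(x$mutations)) 0L else nrow(x$mutations),
              nrow(x$protein), nrow(x$phospho)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of standard flat files
#'
#' Emits `segments.seg`, `mutations.maf`, `mrna.gct`, `protein.gct`,
#' `phospho.gct`, `peptides.tsv`, `survival.tsv`, `gene_model.tsv` and
#' `programs.gmt` (the planted cluster programs). Files round-trip through
#' the package readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @param overwrite Overwrite existing files? Defaults to `FALSE`; a
#'   collision raises an error.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(segments = "segments.seg", mutations = "mutations.maf",
             mrna = "mrna.gct", protein = "protein.gct",
             phospho = "phospho.gct", peptides = "peptides.tsv",
             survival = "survival.tsv", gene_model = "gene_model.tsv",
             programs = "programs.gmt")
  paths <- stats::setNames(file.path(dir, paths), names(paths))
  hit <- paths[file.exists(paths)]
  if (length(hit) && !overwrite)
    stopf("path collision: %s already exists", hit[1])
  write_seg(cohort$segments, paths["segments"])
  mut <- cohort$mutations
  if (is.null(mut)) mut <- empty_mutation_table()
  write_maf(mut, paths["mutations"])
  write_gct(cohort$mrna, paths["mrna"])
  write_gct(cohort$protein, paths["protein"])
  write_gct(cohort$phospho, paths["phospho"])
  utils::write.table(cohort$peptides, paths["peptides"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_survival_tsv(cohort$survival, paths["survival"])
  utils::write.table(cohort$gene_model, paths["gene_model"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  programs <- lapply(cohort$spec$cluster_spec, `[[`, "program")
  names(programs) <- vapply(cohort$spec$cluster_spec, `[[`, character(1),
                            "cluster")
  if (length(programs)) write_gmt(programs, paths["programs"])
  invisible(paths)
}

empty_mutation_table <- function() {
  cols <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
            "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
            "Variant_Classification", "Variant_Type", "Context")
  as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
}

# Reverse complement for plain base strings (vectorized).
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(comp[b])), collapse = ""), character(1))
}

# A random protein sequence guaranteed to yield several 7-30 aa tryptic
# peptides: 8-14 aa blocks of non-K/R/P residues terminated by K or R.
random_tryptic_sequence <- function(n_blocks = NULL) {
  aa <- setdiff(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], character(0))
  if (is.null(n_blocks)) n_blocks <- sample(8:14, 1)
  paste(vapply(seq_len(n_blocks), function(i) {
    len <- sample(7:13, 1)
    paste0(paste(sample(aa, len, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1)), collapse = "")
}
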