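genes2 <- data.frame(gene = c("GA", "GB"), chrom = c("1", "1"),
                     start = c(100L, 1000L), end = c(199L, 1999L),
                     arm = c("1p", "1p"), stringsAsFactors = FALSE)

test_that("gene copy number is the length-weighted mean of overlapping segments", {
  seg <- data.frame(sample = "S1", chrom = "1", start = 1L, end = 5000L,
                    num_mark = 10L, log2ratio = -1)
  m <- gene_copy_number(seg, genes2)
  expect_equal(unname(unclass(m)[, "S1"]), c(-1, -1))

  # gene GA half covered at 0, half at -1 (50 bases each)
  seg2 <- data.frame(sample = "S1", chrom = "1",
                     start = c(100L, 150L), end = c(149L, 199L),
                     num_mark = 1L, log2ratio = c(0, -1))
  m2 <- gene_copy_number(seg2, genes2)
  expect_equal(unclass(m2)["GA", "S1"], -0.5)
  expect_true(is.na(unclass(m2)["GB", "S1"]))
})

test_that("gene and arm scores match the per-base enumeration oracle", {
  set.seed(42)
  for (rep in 1:5) {
    genes <- data.frame(gene = paste0("G", 1:5), chrom = "1",
                        start = sort(sample.int(5000, 5)) * 2L,
                        arm = "1p", stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(50:400, 5)
    starts <- sort(sample.int(11000, 8))
    segs <- data.frame(sample = "S1", chrom = "1", start = starts,
                       end = starts + sample(100:1500, 8), num_mark = 1L,
                       log2ratio = round(rnorm(8), 2))
    # enforce non-overlap within the sample
    segs$end <- pmin(segs$end, c(segs$start[-1] - 1L, max(segs$end)))
    segs <- segs[segs$start <= segs$end, ]
    m <- unclass(gene_copy_number(segs, genes))
    for (i in seq_len(nrow(genes))) {
      expect_equal(m[genes$gene[i], "S1"],
                   per_base_mean(segs$start, segs$end, segs$log2ratio,
                                 genes$start[i], genes$end[i]),
                   tolerance = 1e-12)
    }
    arm <- unclass(arm_score(segs, genes,
                             arm_bounds = data.frame(arm = "1p", chrom = "1",
                                                     start = 1L, end = 15000L)))
    expect_equal(arm["1p", "S1"],
                 per_base_mean(segs$start, segs$end, segs$log2ratio,
                               1L, 15000L), tolerance = 1e-12)
  }
})

test_that("arm scores cancel and degrade gracefully", {
  bounds <- data.frame(arm = "1p", chrom = "1", start = 1L, end = 2000L)
  seg <- data.frame(sample = "S1", chrom = "1", start = c(1L, 1001L),
                    end = c(1000L, 2000L), num_mark = 1L, log2ratio = c(1, -1))
  a <- arm_score(seg, genes2, arm_bounds = bounds)
  expect_equal(unclass(a)["1p", "S1"], 0)
  expect_warning(arm_score(seg[0, ], genes2, arm_bounds = bounds), "empty")
  bad <- transform(seg, chrom = "chrUn")
  expect_error(gene_copy_number(bad, genes2), "chrUn")
})

test_that("amp/del calls use an inclusive log2-ratio cutoff of 1", {
  v <- matrix(c(1, -0.99, 0, -1, 2.5, NA), 2,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  calls <- call_amp_del(v)
  expect_identical(calls["a", "x"], "amplified")    # boundary inclusive
  expect_identical(calls["b", "x"], "neutral")
  expect_identical(calls["a", "y"], "neutral")
  expect_identical(calls["b", "y"], "deleted")
  expect_identical(calls["a", "z"], "amplified")
  expect_true(is.na(calls["b", "z"]))
  expect_error(call_amp_del(v, cutoff = 0), "cutoff")
})

test_that("TMB counts all mutations (synonymous included) per coding megabase", {
  mut <- data.frame(Tumor_Sample_Barcode = rep(c("S1", "S2"), c(30, 0)),
                    Variant_Type = "SNP",
                    Variant_Classification = rep(c("Missense_Mutation",
                                                   "Silent"), 15))
  expect_equal(unname(tmb(mut, 30, samples = c("S1", "S2"))), c(1, 0))
  expect_error(tmb(mut, 0), "positive")
})

test_that("TMB on Poisson mutation counts matches the rate oracle", {
  spec <- cohort_spec(n_samples = 50, n_genes = 80, mutation_rate = 316,
                      indel_fraction = 0.05, cluster_spec = list(),
                      kinase_spec = list(), seed = 9)
  co <- generate_cohort(spec)
  burden <- tmb(co$mutations, coding_mb = 31.6)
  se <- sd(burden) / sqrt(length(burden))
  expect_lt(abs(mean(burden) - 10), 3 * se)
})

test_that("context matrix collapses strands into the pyrimidine convention", {
  # an A>G mutation with context CAT is the reverse complement of A[T>C]G
  mut <- data.frame(Tumor_Sample_Barcode = "S1", Hugo_Symbol = "G1",
                    Chromosome = "1", Start_Position = 1L,
                    Reference_Allele = "A", Tumor_Seq_Allele2 = "G",
                    Variant_Classification = "Missense_Mutation",
                    Variant_Type = "SNP", Context = "CAT",
                    stringsAsFactors = FALSE)
  m <- context_matrix(mut)
  expect_identical(sum(m), 1L)
  expect_identical(m["A[T>C]G", "S1"], 1L)

  # full 192 -> 96 strand-collapse: every record equals its reverse complement
  ctx <- sbs96_contexts()
  fwd <- data.frame(Tumor_Sample_Barcode = "S1", Hugo_Symbol = "G",
                    Chromosome = "1", Start_Position = seq_along(ctx),
                    Reference_Allele = substr(ctx, 3, 3),
                    Tumor_Seq_Allele2 = substr(ctx, 5, 5),
                    Variant_Classification = "Missense_Mutation",
                    Variant_Type = "SNP",
                    Context = paste0(substr(ctx, 1, 1), substr(ctx, 3, 3),
                                     substr(ctx, 7, 7)),
                    stringsAsFactors = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc3 <- function(s) vapply(strsplit(s, ""), function(b)
    paste(rev(unname(comp[b])), collapse = ""), character(1))
  rev_ <- transform(fwd, Reference_Allele = unname(comp[Reference_Allele]),
                    Tumor_Seq_Allele2 = unname(comp[Tumor_Seq_Allele2]),
                    Context = rc3(Context))
  m_fwd <- context_matrix(fwd)
  m_rev <- context_matrix(rev_)
  expect_identical(m_fwd, m_rev)
  expect_true(all(m_fwd[, "S1"] == 1))
  expect_equal(unname(colSums(m_fwd)), 96)

  bad <- transform(mut, Reference_Allele = "N")
  expect_error(context_matrix(bad), "row")
  expect_identical(sum(context_matrix(mut[0, ])), 0L)
})

test_that("NMF factorizes an exact rank-1 matrix and its objective never increases", {
  set.seed(1)
  w <- runif(96, 0.1, 1)
  h <- runif(12, 1, 10)
  V <- outer(w, h)
  dimnames(V) <- list(sbs96_contexts(), paste0("S", 1:12))
  fit <- extract_signatures(V, k = 1, reference = reference_signatures(2),
                            n_restarts = 3, max_iter = 5000)
  expect_lt(fit$error, 1e-6)
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_equal(unname(colSums(fit$profiles)), 1, tolerance = 1e-9)
  expect_true(all(fit$exposures >= 0))
  expect_error(extract_signatures(V, k = 50), "k must lie")
})

test_that("Fisher co-occurrence matches the hypergeometric tail and flags degeneracy", {
  ev <- rbind(a = c(rep(1, 10), rep(0, 10)),
              b = c(rep(1, 10), rep(0, 10)),
              c = rep(0, 20))
  out <- cooccurrence(ev, pairs = cbind("a", "b"))
  expect_identical(out$direction, "co-occurring")
  expect_identical(out$odds_ratio, Inf)
  # two-sided Fisher p for [[10,0],[0,10]] by hypergeometric enumeration
  p_exact <- sum(dhyper(0:10, 10, 10, 10)[dhyper(0:10, 10, 10, 10) <=
                                            dhyper(10, 10, 10, 10) + 1e-12])
  expect_equal(out$p, p_exact, tolerance = 1e-12)

  out2 <- cooccurrence(ev, pairs = cbind("a", "c"))
  expect_identical(out2$p, 1)
  expect_true(out2$degenerate)

  all_pairs <- cooccurrence(ev)
  expect_identical(nrow(all_pairs), 3L)
})
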