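ranked_df <- function(r, ids = sprintf("g%02d", seq_along(r)))
  data.frame(gene_id = ids, r = r, stringsAsFactors = FALSE)

test_that("gene ranking is descending with deterministic tie-break", {
  gs <- data.frame(gene_id = c("A", "B", "C"), r = c(2, 5, 2),
                   stringsAsFactors = FALSE)
  rk <- rank_genes(gs)
  expect_equal(rk$gene_id, c("B", "A", "C"))
  one <- rank_genes(data.frame(gene_id = "Z", r = 1))
  expect_equal(attr(one, "N"), 1L)
  set.seed(31)
  gs2 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    r = sample(rep(1:5, 4)))
  expect_setequal(rank_genes(gs2)$gene_id, gs2$gene_id)
})

test_that("worked enrichment-score examples", {
  rk <- ranked_df(c(5, 4, 3, 2, 1))
  # hits at ranks 1 and 3, p = 1: N_R = 8, running max at rank 3 = 2/3
  expect_equal(enrichment_score(rk, c("g01", "g03"), p_weight = 1),
               2 / 3, tolerance = 1e-15)
  # singleton set at rank 1 jumps straight to 1
  expect_equal(enrichment_score(rk, "g01"), 1)
  # all hits at the bottom: the max is still attained at position N (0)
  expect_equal(enrichment_score(rk, "g05"), 0)
})

test_that("ES equals the brute-force running sum exactly on random instances", {
  set.seed(32)
  for (i in 1:200) {
    inst <- random_es_instance()
    rk <- ranked_df(inst$r)
    impl <- enrichment_score(rk, rk$gene_id[inst$hit], inst$p)
    ref <- oracle_es(inst$r, inst$hit, inst$p)
    expect_identical(impl, ref)
  }
})

test_that("p_weight = 0 reduces to the classical unweighted statistic", {
  set.seed(33)
  for (i in 1:50) {
    inst <- random_es_instance()
    rk <- ranked_df(inst$r)
    expect_equal(enrichment_score(rk, rk$gene_id[inst$hit], 0),
                 oracle_es_unweighted(inst$hit), tolerance = 1e-12)
  }
})

test_that("ES bounds and the all-hits-on-top extreme", {
  set.seed(34)
  for (i in 1:50) {
    inst <- random_es_instance()
    rk <- ranked_df(inst$r)
    es <- enrichment_score(rk, rk$gene_id[inst$hit], inst$p)
    expect_gte(es, -1)
    expect_lte(es, 1 + 1e-12)
  }
  # hits exactly the top NH ranks with p = 0 -> ES = 1
  rk <- ranked_df(10:1)
  expect_equal(enrichment_score(rk, rk$gene_id[1:4], 0), 1,
               tolerance = 1e-12)
})

test_that("ES skip conditions: empty or exhaustive sets", {
  rk <- ranked_df(c(3, 2, 1))
  expect_error(enrichment_score(rk, "absent"),
               class = "pathgsea_data_error")
  expect_error(enrichment_score(rk, rk$gene_id),
               class = "pathgsea_data_error")
})

test_that("empirical P follows the (r+1)/(B+1) convention", {
  expect_equal(empirical_p(0.25, c(0.1, 0.2, 0.3)), 0.5)
  expect_equal(empirical_p(2, runif(1000)), 1 / 1001)
  null <- runif(100)
  expect_equal(empirical_p(-1, null), 1)
  expect_equal(empirical_p(0.3, c(0.3, 0.1)), 2 / 3)  # ties count as >=
})

test_that("normalization standardizes observed and null columns", {
  # null column with mean 0.3 and sample SD 0.15: NES = 2
  expect_equal(normalize_scores(0.6, matrix(c(0.15, 0.3, 0.45), 3))$nes[1],
               2, tolerance = 1e-12)
  set.seed(35)
  null <- matrix(rnorm(200 * 4, mean = 0.3, sd = 0.15), 200, 4)
  obs <- c(0.6, 0.3, 0.1, 0.9)
  nz <- normalize_scores(obs, null)
  expect_equal(unname(colMeans(nz$nes_null)), rep(0, 4),
               tolerance = 1e-9)
  expect_equal(unname(apply(nz$nes_null, 2, sd)), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(nz$nes[2], (0.3 - mean(null[, 2])) / sd(null[, 2]))
  # observed equal to the null mean -> NES 0
  nz0 <- normalize_scores(mean(null[, 1]), null[, 1, drop = FALSE])
  expect_equal(nz0$nes[1], 0, tolerance = 1e-12)
  # zero-SD null flagged
  degen <- normalize_scores(0.5, matrix(0.2, 10, 1))
  expect_true(degen$degenerate[1])
  expect_equal(degen$nes[1], 0)
})

test_that("FDR evaluates the pooled-null ratio", {
  # 2 observed sets NES [2, 1]; pooled null of 100 with 2 >= 2 and 40 >= 1
  nes <- c(2, 1)
  pool <- c(seq(1.005, 1.995, length.out = 38), 2.5, 2.7,
            seq(-2, 0.99, length.out = 60))
  stopifnot(sum(pool >= 2) == 2, sum(pool >= 1) == 40)
  f <- compute_fdr(nes, matrix(pool, ncol = 2))
  expect_equal(f$fdr, c(0.02 / 0.5, 0.40 / 1.0), tolerance = 1e-12)
  # smallest NES: denominator 1, FDR = pooled tail fraction
  expect_equal(f$fdr[2], mean(pool >= 1))
  # observed below the whole pool: numerator 1, clipped to 1
  low <- compute_fdr(c(-5), matrix(pool, ncol = 2))
  expect_equal(low$fdr, 1)
  expect_gte(low$raw, 1)
})

test_that("pathway_gsea is deterministic and respects the size filter", {
  cfg <- sim_config(n_individuals = 120L, n_snps = 240L, n_genes = 60L,
                    n_sets = 8L, set_size_range = c(2L, 30L), seed = 36L)
  st <- simulate_study(cfg)
  gc <- gsea_config(n_perm = 30L, seed = 5L, set_min = 5L,
                    set_max = 20L)
  g1 <- pathway_gsea(st, phenotype = "log_tg", config = gc)
  g2 <- pathway_gsea(st, phenotype = "log_tg", config = gc)
  expect_identical(g1$results, g2$results)
  expect_true(all(g1$results$size_covered >= 5 &
                    g1$results$size_covered <= 20))
  if (nrow(g1$skipped))
    expect_true(all(g1$skipped$reason %in%
                      c("below set_min", "above set_max",
                        "no covered gene", "covers all ranked genes")))
  expect_equal(nrow(g1$results) + nrow(g1$skipped), 8L)
})

test_that("sets sized outside [5, 200] covered genes are not tested", {
  r <- rchisq(300, 1)
  gs <- data.frame(gene_id = sprintf("g%03d", 1:300), r = r,
                   stringsAsFactors = FALSE)
  sets <- gene_set_collection(list(S4 = gs$gene_id[1:4],
                                   S5 = gs$gene_id[1:5],
                                   S201 = gs$gene_id[1:201],
                                   S200 = gs$gene_id[1:200]))
  # drive the engine through pvalue_gsea on a fabricated mapping
  snps <- data.frame(snp_id = sprintf("s%03d", 1:300), chrom = "chr1",
                     pos = seq(1e5, by = 1e5, length.out = 300),
                     p = pchisq(r, 1, lower.tail = FALSE),
                     stringsAsFactors = FALSE)
  genes <- gene_annotation(gs$gene_id, "chr1", snps$pos, snps$pos)
  res <- pvalue_gsea(snps, genes, sets,
                     config = gsea_config(n_perm = 20L, seed = 1L,
                                          mode = "snp_label_perm"),
                     flank = 1000)
  expect_setequal(res$results$set_id, c("S5", "S200"))
  expect_setequal(res$skipped$set_id, c("S4", "S201"))
})

test_that("one-permutation nulls stay within ES bounds", {
  cfg <- sim_config(n_individuals = 80L, n_snps = 160L, n_genes = 40L,
                    n_sets = 4L, set_size_range = c(5L, 15L), seed = 37L)
  st <- simulate_study(cfg)
  g <- pathway_gsea(st, phenotype = "log_tg",
                    config = gsea_config(n_perm = 1L, seed = 2L))
  expect_equal(nrow(g$es_null), 1L)
  expect_true(all(g$es_null >= -1 & g$es_null <= 1 + 1e-12,
                  na.rm = TRUE))
})

test_that("outputs are invariant to the input row order of individuals", {
  cfg <- sim_config(n_individuals = 90L, n_snps = 150L, n_genes = 40L,
                    n_sets = 5L, set_size_range = c(5L, 15L), seed = 38L)
  st <- simulate_study(cfg)
  perm <- sample(nrow(st$genotypes$dosage))
  st2 <- st
  st2$genotypes$dosage <- st$genotypes$dosage[perm, , drop = FALSE]
  st2$genotypes$individual_ids <- st$genotypes$individual_ids[perm]
  st2$phenotypes <- st$phenotypes[perm, , drop = FALSE]
  gc <- gsea_config(n_perm = 25L, seed = 9L)
  g1 <- pathway_gsea(st, phenotype = "log_tg", config = gc)
  g2 <- pathway_gsea(st2, phenotype = "log_tg", config = gc)
  expect_identical(g1$results, g2$results)
  expect_identical(g1$es_null, g2$es_null)
})

test_that("binary-mode permutations exclude unknown-status individuals", {
  set.seed(39)
  n <- 120
  dos <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.25))
  tg <- c(rep(100, 50), rep(175, 20), rep(300, 50))
  st <- tiny_study(dos, tg,
                   sets = gene_set_collection(list(S1 = c("g01", "g02"))))
  y <- pathgsea:::phenotype_vector(st, "binary")
  expect_equal(sum(is.na(y)), 20L)
  g <- pathway_gsea(st, phenotype = "binary",
                    config = gsea_config(n_perm = 10L, seed = 3L,
                                         set_min = 1L))
  expect_s3_class(g, "pathway_gsea")
  # every TG below the case threshold -> degenerate binary arm
  st2 <- tiny_study(dos, rep(100, n))
  expect_error(run_gwas(st2, "binary"),
               "fewer than 2 distinct phenotype values",
               class = "pathgsea_data_error")
})

test_that("SNP-label permutation preserves the statistic multiset", {
  cfg <- sim_config(n_individuals = 80L, n_snps = 120L, n_genes = 30L,
                    n_sets = 3L, set_size_range = c(5L, 10L), seed = 40L)
  st <- simulate_study(cfg)
  a <- run_gwas(st, "log_tg")
  s <- -log10(a$p)
  set.seed(77)
  for (i in 1:5)
    expect_identical(sort(s[sample.int(length(s))]), sort(s))
})
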