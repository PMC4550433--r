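test_that("simulation is deterministic and reproducible from the seed", {
  cfg <- sim_config(n_individuals = 60L, n_snps = 120L, n_genes = 30L,
                    n_sets = 6L, set_size_range = c(3L, 8L), seed = 42L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  d <- simulate_study(sim_config(n_individuals = 60L, n_snps = 120L,
                                 n_genes = 30L, n_sets = 6L,
                                 set_size_range = c(3L, 8L), seed = 43L))
  expect_false(identical(a$genotypes$dosage, d$genotypes$dosage))
})

test_that("degenerate sizes and invalid configs are handled", {
  cfg <- sim_config(n_individuals = 0L, n_snps = 50L, n_genes = 10L,
                    n_sets = 2L, set_size_range = c(2L, 5L),
                    missing_rate = 0, seed = 1L)
  g <- simulate_genotypes(cfg)
  expect_equal(nrow(g$dosage), 0)
  expect_equal(ncol(g$dosage), 50)
  expect_equal(nrow(g$map), 50)
  expect_error(sim_config(n_snps = 0L), class = "pathgsea_config_error")
  expect_error(sim_config(maf_range = c(0, 0.5)),
               class = "pathgsea_config_error")
  expect_error(sim_config(n_genes = 10L, set_size_range = c(5L, 20L)),
               class = "pathgsea_config_error")
})

test_that("simulated allele frequency matches the target MAF", {
  cfg <- sim_config(n_individuals = 10000L, n_snps = 1L, n_genes = 1L,
                    n_sets = 1L, set_size_range = c(1L, 1L),
                    maf_range = c(0.5, 0.5), intergenic_fraction = 0,
                    missing_rate = 0, seed = 7L)
  g <- simulate_genotypes(cfg)
  f <- sum(g$dosage) / (2 * nrow(g$dosage))
  expect_lt(abs(f - 0.5), 0.015)  # 3 binomial SEs at 2n = 20000
})

test_that("simulated genotypes satisfy HWE at the nominal rate", {
  cfg <- sim_config(n_individuals = 500L, n_snps = 5000L,
                    n_genes = 100L, n_sets = 5L,
                    set_size_range = c(5L, 20L), missing_rate = 0,
                    seed = 99L)
  g <- simulate_genotypes(cfg)
  pv <- pathgsea:::snp_qc(g)$hwe_p
  frac <- mean(pv < 0.001)
  expect_gte(frac, 0)
  expect_lte(frac, 0.005)  # nominal 0.001; binomial slack at M = 5000
})

test_that("null phenotypes give uniform association P-values", {
  cfg <- sim_config(n_individuals = 300L, n_snps = 600L, n_genes = 100L,
                    n_sets = 5L, set_size_range = c(5L, 20L),
                    beta = 0, bmi_slope = 0, missing_rate = 0,
                    seed = 17L)
  st <- simulate_study(cfg)
  a <- run_gwas(st, "log_tg", maf_min = 0.01, hwe_min_p = 0.001)
  expect_gte(nrow(a), 500)
  ks <- suppressWarnings(ks.test(a$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("noise-free limit returns the constant TG", {
  cfg <- sim_config(n_individuals = 20L, n_snps = 40L, n_genes = 10L,
                    n_sets = 2L, set_size_range = c(2L, 5L),
                    sigma = 0, beta = 0, bmi_slope = 0,
                    tg_location = 2.0, missing_rate = 0, seed = 5L)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  expect_equal(ph$tg, rep(100, 20), tolerance = 1e-12)
})

test_that("default phenotype scale sits inside the cohort log(TG) range", {
  st <- simulate_study(sim_config(seed = 21L))
  lt <- st$phenotypes$log_tg[st$phenotypes$included]
  expect_gt(mean(lt), 1.53)
  expect_lt(mean(lt), 2.84)
  # central 99% of individuals inside the printed post-QC range
  expect_gt(mean(lt > 1.53 & lt < 2.84), 0.95)
})

test_that("effect recovery: regression on a causal SNP recovers beta", {
  hits <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 400L, n_snps = 300L,
                      n_genes = 60L, n_sets = 5L,
                      set_size_range = c(5L, 20L),
                      causal_set_index = 1L, n_causal_genes = 3L,
                      beta = 0.08, missing_rate = 0, seed = 100L + i)
    st <- simulate_study(cfg)
    s <- st$truth$causal_snps[1]
    d <- st$genotypes$dosage[, s]
    fit <- summary(lm(st$phenotypes$log_tg ~ d))
    est <- fit$coefficients["d", "Estimate"]
    se <- fit$coefficients["d", "Std. Error"]
    if (abs(est - 0.08) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, reps - 1L)
})

test_that("gene architecture respects causal membership and set sizes", {
  cfg <- sim_config(n_individuals = 10L, causal_set_index = 2L,
                    n_causal_genes = 8L, seed = 31L)
  arch <- simulate_gene_architecture(cfg)
  sizes <- lengths(arch$sets$sets)
  expect_true(all(sizes >= 5 & sizes <= 200))
  causal_set <- arch$sets$sets[[arch$truth$causal_set]]
  expect_true(all(arch$truth$causal_genes %in% causal_set))
  # each causal gene carries exactly one causal SNP
  gene_of <- arch$snp_map$gene_id[match(arch$truth$causal_snps,
                                        arch$snp_map$snp_id)]
  expect_setequal(gene_of, arch$truth$causal_genes)
  expect_equal(anyDuplicated(gene_of), 0)
  # gene intervals do not overlap within a chromosome
  for (ch in unique(arch$genes$chrom)) {
    gg <- arch$genes[arch$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1)
      expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
})

test_that("forced set size and fully intergenic placement behave", {
  cfg <- sim_config(n_individuals = 10L, n_snps = 60L, n_genes = 20L,
                    n_sets = 1L, set_size_range = c(5L, 5L), seed = 2L)
  arch <- simulate_gene_architecture(cfg)
  expect_equal(lengths(arch$sets$sets), c(SET001 = 5L))

  cfg2 <- sim_config(n_individuals = 10L, n_snps = 60L, n_genes = 20L,
                     n_sets = 1L, set_size_range = c(5L, 5L),
                     intergenic_fraction = 1, seed = 2L)
  arch2 <- simulate_gene_architecture(cfg2)
  expect_true(all(is.na(arch2$snp_map$gene_id)))
  m <- map_snps_to_genes(data.frame(snp_id = arch2$snp_map$snp_id,
                                    chrom = arch2$snp_map$chrom,
                                    pos = arch2$snp_map$pos),
                         arch2$genes, flank = cfg2$flank)
  expect_length(m$map, 0)
})

test_that("LD proxies are tight proxies of their causal parent", {
  cfg <- sim_config(n_individuals = 1000L, n_snps = 400L, n_genes = 80L,
                    n_sets = 4L, set_size_range = c(5L, 20L),
                    causal_set_index = 1L, n_causal_genes = 2L,
                    ld_proxies = 2L, ld_epsilon = 0.02,
                    missing_rate = 0, seed = 55L)
  st <- simulate_study(cfg)
  s <- st$truth$causal_snps[1]
  proxies <- grep(paste0("^", s, "_p"), st$genotypes$map$snp_id,
                  value = TRUE)
  expect_length(proxies, 2)
  for (pr in proxies) {
    r2 <- ld_r2(st$genotypes$dosage[, s], st$genotypes$dosage[, pr])
    expect_gt(r2, 0.6)
    expect_lt(abs(r2 - (1 - 0.02)^2), 0.08)
  }
})

test_that("beta_for_target_p calibrates the expected F statistic", {
  b <- beta_for_target_p(1e-4, 1000, 0.275, 0.25)
  t_expected <- b * sqrt(2 * 0.275 * 0.725 * 1000) / 0.25
  expect_equal(t_expected^2, qchisq(1e-4, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})
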