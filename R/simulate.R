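#' Simulation configuration
#'
#' Defines one synthetic study: an array-like panel of biallelic SNPs in
#' Hardy-Weinberg equilibrium on a set of unrelated individuals, a
#' non-overlapping gene map with intergenic territory, gene sets drawn
#' from the gene universe (optionally one designated enriched set whose
#' member genes carry causal SNPs), and a log-normal triglyceride
#' phenotype with an additive genetic component and a BMI covariate.
#'
#' The defaults are the desk-scale study conditions used throughout the
#' package's evaluation: 1000 individuals, 2000 SNPs, 400 genes, 50 sets
#' of 5-50 genes, common variants (MAF 0.05-0.5), log10(TG) centred at
#' 2.05 with residual SD 0.25 so that the case (TG > 200 mg/dL) and
#' control (TG < 150 mg/dL) fractions resemble an obesity-enriched
#' cohort, and 1% genotype missingness.
#'
#' @param n_individuals,n_snps,n_genes study dimensions.
#' @param intergenic_fraction fraction of SNPs placed outside every
#'   gene's flanked window (they map to no gene).
#' @param maf_range uniform bounds for per-SNP allele frequency, within
#'   (0, 0.5].
#' @param n_sets,set_size_range gene-set collection shape; sizes drawn
#'   uniformly in `set_size_range`, members without replacement.
#' @param causal_set_index index (1..n_sets) of the set designated
#'   enriched, or `NULL` for a fully null study.
#' @param n_causal_genes causal genes, all members of the causal set;
#'   each carries exactly one causal SNP.
#' @param beta additive per-allele effect of each causal SNP on
#'   log10(TG).
#' @param sigma residual SD of log10(TG).
#' @param tg_location intercept of log10(TG) (mg/dL scale: 2.05 is
#'   ~112 mg/dL).
#' @param bmi_mean,bmi_sd covariate distribution (kg/m^2).
#' @param bmi_slope effect of BMI on log10(TG) per kg/m^2.
#' @param female_fraction sex label frequency (labels only; no
#'   sex-specific effects are simulated).
#' @param missing_rate missing-completely-at-random genotype dropout.
#' @param ld_proxies,ld_epsilon optional LD structure: each causal SNP
#'   is copied into `ld_proxies` nearby proxy SNPs whose entries are
#'   independently redrawn from HWE with probability `ld_epsilon`,
#'   giving expected r^2 of about (1 - ld_epsilon)^2.
#' @param flank gene flank in bp used when placing intergenic SNPs
#'   outside every mappable window.
#' @param seed integer seed; identical configs give byte-identical
#'   studies.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000L, n_snps = 2000L,
                       n_genes = 400L, intergenic_fraction = 0.2,
                       maf_range = c(0.05, 0.5), n_sets = 50L,
                       set_size_range = c(5L, 50L),
                       causal_set_index = NULL, n_causal_genes = 0L,
                       beta = 0.05, sigma = 0.25, tg_location = 2.05,
                       bmi_mean = 30, bmi_sd = 6, bmi_slope = 0.005,
                       female_fraction = 0.95, missing_rate = 0.01,
                       ld_proxies = 0L, ld_epsilon = 0.02,
                       flank = 20000, seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
              intergenic_fraction = intergenic_fraction,
              maf_range = as.numeric(maf_range),
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              causal_set_index = if (is.null(causal_set_index)) NULL
                                 else as.integer(causal_set_index),
              n_causal_genes = as.integer(n_causal_genes),
              beta = beta, sigma = sigma, tg_location = tg_location,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_slope = bmi_slope,
              female_fraction = female_fraction,
              missing_rate = missing_rate,
              ld_proxies = as.integer(ld_proxies),
              ld_epsilon = ld_epsilon, flank = flank,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (is.na(n_individuals) || n_individuals < 0)
      stop_config("n_individuals must be >= 0")
    if (is.na(n_snps) || n_snps < 1) stop_config("n_snps must be positive")
    if (is.na(n_genes) || n_genes < 1) stop_config("n_genes must be positive")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop_config("maf_range must lie within (0, 0.5] with low <= high")
    if (length(set_size_range) != 2 || set_size_range[1] < 1 ||
        set_size_range[2] > n_genes || set_size_range[1] > set_size_range[2])
      stop_config("set_size_range must lie within [1, n_genes]")
    if (n_sets < 1) stop_config("n_sets must be positive")
    if (intergenic_fraction < 0 || intergenic_fraction > 1)
      stop_config("intergenic_fraction must be in [0, 1]")
    if (missing_rate < 0 || missing_rate >= 1)
      stop_config("missing_rate must be in [0, 1)")
    if (sigma < 0 || bmi_sd < 0) stop_config("sigma and bmi_sd must be >= 0")
    if (n_causal_genes < 0) stop_config("n_causal_genes must be >= 0")
    if (n_causal_genes > 0) {
      if (is.null(causal_set_index) || causal_set_index < 1 ||
          causal_set_index > n_sets)
        stop_config("causal_set_index must name one of the %d sets", n_sets)
      if (n_causal_genes > set_size_range[2])
        stop_config("n_causal_genes exceeds the maximum set size")
      if (n_causal_genes > n_genes)
        stop_config("n_causal_genes exceeds n_genes")
      genic <- round((1 - intergenic_fraction) * n_snps)
      if (genic < n_causal_genes)
        stop_config("not enough genic SNPs for %d causal genes",
                    n_causal_genes)
    }
    if (ld_proxies < 0) stop_config("ld_proxies must be >= 0")
    if (ld_epsilon < 0 || ld_epsilon > 1)
      stop_config("ld_epsilon must be in [0, 1]")
    if (abs(seed) > 2^31 - 1000) stop_config("seed too large")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d individuals, %d SNPs, %d genes, ",
                     "%d sets (sizes %d-%d), seed %d\n"),
              x$n_individuals, x$n_snps, x$n_genes, x$n_sets,
              x$set_size_range[1], x$set_size_range[2], x$seed))
  if (x$n_causal_genes > 0)
    cat(sprintf("  causal: %d genes in set %d, beta %g on log10(TG)\n",
                x$n_causal_genes, x$causal_set_index, x$beta))
  invisible(x)
}

#' Simulate the gene map, SNP placement and gene-set collection
#'
#' Non-overlapping gene intervals are laid down chromosome by
#' chromosome with gaps wide enough that intergenic SNPs can be placed
#' beyond every flanked window; genic SNPs are multinomially distributed
#' over genes (each causal gene reserved at least one) and positioned
#' uniformly inside their gene. Gene sets are drawn without replacement
#' from the gene universe; the designated causal set is forced to
#' contain all causal genes.
#'
#' @param config a [sim_config()].
#' @return list with `genes` ([gene_annotation()]), `sets`
#'   ([gene_set_collection()]), `snp_map` (data.frame `snp_id`, `chrom`,
#'   `pos`, `gene_id`, `proxy_of`) and `truth` (causal snp/gene/set ids).
#' @export
simulate_gene_architecture <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  n_chrom <- min(22L, max(1L, ceiling(ng / 25)))
  chrom_of <- sort(rep_len(seq_len(n_chrom), ng))
  gene_id <- sprintf("G%04d", seq_len(ng))
  glen <- round(stats::runif(ng, 10000, 60000))
  gap <- round(stats::runif(ng, 60000, 150000))
  start <- end <- numeric(ng)
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom_of == ch)
    pos <- 1
    for (i in idx) {
      start[i] <- pos + gap[i]
      end[i] <- start[i] + glen[i] - 1
      pos <- end[i]
    }
  }
  genes <- gene_annotation(gene_id, paste0("chr", chrom_of), start, end)

  # causal genes first so each can be reserved a SNP
  ncau <- config$n_causal_genes
  causal_genes <- if (ncau > 0) sort(sample(gene_id, ncau)) else character(0)
  n_genic <- round((1 - config$intergenic_fraction) * config$n_snps)
  n_inter <- config$n_snps - n_genic
  counts <- rep(0L, ng)
  if (n_genic > 0) {
    free <- n_genic - ncau
    if (free > 0)
      counts <- as.integer(stats::rmultinom(1, free, rep(1, ng)))
    counts[match(causal_genes, gene_id)] <-
      counts[match(causal_genes, gene_id)] + 1L
  }
  snp_chrom <- character(0); snp_pos <- numeric(0); snp_gene <- character(0)
  for (i in which(counts > 0)) {
    p <- start[i] + sample.int(glen[i], counts[i]) - 1
    snp_chrom <- c(snp_chrom, rep(genes$chrom[i], counts[i]))
    snp_pos <- c(snp_pos, p)
    snp_gene <- c(snp_gene, rep(gene_id[i], counts[i]))
  }
  if (n_inter > 0) {
    fl <- config$flank
    lo <- hi <- numeric(0); ichrom <- character(0)
    for (ch in seq_len(n_chrom)) {
      idx <- which(chrom_of == ch)
      if (length(idx) > 1) {
        l <- end[idx[-length(idx)]] + fl + 1
        h <- start[idx[-1]] - fl - 1
        ok <- h > l
        lo <- c(lo, l[ok]); hi <- c(hi, h[ok])
        ichrom <- c(ichrom, rep(paste0("chr", ch), sum(ok)))
      }
      lo <- c(lo, end[idx[length(idx)]] + fl + 1)
      hi <- c(hi, end[idx[length(idx)]] + fl + 60000)
      ichrom <- c(ichrom, paste0("chr", ch))
    }
    wid <- hi - lo + 1
    alloc <- as.integer(stats::rmultinom(1, n_inter, wid))
    alloc <- pmin(alloc, wid)
    short <- n_inter - sum(alloc)          # clipped overflow, if any
    while (short > 0) {                    # reassign to roomy intervals
      room <- which(alloc < wid)
      take <- room[seq_len(min(short, length(room)))]
      alloc[take] <- alloc[take] + 1L
      short <- n_inter - sum(alloc)
    }
    for (k in which(alloc > 0)) {
      p <- lo[k] + sample.int(wid[k], alloc[k]) - 1
      snp_chrom <- c(snp_chrom, rep(ichrom[k], alloc[k]))
      snp_pos <- c(snp_pos, p)
      snp_gene <- c(snp_gene, rep(NA_character_, alloc[k]))
    }
  }
  ord <- order(snp_chrom, snp_pos, method = "radix")
  snp_map <- data.frame(snp_id = sprintf("snp%05d", seq_along(ord)),
                        chrom = snp_chrom[ord], pos = snp_pos[ord],
                        gene_id = snp_gene[ord],
                        proxy_of = NA_character_,
                        stringsAsFactors = FALSE)

  # one causal SNP per causal gene
  causal_snps <- character(0)
  if (ncau > 0) {
    causal_snps <- vapply(causal_genes, function(g) {
      cand <- snp_map$snp_id[!is.na(snp_map$gene_id) & snp_map$gene_id == g]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, "")
    names(causal_snps) <- NULL
  }

  # optional proxy SNPs in tight LD with each causal SNP
  if (config$ld_proxies > 0 && length(causal_snps)) {
    add <- list()
    for (s in causal_snps) {
      row <- snp_map[snp_map$snp_id == s, ]
      for (j in seq_len(config$ld_proxies)) {
        p <- row$pos + 173 * j
        while (any(snp_map$chrom == row$chrom & snp_map$pos == p))
          p <- p + 1
        add[[length(add) + 1]] <-
          data.frame(snp_id = sprintf("%s_p%d", s, j), chrom = row$chrom,
                     pos = p, gene_id = row$gene_id, proxy_of = s,
                     stringsAsFactors = FALSE)
      }
    }
    snp_map <- rbind(snp_map, do.call(rbind, add))
    snp_map <- snp_map[order(snp_map$chrom, snp_map$pos,
                             method = "radix"), , drop = FALSE]
    rownames(snp_map) <- NULL
  }

  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_sets, replace = TRUE)
  sets <- vector("list", config$n_sets)
  for (i in seq_len(config$n_sets)) {
    if (!is.null(config$causal_set_index) && i == config$causal_set_index &&
        ncau > 0) {
      sz <- max(sizes[i], ncau)
      extra <- sample(setdiff(gene_id, causal_genes), sz - ncau)
      sets[[i]] <- sample(c(causal_genes, extra))
    } else {
      sets[[i]] <- sample(gene_id, sizes[i])
    }
  }
  names(sets) <- sprintf("SET%03d", seq_len(config$n_sets))
  gsc <- gene_set_collection(sets, rep("simulated gene set",
                                       config$n_sets))
  causal_set <- if (ncau > 0) names(sets)[config$causal_set_index]
                else character(0)
  list(genes = genes, sets = gsc, snp_map = snp_map,
       truth = list(causal_snps = causal_snps,
                    causal_genes = causal_genes,
                    causal_set = causal_set))
}

#' Simulate HWE genotype dosages
#'
#' Per SNP an allele frequency f is drawn uniformly from `maf_range` and
#' each individual's dosage is the sum of two independent Bernoulli(f)
#' trials (Hardy-Weinberg genotype proportions). Proxy SNPs copy their
#' parent's dosages with per-entry corruption probability `ld_epsilon`.
#' Entries are set missing at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param architecture output of [simulate_gene_architecture()]; built
#'   from `config` when omitted.
#' @return a [geno_matrix()].
#' @export
simulate_genotypes <- function(config, architecture = NULL) {
  validate_sim_config(config)
  if (is.null(architecture)) architecture <- simulate_gene_architecture(config)
  snp_map <- architecture$snp_map
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  M <- nrow(snp_map)
  f <- stats::runif(M, config$maf_range[1], config$maf_range[2])
  parent <- match(snp_map$proxy_of, snp_map$snp_id)
  f[!is.na(parent)] <- f[parent[!is.na(parent)]]
  dos <- matrix(stats::rbinom(n * M, 2, rep(f, each = n)), nrow = n,
                ncol = M)
  for (j in which(!is.na(parent))) {
    dos[, j] <- dos[, parent[j]]
    corrupt <- stats::runif(n) < config$ld_epsilon
    if (any(corrupt))
      dos[corrupt, j] <- stats::rbinom(sum(corrupt), 2, f[j])
  }
  if (config$missing_rate > 0 && n > 0) {
    miss <- stats::runif(n * M) < config$missing_rate
    dos[miss] <- NA
  }
  bases <- c("A", "C", "G", "T")
  a_other <- sample(bases, M, replace = TRUE)
  shift <- sample.int(3, M, replace = TRUE)
  a_counted <- bases[(match(a_other, bases) - 1 + shift) %% 4 + 1]
  iid <- if (n > 0) sprintf("I%05d", seq_len(n)) else character(0)
  map <- data.frame(snp_id = snp_map$snp_id, chrom = snp_map$chrom,
                    pos = snp_map$pos, counted = a_counted,
                    other = a_other, stringsAsFactors = FALSE)
  dimnames(dos) <- list(iid, map$snp_id)
  geno_matrix(dos, map, iid)
}

#' Simulate TG and BMI phenotypes
#'
#' log10(TG) = tg_location + beta * sum of causal dosages +
#' bmi_slope * (BMI - bmi_mean) + Normal(0, sigma); TG = 10^log10(TG) in
#' mg/dL; BMI ~ Normal(bmi_mean, bmi_sd). Missing causal dosages are
#' imputed at the SNP's mean dosage for the latent genetic value only.
#'
#' @param genotypes a [geno_matrix()].
#' @param config a [sim_config()].
#' @param causal_snps SNP ids carrying the effect (must exist in
#'   `genotypes`).
#' @return data.frame with columns `iid`, `tg`, `bmi`, `sex`.
#' @export
simulate_phenotypes <- function(genotypes, config, causal_snps = character(0)) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(genotypes$dosage)
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  g <- numeric(n)
  if (length(causal_snps)) {
    cols <- match(causal_snps, genotypes$map$snp_id)
    if (anyNA(cols))
      stop_config("causal SNP(s) absent from genotypes: %s",
                  paste(causal_snps[is.na(cols)], collapse = ", "))
    D <- genotypes$dosage[, cols, drop = FALSE]
    for (k in seq_len(ncol(D))) {
      m <- mean(D[, k], na.rm = TRUE)
      if (is.nan(m)) m <- 1
      D[is.na(D[, k]), k] <- m
    }
    g <- rowSums(D) * config$beta
  }
  log_tg <- config$tg_location + g +
    config$bmi_slope * (bmi - config$bmi_mean) +
    stats::rnorm(n, 0, config$sigma)
  data.frame(iid = genotypes$individual_ids, tg = 10^log_tg, bmi = bmi,
             sex = sex, stringsAsFactors = FALSE)
}

#' Simulate a complete study
#'
#' Runs [simulate_gene_architecture()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under one seed and prepares the analysis
#' phenotypes with [prepare_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return object of class `study_bundle` with elements `genotypes`,
#'   `phenotypes` (prepared), `genes`, `sets`, `truth`, `seed`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  arch <- simulate_gene_architecture(config)
  geno <- simulate_genotypes(config, arch)
  raw <- simulate_phenotypes(geno, config, arch$truth$causal_snps)
  adjust <- nrow(raw) >= 3 && stats::sd(raw$bmi) > 0
  pheno <- prepare_phenotypes(raw, adjust = adjust)
  structure(list(genotypes = geno, phenotypes = pheno, genes = arch$genes,
                 sets = arch$sets, truth = arch$truth,
                 seed = config$seed, config = config),
            class = "study_bundle")
}

#' Effect size giving a target per-SNP association P-value
#'
#' Inverts the expected F statistic of the simple-regression test: for a
#' SNP with allele frequency `maf` on `n` individuals and residual SD
#' `sigma`, `beta = t * sigma / sqrt(2 maf (1 - maf) n)` where t is the
#' normal quantile matching `p_target` on 1 df.
#'
#' @param p_target desired asymptotic P-value at the typical causal SNP.
#' @param n sample size.
#' @param maf allele frequency used for the calibration.
#' @param sigma residual SD of the trait.
#' @export
beta_for_target_p <- function(p_target, n, maf, sigma) {
  t <- sqrt(stats::qchisq(p_target, 1, lower.tail = FALSE))
  t * sigma / sqrt(2 * maf * (1 - maf) * n)
}
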