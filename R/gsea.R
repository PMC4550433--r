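#' Enrichment analysis configuration
#'
#' @param p_weight exponent giving extreme gene statistics more weight
#'   in the running sum (default 1; 0 recovers the classical unweighted
#'   KS statistic).
#' @param n_perm number of permutations B (default 1000).
#' @param set_min,set_max size filter applied to the number of set
#'   members present among ranked genes (defaults 5 and 200).
#' @param seed integer seed for the permutation stream.
#' @param mode `"phenotype_perm"` (labels shuffled, association and
#'   ranking recomputed per replicate) or `"snp_label_perm"` (per-SNP
#'   statistics permuted across SNP labels on fixed geometry).
#' @return object of class `gsea_config`.
#' @export
gsea_config <- function(p_weight = 1, n_perm = 1000L, set_min = 5L,
                        set_max = 200L, seed = 1L,
                        mode = c("phenotype_perm", "snp_label_perm")) {
  mode <- match.arg(mode)
  if (p_weight < 0) stop_config("p_weight must be >= 0")
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  if (set_min > set_max) stop_config("set_min must be <= set_max")
  if (set_min < 1) stop_config("set_min must be >= 1")
  if (abs(seed) > 2^31 - 1000) stop_config("seed too large")
  structure(list(p_weight = p_weight, n_perm = as.integer(n_perm),
                 set_min = as.integer(set_min),
                 set_max = as.integer(set_max), seed = as.integer(seed),
                 mode = mode),
            class = "gsea_config")
}

#' Rank genes by their representative statistic
#'
#' Descending by statistic; ties broken by ascending gene id (C locale)
#' so the order is deterministic across platforms.
#'
#' @param stats data.frame from [gene_statistics()] (columns `gene_id`,
#'   `r`).
#' @return data.frame `gene_id`, `r` in rank order, with attribute `N`.
#' @export
rank_genes <- function(stats) {
  if (!nrow(stats)) stop_data("no genes to rank")
  ord <- order(-stats$r, stats$gene_id, method = "radix")
  out <- data.frame(gene_id = stats$gene_id[ord], r = stats$r[ord],
                    stringsAsFactors = FALSE)
  attr(out, "N") <- nrow(out)
  out
}

#' Weighted KS-like enrichment score
#'
#' Running sum over the ranked gene list: each set member ("hit") at
#' rank j* adds |r(j*)|^p / N_R (N_R the sum of |r|^p over hits), each
#' non-member subtracts 1 / (N - N_H); ES is the maximum of the running
#' sum over all N positions. Since the sum returns to 0 at position N,
#' ES is non-negative and reaches 1 exactly when all hits precede all
#' misses with p = 0 or concentrated weight.
#'
#' @param ranked a [rank_genes()] result (or data.frame with `gene_id`,
#'   `r` in rank order).
#' @param set_members character vector of member gene ids.
#' @param p_weight weight exponent (default 1).
#' @return the enrichment score (scalar).
#' @export
enrichment_score <- function(ranked, set_members, p_weight = 1) {
  hit <- ranked$gene_id %in% set_members
  N <- nrow(ranked)
  NH <- sum(hit)
  if (NH == 0) stop_data("no set member among ranked genes")
  if (NH == N) stop_data("set covers every ranked gene; ES undefined")
  es_running_sum(ranked$r, hit, p_weight)
}

# Shared kernel: sequential cumulative sum, same accumulation order as a
# naive loop, so independent brute-force oracles match exactly.
es_running_sum <- function(r, hit, p_weight) {
  N <- length(r)
  NH <- sum(hit)
  rp <- abs(r)^p_weight
  NR <- sum(rp[hit])
  if (NR == 0) return(NA_real_)          # all hit weights zero: degenerate
  inc <- rep(-1 / (N - NH), N)
  inc[hit] <- rp[hit] / NR
  max(cumsum(inc))
}

#' Permutation empirical P-value
#'
#' One-sided (enrichment direction): P = (1 + #\{ES_null >= ES_obs\}) /
#' (B + 1), never exactly 0; the smallest attainable value is 1/(B+1).
#'
#' @param observed observed enrichment score.
#' @param null_scores vector of permutation scores.
#' @export
empirical_p <- function(observed, null_scores) {
  ok <- !is.na(null_scores)
  (1 + sum(null_scores[ok] >= observed)) / (sum(ok) + 1)
}

#' Normalize enrichment scores against their permutation null
#'
#' NES = (ES - mean ES_null) / SD(ES_null) per set, using that set's own
#' null column and the sample SD (n - 1); the same transform
#' standardizes the null matrix itself. Zero-SD columns give NES = 0 and
#' are flagged.
#'
#' @param observed named vector of observed ES per set.
#' @param es_null B x n_sets matrix of permutation ES (columns follow
#'   `observed`).
#' @return list with `nes`, `nes_null`, `degenerate` (logical per set).
#' @export
normalize_scores <- function(observed, es_null) {
  if (is.null(dim(es_null))) es_null <- matrix(es_null, ncol = length(observed))
  if (nrow(es_null) < 2) stop_data("need at least 2 permutations to normalize")
  mu <- colMeans(es_null, na.rm = TRUE)
  sdv <- apply(es_null, 2, stats::sd, na.rm = TRUE)
  degen <- is.na(sdv) | sdv == 0
  sdv[degen] <- 1
  nes <- (observed - mu) / sdv
  nes[degen] <- 0
  nes_null <- sweep(sweep(es_null, 2, mu), 2, sdv, "/")
  nes_null[, degen] <- 0
  list(nes = nes, nes_null = nes_null, degenerate = degen)
}

#' Pooled-null false discovery rate
#'
#' For each observed NES*, FDR = (fraction of all (set, permutation)
#' standardized null NES >= NES*) / (fraction of observed sets with NES
#' >= NES*). The numerator pools every set's standardized null; the
#' denominator is at least 1/n_sets. Reported values are clipped to
#' [0, 1]; the raw ratio is also returned.
#'
#' @param nes observed NES vector.
#' @param nes_null standardized null matrix from [normalize_scores()].
#' @return list with `fdr` (clipped) and `raw`.
#' @export
compute_fdr <- function(nes, nes_null) {
  pool <- nes_null[!is.na(nes_null)]
  raw <- vapply(nes, function(x) {
    num <- mean(pool >= x)
    den <- mean(nes >= x)
    num / den
  }, 0)
  list(fdr = pmin(pmax(raw, 0), 1), raw = raw)
}

# Observed + permutation ES engine shared by both modes.
#
# snp_df:   data.frame snp_id/chrom/pos for surviving SNPs
# s_obs:    observed per-SNP statistic vector (parallel to snp_df)
# perm_fun: function(b) -> permuted statistic vector (consumes RNG)
gsea_engine <- function(snp_df, s_obs, perm_fun, genes, sets, config,
                        flank, mode, phenotype) {
  map <- map_snps_to_genes(snp_df, genes, flank)
  if (!length(map$map)) stop_data("no SNP maps to any gene")
  gene_idx <- gene_index_list(map, snp_df$snp_id)
  gu <- names(gene_idx)
  N <- length(gu)

  memb <- lapply(sets$sets, function(m) gu %in% m)
  covered <- vapply(memb, sum, 0L)
  total <- lengths(sets$sets)
  reason <- rep(NA_character_, length(memb))
  reason[covered == 0] <- "no covered gene"
  reason[covered > 0 & covered < config$set_min] <- "below set_min"
  reason[covered > config$set_max] <- "above set_max"
  reason[covered == N] <- "covers all ranked genes"
  tested <- which(is.na(reason))
  if (!length(tested))
    stop_data("no gene set passes the size filter (covered sizes: %s)",
              paste(sort(unique(covered)), collapse = ", "))

  es_for <- function(svec) {
    r <- gene_stat_from_index(svec, gene_idx)
    ord <- order(-r, gu, method = "radix")
    r_s <- r[ord]
    vapply(tested, function(k) es_running_sum(r_s, memb[[k]][ord],
                                              config$p_weight), 0)
  }

  es_obs <- es_for(s_obs)
  set.seed(config$seed)
  B <- config$n_perm
  es_null <- matrix(NA_real_, B, length(tested))
  for (b in seq_len(B)) es_null[b, ] <- es_for(perm_fun(b))

  if (B >= 2) {
    nz <- normalize_scores(es_obs, es_null)
    fdr <- compute_fdr(nz$nes, nz$nes_null)
  } else {
    nz <- list(nes = rep(NA_real_, length(tested)),
               nes_null = es_null * NA, degenerate = rep(FALSE, length(tested)))
    fdr <- list(fdr = rep(NA_real_, length(tested)),
                raw = rep(NA_real_, length(tested)))
  }
  emp <- vapply(seq_along(tested),
                function(k) empirical_p(es_obs[k], es_null[, k]), 0)

  ids <- names(sets$sets)
  res <- data.frame(set_id = ids[tested],
                    description = unname(sets$descriptions[tested]),
                    size_total = total[tested],
                    size_covered = covered[tested],
                    es = es_obs, nes = nz$nes, empirical_p = emp,
                    fdr = fdr$fdr, fdr_raw = fdr$raw,
                    degenerate = nz$degenerate,
                    mode = mode, stringsAsFactors = FALSE)
  res <- res[order(res$empirical_p, -res$nes, res$set_id,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  skipped <- data.frame(set_id = ids[!is.na(reason)],
                        size_total = total[!is.na(reason)],
                        size_covered = covered[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  structure(list(results = res, skipped = skipped, es_null = es_null,
                 nes_null = nz$nes_null, n_ranked = N,
                 n_snps_tested = nrow(snp_df), phenotype = phenotype,
                 mode = mode, config = config),
            class = "pathway_gsea")
}

#' Pathway enrichment analysis of a GWAS study
#'
#' The central computation: per-SNP association statistics are collapsed
#' to per-gene maxima, genes are ranked, and each gene set receives a
#' weighted KS-like enrichment score whose significance is judged
#' against a permutation null.
#'
#' Two null models are available. In `phenotype_perm` mode the phenotype
#' labels are shuffled across usable individuals and the full chain
#' (association statistics, gene statistics, ranking, ES) is recomputed
#' for each of B permutations; SNP QC is phenotype-free and computed
#' once. In `snp_label_perm` mode the observed per-SNP statistic (here
#' -log10 P) is permuted across SNP labels with the SNP-gene geometry
#' fixed. NES, empirical P and FDR are computed identically in both
#' modes.
#'
#' @param study a `study_bundle` (genotypes, prepared phenotypes, genes,
#'   sets).
#' @param sets gene sets to test; defaults to the study's own.
#' @param phenotype `"log_tg"`, `"log_tg_adj"` or `"binary"`.
#' @param config a [gsea_config()]; its `mode` selects the null model.
#' @param maf_min,hwe_min_p SNP QC thresholds (see [run_gwas()]).
#' @param flank SNP-to-gene mapping flank in bp (default 20000).
#' @return object of class `pathway_gsea`; see [print.pathway_gsea()].
#' @export
pathway_gsea <- function(study, sets = study$sets, phenotype = "log_tg",
                         config = gsea_config(), maf_min = 0.01,
                         hwe_min_p = 0.001, flank = 20000) {
  study <- canonicalize_study(study)
  assoc <- run_gwas(study, phenotype, maf_min = maf_min,
                    hwe_min_p = hwe_min_p)
  snp_df <- assoc[, c("snp_id", "chrom", "pos")]
  if (config$mode == "phenotype_perm") {
    y <- phenotype_vector(study, phenotype)
    used <- !is.na(y)
    yu <- y[used]
    if (length(unique(yu)) < 2)
      stop_data("fewer than 2 distinct phenotype values")
    keep <- match(assoc$snp_id, study$genotypes$map$snp_id)
    X <- study$genotypes$dosage[used, keep, drop = FALSE]
    prep <- assoc_prep(X)
    stat_fun <- if (phenotype == "binary") binary_stat_vec else quant_stat_vec
    s_obs <- assoc$stat
    nu <- length(yu)
    perm_fun <- function(b) stat_fun(prep, yu[sample.int(nu)])$stat
  } else {
    s_obs <- -log10(assoc$p)
    perm_fun <- function(b) s_obs[sample.int(length(s_obs))]
  }
  gsea_engine(snp_df, s_obs, perm_fun, study$genes, sets, config, flank,
              config$mode, phenotype)
}

#' Pathway enrichment from an external SNP P-value table
#'
#' SNP-label permutation enrichment on pre-computed GWAS P-values, for
#' results produced outside this package. The gene statistic is the
#' maximum -log10(P) among mapped SNPs.
#'
#' @param snp_pvalues data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `p`.
#' @param genes a [gene_annotation()].
#' @param sets a [gene_set_collection()].
#' @param config a [gsea_config()] (mode forced to `snp_label_perm`).
#' @param flank mapping flank in bp.
#' @return object of class `pathway_gsea`.
#' @export
pvalue_gsea <- function(snp_pvalues, genes, sets,
                        config = gsea_config(mode = "snp_label_perm"),
                        flank = 20000) {
  need <- c("snp_id", "chrom", "pos", "p")
  if (!all(need %in% names(snp_pvalues)))
    stop_data("snp_pvalues must provide %s", paste(need, collapse = ", "))
  if (any(snp_pvalues$p <= 0 | snp_pvalues$p > 1, na.rm = TRUE))
    stop_data("P-values must lie in (0, 1]")
  config$mode <- "snp_label_perm"
  s_obs <- -log10(snp_pvalues$p)
  perm_fun <- function(b) s_obs[sample.int(length(s_obs))]
  gsea_engine(snp_pvalues[, c("snp_id", "chrom", "pos")], s_obs, perm_fun,
              genes, sets, config, flank, "snp_label_perm", "external_p")
}
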