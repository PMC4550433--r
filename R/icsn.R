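#' LD search configuration
#'
#' @param r2_min r-squared cutoff for calling a proxy (default 0.6).
#' @param window search distance in bp around the index SNP (default
#'   200000).
#' @export
ld_config <- function(r2_min = 0.6, window = 200000) {
  if (r2_min < 0 || r2_min > 1) stop_config("r2_min must be in [0, 1]")
  if (window <= 0) stop_config("window must be positive")
  structure(list(r2_min = r2_min, window = window), class = "ld_config")
}

#' Composite LD r-squared between two SNPs
#'
#' Squared Pearson correlation of allele dosages (phase-free), computed
#' over complete pairs. Invariant to relabeling the counted allele of
#' either SNP. A monomorphic SNP leaves r^2 undefined; 0 is returned
#' with attribute `flagged = TRUE`.
#'
#' @param dosages_a,dosages_b dosage vectors in \{0, 1, 2, NA\}.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2) stop_data("need at least 2 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(0, flagged = TRUE))
  stats::cor(a, b)^2
}

#' Select candidate SNP sets by LD with top association signals
#'
#' For each of the `top_k` most significant SNPs, collects the
#' same-chromosome SNPs within `window` bp whose dosage r-squared with
#' the index SNP exceeds `r2_min`; the index SNP is always in its own
#' set (r^2 = 1).
#'
#' @param assoc association table from [run_gwas()].
#' @param genotypes a [geno_matrix()] providing the dosages.
#' @param top_k number of index SNPs (truncated with a warning if it
#'   exceeds the SNP count).
#' @param ld a [ld_config()].
#' @return list of lists, each with `index_snp`, `p` and a data.frame
#'   `proxies` (`snp_id`, `r2`, `pos`).
#' @export
select_candidate_snps <- function(assoc, genotypes, top_k = 10,
                                  ld = ld_config()) {
  if (top_k > nrow(assoc)) {
    warning(sprintf("top_k (%d) exceeds SNP count (%d); truncated",
                    top_k, nrow(assoc)), call. = FALSE)
    top_k <- nrow(assoc)
  }
  ord <- order(assoc$p, assoc$snp_id, method = "radix")
  idx <- ord[seq_len(top_k)]
  map <- genotypes$map
  lapply(idx, function(i) {
    id <- assoc$snp_id[i]
    mi <- match(id, map$snp_id)
    near <- which(map$chrom == map$chrom[mi] &
                    abs(map$pos - map$pos[mi]) <= ld$window)
    r2 <- vapply(near, function(j) {
      if (j == mi) return(1)
      as.numeric(ld_r2(genotypes$dosage[, mi], genotypes$dosage[, j]))
    }, 0)
    keep <- r2 > ld$r2_min | near == mi
    proxies <- data.frame(snp_id = map$snp_id[near[keep]],
                          r2 = r2[keep], pos = map$pos[near[keep]],
                          stringsAsFactors = FALSE)
    proxies <- proxies[order(-proxies$r2, proxies$snp_id,
                             method = "radix"), , drop = FALSE]
    rownames(proxies) <- NULL
    list(index_snp = id, p = assoc$p[i], proxies = proxies)
  })
}
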