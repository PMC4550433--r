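#' Minor-allele frequency from dosages
#'
#' @param dosages numeric vector in \{0, 1, 2, NA\}.
#' @return MAF = min(f, 1 - f) where f is the counted-allele frequency.
#' @export
compute_maf <- function(dosages) {
  nm <- !is.na(dosages)
  if (!any(nm)) stop_data("all genotypes missing; MAF undefined")
  f <- sum(dosages[nm]) / (2 * sum(nm))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df goodness-of-fit of observed genotype counts against the HWE
#' expectation computed from the sample allele frequency. Monomorphic
#' SNPs return P = 1 by convention.
#'
#' @param dosages numeric vector in \{0, 1, 2, NA\}.
#' @return list with `chisq`, `p` and the genotype `counts`.
#' @export
hwe_test <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop_data("all genotypes missing; HWE undefined")
  hwe_test_counts(sum(d == 0), sum(d == 1), sum(d == 2))
}

#' @rdname hwe_test
#' @param n0,n1,n2 genotype counts (0, 1 and 2 copies of the counted
#'   allele).
#' @export
hwe_test_counts <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) stop_data("no genotypes")
  p <- (n1 + 2 * n2) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chisq = 0, p = 1, counts = c(n0, n1, n2)))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((c(n0, n1, n2) - e)^2 / e)
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       counts = c(n0, n1, n2))
}

#' Allelic chi-square association test (binary trait)
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' case/control x counted/other allele-count table, each individual
#' contributing two alleles. Individuals with unknown status or missing
#' genotype are dropped pairwise.
#'
#' @param dosages numeric vector in \{0, 1, 2, NA\}.
#' @param status character ("case"/"control"), logical, or 0/1 vector;
#'   anything else is treated as unknown and excluded.
#' @return list with `stat`, `p`, `degenerate`.
#' @export
allelic_chisq <- function(dosages, status) {
  y <- status_to_binary(status)
  ok <- !is.na(dosages) & !is.na(y)
  d <- dosages[ok]; y <- y[ok]
  if (!any(y == 1) || !any(y == 0))
    stop_data("need at least one case and one control with genotypes")
  a <- sum(d[y == 1]); b <- 2 * sum(y == 1) - a      # case counted / other
  cc <- sum(d[y == 0]); dd <- 2 * sum(y == 0) - cc   # control counted / other
  chisq_2x2(a, b, cc, dd)
}

status_to_binary <- function(status) {
  if (is.character(status) || is.factor(status)) {
    s <- as.character(status)
    ifelse(s == "case", 1, ifelse(s == "control", 0, NA))
  } else if (is.logical(status)) {
    as.numeric(status)
  } else {
    s <- as.numeric(status)
    ifelse(s %in% c(0, 1), s, NA)
  }
}

chisq_2x2 <- function(a, b, cc, dd) {
  n <- a + b + cc + dd
  m1 <- a + b; m2 <- cc + dd; m3 <- a + cc; m4 <- b + dd
  if (min(m1, m2, m3, m4) == 0)
    return(list(stat = 0, p = 1, degenerate = TRUE))
  stat <- n * (a * dd - b * cc)^2 / (m1 * m2 * m3 * m4)
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Simple linear regression association test (quantitative trait)
#'
#' y ~ intercept + dosage; the statistic is the squared Wald t,
#' equivalently the 1-df F statistic (n - 2) R^2 / (1 - R^2), with P
#' from F(1, n - 2). P-values never underflow to exactly zero: an exact
#' fit is clamped to the smallest positive double and flagged.
#'
#' @param dosages numeric vector in \{0, 1, 2, NA\}.
#' @param y numeric phenotype vector.
#' @return list with `stat`, `p`, `degenerate`, `exact_fit`.
#' @export
linreg_assoc <- function(dosages, y) {
  ok <- !is.na(dosages) & !is.na(y)
  d <- dosages[ok]; yy <- y[ok]
  n <- length(d)
  if (n < 3) stop_data("need at least 3 complete genotype/phenotype pairs")
  sxx <- sum((d - mean(d))^2)
  if (sxx == 0) return(list(stat = 0, p = 1, degenerate = TRUE,
                            exact_fit = FALSE))
  syy <- sum((yy - mean(yy))^2)
  if (syy == 0) return(list(stat = 0, p = 1, degenerate = TRUE,
                            exact_fit = FALSE))
  sxy <- sum((d - mean(d)) * (yy - mean(yy)))
  r2 <- sxy^2 / (sxx * syy)
  # an exact fit leaves only rounding-noise residuals; clamp rather than
  # report a zero P
  if (r2 >= 1 - 1e-12) {
    stat <- (n - 2) * r2 / max(1 - r2, 1e-300)
    return(list(stat = stat, p = .Machine$double.xmin,
                degenerate = FALSE, exact_fit = TRUE))
  }
  stat <- (n - 2) * r2 / (1 - r2)
  p <- stats::pf(stat, 1, n - 2, lower.tail = FALSE)
  exact <- p == 0
  list(stat = stat, p = max(p, .Machine$double.xmin), degenerate = FALSE,
       exact_fit = exact)
}

#' Cochran-Armitage trend test (optional binary statistic)
#'
#' Non-default alternative to [allelic_chisq()]; equals n times the
#' squared dosage/status correlation, 1 df.
#'
#' @inheritParams allelic_chisq
#' @export
trend_chisq <- function(dosages, status) {
  y <- status_to_binary(status)
  ok <- !is.na(dosages) & !is.na(y)
  d <- dosages[ok]; y <- y[ok]
  if (!any(y == 1) || !any(y == 0))
    stop_data("need at least one case and one control with genotypes")
  if (stats::sd(d) == 0 || stats::sd(y) == 0)
    return(list(stat = 0, p = 1, degenerate = TRUE))
  stat <- length(d) * stats::cor(d, y)^2
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# ---- vectorized internals (shared by run_gwas and the permutation null) ----

# Per-SNP QC summaries over the full sample; phenotype-free by design so
# the permutation null can reuse one QC pass.
snp_qc <- function(geno) {
  X <- geno$dosage
  W <- !is.na(X)
  X0 <- X; X0[!W] <- 0
  nm <- colSums(W)
  f <- ifelse(nm > 0, colSums(X0) / (2 * nm), NA_real_)
  maf <- pmin(f, 1 - f)
  n0 <- colSums(W & X0 == 0)
  n2 <- colSums(X0 == 2, na.rm = TRUE)
  n1 <- nm - n0 - n2
  hwe_p <- hwe_pvec(n0, n1, n2)
  data.frame(snp_id = geno$map$snp_id, maf = maf, hwe_p = hwe_p,
             n_nonmissing = nm, stringsAsFactors = FALSE)
}

hwe_pvec <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (n1 + 2 * n2) / (2 * n), NA_real_)
  out <- rep(1, length(n0))
  out[is.na(p)] <- NA_real_
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (length(poly)) {
    e0 <- n[poly] * (1 - p[poly])^2
    e1 <- n[poly] * 2 * p[poly] * (1 - p[poly])
    e2 <- n[poly] * p[poly]^2
    chisq <- (n0[poly] - e0)^2 / e0 + (n1[poly] - e1)^2 / e1 +
      (n2[poly] - e2)^2 / e2
    out[poly] <- stats::pchisq(chisq, 1, lower.tail = FALSE)
  }
  out
}

# Precompute genotype cross-products on the rows used by a phenotype so
# each permutation replicate needs only three crossprod() calls.
assoc_prep <- function(X) {
  W <- (!is.na(X)) * 1
  X0 <- X; X0[is.na(X)] <- 0
  list(X0 = X0, W = W, n = colSums(W),
       sx = colSums(X0), sxx = colSums(X0^2))
}

quant_stat_vec <- function(prep, y) {
  n <- prep$n
  sy <- drop(crossprod(prep$W, y))
  syy <- drop(crossprod(prep$W, y^2))
  sxy <- drop(crossprod(prep$X0, y))
  cxx <- prep$sxx - prep$sx^2 / n
  cyy <- syy - sy^2 / n
  cxy <- sxy - prep$sx * sy / n
  denom <- cxx * cyy
  r2 <- ifelse(denom > 0, cxy^2 / denom, 0)
  ok <- n >= 3 & denom > 0
  stat <- rep(0, length(n))
  stat[ok] <- (n[ok] - 2) * r2[ok] / pmax(1 - r2[ok], 1e-300)
  p <- rep(1, length(n))
  p[ok] <- pmax(stats::pf(stat[ok], 1, n[ok] - 2, lower.tail = FALSE),
                .Machine$double.xmin)
  list(stat = stat, p = p, n = n)
}

binary_stat_vec <- function(prep, y01) {
  ncase <- drop(crossprod(prep$W, y01))
  nctrl <- prep$n - ncase
  a <- drop(crossprod(prep$X0, y01))   # counted alleles in cases
  b <- 2 * ncase - a
  cc <- prep$sx - a
  dd <- 2 * nctrl - cc
  ntot <- 2 * prep$n
  m1 <- a + b; m2 <- cc + dd; m3 <- a + cc; m4 <- b + dd
  degen <- pmin(m1, m2, m3, m4) == 0
  stat <- rep(0, length(a))
  i <- !degen
  stat[i] <- ntot[i] * (a[i] * dd[i] - b[i] * cc[i])^2 /
    (m1[i] * m2[i] * m3[i] * m4[i])
  p <- rep(1, length(a))
  p[i] <- pmax(stats::pchisq(stat[i], 1, lower.tail = FALSE),
               .Machine$double.xmin)
  list(stat = stat, p = p, n = prep$n)
}

# Phenotype vector for an analysis arm; NA marks individuals the arm
# cannot use (excluded outliers, unknown status, missing values).
phenotype_vector <- function(study, phenotype) {
  ph <- study$phenotypes
  y <- switch(phenotype,
    log_tg = ifelse(ph$included, ph$log_tg, NA_real_),
    log_tg_adj = ifelse(ph$included, ph$log_tg_adj, NA_real_),
    binary = ifelse(ph$included, status_to_binary(ph$status), NA_real_),
    stop_config("unknown phenotype '%s'", phenotype))
  as.numeric(y)
}

#' Run the per-SNP association scan
#'
#' Applies the MAF and HWE quality-control filters (computed on the full
#' sample, phenotype-free), then tests every surviving SNP against the
#' chosen phenotype: simple linear regression (F statistic) for the
#' quantitative traits, allelic chi-square for the case/control trait.
#' Missing genotypes are dropped pairwise per SNP.
#'
#' @param study a `study_bundle` (see [simulate_study()]), or any list
#'   with `genotypes` and prepared `phenotypes`.
#' @param phenotype one of `"log_tg"`, `"log_tg_adj"`, `"binary"`.
#' @param maf_min MAF threshold; SNPs with MAF <= `maf_min` are excluded
#'   (default 0.01).
#' @param hwe_min_p HWE filter; SNPs with HWE P <= `hwe_min_p` are
#'   excluded (default 0.001).
#' @param binary_test `"allelic"` (default) or `"trend"`.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `maf`,
#'   `test`, `stat`, `p`, `n_used`.
#' @export
run_gwas <- function(study, phenotype = c("log_tg", "log_tg_adj", "binary"),
                     maf_min = 0.01, hwe_min_p = 0.001,
                     binary_test = c("allelic", "trend")) {
  phenotype <- match.arg(phenotype)
  binary_test <- match.arg(binary_test)
  study <- canonicalize_study(study)
  qc <- snp_qc(study$genotypes)
  keep <- !is.na(qc$maf) & qc$maf > maf_min & qc$hwe_p > hwe_min_p
  if (!any(keep)) stop_data("no SNPs survive the MAF/HWE filters")
  y <- phenotype_vector(study, phenotype)
  used <- !is.na(y)
  if (sum(used) < 3) stop_data("fewer than 3 usable individuals")
  if (length(unique(y[used])) < 2)
    stop_data("fewer than 2 distinct phenotype values")
  X <- study$genotypes$dosage[used, keep, drop = FALSE]
  prep <- assoc_prep(X)
  if (phenotype == "binary") {
    y01 <- y[used]
    res <- if (binary_test == "allelic") binary_stat_vec(prep, y01)
           else trend_stat_vec(prep, y01)
    test <- if (binary_test == "allelic") "chisq_allelic" else "chisq_trend"
  } else {
    res <- quant_stat_vec(prep, y[used])
    test <- "linreg"
  }
  map <- study$genotypes$map[keep, , drop = FALSE]
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
             maf = qc$maf[keep], test = test, stat = res$stat, p = res$p,
             n_used = res$n, stringsAsFactors = FALSE)
}

trend_stat_vec <- function(prep, y01) {
  n <- prep$n
  sy <- drop(crossprod(prep$W, y01))
  syy <- drop(crossprod(prep$W, y01^2))
  sxy <- drop(crossprod(prep$X0, y01))
  cxx <- prep$sxx - prep$sx^2 / n
  cyy <- syy - sy^2 / n
  cxy <- sxy - prep$sx * sy / n
  denom <- cxx * cyy
  ok <- denom > 0
  stat <- rep(0, length(n))
  stat[ok] <- n[ok] * cxy[ok]^2 / denom[ok]
  p <- rep(1, length(n))
  p[ok] <- pmax(stats::pchisq(stat[ok], 1, lower.tail = FALSE),
                .Machine$double.xmin)
  list(stat = stat, p = p, n = n)
}
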