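# Small in-code fixtures shared across test files.

# A minimal study built by hand: n individuals, dosage matrix supplied
# directly, one chromosome, genes covering given SNP columns.
tiny_study <- function(dosage, tg, bmi = NULL, gene_cols = NULL,
                       sets = NULL, pos = NULL, chrom = "chr1") {
  n <- nrow(dosage); M <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = M)
  iid <- sprintf("I%03d", seq_len(n))
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(M)), chrom = chrom,
                    pos = pos, counted = "A", other = "G",
                    stringsAsFactors = FALSE)
  geno <- geno_matrix(dosage, map, iid)
  if (is.null(bmi)) bmi <- seq(22, 38, length.out = n)
  raw <- data.frame(iid = iid, tg = tg, bmi = bmi, sex = "F",
                    stringsAsFactors = FALSE)
  pheno <- prepare_phenotypes(raw, adjust = n >= 3 && sd(bmi) > 0)
  if (is.null(gene_cols)) gene_cols <- as.list(seq_len(M))
  genes <- gene_annotation(sprintf("g%02d", seq_along(gene_cols)),
                           chrom,
                           vapply(gene_cols, function(j) min(pos[j]), 0),
                           vapply(gene_cols, function(j) max(pos[j]), 0))
  if (is.null(sets))
    sets <- gene_set_collection(list(SALL = genes$gene_id))
  structure(list(genotypes = geno, phenotypes = pheno, genes = genes,
                 sets = sets,
                 truth = list(causal_snps = character(0),
                              causal_genes = character(0),
                              causal_set = character(0)),
                 seed = 1L, config = NULL),
            class = "study_bundle")
}

# Random small ranked list + set for ES oracle sweeps.
random_es_instance <- function() {
  N <- sample(3:50, 1)
  r <- sort(round(runif(N, 0, 10), 3), decreasing = TRUE)
  NH <- sample(seq_len(N - 1), 1)
  hit <- rep(FALSE, N)
  hit[sample.int(N, NH)] <- TRUE
  p <- sample(c(0, 0.5, 1, 1.5, 2), 1)
  list(r = r, hit = hit, p = p)
}

# Config for a causal study with per-SNP P calibrated near a target.
causal_config <- function(seed, n_causal = 10, p_target = 1e-4,
                          n = 1000L, n_perm = 200L) {
  maf_mid <- 0.275
  b <- beta_for_target_p(p_target, n, maf_mid, 0.25)
  sim_config(n_individuals = n, causal_set_index = 1L,
             n_causal_genes = n_causal, beta = b, seed = seed)
}
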