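#' Genomic-inflation diagnostics and QQ plot
#'
#' lambda_GC = median of the 1-df chi-square quantiles of the P-values
#' divided by the null median 0.4549364; a QQ plot of expected versus
#' observed -log10(P) is written when `file` is given.
#'
#' @param p_values numeric vector of P-values in (0, 1]; at least 10.
#' @param file optional PNG path for the QQ plot.
#' @param main plot title.
#' @return list with `lambda` and `n`.
#' @export
qq_diagnostics <- function(p_values, file = NULL, main = "QQ plot") {
  p <- p_values[!is.na(p_values)]
  if (any(p <= 0 | p > 1)) stop_data("P-values must lie in (0, 1]")
  if (length(p) < 10) stop_data("need at least 10 P-values")
  chi <- stats::qchisq(p, 1, lower.tail = FALSE)
  lambda <- stats::median(chi) / stats::qchisq(0.5, 1, lower.tail = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    n <- length(p)
    expd <- -log10((seq_len(n) - 0.5) / n)
    obs <- -log10(sort(p))
    graphics::plot(expd, obs, pch = 20,
                   xlab = "expected -log10(P)",
                   ylab = "observed -log10(P)",
                   main = sprintf("%s (lambda = %.3f)", main, lambda))
    graphics::abline(0, 1, col = "grey50")
  }
  list(lambda = lambda, n = length(p))
}

pipeline_log <- function(con, stage, msg) {
  writeLines(sprintf("[%s] %s", stage, msg), con)
}

#' Run the full analysis pipeline into a result directory
#'
#' Simulates (or accepts) a study, writes its files, prepares
#' phenotypes, runs the GWAS for each requested phenotype with QQ
#' diagnostics, runs the enrichment analysis in both permutation modes,
#' and writes a manifest recording every seed and threshold. All
#' outputs are deterministic given the seeds; re-running reproduces
#' byte-identical text files.
#'
#' @param out_dir output directory (created; must not require
#'   overwriting unrelated content).
#' @param sim a [sim_config()] used when `study` is NULL.
#' @param study optional pre-built `study_bundle`.
#' @param gsea a [gsea_config()]; mode is set per arm internally.
#' @param gsea_phenotype phenotype for the enrichment arms (default
#'   `"binary"`, the case/control design).
#' @param phenotypes GWAS arms to run.
#' @param maf_min,hwe_min_p,flank QC and mapping parameters.
#' @param plots write QQ plot PNGs (side outputs only).
#' @return invisibly, the manifest list.
#' @export
run_full_pipeline <- function(out_dir, sim = sim_config(), study = NULL,
                              gsea = gsea_config(n_perm = 200L),
                              gsea_phenotype = "binary",
                              phenotypes = c("log_tg", "log_tg_adj",
                                             "binary"),
                              maf_min = 0.01, hwe_min_p = 0.001,
                              flank = 20000, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  stage <- "init"
  manifest <- list(package_version = as.character(utils::packageVersion("pathgsea")),
                   maf_min = maf_min, hwe_min_p = hwe_min_p, flank = flank,
                   gsea = unclass(gsea), gsea_phenotype = gsea_phenotype)
  fail <- function(e) {
    writeLines("FAILED", file.path(out_dir, "FAILED"))
    pipeline_log(con, stage, paste("error:", conditionMessage(e)))
    stop_data("pipeline failed at stage '%s': %s", stage,
              conditionMessage(e))
  }
  tryCatch({
    stage <- "simulate"
    if (is.null(study)) {
      pipeline_log(con, stage, sprintf("simulating study, seed %d",
                                       sim$seed))
      study <- simulate_study(sim)
      manifest$sim <- unclass(sim)
    } else {
      pipeline_log(con, stage, "using supplied study")
    }
    manifest$seed <- study$seed

    stage <- "write_study"
    write_study(study, out_dir)
    pipeline_log(con, stage, "study files written")

    stage <- "phenotype_prep"
    write_phenotypes(study$phenotypes,
                     file.path(out_dir, "phenotypes_prepared.tsv"))
    st <- table(study$phenotypes$status[study$phenotypes$included])
    pipeline_log(con, stage,
                 sprintf("included %d of %d individuals; cases %d, controls %d",
                         sum(study$phenotypes$included),
                         nrow(study$phenotypes),
                         sum(st[names(st) == "case"]),
                         sum(st[names(st) == "control"])))

    stage <- "gwas"
    manifest$lambda <- list()
    for (ph in phenotypes) {
      a <- run_gwas(study, ph, maf_min = maf_min, hwe_min_p = hwe_min_p)
      out <- data.frame(SNP = a$snp_id, CHR = a$chrom, BP = a$pos,
                        MAF = a$maf, TEST = a$test, STAT = a$stat,
                        P = a$p, N = a$n_used, stringsAsFactors = FALSE)
      utils::write.table(out, file.path(out_dir,
                                        sprintf("gwas_%s.tsv", ph)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      qq <- qq_diagnostics(a$p,
                           file = if (plots)
                             file.path(out_dir, sprintf("qq_%s.png", ph))
                           else NULL,
                           main = sprintf("GWAS %s", ph))
      manifest$lambda[[ph]] <- qq$lambda
      pipeline_log(con, stage,
                   sprintf("%s: %d SNPs tested, lambda %.3f", ph,
                           nrow(a), qq$lambda))
    }

    stage <- "gsea_phenotype_perm"
    cfg1 <- gsea; cfg1$mode <- "phenotype_perm"
    g1 <- pathway_gsea(study, phenotype = gsea_phenotype, config = cfg1,
                       maf_min = maf_min, hwe_min_p = hwe_min_p,
                       flank = flank)
    write_results(g1, file.path(out_dir, "enrichment_phenotype_perm.tsv"))
    pipeline_log(con, stage, sprintf("%d sets tested", nrow(g1$results)))

    stage <- "gsea_snp_label_perm"
    cfg2 <- gsea; cfg2$mode <- "snp_label_perm"
    g2 <- pathway_gsea(study, phenotype = gsea_phenotype, config = cfg2,
                       maf_min = maf_min, hwe_min_p = hwe_min_p,
                       flank = flank)
    write_results(g2, file.path(out_dir, "enrichment_snp_label_perm.tsv"))
    pipeline_log(con, stage, sprintf("%d sets tested", nrow(g2$results)))

    stage <- "manifest"
    manifest$files <- sort(setdiff(list.files(out_dir),
                                   c("manifest.json", "run.log")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pipeline_log(con, stage, "done")
  }, error = fail)
  invisible(manifest)
}

#' Write a study bundle to disk
#'
#' Files: `study.ped`/`study.map` (genotypes), `phenotypes.tsv` (IID,
#' TG_MGDL, BMI, SEX), `genes.bed`, `sets.gmt`, `truth.json`.
#'
#' @param study a `study_bundle`.
#' @param dir output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ped_map(study$genotypes, file.path(dir, "study.ped"),
                file.path(dir, "study.map"), study$phenotypes)
  raw <- study$phenotypes[, intersect(c("iid", "tg", "bmi", "sex"),
                                      names(study$phenotypes))]
  write_phenotypes(raw, file.path(dir, "phenotypes.tsv"))
  write_bed_genes(study$genes, file.path(dir, "genes.bed"))
  write_gmt(study$sets, file.path(dir, "sets.gmt"))
  jsonlite::write_json(list(truth = study$truth, seed = study$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' Phenotypes are re-prepared from the raw TG/BMI columns.
#'
#' @param dir directory containing the study files.
#' @return a `study_bundle`.
#' @export
read_study <- function(dir) {
  geno <- read_ped_map(file.path(dir, "study.ped"),
                       file.path(dir, "study.map"))
  raw <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  adjust <- nrow(raw) >= 3 && stats::sd(raw$bmi) > 0
  pheno <- prepare_phenotypes(raw, adjust = adjust)
  genes <- read_bed_genes(file.path(dir, "genes.bed"))
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  truth <- list(causal_snps = character(0), causal_genes = character(0),
                causal_set = character(0))
  seed <- NA_integer_
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    if (!is.null(tr$truth)) {
      truth <- lapply(tr$truth, as.character)
    }
    if (!is.null(tr$seed)) seed <- tr$seed
  }
  structure(list(genotypes = geno, phenotypes = pheno, genes = genes,
                 sets = sets, truth = truth, seed = seed, config = NULL),
            class = "study_bundle")
}

#' Build simulation and enrichment configs from a YAML file
#'
#' The YAML may contain top-level `sim:` and `gsea:` mappings whose
#' keys are the arguments of [sim_config()] and [gsea_config()].
#'
#' @param path YAML file path.
#' @return list with `sim` and `gsea` configs.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, if (is.null(y$sim)) list() else y$sim)
  gsea <- do.call(gsea_config, if (is.null(y$gsea)) list() else y$gsea)
  list(sim = sim, gsea = gsea)
}
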