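split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read PLINK-style .ped/.map text files
#'
#' The counted allele is chosen per SNP as the minor allele by observed
#' frequency (ties broken by lexicographic allele order), so dosages are
#' minor-allele counts; `0 0` genotypes are missing. Only biallelic SNPs
#' are supported.
#'
#' @param ped_path,map_path paths to the .ped and .map files. The .map
#'   may have 3 (chrom, id, pos) or 4 (chrom, id, cM, pos) columns.
#' @return a [geno_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(map_path)) stop_format("map file not found: %s", map_path)
  if (!file.exists(ped_path)) stop_format("ped file not found: %s", ped_path)
  ml <- split_ws(readLines(map_path))
  ml <- ml[lengths(ml) > 0]
  nc <- unique(lengths(ml))
  if (length(ml) == 0) stop_format("empty map file")
  if (length(nc) != 1 || !nc %in% c(3, 4))
    stop_format("map file must have 3 or 4 whitespace-separated columns")
  mm <- do.call(rbind, ml)
  chrom <- mm[, 1]
  snp_id <- mm[, 2]
  pos <- as.numeric(mm[, ncol(mm)])
  if (anyNA(pos)) stop_format("non-numeric position in map file")
  dup <- snp_id[duplicated(snp_id)]
  if (length(dup)) stop_format("duplicate SNP id in map: %s", dup[1])
  M <- length(snp_id)

  pl <- readLines(ped_path)
  pl <- pl[nzchar(trimws(pl))]
  n <- length(pl)
  toks <- split_ws(pl)
  want <- 6 + 2 * M
  for (i in seq_len(n))
    if (length(toks[[i]]) != want)
      stop_format("ped line %d has %d fields, expected %d", i,
                  length(toks[[i]]), want)
  iid <- vapply(toks, `[`, "", 2)
  if (anyDuplicated(iid))
    stop_format("duplicate individual id in ped: %s",
                iid[duplicated(iid)][1])
  sex <- if (n > 0) vapply(toks, `[`, "", 5) else character(0)
  al <- matrix("0", nrow = n, ncol = 2 * M)
  for (i in seq_len(n)) al[i, ] <- toks[[i]][-(1:6)]

  dos <- matrix(NA_real_, n, M)
  counted <- other <- character(M)
  for (j in seq_len(M)) {
    a1 <- al[, 2 * j - 1]; a2 <- al[, 2 * j]
    missing <- a1 == "0" | a2 == "0"
    obs <- c(a1[!missing], a2[!missing])
    u <- sort(unique(obs))
    if (length(u) > 2)
      stop_format("SNP %s is not biallelic (alleles %s)", snp_id[j],
                  paste(u, collapse = "/"))
    if (length(u) == 0) {                    # all missing
      counted[j] <- "0"; other[j] <- "0"
      next
    }
    if (length(u) == 1) {
      counted[j] <- u; other[j] <- "0"
      dos[!missing, j] <- 2
      next
    }
    cnt <- c(sum(obs == u[1]), sum(obs == u[2]))
    # minor allele counted; tie -> lexicographically first (u is sorted)
    ctd <- if (cnt[1] <= cnt[2]) u[1] else u[2]
    counted[j] <- ctd
    other[j] <- setdiff(u, ctd)
    dos[!missing, j] <- (a1[!missing] == ctd) + (a2[!missing] == ctd)
  }
  map <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                    counted = counted, other = other,
                    stringsAsFactors = FALSE)
  g <- geno_matrix(dos, map, iid)
  attr(g, "sex") <- stats::setNames(sex, iid)
  g
}

#' Write PLINK-style .ped/.map text files
#'
#' Heterozygotes are written with the lexicographically smaller allele
#' first so that write -> read -> write is the identity at the file
#' level.
#'
#' @param geno a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @param phenotypes optional data.frame with `iid` and `sex` used for
#'   the ped sex column.
#' @export
write_ped_map <- function(geno, ped_path, map_path, phenotypes = NULL) {
  map <- geno$map
  writeLines(paste(map$chrom, map$snp_id, 0, format(map$pos, scientific = FALSE, trim = TRUE),
                   sep = "\t"), map_path)
  n <- nrow(geno$dosage)
  sex <- rep("0", n)
  if (!is.null(phenotypes) && all(c("iid", "sex") %in% names(phenotypes))) {
    m <- match(geno$individual_ids, phenotypes$iid)
    sex <- ifelse(is.na(m), "0",
                  ifelse(phenotypes$sex[m] == "F", "2",
                         ifelse(phenotypes$sex[m] == "M", "1", "0")))
  }
  het <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lines <- character(n)
  M <- ncol(geno$dosage)
  gt <- matrix("0 0", n, M)
  for (j in seq_len(M)) {
    d <- geno$dosage[, j]
    ctd <- map$counted[j]; oth <- map$other[j]
    gt[!is.na(d) & d == 0, j] <- paste(oth, oth)
    gt[!is.na(d) & d == 1, j] <- het(ctd, oth)
    gt[!is.na(d) & d == 2, j] <- paste(ctd, ctd)
  }
  for (i in seq_len(n)) {
    lines[i] <- paste(c(geno$individual_ids[i], geno$individual_ids[i],
                        "0", "0", sex[i], "-9", gt[i, ]), collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set id, description, member genes. Duplicate
#' members within a line are dropped with a warning.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_format("GMT line %d has %d fields; need set id, description and at least one member",
                  i, length(f))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d (%s): duplicate members removed", i, f[1]),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    desc <- c(desc, f[2])
  }
  gene_set_collection(sets, desc)
}

#' Write a GMT gene-set file
#' @param sets a [gene_set_collection()].
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets$sets), function(i) {
    paste(c(names(sets$sets)[i], sets$descriptions[i], sets$sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; internally genes are 1-based inclusive, so
#' `[start, end)` becomes `[start + 1, end]`. Column 4 (name) is
#' required and must be unique.
#'
#' @param path BED3+ file path.
#' @return a [gene_annotation()].
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop_format("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(gene_annotation(character(0), character(0), numeric(0),
                           numeric(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(f))
    if (length(f[[i]]) < 4)
      stop_format("BED line %d lacks a name column", i)
  chrom <- vapply(f, `[`, "", 1)
  start0 <- as.numeric(vapply(f, `[`, "", 2))
  end0 <- as.numeric(vapply(f, `[`, "", 3))
  name <- vapply(f, `[`, "", 4)
  if (anyNA(start0) || anyNA(end0))
    stop_format("non-numeric BED coordinates")
  bad <- which(end0 <= start0)
  if (length(bad)) stop_format("BED line %d has end <= start", bad[1])
  if (anyDuplicated(name))
    stop_format("duplicate gene id in BED: %s", name[duplicated(name)][1])
  gene_annotation(name, chrom, start0 + 1, end0)
}

#' Write gene intervals to BED (inverse of [read_bed_genes()])
#' @param genes a [gene_annotation()].
#' @param path output path.
#' @export
write_bed_genes <- function(genes, path) {
  writeLines(paste(genes$chrom,
                   format(genes$start - 1, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene_id, sep = "\t"), path)
  invisible(path)
}

#' Read/write the tab-separated dosage dialect
#'
#' Rows are individuals (first column IID), columns are SNPs, values are
#' dosages with `NA` for missing.
#'
#' @param geno a [geno_matrix()].
#' @param path file path.
#' @param map optional data.frame (`snp_id`, `chrom`, `pos`) giving SNP
#'   coordinates when reading; defaults to chromosome "1", positions
#'   1..M.
#' @export
write_dosage <- function(geno, path) {
  df <- data.frame(IID = geno$individual_ids, geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path, map = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  iid <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  snp_id <- colnames(dos)
  if (is.null(map)) {
    map <- data.frame(snp_id = snp_id, chrom = "1",
                      pos = seq_along(snp_id), stringsAsFactors = FALSE)
  }
  m <- match(snp_id, map$snp_id)
  if (anyNA(m)) stop_format("SNP ids in dosage file missing from map")
  full <- data.frame(snp_id = snp_id, chrom = map$chrom[m],
                     pos = map$pos[m], counted = "B", other = "A",
                     stringsAsFactors = FALSE)
  geno_matrix(dos, full, iid)
}

#' Write prepared phenotypes to TSV
#'
#' Columns: IID, TG_MGDL, BMI, SEX (if present), LOG_TG, LOG_TG_ADJ,
#' STATUS, INCLUDED (prepared tables), or the raw subset for unprepared
#' tables.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- data.frame(IID = pheno$iid, TG_MGDL = pheno$tg, BMI = pheno$bmi,
                    stringsAsFactors = FALSE)
  if (!is.null(pheno$sex)) out$SEX <- pheno$sex
  if (!is.null(pheno$log_tg)) {
    out$LOG_TG <- pheno$log_tg
    out$LOG_TG_ADJ <- pheno$log_tg_adj
    out$STATUS <- pheno$status
    out$INCLUDED <- pheno$included
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- data.frame(iid = as.character(df$IID), tg = df$TG_MGDL,
                    bmi = df$BMI, stringsAsFactors = FALSE)
  if (!is.null(df$SEX)) out$sex <- as.character(df$SEX)
  if (!is.null(df$LOG_TG)) {
    out$log_tg <- df$LOG_TG
    out$log_tg_adj <- df$LOG_TG_ADJ
    out$status <- df$STATUS
    out$included <- df$INCLUDED
  }
  out
}

format_empirical_p <- function(p, n_perm) {
  floor_p <- 1 / (n_perm + 1)
  ifelse(p <= floor_p + 1e-12,
         paste0("<", format(signif(floor_p, 2), scientific = FALSE)),
         as.character(p))
}

#' Write enrichment results to TSV
#'
#' Columns: set_id, description, size_total, size_covered, ES, NES,
#' empirical_P, FDR, mode; sorted by empirical P then NES descending.
#' Empirical P at the permutation resolution is printed as
#' `<1/(B+1)` (e.g. `<0.001` at B = 1000).
#'
#' @param results a `pathway_gsea` object or its results data.frame.
#' @param path output path.
#' @param n_perm number of permutations (taken from a `pathway_gsea`
#'   object automatically).
#' @export
write_results <- function(results, path, n_perm = NULL) {
  if (inherits(results, "pathway_gsea")) {
    n_perm <- results$config$n_perm
    results <- results$results
  }
  if (is.null(n_perm)) stop_config("n_perm required to format empirical P")
  df <- results[order(results$empirical_p, -results$nes, results$set_id,
                      method = "radix"), , drop = FALSE]
  out <- data.frame(set_id = df$set_id, description = df$description,
                    size_total = df$size_total,
                    size_covered = df$size_covered,
                    ES = as.character(df$es), NES = as.character(df$nes),
                    empirical_P = format_empirical_p(df$empirical_p, n_perm),
                    FDR = as.character(df$fdr), mode = df$mode,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(set_id = "character",
                                   description = "character",
                                   empirical_P = "character",
                                   mode = "character"),
                    stringsAsFactors = FALSE)
}
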