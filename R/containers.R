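#' Genotype matrix container
#'
#' Holds an individuals x SNPs allele-dosage matrix together with its SNP
#' map. Dosages count the *counted* allele (0, 1, 2 or `NA` for missing);
#' at load time the counted allele is the minor allele, so dosage sums
#' translate directly into minor-allele counts. Positions are 1-based.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos`, `counted`,
#'   `other` (allele labels; `counted` is the allele the dosage counts).
#' @param individual_ids character vector of unique individual identifiers.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, individual_ids = rownames(dosage)) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(individual_ids)) {
    if (nrow(dosage) > 0)
      stop_config("individual_ids required when dosage has no rownames")
    individual_ids <- character(0)
  }
  individual_ids <- as.character(individual_ids)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "counted", "other")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop_config("SNP map lacks column(s): %s", paste(miss, collapse = ", "))
  map$snp_id <- as.character(map$snp_id)
  map$chrom  <- as.character(map$chrom)
  map$pos    <- as.numeric(map$pos)
  if (anyDuplicated(map$snp_id))
    stop_config("duplicate SNP ids in map")
  if (anyDuplicated(individual_ids))
    stop_config("duplicate individual ids")
  if (length(individual_ids) != nrow(dosage))
    stop_config("individual_ids length (%d) != rows of dosage (%d)",
                length(individual_ids), nrow(dosage))
  if (ncol(dosage) != nrow(map))
    stop_config("dosage has %d SNP columns but map has %d rows",
                ncol(dosage), nrow(map))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop_data("dosage values must be 0, 1, 2 or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop_data("positions not sorted on chromosome %s", ch)
  }
  rownames(dosage) <- individual_ids
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map,
                 individual_ids = individual_ids),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$dosage))
  if (is.nan(miss)) miss <- 0
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Gene annotation container
#'
#' Gene intervals stored 1-based inclusive (`start <= end`), the internal
#' convention shared with SNP map positions; BED input is converted at the
#' boundary by [read_bed_genes()].
#'
#' @param gene_id,chrom,start,end parallel vectors describing one gene per
#'   element.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyDuplicated(gene_id)) stop_format("duplicate gene ids")
  if (any(start > end)) stop_format("gene interval with start > end")
  if (any(start < 1)) stop_format("gene start below 1")
  out <- data.frame(gene_id = gene_id, chrom = chrom,
                    start = start, end = end, stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Gene-set collection container
#'
#' An ordered collection of named gene sets, mirroring the GMT layout:
#' each set has an id, a free-text description and a vector of unique
#' member gene ids.
#'
#' @param sets named list of character vectors (members, unique within a
#'   set).
#' @param descriptions optional character vector parallel to `sets`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) && length(sets))
    stop_config("sets must be a named list")
  if (anyDuplicated(names(sets))) stop_config("duplicate set ids")
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    if (anyDuplicated(m)) stop_config("duplicate members within a set")
    m
  })
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(sets))
    stop_config("descriptions length mismatch")
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets", length(sz)))
  if (length(sz))
    cat(sprintf(", sizes %d-%d (median %g)", min(sz), max(sz),
                stats::median(sz)))
  cat("\n")
  invisible(x)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study_bundle\n")
  cat(sprintf("  genotypes : %d individuals x %d SNPs\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage)))
  cat(sprintf("  genes     : %d\n", nrow(x$genes)))
  cat(sprintf("  gene sets : %d\n", length(x$sets)))
  if (length(x$truth$causal_snps))
    cat(sprintf("  truth     : %d causal SNPs in set %s\n",
                length(x$truth$causal_snps), x$truth$causal_set))
  cat(sprintf("  seed      : %s\n", format(x$seed)))
  invisible(x)
}

# Canonical individual order (C-locale sort of IDs) so every analysis is
# invariant to the row order of its inputs, including the permutation
# null draws.
canonicalize_study <- function(study) {
  ord <- order(study$genotypes$individual_ids, method = "radix")
  g <- study$genotypes
  g$dosage <- g$dosage[ord, , drop = FALSE]
  g$individual_ids <- g$individual_ids[ord]
  study$genotypes <- g
  ph <- study$phenotypes
  pord <- order(ph$iid, method = "radix")
  study$phenotypes <- ph[pord, , drop = FALSE]
  rownames(study$phenotypes) <- NULL
  if (!identical(study$phenotypes$iid, g$individual_ids))
    stop_data("individual ids differ between genotypes and phenotypes")
  study
}
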