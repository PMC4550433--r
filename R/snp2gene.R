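#' Map SNPs to genes with flanking windows
#'
#' A SNP maps to a gene when it lies on the same chromosome within
#' `[start - flank, end + flank]` (1-based inclusive on both sides; the
#' lower bound is clamped at 1). A SNP inside two flanked windows maps
#' to both genes; genes with no mapped SNP are absent from the result.
#'
#' @param snps a [geno_matrix()], an association result table, or any
#'   data.frame with columns `snp_id`, `chrom`, `pos`.
#' @param genes a [gene_annotation()].
#' @param flank flank size in bp (default 20000).
#' @return object of class `snp_gene_map`: list with `map` (named list,
#'   gene_id -> character vector of snp_ids) and `flank`.
#' @export
map_snps_to_genes <- function(snps, genes, flank = 20000) {
  if (inherits(snps, "geno_matrix")) snps <- snps$map
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps)))
    stop_data("snps must provide snp_id, chrom, pos")
  if (flank < 0) stop_config("flank must be >= 0")
  orphan <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(orphan))
    warning(sprintf("chromosome(s) %s present in SNPs but not in gene annotation; those SNPs are unmapped",
                    paste(orphan, collapse = ", ")), call. = FALSE)
  by_chrom <- split(seq_len(nrow(snps)), snps$chrom)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    idx <- by_chrom[[genes$chrom[i]]]
    if (is.null(idx)) next
    lo <- max(1, genes$start[i] - flank)
    hi <- genes$end[i] + flank
    hit <- idx[snps$pos[idx] >= lo & snps$pos[idx] <= hi]
    if (length(hit)) out[[i]] <- snps$snp_id[hit]
  }
  out <- out[!vapply(out, is.null, TRUE)]
  structure(list(map = out, flank = flank), class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  ns <- lengths(x$map)
  cat(sprintf("snp_gene_map: %d genes with >= 1 SNP (flank %g bp)",
              length(ns), x$flank))
  if (length(ns)) cat(sprintf("; SNPs per gene %d-%d", min(ns), max(ns)))
  cat("\n")
  invisible(x)
}

#' Collapse per-SNP statistics to per-gene representative statistics
#'
#' Each gene is represented by the largest association statistic among
#' its mapped SNPs that survived QC; genes whose mapped SNPs all failed
#' QC are dropped. Ties in the maximum are reported with the SNP of
#' smaller P, then lexicographically smaller id (the statistic itself is
#' unaffected).
#'
#' @param assoc association table from [run_gwas()] (or any data.frame
#'   with `snp_id`, `stat` and optionally `p`).
#' @param map a [map_snps_to_genes()] result.
#' @return data.frame with columns `gene_id`, `r`, `best_snp`, `n_snps`,
#'   ordered by gene_id.
#' @export
gene_statistics <- function(assoc, map) {
  stat <- assoc$stat
  pv <- if (!is.null(assoc$p)) assoc$p else rep(NA_real_, length(stat))
  gene_ids <- names(map$map)
  rows <- lapply(gene_ids, function(g) {
    idx <- match(map$map[[g]], assoc$snp_id)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    s <- stat[idx]
    best <- idx[order(-s, pv[idx], assoc$snp_id[idx], method = "radix")][1]
    data.frame(gene_id = g, r = max(s), best_snp = assoc$snp_id[best],
               n_snps = length(idx), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop_data("no gene has a surviving mapped SNP")
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Integer index version used by the permutation engine: gene -> indices
# into the (fixed) surviving-SNP statistic vector.
gene_index_list <- function(map, snp_ids) {
  idx <- lapply(map$map, function(s) {
    i <- match(s, snp_ids)
    i[!is.na(i)]
  })
  idx <- idx[lengths(idx) > 0]
  idx[order(names(idx), method = "radix")]
}

gene_stat_from_index <- function(stat, gene_idx) {
  vapply(gene_idx, function(i) max(stat[i]), 0)
}
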