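#' @export
print.pathway_gsea <- function(x, n = 10, ...) {
  cat(sprintf("pathway_gsea: %d sets tested (%d skipped), %d ranked genes, %d SNPs\n",
              nrow(x$results), nrow(x$skipped), x$n_ranked,
              x$n_snps_tested))
  cat(sprintf("  mode %s, phenotype %s, B = %d permutations, p-weight %g\n",
              x$mode, x$phenotype, x$config$n_perm, x$config$p_weight))
  top <- utils::head(x$results, n)
  if (nrow(top)) {
    show <- data.frame(set_id = top$set_id,
                       size = top$size_covered,
                       ES = signif(top$es, 4),
                       NES = signif(top$nes, 4),
                       empirical_P = format_empirical_p(top$empirical_p,
                                                       x$config$n_perm),
                       FDR = signif(top$fdr, 3))
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a pathway enrichment result
#'
#' @param object a `pathway_gsea` object.
#' @param fdr_cut FDR threshold used in the count of called sets.
#' @param ... unused.
#' @export
summary.pathway_gsea <- function(object, fdr_cut = 0.25, ...) {
  r <- object$results
  out <- list(n_tested = nrow(r), n_skipped = nrow(object$skipped),
              n_ranked_genes = object$n_ranked,
              n_snps = object$n_snps_tested,
              n_perm = object$config$n_perm, mode = object$mode,
              phenotype = object$phenotype,
              min_empirical_p = if (nrow(r)) min(r$empirical_p) else NA,
              n_fdr_called = sum(r$fdr < fdr_cut, na.rm = TRUE),
              fdr_cut = fdr_cut)
  class(out) <- "summary.pathway_gsea"
  out
}

#' @export
print.summary.pathway_gsea <- function(x, ...) {
  cat(sprintf("Pathway enrichment summary (%s, %s)\n", x$mode, x$phenotype))
  cat(sprintf("  sets tested: %d (skipped %d)\n", x$n_tested, x$n_skipped))
  cat(sprintf("  ranked genes: %d from %d SNPs\n", x$n_ranked_genes,
              x$n_snps))
  cat(sprintf("  permutations: %d\n", x$n_perm))
  cat(sprintf("  smallest empirical P: %s\n",
              format_empirical_p(x$min_empirical_p, x$n_perm)))
  cat(sprintf("  sets with FDR < %g: %d\n", x$fdr_cut, x$n_fdr_called))
  invisible(x)
}

#' @export
as.data.frame.pathway_gsea <- function(x, ...) x$results

#' Plot a pathway enrichment result
#'
#' NES against -log10 empirical P for every tested set; sets below the
#' FDR threshold are filled.
#'
#' @param x a `pathway_gsea` object.
#' @param fdr_cut highlight threshold (default 0.25).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pathway_gsea <- function(x, fdr_cut = 0.25, ...) {
  r <- x$results
  if (!nrow(r)) {
    warning("nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  called <- !is.na(r$fdr) & r$fdr < fdr_cut
  graphics::plot(r$nes, -log10(r$empirical_p),
                 pch = ifelse(called, 19, 1),
                 xlab = "NES", ylab = "-log10 empirical P",
                 main = sprintf("Pathway enrichment (%s)", x$mode), ...)
  if (any(called))
    graphics::legend("topleft", pch = c(19, 1),
                     legend = c(sprintf("FDR < %g", fdr_cut), "other"),
                     bty = "n")
  invisible(x)
}
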