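# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive loops so they share no code path with the package
# internals they check.

# Enrichment score: brute-force evaluation that re-sums the increment
# prefix from scratch at every position (O(N^2); no shared cumsum path).
oracle_es <- function(r_sorted, hit, p_weight = 1) {
  N <- length(r_sorted)
  NH <- sum(hit)
  NR <- sum(abs(r_sorted[hit])^p_weight)
  step <- numeric(N)
  for (j in seq_len(N)) {
    step[j] <- if (hit[j]) abs(r_sorted[j])^p_weight / NR
               else -1 / (N - NH)
  }
  vals <- numeric(N)
  for (j in seq_len(N)) vals[j] <- sum(step[seq_len(j)])
  max(vals)
}

# Unweighted KS-style score (the p = 0 reduction), written separately.
oracle_es_unweighted <- function(hit) {
  N <- length(hit)
  NH <- sum(hit)
  run <- 0
  best <- -Inf
  for (j in seq_len(N)) {
    run <- run + if (hit[j]) 1 / NH else -1 / (N - NH)
    if (run > best) best <- run
  }
  best
}

# Per-gene max statistic via a double loop over (gene, SNP) pairs.
oracle_gene_stats <- function(assoc, map_list) {
  out <- list()
  for (g in names(map_list)) {
    best <- -Inf
    n <- 0
    for (s in map_list[[g]]) {
      k <- which(assoc$snp_id == s)
      if (length(k) == 1) {
        n <- n + 1
        if (assoc$stat[k] > best) best <- assoc$stat[k]
      }
    }
    if (n > 0) out[[g]] <- c(r = best, n = n)
  }
  out
}
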