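# Shared fixtures and independent oracles used across test files.

all_categories <- c(
  "total_up_only", "total_down_only", "poly_up_only", "poly_down_only",
  "concordant_up", "concordant_down", "opposing", "null"
)

null_category_fractions <- c(
  total_up_only = 0, total_down_only = 0, poly_up_only = 0, poly_down_only = 0,
  concordant_up = 0, concordant_down = 0, opposing = 0, null = 1
)

# A small fully-null configuration (no planted effects of any kind).
null_sim_config <- function(n_genes = 1000L, seed = 1L, ...) {
  sim_config(
    n_genes = n_genes,
    category_fractions = null_category_fractions,
    effect_size_log2 = 0,
    motif_attenuation_delta = 0,
    seed = seed,
    ...
  )
}

samples_for <- function(sim, fraction) {
  sim$samples[sim$samples$fraction == fraction, , drop = FALSE]
}

# gene-level ids for probeset-level calls (unique mappers only)
probeset_to_gene <- function(sim) {
  p2t <- suppressMessages(map_probesets(sim$probeset2transcript, "transcript"))
  tibble::tibble(
    probeset_id = p2t$probeset_id,
    gene_id = sim$transcript2gene$gene_id[
      match(p2t$transcript_id, sim$transcript2gene$transcript_id)]
  )
}

# --- independent oracles -----------------------------------------------------

# Brute-force BH: for each i, min over j >= i (in sorted order) of p_(j)*m/j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric tails by enumerating all size-n subsets of an
# N-element urn with K marked elements.
hypergeom_oracle <- function(k, n, K, N) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(subsets, 2L, function(s) sum(s %in% marked))
  c(p_over = mean(overlaps >= k), p_under = mean(overlaps <= k))
}

# KS D by direct ECDF evaluation on the pooled grid.
ks_D_oracle <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
}

# Exact two-sided KS p by enumerating every assignment of the pooled values.
ks_p_oracle <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  D_obs <- ks_D_oracle(x, y)
  idx <- utils::combn(length(pool), nx)
  Ds <- apply(idx, 2L, function(ix) ks_D_oracle(pool[ix], pool[-ix]))
  mean(Ds >= D_obs - 1e-12)
}

# All-offsets motif count: test, at every offset, whether a regex match
# starts exactly there.
motif_count_oracle <- function(seq, regex) {
  L <- nchar(seq)
  anchored <- paste0("^(?:", regex, ")")
  sum(vapply(seq_len(L), function(i) {
    grepl(anchored, substr(seq, i, L), perl = TRUE)
  }, logical(1)))
}

# Hand-written category lookup used as the oracle for the 3x3 state grid.
category_oracle <- function(total_state, poly_state) {
  key <- paste(total_state, poly_state)
  switch(key,
    "up ns" = "total_up_only", "down ns" = "total_down_only",
    "ns up" = "poly_up_only", "ns down" = "poly_down_only",
    "up up" = "concordant_up", "down down" = "concordant_down",
    "up down" = , "down up" = "opposing",
    "ns ns" = "null")
}

# de table with prescribed per-id (log2fc, fdr); p set equal to fdr.
make_de <- function(ids, log2fc, fdr, fraction = "total") {
  tibble::tibble(probeset_id = ids, avg_expr = 8, log2fc = log2fc,
                 p = fdr, fdr = fdr, fraction = fraction)
}
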