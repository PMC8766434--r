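## Shared fixtures and independent oracles used across the suite.

## Small compendium used by several tests.
small_compendium <- function(seed = 1, n_batches = 1, ...) {
  args <- list(
    n_genes = 400,
    modules = list(list(size = 80, effect_sd = 2, phenotype_link = "IBC"),
                   list(size = 80, effect_sd = 2, phenotype_link = "none")),
    n_cell_lines_ibc = 4, n_cell_lines_nibc = 6, replicates_per_line = 3,
    n_batches = n_batches, batch_shift_sd = if (n_batches > 1) 0.5 else 0,
    batch_scale_sd = if (n_batches > 1) 0.1 else 0,
    noise_sd = 1, seed = seed
  )
  args <- utils::modifyList(args, list(...))
  generate_cell_line_compendium(do.call(compendium_spec, args))
}

## Conditions fixed by the recovery benchmark: a compendium of exactly
## 3 x 150 planted module genes, effect_sd/noise_sd = 2, 10 lines x 3
## replicates.
recovery_compendium <- function(seed) {
  generate_cell_line_compendium(compendium_spec(
    n_genes = 450,
    modules = list(list(size = 150, effect_sd = 2, phenotype_link = "IBC"),
                   list(size = 150, effect_sd = 2, phenotype_link = "nIBC"),
                   list(size = 150, effect_sd = 2, phenotype_link = "none")),
    n_cell_lines_ibc = 5, n_cell_lines_nibc = 5, replicates_per_line = 3,
    n_batches = 1, batch_shift_sd = 0, batch_scale_sd = 0,
    noise_sd = 1, seed = seed))
}

planted_truth <- function(compendium) {
  truth <- setNames(rep(0L, nrow(compendium$values)),
                    rownames(compendium$values))
  for (m in seq_along(compendium$truth$module_genes)) {
    truth[compendium$truth$module_genes[[m]]] <- m
  }
  truth
}

## Run the network chain (bicor -> soft threshold -> TOM -> detect) and
## return the adjusted Rand index against the planted truth.
module_recovery_ari <- function(seed) {
  cp <- recovery_compendium(seed)
  vals <- cp$values
  r <- bicor(vals)
  power <- suppressWarnings(pick_soft_threshold(r, candidates = 1:12)$power)
  td <- tom(signed_adjacency_for_tests(r, power))$dissimilarity
  ma <- detect_modules(td, min_size = 100, merge_cut = 0.25, values = vals)
  mclust::adjustedRandIndex(ma$labels, planted_truth(cp))
}

## The signed adjacency map is internal; reproduce it here so test code can
## build adjacencies without reaching into the namespace.
signed_adjacency_for_tests <- function(cor_mat, power) {
  ((1 + cor_mat) / 2)^power
}

## ---- independent oracles ---------------------------------------------------

## Triple-loop topological overlap (independent of the matrix-product code).
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

## Step-up BH from the definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

## Moderated t recomputed literally from the posterior-variance formula.
moderated_t_brute <- function(values, groups, d0, s0sq) {
  g1 <- groups == levels(factor(groups))[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(values[, g1, drop = FALSE])
  m2 <- rowMeans(values[, !g1, drop = FALSE])
  s2 <- (rowSums((values[, g1, drop = FALSE] - m1)^2) +
           rowSums((values[, !g1, drop = FALSE] - m2)^2)) / (n1 + n2 - 2)
  s2post <- if (is.finite(d0)) (d0 * s0sq + (n1 + n2 - 2) * s2) / (d0 + n1 + n2 - 2)
            else rep(s0sq, length(s2))
  (m1 - m2) / sqrt(s2post * (1 / n1 + 1 / n2))
}

## Running-sum GSEA enrichment score from the definition.
gsea_es_brute <- function(ranking, set) {
  ord <- order(-ranking, names(ranking))
  r <- ranking[ord]
  hit <- names(r) %in% set
  w <- abs(r) * hit
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / sum(!hit)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

## Hypergeometric upper tail by direct pmf summation.
hyper_brute <- function(a, m, G, n) {
  ks <- a:min(m, n)
  sum(choose(m, ks) * choose(G - m, n - ks)) / choose(G, n)
}
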