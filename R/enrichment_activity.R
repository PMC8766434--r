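## Preranked gene-set enrichment (weighted-KS ES with gene-label
## permutations), hypergeometric over-representation, and a single-sample
## rank-sum activity score, plus GMT readers/writers.

#' Read a GMT gene-set collection
#'
#' @param path tab-delimited GMT file: set name, description, gene ids.
#' @return Named list of character vectors (unique ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  if (any(lengths(sets) == 0)) stop_ibctx("GMT contains an empty set")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted-KS enrichment score (hit weights |score|) of each set in the
#' ranking, normalized against gene-label permutations: NES is the ES
#' divided by the mean |ES| of same-sign permutations, and the permutation
#' p-value (with a +1 pseudocount) counts same-sign permutations with
#' |ES| at least as large. BH adjustment is applied across sets.
#'
#' @param ranking named numeric vector (gene -> score).
#' @param sets named list of gene sets.
#' @param n_perm number of gene-label permutations (default 1000).
#' @param min_overlap minimum set-universe overlap (default 5).
#' @param seed integer seed.
#' @return A data.frame of class `enrichment_result` with `set`, `size`,
#'   `es`, `nes`, `p`, `p_adjusted`, `leading_edge`.
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000, min_overlap = 5,
                           seed = NULL) {
  genes <- names(ranking)
  with_seed_or_not(seed, {
    rows <- lapply(names(sets), function(nm) {
      set <- intersect(sets[[nm]], genes)
      if (length(set) == 0) stop_ibctx(sprintf("set '%s' is disjoint from the universe", nm))
      if (length(set) < min_overlap) return(NULL)
      obs <- weighted_ks_es(ranking, set, return_lead = TRUE)
      perm <- vapply(seq_len(n_perm), function(i) {
        weighted_ks_es(ranking, sample(genes, length(set)))
      }, numeric(1))
      same <- perm[sign(perm) == sign(obs$es)]
      nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      data.frame(set = nm, size = length(set), es = obs$es, nes = nes,
                 p = p, leading_edge = obs$leading_edge)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop_ibctx("no set meets the minimum overlap")
    out$p_adjusted <- bh_adjust(out$p)
    class(out) <- c("enrichment_result", "data.frame")
    out
  })
}

#' Hypergeometric over-representation analysis
#'
#' Tests whether `hits` are over-represented in `module_genes` within
#' `universe`. The p-value is the hypergeometric upper tail P(X >= a); the
#' odds ratio uses the 2x2 table with a Haldane 0.5 correction when any
#' cell is zero.
#'
#' @param hits,module_genes,universe character vectors of gene ids
#'   (`hits` and `module_genes` must be subsets of `universe`).
#' @return A list with `overlap`, `odds_ratio`, `p` and the 2x2 `table`.
#' @export
ora_hypergeometric <- function(hits, module_genes, universe) {
  if (!length(universe)) stop_ibctx("empty universe")
  universe <- unique(universe)
  hits <- unique(intersect(hits, universe))
  module_genes <- unique(intersect(module_genes, universe))
  G <- length(universe)
  m <- length(module_genes)
  n <- length(hits)
  a <- length(intersect(hits, module_genes))
  b <- n - a
  cc <- m - a
  d <- G - m - n + a
  p <- phyper(a - 1, m, G - m, n, lower.tail = FALSE)
  or <- if (m == 0 || m == G || n == 0 || n == G) {
    1  # degenerate margins: no enrichment is defined
  } else if (a == 0 || b == 0 || cc == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  list(overlap = a, odds_ratio = or, p = p,
       table = matrix(c(a, cc, b, d), 2, 2,
                      dimnames = list(in_module = c("yes", "no"),
                                      hit = c("yes", "no"))))
}

#' Single-sample gene-set activity score
#'
#' Rank-sum z per sample: with G genes, set size |S| and per-sample gene
#' ranks, the score is
#' `(mean rank of set genes - (G + 1) / 2) / sqrt((G + 1) (G - |S|) / (12 |S|))`.
#' Higher scores mean coordinated high expression of the set; the score is
#' invariant under strictly increasing per-sample transforms and has an
#' approximately standard normal null for iid genes.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_set character vector of gene ids (>= 5 present in the
#'   matrix).
#' @return Named numeric vector of per-sample activity scores.
#' @export
activity_score <- function(values, gene_set) {
  assert_matrix(values)
  set <- intersect(gene_set, rownames(values))
  if (length(set) < 5) stop_ibctx("fewer than 5 set genes present in the matrix")
  G <- nrow(values)
  s <- length(set)
  ranks <- apply(values, 2, rank)
  mean_rank <- colMeans(ranks[set, , drop = FALSE])
  z <- (mean_rank - (G + 1) / 2) / sqrt((G + 1) * (G - s) / (12 * s))
  setNames(as.numeric(z), colnames(values))
}
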