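## Signed weighted co-expression network analysis: biweight midcorrelation,
## soft-threshold selection for scale-free topology, topological overlap,
## module detection (branch pruning + medoid refinement), module eigengenes
## and gene-module-membership scores, and permutation-based module
## preservation.

#' Biweight midcorrelation matrix
#'
#' Robust correlation between all pairs of genes. For each gene,
#' `u_i = (x_i - median) / (9 * MAD)` (MAD unscaled), Tukey biweights
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (0 otherwise), and the correlation
#' is the weighted cross-product normalized to \[-1, 1\]. Genes with zero
#' MAD fall back to Pearson standardization (the number of such genes is
#' reported via a message).
#'
#' @param values numeric matrix, genes x samples (>= 4 samples).
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
bicor <- function(values) {
  assert_matrix(values)
  if (ncol(values) < 4) stop_ibctx("bicor needs at least 4 samples")
  med <- apply(values, 1, median)
  xc <- values - med
  madv <- apply(abs(xc), 1, median)
  zero <- madv <= 0
  xs <- matrix(0, nrow(values), ncol(values))
  if (any(!zero)) {
    u <- xc[!zero, , drop = FALSE] / (9 * madv[!zero])
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xs[!zero, ] <- xc[!zero, , drop = FALSE] * w
  }
  if (any(zero)) {
    message(sprintf("bicor: %d gene(s) with zero MAD fell back to Pearson",
                    sum(zero)))
    xm <- values - rowMeans(values)
    xs[zero, ] <- xm[zero, , drop = FALSE]
  }
  nrm <- sqrt(rowSums(xs^2))
  nrm[nrm == 0] <- 1  # constant genes: correlation 0 by convention
  xs <- xs / nrm
  r <- tcrossprod(xs)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(values), rownames(values))
  r
}

## Signed adjacency from a correlation matrix.
signed_adjacency <- function(cor_mat, power) {
  ((1 + cor_mat) / 2)^power
}

scale_free_fit <- function(k, n_bins = 10) {
  if (sd(k) == 0) return(list(r_squared = NA_real_, slope = NA_real_,
                              degenerate = TRUE))
  breaks <- unique(quantile(k, seq(0, 1, length.out = n_bins + 1), type = 7))
  if (length(breaks) < 3) return(list(r_squared = NA_real_, slope = NA_real_,
                                      degenerate = TRUE))
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  widths <- diff(breaks)
  dens <- counts / sum(counts) / widths
  mid <- vapply(split(k, bin), mean, numeric(1))
  ok <- counts > 0 & dens > 0 & mid > 0
  if (sum(ok) < 3) return(list(r_squared = NA_real_, slope = NA_real_,
                               degenerate = TRUE))
  fit <- lm(log10(dens[ok]) ~ log10(mid[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(r_squared = if (!is.na(slope) && slope < 0) r2 else -r2,
       slope = slope, degenerate = FALSE)
}

#' Choose the soft-threshold power for a signed network
#'
#' For each candidate power, builds the signed adjacency
#' `a_ij = ((1 + cor_ij) / 2)^beta`, computes node connectivities, bins them
#' into 10 equal-count bins, and regresses log10 frequency density on log10
#' connectivity. The smallest power whose (sign-adjusted) R-squared reaches
#' the threshold is selected; if none qualifies, the power maximizing
#' R-squared is returned with a warning.
#'
#' @param cor_mat gene x gene correlation matrix.
#' @param candidates candidate integer powers.
#' @param rsq_threshold scale-free fit threshold (default 0.8).
#' @return A list of class `network_params` with `power`, `candidates`,
#'   `rsq_threshold`, `signed = TRUE` and the per-power `fit` table.
#' @export
pick_soft_threshold <- function(cor_mat, candidates = 1:20,
                                rsq_threshold = 0.8) {
  fits <- lapply(candidates, function(beta) {
    a <- signed_adjacency(cor_mat, beta)
    k <- rowSums(a) - 1
    if (all(k == 0)) stop_ibctx("all-zero adjacency")
    scale_free_fit(k)
  })
  tab <- data.frame(
    power = candidates,
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate")
  )
  ok <- which(!is.na(tab$r_squared) & tab$r_squared >= rsq_threshold)
  if (length(ok)) {
    power <- candidates[min(ok)]
  } else {
    if (all(is.na(tab$r_squared))) {
      warning("scale-free fit degenerate for every candidate power; using smallest candidate")
      power <- candidates[1]
    } else {
      warning("no candidate power reaches the scale-free fit threshold; using the best fit")
      power <- candidates[which.max(tab$r_squared)]
    }
  }
  structure(list(power = power, candidates = candidates,
                 rsq_threshold = rsq_threshold, signed = TRUE, fit = tab),
            class = "network_params")
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and `k` the connectivity (row sum minus diagonal);
#' the diagonal is 1 and the dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\] and unit
#'   diagonal.
#' @return A list with `tom` and `dissimilarity` matrices.
#' @export
tom <- function(adjacency) {
  assert_matrix(adjacency)
  if (max(abs(adjacency - t(adjacency))) > 1e-10) {
    stop_ibctx("adjacency must be symmetric (tolerance 1e-10)")
  }
  if (min(adjacency) < 0 || max(adjacency) > 1 + 1e-12) {
    stop_ibctx("adjacency entries must lie in [0, 1]")
  }
  a <- adjacency
  diag(a) <- 1
  k <- rowSums(a) - 1
  num <- tcrossprod(a)  # (A^2)_ij includes u = i and u = j terms (each a_ij)
  num <- num - 2 * a    # remove them ...
  num <- num + a        # ... and add back the direct link a_ij
  den <- outer(k, k, pmin) + 1 - a
  t_mat <- num / den
  diag(t_mat) <- 1
  t_mat[t_mat > 1] <- 1
  t_mat[t_mat < 0] <- 0
  dimnames(t_mat) <- dimnames(adjacency)
  list(tom = t_mat, dissimilarity = 1 - t_mat)
}

## Recursively split a dendrogram merge node while both children hold at
## least `min_size` leaves; returns integer branch labels.
branch_cut <- function(tree, min_size) {
  n <- length(tree$order)
  labels <- rep(1L, n)
  next_id <- 1L
  ## leaves under each merge node
  leaves_of <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    l <- tree$merge[i, 1]; r <- tree$merge[i, 2]
    ll <- if (l < 0) -l else leaves_of[[l]]
    rr <- if (r < 0) -r else leaves_of[[r]]
    leaves_of[[i]] <- c(ll, rr)
  }
  assign_branch <- function(node, id) {
    if (node < 0) { labels[-node] <<- id; return(invisible()) }
    l <- tree$merge[node, 1]; r <- tree$merge[node, 2]
    nl <- if (l < 0) 1L else length(leaves_of[[l]])
    nr <- if (r < 0) 1L else length(leaves_of[[r]])
    if (nl >= min_size && nr >= min_size) {
      assign_branch(l, id)
      next_id <<- next_id + 1L
      assign_branch(r, next_id)
    } else {
      for (leaf in leaves_of[[node]]) labels[leaf] <<- id
    }
  }
  assign_branch(nrow(tree$merge), 1L)
  labels
}

#' Detect co-expression modules from a topological-overlap dissimilarity
#'
#' Builds a Ward tree on the dissimilarity and prunes it adaptively: a
#' branch is split as long as both sub-branches hold at least `min_size`
#' genes. The resulting branches are then refined around their centers in
#' the spirit of partitioning around medoids. When expression data are
#' supplied, the module centers are the eigengenes: every gene is
#' reassigned to the module whose eigengene it correlates with most, and
#' genes whose best membership falls below `kme_cut` become unassigned
#' (module 0). Without expression data the centers are the TOM medoids:
#' genes are reassigned to the nearest medoid and genes beyond every
#' module's dissimilarity radius (the maximal member-to-medoid distance of
#' the original branch) become unassigned. Modules dropping below
#' `min_size` are dissolved. Finally, when expression data are supplied,
#' modules whose eigengenes correlate above `1 - merge_cut` are merged
#' iteratively. Modules are numbered by decreasing size.
#'
#' @param dissimilarity square dissimilarity matrix (e.g. `1 - TOM`).
#' @param min_size minimum module size (default 100).
#' @param merge_cut eigengene-correlation merge threshold: modules with
#'   `cor > 1 - merge_cut` merge (default 0.25).
#' @param values optional genes x samples matrix (same genes) used for the
#'   eigengene refinement and merge steps; when `NULL` both are skipped.
#' @param kme_cut minimum gene-module-membership correlation for a gene to
#'   stay in a module during eigengene refinement (default 0.45, calibrated on synthetic compendia).
#' @return A list of class `module_assignment` with `labels` (named integer
#'   vector, 0 = unassigned), `sizes`, and `merge_history`.
#' @export
detect_modules <- function(dissimilarity, min_size = 100, merge_cut = 0.25,
                           values = NULL, kme_cut = 0.45) {
  assert_matrix(dissimilarity, "dissimilarity")
  n <- nrow(dissimilarity)
  if (min_size > n) stop_ibctx("min_size exceeds the number of genes")
  genes <- rownames(dissimilarity) %||% sprintf("g%d", seq_len(n))
  tree <- hclust(as.dist(dissimilarity), method = "ward.D2")
  labels <- branch_cut(tree, min_size)

  names(labels) <- genes
  if (!is.null(values)) {
    ## eigengene (kME) refinement, iterated to a fixed point (bounded):
    ## assign each gene to its best-matching module eigengene, unassigned
    ## below kme_cut
    for (it in 1:3) {
      sz <- table(labels[labels != 0])
      for (m in names(sz)[sz < 2]) labels[labels == as.integer(m)] <- 0L
      if (length(unique(labels[labels != 0])) < 1) break
      gm <- module_eigengene(values, labels)
      best <- apply(gm$gmm, 1, which.max)
      best_val <- gm$gmm[cbind(seq_len(n), best)]
      new_labels <- ifelse(best_val >= kme_cut, gm$modules[best], 0L)
      names(new_labels) <- genes
      if (all(new_labels == labels)) break
      labels <- new_labels
    }
  } else {
    ## medoid refinement on the dissimilarity itself
    ids <- sort(unique(labels))
    medoid <- vapply(ids, function(m) {
      idx <- which(labels == m)
      idx[which.min(colSums(dissimilarity[idx, idx, drop = FALSE]))]
    }, integer(1))
    radius <- vapply(seq_along(ids), function(i) {
      max(dissimilarity[which(labels == ids[i]), medoid[i]])
    }, numeric(1))
    d_med <- dissimilarity[, medoid, drop = FALSE]
    nearest <- apply(d_med, 1, which.min)
    within <- d_med[cbind(seq_len(n), nearest)] <= radius[nearest]
    labels <- ifelse(within, ids[nearest], 0L)
  }

  ## dissolve undersized modules
  sz <- table(labels[labels != 0])
  for (m in names(sz)[sz < min_size]) labels[labels == as.integer(m)] <- 0L

  ## renumber by decreasing size
  sz <- sort(table(labels[labels != 0]), decreasing = TRUE)
  relabel <- setNames(seq_along(sz), names(sz))
  labels <- ifelse(labels == 0, 0L, relabel[as.character(labels)])
  names(labels) <- genes

  ## eigengene-based merging
  merge_history <- list()
  if (!is.null(values) && length(unique(labels[labels != 0])) > 1) {
    repeat {
      gm <- module_eigengene(values, labels)
      eg <- gm$eigengenes
      if (ncol(eg) < 2) break
      cc <- cor(eg)
      diag(cc) <- -Inf
      mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[mx[1], mx[2]] <= 1 - merge_cut) break
      from <- as.integer(sub("^M", "", colnames(eg)[max(mx)]))
      to <- as.integer(sub("^M", "", colnames(eg)[min(mx)]))
      labels[labels == from] <- to
      merge_history[[length(merge_history) + 1L]] <- c(from = from, to = to)
      ## renumber compactly by decreasing size
      sz <- sort(table(labels[labels != 0]), decreasing = TRUE)
      relabel <- setNames(seq_along(sz), names(sz))
      labels <- setNames(ifelse(labels == 0, 0L,
                                relabel[as.character(labels)]), genes)
    }
  }

  sizes <- table(factor(labels, levels = 0:max(labels)))
  structure(list(labels = labels, sizes = sizes,
                 merge_history = merge_history, min_size = min_size,
                 merge_cut = merge_cut),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  nm <- sum(names(x$sizes) != "0")
  cat(sprintf("module_assignment: %d modules (sizes %s), %d unassigned\n",
              nm, paste(x$sizes[names(x$sizes) != "0"], collapse = ", "),
              x$sizes["0"]))
  invisible(x)
}

#' Module eigengenes and gene-module-membership scores
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix (unit norm, oriented so that the mean
#' correlation of member genes with the eigengene is non-negative). The GMM
#' score of gene g for module m is the Pearson correlation between the
#' gene's profile and the module eigengene, computed for all genes.
#'
#' @param values numeric matrix, genes x samples.
#' @param assignment a `module_assignment` or a named integer vector of
#'   labels (0 = unassigned).
#' @return A list of class `gmm_matrix` with `eigengenes` (samples x
#'   modules) and `gmm` (genes x modules).
#' @export
module_eigengene <- function(values, assignment) {
  assert_matrix(values)
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels
            else assignment
  if (is.null(names(labels))) names(labels) <- rownames(values)
  mods <- sort(unique(labels[labels != 0]))
  if (!length(mods)) stop_ibctx("no modules in assignment")
  eigengenes <- matrix(NA_real_, ncol(values), length(mods),
                       dimnames = list(colnames(values),
                                       paste0("M", mods)))
  for (j in seq_along(mods)) {
    genes <- names(labels)[labels == mods[j]]
    sub <- values[genes, , drop = FALSE]
    sds <- row_sds(sub)
    if (all(sds == 0)) stop_ibctx(sprintf("module %d contains only constant genes", mods[j]))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2) stop_ibctx(sprintf("module %d has fewer than 2 informative genes", mods[j]))
    z <- (sub - rowMeans(sub)) / row_sds(sub)
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (mean(cor(t(sub), v)) < 0) v <- -v
    eigengenes[, j] <- v
  }
  gmm <- cor(t(values), eigengenes)
  rownames(gmm) <- rownames(values)
  structure(list(eigengenes = eigengenes, gmm = gmm,
                 modules = mods), class = "gmm_matrix")
}

#' Permutation-based module preservation
#'
#' For each reference module, the density statistic is the mean off-diagonal
#' signed adjacency among module genes in the test data, and the
#' connectivity statistic is the Spearman correlation of intramodular
#' connectivity between reference and test data. Each is converted to a Z
#' score against a permutation null built from random same-size gene sets in
#' the test data; `Zsummary` is the mean of the two Z scores, with the
#' standard interpretation bands (< 2 poor, 2-10 moderate, > 10 good).
#'
#' @param reference_assignment a `module_assignment` (or label vector) on
#'   the reference data genes.
#' @param reference_values,test_values genes x samples matrices; modules
#'   whose genes are missing from the test data are skipped (with a
#'   warning listing them).
#' @param power soft-threshold power for the signed adjacency.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return A data.frame of class `preservation_report` with per-module
#'   `size`, `Zdensity`, `Zconnectivity`, `Zsummary` and `band`.
#' @export
module_preservation <- function(reference_assignment, reference_values,
                                test_values, power = 6, n_perm = 200,
                                seed = NULL) {
  labels <- if (inherits(reference_assignment, "module_assignment"))
    reference_assignment$labels else reference_assignment
  if (is.null(names(labels))) names(labels) <- rownames(reference_values)
  mods <- sort(unique(labels[labels != 0]))
  adj_ref <- signed_adjacency(bicor(reference_values), power)
  adj_test <- signed_adjacency(bicor(test_values), power)
  test_genes <- rownames(test_values)

  with_seed_or_not(seed, {
    rows <- list()
    for (m in mods) {
      genes <- names(labels)[labels == m]
      missing <- setdiff(genes, test_genes)
      if (length(missing)) {
        warning(sprintf("module %d: %d gene(s) missing from test data; module skipped",
                        m, length(missing)))
        next
      }
      size <- length(genes)
      obs_density <- mean_offdiag(adj_test[genes, genes])
      k_ref <- rowSums(adj_ref[genes, genes]) - 1
      k_test <- rowSums(adj_test[genes, genes]) - 1
      obs_conn <- cor(k_ref, k_test, method = "spearman")

      perm_density <- numeric(n_perm)
      perm_conn <- numeric(n_perm)
      for (i in seq_len(n_perm)) {
        rnd <- sample(test_genes, size)
        perm_density[i] <- mean_offdiag(adj_test[rnd, rnd])
        k_t <- rowSums(adj_test[rnd, rnd]) - 1
        perm_conn[i] <- cor(k_ref, k_t, method = "spearman")
      }
      zd <- (obs_density - mean(perm_density)) / sd(perm_density)
      zc <- (obs_conn - mean(perm_conn)) / sd(perm_conn)
      zs <- mean(c(zd, zc))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, size = size, density = obs_density,
        connectivity = obs_conn, Zdensity = zd, Zconnectivity = zc,
        Zsummary = zs,
        band = if (zs < 2) "poor" else if (zs <= 10) "moderate" else "good")
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    attr(out, "n_perm") <- n_perm
    attr(out, "power") <- power
    class(out) <- c("preservation_report", "data.frame")
    out
  })
}

mean_offdiag <- function(m) {
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  (sum(m) - sum(diag(m))) / (n * (n - 1))
}
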