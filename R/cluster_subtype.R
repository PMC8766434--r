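## Unsupervised clustering of expression profiles (Manhattan distance, Ward
## linkage) with validity-index voting over a k range, plus association of
## the resulting clusters with categorical annotations and multinomial
## model comparison of candidate predictors.

#' Hierarchical clustering of samples on the most variable genes
#'
#' Selects the `top_n_genes` most variable genes by standard deviation (on
#' the input scale), centers and scales each gene to unit variance, and
#' clusters samples with Manhattan distance and Ward linkage. Genes that are
#' constant after selection are dropped with a warning.
#'
#' @param values numeric matrix, genes x samples, log2 scale.
#' @param top_n_genes number of genes to retain (all genes when `top_n_genes
#'   >= nrow(values)`).
#' @return A list of class `uhca` with `tree` (an [stats::hclust] object),
#'   `dist` (the sample dissimilarity), and `scaled` (samples x genes matrix
#'   used for clustering).
#' @export
hierarchical_cluster <- function(values, top_n_genes = 500) {
  assert_matrix(values)
  if (ncol(values) < 3) stop_ibctx("need at least 3 samples")
  sds <- row_sds(values)
  top <- head(order(-sds, rownames(values) %||% seq_len(nrow(values))),
              min(top_n_genes, nrow(values)))
  sub <- values[sort(top), , drop = FALSE]
  sds_sub <- row_sds(sub)
  if (any(sds_sub == 0)) {
    warning(sprintf("dropping %d constant gene(s) after selection",
                    sum(sds_sub == 0)))
    sub <- sub[sds_sub > 0, , drop = FALSE]
  }
  scaled <- scale(t(sub))  # samples x genes, per-gene centered/scaled
  d <- dist(scaled, method = "manhattan")
  tree <- hclust(d, method = "ward.D2")
  structure(list(tree = tree, dist = d, scaled = scaled), class = "uhca")
}

## ---- internal cluster validity indices -------------------------------------
## All take (labels, d = dist object, x = samples x features matrix) and
## return a scalar; `larger` in the panel below says which direction wins.

index_silhouette <- function(labels, d, x) {
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

index_calinski_harabasz <- function(labels, d, x) {
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    cen <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, cen)^2)
    b <- b + nrow(xi) * sum((cen - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

index_dunn <- function(labels, d, x) {
  dm <- as.matrix(d)
  ks <- unique(labels)
  diam <- max(vapply(ks, function(g) {
    idx <- labels == g
    if (sum(idx) < 2) 0 else max(dm[idx, idx])
  }, numeric(1)))
  if (diam == 0) return(NA_real_)
  sep <- min(vapply(seq_along(ks), function(i) {
    min(vapply(seq_along(ks), function(j) {
      if (j <= i) Inf else min(dm[labels == ks[i], labels == ks[j]])
    }, numeric(1)))
  }, numeric(1)))
  sep / diam
}

index_davies_bouldin <- function(labels, d, x) {
  ks <- sort(unique(labels))
  cens <- t(vapply(ks, function(g) colMeans(x[labels == g, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cens[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_along(ks), function(i) {
    r <- vapply(seq_along(ks), function(j) {
      if (i == j) return(-Inf)
      m <- sqrt(sum((cens[i, ] - cens[j, ])^2))
      if (m == 0) Inf else (s[i] + s[j]) / m
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(db)
}

index_c <- function(labels, d, x) {
  dv <- as.numeric(d)
  same <- as.numeric(dist(matrix(as.numeric(factor(labels)))) == 0)
  nw <- sum(same)
  if (nw == 0 || nw == length(dv)) return(NA_real_)
  sw <- sum(dv[same == 1])
  srt <- sort(dv)
  smin <- sum(srt[seq_len(nw)])
  smax <- sum(srt[seq(length(srt) - nw + 1, length(srt))])
  if (smax == smin) return(NA_real_)
  (sw - smin) / (smax - smin)
}

index_point_biserial <- function(labels, d, x) {
  dv <- as.numeric(d)
  diffc <- as.numeric(dist(matrix(as.numeric(factor(labels)))) != 0)
  if (length(unique(diffc)) < 2) return(NA_real_)
  cor(dv, diffc)
}

index_mcclain_rao <- function(labels, d, x) {
  dv <- as.numeric(d)
  same <- dist(matrix(as.numeric(factor(labels)))) == 0
  nw <- sum(same); nb <- sum(!same)
  if (nw == 0 || nb == 0) return(NA_real_)
  (sum(dv[same]) / nw) / (sum(dv[!same]) / nb)
}

wss_for_k <- function(x, tree, k) {
  labels <- cutree(tree, k)
  sum(vapply(unique(labels), function(g) {
    xi <- x[labels == g, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

#' Select the number of clusters by validity-index voting
#'
#' Cuts the tree at each k in `k_range` and scores every cut with a fixed
#' panel of eight validity indices: silhouette (max), Calinski-Harabasz
#' (max), Dunn (max), Davies-Bouldin (min), C-index (min), point-biserial
#' (max), McClain-Rao (min), and an elbow vote on the within-cluster
#' dispersion curve (max second difference). Each index votes for one k; the
#' modal k wins, ties going to the smallest k. Cuts producing only
#' singletons are excluded from voting.
#'
#' @param uhca result of [hierarchical_cluster()].
#' @param k_range candidate cluster numbers (default 2:10, clipped to
#'   n_samples - 1).
#' @return A list of class `clustering_result` with `k`, `labels`, `votes`
#'   (index -> preferred k), and the per-index score matrix.
#' @export
select_k <- function(uhca, k_range = 2:10) {
  stopifnot(inherits(uhca, "uhca"))
  x <- uhca$scaled
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop_ibctx("k_range must lie within 2..n_samples-1")
  panel <- list(
    silhouette = list(f = index_silhouette, larger = TRUE),
    calinski_harabasz = list(f = index_calinski_harabasz, larger = TRUE),
    dunn = list(f = index_dunn, larger = TRUE),
    davies_bouldin = list(f = index_davies_bouldin, larger = FALSE),
    c_index = list(f = index_c, larger = FALSE),
    point_biserial = list(f = index_point_biserial, larger = TRUE),
    mcclain_rao = list(f = index_mcclain_rao, larger = FALSE)
  )
  cuts <- lapply(k_range, function(k) cutree(uhca$tree, k))
  names(cuts) <- k_range
  valid <- vapply(cuts, function(l) max(table(l)) > 1, logical(1))
  scores <- matrix(NA_real_, nrow = length(panel) + 1, ncol = length(k_range),
                   dimnames = list(c(names(panel), "dispersion_drop"), k_range))
  for (i in seq_along(panel)) {
    for (j in seq_along(k_range)) {
      if (!valid[j]) next
      scores[i, j] <- panel[[i]]$f(cuts[[j]], uhca$dist, x)
    }
  }
  ## elbow on within-dispersion: W over k_range extended by one either side
  k_ext <- c(min(k_range) - 1, k_range, max(k_range) + 1)
  k_ext <- k_ext[k_ext >= 1 & k_ext <= n]
  wss <- setNames(vapply(k_ext, function(k) wss_for_k(x, uhca$tree, k),
                         numeric(1)), k_ext)
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    if (as.character(k - 1) %in% names(wss) && as.character(k + 1) %in% names(wss)) {
      scores["dispersion_drop", j] <-
        wss[as.character(k - 1)] - 2 * wss[as.character(k)] + wss[as.character(k + 1)]
    }
  }
  larger <- c(vapply(panel, `[[`, logical(1), "larger"), dispersion_drop = TRUE)
  votes <- vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    if (all(is.na(s))) return(NA_integer_)
    if (larger[i]) k_range[which.max(s)] else k_range[which.min(s)]
  }, integer(1))
  names(votes) <- rownames(scores)
  tab <- table(factor(votes[!is.na(votes)], levels = k_range))
  k <- as.integer(names(tab)[tab == max(tab)][1])  # ties -> smallest k
  structure(list(k = k, labels = cuts[[as.character(k)]], votes = votes,
                 scores = scores, k_range = k_range),
            class = "clustering_result")
}

#' Test association between cluster labels and a categorical annotation
#'
#' Uses Fisher's exact test when the contingency table has at most
#' `fisher_max_cells` cells (falling back to Monte-Carlo estimation of the
#' exact p when the network algorithm runs out of workspace), and the
#' chi-square test otherwise.
#'
#' @param labels cluster labels.
#' @param annotation categorical annotation, same length.
#' @param fisher_max_cells cell-count bound for the exact test.
#' @param mc_b Monte-Carlo replicates for the fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return A list with `table`, `method`, `statistic` (chi-square only) and
#'   `p`.
#' @export
associate_clusters <- function(labels, annotation, fisher_max_cells = 25,
                               mc_b = 1e5, seed = NULL) {
  if (length(labels) != length(annotation)) {
    stop_ibctx("labels and annotation must have the same length")
  }
  annotation <- droplevels(factor(annotation))
  labels <- droplevels(factor(labels))
  if (nlevels(annotation) < 2) stop_ibctx("annotation has a single level")
  tab <- table(labels, annotation)
  if (length(tab) <= fisher_max_cells) {
    ft <- tryCatch(stats::fisher.test(tab),
                   error = function(e) {
                     with_seed_or_not(seed, stats::fisher.test(
                       tab, simulate.p.value = TRUE, B = mc_b))
                   })
    list(table = tab, method = ft$method, statistic = NA_real_,
         p = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(table = tab, method = ct$method,
         statistic = unname(ct$statistic), p = ct$p.value)
  }
}

fit_multinom <- function(labels, data, rhs) {
  f <- stats::as.formula(paste("labels ~", rhs))
  fit <- nnet::multinom(f, data = data, trace = FALSE, maxit = 500,
                        decay = 1e-8)
  probs <- fit$fitted.values
  separated <- max(probs) > 1 - 1e-8
  ## AIC from the unpenalized likelihood at the converged point
  ll <- as.numeric(logLik(fit))
  k <- length(stats::coef(fit))
  list(fit = fit, logLik = ll, edf = k, AIC = 2 * k - 2 * ll,
       separated = separated)
}

#' Compare categorical predictors of a clustering pattern
#'
#' Fits a multinomial logistic regression of the cluster labels on each
#' candidate predictor (and on any requested multivariate combinations) and
#' reports AIC = 2k - 2logL per model plus likelihood-ratio tests for
#' requested nested pairs. A tiny ridge penalty (1e-8) stabilizes the fit
#' under separation; the reported AIC uses the likelihood at the converged
#' point, and separated fits are flagged.
#'
#' @param labels cluster labels (categorical outcome).
#' @param predictors data.frame of categorical/binary predictors.
#' @param combos optional list of character vectors naming multivariate
#'   models (e.g. `list(c("phenotype", "er_her2"))`).
#' @param lrt_pairs optional list of 2-element character vectors naming
#'   nested model pairs (smaller first) to compare by likelihood-ratio test;
#'   model names are predictor names or `paste(combo, collapse = "+")`.
#' @return A list of class `model_comparison` with `models` (data.frame:
#'   model, AIC, logLik, edf, separated) and `lrt` (data.frame: null, full,
#'   statistic, df, p).
#' @export
compare_predictors <- function(labels, predictors, combos = list(),
                               lrt_pairs = list()) {
  labels <- droplevels(factor(labels))
  predictors <- as.data.frame(predictors)
  for (nm in names(predictors)) {
    f <- droplevels(factor(predictors[[nm]]))
    if (nlevels(f) < 2) stop_ibctx(sprintf("predictor '%s' has an empty or single level", nm))
    predictors[[nm]] <- f
  }
  specs <- c(list(null = "1"),
             setNames(as.list(names(predictors)), names(predictors)),
             setNames(lapply(combos, paste, collapse = " + "),
                      vapply(combos, paste, character(1), collapse = "+")))
  fits <- lapply(specs, function(rhs) fit_multinom(labels, predictors, rhs))
  models <- data.frame(
    model = names(specs),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    edf = vapply(fits, `[[`, numeric(1), "edf"),
    separated = vapply(fits, `[[`, logical(1), "separated"),
    row.names = NULL
  )
  lrt <- NULL
  if (length(lrt_pairs)) {
    lrt <- do.call(rbind, lapply(lrt_pairs, function(pr) {
      f0 <- fits[[pr[1]]]; f1 <- fits[[pr[2]]]
      if (is.null(f0) || is.null(f1)) stop_ibctx("unknown model name in lrt_pairs")
      stat <- max(0, 2 * (f1$logLik - f0$logLik))
      df <- f1$edf - f0$edf
      p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else
        (if (stat == 0) 1 else NA_real_)
      data.frame(null = pr[1], full = pr[2], statistic = stat, df = df, p = p)
    }))
  }
  structure(list(models = models, lrt = lrt), class = "model_comparison")
}
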