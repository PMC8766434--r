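## The 79-gene style IBC transcriptomic classifier: tertile stratification,
## elastic-net logistic regression tuned by repeated cross-validated AUROC
## over an alpha/lambda grid, replicate-median posterior calling, confusion
## statistics, McNemar's paired test, and a generic nearest-centroid caller.

#' Stratify a continuous variable into tertiles
#'
#' Cuts at the 33rd and 66th quantiles (tertiles, type-7 interpolation);
#' boundary ties go to the lower stratum.
#'
#' @param values numeric vector (>= 3 values, not all equal).
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
stratify_tertiles <- function(values) {
  if (length(values) < 3) stop_ibctx("need at least 3 values")
  if (length(unique(values)) == 1) stop_ibctx("all values equal: no strata")
  q <- quantile(values, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  factor(ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

## Stratified assignment of samples to folds; returns integer fold per sample.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Train the elastic-net IBC classifier
#'
#' Splits samples into training and validation sets (stratified, 3/1 by
#' default), centers and scales each signature gene using training data
#' only, and tunes a penalized logistic model over an alpha/lambda grid by
#' repeated stratified k-fold cross-validation, selecting the grid point
#' with maximal mean cross-validated AUROC (ties broken toward larger
#' lambda, then larger alpha). The final model is refit on the full training
#' set and evaluated on the held-out validation set. The penalty is the
#' glmnet elastic net, `lambda * ((1 - alpha)/2 * ||b||^2 + alpha * ||b||_1)`
#' on the standardized predictors.
#'
#' @param values numeric matrix, genes x samples.
#' @param y phenotype per sample; values equal to `positive` are the IBC
#'   class.
#' @param signature_genes character vector of signature gene ids (rows of
#'   `values`).
#' @param positive label of the positive (IBC) class.
#' @param split_ratio fraction of samples in the training set.
#' @param folds,repeats cross-validation folds and repeats.
#' @param alpha_grid,lambda_grid tuning grids.
#' @param seed integer seed controlling the split and fold assignments.
#' @return A list of class `ibc_classifier` with the standardization
#'   parameters, selected `alpha`/`lambda`, coefficients, the CV AUROC
#'   surface, and held-out validation accuracy.
#' @export
train_elastic_net <- function(values, y, signature_genes = rownames(values),
                              positive = "IBC", split_ratio = 3 / 4,
                              folds = 10, repeats = 5,
                              alpha_grid = seq(0, 1, 0.1),
                              lambda_grid = seq(0.001, 0.1, 0.001),
                              seed = 1L) {
  assert_matrix(values)
  missing <- setdiff(signature_genes, rownames(values))
  if (length(missing)) {
    stop_ibctx(sprintf("signature genes missing from matrix: %s",
                       paste(head(missing, 10), collapse = ", ")))
  }
  ybin <- as.integer(y == positive)
  if (length(unique(ybin)) < 2) stop_ibctx("both classes must be present")
  x <- t(values[signature_genes, , drop = FALSE])
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)

  with_seed_or_not(seed, {
    ## stratified 3/1 split
    train_idx <- unlist(lapply(unique(ybin), function(cl) {
      idx <- which(ybin == cl)
      sample(idx, max(1, round(length(idx) * split_ratio)))
    }))
    train_idx <- sort(train_idx)
    val_idx <- setdiff(seq_len(nrow(x)), train_idx)
    if (length(unique(ybin[train_idx])) < 2) {
      stop_ibctx("both classes must be present in the training split")
    }
    center <- colMeans(x[train_idx, , drop = FALSE])
    scl <- apply(x[train_idx, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scl, "/")
    xtr <- xs[train_idx, , drop = FALSE]
    ytr <- ybin[train_idx]

    ## repeated stratified CV; refold (new derived seed) if a fold loses a
    ## class, at most 10 attempts
    cv_auc <- array(0, dim = c(length(alpha_grid), length(lambda_grid)))
    n_eval <- 0L
    for (r in seq_len(repeats)) {
      fold <- NULL
      for (attempt in seq_len(10)) {
        cand <- stratified_folds(ytr, folds)
        ok <- all(vapply(seq_len(folds), function(f) {
          length(unique(ytr[cand != f])) == 2 && sum(cand == f) > 0
        }, logical(1)))
        if (ok) { fold <- cand; break }
      }
      if (is.null(fold)) stop_ibctx("could not build folds containing both classes")
      for (f in seq_len(folds)) {
        itr <- fold != f
        if (all(itr) || length(unique(ytr[!itr])) < 1) next
        for (a in seq_along(alpha_grid)) {
          fit <- glmnet::glmnet(xtr[itr, , drop = FALSE], ytr[itr],
                                family = "binomial", alpha = alpha_grid[a],
                                lambda = lambda_grid, standardize = FALSE)
          pred <- predict(fit, xtr[!itr, , drop = FALSE], s = lambda_grid,
                          type = "link")
          auc_f <- apply(pred, 2, auroc, labels = ytr[!itr])
          auc_f[is.na(auc_f)] <- NA
          cv_auc[a, ] <- cv_auc[a, ] + ifelse(is.na(auc_f), 0, auc_f)
        }
      }
      n_eval <- n_eval + folds
    }
    cv_auc <- cv_auc / n_eval
    dimnames(cv_auc) <- list(alpha = alpha_grid, lambda = lambda_grid)

    ## max mean AUROC; ties -> larger lambda, then larger alpha
    best <- which(cv_auc == max(cv_auc), arr.ind = TRUE)
    best <- best[order(-lambda_grid[best[, 2]], -alpha_grid[best[, 1]]), ,
                 drop = FALSE][1, ]
    alpha_sel <- alpha_grid[best[1]]
    lambda_sel <- lambda_grid[best[2]]

    final <- glmnet::glmnet(xtr, ytr, family = "binomial",
                            alpha = alpha_sel, lambda = lambda_grid,
                            standardize = FALSE)
    beta <- as.numeric(coef(final, s = lambda_sel))
    names(beta) <- c("(Intercept)", colnames(x))

    val_acc <- NA_real_
    if (length(val_idx)) {
      post <- plogis(beta[1] + xs[val_idx, , drop = FALSE] %*% beta[-1])
      val_acc <- mean((post >= 0.5) == (ybin[val_idx] == 1))
    }

    structure(list(
      signature_genes = signature_genes, positive = positive,
      center = center, scale = scl,
      alpha = alpha_sel, lambda = lambda_sel,
      intercept = unname(beta[1]), coefficients = beta[-1],
      cv_auc = cv_auc, cv_auc_selected = max(cv_auc),
      folds = folds, repeats = repeats, seed = seed,
      train_samples = rownames(x)[train_idx] %||% train_idx,
      validation_samples = rownames(x)[val_idx] %||% val_idx,
      validation_accuracy = val_acc
    ), class = "ibc_classifier")
  })
}

#' @export
print.ibc_classifier <- function(x, ...) {
  cat(sprintf("ibc_classifier: %d genes, alpha = %.2f, lambda = %.3f, CV AUROC = %.3f, validation accuracy = %.3f\n",
              length(x$signature_genes), x$alpha, x$lambda,
              x$cv_auc_selected, x$validation_accuracy))
  invisible(x)
}

#' Posterior probabilities and replicate-median calls
#'
#' Applies a trained classifier to replicate-level profiles, then calls each
#' model (replicate group) IBC when the median posterior across its
#' replicates is at least 0.5 (ties at exactly 0.5 call IBC).
#'
#' @param model an `ibc_classifier`.
#' @param values numeric matrix, genes x profiles, containing every
#'   signature gene.
#' @param replicate_group group label per profile.
#' @return A list of class `prediction_set` with `posterior` (per profile),
#'   `median_posterior` (per group) and `call` (per group).
#' @export
call_models <- function(model, values, replicate_group) {
  stopifnot(inherits(model, "ibc_classifier"))
  missing <- setdiff(model$signature_genes, rownames(values))
  if (length(missing)) {
    stop_ibctx(sprintf("signature genes missing from matrix: %s",
                       paste(head(missing, 10), collapse = ", ")))
  }
  x <- t(values[model$signature_genes, , drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  post <- as.numeric(plogis(model$intercept + xs %*% model$coefficients))
  names(post) <- colnames(values)
  groups <- unique(as.character(replicate_group))
  med <- vapply(groups, function(g) {
    median(post[replicate_group == g])
  }, numeric(1))
  calls <- ifelse(med >= 0.5, model$positive, paste0("n", model$positive))
  structure(list(posterior = post, median_posterior = med,
                 call = setNames(calls, groups)),
            class = "prediction_set")
}

#' Confusion statistics for binary calls
#'
#' @param calls,truth vectors of binary labels.
#' @param positive label of the positive class.
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` and the 2x2 `table`.
#' @export
confusion_stats <- function(calls, truth, positive = "IBC") {
  if (!length(calls) || length(calls) != length(truth)) {
    stop_ibctx("calls and truth must be non-empty and the same length")
  }
  cp <- calls == positive
  tp <- truth == positive
  TP <- sum(cp & tp); FP <- sum(cp & !tp)
  FN <- sum(!cp & tp); TN <- sum(!cp & !tp)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = safe(TP + TN, TP + TN + FP + FN),
       sensitivity = safe(TP, TP + FN),
       specificity = safe(TN, TN + FP),
       ppv = safe(TP, TP + FP),
       npv = safe(TN, TN + FN),
       table = matrix(c(TP, FN, FP, TN), 2, 2,
                      dimnames = list(call = c("pos", "neg"),
                                      truth = c("pos", "neg"))))
}

#' McNemar's test for paired binary outcomes
#'
#' Chi-square on the discordant counts, `(b - c)^2 / (b + c)` with 1 df and
#' no continuity correction by default. When the discordant total is small
#' (`b + c < 10`, the usual expected-count validity bound) an exact
#' two-sided binomial test is used instead. `b + c = 0` returns p = 1.
#'
#' @param a,b paired binary outcome vectors (logical or 0/1).
#' @param correct apply the continuity correction to the chi-square form.
#' @return A list with `statistic` (NA for the exact form), `b`, `c`, `p`
#'   and `method`.
#' @export
mcnemar_test <- function(a, b, correct = FALSE) {
  if (length(a) != length(b)) stop_ibctx("paired vectors must match in length")
  a <- as.logical(a); b <- as.logical(b)
  nb <- sum(a & !b)
  nc <- sum(!a & b)
  if (nb + nc == 0) {
    return(list(statistic = 0, b = nb, c = nc, p = 1,
                method = "degenerate (no discordant pairs)"))
  }
  if (nb + nc < 10) {
    p <- min(1, 2 * pbinom(min(nb, nc), nb + nc, 0.5))
    return(list(statistic = NA_real_, b = nb, c = nc, p = p,
                method = "exact binomial"))
  }
  num <- if (correct) (abs(nb - nc) - 1)^2 else (nb - nc)^2
  stat <- num / (nb + nc)
  list(statistic = stat, b = nb, c = nc,
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       method = "chi-square")
}

#' Nearest-centroid subtype classification
#'
#' Generic plumbing for centroid-based subtype callers: each sample gets the
#' label of the centroid with maximal correlation (Spearman by default);
#' ties go to the first centroid in column order.
#'
#' @param values numeric matrix, genes x samples.
#' @param centroids numeric matrix, genes x centroids, with gene rownames
#'   and centroid colnames.
#' @param method correlation method.
#' @return Character vector of centroid labels per sample, with the
#'   correlation matrix as attribute `correlations`.
#' @export
classify_nearest_centroid <- function(values, centroids, method = "spearman") {
  common <- intersect(rownames(values), rownames(centroids))
  if (length(common) < 5) {
    stop_ibctx("fewer than 5 genes overlap between matrix and centroids")
  }
  v <- values[common, , drop = FALSE]
  ce <- centroids[common, , drop = FALSE]
  cors <- cor(v, ce, method = method)
  labels <- colnames(ce)[apply(cors, 1, which.max)]
  names(labels) <- colnames(values)
  attr(labels, "correlations") <- cors
  labels
}
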