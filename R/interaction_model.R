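## Nested ER-by-phenotype interaction regression for MYC expression or
## transcriptional activity, blocking-variable sensitivity analysis, and the
## proximal-MYC-network correlation and outlier report.

nested_design <- function(phenotype, er_stratum) {
  phenotype <- factor(phenotype, levels = c("nIBC", "IBC"))
  er_stratum <- factor(er_stratum, levels = c("low", "moderate", "high"))
  if (any(is.na(phenotype)) || any(is.na(er_stratum))) {
    stop_ibctx("phenotype must be IBC/nIBC and ER stratum low/moderate/high")
  }
  cells <- table(phenotype, er_stratum)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop_ibctx(sprintf("empty design cell: %s/%s",
                       rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  cbind(
    `nIBC:ERmod` = as.numeric(phenotype == "nIBC" & er_stratum == "moderate"),
    `nIBC:ERhigh` = as.numeric(phenotype == "nIBC" & er_stratum == "high"),
    `IBC:ERlow` = as.numeric(phenotype == "IBC"),
    `IBC:ERmod` = as.numeric(phenotype == "IBC" & er_stratum == "moderate"),
    `IBC:ERhigh` = as.numeric(phenotype == "IBC" & er_stratum == "high")
  )
}

#' Fit the nested ER-by-phenotype interaction model
#'
#' Least-squares fit of a five-indicator design with reference cell
#' nIBC/ER-low: coefficients for nIBC/ER-moderate and nIBC/ER-high are
#' changes relative to the reference; the IBC/ER-low coefficient is the
#' IBC main effect at low ER; and the IBC/ER-moderate and IBC/ER-high
#' coefficients are increments over IBC/ER-low (so a coefficient of +1.414
#' means IBC ER-high samples lie 1.414 units above IBC ER-low samples).
#' Wald p-values per coefficient.
#'
#' @param response numeric vector (MYC expression or an activity score).
#' @param phenotype vector with values "IBC"/"nIBC".
#' @param er_stratum vector with values "low"/"moderate"/"high" (see
#'   [stratify_tertiles()]); all six phenotype-by-stratum cells must be
#'   populated.
#' @param extra optional additional design columns (used internally for
#'   blocking factors).
#' @return A list of class `nested_fit` with `coefficients` (the five
#'   interaction terms), `se`, `p`, `intercept`, `logLik`, `AIC` and the
#'   underlying `lm` fit.
#' @export
fit_nested_interaction <- function(response, phenotype, er_stratum,
                                   extra = NULL) {
  X <- nested_design(phenotype, er_stratum)
  dat <- data.frame(response = response, X, check.names = FALSE)
  dropped <- character(0)
  if (!is.null(extra)) {
    full <- cbind(1, X, extra)
    qrf <- qr(full)
    if (qrf$rank < ncol(full)) {
      keep_idx <- qrf$pivot[seq_len(qrf$rank)]
      aliased <- setdiff(seq_len(ncol(full)), keep_idx)
      aliased <- aliased[aliased > ncol(X) + 1]
      dropped <- colnames(extra)[aliased - ncol(X) - 1]
      if (length(dropped)) {
        warning(sprintf("aliased blocking column(s) dropped: %s",
                        paste(dropped, collapse = ", ")))
        extra <- extra[, setdiff(colnames(extra), dropped), drop = FALSE]
      }
    }
    if (ncol(extra)) dat <- cbind(dat, as.data.frame(extra))
  }
  fit <- lm(response ~ ., data = dat)
  sm <- summary(fit)$coefficients
  terms5 <- colnames(X)
  ## formula interfaces may backtick-quote or mangle the names; map back
  rn <- gsub("`", "", rownames(sm), fixed = TRUE)
  idx <- match(terms5, rn)
  if (any(is.na(idx))) idx <- match(make.names(terms5), make.names(rn))
  structure(list(
    coefficients = setNames(sm[idx, "Estimate"], terms5),
    se = setNames(sm[idx, "Std. Error"], terms5),
    p = setNames(sm[idx, "Pr(>|t|)"], terms5),
    intercept = unname(coef(fit)[1]),
    logLik = as.numeric(logLik(fit)),
    AIC = stats::AIC(fit),
    dropped_columns = dropped,
    lm = fit
  ), class = "nested_fit")
}

#' @export
print.nested_fit <- function(x, ...) {
  cat("nested ER-by-phenotype interaction fit (reference nIBC/ER-low)\n")
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p))
  invisible(x)
}

#' Nested interaction fit with a blocking variable
#'
#' Adds indicators for a blocking factor (tumor stage or molecular subtype)
#' to the nested design, compares blocked and unblocked models with a
#' likelihood-ratio test, and reports whether each interaction coefficient
#' retains its sign and nominal significance.
#'
#' @param response,phenotype,er_stratum as in [fit_nested_interaction()].
#' @param blocking non-constant factor; levels aliased with the
#'   phenotype-by-stratum cells are dropped with a warning.
#' @param alpha significance level for the retention report.
#' @return A list with `fit` (blocked `nested_fit`), `unblocked_fit`,
#'   `lrt` (statistic, df, p) and `retention` (data.frame per coefficient).
#' @export
fit_with_blocking <- function(response, phenotype, er_stratum, blocking,
                              alpha = 0.05) {
  blocking <- droplevels(factor(blocking))
  if (nlevels(blocking) < 2) stop_ibctx("blocking factor is constant")
  B <- model.matrix(~ blocking)[, -1, drop = FALSE]
  colnames(B) <- paste0("block_", levels(blocking)[-1])
  fit0 <- fit_nested_interaction(response, phenotype, er_stratum)
  fit1 <- fit_nested_interaction(response, phenotype, er_stratum, extra = B)
  n <- length(response)
  rss0 <- sum(stats::residuals(fit0$lm)^2)
  rss1 <- sum(stats::residuals(fit1$lm)^2)
  df <- length(coef(fit1$lm)) - length(coef(fit0$lm))
  stat <- max(0, n * log(rss0 / rss1))
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1
  retention <- data.frame(
    term = names(fit0$coefficients),
    unblocked = fit0$coefficients,
    blocked = fit1$coefficients,
    sign_retained = sign(fit0$coefficients) == sign(fit1$coefficients),
    significant_unblocked = fit0$p < alpha,
    significant_blocked = fit1$p < alpha,
    row.names = NULL
  )
  list(fit = fit1, unblocked_fit = fit0,
       lrt = list(statistic = stat, df = df, p = p),
       retention = retention)
}

#' Proximal-MYC-network correlation report
#'
#' Spearman correlations (with p-values) of each network member against MYC
#' and against each activity score, plus the pairwise member correlation
#' matrix ordered by Ward clustering of `1 - rho`. Constant members yield
#' missing correlations.
#'
#' @param members numeric matrix, member genes x samples.
#' @param myc numeric vector of MYC expression per sample.
#' @param activity optional numeric vector or samples x scores matrix of
#'   activity scores.
#' @return A list of class `pmn_report` with `vs_myc`, `vs_activity`,
#'   `pairwise` (ordered correlation matrix) and `order`.
#' @export
pmn_correlations <- function(members, myc, activity = NULL) {
  if (ncol(members) < 4) stop_ibctx("need at least 4 observations")
  spearman <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  vs_myc <- t(apply(members, 1, spearman, y = myc))
  vs_myc <- data.frame(member = rownames(members), rho = vs_myc[, "rho"],
                       p = vs_myc[, "p"], row.names = NULL)
  vs_activity <- NULL
  if (!is.null(activity)) {
    act <- if (is.matrix(activity)) activity else
      matrix(activity, ncol = 1, dimnames = list(NULL, "activity"))
    vs_activity <- do.call(rbind, lapply(colnames(act), function(a) {
      sm <- t(apply(members, 1, spearman, y = act[, a]))
      data.frame(member = rownames(members), score = a, rho = sm[, "rho"],
                 p = sm[, "p"], row.names = NULL)
    }))
  }
  all_mat <- rbind(MYC = myc, members)
  rho <- suppressWarnings(cor(t(all_mat), method = "spearman"))
  ## constant members leave NA correlations: order the complete submatrix
  keep <- rowSums(is.na(rho)) == 0
  rho_c <- rho[keep, keep, drop = FALSE]
  ord <- if (nrow(rho_c) > 2) {
    hclust(as.dist(1 - rho_c), method = "ward.D2")$order
  } else {
    seq_len(nrow(rho_c))
  }
  structure(list(vs_myc = vs_myc, vs_activity = vs_activity,
                 pairwise = rho_c[ord, ord], order = rownames(rho_c)[ord]),
            class = "pmn_report")
}

#' Flag samples with outlying candidate-gene expression
#'
#' A sample is flagged for a candidate gene when its expression strictly
#' exceeds the empirical `percentile` (default 90th) of that gene across
#' samples. Flags are reported alongside the residuals of the
#' activity-on-MYC regression so that candidate-driven activity (high
#' activity not explained by MYC itself) stands out.
#'
#' @param myc numeric vector of MYC expression.
#' @param activity numeric vector of activity scores (same samples).
#' @param candidates numeric vector or genes x samples matrix of candidate
#'   expression.
#' @param percentile flagging percentile (default 0.90).
#' @return A list with `flags` (samples x candidates logical matrix),
#'   `residuals` (activity ~ MYC), and `cutoffs`.
#' @export
flag_activity_outliers <- function(myc, activity, candidates,
                                   percentile = 0.90) {
  if (is.null(dim(candidates))) {
    candidates <- matrix(candidates, nrow = 1,
                         dimnames = list("candidate", names(candidates)))
  }
  n <- length(myc)
  if (length(activity) != n || ncol(candidates) != n) {
    stop_ibctx("samples must be aligned across inputs")
  }
  if (n < 10) warning("fewer than 10 samples: percentile cutoff is unstable")
  cutoffs <- apply(candidates, 1, quantile, probs = percentile, type = 7)
  flags <- t(candidates > cutoffs)
  res <- stats::residuals(lm(activity ~ myc))
  list(flags = flags, residuals = res, cutoffs = cutoffs)
}
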