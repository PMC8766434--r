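## Moderated two-group differential expression with empirical-Bayes variance
## shrinkage, BH adjustment, and the percentile-based paired comparison of a
## cell line against its source tumor.

## Newton inversion of the trigamma function (for the prior-df estimate).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per gene, fits the two-group linear model, then shrinks the residual
#' variances toward a common prior: the prior degrees of freedom `d0` and
#' prior variance `s0^2` are estimated by closed-form moment matching of the
#' log residual variances (matching the mean and variance of `log s_g^2`
#' under the scaled-F marginal), the posterior variance is
#' `(d0 s0^2 + d s_g^2) / (d0 + d)`, and the moderated t uses `d0 + d`
#' degrees of freedom. When the log-variance spread is no larger than
#' expected under equal true variances, `d0` is infinite and the pooled
#' prior variance is used (ordinary-t limit with pooled prior).
#'
#' @param values numeric matrix, genes x samples, log2 scale.
#' @param groups two-level factor (or coercible); the log2 fold change is
#'   `mean(level 1) - mean(level 2)` (e.g. IBC - nIBC with the default
#'   level order).
#' @return A data.frame of class `moderated_test_result` with `lfc`,
#'   `t_ordinary`, `t_moderated`, `p`, `p_adjusted`, plus attributes `d0`
#'   and `s0sq`.
#' @export
moderated_t_test <- function(values, groups) {
  assert_matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_ibctx("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stop_ibctx("both groups need >= 2 samples")
  d <- n1 + n2 - 2
  if (d == 0) stop_ibctx("zero residual degrees of freedom")
  x1 <- values[, groups == levels(groups)[1], drop = FALSE]
  x2 <- values[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / d
  lfc <- m1 - m2
  sef <- sqrt(1 / n1 + 1 / n2)

  ## moment matching on z = log(s2): under s2 ~ s0^2 * F(d, d0),
  ## var(z) = trigamma(d/2) + trigamma(d0/2)
  ## mean(z) = log(s0^2) + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
  z <- log(pmax(s2, 1e-300))
  excess <- var(z) - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    s2post <- rep(s0sq, length(s2))
    df_total <- Inf
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s0sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }

  t_ord <- lfc / (sqrt(s2) * sef)
  t_mod <- lfc / (sqrt(s2post) * sef)
  p <- if (is.finite(df_total)) 2 * pt(abs(t_mod), df_total, lower.tail = FALSE)
       else 2 * pnorm(abs(t_mod), lower.tail = FALSE)
  out <- data.frame(lfc = lfc, t_ordinary = t_ord, t_moderated = t_mod,
                    p = p, p_adjusted = bh_adjust(p),
                    row.names = rownames(values))
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "df_residual") <- d
  class(out) <- c("moderated_test_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1 and monotone in p-rank.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_ibctx("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Percentile-based paired differential expression
#'
#' Computes gene-wise differences `profile_a - profile_b` (e.g. tumor minus
#' cell line) over the genes in `expressed_mask`, cuts the empirical
#' distribution of differences at the `upper` and `lower` percentiles
#' (type-7), and reports the genes strictly above the upper cut
#' (overexpressed in `profile_a`) and strictly below the lower cut
#' (overexpressed in `profile_b`).
#'
#' @param profile_a,profile_b named numeric vectors on the same gene
#'   universe.
#' @param upper,lower percentile cuts (defaults 0.975 and 0.025).
#' @param expressed_mask logical vector (or character vector of gene ids)
#'   restricting the comparison to genes expressed above background in both
#'   samples; defaults to all genes.
#' @return A list of class `paired_percentile_result` with `differences`,
#'   `upper_cut`, `lower_cut`, `a_high` and `b_high` gene sets.
#' @export
percentile_de <- function(profile_a, profile_b, upper = 0.975, lower = 0.025,
                          expressed_mask = NULL) {
  if (length(profile_a) != length(profile_b)) {
    stop_ibctx("profiles must share a gene universe")
  }
  genes <- names(profile_a) %||% as.character(seq_along(profile_a))
  if (is.null(expressed_mask)) {
    mask <- rep(TRUE, length(profile_a))
  } else if (is.character(expressed_mask)) {
    mask <- genes %in% expressed_mask
  } else {
    mask <- as.logical(expressed_mask)
  }
  if (!any(mask)) stop_ibctx("expressed mask is empty")
  d <- (profile_a - profile_b)[mask]
  names(d) <- genes[mask]
  up_cut <- quantile(d, upper, type = 7, names = FALSE)
  lo_cut <- quantile(d, lower, type = 7, names = FALSE)
  structure(list(differences = d, upper_cut = up_cut, lower_cut = lo_cut,
                 a_high = names(d)[d > up_cut],
                 b_high = names(d)[d < lo_cut]),
            class = "paired_percentile_result")
}
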