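#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx aov as.dist complete.cases coef cor cov cutree dist
#'   hclust lm logLik mad median model.matrix na.omit p.adjust pbinom pchisq
#'   phyper plogis pnorm prcomp predict pt qnorm quantile rbinom rnorm runif
#'   sd setNames var
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Row standard deviations without extra dependencies (used on large matrices
## where apply(x, 1, sd) would dominate runtime).
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

## Deterministic substream seeds: one user-facing seed, fixed per-generator
## stream ids (compendium = 1, catalog = 2, cohort = 3, ...). Adding a new
## stream id never perturbs existing streams.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) + 1000003 * stream) %% 2147483647L)
}

## Run `expr` under a local RNG state when `seed` is given; leave the global
## stream untouched either way.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

## Rank-based AUROC (Mann-Whitney form). `labels` logical/0-1, TRUE = positive.
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stop_ibctx <- function(...) stop(..., call. = FALSE)

assert_matrix <- function(x, what = "values") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_ibctx(sprintf("`%s` must be a numeric matrix", what))
  }
  if (any(!is.finite(x))) {
    stop_ibctx(sprintf("`%s` contains non-finite entries", what))
  }
  invisible(x)
}
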