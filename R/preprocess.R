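## Multi-batch expression merging: filter -> batch-correct -> quantile
## normalize -> collapse probes -> average replicates. Inputs are assumed to
## be log2-summarized already (per-dataset background correction and
## summarization are upstream of this package and out of scope). Missing
## values are rejected, not imputed.

#' Filter rows expressed above background
#'
#' Retains genes (rows) whose expression exceeds `threshold` in at least
#' `min_samples` samples. The default threshold, log2(100), is the usual
#' fluorescence-intensity floor for log2 microarray data.
#'
#' @param values numeric matrix, genes x samples, log2 scale.
#' @param threshold log2-intensity cutoff (strict inequality).
#' @param min_samples minimum number of samples above the cutoff.
#' @return The filtered matrix, row order preserved.
#' @export
filter_expressed <- function(values, threshold = log2(100), min_samples = 2) {
  assert_matrix(values)
  if (!is.finite(threshold) && threshold != -Inf) {
    stop_ibctx("threshold must be finite or -Inf")
  }
  if (min_samples < 1) stop_ibctx("min_samples must be >= 1")
  if (min_samples > ncol(values)) {
    stop_ibctx("min_samples exceeds the number of samples")
  }
  keep <- rowSums(values > threshold) >= min_samples
  values[keep, , drop = FALSE]
}

#' Empirical-Bayes batch correction
#'
#' Location/scale batch adjustment in the ComBat family. Per gene, protected
#' covariate effects and per-batch location effects are fitted jointly by
#' least squares; the batch location deviations (relative to their
#' sample-weighted mean) are removed exactly, so a constant cross-batch
#' shift vanishes to numerical precision and protected effects are
#' untouched. The per-batch residual variances are then shrunk toward an
#' across-gene inverse-gamma prior (moment-matched, the parametric
#' empirical-Bayes form) and the residuals rescaled. Location effects are
#' well determined at typical batch sizes, while scale estimates are the
#' ones that benefit from pooling across genes - hence shrinkage is applied
#' to scales only. A single batch returns the matrix unchanged; a batch
#' perfectly confounded with a protected covariate is an error naming the
#' confounded pair.
#'
#' @param values numeric matrix, genes x samples.
#' @param batch batch label per sample (>= 2 levels for any adjustment).
#' @param covariates optional data.frame of protected covariates (e.g. the
#'   replicate group / cell line of each sample).
#' @return Adjusted matrix, same dimensions.
#' @export
correct_batch <- function(values, batch, covariates = NULL) {
  assert_matrix(values)
  batch <- droplevels(factor(batch))
  if (length(batch) != ncol(values)) {
    stop_ibctx("`batch` must have one label per sample")
  }
  if (nlevels(batch) < 2) {
    message("single batch: matrix returned unchanged")
    return(values)
  }
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.factor(v) || is.logical(v)) {
        f <- droplevels(factor(v))
        ## aliasing check: if every covariate level sits inside a single
        ## batch, the batch indicators are linear combinations of the
        ## covariate indicators and the batch effect is unidentifiable
        if (nlevels(f) > 1) {
          joint <- table(f, batch)
          if (all(rowSums(joint > 0) == 1)) {
            stop_ibctx(sprintf(
              "batch is perfectly confounded with protected covariate '%s'", nm))
          }
        }
      }
    }
    mod <- model.matrix(~ ., data = covariates)
    full <- cbind(mod, model.matrix(~ 0 + batch))
    if (qr(full)$rank < (ncol(mod) + nlevels(batch) - 1)) {
      stop_ibctx(sprintf(
        "design of protected covariates (%s) plus batch indicators is rank deficient; a covariate is confounded with batch",
        paste(names(covariates), collapse = ", ")))
    }
  }
  if (is.null(mod)) mod <- matrix(1, ncol(values), 1,
                                  dimnames = list(NULL, "(Intercept)"))
  nb <- table(batch)
  n <- ncol(values)
  design <- cbind(mod, model.matrix(~ batch)[, -1, drop = FALSE])
  n_cov <- ncol(mod)
  qrd <- qr(design)
  coefs <- t(qr.coef(qrd, t(values)))           # genes x coefficients
  gamma <- cbind(0, coefs[, -(seq_len(n_cov)), drop = FALSE])  # batch 1 ref
  gbar <- as.numeric(gamma %*% (as.numeric(nb) / n))
  gamma_c <- gamma - gbar                        # weighted-centered deviations
  out <- values - gamma_c[, as.integer(batch), drop = FALSE]

  ## EB scale adjustment on the residuals
  resid <- t(qr.resid(qrd, t(values)))
  sigma2 <- rowSums(resid^2) / max(1, n - qrd$rank)
  if (all(nb >= 2) && any(sigma2 > 0)) {
    z <- resid / sqrt(pmax(sigma2, 1e-300))
    for (b in levels(batch)) {
      cols <- which(batch == b)
      d_hat <- rowSums(z[, cols, drop = FALSE]^2) / (length(cols) - 1)
      m <- mean(d_hat); v <- var(d_hat)
      if (!is.finite(v) || v <= 0) next
      a_prior <- (2 * v + m^2) / v              # inverse-gamma moment match
      b_prior <- (m * v + m^3) / v
      d_star <- (b_prior + 0.5 * rowSums(z[, cols, drop = FALSE]^2)) /
        (length(cols) / 2 + a_prior - 1)
      scale_fac <- sqrt(pmax(d_star, 1e-12))
      out[, cols] <- out[, cols] - resid[, cols] +
        resid[, cols] / scale_fac
    }
  } else if (any(nb < 2)) {
    warning("a batch has fewer than 2 samples: scale adjustment skipped")
  }
  dimnames(out) <- dimnames(values)
  out
}

#' Quantile normalization
#'
#' Forces every column to the same empirical distribution (rank-wise column
#' means), averaging over ties. Wraps [limma::normalizeQuantiles()].
#'
#' @param values numeric matrix without missing entries.
#' @return Matrix with identical sorted column values.
#' @export
quantile_normalize <- function(values) {
  assert_matrix(values)
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Collapse probes to genes by maximal standard deviation
#'
#' For each gene, retains the probe with the largest across-sample standard
#' deviation; ties are broken by the lexicographically smallest probe id.
#'
#' @param values numeric matrix with probe ids as rownames.
#' @param probe_map data.frame with columns `probe_id` and `gene_id`
#'   (many-to-one), or a named character vector (names = probes, values =
#'   genes).
#' @return Gene-level matrix (one row per gene, named by gene id), genes in
#'   order of first appearance among the input rows.
#' @export
collapse_probes <- function(values, probe_map) {
  assert_matrix(values)
  if (is.null(rownames(values))) stop_ibctx("`values` must have probe rownames")
  if (is.data.frame(probe_map)) {
    map <- setNames(as.character(probe_map$gene_id), probe_map$probe_id)
  } else {
    map <- probe_map
  }
  missing <- setdiff(rownames(values), names(map))
  if (length(missing)) {
    stop_ibctx(sprintf("unmapped probes: %s",
                       paste(head(missing, 10), collapse = ", ")))
  }
  gene <- map[rownames(values)]
  sds <- row_sds(values)
  ord <- order(match(gene, unique(gene)), -sds, rownames(values))
  keep <- ord[!duplicated(gene[ord])]
  keep <- keep[order(match(gene[keep], unique(gene)))]
  out <- values[keep, , drop = FALSE]
  rownames(out) <- unname(gene[keep])
  out
}

#' Average replicate profiles
#'
#' Arithmetic mean per gene within each replicate group; output columns are
#' ordered by first appearance of each group.
#'
#' @param values numeric matrix, genes x samples.
#' @param replicate_group group label per sample.
#' @return Matrix with one column per group.
#' @export
average_replicates <- function(values, replicate_group) {
  assert_matrix(values)
  replicate_group <- as.character(replicate_group)
  if (length(replicate_group) != ncol(values)) {
    stop_ibctx("`replicate_group` must have one label per sample")
  }
  if (any(is.na(replicate_group) | replicate_group == "")) {
    stop_ibctx("empty replicate group label")
  }
  groups <- unique(replicate_group)
  out <- vapply(groups, function(g) {
    rowMeans(values[, replicate_group == g, drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(values), groups)
  out
}

#' Run the full preprocessing chain on a compendium
#'
#' Applies, in fixed order: expression filtering, empirical-Bayes batch
#' correction (protecting the replicate group), quantile normalization,
#' probe collapsing (when a probe map is given), and replicate averaging.
#'
#' @param compendium an `expression_compendium` (see
#'   [generate_cell_line_compendium()]) or a list with `values` and
#'   `annotation`.
#' @param threshold,min_samples passed to [filter_expressed()].
#' @param probe_map optional probe-to-gene map for [collapse_probes()].
#' @param protect character vector of annotation columns protected during
#'   batch correction (default the replicate group).
#' @return A list with `values` (averaged genes x models matrix),
#'   `replicate_values` (post-normalization, pre-averaging matrix) and
#'   `annotation` (one row per model).
#' @export
preprocess_pipeline <- function(compendium, threshold = log2(100),
                                min_samples = 2, probe_map = NULL,
                                protect = "replicate_group") {
  values <- compendium$values
  ann <- compendium$annotation
  values <- filter_expressed(values, threshold, min_samples)
  covs <- if (length(protect)) ann[, protect, drop = FALSE] else NULL
  values <- correct_batch(values, ann$batch, covs)
  values <- quantile_normalize(values)
  if (!is.null(probe_map)) values <- collapse_probes(values, probe_map)
  averaged <- average_replicates(values, ann$replicate_group)
  model_ann <- ann[!duplicated(ann$replicate_group),
                   setdiff(names(ann), c("sample_id", "batch")), drop = FALSE]
  rownames(model_ann) <- model_ann$replicate_group
  model_ann <- model_ann[colnames(averaged), , drop = FALSE]
  list(values = averaged, replicate_values = values, annotation = model_ann)
}
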