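## Synthetic-data generators. These define the study conditions every other
## module is exercised against: a multi-batch cell-line compendium with
## planted co-expression modules, an L1000-like perturbation catalog with
## planted regulators and drug/target pairs, and an IBC/nIBC patient cohort
## with ER-stratum-dependent MYC effects.

#' Specification for a synthetic cell-line expression compendium
#'
#' Describes a multi-batch, replicated cell-line compendium with planted
#' co-expression modules. Defaults emulate the study design the package
#' targets: 10 IBC and 22 nIBC models profiled in triplicate across five
#' batches, with three 150-gene modules (one IBC-linked, one nIBC-linked, one
#' phenotype-neutral) at a signal-to-noise ratio of 2.
#'
#' Module genes load on a latent per-line factor: loadings are graded
#' (`0.3 + |N(0, 0.7^2)|`, a floored half-normal) and scaled by `effect_sd`,
#' the factor is N(0,1) per cell line with its mean shifted by +1/-1 for
#' phenotype-linked modules. The loading floor guarantees that every planted
#' gene is a genuine module member while loadings (and hence gene-module
#' membership scores) remain graded. Batch distortions
#' are per-gene location shifts (log2 units, i.e. multiplicative on the
#' linear scale) plus per-gene scale factors applied to deviations.
#'
#' @param n_genes total number of genes.
#' @param modules list of module descriptors, each a list with `size`,
#'   `effect_sd` and `phenotype_link` (one of "IBC", "nIBC", "none").
#' @param n_cell_lines_ibc,n_cell_lines_nibc number of cell lines per
#'   phenotype.
#' @param replicates_per_line replicate profiles per cell line.
#' @param n_batches number of batches; replicates are distributed round-robin
#'   so every cell line spans several batches.
#' @param batch_shift_sd,batch_scale_sd SDs of the per-gene batch location
#'   (log2 units) and log-scale distortions.
#' @param phenotype_shift half-distance between the latent-factor means of
#'   the two phenotypes for phenotype-linked modules (the linked phenotype's
#'   factor mean is `+phenotype_shift`, the other `-phenotype_shift`;
#'   factor SD is 1). Default 1.
#' @param noise_sd residual noise SD (log2 units).
#' @param seed integer seed for the compendium substream.
#' @return A list of class `compendium_spec`.
#' @export
compendium_spec <- function(n_genes = 2000,
                            modules = list(
                              list(size = 150, effect_sd = 2, phenotype_link = "IBC"),
                              list(size = 150, effect_sd = 2, phenotype_link = "nIBC"),
                              list(size = 150, effect_sd = 2, phenotype_link = "none")
                            ),
                            n_cell_lines_ibc = 10,
                            n_cell_lines_nibc = 22,
                            replicates_per_line = 3,
                            n_batches = 5,
                            batch_shift_sd = 0.5,
                            batch_scale_sd = 0.1,
                            noise_sd = 1,
                            phenotype_shift = 1,
                            seed = 1L) {
  spec <- list(
    n_genes = n_genes, modules = modules,
    n_cell_lines_ibc = n_cell_lines_ibc, n_cell_lines_nibc = n_cell_lines_nibc,
    replicates_per_line = replicates_per_line, n_batches = n_batches,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    noise_sd = noise_sd, phenotype_shift = phenotype_shift, seed = seed
  )
  counts <- c(n_genes, n_cell_lines_ibc, n_cell_lines_nibc,
              replicates_per_line, n_batches)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_ibctx("all counts in a compendium spec must be integers >= 1")
  }
  if (any(c(batch_shift_sd, batch_scale_sd, noise_sd) < 0)) {
    stop_ibctx("sds must be >= 0")
  }
  sizes <- vapply(modules, function(m) as.numeric(m$size), numeric(1))
  if (sum(sizes) > n_genes) {
    stop_ibctx("sum of module sizes exceeds n_genes")
  }
  links <- vapply(modules, function(m) m$phenotype_link, character(1))
  if (!all(links %in% c("IBC", "nIBC", "none"))) {
    stop_ibctx("phenotype_link must be one of 'IBC', 'nIBC', 'none'")
  }
  structure(spec, class = "compendium_spec")
}

#' Generate a synthetic multi-batch cell-line expression compendium
#'
#' Draws log2-scale expression for `n_genes` genes across
#' `(n_cell_lines_ibc + n_cell_lines_nibc) * replicates_per_line` profiles.
#' Planted module genes share a latent per-line factor (see
#' [compendium_spec()]); batches add per-gene location/scale distortions;
#' iid Gaussian noise is added throughout. The returned object carries the
#' planted truth (module membership, loadings, factors) for benchmarking.
#'
#' @param spec a [compendium_spec()].
#' @return A list of class `expression_compendium` with elements `values`
#'   (genes x samples log2 matrix), `annotation` (data.frame with `sample_id`,
#'   `batch`, `replicate_group`, `phenotype`, `ER`, `PR`, `HER2`, `subtype`),
#'   and `truth` (planted module structure).
#' @export
generate_cell_line_compendium <- function(spec) {
  if (!inherits(spec, "compendium_spec")) spec <- do.call(compendium_spec, spec)
  with_seed_or_not(substream_seed(spec$seed, 1L), {
    n_lines <- spec$n_cell_lines_ibc + spec$n_cell_lines_nibc
    phen_line <- c(rep("IBC", spec$n_cell_lines_ibc),
                   rep("nIBC", spec$n_cell_lines_nibc))
    line_ids <- sprintf("%s_L%02d", phen_line, seq_len(n_lines))
    reps <- spec$replicates_per_line
    n_samples <- n_lines * reps
    sample_line <- rep(seq_len(n_lines), each = reps)
    sample_rep <- rep(seq_len(reps), times = n_lines)
    sample_ids <- sprintf("%s_R%d", line_ids[sample_line], sample_rep)
    ## round-robin so cell lines span batches (keeps batch and replicate
    ## group unconfounded for empirical-Bayes correction)
    batch <- ((sample_line + sample_rep - 2L) %% spec$n_batches) + 1L

    gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
    baseline <- rnorm(spec$n_genes, mean = 8, sd = 2)
    values <- matrix(baseline, nrow = spec$n_genes, ncol = n_samples)
    dimnames(values) <- list(gene_ids, sample_ids)

    ## planted modules
    module_genes <- list()
    module_loadings <- list()
    module_factors <- list()
    offset <- 0L
    for (m in seq_along(spec$modules)) {
      mod <- spec$modules[[m]]
      idx <- offset + seq_len(mod$size)
      offset <- offset + mod$size
      ## graded loadings with a floor: a pure half-normal from zero would
      ## plant "members" carrying no signal at all
      loading <- (0.3 + abs(rnorm(mod$size, sd = 0.7))) * mod$effect_sd
      ps <- spec$phenotype_shift %||% 1
      shift <- switch(mod$phenotype_link,
                      IBC = ifelse(phen_line == "IBC", ps, -ps),
                      nIBC = ifelse(phen_line == "nIBC", ps, -ps),
                      none = rep(0, n_lines))
      f_line <- rnorm(n_lines, mean = shift, sd = 1)
      values[idx, ] <- values[idx, ] + outer(loading, f_line[sample_line])
      module_genes[[m]] <- gene_ids[idx]
      module_loadings[[m]] <- setNames(loading, gene_ids[idx])
      module_factors[[m]] <- setNames(f_line, line_ids)
    }

    ## batch distortions: per-gene location shift (log2 units) and scale on
    ## deviations from the gene mean
    shifts <- matrix(rnorm(spec$n_genes * spec$n_batches, sd = spec$batch_shift_sd),
                     nrow = spec$n_genes)
    scales <- matrix(exp(rnorm(spec$n_genes * spec$n_batches, sd = spec$batch_scale_sd)),
                     nrow = spec$n_genes)
    gm <- rowMeans(values)
    for (b in seq_len(spec$n_batches)) {
      cols <- which(batch == b)
      if (!length(cols)) next
      values[, cols] <- gm + (values[, cols] - gm) * scales[, b] + shifts[, b]
    }

    values <- values + matrix(rnorm(length(values), sd = spec$noise_sd),
                              nrow = nrow(values))

    ## receptor labels: IBC models in this panel are ER-negative; nIBC mixed
    er_line <- ifelse(phen_line == "IBC", "NEG",
                      ifelse(runif(n_lines) < 0.55, "POS", "NEG"))
    pr_line <- ifelse(er_line == "POS" & runif(n_lines) < 0.7, "POS", "NEG")
    her2_line <- ifelse(runif(n_lines) < 0.3, "POS", "NEG")
    subtype_line <- ifelse(er_line == "POS", "luminal",
                           ifelse(her2_line == "POS", "HER2", "basal"))

    annotation <- data.frame(
      sample_id = sample_ids,
      batch = factor(batch),
      replicate_group = line_ids[sample_line],
      phenotype = phen_line[sample_line],
      ER = er_line[sample_line],
      PR = pr_line[sample_line],
      HER2 = her2_line[sample_line],
      subtype = subtype_line[sample_line],
      stringsAsFactors = FALSE
    )

    structure(list(
      values = values,
      annotation = annotation,
      truth = list(module_genes = module_genes,
                   module_loadings = module_loadings,
                   module_factors = module_factors,
                   phenotype_link = vapply(spec$modules, `[[`, character(1),
                                           "phenotype_link")),
      spec = spec
    ), class = "expression_compendium")
  })
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression_compendium: %d genes x %d profiles (%d cell lines, %d batches)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotation$replicate_group)),
              length(unique(x$annotation$batch))))
  invisible(x)
}

#' Specification for a synthetic perturbation catalog
#'
#' @param n_signature_genes number of genes in the signature universe (used
#'   when no compendium modules are supplied).
#' @param n_perturbagens number of filler (pure-noise) perturbagens.
#' @param planted_regulators list of lists with `module_id` (index into the
#'   compendium's planted modules), `strength` in \[0, 1\], and optional
#'   `gene` id for the regulator.
#' @param planted_drug_pairs list of lists with `target_id` (a planted
#'   regulator's gene id), `drug_id`, and `strength` in \[0, 1\].
#' @param seed integer seed for the catalog substream.
#' @return A list of class `catalog_spec`.
#' @export
catalog_spec <- function(n_signature_genes = 2000,
                         n_perturbagens = 50,
                         planted_regulators = list(),
                         planted_drug_pairs = list(),
                         seed = 1L) {
  reg_genes <- vapply(seq_along(planted_regulators), function(i) {
    planted_regulators[[i]]$gene %||% sprintf("REG%02d", i)
  }, character(1))
  if (anyDuplicated(reg_genes)) stop_ibctx("planted regulator ids must be unique")
  strengths <- c(
    vapply(planted_regulators, function(r) as.numeric(r$strength), numeric(1)),
    vapply(planted_drug_pairs, function(d) as.numeric(d$strength), numeric(1))
  )
  if (length(strengths) && (any(strengths < 0) || any(strengths > 1))) {
    stop_ibctx("strengths must lie in [0, 1]")
  }
  drug_ids <- vapply(planted_drug_pairs, function(d) d$drug_id, character(1))
  if (anyDuplicated(drug_ids)) stop_ibctx("planted drug ids must be unique")
  structure(list(n_signature_genes = n_signature_genes,
                 n_perturbagens = n_perturbagens,
                 planted_regulators = planted_regulators,
                 planted_regulator_genes = reg_genes,
                 planted_drug_pairs = planted_drug_pairs,
                 seed = seed),
            class = "catalog_spec")
}

#' Generate an L1000-like perturbation catalog
#'
#' Builds ranked differential-expression signatures (one column per
#' perturbagen) over a gene universe. For each planted regulator of a
#' compendium module, an overexpression signature is positively aligned with
#' the module's characteristic profile - the gene-wise module-membership
#' vector (the correlation of every gene with the module's latent factor
#' when the full compendium is supplied, the loading vector plus a faint
#' dense background otherwise) - and the matching knockdown signature is
#' its negation plus noise; at `strength = 1` the negation is exact.
#' Planted drugs mimic knockdown of their declared target. Filler
#' perturbagens are independent noise.
#'
#' @param spec a [catalog_spec()].
#' @param compendium_modules an `expression_compendium` (its full gene
#'   universe and planted truth are used), or just the `truth` element of
#'   one (any list with `module_genes` and `module_loadings`); may be
#'   `NULL` when no regulators are planted.
#' @return A list of class `perturbation_catalog` with `values` (genes x
#'   perturbagens matrix of signature scores) and `meta` (data.frame with
#'   `perturbagen`, `type`, `gene`, `target`, `module_id`).
#' @export
generate_perturbation_catalog <- function(spec, compendium_modules = NULL) {
  if (!inherits(spec, "catalog_spec")) spec <- do.call(catalog_spec, spec)
  with_seed_or_not(substream_seed(spec$seed, 2L), {
    compendium_values <- NULL
    if (!is.null(compendium_modules)) {
      if (inherits(compendium_modules, "expression_compendium")) {
        universe <- rownames(compendium_modules$values)
        compendium_values <- compendium_modules$values
        compendium_ann <- compendium_modules$annotation
        compendium_modules <- compendium_modules$truth
      } else {
        universe <- unique(unlist(compendium_modules$module_genes))
      }
      extra <- spec$n_signature_genes - length(universe)
      if (extra > 0) universe <- c(universe, sprintf("F%05d", seq_len(extra)))
    } else {
      universe <- sprintf("G%05d", seq_len(spec$n_signature_genes))
    }
    ng <- length(universe)

    base_profile <- function(module_id) {
      if (is.null(compendium_modules) ||
          module_id > length(compendium_modules$module_genes)) {
        stop_ibctx(sprintf("unknown module id %s in planted regulator", module_id))
      }
      v <- setNames(numeric(ng), universe)
      if (!is.null(compendium_values)) {
        ## gene-wise membership vector: correlation of every compendium gene
        ## with the module's realized latent factor
        f <- compendium_modules$module_factors[[module_id]]
        f_samp <- f[compendium_ann$replicate_group]
        cors <- as.numeric(cor(t(compendium_values), f_samp))
        v[rownames(compendium_values)] <- cors
        ## padded filler genes stay at zero background
      } else {
        genes <- compendium_modules$module_genes[[module_id]]
        v[genes] <- compendium_modules$module_loadings[[module_id]]
        v[setdiff(universe, genes)] <- rnorm(ng - length(genes), sd = 0.02)
      }
      v / sqrt(sum(v^2))
    }

    cols <- list()
    meta <- list()
    reg_base <- list()
    for (i in seq_along(spec$planted_regulators)) {
      reg <- spec$planted_regulators[[i]]
      gene <- spec$planted_regulator_genes[i]
      s <- reg$strength
      base <- base_profile(reg$module_id)
      oe <- s * base + (1 - s) * rnorm(ng) / sqrt(ng)
      kd <- -oe + (1 - s) * rnorm(ng) / sqrt(ng)
      reg_base[[gene]] <- list(base = base, module_id = reg$module_id)
      cols[[paste0(gene, "_oe")]] <- oe
      cols[[paste0(gene, "_kd")]] <- kd
      meta[[length(meta) + 1L]] <- data.frame(
        perturbagen = paste0(gene, "_oe"), type = "overexpression",
        gene = gene, target = NA_character_, module_id = reg$module_id)
      meta[[length(meta) + 1L]] <- data.frame(
        perturbagen = paste0(gene, "_kd"), type = "knockdown",
        gene = gene, target = NA_character_, module_id = reg$module_id)
    }
    for (d in spec$planted_drug_pairs) {
      if (is.null(reg_base[[d$target_id]])) {
        stop_ibctx(sprintf("drug target '%s' is not a planted regulator", d$target_id))
      }
      s <- d$strength
      sig <- -s * reg_base[[d$target_id]]$base + (1 - s) * rnorm(ng) / sqrt(ng)
      cols[[d$drug_id]] <- sig
      meta[[length(meta) + 1L]] <- data.frame(
        perturbagen = d$drug_id, type = "drug", gene = NA_character_,
        target = d$target_id, module_id = reg_base[[d$target_id]]$module_id)
    }
    for (i in seq_len(spec$n_perturbagens)) {
      id <- sprintf("FILLER%03d", i)
      cols[[id]] <- rnorm(ng) / sqrt(ng)
      meta[[length(meta) + 1L]] <- data.frame(
        perturbagen = id, type = "drug", gene = NA_character_,
        target = NA_character_, module_id = NA_integer_)
    }

    values <- do.call(cbind, cols)
    rownames(values) <- universe
    structure(list(values = values, meta = do.call(rbind, meta), spec = spec),
              class = "perturbation_catalog")
  })
}

#' Specification for a synthetic IBC/nIBC patient cohort
#'
#' Default coefficients are the study-scale effects on log2 MYC expression:
#' relative to nIBC with low ER expression, MYC decreases by 0.754 and 0.931
#' units in nIBC ER-moderate and ER-high samples; IBC ER-low samples lie
#' 0.832 units lower; within IBC, ER-moderate and ER-high samples increase
#' by 0.599 and 1.414 units over IBC ER-low.
#'
#' @param n_ibc,n_nibc cohort sizes (defaults 146 and 252).
#' @param coef_nibc_er_mod,coef_nibc_er_high,coef_ibc_er_low,coef_ibc_er_mod,coef_ibc_er_high
#'   expression-unit effects, parameterized as in [fit_nested_interaction()].
#' @param noise_sd residual SD of MYC around its cell mean (>= 0; 0 gives
#'   the exact-recovery limit).
#' @param pmn_cor_targets named numeric vector of Spearman correlation
#'   targets between proximal-MYC-network member genes and MYC.
#' @param activity_cor correlation between MYC expression and the generated
#'   transcriptional-activity score.
#' @param seed integer seed for the cohort substream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ibc = 146, n_nibc = 252,
                        coef_nibc_er_mod = -0.754,
                        coef_nibc_er_high = -0.931,
                        coef_ibc_er_low = -0.832,
                        coef_ibc_er_mod = 0.599,
                        coef_ibc_er_high = 1.414,
                        noise_sd = 1,
                        pmn_cor_targets = c(MAX = 0.4, MLX = 0.3,
                                            MXD3 = -0.4, MYCN = -0.25),
                        activity_cor = 0.8,
                        seed = 1L) {
  if (n_ibc < 9 || n_nibc < 9) {
    stop_ibctx("need at least 3 samples per ER stratum in each phenotype")
  }
  if (noise_sd < 0) stop_ibctx("noise_sd must be >= 0")
  structure(list(n_ibc = n_ibc, n_nibc = n_nibc,
                 coef_nibc_er_mod = coef_nibc_er_mod,
                 coef_nibc_er_high = coef_nibc_er_high,
                 coef_ibc_er_low = coef_ibc_er_low,
                 coef_ibc_er_mod = coef_ibc_er_mod,
                 coef_ibc_er_high = coef_ibc_er_high,
                 noise_sd = noise_sd, pmn_cor_targets = pmn_cor_targets,
                 activity_cor = activity_cor, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic IBC/nIBC patient cohort
#'
#' ESR1 expression is drawn continuously; ER strata are the pooled tertiles
#' (33rd/66th quantiles) of ESR1. MYC expression follows the reference mean
#' (nIBC/ER-low) plus the five spec coefficients per phenotype-by-stratum
#' cell plus Gaussian noise. Proximal-MYC-network member genes are drawn via
#' a Gaussian copula to hit the requested Spearman correlations with MYC;
#' stage and subtype labels have ER-stratum-dependent frequencies.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame of class `patient_cohort` with columns `sample_id`,
#'   `phenotype`, `ESR1`, `er_stratum`, `MYC`, the PMN member genes, `stage`,
#'   `subtype`, `activity`.
#' @export
generate_patient_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed_or_not(substream_seed(spec$seed, 3L), {
    n <- spec$n_ibc + spec$n_nibc
    phenotype <- c(rep("IBC", spec$n_ibc), rep("nIBC", spec$n_nibc))
    esr1 <- rnorm(n, mean = 6, sd = 1.5)
    ## stratify within phenotype so strata sizes are balanced (to within 1)
    ## in both the IBC and nIBC arms
    stratum <- factor(rep("low", n), levels = c("low", "moderate", "high"))
    for (ph in c("IBC", "nIBC")) {
      idx <- phenotype == ph
      stratum[idx] <- stratify_tertiles(esr1[idx])
    }
    tab <- table(phenotype, stratum)
    if (any(tab < 1)) {
      empty <- which(tab < 1, arr.ind = TRUE)
      stop_ibctx(sprintf("empty stratum after assignment: %s/%s",
                         rownames(tab)[empty[1, 1]], colnames(tab)[empty[1, 2]]))
    }
    ref <- 8
    eff <- numeric(n)
    eff[phenotype == "nIBC" & stratum == "moderate"] <- spec$coef_nibc_er_mod
    eff[phenotype == "nIBC" & stratum == "high"] <- spec$coef_nibc_er_high
    eff[phenotype == "IBC"] <- spec$coef_ibc_er_low
    eff[phenotype == "IBC" & stratum == "moderate"] <-
      spec$coef_ibc_er_low + spec$coef_ibc_er_mod
    eff[phenotype == "IBC" & stratum == "high"] <-
      spec$coef_ibc_er_low + spec$coef_ibc_er_high
    myc <- ref + eff + rnorm(n, sd = spec$noise_sd)

    ## PMN members: Gaussian copula on the standardized MYC values; the
    ## Pearson coefficient 2*sin(pi*rho_s/6) yields the Spearman target.
    z_myc <- as.numeric(scale(myc))
    if (all(!is.finite(z_myc))) z_myc <- rep(0, n)  # zero-noise degenerate scale
    pmn <- lapply(names(spec$pmn_cor_targets), function(g) {
      rho_s <- spec$pmn_cor_targets[[g]]
      rho_p <- 2 * sin(pi * rho_s / 6)
      7 + rho_p * z_myc + sqrt(max(0, 1 - rho_p^2)) * rnorm(n)
    })
    names(pmn) <- names(spec$pmn_cor_targets)

    a <- spec$activity_cor
    activity <- a * z_myc + sqrt(max(0, 1 - a^2)) * rnorm(n)

    stage_probs <- list(low = c(0.1, 0.3, 0.4, 0.2),
                        moderate = c(0.2, 0.35, 0.3, 0.15),
                        high = c(0.3, 0.35, 0.25, 0.1))
    stage <- vapply(as.character(stratum), function(s) {
      sample(c("I", "II", "III", "IV"), 1, prob = stage_probs[[s]])
    }, character(1))
    subtype_probs <- list(low = c(0.05, 0.10, 0.25, 0.60),
                          moderate = c(0.30, 0.30, 0.20, 0.20),
                          high = c(0.45, 0.35, 0.10, 0.10))
    subtype <- vapply(as.character(stratum), function(s) {
      sample(c("LumA", "LumB", "Her2", "Basal"), 1, prob = subtype_probs[[s]])
    }, character(1))

    out <- data.frame(sample_id = sprintf("P%03d", seq_len(n)),
                      phenotype = phenotype, ESR1 = esr1,
                      er_stratum = stratum, MYC = myc,
                      as.data.frame(pmn), stage = stage, subtype = subtype,
                      activity = activity, stringsAsFactors = FALSE)
    class(out) <- c("patient_cohort", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}
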