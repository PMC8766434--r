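## Connectivity-map style screening: module marker queries (150 up / 150
## down genes by GMM score), weighted-KS connectivity scores against a
## catalog of ranked perturbation signatures, and the regulator and
## drug/target decision rules.

## Weighted Kolmogorov-Smirnov enrichment score of `set` in the ranking
## defined by `stat` (named scores). Hit increments are proportional to
## |stat|^weight_exponent (0 = rank-only), miss decrements are uniform.
## Returns the signed maximal running deviation; also used by
## preranked_gsea().
weighted_ks_es <- function(stat, set, weight_exponent = 1,
                           return_lead = FALSE) {
  genes <- names(stat)
  ord <- order(-stat, genes)
  stat_o <- stat[ord]
  hit <- names(stat_o) %in% set
  nh <- sum(hit)
  if (nh == 0) stop_ibctx("set is disjoint from the ranking universe")
  if (nh == length(stat_o)) stop_ibctx("set covers the whole universe")
  w <- abs(stat_o)^weight_exponent
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- nh }  # all-zero scores: rank-only
  p_hit <- cumsum(w) / tot
  p_miss <- cumsum(!hit) / (length(stat_o) - nh)
  dev <- p_hit - p_miss
  i_max <- which.max(abs(dev))
  es <- dev[i_max]
  if (!return_lead) return(unname(es))
  lead <- if (es >= 0) sum(hit[seq_len(i_max)]) else sum(hit[-seq_len(i_max)])
  list(es = unname(es), leading_edge = lead)
}

#' Build a module marker query from GMM scores
#'
#' Takes the `n_each` genes with the highest GMM scores as the up set and
#' the `n_each` lowest as the down set (ties broken by gene id). When the
#' universe holds fewer than `2 * n_each` genes the sizes shrink
#' proportionally, which requires `allow_small = TRUE`.
#'
#' @param gmm_column named numeric vector of gene-module-membership scores
#'   for one module.
#' @param n_each genes per direction (default 150).
#' @param allow_small allow proportional shrinking on small universes.
#' @param module_id optional source module id carried in the result.
#' @return A list of class `query_signature` with `up`, `down`,
#'   `module_id`.
#' @export
make_query <- function(gmm_column, n_each = 150, allow_small = FALSE,
                       module_id = NA) {
  g <- gmm_column[is.finite(gmm_column)]
  if (is.null(names(g))) stop_ibctx("gmm_column must be named by gene")
  if (length(g) < 2 * n_each) {
    if (!allow_small) {
      stop_ibctx(sprintf("only %d genes with finite GMM (< %d); set allow_small = TRUE",
                         length(g), 2 * n_each))
    }
    n_each <- floor(length(g) / 2)
    message(sprintf("small universe: using %d genes per direction", n_each))
  }
  ord_up <- order(-g, names(g))
  ord_dn <- order(g, names(g))
  up <- names(g)[ord_up[seq_len(n_each)]]
  down <- setdiff(names(g)[ord_dn], up)[seq_len(n_each)]
  structure(list(up = sort(up), down = sort(down), module_id = module_id),
            class = "query_signature")
}

#' Connectivity score between a query and one ranked signature
#'
#' Weighted-KS enrichment of the up and down sets in the signature ranking
#' (hit increments proportional to |signature value|, uniform miss
#' decrements, signed maximal running deviation). The score is
#' `100 * (ES_up - ES_down) / 2` when the two enrichment scores have
#' opposite signs and 0 otherwise, so congruent profiles score +100 and
#' opposed profiles -100.
#'
#' @param query a `query_signature` (or list with `up` and `down`).
#' @param signature named numeric vector of differential-expression scores
#'   covering all query genes.
#' @param weight_exponent 1 for value-weighted hits (default), 0 for the
#'   rank-only variant.
#' @return Connectivity score in \[-100, 100\].
#' @export
connectivity_score <- function(query, signature, weight_exponent = 1) {
  missing <- setdiff(c(query$up, query$down), names(signature))
  if (length(missing)) {
    stop_ibctx(sprintf("query genes missing from signature: %s",
                       paste(head(missing, 10), collapse = ", ")))
  }
  es_up <- weighted_ks_es(signature, query$up, weight_exponent)
  es_down <- weighted_ks_es(signature, query$down, weight_exponent)
  if (sign(es_up) == sign(es_down)) return(0)
  100 * (es_up - es_down) / 2
}

#' Score module queries against a whole perturbation catalog
#'
#' @param queries a named list of `query_signature` objects.
#' @param catalog a `perturbation_catalog` (see
#'   [generate_perturbation_catalog()]) or a list with `values` and `meta`.
#' @param weight_exponent passed to [connectivity_score()].
#' @return A data.frame of connectivity records: `query`, `perturbagen`,
#'   `type`, `gene`, `target`, `cs`.
#' @export
connectivity_screen <- function(queries, catalog, weight_exponent = 1) {
  values <- catalog$values
  meta <- catalog$meta
  rows <- list()
  for (q in names(queries)) {
    for (j in seq_len(ncol(values))) {
      sig <- setNames(values[, j], rownames(values))
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, perturbagen = colnames(values)[j],
        type = meta$type[j], gene = meta$gene[j], target = meta$target[j],
        cs = connectivity_score(queries[[q]], sig, weight_exponent))
    }
  }
  do.call(rbind, rows)
}

#' Flag module regulators from paired overexpression/knockdown scores
#'
#' A gene is a regulator of a module when its overexpression connectivity
#' score is at least `oe_cut` and its knockdown score at most `kd_cut`
#' (i.e. the OE - KD difference is at least 150 with both sub-thresholds
#' met). Candidates lacking either record are skipped with a warning.
#'
#' @param records connectivity records (see [connectivity_screen()]).
#' @param oe_cut,kd_cut thresholds (defaults 75 and -75).
#' @return data.frame of flagged (query, gene) pairs with both scores.
#' @export
find_regulators <- function(records, oe_cut = 75, kd_cut = -75) {
  cand <- records[records$type %in% c("overexpression", "knockdown") &
                    !is.na(records$gene), , drop = FALSE]
  out <- list()
  for (key in unique(paste(cand$query, cand$gene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- cand[cand$query == parts[1] & cand$gene == parts[2], , drop = FALSE]
    oe <- sub$cs[sub$type == "overexpression"]
    kd <- sub$cs[sub$type == "knockdown"]
    if (length(oe) != 1 || length(kd) != 1) {
      warning(sprintf("unpaired OE/KD records for gene '%s' (query '%s'); skipped",
                      parts[2], parts[1]))
      next
    }
    if (oe >= oe_cut && kd <= kd_cut) {
      out[[length(out) + 1L]] <- data.frame(
        query = parts[1], gene = parts[2], cs_oe = oe, cs_kd = kd,
        cs_difference = oe - kd)
    }
  }
  if (!length(out)) {
    return(data.frame(query = character(), gene = character(),
                      cs_oe = numeric(), cs_kd = numeric(),
                      cs_difference = numeric()))
  }
  do.call(rbind, out)
}

#' Flag drug/target combinations
#'
#' A drug/target pair is reported for a module when the drug's connectivity
#' score is strictly below `drug_cut` and the declared target's
#' overexpression score strictly above `oe_cut`. Drugs without a known
#' target among the overexpression records are skipped with a warning.
#'
#' @param records connectivity records (see [connectivity_screen()]).
#' @param drug_cut,oe_cut strict thresholds (defaults -75 and 75).
#' @return data.frame of flagged (query, target, drug) triples.
#' @export
find_drug_target_pairs <- function(records, drug_cut = -75, oe_cut = 75) {
  drugs <- records[records$type == "drug" & !is.na(records$target), ,
                   drop = FALSE]
  oes <- records[records$type == "overexpression", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    dr <- drugs[i, ]
    hit <- oes[oes$query == dr$query & oes$gene == dr$target, , drop = FALSE]
    if (nrow(hit) != 1) {
      warning(sprintf("drug '%s': no overexpression record for target '%s'; skipped",
                      dr$perturbagen, dr$target))
      next
    }
    if (dr$cs < drug_cut && hit$cs > oe_cut) {
      out[[length(out) + 1L]] <- data.frame(
        query = dr$query, target = dr$target, drug = dr$perturbagen,
        cs_drug = dr$cs, cs_target_oe = hit$cs)
    }
  }
  if (!length(out)) {
    return(data.frame(query = character(), target = character(),
                      drug = character(), cs_drug = numeric(),
                      cs_target_oe = numeric()))
  }
  do.call(rbind, out)
}
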