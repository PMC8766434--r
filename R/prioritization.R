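## Network-based module prioritization: dichotomize module-module eigengene
## correlations and per-cell-line module expression into a binary
## module/cell-line graph, then extract the minimal edge set connecting the
## target cell lines through modules with a deterministic minimum spanning
## tree.

#' Build the binary module/cell-line adjacency
#'
#' Module-module edges exist where the eigengene correlation is strictly
#' positive; module-cell-line edges exist where that cell line's eigengene
#' value is strictly positive. Exact zeros yield no edge (their count is
#' reported via a message). Cell lines are never linked directly.
#'
#' @param module_cor modules x modules eigengene correlation matrix (module
#'   names as dimnames).
#' @param module_expression modules x cell-lines matrix of eigengene values
#'   (cell-line names as colnames).
#' @return A list of class `bipartite_adjacency` with `adjacency` (binary
#'   matrix over modules + cell lines), `nodes` (data.frame id/type) and
#'   `edges` (data.frame from/to).
#' @export
build_bipartite_adjacency <- function(module_cor, module_expression) {
  if (!identical(rownames(module_cor), rownames(module_expression))) {
    stop_ibctx("module sets of the correlation and expression inputs differ")
  }
  modules <- rownames(module_cor) %||% paste0("M", seq_len(nrow(module_cor)))
  lines <- colnames(module_expression) %||%
    paste0("CL", seq_len(ncol(module_expression)))
  n_zero <- sum(module_cor[upper.tri(module_cor)] == 0) +
    sum(module_expression == 0)
  if (n_zero > 0) {
    message(sprintf("%d exact zero value(s) produced no edge", n_zero))
  }
  nodes <- data.frame(id = c(modules, lines),
                      type = rep(c("module", "cell_line"),
                                 c(length(modules), length(lines))))
  n <- nrow(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes$id, nodes$id))
  mm <- (module_cor > 0) * 1L
  diag(mm) <- 0L
  adj[modules, modules] <- mm
  ml <- (module_expression > 0) * 1L
  adj[modules, lines] <- ml
  adj[lines, modules] <- t(ml)
  edges <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = nodes$id[edges[, 1]], to = nodes$id[edges[, 2]])
  structure(list(adjacency = adj, nodes = nodes, edges = edges),
            class = "bipartite_adjacency")
}

#' Minimal set of modules connecting target cell lines
#'
#' Computes a deterministic minimum spanning tree of the unweighted binary
#' graph (unit edge weights; ties broken by lexicographic node-pair order so
#' the result is canonical), then returns the union of nodes on the unique
#' tree paths joining all target cell lines. The prioritized module subset
#' is the set of module nodes on those paths; tree edges are flagged by
#' whether they lie on a target-connecting path.
#'
#' @param bipartite a `bipartite_adjacency` (or a binary adjacency matrix
#'   with node names; in that case every node is treated as a module unless
#'   listed in `targets`).
#' @param targets character vector of target cell-line ids; all must lie in
#'   one connected component.
#' @return A list with `mst_edges` (data.frame from/to/on_path), `modules`
#'   (prioritized module ids), `path_nodes` and the igraph tree.
#' @export
minimal_connecting_modules <- function(bipartite, targets) {
  if (inherits(bipartite, "bipartite_adjacency")) {
    adj <- bipartite$adjacency
    node_type <- setNames(bipartite$nodes$type, bipartite$nodes$id)
  } else {
    adj <- bipartite
    node_type <- setNames(ifelse(rownames(adj) %in% targets, "cell_line",
                                 "module"), rownames(adj))
  }
  missing <- setdiff(targets, rownames(adj))
  if (length(missing)) {
    stop_ibctx(sprintf("unknown target(s): %s", paste(missing, collapse = ", ")))
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  target_comp <- comp[targets]
  if (length(unique(target_comp)) > 1) {
    main <- names(sort(table(target_comp), decreasing = TRUE))[1]
    isolated <- targets[target_comp != as.integer(main)]
    stop_ibctx(sprintf("target cell line(s) not connected to the rest: %s",
                       paste(isolated, collapse = ", ")))
  }

  ## canonical MST: unit weights perturbed by the lexicographic rank of the
  ## sorted node-name pair, so the spanning tree is unique and input-order
  ## invariant
  el <- igraph::as_edgelist(g)
  pair <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  w <- 1 + rank(pair, ties.method = "first") * 1e-9
  tree <- igraph::mst(g, weights = w)

  ## union of path nodes over all target pairs (paths on a tree are unique)
  path_nodes <- character(0)
  if (length(targets) == 1) {
    path_nodes <- targets
  } else {
    for (i in seq_along(targets)[-1]) {
      sp <- igraph::shortest_paths(tree, from = targets[1], to = targets[i],
                                   output = "vpath")
      path_nodes <- union(path_nodes, names(sp$vpath[[1]]))
    }
  }
  modules <- sort(path_nodes[node_type[path_nodes] == "module"])

  tel <- igraph::as_edgelist(tree)
  on_path <- (tel[, 1] %in% path_nodes) & (tel[, 2] %in% path_nodes)
  mst_edges <- data.frame(from = tel[, 1], to = tel[, 2], on_path = on_path)
  list(mst_edges = mst_edges, modules = modules, path_nodes = sort(path_nodes),
       tree = tree)
}
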