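test_that("bipartite adjacency dichotomizes strictly at zero", {
  mc <- matrix(c(1, 0.3, -0.3, 0.3, 1, 0, -0.3, 0, 1), 3, 3,
               dimnames = list(c("M1", "M2", "M3"), c("M1", "M2", "M3")))
  me <- matrix(c(0.5, -1, 0, 2, 0.1, -0.2), 3, 2,
               dimnames = list(c("M1", "M2", "M3"), c("CL1", "CL2")))
  expect_message(ba <- build_bipartite_adjacency(mc, me), "zero")
  expect_equal(ba$adjacency["M1", "M2"], 1L)  # +0.3 -> edge
  expect_equal(ba$adjacency["M1", "M3"], 0L)  # -0.3 -> none
  expect_equal(ba$adjacency["M2", "M3"], 0L)  # exact 0 -> none
  expect_equal(ba$adjacency["M1", "CL1"], 1L)
  expect_equal(ba$adjacency["M2", "CL1"], 0L)
  ## no cell-line/cell-line edges and symmetric module block
  expect_true(all(ba$adjacency[c("CL1", "CL2"), c("CL1", "CL2")] == 0))
  expect_true(isSymmetric(ba$adjacency))

  allneg <- suppressMessages(build_bipartite_adjacency(-abs(mc) + diag(3) * 2,
                                                       -abs(me) - 0.1))
  expect_equal(nrow(allneg$edges), 0)
})

test_that("minimal connecting modules: trivial cases and errors", {
  ## two cell lines linked through one module
  adj <- matrix(0L, 3, 3, dimnames = list(c("M1", "a", "b"), c("M1", "a", "b")))
  adj["M1", "a"] <- adj["a", "M1"] <- 1L
  adj["M1", "b"] <- adj["b", "M1"] <- 1L
  ba <- list(adjacency = adj,
             nodes = data.frame(id = c("M1", "a", "b"),
                                type = c("module", "cell_line", "cell_line")))
  class(ba) <- "bipartite_adjacency"
  res <- minimal_connecting_modules(ba, c("a", "b"))
  expect_equal(res$modules, "M1")
  expect_true(all(res$mst_edges$on_path))

  ## disconnected target errors with its name
  adj2 <- rbind(cbind(adj, c = 0L), c = 0L)
  dimnames(adj2) <- list(c("M1", "a", "b", "c"), c("M1", "a", "b", "c"))
  ba2 <- list(adjacency = adj2,
              nodes = data.frame(id = rownames(adj2),
                                 type = c("module", rep("cell_line", 3))))
  class(ba2) <- "bipartite_adjacency"
  expect_error(minimal_connecting_modules(ba2, c("a", "b", "c")), "c")
})

test_that("tree inputs are their own MST and results are order-invariant", {
  ## path graph a - M1 - M2 - b (already a tree)
  nodes <- c("M1", "M2", "a", "b")
  adj <- matrix(0L, 4, 4, dimnames = list(nodes, nodes))
  adj["a", "M1"] <- adj["M1", "a"] <- 1L
  adj["M1", "M2"] <- adj["M2", "M1"] <- 1L
  adj["M2", "b"] <- adj["b", "M2"] <- 1L
  ba <- list(adjacency = adj,
             nodes = data.frame(id = nodes,
                                type = c("module", "module", "cell_line", "cell_line")))
  class(ba) <- "bipartite_adjacency"
  res <- minimal_connecting_modules(ba, c("a", "b"))
  expect_equal(nrow(res$mst_edges), 3)  # identical edge set
  expect_equal(res$modules, c("M1", "M2"))

  perm <- c("b", "M2", "a", "M1")
  ba_p <- list(adjacency = adj[perm, perm],
               nodes = data.frame(id = perm,
                                  type = c("cell_line", "module", "cell_line", "module")))
  class(ba_p) <- "bipartite_adjacency"
  res_p <- minimal_connecting_modules(ba_p, c("a", "b"))
  expect_equal(res_p$modules, res$modules)
  expect_equal(sort(paste(pmin(res_p$mst_edges$from, res_p$mst_edges$to),
                          pmax(res_p$mst_edges$from, res_p$mst_edges$to))),
               sort(paste(pmin(res$mst_edges$from, res$mst_edges$to),
                          pmax(res$mst_edges$from, res$mst_edges$to))))
})

test_that("module subsets agree with an independent BFS oracle on random graphs", {
  ## independent path finder: BFS with parent tracing on the tree adjacency
  bfs_path <- function(adj, from, to) {
    nodes <- rownames(adj)
    parent <- setNames(rep(NA_character_, length(nodes)), nodes)
    visited <- setNames(logical(length(nodes)), nodes)
    queue <- from; visited[from] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (cur == to) break
      for (nb in nodes[adj[cur, ] == 1 & !visited]) {
        visited[nb] <- TRUE; parent[nb] <- cur; queue <- c(queue, nb)
      }
    }
    path <- to
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  }
  agree <- 0L
  checked <- 0L
  for (s in 1:100) {
    g <- withr::with_seed(s, {
      n_mod <- sample(2:5, 1)
      n_cl <- sample(2:3, 1)
      mods <- paste0("M", seq_len(n_mod))
      cls <- paste0("CL", seq_len(n_cl))
      nodes <- c(mods, cls)
      adj <- matrix(0L, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
      for (i in seq_along(mods)) for (j in seq_along(mods)) {
        if (j > i && runif(1) < 0.5) {
          adj[mods[i], mods[j]] <- adj[mods[j], mods[i]] <- 1L
        }
      }
      for (m in mods) for (cl in cls) {
        if (runif(1) < 0.5) adj[m, cl] <- adj[cl, m] <- 1L
      }
      list(adj = adj, mods = mods, cls = cls)
    })
    ba <- list(adjacency = g$adj,
               nodes = data.frame(id = rownames(g$adj),
                                  type = rep(c("module", "cell_line"),
                                             c(length(g$mods), length(g$cls)))))
    class(ba) <- "bipartite_adjacency"
    res <- tryCatch(minimal_connecting_modules(ba, g$cls), error = function(e) NULL)
    if (is.null(res)) next  # disconnected targets
    checked <- checked + 1L
    ## oracle: union of BFS paths between consecutive targets on the MST
    tree_adj <- matrix(0L, nrow(g$adj), ncol(g$adj), dimnames = dimnames(g$adj))
    for (i in seq_len(nrow(res$mst_edges))) {
      tree_adj[res$mst_edges$from[i], res$mst_edges$to[i]] <- 1L
      tree_adj[res$mst_edges$to[i], res$mst_edges$from[i]] <- 1L
    }
    path_nodes <- unique(unlist(lapply(g$cls[-1], function(cl) {
      bfs_path(tree_adj, g$cls[1], cl)
    })))
    oracle_modules <- sort(intersect(path_nodes, g$mods))
    if (identical(oracle_modules, res$modules)) agree <- agree + 1L
    ## MST edge count invariant: nodes - components
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected"))$no
    expect_equal(nrow(res$mst_edges), nrow(g$adj) - comp)
  }
  expect_gt(checked, 50)
  expect_equal(agree, checked)
})
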