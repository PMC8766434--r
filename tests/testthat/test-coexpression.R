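test_that("bicor is affine-invariant, symmetric and close to Pearson on clean data", {
  set.seed(1)
  x <- rnorm(50)
  vals <- rbind(a = x, b = 2 * x + 1, c = rnorm(50))
  r <- bicor(vals)
  expect_equal(unname(r["a", "b"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_true(all(r >= -1 & r <= 1))
  expect_true(all(diag(r) == 1))

  ## bivariate normal, n = 1000, rho = 0.5: |bicor - pearson| < 0.05
  set.seed(2)
  z <- rnorm(1000)
  y1 <- z
  y2 <- 0.5 * z + sqrt(0.75) * rnorm(1000)
  rb <- bicor(rbind(y1 = y1, y2 = y2))["y1", "y2"]
  expect_lt(abs(rb - cor(y1, y2)), 0.05)
  expect_error(bicor(vals[, 1:3]), "4 samples")
})

test_that("bicor resists a gross outlier better than Pearson", {
  hits <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      x <- rnorm(30)
      y <- x + rnorm(30, sd = 0.2)
      x[1] <- 15  # gross outlier in x only
    })
    rb <- bicor(rbind(x = x, y = y))["x", "y"]
    abs(rb) > abs(cor(x, y))
  }, logical(1))
  expect_gte(sum(hits), 57)
})

test_that("soft-threshold selection behaves on planted and degenerate inputs", {
  cp <- recovery_compendium(31)
  r <- bicor(cp$values)
  st <- pick_soft_threshold(r, candidates = 1:20)
  expect_gte(max(st$fit$r_squared, na.rm = TRUE), 0.8)
  expect_true(st$power %in% 1:20)

  ## adjacency is strictly decreasing in the power wherever cor < 1
  a2 <- signed_adjacency_for_tests(r, 2)
  a5 <- signed_adjacency_for_tests(r, 5)
  off <- upper.tri(r)
  expect_true(all(a5[off] <= a2[off]))

  ## identity correlation: constant connectivity flagged as degenerate
  expect_warning(st0 <- pick_soft_threshold(diag(10), candidates = 1:3),
                 "degenerate|threshold")
  expect_true(st0$power %in% 1:3)
})

test_that("tom matches hand computations and the brute-force triple loop", {
  ## complete graph
  ones <- matrix(1, 4, 4)
  expect_true(all(tom(ones)$tom == 1))
  ## 3 nodes with a single edge
  a <- diag(3); a[1, 2] <- a[2, 1] <- 1
  expect_equal(tom(a)$tom[1, 2], 1)
  ## zero adjacency off-diagonal
  expect_true(all(tom(diag(5))$tom[upper.tri(diag(5))] == 0))

  set.seed(4)
  r <- cor(matrix(rnorm(30 * 12), 12))
  adj <- signed_adjacency_for_tests(r, 4)
  got <- tom(adj)$tom
  expect_lt(max(abs(got - tom_brute(adj))), 1e-12)
  expect_lt(max(abs(got - t(got))), 1e-12)
  bad <- adj; bad[1, 2] <- bad[1, 2] + 1e-4
  expect_error(tom(bad), "symmetric")
})

test_that("module detection recovers planted modules and merges duplicated factors", {
  cp <- recovery_compendium(3)
  r <- bicor(cp$values)
  td <- tom(signed_adjacency_for_tests(r, 6))$dissimilarity
  ma <- detect_modules(td, min_size = 100, merge_cut = 0.25, values = cp$values)
  expect_gte(mclust::adjustedRandIndex(ma$labels, planted_truth(cp)), 0.9)
  expect_true(all(ma$sizes[names(ma$sizes) != "0"] >= 100))

  ## two modules driven by one factor merge
  set.seed(6)
  f <- rnorm(12)
  vals <- rbind(
    matrix(rep(f, each = 60), 60) * (0.5 + runif(60)) + matrix(rnorm(720, sd = 0.3), 60),
    matrix(rep(f, each = 60), 60) * (0.5 + runif(60)) + matrix(rnorm(720, sd = 0.3), 60),
    matrix(rnorm(60 * 12), 60))
  rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
  r2 <- bicor(vals)
  td2 <- tom(signed_adjacency_for_tests(r2, 6))$dissimilarity
  ma2 <- detect_modules(td2, min_size = 40, merge_cut = 0.25, values = vals)
  in_modules <- ma2$labels[1:120]
  biggest <- as.integer(names(sort(table(in_modules[in_modules != 0]),
                                   decreasing = TRUE))[1])
  expect_gte(mean(in_modules == biggest), 0.9)
  expect_error(detect_modules(td2, min_size = 1e5), "min_size")
})

test_that("pure-noise data never yields several large modules", {
  many <- vapply(1:20, function(s) {
    vals <- withr::with_seed(s, matrix(rnorm(300 * 12), 300,
                                       dimnames = list(sprintf("g%d", 1:300), NULL)))
    r <- bicor(vals)
    td <- tom(signed_adjacency_for_tests(r, 6))$dissimilarity
    ma <- detect_modules(td, min_size = 100, merge_cut = 0.25, values = vals)
    sum(table(ma$labels[ma$labels != 0]) >= 100)
  }, numeric(1))
  expect_gte(sum(many <= 3), 18)
})

test_that("eigengenes are unit-norm, orientation-stable and rank members first", {
  cp <- recovery_compendium(8)
  labels <- planted_truth(cp)
  gm <- module_eigengene(cp$values, labels)
  expect_equal(unname(colSums(gm$eigengenes^2)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(gm$gmm >= -1 & gm$gmm <= 1))

  ## member |GMM| beats non-member |GMM| on average
  for (m in 1:3) {
    mem <- names(labels)[labels == m]
    non <- names(labels)[labels != m & labels != 0]
    expect_gte(mean(abs(gm$gmm[mem, paste0("M", m)])) -
                 mean(abs(gm$gmm[non, paste0("M", m)])), 0.2)
  }

  ## negating member profiles leaves member GMM signs unchanged (re-orientation)
  vals2 <- cp$values
  m1 <- names(labels)[labels == 1]
  vals2[m1, ] <- -vals2[m1, ]
  gm2 <- module_eigengene(vals2, labels)
  expect_gt(mean(gm2$gmm[m1, "M1"]), 0)

  ## perfectly correlated module genes have GMM 1
  f <- rnorm(10)
  perf <- rbind(a = f, b = 2 * f, c = f + 3, d = rnorm(10))
  gmp <- module_eigengene(perf, c(a = 1, b = 1, c = 1, d = 0))
  expect_equal(unname(gmp$gmm[c("a", "b", "c"), "M1"]), rep(1, 3),
               tolerance = 1e-10)
  constant <- rbind(a = rep(1, 10), b = rep(2, 10))
  expect_error(module_eigengene(constant, c(a = 1, b = 1)), "constant")
})

test_that("module preservation separates planted from label-permuted test data", {
  spec <- compendium_spec(
    n_genes = 450,
    modules = list(list(size = 150, effect_sd = 2, phenotype_link = "none")),
    n_cell_lines_ibc = 5, n_cell_lines_nibc = 5, replicates_per_line = 3,
    n_batches = 1, batch_shift_sd = 0, batch_scale_sd = 0, noise_sd = 1,
    seed = 101)
  ref <- generate_cell_line_compendium(spec)
  spec2 <- spec; spec2$seed <- 202
  test_cp <- generate_cell_line_compendium(spec2)
  labels <- planted_truth(ref)

  pres <- module_preservation(labels, ref$values, test_cp$values,
                              power = 6, n_perm = 200, seed = 1)
  expect_gte(pres$Zsummary[1], 10)
  expect_equal(pres$band[1], "good")

  perm_vals <- test_cp$values
  rownames(perm_vals) <- withr::with_seed(2, sample(rownames(perm_vals)))
  pres_null <- module_preservation(labels, ref$values, perm_vals,
                                   power = 6, n_perm = 200, seed = 1)
  expect_lt(pres_null$Zsummary[1], 2)
  expect_equal(pres_null$band[1], "poor")

  ## missing genes -> module skipped with a warning
  expect_warning(
    empty <- module_preservation(labels, ref$values,
                                 test_cp$values[1:100, ], power = 6,
                                 n_perm = 10, seed = 1),
    "missing")
  expect_null(empty)
})

test_that("the network chain is deterministic under a fixed seed", {
  a1 <- module_recovery_ari(77)
  a2 <- module_recovery_ari(77)
  expect_identical(a1, a2)
})
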