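test_that("tertile stratification cuts at the tertiles with ties to the lower stratum", {
  s <- stratify_tertiles(1:9)
  expect_equal(as.vector(table(s)), c(3, 3, 3))
  ## rank invariance under a monotone transform
  x <- withr::with_seed(4, rnorm(300))
  expect_identical(stratify_tertiles(x), stratify_tertiles(exp(x)))
  tab <- table(stratify_tertiles(x))
  expect_true(all(abs(tab - 100) <= 1))
  expect_error(stratify_tertiles(rep(1, 10)), "all values equal")
  ## boundary tie goes low
  expect_equal(as.character(stratify_tertiles(c(1, 1, 1, 2, 2, 2, 3, 3, 3))[3]), "low")
})

test_that("elastic net separates a strongly phenotype-linked compendium", {
  cp <- generate_cell_line_compendium(compendium_spec(
    n_genes = 300,
    modules = list(list(size = 79, effect_sd = 4, phenotype_link = "IBC")),
    n_cell_lines_ibc = 10, n_cell_lines_nibc = 22, replicates_per_line = 3,
    noise_sd = 0.5, phenotype_shift = 3, seed = 11))
  sig <- cp$truth$module_genes[[1]]
  m <- train_elastic_net(cp$values, cp$annotation$phenotype, sig,
                         alpha_grid = c(0, 0.5, 1),
                         lambda_grid = c(0.001, 0.01, 0.05, 0.1),
                         folds = 5, repeats = 2, seed = 4)
  expect_gte(m$validation_accuracy, 0.95)
  expect_true(m$alpha %in% c(0, 0.5, 1))
  ## determinism under a fixed seed
  m2 <- train_elastic_net(cp$values, cp$annotation$phenotype, sig,
                          alpha_grid = c(0, 0.5, 1),
                          lambda_grid = c(0.001, 0.01, 0.05, 0.1),
                          folds = 5, repeats = 2, seed = 4)
  expect_identical(m$coefficients, m2$coefficients)
  expect_error(train_elastic_net(cp$values, cp$annotation$phenotype,
                                 c(sig, "NOPE")), "missing")
})

test_that("ridge column of the grid matches a Newton-optimized ridge logistic fit", {
  set.seed(7)
  n <- 200
  x <- cbind(g1 = rnorm(n), g2 = rnorm(n))
  eta <- 0.8 * x[, 1] - 0.5 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  lambda <- 0.05
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = c(0.2, 0.1, lambda), standardize = FALSE)
  b_glmnet <- as.numeric(coef(fit, s = lambda))
  ## independent Newton solver for the penalized logistic objective
  ## (1/n) sum -loglik + lambda/2 * ||b||^2 (no penalty on intercept)
  beta <- c(0, 0, 0)
  X <- cbind(1, x)
  for (i in 1:100) {
    p <- plogis(X %*% beta)
    w <- as.numeric(p * (1 - p))
    grad <- -crossprod(X, y - p) / n + lambda * c(0, beta[-1])
    hess <- crossprod(X * w, X) / n + lambda * diag(c(0, 1, 1))
    step <- solve(hess, grad)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  expect_lt(max(abs(beta - b_glmnet)), 1e-4)
})

test_that("replicate-median calling follows the stated conventions", {
  model <- structure(list(
    signature_genes = c("g1", "g2"), positive = "IBC",
    center = c(g1 = 0, g2 = 0), scale = c(g1 = 1, g2 = 1),
    alpha = 0.5, lambda = 0.01, intercept = 0,
    coefficients = c(g1 = 2, g2 = 0)), class = "ibc_classifier")
  vals <- rbind(g1 = c(-0.2, 0.2, 0.4, 0, 0), g2 = rnorm(5))
  colnames(vals) <- sprintf("s%d", 1:5)
  ps <- call_models(model, vals, c("m1", "m1", "m1", "m2", "m2"))
  expect_equal(unname(ps$median_posterior["m1"]), plogis(0.4))
  expect_equal(unname(ps$call["m1"]), "IBC")
  ## all posteriors exactly 0.5 -> IBC by the >= convention
  expect_equal(unname(ps$call["m2"]), "IBC")
  ## single replicate median is the posterior itself
  ps1 <- call_models(model, vals[, 1, drop = FALSE], "solo")
  expect_equal(unname(ps1$median_posterior), unname(ps1$posterior))
  expect_error(call_models(model, vals[1, , drop = FALSE], rep("m", 5)),
               "missing")
})

test_that("confusion statistics reproduce the published confusion shape", {
  calls <- c(rep("IBC", 10), rep("nIBC", 0), rep("IBC", 7), rep("nIBC", 15))
  truth <- c(rep("IBC", 10), rep("nIBC", 22))
  cs <- confusion_stats(calls, truth)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 15 / 22)
  expect_equal(cs$accuracy, 25 / 32)
  expect_equal(cs$ppv, 10 / 17)

  perfect <- confusion_stats(truth, truth)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 1))
  allpos <- confusion_stats(rep("IBC", 32), truth)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
})

test_that("mcnemar_test uses the chi-square and exact forms appropriately", {
  ## b = 10, c = 2: chi-square (b - c)^2 / (b + c)
  a <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 20))
  b <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 20))
  res <- mcnemar_test(a, b)
  expect_equal(res$statistic, 64 / 12, tolerance = 1e-12)
  expect_equal(res$p, pchisq(64 / 12, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(res$p, 4), 0.0209)

  ## b = c -> statistic 0, p 1
  res0 <- mcnemar_test(c(rep(TRUE, 6), rep(FALSE, 6)),
                       c(rep(FALSE, 6), rep(TRUE, 6)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  ## b = 3, c = 0 -> exact binomial 2 * (1/2)^3
  res3 <- mcnemar_test(c(TRUE, TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(res3$method, "exact binomial")
  expect_equal(res3$p, 0.25)
  resd <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(resd$p, 1)
})

test_that("nearest-centroid caller matches brute-force correlation argmax", {
  set.seed(10)
  cents <- matrix(rnorm(60), 20, 3,
                  dimnames = list(sprintf("g%d", 1:20), c("A", "B", "C")))
  ## sample equal to a centroid gets its label
  vals <- cbind(s1 = cents[, "B"], s2 = -cents[, "C"],
                s3 = rnorm(20), s4 = rnorm(20))
  rownames(vals) <- rownames(cents)
  labels <- classify_nearest_centroid(vals, cents)
  expect_equal(unname(labels["s1"]), "B")
  for (s in colnames(vals)) {
    cors <- apply(cents, 2, cor, y = vals[, s], method = "spearman")
    expect_equal(unname(labels[s]), names(which.max(cors)))
  }
  expect_error(classify_nearest_centroid(vals[1:3, ], cents[1:3, ]), "5 genes")
})
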