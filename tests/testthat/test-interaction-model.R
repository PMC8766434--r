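test_that("nested fit equals cell-mean differences in the balanced case", {
  ## closed-form oracle: with one observation pattern per cell, each
  ## coefficient is a cell-mean contrast per the nesting
  cells <- expand.grid(ph = c("nIBC", "IBC"),
                       er = c("low", "moderate", "high"),
                       rep = 1:10, stringsAsFactors = FALSE)
  means <- c(`nIBC.low` = 8, `nIBC.moderate` = 7.2, `nIBC.high` = 7,
             `IBC.low` = 7.5, `IBC.moderate` = 7.9, `IBC.high` = 8.4)
  y <- means[paste(cells$ph, cells$er, sep = ".")]
  fit <- suppressWarnings(fit_nested_interaction(y, cells$ph, cells$er))
  expect_equal(unname(fit$coefficients["nIBC:ERmod"]),
               means[["nIBC.moderate"]] - means[["nIBC.low"]], tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["nIBC:ERhigh"]),
               means[["nIBC.high"]] - means[["nIBC.low"]], tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["IBC:ERlow"]),
               means[["IBC.low"]] - means[["nIBC.low"]], tolerance = 1e-9)
  ## IBC ER coefficients are increments over IBC/ER-low
  expect_equal(unname(fit$coefficients["IBC:ERmod"]),
               means[["IBC.moderate"]] - means[["IBC.low"]], tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["IBC:ERhigh"]),
               means[["IBC.high"]] - means[["IBC.low"]], tolerance = 1e-9)

  ## empty cell errors with its name
  keep <- !(cells$ph == "IBC" & cells$er == "high")
  expect_error(fit_nested_interaction(y[keep], cells$ph[keep], cells$er[keep]),
               "IBC/high")
})

test_that("generator coefficients are recovered exactly at zero noise", {
  co <- generate_patient_cohort(cohort_spec(noise_sd = 0, seed = 13))
  fit <- suppressWarnings(fit_nested_interaction(co$MYC, co$phenotype, co$er_stratum))
  expect_equal(unname(fit$coefficients),
               c(-0.754, -0.931, -0.832, 0.599, 1.414), tolerance = 1e-6)
})

test_that("coefficients fall within 2 SE of truth across seeds at default noise", {
  truth <- c(-0.754, -0.931, -0.832, 0.599, 1.414)
  hits <- matrix(FALSE, 40, 5)
  for (s in 1:40) {
    co <- generate_patient_cohort(cohort_spec(seed = s))
    fit <- fit_nested_interaction(co$MYC, co$phenotype, co$er_stratum)
    hits[s, ] <- abs(fit$coefficients - truth) <= 2 * fit$se
  }
  ## per-coefficient coverage ~95%; require >= 90%
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("null responses give uniform p-values", {
  ps <- t(vapply(1:60, function(s) {
    co <- generate_patient_cohort(cohort_spec(
      coef_nibc_er_mod = 0, coef_nibc_er_high = 0, coef_ibc_er_low = 0,
      coef_ibc_er_mod = 0, coef_ibc_er_high = 0, seed = s))
    fit_nested_interaction(co$MYC, co$phenotype, co$er_stratum)$p
  }, numeric(5)))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("blocking variables behave: independent blocks shift estimates little", {
  co <- generate_patient_cohort(cohort_spec(seed = 17))
  block <- withr::with_seed(18, sample(c("u", "v", "w"), nrow(co), TRUE))
  res <- fit_with_blocking(co$MYC, co$phenotype, co$er_stratum, block)
  shift <- abs(res$fit$coefficients - res$unblocked_fit$coefficients)
  expect_lt(max(shift), 0.05)
  expect_true(all(res$retention$sign_retained))
  expect_gte(res$lrt$p, 0)

  ## blocking factor duplicating phenotype triggers the aliasing path
  expect_warning(
    res2 <- fit_with_blocking(co$MYC, co$phenotype, co$er_stratum, co$phenotype),
    "aliased")
  expect_error(fit_with_blocking(co$MYC, co$phenotype, co$er_stratum,
                                 rep("z", nrow(co))), "constant")
})

test_that("blocking removes planted confounding through the subtype", {
  truth <- c(-0.754, -0.931, -0.832, 0.599, 1.414)
  hits <- matrix(FALSE, 40, 5)
  for (s in 1:40) {
    co <- generate_patient_cohort(cohort_spec(seed = s))
    ## plant a subtype effect on the response: confounds the ER effects
    ## because subtype frequencies depend on the ER stratum
    bump <- c(LumA = 1.2, LumB = 0.6, Her2 = 0, Basal = -0.6)
    y <- co$MYC + bump[co$subtype]
    blocked <- suppressWarnings(
      fit_with_blocking(y, co$phenotype, co$er_stratum, co$subtype))
    hits[s, ] <- abs(blocked$fit$coefficients - truth) <= 2 * blocked$fit$se
  }
  ## per-coefficient coverage after blocking
  expect_true(all(colMeans(hits) >= 0.9))
  ## and the unblocked fit is visibly biased on at least one ER term
  co <- generate_patient_cohort(cohort_spec(seed = 4))
  bump <- c(LumA = 1.2, LumB = 0.6, Her2 = 0, Basal = -0.6)
  y <- co$MYC + bump[co$subtype]
  un <- fit_nested_interaction(y, co$phenotype, co$er_stratum)
  expect_gt(max(abs(un$coefficients - truth)), 0.2)
})

test_that("PMN correlations hit exact limits and simulation targets", {
  set.seed(19)
  myc <- rnorm(60)
  members <- rbind(same = myc, flip = -myc, noise = rnorm(60))
  rep_ <- pmn_correlations(members, myc)
  rho <- setNames(rep_$vs_myc$rho, rep_$vs_myc$member)
  expect_equal(unname(rho["same"]), 1)
  expect_equal(unname(rho["flip"]), -1)
  expect_lt(rep_$vs_myc$p[rep_$vs_myc$member == "same"], 1e-10)

  ## constant member reported as missing
  members2 <- rbind(members, flat = rep(1, 60))
  rep2 <- pmn_correlations(members2, myc)
  expect_true(is.na(rep2$vs_myc$rho[rep2$vs_myc$member == "flat"]))

  ## cohort targets recovered within 0.15 at n = 146
  co <- generate_patient_cohort(cohort_spec(n_ibc = 146, n_nibc = 252, seed = 23))
  ibc <- co[co$phenotype == "IBC", ]
  mem <- t(as.matrix(ibc[, c("MAX", "MXD3")]))
  rep3 <- pmn_correlations(mem, ibc$MYC, activity = ibc$activity)
  rho3 <- setNames(rep3$vs_myc$rho, rep3$vs_myc$member)
  expect_lt(abs(rho3[["MAX"]] - 0.4), 0.15)
  expect_lt(abs(rho3[["MXD3"]] - (-0.4)), 0.15)
  expect_false(is.null(rep3$vs_activity))
})

test_that("activity outlier flags follow the strict 90th-percentile rule", {
  set.seed(20)
  myc <- rnorm(100)
  activity <- 0.8 * myc + rnorm(100, sd = 0.4)
  cand <- matrix(rnorm(200), 2, 100, dimnames = list(c("MXD3", "MYCN"), NULL))
  res <- flag_activity_outliers(myc, activity, cand)
  expect_equal(unname(colSums(res$flags)), c(10, 10))  # exactly 10 of 100
  ## all-equal candidate -> none flagged
  res0 <- flag_activity_outliers(myc, activity, rbind(flat = rep(2, 100)))
  expect_equal(sum(res0$flags), 0)
  expect_warning(flag_activity_outliers(myc[1:8], activity[1:8],
                                        rbind(x = rnorm(8))), "unstable")
})

test_that("planted outlier subpopulations enrich among positive residuals", {
  hits <- vapply(1:30, function(s) {
    dat <- withr::with_seed(s, {
      n <- 150
      myc <- rnorm(n)
      cand <- rnorm(n)
      act <- 0.8 * myc + rnorm(n, sd = 0.3)
      out_idx <- sample(n, 12)
      cand[out_idx] <- cand[out_idx] + 3   # high candidate
      act[out_idx] <- act[out_idx] + 1.5   # high activity at the same MYC
      list(myc = myc, act = act, cand = cand)
    })
    res <- flag_activity_outliers(dat$myc, dat$act, rbind(C = dat$cand))
    flagged <- which(res$flags[, "C"])
    pos <- which(res$residuals > 0)
    ora <- ora_hypergeometric(as.character(flagged), as.character(pos),
                              as.character(seq_along(dat$myc)))
    ora$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
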