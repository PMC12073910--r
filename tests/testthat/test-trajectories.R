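make_table <- function(est, at_lb = FALSE, valid = TRUE,
                       region = "cerebellum", metabolite = "tNAA",
                       model = "astrosticks", parameter = "Dintra",
                       ages = NULL) {
  n <- length(est)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             age = if (is.null(ages)) seq(25, 80, length.out = n) else ages,
             sex = "F", region = region, metabolite = metabolite,
             model = model, parameter = parameter, estimate = est,
             stderr = 0.01, at_lower_bound = rep_len(at_lb, n),
             valid = rep_len(valid, n), n_points = 6L,
             stringsAsFactors = FALSE)
}

test_that("lower-bound exclusion removes exactly the flagged rows", {
  tab <- make_table(runif(24, 0.3, 0.4))
  tab$at_lower_bound[c(2, 7, 19)] <- TRUE
  out <- exclude_at_bound(tab)
  expect_equal(nrow(out$table), 21)
  expect_equal(nrow(out$log), 3)
  expect_setequal(out$log$subject_id, sprintf("S%03d", c(2, 7, 19)))
  expect_true(all(out$log$reason == "at lower bound"))
  # no flags: identity
  tab2 <- make_table(runif(10, 0.3, 0.4))
  out2 <- exclude_at_bound(tab2)
  expect_equal(out2$table, tab2)
  expect_equal(nrow(out2$log), 0)
  # invalid fits are excluded too, with their own reason
  tab3 <- make_table(runif(5, 0.3, 0.4))
  tab3$valid[2] <- FALSE
  out3 <- exclude_at_bound(tab3)
  expect_equal(out3$log$reason, "invalid or failed fit")
})

test_that("univariate OLS matches the hand-computed normal equations", {
  y <- c(1, 2, 2, 3)
  x <- c(30, 40, 60, 70)
  tr <- linear_trajectory(y, x, grid_n = 10)
  oracle <- ols_oracle(y, x)
  expect_equal(tr$slope, oracle$slope, tolerance = 1e-10)   # 0.04
  expect_equal(tr$intercept, oracle$intercept, tolerance = 1e-10)  # 0
  expect_equal(tr$slope_se, oracle$se, tolerance = 1e-10)
  expect_equal(tr$slope_p, oracle$p, tolerance = 1e-10)
  expect_equal(tr$slope, 0.04)
  expect_equal(tr$intercept, 0)

  # exact line: slope recovered, p essentially zero
  ages <- seq(25, 70, by = 5)
  tr2 <- linear_trajectory(0.1 + 0.001 * ages, ages)
  expect_equal(tr2$slope, 0.001, tolerance = 1e-12)
  expect_lt(tr2$slope_p, 1e-10)

  # constant response: zero slope, p = 1
  tr3 <- linear_trajectory(rep(2, 8), seq(25, 60, by = 5))
  expect_equal(tr3$slope, 0, tolerance = 1e-12)
  expect_equal(tr3$slope_p, 1, tolerance = 1e-6)

  # too few points
  expect_false(linear_trajectory(c(1, 2), c(30, 40))$analyzable)
})

test_that("prediction band contains the confidence band pointwise", {
  withr::with_seed(8, {
    y <- 0.3 + 0.001 * seq(25, 80, length.out = 20) + rnorm(20, 0, 0.02)
  })
  tr <- linear_trajectory(y, seq(25, 80, length.out = 20))
  expect_true(all(tr$bands$pred_lo <= tr$bands$conf_lo))
  expect_true(all(tr$bands$pred_hi >= tr$bands$conf_hi))
  expect_equal(nrow(tr$bands), 100)
})

test_that("covariate regression isolates age from tissue composition", {
  withr::with_seed(11, {
    ages <- runif(25, 25, 80)
    fgmfwm <- runif(25, 4, 9)  # uncorrelated with age
    y <- 0.4 - 0.002 * ages + rnorm(25, 0, 0.01)
    cv <- covariate_regression(y, ages, fgmfwm)
    expect_true(cv$analyzable)
    expect_lt(cv$p[["age"]], 0.01)
    expect_gt(cv$p[["fgmfwm"]], 0.05)
    # response driven by the covariate only: age coefficient near zero
    y2 <- 0.1 * fgmfwm + rnorm(25, 0, 0.001)
    cv2 <- covariate_regression(y2, ages, fgmfwm)
    expect_lt(abs(cv2$coef[["age"]]), 1e-3)
    expect_lt(cv2$p[["fgmfwm"]], 1e-10)
  })
  # duplicate regressor: collinear design reported, not fitted
  ages <- seq(25, 80, length.out = 10)
  cv3 <- covariate_regression(ages * 0.01, ages, ages)
  expect_false(cv3$analyzable)
  expect_true(is.finite(cv3$condition_number))
})

test_that("group t-test matches the Welch oracle and splits at age 50", {
  out <- group_ttest(c(1, 2, 3, 2, 3, 4), c(30, 40, 45, 55, 60, 70))
  oracle <- welch_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$t, oracle$t, tolerance = 1e-10)
  expect_equal(out$df, oracle$df, tolerance = 1e-10)
  expect_equal(out$p, oracle$p, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  out2 <- group_ttest(rep(c(1, 2), 4), c(30, 35, 40, 45, 55, 60, 65, 70))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)

  # age exactly 50 belongs to the older group
  out3 <- group_ttest(c(1, 2, 3, 4, 5), c(30, 40, 50, 60, 70))
  expect_equal(out3$young$n, 2)
  expect_equal(out3$old$n, 3)

  # an empty group is not analyzable
  expect_false(group_ttest(c(1, 2, 3), c(30, 35, 40))$analyzable)

  # pooled variant matches stats::t.test with var.equal
  a <- c(1, 2, 3); b <- c(2, 3, 4, 5)
  outp <- group_ttest(c(a, b), c(30, 35, 40, 55, 60, 65, 70),
                      pooled = TRUE)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(outp$p, ref$p.value, tolerance = 1e-12)
})

test_that("Bonferroni threshold is alpha/m with strict comparison", {
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_threshold(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("the suite grid is complete, ordered, and order-invariant", {
  withr::with_seed(21, {
    tabs <- lapply(c("tNAA", "tCho"), function(met) {
      do.call(rbind, lapply(c("cerebellum", "PCC"), function(rg) {
        make_table(runif(12, 0.3, 0.5), region = rg, metabolite = met)
      }))
    })
    tab <- do.call(rbind, tabs)
    fr <- data.frame(subject_id = rep(sprintf("S%03d", 1:12), 2),
                     region = rep(c("cerebellum", "PCC"), each = 12),
                     fgm_fwm = runif(24, 4, 9))
    s1 <- run_trajectory_suite(tab, fr)
    expect_equal(nrow(s1$grid), 4)
    expect_equal(s1$threshold, 0.05 / 4)  # 2 regions x 2 metabolites here
    # shuffling input rows changes nothing
    s2 <- run_trajectory_suite(tab[sample(nrow(tab)), ], fr)
    expect_equal(s1$grid, s2$grid)
  })
})

test_that("excluded rows never influence any statistic", {
  withr::with_seed(33, {
    tab <- make_table(runif(24, 0.3, 0.5))
    fr <- data.frame(subject_id = tab$subject_id, region = "cerebellum",
                     fgm_fwm = runif(24, 4, 9))
    tab2 <- tab
    tab2$at_lower_bound[c(3, 11)] <- TRUE
    tab2$estimate[c(3, 11)] <- 1e6   # absurd values in flagged rows
    ref <- run_trajectory_suite(tab[-c(3, 11), ], fr)
    got <- run_trajectory_suite(tab2, fr)
    expect_equal(got$grid$slope, ref$grid$slope, tolerance = 1e-12)
    expect_equal(got$grid$t_p, ref$grid$t_p, tolerance = 1e-12)
    expect_equal(got$grid$n_used, ref$grid$n_used)
    expect_equal(got$grid$n_excluded, c(2))
  })
})

test_that("engineered at-bound concentration shows up in cell bookkeeping", {
  withr::with_seed(44, {
    est <- runif(24, 0, 0.2)
    at <- rep(c(TRUE, FALSE), 12)   # half the Kintra column at bound
    tab <- make_table(est, model = "mod_astrosticks", parameter = "Kintra")
    tab$at_lower_bound <- at
    fr <- data.frame(subject_id = tab$subject_id, region = "cerebellum",
                     fgm_fwm = runif(24, 4, 9))
    s <- run_trajectory_suite(tab, fr)
    expect_equal(s$grid$n_used, 12)
    expect_equal(s$grid$n_excluded, 12)
    expect_true(all(s$exclusions$parameter == "Kintra"))
  })
})

test_that("type-I error of the slope test is nominal under the null", {
  # estimates fluctuate around a constant; no age effect
  withr::with_seed(55, {
    hits <- replicate(400, {
      ages <- runif(25, 25, 80)
      y <- 0.35 * (1 + rnorm(25, 0, 0.05))
      linear_trajectory(y, ages)$slope_p < 0.05
    })
  })
  expect_lt(abs(mean(hits) - 0.05), 2.5 * sqrt(0.05 * 0.95 / 400))
})
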