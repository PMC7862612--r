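# Factorial linear model: design matrix, OLS fit, Wald contrasts, LOEC.

test_that("design matrix has the indicator-coding column structure", {
  # degenerate design: 1 fish, 2 times, 2 LPS, control only -> 4 columns
  cells <- expand.grid(fish_id = "F1", time = c("3h", "19h"),
                       lps = c("no", "yes"), concentration = 0,
                       stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells))
  dm <- suppressMessages(build_design_matrix(cells))
  expect_equal(colnames(dm$X),
               c("(Intercept)", "time:19h", "lps:yes", "time:lps"))
  # 7 fish, 2 x 2, three non-control concentrations -> 19 columns:
  # 1 + 6 + 1 + 1 + 3 + 1 + 3 + 3
  d <- make_design(n_fish = 7, concs = c(0, 1, 5, 10), n_technical = 1)
  p <- make_params(d, residual_sd = 0.3)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 1))
  dm7 <- build_design_matrix(avg)
  expect_equal(ncol(dm7$X), 19)
  expect_true(all(dm7$X %in% c(0, 1)))
  # complete balanced design is full column rank (independent check via svd)
  sv <- svd(dm7$X)$d
  expect_equal(sum(sv > max(sv) * 1e-10), ncol(dm7$X))
})

test_that("duplicate treatment rows are rejected", {
  cells <- data.frame(fish_id = "F1", time = "3h", lps = "no",
                      concentration = 0, value = c(1, 2))
  expect_error(build_design_matrix(cells), "duplicate")
})

test_that("noise-free data are interpolated exactly", {
  d <- make_design(n_fish = 5, concs = c(0, 1, 5, 10))
  p <- make_params(d, residual_sd = 0, technical_sd = 0)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 1))
  fit <- fit_immune_lm(avg)
  expect_equal(unname(fit$residuals), rep(0, nrow(avg)))
  bt <- true_beta(d, p)
  expect_equal(fit$coefficients[names(bt)], bt)
})

test_that("OLS matches a normal-equations brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    d <- make_design(n_fish = sample(3:7, 1),
                     concs = c(0, sort(sample(c(1, 2, 5, 10, 20), 3))))
    p <- rand_params(d, residual_sd = 0.7)
    avg <- average_technical_replicates(simulate_assay(d, p, seed = rep))
    dm <- build_design_matrix(avg)
    fit <- fit_immune_lm(dm)
    # independent solver: explicit normal equations
    XtX <- crossprod(dm$X)
    beta_orc <- drop(solve(XtX, crossprod(dm$X, dm$y)))
    expect_equal(unname(fit$coefficients), unname(beta_orc), tolerance = 1e-8)
    rss <- sum((dm$y - dm$X %*% beta_orc)^2)
    expect_equal(fit$sigma2, rss / (nrow(dm$X) - ncol(dm$X)),
                 tolerance = 1e-10)
    expect_equal(unname(fit$cov), unname(fit$sigma2 * solve(XtX)),
                 tolerance = 1e-8)
  }
})

test_that("fit matches the reference lm implementation", {
  set.seed(31)
  d <- make_design(n_fish = 6, concs = c(0, 1, 5, 10))
  p <- rand_params(d, residual_sd = 1)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 31))
  fit <- fit_immune_lm(avg)
  orc <- lm_oracle(avg)
  expect_equal(fit$coefficients[names(orc$coef)], orc$coef, tolerance = 1e-9)
  expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-9)
  expect_equal(fit$df, orc$df)
})

test_that("rank-deficient designs alias columns without changing the projection", {
  d <- make_design(n_fish = 4, concs = c(0, 1, 5))
  p <- make_params(d, residual_sd = 0.5)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 8))
  dm <- build_design_matrix(avg)
  dm_dup <- dm
  dm_dup$X <- cbind(dm$X, dup = dm$X[, "lps:yes"])
  fit_dup <- fit_immune_lm(dm_dup)
  fit <- fit_immune_lm(dm)
  expect_true("dup" %in% fit_dup$aliased)
  expect_true(is.na(fit_dup$coefficients["dup"]))
  expect_equal(fit_dup$fitted, fit$fitted, tolerance = 1e-10)
  expect_equal(fit_dup$sigma2, fit$sigma2, tolerance = 1e-10)
  # contrasts touching the aliased column are refused
  expect_error(wald_contrast(fit_dup, c(dup = 1)), "aliased")
})

test_that("single-coefficient Wald test equals the classical two-sample t-test", {
  set.seed(41)
  y_no <- rnorm(8, 10, 1)
  y_yes <- rnorm(8, 11, 1)
  # two-group design built directly: intercept + group indicator
  X <- cbind("(Intercept)" = 1, "lps:yes" = rep(c(0, 1), each = 8))
  dm <- structure(list(X = X, y = c(y_no, y_yes),
                       row_meta = data.frame(lps = rep(c("no", "yes"), each = 8)),
                       levels = list(fish = "F1", time = "3h",
                                     lps = c("no", "yes"), conc = 0)),
                  class = "immune_design")
  fit <- fit_immune_lm(dm)
  ct <- wald_contrast(fit, c("lps:yes" = 1))
  tt <- t.test(y_yes, y_no, var.equal = TRUE)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-12)
  expect_equal(ct$estimate, unname(diff(c(mean(y_no), mean(y_yes)))),
               tolerance = 1e-12)
})

test_that("degenerate contrasts are rejected as non-estimable", {
  d <- make_design(n_fish = 3, concs = c(0, 1))
  p <- make_params(d, residual_sd = 0.5)
  fit <- fit_immune_lm(average_technical_replicates(simulate_assay(d, p, 1)))
  expect_error(wald_contrast(fit, rep(0, length(coef(fit)))), "non-estimable")
  expect_error(wald_contrast(fit, c(nonexistent = 1)), "unknown")
})

test_that("standard comparisons reproduce noise-free cell-mean differences", {
  d <- make_design(n_fish = 4, concs = c(0, 1, 5))
  p <- make_params(d, residual_sd = 0, technical_sd = 0)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 1))
  fit <- fit_immune_lm(avg)
  sc <- standard_comparisons(fit)
  cell_mean <- function(time, lps, conc) {
    mean(avg$value[avg$time == time & avg$lps == lps &
                     avg$concentration == conc])
  }
  for (i in seq_len(nrow(sc))) {
    r <- sc[i, ]
    expected <- if (r$comparison == "lps_vs_control") {
      cell_mean(r$time, "yes", 0) - cell_mean(r$time, "no", 0)
    } else if (r$comparison == "conc_vs_control_noLPS") {
      cell_mean(r$time, "no", r$concentration) - cell_mean(r$time, "no", 0)
    } else {
      cell_mean(r$time, "yes", r$concentration) - cell_mean(r$time, "yes", 0)
    }
    expect_equal(r$estimate, expected, tolerance = 1e-10)
  }
  # contrast coding: LPS comparison selects beta_lps at 3 h and adds the
  # time x LPS interaction at 19 h
  expect_equal(sc$estimate[sc$comparison == "lps_vs_control" & sc$time == "3h"],
               p$lps_effect)
  expect_equal(sc$estimate[sc$comparison == "lps_vs_control" & sc$time == "19h"],
               p$lps_effect + p$time_lps_interaction)
})

test_that("LOEC is the smallest significant concentration", {
  mk <- function(p, est = -seq_along(p)) {
    data.frame(concentration = c(1, 5, 10), p = p, estimate = est)
  }
  expect_equal(determine_loec(mk(c(0.2, 0.03, 0.01)))$loec, 5)
  nd <- determine_loec(mk(c(0.2, 0.3, 0.5)))
  expect_false(nd$determinable)
  expect_true(is.na(nd$loec))
  # non-monotone p values: the definition takes the minimum concentration
  expect_equal(determine_loec(mk(c(0.04, 0.5, 0.01)))$loec, 1)
  # direction from the sign of the estimate at the LOEC
  expect_equal(determine_loec(mk(c(0.01, 0.5, 0.5), est = c(2, 1, 1)))$direction,
               "increase")
})

test_that("adding a constant to the response shifts only the intercept", {
  d <- make_design(n_fish = 4, concs = c(0, 1, 5))
  p <- make_params(d, residual_sd = 0.5)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 13))
  fit1 <- fit_immune_lm(avg)
  avg2 <- avg
  avg2$value <- avg$value + 100
  fit2 <- fit_immune_lm(avg2)
  expect_equal(fit2$coefficients["(Intercept)"],
               fit1$coefficients["(Intercept)"] + 100)
  others <- setdiff(names(coef(fit1)), "(Intercept)")
  expect_equal(fit2$coefficients[others], fit1$coefficients[others],
               tolerance = 1e-9)
})

test_that("fit methods expose the usual modelling interface", {
  d <- make_design(n_fish = 3, concs = c(0, 1))
  p <- make_params(d, residual_sd = 0.5)
  avg <- average_technical_replicates(simulate_assay(d, p, seed = 5))
  fit <- fit_immune_lm(avg)
  expect_equal(length(fitted(fit)), nrow(avg))
  expect_equal(fitted(fit) + residuals(fit), avg$value)
  expect_equal(df.residual(fit), nrow(avg) - ncol(model.matrix(fit)))
  expect_equal(unname(predict(fit, avg)), unname(fitted(fit)),
               tolerance = 1e-10)
  st <- summary(fit)
  expect_true(all(st$coefficients[, "Pr(>|t|)"] >= 0 &
                    st$coefficients[, "Pr(>|t|)"] <= 1))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(avg), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
})
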