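test_that("the inclusion rule is visibility plus a strict 677 uA cutoff", {
  expect_true(include_electrode(list(visible = TRUE, threshold_uA = 500)))
  expect_false(include_electrode(list(visible = TRUE, threshold_uA = 677)))
  expect_true(include_electrode(list(visible = TRUE, threshold_uA = 676.9)))
  expect_false(include_electrode(list(visible = FALSE, threshold_uA = 100)))
  expect_true(include_electrode(list(visible = TRUE,
                                     threshold_uA = NA_real_)))
})

test_that("OLS reproduces exact fits and an independent normal-equations oracle", {
  x <- 1:10
  fit <- ols_fit(data.frame(x = x), 2 * x)
  expect_equal(fit$coefficients$estimate, c(0, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  set.seed(11)
  X <- data.frame(a = rnorm(50), b = runif(50), c = rnorm(50, 2))
  y <- 1.5 - 2 * X$a + 0.3 * X$b + rnorm(50)
  fit <- ols_fit(X, y)
  M <- cbind(1, as.matrix(X))
  beta_oracle <- solve(t(M) %*% M) %*% t(M) %*% y
  expect_equal(fit$coefficients$estimate, drop(beta_oracle),
               tolerance = 1e-10, ignore_attr = TRUE)
  # cross-check inference against the reference linear-model fit
  lmf <- summary(lm(y ~ a + b + c, data = X))
  expect_equal(fit$coefficients$se, unname(lmf$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, lmf$r.squared, tolerance = 1e-12)
  expect_equal(fit$p_value,
               unname(pf(lmf$fstatistic[1], lmf$fstatistic[2],
                         lmf$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("OLS rejects missing data and collinear designs by name", {
  expect_error(ols_fit(data.frame(x = c(1, NA, 3)), 1:3), "missing")
  X <- data.frame(x = 1:10, twice_x = 2 * (1:10))
  expect_error(ols_fit(X, rnorm(10)), "twice_x")
  expect_error(ols_fit(data.frame(x = 1:2), 1:2), "n >")
})

test_that("planted generator coefficients are recovered exactly without noise", {
  pat <- generate_synthetic_patient(60, seed = 8, coef = list(noise_sd = 0))
  fit <- ols_fit(pat[c("erd_um", "thickness_um")], pat$threshold_uA)
  expect_equal(fit$coefficients$estimate, c(200, 0.9, -0.5),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("multiple regression R^2 dominates single predictors", {
  pat <- generate_synthetic_patient(60, seed = 3)
  preds <- c("erd_um", "thickness_um", "impedance_kohm")
  single <- vapply(preds, function(p)
    ols_fit(pat[p], pat$threshold_uA)$r_squared, numeric(1))
  multi <- ols_fit(pat[preds], pat$threshold_uA)$r_squared
  expect_gte(multi, max(single) - 1e-12)
})

test_that("p-values are uniform under the null", {
  set.seed(99)
  pv <- replicate(1000, {
    x <- rnorm(20); y <- rnorm(20)
    ols_fit(data.frame(x = x), y)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("predicted-versus-perceptual regression recovers planted slopes", {
  pred <- data.frame(electrode = paste0("A", 1:12),
                     min_threshold_uA = seq(10, 120, by = 10))
  meas <- data.frame(label = paste0("A", 1:12),
                     threshold_uA = seq(10, 120, by = 10),
                     visible = TRUE, stringsAsFactors = FALSE)
  fit <- compare_predicted_vs_perceptual(pred, meas)
  expect_equal(fit$coefficients$estimate[2], 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$significant)

  set.seed(21)
  meas2 <- meas
  meas2$threshold_uA <- 3 * pred$min_threshold_uA + rnorm(12, 0, 5)
  fit2 <- compare_predicted_vs_perceptual(pred, meas2)
  est <- fit2$coefficients$estimate[2]
  se <- fit2$coefficients$se[2]
  expect_lt(abs(est - 3), 3 * se)

  meas3 <- meas
  meas3$label <- paste0("Z", 1:12)
  expect_error(compare_predicted_vs_perceptual(pred, meas3), "matched")
  expect_error(compare_predicted_vs_perceptual(pred, meas[1:2, ]),
               "matched")
})
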