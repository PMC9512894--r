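gen_under <- function(form, noise_sd = 0, seed = 1) {
  gen_field_trace(universal_profile(), linear_cooling(0.5),
                  noise_sd = noise_sd, q10 = form$q10,
                  decline = form$decline$enabled, seed = seed)
}

test_that("each formulation is self-consistent and distinguishable", {
  forms <- all_formulations()
  rmse <- sapply(forms, function(gen_f) {
    tr <- gen_under(gen_f)
    obs <- tr$respiration / tr$respiration[1]
    vapply(forms, function(fit_f)
      one_to_one_stats(simulate_trace(tr, fit_f), obs)$rmse, numeric(1))
  })
  # generator on the diagonal: exact; everything else: measurably wrong
  for (nm in names(forms)) {
    expect_lt(rmse[nm, nm], 1e-12)
    expect_true(all(rmse[setdiff(names(forms), nm), nm] > 1e-4))
  }
})

test_that("the prediction anchors at 1 and tracks the drivers", {
  tr <- gen_under(formulation("new"))
  for (f in all_formulations()) {
    expect_equal(simulate_trace(tr, f)[1], 1)
  }
  # constant-temperature trace: the standard model predicts a flat 1
  flat <- gen_field_trace(universal_profile(), constant_night(), noise_sd = 0,
                          seed = 2)
  expect_equal(simulate_trace(flat, formulation("standard")),
               rep(1, nrow(flat)))
  # cooling trace, temperature-dependent Q10: the pure TDQ10 curve
  pred <- simulate_trace(tr, formulation("standard-modified"))
  expect_equal(pred, tdq10(tr$temperature_C)^
                 (0.1 * (tr$temperature_C - tr$temperature_C[1])),
               tolerance = 1e-12)
  bad <- tr; bad$temperature_C[3] <- NA
  expect_error(simulate_trace(bad, formulation("new")), "temperature")
})

test_that("one-to-one regression statistics match their contracts", {
  obs <- c(1, 0.95, 0.9, 0.82, 0.77, 0.7)
  s <- one_to_one_stats(obs, obs)
  expect_equal(s$slope, 1)
  expect_equal(s$r_squared, 1)
  expect_equal(s$rmse, 0)
  s2 <- one_to_one_stats(obs + 0.1, obs)
  expect_equal(s2$slope, 1)
  expect_equal(s2$rmse, 0.1)
  expect_equal(s2$intercept, 0.1)
  expect_equal(s$n, length(obs) - 1)  # first point excluded
  expect_error(one_to_one_stats(obs, rep(1, 6)), "zero variance")
  expect_error(one_to_one_stats(obs[1:3], obs[1:3]), "3 paired")
})

test_that("the merged formulation beats the standard model on declining nights", {
  rmse_gap <- vapply(1:10, function(s) {
    tr <- gen_under(formulation("new"), noise_sd = 0.03, seed = s)
    obs <- tr$respiration / tr$respiration[1]
    std <- one_to_one_stats(simulate_trace(tr, formulation("standard")), obs)
    new <- one_to_one_stats(simulate_trace(tr, formulation("new")), obs)
    std$rmse - new$rmse
  }, numeric(1))
  expect_true(all(rmse_gap > 0))
})

test_that("standardized residuals implement the documented formula", {
  obs <- c(1, 0.9, 0.8, 0.75, 0.7)
  expect_identical(standardized_residuals(obs, obs), rep(0, 5))
  # single non-zero residual among zeros scales to sqrt(N - 1)
  pred <- obs; pred[3] <- obs[3] + 0.2
  s <- standardized_residuals(pred, obs)
  expect_equal(s[3], sqrt(4))
  expect_equal(s[-3], rep(0, 4))
  neg <- obs; neg[4] <- obs[4] - 0.1
  expect_equal(standardized_residuals(neg, obs)[4], -sqrt(4))
  # the normalization is idempotent: unanchored series give the same result
  expect_equal(standardized_residuals(2.5 * pred, 2.5 * obs), s)
  # explicit df is honoured
  expect_equal(standardized_residuals(pred, obs, df = 5)[3], sqrt(5))
})

test_that("standardized residuals show no trend when the model is right", {
  tr <- gen_under(formulation("new"), noise_sd = 0.03, seed = 12)
  obs <- tr$respiration / tr$respiration[1]
  s <- standardized_residuals(simulate_trace(tr, formulation("new")), obs)
  trend <- stats::coef(stats::lm(s ~ tr$h))[2]
  expect_lt(abs(trend), 0.1)
})

test_that("Taylor statistics satisfy the Taylor identity", {
  obs <- c(1, 0.9, 0.85, 0.8, 0.72)
  t1 <- taylor_stats(obs, obs)
  expect_equal(t1$correlation, 1)
  expect_equal(t1$sd_ratio, 1)
  expect_equal(t1$crms, 0)
  t2 <- taylor_stats(2 * obs, obs)
  expect_equal(t2$correlation, 1)
  expect_equal(t2$sd_ratio, 2)
  set.seed(8)
  for (i in 1:20) {
    p <- rnorm(15); o <- rnorm(15)
    ts <- taylor_stats(p, o)
    expect_equal(ts$crms^2,
                 ts$sd_pred^2 + ts$sd_obs^2 -
                   2 * ts$sd_pred * ts$sd_obs * ts$correlation,
                 tolerance = 1e-12)
  }
  expect_error(taylor_stats(rep(1, 5), obs), "zero variance")
})

test_that("the anchor point inflates apparent fit quality, so excluding it is conservative", {
  gap <- vapply(1:20, function(s) {
    tr <- gen_under(formulation("new"), noise_sd = 0.05, seed = s)
    obs <- tr$respiration / tr$respiration[1]
    pred <- simulate_trace(tr, formulation("new"))
    one_to_one_stats(pred, obs, exclude_first = FALSE)$r_squared -
      one_to_one_stats(pred, obs, exclude_first = TRUE)$r_squared
  }, numeric(1))
  # the exact (1, 1) anchor pair raises R^2 on average; excluding it never
  # helps by more than sampling noise
  expect_gt(mean(gap), 0)
  expect_lt(max(-gap), 0.05)
})

test_that("the evaluation report collects all four formulations", {
  tr <- gen_under(formulation("new"), noise_sd = 0.02, seed = 3)
  ev <- evaluate_formulations(tr)
  expect_s3_class(ev, "resp_eval")
  expect_equal(nrow(ev$table), 4)
  expect_setequal(ev$table$formulation,
                  c("standard", "standard-modified", "new", "new-modified"))
  best <- ev$table$formulation[which.min(ev$table$rmse)]
  expect_equal(best, "new")
  expect_output(print(ev), "Formulation evaluation")
})
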