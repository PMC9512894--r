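toy_trace <- function(h, resp, temp = 25) {
  structure(data.frame(timestamp = as.POSIXct("2022-01-01", tz = "UTC") +
                         h * 3600,
                       species = "toy", replicate = "r1", condition = "lab",
                       growth_form = "tree", biome = "temperate",
                       scale = "leaf", h = h, temperature_C = temp,
                       respiration = resp),
            class = c("resp_trace", "data.frame"))
}

test_that("normalization drops the exclusion window and anchors at 1", {
  tr <- toy_trace(c(0.2, 0.6, 1.2), c(3, 2, 1.5))
  nz <- normalize_trace(tr, exclusion_min = 30)
  expect_equal(nz$h, c(0.6, 1.2))
  expect_equal(nz$ratio, c(1, 0.75))
  nz0 <- normalize_trace(tr, exclusion_min = 0)
  expect_equal(nz0$ratio, c(1, 2 / 3, 0.5))
  expect_error(normalize_trace(toy_trace(0.1, 2), exclusion_min = 30),
               "exclusion window")
})

test_that("the exclusion window makes LEDR-contaminated traces clean", {
  pr <- universal_profile()
  on_ <- gen_lab_trace(pr, sampling = 6, noise_sd = 0, ledr = TRUE, seed = 4)
  off <- gen_lab_trace(pr, sampling = 6, noise_sd = 0, ledr = FALSE, seed = 4)
  expect_equal(normalize_trace(on_, 30)$ratio, normalize_trace(off, 30)$ratio,
               tolerance = 1e-12)
})

test_that("hourly binning averages within [k, k+1) and keeps the sampled hours", {
  tr <- toy_trace(c(2.1, 2.5, 2.9, 4.2), c(1, 1, 1, 1))
  tr <- normalize_trace(tr, 0)
  tr$ratio <- c(0.8, 0.9, 1.0, 0.7)
  b <- bin_hourly(tr)
  expect_equal(b$bin, c(2, 4))
  expect_equal(b$h, c(2.5, 4.5))
  expect_equal(b$ratio, c(0.9, 0.7))
  expect_equal(b$n, c(3L, 1L))
  expect_equal(b$h_samples[[1]], c(2.1, 2.5, 2.9))
  expect_error(bin_hourly(toy_trace(1, 2)), "normalize_trace")
})

test_that("sub-hourly and hourly sampling of the same curve agree after binning", {
  pr <- universal_profile()
  fine <- bin_hourly(normalize_trace(
    gen_lab_trace(pr, sampling = 3, noise_sd = 0, seed = 1), 0))
  coarse <- bin_hourly(normalize_trace(
    gen_lab_trace(pr, sampling = 60, noise_sd = 0, seed = 1), 0))
  joint <- merge(fine, coarse, by = "bin")
  keep <- joint$bin >= 1
  expect_lt(max(abs(joint$ratio.x - joint$ratio.y)[keep]), 0.03)
})

test_that("species aggregation computes mean, SEM and counts", {
  b1 <- data.frame(bin = 2, h = 2.5, ratio = 0.8, n = 1L,
                   h_samples = I(list(2.5)))
  b2 <- data.frame(bin = 2, h = 2.5, ratio = 1.0, n = 1L,
                   h_samples = I(list(2.5)))
  agg <- aggregate_species(list(b1, b2), species = "sp")
  expect_equal(agg$mean_ratio, 0.9)
  expect_equal(agg$sem, 0.1)
  expect_equal(agg$n_rep, 2L)
  one <- aggregate_species(list(b1), species = "sp")
  expect_equal(one$mean_ratio, 0.8)
  expect_identical(one$sem, 0)
})

test_that("the noiseless pipeline reproduces the generating curve", {
  pr <- universal_profile(replicate_cv = 0.1)
  traces <- lapply(1:3, function(i)
    gen_lab_trace(pr, sampling = 6, noise_sd = 0,
                  replicate = paste0("r", i), seed = i))
  agg <- aggregate_dataset(traces, exclusion_min = 0)
  # each bin mean equals the within-bin average of the decline curve
  for (i in seq_len(nrow(agg))) {
    hs <- agg$h_samples[[i]][[1]]
    expect_equal(agg$mean_ratio[i], mean(decline_fraction(hs)),
                 tolerance = 1e-12)
  }
  expect_true(all(agg$sem < 1e-12))
})

test_that("log-linearization recovers the exponent of an exact power law", {
  agg <- curve_aggregate(a = 0.05, b = 0.7)
  sl <- linearize_and_slope(agg)
  expect_equal(sl$slope, 0.7, tolerance = 1e-2)
  expect_equal(sl$n, nrow(agg))
  # constant ratios linearize to slope zero
  flat <- curve_aggregate(a = 0, b = 0.5)
  flat$mean_ratio <- rep(0.9, nrow(flat))
  expect_equal(linearize_and_slope(flat)$slope, 0, tolerance = 1e-10)
  # ratios at/above one are dropped with a warning
  up <- curve_aggregate(a = 0.05, b = 0.7)
  up$mean_ratio[3] <- 1.01
  expect_warning(linearize_and_slope(up), "dropped")
})

test_that("slope standard errors shrink roughly as 1/sqrt(replicates)", {
  se_for <- function(n_rep, seed) {
    pr <- universal_profile(replicate_cv = 0)
    traces <- lapply(seq_len(n_rep), function(i)
      gen_lab_trace(pr, sampling = 20, noise_sd = 0.05,
                    replicate = paste0("r", i), seed = seed * 1000 + i))
    suppressWarnings(
      linearize_and_slope(aggregate_dataset(traces, exclusion_min = 0))$se)
  }
  r <- vapply(1:12, function(s) se_for(4, s) / se_for(16, s), numeric(1))
  expect_gt(median(r), 1.2)
  expect_lt(median(r), 3.5)
})

test_that("Welch test matches its contract", {
  same <- c(-0.2, -0.21, -0.19, -0.2)
  w <- welch_test(same, same)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  a <- c(-0.25, -0.22, -0.20, -0.24, -0.18)
  b <- c(-0.15, -0.18, -0.12, -0.20, -0.16, -0.17)
  w2 <- welch_test(a, b)
  # Welch-Satterthwaite df lies between min(n)-1 and n1+n2-2
  expect_gte(w2$df, min(length(a), length(b)) - 1)
  expect_lte(w2$df, length(a) + length(b) - 2)
  expect_error(welch_test(-0.2, c(-0.1, -0.2)), "two slopes")
  expect_error(welch_test(rep(0.5, 3), rep(0.5, 4)), "constant")
})

test_that("pairwise slope tests count comparisons like the grouped design", {
  k <- 31
  slopes <- rep(-0.2, k); ses <- rep(0.02, k); ns <- rep(10, k)
  partitions <- list(rep(c("lab", "field"), c(15, 16)),
                     rep(c("tree", "herb"), c(13, 18)),
                     rep(c("temperate", "tropical"), c(11, 20)))
  m_total <- sum(vapply(partitions, function(g)
    pairwise_slope_tests(slopes, ses, ns, groups = g)$m, numeric(1)))
  expect_equal(m_total, 701)
  # identical slopes are never significant
  res <- pairwise_slope_tests(slopes, ses, ns)
  expect_equal(res$n_significant, 0)
  expect_equal(res$m, choose(31, 2))
})

test_that("Bonferroni keeps the family-wise error in check under the null", {
  set.seed(99)
  fwer <- mean(replicate(300, {
    slopes <- rnorm(31, -0.2, 0.02)
    ses <- rep(0.02, 31)
    m <- sum(vapply(list(rep(1:2, c(15, 16)), rep(1:2, c(13, 18)),
                         rep(1:2, c(11, 20))),
                    function(g) pairwise_slope_tests(slopes, ses, rep(10, 31),
                                                     groups = g)$n_significant,
                    numeric(1)))
    m > 0
  }))
  expect_lt(fwer, 0.1)
})
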