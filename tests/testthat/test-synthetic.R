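test_that("noiseless lab traces reproduce the decline curve exactly", {
  pr <- universal_profile()
  tr <- gen_lab_trace(pr, noise_sd = 0, seed = 11)
  ratio <- tr$respiration / tr$respiration[1]
  expect_equal(ratio, decline_fraction(tr$h), tolerance = 1e-12)
  expect_equal(ratio[tr$h == 8], 0.75409997, tolerance = 1e-7)
  expect_true(all(tr$temperature_C == 25))
})

test_that("a zero decline scale gives a constant trace", {
  tr <- gen_lab_trace(universal_profile(a = 0), noise_sd = 0, seed = 3)
  expect_true(all(tr$respiration == tr$respiration[1]))
})

test_that("generators are pure functions of parameters and seed", {
  pr <- universal_profile()
  expect_identical(gen_lab_trace(pr, seed = 5), gen_lab_trace(pr, seed = 5))
  expect_false(isTRUE(all.equal(gen_lab_trace(pr, seed = 5)$respiration,
                                gen_lab_trace(pr, seed = 6)$respiration)))
  sch <- linear_cooling()
  expect_identical(gen_field_trace(pr, sch, seed = 5),
                   gen_field_trace(pr, sch, seed = 5))
  expect_identical(gen_tree_trace(pr, sch, n_nights = 5, seed = 2),
                   gen_tree_trace(pr, sch, n_nights = 5, seed = 2))
  d1 <- gen_dataset(n_species = 3, sampling = 30, seed = 9)
  d2 <- gen_dataset(n_species = 3, sampling = 30, seed = 9)
  expect_identical(d1, d2)
  # the generator leaves the caller's RNG stream untouched
  set.seed(42); before <- .Random.seed
  invisible(gen_lab_trace(pr, seed = 123))
  expect_identical(.Random.seed, before)
})

test_that("the LEDR transient is confined to the first 30 minutes", {
  pr <- universal_profile()
  on_ <- gen_lab_trace(pr, sampling = 6, noise_sd = 0, ledr = TRUE, seed = 7)
  off <- gen_lab_trace(pr, sampling = 6, noise_sd = 0, ledr = FALSE, seed = 7)
  early <- on_$h * 60 < 30
  expect_true(all(on_$respiration[early] > off$respiration[early]))
  expect_equal(on_$respiration[!early], off$respiration[!early],
               tolerance = 1e-12)
})

test_that("a constant field schedule degenerates to the lab trace", {
  pr <- universal_profile()
  lab <- gen_lab_trace(pr, t_o = 18, noise_sd = 0.02, seed = 21)
  fld <- gen_field_trace(pr, constant_night(18), noise_sd = 0.02, seed = 21)
  expect_equal(fld$respiration, lab$respiration, tolerance = 1e-12)
  expect_equal(fld$temperature_C, lab$temperature_C)
})

test_that("field traces follow Q10 cooling times the decline", {
  pr <- universal_profile()
  fld <- gen_field_trace(pr, linear_cooling(0.5), noise_sd = 0, seed = 2)
  ratio <- fld$respiration / fld$respiration[1]
  # frozen: 2^(-0.4) * (1 - 0.08 * 8^0.54) at h = 8 under 0.5 degC/h
  expect_equal(ratio[fld$h == 8], 2^-0.4 * 0.75409997, tolerance = 1e-6)
  # decline disabled: pure Q10 curve
  nod <- gen_field_trace(pr, linear_cooling(0.5), noise_sd = 0,
                         decline = FALSE, seed = 2)
  expect_equal(nod$respiration / nod$respiration[1],
               2^(0.1 * (nod$temperature_C - 18)), tolerance = 1e-12)
  # trace divided by its no-decline twin is exactly the decline curve
  expect_equal(fld$respiration / nod$respiration, decline_fraction(fld$h),
               tolerance = 1e-12)
})

test_that("whole-tree nights support the top-decile initial-signal filter", {
  pr <- universal_profile(r_initial_mean = 40)
  nights <- gen_tree_trace(pr, linear_cooling(), noise_to_signal = 0.3,
                           n_nights = 62, seed = 31)
  expect_length(nights, 62)
  expect_true(all(vapply(nights, function(t) t$scale[1], "") == "tree"))
  kept <- filter_top_initial(nights, 0.10)
  expect_length(kept, ceiling(0.10 * 62))
  init <- vapply(nights, function(t) t$respiration[1], numeric(1))
  kept_init <- vapply(kept, function(t) t$respiration[1], numeric(1))
  expect_true(min(kept_init) >= sort(init, decreasing = TRUE)[length(kept)])
  # noise-free nights all share the model shape
  clean <- gen_tree_trace(pr, linear_cooling(), noise_to_signal = 0,
                          n_nights = 4, seed = 8)
  shapes <- vapply(clean, function(t) t$respiration / t$respiration[1],
                   numeric(nrow(clean[[1]])))
  expect_equal(shapes[, 2], shapes[, 1], tolerance = 1e-12)
  expect_equal(shapes[, 4], shapes[, 1], tolerance = 1e-12)
})

test_that("the multi-species dataset honours its design", {
  ds <- gen_dataset(n_species = 31, sampling = 30, seed = 14)
  sp <- vapply(ds, function(t) t$species[1], "")
  expect_length(unique(sp), 31)
  reps <- table(sp)
  expect_true(all(reps >= 4 & reps <= 20))
  meta <- do.call(rbind, lapply(ds, function(t) t[1, c("species", "condition",
                                                       "growth_form", "biome")]))
  meta <- meta[!duplicated(meta$species), ]
  expect_equal(sort(as.integer(table(meta$condition))), c(15, 16))
  expect_equal(sort(as.integer(table(meta$growth_form))), c(13, 18))
  expect_equal(sort(as.integer(table(meta$biome))), c(11, 20))
})

test_that("forcing has a clean diurnal structure", {
  f <- gen_forcing(latitude = 0, n_days = 2, doy_start = 80,
                   t_amplitude = 0, gpp_peak = 12)
  expect_true(all(f$t_air == f$t_air[1]))
  st <- sun_times(0, 80)
  expect_equal(st$night_length, 12, tolerance = 0.1)
  night <- f$hour < st$sunrise | f$hour > st$sunset
  expect_true(all(f$gpp[night] == 0))
  expect_true(any(f$gpp > 0))
  expect_equal(nrow(f), 2 * 96)
  # amplitude produces an early-afternoon peak
  f2 <- gen_forcing(latitude = 0, n_days = 1, t_amplitude = 5)
  expect_equal(f2$hour[which.max(f2$t_air)], 14)
})
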