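test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_per_group = c(boy_1 = 8, girl_2 = 5))
  a <- generate_cohort(cfg, seed = 123)
  b <- generate_cohort(cfg, seed = 123)
  expect_identical(a, b)
  c_ <- generate_cohort(cfg, seed = 124)
  expect_false(identical(a$trials$value_nm, c_$trials$value_nm))
})

test_that("group totals match the configuration exactly and metadata is consistent", {
  cfg <- generator_config(n_per_group = c(boy_1 = 12, girl_1 = 7, boy_2 = 3))
  cohort <- generate_cohort(cfg, seed = 1)
  counts <- dplyr::count(cohort$truth, sex, phase)
  expect_equal(counts$n[counts$sex == "boy" & counts$phase == "1"], 12)
  expect_equal(counts$n[counts$sex == "girl" & counts$phase == "1"], 7)
  expect_equal(counts$n[counts$sex == "boy" & counts$phase == "2"], 3)
  expect_equal(nrow(cohort$truth), 22)
  expect_true(all(cohort$trials$mass_kg > 0))
  # frames are contiguous 0-based runs (validates against trial_io rules)
  expect_s3_class(validate_trials(cohort$trials), "tbl_df")
})

test_that("noise-free trials encode as their family's canonical sign pattern", {
  cfg <- generator_config(noise_sd = 0, trend_sd = 0)
  withr::with_seed(3, {
    ep <- generate_trial("early_peak", "small", cfg, n_frames = 100)
    e <- encode_signs(window_series(ep$values_nm_kg, 0.3))
    expect_equal(sum(diff(e) != 0), 1)  # one +1 run then one -1 run
    expect_equal(e[1], 1)

    up <- generate_trial("upslope", "medium", cfg, n_frames = 90)
    expect_true(all(encode_signs(window_series(up$values_nm_kg, 0.3)) == 1))

    dn <- generate_trial("downslope", "large", cfg, n_frames = 95)
    expect_true(all(encode_signs(window_series(dn$values_nm_kg, 0.3)) == -1))
  })
})

test_that("doubling the amplitude leaves the encoding unchanged and scales distances", {
  cfg1 <- generator_config(noise_sd = 0, trend_sd = 0, base_amplitude = 0.3)
  cfg2 <- generator_config(noise_sd = 0, trend_sd = 0, base_amplitude = 0.6)
  t1 <- withr::with_seed(9, generate_trial("peak", "small", cfg1, n_frames = 100, mass_kg = 50))
  t2 <- withr::with_seed(9, generate_trial("peak", "small", cfg2, n_frames = 100, mass_kg = 50))
  w1 <- window_series(t1$values_nm_kg, 0.3)
  w2 <- window_series(t2$values_nm_kg, 0.3)
  expect_identical(encode_signs(w1), encode_signs(w2))
  expect_equal(w2, 2 * w1, tolerance = 1e-12)
  d <- as.matrix(distance_matrix(list(w1, w2, 2 * w2)))
  expect_equal(d[2, 3], 2 * d[1, 2], tolerance = 1e-12)
})

test_that("empirical shape frequencies converge to the configured vectors", {
  cfg <- generator_config(n_per_group = c(boy_1 = 1500))
  cohort <- generate_cohort(cfg, seed = 10)
  emp <- prop.table(table(cohort$truth$shape))
  target <- cfg$shape_freqs["boy_1", names(emp)]
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("a study-sized cohort reproduces the reference table's group differences", {
  # ground-truth labels drawn at the reference row proportions must reject
  # homogeneity at the same alpha = 0.001 as the reference table itself
  cohort <- generate_cohort(generator_config(), seed = 4)
  expect_equal(nrow(cohort$truth), 4797)
  tab <- build_table(cohort$truth, c(sex, phase), shape)
  fit <- chi_square_test(tab)
  expect_lt(fit$p_asymptotic, 0.001)
})
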