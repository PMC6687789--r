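test_that("cluster profiles aggregate member curves as stated", {
  x <- sin(seq(0, pi, length.out = 20))
  p <- profile_cluster(list(x, x))
  expect_equal(p$mean_curve, x)
  expect_equal(p$n_members, 2L)

  p2 <- profile_cluster(list(x, -x))
  expect_equal(p2$mean_curve, rep(0, 20))
  expect_equal(p2$apex_sign, 0)

  expect_error(profile_cluster(list(1:3, 1:4)), class = "vmshapes_validation_error")
})

test_that("profiles of noise-free generated early peaks recover the template", {
  cfg <- generator_config(noise_sd = 0, trend_sd = 0)
  curves <- withr::with_seed(2, {
    purrr::map(1:5, function(i) {
      tr <- generate_trial("early_peak", "small", cfg, n_frames = 100)
      window_series(tr$values_nm_kg, 0.3)
    })
  })
  p <- profile_cluster(curves)
  tmpl <- 0.3 * vmshapes:::template_curve("early_peak", seq(0, 1, length.out = 100))[1:30]
  expect_equal(p$mean_curve, tmpl, tolerance = 1e-9)
  expect_equal(classify_shape(p), "early_peak")
})

test_that("shape rules separate early/late bumps and monotone slopes", {
  grid <- seq(0, 1, length.out = 30)
  bump_at <- function(c0, sgn = 1) sgn * exp(-0.5 * ((grid - c0) / 0.15)^2)

  expect_equal(classify_shape(profile_cluster(list(bump_at(0.27)))), "early_peak")
  expect_equal(classify_shape(profile_cluster(list(bump_at(0.85, -1)))), "trough")
  expect_equal(classify_shape(profile_cluster(list(plogis((grid - 0.5) / 0.15)))), "upslope")
  expect_equal(classify_shape(profile_cluster(list(plogis(-(grid - 0.5) / 0.15)))), "downslope")

  # classification is invariant to positive rescaling
  p1 <- profile_cluster(list(bump_at(0.85)))
  p2 <- profile_cluster(list(100 * bump_at(0.85)))
  expect_equal(classify_shape(p1), classify_shape(p2))

  flat <- profile_cluster(list(rep(1, 30)))
  expect_error(classify_shape(flat), regexp = "override",
               class = "vmshapes_validation_error")
})

test_that("every noiseless family template classifies back to its own label", {
  t <- seq(0, 1, length.out = 100)
  for (fam in shape_levels()) {
    curve <- window_series(vmshapes:::template_curve(fam, t), 0.3)
    expect_equal(classify_shape(profile_cluster(list(curve))), fam, label = fam)
  }
})

test_that("magnitude labels rank sub-clusters and respect scaling", {
  flat_profile <- function(level) profile_cluster(list(rep(level, 10)))

  expect_equal(classify_magnitude(list(flat_profile(0.3), flat_profile(1.1))),
               c("small", "large"))
  expect_equal(classify_magnitude(list(flat_profile(1.2), flat_profile(0.3), flat_profile(0.6))),
               c("large", "small", "medium"))
  expect_equal(
    classify_magnitude(list(flat_profile(0.3), flat_profile(0.6), flat_profile(1.2), flat_profile(2.4))),
    c("small", "small", "medium", "large")
  )
  # uniform scaling leaves labels unchanged
  expect_equal(classify_magnitude(list(flat_profile(0.6), flat_profile(2.2))),
               classify_magnitude(list(flat_profile(0.3), flat_profile(1.1))))
  # indistinguishable sub-clusters share a label instead of inventing levels
  expect_equal(classify_magnitude(list(flat_profile(0.30), flat_profile(0.33), flat_profile(1.2))),
               c("small", "small", "large"))
  expect_equal(classify_magnitude(list(flat_profile(0.5))), "small")
})

test_that("override files are validated against the label set", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(cluster = c(1, 2), label = c("peak", "early_trough")), path)
  ov <- read_shape_overrides(path)
  expect_equal(ov$cluster, c(1L, 2L))

  readr::write_csv(tibble::tibble(cluster = 1, label = "sideways"), path)
  expect_error(read_shape_overrides(path), regexp = "sideways",
               class = "vmshapes_validation_error")
})
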