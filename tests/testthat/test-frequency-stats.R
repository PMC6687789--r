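test_that("contingency tables count pairs with first-appearance ordering", {
  df <- tibble::tibble(
    sex = c("boy", "boy", "girl"),
    phase = c("1", "1", "1"),
    shape = c("early_peak", "early_peak", "peak")
  )
  tab <- build_table(df, c(sex, phase), shape)
  expect_equal(rownames(tab), c("boy-1", "girl-1"))
  expect_equal(colnames(tab), c("early_peak", "peak"))
  expect_equal(as.vector(tab), c(2L, 0L, 0L, 1L))
  expect_equal(sum(tab), nrow(df))
})

test_that("the reference shape table has the published group margins", {
  tab <- counts_matrix(ref_shape_counts())
  expect_equal(unname(rowSums(tab)[c("boy-1", "girl-1", "boy-2", "girl-2")]),
               c(1512, 2502, 364, 419))
  expect_equal(sum(tab), 4797)
})

test_that("the chi-square statistic matches closed forms and stats::chisq.test", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  fit <- chi_square_test(tab)
  expect_equal(fit$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(fit$df, 1)
  expect_true(all(fit$expected == 15))

  # independence identity: observed equal to outer(margins)/N scores zero
  ind <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(chi_square_test(ind)$statistic, 0)

  withr::local_seed(17)
  for (rep in 1:5) {
    m <- matrix(rpois(12, 30) + 1, 3, 4)
    fit <- chi_square_test(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(fit$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(fit$p_asymptotic, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(fit$expected, unname(ref$expected), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(sum(fit$contributions), fit$statistic, tolerance = 1e-9)
    expect_equal(rowSums(fit$expected), rowSums(m), ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(colSums(fit$expected), colSums(m), ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("the statistic is invariant under row and column permutation", {
  tab <- counts_matrix(ref_shape_counts())
  base <- chi_square_test(tab)$statistic
  perm <- tab[sample(nrow(tab)), sample(ncol(tab))]
  expect_equal(chi_square_test(perm)$statistic, base, tolerance = 1e-12)
})

test_that("invalid tables are rejected", {
  expect_error(chi_square_test(matrix(c(1, -1, 2, 3), 2, 2)), class = "vmshapes_validation_error")
  z <- matrix(c(5, 2, 0, 0, 7, 4), 2, 3)  # all-zero middle column
  expect_error(chi_square_test(z), class = "vmshapes_validation_error")
  dropped <- chi_square_test(z, drop_empty = TRUE)
  expect_equal(dim(dropped$observed), c(2L, 2L))
})

test_that("every fixed-margin draw preserves the observed margins exactly", {
  tab <- matrix(c(12, 3, 5, 9, 2, 7), 2, 3)
  draws <- withr::with_seed(5, simulate_margin_tables(tab, 200))
  expect_length(draws, 200)
  for (tb in draws) {
    expect_identical(rowSums(tb), rowSums(tab))
    expect_identical(colSums(tb), colSums(tab))
  }
})

test_that("the Monte-Carlo p equals one at independence and matches exact enumeration", {
  ind <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(monte_carlo_p(ind, n_sim = 999, seed = 1), 1)

  # margins (3,3)/(3,3): four feasible tables, exact p by hypergeometric
  obs <- matrix(c(3, 0, 0, 3), 2, 2)
  p_exact <- oracle_exact_p_2x2(obs)
  expect_equal(p_exact, 0.1, tolerance = 1e-12)
  n_sim <- 10000
  p_mc <- monte_carlo_p(obs, n_sim = n_sim, seed = 42)
  se <- sqrt(p_exact * (1 - p_exact) / n_sim)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / n_sim)
})

test_that("simulated and asymptotic p agree on a well-populated table", {
  # fixed 4x6 table with all expected counts >= 10 and a mid-range p
  withr::local_seed(30)
  repeat {
    tab <- matrix(rpois(24, 40), 4, 6)
    fit <- chi_square_test(tab)
    if (min(fit$expected) >= 10 && fit$p_asymptotic > 0.1 && fit$p_asymptotic < 0.9) break
  }
  p_mc <- monte_carlo_p(tab, n_sim = 9999, seed = 8)
  expect_lt(abs(p_mc - fit$p_asymptotic), 0.03)
})

test_that("monte_carlo_p is reproducible under a fixed seed and guards n_sim", {
  tab <- matrix(c(12, 3, 5, 9, 2, 7), 2, 3)
  expect_identical(monte_carlo_p(tab, n_sim = 999, seed = 3),
                   monte_carlo_p(tab, n_sim = 999, seed = 3))
  expect_error(monte_carlo_p(tab, n_sim = 10), class = "vmshapes_validation_error")
  # unconditional sampler runs and lands near the conditional answer
  p_u <- monte_carlo_p(tab, n_sim = 999, seed = 3, sampler = "multinomial")
  expect_gt(p_u, 0)
  expect_lte(p_u, 1)
})

test_that("frequency reports give row percentages that sum to 100", {
  tab <- counts_matrix(ref_shape_counts())
  rep_ <- frequency_report(tab)
  sums <- rep_ |> dplyr::group_by(row) |> dplyr::summarise(s = sum(pct))
  expect_equal(sums$s, rep(100, 4), tolerance = 1e-9)

  single <- matrix(c(5L, 9L), 2, 1, dimnames = list(c("a", "b"), "only"))
  expect_true(all(frequency_report(single)$pct == 100))

  zero <- matrix(c(0L, 3L, 0L, 4L), 2, 2, dimnames = list(c("z", "b"), c("c1", "c2")))
  expect_warning(out <- frequency_report(zero), regexp = "zero")
  expect_true(all(is.na(out$pct[out$row == "z"])))
})

test_that("tidy and glance expose the chi-square fit as tibbles", {
  fit <- chi_square_test(counts_matrix(ref_shape_counts()), n_sim = 999, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 24)
  expect_equal(sum(td$contribution), fit$statistic)
  g <- glance(fit)
  expect_equal(g$statistic, fit$statistic)
  expect_equal(g$n_sim, 999L)
  expect_lte(g$p_monte_carlo, 1)
})
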