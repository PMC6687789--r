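test_that("perfectly separated clusters score a C-Index of zero", {
  d <- dist(c(0, 1, 10, 11))
  expect_equal(c_index(d, c(1, 1, 2, 2)), 0)
})

test_that("the C-Index matches hand enumeration on a small instance", {
  # points {0,1,2,10}, clusters {0,1,10},{2}: S_w = 20, n_w = 3,
  # all pair distances {1,1,2,8,9,10} -> S_min = 4, S_max = 27
  d <- dist(c(0, 1, 2, 10))
  expect_equal(c_index(d, c(1, 1, 2, 1)), 16 / 23, tolerance = 1e-12)
})

test_that("the C-Index agrees with a brute-force oracle on random instances", {
  withr::local_seed(21)
  for (rep in 1:10) {
    m <- matrix(rnorm(20), nrow = 10)
    d <- dist(m)
    labels <- sample(1:3, 10, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(c_index(d, labels), oracle_c_index(d, labels), tolerance = 1e-12)
  }
})

test_that("the C-Index is invariant to relabeling and to uniform scaling", {
  withr::local_seed(4)
  d <- dist(matrix(rnorm(16), nrow = 8))
  labels <- c(1, 1, 2, 2, 3, 3, 1, 2)
  base <- c_index(d, labels)
  expect_equal(c_index(d, c(3, 3, 1, 1, 2, 2, 3, 1)), base)
  expect_equal(c_index(d * 7.5, labels), base, tolerance = 1e-12)
  expect_gte(base, 0)
  expect_lte(base, 1)
})

test_that("degenerate partitions are rejected as undefined", {
  d <- dist(c(0, 1, 2))
  expect_error(c_index(d, c(1, 1, 1)), regexp = "single cluster",
               class = "vmshapes_validation_error")
  expect_error(c_index(d, c(1, 2, 3)), regexp = "singleton",
               class = "vmshapes_validation_error")
})

test_that("the scan evaluates each k and records undefined cuts as missing", {
  withr::local_seed(6)
  m <- matrix(rnorm(24), nrow = 8)
  d <- dist(m)
  hc <- ward_linkage(d)
  scan <- c_index_scan(d, hc, k_min = 2, k_max = 8)
  expect_equal(scan$k, 2:8)
  expect_true(is.na(scan$c_index[scan$k == 8]))  # all singletons
  defined <- !is.na(scan$c_index)
  expect_true(all(scan$c_index[defined] >= 0 & scan$c_index[defined] <= 1))
  # each defined value matches a direct evaluation of the same cut
  for (k in scan$k[defined]) {
    expect_equal(scan$c_index[scan$k == k], c_index(d, cut_clusters(hc, k)))
  }
  expect_equal(nrow(c_index_scan(d, hc, k_min = 3, k_max = 3)), 1)
  expect_error(c_index_scan(d, hc, k_min = 5, k_max = 4), class = "vmshapes_validation_error")
})

test_that("on a synthetic six-family cohort the C-Index prefers the true family count over k = 2", {
  cohort <- make_test_cohort(n_per_group = 30, seed = 9)
  curves <- preprocess_trials(cohort$trials)
  enc <- purrr::map(curves$curve, encode_signs)
  d <- distance_matrix(enc, ids = curves$trial_id)
  hc <- ward_linkage(d)
  scan <- c_index_scan(d, hc, k_min = 2, k_max = 10)
  expect_lte(scan$c_index[scan$k == 6], scan$c_index[scan$k == 2])
})

test_that("k selection follows the threshold, elbow, and fallback rules", {
  scan_t <- tibble::tibble(k = 2:5, c_index = c(0.20, 0.06, 0.049, 0.048))
  k <- select_k(scan_t, threshold = 0.05)
  expect_equal(as.integer(k), 4L)
  expect_equal(attr(k, "rule_used"), "threshold")

  scan_e <- tibble::tibble(k = 2:5, c_index = c(0.50, 0.20, 0.18, 0.17))
  k <- select_k(scan_e, rule = "elbow")
  expect_equal(as.integer(k), 3L)
  expect_equal(attr(k, "rule_used"), "elbow")

  scan_m <- tibble::tibble(k = 2:5, c_index = c(0.50, 0.40, 0.30, 0.20))
  k <- select_k(scan_m, threshold = 0.05)
  expect_equal(as.integer(k), 5L)
  expect_equal(attr(k, "rule_used"), "argmin-fallback")

  # threshold comparison is <=, so exact equality is accepted
  scan_eq <- tibble::tibble(k = 2:3, c_index = c(0.30, 0.05))
  expect_equal(as.integer(select_k(scan_eq, threshold = 0.05)), 3L)
})
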