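test_that("a perfectly separable class pair yields a diagonal confusion and 1 bit", {
  d <- labeled_trials(matrix(c(rep(0, 20), rep(5, 20)), ncol = 1),
                      stimulus = rep(0:1, each = 20))
  r <- decoder_info(d, decoder = "linear_svm", k_folds = 2,
                    correction = correction_spec("naive"), seed = 1)
  expect_equal(sum(diag(r$confusion)), 40)
  expect_equal(r$info$value, 1, tolerance = 1e-10)
  expect_equal(length(r$weights), 1L)
})

test_that("decoding permuted labels carries no information", {
  set.seed(91)
  d <- simulate_population(population_sim_spec("rate_coded_limited", N = 8,
                                               n_trials = 120, seed = 4))
  d$stimulus <- sample(d$stimulus)
  r <- decoder_info(d, decoder = "rbf_svm", k_folds = 2,
                    correction = correction_spec("shuffle_sub", 20, seed = 2), seed = 1)
  expect_lt(abs(r$info$value), 0.05)
})

test_that("stratified folds keep every class in every training fold", {
  d <- labeled_trials(matrix(rnorm(60), ncol = 2),
                      stimulus = rep(0:2, each = 10))
  r <- decoder_info(d, decoder = "glm", k_folds = 5,
                    correction = correction_spec("naive"), seed = 3)
  expect_equal(sum(r$confusion), 30)
  expect_true(all(rowSums(r$confusion) == 10))
  d_small <- labeled_trials(matrix(rnorm(8), ncol = 1), stimulus = rep(0:1, each = 4))
  expect_error(decoder_info(d_small, k_folds = 5,
                            correction = correction_spec("naive")), "fewer folds")
})

test_that("decoder info never exceeds the direct plugin information (data processing)", {
  set.seed(92)
  for (i in 1:5) {
    d <- simulate_population(population_sim_spec("rate_coded_limited", N = 2,
                                                 n_trials = 200, seed = 10 + i))
    direct <- mutual_information(as_codes(d$stimulus),
                                 code_join(as.integer(d$activity[, 1, 1]),
                                           as.integer(d$activity[, 2, 1])))$value
    dec <- decoder_info(d, decoder = "linear_svm", k_folds = 2,
                        correction = correction_spec("naive"), seed = i)
    expect_lte(dec$info$value, direct + 1e-10)
  }
})

test_that("decoder runs are reproducible from the seed", {
  d <- simulate_population(population_sim_spec("corr_coded", N = 6,
                                               n_trials = 100, seed = 8))
  a <- decoder_info(d, decoder = "rbf_svm", seed = 7,
                    correction = correction_spec("shuffle_sub", 10, seed = 1))
  b <- decoder_info(d, decoder = "rbf_svm", seed = 7,
                    correction = correction_spec("shuffle_sub", 10, seed = 1))
  expect_identical(a$info$value, b$info$value)
  expect_identical(a$confusion, b$confusion)
})

test_that("PCA reduction reports explained variance; rank-1 data needs one component", {
  set.seed(93)
  base <- rnorm(50)
  act <- cbind(base, 2 * base, -base)
  d <- labeled_trials(act, stimulus = rep(0:1, 25))
  red <- reduce_dims(d, "pca", k = 1)
  expect_equal(attr(red, "explained_variance"), 100, tolerance = 1e-8)
  expect_equal(dim(red$activity), c(50L, 1L, 1L))
})

test_that("NMF factorizes an exactly low-rank non-negative matrix", {
  set.seed(94)
  W0 <- matrix(runif(40, 0.2, 1), 20, 2)
  H0 <- matrix(runif(12, 0.2, 1), 2, 6)
  d <- labeled_trials(W0 %*% H0, stimulus = rep(0:1, 10))
  red <- reduce_dims(d, "nmf", k = 2, seed = 1)
  expect_lt(attr(red, "reconstruction_error"), 1e-6)
  dneg <- labeled_trials(matrix(rnorm(40), 20, 2), stimulus = rep(0:1, 10))
  expect_error(reduce_dims(dneg, "nmf", k = 1), "non-negative")
})

test_that("axis angles come out in degrees within [0, 90]", {
  expect_equal(axis_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(axis_angle(c(2, 1), c(-2, -1)), 0, tolerance = 1e-5)
  expect_equal(axis_angle(c(1, 1), c(1, 0)), 45)
  expect_error(axis_angle(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(axis_angle(c(1, 0, 0), c(1, 0)), "equal dimension")
})

test_that("scaling curves saturate for duplicated units and grow for independent ones", {
  set.seed(95)
  base <- simulate_population(population_sim_spec("rate_coded_limited", N = 1,
                                                  n_trials = 150, seed = 5))
  dup <- labeled_trials(base$activity[, rep(1, 6), , drop = FALSE], base$stimulus)
  sc_dup <- scaling_curve(dup, sizes = c(1, 3, 6), n_subpops = 3,
                          decoder = "linear_svm",
                          correction = correction_spec("naive"), seed = 2)
  expect_lt(abs(sc_dup$curve$mean_info[3] - sc_dup$curve$mean_info[1]), 0.05)
  ind <- simulate_population(population_sim_spec("custom", N = 8, n_trials = 150,
                                                 rates = rbind(rep(.42, 8), rep(.58, 8)),
                                                 noise_corr = c(0, 0), seed = 6))
  sc_ind <- scaling_curve(ind, sizes = c(1, 4, 8), n_subpops = 4,
                          decoder = "linear_svm",
                          correction = correction_spec("naive"), seed = 2,
                          reference = 0)
  expect_gt(sc_ind$curve$mean_info[3], sc_ind$curve$mean_info[1])
  # reference 0 is crossed at the smallest evaluated size with positive info
  expect_equal(sc_ind$crossing_N, 1, tolerance = 1e-9)
})
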