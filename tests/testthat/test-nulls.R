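test_that("within-class shuffling preserves class-conditional marginals exactly", {
  set.seed(1)
  d <- simulate_population(population_sim_spec("custom", N = 2, n_trials = 400,
                                               rates = rbind(c(.4, .6), c(.6, .4)),
                                               noise_corr = c(0.5, 0.5), seed = 2))
  sh <- shuffle_within_class(d, "stimulus", seed = 9)
  for (s in unique(d$stimulus)) for (u in 1:2) {
    expect_equal(sort(sh$activity[sh$stimulus == s, u, 1]),
                 sort(d$activity[d$stimulus == s, u, 1]))
    expect_equal(mean(sh$activity[sh$stimulus == s, u, 1]),
                 mean(d$activity[d$stimulus == s, u, 1]), tolerance = 1e-15)
  }
})

test_that("within-class shuffling destroys noise correlations", {
  d <- simulate_population(population_sim_spec("custom", N = 2, n_trials = 50000,
                                               rates = rbind(c(.5, .5), c(.5, .5)),
                                               noise_corr = c(0.8, 0.8), seed = 3))
  r_pre <- cor(d$activity[d$stimulus == 0, 1, 1], d$activity[d$stimulus == 0, 2, 1])
  expect_gt(r_pre, 0.7)
  sh <- shuffle_within_class(d, "stimulus", seed = 4)
  r_post <- cor(sh$activity[sh$stimulus == 0, 1, 1], sh$activity[sh$stimulus == 0, 2, 1])
  expect_lt(abs(r_post), 0.01)
})

test_that("hierarchical shuffles preserve the intended conditional structure", {
  set.seed(6)
  act <- array(rpois(60 * 3 * 5, 2), dim = c(60, 3, 5))
  d <- labeled_trials(act, stimulus = rep(0:1, each = 30))
  # time shuffle: per-unit per-stimulus time-summed counts unchanged
  ts <- hierarchical_shuffle(d, condition_on = "stimulus", permute_axis = "time",
                             seed = 7)
  for (s in 0:1) for (u in 1:3)
    expect_equal(sum(ts$activity[d$stimulus == s, u, ]),
                 sum(d$activity[d$stimulus == s, u, ]))
  # unconditioned trial shuffle destroys the stimulus-response association
  s_codes <- rand_codes(100000, 2)
  resp <- structure(as.integer(s_codes), n_bins = 2L)  # perfect copy
  d2 <- labeled_trials(matrix(resp, ncol = 1), stimulus = as.integer(s_codes))
  g <- hierarchical_shuffle(d2, condition_on = character(0),
                            permute_axis = "trials", seed = 8)
  mi_after <- mutual_information(as_codes(g$stimulus),
                                 structure(as.integer(g$activity[, 1, 1]), n_bins = 2L))$value
  expect_lt(mi_after, 1e-3)
  expect_error(hierarchical_shuffle(d, condition_on = "weather"), "unknown")
  # same seed, same surrogate
  a <- hierarchical_shuffle(d, "stimulus", "trials", seed = 11)
  b <- hierarchical_shuffle(d, "stimulus", "trials", seed = 11)
  expect_identical(a$activity, b$activity)
})

test_that("permutation p-values follow the add-one convention with ties counted", {
  fake_null <- function(values) {
    i <- 0
    function(d, s) { i <<- i + 1; attr(d, "v") <- values[i]; d }
  }
  stat <- function(d) if (is.null(attr(d, "v"))) 0.5 else attr(d, "v")
  d <- labeled_trials(matrix(0, 4, 1), stimulus = c(0, 0, 1, 1))
  p_hi <- permutation_test(stat, d, fake_null(rep(0.1, 99)), n_perm = 99)
  expect_equal(p_hi$p_value, 0.01)
  p_lo <- permutation_test(stat, d, fake_null(rep(0.9, 99)), n_perm = 99)
  expect_equal(p_lo$p_value, 1)
  p_tie <- permutation_test(stat, d, fake_null(c(rep(0.5, 4), rep(0.1, 95))),
                            n_perm = 99)
  expect_equal(p_tie$p_value, 0.05)
  expect_error(permutation_test(stat, d, n_perm = 10), ">= 19")
})

test_that("p-values are uniform on the achievable grid under a true null", {
  # a tie-free statistic, so the add-one p-value is exactly uniform on the
  # achievable grid {1/20, ..., 20/20}
  set.seed(55)
  ps <- vapply(1:400, function(r) {
    d <- labeled_trials(matrix(rnorm(80), ncol = 1),
                        stimulus = rep(0:1, each = 40))
    stat <- function(dd) abs(mean(dd$activity[dd$stimulus == 0, 1, 1]) -
                               mean(dd$activity[dd$stimulus == 1, 1, 1]))
    permutation_test(stat, d, n_perm = 19, seed = r * 100)$p_value
  }, numeric(1))
  expect_true(all(ps %in% (1:20 / 20)))
  # goodness of fit to the discrete uniform on the 20-point grid
  expect_gt(stats::chisq.test(tabulate(round(ps * 20), 20))$p.value, 0.01)
})

test_that("null distributions export to a tidy table", {
  d <- labeled_trials(matrix(sample(0:1, 40, TRUE), ncol = 1),
                      stimulus = rep(0:1, each = 20))
  stat <- function(dd) mean(dd$activity)
  nr <- permutation_test(stat, d, n_perm = 19, seed = 2)
  tab <- null_to_csv(nr)
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$value[1], nr$observed)
})
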