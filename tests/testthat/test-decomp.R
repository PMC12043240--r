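test_that("PID recovers the canonical XOR / COPY / UNIQUE systems", {
  xs <- xor_system(4)
  for (m in c("imin", "mmi")) {
    p_xor <- pid(xs$y, list(xs$x1, xs$x2), measure = m)
    expect_equal(p_xor$SI, 0, tolerance = 1e-12)
    expect_equal(p_xor$UI, c(0, 0), tolerance = 1e-12)
    expect_equal(p_xor$CI, 1, tolerance = 1e-12)
    s <- rep(0:1, each = 4)
    p_copy <- pid(s, list(s, s), measure = m)
    expect_equal(p_copy$SI, 1, tolerance = 1e-12)
    expect_equal(p_copy$CI, 0, tolerance = 1e-12)
    # unique-only: x2 independent of the target by exact construction
    g <- expand.grid(t = 0:1, x2 = 0:1)
    p_uni <- pid(g$t, list(g$t, g$x2), measure = m)
    expect_equal(p_uni$UI[1], 1, tolerance = 1e-12)
    expect_equal(p_uni$SI, 0, tolerance = 1e-12)
    expect_equal(p_uni$UI[2], 0, tolerance = 1e-12)
    expect_equal(p_uni$CI, 0, tolerance = 1e-12)
  }
})

test_that("PID consistency equations hold exactly on random data", {
  set.seed(71)
  for (m in c("imin", "mmi")) {
    for (i in 1:40) {
      s <- rand_codes(120, 2); x1 <- rand_codes(120, 3); x2 <- rand_codes(120, 2)
      p <- pid(s, list(x1, x2), measure = m)
      expect_lt(abs(p$UI[1] + p$SI - mutual_information(s, x1)$value), 1e-10)
      expect_lt(abs(p$UI[2] + p$SI - mutual_information(s, x2)$value), 1e-10)
      expect_lt(abs(p$SI + p$UI[1] + p$UI[2] + p$CI -
                    mutual_information(s, code_join(x1, x2))$value), 1e-10)
      if (m == "imin") expect_true(all(p$lattice$atom >= -1e-10))
    }
  }
})

test_that("the three-source lattice has 18 nodes and sums to the joint information", {
  set.seed(72)
  s <- rand_codes(150, 2)
  xs <- list(rand_codes(150, 2), rand_codes(150, 2), rand_codes(150, 2))
  p <- pid(s, xs)
  expect_equal(nrow(p$lattice), 18L)
  expect_equal(sum(p$lattice$atom),
               mutual_information(s, do.call(code_join, xs))$value,
               tolerance = 1e-10)
  expect_true(all(p$lattice$atom >= -1e-10))
  expect_error(pid(s, c(xs, xs[1])), "2 or 3 sources")
})

test_that("information breakdown matches the hand-derived noiseless-copy case", {
  s <- rep(0:1, each = 4)
  b <- info_breakdown(s, s, s)
  expect_equal(b$I_joint, 1, tolerance = 1e-12)
  expect_equal(b$I_lin, 2, tolerance = 1e-12)
  expect_equal(b$I_sig_sim, -1, tolerance = 1e-12)
  expect_equal(b$I_cor_ind, 0, tolerance = 1e-12)
  expect_equal(b$I_cor_dep, 0, tolerance = 1e-12)
  expect_equal(b$RSI, -1, tolerance = 1e-12)
})

test_that("breakdown additivity, the RSI identity and I_cor_dep >= 0 hold on random tables", {
  set.seed(73)
  for (i in 1:200) {
    d <- rand_triple(100, ks = sample(2:3, 1), k1 = 2L, k2 = sample(2:3, 1))
    b <- info_breakdown(d$s, d$r1, d$r2)
    expect_equal(b$I_lin + b$I_sig_sim + b$I_cor_ind + b$I_cor_dep, b$I_joint,
                 tolerance = 1e-10)
    expect_equal(b$RSI, b$I_joint - b$I_lin, tolerance = 1e-12)
    expect_gte(b$I_cor_dep, -1e-10)
    expect_equal(rsi(d$s, list(d$r1, d$r2)),
                 b$I_sig_sim + b$I_cor_ind + b$I_cor_dep, tolerance = 1e-10)
  }
})

test_that("conditionally independent responses have zero I_cor_dep", {
  # r1, r2 generated independently given s
  set.seed(74)
  s <- rep(0:1, each = 300)
  r1 <- ifelse(runif(600) < ifelse(s == 0, .3, .7), 1L, 0L)
  r2 <- ifelse(runif(600) < ifelse(s == 0, .4, .6), 1L, 0L)
  b <- info_breakdown(s, r1, r2)
  # trial-sampled, so only approximately zero; exact version via tables
  expect_lt(b$I_cor_dep, 0.01)
  g <- expand.grid(s = 0:1, r1 = 0:1, r2 = 0:1)
  w <- ifelse(g$s == 0, (2 + 2 * g$r1) * (1 + 2 * g$r2), (4 - 2 * g$r1) * (3 - 2 * g$r2))
  dat <- exact_data(as.matrix(g), w)
  b2 <- info_breakdown(dat[, "s"], dat[, "r1"], dat[, "r2"])
  expect_equal(b2$I_cor_dep, 0, tolerance = 1e-12)
})

test_that("RSI sign reflects redundancy vs synergy", {
  s <- rep(0:1, each = 4)
  expect_equal(rsi(s, list(s, s)), -1, tolerance = 1e-12)  # duplicated neuron
  xs <- xor_system(4)
  expect_equal(rsi(xs$y, list(xs$x1, xs$x2)), 1, tolerance = 1e-12)
  expect_error(rsi(s, list(s)), "at least 2")
})

test_that("stimulus coded purely by correlation sign loads on I_cor_dep", {
  d <- simulate_population(population_sim_spec("custom", N = 2, n_trials = 20000,
                                               rates = rbind(c(.5, .5), c(.5, .5)),
                                               noise_corr = c(0.8, -0.8), seed = 5))
  b <- info_breakdown(as_codes(d$stimulus),
                      as.integer(d$activity[, 1, 1]), as.integer(d$activity[, 2, 1]))
  expect_lt(b$I_lin, 0.001)
  expect_gt(b$I_joint, 0.1)
  expect_equal(b$I_cor_dep, b$I_joint, tolerance = 0.05)
})

test_that("intersection information is bounded by every pairwise information", {
  s <- rep(0:1, each = 4)
  expect_equal(intersection_information(s, s, s), 1, tolerance = 1e-12)
  g <- expand.grid(s = 0:1, r = 0:1, c = 0:1)
  # r independent of (s, c): no intersection
  expect_equal(intersection_information(g$s, g$r, g$s), 0, tolerance = 1e-12)
  # c independent of (s, r): nothing read out
  expect_equal(intersection_information(g$s, g$s, g$c), 0, tolerance = 1e-12)
  expect_warning(ii0 <- intersection_information(s, s, rep(0L, 8)), "constant")
  expect_equal(ii0, 0)
  set.seed(75)
  for (i in 1:30) {
    s <- rand_codes(150, 2); r <- rand_codes(150, 3); cc <- rand_codes(150, 2)
    ii <- intersection_information(s, r, cc)
    expect_lte(ii, mutual_information(s, r)$value + 1e-10)
    expect_lte(ii, mutual_information(s, cc)$value + 1e-10)
    expect_lte(ii, mutual_information(r, cc)$value + 1e-10)
  }
})

test_that("decomposition results export as tidy atom tables", {
  xs <- xor_system(2)
  tab <- decomposition_to_csv(pid(xs$y, list(xs$x1, xs$x2)))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$bits[tab$atom == "synergy"], 1, tolerance = 1e-12)
  b <- info_breakdown(xs$y, xs$x1, xs$x2)
  expect_equal(nrow(decomposition_to_csv(b)), 6L)
})
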