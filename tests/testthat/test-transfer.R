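test_that("transfer entropy detects a perfect lagged copy and nothing else", {
  set.seed(81)
  n <- 1500; Tm <- 5
  x <- matrix(sample(0:1, n * Tm, TRUE), n, Tm)
  y <- cbind(sample(0:1, n, TRUE), x[, 1:(Tm - 1)])
  te <- transfer_entropy(x, y, delay = 1)
  # the receiver is an exact lagged copy; the plugin estimate sits at the
  # empirical H(Y_t | Y_past), within sampling error of 1 bit
  expect_true(all(abs(te$value - 1) < 0.01))
  # independent white processes: corrected TE within 3 null SDs of 0
  y_ind <- matrix(sample(0:1, n * Tm, TRUE), n, Tm)
  te0 <- transfer_entropy(x, y_ind, delay = 1, times = 3,
                          correction = correction_spec("shuffle_sub", 30, seed = 1))
  null_sd <- sd(vapply(1:30, function(i) {
    popinfo:::te_eval(x[sample(n), ], y_ind, 1, 3, 1, 2L, 2L)
  }, numeric(1)))
  expect_lt(abs(te0$value), 3 * null_sd)
  # pure self-copy: conditioning removes all self-predictability
  y_self <- matrix(sample(0:1, n, TRUE), n, 1)[, rep(1, Tm)]
  expect_true(all(transfer_entropy(x, y_self, delay = 2)$value < 1e-12))
})

test_that("TE via the cMI identity equals a direct joint-table evaluation", {
  set.seed(82)
  x <- matrix(sample(0:2, 600, TRUE), 200, 3)
  y <- matrix(sample(0:1, 600, TRUE), 200, 3)
  te <- transfer_entropy(x, y, delay = 1, times = 3)$value
  # independent route: I(Yt; Xp, Yp) - I(Yt; Yp) from plugin MI on tables
  yt <- structure(y[, 3], n_bins = 2L)
  xp <- structure(x[, 2], n_bins = 3L); yp <- structure(y[, 2], n_bins = 2L)
  direct <- mutual_information(yt, code_join(xp, yp))$value -
    mutual_information(yt, yp)$value
  expect_equal(te, direct, tolerance = 1e-12)
})

test_that("conditional TE discounts shared drive and third-node routes", {
  set.seed(83)
  n <- 1200
  # Z independent of everything: cTE = TE exactly on exact data
  g <- expand.grid(xp = 0:1, yt = 0:1, yp = 0:1, zp = 0:1)
  w <- rep(c(3, 1, 1, 3, 1, 3, 3, 1), times = 2)  # some (xp,yt,yp) dependence
  dat <- exact_data(as.matrix(g), w)
  x <- cbind(dat[, "xp"], 0L); y <- cbind(dat[, "yp"], dat[, "yt"])
  z <- cbind(dat[, "zp"], 0L)
  expect_equal(conditional_te(x, y, z, delay = 1, times = 2)$value,
               transfer_entropy(x, y, delay = 1, times = 2)$value,
               tolerance = 1e-10)
  # fully shared drive X_(t-d) = Z_(t-d): conditioning absorbs the sender
  xp <- sample(0:1, n, TRUE)
  yt <- as.integer(xor(xp, runif(n) < 0.1))
  x2 <- cbind(xp, 0L); z2 <- cbind(xp, 0L)
  y2 <- cbind(sample(0:1, n, TRUE), yt)
  expect_gt(transfer_entropy(x2, y2, delay = 1, times = 2)$value, 0.4)
  expect_equal(conditional_te(x2, y2, z2, delay = 1, times = 2)$value, 0,
               tolerance = 1e-12)
  # chain S -> Z -> X -> Y: conditioning on Z reduces apparent X -> Y flow
  s <- sample(0:1, n, TRUE)
  zt <- as.integer(xor(s, runif(n) < 0.15))
  xt <- as.integer(xor(zt, runif(n) < 0.15))
  yt3 <- as.integer(xor(xt, runif(n) < 0.15))
  x3 <- cbind(xt, 0L); y3 <- cbind(sample(0:1, n, TRUE), yt3); z3 <- cbind(zt, 0L)
  expect_lt(conditional_te(x3, y3, z3, delay = 1, times = 2)$value,
            transfer_entropy(x3, y3, delay = 1, times = 2)$value)
})

test_that("FIT detects feature-specific relay and respects invariances", {
  set.seed(84)
  n <- 2000
  s <- sample(0:1, n, TRUE)
  # X_(t-d) = S, Y_t = X_(t-d), Y_(t-d) independent: FIT = 1 bit
  x <- cbind(s, sample(0:1, n, TRUE))
  y <- cbind(sample(0:1, n, TRUE), s)
  expect_equal(fit_transfer(s, x, y, delay = 1, times = 2)$value, 1,
               tolerance = 0.01)
  # sender carries no feature information: FIT = 0 on exact data
  g <- expand.grid(s = 0:1, xp = 0:1, yt = 0:1)
  dat <- exact_data(as.matrix(g), rep(2L, 8))
  expect_equal(fit_transfer(dat[, "s"], cbind(dat[, "xp"], 0L),
                            cbind(0L, dat[, "yt"]), delay = 1, times = 2)$value,
               0, tolerance = 1e-12)
  # relabeling the feature alphabet leaves FIT unchanged
  xr <- cbind(sample(0:1, n, TRUE), s)
  yr <- cbind(sample(0:1, n, TRUE), as.integer(xor(s, runif(n) < 0.2)))
  f1 <- fit_transfer(s, xr, yr, delay = 1, times = 2)$value
  f2 <- fit_transfer(1L - s, xr, yr, delay = 1, times = 2)$value
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_warning(f0 <- fit_transfer(rep(0L, n), xr, yr, delay = 1, times = 2),
                 "constant")
  expect_equal(f0$value, 0)
})

test_that("FIT obeys its defining bounds on random small distributions", {
  set.seed(85)
  for (i in 1:120) {
    n <- 250
    s <- rand_codes(n, 2)
    x <- cbind(as.integer(rand_codes(n, 3)), 0L)
    y <- cbind(sample(0:1, n, TRUE), sample(0:1, n, TRUE))
    f <- fit_transfer(s, x, y, delay = 1, times = 2)$value
    te <- transfer_entropy(x, y, delay = 1, times = 2)$value
    expect_gte(f, 0)
    expect_lte(f, te + 1e-10)
    expect_lte(f, mutual_information(s, structure(y[, 2], n_bins = 2L))$value + 1e-10)
    expect_lte(f, mutual_information(s, structure(x[, 1], n_bins = 3L))$value + 1e-10)
  }
})

test_that("conditional FIT discounts feature information relayed through Z", {
  set.seed(86)
  n <- 1000
  s <- sample(0:1, n, TRUE)
  # Z holds S at all times; X's feature content came through Z
  z <- cbind(s, s)
  x <- cbind(s, sample(0:1, n, TRUE))
  y <- cbind(sample(0:1, n, TRUE), s)
  expect_gt(fit_transfer(s, x, y, delay = 1, times = 2)$value, 0.9)
  expect_lt(conditional_fit(s, x, y, z, delay = 1, times = 2)$value, 1e-10)
  # independent Z: cFIT = FIT on exact data
  g <- expand.grid(s = 0:1, yp = 0:1, zp = 0:1)
  dat <- exact_data(as.matrix(g), rep(3L, 8))
  xe <- cbind(dat[, "s"], 0L); ye <- cbind(dat[, "yp"], dat[, "s"])
  ze <- cbind(dat[, "zp"], 0L)
  expect_equal(conditional_fit(dat[, "s"], xe, ye, ze, delay = 1, times = 2)$value,
               fit_transfer(dat[, "s"], xe, ye, delay = 1, times = 2)$value,
               tolerance = 1e-10)
  # constant Z changes nothing
  zc <- cbind(rep(0L, n), 0L)
  expect_equal(conditional_fit(s, x, y, zc, delay = 1, times = 2)$value,
               fit_transfer(s, x, y, delay = 1, times = 2)$value,
               tolerance = 1e-12)
})

test_that("sweeps validate their grids and locate the strongest delay", {
  set.seed(87)
  n <- 800
  x <- matrix(sample(0:1, n * 8, TRUE), n, 8)
  y <- cbind(matrix(sample(0:1, n * 3, TRUE), n, 3), x[, 1:5])
  sw <- transfer_sweep("te", x, y, delays = 1:3, times = 5:8)
  expect_equal(sw$best_delay, 3L)  # y lags x by 3
  expect_error(transfer_sweep("te", x, y, delays = integer(0), times = 5),
               "empty delay")
  expect_error(transfer_sweep("te", x, y, delays = 1:4, times = 3),
               "first sample")
  expect_error(transfer_sweep("fit", x, y, delays = 1, times = 5), "feature")
  expect_error(transfer_entropy(x, y, delay = 2, times = 1), "first sample")
})

test_that("sweep permutation nulls are calibrated under independence", {
  set.seed(88)
  n <- 400
  x <- matrix(sample(0:1, n * 6, TRUE), n, 6)
  y <- matrix(sample(0:1, n * 6, TRUE), n, 6)
  ps <- vapply(1:25, function(i) {
    xi <- matrix(sample(0:1, n * 6, TRUE), n, 6)
    yi <- matrix(sample(0:1, n * 6, TRUE), n, 6)
    transfer_sweep("te", xi, yi, delays = 1:2, times = 4:6,
                   n_perm = 19, seed = i)$edge_p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.6)   # mostly non-significant
  expect_lt(mean(ps <= 0.05), 0.3)  # false-positive rate near nominal
})
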