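# Ground-truth generators: dichotomized-Gaussian correlated binary
# populations (stimulus coded by correlations, or by rates with
# information-limiting correlations) and a four-node delayed-communication
# network with two binary stimulus features.

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation lambda
bvn_upper <- function(a, b, lambda) {
  if (abs(lambda) < 1e-12) return((1 - stats::pnorm(a)) * (1 - stats::pnorm(b)))
  f <- function(z) stats::dnorm(z) *
    (1 - stats::pnorm((b - lambda * z) / sqrt(1 - lambda^2)))
  stats::integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# Latent correlation achieving a target count correlation between two
# thresholded units with firing probabilities p1, p2.
latent_corr_for <- function(r_target, p1, p2) {
  if (abs(r_target) < 1e-12) return(0)
  a <- stats::qnorm(1 - p1); b <- stats::qnorm(1 - p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  g <- function(l) (bvn_upper(a, b, l) - p1 * p2) / denom - r_target
  lo <- -0.999; hi <- 0.999
  if (g(lo) > 0 || g(hi) < 0)
    stop(sprintf("count correlation %.3f infeasible for rates (%.2f, %.2f); feasible range [%.3f, %.3f]",
                 r_target, p1, p2, g(lo) + r_target, g(hi) + r_target), call. = FALSE)
  stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
}

#' Specification of a correlated-population simulation
#'
#' Two ready-made scenarios plus a custom mode:
#' \describe{
#'   \item{corr_coded}{every unit's marginal response distribution is
#'     identical across stimuli; only the pairwise noise correlation is
#'     stimulus-modulated, so all stimulus information lives in
#'     correlations.}
#'   \item{rate_coded_limited}{all units respond more strongly to stimulus
#'     2, and positive, only weakly stimulus-modulated noise correlations
#'     limit the population information (signal-aligned covariability).}
#'   \item{custom}{`rates` and `noise_corr` fully caller-specified.}
#' }
#' Binary responses are generated by thresholding a latent equicorrelated
#' Gaussian (dichotomized Gaussian), which gives exact control of marginals
#' and an analytic feasibility bound for the requested count correlation.
#'
#' @param scenario `"corr_coded"`, `"rate_coded_limited"` or `"custom"`.
#' @param N Number of units.
#' @param n_trials Trials per stimulus.
#' @param n_stimuli Number of stimuli (default 2).
#' @param rates `n_stimuli x N` matrix of per-stimulus per-unit mean (binary)
#'   counts, i.e. firing probabilities; scenario defaults used when `NULL`.
#' @param noise_corr Length-`n_stimuli` vector of target pairwise count
#'   correlations (one per stimulus).
#' @param seed Integer seed.
#' @return An object of class `population_sim_spec`.
#' @export
population_sim_spec <- function(scenario = c("corr_coded", "rate_coded_limited", "custom"),
                                N = 20L, n_trials = 500L, n_stimuli = 2L,
                                rates = NULL, noise_corr = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  N <- as.integer(N); n_trials <- as.integer(n_trials); n_stimuli <- as.integer(n_stimuli)
  if (is.null(rates)) {
    rates <- switch(scenario,
      corr_coded = matrix(0.5, n_stimuli, N),
      rate_coded_limited = {
        if (n_stimuli != 2L) stop("rate_coded_limited uses 2 stimuli", call. = FALSE)
        rbind(rep(0.35, N), rep(0.65, N))
      },
      custom = stop("scenario 'custom' requires `rates`", call. = FALSE))
  }
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(n_stimuli, N)))
    stop("`rates` must be n_stimuli x N", call. = FALSE)
  if (any(rates <= 0) || any(rates >= 1))
    stop("binary-model rates must lie in (0, 1)", call. = FALSE)
  if (is.null(noise_corr)) {
    noise_corr <- switch(scenario,
      corr_coded = c(0.4, rep(0, n_stimuli - 1L)),
      rate_coded_limited = c(0.30, 0.35),
      custom = stop("scenario 'custom' requires `noise_corr`", call. = FALSE))
  }
  if (length(noise_corr) != n_stimuli)
    stop("`noise_corr` needs one value per stimulus", call. = FALSE)
  structure(list(scenario = scenario, N = N, n_trials = n_trials,
                 n_stimuli = n_stimuli, rates = rates, noise_corr = noise_corr,
                 seed = as.integer(seed)),
            class = "population_sim_spec")
}

#' Simulate a correlated binary population
#'
#' Draws `n_trials` trials per stimulus from the dichotomized-Gaussian model
#' in the spec: a latent equicorrelated Gaussian per stimulus is thresholded
#' so each unit fires with its specified probability while unit pairs attain
#' the requested count correlation.
#'
#' @param spec A [population_sim_spec()].
#' @return A [labeled_trials()] object (`activity` is 0/1 counts, one time
#'   bin; `stimulus` codes are `0 .. n_stimuli-1`).
#' @export
#' @examples
#' d <- simulate_population(population_sim_spec("corr_coded", N = 2,
#'                                              n_trials = 100, seed = 7))
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_sim_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  N <- spec$N
  acts <- vector("list", spec$n_stimuli)
  for (s in seq_len(spec$n_stimuli)) {
    p <- spec$rates[s, ]
    lambda <- latent_corr_for(spec$noise_corr[s], p[1], p[min(2, N)])
    if (N > 1L && lambda < -1 / (N - 1))
      stop(sprintf("latent correlation %.3f infeasible for N = %d (minimum %.3f)",
                   lambda, N, -1 / (N - 1)), call. = FALSE)
    sigma <- matrix(lambda, N, N); diag(sigma) <- 1
    z <- if (N == 1L) matrix(stats::rnorm(spec$n_trials), ncol = 1)
         else MASS::mvrnorm(spec$n_trials, mu = rep(0, N), Sigma = sigma)
    thr <- stats::qnorm(1 - p)
    acts[[s]] <- 1L * (z > matrix(thr, spec$n_trials, N, byrow = TRUE))
  }
  activity <- do.call(rbind, acts)
  stimulus <- rep(seq_len(spec$n_stimuli) - 1L, each = spec$n_trials)
  labeled_trials(activity, stimulus)
}

#' Specification of the four-node delayed-communication network
#'
#' A network of four nodes whose aggregate activity is sampled at 1 ms
#' resolution. Two independent binary stimulus features `S1`, `S2` (values
#' -1/+1) are injected from outside: `S1` into node X1 during 3-12 ms and
#' into node X4 during 15-24 ms, `S2` into node X2 during 3-12 ms. Linear
#' couplings with a common transmission delay (default 5 ms) implement the
#' ground-truth edges X1 -> X2, X1 -> X3, X2 -> X1 and X3 -> X4; the
#' X3 -> X4 edge carries X3's private (non-feature) signal only. Gaussian
#' noise is added everywhere.
#'
#' @param T_ms Simulation duration in ms (samples; default 60).
#' @param n_trials Number of trials (default 1000).
#' @param delay_ms Transmission delay on every edge (default 5).
#' @param gain Injection amplitude: the feature adds `gain * S` inside its
#'   encoding window.
#' @param coupling Linear coupling gain on the edges.
#' @param noise_sd Standard deviation of the per-sample Gaussian noise.
#' @param private_sd Standard deviation of X3's private transmitted signal.
#' @param private_window Window `c(start_ms, end_ms)` in which the private
#'   (non-feature) signal exchanged on X3 -> X4 is active. Kept disjoint
#'   from X4's stimulus-encoding window by default, so the ground truth
#'   "the X3 -> X4 exchange carries no feature information" holds in the
#'   generated data itself.
#' @param windows Named list of encoding windows (`x1_s1`, `x4_s1`,
#'   `x2_s2`), each `c(start_ms, end_ms)` inclusive.
#' @param bidirectional_x34 If `TRUE`, X3 also receives X4's private signal.
#' @param seed Integer seed.
#' @return An object of class `network_sim_spec`.
#' @export
network_sim_spec <- function(T_ms = 60L, n_trials = 1000L, delay_ms = 5L,
                             gain = 1, coupling = 1, noise_sd = 1,
                             private_sd = 1.5, private_window = c(30, 50),
                             windows = list(x1_s1 = c(3, 12),
                                            x4_s1 = c(15, 24),
                                            x2_s2 = c(3, 12)),
                             bidirectional_x34 = FALSE, seed = 1L) {
  T_ms <- as.integer(T_ms)
  if (delay_ms >= T_ms) stop("delay must be smaller than the duration", call. = FALSE)
  for (w in c(windows, list(private_window))) {
    if (w[1] < 0 || w[2] >= T_ms || w[1] > w[2])
      stop("encoding windows must lie within [0, T)", call. = FALSE)
  }
  structure(list(T_ms = T_ms, n_trials = as.integer(n_trials),
                 delay_ms = as.integer(delay_ms), gain = gain,
                 coupling = coupling, noise_sd = noise_sd,
                 private_sd = private_sd, private_window = private_window,
                 windows = windows,
                 bidirectional_x34 = isTRUE(bidirectional_x34),
                 seed = as.integer(seed)),
            class = "network_sim_spec")
}

#' Simulate the four-node feature-communication network
#'
#' @param spec A [network_sim_spec()].
#' @return A list of class `network_sim`: `activity` (trials x 4 nodes x
#'   T time samples), `s1`, `s2` (per-trial features, -1/+1), `time_ms`,
#'   and the `spec`.
#' @export
simulate_network <- function(spec = network_sim_spec()) {
  stopifnot(inherits(spec, "network_sim_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_trials; T_ms <- spec$T_ms
  d <- spec$delay_ms; g <- spec$gain; cc <- spec$coupling
  time_ms <- seq_len(T_ms) - 1L          # sample t (1-based) is time t-1 ms
  in_window <- function(w) as.numeric(time_ms >= w[1] & time_ms <= w[2])
  w1 <- in_window(spec$windows$x1_s1)
  w4 <- in_window(spec$windows$x4_s1)
  w2 <- in_window(spec$windows$x2_s2)
  s1 <- sample(c(-1, 1), n, replace = TRUE)
  s2 <- sample(c(-1, 1), n, replace = TRUE)
  rnd <- function(sd) matrix(stats::rnorm(n * T_ms, sd = sd), n, T_ms)
  lag5 <- function(m) cbind(matrix(0, n, d), m[, seq_len(T_ms - d), drop = FALSE])
  wp <- in_window(spec$private_window)
  u1 <- g * outer(s1, w1) + rnd(spec$noise_sd)   # S1 component born at X1
  u2 <- g * outer(s2, w2) + rnd(spec$noise_sd)   # S2 component born at X2
  w3 <- rnd(spec$private_sd) * rep(wp, each = n) # X3's private signal
  w4p <- rnd(spec$private_sd) * rep(wp, each = n)
  x1 <- u1 + cc * lag5(u2)
  x2 <- u2 + cc * lag5(u1)
  x3 <- w3 + rnd(spec$noise_sd) + cc * lag5(u1) +
    (if (spec$bidirectional_x34) cc * lag5(w4p) else 0)
  x4 <- g * outer(s1, w4) + cc * lag5(w3) + rnd(spec$noise_sd) +
    (if (spec$bidirectional_x34) w4p else 0)
  activity <- array(0, dim = c(n, 4L, T_ms))
  activity[, 1L, ] <- x1; activity[, 2L, ] <- x2
  activity[, 3L, ] <- x3; activity[, 4L, ] <- x4
  structure(list(activity = activity, s1 = s1, s2 = s2,
                 time_ms = as.numeric(time_ms), spec = spec),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("<network_sim> %d trials x 4 nodes x %d ms (delay %d ms)\n",
              dim(x$activity)[1], dim(x$activity)[3], x$spec$delay_ms))
  invisible(x)
}

#' Extract one node's trials x time activity matrix
#'
#' @param sim A `network_sim` object.
#' @param node Node index 1-4.
#' @return A trials x time numeric matrix.
#' @export
network_node <- function(sim, node) {
  stopifnot(inherits(sim, "network_sim"), node %in% 1:4)
  sim$activity[, node, ]
}
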