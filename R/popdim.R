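# Population-scale information via dimensionality reduction: stratified
# cross-validated decoders whose confusion matrix carries a scalable lower
# bound on population information, unsupervised reduction (PCA / NMF),
# decoding-axis geometry, and population-size scaling curves.

features_matrix <- function(data) {
  d <- dim(data$activity)
  matrix(data$activity, d[1], d[2] * d[3])
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer trials than folds; use fewer folds",
           call. = FALSE)
    folds[idx] <- (sample.int(length(idx)) %% k) + 1L
  }
  folds
}

train_predict <- function(decoder, xtr, ytr, xte) {
  ytr <- factor(ytr)
  if (nlevels(droplevels(ytr)) < length(levels(ytr)))
    stop("a class is absent from a training fold; use fewer folds", call. = FALSE)
  if (decoder %in% c("linear_svm", "rbf_svm")) {
    kern <- if (decoder == "linear_svm") "linear" else "radial"
    m <- e1071::svm(xtr, ytr, kernel = kern, scale = FALSE)
    list(pred = stats::predict(m, xte), model = m)
  } else if (decoder == "glm") {
    if (nlevels(ytr) == 2L) {
      df <- data.frame(xtr)
      m <- stats::glm(y ~ ., data = cbind(df, y = ytr), family = stats::binomial())
      pr <- stats::predict(m, data.frame(xte), type = "response")
      list(pred = factor(levels(ytr)[1L + (pr > 0.5)], levels = levels(ytr)),
           model = m)
    } else {
      df <- cbind(data.frame(xtr), y = ytr)
      m <- nnet::multinom(y ~ ., data = df, trace = FALSE)
      list(pred = stats::predict(m, data.frame(xte)), model = m)
    }
  } else stop("unknown decoder: ", decoder, call. = FALSE)
}

svm_weights <- function(model) {
  # binary linear SVM discriminant vector
  as.numeric(t(model$coefs) %*% model$SV)
}

#' Cross-validated decoder confusion-matrix information
#'
#' Trains a decoder with stratified k-fold cross-validation, accumulates the
#' out-of-fold predictions into a confusion table of true versus decoded
#' labels, and computes the bias-corrected mutual information of that table.
#' This is a scalable lower bound on the population information that the
#' direct method cannot reach for large populations.
#'
#' @param data A [labeled_trials()] object (activity is flattened across
#'   units and time bins into the feature vector).
#' @param label `"stimulus"` or `"choice"`.
#' @param decoder `"linear_svm"`, `"rbf_svm"` or `"glm"`.
#' @param k_folds Number of stratified folds (default 2).
#' @param correction A [correction_spec()] for the confusion-table MI
#'   (default shuffle subtraction, 20 surrogates).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `decoder_result`: `confusion` (true x decoded
#'   count table), `info` (an `info_estimate`), `weights` (binary linear
#'   decoders only), `decoder`, `folds`, `seed`.
#' @export
decoder_info <- function(data, label = c("stimulus", "choice"),
                         decoder = c("linear_svm", "rbf_svm", "glm"),
                         k_folds = 2L,
                         correction = correction_spec("shuffle_sub", 20L, seed = 1L),
                         seed = 1L) {
  stopifnot(inherits(data, "labeled_trials"))
  label <- match.arg(label); decoder <- match.arg(decoder)
  y <- if (label == "stimulus") data$stimulus else data$choice
  if (is.null(y)) stop("no ", label, " labels present", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (k_folds < 2L) stop("k_folds must be >= 2", call. = FALSE)
  x <- features_matrix(data)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  folds <- stratified_folds(y, k_folds)
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  weights <- NULL
  for (f in seq_len(k_folds)) {
    te <- folds == f
    fitted <- train_predict(decoder, x[!te, , drop = FALSE], y[!te],
                            x[te, , drop = FALSE])
    pred[te] <- fitted$pred
    if (decoder == "linear_svm" && nlevels(y) == 2L) {
      w <- svm_weights(fitted$model)
      weights <- if (is.null(weights)) w / k_folds else weights + w / k_folds
    }
  }
  confusion <- table(true = y, decoded = pred)
  info <- corrected_mi(as_codes(y), as_codes(pred), correction)
  structure(list(confusion = confusion, info = info, weights = weights,
                 decoder = decoder, folds = k_folds, label = label,
                 seed = seed),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> %s on %s, %d-fold CV\n", x$decoder, x$label, x$folds))
  cat(sprintf("  information = %.5f bits [%s]\n", x$info$value, x$info$method))
  print(x$confusion)
  invisible(x)
}

#' Unsupervised dimensionality reduction of population activity
#'
#' Reduces the trials x features activity to `k` components by PCA or by
#' non-negative matrix factorization (multiplicative-update NMF with a
#' non-negative least-squares polish). Downstream information is computed by
#' discretizing the components.
#'
#' @param data A [labeled_trials()] object.
#' @param method `"pca"` or `"nmf"` (NMF requires non-negative activity).
#' @param k Number of components (`k <= units x time`).
#' @param seed Seed for the NMF initialization.
#' @param max_iter,tol NMF iteration controls.
#' @return A reduced [labeled_trials()] (trials x k x 1) with attributes
#'   `explained_variance` (PCA, percent) or `reconstruction_error` (NMF,
#'   relative Frobenius), and `loadings`.
#' @export
reduce_dims <- function(data, method = c("pca", "nmf"), k,
                        seed = 1L, max_iter = 2000L, tol = 1e-12) {
  stopifnot(inherits(data, "labeled_trials"))
  method <- match.arg(method)
  x <- features_matrix(data)
  if (k > ncol(x)) stop("k must not exceed the number of features", call. = FALSE)
  if (method == "pca") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    ev <- 100 * sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
    out <- labeled_trials(scores, data$stimulus, data$choice,
                          unit_ids = paste0("PC", seq_len(k)))
    attr(out, "explained_variance") <- ev
    attr(out, "loadings") <- pc$rotation[, seq_len(k), drop = FALSE]
    return(out)
  }
  if (any(x < 0)) stop("NMF requires non-negative activity", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n <- nrow(x); m <- ncol(x)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- 1e-12
  err_prev <- Inf
  nx <- norm(x, "F")
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, x) / (crossprod(W, W %*% H) + eps))
    W <- W * ((x %*% t(H)) / (W %*% tcrossprod(H) + eps))
    if (it %% 25L == 0L) {
      err <- norm(x - W %*% H, "F") / nx
      if (abs(err_prev - err) < tol) break
      err_prev <- err
    }
  }
  err <- norm(x - W %*% H, "F") / nx
  out <- labeled_trials(W, data$stimulus, data$choice,
                        unit_ids = paste0("NMF", seq_len(k)))
  attr(out, "reconstruction_error") <- err
  attr(out, "loadings") <- H
  out
}

#' Angle between two decoding axes
#'
#' `arccos(|a . b| / (||a|| ||b||))` in degrees, in `[0, 90]` (sign
#' ignored): the misalignment between, e.g., the stimulus and choice
#' discriminant boundaries in neural activity space.
#'
#' @param weights_a,weights_b Equal-length non-zero numeric vectors.
#' @return Angle in degrees.
#' @export
#' @examples
#' axis_angle(c(1, 0), c(0, 1)) # 90
axis_angle <- function(weights_a, weights_b) {
  if (length(weights_a) != length(weights_b))
    stop("weight vectors must have equal dimension", call. = FALSE)
  na <- sqrt(sum(weights_a^2)); nb <- sqrt(sum(weights_b^2))
  if (na == 0 || nb == 0) stop("zero-norm weight vector", call. = FALSE)
  acos(min(1, abs(sum(weights_a * weights_b)) / (na * nb))) * 180 / pi
}

#' Decoder information as a function of population size
#'
#' For each requested size `N`, decodes random unit subpopulations (all
#' subpopulations when no more than `n_subpops` exist) and summarizes the
#' bias-corrected confusion-matrix information as mean +/- SEM. A quadratic
#' polynomial in `log N` is fitted to the means, and the smallest population
#' size at which the fitted curve reaches a reference information level is
#' reported (extrapolating up to `extrapolate_to`; `NA` when never reached).
#'
#' @param data A [labeled_trials()] object.
#' @param label,decoder,correction,k_folds Passed to [decoder_info()].
#' @param sizes Population sizes to evaluate.
#' @param n_subpops Subpopulations per size.
#' @param reference Optional reference information level (bits).
#' @param extrapolate_to Upper N bound for the crossing search (default
#'   4 x max size).
#' @param seed Integer seed.
#' @return A list of class `scaling_curve`: `curve` (tibble with `N`,
#'   `mean_info`, `sem`, `n_subpops`), `fit` (lm in log N), `crossing_N`,
#'   `reference`.
#' @export
scaling_curve <- function(data, label = "stimulus", sizes, n_subpops = 10L,
                          decoder = "rbf_svm", k_folds = 2L,
                          correction = correction_spec("shuffle_sub", 20L, seed = 1L),
                          reference = NULL, extrapolate_to = NULL, seed = 1L) {
  stopifnot(inherits(data, "labeled_trials"))
  n_units <- dim(data$activity)[2]
  if (any(sizes > n_units)) stop("sizes must not exceed the number of units", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rows <- purrr::map_dfr(sizes, function(N) {
    total <- choose(n_units, N)
    subs <- if (total <= n_subpops) {
      asplit(utils::combn(n_units, N), 2)
    } else {
      lapply(seq_len(n_subpops), function(i) sort(sample.int(n_units, N)))
    }
    vals <- vapply(seq_along(subs), function(i) {
      sel <- subs[[i]]
      sub <- labeled_trials(data$activity[, sel, , drop = FALSE],
                            data$stimulus, data$choice)
      decoder_info(sub, label = label, decoder = decoder, k_folds = k_folds,
                   correction = correction, seed = seed + i)$info$value
    }, numeric(1))
    tibble::tibble(N = N, mean_info = mean(vals),
                   sem = stats::sd(vals) / sqrt(length(vals)),
                   n_subpops = length(vals))
  })
  fit <- stats::lm(mean_info ~ poly(log(N), degree = min(2L, length(sizes) - 1L),
                                    raw = TRUE), data = rows)
  crossing <- NA_real_
  if (!is.null(reference)) {
    upper <- if (is.null(extrapolate_to)) 4 * max(sizes) else extrapolate_to
    grid <- seq(min(sizes), upper, by = 0.25)
    pred <- stats::predict(fit, newdata = data.frame(N = grid))
    hit <- which(pred >= reference)
    crossing <- if (length(hit)) grid[hit[1]] else NA_real_
  }
  structure(list(curve = rows, fit = fit, crossing_N = crossing,
                 reference = reference, decoder = decoder, seed = seed),
            class = "scaling_curve")
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat(sprintf("<scaling_curve> %s decoder, %d sizes\n", x$decoder, nrow(x$curve)))
  print(x$curve)
  if (!is.null(x$reference))
    cat(sprintf("  reference %.4f bits %s\n", x$reference,
                if (is.na(x$crossing_N)) "not reached"
                else sprintf("reached at N ~ %.1f", x$crossing_N)))
  invisible(x)
}
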