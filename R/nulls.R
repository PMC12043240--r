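#' Shuffle trials within each class, independently per unit
#'
#' For each unit (its whole time course moving together), the trial order is
#' permuted independently within each class of `class_var`. Each unit's
#' class-conditional response multiset is preserved exactly while the
#' trial-by-trial pairing between units — the noise correlation — is
#' destroyed. Classes with a single trial are left unpermuted and flagged in
#' `attr(, "single_trial_classes")`.
#'
#' @param data A [labeled_trials()] object.
#' @param class_var `"stimulus"` or `"choice"`.
#' @param seed Optional integer seed.
#' @return A shuffled `labeled_trials` object.
#' @export
shuffle_within_class <- function(data, class_var = c("stimulus", "choice"),
                                 seed = NULL) {
  class_var <- match.arg(class_var)
  hierarchical_shuffle(data, condition_on = class_var,
                       permute_axis = "trials", seed = seed)
}

#' Hierarchical shuffling of trial-structured data
#'
#' Applies a permutation independently within each stratum defined by
#' `condition_on`, along the chosen axis:
#' \describe{
#'   \item{trials}{each unit's trials (whole time courses) are permuted
#'     within each stratum independently of other units, destroying
#'     cross-unit pairing while preserving every per-unit conditional
#'     marginal.}
#'   \item{time}{time bins are permuted within each (trial, unit) pair,
#'     destroying response timing while preserving per-trial time-summed
#'     activity (hence all per-unit per-stratum sums).}
#'   \item{units}{the unit axis is permuted within each trial, destroying
#'     unit identity.}
#' }
#' With `condition_on = character(0)` the trial permutation is global, which
#' destroys the stimulus-response association.
#'
#' @param data A [labeled_trials()] object.
#' @param condition_on Character vector of stratifying variables among
#'   `"stimulus"` and `"choice"` (may be empty).
#' @param permute_axis `"trials"`, `"time"` or `"units"`.
#' @param seed Optional integer seed.
#' @return A shuffled `labeled_trials` object.
#' @export
hierarchical_shuffle <- function(data, condition_on = "stimulus",
                                 permute_axis = c("trials", "time", "units"),
                                 seed = NULL) {
  stopifnot(inherits(data, "labeled_trials"))
  permute_axis <- match.arg(permute_axis)
  bad <- setdiff(condition_on, c("stimulus", "choice"))
  if (length(bad)) stop("unknown conditioning variable: ", bad[1], call. = FALSE)
  if ("choice" %in% condition_on && is.null(data$choice))
    stop("no choice labels present", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  act <- data$activity
  d <- dim(act)
  strata <- if (length(condition_on) == 0L) rep.int(1L, d[1]) else {
    parts <- lapply(condition_on, function(v)
      if (v == "stimulus") data$stimulus else data$choice)
    as.integer(interaction(parts, drop = TRUE))
  }
  single <- character(0)
  if (permute_axis == "trials") {
    for (u in seq_len(d[2])) {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        if (length(idx) < 2L) {
          if (u == 1L) single <- c(single, as.character(s))
          next
        }
        act[idx, u, ] <- act[idx[sample.int(length(idx))], u, , drop = FALSE]
      }
    }
  } else if (permute_axis == "time") {
    if (d[3] < 2L) stop("no time axis to permute", call. = FALSE)
    for (u in seq_len(d[2])) {
      for (tr in seq_len(d[1])) {
        act[tr, u, ] <- act[tr, u, sample.int(d[3])]
      }
    }
  } else { # units
    if (d[2] < 2L) stop("no unit axis to permute", call. = FALSE)
    for (tr in seq_len(d[1])) {
      act[tr, , ] <- act[tr, sample.int(d[2]), , drop = FALSE]
    }
  }
  out <- data
  out$activity <- act
  if (length(single)) attr(out, "single_trial_classes") <- single
  out
}

#' Permutation significance test for an information statistic
#'
#' Recomputes `statistic` on `n_perm` surrogates generated by `null_scheme`
#' and reports the add-one permutation p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` (one-sided by default;
#' information statistics are non-negative excess measures). Ties count
#' toward the numerator.
#'
#' @param statistic Function `labeled_trials -> numeric(1)`.
#' @param data A [labeled_trials()] object.
#' @param null_scheme Function `(data, seed) -> labeled_trials` producing one
#'   surrogate; defaults to a global trial shuffle of the stimulus-response
#'   association via [hierarchical_shuffle()].
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed; surrogate `i` uses `seed + i`.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return An object of class `null_result` with `observed`, `null_values`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(statistic, data, null_scheme = NULL,
                             n_perm = 99L, seed = 1L,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  if (n_perm < 19L) stop("n_perm must be >= 19", call. = FALSE)
  if (is.null(null_scheme))
    null_scheme <- function(d, s)
      hierarchical_shuffle(d, condition_on = character(0),
                           permute_axis = "trials", seed = s)
  observed <- statistic(data)
  null_values <- vapply(seq_len(n_perm), function(i) {
    surr <- tryCatch(null_scheme(data, seed + i),
                     error = function(e) stop("null_scheme failed at surrogate ", i,
                                              ": ", conditionMessage(e), call. = FALSE))
    tryCatch(statistic(surr),
             error = function(e) stop("statistic failed at surrogate ", i,
                                      ": ", conditionMessage(e), call. = FALSE))
  }, numeric(1))
  p <- if (alternative == "greater") {
    (1 + sum(null_values >= observed)) / (1 + n_perm)
  } else {
    ctr <- null_values - mean(null_values)
    (1 + sum(abs(ctr) >= abs(observed - mean(null_values)))) / (1 + n_perm)
  }
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, n_perm = n_perm, seed = seed,
                 alternative = alternative),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> observed = %.6f, null mean = %.6f (sd %.6f), p = %.4g [n_perm = %d]\n",
              x$observed, mean(x$null_values), stats::sd(x$null_values),
              x$p_value, x$n_perm))
  invisible(x)
}

#' Export a null distribution as a tidy table / CSV
#'
#' @param x A `null_result`.
#' @param path Optional file path; when given, the table is also written as
#'   CSV (one row per surrogate).
#' @return A tibble with columns `surrogate` (0 = observed) and `value`.
#' @export
null_to_csv <- function(x, path = NULL) {
  stopifnot(inherits(x, "null_result"))
  out <- tibble::tibble(surrogate = c(0L, seq_len(x$n_perm)),
                        value = c(x$observed, x$null_values))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
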