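#' Trial-structured neural data with task labels
#'
#' The universal input container: a `trials x units x time` activity array
#' (the time axis may have length 1 for single-window spike counts), a
#' per-trial discrete stimulus label and an optional per-trial choice label.
#'
#' @param activity Numeric matrix (`trials x units`) or 3-d array
#'   (`trials x units x time`).
#' @param stimulus Per-trial stimulus label (length = trials).
#' @param choice Optional per-trial choice label.
#' @param unit_ids Optional unit names.
#' @param time_ms Optional numeric time-axis annotation (length = time).
#' @return An object of class `labeled_trials` with elements `activity`
#'   (always a 3-d array), `stimulus`, `choice`, `unit_ids`, `time_ms`.
#' @export
labeled_trials <- function(activity, stimulus, choice = NULL,
                           unit_ids = NULL, time_ms = NULL) {
  if (is.matrix(activity)) activity <- array(activity, c(nrow(activity), ncol(activity), 1L))
  if (length(dim(activity)) != 3L)
    stop("`activity` must be a trials x units (x time) matrix or array", call. = FALSE)
  n <- dim(activity)[1]
  if (length(stimulus) != n)
    stop("`stimulus` length must equal the number of trials", call. = FALSE)
  if (!is.null(choice) && length(choice) != n)
    stop("`choice` length must equal the number of trials", call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(dim(activity)[2]))
  if (is.null(time_ms)) time_ms <- seq_len(dim(activity)[3]) - 1
  structure(list(activity = activity, stimulus = stimulus, choice = choice,
                 unit_ids = unit_ids, time_ms = as.numeric(time_ms)),
            class = "labeled_trials")
}

#' @export
print.labeled_trials <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("<labeled_trials> %d trials x %d units x %d time bins\n", d[1], d[2], d[3]))
  cat("  stimulus levels:", paste(sort(unique(x$stimulus)), collapse = " "), "\n")
  if (!is.null(x$choice))
    cat("  choice levels:  ", paste(sort(unique(x$choice)), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in a labeled_trials object
#' @param data A `labeled_trials` object.
#' @return Integer trial count.
#' @export
n_trials <- function(data) dim(data$activity)[1]

#' Coerce an arbitrary discrete label vector to 0-based integer codes
#'
#' @param x A vector of discrete labels (integer, character or factor).
#' @return Integer codes in `[0, K)` with attribute `n_bins = K`.
#' @export
as_codes <- function(x) {
  if (is.integer(x) && length(x) && min(x) >= 0L) {
    nb <- attr(x, "n_bins")
    return(structure(as.integer(x), n_bins = if (is.null(nb)) max(x) + 1L else nb))
  }
  f <- factor(x)
  structure(as.integer(f) - 1L, n_bins = nlevels(f))
}

n_codes <- function(x) {
  nb <- attr(x, "n_bins")
  if (is.null(nb)) max(x) + 1L else as.integer(nb)
}

#' Flatten several code vectors into a single joint code
#'
#' Multi-unit joint responses are encoded by mixed-radix flattening of the
#' per-unit codes, so the joint response can be fed to any scalar-code
#' operation.
#'
#' @param ... Two or more 0-based integer code vectors of equal length.
#' @return Integer joint codes with attribute `n_bins` equal to the product
#'   of the per-variable alphabet sizes.
#' @export
code_join <- function(...) {
  vs <- lapply(list(...), as_codes)
  if (length(vs) == 1L) return(vs[[1L]])
  ns <- vapply(vs, n_codes, integer(1))
  len <- lengths(vs)
  if (length(unique(len)) != 1L) stop("code vectors must have equal length", call. = FALSE)
  out <- vs[[1L]]
  radix <- ns[1L]
  for (i in seq_along(vs)[-1L]) {
    out <- out + radix * vs[[i]]
    radix <- radix * ns[i]
  }
  structure(as.integer(out), n_bins = as.integer(radix))
}

#' Joint count table over discretized variables
#'
#' Builds the multi-way table of empirical occurrences across trials of the
#' supplied code tuples — the substrate of every plugin (direct-method)
#' information estimate.
#'
#' @param ... 0-based integer code vectors of equal length (one per
#'   variable), or a single `labeled_trials` object together with
#'   `variables`.
#' @param variables When the first argument is a `labeled_trials`, a
#'   character vector naming what to tabulate; entries may be `"stimulus"`,
#'   `"choice"`, or unit names / indices (each unit taken at the first time
#'   bin unless `time` is given).
#' @param time Time-bin index (1-based) used when extracting unit activity
#'   from a `labeled_trials`; defaults to 1.
#' @return An object of class `joint_table`: a list with `counts` (k-way
#'   integer array), `n` (total trials) and `vars` (variable names).
#' @export
#' @examples
#' jt <- joint_counts(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
#' jt$counts
joint_counts <- function(..., variables = NULL, time = 1L) {
  args <- list(...)
  if (length(args) == 1L && inherits(args[[1L]], "labeled_trials")) {
    data <- args[[1L]]
    if (is.null(variables)) stop("`variables` required with labeled_trials input", call. = FALSE)
    vs <- lapply(variables, function(v) {
      if (identical(v, "stimulus")) return(as_codes(data$stimulus))
      if (identical(v, "choice")) {
        if (is.null(data$choice)) stop("no choice labels present", call. = FALSE)
        return(as_codes(data$choice))
      }
      idx <- if (is.character(v)) match(v, data$unit_ids) else as.integer(v)
      if (is.na(idx) || idx < 1 || idx > dim(data$activity)[2])
        stop("unknown variable: ", v, call. = FALSE)
      as_codes(as.integer(data$activity[, idx, time]))
    })
    names(vs) <- as.character(variables)
  } else {
    vs <- lapply(args, as_codes)
    nm <- names(args)
    names(vs) <- if (is.null(nm) || any(nm == "")) paste0("V", seq_along(vs)) else nm
  }
  len <- lengths(vs)
  if (length(unique(len)) != 1L)
    stop("all variables must have the same number of trials", call. = FALSE)
  ns <- vapply(vs, n_codes, integer(1))
  flat <- 0L
  radix <- 1L
  for (i in seq_along(vs)) {
    flat <- flat + radix * vs[[i]]
    radix <- radix * ns[i]
  }
  counts <- tabulate(flat + 1L, nbins = radix)
  counts <- array(as.integer(counts), dim = unname(ns))
  structure(list(counts = counts, n = len[[1L]], vars = names(vs)),
            class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat("<joint_table>", paste(x$vars, collapse = " x "),
      "| dims:", paste(dim(x$counts), collapse = " x "),
      "| n =", x$n, "\n")
  invisible(x)
}

as_joint_counts <- function(x) {
  if (inherits(x, "joint_table")) return(x$counts)
  x
}

#' Plugin Shannon entropy in bits
#'
#' `H = -sum p log2 p` over non-zero cells, with `p = counts / n` and the
#' convention `0 log 0 = 0`. No pseudo-counts are added (maximum-likelihood
#' plugin estimate).
#'
#' @param x A [joint_counts()] table, or a non-negative count array/vector.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy_bits(c(1, 1, 1, 1)) # 2 bits
entropy_bits <- function(x) {
  counts <- as_joint_counts(x)
  n <- sum(counts)
  if (n < 1) stop("empty table", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

new_info_estimate <- function(value, method, plugin_value = value,
                              bias_term = 0, null_summary = NULL, seed = NULL) {
  structure(list(value = value, method = method, plugin_value = plugin_value,
                 bias_term = bias_term, null_summary = null_summary, seed = seed),
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("<info_estimate> %.6f bits [%s]", x$value, x$method))
  if (x$method != "plugin")
    cat(sprintf(" (plugin %.6f, bias %.6f)", x$plugin_value, x$bias_term))
  if (!is.null(x$null_summary))
    cat(sprintf("  p = %.4g (n_perm = %d)", x$null_summary$p_value, x$null_summary$n_perm))
  cat("\n")
  invisible(x)
}

#' Plugin mutual information between two discrete variables
#'
#' `I(X;Y) = H(X) + H(Y) - H(X,Y)` in bits, computed from the empirical
#' joint table (direct method, no bias correction). For bias-corrected
#' estimates see [corrected_mi()].
#'
#' @param x A two-variable [joint_counts()] table, or a code vector (then
#'   `y` must be supplied).
#' @param y Optional code vector paired with `x`.
#' @return An `info_estimate` with method `"plugin"`.
#' @export
#' @examples
#' mutual_information(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L))$value # 1 bit
mutual_information <- function(x, y = NULL) {
  tab <- if (inherits(x, "joint_table")) x else joint_counts(x, y)
  if (length(dim(tab$counts)) != 2L)
    stop("mutual_information needs a two-variable table", call. = FALSE)
  cts <- tab$counts
  value <- entropy_bits(rowSums(cts)) + entropy_bits(colSums(cts)) - entropy_bits(cts)
  new_info_estimate(value, "plugin")
}

#' Conditional mutual information I(X;Y|Z)
#'
#' Computed via the entropy identity
#' `I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)` on a three-variable
#' joint table; non-negative up to rounding.
#'
#' @param x A three-variable [joint_counts()] table over `(X, Y, Z)`, or a
#'   code vector (then `y` and `z` must be supplied).
#' @param y,z Optional code vectors.
#' @return Conditional mutual information in bits.
#' @export
conditional_mi <- function(x, y = NULL, z = NULL) {
  tab <- if (inherits(x, "joint_table")) x else joint_counts(x, y, z)
  if (length(dim(tab$counts)) != 3L)
    stop("conditional_mi needs a three-variable table", call. = FALSE)
  cts <- tab$counts
  h_xz <- entropy_bits(apply(cts, c(1, 3), sum))
  h_yz <- entropy_bits(apply(cts, c(2, 3), sum))
  h_z <- entropy_bits(apply(cts, 3, sum))
  h_xyz <- entropy_bits(cts)
  h_xz + h_yz - h_xyz - h_z
}
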