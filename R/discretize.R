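#' Binning specification for discretizing neural activity
#'
#' Describes how continuous (or integer-valued) activity is converted into
#' discrete response codes before any plugin probability estimate. Four
#' methods are supported: `"equispaced"` (equal-width bins over the data
#' range), `"equipopulated"` (empirical-quantile edges, approximately equal
#' occupancy), `"user_edges"` (caller-supplied ascending edges) and `"none"`
#' (integer data passed through unchanged, optionally capped).
#'
#' @param method One of `"equispaced"`, `"equipopulated"`, `"user_edges"`,
#'   `"none"`.
#' @param n_bins Positive integer, the number of response bins. Ignored for
#'   `"user_edges"` (taken from `edges`) and `"none"`.
#' @param edges Optional strictly ascending numeric vector of bin edges,
#'   required for `method = "user_edges"`.
#' @param cap Optional non-negative integer: counts are capped at this value
#'   before coding, so e.g. `cap = 2` yields the 3-code alphabet
#'   \{0 spikes, 1 spike, 2 or more spikes\}.
#'
#' @return An object of class `bin_spec`.
#' @seealso [discretize()], [auto_bin_count()]
#' @export
#' @examples
#' bin_spec("equipopulated", n_bins = 2)
#' bin_spec("none", cap = 2)
bin_spec <- function(method = c("equispaced", "equipopulated", "user_edges", "none"),
                     n_bins = 2L, edges = NULL, cap = NULL) {
  method <- match.arg(method)
  if (method == "user_edges") {
    if (is.null(edges)) stop("method 'user_edges' requires `edges`", call. = FALSE)
    if (any(diff(edges) <= 0)) stop("`edges` must be strictly ascending", call. = FALSE)
    n_bins <- length(edges) - 1L
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  if (!is.null(cap)) {
    cap <- as.integer(cap)
    if (is.na(cap) || cap < 0L) stop("`cap` must be a non-negative integer", call. = FALSE)
  }
  structure(list(method = method, n_bins = n_bins, edges = edges, cap = cap),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat("<bin_spec>", x$method, "R =", x$n_bins)
  if (!is.null(x$cap)) cat(", cap =", x$cap)
  if (!is.null(x$edges)) cat(", edges =", paste(signif(x$edges, 4), collapse = " "))
  cat("\n")
  invisible(x)
}

#' Serialize / deserialize a binning specification as JSON
#'
#' @param spec A [bin_spec()] object.
#' @param json A JSON string produced by `bin_spec_to_json()`.
#' @return `bin_spec_to_json()` returns a JSON string; `bin_spec_from_json()`
#'   returns a `bin_spec`.
#' @export
bin_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "bin_spec"))
  jsonlite::toJSON(spec[!vapply(spec, is.null, logical(1))],
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname bin_spec_to_json
#' @export
bin_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  bin_spec(method = x$method,
           n_bins = if (is.null(x$n_bins)) 2L else x$n_bins,
           edges = x$edges, cap = x$cap)
}

#' Discretize a vector of activity values
#'
#' Converts activity values to 0-based integer codes in `[0, n_bins)`.
#' Equispaced bins are half-open `[e_k, e_{k+1})` with the last bin closed;
#' equipopulated bins use empirical quantile edges with ties at an edge
#' assigned to the lower bin. With `method = "none"` integer data pass
#' through unchanged (after the optional cap).
#'
#' When equipopulated binning is requested with more bins than distinct
#' quantile edges, the number of bins is reduced and the result carries
#' `attr(, "reduced_bins") = TRUE`.
#'
#' @param values Finite numeric vector.
#' @param spec A [bin_spec()].
#' @return Integer vector of codes in `[0, n_bins)`, with attribute
#'   `n_bins` (the effective alphabet size).
#' @export
#' @examples
#' discretize(c(1, 2, 3, 4, 5, 6), bin_spec("equipopulated", 2))
#' discretize(c(0, 1, 2, 5, 0), bin_spec("none", cap = 2))
discretize <- function(values, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  if (!is.null(spec$cap)) values <- pmin(values, spec$cap)
  reduced <- FALSE
  codes <- switch(spec$method,
    none = {
      if (any(values != round(values)) || any(values < 0))
        stop("method 'none' requires non-negative integer values", call. = FALSE)
      out <- as.integer(values)
      attr(out, "n_bins") <- max(out) + 1L
      return(structure(out, n_bins = max(out) + 1L))
    },
    equispaced = {
      rng <- range(values)
      if (rng[1] == rng[2]) {
        rep.int(0L, length(values))
      } else {
        edges <- seq(rng[1], rng[2], length.out = spec$n_bins + 1L)
        # half-open [e_k, e_{k+1}), last bin closed
        as.integer(findInterval(values, edges, rightmost.closed = TRUE,
                                all.inside = TRUE)) - 1L
      }
    },
    equipopulated = {
      qs <- stats::quantile(values, probs = seq(0, 1, length.out = spec$n_bins + 1L),
                            names = FALSE, type = 7)
      inner <- unique(qs[-c(1L, length(qs))])
      inner <- inner[inner > min(values) & inner <= max(values)]
      if (length(inner) < spec$n_bins - 1L) reduced <- TRUE
      # ties at a quantile edge go to the lower bin
      as.integer(findInterval(values, inner, left.open = TRUE))
    },
    user_edges = {
      if (any(values < spec$edges[1]) || any(values > spec$edges[length(spec$edges)]))
        stop("values outside user-defined edges", call. = FALSE)
      as.integer(findInterval(values, spec$edges, rightmost.closed = TRUE,
                              all.inside = TRUE)) - 1L
    }
  )
  n_eff <- if (spec$method == "equipopulated") length(unique(codes)) else spec$n_bins
  structure(codes, n_bins = as.integer(max(n_eff, max(codes) + 1L)),
            reduced_bins = if (reduced) TRUE else NULL)
}

#' Automatic bin-count selection
#'
#' Returns the number of equispaced bins suggested by the Freedman-Diaconis
#' rule (width `2 IQR n^(-1/3)`) or Scott's rule (width `3.49 sd n^(-1/3)`).
#' Degenerate inputs (zero IQR or zero sd) fall back to a single bin with a
#' warning.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param rule `"freedman_diaconis"` or `"scott"`.
#' @return A positive integer bin count.
#' @export
auto_bin_count <- function(values, rule = c("freedman_diaconis", "scott")) {
  rule <- match.arg(rule)
  if (sum(is.finite(values)) < 4) stop("need at least 4 finite values", call. = FALSE)
  values <- values[is.finite(values)]
  n <- length(values)
  width <- switch(rule,
    freedman_diaconis = 2 * stats::IQR(values) * n^(-1 / 3),
    scott = 3.49 * stats::sd(values) * n^(-1 / 3)
  )
  if (width <= 0) {
    warning("degenerate spread; falling back to 1 bin")
    return(1L)
  }
  max(1L, as.integer(ceiling(diff(range(values)) / width)))
}
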