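# Partial information decomposition on the Williams-Beer redundancy
# lattice, the exact information breakdown of pairwise population
# information, the redundancy-synergy index, and intersection information.

# Specific information of source codes `a` about target value s:
#   I_spec(s; A) = sum_a p(a|s) [log2 p(s|a) - log2 p(s)]
# Returns the length-|S| profile over target values; p built from counts.
specific_info_profile <- function(t_codes, a_codes, nt, na) {
  cm <- matrix(tabulate(t_codes + nt * a_codes + 1L, nbins = nt * na), nt, na)
  n <- length(t_codes)
  p_t <- rowSums(cm) / n
  p_a <- colSums(cm) / n
  prof <- numeric(nt)
  for (s in seq_len(nt)) {
    if (p_t[s] == 0) next
    sel <- cm[s, ] > 0
    p_as <- cm[s, sel] / sum(cm[s, ])          # p(a|s)
    p_sa <- cm[s, sel] / (n * p_a[sel])         # p(s|a)
    prof[s] <- sum(p_as * (log2(p_sa) - log2(p_t[s])))
  }
  prof
}

# Redundancy of a collection of (joint) sources about the target.
# measure "imin": Williams-Beer I_min = sum_s p(s) min_A I_spec(s; A)
# measure "mmi":  minimal mutual information = min_A I(target; A)
redundancy_value <- function(target, source_list, measure = "imin") {
  target <- as_codes(target)
  nt <- n_codes(target)
  if (measure == "mmi") {
    return(min(vapply(source_list, function(a) {
      a <- as_codes(a)
      plugin_mi_codes(target, a, nt, n_codes(a))
    }, numeric(1))))
  }
  n <- length(target)
  p_t <- tabulate(target + 1L, nbins = nt) / n
  profs <- vapply(source_list, function(a) {
    a <- as_codes(a)
    specific_info_profile(target, a, nt, n_codes(a))
  }, numeric(nt))
  profs <- matrix(profs, nrow = nt)
  sum(p_t * apply(profs, 1, min))
}

# Lattice of antichains of non-empty subsets of k sources (bitmask
# representation). k = 2 gives 4 nodes, k = 3 the 18-node lattice.
pid_lattice_nodes <- function(k) {
  subsets <- seq_len(2^k - 1L)
  colls <- list()
  for (m in seq_len(2^length(subsets) - 1L)) {
    members <- subsets[bitwAnd(m, bitwShiftL(1L, seq_along(subsets) - 1L)) != 0L]
    # antichain: no member contained in another
    ok <- TRUE
    if (length(members) > 1L) {
      for (i in seq_along(members)) for (j in seq_along(members)) {
        if (i != j && bitwAnd(members[i], members[j]) == members[i]) { ok <- FALSE; break }
      }
    }
    if (ok) colls[[length(colls) + 1L]] <- sort(members)
  }
  colls
}

# alpha below-or-equal beta: every B in beta has some A in alpha with A subset of B
lattice_leq <- function(alpha, beta) {
  all(vapply(beta, function(b)
    any(vapply(alpha, function(a) bitwAnd(a, b) == a, logical(1))), logical(1)))
}

node_label <- function(node, k) {
  paste(vapply(node, function(m)
    paste0("{", paste(which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L), collapse = ""), "}"),
    character(1)), collapse = "")
}

#' Partial information decomposition of target information across sources
#'
#' Decomposes the information that 2 or 3 source variables carry about a
#' target into redundancy (shared), per-source unique, and synergy atoms by
#' Moebius inversion of a redundancy measure over the Williams-Beer lattice
#' of source collections. Two redundancy measures are shipped: the
#' Williams-Beer specific-information minimum (`"imin"`, default) and the
#' minimal-mutual-information measure (`"mmi"`). Other redundancy measures
#' can be plugged in as a function `(target, list_of_sources) -> bits`.
#'
#' For two sources the atoms satisfy, exactly,
#' `UI_i + SI = I(target; source_i)` and
#' `SI + UI_1 + UI_2 + CI = I(target; sources jointly)`.
#'
#' @param target 0-based integer code vector.
#' @param sources List of 2 or 3 code vectors of the same length.
#' @param measure `"imin"`, `"mmi"`, or a redundancy function.
#' @return An object of class `pid_atoms` with elements `SI` (redundancy),
#'   `UI` (one per source), `CI` (top-node synergy), `lattice` (tibble of
#'   every lattice atom), `measure`.
#' @export
#' @examples
#' x1 <- rep(0:1, each = 2); x2 <- rep(0:1, times = 2)
#' pid(bitwXor(x1, x2), list(x1, x2))  # pure synergy: CI = 1 bit
pid <- function(target, sources, measure = c("imin", "mmi")) {
  if (is.function(measure)) {
    red_fun <- measure
    measure_tag <- "custom"
  } else {
    measure_tag <- match.arg(measure)
    red_fun <- function(t, sl) redundancy_value(t, sl, measure_tag)
  }
  k <- length(sources)
  if (k < 2L || k > 3L)
    stop("pid supports 2 or 3 sources (the direct method does not scale further)",
         call. = FALSE)
  target <- as_codes(target)
  sources <- lapply(sources, as_codes)
  if (any(lengths(sources) != length(target)))
    stop("target and sources must have equal length", call. = FALSE)
  nodes <- pid_lattice_nodes(k)
  nn <- length(nodes)
  # joint source for each subset mask
  subset_source <- lapply(seq_len(2^k - 1L), function(m) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L)
    do.call(code_join, sources[idx])
  })
  red <- vapply(nodes, function(nd) red_fun(target, subset_source[nd]), numeric(1))
  below <- matrix(FALSE, nn, nn)
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (i != j) below[i, j] <- lattice_leq(nodes[[i]], nodes[[j]])
  }
  pi_atoms <- numeric(nn)
  order_idx <- order(colSums(below))
  for (j in order_idx) {
    pi_atoms[j] <- red[j] - sum(pi_atoms[below[, j]])
  }
  labels <- vapply(nodes, node_label, character(1), k = k)
  full_mask <- 2^k - 1L
  si_node <- which(vapply(nodes, function(nd)
    length(nd) == k && all(nd == bitwShiftL(1L, 0:(k - 1))), logical(1)))
  ui <- vapply(seq_len(k), function(i) {
    pi_atoms[which(vapply(nodes, function(nd)
      length(nd) == 1L && nd == bitwShiftL(1L, i - 1L), logical(1)))]
  }, numeric(1))
  ci <- pi_atoms[which(vapply(nodes, function(nd)
    length(nd) == 1L && nd == full_mask, logical(1)))]
  structure(list(
    SI = pi_atoms[si_node],
    UI = ui,
    CI = ci,
    lattice = tibble::tibble(node = labels, redundancy = red, atom = pi_atoms),
    measure = measure_tag,
    n_sources = k
  ), class = "pid_atoms")
}

#' @export
print.pid_atoms <- function(x, ...) {
  cat(sprintf("<pid_atoms> [%s, %d sources]\n", x$measure, x$n_sources))
  cat(sprintf("  redundancy SI = %.6f bits\n", x$SI))
  for (i in seq_along(x$UI))
    cat(sprintf("  unique UI_%d   = %.6f bits\n", i, x$UI[i]))
  cat(sprintf("  synergy CI    = %.6f bits\n", x$CI))
  invisible(x)
}

#' Information breakdown of pairwise population information
#'
#' Splits the joint stimulus information `I(S; R1, R2)` exactly into the
#' linear term plus three interaction components, built from the
#' independent-conditional reference distribution
#' `P_ind(r|s) = prod_i P(r_i|s)`:
#' \describe{
#'   \item{I_lin}{`sum_i I(S; R_i)` — summed single-unit information.}
#'   \item{I_sig_sim}{signal-similarity term, `I_ind - I_lin`, where `I_ind`
#'     uses `P_ind` as both weight and argument.}
#'   \item{I_cor_ind}{stimulus-independent correlation term.}
#'   \item{I_cor_dep}{stimulus-dependent correlation term — an average
#'     Kullback-Leibler divergence between the true and correlation-blind
#'     posteriors, hence always non-negative. It bounds the information lost
#'     by decoders trained without considering correlations.}
#' }
#' The four terms sum to `I(S; R1, R2)` identically, and
#' `RSI = I_sig_sim + I_cor_ind + I_cor_dep`.
#'
#' @param s Stimulus code vector.
#' @param r1,r2 Response code vectors of the same length.
#' @return An object of class `breakdown_terms` with `I_joint`, `I_lin`,
#'   `I_sig_sim`, `I_cor_ind`, `I_cor_dep`, `RSI`.
#' @export
info_breakdown <- function(s, r1, r2) {
  s <- as_codes(s); r1 <- as_codes(r1); r2 <- as_codes(r2)
  if (length(unique(c(length(s), length(r1), length(r2)))) != 1L)
    stop("inputs must have equal length", call. = FALSE)
  ns <- n_codes(s); n1 <- n_codes(r1); n2 <- n_codes(r2)
  n <- length(s)
  cts <- array(tabulate(s + ns * r1 + ns * n1 * r2 + 1L, nbins = ns * n1 * n2),
               dim = c(ns, n1, n2))
  p_sr <- cts / n                              # P(s, r1, r2)
  p_s <- apply(p_sr, 1, sum)
  p_r <- apply(p_sr, c(2, 3), sum)             # P(r1, r2)
  p_r1_s <- apply(p_sr, c(1, 2), sum) / p_s    # P(r1|s), rows s
  p_r2_s <- apply(p_sr, c(1, 3), sum) / p_s
  # P_ind(r|s) and P_ind(r)
  p_ind_rs <- array(0, dim = c(ns, n1, n2))
  for (si in seq_len(ns)) p_ind_rs[si, , ] <- outer(p_r1_s[si, ], p_r2_s[si, ])
  p_ind_r <- apply(p_ind_rs * p_s, c(2, 3), sum)
  i_lin <- plugin_mi_codes(s, r1, ns, n1) + plugin_mi_codes(s, r2, ns, n2)
  # I_ind: P_ind as both weight and argument
  w <- p_ind_rs * p_s
  sel <- w > 0
  lr <- array(0, dim = dim(p_ind_rs))
  pir <- aperm(array(p_ind_r, dim = c(n1, n2, ns)), c(3, 1, 2))
  lr[sel] <- log2(p_ind_rs[sel] / pir[sel])
  i_ind <- sum(w[sel] * lr[sel])
  i_sig_sim <- i_ind - i_lin
  # I_cor_ind: [P(s,r) - P(s) P_ind(r|s)] log2(P_ind(r|s)/P_ind(r))
  i_cor_ind <- sum((p_sr[sel] - w[sel]) * lr[sel])
  # I_cor_dep: P(s,r) log2( P(r|s) P_ind(r) / (P_ind(r|s) P(r)) )
  sel2 <- p_sr > 0
  p_r_s <- p_sr / p_s                          # P(r|s) via recycling over first dim
  pr_full <- aperm(array(p_r, dim = c(n1, n2, ns)), c(3, 1, 2))
  i_cor_dep <- sum(p_sr[sel2] *
                     log2(p_r_s[sel2] * pir[sel2] / (p_ind_rs[sel2] * pr_full[sel2])))
  i_joint <- plugin_mi_codes(s, code_join(r1, r2), ns, n1 * n2)
  structure(list(I_joint = i_joint, I_lin = i_lin, I_sig_sim = i_sig_sim,
                 I_cor_ind = i_cor_ind, I_cor_dep = i_cor_dep,
                 RSI = i_joint - i_lin),
            class = "breakdown_terms")
}

#' @export
print.breakdown_terms <- function(x, ...) {
  cat("<breakdown_terms> (bits)\n")
  for (nm in c("I_joint", "I_lin", "I_sig_sim", "I_cor_ind", "I_cor_dep", "RSI"))
    cat(sprintf("  %-10s %+.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' Redundancy-synergy index
#'
#' `RSI = I(S; joint response) - sum_i I(S; R_i)`. Positive values indicate
#' predominantly synergistic interactions between the response variables,
#' negative values predominantly redundant ones.
#'
#' @param s Stimulus code vector.
#' @param responses List of >= 2 response code vectors.
#' @return RSI in bits.
#' @export
rsi <- function(s, responses) {
  if (!is.list(responses) || length(responses) < 2L)
    stop("rsi needs a list of at least 2 response variables", call. = FALSE)
  s <- as_codes(s)
  responses <- lapply(responses, as_codes)
  joint <- do.call(code_join, responses)
  i_joint <- plugin_mi_codes(s, joint, n_codes(s), n_codes(joint))
  i_sum <- sum(vapply(responses, function(r)
    plugin_mi_codes(s, r, n_codes(s), n_codes(r)), numeric(1)))
  i_joint - i_sum
}

#' Intersection information between stimulus, response and choice
#'
#' The component of neural information that is simultaneously about the
#' stimulus and used to inform the choice: the redundancy atom that response
#' and choice share about the stimulus, symmetrized by taking the minimum
#' over the two PID orientations (target = stimulus and target = choice).
#' Guarantees `II <= I(S;R)`, `II <= I(S;C)` and `II <= I(R;C)`.
#'
#' @param s Stimulus codes.
#' @param r Response codes (possibly a decoded/compressed response).
#' @param c_codes Choice codes.
#' @param measure Redundancy measure passed to [pid()].
#' @return Intersection information in bits.
#' @export
intersection_information <- function(s, r, c_codes, measure = "imin") {
  s <- as_codes(s); r <- as_codes(r); c_codes <- as_codes(c_codes)
  if (length(unique(c(length(s), length(r), length(c_codes)))) != 1L)
    stop("inputs must have equal length", call. = FALSE)
  if (n_codes(c_codes) < 2L || length(unique(c_codes)) < 2L) {
    warning("constant choice variable; intersection information is 0")
    return(0)
  }
  si_s <- pid(s, list(r, c_codes), measure = measure)$SI
  si_c <- pid(c_codes, list(r, s), measure = measure)$SI
  min(si_s, si_c)
}

#' Export PID or breakdown results as a tidy table / CSV
#'
#' @param x A `pid_atoms` or `breakdown_terms` object.
#' @param path Optional CSV path (one atom per row, with method metadata).
#' @return A tibble.
#' @export
decomposition_to_csv <- function(x, path = NULL) {
  out <- if (inherits(x, "pid_atoms")) {
    tibble::tibble(
      atom = c("redundancy", paste0("unique_", seq_along(x$UI)), "synergy"),
      bits = c(x$SI, x$UI, x$CI),
      measure = x$measure)
  } else if (inherits(x, "breakdown_terms")) {
    tibble::tibble(
      atom = c("I_joint", "I_lin", "I_sig_sim", "I_cor_ind", "I_cor_dep", "RSI"),
      bits = unlist(x[c("I_joint", "I_lin", "I_sig_sim", "I_cor_ind",
                        "I_cor_dep", "RSI")], use.names = FALSE),
      measure = "plugin")
  } else stop("unsupported object", call. = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
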