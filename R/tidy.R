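# broom-style tidy()/glance() methods and ggplot2 autoplot()s for the
# result types, so pipelines compose with the tidyverse.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.info_estimate <- function(x, ...) {
  tibble::tibble(value = x$value, method = x$method,
                 plugin = x$plugin_value, bias = x$bias_term,
                 p_value = if (is.null(x$null_summary)) NA_real_
                           else x$null_summary$p_value)
}

#' @export
tidy.pid_atoms <- function(x, ...) {
  tibble::tibble(
    atom = c("redundancy", paste0("unique_", seq_along(x$UI)), "synergy"),
    bits = c(x$SI, x$UI, x$CI),
    measure = x$measure)
}

#' @export
glance.pid_atoms <- function(x, ...) {
  tibble::tibble(measure = x$measure, n_sources = x$n_sources,
                 total = sum(x$lattice$atom))
}

#' @export
tidy.breakdown_terms <- function(x, ...) {
  tibble::tibble(
    term = c("I_lin", "I_sig_sim", "I_cor_ind", "I_cor_dep"),
    bits = c(x$I_lin, x$I_sig_sim, x$I_cor_ind, x$I_cor_dep))
}

#' @export
glance.breakdown_terms <- function(x, ...) {
  tibble::tibble(I_joint = x$I_joint, RSI = x$RSI)
}

#' @export
tidy.null_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = mean(x$null_values),
                 null_sd = stats::sd(x$null_values), p_value = x$p_value,
                 n_perm = x$n_perm)
}

#' @export
tidy.transfer_sweep <- function(x, ...) {
  out <- x$grid
  out$measure <- x$measure
  out$sender <- x$sender
  out$receiver <- x$receiver
  out
}

#' @export
glance.transfer_sweep <- function(x, ...) {
  tibble::tibble(measure = x$measure, sender = x$sender, receiver = x$receiver,
                 max_value = x$max_value, best_delay = x$best_delay,
                 edge_p = x$edge_p, n_perm = x$n_perm)
}

#' @export
tidy.decoder_result <- function(x, ...) {
  df <- as.data.frame(x$confusion)
  tibble::tibble(true = df$true, decoded = df$decoded, n = df$Freq)
}

#' @export
glance.decoder_result <- function(x, ...) {
  tibble::tibble(decoder = x$decoder, label = x$label, folds = x$folds,
                 info = x$info$value, info_method = x$info$method,
                 accuracy = sum(diag(x$confusion)) / sum(x$confusion))
}

#' @export
tidy.scaling_curve <- function(x, ...) x$curve

#' @export
glance.scaling_curve <- function(x, ...) {
  tibble::tibble(decoder = x$decoder,
                 reference = if (is.null(x$reference)) NA_real_ else x$reference,
                 crossing_N = x$crossing_N)
}

#' @export
autoplot.breakdown_terms <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$bits)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(y = "information (bits)", x = NULL,
                  title = sprintf("Information breakdown (I_joint = %.3f, RSI = %+.3f bits)",
                                  object$I_joint, object$RSI)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pid_atoms <- function(object, ...) {
  df <- tidy(object)
  df$atom <- factor(df$atom, levels = df$atom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atom, y = .data$bits)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "information (bits)", x = NULL,
                  title = sprintf("Partial information decomposition (%s)", object$measure)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_result <- function(object, ...) {
  df <- tibble::tibble(value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "statistic (bits)", y = "surrogates",
                  title = sprintf("Permutation null (p = %.3g)", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.transfer_sweep <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$time, y = .data$delay, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "bits") +
    ggplot2::labs(x = "time (samples)", y = "delay (samples)",
                  title = sprintf("%s %s → %s", toupper(object$measure),
                                  object$sender, object$receiver)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scaling_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$N, y = .data$mean_info)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_info - .data$sem,
                                      ymax = .data$mean_info + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "population size N", y = "information (bits)") +
    ggplot2::theme_minimal()
  if (!is.null(object$reference))
    p <- p + ggplot2::geom_hline(yintercept = object$reference, linetype = 2)
  p
}

#' @importFrom rlang .data
NULL
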