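# Delimited-text I/O for trial-structured data and run configuration.
# Single-window data use a wide CSV/TSV (one row per trial, one column per
# unit plus the label columns); time-resolved data use a long CSV
# (trial, unit, time, value) since a flat table cannot express three axes.

#' Read trial-structured data from a delimited text file
#'
#' Wide layout: one row per trial, a header row, one column per unit plus a
#' stimulus column and optionally a choice column. The delimiter is
#' inferred from the file extension (`.tsv` = tab, otherwise comma).
#'
#' @param path File path.
#' @param stimulus_col Name of the stimulus column (default `"stim"`).
#' @param choice_col Optional name of the choice column.
#' @param unit_cols Optional character vector of unit columns; defaults to
#'   every remaining column.
#' @param na_policy `"error"` (default) or `"drop"` (remove rows with
#'   missing values, reporting how many).
#' @return A [labeled_trials()] object.
#' @export
read_trials <- function(path, stimulus_col = "stim", choice_col = NULL,
                        unit_cols = NULL, na_policy = c("error", "drop")) {
  na_policy <- match.arg(na_policy)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  for (col in c(stimulus_col, choice_col)) {
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  }
  if (is.null(unit_cols)) unit_cols <- setdiff(names(df), c(stimulus_col, choice_col))
  missing_units <- setdiff(unit_cols, names(df))
  if (length(missing_units))
    stop("missing unit column(s): ", paste(missing_units, collapse = ", "),
         call. = FALSE)
  bad <- !stats::complete.cases(df[, c(unit_cols, stimulus_col, choice_col)])
  if (any(bad)) {
    if (na_policy == "error")
      stop("missing values in row(s) ", paste(which(bad), collapse = ", "),
           "; use na_policy = 'drop' to remove them", call. = FALSE)
    message("dropped ", sum(bad), " row(s) with missing values")
    df <- df[!bad, , drop = FALSE]
  }
  labeled_trials(as.matrix(df[, unit_cols, drop = FALSE]),
                 stimulus = df[[stimulus_col]],
                 choice = if (!is.null(choice_col)) df[[choice_col]],
                 unit_ids = unit_cols)
}

#' Write trial-structured data to CSV
#'
#' Single-time-bin data are written wide (trials x columns); data with a
#' time axis are written in long format (`trial`, `unit`, `time_ms`,
#' `value`) with the labels repeated per row.
#'
#' @param data A [labeled_trials()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  stopifnot(inherits(data, "labeled_trials"))
  d <- dim(data$activity)
  if (d[3] == 1L) {
    df <- as.data.frame(data$activity[, , 1, drop = TRUE])
    if (d[2] == 1L) df <- data.frame(V1 = data$activity[, 1, 1])
    names(df) <- data$unit_ids
    df$stim <- data$stimulus
    if (!is.null(data$choice)) df$choice <- data$choice
  } else {
    df <- expand.grid(trial = seq_len(d[1]), unit = data$unit_ids,
                      time_ms = data$time_ms, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    df$value <- as.vector(data$activity)
    df$stim <- data$stimulus[df$trial]
    if (!is.null(data$choice)) df$choice <- data$choice[df$trial]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read long-format time-resolved trial data
#'
#' Inverse of [write_trials()] for the long layout (`trial`, `unit`,
#' `time_ms`, `value`, `stim`, optionally `choice`).
#'
#' @param path CSV path.
#' @return A [labeled_trials()] object.
#' @export
read_trials_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "unit", "time_ms", "value", "stim")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  trials <- sort(unique(df$trial))
  units <- unique(df$unit)
  times <- sort(unique(df$time_ms))
  act <- array(NA_real_, dim = c(length(trials), length(units), length(times)))
  ti <- match(df$trial, trials); ui <- match(df$unit, units)
  zi <- match(df$time_ms, times)
  act[cbind(ti, ui, zi)] <- df$value
  if (anyNA(act)) stop("ragged long file: some (trial, unit, time) cells missing",
                       call. = FALSE)
  stim <- df$stim[match(trials, df$trial)]
  choice <- if ("choice" %in% names(df)) df$choice[match(trials, df$trial)]
  labeled_trials(act, stim, choice, unit_ids = units, time_ms = times)
}

#' Run configuration for scripted analyses
#'
#' Bundles input paths, variable roles, binning and correction specs, the
#' measure selection, permutation count and the mandatory seed; serializes
#' to/from JSON so every output can embed the configuration it was produced
#' with.
#'
#' @param input Input file path(s).
#' @param stimulus_col,choice_col Column roles for [read_trials()].
#' @param bin A [bin_spec()].
#' @param correction A [correction_spec()].
#' @param measure Measure name (free-form; interpreted by the caller/CLI).
#' @param n_perm Number of permutations.
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, stimulus_col = "stim", choice_col = NULL,
                       bin = bin_spec("none"), correction = correction_spec("naive"),
                       measure = "info", n_perm = 0L, seed, out_dir = ".") {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(input = input, stimulus_col = stimulus_col,
                 choice_col = choice_col, bin = bin, correction = correction,
                 measure = measure, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$bin <- unclass(x$bin)[!vapply(x$bin, is.null, logical(1))]
  x$correction <- unclass(x$correction)[!vapply(x$correction, is.null, logical(1))]
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  run_config(input = x$input, stimulus_col = x$stimulus_col,
             choice_col = x$choice_col,
             bin = bin_spec(x$bin$method,
                            n_bins = if (is.null(x$bin$n_bins)) 2L else x$bin$n_bins,
                            edges = x$bin$edges, cap = x$bin$cap),
             correction = correction_spec(x$correction$method,
                                          n_surrogates = if (is.null(x$correction$n_surrogates)) 100L
                                                         else x$correction$n_surrogates,
                                          seed = x$correction$seed),
             measure = x$measure, n_perm = x$n_perm, seed = x$seed,
             out_dir = x$out_dir)
}
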