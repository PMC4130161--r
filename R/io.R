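# Delimited-text I/O: tidy trace tables, ground-truth sidecars, flat
# key-value run configs, and machine-readable analysis reports.

#' Write a trace table to tab-separated text
#'
#' One row per frame per channel per spot: `spot_id`, `channel`, `time_s`,
#' `intensity`.
#'
#' @param x An `"sv_experiment"` or a long trace-table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  if (inherits(x, "sv_experiment")) x <- as_trace_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tidy trace table
#'
#' Validates the schema (`spot_id`, `channel`, `time_s`, `intensity`),
#' finiteness of intensities, and per-(spot, channel) time ordering.
#'
#' @param path Path to a tab- or comma-separated trace table.
#' @return Data frame with one row per frame per channel per spot.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop("trace table not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("spot_id", "channel", "time_s", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trace table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$intensity))
  if (length(bad) > 0)
    stop("non-finite intensity at row ", bad[1L])
  if (nrow(df) > 0) {
    ord <- tapply(df$time_s, interaction(df$spot_id, df$channel, drop = TRUE),
                  function(t) !is.unsorted(t, strictly = TRUE))
    if (!all(unlist(ord))) {
      badkey <- names(ord)[!unlist(ord)][1L]
      stop("unsorted times for spot/channel ", badkey)
    }
  }
  df
}

#' Write the ground-truth sidecar table
#'
#' @param experiment An `"sv_experiment"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(experiment, path) {
  utils::write.table(experiment$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar table
#'
#' @param path Path written by [write_truth_table()].
#' @return Data frame `spot_id`, `truth_fate`, `truth_assoc_time`,
#'   `truth_fusion_time`.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("spot_id", "truth_fate", "truth_assoc_time", "truth_fusion_time")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("truth table is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Read a flat key-value run configuration
#'
#' Accepts `key = value` or `key: value` lines; `#` starts a comment.
#' Keys mirror the [ground_truth()] and [acquisition_schedule()] field
#' names plus the detection/analysis parameters. Values that parse as
#' numbers are returned numeric.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- m[2L]
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value run configuration
#'
#' @param config Named list of scalar values.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 15)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a machine-readable analysis report
#'
#' Writes `report.json` (counts, per-round tallies, rates, fit parameters
#' with standard errors, comparison p values, and the exact configuration
#' used, so the report is self-describing) plus one TSV per histogram.
#' Re-running on identical inputs reproduces byte-identical files.
#'
#' @param event_table An `"sv_event_table"`.
#' @param histograms Named list of [fusion_histogram()] objects (may be
#'   empty).
#' @param fits Named list of `"decay_fit"` objects (may be empty).
#' @param comparisons Named list of `"sv_comparison"` objects (may be
#'   empty).
#' @param dir_path Output directory (created if needed).
#' @param config Named list echoed into the report as provenance (seeds,
#'   parameters).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(event_table, histograms = list(), fits = list(),
                         comparisons = list(), dir_path,
                         config = list()) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir_path)) stop("cannot create report directory: ", dir_path)

  report <- list(
    software = list(package = "svfusion",
                    version = as.character(utils::packageVersion("svfusion"))),
    config = config,
    condition = event_table$condition,
    t_Ca = as.list(event_table$t_Ca),
    counts = list(n_traces = nrow(event_table$records),
                  n_associated = event_table$n_associated,
                  n_spontaneous = event_table$n_spontaneous,
                  n_triggered = event_table$n_triggered,
                  n_excluded = event_table$n_excluded),
    per_round = per_round_counts(event_table)
  )
  if (event_table$n_associated > 0)
    report$spontaneous_rate <- spontaneous_rate(event_table)
  if (length(fits) > 0)
    report$fits <- lapply(fits, function(f)
      list(A = f$A, lambda = f$lambda, se_A = f$se_A,
           se_lambda = f$se_lambda, rss = f$rss,
           n_bins_used = f$n_bins_used))
  if (length(comparisons) > 0)
    report$comparisons <- lapply(comparisons, function(cmp)
      list(mean_a = cmp$mean_a, mean_b = cmp$mean_b, sd_a = cmp$sd_a,
           sd_b = cmp$sd_b, n_a = cmp$n_a, n_b = cmp$n_b, t = cmp$t,
           p_value = cmp$p_value, significant = cmp$significant))

  json_path <- file.path(dir_path, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  paths <- json_path
  for (nm in names(histograms)) {
    h <- histograms[[nm]]
    hp <- file.path(dir_path, paste0("histogram_", nm, ".tsv"))
    utils::write.table(
      data.frame(bin_left_s = h$left, counts = h$counts,
                 normalized = h$normalized),
      hp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, hp)
  }
  invisible(paths)
}
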