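#' Write a time series to CSV
#'
#' Comma-separated, `.` decimal, UTF-8; a `# t:min S:mM` comment line
#' documents the units, followed by a `t,S` header. Values are written
#' with 17 significant digits so a read/write round trip is exact.
#'
#' @param series a [time_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  stopifnot(inherits(series, "time_series"))
  lines <- c("# t:min S:mM", "t,S",
             paste(format(series$t, digits = 17, scientific = FALSE, trim = TRUE),
                   format(series$S, digits = 17, scientific = FALSE, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a time series from CSV
#'
#' Expects a `t,S` header; lines starting with `#` are ignored. The
#' [time_series()] invariants (strictly increasing t, non-negative S,
#' at least 2 rows) are enforced with errors naming the offending row.
#'
#' @param path CSV file path.
#' @return A [time_series()] labelled with the file name.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop_f("file not found: %s", path)
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) stop_f("cannot parse %s: %s", path, conditionMessage(e)))
  if (!all(c("t", "S") %in% names(df))) {
    stop_f("%s: missing required columns `t` and `S`", path)
  }
  if (nrow(df) < 2) stop_f("%s: a time series needs at least 2 rows, found %d",
                           path, nrow(df))
  t <- as.numeric(df$t); S <- as.numeric(df$S)
  if (any(is.na(t)) || any(is.na(S))) {
    stop_f("%s: non-numeric value in row %d", path,
           which(is.na(t) | is.na(S))[1])
  }
  if (any(diff(t) <= 0)) {
    stop_f("%s: `t` not strictly increasing at row %d", path,
           which(diff(t) <= 0)[1] + 1L)
  }
  if (any(S < 0)) stop_f("%s: negative `S` in row %d", path, which(S < 0)[1])
  time_series(t, S, label = basename(path))
}

# plain-list views for JSON serialization ------------------------------------

design_to_list <- function(design) {
  list(model = list(n = design$model$n, v_max = design$model$v_max,
                    K_m = design$model$K_m),
       S0 = design$S0, m_points = design$m_points,
       t_end = design$t_end, t_end_spec = design$t_end_spec,
       sigma = design$noise$sigma, n_replicates = design$n_replicates,
       master_seed = design$master_seed,
       replicate_seeds = vapply(seq_len(design$n_replicates) - 1L,
                                function(k) derive_stream_seed(design$master_seed, k),
                                integer(1)))
}

verdict_to_list <- function(verdict) {
  out <- list(method = verdict$method,
              selected_order = if (is.na(verdict$selected_order)) NULL else verdict$selected_order,
              rejected_orders = verdict$rejected_orders,
              indistinguishable_orders = verdict$indistinguishable_orders,
              excluded_orders = verdict$excluded_orders,
              diagnostics = verdict$diagnostics)
  if (!is.null(verdict$eps_range_used)) out$eps_range_used <- verdict$eps_range_used
  if (!is.null(verdict$steady_state_reached)) {
    out$steady_state_reached <- as.list(verdict$steady_state_reached)
  }
  if (!is.null(verdict$summary)) out$summary <- verdict$summary
  out
}

write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# tidy per-point curve table: family, order, replicate, eps, rho
curves_to_table <- function(curves_nested) {
  rows <- list()
  for (per_cand in curves_nested) {
    for (cv in per_cand) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = cv$family, order = cv$candidate_order,
        replicate = cv$replicate_index, eps = cv$eps_grid, rho = cv$rho)
    }
  }
  do.call(rbind, rows)
}

#' Read a run configuration file
#'
#' A single human-readable structured file; YAML and JSON are both
#' accepted (JSON is a YAML subset). Command-line flags override
#' configuration values.
#'
#' @param path configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_f("config file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
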