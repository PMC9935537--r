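#' Trace CSV and manifest JSON round trip
#'
#' Traces are plain CSV with columns `time_s`, `temperature_C`,
#' `absorbance_AU` (plus optional per-species molarity columns for simulated
#' traces). Numbers are written with 17 significant digits so
#' write -> read -> write is byte-identical.
#'
#' @param trace a `th_trace`
#' @param path file path
#' @param conditions list of conditions to attach on read (usually from the
#'   manifest); if `NULL`, taken from the file's companion manifest row
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `th_trace`
#' @export
write_trace_csv <- function(trace, path) {
  cols <- names(trace)
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(paste(cols, collapse = ","),
             do.call(paste, c(lapply(trace[cols], fmt), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, conditions = NULL) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("time_s", "temperature_C", "absorbance_AU")
  if (!all(need %in% names(df)))
    stop("malformed trace CSV ", path, ": needs columns ",
         paste(need, collapse = ", "))
  if (any(diff(df$time_s) <= 0) && !all(is.na(df$time_s)))
    stop("malformed trace CSV ", path, ": time_s must be strictly increasing")
  attr(df, "conditions") <- conditions
  class(df) <- c("th_trace", "data.frame")
  df
}

#' Write / read a full dataset (trace CSVs + manifest JSON)
#'
#' @param dataset a `th_dataset` from [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` a
#'   `th_dataset`
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- attr(dataset, "manifest")
  for (i in seq_along(dataset))
    write_trace_csv(dataset[[i]], file.path(dir, manifest$file[i]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mpath)
  traces <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    read_trace_csv(file.path(dir, row$file),
                   conditions = list(C_tot = row$C_tot_strand_uM * 1e-6,
                                     direction = row$direction,
                                     rate = row$rate_C_per_min,
                                     path_length = row$path_length_cm,
                                     init_protocol = row$init_protocol))
  })
  names(traces) <- manifest$trace_id
  structure(traces, manifest = manifest, class = "th_dataset")
}

#' Serialise fit and comparison results to JSON
#'
#' @param x a `fit_result` or `f_test_result`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_fit_json <- function(x, path) {
  obj <- list(model = x$model_name,
              rss = x$rss, n_points = x$n_points, n_params = x$n_params,
              converged = x$converged,
              dialect = x$params$dialect, T_ref = x$params$T_ref,
              steps = lapply(x$params$steps, unclass),
              baseline = as.list(x$params$baseline),
              package_version = as.character(utils::packageVersion("imotifTH")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  steps <- lapply(obj$steps, function(s) do.call(rate_params, s))
  structure(list(params = parameter_set(steps,
                                        unlist(obj$baseline),
                                        dialect = obj$dialect,
                                        T_ref = obj$T_ref),
                 rss = obj$rss, n_points = obj$n_points,
                 n_params = obj$n_params, converged = obj$converged,
                 model_name = obj$model),
            class = "fit_result")
}

#' @rdname write_fit_json
#' @export
write_ftest_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
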