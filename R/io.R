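#' Write and read trace tables
#'
#' Traces serialize to CSV with a header row and a fixed column order
#' (`time` first); time is written with six decimal places.  Writers and
#' readers are mutual inverses on valid data.
#'
#' @param table a trace `data.frame` (first column `time`).
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` the
#'   `data.frame`.
#' @export
write_trace <- function(table, path) {
  if (!is.data.frame(table) || !nrow(table))
    tcob_abort("tcob_io_error", "table must be a non-empty data.frame")
  tab <- table
  if ("time" %in% names(tab)) tab$time <- sprintf("%.6f", tab$time)
  ok <- tryCatch({
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) tcob_abort("tcob_io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    tcob_abort("tcob_io_error", sprintf("no such file: '%s'", path))
  read.csv(path, check.names = FALSE)
}

#' Write and read spike-time files
#'
#' Plain text, one spike time (ms) per line; an empty train writes an
#' empty file that reads back empty.
#'
#' @param train a [spike_train()] or numeric vector of times.
#' @param path file path.
#' @param source identifier attached to the train read back.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` a
#'   [spike_train()].
#' @export
write_spikes <- function(train, path) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  ok <- tryCatch({
    writeLines(sprintf("%.6f", times), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) tcob_abort("tcob_io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, source = NA_character_) {
  if (!file.exists(path))
    tcob_abort("tcob_io_error", sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(spike_train(numeric(), source))
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    tcob_abort("tcob_io_error",
               sprintf("malformed spike time at line %d of '%s'",
                       which(is.na(vals))[1], path))
  spike_train(vals, source)
}

#' Read a JSON or YAML configuration file
#'
#' The format is chosen by extension: `.json` via jsonlite, `.yml`/`.yaml`
#' via yaml.
#'
#' @param path configuration file.
#' @return the parsed list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    tcob_abort("tcob_io_error", sprintf("no such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    return(jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE))
  if (ext %in% c("yml", "yaml"))
    return(yaml::read_yaml(path))
  tcob_abort("tcob_io_error",
             sprintf("unknown config format '.%s' (use .json or .yaml)", ext))
}

#' Write a run manifest
#'
#' Echoes every resolved parameter, the seed and the grid into a JSON
#' manifest next to the outputs, for reproducibility.
#'
#' @param params named list of resolved parameters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
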