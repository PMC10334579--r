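#' Structured run log
#'
#' Append-only JSON-lines log of pipeline events. Every event is written
#' and flushed as its own JSON object (one per line), so the log remains
#' parseable even after abnormal termination. Events carry a schema
#' version, timestamp, stage name, event type, optional message and a
#' parameter record.
#'
#' @param path Path of the log file (created or appended to).
#' @return A `RunLog` handle to pass to [log_event()].
#' @export
run_log_open <- function(path) {
  if (!file.exists(path)) file.create(path)
  structure(list(path = path), class = "RunLog")
}

#' Append an event to a run log
#'
#' No-op when `log` is `NULL`, so pipeline code can log unconditionally.
#'
#' @param log A `RunLog` from [run_log_open()], or `NULL`.
#' @param stage Pipeline stage name (e.g., `"transport"`).
#' @param type `"info"` or `"warning"`.
#' @param message Optional human-readable message.
#' @param params Optional named list of parameters/values.
#' @return Invisibly, the event list.
#' @export
log_event <- function(log, stage, type = "info", message = NULL,
                      params = NULL) {
  if (is.null(log)) return(invisible(NULL))
  event <- list(schema = "1.0",
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                stage = stage, type = type)
  if (!is.null(message)) event$message <- message
  if (!is.null(params)) event$params <- params
  line <- jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA)
  con <- file(log$path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(event)
}

#' Read a run log back as a list of events
#'
#' @param path Path written by [log_event()].
#' @return List of event lists.
#' @export
read_run_log <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON)
}
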