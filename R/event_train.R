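#' Event trains
#'
#' An event train is a strictly increasing vector of non-negative event times
#' in seconds. `event_train()` validates and tags a numeric vector;
#' `read_event_train()` / `write_event_train()` exchange the plain-text
#' format used throughout the package: one ASCII-decimal event time per line.
#'
#' @param times numeric vector of event times in s
#' @return `event_train()` returns the validated vector with class
#'   `event_train`
#' @export
event_train <- function(times) {
  times <- as.numeric(times)
  if (length(times) == 0) stop("event train must contain at least one event")
  if (any(!is.finite(times))) stop("event times must be finite")
  if (any(times < 0)) stop("event times must be non-negative")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing")
  }
  structure(times, class = "event_train")
}

#' @rdname event_train
#' @param path file path
#' @export
read_event_train <- function(path) {
  event_train(scan(path, what = double(), quiet = TRUE,
                   comment.char = "#"))
}

#' @rdname event_train
#' @param train an event train (or plain numeric vector of times)
#' @param digits significant digits written
#' @export
write_event_train <- function(train, path, digits = 12) {
  train <- event_train(unclass(train))
  writeLines(formatC(as.numeric(train), digits = digits, format = "g"), path)
  invisible(path)
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event train> %d events on [%.4g, %.4g] s\n",
              length(x), min(x), max(x)))
  invisible(x)
}
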