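#' Spike trains on a millisecond grid
#'
#' A `spike_train` is an ordered set of spike times on an integer 1-ms grid
#' over a single episode of `length_ms` milliseconds. Times are 0-based, so
#' all events lie in `[0, length_ms)` with at most one event per step.
#'
#' @param times Integer vector of spike times (ms, 0-based grid positions),
#'   strictly increasing.
#' @param length_ms Episode duration in ms.
#'
#' @return An object of class `spike_train` with fields `times` and
#'   `length_ms`.
#' @examples
#' st <- spike_train(c(3, 10, 42), length_ms = 200)
#' n_spikes(st)
#' @export
spike_train <- function(times = integer(), length_ms) {
  if (length(length_ms) != 1L || is.na(length_ms) || length_ms <= 0) {
    stop("`length_ms` must be a single positive number", call. = FALSE)
  }
  times <- as.integer(round(times))
  if (anyNA(times)) stop("spike times must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    times <- sort(unique(times))
  }
  if (length(times) && (times[1] < 0L || times[length(times)] >= length_ms)) {
    stop("spike times must lie in [0, length_ms)", call. = FALSE)
  }
  structure(
    list(times = times, length_ms = as.integer(length_ms)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %d spikes over %d ms\n", length(x$times), x$length_ms
  ))
  if (length(x$times)) {
    cat("  times (ms):", paste(utils::head(x$times, 20), collapse = " "),
        if (length(x$times) > 20) "..." else "", "\n")
  }
  invisible(x)
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  length(x$times)
}

#' Convert a spike train to a 0/1 vector, one element per 1-ms step
#'
#' @param x A `spike_train`.
#' @return Integer vector of length `length_ms` with 1 at spike steps.
#' @export
as_binary <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  v <- integer(x$length_ms)
  v[x$times + 1L] <- 1L
  v
}

#' Build a spike train from a 0/1 step vector
#'
#' @param bits 0/1 (or logical) vector, one element per 1-ms step.
#' @return A `spike_train` of length `length(bits)` ms.
#' @export
spike_train_from_binary <- function(bits) {
  spike_train(which(as.logical(bits)) - 1L, length_ms = length(bits))
}
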