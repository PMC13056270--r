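#' Event sequences
#'
#' An `event_seq` is the universal currency of the package: a strictly
#' increasing vector of event timestamps in milliseconds, tagged with the kind
#' of event it records (`"stimulus"`, `"spike"` or `"chirp"`).
#'
#' @param times numeric vector of event times in ms; strictly increasing,
#'   all non-negative.
#' @param kind one of `"stimulus"`, `"spike"`, `"chirp"`.
#' @return An object of class `event_seq`: a numeric vector with a `kind`
#'   attribute.
#' @examples
#' event_seq(c(0, 250, 500), kind = "stimulus")
#' @export
event_seq <- function(times, kind = c("stimulus", "spike", "chirp")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) == 0) stop("event_seq: at least one event time required")
  if (anyNA(times)) stop("event_seq: times must not contain NA")
  if (any(times < 0)) stop("event_seq: all times must be >= 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("event_seq: times must be strictly increasing")
  structure(times, kind = kind, class = "event_seq")
}

#' @export
print.event_seq <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<event_seq> %d %s events spanning %.1f ms\n",
              n, attr(x, "kind"), if (n > 1) x[n] - x[1] else 0))
  if (n > 6) {
    cat("  times:", paste(signif(utils::head(unclass(x), 3), 6), collapse = ", "),
        "...", paste(signif(utils::tail(unclass(x), 2), 6), collapse = ", "), "\n")
  } else {
    cat("  times:", paste(signif(unclass(x), 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a Poisson event train
#'
#' Draws `n_intervals` i.i.d. exponential inter-event gaps with mean
#' `1000/rate` ms and cumulates them, giving a homogeneous Poisson process
#' observed by event count. This is the "random" stimulus class: its rhythm
#' ratios are Uniform(0, 1) by construction (the ratio of two i.i.d.
#' exponentials i/(i + j) is uniform).
#'
#' @param rate mean event rate in Hz (events per second); must be positive.
#' @param n_intervals number of inter-event intervals; the returned sequence
#'   has `n_intervals + 1` events.
#' @param seed optional integer seed for reproducibility.
#' @param start time of the first event in ms.
#' @return An `event_seq` of kind `"stimulus"`.
#' @examples
#' s <- generate_poisson(rate = 2, n_intervals = 100, seed = 1)
#' mean(diff(s))  # approx 500 ms
#' @export
generate_poisson <- function(rate, n_intervals, seed = NULL, start = 0) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("generate_poisson: 'rate' must be a positive number (Hz)")
  if (!is.numeric(n_intervals) || length(n_intervals) != 1 || n_intervals < 1)
    stop("generate_poisson: 'n_intervals' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  gaps <- stats::rexp(n_intervals, rate = rate / 1000)  # mean 1000/rate ms
  event_seq(start + c(0, cumsum(gaps)), kind = "stimulus")
}

#' Generate an isochronous event train
#'
#' Perfectly periodic events with period `1000/frequency` ms, the most
#' structured stimulus class; every rhythm ratio of the output equals 0.5.
#'
#' @param frequency event frequency in Hz; must be positive.
#' @param n_events number of events (>= 2).
#' @param start time of the first event in ms.
#' @return An `event_seq` of kind `"stimulus"`.
#' @examples
#' generate_isochronous(frequency = 4, n_events = 5)
#' @export
generate_isochronous <- function(frequency, n_events, start = 0) {
  if (!is.numeric(frequency) || length(frequency) != 1 ||
      !is.finite(frequency) || frequency <= 0)
    stop("generate_isochronous: 'frequency' must be a positive number (Hz)")
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 2)
    stop("generate_isochronous: 'n_events' must be >= 2")
  period <- 1000 / frequency
  event_seq(start + period * (seq_len(n_events) - 1), kind = "stimulus")
}

#' Input-frequency ratio
#'
#' The dimensionless statistic f_input / (f_input + f_model) locating a forcing
#' frequency relative to a model's intrinsic frequency: 0.5 means the two match
#' (1:1); an input three times faster (3:1) gives 0.75; slower inputs give
#' values below 0.5.
#'
#' @param f_input input (forcing) frequency in Hz.
#' @param f_model the model's intrinsic frequency in Hz.
#' @return A scalar in (0, 1).
#' @seealso [input_rate_for_ratio()] for the inverse.
#' @export
frequency_ratio <- function(f_input, f_model) {
  if (!is.numeric(f_input) || !is.numeric(f_model) ||
      any(!is.finite(f_input)) || any(!is.finite(f_model)) ||
      any(f_input <= 0) || any(f_model <= 0))
    stop("frequency_ratio: both frequencies must be positive and finite")
  f_input / (f_input + f_model)
}

#' Input rate realising a given frequency ratio
#'
#' Inverse of [frequency_ratio()]: the forcing frequency such that
#' `frequency_ratio(result, f_model)` equals `ratio`. Used to lay out sweep
#' grids on the frequency-ratio axis.
#'
#' @param ratio target frequency ratio, strictly inside (0, 1).
#' @param f_model the model's intrinsic frequency in Hz.
#' @return Forcing frequency in Hz.
#' @export
input_rate_for_ratio <- function(ratio, f_model) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) ||
      any(ratio <= 0) || any(ratio >= 1))
    stop("input_rate_for_ratio: 'ratio' must lie strictly inside (0, 1)")
  if (!is.numeric(f_model) || any(!is.finite(f_model)) || any(f_model <= 0))
    stop("input_rate_for_ratio: 'f_model' must be positive")
  f_model * ratio / (1 - ratio)
}

#' Read / write event sequences as CSV
#'
#' The on-disk dialect is a two-column CSV `time_ms,kind` with a header row.
#' `read_events()` also accepts a bare single-column list of times (no header),
#' in which case `kind` defaults to `"stimulus"`.
#'
#' @param x an `event_seq`.
#' @param path file path.
#' @return `read_events()` returns an `event_seq`; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_seq"))
  utils::write.csv(
    data.frame(time_ms = as.numeric(x), kind = attr(x, "kind")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("time_ms", first, fixed = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    kind <- if ("kind" %in% names(df) && nrow(df) > 0) df$kind[1] else "stimulus"
    if (!kind %in% c("stimulus", "spike", "chirp")) kind <- "stimulus"
    event_seq(df$time_ms, kind = kind)
  } else {
    event_seq(scan(path, what = numeric(), quiet = TRUE), kind = "stimulus")
  }
}
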