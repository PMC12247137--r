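#' Construct a fluorescence recording
#'
#' Container for an in vivo calcium-imaging session: a wide tibble of raw
#' fluorescence traces (first column `time` in seconds, one column per neuron,
#' arbitrary units), the frame rate, and the stimulus-epoch table. Fluorescence
#' must be strictly positive (the baseline division downstream is undefined
#' otherwise) and epoch onsets strictly increasing within the recording.
#'
#' @param traces Tibble/data frame whose first column is `time` (seconds) and
#'   remaining columns are per-neuron fluorescence traces (a.u.).
#' @param frame_rate Frames per second.
#' @param epochs Tibble with columns `label`, `onset`, `offset` (seconds) and
#'   `kind` (`"mechanical"` or `"chemical"`).
#' @return A `fluor_recording` object.
#' @export
fluor_recording <- function(traces, frame_rate, epochs) {
  traces <- as_tibble(traces)
  if (names(traces)[1] != "time" || ncol(traces) < 2) {
    data_error("`traces` must have a `time` first column and >= 1 neuron column.")
  }
  check_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  vals <- as.matrix(traces[-1])
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    data_error("all fluorescence values must be finite and > 0.")
  }
  epochs <- as_tibble(epochs)
  need <- c("label", "onset", "offset", "kind")
  if (!all(need %in% names(epochs))) {
    data_error("`epochs` must have columns %s.", paste(need, collapse = ", "))
  }
  t_max <- max(traces$time)
  if (any(epochs$onset < 0) || any(epochs$onset > t_max)) {
    data_error("epoch onsets must lie within the recording.")
  }
  if (is.unsorted(epochs$onset, strictly = TRUE)) {
    data_error("epoch onsets must be strictly increasing.")
  }
  structure(
    list(traces = traces, frame_rate = frame_rate, epochs = epochs),
    class = "fluor_recording"
  )
}

#' @export
print.fluor_recording <- function(x, ...) {
  cat(sprintf(
    "<fluor_recording> %d neurons x %d frames @ %g Hz (%.0f s), %d epochs\n",
    ncol(x$traces) - 1, nrow(x$traces), x$frame_rate,
    max(x$traces$time), nrow(x$epochs)
  ))
  print(x$epochs, ...)
  invisible(x)
}

#' Neuron identifiers of a recording
#' @param recording A [fluor_recording()].
#' @return Character vector of neuron column names.
#' @export
neuron_ids <- function(recording) {
  stopifnot(inherits(recording, "fluor_recording"))
  names(recording$traces)[-1]
}
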