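# EMG conditioning chain: band-pass -> MVC normalization (with
# rectification) -> linear-envelope low-pass. Each recording carries a stage
# tag and the operations enforce the order raw -> bandpassed -> normalized ->
# envelope, so a signal can never be silently re-filtered.

#' Multichannel EMG recording container
#'
#' @param data Numeric matrix, one column per channel (TA, MG, LG order).
#' @param sampling_rate Sampling rate in Hz.
#' @param stage Processing stage tag: `"raw"`, `"bandpassed"`, `"normalized"`
#'   or `"envelope"`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(data, sampling_rate, stage = "raw") {
  data <- as.matrix(data)
  if (ncol(data) != 3) stop_config("expected 3 channels, got %d", ncol(data))
  if (is.null(colnames(data))) colnames(data) <- EMG_CHANNELS
  if (!identical(colnames(data), EMG_CHANNELS)) {
    data <- data[, EMG_CHANNELS, drop = FALSE]
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_config("sampling_rate must be > 0")
  }
  stages <- c("raw", "bandpassed", "normalized", "envelope")
  if (!stage %in% stages) stop_config("unknown stage '%s'", stage)
  structure(list(data = data, sampling_rate = sampling_rate, stage = stage),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording>", nrow(x$data), "samples x", ncol(x$data),
      "channels @", x$sampling_rate, "Hz, stage:", x$stage, "\n")
  invisible(x)
}

require_stage <- function(rec, stage, op) {
  if (!inherits(rec, "emg_recording")) stop_config("not an emg_recording")
  if (!identical(rec$stage, stage)) {
    stop_stage("%s expects stage '%s' but recording is at stage '%s'",
               op, stage, rec$stage)
  }
}

apply_filter <- function(filt, data, zero_phase) {
  apply(data, 2, function(x) {
    if (zero_phase) signal::filtfilt(filt, x) else {
      as.numeric(signal::filter(filt, x))
    }
  })
}

#' Band-pass filter a raw recording (20-450 Hz Butterworth)
#'
#' Removes motion artifact and non-physiological content. The default is a
#' causal (single-pass, real-time-compatible) 4th-order Butterworth design;
#' set `zero_phase = TRUE` for forward-backward filtering in offline work.
#'
#' @param rec An `emg_recording` at stage `"raw"`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth design order.
#' @param zero_phase Apply forward-backward instead of causal filtering.
#' @return The filtered recording at stage `"bandpassed"`.
#' @export
bandpass <- function(rec, low = 20, high = 450, order = 4,
                     zero_phase = FALSE) {
  require_stage(rec, "raw", "bandpass")
  nyq <- rec$sampling_rate / 2
  if (low <= 0 || high >= nyq) {
    stop_config("band edges must satisfy 0 < low < high < Nyquist (%g Hz)",
                nyq)
  }
  if (order < 1) stop_config("order must be >= 1")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$data <- apply_filter(bf, rec$data, zero_phase)
  colnames(rec$data) <- EMG_CHANNELS
  rec$stage <- "bandpassed"
  rec
}

#' Rectify and amplitude-normalize by maximum voluntary contraction
#'
#' Each channel is full-wave rectified (absolute value) and divided by that
#' muscle's MVC amplitude, yielding non-negative values in MVC-fraction
#' units. Rectification happens here because a 20 Hz low-passed,
#' MVC-normalized signal is only meaningful as a linear envelope of
#' rectified EMG.
#'
#' @param rec An `emg_recording` at stage `"bandpassed"`.
#' @param mvc Per-channel MVC amplitudes (length 3, > 0), TA/MG/LG order or
#'   named.
#' @return The recording at stage `"normalized"`.
#' @export
mvc_normalize <- function(rec, mvc) {
  require_stage(rec, "bandpassed", "mvc_normalize")
  mvc <- as.numeric(if (!is.null(names(mvc))) mvc[EMG_CHANNELS] else mvc)
  if (length(mvc) != 3 || anyNA(mvc) || any(mvc <= 0)) {
    stop_config("mvc must be three positive per-channel amplitudes")
  }
  rec$data <- abs(rec$data) / rep(mvc, each = nrow(rec$data))
  rec$stage <- "normalized"
  rec
}

#' Linear-envelope low-pass filter (2nd-order Butterworth, 20 Hz)
#'
#' Smooths the rectified, normalized signal into a linear envelope. Default
#' is a causal ("recursive") single pass, matching a real-time control
#' pipeline; negative ripple is clipped to zero.
#'
#' @param rec An `emg_recording` at stage `"normalized"`.
#' @param cutoff Cut-off frequency in Hz.
#' @param order Butterworth design order.
#' @param zero_phase Apply forward-backward instead of causal filtering.
#' @return The recording at stage `"envelope"`.
#' @export
envelope_lowpass <- function(rec, cutoff = 20, order = 2,
                             zero_phase = FALSE) {
  require_stage(rec, "normalized", "envelope_lowpass")
  nyq <- rec$sampling_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop_config("cutoff must lie in (0, Nyquist)")
  }
  lf <- signal::butter(order, cutoff / nyq, type = "low")
  rec$data <- pmax(apply_filter(lf, rec$data, zero_phase), 0)
  colnames(rec$data) <- EMG_CHANNELS
  rec$stage <- "envelope"
  rec
}

#' Run the full conditioning chain on a trial
#'
#' Band-pass (20-450 Hz), rectify + MVC-normalize, envelope low-pass (20 Hz).
#' The MVC defaults to the simulator's true per-muscle MVC stored in the
#' trial metadata; for external data supply `mvc` or use [estimate_mvc()].
#'
#' @param trial An `emg_trial` whose recording is at stage `"raw"`.
#' @param mvc Optional per-channel MVC amplitudes.
#' @param zero_phase Use forward-backward filtering throughout.
#' @return The trial with its recording replaced by the envelope-stage
#'   recording.
#' @export
preprocess_trial <- function(trial, mvc = NULL, zero_phase = FALSE) {
  if (!inherits(trial, "emg_trial")) stop_config("trial must be an emg_trial")
  mvc <- mvc %||% trial$meta$participant$mvc
  if (is.null(mvc)) stop_config("no MVC available; supply mvc")
  rec <- bandpass(trial$rec, zero_phase = zero_phase)
  rec <- mvc_normalize(rec, mvc)
  trial$rec <- envelope_lowpass(rec, zero_phase = zero_phase)
  trial
}

#' Fallback MVC estimator for external recordings
#'
#' Estimates per-muscle MVC as a high quantile of the rectified band-passed
#' signal, for data sets that ship no isometric MVC calibration.
#'
#' @param rec An `emg_recording` at stage `"bandpassed"`.
#' @param prob Quantile used as the MVC estimate.
#' @return Named per-channel amplitude vector.
#' @export
estimate_mvc <- function(rec, prob = 0.995) {
  require_stage(rec, "bandpassed", "estimate_mvc")
  apply(abs(rec$data), 2, stats::quantile, probs = prob, names = FALSE)
}
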