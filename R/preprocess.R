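#' Preprocessing configuration
#'
#' Defaults follow standard clinical sEMG practice: a 50 Hz notch for power
#' line interference, a fourth-order Butterworth 20-450 Hz bandpass for
#' motion artifact and out-of-band noise, and overlapping 250 ms windows
#' advancing by 50%.
#'
#' @param notch_hz Notch center frequency (Hz).
#' @param notch_q Notch quality factor; bandwidth = notch_hz / notch_q
#'   (Q = 30 gives about 1.7 Hz).
#' @param band_lo_hz,band_hi_hz Bandpass corner frequencies (Hz).
#' @param order Overall Butterworth bandpass order (must be even).
#' @param window_ms Analysis window length (ms).
#' @param overlap_frac Fractional window overlap in \[0, 1).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_hz = 50, notch_q = 30, band_lo_hz = 20,
                              band_hi_hz = 450, order = 4, window_ms = 250,
                              overlap_frac = 0.5) {
  if (band_lo_hz <= 0 || band_lo_hz >= band_hi_hz)
    stop_config("need 0 < band_lo_hz < band_hi_hz")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop_config("overlap_frac must be in [0, 1)")
  if (window_ms <= 0) stop_config("window_ms must be positive")
  if (order %% 2 != 0) stop_config("bandpass order must be even")
  structure(list(notch_hz = notch_hz, notch_q = notch_q,
                 band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 order = order, window_ms = window_ms,
                 overlap_frac = overlap_frac),
            class = "preprocess_config")
}

check_finite <- function(rec) {
  for (c in seq_len(ncol(rec$signal))) {
    bad <- which(!is.finite(rec$signal[, c]))
    if (length(bad))
      stop_data("non-finite sample in channel ", rec$channels[c],
                " at index ", bad[1] - 1L)
  }
}

#' Apply a zero-phase 50 Hz notch filter
#'
#' Second-order Butterworth band-stop centred on `notch_hz` with bandwidth
#' `notch_hz / notch_q`, applied forward-backward (zero phase) per channel.
#' Output length equals input length.
#'
#' @param rec An `emg_recording`.
#' @param cfg A [preprocess_config()].
#' @return The filtered recording, with the filter logged in `$filters`.
#' @export
apply_notch <- function(rec, cfg = preprocess_config()) {
  check_finite(rec)
  bw <- cfg$notch_hz / cfg$notch_q
  w <- c(cfg$notch_hz - bw / 2, cfg$notch_hz + bw / 2) / (rec$fs / 2)
  bf <- signal::butter(2, w, type = "stop")
  rec$signal <- apply(rec$signal, 2, function(x) signal::filtfilt(bf, x))
  colnames(rec$signal) <- rec$channels
  rec$filters <- c(rec$filters, sprintf("notch%g_q%g", cfg$notch_hz,
                                        cfg$notch_q))
  rec
}

#' Apply a zero-phase Butterworth bandpass filter
#'
#' `order`-th order (order/2 section each side) Butterworth bandpass
#' between `band_lo_hz` and `band_hi_hz`, applied forward-backward per
#' channel; length preserved.
#'
#' @inheritParams apply_notch
#' @return The filtered recording.
#' @export
apply_bandpass <- function(rec, cfg = preprocess_config()) {
  check_finite(rec)
  if (cfg$band_hi_hz >= rec$fs / 2)
    stop_config("band_hi_hz (", cfg$band_hi_hz, ") must be below fs/2 = ",
                rec$fs / 2)
  bf <- signal::butter(cfg$order / 2,
                       c(cfg$band_lo_hz, cfg$band_hi_hz) / (rec$fs / 2),
                       type = "pass")
  rec$signal <- apply(rec$signal, 2, function(x) signal::filtfilt(bf, x))
  colnames(rec$signal) <- rec$channels
  rec$filters <- c(rec$filters, sprintf("bandpass%g-%g_o%d", cfg$band_lo_hz,
                                        cfg$band_hi_hz, cfg$order))
  rec
}

#' Extract contraction epochs from a recording
#'
#' Cue-based epoching: contraction segments are taken from the sidecar's
#' repetition boundaries (the acquisition was visually cued with fixed
#' timing), never detected from amplitude. Each epoch is trimmed by
#' `guard_ms` at both ends to drop the onset/offset transition ramps.
#'
#' @param rec An `emg_recording` with `$boundaries`.
#' @param protocol The [acquisition_protocol()] (for the expected count).
#' @param guard_ms Guard trim at each epoch end, in ms (floor-converted to
#'   samples); 0 keeps the full cued contraction.
#' @return List of `contraction_epoch` objects (signal slice plus labels
#'   and 0-based half-open start/end).
#' @export
extract_epochs <- function(rec, protocol, guard_ms = 250) {
  b <- rec$boundaries
  if (is.null(b) || !nrow(b))
    stop_data("recording ", rec$patient_id, "/", rec$movement,
              " has no repetition boundaries; cue-based epoching requires ",
              "the sidecar (amplitude-threshold detection is not supported)")
  n <- nrow(rec$signal)
  if (any(b$start < 0) || any(b$end > n))
    stop_data("repetition boundaries outside signal (n = ", n, ")")
  g <- ms_to_samples(guard_ms, rec$fs)
  lapply(seq_len(nrow(b)), function(r) {
    s0 <- b$start[r] + g
    s1 <- b$end[r] - g
    if (s1 - s0 < 1) stop_data("guard trim leaves empty epoch ", r)
    structure(list(
      signal = rec$signal[(s0 + 1L):s1, , drop = FALSE],
      start = s0, end = s1, repetition = b$repetition[r],
      patient_id = rec$patient_id, group = rec$group, week = rec$week,
      movement = rec$movement, fs = rec$fs, channels = rec$channels
    ), class = "contraction_epoch")
  })
}

#' Segment an epoch into overlapping windows
#'
#' `window_samples = floor(window_ms * fs / 1000)`; `step_samples =
#' floor(window_samples * (1 - overlap_frac))`; starts form an arithmetic
#' progression and a trailing partial window is discarded, giving
#' `floor((L - window) / step) + 1` windows.
#'
#' @param epoch A `contraction_epoch`.
#' @param cfg A [preprocess_config()].
#' @param fs Sampling frequency (default: the epoch's).
#' @return An object of class `window_set` holding the epoch signal, the
#'   0-based window starts, and sizes; use [get_window()] to materialise
#'   one window.
#' @export
make_windows <- function(epoch, cfg = preprocess_config(), fs = epoch$fs) {
  L <- nrow(epoch$signal)
  win <- ms_to_samples(cfg$window_ms, fs)
  if (L < win)
    stop_data("epoch length ", L, " shorter than one window (", win, ")")
  step <- floor(win * (1 - cfg$overlap_frac))
  if (step < 1) stop_config("overlap_frac too large: step below 1 sample")
  starts <- seq.int(0L, L - win, by = step)
  structure(list(signal = epoch$signal, starts = starts,
                 window_samples = win, step_samples = step,
                 n_windows = length(starts), fs = fs,
                 patient_id = epoch$patient_id, group = epoch$group,
                 week = epoch$week, movement = epoch$movement,
                 repetition = epoch$repetition, channels = epoch$channels),
            class = "window_set")
}

#' Materialise one window from a window set
#' @param ws A `window_set`.
#' @param i Window index (1-based).
#' @return samples x channels matrix.
#' @export
get_window <- function(ws, i) {
  s <- ws$starts[i]
  ws$signal[(s + 1L):(s + ws$window_samples), , drop = FALSE]
}
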