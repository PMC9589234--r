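# FIR filter design and zero-phase application.
#
# Filters are linear-phase Hamming-window FIR designs (signal::fir1) applied
# in a single pass with group-delay compensation, which yields an exactly
# zero-phase response. Filter order follows the usual 3.3/transition-width
# rule for a Hamming window.

fir_order <- function(trans_hz, fs) {
  m <- ceiling(3.3 / (trans_hz / fs))
  m + (m %% 2)                        # even order -> odd-length symmetric FIR
}

# Apply an odd-length linear-phase FIR kernel with zero phase via FFT
# convolution and delay removal. Edges use zero padding.
apply_fir <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  d <- (length(h) - 1) / 2
  n <- length(x)
  y <- signal::fftfilt(h, c(x, numeric(2 * d)))
  y[(d + 1):(d + n)]
}

#' Zero-phase FIR bandpass plus mains notch filter
#'
#' The offline filtering stage: a 0.5-50 Hz Hamming-window FIR bandpass
#' followed by a narrow band-stop around the 50 Hz power-line frequency.
#' Both filters are applied with zero phase; signal length is preserved.
#'
#' @param rec an `eeg_recording`.
#' @param low,high bandpass edges in Hz (defaults 0.5 and 50).
#' @param notch mains frequency in Hz (default 50); the stop band is
#'   `notch +/- 2` Hz. `NA` disables the notch.
#' @param trans_low transition width at the low edge in Hz (default 0.5).
#' @return the filtered `eeg_recording`.
#' @export
bandpass_notch_filter <- function(rec, low = 0.5, high = 50, notch = 50,
                                  trans_low = 0.5) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("require 0 < low < high < fs/2 for the bandpass design")
  bp_ord <- fir_order(trans_low, fs)
  h_bp <- signal::fir1(bp_ord, c(low, high) / (fs / 2), type = "pass")
  h_nt <- NULL
  if (!is.na(notch)) {
    if (notch + 2 >= fs / 2) stop("notch band exceeds Nyquist")
    nt_ord <- fir_order(1, fs)
    h_nt <- signal::fir1(nt_ord, c(notch - 2, notch + 2) / (fs / 2),
                         type = "stop")
  }
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    y <- apply_fir(out[i, ], h_bp)
    if (!is.null(h_nt)) y <- apply_fir(y, h_nt)
    out[i, ] <- y
  }
  eeg_recording(out, fs = fs, channels = rec$channels,
                subject_id = rec$subject_id)
}
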