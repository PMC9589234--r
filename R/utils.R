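#' @useDynLib eegdx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window, used throughout the
#' package to measure band power (e.g. the 8-13 Hz alpha band on F3 vs F4).
#'
#' @param x numeric vector, a single-channel signal.
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz) vectors.
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  if (nseg < 8 || length(x) < nseg) stop("signal too short for Welch segments")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nseg %/% 2 + 1)]
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  idx <- 2:(length(psd) - if (nseg %% 2 == 0) 1L else 0L)
  psd[idx] <- 2 * psd[idx]
  list(freq = (seq_along(psd) - 1) * fs / nseg, psd = psd)
}

#' Band power from a Welch PSD
#'
#' @param x numeric signal; @param fs Hz; @param band length-2 Hz range.
#' @inheritParams welch_psd
#' @return integrated power in the band (trapezoidal).
#' @export
band_power <- function(x, fs, band = c(8, 13), seg_s = 2) {
  p <- welch_psd(x, fs, seg_s = seg_s)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  if (sum(sel) < 2) stop("band contains fewer than 2 frequency bins")
  f <- p$freq[sel]; y <- p$psd[sel]
  sum(diff(f) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Derive a stage- or subject-specific seed from a master seed
#'
#' Deterministic 31-bit sub-seed from a master seed and a label (a
#' 31-based string hash modulo 2^31 - 1). Every pipeline stage and every
#' subject draws from its own derived stream, so adding a subject or
#' reordering stages never perturbs the others.
#'
#' @param master_seed integer master seed.
#' @param label character stage/subject label.
#' @return integer seed in \[0, 2^31 - 1).
#' @export
derive_seed <- function(master_seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", master_seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}
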