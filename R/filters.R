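# Zero-phase Butterworth filtering shared by the EMG and landing modules.
#
# "Fourth-order zero-phase" is implemented as a forward-backward pass of
# a second-order design (effective fourth order, zero phase); a
# forward-backward fourth-order design is available via `design_order`.
# Edge transients are controlled by odd-reflection padding, after which
# the padding is stripped.

.zero_phase_filter <- function(x, filt, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen < 1L) stop("series too short for zero-phase filtering", call. = FALSE)
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(pre, x, post)
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  as.numeric(y[(padlen + 1L):(padlen + n)])
}

.butter_lowpass <- function(x, fs, cutoff, design_order = 2L) {
  if (fs <= 2 * cutoff) {
    stop(sprintf("sampling rate %g Hz cannot support a %g Hz low-pass filter",
                 fs, cutoff), call. = FALSE)
  }
  filt <- signal::butter(design_order, cutoff / (fs / 2), type = "low")
  .zero_phase_filter(x, filt, padlen = max(15L, round(3 * fs / cutoff)))
}

.butter_bandpass <- function(x, fs, band, design_order = 2L) {
  if (fs <= 2 * band[2]) {
    stop(sprintf(
      "sampling rate %g Hz cannot support a %g-%g Hz band-pass filter",
      fs, band[1], band[2]), call. = FALSE)
  }
  filt <- signal::butter(design_order, band / (fs / 2), type = "pass")
  .zero_phase_filter(x, filt, padlen = max(15L, round(3 * fs / band[1])))
}
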