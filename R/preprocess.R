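#' Filtering specification for iEEG preprocessing
#'
#' A 60 Hz zero-phase notch plus a `[0.5, 180]` Hz zero-phase band-pass,
#' the standard preprocessing for 400 Hz intracranial recordings: the notch
#' removes mains interference and the band-pass restricts the analysis to
#' the band the bispectral features are defined on. Both filters are applied
#' forward-backward so the net phase shift is zero and phase relationships
#' between frequency components — the quantity the bispectrum measures —
#' are untouched.
#'
#' @param notch_freq notch center frequency in Hz.
#' @param notch_q dimensionless notch quality factor (bandwidth =
#'   `notch_freq / notch_q`).
#' @param band_low,band_high band-pass edges in Hz.
#' @param bp_order Butterworth band-pass order (applied forward-backward,
#'   doubling the effective order).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 60, notch_q = 30,
                        band_low = 0.5, band_high = 180, bp_order = 4) {
  if (!is_number(notch_freq) || notch_freq <= 0) {
    stop_param("notch_freq must be positive")
  }
  if (!is_number(notch_q) || notch_q <= 0) stop_param("notch_q must be positive")
  if (!is_number(band_low) || !is_number(band_high) ||
      band_low <= 0 || band_low >= band_high) {
    stop_param("need 0 < band_low < band_high")
  }
  if (!is_count(bp_order)) stop_param("bp_order must be a positive integer")
  structure(
    list(notch_freq = notch_freq, notch_q = notch_q,
         band_low = band_low, band_high = band_high,
         bp_order = as.integer(bp_order)),
    class = "filter_spec"
  )
}

# Standard second-order IIR notch biquad (constrained pole-zero design):
# zeros on the unit circle at +-w0, poles pulled inside by the bandwidth.
design_notch <- function(freq, q, fs) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

# One forward-backward (zero-phase) pass of an IIR filter.
filtfilt_pass <- function(b, a, x) {
  y <- signal::filter(b, a, x)
  rev(signal::filter(b, a, rev(y)))
}

# Extend a signal by `pad` samples at both ends with stable Burg AR
# extrapolation fitted to the adjacent chunk. Constant (zero-variance)
# tails are continued as constants.
ar_extend <- function(x, pad) {
  n <- length(x)
  ord <- min(32L, n %/% 4L)
  chunk <- min(n, max(10L * ord, 1000L))
  extend_fwd <- function(v) {
    tailv <- v[(length(v) - chunk + 1L):length(v)]
    if (var(tailv) < 1e-24) return(rep(tailv[chunk], pad))
    fit <- stats::ar.burg(tailv, aic = FALSE, order.max = ord, demean = TRUE)
    co <- fit$ar
    m <- fit$x.mean
    p <- length(co)
    buf <- c(v[(length(v) - p + 1L):length(v)] - m, numeric(pad))
    for (k in seq_len(pad)) buf[p + k] <- sum(co * buf[(p + k - 1L):k])
    buf[(p + 1L):(p + pad)] + m
  }
  c(rev(extend_fwd(rev(x))), x, extend_fwd(x))
}

#' Zero-phase notch and band-pass filtering
#'
#' Applies the notch and the Butterworth band-pass of a [filter_spec()]
#' forward-backward (zero net phase shift). Before filtering, the signal is
#' extended at both ends by three periods of the lowest passband frequency
#' using autoregressive (Burg) extrapolation, then trimmed. Unlike
#' reflection padding, AR extrapolation continues oscillatory content
#' phase-coherently — no value or derivative discontinuity at the
#' boundary — so the start-up transients of the narrow notch and of the
#' 0.5 Hz high-pass edge die out inside the discarded extension.
#'
#' @param x numeric vector, or a channels-by-samples matrix filtered row-wise.
#' @param fs sampling rate in Hz; must exceed `2 * band_high`.
#' @param spec a [filter_spec()].
#' @return filtered signal with the same shape as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 20 * (0:4000) / 400)
#' y <- zero_phase_filter(x, 400, filter_spec())
zero_phase_filter <- function(x, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop_param("spec must be a filter_spec")
  if (!is_number(fs) || fs <= 2 * spec$band_high) {
    stop_param("fs must exceed twice band_high (%g Hz)", spec$band_high)
  }
  if (is.matrix(x)) {
    out <- x
    for (ch in seq_len(nrow(x))) out[ch, ] <- zero_phase_filter(x[ch, ], fs, spec)
    return(out)
  }
  if (any(!is.finite(x))) stop_data("signal contains non-finite samples")
  n <- length(x)
  min_len <- 3L * (2L * spec$bp_order + 1L)
  if (n <= min_len) {
    stop_length("signal too short (%d samples) for stable zero-phase filtering", n)
  }
  pad <- min(n - 1L, ceiling(3 * fs / spec$band_low))
  xp <- ar_extend(x, pad)
  nt <- design_notch(spec$notch_freq, spec$notch_q, fs)
  bf <- signal::butter(spec$bp_order,
                       c(spec$band_low, spec$band_high) / (fs / 2),
                       type = "pass")
  xp <- filtfilt_pass(nt$b, nt$a, xp)
  xp <- filtfilt_pass(bf$b, bf$a, xp)
  xp[(pad + 1L):(pad + n)]
}

#' Cut a segment into non-overlapping analysis windows
#'
#' Tiles the segment with contiguous windows of `window_length_s` seconds
#' (default 30 s, the analysis resolution used throughout the package). The
#' trailing partial window, if any, is dropped, so a 1-hour segment yields
#' exactly 120 windows.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @param fs sampling rate in Hz.
#' @param window_length_s window length in seconds; `fs * window_length_s`
#'   must be an integer number of samples.
#' @param state optional state label (`"preictal"` or `"interictal"`).
#' @param seizure_id,subject_id optional identifiers carried into the
#'   feature table.
#' @return an object of class `window_set`: a list with `windows` (list of
#'   channels-by-samples matrices), `n_windows`, `window_length_s`, `fs` and
#'   the identifying metadata.
#' @export
#' @examples
#' ws <- segment_windows(matrix(rnorm(2 * 400 * 65), nrow = 2), 400)
#' ws$n_windows  # 2 complete 30-s windows, 5 s dropped
segment_windows <- function(x, fs, window_length_s = 30, state = NULL,
                            seizure_id = NULL, subject_id = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is_number(fs) || fs <= 0) stop_param("fs must be positive")
  wlen <- fs * window_length_s
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop_param("fs * window_length_s must be an integer number of samples")
  }
  wlen <- as.integer(round(wlen))
  if (!is.null(state)) state <- match.arg(state, c("preictal", "interictal"))
  n <- ncol(x)
  n_win <- n %/% wlen
  if (n_win == 0L) {
    warning(sprintf("segment of %d samples is shorter than one %g-s window; empty window set",
                    n, window_length_s), call. = FALSE)
    windows <- list()
  } else {
    windows <- lapply(seq_len(n_win), function(w) {
      x[, ((w - 1L) * wlen + 1L):(w * wlen), drop = FALSE]
    })
  }
  structure(
    list(windows = windows, n_windows = n_win,
         window_length_s = window_length_s, fs = fs,
         state = state, seizure_id = seizure_id, subject_id = subject_id),
    class = "window_set"
  )
}
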