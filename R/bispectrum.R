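#' Bispectrum estimator settings
#'
#' Parameters of the direct-FFT bispectrum estimator: the 30-s window is
#' split into `seg_len` -sample segments (optionally overlapping), each
#' segment is mean-subtracted, tapered and Fourier transformed, and the
#' triple products are averaged over segments. The defaults (512 samples =
#' 1.28 s at 400 Hz, Hann taper, no overlap, mean subtraction) give 23
#' averaging segments per 30-s window at 0.78 Hz frequency resolution —
#' enough averaging for a stable estimate while resolving the coupling
#' band. `nfft` equals `seg_len`.
#'
#' @param seg_len segment length in samples.
#' @param taper `"hann"` or `"none"`.
#' @param overlap_fraction segment overlap in `[0, 1)`.
#' @param mean_subtract subtract each segment's mean before tapering.
#' @return an object of class `estimator_spec`.
#' @export
estimator_spec <- function(seg_len = 512, taper = c("hann", "none"),
                           overlap_fraction = 0, mean_subtract = TRUE) {
  if (!is_count(seg_len) || seg_len %% 2 != 0) {
    stop_param("seg_len must be a positive even integer")
  }
  taper <- match.arg(taper)
  if (!is_number(overlap_fraction) ||
      overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_param("overlap_fraction must lie in [0, 1)")
  }
  structure(
    list(seg_len = as.integer(seg_len), taper = taper,
         overlap_fraction = overlap_fraction,
         mean_subtract = isTRUE(mean_subtract)),
    class = "estimator_spec"
  )
}

taper_vector <- function(taper, n) {
  switch(taper,
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    none = rep(1, n),
    stop_param("unknown taper '%s'", taper)
  )
}

new_bispectrum_estimate <- function(values, fs, nfft, n_segments,
                                    band = c(0.5, 180), spec = NULL) {
  pd <- principal_domain_mask(nfft, fs, band[1L], band[2L])
  structure(
    list(values = values, fs = fs, nfft = nfft,
         freq_step = fs / nfft,
         freqs = (0:(nfft / 2)) * fs / nfft,
         n_segments = n_segments,
         principal_mask = pd$mask, L = pd$L, band = band,
         estimator = spec),
    class = "bispectrum_estimate"
  )
}

#' Direct-FFT bispectrum of one window
#'
#' Estimates the bispectrum
#' \deqn{B(f_1, f_2) = E[X(f_1) X(f_2) X^{*}(f_1 + f_2)]}
#' by splitting the window into segments per `spec`, Fourier transforming
#' each (scaled by `1/seg_len` so the estimate is invariant to the segment
#' length at fixed signal), and averaging the frequency-triple products
#' over segments. For a real-valued signal this convention is the complex
#' conjugate of the equivalent form
#' \eqn{E[X(f_1+f_2)X^{*}(f_1)X^{*}(f_2)]}; both have identical magnitude,
#' which is what every downstream feature consumes. A quadratically
#' phase-coupled triple at \eqn{(f_1, f_2, f_1+f_2)} contributes coherently
#' and produces a peak at bin \eqn{(f_1, f_2)}; uncoupled components
#' average toward zero at rate \eqn{1/\sqrt{K}}.
#'
#' @param x real, finite numeric vector (one channel of one window), at
#'   least `spec$seg_len` samples long.
#' @param fs sampling rate in Hz.
#' @param spec an [estimator_spec()].
#' @param band analysis band in Hz used for the principal-domain mask.
#' @return an object of class `bispectrum_estimate` with elements `values`
#'   (complex `(nfft/2+1)` square matrix over 0-based frequency bins, 1-based
#'   R indexing), `freqs`, `freq_step`, `n_segments`, `principal_mask`, `L`
#'   and `band`.
#' @seealso [brute_force_bispectrum()] for the independent time-domain
#'   oracle, [principal_domain_mask()] for the non-redundant region.
#' @export
#' @examples
#' set.seed(1)
#' x <- generate_qpc_channel(10, 400, 40, 30, 1, epoch_s = 1)
#' est <- direct_bispectrum(x, 400, estimator_spec(seg_len = 400))
direct_bispectrum <- function(x, fs, spec = estimator_spec(),
                              band = c(0.5, 180)) {
  if (!inherits(spec, "estimator_spec")) {
    stop_param("spec must be an estimator_spec")
  }
  if (!is.numeric(x)) stop_data("signal must be numeric")
  if (any(!is.finite(x))) stop_data("signal contains non-finite samples")
  n <- length(x)
  if (n < spec$seg_len) {
    stop_param("signal (%d samples) shorter than seg_len (%d)", n, spec$seg_len)
  }
  segs <- segment_matrix(x, spec)
  values <- bispec_direct_cpp(segs, taper_vector(spec$taper, spec$seg_len),
                              spec$mean_subtract)
  new_bispectrum_estimate(values, fs, spec$seg_len, ncol(segs), band, spec)
}

segment_matrix <- function(x, spec) {
  step <- max(1L, as.integer(round(spec$seg_len * (1 - spec$overlap_fraction))))
  starts <- seq(1L, length(x) - spec$seg_len + 1L, by = step)
  vapply(starts, function(s) x[s:(s + spec$seg_len - 1L)],
         numeric(spec$seg_len))
}

#' Time-domain bispectrum oracle (triple correlation + 2-D DFT)
#'
#' Computes the bispectrum of a list of equal-length segments the slow way:
#' the circular third-order correlation
#' \eqn{c(\tau_1, \tau_2) = (1/n)\sum_t x_t x_{t+\tau_1} x_{t+\tau_2}}
#' is accumulated by explicit double-lag summation, transformed with an
#' explicit 2-D DFT, rescaled to the [direct_bispectrum()] convention and
#' averaged over segments. This is an independent cross-check of the
#' FFT-based estimator and is only practical for tiny inputs; it applies no
#' taper and no mean subtraction, so compare against
#' `estimator_spec(taper = "none", mean_subtract = FALSE)`.
#'
#' @param segments list of at most 8 real numeric vectors, each of equal
#'   length at most 128 samples.
#' @param fs sampling rate in Hz.
#' @param band analysis band in Hz for the principal-domain mask.
#' @return a `bispectrum_estimate`.
#' @export
brute_force_bispectrum <- function(segments, fs, band = c(0.5, 180)) {
  if (!is.list(segments) || length(segments) == 0L) {
    stop_size("segments must be a non-empty list")
  }
  if (length(segments) > 8L) stop_size("oracle accepts at most 8 segments")
  n <- length(segments[[1L]])
  if (n > 128L) stop_size("oracle accepts segments of at most 128 samples")
  if (n %% 2 != 0) stop_param("segment length must be even")
  if (!all(vapply(segments, length, 1L) == n)) {
    stop_param("all segments must have equal length")
  }
  n2 <- n %/% 2
  # 2-D DFT operator restricted to non-negative frequency bins
  E <- exp(-2i * pi * outer(0:n2, 0:(n - 1)) / n)
  acc <- matrix(0 + 0i, n2 + 1L, n2 + 1L)
  for (x in segments) {
    cc <- matrix(0, n, n)
    for (t1 in 0:(n - 1)) {
      xs1 <- x[(((0:(n - 1)) + t1) %% n) + 1L]
      for (t2 in 0:(n - 1)) {
        xs2 <- x[(((0:(n - 1)) + t2) %% n) + 1L]
        cc[t1 + 1L, t2 + 1L] <- sum(x * xs1 * xs2) / n
      }
    }
    acc <- acc + (E %*% cc %*% t(E)) / n^2
  }
  values <- acc / length(segments)
  # bins beyond the i + j <= nfft/2 support are zeroed to match the
  # direct estimator's stored grid
  idx <- outer(0:n2, 0:n2, `+`) > n2
  values[idx] <- 0
  new_bispectrum_estimate(values, fs, n, length(segments), band, NULL)
}

#' Non-redundant principal domain of the bispectrum
#'
#' For a real signal all unique bispectral information lives in the
#' triangle \eqn{\{(f_1, f_2): f_2 \le f_1,\ f_1 + f_2 \le f_s/2\}}. This
#' function returns that triangle intersected with the analysis band
#' (inclusive inequalities on all boundaries) as a boolean matrix over the
#' 0-based FFT bin grid, along with `L`, the number of bins in the region —
#' the normalizing count of the mean-magnitude feature and the maximum
#' attainable entropy `ln(L)`.
#'
#' @param nfft even FFT length.
#' @param fs sampling rate in Hz.
#' @param band_low,band_high analysis band in Hz, inside `[0, fs/2]`.
#' @return list with `mask` (logical `(nfft/2+1)` square matrix, rows = f1
#'   bin, columns = f2 bin, 1-based indexing of 0-based bins) and `L`.
#' @export
#' @examples
#' principal_domain_mask(8, 8, 0, 4)$L
principal_domain_mask <- function(nfft, fs, band_low = 0.5, band_high = 180) {
  if (!is_count(nfft) || nfft %% 2 != 0) stop_param("nfft must be even")
  if (!is_number(fs) || fs <= 0) stop_param("fs must be positive")
  if (!is_number(band_low) || !is_number(band_high) || band_low > band_high) {
    stop_param("need band_low <= band_high")
  }
  if (band_low < 0 || band_high > fs / 2) {
    stop_param("band must lie within [0, fs/2] = [0, %g] Hz", fs / 2)
  }
  n2 <- nfft %/% 2
  f <- (0:n2) * fs / nfft
  i <- matrix(0:n2, n2 + 1L, n2 + 1L)              # f1 bin index (rows)
  j <- matrix(0:n2, n2 + 1L, n2 + 1L, byrow = TRUE) # f2 bin index (cols)
  in_band <- f >= band_low & f <= band_high
  mask <- (j <= i) & (i + j <= n2) &
    matrix(in_band, n2 + 1L, n2 + 1L) &
    matrix(in_band, n2 + 1L, n2 + 1L, byrow = TRUE)
  list(mask = mask, L = sum(mask))
}

#' @export
print.bispectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<bispectrum_estimate> nfft=%d, K=%d segments, %.3g Hz/bin, band [%g, %g] Hz, L=%d\n",
    x$nfft, x$n_segments, x$freq_step, x$band[1L], x$band[2L], x$L
  ))
  invisible(x)
}
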