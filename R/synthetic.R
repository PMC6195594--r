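#' Specification of a synthetic iEEG subject
#'
#' Describes one synthetic subject: how many seizures to simulate, the
#' recording geometry (channels, sampling rate, segment duration) and the
#' quadratic-phase-coupling (QPC) model that differentiates brain states.
#' Each seizure contributes one preictal and one interictal 1-hour segment,
#' mirroring the common seizure-prediction design of one preictal hour
#' (ending a few minutes before onset) paired with one interictal hour taken
#' far from any seizure.
#'
#' The QPC model superimposes three oscillations at `f1`, `f2` and `f1 + f2`
#' Hz on 1/f background noise. The phase of the `f1 + f2` component is a
#' mixture controlled by the coupling strength `lambda`: a fraction `lambda`
#' of its amplitude carries the phase sum `phi1 + phi2` (true quadratic
#' coupling, which the bispectrum detects) and the rest carries an
#' independent random phase. `lambda = 1` gives a fully coupled harmonic,
#' `lambda = 0` an uncoupled one with the same power spectrum, so coupling
#' strength is invisible to ordinary spectral analysis. Channels listed in
#' `coupled_channels` use `lambda_preictal` during preictal segments and
#' `lambda_interictal` during interictal ones; all other channels use
#' `lambda_interictal` in both states.
#'
#' @param subject_id character label.
#' @param n_seizures number of seizures to simulate.
#' @param n_channels number of recording channels (default 16).
#' @param fs sampling rate in Hz (default 400).
#' @param segment_duration duration of each segment in seconds (default 3600).
#' @param coupled_channels integer vector of 1-based channel indices carrying
#'   state-dependent coupling; defaults to the first `min(4, n_channels)`
#'   channels.
#' @param f1,f2 coupling base frequencies in Hz; both must lie at or above
#'   0.5 Hz with `f1 + f2 <= 180` so the triple sits inside the analysis band.
#' @param lambda_preictal,lambda_interictal coupling strengths in `[0, 1]`.
#' @param noise_sigma standard deviation of the 1/f background noise.
#' @param amp_triplet amplitudes of the `f1`, `f2` and `f1 + f2` components.
#' @param epoch_s sub-epoch length in seconds after which all phases are
#'   redrawn (default 1). Phases must decorrelate across the averaging
#'   segments of the bispectrum estimator, otherwise even `lambda = 0`
#'   signals would look coupled.
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @return an object of class `subject_spec`.
#' @seealso [generate_subject()], [generate_qpc_channel()]
#' @export
subject_spec <- function(subject_id = "S1",
                         n_seizures = 17,
                         n_channels = 16,
                         fs = 400,
                         segment_duration = 3600,
                         coupled_channels = NULL,
                         f1 = 40,
                         f2 = 30,
                         lambda_preictal = 0.8,
                         lambda_interictal = 0.1,
                         noise_sigma = 0.5,
                         amp_triplet = c(1, 1, 1),
                         epoch_s = 1,
                         seed = 1L) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop_param("subject_id must be a single string")
  }
  if (!is_count(n_seizures)) stop_param("n_seizures must be a positive integer")
  if (!is_count(n_channels)) stop_param("n_channels must be a positive integer")
  if (!is_number(fs) || fs <= 0) stop_param("fs must be positive")
  if (!is_number(segment_duration) || segment_duration <= 0) {
    stop_param("segment_duration must be positive")
  }
  check_qpc_params(f1, f2, lambda_preictal, amp_triplet, noise_sigma)
  check_qpc_params(f1, f2, lambda_interictal, amp_triplet, noise_sigma)
  coupled_channels <- as.integer(coupled_channels %||%
                                   seq_len(min(4L, n_channels)))
  if (anyNA(coupled_channels) ||
      !all(coupled_channels %in% seq_len(n_channels))) {
    stop_param("coupled_channels must be channel indices in 1..%d", n_channels)
  }
  if (!is_number(epoch_s) || epoch_s <= 0) stop_param("epoch_s must be positive")
  structure(
    list(
      subject_id = subject_id, n_seizures = as.integer(n_seizures),
      n_channels = as.integer(n_channels), fs = fs,
      segment_duration = segment_duration,
      coupled_channels = coupled_channels,
      f1 = f1, f2 = f2,
      lambda_preictal = lambda_preictal,
      lambda_interictal = lambda_interictal,
      noise_sigma = noise_sigma, amp_triplet = amp_triplet,
      epoch_s = epoch_s, seed = as.integer(seed)
    ),
    class = "subject_spec"
  )
}

check_qpc_params <- function(f1, f2, lambda, amp_triplet, noise_sigma) {
  if (!is_number(f1) || !is_number(f2) || f1 < 0.5 || f2 < 0.5) {
    stop_param("f1 and f2 must be >= 0.5 Hz")
  }
  if (f1 + f2 > 180) stop_param("f1 + f2 must be <= 180 Hz (analysis band)")
  if (f1 == f2) stop_param("f1 and f2 must differ")
  if (!is_number(lambda) || lambda < 0 || lambda > 1) {
    stop_param("coupling strength lambda must lie in [0, 1]")
  }
  if (!is.numeric(amp_triplet) || length(amp_triplet) != 3L ||
      any(!is.finite(amp_triplet)) || any(amp_triplet < 0)) {
    stop_param("amp_triplet must be three non-negative amplitudes")
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) {
    stop_param("noise_sigma must be >= 0")
  }
  invisible(TRUE)
}

#' Generate one channel of surrogate iEEG with quadratic phase coupling
#'
#' Builds a signal from consecutive sub-epochs (length `epoch_s` seconds).
#' Within each sub-epoch the signal is
#' \deqn{a_1\cos(2\pi f_1 t+\phi_1)+a_2\cos(2\pi f_2 t+\phi_2)
#'   +\lambda a_3\cos(2\pi(f_1+f_2)t+\phi_1+\phi_2)
#'   +(1-\lambda)a_3\cos(2\pi(f_1+f_2)t+\phi_3)}
#' plus band-limited 1/f Gaussian noise; the phases \eqn{\phi_1,\phi_2,\phi_3}
#' are drawn independently and uniformly on \eqn{[0,2\pi)} for every
#' sub-epoch. `lambda = 1` yields a fully phase-coupled harmonic at
#' `f1 + f2`; `lambda = 0` yields an uncoupled harmonic with an identical
#' power spectral density, detectable only through third-order statistics.
#'
#' Randomness is drawn from R's current RNG stream; seed it with
#' [set.seed()] (or use [generate_subject()], which manages per-record
#' sub-streams) for reproducibility.
#'
#' @param duration_s signal duration in seconds.
#' @param fs sampling rate in Hz.
#' @param f1,f2 base frequencies in Hz.
#' @param lambda_coupling coupling strength in `[0, 1]`.
#' @param amp_triplet amplitudes of the `f1`, `f2`, `f1 + f2` components.
#' @param noise_sigma standard deviation of the background noise.
#' @param epoch_s sub-epoch length in seconds for phase redrawing.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
#' @examples
#' set.seed(7)
#' x <- generate_qpc_channel(10, 400, 40, 30, lambda_coupling = 1)
generate_qpc_channel <- function(duration_s, fs, f1, f2, lambda_coupling,
                                 amp_triplet = c(1, 1, 1), noise_sigma = 0,
                                 epoch_s = 1) {
  if (!is_number(duration_s) || duration_s <= 0) {
    stop_param("duration_s must be positive")
  }
  if (!is_number(fs) || fs <= 0) stop_param("fs must be positive")
  check_qpc_params(f1, f2, lambda_coupling, amp_triplet, noise_sigma)

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  n_ep <- ceiling(duration_s / epoch_s)
  # per-sub-epoch uniform phases, expanded to sample resolution
  phases <- matrix(runif(n_ep * 3L, 0, 2 * pi), nrow = n_ep, ncol = 3L)
  idx <- pmin(floor(t / epoch_s) + 1L, n_ep)
  ph1 <- phases[idx, 1L]
  ph2 <- phases[idx, 2L]
  ph3 <- phases[idx, 3L]

  a <- amp_triplet
  lam <- lambda_coupling
  sig <- a[1L] * cos(2 * pi * f1 * t + ph1) +
    a[2L] * cos(2 * pi * f2 * t + ph2) +
    lam * a[3L] * cos(2 * pi * (f1 + f2) * t + ph1 + ph2) +
    (1 - lam) * a[3L] * cos(2 * pi * (f1 + f2) * t + ph3)
  if (noise_sigma > 0) {
    sig <- sig + one_over_f_noise(n, fs, noise_sigma)
  }
  sig
}

# Band-limited 1/f-shaped Gaussian noise synthesized in the frequency
# domain: Fourier amplitudes proportional to f^(-1/2) (power ~ 1/f) on
# [0.5, 180] Hz, random phases, rescaled to standard deviation `sigma`.
one_over_f_noise <- function(n, fs, sigma, band = c(0.5, 180)) {
  freqs <- seq(0, fs / 2, by = fs / n)
  n_pos <- length(freqs)
  amp <- numeric(n_pos)
  in_band <- freqs >= band[1L] & freqs <= min(band[2L], fs / 2)
  amp[in_band] <- 1 / sqrt(freqs[in_band])
  z <- complex(
    real = rnorm(n_pos), imaginary = rnorm(n_pos)
  ) * amp
  z[1L] <- 0
  # assemble Hermitian spectrum for a real inverse transform
  spec <- complex(length.out = n)
  spec[seq_len(n_pos)] <- z
  if (n %% 2 == 0) spec[n_pos] <- complex(real = Re(z[n_pos]), imaginary = 0)
  half <- if (n %% 2 == 0) n_pos - 1L else n_pos
  if (half >= 2L) spec[n - (2:half) + 2L] <- Conj(z[2:half])
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * (sigma / s)
}

#' Construct a seizure record
#'
#' A `seizure_record` pairs one preictal and one interictal multichannel
#' segment for a single seizure, both stored as channels-by-samples
#' matrices at a common sampling rate.
#'
#' @param subject_id character label.
#' @param seizure_id integer seizure index.
#' @param preictal,interictal numeric channels-by-samples matrices of equal
#'   shape with finite entries.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @return an object of class `seizure_record`.
#' @export
seizure_record <- function(subject_id, seizure_id, preictal, interictal, fs,
                           channel_labels = NULL) {
  if (!is.matrix(preictal) || !is.matrix(interictal)) {
    stop_param("preictal and interictal must be channels x samples matrices")
  }
  if (!identical(dim(preictal), dim(interictal))) {
    stop_param("preictal and interictal segments must have identical shape")
  }
  if (any(!is.finite(preictal)) || any(!is.finite(interictal))) {
    stop_data("seizure record contains non-finite samples")
  }
  if (!is_number(fs) || fs <= 0) stop_param("fs must be positive")
  channel_labels <- channel_labels %||%
    sprintf("ch%02d", seq_len(nrow(preictal)))
  if (length(channel_labels) != nrow(preictal)) {
    stop_param("channel_labels must match the number of channels")
  }
  structure(
    list(
      subject_id = subject_id, seizure_id = as.integer(seizure_id),
      preictal = preictal, interictal = interictal, fs = fs,
      channel_labels = as.character(channel_labels)
    ),
    class = "seizure_record"
  )
}

#' Generate all seizure records for a synthetic subject
#'
#' Produces `spec$n_seizures` paired preictal/interictal segments. Channels
#' in `spec$coupled_channels` are generated with `lambda_preictal` in the
#' preictal state and `lambda_interictal` in the interictal state;
#' all other channels use `lambda_interictal` in both states, so only the
#' coupled channels carry a state difference. Interictal segments are
#' generated independently for every seizure. Each (seizure, state, channel)
#' stream is seeded deterministically from `spec$seed` via [derive_seed()],
#' so the output is a pure function of the spec and identical across calls.
#'
#' @param spec a [subject_spec()].
#' @return list of [seizure_record()] objects, one per seizure.
#' @export
#' @examples
#' sp <- subject_spec("demo", n_seizures = 2, n_channels = 2,
#'                    segment_duration = 60, seed = 42)
#' recs <- generate_subject(sp)
#' dim(recs[[1]]$preictal)
generate_subject <- function(spec) {
  if (!inherits(spec, "subject_spec")) {
    stop_param("spec must be a subject_spec object")
  }
  lapply(seq_len(spec$n_seizures), function(sz) {
    segs <- lapply(c("preictal", "interictal"), function(state) {
      mat <- matrix(
        0, nrow = spec$n_channels,
        ncol = round(spec$segment_duration * spec$fs)
      )
      for (ch in seq_len(spec$n_channels)) {
        lam <- if (ch %in% spec$coupled_channels && state == "preictal") {
          spec$lambda_preictal
        } else {
          spec$lambda_interictal
        }
        mat[ch, ] <- with_seed(
          derive_seed(spec$seed, spec$subject_id, sz, state, ch),
          generate_qpc_channel(
            spec$segment_duration, spec$fs, spec$f1, spec$f2,
            lambda_coupling = lam, amp_triplet = spec$amp_triplet,
            noise_sigma = spec$noise_sigma, epoch_s = spec$epoch_s
          )
        )
      }
      mat
    })
    seizure_record(spec$subject_id, sz, segs[[1L]], segs[[2L]], spec$fs)
  })
}
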