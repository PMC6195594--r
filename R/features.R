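masked_magnitudes <- function(estimate) {
  if (!inherits(estimate, "bispectrum_estimate")) {
    stop_param("estimate must be a bispectrum_estimate")
  }
  if (estimate$L < 1L) stop_degenerate("principal-domain mask is empty")
  Mod(estimate$values[estimate$principal_mask])
}

#' Mean bispectral magnitude (Mave)
#'
#' The average of `|B(f1, f2)|` over the `L` bins of the non-redundant
#' principal region. Sensitive to the overall strength of third-order
#' structure; scales as `|c|^3` when the input signal is scaled by `c`.
#'
#' @param estimate a `bispectrum_estimate`.
#' @return non-negative scalar.
#' @export
mave <- function(estimate) {
  mean(masked_magnitudes(estimate))
}

shannon_entropy <- function(w) {
  total <- sum(w)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  p <- w / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized bispectral entropy (P1)
#'
#' Shannon entropy (natural log, in nats) of the bispectral magnitude
#' distribution \eqn{p_n = |B|/\sum_\Omega |B|} over the `L`
#' principal-domain bins. Ranges from 0 (all bispectral mass in a single
#' frequency pair — a perfectly regular, concentrated bispectrum) to
#' `ln(L)` (flat bispectrum). Invariant under scaling of the input signal.
#' Strong quadratic phase coupling concentrates the bispectrum and lowers
#' P1.
#'
#' Returns `NA` for an all-zero (degenerate) bispectrum; callers such as
#' [extract_features()] drop and count such windows rather than aborting.
#'
#' @param estimate a `bispectrum_estimate`.
#' @return scalar in `[0, ln(L)]`, or `NA` for a degenerate window.
#' @export
p1 <- function(estimate) {
  shannon_entropy(masked_magnitudes(estimate))
}

#' Normalized bispectral squared entropy (P2)
#'
#' Shannon entropy of the squared-magnitude distribution
#' \eqn{q_i = |B|^2/\sum_\Omega |B|^2}. Squaring sharpens the distribution
#' (an escort distribution of the one underlying P1), hence
#' `P2 <= P1` always, with equality for a flat bispectrum.
#'
#' @inheritParams p1
#' @return scalar in `[0, ln(L)]`, or `NA` for a degenerate window.
#' @export
p2 <- function(estimate) {
  shannon_entropy(masked_magnitudes(estimate)^2)
}

# Fast path shared by extract_features: one channel of one window to the
# (mave, p1, p2) triple, reusing a precomputed mask index and taper. The
# reduction runs inside the compiled kernel so the full complex grid is
# never materialized per window.
window_feature_triple <- function(x, spec, taper, mask_idx, L) {
  segs <- segment_matrix(x, spec)
  tri <- bispec_features_cpp(segs, taper, spec$mean_subtract, mask_idx - 1L)
  c(mave = tri[1L], p1 = tri[2L], p2 = tri[3L])
}

#' Extract bispectral features from a window set
#'
#' Computes the bispectrum of every (window, channel) independently and
#' reduces it to the three higher-order-spectral features. Windows whose
#' bispectrum is identically zero on the principal domain (degenerate, e.g.
#' flat-lined channels) are dropped and reported via a message.
#'
#' @param window_set a [segment_windows()] result carrying `state`,
#'   `seizure_id` and `subject_id` metadata.
#' @param spec an [estimator_spec()].
#' @param band analysis band in Hz.
#' @return a tibble with one row per (window, channel): `subject_id`,
#'   `seizure_id`, `state`, `window_index`, `channel`, `mave`, `p1`, `p2`.
#' @seealso [extract_features_dataset()] for the filter + window + extract
#'   composition over whole seizure records.
#' @export
extract_features <- function(window_set, spec = estimator_spec(),
                             band = c(0.5, 180)) {
  if (!inherits(window_set, "window_set")) {
    stop_param("window_set must come from segment_windows()")
  }
  if (!inherits(spec, "estimator_spec")) {
    stop_param("spec must be an estimator_spec")
  }
  pd <- principal_domain_mask(spec$seg_len, window_set$fs, band[1L], band[2L])
  mask_idx <- which(pd$mask)
  taper <- taper_vector(spec$taper, spec$seg_len)
  n_win <- window_set$n_windows
  if (n_win == 0L) {
    return(empty_feature_table())
  }
  n_ch <- nrow(window_set$windows[[1L]])
  rows <- vector("list", n_win * n_ch)
  k <- 0L
  dropped <- 0L
  for (w in seq_len(n_win)) {
    win <- window_set$windows[[w]]
    for (ch in seq_len(n_ch)) {
      tri <- window_feature_triple(win[ch, ], spec, taper, mask_idx, pd$L)
      if (anyNA(tri)) {
        dropped <- dropped + 1L
        next
      }
      k <- k + 1L
      rows[[k]] <- c(window_index = w, channel = ch, tri)
    }
  }
  if (dropped > 0L) {
    message(sprintf("extract_features: dropped %d degenerate (all-zero bispectrum) window-channel rows",
                    dropped))
  }
  if (k == 0L) return(empty_feature_table())
  mat <- do.call(rbind, rows[seq_len(k)])
  tibble::tibble(
    subject_id = window_set$subject_id %||% NA_character_,
    seizure_id = window_set$seizure_id %||% NA_integer_,
    state = window_set$state %||% NA_character_,
    window_index = as.integer(mat[, "window_index"]),
    channel = as.integer(mat[, "channel"]),
    mave = mat[, "mave"],
    p1 = mat[, "p1"],
    p2 = mat[, "p2"]
  )
}

empty_feature_table <- function() {
  tibble::tibble(
    subject_id = character(), seizure_id = integer(), state = character(),
    window_index = integer(), channel = integer(),
    mave = numeric(), p1 = numeric(), p2 = numeric()
  )
}

#' Full feature table for a list of seizure records
#'
#' For every record: zero-phase filter both segments, cut them into
#' non-overlapping windows and extract the bispectral features per window
#' and channel.
#'
#' @param records list of [seizure_record()] objects.
#' @param filter filtering settings, a [filter_spec()], or `NULL` to skip
#'   filtering.
#' @param spec an [estimator_spec()].
#' @param window_length_s analysis window length in seconds.
#' @param band analysis band in Hz.
#' @param verbose emit one progress message per record.
#' @return a tibble, rows keyed by
#'   (subject_id, seizure_id, state, window_index, channel).
#' @export
extract_features_dataset <- function(records, filter = filter_spec(),
                                     spec = estimator_spec(),
                                     window_length_s = 30,
                                     band = c(0.5, 180), verbose = FALSE) {
  if (inherits(records, "seizure_record")) records <- list(records)
  tabs <- lapply(records, function(rec) {
    both <- lapply(c("preictal", "interictal"), function(state) {
      sig <- rec[[state]]
      if (!is.null(filter)) sig <- zero_phase_filter(sig, rec$fs, filter)
      ws <- segment_windows(sig, rec$fs, window_length_s, state = state,
                            seizure_id = rec$seizure_id,
                            subject_id = rec$subject_id)
      extract_features(ws, spec, band)
    })
    if (verbose) {
      message(sprintf("features: %s seizure %d done", rec$subject_id,
                      rec$seizure_id))
    }
    do.call(rbind, both)
  })
  do.call(rbind, tabs)
}
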