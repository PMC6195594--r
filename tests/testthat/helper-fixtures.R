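# Small fixtures shared across test files. All data are generated in code.

# A tiny subject: short segments and few channels keep the bispectrum count
# low while exercising the full record structure.
tiny_spec <- function(...) {
  args <- modifyList(
    list(subject_id = "T1", n_seizures = 2, n_channels = 2,
         segment_duration = 90, coupled_channels = 1, seed = 101),
    list(...)
  )
  do.call(subject_spec, args)
}

# Directly assembled bispectrum estimate with prescribed magnitudes on the
# principal domain, for testing the feature reductions in isolation.
synthetic_estimate <- function(masked_values, nfft = 16, fs = 16,
                               band = c(0, 8)) {
  pd <- principal_domain_mask(nfft, fs, band[1], band[2])
  stopifnot(length(masked_values) <= pd$L)
  values <- matrix(0 + 0i, nfft / 2 + 1, nfft / 2 + 1)
  idx <- which(pd$mask)[seq_along(masked_values)]
  values[idx] <- masked_values
  est <- preictal:::new_bispectrum_estimate(values, fs, nfft, 1L, band)
  est
}

# Gaussian feature table (no bispectra) for classifier-only tests:
# per (seizure, state, window, channel) rows with a controllable state
# shift on a subset of channels.
gaussian_feature_table <- function(n_seizures, n_windows, n_channels,
                                   shift = 0, shifted_channels = integer(),
                                   seed = 1) {
  preictal:::with_seed(seed, {
    grid <- expand.grid(
      channel = seq_len(n_channels),
      window_index = seq_len(n_windows),
      state = c("preictal", "interictal"),
      seizure_id = seq_len(n_seizures),
      stringsAsFactors = FALSE
    )
    mu <- ifelse(
      grid$state == "preictal" & grid$channel %in% shifted_channels,
      shift, 0
    )
    tibble::tibble(
      subject_id = "G1",
      seizure_id = grid$seizure_id,
      state = grid$state,
      window_index = grid$window_index,
      channel = grid$channel,
      mave = abs(rnorm(nrow(grid), 10 + mu)),
      p1 = rnorm(nrow(grid), 4 + mu, 1),
      p2 = rnorm(nrow(grid), 3 + mu, 1)
    )
  })
}
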