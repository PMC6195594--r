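test_that("generation is a pure function of spec and seed", {
  sp <- tiny_spec()
  r1 <- generate_subject(sp)
  r2 <- generate_subject(sp)
  expect_identical(r1, r2)
  expect_length(r1, 2L)
  expect_identical(dim(r1[[1]]$preictal), c(2L, 90L * 400L))
  expect_identical(dim(r1[[1]]$interictal), dim(r1[[1]]$preictal))

  set.seed(9)
  a <- generate_qpc_channel(5, 400, 40, 30, 0.5, noise_sigma = 0.3)
  set.seed(9)
  b <- generate_qpc_channel(5, 400, 40, 30, 0.5, noise_sigma = 0.3)
  expect_identical(a, b)
})

test_that("degenerate amplitudes give the all-zero signal", {
  set.seed(1)
  x <- generate_qpc_channel(3, 400, 40, 30, 1, amp_triplet = c(0, 0, 0),
                            noise_sigma = 0)
  expect_identical(x, rep(0, 1200))
})

test_that("invalid coupling parameters are rejected", {
  expect_error(generate_qpc_channel(5, 400, 40, 30, 1.2),
               class = "preictal_parameter_error")
  expect_error(generate_qpc_channel(5, 400, 0.1, 30, 0.5),
               class = "preictal_parameter_error")
  expect_error(generate_qpc_channel(5, 400, 100, 100, 0.5),
               class = "preictal_parameter_error")
  expect_error(generate_qpc_channel(5, 400, 120, 90, 0.5),
               class = "preictal_parameter_error")
  expect_error(subject_spec(coupled_channels = 20, n_channels = 16),
               class = "preictal_parameter_error")
  expect_error(subject_spec(lambda_preictal = -0.1),
               class = "preictal_parameter_error")
})

test_that("coupling strength is spectrally stealthy: identical PSD at the harmonic", {
  # lambda changes only third-order structure; the power at f1 + f2 must
  # agree between lambda = 0 and lambda = 1 within Monte-Carlo error.
  psd_at_bin <- function(x, fs, f) {
    n <- fs  # 1-s epochs, bin-aligned
    segm <- matrix(x[seq_len(n * (length(x) %/% n))], nrow = n)
    X <- mvfft(segm) / n
    Mod(X[f + 1, ])^2
  }
  set.seed(11)
  p0 <- psd_at_bin(generate_qpc_channel(50, 400, 40, 30, 0, noise_sigma = 0.3),
                   400, 70)
  set.seed(12)
  p1v <- psd_at_bin(generate_qpc_channel(50, 400, 40, 30, 1, noise_sigma = 0.3),
                    400, 70)
  se <- sqrt(var(p0) / length(p0) + var(p1v) / length(p1v))
  expect_lt(abs(mean(p0) - mean(p1v)), 3 * max(se, 1e-12))
})

test_that("state-dependent coupling lands on the coupled channels only", {
  sp <- tiny_spec(n_channels = 3, coupled_channels = 2, noise_sigma = 0,
                  segment_duration = 50)
  recs <- generate_subject(sp)
  peak <- function(x) {
    e <- direct_bispectrum(x, 400, estimator_spec(seg_len = 400))
    Mod(e$values)[41, 31]
  }
  r <- recs[[1]]
  # coupled channel: strong peak preictally, weak interictally (the
  # interictal bin keeps a finite-K sampling fluctuation, so the contrast
  # is bounded but must be clear)
  expect_gt(peak(r$preictal[2, ]), 2 * peak(r$interictal[2, ]))
  # uncoupled channel: weak in both states
  expect_lt(peak(r$preictal[1, ]), 0.5 * peak(r$preictal[2, ]))
})

test_that("dataset write/read round-trips records through float32 + manifest", {
  sp <- tiny_spec(segment_duration = 2, n_channels = 4,
                  coupled_channels = 1:2)
  recs <- generate_subject(sp)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(recs, dir)
  expect_true(file.exists(manifest))
  back <- read_dataset(dir)
  expect_length(back, length(recs))
  # reduced fixture: reader must honor the manifest's 4 channels
  expect_identical(nrow(back[[1]]$preictal), 4L)
  expect_identical(back[[1]]$channel_labels, recs[[1]]$channel_labels)
  # first cycle: equal at float32 precision
  expect_equal(back[[1]]$preictal, recs[[1]]$preictal, tolerance = 1e-6)
  # second cycle: bit-exact
  dir2 <- withr::local_tempdir()
  write_dataset(back, dir2)
  again <- read_dataset(dir2)
  expect_identical(again[[1]]$preictal, back[[1]]$preictal)
  expect_identical(again[[2]]$interictal, back[[2]]$interictal)
})

test_that("corrupt datasets are rejected with integrity/format errors", {
  sp <- tiny_spec(segment_duration = 2)
  recs <- generate_subject(sp)
  dir <- withr::local_tempdir()
  write_dataset(recs, dir)

  expect_error(read_dataset(withr::local_tempdir()),
               class = "preictal_format_error")

  # checksum mismatch
  f32 <- list.files(dir, pattern = "\\.f32$", full.names = TRUE)[1]
  bytes <- readBin(f32, "raw", file.info(f32)$size)
  bytes[1] <- as.raw(bitwXor(as.integer(bytes[1]), 255L))
  writeBin(bytes, f32)
  expect_error(read_dataset(dir), class = "preictal_integrity_error")

  # missing file entry
  file.remove(f32)
  expect_error(read_dataset(dir), class = "preictal_integrity_error")
})
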