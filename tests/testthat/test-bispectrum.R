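test_that("direct estimator matches the time-domain triple-correlation oracle", {
  set.seed(42)
  for (rep in 1:3) {
    segs <- lapply(1:3, function(i) rnorm(64))
    oracle <- brute_force_bispectrum(segs, fs = 64, band = c(0.5, 30))
    direct <- direct_bispectrum(
      unlist(segs), 64,
      estimator_spec(seg_len = 64, taper = "none", mean_subtract = FALSE),
      band = c(0.5, 30)
    )
    rel <- max(abs(direct$values - oracle$values)) / max(abs(oracle$values))
    expect_lt(rel, 1e-8)
  }
})

test_that("oracle input contracts are enforced", {
  expect_error(brute_force_bispectrum(list(), 64),
               class = "preictal_size_error")
  expect_error(brute_force_bispectrum(lapply(1:9, function(i) rnorm(32)), 64),
               class = "preictal_size_error")
  expect_error(brute_force_bispectrum(list(rnorm(256)), 64),
               class = "preictal_size_error")
})

test_that("bispectrum is symmetric, zero for zero input, and scales as |c|^3", {
  z <- direct_bispectrum(numeric(12000), 400)
  expect_true(all(z$values == 0))

  set.seed(7)
  x <- rnorm(12000)
  e <- direct_bispectrum(x, 400)
  expect_equal(e$values, t(e$values))
  expect_identical(e$n_segments, 23L)

  e2 <- direct_bispectrum(2 * x, 400)
  expect_equal(Mod(e2$values), 8 * Mod(e$values), tolerance = 1e-9)

  # oracle route keeps symmetry to numerical precision on a coupled triple
  tt <- (0:63) / 64
  trip <- cos(2 * pi * 8 * tt + 0.4) + cos(2 * pi * 5 * tt + 1.1) +
    cos(2 * pi * 13 * tt + 1.5)
  co <- brute_force_bispectrum(list(trip), 64, band = c(0.5, 30))
  expect_lt(max(abs(co$values - t(co$values))), 1e-10 * max(abs(co$values)))
})

test_that("quadratic phase coupling raises a peak at (f1, f2)", {
  set.seed(31)
  x <- generate_qpc_channel(60, 400, 40, 30, 1, noise_sigma = 0)
  e <- direct_bispectrum(x, 400, estimator_spec(seg_len = 400))
  expect_gte(e$n_segments, 20L)
  m <- Mod(e$values)
  onpeak <- matrix(FALSE, nrow(m), ncol(m))
  onpeak[41, 31] <- TRUE
  bg <- m[e$principal_mask & !onpeak]
  expect_gt(m[41, 31], 10 * max(median(bg), 1e-12))
})

test_that("peak-to-background ratio increases with coupling strength", {
  ratio_at <- function(lam, seed) {
    set.seed(seed)
    x <- generate_qpc_channel(50, 400, 40, 30, lam, noise_sigma = 0.5)
    e <- direct_bispectrum(x, 400, estimator_spec(seg_len = 400))
    m <- Mod(e$values)
    off <- e$principal_mask &
      !(abs(row(m) - 41) <= 1 & abs(col(m) - 31) <= 1)
    m[41, 31] / median(m[off])
  }
  reps <- 1:20
  r0 <- mean(vapply(reps, function(s) ratio_at(0, s), 1))
  r05 <- mean(vapply(reps, function(s) ratio_at(0.5, 100 + s), 1))
  r1 <- mean(vapply(reps, function(s) ratio_at(1, 200 + s), 1))
  expect_lt(r0, r05)
  expect_lt(r05, r1)
})

test_that("principal domain mask matches hand enumeration and is monotone in band", {
  # nfft = 8, fs = 8: bins at 0..4 Hz; triangle j <= i, i + j <= 4
  pd <- principal_domain_mask(8, 8, 0, 4)
  expected <- rbind(
    c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0),
    c(1, 1), c(2, 1), c(3, 1), c(2, 2)
  )
  hits <- which(pd$mask, arr.ind = TRUE) - 1L
  expect_identical(pd$L, nrow(expected))
  expect_setequal(paste(hits[, 1], hits[, 2]), paste(expected[, 1], expected[, 2]))

  # excluding 0 Hz drops the f2 = 0 row
  pd2 <- principal_domain_mask(8, 8, 1, 4)
  expect_identical(pd2$L, 4L)  # (1,1), (2,1), (3,1), (2,2)

  expect_error(principal_domain_mask(8, 8, 3, 2),
               class = "preictal_parameter_error")
  expect_error(principal_domain_mask(8, 8, 0, 5),
               class = "preictal_parameter_error")

  # widening the band never decreases L
  set.seed(5)
  for (i in 1:20) {
    nfft <- 2 * sample(8:64, 1)
    fs <- sample(c(64, 128, 400), 1)
    lo <- runif(1, 0, fs / 8)
    hi <- runif(1, lo, fs / 2)
    lo2 <- runif(1, 0, lo)
    hi2 <- runif(1, hi, fs / 2)
    expect_gte(principal_domain_mask(nfft, fs, lo2, hi2)$L,
               principal_domain_mask(nfft, fs, lo, hi)$L)
  }
})

test_that("estimator rejects bad inputs", {
  expect_error(direct_bispectrum(c(rnorm(999), NaN), 400,
                                 estimator_spec(seg_len = 256)),
               class = "preictal_data_error")
  expect_error(direct_bispectrum(rnorm(100), 400, estimator_spec(seg_len = 512)),
               class = "preictal_parameter_error")
  expect_error(estimator_spec(seg_len = 511),
               class = "preictal_parameter_error")
})
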