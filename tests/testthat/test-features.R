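test_that("feature identities hold on prescribed bispectra", {
  # uniform magnitude c over all L bins: Mave = c, P1 = P2 = ln(L)
  L <- principal_domain_mask(16, 16, 0, 8)$L
  est <- synthetic_estimate(rep(3.5 + 0i, L), nfft = 16, fs = 16,
                            band = c(0, 8))
  expect_equal(mave(est), 3.5)
  expect_equal(p1(est), log(L))
  expect_equal(p2(est), log(L))

  # point mass: zero entropy
  pm <- synthetic_estimate(c(7 + 0i, rep(0, L - 1)), nfft = 16, fs = 16,
                           band = c(0, 8))
  expect_equal(p1(pm), 0)
  expect_equal(p2(pm), 0)

  # magnitudes (1, 1, 2) on an exactly 3-bin principal domain:
  # P1 = -(1/4 ln 1/4 + 1/4 ln 1/4 + 1/2 ln 1/2) and q = (1/6, 1/6, 2/3)
  expect_identical(principal_domain_mask(8, 8, 1, 2)$L, 3L)
  tri <- synthetic_estimate(c(1, 1, 2), nfft = 8, fs = 8, band = c(1, 2))
  expect_equal(p1(tri), -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_equal(p2(tri), -(2 * (1 / 6) * log(1 / 6) + (2 / 3) * log(2 / 3)))
  expect_equal(p1(tri), 1.0397, tolerance = 1e-4)
  expect_equal(p2(tri), 0.8675, tolerance = 1e-4)

  # random field mean matches direct summation
  set.seed(8)
  vals <- complex(real = rnorm(5), imaginary = rnorm(5))
  rf <- synthetic_estimate(vals, nfft = 16, fs = 16, band = c(0, 8))
  expect_equal(mave(rf), sum(Mod(vals)) / rf$L, tolerance = 1e-12)
})

test_that("P2 <= P1 and entropy bounds hold over random fields", {
  set.seed(123)
  for (i in 1:1000) {
    L <- sample(2:9, 1)
    m <- runif(L, 0, 10)
    est <- synthetic_estimate(m + 0i, nfft = 16, fs = 16, band = c(0, 8))
    v1 <- p1(est); v2 <- p2(est)
    expect_lte(v2, v1 + 1e-12)
    expect_gte(v1, 0); expect_lte(v1, log(est$L) + 1e-12)
    expect_gte(v2, 0)
  }
})

test_that("Mave scales as |c|^3 while P1 and P2 are scale-invariant", {
  set.seed(21)
  x <- generate_qpc_channel(30, 400, 40, 30, 0.6, noise_sigma = 0.5)
  a <- direct_bispectrum(x, 400)
  b <- direct_bispectrum(2 * x, 400)
  expect_equal(mave(b), 8 * mave(a), tolerance = 1e-9)
  expect_equal(p1(b), p1(a), tolerance = 1e-9)
  expect_equal(p2(b), p2(a), tolerance = 1e-9)
})

test_that("degenerate windows yield NA entropies and are dropped from tables", {
  z <- direct_bispectrum(numeric(12000), 400)
  expect_equal(mave(z), 0)
  expect_true(is.na(p1(z)))
  expect_true(is.na(p2(z)))

  ws <- segment_windows(matrix(0, 1, 12000), 400, 30, state = "preictal",
                        seizure_id = 1, subject_id = "Z")
  expect_message(ft <- extract_features(ws), "degenerate")
  expect_identical(nrow(ft), 0L)
})

test_that("feature tables have one row per window and channel, deterministically", {
  sp <- tiny_spec(n_channels = 2, segment_duration = 90)
  recs <- generate_subject(sp)
  ft <- extract_features_dataset(recs)
  # 2 seizures x 2 states x 3 windows x 2 channels
  expect_identical(nrow(ft), 24L)
  expect_identical(sort(unique(ft$state)), c("interictal", "preictal"))
  ft2 <- extract_features_dataset(recs)
  expect_identical(ft, ft2)
  # entropy invariants on real rows
  expect_true(all(ft$p2 <= ft$p1 + 1e-12))
  expect_true(all(ft$mave >= 0))
})

test_that("preictal coupling lowers P1 on the coupled channel", {
  sp <- tiny_spec(n_channels = 2, coupled_channels = 1,
                  segment_duration = 300, n_seizures = 2)
  ft <- extract_features_dataset(generate_subject(sp))
  coupled <- ft[ft$channel == 1, ]
  expect_lt(mean(coupled$p1[coupled$state == "preictal"]),
            mean(coupled$p1[coupled$state == "interictal"]))
})
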