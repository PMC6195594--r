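test_that("two-group ANOVA matches its closed-form cases and t^2", {
  r <- one_way_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_identical(r$df_between, 1L)
  expect_identical(r$df_within, 4L)

  # df arithmetic at the 17-seizure scale: N = 4080 -> df_within = 4078
  set.seed(2)
  big <- one_way_anova(rnorm(2040), rnorm(2040))
  expect_identical(big$df_within, 4078L)

  # near-zero within variance
  jit <- one_way_anova(rnorm(4, 0, 1e-9), 1 + rnorm(4, 0, 1e-9))
  expect_gt(jit$F, 1e10)

  # F == t^2 for two groups
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = runif(1))
    f <- one_way_anova(a, b)$F
    t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-10)
  }

  expect_error(one_way_anova(1, c(1, 2)), class = "preictal_size_error")
  expect_error(one_way_anova(c(1, 1), c(1, 1)),
               class = "preictal_degenerate_error")
})

test_that("Mann-Whitney U handles exact, tied and shifted cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)

  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  same <- mann_whitney_u(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_gt(same$p, 0.95)

  set.seed(4)
  shifted <- mann_whitney_u(rnorm(120), rnorm(120, 1))
  expect_lt(shifted$p, 0.001)
  expect_true(shifted$U >= 0 && shifted$U <= 120^2)

  expect_error(mann_whitney_u(numeric(), 1:3), class = "preictal_size_error")
})

test_that("normal approximation tracks exact enumeration at n = 12", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12, runif(1, 0, 1))
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("per-seizure tests produce one row per seizure, channel and feature", {
  ft <- gaussian_feature_table(n_seizures = 17, n_windows = 10,
                               n_channels = 16, seed = 10)
  mw <- per_seizure_tests(ft)
  expect_identical(nrow(mw), 17L * 16L * 3L)  # 816
  expect_true(all(mw$n1 == 10 & mw$n2 == 10))

  # a seizure missing one state is skipped with a warning
  ft_miss <- ft[!(ft$seizure_id == 3 & ft$state == "preictal"), ]
  expect_warning(mw2 <- per_seizure_tests(ft_miss), "missing a state")
  expect_identical(nrow(mw2), 16L * 16L * 3L)
})

test_that("predictability map cells are exact multiples of 100 / n_seizures", {
  ft <- gaussian_feature_table(n_seizures = 17, n_windows = 12,
                               n_channels = 2, shift = 3,
                               shifted_channels = 1, seed = 20)
  mw <- per_seizure_tests(ft)
  pm <- predictability_map(mw, alpha = 0.05)
  expect_true(all(pm$n_seizures == 17L))
  mult <- pm$pct * 17 / 100
  expect_equal(mult, round(mult), tolerance = 1e-9)
  mat <- predictability_matrix(pm, "G1")
  # strongly shifted channel flags every seizure; p2/p1/mave all shifted
  expect_equal(unname(mat["ch1", "p1"]), 100)

  # all / none significant edge cases via synthetic p-value tables
  fake <- tibble::tibble(
    subject_id = "S", seizure_id = rep(1:5, each = 2),
    channel = rep(1:2, 5), feature = "p1", U = 0,
    p = 0.001, n1 = 10L, n2 = 10L
  )
  expect_true(all(predictability_map(fake)$pct == 100))
  fake$p <- 0.9
  expect_true(all(predictability_map(fake)$pct == 0))
  # 9 of 17 significant -> 52.94
  fake17 <- tibble::tibble(
    subject_id = "S", seizure_id = 1:17, channel = 1, feature = "p1",
    U = 0, p = c(rep(0.01, 9), rep(0.5, 8)), n1 = 10L, n2 = 10L
  )
  expect_equal(predictability_map(fake17)$pct, 100 * 9 / 17,
               tolerance = 1e-9)
})

test_that("global ANOVA collapses channels per window before testing", {
  ft <- gaussian_feature_table(n_seizures = 3, n_windows = 8, n_channels = 4,
                               shift = 2, shifted_channels = 1:4, seed = 30)
  res <- global_anova(ft)
  expect_identical(nrow(res), 3L)  # one row per feature
  # N = 3 seizures x 2 states x 8 windows = 48 -> df 46
  expect_true(all(res$df_within == 46L))
  expect_lt(res$p[res$feature == "p1"], 0.001)
})
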