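test_that("seizure-wise split uses largest-remainder rounding and is leakage-free", {
  p17 <- split_by_seizure(1:17, seed = 1)
  expect_identical(lengths(p17[c("train", "validation", "test")]),
                   c(train = 7L, validation = 5L, test = 5L))
  p10 <- split_by_seizure(1:10, seed = 2)
  expect_identical(lengths(p10[c("train", "validation", "test")]),
                   c(train = 4L, validation = 3L, test = 3L))
  # partition property: disjoint and exhaustive
  ids <- c(p17$train, p17$validation, p17$test)
  expect_setequal(ids, 1:17)
  expect_identical(anyDuplicated(ids), 0L)
  # window-level leakage: no (seizure, state) key in two partitions
  ft <- gaussian_feature_table(17, 4, 2, seed = 3)
  keys <- lapply(p17[c("train", "validation", "test")], function(sz) {
    unique(paste(ft$seizure_id[ft$seizure_id %in% sz],
                 ft$state[ft$seizure_id %in% sz]))
  })
  expect_length(Reduce(intersect, keys), 0L)

  expect_error(split_by_seizure(1:2), class = "preictal_size_error")

  # seeded determinism
  expect_identical(split_by_seizure(1:17, seed = 9),
                   split_by_seizure(1:17, seed = 9))
})

test_that("analytic gradients match central finite differences", {
  err <- preictal:::with_seed(42, {
    X <- matrix(rnorm(4 * 3), 4, 3)
    Y <- preictal:::one_hot(sample(c("preictal", "interictal"), 4, TRUE))
    params <- preictal:::mlp_init(c(3, 4, 2))
    g <- preictal:::mlp_grads(params, X, Y)
    loss_at <- function(p) {
      preictal:::mlp_loss(
        preictal:::mlp_forward(p, X)[[length(p$W) + 1]], Y
      )
    }
    h <- 1e-6
    max_err <- 0
    max_grad <- 0
    for (l in seq_along(params$W)) {
      for (slot in c("W", "b")) {
        for (i in seq_along(params[[slot]][[l]])) {
          pp <- params; pp[[slot]][[l]][i] <- pp[[slot]][[l]][i] + h
          pm <- params; pm[[slot]][[l]][i] <- pm[[slot]][[l]][i] - h
          gn <- (loss_at(pp) - loss_at(pm)) / (2 * h)
          ga <- g[[slot]][[l]][i]
          max_err <- max(max_err, abs(gn - ga))
          max_grad <- max(max_grad, abs(ga))
        }
      }
    }
    max_err / max_grad
  })
  expect_lt(err, 1e-5)
})

test_that("the MLP separates well-separated classes and stays at chance on nulls", {
  # feature tables built directly: channel-shifted Gaussians on 4 of 16
  # channels stand in for the coupled-channel feature contrast
  sep <- gaussian_feature_table(12, 20, 16, shift = 2,
                                shifted_channels = 1:4, seed = 50)
  plan <- split_by_seizure(1:12, seed = 7)
  cfg <- mlp_config(max_epochs = 1500, seed = 11)
  fit <- train_mlp(sep, plan, "p1", cfg)
  expect_gte(fit$report$test_accuracy, 0.90)
  expect_true(all(dim(fit$report$confusion) == c(2, 2)))

  nul <- gaussian_feature_table(12, 20, 16, shift = 0, seed = 51)
  accs <- vapply(1:3, function(s) {
    train_mlp(nul, plan, "p1", mlp_config(max_epochs = 200, seed = s)
    )$report$test_accuracy
  }, 1)
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("training is reproducible and the loss decreases on separable data", {
  sep <- gaussian_feature_table(10, 12, 8, shift = 2, shifted_channels = 1:4,
                                seed = 60)
  plan <- split_by_seizure(1:10, seed = 3)
  cfg <- mlp_config(layer_sizes = c(8, 30, 60, 30, 2), batch_size = 90,
                    max_epochs = 120, seed = 5)
  f1 <- train_mlp(sep, plan, "p1", cfg)
  f2 <- train_mlp(sep, plan, "p1", cfg)
  expect_identical(f1$report$selected_checkpoint_epoch,
                   f2$report$selected_checkpoint_epoch)
  expect_identical(f1$report$test_accuracy, f2$report$test_accuracy)
  expect_identical(f1$model$W, f2$model$W)
  expect_lt(f1$report$train_loss[100], f1$report$train_loss[1])
})

test_that("evaluation contracts: accuracy, confusion orientation, empty partitions", {
  sep <- gaussian_feature_table(10, 12, 8, shift = 2, shifted_channels = 1:4,
                                seed = 61)
  plan <- split_by_seizure(1:10, seed = 3)
  cfg <- mlp_config(layer_sizes = c(8, 30, 60, 30, 2), batch_size = 90,
                    max_epochs = 100, seed = 5)
  fit <- train_mlp(sep, plan, "p1", cfg)
  ev <- evaluate_mlp(fit$model, sep, plan, "test")
  expect_equal(ev$accuracy, fit$report$test_accuracy)
  expect_identical(sum(ev$confusion), ev$n)

  # a constant predictor on balanced labels scores 0.5
  const <- fit$model
  for (l in seq_along(const$W)) const$W[[l]][] <- 0
  const$b[[length(const$b)]] <- c(1, 0)  # always "interictal"
  for (l in seq_len(length(const$b) - 1)) const$b[[l]][] <- 0
  ev0 <- evaluate_mlp(const, sep, plan, "test")
  expect_equal(ev0$accuracy, 0.5)

  # too-small training partition -> size error
  expect_error(
    train_mlp(sep, plan, "p1",
              mlp_config(layer_sizes = c(8, 4, 2), batch_size = 5000,
                         max_epochs = 10)),
    class = "preictal_size_error"
  )
})

test_that("models round-trip through the JSON serialization", {
  sep <- gaussian_feature_table(10, 8, 4, shift = 2, shifted_channels = 1:2,
                                seed = 70)
  plan <- split_by_seizure(1:10, seed = 3)
  fit <- train_mlp(sep, plan, "p2",
                   mlp_config(layer_sizes = c(4, 6, 2), batch_size = 60,
                              max_epochs = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_model(fit$model, path)
  back <- read_mlp_model(path)
  expect_equal(back$W, fit$model$W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$b, fit$model$b, tolerance = 1e-12, ignore_attr = TRUE)
  ev1 <- evaluate_mlp(fit$model, sep, plan, "test")
  ev2 <- evaluate_mlp(back, sep, plan, "test")
  expect_identical(ev1$accuracy, ev2$accuracy)
})
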