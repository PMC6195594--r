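#' Multilayer perceptron configuration
#'
#' The reference architecture is a 5-layer fully connected network,
#' 16 inputs (one bispectral feature value per channel) through hidden
#' layers of 30, 60 and 30 rectified-linear units to a 2-node softmax
#' output (preictal vs interictal), trained with plain stochastic gradient
#' descent on the categorical cross-entropy, learning rate 0.001,
#' mini-batches of 200, up to 10,000 epochs, with a model checkpoint every
#' 10 epochs and checkpoint-based early stopping on validation loss.
#'
#' @param layer_sizes integer vector of layer widths, input to output.
#' @param learning_rate SGD learning rate.
#' @param batch_size mini-batch size; training requires at least one full
#'   batch of training samples.
#' @param max_epochs number of training epochs.
#' @param checkpoint_every checkpoint (validation-loss evaluation) interval
#'   in epochs.
#' @param standardize z-score inputs per channel using training-partition
#'   statistics only (raw bispectral magnitudes can sit at 1e3 scale, which
#'   would stall SGD at this learning rate).
#' @param selection checkpoint selection rule: `"min_val_loss"` picks the
#'   checkpoint with global minimum validation loss; `"first_increase"`
#'   picks the last checkpoint before the validation loss first increases.
#' @param seed RNG seed controlling weight initialization and epoch
#'   shuffling.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(layer_sizes = c(16, 30, 60, 30, 2),
                       learning_rate = 0.001,
                       batch_size = 200,
                       max_epochs = 10000,
                       checkpoint_every = 10,
                       standardize = TRUE,
                       selection = c("min_val_loss", "first_increase"),
                       seed = 1L) {
  if (!is.numeric(layer_sizes) || length(layer_sizes) < 2L ||
      any(layer_sizes < 1)) {
    stop_param("layer_sizes must be at least two positive widths")
  }
  if (!is_number(learning_rate) || learning_rate <= 0) {
    stop_param("learning_rate must be positive")
  }
  if (!is_count(batch_size)) stop_param("batch_size must be a positive integer")
  if (!is_count(max_epochs)) stop_param("max_epochs must be a positive integer")
  if (!is_count(checkpoint_every)) {
    stop_param("checkpoint_every must be a positive integer")
  }
  structure(
    list(layer_sizes = as.integer(layer_sizes),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         checkpoint_every = as.integer(checkpoint_every),
         standardize = isTRUE(standardize),
         selection = match.arg(selection),
         seed = as.integer(seed)),
    class = "mlp_config"
  )
}

#' Seizure-wise train/validation/test split
#'
#' Shuffles the seizure ids with a seeded RNG and partitions them into
#' train/validation/test by largest-remainder rounding of the target
#' fractions (ties and remainders resolved in train > validation > test
#' order). Because assignment happens at the seizure level, every window
#' (preictal and interictal) of a seizure lands in exactly one partition,
#' which prevents temporal leakage between partitions.
#'
#' @param seizure_ids vector of at least 3 seizure identifiers.
#' @param fractions length-3 numeric summing to 1, train/validation/test.
#' @param seed RNG seed for the shuffle.
#' @return an object of class `split_plan`: list with `train`,
#'   `validation`, `test` id vectors and `fractions`.
#' @export
#' @examples
#' split_by_seizure(1:17, seed = 1)  # 7 / 5 / 5
split_by_seizure <- function(seizure_ids, fractions = c(0.4, 0.3, 0.3),
                             seed = 1L) {
  S <- length(seizure_ids)
  if (S < 3L) stop_size("need at least 3 seizures to split, got %d", S)
  if (anyDuplicated(seizure_ids)) stop_param("seizure_ids must be unique")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0)) {
    stop_param("fractions must be three non-negative numbers summing to 1")
  }
  raw <- fractions * S
  counts <- floor(raw)
  rem <- raw - counts
  need <- S - sum(counts)
  if (need > 0L) {
    # largest remainder; ties broken by partition priority train > val > test
    pick <- order(-rem, seq_along(rem))[seq_len(need)]
    counts[pick] <- counts[pick] + 1L
  }
  shuffled <- with_seed(seed, sample(seizure_ids, S))
  bounds <- cumsum(counts)
  structure(
    list(
      train = shuffled[seq_len(counts[1L])],
      validation = if (counts[2L] > 0)
        shuffled[(bounds[1L] + 1L):bounds[2L]] else seizure_ids[0],
      test = if (counts[3L] > 0)
        shuffled[(bounds[2L] + 1L):bounds[3L]] else seizure_ids[0],
      fractions = fractions
    ),
    class = "split_plan"
  )
}

assert_leakage_free <- function(plan) {
  ids <- c(plan$train, plan$validation, plan$test)
  if (anyDuplicated(ids)) {
    stop_param("split plan leaks: a seizure appears in more than one partition")
  }
  invisible(TRUE)
}

# --- design matrix assembly -------------------------------------------------

# One classification sample per (seizure, state, window): the chosen
# feature across channels, in channel order.
build_design <- function(feature_table, feature_name) {
  if (!feature_name %in% names(feature_table)) {
    stop_param("feature '%s' not in table", feature_name)
  }
  channels <- sort(unique(feature_table$channel))
  key <- interaction(feature_table$seizure_id, feature_table$state,
                     feature_table$window_index, drop = TRUE)
  groups <- split(feature_table, key)
  keep <- vapply(groups, function(g) nrow(g) == length(channels), TRUE)
  if (!all(keep)) {
    warning(sprintf("dropped %d windows with incomplete channel coverage",
                    sum(!keep)), call. = FALSE)
    groups <- groups[keep]
  }
  X <- t(vapply(groups, function(g) {
    g[[feature_name]][match(channels, g$channel)]
  }, numeric(length(channels))))
  meta <- do.call(rbind, lapply(groups, function(g) {
    data.frame(seizure_id = g$seizure_id[1L], state = g$state[1L],
               window_index = g$window_index[1L])
  }))
  rownames(X) <- rownames(meta) <- NULL
  list(X = X, state = meta$state, seizure_id = meta$seizure_id,
       n_channels = length(channels))
}

# --- MLP internals ----------------------------------------------------------

MLP_CLASSES <- c("interictal", "preictal")

mlp_init <- function(layer_sizes) {
  n_layers <- length(layer_sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- layer_sizes[l]
    lim <- sqrt(6 / fan_in)   # fan-in-scaled uniform init
    W[[l]] <- matrix(runif(fan_in * layer_sizes[l + 1L], -lim, lim),
                     fan_in, layer_sizes[l + 1L])
    b[[l]] <- numeric(layer_sizes[l + 1L])
  }
  list(W = W, b = b)
}

relu <- function(z) pmax(z, 0)

mlp_forward <- function(params, X) {
  n_layers <- length(params$W)
  A <- vector("list", n_layers + 1L)
  A[[1L]] <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2L, params$b[[l]], `+`)
    A[[l + 1L]] <- if (l < n_layers) relu(Z) else Z
  }
  A
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean categorical cross-entropy of logits against one-hot Y.
mlp_loss <- function(logits, Y) {
  P <- softmax_rows(logits)
  -mean(rowSums(Y * log(pmax(P, 1e-300))))
}

# Analytic gradients of the mean cross-entropy w.r.t. all weights/biases.
mlp_grads <- function(params, X, Y) {
  n_layers <- length(params$W)
  A <- mlp_forward(params, X)
  P <- softmax_rows(A[[n_layers + 1L]])
  n <- nrow(X)
  delta <- (P - Y) / n
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

mlp_predict <- function(params, X) {
  logits <- mlp_forward(params, X)[[length(params$W) + 1L]]
  MLP_CLASSES[max.col(logits, ties.method = "first")]
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2L, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  list(mu = mu, sigma = sigma)
}

apply_standardizer <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mu, `-`), 2L, sc$sigma, `/`)
}

one_hot <- function(state) {
  Y <- matrix(0, length(state), 2L, dimnames = list(NULL, MLP_CLASSES))
  Y[cbind(seq_along(state), match(state, MLP_CLASSES))] <- 1
  Y
}

# --- training ---------------------------------------------------------------

#' Train the seizure-prediction MLP on one feature
#'
#' Builds one classification sample per (seizure, state, window) — the
#' chosen feature across all channels — assigns samples to partitions by
#' the seizure-wise split plan (asserted leakage-free on every run), and
#' trains the network with seeded mini-batch SGD. Every
#' `checkpoint_every` epochs the model is checkpointed together with its
#' validation loss; after training the selected model is, by default, the
#' checkpoint with minimum validation loss (a `"first_increase"` rule —
#' the last checkpoint before validation loss first rises — is available
#' via the config).
#'
#' @param feature_table tibble from [extract_features_dataset()] for one
#'   subject.
#' @param split_plan a [split_by_seizure()] plan over the table's seizures.
#' @param feature_name `"mave"`, `"p1"` or `"p2"`.
#' @param config an [mlp_config()].
#' @return list with `model` (weights, biases, scaler, classes, config,
#'   feature) and `report` (per-epoch training loss, checkpoint validation
#'   losses, `selected_checkpoint_epoch`, train/test accuracy, test
#'   confusion matrix).
#' @export
train_mlp <- function(feature_table, split_plan, feature_name = "p1",
                      config = mlp_config()) {
  if (!inherits(split_plan, "split_plan")) {
    stop_param("split_plan must come from split_by_seizure()")
  }
  if (!inherits(config, "mlp_config")) stop_param("config must be an mlp_config")
  assert_leakage_free(split_plan)
  design <- build_design(feature_table, feature_name)
  layer_sizes <- config$layer_sizes
  if (layer_sizes[1L] != design$n_channels) {
    layer_sizes[1L] <- design$n_channels
  }

  part_of <- function(sz) {
    ifelse(sz %in% split_plan$train, "train",
           ifelse(sz %in% split_plan$validation, "validation",
                  ifelse(sz %in% split_plan$test, "test", NA)))
  }
  partition <- part_of(design$seizure_id)
  if (anyNA(partition)) {
    stop_param("feature table contains seizures absent from the split plan")
  }
  idx_train <- which(partition == "train")
  idx_val <- which(partition == "validation")
  idx_test <- which(partition == "test")
  if (length(idx_train) < config$batch_size) {
    stop_size("training partition (%d samples) smaller than one batch (%d)",
              length(idx_train), config$batch_size)
  }
  if (!length(idx_val)) stop_size("validation partition is empty")

  sc <- if (config$standardize) {
    standardizer(design$X[idx_train, , drop = FALSE])
  } else {
    list(mu = numeric(ncol(design$X)) * 0, sigma = rep(1, ncol(design$X)))
  }
  X <- apply_standardizer(design$X, sc)
  Y <- one_hot(design$state)
  Xtr <- X[idx_train, , drop = FALSE]; Ytr <- Y[idx_train, , drop = FALSE]
  Xva <- X[idx_val, , drop = FALSE];   Yva <- Y[idx_val, , drop = FALSE]

  n_tr <- nrow(Xtr)
  lr <- config$learning_rate
  train_loss <- numeric(config$max_epochs)
  ckpt_epochs <- integer(0)
  ckpt_val_loss <- numeric(0)
  ckpts <- list()

  with_seed(config$seed, {
    params <- mlp_init(layer_sizes)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n_tr)]
        Xb <- Xtr[rows, , drop = FALSE]
        Yb <- Ytr[rows, , drop = FALSE]
        g <- mlp_grads(params, Xb, Yb)
        for (l in seq_along(params$W)) {
          params$W[[l]] <- params$W[[l]] - lr * g$W[[l]]
          params$b[[l]] <- params$b[[l]] - lr * g$b[[l]]
        }
        epoch_loss <- epoch_loss +
          mlp_loss(mlp_forward(params, Xb)[[length(params$W) + 1L]], Yb) *
          length(rows)
      }
      train_loss[epoch] <- epoch_loss / n_tr
      if (!is.finite(train_loss[epoch])) {
        stop_divergence("non-finite training loss at epoch %d; config: %s",
                        epoch, paste(deparse(unclass(config)), collapse = " "))
      }
      if (epoch %% config$checkpoint_every == 0L) {
        vl <- mlp_loss(mlp_forward(params, Xva)[[length(params$W) + 1L]], Yva)
        ckpt_epochs <- c(ckpt_epochs, epoch)
        ckpt_val_loss <- c(ckpt_val_loss, vl)
        ckpts[[length(ckpts) + 1L]] <- params
      }
    }
  })

  if (!length(ckpts)) stop_size("no checkpoints recorded; increase max_epochs")
  sel <- if (config$selection == "min_val_loss") {
    which.min(ckpt_val_loss)
  } else {
    inc <- which(diff(ckpt_val_loss) > 0)
    if (length(inc)) inc[1L] else length(ckpt_val_loss)
  }
  params <- ckpts[[sel]]

  model <- structure(
    list(W = params$W, b = params$b, scaler = sc, classes = MLP_CLASSES,
         layer_sizes = layer_sizes, feature_name = feature_name,
         config = config),
    class = "mlp_model"
  )
  acc <- function(idx) {
    pred <- mlp_predict(params, X[idx, , drop = FALSE])
    mean(pred == design$state[idx])
  }
  confusion <- if (length(idx_test)) {
    pred <- mlp_predict(params, X[idx_test, , drop = FALSE])
    table(true = factor(design$state[idx_test], MLP_CLASSES),
          predicted = factor(pred, MLP_CLASSES))
  } else {
    NULL
  }
  report <- list(
    feature_name = feature_name,
    train_loss = train_loss,
    checkpoint_epochs = ckpt_epochs,
    checkpoint_val_loss = ckpt_val_loss,
    selected_checkpoint_epoch = ckpt_epochs[sel],
    train_accuracy = acc(idx_train),
    test_accuracy = if (length(idx_test)) acc(idx_test) else NA_real_,
    confusion = confusion,
    n_train = length(idx_train), n_validation = length(idx_val),
    n_test = length(idx_test)
  )
  list(model = model, report = report)
}

#' Evaluate a trained MLP on one partition
#'
#' @param model trained `mlp_model` from [train_mlp()].
#' @param feature_table tibble of features for the same subject.
#' @param split_plan the [split_by_seizure()] plan used in training.
#' @param partition `"train"`, `"validation"` or `"test"`.
#' @return list with `accuracy`, `confusion` (rows = true state), `n`.
#' @export
evaluate_mlp <- function(model, feature_table, split_plan,
                         partition = c("test", "validation", "train")) {
  partition <- match.arg(partition)
  if (!inherits(model, "mlp_model")) stop_param("model must be an mlp_model")
  assert_leakage_free(split_plan)
  design <- build_design(feature_table, model$feature_name)
  ids <- split_plan[[if (partition == "train") "train" else partition]]
  idx <- which(design$seizure_id %in% ids)
  if (!length(idx)) stop_size("partition '%s' holds no samples", partition)
  X <- apply_standardizer(design$X[idx, , drop = FALSE], model$scaler)
  pred <- mlp_predict(list(W = model$W, b = model$b), X)
  truth <- design$state[idx]
  list(
    accuracy = mean(pred == truth),
    confusion = table(true = factor(truth, model$classes),
                      predicted = factor(pred, model$classes)),
    n = length(idx)
  )
}

#' Write / read an MLP model as a JSON file
#'
#' The model is serialized as a single JSON document: a header (layer
#' sizes, activation, classes, feature, scaler parameters, seed) plus one
#' flat numeric array per weight matrix and bias vector, at full double
#' precision.
#'
#' @param model an `mlp_model`.
#' @param path file path.
#' @return `path` (write) or the restored `mlp_model` (read).
#' @export
write_mlp_model <- function(model, path) {
  if (!inherits(model, "mlp_model")) stop_param("model must be an mlp_model")
  doc <- list(
    format = "preictal-mlp", format_version = 1L,
    layer_sizes = model$layer_sizes,
    activation = "relu",
    classes = model$classes,
    feature_name = model$feature_name,
    seed = model$config$seed,
    scaler = model$scaler,
    weights = lapply(model$W, as.vector),
    biases = model$b
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "preictal-mlp")) {
    stop_format("'%s' is not a serialized MLP model", path)
  }
  sizes <- as.integer(doc$layer_sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(doc$weights[[l]], sizes[l], sizes[l + 1L])
  })
  structure(
    list(W = W, b = doc$biases, scaler = doc$scaler, classes = doc$classes,
         layer_sizes = sizes, feature_name = doc$feature_name,
         config = NULL),
    class = "mlp_model"
  )
}
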