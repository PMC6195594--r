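#' Two-group one-way ANOVA
#'
#' Classical between/within variance decomposition for two groups
#' (preictal vs interictal feature values), reported with the F statistic
#' on `(1, N - 2)` degrees of freedom. For two groups this is equivalent to
#' the squared pooled-variance t statistic.
#'
#' @param group_a,group_b numeric vectors with at least 2 finite values each.
#' @param feature_name optional label carried in the result.
#' @return an object of class `anova_result`: `feature_name`, `F`,
#'   `df_between` (always 1), `df_within`, `p`, and per-group `means` / `sds`
#'   named `a` and `b`.
#' @export
#' @examples
#' one_way_anova(rnorm(120, 0), rnorm(120, 1))
one_way_anova <- function(group_a, group_b, feature_name = NULL) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_size("each group needs at least 2 values")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    stop_data("groups contain non-finite values")
  }
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                   sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2L)
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      stop_degenerate("zero pooled variance and equal means: F undefined")
    }
    stop_degenerate("zero within-group variance: F is infinite")
  }
  values <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  structure(
    list(
      feature_name = feature_name,
      F = unname(ow$statistic),
      df_between = 1L,
      df_within = length(values) - 2L,
      p = unname(ow$p.value),
      means = c(a = mean(group_a), b = mean(group_b)),
      sds = c(a = sd(group_a), b = sd(group_b))
    ),
    class = "anova_result"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank tie handling. The
#' p-value is computed by exact enumeration when either sample has fewer
#' than 8 observations (and no ties are present), and otherwise by the
#' normal approximation with tie and continuity correction — the regime of
#' the per-seizure channel tests, which compare 120 windows per state.
#'
#' @param x,y numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param feature_name,seizure_id,channel optional labels carried in the
#'   result.
#' @return an object of class `mwu_result`: `U` (the rank-sum statistic for
#'   `x`, in `[0, n1 * n2]`), `p`, `n1`, `n2` and the labels.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # exact: 1/3
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           feature_name = NULL, seizure_id = NULL,
                           channel = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop_size("samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_data("samples contain non-finite values")
  }
  use_exact <- length(x) < 8L || length(y) < 8L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE)
  )
  structure(
    list(
      seizure_id = seizure_id, channel = channel,
      feature_name = feature_name,
      U = unname(wt$statistic),
      p = unname(wt$p.value),
      n1 = length(x), n2 = length(y)
    ),
    class = "mwu_result"
  )
}

#' Per-seizure, per-channel Mann-Whitney tests
#'
#' For every (seizure, channel, feature) combination in the table, compares
#' the preictal window values against the paired interictal window values
#' of the same seizure and channel with [mann_whitney_u()]. Seizures
#' missing one of the two states are skipped with a warning.
#'
#' @param feature_table a tibble from [extract_features_dataset()].
#' @param features feature columns to test.
#' @param alternative passed to [mann_whitney_u()].
#' @return a tibble with one row per test: `subject_id`, `seizure_id`,
#'   `channel`, `feature`, `U`, `p`, `n1`, `n2`.
#' @export
per_seizure_tests <- function(feature_table,
                              features = c("mave", "p1", "p2"),
                              alternative = "two.sided") {
  stopifnot(is.data.frame(feature_table))
  missing_cols <- setdiff(
    c("subject_id", "seizure_id", "state", "channel", features),
    names(feature_table)
  )
  if (length(missing_cols)) {
    stop_param("feature_table lacks columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  key <- interaction(feature_table$subject_id, feature_table$seizure_id,
                     feature_table$channel, drop = TRUE)
  groups <- split(feature_table, key)
  rows <- list()
  skipped <- character(0)
  for (gr in groups) {
    pre <- gr[gr$state == "preictal", , drop = FALSE]
    inter <- gr[gr$state == "interictal", , drop = FALSE]
    if (nrow(pre) == 0L || nrow(inter) == 0L) {
      skipped <- c(skipped,
                   sprintf("%s/%s", gr$subject_id[1L], gr$seizure_id[1L]))
      next
    }
    for (f in features) {
      res <- mann_whitney_u(pre[[f]], inter[[f]], alternative = alternative)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = gr$subject_id[1L],
        seizure_id = gr$seizure_id[1L],
        channel = gr$channel[1L],
        feature = f,
        U = res$U, p = res$p, n1 = res$n1, n2 = res$n2
      )
    }
  }
  if (length(skipped)) {
    warning(sprintf("missing a state, skipped: seizure(s) %s",
                    paste(unique(skipped), collapse = ", ")),
            call. = FALSE)
  }
  if (!length(rows)) {
    return(tibble::tibble(
      subject_id = character(), seizure_id = integer(), channel = integer(),
      feature = character(), U = numeric(), p = numeric(),
      n1 = integer(), n2 = integer()
    ))
  }
  do.call(rbind, rows)
}

#' Percent-of-predictable-seizures map
#'
#' Summarizes [per_seizure_tests()] results as, for every (channel,
#' feature) cell within a subject, the percentage of that subject's
#' seizures whose preictal-vs-interictal difference is significant at
#' `alpha`. Cells are exact multiples of `100 / n_seizures`. No
#' multiple-testing correction is applied; the map reports raw `p < alpha`
#' exceedance as a spatial localization display, not a family-wise claim.
#'
#' @param mwu_results tibble from [per_seizure_tests()].
#' @param alpha significance level (default 0.05).
#' @return a tibble of class `predictability_map`: `subject_id`, `channel`,
#'   `feature`, `pct` in `[0, 100]`, `n_seizures`.
#' @export
predictability_map <- function(mwu_results, alpha = 0.05) {
  stopifnot(is.data.frame(mwu_results))
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_param("alpha must lie in (0, 1)")
  }
  key <- interaction(mwu_results$subject_id, mwu_results$channel,
                     mwu_results$feature, drop = TRUE)
  cells <- lapply(split(mwu_results, key), function(cell) {
    tibble::tibble(
      subject_id = cell$subject_id[1L],
      channel = cell$channel[1L],
      feature = cell$feature[1L],
      pct = 100 * mean(cell$p < alpha),
      n_seizures = nrow(cell)
    )
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$subject_id, out$feature, out$channel), ]
  rownames(out) <- NULL
  class(out) <- c("predictability_map", class(out))
  out
}

#' Matrix view of a predictability map
#'
#' @param map a [predictability_map()] result restricted to (or containing)
#'   one subject.
#' @param subject_id subject to select; defaults to the only subject present.
#' @return numeric channels-by-features matrix of percentages.
#' @export
predictability_matrix <- function(map, subject_id = NULL) {
  subject_id <- subject_id %||% unique(map$subject_id)
  if (length(subject_id) != 1L) {
    stop_param("map contains several subjects; pass subject_id")
  }
  m <- map[map$subject_id == subject_id, , drop = FALSE]
  channels <- sort(unique(m$channel))
  feats <- unique(m$feature)
  out <- matrix(NA_real_, length(channels), length(feats),
                dimnames = list(paste0("ch", channels), feats))
  for (r in seq_len(nrow(m))) {
    out[match(m$channel[r], channels), match(m$feature[r], feats)] <- m$pct[r]
  }
  out
}

#' Plot a predictability map as a heatmap
#'
#' Plain channel-by-feature heatmap of the percent-of-predictable-seizures
#' matrix (no anatomical rendering; electrode coordinates are not part of
#' the data model).
#'
#' @param map a [predictability_map()] result.
#' @param subject_id subject to plot.
#' @param file optional PNG path; when given the plot is written there.
#' @return the plotted matrix, invisibly.
#' @export
plot_predictability_map <- function(map, subject_id = NULL, file = NULL) {
  m <- predictability_matrix(map, subject_id)
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 640)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)
  graphics::image(
    x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
    zlim = c(0, 100), col = pal, axes = FALSE,
    xlab = "feature", ylab = "channel",
    main = "% of seizures with significant preictal change"
  )
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2)
  invisible(m)
}

#' Global per-subject ANOVA over a feature table
#'
#' Collapses the channel dimension (mean or median across channels per
#' window) and runs [one_way_anova()] preictal vs interictal per feature,
#' pooling windows across a subject's seizures. With 17 seizures of 120
#' windows per state this compares two groups of 2,040 values
#' (`df_within = 4078`).
#'
#' @param feature_table tibble from [extract_features_dataset()].
#' @param features feature columns to test.
#' @param aggregate `"mean"` (default) or `"median"` across channels.
#' @return a tibble: `subject_id`, `feature`, `F`, `df_between`,
#'   `df_within`, `p`, group means and sds.
#' @export
global_anova <- function(feature_table, features = c("mave", "p1", "p2"),
                         aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  aggfun <- if (aggregate == "mean") mean else stats::median
  rows <- list()
  for (sid in unique(feature_table$subject_id)) {
    sub <- feature_table[feature_table$subject_id == sid, , drop = FALSE]
    for (f in features) {
      per_window <- tapply(
        sub[[f]],
        interaction(sub$state, sub$seizure_id, sub$window_index, drop = TRUE),
        aggfun
      )
      states <- vapply(strsplit(names(per_window), ".", fixed = TRUE),
                       `[[`, "", 1L)
      res <- one_way_anova(per_window[states == "preictal"],
                           per_window[states == "interictal"],
                           feature_name = f)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, feature = f, F = res$F,
        df_between = res$df_between, df_within = res$df_within, p = res$p,
        mean_preictal = res$means[["a"]], mean_interictal = res$means[["b"]],
        sd_preictal = res$sds[["a"]], sd_interictal = res$sds[["b"]]
      )
    }
  }
  do.call(rbind, rows)
}
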