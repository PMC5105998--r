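#' Train / validation / test split specification
#'
#' The test set is the last `test_fraction` of the modeled bins of every clip
#' and is never touched during fitting or hyperparameter selection. The
#' remaining cross-validation bins are split into `k` folds whose validation
#' sets are the cross-validation portions of whole clips (`n_clips / k` clips
#' per fold), jointly partitioning the clip set.
#'
#' @param data An `nrf_data` from [build_design()].
#' @param k Number of folds. Default 10.
#' @param test_fraction Per-clip tail fraction reserved for testing.
#'   Default 0.2.
#' @param seed Seed for assigning clips to folds. Default 1.
#' @return A `split_spec`: list with `test` (logical over rows of
#'   `data$index`), `folds` (list of lists with logical `train`,
#'   `validation`), `fold_clips`, `k`, `test_fraction`.
#' @export
make_splits <- function(data, k = 10, test_fraction = 0.2, seed = 1) {
  idx <- data$index
  clips <- sort(unique(idx$clip))
  n_clips <- length(clips)
  if (n_clips %% k != 0) {
    abort(sprintf(
      "%d clips cannot be divided into %d folds of equal clip count; use k in {%s}",
      n_clips, k, paste(which(n_clips %% seq_len(n_clips) == 0), collapse = ", ")
    ))
  }
  per_fold <- n_clips %/% k

  test <- rep(FALSE, nrow(idx))
  for (cl in clips) {
    rows <- which(idx$clip == cl)
    n_test <- round(test_fraction * length(rows))
    if (n_test > 0) test[tail(rows, n_test)] <- TRUE
  }

  shuffled <- with_seed(seed, sample(clips))
  fold_clips <- split(shuffled, rep(seq_len(k), each = per_fold))
  folds <- lapply(fold_clips, function(vc) {
    validation <- !test & idx$clip %in% vc
    train <- !test & !validation
    list(train = train, validation = validation)
  })
  structure(
    list(test = test, folds = unname(folds), fold_clips = unname(fold_clips),
         k = k, test_fraction = test_fraction),
    class = "split_spec"
  )
}

subset_data <- function(data, rows) {
  structure(
    list(X = data$X[rows, , drop = FALSE],
         y = if (!is.null(data$y)) data$y[rows] else NULL,
         index = data$index[rows, , drop = FALSE],
         F = data$F, H = data$H, discard_bins = data$discard_bins),
    class = "nrf_data"
  )
}

# Post-discard bin indices per clip for a row subset (for cc_half restriction).
bins_by_clip <- function(data, rows) {
  idx <- data$index
  clips <- sort(unique(idx$clip))
  lapply(clips, function(cl) {
    b <- idx$bin[rows & idx$clip == cl]
    b - data$discard_bins
  })
}

#' Data-driven log-spaced penalty grid
#'
#' The largest value is the smallest penalty that zeroes every weight in the
#' linear problem (`max |x_j' (y - mean(y))|`); the smallest is
#' `ratio` times that.
#'
#' @param data An `nrf_data` with response `y`.
#' @param n Grid size. Default 20.
#' @param ratio Smallest/largest penalty ratio. Default 1e-4.
#' @param target `"count"` for the LN/L linear stage, `"rescaled"` to anchor
#'   the grid on the rescaled network targets (NRF fits).
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(data, n = 20, ratio = 1e-4,
                        target = c("count", "rescaled")) {
  target <- match.arg(target)
  y <- if (target == "rescaled") rescale_targets(data$y) else data$y
  lam_max <- max(abs(crossprod(data$X, y - mean(y))))
  exp(seq(log(lam_max), log(lam_max * ratio), length.out = n))
}

fit_one <- function(model_kind, data, lambda, J, seed, init = NULL, ...) {
  switch(model_kind,
    L = fit_linear_lasso(data, lambda = lambda),
    LN = fit_ln(data, lambda = lambda),
    NRF = fit_nrf(data, lambda = lambda, J = J, seed = seed, init = init, ...),
    abort(sprintf("unknown model kind '%s'", model_kind))
  )
}

predict_one <- function(model_kind, fit, data) {
  switch(model_kind,
    L = predict_linear(fit, data),
    LN = predict_ln(fit, data),
    NRF = predict_nrf(fit, data, scale = "count")
  )
}

#' Cross-validated penalty selection
#'
#' Fits the model on each fold's training set at every penalty in the grid,
#' scores the fold's validation set by `CC_norm` (with the reliability
#' ceiling computed from the trials restricted to the validation bins), and
#' selects the penalty maximizing the unweighted fold-mean. Ties are broken
#' toward the larger penalty. A penalty at which a fold's fit fails scores
#' `-Inf` for that fold, with a warning.
#'
#' @param model_kind One of `"L"`, `"LN"`, `"NRF"`.
#' @param data An `nrf_data` with spike-count response `y`.
#' @param trials A `trial_responses` (for the reliability ceiling).
#' @param splits A `split_spec`.
#' @param grid Penalty grid (non-empty numeric vector).
#' @param J Hidden units for NRF fits. Default 20.
#' @param seed Seed for NRF initialization.
#' @param n_splits_cchalf Split-half resamples for the validation ceiling.
#'   Default 30 (the ceiling enters only as a fold-constant rescaling of the
#'   scores compared across penalties).
#' @param smooth_ms,onset_discard_ms PSTH pipeline settings for the ceiling.
#' @param ... Further arguments to the NRF trainer.
#' @return A `cv_result`: list with `table` (tibble: lambda, fold, cc_norm),
#'   `mean_cc` (tibble: lambda, mean_cc_norm), `best_lambda`.
#' @export
select_lambda <- function(model_kind, data, trials, splits, grid, J = 20,
                          seed = 1, n_splits_cchalf = 30, smooth_ms = 21,
                          onset_discard_ms = 250, ...) {
  if (length(grid) == 0) abort("empty penalty grid")
  grid <- sort(unique(grid), decreasing = TRUE)
  rows <- list()
  for (f in seq_along(splits$folds)) {
    fold <- splits$folds[[f]]
    train <- subset_data(data, fold$train)
    val <- subset_data(data, fold$validation)
    val_bins <- bins_by_clip(data, fold$validation)
    cch <- cc_half(trials, n_splits = n_splits_cchalf, seed = seed,
                   smooth_ms = smooth_ms, onset_discard_ms = onset_discard_ms,
                   bins = val_bins)
    ccm <- if (!is.na(cch) && cch > 0) cc_max(cch) else NA_real_
    # every penalty is fit fresh from the seeded initialization: warm-starting
    # down the path traps the network in the previous penalty's sparse basin
    # and flattens the validation surface
    for (lam in grid) {
      score <- tryCatch({
        fit <- fit_one(model_kind, train, lam, J, seed, ...)
        pred <- predict_one(model_kind, fit, val)
        if (sd(pred) == 0) {
          0 # fully shrunk model: uninformative, not a failure
        } else if (is.na(ccm)) {
          cc_raw(val$y, pred)
        } else {
          cc_norm(val$y, pred, ccm)
        }
      }, error = function(e) {
        warn(sprintf("fold %d, lambda %.4g: fit failed (%s)", f, lam,
                     conditionMessage(e)))
        -Inf
      })
      rows[[length(rows) + 1]] <- tibble(lambda = lam, fold = f, cc_norm = score)
    }
  }
  table <- dplyr::bind_rows(rows)
  mean_cc <- table |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_cc_norm = mean(.data$cc_norm), .groups = "drop")
  best <- max(mean_cc$lambda[mean_cc$mean_cc_norm == max(mean_cc$mean_cc_norm)])
  structure(
    list(table = table, mean_cc = mean_cc, best_lambda = best,
         model_kind = model_kind),
    class = "cv_result"
  )
}

#' Refit on the full cross-validation set and score the held-out test set
#'
#' @inheritParams select_lambda
#' @param best_lambda Selected penalty (e.g. `cv$best_lambda`).
#' @param n_splits Split-half resamples for the test-set ceiling. Default 126.
#' @return List with `fit` (trained on all non-test bins) and `metrics`
#'   (one-row tibble from [metric_report()] on the test set only).
#' @export
refit_full <- function(model_kind, data, trials, splits, best_lambda, J = 20,
                       seed = 1, n_splits = 126, smooth_ms = 21,
                       onset_discard_ms = 250, ...) {
  cv_rows <- !splits$test
  fit <- fit_one(model_kind, subset_data(data, cv_rows), best_lambda, J, seed, ...)
  test <- subset_data(data, splits$test)
  pred <- predict_one(model_kind, fit, test)
  test_bins <- bins_by_clip(data, splits$test)
  clips <- sort(unique(data$index$clip))
  y_list <- lapply(seq_along(clips), function(i) {
    test$y[test$index$clip == clips[i]]
  })
  pred_list <- lapply(seq_along(clips), function(i) {
    pred[test$index$clip == clips[i]]
  })
  metrics <- metric_report(y_list, pred_list, trials, bins = test_bins,
                           n_splits = n_splits, seed = seed,
                           smooth_ms = smooth_ms,
                           onset_discard_ms = onset_discard_ms)
  list(fit = fit, metrics = metrics)
}

#' Consistency of effective hidden units across cross-validation fits
#'
#' For every ordered pair of fits, correlates the display STRFs of the
#' effective HUs of one fit with those of the other and records the best and
#' second-best greedily matched correlations. A permutation control repeats
#' the matching after shuffling the weights within every effective-HU STRF
#' matrix; consistent fits give high matched correlations while the control
#' collapses toward zero.
#'
#' @param fits List of `nrf_fit` / `nrf_params` objects (>= 2).
#' @param data Stimulus set used to determine effective HUs.
#' @param n_shuffles Number of within-STRF permutations for the control.
#'   Default 20.
#' @param seed RNG seed for the control.
#' @param threshold Effective-HU variance-fraction threshold. Default 0.05.
#' @return List with `matches` (tibble: fit_a, fit_b, best, second) and
#'   `control` (same columns plus `shuffle`); fits with no effective HUs are
#'   excluded with a warning.
#' @export
fit_consistency <- function(fits, data, n_shuffles = 20, seed = 1,
                            threshold = 0.05) {
  strfs <- lapply(fits, function(f) {
    adj <- adjust_network(f)
    prof <- effective_hus(adj, data, threshold)
    eff <- which(prof$effective)
    lapply(eff, function(j) {
      as.numeric(display_strf(hu_strf(adj$params, j), prof$kind[j]))
    })
  })
  keep <- lengths(strfs) > 0
  if (any(!keep)) warn(sprintf("%d fit(s) with no effective HUs excluded", sum(!keep)))
  strfs <- strfs[keep]
  if (length(strfs) < 2) abort("need at least 2 fits with effective HUs")

  match_pairs <- function(strf_sets) {
    out <- list()
    n <- length(strf_sets)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      M <- outer(seq_along(strf_sets[[a]]), seq_along(strf_sets[[b]]),
                 Vectorize(function(i, j) cor(strf_sets[[a]][[i]], strf_sets[[b]][[j]])))
      M <- matrix(M, length(strf_sets[[a]]), length(strf_sets[[b]]))
      best <- max(M)
      second <- NA_real_
      if (nrow(M) > 1 && ncol(M) > 1) {
        ij <- which(M == best, arr.ind = TRUE)[1, ]
        second <- max(M[-ij[1], -ij[2], drop = FALSE])
      }
      out[[length(out) + 1]] <- tibble(fit_a = a, fit_b = b, best = best,
                                       second = second)
    }
    dplyr::bind_rows(out)
  }

  matches <- match_pairs(strfs)
  control <- with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_shuffles), function(s) {
      shuffled <- lapply(strfs, function(set) lapply(set, function(v) sample(v)))
      dplyr::mutate(match_pairs(shuffled), shuffle = s)
    }))
  })
  list(matches = matches, control = control)
}
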