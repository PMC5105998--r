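#' Pearson correlation between observed and predicted responses
#'
#' @param y Observed response vector.
#' @param y_hat Predicted response vector.
#' @return Correlation coefficient.
#' @export
cc_raw <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("length mismatch")
  if (sd(y) == 0 || sd(y_hat) == 0) abort("correlation undefined for constant input")
  cor(y, y_hat)
}

#' Split-half reliability of a multi-trial response
#'
#' Mean Pearson correlation between the PSTHs of two disjoint random halves
#' of the trials, over `n_splits` random partitions. Each half-PSTH is built
#' with the same smoothing and onset-discard pipeline as the full PSTH.
#'
#' @param responses A `trial_responses` with an even number of trials.
#' @param n_splits Number of random half partitions. Default 126.
#' @param seed RNG seed for the partitions.
#' @param smooth_ms,onset_discard_ms Passed to [compute_psth()].
#' @param bins Optional list (per clip) of post-discard bin indices to
#'   restrict the correlation to (e.g. validation bins).
#' @return Mean split-half correlation.
#' @export
cc_half <- function(responses, n_splits = 126, seed = 1,
                    smooth_ms = 21, onset_discard_ms = 250, bins = NULL) {
  stopifnot(inherits(responses, "trial_responses"))
  R <- dim(responses$counts)[2]
  if (R %% 2 != 0) abort("cc_half requires an even number of trials")
  if (R < 2) abort("cc_half requires at least 2 trials")
  with_seed(seed, {
    vals <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      half <- sample(R, R / 2)
      y1 <- psth_vector(subset_trials(responses, half), smooth_ms, onset_discard_ms, bins)
      y2 <- psth_vector(subset_trials(responses, setdiff(seq_len(R), half)),
                        smooth_ms, onset_discard_ms, bins)
      vals[s] <- if (sd(y1) == 0 || sd(y2) == 0) NA_real_ else cor(y1, y2)
    }
    mean(vals, na.rm = TRUE)
  })
}

subset_trials <- function(responses, trials) {
  structure(
    list(counts = responses$counts[, trials, , drop = FALSE],
         bin_ms = responses$bin_ms),
    class = "trial_responses"
  )
}

psth_vector <- function(responses, smooth_ms, onset_discard_ms, bins = NULL) {
  p <- compute_psth(responses, smooth_ms, onset_discard_ms)
  if (is.null(bins)) return(unlist(p$y))
  unlist(lapply(seq_along(p$y), function(n) p$y[[n]][bins[[n]]]))
}

# Evaluate code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Estimated ceiling correlation from split-half reliability
#'
#' The highest correlation a perfect model could attain against the R-trial
#' PSTH, estimated as `CC_max = sqrt(2 / (1 + 1 / CC_half))`.
#'
#' @param cc_half Mean split-half correlation in `(0, 1]`.
#' @return Ceiling correlation `CC_max`.
#' @export
cc_max <- function(cc_half) {
  if (is.na(cc_half) || cc_half <= 0) {
    abort("cc_max undefined for non-positive cc_half; neuron should be flagged")
  }
  sqrt(2 / (1 + 1 / cc_half))
}

#' Noise-corrected prediction performance
#'
#' `CC_norm = CC_raw / CC_max`: the fraction of the stimulus-driven, i.e.
#' achievable, response variability captured by the model.
#'
#' @param y Observed PSTH vector.
#' @param y_hat Predicted PSTH vector.
#' @param ccmax Ceiling correlation from [cc_max()].
#' @return Normalized correlation coefficient.
#' @export
cc_norm <- function(y, y_hat, ccmax) {
  if (ccmax <= 0) abort("cc_norm undefined for non-positive cc_max")
  cc_raw(y, y_hat) / ccmax
}

#' Peak windows of an observed response
#'
#' Marks, per clip, the bins where the observed response reaches or exceeds
#' its per-clip mean plus two standard deviations (the "2-sigma threshold").
#'
#' @param y List of per-clip observed response vectors (spike-count scale).
#' @param n_sd Threshold in SD units. Default 2.
#' @return A `peak_window`: list with `p` (list of 0/1 vectors), `mu`, `sigma`,
#'   `threshold` (per-clip numeric vectors) and `n_peak_bins`.
#' @export
peak_window <- function(y, n_sd = 2) {
  if (!is.list(y)) y <- list(y)
  mu <- vapply(y, mean, numeric(1))
  sigma <- vapply(y, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  thr <- mu + n_sd * sigma
  p <- lapply(seq_along(y), function(n) as.numeric(y[[n]] >= thr[n]))
  structure(
    list(p = p, mu = mu, sigma = sigma, threshold = thr,
         n_peak_bins = sum(unlist(p))),
    class = "peak_window"
  )
}

#' Peak-activity mean squared error
#'
#' MSE between observed and predicted responses restricted to the peak bins
#' of the observed response (see [peak_window()]).
#'
#' @param y,y_hat Lists of per-clip observed/predicted vectors (or single
#'   vectors), spike-count scale.
#' @param window A `peak_window` computed from the observed response.
#' @return pMSE, or `NA` (with a warning) if there are no peak bins.
#' @export
pmse <- function(y, y_hat, window = peak_window(y)) {
  if (!is.list(y)) y <- list(y)
  if (!is.list(y_hat)) y_hat <- list(y_hat)
  if (window$n_peak_bins == 0) {
    warn("no peak bins: pMSE undefined")
    return(NA_real_)
  }
  num <- 0
  for (n in seq_along(y)) {
    pn <- window$p[[n]]
    num <- num + sum(pn * (y_hat[[n]] - y[[n]])^2)
  }
  num / window$n_peak_bins
}

#' Full metric report for a prediction
#'
#' @param y List of per-clip observed PSTH vectors (spike-count scale).
#' @param y_hat List of per-clip predicted vectors (spike-count scale).
#' @param responses Optional `trial_responses` for the reliability ceiling;
#'   if omitted, `cc_half`/`cc_max`/`cc_norm` are `NA`.
#' @param bins Optional per-clip post-discard bin indices the prediction
#'   covers (passed to [cc_half()]).
#' @param n_splits,seed,smooth_ms,onset_discard_ms Passed to [cc_half()].
#' @return One-row tibble: `cc_raw`, `cc_half`, `cc_max`, `cc_norm`, `mse`,
#'   `pmse`, `n_peak_bins`, `n_bins`.
#' @export
metric_report <- function(y, y_hat, responses = NULL, bins = NULL,
                          n_splits = 126, seed = 1, smooth_ms = 21,
                          onset_discard_ms = 250) {
  if (!is.list(y)) y <- list(y)
  if (!is.list(y_hat)) y_hat <- list(y_hat)
  yv <- unlist(y)
  yhv <- unlist(y_hat)
  ccr <- cc_raw(yv, yhv)
  cch <- ccm <- ccn <- NA_real_
  if (!is.null(responses)) {
    cch <- cc_half(responses, n_splits, seed, smooth_ms, onset_discard_ms, bins)
    if (!is.na(cch) && cch > 0) {
      ccm <- cc_max(cch)
      ccn <- ccr / ccm
    }
  }
  w <- peak_window(y)
  tibble(
    cc_raw = ccr, cc_half = cch, cc_max = ccm, cc_norm = ccn,
    mse = mean((yhv - yv)^2),
    pmse = if (w$n_peak_bins > 0) pmse(y, y_hat, w) else NA_real_,
    n_peak_bins = w$n_peak_bins,
    n_bins = length(yv)
  )
}
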