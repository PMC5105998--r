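#' Construct trial responses from binned counts or a spike table
#'
#' @param counts Either a 3-d array `clip x trial x bin` of spike counts, or a
#'   data frame with columns `clip`, `trial`, `spike_time_s` (one row per
#'   spike), in which case `clip_duration_s` and `bin_ms` define the binning.
#' @param bin_ms Bin width in ms. Default 5.
#' @param clip_duration_s Clip duration in seconds (required for spike tables).
#' @param n_trials Number of trials (required for spike tables; inferred from
#'   the array otherwise).
#' @param n_clips Number of clips (spike tables only; default max clip index).
#' @return A `trial_responses`: list with `counts` (clip x trial x bin array)
#'   and `bin_ms`.
#' @export
trial_responses <- function(counts, bin_ms = 5, clip_duration_s = NULL,
                            n_trials = NULL, n_clips = NULL) {
  if (is.data.frame(counts)) {
    df <- counts
    if ("clip_id" %in% names(df) && !"clip" %in% names(df)) {
      df$clip <- df$clip_id
    }
    stopifnot(all(c("clip", "trial", "spike_time_s") %in% names(df)))
    if (is.null(clip_duration_s)) abort("clip_duration_s required for spike tables")
    if (any(df$spike_time_s < 0 | df$spike_time_s > clip_duration_s)) {
      abort("spike times beyond clip duration")
    }
    n_bins <- floor(clip_duration_s * 1000 / bin_ms)
    n_clips <- n_clips %||% max(df$clip)
    n_trials <- n_trials %||% max(df$trial)
    arr <- array(0, c(n_clips, n_trials, n_bins))
    bin <- pmin(floor(df$spike_time_s * 1000 / bin_ms) + 1, n_bins)
    for (i in seq_len(nrow(df))) {
      arr[df$clip[i], df$trial[i], bin[i]] <- arr[df$clip[i], df$trial[i], bin[i]] + 1
    }
    counts <- arr
  }
  stopifnot(length(dim(counts)) == 3, all(counts >= 0))
  structure(list(counts = counts, bin_ms = bin_ms), class = "trial_responses")
}

#' Unit-sum Hanning smoothing kernel
#'
#' @param smooth_ms Kernel width in ms.
#' @param bin_ms Bin width in ms.
#' @return Odd-length numeric kernel summing to 1.
#' @export
hanning_kernel <- function(smooth_ms = 21, bin_ms = 5) {
  n <- round(smooth_ms / bin_ms)
  if (n %% 2 == 0) n <- n + 1 # nearest odd bin count
  if (n <= 1) return(1)
  k <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  k / sum(k)
}

smooth_psth <- function(y, kernel) {
  if (length(kernel) == 1) return(y)
  half <- (length(kernel) - 1) / 2
  padded <- c(rep(0, half), y, rep(0, half))
  as.numeric(stats::filter(padded, kernel, sides = 2))[(half + 1):(half + length(y))]
}

#' Compute the smoothed PSTH target
#'
#' Trial-averaged spike counts per bin, smoothed with a unit-sum Hanning
#' window, with the onset-transient bins then discarded. Smoothing is applied
#' after trial averaging and before the onset discard.
#'
#' @param responses A `trial_responses`.
#' @param smooth_ms Hanning window width in ms (rounded to the nearest odd
#'   number of bins). Default 21.
#' @param onset_discard_ms Initial period removed from each clip in ms.
#'   Default 250.
#' @return A `psth`: list with `y` (list of per-clip smoothed mean-count
#'   vectors after discard), `bin_ms`, `onset_discard_ms`, `discard_bins`.
#' @export
compute_psth <- function(responses, smooth_ms = 21, onset_discard_ms = 250) {
  stopifnot(inherits(responses, "trial_responses"))
  counts <- responses$counts
  bin_ms <- responses$bin_ms
  kernel <- hanning_kernel(smooth_ms, bin_ms)
  discard <- round(onset_discard_ms / bin_ms)
  n_bins <- dim(counts)[3]
  if (discard >= n_bins) abort("onset discard removes every bin")
  y <- lapply(seq_len(dim(counts)[1]), function(n) {
    m <- colMeans(counts[n, , , drop = FALSE][1, , ])
    sm <- smooth_psth(m, kernel)
    sm[(discard + 1):n_bins]
  })
  structure(
    list(y = y, bin_ms = bin_ms, onset_discard_ms = onset_discard_ms,
         discard_bins = discard),
    class = "psth"
  )
}

#' Noise ratio of a neuron's trial-to-trial variability
#'
#' Signal/noise power decomposition over raw binned counts (all clips
#' concatenated): `noise_power` is the mean over bins of the across-trial
#' variance; `signal_power` is the variance over bins of the trial mean minus
#' `noise_power / R` (the trial-noise contribution to the mean's variance);
#' `NR = noise_power / (R * signal_power)` — the residual noise power in the
#' R-trial mean relative to the stimulus-driven signal power. Weakly driven
#' neurons are flagged for exclusion at `NR > threshold`.
#'
#' @param responses A `trial_responses` with `R >= 2` trials.
#' @param threshold Exclusion threshold. Default 40.
#' @return One-row tibble: `signal_power`, `noise_power`, `nr`, `excluded`.
#' @export
noise_ratio <- function(responses, threshold = 40) {
  stopifnot(inherits(responses, "trial_responses"))
  counts <- responses$counts
  R <- dim(counts)[2]
  if (R < 2) abort("noise ratio requires at least 2 trials")
  # bins x trials, clips concatenated
  M <- do.call(rbind, lapply(seq_len(dim(counts)[1]), function(n) t(counts[n, , ])))
  trial_mean <- rowMeans(M)
  noise_power <- mean(apply(M, 1, var))
  signal_power <- var(trial_mean) - noise_power / R
  nr <- if (signal_power <= 0) Inf else noise_power / (R * signal_power)
  tibble(
    signal_power = signal_power,
    noise_power = noise_power,
    nr = nr,
    excluded = nr > threshold
  )
}

#' Rescale spike-count targets to span the network nonlinearity
#'
#' Affine map sending spike count 0 to `-sigma1` and count 1 to `+sigma1`:
#' `y' = sigma1 * (2 y - 1)`. Used only for network training targets; all
#' reported metrics are computed on the spike-count scale.
#'
#' @param y Numeric vector (or list of vectors) of spike counts per bin.
#' @param sigma1 Scale constant. Default 1.7159.
#' @return Rescaled values, same shape as `y`.
#' @export
rescale_targets <- function(y, sigma1 = NRF_SIGMA1) {
  if (is.list(y)) return(lapply(y, rescale_targets, sigma1 = sigma1))
  sigma1 * (2 * y - 1)
}

#' Inverse of [rescale_targets()]
#'
#' @param y_rescaled Rescaled values.
#' @param sigma1 Scale constant. Default 1.7159.
#' @return Spike-count-scale values.
#' @export
unrescale_targets <- function(y_rescaled, sigma1 = NRF_SIGMA1) {
  if (is.list(y_rescaled)) return(lapply(y_rescaled, unrescale_targets, sigma1 = sigma1))
  (y_rescaled / sigma1 + 1) / 2
}
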