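#' Build a log-spaced triangular filterbank
#'
#' Channels have geometrically spaced center frequencies
#' `f_lo * 2^((k - 1) * spacing_octaves)` and triangular aggregation weights
#' spanning from the previous to the next center frequency (virtual neighbors
#' are extrapolated at the same geometric spacing for the edge channels, and
#' any part of a triangle beyond the Nyquist frequency is truncated).
#'
#' @param n_channels Number of frequency channels (>= 1). Default 34.
#' @param f_lo Center frequency of the lowest channel in Hz. Default 500.
#' @param spacing_octaves Octave spacing between neighboring channels.
#'   Default 1/6.
#' @param nyquist Optional Nyquist frequency in Hz; if supplied, the top
#'   center frequency must lie strictly below it.
#' @return A `filterbank`: list with `center_freqs` (Hz), `spacing_octaves`
#'   and `nyquist`.
#' @examples
#' fb <- build_filterbank(34, 500, 1/6, nyquist = 48828.125 / 2)
#' round(max(fb$center_freqs))  # 22627
#' @export
build_filterbank <- function(n_channels = 34, f_lo = 500, spacing_octaves = 1 / 6,
                             nyquist = NULL) {
  if (n_channels < 1) abort("n_channels must be >= 1")
  if (f_lo <= 0) abort("f_lo must be positive")
  cf <- f_lo * 2^((seq_len(n_channels) - 1) * spacing_octaves)
  if (!is.null(nyquist) && max(cf) >= nyquist) {
    abort(sprintf(
      "top center frequency %.1f Hz is not below the Nyquist frequency %.1f Hz",
      max(cf), nyquist
    ))
  }
  structure(
    list(center_freqs = cf, spacing_octaves = spacing_octaves, nyquist = nyquist),
    class = "filterbank"
  )
}

#' Triangular channel weights over a set of FFT bin frequencies
#'
#' @param bank A `filterbank`.
#' @param fft_freqs Frequencies (Hz) of the one-sided FFT bins.
#' @return A `length(fft_freqs) x n_channels` non-negative weight matrix.
#' @export
filterbank_weights <- function(bank, fft_freqs) {
  cf <- bank$center_freqs
  n <- length(cf)
  r <- 2^bank$spacing_octaves
  lo <- c(cf[1] / r, cf[-n])
  hi <- c(cf[-1], cf[n] * r)
  W <- matrix(0, length(fft_freqs), n)
  for (k in seq_len(n)) {
    up <- fft_freqs >= lo[k] & fft_freqs <= cf[k]
    dn <- fft_freqs > cf[k] & fft_freqs <= hi[k]
    if (cf[k] > lo[k]) W[up, k] <- (fft_freqs[up] - lo[k]) / (cf[k] - lo[k])
    if (hi[k] > cf[k]) W[dn, k] <- (hi[k] - fft_freqs[dn]) / (hi[k] - cf[k])
  }
  if (!is.null(bank$nyquist)) W[fft_freqs > bank$nyquist, ] <- 0
  W
}

#' Compute a log-power cochleagram from an audio clip
#'
#' A Hamming-windowed power spectrogram (frames fully contained in the clip)
#' is aggregated into log-spaced channels with triangular weights, log
#' transformed, and clipped from below at a floor.
#'
#' @param audio An `audio_clip`.
#' @param bank A `filterbank`.
#' @param frame_ms Analysis window length in ms. Default 10.
#' @param hop_ms Hop between frame starts in ms. Default 5.
#' @param floor_db Dynamic range in dB: the floor is this many dB below the
#'   clip's maximum log power. Default 60.
#' @param floor Optional absolute floor in natural-log power units,
#'   overriding `floor_db`.
#' @return A `cochleagram`: `T x F` matrix of natural-log power with
#'   attributes `channel_freqs`, `hop_ms`, `frame_ms`, `floor`, `clip_id`.
#' @export
compute_cochleagram <- function(audio, bank, frame_ms = 10, hop_ms = 5,
                                floor_db = 60, floor = NULL) {
  if (!inherits(audio, "audio_clip")) abort("audio must be an audio_clip")
  x <- audio$samples
  frame_n <- round(frame_ms / 1000 * audio$rate)
  hop_n <- round(hop_ms / 1000 * audio$rate)
  if (frame_n < hop_n) abort("frame_ms must be >= hop_ms")
  if (length(x) < frame_n) abort("audio shorter than one analysis frame")

  n_frames <- floor((length(x) - frame_n) / hop_n) + 1
  starts <- (seq_len(n_frames) - 1) * hop_n + 1
  idx <- outer(seq_len(frame_n) - 1L, starts, `+`)
  frames <- matrix(x[idx], nrow = frame_n)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_n) - 1) / (frame_n - 1))
  frames <- frames * w

  # one-sided power spectrum; FFT length = frame length (no zero padding)
  spec <- stats::mvfft(frames)
  n_bins <- floor(frame_n / 2) + 1
  P <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  fft_freqs <- (seq_len(n_bins) - 1) * audio$rate / frame_n

  Wt <- filterbank_weights(bank, fft_freqs)
  chan_power <- crossprod(P, Wt) # n_frames x F
  lp <- suppressWarnings(log(chan_power))

  finite <- lp[is.finite(lp)]
  thr <- if (!is.null(floor)) {
    floor
  } else if (length(finite) == 0) {
    log(.Machine$double.xmin)
  } else {
    max(finite) - floor_db / 10 * log(10)
  }
  vals <- pmax(lp, thr)

  structure(
    vals,
    channel_freqs = bank$center_freqs,
    hop_ms = hop_ms,
    frame_ms = frame_ms,
    floor = thr,
    clip_id = audio$clip_id,
    class = c("cochleagram", "matrix", "array")
  )
}

#' Number of fully contained analysis frames
#'
#' @param n_samples Clip length in samples.
#' @param frame_n Frame length in samples.
#' @param hop_n Hop in samples.
#' @return Frame count `floor((n_samples - frame_n) / hop_n) + 1`.
#' @export
n_frames <- function(n_samples, frame_n, hop_n) {
  floor((n_samples - frame_n) / hop_n) + 1
}

#' Z-score a set of cochleagrams with pooled statistics
#'
#' Computes the pooled mean and standard deviation over every value of every
#' clip and standardizes all clips with them, so the whole dataset has zero
#' mean and unit variance. The returned statistics can be reused to
#' standardize held-out data with [apply_normalization()].
#'
#' @param cochleagrams List of `cochleagram` matrices (or plain matrices).
#' @return List with `cochleagrams` (normalized), `mean`, `sd`.
#' @export
normalize_dataset <- function(cochleagrams) {
  if (inherits(cochleagrams, "cochleagram")) cochleagrams <- list(cochleagrams)
  all_vals <- unlist(lapply(cochleagrams, as.numeric))
  if (length(unique(all_vals)) < 2) abort("constant dataset: zero pooled variance")
  m <- mean(all_vals)
  s <- sqrt(mean((all_vals - m)^2)) # population SD: pooled variance exactly 1
  if (s == 0) abort("constant dataset: zero pooled variance")
  list(
    cochleagrams = lapply(cochleagrams, function(cg) {
      out <- (cg - m) / s
      attributes(out) <- attributes(cg)
      out
    }),
    mean = m,
    sd = s
  )
}

#' Standardize cochleagrams with previously computed statistics
#'
#' @param cochleagrams List of cochleagram matrices.
#' @param mean,sd Statistics from [normalize_dataset()] on the training set.
#' @return List of standardized cochleagrams.
#' @export
apply_normalization <- function(cochleagrams, mean, sd) {
  if (inherits(cochleagrams, "cochleagram")) cochleagrams <- list(cochleagrams)
  lapply(cochleagrams, function(cg) {
    out <- (cg - mean) / sd
    attributes(out) <- attributes(cg)
    out
  })
}

#' Build the lagged stimulus design from a cochleagram
#'
#' For each time bin `t` with a full in-clip history, the model input is the
#' `F x H` matrix whose entry `(f, tau)` is the cochleagram frame `t - tau + 1`
#' at channel `f` (`tau = 1` is the current frame). Windows are stored as rows
#' of a design matrix with column index `(tau - 1) * F + f`.
#'
#' @param cochleagram A `T x F` cochleagram matrix.
#' @param H Number of history bins. Default 20.
#' @return A `lagged_stimulus`: list with `X` (`(T - H + 1) x (F * H)` design
#'   matrix), `valid_bins` (`H:T`), `F`, `H`.
#' @export
lag_stimulus <- function(cochleagram, H = 20) {
  V <- unclass(cochleagram)
  T_ <- nrow(V)
  F_ <- ncol(V)
  if (T_ < H) abort(sprintf("clip has %d frames, fewer than H = %d", T_, H))
  valid <- H:T_
  X <- matrix(0, length(valid), F_ * H)
  for (tau in seq_len(H)) {
    X[, (tau - 1) * F_ + seq_len(F_)] <- V[valid - tau + 1, , drop = FALSE]
  }
  structure(
    list(X = X, valid_bins = valid, F = F_, H = H),
    class = "lagged_stimulus"
  )
}

#' Extract the `F x H` window at one time bin
#'
#' @param lagged A `lagged_stimulus`.
#' @param t Time bin (must be in `valid_bins`).
#' @return `F x H` matrix `x[f, tau]`.
#' @export
lagged_window <- function(lagged, t) {
  i <- match(t, lagged$valid_bins)
  if (is.na(i)) abort("t is not a valid (full-history) bin")
  matrix(lagged$X[i, ], nrow = lagged$F, ncol = lagged$H)
}

#' Reconstruct the cochleagram from its lagged design (round trip)
#'
#' @param lagged A `lagged_stimulus`.
#' @return The original `T x F` matrix.
#' @export
unstack_lagged <- function(lagged) {
  F_ <- lagged$F
  H <- lagged$H
  T_ <- max(lagged$valid_bins)
  V <- matrix(NA_real_, T_, F_)
  # tau = 1 covers frames H..T; earlier frames from the first window's history
  V[lagged$valid_bins, ] <- lagged$X[, seq_len(F_), drop = FALSE]
  first <- matrix(lagged$X[1, ], nrow = F_, ncol = H)
  V[seq_len(H), ] <- t(first[, H:1, drop = FALSE])
  V
}

#' Assemble a multi-clip model dataset
#'
#' Lags every clip, keeps only modeled bins (full history and past the onset
#' discard), and stacks them with clip/bin bookkeeping. The response vector,
#' when supplied, must hold one value per retained bin per clip (i.e. the
#' PSTH after onset discard).
#'
#' @param cochleagrams List of (normalized) cochleagram matrices, one per clip.
#' @param H History bins.
#' @param discard_bins Number of initial frames whose responses are discarded
#'   (onset transient); modeled bins start at `max(H, discard_bins + 1)`.
#' @param psth Optional list of per-clip response vectors aligned to bins
#'   `(discard_bins + 1):T`.
#' @return An `nrf_data`: list with `X` (stacked design), `y` (response or
#'   NULL), `index` (tibble: clip, bin), `F`, `H`.
#' @export
build_design <- function(cochleagrams, H = 20, discard_bins = 50, psth = NULL) {
  stopifnot(length(cochleagrams) >= 1)
  first_bin <- max(H, discard_bins + 1)
  Xs <- list(); ys <- list(); idx <- list()
  for (i in seq_along(cochleagrams)) {
    lg <- lag_stimulus(cochleagrams[[i]], H)
    keep <- lg$valid_bins >= first_bin
    bins <- lg$valid_bins[keep]
    Xs[[i]] <- lg$X[keep, , drop = FALSE]
    idx[[i]] <- tibble(clip = i, bin = bins)
    if (!is.null(psth)) {
      yv <- psth[[i]]
      # psth is aligned to bins (discard_bins+1):T
      ys[[i]] <- yv[bins - discard_bins]
    }
  }
  lg1 <- lag_stimulus(cochleagrams[[1]], H)
  structure(
    list(
      X = do.call(rbind, Xs),
      y = if (is.null(psth)) NULL else unlist(ys),
      index = dplyr::bind_rows(idx),
      F = lg1$F,
      H = H,
      discard_bins = discard_bins
    ),
    class = "nrf_data"
  )
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf(
    "<cochleagram '%s': %d frames x %d channels, hop %g ms, floor %.2f>\n",
    attr(x, "clip_id") %||% "?", nrow(x), ncol(x), attr(x, "hop_ms") %||% NA,
    attr(x, "floor") %||% NA
  ))
  invisible(x)
}
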