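#' Gabor-shaped STRF
#'
#' Gaussian spectrotemporal envelope times an oriented cosine carrier:
#' the building block for designed ground-truth hidden units.
#'
#' @param F,H STRF dimensions (frequency channels, history bins).
#' @param cf Center frequency bin.
#' @param lat Center latency bin.
#' @param bw Frequency bandwidth (SD, bins).
#' @param dur Temporal duration (SD, bins).
#' @param kf,kt Carrier spatial frequencies (cycles per bin) along frequency
#'   and time.
#' @param phase Carrier phase (radians).
#' @param amp Peak amplitude.
#' @return `F x H` matrix.
#' @export
gabor_strf <- function(F, H, cf, lat, bw = 2, dur = 1.5, kf = 0, kt = 0,
                       phase = 0, amp = 1) {
  f <- matrix(seq_len(F), F, H)
  tau <- matrix(seq_len(H), F, H, byrow = TRUE)
  env <- exp(-((f - cf)^2 / (2 * bw^2) + (tau - lat)^2 / (2 * dur^2)))
  amp * env * cos(2 * pi * (kf * (f - cf) + kt * (tau - lat)) + phase)
}

#' Design a ground-truth NRF neuron
#'
#' Places `K_exc` excitatory and `K_inh` inhibitory Gabor-shaped hidden-unit
#' STRFs at random non-overlapping spectrotemporal centers, normalized to
#' unit L2 norm and scaled by `input_gain`. Output weights are `+w_exc` /
#' `-w_inh`; the output bias is set so the resting output (all hidden
#' activations at their stimulus mean, taken as 0) corresponds to
#' `baseline_count` spike counts per bin, giving a sparse, near-threshold
#' output unit.
#'
#' @param K_exc,K_inh Numbers of designed excitatory/inhibitory HUs.
#' @param F,H Stimulus dimensions.
#' @param seed RNG seed.
#' @param input_gain L2 norm of each hidden STRF. Default 1.
#' @param w_exc,w_inh Output weight magnitudes. Defaults 0.9 and 0.6.
#' @param baseline_count Resting spike count per bin. Default 0.05.
#' @param J Total hidden units in the parameter arrays (extra units are
#'   all-zero). Default `K_exc + K_inh`.
#' @return An `nrf_gt`: list with `params` (`nrf_params`), `kind` (designed
#'   sign per designed HU), `designed` (their indices).
#' @export
make_ground_truth <- function(K_exc, K_inh, F = 18, H = 12, seed = 1,
                              input_gain = 1, w_exc = 0.9, w_inh = 0.6,
                              baseline_count = 0.05, J = K_exc + K_inh) {
  K <- K_exc + K_inh
  if (K < 1 || K > J) abort("need 1 <= K_exc + K_inh <= J")
  with_seed(seed, {
    # non-overlapping centers: rejection-sample with a minimum separation
    centers <- matrix(NA_real_, 0, 2)
    min_sep <- max(3, min(F, H) / (K + 1))
    guard <- 0
    while (nrow(centers) < K) {
      cand <- c(runif(1, 3, F - 2), runif(1, 2.5, H - 1.5))
      ok <- nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep)
      if (ok) centers <- rbind(centers, cand)
      guard <- guard + 1
      if (guard > 5000) {
        min_sep <- min_sep * 0.9
        guard <- 0
      }
    }
    W <- matrix(0, J, F * H)
    kind <- character(K)
    for (i in seq_len(K)) {
      g <- gabor_strf(F, H, centers[i, 1], centers[i, 2],
                      bw = runif(1, 1.5, 2.5), dur = runif(1, 1, 2),
                      kf = runif(1, 0, 0.06), kt = runif(1, 0, 0.08))
      g <- g / sqrt(sum(g^2)) * input_gain
      W[i, ] <- as.numeric(g)
      kind[i] <- if (i <= K_exc) "excitatory" else "inhibitory"
    }
    w_out <- rep(0, J)
    w_out[seq_len(K_exc)] <- w_exc
    if (K_inh > 0) w_out[K_exc + seq_len(K_inh)] <- -w_inh
    target <- rescale_targets(baseline_count)
    b_out <- NRF_RHO2 * atanh(target / NRF_RHO1)
    params <- nrf_params(W, rep(0, J), w_out, b_out, F, H)
    structure(
      list(params = params, kind = kind, designed = seq_len(K)),
      class = "nrf_gt"
    )
  })
}

#' Synthesize a naturalistic stimulus ensemble
#'
#' Two generators emulating the structure of a natural-sound cochleagram
#' set: `"correlated-field"` draws spectrotemporally low-pass Gaussian
#' fields directly in cochleagram space (fast; the default for simulation
#' studies); `"tone-cloud-audio"` synthesizes audio from random tone onsets
#' and runs it through the real cochleagram front end.
#'
#' @param n_clips Number of clips.
#' @param duration_s Clip duration in seconds.
#' @param F Frequency channels.
#' @param seed RNG seed.
#' @param kind `"correlated-field"` or `"tone-cloud-audio"`.
#' @param hop_ms,frame_ms Framing (5/10 ms defaults).
#' @param corr_f,corr_t Gaussian correlation lengths (bins) for the field
#'   generator. Defaults 1.5 and 2.
#' @param rate Audio sampling rate in Hz (tone-cloud only).
#'   Default 48828.125.
#' @param f_lo,spacing_octaves Filterbank layout (tone-cloud only).
#' @return List of `cochleagram` matrices (un-normalized); for the audio
#'   kind, the clips carry an `audio` attribute with the source `audio_clip`.
#' @export
synth_stimulus <- function(n_clips, duration_s, F = 18, seed = 1,
                           kind = c("correlated-field", "tone-cloud-audio"),
                           hop_ms = 5, frame_ms = 10, corr_f = 1.5, corr_t = 2,
                           rate = 48828.125, f_lo = 500, spacing_octaves = 1 / 6) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "correlated-field") {
      T_ <- n_frames(round(duration_s * 1000), frame_ms, hop_ms)
      lapply(seq_len(n_clips), function(n) {
        V <- matrix(rnorm(T_ * F), T_, F)
        V <- gauss_smooth(V, corr_t, margin = 1)
        V <- gauss_smooth(V, corr_f, margin = 2)
        structure(V, hop_ms = hop_ms, frame_ms = frame_ms,
                  channel_freqs = f_lo * 2^((seq_len(F) - 1) * spacing_octaves),
                  floor = -Inf, clip_id = paste0("synth", n),
                  class = c("cochleagram", "matrix", "array"))
      })
    } else {
      bank <- build_filterbank(F, f_lo, spacing_octaves, nyquist = rate / 2)
      lapply(seq_len(n_clips), function(n) {
        audio <- tone_cloud(duration_s, rate, bank, clip_id = paste0("synth", n))
        cg <- compute_cochleagram(audio, bank, frame_ms, hop_ms)
        attr(cg, "audio") <- audio
        cg
      })
    }
  })
}

# Separable Gaussian smoothing along rows (margin = 1) or columns (2),
# zero correlation length leaves the field white.
gauss_smooth <- function(V, len, margin) {
  if (len <= 0) return(V)
  half <- max(1, ceiling(3 * len))
  k <- exp(-(seq(-half, half))^2 / (2 * len^2))
  k <- k / sum(k)
  sm <- function(v) {
    padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + length(v))]
  }
  if (margin == 1) apply(V, 2, sm) else t(apply(V, 1, sm))
}

# Random tone cloud: overlapping ramped sinusoids with log-uniform
# frequencies within the filterbank span.
tone_cloud <- function(duration_s, rate, bank, tones_per_s = 12,
                       clip_id = "tonecloud") {
  n <- round(duration_s * rate)
  x <- numeric(n)
  n_tones <- max(1, rpois(1, tones_per_s * duration_s))
  f_range <- range(bank$center_freqs)
  for (i in seq_len(n_tones)) {
    f <- exp(runif(1, log(f_range[1]), log(f_range[2])))
    dur <- runif(1, 0.05, 0.3)
    onset <- runif(1, 0, max(duration_s - dur, 0))
    i0 <- floor(onset * rate) + 1
    len <- min(round(dur * rate), n - i0 + 1)
    if (len < 8) next
    tt <- seq_len(len) / rate
    ramp <- pmin(1, seq_len(len) / (0.005 * rate), rev(seq_len(len)) / (0.005 * rate))
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] +
      10^runif(1, -1.5, 0) * ramp * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  }
  audio_clip(x / max(abs(x), 1), rate, clip_id)
}

#' Simulate noisy multi-trial responses from a ground-truth NRF
#'
#' Runs the (normalized) stimuli through the ground-truth network to obtain
#' the per-bin firing rate in spike-count units, then draws `R` trials per
#' clip as `max(0, rate + gaussian noise)` (default) or Poisson counts. Bins
#' before the first modeled bin (no full stimulus history) are filled with
#' the clip's first modeled rate; they fall inside the onset-discard region
#' downstream.
#'
#' @param gt An `nrf_gt` (or `nrf_params`).
#' @param data An `nrf_data` built (without a response) from the normalized
#'   stimuli.
#' @param R Trials per clip. Default 20.
#' @param noise `"gaussian"` (truncated at 0) or `"poisson"`.
#' @param noise_sd Trial noise SD in count units (gaussian). Default 0.05.
#' @param seed RNG seed.
#' @return A `synthetic_dataset`: list with `trials` (`trial_responses`),
#'   `rate` (list of per-clip rate vectors over *all* bins), `rate_modeled`
#'   (vector over the modeled rows of `data`), `bin_ms`, `noise`, `seed`.
#' @export
simulate_responses <- function(gt, data, R = 20, noise = c("gaussian", "poisson"),
                               noise_sd = 0.05, seed = 1) {
  noise <- match.arg(noise)
  if (R < 2) abort("R must be >= 2")
  params <- if (inherits(gt, "nrf_gt")) gt$params else gt
  rate_modeled <- predict_nrf(params, data, scale = "count")
  idx <- data$index
  clips <- sort(unique(idx$clip))
  n_bins <- max(idx$bin)
  rate <- lapply(clips, function(cl) {
    rows <- idx$clip == cl
    r <- rep(rate_modeled[rows][1], n_bins)
    r[idx$bin[rows]] <- rate_modeled[rows]
    r
  })
  counts <- with_seed(seed, {
    arr <- array(0, c(length(clips), R, n_bins))
    for (ci in seq_along(clips)) {
      for (tr in seq_len(R)) {
        arr[ci, tr, ] <- if (noise == "gaussian") {
          pmax(0, rate[[ci]] + rnorm(n_bins, 0, noise_sd))
        } else {
          rpois(n_bins, pmax(rate[[ci]], 0))
        }
      }
    }
    arr
  })
  structure(
    list(trials = trial_responses(counts, bin_ms = 5), rate = rate,
         rate_modeled = rate_modeled, bin_ms = 5, noise = noise, seed = seed),
    class = "synthetic_dataset"
  )
}

#' Assemble a complete synthetic experiment
#'
#' End-to-end generator used throughout the simulation studies: synthesizes
#' stimuli, normalizes them, designs a ground-truth network, simulates noisy
#' trials, and builds the PSTH and modeling design. Presets:
#' \describe{
#'   \item{`bifeature`}{1 excitatory + 1 inhibitory HU.}
#'   \item{`multifeature`}{3 excitatory + 1 inhibitory HUs.}
#'   \item{`linear`}{a single weakly driven HU operating in the linear range
#'     of both nonlinearities (LN-equivalent neuron).}
#'   \item{`conjunctive`}{2 disjoint excitatory HUs with a strongly expansive
#'     output unit that responds mainly to their coincidence.}
#' }
#'
#' @param preset Preset name.
#' @param n_clips,duration_s,F,H,R Experiment scale. Defaults: 6 clips of
#'   2 s, 18 channels, 12 history bins, 20 trials.
#' @param noise_sd Trial noise SD (count units). Default 0.05.
#' @param seed RNG seed (stimuli, ground truth and noise derive from it).
#' @param onset_discard_ms Onset discard. Default 250.
#' @param stimulus_kind Passed to [synth_stimulus()].
#' @return List with `data` (an `nrf_data` with the PSTH response), `trials`,
#'   `psth`, `gt`, `sim`, `y_by_clip` (per-clip modeled-bin PSTH vectors),
#'   `rate_by_clip` (noiseless rates over modeled bins), `norm` (stimulus
#'   normalization stats).
#' @export
synth_experiment <- function(preset = c("bifeature", "multifeature", "linear",
                                        "conjunctive"),
                             n_clips = 6, duration_s = 2, F = 18, H = 12,
                             R = 20, noise_sd = 0.05, seed = 1,
                             onset_discard_ms = 250,
                             stimulus_kind = "correlated-field") {
  preset <- match.arg(preset)
  stim <- synth_stimulus(n_clips, duration_s, F, seed = seed, kind = stimulus_kind)
  norm <- normalize_dataset(stim)
  discard_bins <- round(onset_discard_ms / 5)
  design <- build_design(norm$cochleagrams, H = H, discard_bins = discard_bins)

  gt <- switch(preset,
    bifeature = make_ground_truth(1, 1, F, H, seed = seed + 1000),
    multifeature = make_ground_truth(3, 1, F, H, seed = seed + 1000),
    linear = make_ground_truth(1, 0, F, H, seed = seed + 1000,
                               input_gain = 0.15, w_exc = 0.6,
                               baseline_count = 0.3),
    conjunctive = make_ground_truth(2, 0, F, H, seed = seed + 1000,
                                    input_gain = 1.4, w_exc = 0.9,
                                    baseline_count = 0.02)
  )

  sim <- simulate_responses(gt, design, R = R, noise_sd = noise_sd,
                            seed = seed + 2000)
  psth <- compute_psth(sim$trials, smooth_ms = 21,
                       onset_discard_ms = onset_discard_ms)
  data <- build_design(norm$cochleagrams, H = H, discard_bins = discard_bins,
                       psth = psth$y)
  idx <- data$index
  clips <- sort(unique(idx$clip))
  y_by_clip <- lapply(clips, function(cl) data$y[idx$clip == cl])
  rate_by_clip <- lapply(clips, function(cl) sim$rate_modeled[idx$clip == cl])
  list(
    data = data, trials = sim$trials, psth = psth, gt = gt, sim = sim,
    y_by_clip = y_by_clip, rate_by_clip = rate_by_clip,
    norm = list(mean = norm$mean, sd = norm$sd)
  )
}

#' Compare a fitted NRF against its generating ground truth
#'
#' Reports held-out prediction quality and structural recovery: the
#' correlation of the fitted prediction with the noiseless ground-truth rate,
#' the test-set `CC_norm` against the observed PSTH, greedily matched
#' correlations between designed and fitted effective-HU display STRFs, and
#' the effective-HU count.
#'
#' @param gt An `nrf_gt`.
#' @param fit A fitted `nrf_fit`/`nrf_params`.
#' @param data Held-out stimulus `nrf_data` (with observed PSTH `y` if
#'   `cc_norm` is wanted).
#' @param rate Noiseless ground-truth rate over the rows of `data`.
#' @param ccmax Optional reliability ceiling for `cc_norm`.
#' @param threshold Effective-HU threshold. Default 0.05.
#' @return List with `summary` (one-row tibble: `cc_vs_rate`, `cc_norm`,
#'   `n_effective`, `n_designed`, `mean_matched_cor`) and `matches` (tibble:
#'   designed HU, best-matching fitted HU, correlation).
#' @export
recovery_report <- function(gt, fit, data, rate, ccmax = NULL, threshold = 0.05) {
  params <- if (inherits(fit, "nrf_fit")) fit$params else fit
  pred <- predict_nrf(params, data, scale = "count")
  cc_rate <- cc_raw(rate, pred)
  ccn <- if (!is.null(ccmax) && !is.null(data$y)) {
    cc_norm(data$y, pred, ccmax)
  } else NA_real_

  adj <- adjust_network(params)
  prof <- effective_hus(adj, data, threshold)
  eff <- which(prof$effective)

  gt_adj <- adjust_network(gt$params)
  gt_prof <- effective_hus(gt_adj, data, threshold)
  matches <- list()
  avail <- eff
  for (i in gt$designed) {
    disp_gt <- as.numeric(display_strf(hu_strf(gt_adj$params, i), gt_prof$kind[i]))
    if (length(avail) == 0) {
      matches[[length(matches) + 1]] <- tibble(designed = i, fitted = NA_integer_,
                                               correlation = NA_real_)
      next
    }
    cors <- vapply(avail, function(j) {
      cor(disp_gt, as.numeric(display_strf(hu_strf(adj$params, j), prof$kind[j])))
    }, numeric(1))
    k <- which.max(cors)
    matches[[length(matches) + 1]] <- tibble(designed = i, fitted = avail[k],
                                             correlation = cors[k])
    avail <- avail[-k]
  }
  matches <- dplyr::bind_rows(matches)
  list(
    summary = tibble(
      cc_vs_rate = cc_rate,
      cc_norm = ccn,
      n_effective = length(eff),
      n_designed = length(gt$designed),
      mean_matched_cor = mean(matches$correlation, na.rm = TRUE)
    ),
    matches = matches
  )
}
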