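#' Gain-control analysis of a bi-feature NRF
#'
#' For a fitted network with exactly one effective excitatory and one
#' effective inhibitory hidden unit, computes the output-unit firing rate
#' (spike-count scale) as a function of excitatory HU activation, at 7 levels
#' of inhibitory HU activation evenly spanning the inhibitory unit's
#' activation range. Activations are normalized so 0 is the 1st and 1 the
#' 99th centile of the activation distribution over the stimulus set; the
#' excitatory sweep extends beyond the centiles to cover the unit's full
#' operating range from threshold to saturation. The gain of each curve is
#' its steepest slope (central differences), normalized to 1 at the lowest
#' inhibitory level.
#'
#' @param fit An `nrf_fit`, `nrf_params` or `adjusted_nrf` (bi-feature).
#' @param data Stimulus set defining the activation distributions.
#' @param n_levels Number of inhibitory activation levels. Default 7.
#' @param n_sweep Points in the excitatory sweep. Default 201.
#' @param ou Output-unit nonlinearity: `"sigmoid"` (the fitted network) or
#'   `"linear"` (diagnostic: inhibition becomes purely subtractive).
#' @param threshold Effective-HU threshold. Default 0.05.
#' @param exc_hu,inh_hu Optional explicit HU indices (in the adjusted
#'   network), bypassing the effective-HU screen — useful for constructed
#'   networks.
#' @return A `gain_curves`: list with `curves` (tibble: level, inh_norm,
#'   exc_norm, exc_activation, rate) and `gains` (tibble: level, inh_norm,
#'   gain, gain_norm).
#' @export
gain_analysis <- function(fit, data, n_levels = 7, n_sweep = 201,
                          ou = c("sigmoid", "linear"), threshold = 0.05,
                          exc_hu = NULL, inh_hu = NULL) {
  ou <- match.arg(ou)
  adj <- if (inherits(fit, "adjusted_nrf")) fit else adjust_network(fit)
  p <- adj$params
  if (is.null(exc_hu) || is.null(inh_hu)) {
    prof <- effective_hus(adj, data, threshold)
    exc <- exc_hu %||% prof$hu[prof$effective & prof$kind == "excitatory"]
    inh <- inh_hu %||% prof$hu[prof$effective & prof$kind == "inhibitory"]
    if (length(exc) != 1 || length(inh) != 1) {
      abort(paste0(
        "gain analysis requires exactly 1 effective excitatory and 1 effective ",
        "inhibitory HU (found ", length(exc), " + ", length(inh),
        "); use the reduced-NRF conjunction analysis for multi-feature fits"
      ))
    }
  } else {
    exc <- exc_hu
    inh <- inh_hu
  }
  tr <- nrf_forward(p, data)
  a_e <- tr$a_hidden[, exc]
  a_i <- tr$a_hidden[, inh]
  qe <- quantile(a_e, c(0.01, 0.99), names = FALSE)
  qi <- quantile(a_i, c(0.01, 0.99), names = FALSE)
  norm_e <- function(a) (a - qe[1]) / max(qe[2] - qe[1], .Machine$double.eps)
  norm_i <- function(a) (a - qi[1]) / max(qi[2] - qi[1], .Machine$double.eps)

  # full operating range of the excitatory unit: threshold to saturation
  sat <- 6 * p$rho2
  sweep_a <- seq(min(min(a_e), -sat), max(max(a_e), sat), length.out = n_sweep)
  levels_a <- seq(min(a_i), max(a_i), length.out = n_levels)

  curves <- list()
  gains <- numeric(n_levels)
  for (l in seq_len(n_levels)) {
    a_o <- p$w_out[exc] * activation_g(sweep_a, p$rho1, p$rho2) +
      p$w_out[inh] * activation_g(levels_a[l], p$rho1, p$rho2) + p$b_out
    out <- if (ou == "sigmoid") activation_g(a_o, p$rho1, p$rho2) else a_o
    rate <- unrescale_targets(out)
    x <- norm_e(sweep_a)
    slope <- (rate[-(1:2)] - rate[seq_len(n_sweep - 2)]) /
      (x[-(1:2)] - x[seq_len(n_sweep - 2)])
    gains[l] <- max(slope)
    curves[[l]] <- tibble(
      level = l, inh_norm = norm_i(levels_a[l]),
      exc_norm = x, exc_activation = sweep_a, rate = rate
    )
  }
  structure(
    list(
      curves = dplyr::bind_rows(curves),
      gains = tibble(
        level = seq_len(n_levels),
        inh_norm = norm_i(levels_a),
        gain = gains,
        gain_norm = gains / gains[1]
      )
    ),
    class = "gain_curves"
  )
}

#' Reduced NRF with all but one effective excitatory HU disabled
#'
#' Every other effective excitatory hidden unit's output is clamped at its
#' minimum (`-rho1`; zero in the non-negative-output description), so it
#' contributes the constant `-rho1 * w_j` to the output activation.
#' Inhibitory and ineffective HUs are untouched.
#'
#' @param fit An `nrf_fit`, `nrf_params` or `adjusted_nrf`.
#' @param keep_exc_hu Index (in the adjusted network) of the effective
#'   excitatory HU to retain.
#' @param data Stimulus set used to determine effective HUs.
#' @param threshold Effective-HU threshold. Default 0.05.
#' @return A `reduced_nrf`: list with `params` (adjusted), `clamped` (HU
#'   indices held at threshold), `keep` (the retained HU).
#' @export
reduced_nrf <- function(fit, keep_exc_hu, data, threshold = 0.05) {
  adj <- if (inherits(fit, "adjusted_nrf")) fit else adjust_network(fit)
  prof <- effective_hus(adj, data, threshold)
  exc <- prof$hu[prof$effective & prof$kind == "excitatory"]
  if (!keep_exc_hu %in% exc) {
    abort("keep_exc_hu must be an effective excitatory HU of the adjusted network")
  }
  structure(
    list(params = adj$params, clamped = setdiff(exc, keep_exc_hu),
         keep = keep_exc_hu),
    class = "reduced_nrf"
  )
}

#' Predict with a reduced NRF
#'
#' @param reduced A `reduced_nrf`.
#' @param data Stimulus data.
#' @param scale `"count"` or `"rescaled"`.
#' @return Predicted response vector.
#' @export
predict_reduced <- function(reduced, data, scale = c("count", "rescaled")) {
  scale <- match.arg(scale)
  p <- reduced$params
  tr <- nrf_forward(p, data)
  Z <- tr$z_hidden
  if (length(reduced$clamped) > 0) Z[, reduced$clamped] <- -p$rho1
  a_out <- as.numeric(Z %*% p$w_out) + p$b_out
  y_hat <- activation_g(a_out, p$rho1, p$rho2)
  if (scale == "count") unrescale_targets(y_hat) else y_hat
}

#' Conjunctive feature selectivity via reduced NRFs
#'
#' Runs the stimulus through the full model and through each
#' single-excitatory-HU reduced model, sums the reduced-model responses, and
#' counts, against the per-clip 2-sigma thresholds of the *observed* PSTH,
#' how often each exceeds threshold. A peak time ratio (summed-reduced /
#' full) below 1 indicates supra-additive, conjunctive interaction of the
#' excitatory features.
#'
#' @param fit An `nrf_fit`, `nrf_params` or `adjusted_nrf` with >= 2
#'   effective excitatory HUs.
#' @param data Stimulus set (an `nrf_data` with clip index).
#' @param y_observed List of per-clip observed PSTH vectors on the
#'   spike-count scale, aligned to the modeled bins of `data`.
#' @param threshold Effective-HU threshold. Default 0.05.
#' @param n_sd Peak threshold in SD units. Default 2.
#' @return One-row tibble: `n_exc_hus`, `nrf_peak_time`,
#'   `summed_reduced_peak_time`, `peak_time_ratio` (NA if the full model
#'   never crosses threshold).
#' @export
peak_time_ratio <- function(fit, data, y_observed, threshold = 0.05, n_sd = 2) {
  adj <- if (inherits(fit, "adjusted_nrf")) fit else adjust_network(fit)
  prof <- effective_hus(adj, data, threshold)
  exc <- prof$hu[prof$effective & prof$kind == "excitatory"]
  if (length(exc) < 2) {
    abort("peak time ratio requires >= 2 effective excitatory HUs")
  }
  w <- peak_window(y_observed, n_sd)
  clips <- sort(unique(data$index$clip))
  thr_by_row <- w$threshold[match(data$index$clip, clips)]

  full_pred <- predict_nrf(adj$params, data, scale = "count")
  nrf_peak <- sum(full_pred >= thr_by_row)

  summed <- 0
  for (j in exc) {
    r <- reduced_nrf(adj, j, data, threshold)
    summed <- summed + predict_reduced(r, data, scale = "count")
  }
  reduced_peak <- sum(summed >= thr_by_row)

  tibble(
    n_exc_hus = length(exc),
    nrf_peak_time = nrf_peak,
    summed_reduced_peak_time = reduced_peak,
    peak_time_ratio = if (nrf_peak > 0) reduced_peak / nrf_peak else NA_real_
  )
}
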