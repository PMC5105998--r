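#' Hidden-unit STRF as an F x H matrix
#'
#' @param params An `nrf_params`.
#' @param j Hidden-unit index.
#' @return `F x H` weight matrix (frequency x history).
#' @export
hu_strf <- function(params, j) {
  matrix(params$W[j, ], nrow = params$F, ncol = params$H)
}

#' Canonicalize a fitted NRF into its adjusted form
#'
#' The tanh nonlinearity is odd, so negating `(w_j, b_j, w_jfτ)` of any hidden
#' unit leaves predictions unchanged. The adjusted network flips every HU
#' whose summed STRF weights are negative, after which the sign of the output
#' weight `w_j` alone classifies the unit as excitatory (`w_j > 0`) or
#' inhibitory (`w_j < 0`). The equivalent non-negative-output description
#' (outputs shifted to `[0, 2*rho1]`) has output bias
#' `b_o - rho1 * sum_j w_j`, recorded as `nonneg_bias_shift`.
#'
#' @param params An `nrf_params` (or `nrf_fit`).
#' @return An `adjusted_nrf`: list with `params` (sign-canonical, predictions
#'   identical to the input), `flipped` (logical per HU), `nonneg_b_out`.
#' @export
adjust_network <- function(params) {
  if (inherits(params, "adjusted_nrf")) return(params)
  if (inherits(params, "nrf_fit")) params <- params$params
  flip <- rowSums(params$W) < 0
  W <- params$W
  W[flip, ] <- -W[flip, , drop = FALSE]
  b_hidden <- ifelse(flip, -params$b_hidden, params$b_hidden)
  w_out <- ifelse(flip, -params$w_out, params$w_out)
  adj <- nrf_params(W, b_hidden, w_out, params$b_out, params$F, params$H,
                    params$rho1, params$rho2)
  structure(
    list(
      params = adj,
      flipped = flip,
      nonneg_b_out = params$b_out - params$rho1 * sum(w_out)
    ),
    class = "adjusted_nrf"
  )
}

#' Inhibitory/excitatory score of a hidden unit
#'
#' `IE = sign(w_j) * sum(w_jfτ) / sum(|w_jfτ|)`, bounded in `[-1, 1]`:
#' +1 for a purely excitatory influence on the output unit, -1 for purely
#' inhibitory.
#'
#' @param w_strf STRF weight matrix (or vector) of the HU.
#' @param w_j Output weight of the HU.
#' @return IE score, or `NA` for an all-zero STRF.
#' @export
ie_score <- function(w_strf, w_j) {
  denom <- sum(abs(w_strf))
  if (denom == 0) return(NA_real_)
  sign(w_j) * sum(w_strf) / denom
}

#' Expansive/compressive score of a unit
#'
#' The average output of the unit over the stimulus set, scaled to lie
#' between -1 at threshold and +1 at saturation:
#' `EC = (rho6 / rho1) * (mean(output) - rho4) - rho5`.
#' NRF units use `rho4 = 0, rho5 = 0, rho6 = 1` (with `rho1` the activation
#' constant); LN-model units use the fitted `rho1`, `rho4` with
#' `rho5 = 1, rho6 = 2`.
#'
#' @param outputs Unit outputs over the stimulus set (HU output `z_j(t)`,
#'   or model prediction for the OU/LN cases).
#' @param rho1 Output-range constant (> 0).
#' @param rho4 Output offset.
#' @param rho5,rho6 Scale constants for the parameterization in use.
#' @return EC score.
#' @export
ec_score <- function(outputs, rho1 = NRF_RHO1, rho4 = 0, rho5 = 0, rho6 = 1) {
  if (rho1 == 0) abort("rho1 must be nonzero")
  (rho6 / rho1) * (mean(outputs) - rho4) - rho5
}

#' Profile the hidden units of a fitted NRF
#'
#' Works on the adjusted network. The variance over the stimulus set of each
#' HU's weighted output (`w_j * z_j(t)`) measures its effectiveness; HUs at or
#' above `threshold` (default 5%) of the summed variance are effective.
#' IE and EC scores are computed after adjustment.
#'
#' @param fit An `nrf_fit`, `nrf_params` or `adjusted_nrf`.
#' @param data Stimulus set over which variances and EC scores are computed
#'   (typically the cross-validation set).
#' @param threshold Effectiveness threshold on the variance fraction.
#'   Default 0.05.
#' @return Tibble, one row per HU: `hu`, `kind`, `w_out`, `variance`,
#'   `variance_fraction`, `effective`, `ie`, `ec`.
#' @export
effective_hus <- function(fit, data, threshold = 0.05) {
  adj <- if (inherits(fit, "adjusted_nrf")) fit else adjust_network(fit)
  p <- adj$params
  tr <- nrf_forward(p, data)
  wz <- sweep(tr$z_hidden, 2, p$w_out, `*`)
  v <- unname(apply(wz, 2, function(col) mean((col - mean(col))^2)))
  total <- sum(v)
  frac <- if (total == 0) rep(0, p$J) else v / total
  if (total == 0) warn("all weighted-output variances are zero: no effective HUs")
  tibble(
    hu = seq_len(p$J),
    kind = unname(ifelse(p$w_out >= 0, "excitatory", "inhibitory")),
    w_out = unname(p$w_out),
    variance = v,
    variance_fraction = frac,
    effective = frac >= threshold,
    ie = vapply(seq_len(p$J), function(j) ie_score(p$W[j, ], p$w_out[j]), numeric(1)),
    ec = unname(apply(tr$z_hidden, 2, ec_score, rho1 = p$rho1))
  )
}

#' Display form of a hidden-unit STRF
#'
#' Inhibitory HU STRFs are sign-reversed so plots show the direction of
#' effect of each weight on the model output rather than on the HU.
#'
#' @param w_strf STRF matrix of the (adjusted) HU.
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @return Display matrix.
#' @export
display_strf <- function(w_strf, kind = c("excitatory", "inhibitory")) {
  kind <- match.arg(kind)
  if (kind == "inhibitory") -w_strf else w_strf
}

#' Spline-interpolate an STRF onto a finer grid
#'
#' Cubic-spline interpolation onto an evenly spaced grid at `factor` times
#' the resolution on both axes (`factor - 1` inserted values per gap),
#' applied separably (time, then frequency).
#'
#' @param m `F x H` matrix.
#' @param factor Upsampling factor. Default 8.
#' @return `((F-1)*factor + 1) x ((H-1)*factor + 1)` matrix.
#' @export
interpolate_strf <- function(m, factor = 8) {
  interp_axis <- function(mat) {
    n <- ncol(mat)
    if (n == 1) return(mat)
    xout <- seq(1, n, by = 1 / factor)
    t(apply(mat, 1, function(row) spline(seq_len(n), row, xout = xout)$y))
  }
  m1 <- interp_axis(unclass(m))     # along time
  t(interp_axis(t(m1)))             # along frequency
}

#' Tuning widths of a power STRF
#'
#' The power STRF is the elementwise square of the interpolated (display)
#' STRF. Marginal power profiles are obtained by summation over the other
#' axis; a width at height fraction `q` counts the interpolated bins whose
#' profile is `>= q * max` and multiplies by the interpolated bin size
#' (`freq_spacing/factor` octaves; `bin_ms/factor` ms).
#'
#' @param power Interpolated power STRF (`F' x H'`, frequency x history).
#' @param freq_spacing_octaves Original channel spacing in octaves.
#'   Default 1/6.
#' @param bin_ms Original time-bin size in ms. Default 5.
#' @param factor Interpolation factor used. Default 8.
#' @return One-row tibble: `freq_width_half`, `freq_width_quarter` (octaves),
#'   `time_width_half`, `time_width_quarter` (ms).
#' @export
tuning_widths <- function(power, freq_spacing_octaves = 1 / 6, bin_ms = 5,
                          factor = 8) {
  if (all(power == 0)) abort("all-zero power STRF: tuning widths undefined")
  fprof <- rowSums(power)
  tprof <- colSums(power)
  fw <- function(profile, q) sum(profile >= q * max(profile))
  tibble(
    freq_width_half = fw(fprof, 0.5) * freq_spacing_octaves / factor,
    freq_width_quarter = fw(fprof, 0.25) * freq_spacing_octaves / factor,
    time_width_half = fw(tprof, 0.5) * bin_ms / factor,
    time_width_quarter = fw(tprof, 0.25) * bin_ms / factor
  )
}

#' Interpolated power STRF of a fitted model
#'
#' For an LN fit: the square of the interpolated STRF. For an NRF fit: the
#' sum over hidden units of their interpolated display-STRF squares, each
#' weighted by the variance of the unit's weighted output over the stimulus
#' set (the strength of the signal it contributes to the output unit).
#'
#' @param fit An `ln_fit`/`strf`, or an `nrf_fit`/`nrf_params`/`adjusted_nrf`.
#' @param data Stimulus set (required for NRF fits, for the variance weights).
#' @param factor Interpolation factor. Default 8.
#' @return Interpolated power STRF matrix.
#' @export
model_power_strf <- function(fit, data = NULL, factor = 8) {
  if (inherits(fit, "ln_fit")) fit <- fit$strf
  if (inherits(fit, "strf")) {
    return(interpolate_strf(fit$w, factor)^2)
  }
  adj <- if (inherits(fit, "adjusted_nrf")) fit else adjust_network(fit)
  if (is.null(data)) abort("stimulus data required for NRF power STRFs")
  prof <- effective_hus(adj, data)
  p <- adj$params
  out <- 0
  for (j in seq_len(p$J)) {
    disp <- display_strf(hu_strf(p, j), prof$kind[j])
    out <- out + prof$variance[j] * interpolate_strf(disp, factor)^2
  }
  out
}

#' Half-maximum contours of a display STRF
#'
#' Level-set polygons on the interpolated grid, at half the maximum value
#' (excitatory HUs) or half the minimum value (inhibitory HUs).
#'
#' @param disp Display STRF matrix (`F x H`, original resolution).
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param factor Interpolation factor. Default 8.
#' @return Tibble with columns `contour`, `level`, `time`, `freq` (in
#'   interpolated bin units), empty for a flat STRF.
#' @export
strf_contours <- function(disp, kind = c("excitatory", "inhibitory"), factor = 8) {
  kind <- match.arg(kind)
  m <- interpolate_strf(disp, factor)
  if (max(m) == min(m)) {
    return(tibble(contour = integer(), level = numeric(),
                  time = numeric(), freq = numeric()))
  }
  level <- if (kind == "excitatory") 0.5 * max(m) else 0.5 * min(m)
  cl <- grDevices::contourLines(
    x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m), levels = level
  )
  if (length(cl) == 0) {
    return(tibble(contour = integer(), level = numeric(),
                  time = numeric(), freq = numeric()))
  }
  dplyr::bind_rows(lapply(seq_along(cl), function(i) {
    tibble(contour = i, level = cl[[i]]$level, time = cl[[i]]$x, freq = cl[[i]]$y)
  }))
}
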