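#' @export
tidy.strf <- function(x, ...) {
  tibble(
    freq_bin = rep(seq_len(nrow(x$w)), ncol(x$w)),
    lag_bin = rep(seq_len(ncol(x$w)), each = nrow(x$w)),
    weight = as.numeric(x$w)
  )
}

#' @export
glance.strf <- function(x, ...) {
  tibble(
    n_weights = length(x$w),
    n_nonzero = sum(x$w != 0),
    bias = x$b,
    lambda = x$lambda
  )
}

#' @export
tidy.ln_fit <- function(x, ...) tidy(x$strf, ...)

#' @export
glance.ln_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$strf),
    tibble(rho1 = x$sigmoid$rho1, rho2 = x$sigmoid$rho2,
           rho3 = x$sigmoid$rho3, rho4 = x$sigmoid$rho4,
           sigmoid_sse = x$sigmoid$sse)
  )
}

#' @export
tidy.nrf_fit <- function(x, ...) tidy(x$params, ...)

#' @export
tidy.nrf_params <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(x$J), function(j) {
    tibble(
      hu = j,
      freq_bin = rep(seq_len(x$F), x$H),
      lag_bin = rep(seq_len(x$H), each = x$F),
      weight = x$W[j, ],
      w_out = x$w_out[j],
      b_hidden = x$b_hidden[j]
    )
  }))
}

#' @export
glance.nrf_fit <- function(x, ...) {
  tibble(
    J = x$params$J,
    lambda = x$lambda,
    objective = tail(x$trace, 1),
    checkpoints = length(x$trace),
    n_nonzero_hidden = sum(x$params$W != 0),
    n_nonzero_output = sum(x$params$w_out != 0),
    seed = x$hyper$seed
  )
}

#' @export
tidy.cv_result <- function(x, ...) x$table

#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    model_kind = x$model_kind,
    best_lambda = x$best_lambda,
    best_mean_cc_norm = max(x$mean_cc$mean_cc_norm),
    grid_size = nrow(x$mean_cc)
  )
}

#' @export
autoplot.cochleagram <- function(object, ...) {
  df <- tibble(
    time_bin = rep(seq_len(nrow(object)), ncol(object)),
    channel = rep(seq_len(ncol(object)), each = nrow(object)),
    log_power = as.numeric(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_bin, .data$channel,
                                   fill = .data$log_power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time bin", y = "frequency channel",
                  fill = "log power",
                  title = attr(object, "clip_id") %||% NULL)
}

#' @export
autoplot.strf <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$weight), .Machine$double.eps)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_bin, .data$freq_bin,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim)) +
    ggplot2::labs(x = "history bin", y = "frequency channel", fill = "weight")
}

#' @export
autoplot.ln_fit <- function(object, ...) autoplot(object$strf, ...)

#' Plot the (adjusted) hidden-unit display STRFs of an NRF
#'
#' @param object An `nrf_fit`, `nrf_params` or `adjusted_nrf`.
#' @param data Optional stimulus set; when given, only effective HUs are
#'   shown and panels are labeled by kind and variance fraction.
#' @param ... Unused.
#' @export
autoplot.nrf_fit <- function(object, data = NULL, ...) {
  adj <- adjust_network(object)
  p <- adj$params
  show <- seq_len(p$J)
  kind <- ifelse(p$w_out >= 0, "excitatory", "inhibitory")
  label <- paste0("HU ", show)
  if (!is.null(data)) {
    prof <- effective_hus(adj, data)
    show <- prof$hu[prof$effective]
    kind <- prof$kind
    label <- sprintf("HU %d (%s, %.0f%%)", prof$hu, prof$kind,
                     100 * prof$variance_fraction)
  }
  df <- dplyr::bind_rows(lapply(show, function(j) {
    d <- display_strf(hu_strf(p, j), kind[j])
    tibble(
      hu = label[j],
      freq_bin = rep(seq_len(p$F), p$H),
      lag_bin = rep(seq_len(p$H), each = p$F),
      weight = as.numeric(d)
    )
  }))
  lim <- max(abs(df$weight), .Machine$double.eps)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_bin, .data$freq_bin,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim)) +
    ggplot2::facet_wrap(~hu) +
    ggplot2::labs(x = "history bin", y = "frequency channel", fill = "weight")
}

#' @export
autoplot.nrf_params <- autoplot.nrf_fit

#' @export
autoplot.adjusted_nrf <- autoplot.nrf_fit

#' @export
autoplot.gain_curves <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$exc_norm, .data$rate,
                               color = .data$inh_norm,
                               group = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_gradient(low = "red", high = "magenta") +
    ggplot2::labs(x = "normalized excitatory HU activation",
                  y = "output rate (spike counts per bin)",
                  color = "inhibitory\nactivation")
}
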