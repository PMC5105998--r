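#' Fit the L1-regularized linear STRF stage (LASSO)
#'
#' Minimizes `0.5 * sum((y - b - X w)^2) + lambda * sum(|w|)` with the bias
#' unpenalized, via coordinate-descent LASSO (glmnet) with the penalty
#' rescaled to this objective.
#'
#' @param data An `nrf_data` (from [build_design()]) or a plain design matrix.
#' @param y Response vector (ignored when `data` is an `nrf_data` carrying
#'   its own `y`).
#' @param lambda Non-negative L1 penalty weight on the unnormalized objective.
#' @return An `strf`: list with `w` (`F x H` matrix), `b`, `lambda`, `F`, `H`.
#' @export
fit_linear_lasso <- function(data, y = NULL, lambda = 0) {
  if (lambda < 0) abort("lambda must be non-negative")
  X <- if (inherits(data, "nrf_data")) data$X else data
  y <- if (inherits(data, "nrf_data") && !is.null(data$y)) data$y else y
  if (is.null(y)) abort("response y is required")
  if (nrow(X) != length(y)) abort("design and response lengths are misaligned")
  N <- nrow(X)

  if (lambda == 0 || sd(y) == 0) {
    if (sd(y) == 0) {
      w <- rep(0, ncol(X)); b <- mean(y)
    } else {
      fit <- stats::lm.fit(cbind(1, X), y)
      b <- fit$coefficients[1]
      w <- fit$coefficients[-1]
      w[is.na(w)] <- 0
    }
  } else {
    lam_g <- lambda / N
    lam_max <- max(abs(crossprod(X, y - mean(y)))) / N
    path <- if (lam_g >= lam_max) {
      lam_g
    } else {
      unique(sort(c(exp(seq(log(lam_max), log(lam_g), length.out = 25)), lam_g),
                  decreasing = TRUE))
    }
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1, lambda = path,
                          standardize = FALSE, intercept = TRUE, thresh = 1e-12,
                          maxit = 1e6)
    # lam_g is in the fitted path exactly; pick its column directly
    k <- which.min(abs(fit$lambda - lam_g))
    b <- fit$a0[k]
    w <- as.numeric(fit$beta[, k])
  }

  F_ <- if (inherits(data, "nrf_data")) data$F else NA_integer_
  H <- if (inherits(data, "nrf_data")) data$H else NA_integer_
  wm <- if (!is.na(F_)) matrix(w, nrow = F_, ncol = H) else matrix(w, ncol = 1)
  structure(
    list(w = wm, b = unname(b), lambda = lambda, F = F_, H = H),
    class = "strf"
  )
}

#' Linear activation of an STRF (the L-model prediction)
#'
#' `a(t) = sum_{f,tau} w[f,tau] * x[f,tau](t) + b`.
#'
#' @param strf An `strf`.
#' @param data An `nrf_data`, `lagged_stimulus`, or design matrix.
#' @return Activation vector `a(t)`.
#' @export
predict_linear <- function(strf, data) {
  X <- design_matrix(data)
  if (ncol(X) != length(strf$w)) abort("dimension mismatch between STRF and stimulus")
  as.numeric(X %*% as.numeric(strf$w)) + strf$b
}

design_matrix <- function(data) {
  if (inherits(data, "nrf_data") || inherits(data, "lagged_stimulus")) data$X
  else as.matrix(data)
}

sigmoid_curve <- function(a, p) {
  p[1] * stats::plogis((a - p[3]) / p[2]) + p[4]
}

#' Fit the 4-parameter logistic output nonlinearity
#'
#' Fits `y_hat = rho1 / (1 + exp(-(a - rho3)/rho2)) + rho4` to minimize the
#' squared error, by quasi-Newton minimization from multiple starts
#' (`rho1 = range(y)`, `rho4 = min(y)`, `rho3 = median(a)`,
#' `rho2 in {+-sd(a), +-sd(a)/4}`), keeping the best. `rho1` is constrained
#' positive; fits are reported with `rho1 > 0` canonically (a decreasing
#' relationship appears as `rho2 < 0`).
#'
#' @param a Linear activation vector.
#' @param y Target response vector (spike-count scale), non-constant.
#' @return A `sigmoid_params`: list with `rho1`, `rho2`, `rho3`, `rho4`, `sse`.
#' @export
fit_output_sigmoid <- function(a, y) {
  if (length(a) != length(y)) abort("length mismatch")
  if (sd(y) == 0) abort("constant target: sigmoid fit is degenerate")
  sse <- function(p) {
    r <- sigmoid_curve(a, p) - y
    sum(r * r)
  }
  sda <- max(sd(a), .Machine$double.eps)
  starts <- lapply(c(sda, -sda, sda / 4, -sda / 4), function(r2) {
    c(diff(range(y)), r2, median(a), min(y))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, sse, method = "L-BFGS-B",
            lower = c(1e-8, -Inf, -Inf, -Inf),
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("sigmoid fit failed from every start")
  # never worse than the best initialization itself
  p0_best <- starts[[which.min(vapply(starts, sse, numeric(1)))]]
  if (sse(p0_best) < best$value) best <- list(par = p0_best, value = sse(p0_best))
  p <- best$par
  structure(
    list(rho1 = p[1], rho2 = p[2], rho3 = p[3], rho4 = p[4], sse = best$value),
    class = "sigmoid_params"
  )
}

#' Predict with a fitted sigmoid nonlinearity
#'
#' @param sig A `sigmoid_params`.
#' @param a Activation vector.
#' @return Predicted response, bounded in `(rho4, rho4 + rho1)`.
#' @export
predict_sigmoid <- function(sig, a) {
  sigmoid_curve(a, c(sig$rho1, sig$rho2, sig$rho3, sig$rho4))
}

#' Fit the full LN model (LASSO STRF + logistic output nonlinearity)
#'
#' @param data An `nrf_data` with response `y` on the spike-count scale.
#' @param lambda L1 penalty for the linear stage.
#' @return An `ln_fit`: list with `strf`, `sigmoid`, `lambda`.
#' @export
fit_ln <- function(data, lambda = 0) {
  strf <- fit_linear_lasso(data, lambda = lambda)
  a <- predict_linear(strf, data)
  sig <- if (sd(a) == 0) {
    # fully shrunk linear stage: constant prediction at the mean
    structure(list(rho1 = max(diff(range(data$y)), 1e-8), rho2 = 1,
                   rho3 = 0, rho4 = mean(data$y) - max(diff(range(data$y)), 1e-8) / 2,
                   sse = sum((mean(data$y) - data$y)^2)),
              class = "sigmoid_params")
  } else {
    fit_output_sigmoid(a, data$y)
  }
  structure(list(strf = strf, sigmoid = sig, lambda = lambda), class = "ln_fit")
}

#' Predict responses with a fitted LN model
#'
#' @param ln An `ln_fit`.
#' @param data Stimulus data (`nrf_data`, `lagged_stimulus`, or matrix).
#' @return Predicted response vector (spike-count scale).
#' @export
predict_ln <- function(ln, data) {
  predict_sigmoid(ln$sigmoid, predict_linear(ln$strf, data))
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("<strf: %d x %d weights (%d nonzero), b = %.4g, lambda = %.4g>\n",
              nrow(x$w), ncol(x$w), sum(x$w != 0), x$b, x$lambda))
  invisible(x)
}

#' @export
print.ln_fit <- function(x, ...) {
  print(x$strf)
  s <- x$sigmoid
  cat(sprintf("  sigmoid: rho1 = %.4g, rho2 = %.4g, rho3 = %.4g, rho4 = %.4g\n",
              s$rho1, s$rho2, s$rho3, s$rho4))
  invisible(x)
}
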