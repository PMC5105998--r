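#' Network activation function
#'
#' `g(zeta) = rho1 * tanh(zeta / rho2)`, an odd sigmoid with range
#' `(-rho1, rho1)`. With the fixed constants `rho1 = 1/tanh(2/3)` (~1.7159)
#' and `rho2 = 3/2`, `g(1) = 1` and `g(-1) = -1`.
#'
#' @param zeta Activation (any numeric shape).
#' @param rho1,rho2 Shape constants.
#' @return Unit output, same shape as `zeta`.
#' @export
activation_g <- function(zeta, rho1 = NRF_RHO1, rho2 = NRF_RHO2) {
  rho1 * tanh(zeta / rho2)
}

#' Derivative of the network activation function
#'
#' @inheritParams activation_g
#' @return `g'(zeta) = (rho1 / rho2) * (1 - tanh(zeta / rho2)^2)`.
#' @export
activation_g_prime <- function(zeta, rho1 = NRF_RHO1, rho2 = NRF_RHO2) {
  (rho1 / rho2) * (1 - tanh(zeta / rho2)^2)
}

#' Hyperparameters for NRF fitting
#'
#' @param J Number of hidden units. Default 20.
#' @param lambda L1 penalty weight on all connection weights (hidden and
#'   output; biases unpenalized).
#' @param max_iter Outer optimizer iterations (checkpoints). Default 40.
#' @param inner_steps Proximal gradient steps per outer iteration. Default 15.
#' @param warmup_steps Unpenalized gradient steps run from the random
#'   initialization before the L1 proximal phase, letting the near-zero
#'   initial weights grow toward the signal (the all-zero configuration is a
#'   fixed point of the soft-thresholding step). Default 30.
#' @param tol Relative objective-change convergence tolerance across an outer
#'   iteration. Default 1e-6.
#' @param seed RNG seed for initialization.
#' @param rho1,rho2 Activation constants (fixed; see [activation_g()]).
#' @return An `nrf_hyper` list.
#' @export
nrf_hyper <- function(J = 20, lambda = 0, max_iter = 40, inner_steps = 15,
                      warmup_steps = 30, tol = 1e-6, seed = 1,
                      rho1 = NRF_RHO1, rho2 = NRF_RHO2) {
  if (J < 1) abort("J must be >= 1")
  if (lambda < 0) abort("lambda must be non-negative")
  structure(
    list(J = J, lambda = lambda, max_iter = max_iter, inner_steps = inner_steps,
         warmup_steps = warmup_steps, tol = tol, seed = seed,
         rho1 = rho1, rho2 = rho2),
    class = "nrf_hyper"
  )
}

#' Initialize NRF parameters
#'
#' Weights and biases drawn independently from a uniform distribution on
#' `(-1/M, +1/M)`, where `M` is the number of incoming connection weights and
#' biases to the unit (`F*H + 1` for a hidden unit, `J + 1` for the output
#' unit).
#'
#' @param hyper An `nrf_hyper`.
#' @param F Number of frequency channels.
#' @param H Number of history bins.
#' @return An `nrf_params`: list with `W` (`J x (F*H)` hidden weights),
#'   `b_hidden` (J), `w_out` (J), `b_out`, `F`, `H`, `J`, `rho1`, `rho2`.
#' @export
init_params <- function(hyper, F, H) {
  J <- hyper$J
  P <- F * H
  m_h <- P + 1
  m_o <- J + 1
  with_seed(hyper$seed, {
    W <- matrix(runif(J * P, -1 / m_h, 1 / m_h), J, P)
    b_hidden <- runif(J, -1 / m_h, 1 / m_h)
    w_out <- runif(J, -1 / m_o, 1 / m_o)
    b_out <- runif(1, -1 / m_o, 1 / m_o)
    nrf_params(W, b_hidden, w_out, b_out, F, H, hyper$rho1, hyper$rho2)
  })
}

#' Construct an NRF parameter object
#'
#' @param W `J x (F*H)` hidden weight matrix (rows are hidden-unit STRFs,
#'   column index `(tau - 1) * F + f`).
#' @param b_hidden Hidden biases (length J).
#' @param w_out Output weights (length J).
#' @param b_out Output bias (scalar).
#' @param F,H Stimulus dimensions.
#' @param rho1,rho2 Activation constants.
#' @return An `nrf_params`.
#' @export
nrf_params <- function(W, b_hidden, w_out, b_out, F, H,
                       rho1 = NRF_RHO1, rho2 = NRF_RHO2) {
  stopifnot(nrow(W) == length(b_hidden), length(w_out) == length(b_hidden))
  structure(
    list(W = W, b_hidden = as.numeric(b_hidden), w_out = as.numeric(w_out),
         b_out = as.numeric(b_out), F = F, H = H, J = nrow(W),
         rho1 = rho1, rho2 = rho2),
    class = "nrf_params"
  )
}

#' Forward pass of the NRF
#'
#' `a_j(t) = sum_{f,tau} w_jfτ x_fτ(t) + b_j`; `z_j = g(a_j)`;
#' `a_o = sum_j w_j z_j + b_o`; `y_hat = g(a_o)` (rescaled units).
#'
#' @param params An `nrf_params`.
#' @param data Stimulus (`nrf_data`, `lagged_stimulus`, or design matrix).
#' @return A `forward_trace`: list with `a_hidden` (`T x J`), `z_hidden`
#'   (`T x J`), `a_out` (T), `y_hat` (T).
#' @export
nrf_forward <- function(params, data) {
  X <- design_matrix(data)
  if (ncol(X) != ncol(params$W)) abort("dimension mismatch between params and stimulus")
  A <- sweep(X %*% t(params$W), 2, params$b_hidden, `+`)
  Z <- activation_g(A, params$rho1, params$rho2)
  a_out <- as.numeric(Z %*% params$w_out) + params$b_out
  structure(
    list(a_hidden = A, z_hidden = Z, a_out = a_out,
         y_hat = activation_g(a_out, params$rho1, params$rho2)),
    class = "forward_trace"
  )
}

#' NRF training objective
#'
#' `E = 0.5 * sum_t (y_hat - y)^2 + lambda * (sum |w_jfτ| + sum |w_j|)`;
#' biases are unpenalized.
#'
#' @param params An `nrf_params`.
#' @param data Stimulus data.
#' @param y_rescaled Target on the rescaled (`+-sigma1`) scale.
#' @param lambda Penalty weight.
#' @return Scalar objective value.
#' @export
nrf_objective <- function(params, data, y_rescaled, lambda = 0) {
  tr <- nrf_forward(params, data)
  0.5 * sum((tr$y_hat - y_rescaled)^2) +
    lambda * (sum(abs(params$W)) + sum(abs(params$w_out)))
}

# Forward pass caching everything the gradient needs; f is the smooth loss.
nrf_smooth_forward <- function(params, X, y_rescaled) {
  A <- sweep(X %*% t(params$W), 2, params$b_hidden, `+`)
  Z <- activation_g(A, params$rho1, params$rho2)
  a_out <- as.numeric(Z %*% params$w_out) + params$b_out
  y_hat <- activation_g(a_out, params$rho1, params$rho2)
  e <- y_hat - y_rescaled
  list(A = A, Z = Z, a_out = a_out, e = e, f = 0.5 * sum(e * e))
}

# Backpropagated gradient of the smooth loss from a cached forward pass.
nrf_grad_from_cache <- function(params, X, cache) {
  d_o <- cache$e * activation_g_prime(cache$a_out, params$rho1, params$rho2)
  D <- (d_o %*% t(params$w_out)) *
    activation_g_prime(cache$A, params$rho1, params$rho2)
  list(
    W = crossprod(D, X), # J x P, matching the layout of params$W
    b_hidden = colSums(D),
    w_out = as.numeric(crossprod(cache$Z, d_o)),
    b_out = sum(d_o)
  )
}

# Smooth part of the objective and its analytic gradient (backpropagation).
nrf_smooth_grad <- function(params, X, y_rescaled) {
  cache <- nrf_smooth_forward(params, X, y_rescaled)
  list(f = cache$f, g = nrf_grad_from_cache(params, X, cache))
}

pack_params <- function(p) c(as.numeric(p$W), p$b_hidden, p$w_out, p$b_out)

unpack_params <- function(theta, template) {
  J <- template$J
  P <- ncol(template$W)
  W <- matrix(theta[seq_len(J * P)], J, P)
  i <- J * P
  nrf_params(W, theta[i + seq_len(J)], theta[i + J + seq_len(J)],
             theta[i + 2 * J + 1], template$F, template$H,
             template$rho1, template$rho2)
}

#' Train an NRF by proximal gradient descent
#'
#' Full-batch proximal gradient on the smooth squared-error loss with an
#' exact soft-thresholding step for the L1 weight penalty (biases excluded),
#' Barzilai-Borwein initial step sizes and backtracking line search. The
#' objective is non-increasing across outer checkpoints by construction;
#' training stops early when the relative objective change over an outer
#' iteration falls below `tol`.
#'
#' @param data Stimulus data (`nrf_data` or design matrix).
#' @param y_rescaled Target on the rescaled scale (see [rescale_targets()]).
#' @param hyper An `nrf_hyper`.
#' @param init Optional `nrf_params` to start from (defaults to
#'   [init_params()] under `hyper$seed`).
#' @return An `nrf_params` with attributes `trace` (objective per checkpoint)
#'   and `hyper`.
#' @export
train_nrf <- function(data, y_rescaled, hyper, init = NULL) {
  X <- design_matrix(data)
  if (nrow(X) != length(y_rescaled)) abort("design and target lengths are misaligned")
  F_ <- if (inherits(data, "nrf_data")) data$F else ncol(X)
  H <- if (inherits(data, "nrf_data")) data$H else 1L
  params <- init %||% init_params(hyper, F_, H)
  lambda <- hyper$lambda
  J <- params$J
  P <- ncol(params$W)
  n_w <- J * P # leading weights in the packed vector
  is_weight <- c(rep(TRUE, n_w), rep(FALSE, J), rep(TRUE, J), FALSE)

  theta <- pack_params(params)
  sg <- nrf_smooth_grad(params, X, y_rescaled)
  if (!is.finite(sg$f)) abort("non-finite objective at initialization")
  E_init <- sg$f + lambda * sum(abs(theta[is_weight]))
  theta_init <- theta

  state <- list(
    theta = theta, sg = sg,
    step = 1 / max(1, sqrt(sum(pack_params(sg$g)^2))),
    prev_theta = NULL, prev_grad = NULL
  )

  # One block of monotone proximal gradient steps at penalty lam.
  prox_block <- function(state, lam, n_steps) {
    for (inner in seq_len(n_steps)) {
      gvec <- pack_params(state$sg$g)
      # Barzilai-Borwein step from the previous accepted move
      if (!is.null(state$prev_theta)) {
        dth <- state$theta - state$prev_theta
        dg <- gvec - state$prev_grad
        denom <- sum(dth * dg)
        if (is.finite(denom) && denom > 0) {
          state$step <- min(max(sum(dth * dth) / denom, 1e-12), 1e6)
        }
      }
      E_cur <- state$sg$f + lam * sum(abs(state$theta[is_weight]))
      accepted <- FALSE
      for (bt in seq_len(60)) {
        cand <- state$theta - state$step * gvec
        if (lam > 0) {
          cand[is_weight] <- soft_threshold(cand[is_weight], state$step * lam)
        }
        d <- cand - state$theta
        cand_params <- unpack_params(cand, params)
        cache <- nrf_smooth_forward(cand_params, X, y_rescaled)
        ok <- is.finite(cache$f) &&
          cache$f <= state$sg$f + sum(gvec * d) + sum(d * d) / (2 * state$step)
        E_cand <- cache$f + lam * sum(abs(cand[is_weight]))
        if (ok && E_cand <= E_cur + 1e-12) {
          state$prev_theta <- state$theta
          state$prev_grad <- gvec
          state$theta <- cand
          state$sg <- list(f = cache$f,
                           g = nrf_grad_from_cache(cand_params, X, cache))
          accepted <- TRUE
          break
        }
        state$step <- state$step / 2
      }
      if (!accepted) break
    }
    state
  }

  # Unpenalized warm-up from the near-zero random initialization (the
  # all-zero weight configuration is a fixed point of the proximal step).
  if (is.null(init) && lambda > 0 && hyper$warmup_steps > 0) {
    state <- prox_block(state, 0, hyper$warmup_steps)
    state$prev_theta <- NULL
    state$prev_grad <- NULL
  }

  E <- state$sg$f + lambda * sum(abs(state$theta[is_weight]))
  trace <- E
  for (outer in seq_len(hyper$max_iter)) {
    E_start <- E
    state <- prox_block(state, lambda, hyper$inner_steps)
    E <- state$sg$f + lambda * sum(abs(state$theta[is_weight]))
    trace <- c(trace, E)
    if (!is.finite(E)) abort("training diverged: non-finite objective")
    if (abs(E_start - E) <= hyper$tol * max(abs(E_start), 1e-12)) break
  }

  # contract: never return anything worse than the initialization
  theta <- if (E <= E_init) state$theta else theta_init
  out <- unpack_params(theta, params)
  attr(out, "trace") <- trace
  attr(out, "hyper") <- hyper
  out
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit an NRF to spike-count data
#'
#' Convenience wrapper: rescales the spike-count target to the network scale,
#' trains by [train_nrf()], and returns a fit whose predictions can be mapped
#' back to spike counts with [predict_nrf()].
#'
#' @param data An `nrf_data` with response `y` on the spike-count scale.
#' @param lambda L1 penalty weight.
#' @param J Hidden units. Default 20.
#' @param seed Initialization seed.
#' @param init Optional `nrf_params` to warm-start from.
#' @param ... Further arguments to [nrf_hyper()].
#' @return An `nrf_fit`: list with `params`, `hyper`, `trace`.
#' @export
fit_nrf <- function(data, lambda = 0, J = 20, seed = 1, init = NULL, ...) {
  hyper <- nrf_hyper(J = J, lambda = lambda, seed = seed, ...)
  params <- train_nrf(data, rescale_targets(data$y), hyper, init = init)
  structure(
    list(params = params, hyper = hyper, trace = attr(params, "trace"),
         lambda = lambda),
    class = "nrf_fit"
  )
}

#' Predict responses with a fitted NRF
#'
#' @param fit An `nrf_fit` (or `nrf_params`).
#' @param data Stimulus data.
#' @param scale `"count"` (default) to map the network output back to the
#'   spike-count scale, or `"rescaled"` for raw network output.
#' @return Predicted response vector.
#' @export
predict_nrf <- function(fit, data, scale = c("count", "rescaled")) {
  scale <- match.arg(scale)
  params <- if (inherits(fit, "nrf_fit")) fit$params else fit
  y_hat <- nrf_forward(params, data)$y_hat
  if (scale == "count") unrescale_targets(y_hat) else y_hat
}

#' Report pruned (effectively zero) weights
#'
#' @param params An `nrf_params`.
#' @param tol Magnitude below which a weight counts as pruned. Default 1e-8.
#' @return Tibble with per-unit counts of pruned hidden weights and whether
#'   the output weight is pruned.
#' @export
pruned_weights <- function(params, tol = 1e-8) {
  tibble(
    hu = seq_len(params$J),
    n_hidden_weights = ncol(params$W),
    n_pruned_hidden = rowSums(abs(params$W) < tol),
    output_weight_pruned = abs(params$w_out) < tol
  )
}

#' @export
print.nrf_params <- function(x, ...) {
  cat(sprintf(
    "<nrf_params: J = %d hidden units, F = %s, H = %s, %d/%d nonzero hidden weights>\n",
    x$J, x$F, x$H, sum(x$W != 0), length(x$W)
  ))
  invisible(x)
}

#' @export
print.nrf_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  lambda = %.4g, final objective = %.6g (%d checkpoints)\n",
              x$lambda, tail(x$trace, 1), length(x$trace)))
  invisible(x)
}
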