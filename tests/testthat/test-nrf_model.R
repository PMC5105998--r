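test_that("the activation function honors its fixed-point constants", {
  expect_equal(activation_g(1), 1, tolerance = 1e-12)
  expect_equal(activation_g(-1), -1, tolerance = 1e-12)
  expect_equal(activation_g(0), 0)
  expect_equal(activation_g(1e6), 1 / tanh(2 / 3), tolerance = 1e-12)
  expect_equal(round(1 / tanh(2 / 3), 4), 1.7159)
  # odd function
  z <- seq(-4, 4, by = 0.37)
  expect_equal(activation_g(-z), -activation_g(z), tolerance = 1e-14)
})

test_that("the forward pass matches a naive nested-loop oracle", {
  p <- random_nrf(J = 3, F = 4, H = 2, seed = 2)
  X <- random_design(T = 25, F = 4, H = 2, seed = 3)
  tr <- nrf_forward(p, X)
  for (t in c(1, 10, 25)) {
    for (j in 1:3) {
      a <- p$b_hidden[j]
      for (f in 1:4) for (tau in 1:2) {
        a <- a + matrix(p$W[j, ], 4, 2)[f, tau] * X[t, (tau - 1) * 4 + f]
      }
      expect_equal(tr$a_hidden[t, j], a, tolerance = 1e-12)
    }
    ao <- sum(p$w_out * p$rho1 * tanh(tr$a_hidden[t, ] / p$rho2)) + p$b_out
    expect_equal(tr$a_out[t], ao, tolerance = 1e-12)
    expect_equal(tr$y_hat[t], p$rho1 * tanh(ao / p$rho2), tolerance = 1e-12)
  }
})

test_that("an all-zero-weight network predicts the constant g(b_o)", {
  p <- nrf_params(matrix(0, 2, 8), c(0, 0), c(0, 0), 0.4, 4, 2)
  tr <- nrf_forward(p, random_design(T = 10, F = 4, H = 2))
  expect_equal(tr$y_hat, rep(activation_g(0.4), 10))
})

test_that("tiny inputs put a 1-HU network in its linear regime (Taylor)", {
  F <- 3; H <- 2
  w <- rnorm(F * H)
  p <- nrf_params(matrix(w, 1), 0, 1, 0, F, H)
  X <- matrix(rnorm(50 * F * H), 50) * 1e-5
  a1 <- as.numeric(X %*% w)
  tr <- nrf_forward(p, X)
  # y_hat ~ (rho1/rho2)^2 * a_1 to first order
  expect_equal(tr$y_hat, (NRF_RHO1 / NRF_RHO2)^2 * a1, tolerance = 1e-6)
})

test_that("outputs are bounded by rho1", {
  p <- random_nrf(J = 5, F = 4, H = 3, seed = 4)
  X <- random_design(T = 200, F = 4, H = 3, seed = 5) * 10
  tr <- nrf_forward(p, X)
  expect_true(all(abs(tr$z_hidden) <= NRF_RHO1))
  expect_true(all(abs(tr$y_hat) <= NRF_RHO1))
  expect_true(all(abs(nrf_forward(p, X / 20)$y_hat) < NRF_RHO1))
})

test_that("the objective matches a hand computation on a 2-bin toy", {
  p <- nrf_params(matrix(c(0.5, -0.25), 1), 0.1, 2, -0.3, 2, 1)
  X <- matrix(c(1, 0.5, -1, 2), 2, 2, byrow = TRUE)
  y <- c(0.2, -0.4)
  lambda <- 0.7
  a <- c(1 * 0.5 + 0.5 * -0.25 + 0.1, -1 * 0.5 + 2 * -0.25 + 0.1)
  z <- NRF_RHO1 * tanh(a / NRF_RHO2)
  yh <- NRF_RHO1 * tanh((2 * z - 0.3) / NRF_RHO2)
  expected <- 0.5 * sum((yh - y)^2) + lambda * (0.5 + 0.25 + 2)
  expect_equal(nrf_objective(p, X, y, lambda), expected, tolerance = 1e-12)
  # perfect prediction, lambda = 0 -> E = 0
  expect_equal(nrf_objective(p, X, yh, 0), 0)
  # adding delta to a zero weight raises the penalty by lambda * |delta|
  p2 <- p; p2$w_out <- c(2)
  W3 <- rbind(p$W, 0); p3 <- nrf_params(W3, c(0.1, 0), c(2, 0), -0.3, 2, 1)
  p4 <- p3; p4$W[2, 1] <- 1e-6
  expect_equal(nrf_objective(p4, X, y, lambda) - nrf_objective(p3, X, y, lambda),
               lambda * 1e-6, tolerance = 1e-8)
})

test_that("initialization bounds scale with unit fan-in and are reproducible", {
  hy <- nrf_hyper(J = 20, seed = 7)
  p <- init_params(hy, 34, 20)
  expect_true(all(abs(p$W) <= 1 / 681))
  expect_true(all(abs(p$b_hidden) <= 1 / 681))
  expect_true(all(abs(p$w_out) <= 1 / 21))
  expect_true(abs(p$b_out) <= 1 / 21)
  p2 <- init_params(hy, 34, 20)
  expect_identical(p, p2)
  p3 <- init_params(nrf_hyper(J = 20, seed = 8), 34, 20)
  expect_false(identical(p$W, p3$W))
})

test_that("negating a hidden unit's triplet leaves predictions unchanged", {
  p <- random_nrf(J = 4, F = 5, H = 3, seed = 9)
  X <- random_design(T = 80, F = 5, H = 3, seed = 10)
  base <- nrf_forward(p, X)$y_hat
  for (j in 1:4) {
    q <- p
    q$W[j, ] <- -q$W[j, ]
    q$b_hidden[j] <- -q$b_hidden[j]
    q$w_out[j] <- -q$w_out[j]
    expect_equal(nrf_forward(q, X)$y_hat, base, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  p <- random_nrf(J = 3, F = 3, H = 2, seed = 11)
  X <- random_design(T = 30, F = 3, H = 2, seed = 12)
  y <- rnorm(30)
  sg <- nrfkit:::nrf_smooth_grad(p, X, y)
  th <- nrfkit:::pack_params(p)
  g_num <- vapply(seq_along(th), function(i) {
    e <- 1e-6
    tp <- th; tp[i] <- tp[i] + e
    tm <- th; tm[i] <- tm[i] - e
    (nrfkit:::nrf_smooth_grad(nrfkit:::unpack_params(tp, p), X, y)$f -
       nrfkit:::nrf_smooth_grad(nrfkit:::unpack_params(tm, p), X, y)$f) / (2 * e)
  }, numeric(1))
  ga <- nrfkit:::pack_params(sg$g)
  expect_lt(max(abs(ga - g_num)) / max(abs(g_num)), 1e-5)
})

test_that("training decreases the objective monotonically and is seeded", {
  set.seed(13)
  F <- 4; H <- 3; T <- 200
  X <- matrix(rnorm(T * F * H), T, F * H)
  w <- as.numeric(gabor_strf(F, H, 2, 2))
  y <- activation_g(1.2 * activation_g(as.numeric(X %*% w)) - 0.8)
  hy <- nrf_hyper(J = 4, lambda = 0.3, seed = 14, max_iter = 15)
  fit <- train_nrf(X, y, hy)
  tr <- attr(fit, "trace")
  expect_true(all(diff(tr) <= 1e-9))
  fit2 <- train_nrf(X, y, hy)
  expect_identical(fit$W, fit2$W)
  expect_identical(attr(fit, "trace"), attr(fit2, "trace"))
})

test_that("a dominating penalty prunes the whole network", {
  set.seed(15)
  X <- matrix(rnorm(150 * 12), 150, 12)
  y <- rnorm(150, sd = 0.1)
  hy <- nrf_hyper(J = 3, lambda = 1e5, seed = 16, max_iter = 10)
  fit <- train_nrf(X, y, hy)
  expect_true(all(abs(fit$W) < 1e-3))
  expect_true(all(abs(fit$w_out) < 1e-3))
  pred <- nrf_forward(fit, X)$y_hat
  expect_lt(sd(pred), 1e-3)
  pr <- pruned_weights(fit)
  expect_true(all(pr$n_pruned_hidden == ncol(fit$W)))
})

test_that("effective HU count does not grow with the penalty", {
  set.seed(17)
  ex <- bifeature_experiment()
  rows <- seq_len(500)
  d <- nrfkit:::subset_data(ex$data, seq_len(nrow(ex$data$X)) %in% rows)
  lams <- c(0.5, 5, 50)
  counts <- vapply(lams, function(l) {
    fit <- fit_nrf(d, lambda = l, J = 6, seed = 18, max_iter = 20)
    prof <- suppressWarnings(effective_hus(fit, d))
    sum(prof$effective & prof$variance > 1e-12)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
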