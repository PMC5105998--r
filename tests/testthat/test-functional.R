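# A hand-built bi-feature network with well-separated Gabor sub-fields.
bifeature_toy <- function(w_inh = -0.7, F = 8, H = 6) {
  e <- gabor_strf(F, H, 3, 2, bw = 1.2, dur = 1)
  i <- gabor_strf(F, H, 6, 4, bw = 1.2, dur = 1)
  e <- e / sqrt(sum(e^2)) * 1.5
  i <- i / sqrt(sum(i^2)) * 1.5
  nrf_params(rbind(as.numeric(e), as.numeric(i)), c(0, 0), c(0.9, w_inh),
             -1.6, F, H)
}

toy_stim <- function(F = 8, H = 6, T = 600, seed = 61) {
  set.seed(seed)
  structure(list(X = matrix(rnorm(T * F * H), T), y = NULL,
                 index = tibble::tibble(clip = 1, bin = seq_len(T)),
                 F = F, H = H, discard_bins = 0),
            class = "nrf_data")
}

test_that("inhibition reduces the gain of the excitatory drive", {
  p <- bifeature_toy()
  d <- toy_stim()
  gc <- gain_analysis(p, d)
  expect_equal(nrow(gc$gains), 7)
  expect_equal(gc$gains$gain_norm[1], 1)
  # gain at the highest inhibitory level is below the lowest level
  expect_lt(gc$gains$gain_norm[7], gc$gains$gain_norm[1])
  # curves are monotone non-decreasing in excitatory activation
  by_level <- split(gc$curves$rate, gc$curves$level)
  for (r in by_level) expect_true(all(diff(r) >= -1e-12))
})

test_that("a zero inhibitory output weight leaves every gain curve identical", {
  p <- bifeature_toy(w_inh = 0)
  d <- toy_stim(seed = 62)
  gc <- gain_analysis(p, d, exc_hu = 1, inh_hu = 2)
  m <- matrix(gc$curves$rate, ncol = 7)
  for (l in 2:7) expect_equal(m[, l], m[, 1], tolerance = 1e-12)
  expect_equal(gc$gains$gain_norm, rep(1, 7), tolerance = 1e-12)
})

test_that("a linear output unit turns inhibition purely subtractive", {
  p <- bifeature_toy()
  d <- toy_stim(seed = 63)
  gc <- gain_analysis(p, d, ou = "linear")
  # slopes identical across inhibitory levels: only the offset shifts
  expect_equal(gc$gains$gain_norm, rep(1, 7), tolerance = 1e-10)
  m <- matrix(gc$curves$rate, ncol = 7)
  offsets <- m[1, ] - m[1, 1]
  for (l in 2:7) {
    expect_equal(m[, l], m[, 1] + offsets[l], tolerance = 1e-10)
  }
})

test_that("gain analysis rejects non-bi-feature networks", {
  F <- 8; H <- 6
  e1 <- as.numeric(gabor_strf(F, H, 3, 2, bw = 1.2, dur = 1))
  e2 <- as.numeric(gabor_strf(F, H, 6, 4, bw = 1.2, dur = 1))
  p <- nrf_params(rbind(e1 / sqrt(sum(e1^2)), e2 / sqrt(sum(e2^2))) * 1.5,
                  c(0, 0), c(0.9, 0.9), -1.6, F, H)
  expect_error(gain_analysis(p, toy_stim(seed = 64)), "reduced-NRF")
})

test_that("reduced models clamp the disabled units at threshold", {
  F <- 8; H <- 6
  g1 <- as.numeric(gabor_strf(F, H, 2.5, 2, bw = 1, dur = 1))
  g2 <- as.numeric(gabor_strf(F, H, 5, 3.5, bw = 1, dur = 1))
  g3 <- as.numeric(gabor_strf(F, H, 7, 5, bw = 1, dur = 1))
  norm <- function(v) v / sqrt(sum(v^2)) * 1.5
  p <- nrf_params(rbind(norm(g1), norm(g2), norm(g3)), rep(0, 3),
                  c(0.8, 0.7, 0.6), -1.8, F, H)
  d <- toy_stim(F = F, H = H, T = 500, seed = 65)
  adj <- adjust_network(p)

  # single-excitatory-HU network: reduced model equals the full model
  p1 <- nrf_params(rbind(norm(g1)), 0, 0.8, -1.8, F, H)
  r1 <- reduced_nrf(p1, 1, d)
  expect_equal(predict_reduced(r1, d), predict_nrf(p1, d), tolerance = 1e-12)

  # clamped units contribute the constant -rho1 * w_j (brute-force oracle)
  r <- reduced_nrf(adj, 1, d)
  tr <- nrf_forward(adj$params, d)
  a_oracle <- tr$z_hidden[, 1] * adj$params$w_out[1] +
    (-adj$params$rho1) * (adj$params$w_out[2] + adj$params$w_out[3]) +
    adj$params$b_out
  expect_equal(predict_reduced(r, d, scale = "rescaled"),
               activation_g(a_oracle), tolerance = 1e-12)

  # sum over the three reduced models matches explicit enumeration
  summed <- Reduce(`+`, lapply(1:3, function(j) {
    predict_reduced(reduced_nrf(adj, j, d), d)
  }))
  manual <- Reduce(`+`, lapply(1:3, function(j) {
    Z <- tr$z_hidden
    Z[, setdiff(1:3, j)] <- -adj$params$rho1
    unrescale_targets(activation_g(as.numeric(Z %*% adj$params$w_out) +
                                     adj$params$b_out))
  }))
  expect_equal(summed, manual, tolerance = 1e-12)
})

test_that("peak time ratio counts threshold crossings against the PSTH", {
  F <- 8; H <- 6
  g1 <- as.numeric(gabor_strf(F, H, 2.5, 2, bw = 1, dur = 1))
  g2 <- as.numeric(gabor_strf(F, H, 6, 4, bw = 1, dur = 1))
  norm <- function(v) v / sqrt(sum(v^2)) * 1.6
  p <- nrf_params(rbind(norm(g1), norm(g2)), c(0, 0), c(0.9, 0.9), -2.6, F, H)
  d <- toy_stim(F = F, H = H, T = 800, seed = 66)
  y <- predict_nrf(p, d) # observed = the model's own response (clean case)
  rep_ <- peak_time_ratio(p, d, list(y))

  # oracle: direct bin counting
  thr <- mean(y) + 2 * sqrt(mean((y - mean(y))^2))
  expect_equal(rep_$nrf_peak_time, sum(y >= thr))
  adj <- adjust_network(p)
  summed <- predict_reduced(reduced_nrf(adj, 1, d), d) +
    predict_reduced(reduced_nrf(adj, 2, d), d)
  expect_equal(rep_$summed_reduced_peak_time, sum(summed >= thr))
  expect_equal(rep_$peak_time_ratio,
               rep_$summed_reduced_peak_time / rep_$nrf_peak_time)

  # strongly expansive OU + disjoint features: conjunctive regime
  expect_lt(rep_$peak_time_ratio, 1)

  expect_error(peak_time_ratio(nrf_params(rbind(norm(g1)), 0, 0.9, -2.6, F, H),
                               d, list(y)),
               ">= 2 effective excitatory")
})

test_that("duplicate excitatory units lose half their drive when reduced", {
  F <- 6; H <- 4
  g <- as.numeric(gabor_strf(F, H, 3, 2, bw = 1, dur = 1))
  g <- g / sqrt(sum(g^2)) * 1.5
  p <- nrf_params(rbind(g, g), c(0, 0), c(0.8, 0.8), -2, F, H)
  d <- toy_stim(F = F, H = H, T = 400, seed = 67)
  adj <- adjust_network(p)
  tr <- nrf_forward(adj$params, d)
  r1 <- predict_reduced(reduced_nrf(adj, 1, d), d, scale = "rescaled")
  # analytic toy: one unit live, the twin clamped at -rho1
  a_expect <- 0.8 * tr$z_hidden[, 1] + 0.8 * (-p$rho1) - 2
  expect_equal(r1, activation_g(a_expect), tolerance = 1e-12)
})

test_that("peak time ratio is invariant to clip ordering", {
  F <- 8; H <- 6
  g1 <- as.numeric(gabor_strf(F, H, 2.5, 2, bw = 1, dur = 1))
  g2 <- as.numeric(gabor_strf(F, H, 6, 4, bw = 1, dur = 1))
  norm <- function(v) v / sqrt(sum(v^2)) * 1.6
  p <- nrf_params(rbind(norm(g1), norm(g2)), c(0, 0), c(0.9, 0.9), -2.4, F, H)
  set.seed(68)
  T_ <- 300
  X1 <- matrix(rnorm(T_ * F * H), T_)
  X2 <- matrix(rnorm(T_ * F * H), T_)
  mk <- function(Xa, Xb) {
    structure(list(X = rbind(Xa, Xb), y = NULL,
                   index = tibble::tibble(clip = rep(1:2, each = T_),
                                          bin = rep(seq_len(T_), 2)),
                   F = F, H = H, discard_bins = 0), class = "nrf_data")
  }
  d12 <- mk(X1, X2); d21 <- mk(X2, X1)
  y1 <- predict_nrf(p, structure(list(X = X1, F = F, H = H), class = "nrf_data"))
  y2 <- predict_nrf(p, structure(list(X = X2, F = F, H = H), class = "nrf_data"))
  a <- peak_time_ratio(p, d12, list(y1, y2))
  b <- peak_time_ratio(p, d21, list(y2, y1))
  expect_equal(a$peak_time_ratio, b$peak_time_ratio)
})
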