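test_that("network adjustment preserves predictions and is idempotent", {
  X <- random_design(T = 40, F = 5, H = 3, seed = 51)
  worst <- 0
  for (s in 1:100) {
    p <- random_nrf(J = 4, F = 5, H = 3, seed = s)
    adj <- adjust_network(p)
    worst <- max(worst, max(abs(nrf_forward(adj$params, X)$y_hat -
                                  nrf_forward(p, X)$y_hat)))
    expect_true(all(rowSums(adj$params$W) >= 0))
    # idempotent
    again <- adjust_network(adj$params)
    expect_identical(again$params$W, adj$params$W)
  }
  expect_lt(worst, 1e-10)
})

test_that("an all-negative STRF with negative output weight is excitatory", {
  W <- matrix(-abs(rnorm(12)), 1)
  p <- nrf_params(W, 0.2, -0.8, 0, 4, 3)
  adj <- adjust_network(p)
  expect_gt(adj$params$w_out[1], 0)
  expect_true(all(adj$params$W >= 0))
  X <- random_design(T = 30, F = 4, H = 3, seed = 52)
  prof <- effective_hus(adj, X)
  expect_equal(prof$kind[1], "excitatory")
  expect_equal(prof$ie[1], 1) # all-nonnegative adjusted STRF, positive w_out
})

test_that("all-positive networks are left untouched by adjustment", {
  W <- matrix(abs(rnorm(24)), 2)
  p <- nrf_params(W, c(0.1, -0.1), c(0.5, -0.5), 0.2, 4, 3)
  adj <- adjust_network(p)
  expect_identical(adj$params$W, p$W)
  expect_identical(adj$params$w_out, p$w_out)
  expect_equal(adj$nonneg_b_out, 0.2 - p$rho1 * sum(p$w_out))
})

test_that("variance fractions sum to one and the 5% rule selects HUs", {
  # constructed case with variance fractions ~ 70/20/6/4
  set.seed(53)
  T <- 4000
  Z <- cbind(rnorm(T, sd = sqrt(70)), rnorm(T, sd = sqrt(20)),
             rnorm(T, sd = sqrt(6)), rnorm(T, sd = sqrt(4)))
  # network whose hidden activations are tiny multiples of independent
  # inputs, keeping every unit in its linear regime (z ~ (rho1/rho2) a)
  F <- 4; H <- 1
  W <- diag(4) * 1e-4
  p <- nrf_params(W, rep(0, 4), rep(1, 4), 0, F, H)
  prof <- effective_hus(p, Z)
  expect_equal(sum(prof$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(prof$effective, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(prof$variance_fraction, c(0.7, 0.2, 0.06, 0.04),
               tolerance = 0.05)
})

test_that("single-unit and duplicated-unit variance fractions are exact", {
  F <- 3; H <- 2
  X <- random_design(T = 50, F = F, H = H, seed = 54)
  w <- rnorm(F * H)
  one <- nrf_params(rbind(w, 0 * w), c(0, 0), c(1, 0), 0, F, H)
  prof <- effective_hus(one, X)
  expect_equal(prof$variance_fraction, c(1, 0))
  expect_equal(prof$effective, c(TRUE, FALSE))
  dup <- nrf_params(rbind(w, w), c(0, 0), c(1, 1), 0, F, H)
  prof2 <- effective_hus(dup, X)
  expect_equal(prof2$variance_fraction, c(0.5, 0.5))
})

test_that("IE scores follow the signed weight-balance formula", {
  expect_equal(ie_score(c(1, 2, 0.5), 2), 1)
  expect_equal(ie_score(c(-1, -2), 1), -1)
  expect_equal(ie_score(c(-1, -2), -1), 1)
  expect_equal(ie_score(c(3, -3), 1), 0)
  expect_equal(ie_score(c(2, -1), -1), -1 / 3)
  expect_true(is.na(ie_score(c(0, 0), 1)))
  # bounded
  set.seed(55)
  for (i in 1:20) {
    s <- ie_score(rnorm(10), rnorm(1))
    expect_true(s >= -1 && s <= 1)
  }
})

test_that("EC scores hit the threshold/saturation/linear anchors", {
  # NRF parameterization: rho4 = 0, rho5 = 0, rho6 = 1
  expect_equal(ec_score(rep(NRF_RHO1, 10)), 1)
  expect_equal(ec_score(rep(-NRF_RHO1, 10)), -1)
  expect_equal(ec_score(rep(0, 10)), 0)
  # LN parameterization: fitted rho1, rho4; rho5 = 1, rho6 = 2
  rho1 <- 2.4; rho4 <- 0.3
  expect_equal(ec_score(rep(rho4, 5), rho1, rho4, 1, 2), -1)
  expect_equal(ec_score(rep(rho4 + rho1, 5), rho1, rho4, 1, 2), 1)
  expect_equal(ec_score(rep(rho4 + rho1 / 2, 5), rho1, rho4, 1, 2), 0)
  expect_error(ec_score(1:5, 0), "rho1")
})

test_that("IE and EC are invariant to the hidden-unit sign symmetry", {
  X <- random_design(T = 60, F = 5, H = 3, seed = 56)
  p <- random_nrf(J = 3, F = 5, H = 3, seed = 57)
  q <- p
  q$W[2, ] <- -q$W[2, ]; q$b_hidden[2] <- -q$b_hidden[2]; q$w_out[2] <- -q$w_out[2]
  a <- effective_hus(p, X)
  b <- effective_hus(q, X)
  expect_equal(a$ie, b$ie, tolerance = 1e-12)
  expect_equal(a$ec, b$ec, tolerance = 1e-12)
  expect_equal(a$variance_fraction, b$variance_fraction, tolerance = 1e-12)
})

test_that("display STRFs flip only inhibitory units and self-invert", {
  m <- matrix(rnorm(12), 4, 3)
  expect_identical(display_strf(m, "excitatory"), m)
  expect_identical(display_strf(m, "inhibitory"), -m)
  expect_identical(display_strf(display_strf(m, "inhibitory"), "inhibitory"), m)
})

test_that("interpolation produces the 1/48-octave grid", {
  m <- matrix(rnorm(6 * 5), 6, 5)
  mi <- interpolate_strf(m, factor = 8)
  expect_equal(dim(mi), c((6 - 1) * 8 + 1, (5 - 1) * 8 + 1))
  # original nodes preserved
  expect_equal(mi[seq(1, 41, by = 8), seq(1, 33, by = 8)], m,
               ignore_attr = TRUE)
  # interpolated frequency bin covers 1/6 * 1/8 = 1/48 octave
  expect_equal((1 / 6) / 8, 1 / 48)
})

test_that("a boxcar power profile spanning 6 channels is one octave wide", {
  F <- 20; H <- 9
  m <- matrix(0, F, H)
  m[8:13, 5] <- 1 # boxcar over exactly 6 frequency bins at 1/6 octave
  mi <- interpolate_strf(m, factor = 8)
  tw <- tuning_widths(mi^2)
  # 6 bins x 1/6 octave = 1 octave, within one interpolated bin (1/48)
  expect_equal(tw$freq_width_quarter, 1, tolerance = 0.12)
  expect_equal(tw$freq_width_half, 1, tolerance = 0.12)
  expect_lte(tw$freq_width_half, tw$freq_width_quarter)
})

test_that("tuning widths match a brute-force oracle for a single hot bin", {
  F <- 12; H <- 10
  m <- matrix(0, F, H); m[6, 4] <- 2
  mi <- interpolate_strf(m, 8)
  tw <- tuning_widths(mi^2)
  pw <- mi^2
  # oracle: direct counting on the interpolated marginals
  fprof <- rowSums(pw); tprof <- colSums(pw)
  expect_equal(tw$freq_width_quarter,
               sum(fprof >= 0.25 * max(fprof)) / 48)
  expect_equal(tw$time_width_quarter,
               sum(tprof >= 0.25 * max(tprof)) * 5 / 8)
  expect_lte(tw$time_width_half, tw$time_width_quarter)
  expect_lte(tw$time_width_quarter, 4 * 5) # concentrated well under 4 bins
})

test_that("tuning widths are invariant to positive weight scaling", {
  set.seed(58)
  m <- gabor_strf(10, 8, 5, 4, bw = 1.5, dur = 1.5)
  a <- tuning_widths(interpolate_strf(m, 8)^2)
  b <- tuning_widths(interpolate_strf(7.3 * m, 8)^2)
  expect_equal(a, b)
  expect_error(tuning_widths(matrix(0, 5, 5)), "all-zero")
})

test_that("NRF power STRFs weight hidden units by their output variance", {
  ex <- bifeature_experiment()
  fit <- bifeature_fit()
  pw <- model_power_strf(fit, ex$data)
  expect_true(all(pw >= 0))
  adj <- adjust_network(fit)
  prof <- effective_hus(adj, ex$data)
  manual <- 0
  for (j in seq_len(adj$params$J)) {
    disp <- display_strf(hu_strf(adj$params, j), prof$kind[j])
    manual <- manual + prof$variance[j] * interpolate_strf(disp, 8)^2
  }
  expect_equal(pw, manual, tolerance = 1e-12)
})

test_that("contours trace level sets of bumps with mirror symmetry", {
  m <- gabor_strf(15, 12, 8, 6, bw = 2, dur = 2)
  ex <- strf_contours(m, "excitatory")
  expect_gt(nrow(ex), 0)
  expect_equal(length(unique(ex$contour)), 1)

  two <- gabor_strf(17, 14, 5, 4, bw = 1.2, dur = 1.2) +
    gabor_strf(17, 14, 13, 10, bw = 1.2, dur = 1.2)
  c2 <- strf_contours(two, "excitatory")
  expect_equal(length(unique(c2$contour)), 2)

  inh <- strf_contours(-m, "inhibitory")
  expect_equal(inh$time, ex$time)
  expect_equal(inh$freq, ex$freq)

  flat <- strf_contours(matrix(1, 5, 5), "excitatory")
  expect_equal(nrow(flat), 0)
})
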