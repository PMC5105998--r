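# Shared fixtures, built once per test run. Kept deliberately small: 6 clips
# of 2 s, 18 channels, 12 history bins (the desk-scale study conditions).

fixture_env <- new.env()

# Memoize expensive fixtures across test files.
fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

bifeature_experiment <- function() {
  fixture("ex_bif", synth_experiment("bifeature", seed = 1))
}

# One fitted NRF on the bifeature experiment, reused by analysis tests.
bifeature_fit <- function() {
  fixture("fit_bif", fit_nrf(bifeature_experiment()$data, lambda = 0.8,
                             J = 10, seed = 1))
}

# Small random network for structural tests.
random_nrf <- function(J = 4, F = 5, H = 3, seed = 1) {
  hy <- nrf_hyper(J = J, seed = seed)
  p <- init_params(hy, F, H)
  # scale up so activations traverse the nonlinearity
  nrf_params(p$W * 50, p$b_hidden * 20, p$w_out * 15, p$b_out, F, H)
}

random_design <- function(T = 60, F = 5, H = 3, seed = 1) {
  set.seed(seed)
  matrix(rnorm(T * F * H), T, F * H)
}
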