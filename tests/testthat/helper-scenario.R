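## Shared fixtures, built once per test run. The default scenario is the
## package's standard desk-scale study configuration; the small scenario is
## a faster variant for I/O round trips and toy checks.

.fixtures <- new.env(parent = emptyenv())

test_scenario <- function() {
  if (is.null(.fixtures$scen)) .fixtures$scen <- synth_scenario(seed = 1)
  .fixtures$scen
}

test_run <- function() {
  if (is.null(.fixtures$run)) .fixtures$run <- run_pipeline(test_scenario())
  .fixtures$run
}

small_scenario <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- synth_scenario(
      R = 4L, L = 5L, seed = 7L,
      grid = ch_grid(100, 108, 24, 30), n_receptors = 2L)
  }
  .fixtures$small
}

## Random productive nonnegative coefficient matrix for Leontief checks.
random_productive_A <- function(n, rho = NULL) {
  A <- matrix(runif(n * n), n, n)
  target <- rho %||% runif(1, 0.2, 0.9)
  A * (target / spectral_radius(A, iter = 200L, tol = 1e-12))
}

## Truncated Neumann-series oracle for the Leontief inverse.
leontief_series_oracle <- function(A, tail_tol = 1e-12) {
  S <- diag(nrow(A)); term <- diag(nrow(A))
  repeat {
    term <- term %*% A
    S <- S + term
    if (max(abs(term)) < tail_tol) break
  }
  S
}

## Population-weighted pairwise mean-absolute-difference Gini.
gini_mad_oracle <- function(population, quantity) {
  w <- population / sum(population)
  x <- quantity / population
  mu <- sum(w * x)
  sum(outer(w, w) * abs(outer(x, x, "-"))) / (2 * mu)
}
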