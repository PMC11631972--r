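# shared oracles and fixtures, built in code

# adaptive-quadrature expectation of g(X) against the package density,
# independent of any closed-form moment code path
quad_expect <- function(g, lambda, theta, indet = 0, rel.tol = 1e-10) {
  f <- function(t) {
    x <- t / (1 - t)
    g(x) * dnesbr3(x, lambda, theta, indet) / (1 - t)^2
  }
  stats::integrate(f, 0, 1, rel.tol = rel.tol, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# parameter grid spanning the moment-table ranges (valid-parameter subset:
# theta large enough for the moments under test to exist)
param_grid <- function() {
  expand.grid(lambda = c(0.5, 1, 2, 5),
              theta = c(2.5, 4, 6, 9),
              indet = c(0, 0.05, 0.3))
}

covid_fixture <- function() suppressWarnings(load_dataset("covid_nl"))
relief_fixture <- function() suppressWarnings(load_dataset("relief"))
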