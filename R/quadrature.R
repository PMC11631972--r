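## Adaptive quadrature over (0, Inf) after the change of variables
## t = x / (1 + x)  (x = t/(1-t), dx = dt/(1-t)^2), which maps the half line
## onto (0, 1) and tames both endpoint tails.  Tolerances follow the
## package-wide numerical policy: abs.tol 1e-10, rel.tol 1e-8.
integrate_0inf <- function(f, rel.tol = 1e-8, abs.tol = 1e-10,
                           subdivisions = 400L) {
  g <- function(t) {
    x <- t / (1 - t)
    f(x) / (1 - t)^2
  }
  stats::integrate(g, 0, 1, rel.tol = rel.tol, abs.tol = abs.tol,
                   subdivisions = subdivisions, stop.on.error = FALSE)$value
}

## Plain quadrature on (0, Inf) via stats::integrate's own infinite-range
## transform; used as the *second*, independent scheme in dual-quadrature
## checks.
integrate_0inf_direct <- function(f, rel.tol = 1e-8, abs.tol = 1e-10) {
  stats::integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = abs.tol,
                   subdivisions = 400L, stop.on.error = FALSE)$value
}
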