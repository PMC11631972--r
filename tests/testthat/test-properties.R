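test_that("raw moments: beta identity, conventions, divergence signal", {
  # direct beta identity at lambda = 1, theta = 3
  m <- nesbr3_moment(1, 1, 3)
  expect_equal(m$value, gamma(2 / 3) * gamma(4 / 3) / gamma(2),
               tolerance = 1e-12)
  expect_true(m$exists)
  # quadrature oracle
  expect_equal(nesbr3_moment(1, 2, 4)$value,
               quad_expect(function(x) x, 2, 4), tolerance = 1e-6)
  # prefactor conventions: paper scales by (1.3)^2, pdf-consistent by (1.3)^-2
  base <- nesbr3_moment(2, 1, 2.5, 0)$value
  expect_equal(nesbr3_moment(2, 1, 2.5, 0.3, "paper_eq6")$value,
               base * 1.3^2, tolerance = 1e-12)
  expect_equal(nesbr3_moment(2, 1, 2.5, 0.3, "pdf_consistent")$value,
               base / 1.3^2, tolerance = 1e-12)
  # classical cross-check: lambda * B(lambda + r/theta, 1 - r/theta)
  expect_equal(nesbr3_moment(2, 2, 5)$value, 2 * beta(2 + 2 / 5, 1 - 2 / 5),
               tolerance = 1e-12)
  # divergence: r >= theta
  d <- nesbr3_moment(2, 1, 1.5)
  expect_false(d$exists)
  expect_true(is.na(d$value))
  expect_false(is.nan(d$value))
})

test_that("pdf-consistent moments agree with quadrature across the grid", {
  g <- param_grid()
  for (i in seq_len(nrow(g))) {
    p <- g[i, ]
    for (r in 1:2) {
      if (p$theta <= r + 1) next
      expect_equal(nesbr3_moment(r, p$lambda, p$theta, p$indet)$value,
                   quad_expect(function(x) x^r, p$lambda, p$theta, p$indet),
                   tolerance = 1e-6, info = sprintf("row %d r %d", i, r))
    }
  }
})

test_that("negative moments: closed form, quadrature, divergence", {
  expect_equal(nesbr3_negative_moment(1, 2, 2)$value, 2 * beta(1.5, 1.5),
               tolerance = 1e-12)
  expect_equal(nesbr3_negative_moment(1, 3, 2)$value,
               quad_expect(function(x) 1 / x, 3, 2), tolerance = 1e-6)
  # reciprocal scales *up* with the indeterminacy
  expect_equal(nesbr3_negative_moment(1, 3, 2, 0.3)$value,
               1.3 * nesbr3_negative_moment(1, 3, 2, 0)$value,
               tolerance = 1e-12)
  d <- nesbr3_negative_moment(1, 0.5, 1)
  expect_false(d$exists)
})

test_that("mean/variance: composition, quadrature, flagged literal variant", {
  mv <- nesbr3_mean_variance(1, 3)
  expect_equal(mv$mean, nesbr3_moment(1, 1, 3)$value)
  mv2 <- nesbr3_mean_variance(2, 5)
  mu <- quad_expect(function(x) x, 2, 5)
  expect_equal(mv2$variance, quad_expect(function(x) (x - mu)^2, 2, 5),
               tolerance = 1e-6)
  # the literal published mean/variance uses different beta arguments and
  # disagrees for generic parameters; the convention is reported, not hidden
  lit <- nesbr3_mean_variance(2, 5, convention = "paper_eq8")
  expect_identical(lit$convention, "paper_eq8")
  expect_gt(abs(lit$mean - mv2$mean), 1e-3)
})

test_that("skewness/kurtosis: quadrature oracle, scale invariance, symmetry sanity", {
  sk <- nesbr3_skewness_kurtosis(2, 6)
  mus <- vapply(1:4, function(r) quad_expect(function(x) x^r, 2, 6),
                numeric(1))
  v <- mus[2] - mus[1]^2
  c1 <- (mus[3] - 3 * mus[1] * mus[2] + 2 * mus[1]^3) / v^1.5
  c2 <- (mus[4] - 4 * mus[1] * mus[3] + 6 * mus[2] * mus[1]^2 -
           3 * mus[1]^4) / v^2
  expect_equal(sk$skewness, c1, tolerance = 1e-6)
  expect_equal(sk$kurtosis, c2, tolerance = 1e-6)
  # moment ratios are scale-free, hence indeterminacy-invariant
  skI <- nesbr3_skewness_kurtosis(2, 6, 0.3)
  expect_equal(skI$skewness, sk$skewness, tolerance = 1e-10)
  expect_equal(skI$kurtosis, sk$kurtosis, tolerance = 1e-10)
  # oracle sanity: the same ratio machinery on a symmetric density gives 0
  mom_sym <- function(r) stats::integrate(function(x) x^r * stats::dnorm(x, 5, 1),
                                          -Inf, Inf, rel.tol = 1e-10)$value
  ms <- vapply(1:3, mom_sym, numeric(1))
  vs <- ms[2] - ms[1]^2
  expect_equal((ms[3] - 3 * ms[1] * ms[2] + 2 * ms[1]^3) / vs^1.5, 0,
               tolerance = 1e-6)
  # divergence: kurtosis needs theta > 4
  expect_false(nesbr3_skewness_kurtosis(2, 3.5)$exists[["kurtosis"]])
})

test_that("stress-strength equals lambda1/(lambda1+lambda2), independent of theta and I", {
  expect_equal(stress_strength(3, 3), 0.5)
  expect_equal(stress_strength(2, 1), 2 / 3)
  expect_identical(stress_strength(2, 1, theta = 5, indet = 0),
                   stress_strength(2, 1, theta = 0.7, indet = 0.5))
  # property: in (0,1), 0.5 iff equal
  set.seed(7)
  for (k in 1:20) {
    l1 <- runif(1, 0.1, 10); l2 <- runif(1, 0.1, 10)
    r <- stress_strength(l1, l2)
    expect_true(r > 0 && r < 1)
    if (abs(l1 - l2) > 1e-12) expect_true(abs(r - 0.5) > 0)
  }
  # Monte-Carlo oracle: P(X2 < X1) with 1e6 paired draws, 3 SE band
  set.seed(20240511)
  n <- 1e6
  x1 <- rnesbr3(n, 2, 3, 0.05)
  x2 <- rnesbr3(n, 1, 3, 0.05)
  phat <- mean(x2 < x1)
  se <- sqrt(phat * (1 - phat) / n)
  expect_lt(abs(phat - 2 / 3), 3 * se)
})

test_that("order-statistic density: reduction, normalization, simulation oracle", {
  xs <- exp(seq(log(0.05), log(20), length.out = 30))
  expect_equal(order_stat_pdf(xs, 1, 1, 2, 3, 0.05),
               dnesbr3(xs, 2, 3, 0.05), tolerance = 1e-12)
  intg <- stats::integrate(function(x) order_stat_pdf(x, 2, 3, 2, 3), 0, Inf,
                           rel.tol = 1e-9)$value
  expect_equal(intg, 1, tolerance = 1e-6)
  # the literal published sum coincides with the standard construction at I=0
  expect_equal(order_stat_pdf(xs, 2, 3, 2, 3, 0, variant = "paper"),
               order_stat_pdf(xs, 2, 3, 2, 3, 0), tolerance = 1e-10)
  # ...but carries an extra (1+I)^{j+k} scale at I > 0 (flagged variant)
  expect_gt(max(abs(order_stat_pdf(xs, 2, 3, 2, 3, 0.3, variant = "paper") -
                      order_stat_pdf(xs, 2, 3, 2, 3, 0.3))), 1e-3)
  # simulation oracle: sample median of n=5, KS against the implied cdf
  set.seed(99)
  u <- matrix(runif(2e5 * 5), ncol = 5)
  med <- apply(qnesbr3(u, 2, 3, 0), 1, stats::median)
  ks <- suppressWarnings(stats::ks.test(
    med, function(q) stats::pbeta(pnesbr3(q, 2, 3, 0), 3, 3)))
  expect_gt(ks$p.value, 0.01)
  expect_error(order_stat_pdf(1, 4, 3, 2, 3), "rank")
})

test_that("order-statistic moments: reduction, simulation oracle, ordering", {
  expect_equal(order_stat_moment(1, 1, 1, 2, 4)$value,
               nesbr3_moment(1, 2, 4)$value, tolerance = 1e-8)
  # mean of the median of n=5 vs simulation, 3 MC standard errors
  set.seed(123)
  u <- matrix(runif(1e5 * 5), ncol = 5)
  med <- apply(qnesbr3(u, 2, 4, 0), 1, stats::median)
  target <- order_stat_moment(3, 5, 1, 2, 4)$value
  expect_lt(abs(mean(med) - target), 3 * stats::sd(med) / sqrt(length(med)))
  # stochastic ordering of order statistics
  e <- vapply(1:3, function(j) order_stat_moment(j, 3, 1, 2, 4)$value,
              numeric(1))
  expect_true(all(diff(e) > 0))
  # the literal series agrees with quadrature at I = 0
  expect_equal(order_stat_moment(3, 5, 1, 2, 4, variant = "paper")$value,
               target, tolerance = 1e-6)
  expect_false(order_stat_moment(2, 3, 5, 2, 4)$exists)
})

test_that("Renyi entropy: Shannon limit, scale shift, dual quadrature, flagged variant", {
  shannon <- -stats::integrate(function(x) {
    lf <- dnesbr3(x, 2, 3, log = TRUE)
    exp(lf) * lf
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(renyi_entropy(1.0001, 2, 3), shannon, tolerance = 1e-3)
  expect_equal(renyi_entropy(0.9999, 2, 3), shannon, tolerance = 1e-3)
  # entropy under pure scaling: H_I - H_0 = -log(1+I)
  expect_equal(renyi_entropy(2, 2, 3, 0.5) - renyi_entropy(2, 2, 3, 0),
               -log(1.5), tolerance = 1e-8)
  # dual-quadrature oracle with an independent integration scheme
  direct <- log(stats::integrate(function(x) dnesbr3(x, 2, 3)^2, 0, Inf,
                                 rel.tol = 1e-11)$value) / (1 - 2)
  expect_equal(renyi_entropy(2, 2, 3), direct, tolerance = 1e-6)
  # the literal published beta expression disagrees even at I = 0 (flagged)
  expect_gt(abs(renyi_entropy(2, 2, 3, method = "paper") -
                  renyi_entropy(2, 2, 3)), 0.1)
  expect_error(renyi_entropy(1, 2, 3), "epsilon")
})

test_that("property table mirrors the moment layout and exports", {
  tab <- property_table(c(2, 2), c(6, 3.5), 0)
  expect_identical(names(tab),
                   c("lambda", "theta", "indet", "mu1", "mu2", "mu3", "mu4",
                     "V", "C1", "C2"))
  expect_equal(tab$mu1[1], nesbr3_moment(1, 2, 6)$value)
  expect_true(is.na(tab$C2[2]))  # kurtosis divergent at theta = 3.5
  csv <- tempfile(fileext = ".csv")
  write_property_table(tab, csv, "csv")
  back <- read.csv(csv)
  expect_equal(back$mu2, tab$mu2, tolerance = 1e-12)
  js <- tempfile(fileext = ".json")
  write_property_table(tab, js, "json")
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$mu1[1],
               tab$mu1[1], tolerance = 1e-12)
})
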