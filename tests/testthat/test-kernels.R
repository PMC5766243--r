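# The seven location kernels: parameter validation, densities, distance
# distributions, CDFs, quantiles and moments.

test_that("parameter validation enforces the family domains", {
  expect_error(kernel_params("weibull", a = -1, b = 2), "positive")
  expect_error(kernel_params("weibull", a = 2), "shape parameter")
  expect_error(kernel_params("gaussian", a = 2, b = 1), "no shape")
  expect_error(kernel_params("twoDt", a = 2, b = 1), "b > 1")
  expect_error(kernel_params("twoDt", a = 2, b = 0.5))
  expect_silent(kernel_params("twoDt", a = 2, b = 1.01))
  expect_error(kernel_params("nope", a = 1))
})

test_that("location densities match hand evaluations of the closed forms", {
  # gaussian at the origin: exp(0) / (pi a^2)
  expect_equal(location_density(kernel_params("gaussian", 1), 0), 1 / pi)
  # weibull at parameters typical of the fitted kernels, against a direct
  # scalar transcription of b r^(b-2) exp(-(r/a)^b) / (2 pi a^b)
  a <- 8.563; b <- 1.802; r <- 1
  expect_equal(location_density(kernel_params("weibull", a, b), r),
               b * r^(b - 2) * exp(-(r / a)^b) / (2 * pi * a^b),
               tolerance = 1e-12)
  # negative exponential: e^{-r/a} / (2 pi a^2)
  expect_equal(location_density(kernel_params("negative_exponential", 2), 3),
               exp(-1.5) / (8 * pi), tolerance = 1e-12)
  # 2Dt: (b-1)/(pi a^2) (1 + r^2/a^2)^(-b)
  expect_equal(location_density(kernel_params("twoDt", 2, 2.5), 2),
               1.5 / (4 * pi) * 2^(-2.5), tolerance = 1e-12)
})

test_that("densities singular at the origin refuse r = 0 and vanish nearby", {
  for (k in list(kernel_params("lognormal", 5, 0.7),
                 kernel_params("inverse_gaussian", 3, 5),
                 kernel_params("weibull", 8, 1.5))) {
    expect_error(location_density(k, 0), "singular")
  }
  # the lognormal location density tends to 0 as r -> 0+
  lk <- kernel_params("lognormal", 5, 0.7)
  expect_lt(location_density(lk, 1e-8), 1e-12)
  # weibull with b >= 2 is finite at the origin
  expect_silent(location_density(kernel_params("weibull", 8, 2), 0))
})

test_that("every kernel integrates to one over the plane", {
  for (k in example_kernels()) {
    expect_equal(plane_integral(k), 1, tolerance = 1e-6,
                 label = sprintf("plane integral (%s)", k$family))
  }
})

test_that("distance densities reduce to the named univariate laws", {
  r <- c(0.3, 1, 2.7, 5, 11)
  expect_equal(distance_density(kernel_params("negative_exponential", 2), r),
               dgamma(r, shape = 2, scale = 2), tolerance = 1e-12)
  expect_equal(distance_density(kernel_params("gaussian", 3), r),
               dweibull(r, shape = 2, scale = 3), tolerance = 1e-12)
  expect_equal(distance_density(kernel_params("lognormal", 5, 0.7), r),
               dlnorm(r, meanlog = log(5), sdlog = 0.7), tolerance = 1e-12)
  expect_equal(distance_density(kernel_params("weibull", 8, 1.8), r),
               dweibull(r, shape = 1.8, scale = 8), tolerance = 1e-12)
  # distance density vanishes at the origin
  for (k in example_kernels())
    expect_identical(distance_density(k, 0), 0)
})

test_that("numeric CDFs agree with independent closed-form laws", {
  cases <- list(
    list(k = kernel_params("negative_exponential", 2),
         p = function(r) pgamma(r, 2, scale = 2)),
    list(k = kernel_params("gaussian", 3),
         p = function(r) pweibull(r, 2, scale = 3)),
    list(k = kernel_params("lognormal", 5, 0.7),
         p = function(r) plnorm(r, log(5), 0.7)),
    list(k = kernel_params("weibull", 8, 1.8),
         p = function(r) pweibull(r, 1.8, scale = 8)),
    list(k = kernel_params("twoDt", 2, 2.5),
         p = function(r) 1 - (1 + (r / 2)^2)^(1 - 2.5)))
  for (case in cases) {
    rs <- seq(0.25, 5, length.out = 20) * case$k$a
    expect_equal(distance_cdf(case$k, rs, method = "numeric"),
                 case$p(rs), tolerance = 1e-7,
                 label = sprintf("numeric CDF (%s)", case$k$family))
    expect_equal(distance_cdf(case$k, rs, method = "closed"),
                 case$p(rs), tolerance = 1e-12,
                 label = sprintf("closed CDF (%s)", case$k$family))
  }
})

test_that("inverse-Gaussian distance law has mean a and a quadrature CDF", {
  k <- kernel_params("inverse_gaussian", 3, 5)
  # mean of the Wald(mean a, shape b) distance law
  mean_num <- stats::integrate(function(r) r * distance_density(k, r),
                               0, Inf, rel.tol = 1e-10)$value
  expect_equal(mean_num, 3, tolerance = 1e-8)
  expect_equal(distance_mean(k), 3, tolerance = 1e-12)
  # closed-form Wald CDF against adaptive quadrature of the distance density
  p_num <- stats::integrate(function(r) distance_density(k, r), 0, 3,
                            rel.tol = 1e-10)$value
  expect_equal(distance_cdf(k, 3), p_num, tolerance = 1e-8)
})

test_that("CDFs are monotone with cdf(0) = 0", {
  for (k in example_kernels()) {
    rs <- seq(0, 6, length.out = 25) * k$a
    ps <- distance_cdf(k, rs)
    expect_identical(ps[1], 0)
    expect_true(all(diff(ps) >= 0), label = sprintf("monotone (%s)", k$family))
    expect_true(all(ps <= 1))
  }
})

test_that("quantiles invert the CDF and match the closed forms", {
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  for (k in example_kernels()) {
    r_closed <- distance_quantile(k, qs, method = "closed")
    # round trip through the CDF
    expect_equal(distance_cdf(k, r_closed), qs, tolerance = 1e-8,
                 label = sprintf("round trip (%s)", k$family))
    # closed-form and numerically root-found quantiles agree
    r_num <- distance_quantile(k, qs, method = "numeric")
    expect_equal(r_num / r_closed, rep(1, length(qs)), tolerance = 1e-6,
                 label = sprintf("closed vs numeric quantile (%s)", k$family))
  }
})

test_that("specific quantiles match independent oracles", {
  # log-normal median equals the scale parameter exactly
  expect_equal(distance_quantile(kernel_params("lognormal", 5, 0.7), 0.5), 5,
               tolerance = 1e-12)
  # weibull: (r/a)^b = 1 at r = a gives CDF 1 - e^-1
  expect_equal(distance_cdf(kernel_params("weibull", 2, 3), 2),
               1 - exp(-1), tolerance = 1e-12)
  # negative exponential median: root of the Gamma(2, 1) CDF
  # 1 - e^-x (1 + x) = 1/2, found independently of qgamma
  oracle <- uniroot(function(x) 1 - exp(-x) * (1 + x) - 0.5, c(0.1, 10),
                    tol = 1e-12)$root
  expect_equal(distance_quantile(kernel_params("negative_exponential", 1),
                                 0.5),
               oracle, tolerance = 1e-9)
  # 2Dt closed form a sqrt((1-q)^(1/(1-b)) - 1)
  k <- kernel_params("twoDt", 2, 2.5)
  expect_equal(distance_quantile(k, 0.95),
               2 * sqrt(0.05^(1 / (1 - 2.5)) - 1), tolerance = 1e-12)
})

test_that("quantile probabilities outside (0,1) are rejected", {
  k <- kernel_params("weibull", 8, 2)
  expect_error(distance_quantile(k, 0), "strictly between")
  expect_error(distance_quantile(k, 1), "strictly between")
  expect_error(distance_quantile(k, -0.1), "strictly between")
})

test_that("weibull mean distance equals a * gamma(1 + 1/b)", {
  k <- kernel_params("weibull", 8.5, 1.8)
  mean_num <- stats::integrate(function(r) r * distance_density(k, r),
                               0, Inf, rel.tol = 1e-10)$value
  expect_equal(distance_mean(k), 8.5 * gamma(1 + 1 / 1.8), tolerance = 1e-12)
  expect_equal(mean_num, distance_mean(k), tolerance = 1e-6)
})
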