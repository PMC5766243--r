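# Poisson count-model likelihood and maximum-likelihood kernel fitting.

test_that("expected counts follow the A * Q * f(r) model", {
  k <- kernel_params("weibull", 8, 2)
  # linear in area
  expect_equal(expected_count(k, 11, 3, area = 0.10),
               2 * expected_count(k, 11, 3, area = 0.05))
  # Q -> 0 sends every expectation to 0
  expect_equal(expected_count(k, -Inf, c(0, 1, 5), area = 0.05),
               rep(0, 3))
  # source collectors evaluated at the effective distance
  expect_equal(expected_count(k, 11, 0, 0.05, r_eff = 0.1),
               0.05 * exp(11) * location_density(k, 0.1))
  # direct scalar transcription of A e^logQ f(r)
  kt <- kernel_params("weibull", 8.563, 1.802)
  expect_equal(expected_count(kt, 10.654, 1, 0.05),
               0.05 * exp(10.654) *
                 1.802 * 1^(1.802 - 2) * exp(-(1 / 8.563)^1.802) /
                 (2 * pi * 8.563^1.802),
               tolerance = 1e-12)
})

test_that("negative log-likelihood matches brute-force Poisson summation", {
  data <- toy_counts()
  theta <- c(log(500), log(4), log(1.8))
  k <- dispkern:::theta_to_params("weibull", theta)
  mu <- expected_count(k, theta[1], data$distance_m, data$area_m2, 0.1)
  # independent evaluation from the Poisson log-pmf written out by hand
  nll_brute <- -sum(data$count * log(mu) - mu - lfactorial(data$count))
  expect_equal(kernel_nll("weibull", theta, data), nll_brute,
               tolerance = 1e-10)
  # additivity: duplicating the dataset doubles the NLL
  expect_equal(kernel_nll("weibull", theta, rbind(data, data)),
               2 * kernel_nll("weibull", theta, data), tolerance = 1e-12)
})

test_that("NLL of a zero count equals the expected mean", {
  one <- data.frame(site = "s1", direction = "N", distance_m = 2,
                    area_m2 = 0.05, count = 0L)
  theta <- c(log(300), log(5))
  mu <- expected_count(dispkern:::theta_to_params("gaussian", theta), theta[1], 2, 0.05)
  expect_equal(kernel_nll("gaussian", theta, one), mu, tolerance = 1e-12)
})

test_that("invalid parameters yield +Inf, not errors", {
  data <- toy_counts()
  expect_identical(kernel_nll("weibull", c(NA, 1, 1), data), Inf)
  expect_identical(kernel_nll("weibull", c(5, Inf, 0), data), Inf)
  expect_identical(kernel_nll("weibull", c(1e300, 0, 0), data), Inf)
})

test_that("rescaling areas and Q in opposite directions leaves the NLL fixed", {
  data <- toy_counts()
  theta <- c(log(500), log(4), log(1.8))
  scaled <- data
  scaled$area_m2 <- data$area_m2 * 3
  theta_scaled <- theta - c(log(3), 0, 0)
  expect_equal(kernel_nll("weibull", theta, data),
               kernel_nll("weibull", theta_scaled, scaled),
               tolerance = 1e-12)
})

test_that("fitting recovers known weibull parameters from one experiment", {
  des <- experiment_design(n_sites = 1)
  truth <- synthetic_truth(kernel = kernel_params("weibull", 8, 2),
                           logQ = 12, seed = 99)
  counts <- simulate_counts(generate_layout(des, seed = 99), truth)
  fit <- fit_kernel("weibull", counts)
  expect_true(fit$converged)
  expect_equal(fit$n_free_params, 3L)
  expect_lt(abs(fit$params$a / 8 - 1), 0.25)
  expect_lt(abs(fit$params$b / 2 - 1), 0.30)
  # at the optimum, Q matches its closed-form Poisson MLE
  # Q_hat = sum(c) / sum(A f(r))
  fr <- location_density(fit$params,
                         ifelse(counts$distance_m == 0, 0.1,
                                counts$distance_m))
  logQ_hat <- log(sum(counts$count)) - log(sum(counts$area_m2 * fr))
  expect_equal(fit$logQ, logQ_hat, tolerance = 1e-4)
})

test_that("fits are deterministic and robust to the starting points", {
  des <- experiment_design(n_sites = 1)
  truth <- synthetic_truth(seed = 5)
  counts <- simulate_counts(generate_layout(des, seed = 5), truth)
  f1 <- fit_kernel("lognormal", counts)
  f2 <- fit_kernel("lognormal", counts)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  # different jitter magnitudes land on the same optimum
  f3 <- fit_kernel("lognormal", counts,
                   fit_control(jitter_sd = 1.0))
  expect_equal(-f1$loglik, -f3$loglik, tolerance = 1e-4)
})

test_that("subsets with too few recruits are refused", {
  empty <- toy_counts()
  empty$count <- 0L
  expect_error(fit_kernel("weibull", empty), "below the minimum")
})

test_that("fit_all splits by site and direction, sharing source collectors", {
  des <- experiment_design(n_sites = 1)
  truth <- synthetic_truth(seed = 3)
  counts <- simulate_counts(generate_layout(des, seed = 3), truth)
  fs <- fit_all(counts, families = c("gaussian", "weibull"))
  expect_equal(length(fs$fits), 4 * 2)  # 4 directions x 2 families
  expect_equal(nrow(fs$exclusions), 0L)
  # every fit saw the 7 directional + 3 source collectors
  expect_true(all(fs$table$n_obs == 10L))
  # deterministic: a second run gives an identical table
  fs2 <- fit_all(counts, families = c("gaussian", "weibull"))
  expect_identical(fs$table, fs2$table)
})

test_that("near-empty transects are excluded with a reason, not fitted", {
  des <- experiment_design(n_sites = 1)
  truth <- synthetic_truth(seed = 11)
  counts <- simulate_counts(generate_layout(des, seed = 11), truth)
  counts$count[counts$direction %in% c("N", "E")] <- 0L
  fs <- fit_all(counts, families = "weibull")
  expect_setequal(fs$exclusions$direction, c("N", "E"))
  expect_match(fs$exclusions$reason[1], "below minimum")
  expect_setequal(unique(fs$table$direction), c("S", "W"))
})

test_that("count tables are validated with informative errors", {
  bad_dir <- toy_counts()
  bad_dir$direction[2] <- "NE"
  expect_error(fit_all(bad_dir), "unknown direction")
  bad_src <- toy_counts()
  bad_src$distance_m[1] <- 0
  expect_error(fit_all(bad_src), "SOURCE")
  bad_cnt <- toy_counts()
  bad_cnt$count[1] <- -1L
  expect_error(fit_all(bad_cnt), "nonnegative")
  expect_error(fit_all(toy_counts()[, -5]), "missing column")
})
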