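# Shared fixtures: tiny count tables and a parameter grid for the kernel
# property tests.

toy_counts <- function() {
  data.frame(
    site = "s1",
    direction = c("N", "N", "N", "SOURCE", "SOURCE"),
    distance_m = c(1, 3, 7.5, 0, 0),
    area_m2 = c(0.05, 0.05, 0.04, 0.06, 0.05),
    count = c(12L, 7L, 1L, 30L, 22L),
    stringsAsFactors = FALSE)
}

# one representative parameter set per family
example_kernels <- function() {
  list(
    kernel_params("negative_exponential", a = 2),
    kernel_params("gaussian", a = 3),
    kernel_params("power_exponential", a = 4, b = 1.5),
    kernel_params("twoDt", a = 2, b = 2.5),
    kernel_params("inverse_gaussian", a = 3, b = 5),
    kernel_params("lognormal", a = 5, b = 0.7),
    kernel_params("weibull", a = 8, b = 2))
}

# grid of valid parameters per family, as in the normalization property
kernel_grid <- function(a_vals = c(0.5, 2, 8, 20),
                        b_vals = c(1.1, 1.5, 2, 3, 5)) {
  out <- list()
  for (fam in kernel_families()) {
    for (a in a_vals) {
      if (fam %in% c("negative_exponential", "gaussian")) {
        out[[length(out) + 1L]] <- kernel_params(fam, a)
      } else {
        for (b in b_vals) {
          out[[length(out) + 1L]] <- kernel_params(fam, a, b)
        }
      }
    }
  }
  out
}

plane_integral <- function(params) {
  f <- function(r) distance_density(params, r)
  stats::integrate(f, 0, params$a, rel.tol = 1e-9,
                   subdivisions = 500L)$value +
    stats::integrate(f, params$a, Inf, rel.tol = 1e-9,
                     subdivisions = 500L)$value
}
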