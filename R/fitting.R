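# Maximum-likelihood fitting of the count model c = A * Q * f(r):
# recruit counts on a collector of area A at distance r are Poisson with
# mean A * Q * f(r), where Q scales the kernel density to the number of
# propagules dispersed. Fits are per site x direction x kernel family.

DIRECTIONS <- c("N", "E", "S", "W")

#' Fitting options for dispersal kernel estimation
#'
#' @param r_eff Effective distance (m) substituted for source collectors at
#'   nominal distance 0, where several location kernels are singular. The
#'   default 0.1 m is of the order of a collector tile's radius.
#' @param min_count Minimum total recruit count over a subset's directional
#'   collectors required before a kernel is fitted; subsets below it are
#'   reported as excluded rather than fitted, to avoid misleading dispersal
#'   estimates from near-empty transects.
#' @param n_starts Number of optimizer starts: one method-of-moments start
#'   plus `n_starts - 1` jittered starts drawn from a fixed seeded generator,
#'   so fits are reproducible.
#' @param maxit Maximum iterations per optimizer run.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @param jitter_sd Standard deviation of the log-scale jitter applied to the
#'   extra starts.
#'
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(r_eff = 0.1, min_count = 20, n_starts = 5,
                        maxit = 2000, reltol = 1e-10, jitter_sd = 0.5) {
  stopifnot(r_eff > 0, min_count >= 0, n_starts >= 1)
  structure(list(r_eff = r_eff, min_count = min_count,
                 n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 reltol = reltol, jitter_sd = jitter_sd),
            class = "fit_control")
}

effective_distance <- function(distance, r_eff) {
  ifelse(distance <= 0, r_eff, distance)
}

#' Expected recruit count on a collector
#'
#' The count model: a collector of area `area` (m^2) at distance `distance`
#' (m) from the source receives a Poisson-distributed number of recruits with
#' mean `area * Q * f(r)`, `f` the location kernel density and `Q` the fitted
#' number of propagules dispersed. Distance 0 (source collectors) is replaced
#' by the effective distance `r_eff`.
#'
#' @param params A [kernel_params()] object.
#' @param logQ Natural log of the propagule number Q.
#' @param distance,area Collector distance (m) and tile area (m^2); vectors
#'   are recycled as usual.
#' @param r_eff Effective distance substituted for distance 0.
#' @return Expected counts (same length as the longer of `distance`/`area`).
#' @export
#' @examples
#' k <- kernel_params("weibull", a = 8, b = 2)
#' expected_count(k, logQ = 11.5, distance = c(0, 1, 5), area = 0.05)
expected_count <- function(params, logQ, distance, area, r_eff = 0.1) {
  if (any(area <= 0)) stop("'area' must be positive", call. = FALSE)
  r <- effective_distance(distance, r_eff)
  area * exp(logQ) * location_density(params, r)
}

# theta -> kernel_params; theta is (logQ, log a[, log b]) with log(b - 1)
# for the 2Dt family so the b > 1 constraint maps to the whole real line.
theta_to_params <- function(family, theta) {
  a <- exp(theta[2L])
  if (n_shape_params(family) == 0L) return(kernel_params(family, a))
  b <- if (family == "twoDt") 1 + exp(theta[3L]) else exp(theta[3L])
  kernel_params(family, a, b)
}

params_to_theta <- function(params, logQ) {
  th <- c(logQ, log(params$a))
  if (!is.null(params$b)) {
    th <- c(th, if (params$family == "twoDt") log(params$b - 1)
            else log(params$b))
  }
  th
}

#' Negative log-likelihood of the Poisson count model
#'
#' For parameter vector `theta = (logQ, log a[, log b])` (the 2Dt shape is
#' parameterized as `log(b - 1)`), returns
#' `-sum(log dPois(count_i; A_i * Q * f(r_i)))`. Parameter values outside the
#' family's domain, or that give non-finite means, return `+Inf` so the
#' optimizer can retreat.
#'
#' @param family A kernel family name.
#' @param theta Numeric parameter vector on the unconstrained scale.
#' @param data Data frame with columns `distance_m`, `area_m2`, `count`.
#' @param r_eff Effective distance for source collectors.
#' @return A single number (possibly `Inf`).
#' @export
kernel_nll <- function(family, theta, data, r_eff = 0.1) {
  if (any(!is.finite(theta))) return(Inf)
  params <- tryCatch(theta_to_params(family, theta), error = function(e) NULL)
  if (is.null(params)) return(Inf)
  mu <- tryCatch(
    expected_count(params, theta[1L], data$distance_m, data$area_m2, r_eff),
    error = function(e) NULL)
  if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) return(Inf)
  nll <- -sum(stats::dpois(data$count, lambda = mu, log = TRUE))
  if (!is.finite(nll)) Inf else nll
}

# Closed-form Poisson MLE of Q given fixed kernel parameters:
# Q_hat = sum(c_i) / sum(A_i f(r_i)).
profile_logQ <- function(params, data, r_eff) {
  fr <- location_density(params, effective_distance(data$distance_m, r_eff))
  denom <- sum(data$area_m2 * fr)
  if (denom <= 0 || !is.finite(denom)) return(NA_real_)
  log(sum(data$count)) - log(denom)
}

# Method-of-moments starting values: match the count-weighted mean distance
# to the kernel's mean with shape fixed at a neutral value, then set logQ at
# its profile optimum.
mom_start <- function(family, data, r_eff) {
  r <- effective_distance(data$distance_m, r_eff)
  w <- data$count
  rbar <- if (sum(w) > 0) sum(w * r) / sum(w) else mean(r)
  rbar <- max(rbar, 0.5)
  b0 <- switch(family, twoDt = 2.5, power_exponential = 1, 2)
  unit <- kernel_params(family, 1,
                        if (n_shape_params(family) == 0L) NULL else b0)
  a0 <- rbar / distance_mean(unit)
  params0 <- kernel_params(family, a0,
                           if (n_shape_params(family) == 0L) NULL else b0)
  logQ0 <- profile_logQ(params0, data, r_eff)
  if (!is.finite(logQ0)) logQ0 <- log(max(sum(data$count), 1))
  params_to_theta(params0, logQ0)
}

# Run an expression with a private, fixed RNG stream, restoring the caller's
# RNG state afterwards, so jittered starts never perturb user-level seeds.
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit one dispersal kernel family to collector counts
#'
#' Minimizes the Poisson negative log-likelihood of the count model over
#' `(logQ, log a[, log b])` by multi-start Nelder-Mead with a BFGS polish.
#' The first start is a method-of-moments guess (scale matched to the
#' count-weighted mean distance, profile-optimal `logQ`); the remaining
#' starts jitter it with a fixed seeded generator, so repeated calls on the
#' same data give identical results.
#'
#' @param family A kernel family name (see [kernel_families()]).
#' @param data Data frame with columns `distance_m`, `area_m2`, `count`;
#'   counts must be nonnegative integers.
#' @param control A [fit_control()] object.
#' @return An object of class `kernel_fit`: a list with elements `family`,
#'   `params` ([kernel_params()]), `logQ`, `loglik`, `n_obs`,
#'   `n_free_params`, `converged`, and `subset`.
#' @export
#' @examples
#' set.seed(1)
#' lay <- generate_layout(experiment_design(n_sites = 1), seed = 1)
#' cnt <- simulate_counts(lay, synthetic_truth(seed = 1))
#' fit_kernel("weibull", cnt)
fit_kernel <- function(family, data, control = fit_control()) {
  family <- match.arg(family, kernel_families())
  validate_count_data(data)
  total_direction <- sum(data$count[data$distance_m > 0])
  if (nrow(data) == 0L || total_direction < control$min_count)
    stop(sprintf(paste0("subset has %d recruits on directional collectors, ",
                        "below the minimum of %s required to fit; excluded ",
                        "to avoid misleading dispersal estimates"),
                 total_direction, format(control$min_count)), call. = FALSE)

  start0 <- mom_start(family, data, control$r_eff)
  starts <- list(start0)
  if (control$n_starts > 1L) {
    jit <- with_private_rng(760613L, {
      lapply(seq_len(control$n_starts - 1L), function(i)
        start0 + stats::rnorm(length(start0), sd = control$jitter_sd))
    })
    starts <- c(starts, jit)
  }

  nll_fun <- function(th) kernel_nll(family, th, data, control$r_eff)
  best <- NULL
  any_converged <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll_fun, method = "Nelder-Mead",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    polish <- tryCatch(
      suppressWarnings(
        stats::optim(opt$par, nll_fun, method = "BFGS",
                     control = list(maxit = control$maxit,
                                    reltol = control$reltol))),
      error = function(e) NULL)
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value <= opt$value) opt <- polish
    if (opt$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  if (is.null(best))
    return(structure(list(family = family, params = NULL, logQ = NA_real_,
                          loglik = NA_real_, n_obs = nrow(data),
                          n_free_params = 2L + n_shape_params(family),
                          converged = FALSE, subset = subset_label(data)),
                     class = "kernel_fit"))

  params <- theta_to_params(family, best$par)
  structure(list(family = family, params = params, logQ = best$par[1L],
                 loglik = -best$value, n_obs = nrow(data),
                 n_free_params = 2L + n_shape_params(family),
                 converged = any_converged, subset = subset_label(data)),
            class = "kernel_fit")
}

subset_label <- function(data) {
  site <- unique(data$site)
  dir <- setdiff(unique(as.character(data$direction)), "SOURCE")
  c(site = if (length(site) == 1L) as.character(site) else NA_character_,
    direction = if (length(dir) == 1L) dir else NA_character_)
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel fit: %s%s>\n", x$family,
              if (!x$converged) " (not converged)" else ""))
  if (!is.null(x$params)) {
    cat(sprintf("  logQ = %.3f, a = %.3f%s\n", x$logQ, x$params$a,
                if (is.null(x$params$b)) ""
                else sprintf(", b = %.3f", x$params$b)))
    cat(sprintf("  loglik = %.3f on %d collectors\n", x$loglik, x$n_obs))
  }
  invisible(x)
}

#' @export
as.data.frame.kernel_fit <- function(x, ...) {
  data.frame(site = unname(x$subset["site"]),
             direction = unname(x$subset["direction"]),
             family = x$family,
             logQ = x$logQ,
             a = if (is.null(x$params)) NA_real_ else x$params$a,
             b = if (is.null(x$params) || is.null(x$params$b)) NA_real_
                 else x$params$b,
             loglik = x$loglik,
             n_obs = x$n_obs,
             n_free_params = x$n_free_params,
             converged = x$converged,
             stringsAsFactors = FALSE)
}

validate_count_data <- function(data) {
  req <- c("site", "direction", "distance_m", "area_m2", "count")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L)
    stop("count table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_dir <- !(as.character(data$direction) %in% c(DIRECTIONS, "SOURCE"))
  if (any(bad_dir))
    stop("unknown direction label(s) in row(s) ",
         paste(utils::head(which(bad_dir), 10L), collapse = ", "),
         ": ", paste(unique(data$direction[bad_dir]), collapse = ", "),
         call. = FALSE)
  src_mismatch <- xor(data$distance_m == 0, data$direction == "SOURCE")
  if (any(src_mismatch))
    stop("distance 0 must coincide with direction SOURCE; offending row(s): ",
         paste(utils::head(which(src_mismatch), 10L), collapse = ", "),
         call. = FALSE)
  if (any(data$distance_m < 0)) stop("negative distances", call. = FALSE)
  if (any(data$area_m2 <= 0)) stop("non-positive tile areas", call. = FALSE)
  if (any(data$count < 0) || any(data$count != round(data$count)))
    stop("counts must be nonnegative integers", call. = FALSE)
  invisible(TRUE)
}

#' Fit all kernel families to every site-by-direction subset
#'
#' Splits the count table by site and cardinal direction, appends each site's
#' shared source collectors (distance 0, direction `SOURCE`) to each of its
#' four directional subsets so every fit is anchored near the source, and
#' fits each requested family to each subset. Subsets whose directional
#' collectors hold fewer than `control$min_count` recruits are excluded and
#' listed with the reason.
#'
#' @param data Count table with columns `site`, `direction`, `distance_m`,
#'   `area_m2`, `count` (see [read_counts()]).
#' @param families Character vector of kernel family names to fit.
#' @param control A [fit_control()] object.
#' @return A list of class `kernel_fit_set` with elements `fits` (list of
#'   [fit_kernel()] results), `table` (one row per fit), and `exclusions`
#'   (data frame of skipped subsets).
#' @export
fit_all <- function(data, families = kernel_families(),
                    control = fit_control()) {
  validate_count_data(data)
  families <- vapply(families, match.arg, "", choices = kernel_families())
  fits <- list()
  excl <- list()
  for (site in unique(data$site)) {
    site_rows <- data[data$site == site, , drop = FALSE]
    source_rows <- site_rows[site_rows$direction == "SOURCE", , drop = FALSE]
    for (dir in intersect(DIRECTIONS, unique(site_rows$direction))) {
      sub <- rbind(site_rows[site_rows$direction == dir, , drop = FALSE],
                   source_rows)
      total <- sum(sub$count[sub$distance_m > 0])
      if (total < control$min_count) {
        excl[[length(excl) + 1L]] <- data.frame(
          site = as.character(site), direction = dir, total_count = total,
          reason = sprintf("directional recruit count %d below minimum %s",
                           total, format(control$min_count)),
          stringsAsFactors = FALSE)
        next
      }
      for (fam in families) {
        fit <- fit_kernel(fam, sub, control)
        fits[[length(fits) + 1L]] <- fit
      }
    }
  }
  tab <- if (length(fits) > 0L)
    do.call(rbind, lapply(fits, as.data.frame)) else
    data.frame()
  exclusions <- if (length(excl) > 0L) do.call(rbind, excl) else
    data.frame(site = character(), direction = character(),
               total_count = integer(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(fits = fits, table = tab, exclusions = exclusions),
            class = "kernel_fit_set")
}

#' @export
print.kernel_fit_set <- function(x, ...) {
  cat(sprintf("<kernel fit set: %d fits, %d excluded subset(s)>\n",
              length(x$fits), nrow(x$exclusions)))
  invisible(x)
}

#' Read a collector count table
#'
#' Comma-separated UTF-8 text with header; required columns `site`,
#' `direction` (N/E/S/W/SOURCE), `distance_m`, `area_m2`, `count`, and
#' optionally `census`.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_counts <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_count_data(data)
  data
}
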