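# Pipeline glue: run configurations, file-based entry points tying the
# simulation, fitting, selection, distance and survival stages together,
# and the bundled reference table of fitted Weibull kernels. A thin
# command-line wrapper over these functions ships in inst/cli/dispkern.R.

#' Read a pipeline run configuration
#'
#' YAML or JSON file with either an `input` block (`counts`, `survival` file
#' paths) or a `synthetic` block (fields of [experiment_design()] and
#' [synthetic_truth()]), plus optional `families`, `r_eff`, `min_count`,
#' `seed`, and `out_dir`. Exactly one of `input` / `synthetic` must be
#' present.
#'
#' @param path Path to the configuration file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_input <- !is.null(cfg$input)
  has_synth <- !is.null(cfg$synthetic)
  if (has_input == has_synth)
    stop("config must contain exactly one of 'input' or 'synthetic'",
         call. = FALSE)
  if (!is.null(cfg$families)) {
    bad <- setdiff(cfg$families, kernel_families())
    if (length(bad) > 0L)
      stop("config field 'families' has unknown value(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (num in c("r_eff", "min_count", "seed")) {
    if (!is.null(cfg[[num]]) && !is.numeric(cfg[[num]]))
      stop(sprintf("config field '%s' must be numeric", num), call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

config_design <- function(cfg) {
  syn <- cfg$synthetic
  do.call(experiment_design,
          syn[intersect(names(syn),
                        names(formals(experiment_design)))])
}

config_truth <- function(cfg) {
  syn <- cfg$synthetic
  kernel <- if (!is.null(syn$kernel))
    kernel_params(syn$kernel$family, syn$kernel$a, syn$kernel$b)
  else kernel_params("weibull", a = 8, b = 2)
  synthetic_truth(kernel = kernel,
                  logQ = syn$logQ %||% 11.5,
                  survival_inside = syn$survival_inside %||% 0.30,
                  survival_outside = syn$survival_outside %||% 0.55,
                  seed = cfg$seed %||% 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Simulate an experiment and write its data files
#'
#' Writes `counts.csv`, `survival.csv` and `truth.yaml` (the generating
#' parameters, for recovery scoring) to `out_dir`. Re-running with the same
#' configuration produces byte-identical files.
#'
#' @param config A `run_config` (see [read_run_config()]) with a
#'   `synthetic` block, or `NULL` to use the defaults.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the named vector of file paths.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  if (is.null(config)) {
    design <- experiment_design()
    truth <- synthetic_truth()
  } else {
    if (is.null(config$synthetic))
      stop("run_simulate() needs a config with a 'synthetic' block",
           call. = FALSE)
    design <- config_design(config)
    truth <- config_truth(config)
  }
  sim <- simulate_experiment(design, truth,
                             r_eff = config$r_eff %||% 0.1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(out_dir, "counts.csv"),
             survival = file.path(out_dir, "survival.csv"),
             truth = file.path(out_dir, "truth.yaml"))
  utils::write.csv(sim$counts, paths["counts"], row.names = FALSE)
  utils::write.csv(sim$survival, paths["survival"], row.names = FALSE)
  yaml::write_yaml(list(kernel = list(family = truth$kernel$family,
                                      a = truth$kernel$a,
                                      b = truth$kernel$b),
                        logQ = truth$logQ,
                        survival_inside = truth$survival_inside,
                        survival_outside = truth$survival_outside,
                        seed = truth$seed),
                   paths["truth"])
  invisible(paths)
}

#' Fit, select and summarize dispersal kernels from a count table
#'
#' Runs the full dispersal stage: per site-by-direction fits of every
#' requested kernel family, the AIC selection table with Akaike weights,
#' the consensus family, and the median and 95th-percentile dispersal
#' distances of the consensus fits with their grand means. If `out_dir` is
#' given, writes `fits.csv`, `selection.csv`, `distances.csv` and
#' `exclusions.csv`.
#'
#' @param counts A count table or path to one (see [read_counts()]).
#' @param families Kernel families to fit.
#' @param control A [fit_control()].
#' @param out_dir Optional output directory.
#' @return A list with `fits` (the `kernel_fit_set`), `selection`,
#'   `consensus`, and `distances`.
#' @export
run_fit <- function(counts, families = kernel_families(),
                    control = fit_control(), out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  fit_set <- fit_all(counts, families = families, control = control)
  if (length(fit_set$fits) == 0L)
    stop("no subset met the minimum-count threshold; nothing was fitted",
         call. = FALSE)
  selection <- selection_table(fit_set)
  consensus <- consensus_best_family(selection)
  distances <- dispersal_distances(fit_set, family = consensus$family)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fit_set$table, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(selection, file.path(out_dir, "selection.csv"),
                     row.names = FALSE)
    dist_tab <- distances$distances
    utils::write.csv(dist_tab, file.path(out_dir, "distances.csv"),
                     row.names = FALSE)
    utils::write.csv(fit_set$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  list(fits = fit_set, selection = selection, consensus = consensus,
       distances = distances)
}

#' Run the recruit survival analysis from a survival table
#'
#' Computes survival proportions per canopy position and census, and fits
#' the binomial logit GLM for the canopy density-dependence test. If
#' `out_dir` is given, writes `proportions.csv` and `glm_summary.csv`
#' (coefficient, SE, and the per-term Wald chi-square table).
#'
#' @param records A survival table or path to one (see [read_survival()]).
#' @param formula Model formula for [fit_binomial_glm()].
#' @param out_dir Optional output directory.
#' @return A list with `proportions` and `glm` (a `survival_glm`).
#' @export
run_survival <- function(records, formula = ~ position * site,
                         out_dir = NULL) {
  if (is.character(records)) records <- read_survival(records)
  proportions <- survival_proportion(records, by = c("position"))
  model <- fit_binomial_glm(records, formula = formula)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(proportions, file.path(out_dir, "proportions.csv"),
                     row.names = FALSE)
    coefs <- data.frame(coefficient = names(model$coefficients),
                        estimate = unname(model$coefficients),
                        se = sqrt(diag(model$covariance)))
    utils::write.csv(merge_summary(coefs, model$wald),
                     file.path(out_dir, "glm_summary.csv"),
                     row.names = FALSE)
  }
  list(proportions = proportions, glm = model)
}

merge_summary <- function(coefs, wald) {
  coefs$section <- "coefficient"
  wald2 <- data.frame(coefficient = wald$term, estimate = wald$statistic,
                      se = NA_real_, section = "wald_chisq")
  wald2$df <- wald$df; wald2$p <- wald$p
  coefs$df <- NA_integer_; coefs$p <- NA_real_
  rbind(coefs, wald2)
}

#' Reference table of fitted Weibull dispersal kernels
#'
#' The published maximum-likelihood Weibull kernel fits for a three-site
#' *Cystoseira zosteroides* settlement experiment: per site and orientation,
#' log propagule number `logQ`, scale `a` (m), shape `b`, and the reported
#' median and 95th-percentile dispersal distances (m). Two transects with
#' too few recruits to fit are absent, leaving ten rows. Useful as a worked
#' example and as a check of the quantile machinery against independently
#' reported distances.
#'
#' @return Data frame with columns `site`, `orientation`, `logQ`, `a`, `b`,
#'   `median_m`, `q95_m`.
#' @export
#' @examples
#' tab <- weibull_fit_table()
#' k <- kernel_params("weibull", a = tab$a[1], b = tab$b[1])
#' distance_quantile(k, c(0.5, 0.95))
weibull_fit_table <- function() {
  path <- system.file("extdata", "czosteroides_weibull_fits.csv",
                      package = "dispkern", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
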