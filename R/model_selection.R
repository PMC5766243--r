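# AIC model selection among the candidate kernel families, per
# site x direction subset, and the consensus best family across subsets.

#' Akaike information criterion
#'
#' `AIC = -2 logL + 2V` with `V` free parameters. With `correct = TRUE` the
#' small-sample correction `AICc = AIC + 2V(V+1)/(n - V - 1)` is applied
#' (off by default; the plain AIC is the conventional choice for these
#' kernel comparisons).
#'
#' @param loglik Maximized log-likelihood.
#' @param n_free_params Number of free parameters `V` (>= 1).
#' @param correct Apply the small-sample correction?
#' @param n_obs Number of observations; required when `correct = TRUE`.
#' @return AIC value(s).
#' @export
#' @examples
#' aic(-100, 3)  # 206
aic <- function(loglik, n_free_params, correct = FALSE, n_obs = NULL) {
  if (any(n_free_params < 1)) stop("n_free_params must be >= 1", call. = FALSE)
  out <- -2 * loglik + 2 * n_free_params
  if (correct) {
    if (is.null(n_obs)) stop("n_obs is required for AICc", call. = FALSE)
    out <- out + 2 * n_free_params * (n_free_params + 1) /
      (n_obs - n_free_params - 1)
  }
  out
}

#' AIC differences from the best candidate
#'
#' @param aics Numeric vector of AIC values, one per candidate model.
#' @return `aics - min(aics)`; at least one element is exactly zero.
#' @export
#' @examples
#' delta_aic(c(100, 102, 110))
delta_aic <- function(aics) {
  if (length(aics) == 0L) stop("'aics' must be nonempty", call. = FALSE)
  aics - min(aics)
}

#' Akaike weights
#'
#' Normalized model evidence `w_i = exp(-delta_i / 2) / sum_k exp(-delta_k /
#' 2)`; the weights sum to one and decrease monotonically in the AIC
#' difference.
#'
#' @param delta Vector of AIC differences from [delta_aic()].
#' @return Vector of probabilities summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 2))
akaike_weights <- function(delta) {
  if (length(delta) == 0L) stop("'delta' must be nonempty", call. = FALSE)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Per-subset model selection table
#'
#' Ranks the fitted kernel families within each site-by-direction subset by
#' AIC and attaches AIC differences and Akaike weights.
#'
#' @param fit_set A `kernel_fit_set` from [fit_all()], or its `table`
#'   data frame.
#' @param correct Use the small-sample AICc instead of AIC.
#' @return A data frame with columns `site`, `direction`, `family`,
#'   `loglik`, `aic`, `delta_aic`, `weight`, `rank`.
#' @export
selection_table <- function(fit_set, correct = FALSE) {
  tab <- if (inherits(fit_set, "kernel_fit_set")) fit_set$table else fit_set
  if (nrow(tab) == 0L) stop("no fits to select among", call. = FALSE)
  tab$aic <- aic(tab$loglik, tab$n_free_params, correct = correct,
                 n_obs = if (correct) tab$n_obs else NULL)
  pieces <- lapply(split(tab, list(tab$site, tab$direction), drop = TRUE),
                   function(g) {
    g$delta_aic <- delta_aic(g$aic)
    g$weight <- akaike_weights(g$delta_aic)
    g$rank <- rank(g$aic, ties.method = "min")
    g[order(g$rank), c("site", "direction", "family", "loglik", "aic",
                       "delta_aic", "weight", "rank")]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Consensus best kernel family across subsets
#'
#' The family that ranks first (minimum AIC) in the largest number of
#' site-by-direction subsets. Ties in the rank-1 tally are broken by the
#' summed Akaike weight across all subsets, and flagged.
#'
#' @param selection A selection table from [selection_table()].
#' @return A list with elements `family` (the consensus choice), `tally`
#'   (data frame of rank-1 counts and summed weights per family),
#'   `n_subsets`, and `tie` (logical).
#' @export
consensus_best_family <- function(selection) {
  if (nrow(selection) == 0L) stop("empty selection table", call. = FALSE)
  fams <- sort(unique(selection$family))
  best <- selection[selection$rank == 1L, , drop = FALSE]
  # a subset can hold several rank-1 rows on exact AIC ties; each counts
  tally <- data.frame(
    family = fams,
    n_best = vapply(fams, function(f) sum(best$family == f), integer(1)),
    sum_weight = vapply(fams, function(f)
      sum(selection$weight[selection$family == f]), numeric(1)),
    stringsAsFactors = FALSE)
  tally <- tally[order(-tally$n_best, -tally$sum_weight, tally$family), ]
  rownames(tally) <- NULL
  tie <- sum(tally$n_best == tally$n_best[1L]) > 1L
  list(family = tally$family[1L], tally = tally,
       n_subsets = length(unique(paste(selection$site, selection$direction))),
       tie = tie)
}

#' Median and tail dispersal distances from fitted kernels
#'
#' For each fitted subset of the chosen family, computes quantile dispersal
#' distances (by default the median and the 95th percentile, the
#' conventional measures of the average dispersal distance and its tail),
#' plus their grand means across subsets.
#'
#' @param fit_set A `kernel_fit_set` from [fit_all()].
#' @param family Family whose fits to summarize; defaults to the consensus
#'   best family over the set.
#' @param probs Quantile probabilities.
#' @return A list with `distances` (per-subset data frame, columns `site`,
#'   `direction`, `logQ`, `a`, `b`, then one column per quantile) and
#'   `means` (named vector of grand means across subsets).
#' @export
dispersal_distances <- function(fit_set, family = NULL,
                                probs = c(0.5, 0.95)) {
  stopifnot(inherits(fit_set, "kernel_fit_set"))
  if (is.null(family)) {
    family <- consensus_best_family(selection_table(fit_set))$family
  }
  fits <- Filter(function(f) f$family == family && f$converged, fit_set$fits)
  if (length(fits) == 0L)
    stop(sprintf("no converged fits for family '%s'", family), call. = FALSE)
  qnames <- sprintf("q%02d", round(probs * 100))
  rows <- lapply(fits, function(f) {
    qs <- distance_quantile(f$params, probs)
    cbind(as.data.frame(f)[, c("site", "direction", "logQ", "a", "b")],
          stats::setNames(as.data.frame(as.list(qs)), qnames))
  })
  distances <- do.call(rbind, rows)
  rownames(distances) <- NULL
  means <- colMeans(distances[, qnames, drop = FALSE])
  list(family = family, distances = distances, means = means)
}
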