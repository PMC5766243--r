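# Recruit survival across censuses and the density-dependence test:
# yearly survival inside versus outside the adult canopy, modelled with a
# binomial logit GLM and Wald chi-square tests per term.

#' Read a recruit survival table
#'
#' Comma-separated UTF-8 text with header; required columns `tile_id`,
#' `site`, `position` (inside/outside), `census_day`, `alive`, `initial`,
#' and optionally `distance_m`.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_survival <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survival_data(data)
  data
}

validate_survival_data <- function(data) {
  req <- c("tile_id", "site", "position", "census_day", "alive", "initial")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L)
    stop("survival table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(data$position %in% c("inside", "outside")))
    stop("'position' must be 'inside' or 'outside'", call. = FALSE)
  if (any(data$alive < 0) || any(data$initial < 0) ||
      any(data$alive > data$initial))
    stop("need 0 <= alive <= initial", call. = FALSE)
  # alive counts must not increase over time within a tile
  for (tile in split(data, data$tile_id)) {
    tile <- tile[order(tile$census_day), , drop = FALSE]
    if (is.unsorted(rev(tile$alive)))
      stop(sprintf("alive counts increase over censuses for tile '%s'",
                   tile$tile_id[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Survival proportions by group and census
#'
#' Pools tiles within each group and census day and reports the survival
#' proportion `sum(alive) / sum(initial)` with its binomial standard error
#' `sqrt(p (1 - p) / sum(initial))`. Groups with zero initial recruits are
#' dropped with a warning.
#'
#' @param records Survival table (see [read_survival()]).
#' @param by Character vector of grouping columns (default `"position"`).
#' @return Data frame with the grouping columns, `census_day`, `n_initial`,
#'   `n_alive`, `proportion`, `se`.
#' @export
survival_proportion <- function(records, by = "position") {
  validate_survival_data(records)
  keys <- c(by, "census_day")
  groups <- split(records, records[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    n0 <- sum(g$initial)
    if (n0 == 0) return(NULL)
    p <- sum(g$alive) / n0
    cbind(g[1L, keys, drop = FALSE],
          data.frame(n_initial = n0, n_alive = sum(g$alive),
                     proportion = p, se = sqrt(p * (1 - p) / n0)))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(sprintf("%d group(s) with zero initial recruits dropped", dropped),
            call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial logit GLM for canopy density-dependence in recruit survival
#'
#' Fits yearly survival (alive at the final census out of the initial count
#' per tile) against canopy position, site, and their interaction, with a
#' binomial error distribution and logit link. To balance the design, only
#' tiles at 0 m (inside the canopy) and 1 m (just outside) are used when a
#' `distance_m` column is present. A Wald chi-square test is reported per
#' term from the coefficient covariance matrix.
#'
#' @param records Survival table (see [read_survival()]).
#' @param formula Right-hand-side model formula; terms must reference
#'   columns of `records`. Default `~ position * site`.
#' @param census_day Census (days) at which survival is analysed; default
#'   365, the yearly survival.
#' @param max_distance Tiles farther than this (m) are excluded when
#'   `distance_m` is present; default 1.
#' @return An object of class `survival_glm`: a list with the fitted `glm`
#'   object (`fit`), the per-term Wald table (`wald`), `coefficients`,
#'   `covariance` and `deviance`.
#' @export
#' @examples
#' rec <- data.frame(tile_id = c("t1", "t2"), site = "s1",
#'                   position = c("inside", "outside"), census_day = 365,
#'                   alive = c(30, 60), initial = c(100, 100))
#' fit_binomial_glm(rec, ~ position)
fit_binomial_glm <- function(records, formula = ~ position * site,
                             census_day = 365, max_distance = 1) {
  validate_survival_data(records)
  data <- records[records$census_day == census_day, , drop = FALSE]
  if (nrow(data) == 0L)
    stop(sprintf("no records at census_day %s", census_day), call. = FALSE)
  if ("distance_m" %in% names(data))
    data <- data[data$distance_m <= max_distance, , drop = FALSE]
  for (v in all.vars(formula)) {
    if (!v %in% names(data))
      stop(sprintf("formula term '%s' is not a column of the records", v),
           call. = FALSE)
    if (length(unique(data[[v]])) < 2L)
      stop(sprintf("factor '%s' has a single level in the analysed records",
                   v), call. = FALSE)
  }
  if (length(unique(data$position)) < 2L)
    stop("both canopy positions must be present", call. = FALSE)
  full <- stats::update(formula, cbind(alive, initial - alive) ~ .)
  fit <- stats::glm(full, family = stats::binomial("logit"), data = data)
  # complete separation shows up as fitted probabilities at the boundary
  # with exploding coefficients
  eps <- 1e-8
  if (any(abs(stats::coef(fit)) > 15) &&
      any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    cells <- unique(data[fit$fitted.values < eps |
                           fit$fitted.values > 1 - eps,
                         intersect(c("site", "position"), names(data)),
                         drop = FALSE])
    stop("complete separation: all-or-none survival in cell(s) ",
         paste(apply(cells, 1L, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 covariance = stats::vcov(fit),
                 deviance = stats::deviance(fit),
                 wald = wald_tests(fit)),
            class = "survival_glm")
}

#' Wald chi-square tests per model term
#'
#' For each term of a fitted GLM, tests that all of its coefficients are
#' zero with the Wald statistic `beta' V^-1 beta` on the term's block of the
#' coefficient covariance matrix; for a single-df term this reduces to
#' `(coef / SE)^2`.
#'
#' @param fit A fitted [stats::glm] object.
#' @return Data frame with columns `term`, `statistic`, `df`, `p`.
#' @export
wald_tests <- function(fit) {
  asgn <- attr(stats::model.matrix(fit), "assign")
  terms <- attr(stats::terms(fit), "term.labels")
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  rows <- lapply(seq_along(terms), function(i) {
    idx <- which(asgn == i & !is.na(beta))
    if (length(idx) == 0L) return(NULL)
    b <- beta[idx]
    stat <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE], b))
    data.frame(term = terms[i], statistic = stat, df = length(idx),
               p = stats::pchisq(stat, df = length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.survival_glm <- function(x, ...) {
  cat("<binomial logit GLM for recruit survival>\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat("Wald chi-square tests:\n")
  print(x$wald, row.names = FALSE)
  invisible(x)
}
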