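# Synthetic settlement experiments with the cross-shaped collector layout:
# per site, collectors at fixed distances along the four cardinal directions
# plus source collectors at distance 0, Poisson settlement counts following
# the count model c = A * Q * f(r), and binomial first-year recruit survival
# that is lower inside the adult canopy than outside.

#' Describe a settlement-collector experimental design
#'
#' Defaults reproduce the field layout of the study system: 3 sites, 7
#' distances (1, 2, 3, 4, 5, 7.5, 10 m) along each of the four cardinal
#' directions, plus 3 source collectors at distance 0, i.e. 31 collectors
#' per site; tile areas drawn uniformly from 0.04-0.06 m^2.
#'
#' @param n_sites Number of sites.
#' @param distances Collector distances from the source edge (m), all > 0.
#' @param directions Cardinal direction labels.
#' @param n_source_collectors Collectors inside the source stand
#'   (distance 0).
#' @param area_range Lower and upper bound of tile area (m^2).
#' @param anisotropy Optional named numeric vector of per-direction
#'   multipliers on the propagule number Q (e.g. `c(S = 2)`); unnamed
#'   directions default to 1.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(n_sites = 3,
                              distances = c(1, 2, 3, 4, 5, 7.5, 10),
                              directions = c("N", "E", "S", "W"),
                              n_source_collectors = 3,
                              area_range = c(0.04, 0.06),
                              anisotropy = NULL) {
  if (length(distances) == 0L)
    stop("'distances' must be nonempty", call. = FALSE)
  if (any(distances <= 0))
    stop("'distances' must be positive (source collectors are added via ",
         "n_source_collectors)", call. = FALSE)
  if (!all(directions %in% DIRECTIONS))
    stop("'directions' must be among N, E, S, W", call. = FALSE)
  stopifnot(n_sites >= 1, n_source_collectors >= 0,
            length(area_range) == 2L, all(area_range > 0),
            area_range[1] <= area_range[2])
  if (!is.null(anisotropy)) {
    if (is.null(names(anisotropy)) ||
        !all(names(anisotropy) %in% directions) || any(anisotropy <= 0))
      stop("'anisotropy' must be a named vector of positive multipliers ",
           "for a subset of the directions", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites), distances = distances,
                 directions = directions,
                 n_source_collectors = as.integer(n_source_collectors),
                 area_range = area_range, anisotropy = anisotropy),
            class = "experiment_design")
}

#' True parameter values for a synthetic experiment
#'
#' The defaults place the kernel inside the range of fitted values observed
#' in comparable settlement experiments (Weibull with scale 8 m, shape 2,
#' log propagule number 11.5, yielding some hundreds of recruits per site)
#' and make yearly survival lower inside the canopy (0.30) than outside
#' (0.55), the negative density-dependence the survival analysis is meant
#' to detect.
#'
#' @param kernel A [kernel_params()] object.
#' @param logQ Natural log of the propagule number per site and direction.
#' @param survival_inside,survival_outside Yearly survival probabilities in
#'   (0, 1].
#' @param seed Integer seed driving all simulation randomness.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(kernel = kernel_params("weibull", a = 8, b = 2),
                            logQ = 11.5,
                            survival_inside = 0.30,
                            survival_outside = 0.55,
                            seed = 1L) {
  stopifnot_kernel(kernel)
  stopifnot(is.finite(logQ),
            survival_inside > 0, survival_inside <= 1,
            survival_outside > 0, survival_outside <= 1)
  structure(list(kernel = kernel, logQ = logQ,
                 survival_inside = survival_inside,
                 survival_outside = survival_outside,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Enumerate the collectors of a design
#'
#' Deterministically lists every collector of every site with its direction,
#' distance, and a tile area drawn from the seeded generator; counts are not
#' yet simulated. Source collectors carry direction `SOURCE` and distance 0.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed for the tile areas.
#' @return Data frame with columns `tile_id`, `site`, `direction`,
#'   `distance_m`, `area_m2`.
#' @export
#' @examples
#' nrow(generate_layout(experiment_design(n_sites = 1), seed = 1))  # 31
generate_layout <- function(design = experiment_design(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  per_site <- rbind(
    expand.grid(direction = design$directions,
                distance_m = design$distances,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    if (design$n_source_collectors > 0L)
      data.frame(direction = "SOURCE",
                 distance_m = rep(0, design$n_source_collectors)))
  rows <- do.call(rbind, lapply(seq_len(design$n_sites), function(s) {
    cbind(site = sprintf("site%d", s), per_site)
  }))
  rows <- rows[order(rows$site, rows$direction, rows$distance_m), ,
               drop = FALSE]
  with_private_rng(seed, {
    rows$area_m2 <- stats::runif(nrow(rows), design$area_range[1],
                                 design$area_range[2])
  })
  rows$tile_id <- sprintf("%s_%s_%g_%d", rows$site, rows$direction,
                          rows$distance_m, stats::ave(
                            seq_len(nrow(rows)),
                            rows$site, rows$direction, rows$distance_m,
                            FUN = seq_along))
  rownames(rows) <- NULL
  rows[, c("tile_id", "site", "direction", "distance_m", "area_m2")]
}

#' Simulate settlement counts on a collector layout
#'
#' Draws each collector's recruit count from a Poisson distribution with
#' mean `A * Q * f(r)` (effective distance `r_eff` for source collectors),
#' applying any per-direction anisotropy multipliers of the design to Q.
#'
#' @param layout Output of [generate_layout()].
#' @param truth A [synthetic_truth()]; its `seed` drives the draws.
#' @param r_eff Effective distance (m) for the distance-0 collectors; keep
#'   equal to the value used at fitting time.
#' @param design The [experiment_design()] supplying anisotropy multipliers;
#'   omit for isotropic dispersal.
#' @return The layout with columns `count` and `census` (`"day0"`) added.
#' @export
simulate_counts <- function(layout, truth, r_eff = 0.1, design = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), nrow(layout) > 0L)
  mult <- rep(1, nrow(layout))
  if (!is.null(design) && !is.null(design$anisotropy)) {
    for (d in names(design$anisotropy))
      mult[layout$direction == d] <- design$anisotropy[[d]]
  }
  mu <- mult * expected_count(truth$kernel, truth$logQ, layout$distance_m,
                              layout$area_m2, r_eff = r_eff)
  out <- layout
  with_private_rng(truth$seed, {
    out$count <- stats::rpois(nrow(out), lambda = mu)
  })
  out$census <- "day0"
  out
}

#' Simulate recruit survival on settled tiles
#'
#' Takes the tiles inside the canopy (distance 0) and just outside it
#' (distance 1 m), uses their settlement counts as the initial cohort, and
#' thins each cohort through censuses at 60, 120 and 365 days by sequential
#' binomial draws. The yearly survival probability p (position-specific:
#' `survival_inside` under the canopy, `survival_outside` on bare ground) is
#' decomposed over census intervals with a constant per-day hazard,
#' `p_interval = p^(days / 365)`, so alive counts are monotone by
#' construction and the product of interval survivals equals p.
#'
#' @param counts Output of [simulate_counts()] (or any layout with a
#'   `count` column).
#' @param truth A [synthetic_truth()].
#' @param census_days Census times in days; day 0 is the initial census.
#' @param max_distance Tiles farther than this (m) are not followed;
#'   default 1, giving the balanced inside/outside comparison.
#' @return Data frame with columns `tile_id`, `site`, `position`,
#'   `distance_m`, `census_day`, `alive`, `initial`.
#' @export
simulate_survival <- function(counts, truth,
                              census_days = c(0, 60, 120, 365),
                              max_distance = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            "count" %in% names(counts))
  tiles <- counts[counts$distance_m <= max_distance, , drop = FALSE]
  tiles$position <- ifelse(tiles$distance_m == 0, "inside", "outside")
  census_days <- sort(unique(census_days))
  stopifnot(census_days[1] == 0)
  rows <- vector("list", nrow(tiles) * length(census_days))
  with_private_rng(truth$seed + 1L, {
    k <- 0L
    for (i in seq_len(nrow(tiles))) {
      p_year <- if (tiles$position[i] == "inside") truth$survival_inside
                else truth$survival_outside
      alive <- tiles$count[i]
      initial <- alive
      for (j in seq_along(census_days)) {
        if (j > 1L) {
          dt <- census_days[j] - census_days[j - 1L]
          alive <- stats::rbinom(1L, alive, p_year^(dt / 365))
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          tile_id = tiles$tile_id[i], site = tiles$site[i],
          position = tiles$position[i], distance_m = tiles$distance_m[i],
          census_day = census_days[j], alive = alive, initial = initial,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full settlement experiment
#'
#' Convenience wrapper: layout, settlement counts, and survival records in
#' one call, all driven by the truth's seed.
#'
#' @param design An [experiment_design()].
#' @param truth A [synthetic_truth()].
#' @param r_eff Effective distance for distance-0 collectors.
#' @return A list with elements `layout`, `counts`, `survival`, `truth`.
#' @export
#' @examples
#' sim <- simulate_experiment(experiment_design(n_sites = 1),
#'                            synthetic_truth(seed = 42))
#' head(sim$counts)
simulate_experiment <- function(design = experiment_design(),
                                truth = synthetic_truth(),
                                r_eff = 0.1) {
  layout <- generate_layout(design, seed = truth$seed)
  counts <- simulate_counts(layout, truth, r_eff = r_eff, design = design)
  surv <- simulate_survival(counts, truth)
  list(layout = layout, counts = counts, survival = surv, truth = truth)
}
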