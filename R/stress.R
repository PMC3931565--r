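#' Calibrate patch intensity against cell counts
#'
#' Ordinary least squares of cell count on patch intensity, establishing
#' the linear law used to convert image intensities to cell numbers.
#'
#' @param intensity,cell_count paired measurements (>= 3 pairs, all
#'   positive).
#' @return An object of class `calibration`: `slope` (cells per intensity
#'   unit), `intercept` (cells), `pearson_r`, `n`. A warning is raised if
#'   the fitted line predicts non-positive counts anywhere over the
#'   observed intensity range, or if the slope is not positive.
#' @examples
#' cal <- calibrate_intensity(1:10, 1000 * (1:10))
#' cal$slope  # 1000
#' @export
calibrate_intensity <- function(intensity, cell_count) {
  if (length(intensity) < 3L || length(cell_count) != length(intensity)) {
    stop("need at least 3 (intensity, cell_count) pairs")
  }
  if (any(intensity <= 0) || any(cell_count <= 0)) {
    stop("intensity and cell counts must be positive")
  }
  fit <- stats::lm(cell_count ~ intensity)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (slope <= 0) warning("calibration slope is not positive")
  pred <- intercept + slope * range(intensity)
  if (any(pred <= 0)) {
    warning("calibration predicts non-positive cell counts over the observed intensity range")
  }
  structure(list(slope = slope, intercept = intercept,
                 pearson_r = stats::cor(intensity, cell_count),
                 n = length(intensity)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Intensity-to-cell-count calibration: cells = %.4g + %.4g * intensity (r = %.4f, n = %d)\n",
              x$intercept, x$slope, x$pearson_r, x$n))
  invisible(x)
}

#' Convert intensities to cell counts with a calibration
#'
#' @param calibration a [calibrate_intensity()] result.
#' @param intensity intensities to convert.
#' @return Estimated cell counts.
#' @export
intensity_to_cells <- function(calibration, intensity) {
  stopifnot(inherits(calibration, "calibration"))
  calibration$intercept + calibration$slope * intensity
}

#' Mean growth rate and doublings of an agar patch
#'
#' The mean growth rate over the whole incubation is the natural-log ratio
#' of final to initial cell numbers divided by the incubation time
#' (per hour); doublings are the base-2 log ratio.
#'
#' @param cells_initial,cells_final,incubation_h positive numerics
#'   (vectors recycle).
#' @return A data.frame with columns `growth_rate` (per hour) and
#'   `doublings`.
#' @examples
#' patch_growth_rate(1e5, 8e5, 24)  # 3 doublings, ln(8)/24 per hour
#' @export
patch_growth_rate <- function(cells_initial, cells_final, incubation_h) {
  if (any(cells_initial <= 0) || any(cells_final <= 0)) {
    stop("cell counts must be positive")
  }
  if (any(incubation_h <= 0)) stop("incubation time must be positive")
  ratio <- cells_final / cells_initial
  data.frame(growth_rate = log(ratio) / incubation_h,
             doublings = log2(ratio))
}

#' Classify a strain x condition as grower or non-grower
#'
#' Applies the two-stage rule to the trials of one strain under one stress
#' condition: if the mean number of cell doublings over the trials is at
#' most `doubling_threshold` (default 3), the condition is classified
#' non-growing and all its fitness values are set to zero (the residual
#' doublings are attributed to carry-over from benign pre-growth); the
#' strain then counts as a grower iff at least one trial retains a
#' positive fitness score. Zeroing precedes the one-positive test, so a
#' condition with a single good trial among failures is still a
#' non-grower.
#'
#' @param growth_rate,doublings per-trial values (1-3 trials).
#' @param doubling_threshold mean-doublings cutoff (default 3).
#' @param zero_first apply the zeroing rule before the one-positive-trial
#'   test (default `TRUE`; `FALSE` gives the alternative order for
#'   sensitivity analysis).
#' @return A list: `is_grower`, `condition_nongrowing`, `growth_rate`
#'   (possibly zeroed), `doublings` (possibly zeroed).
#' @examples
#' classify_grower(c(0.10, 0, 0), c(3.5, 0, 0))$is_grower  # FALSE
#' @export
classify_grower <- function(growth_rate, doublings, doubling_threshold = 3,
                            zero_first = TRUE) {
  stopifnot(length(growth_rate) == length(doublings),
            length(growth_rate) >= 1L, length(growth_rate) <= 3L)
  nongrowing <- mean(doublings) <= doubling_threshold
  if (zero_first) {
    if (nongrowing) {
      growth_rate <- rep(0, length(growth_rate))
      doublings <- rep(0, length(doublings))
    }
    is_grower <- any(growth_rate > 0)
  } else {
    is_grower <- any(growth_rate > 0)
    if (nongrowing) {
      growth_rate <- rep(0, length(growth_rate))
      doublings <- rep(0, length(doublings))
    }
  }
  list(is_grower = is_grower, condition_nongrowing = nongrowing,
       growth_rate = growth_rate, doublings = doublings)
}

#' Agar-patch fitness from intensities
#'
#' The agar pipeline: converts initial and final patch intensities to cell
#' numbers with the calibration, computes per-trial growth rates and
#' doublings, and applies the grower classification per strain x agent x
#' dose condition.
#'
#' @param assays data.frame with columns `strain_id`, `stress_agent`,
#'   `dose`, `trial`, `intensity_initial`, `intensity_final`,
#'   `incubation_h`.
#' @param calibration a [calibrate_intensity()] result (or the
#'   (intensity, cell_count) pair table to fit one from).
#' @inheritParams classify_grower
#' @return A data.frame of class `agar_fitness`: the assay rows plus
#'   `cells_initial`, `cells_final`, `growth_rate`, `doublings`,
#'   `condition_nongrowing`, `is_grower` (constant within a
#'   strain x condition).
#' @export
agar_fitness <- function(assays, calibration, doubling_threshold = 3,
                         zero_first = TRUE) {
  need <- c("strain_id", "stress_agent", "dose", "trial",
            "intensity_initial", "intensity_final", "incubation_h")
  stopifnot(all(need %in% names(assays)))
  if (!inherits(calibration, "calibration")) {
    calibration <- calibrate_intensity(calibration$intensity,
                                       calibration$cell_count)
  }
  x <- assays
  x$cells_initial <- pmax(intensity_to_cells(calibration, x$intensity_initial), 1)
  x$cells_final <- pmax(intensity_to_cells(calibration, x$intensity_final), 1)
  pg <- patch_growth_rate(x$cells_initial, x$cells_final, x$incubation_h)
  x$growth_rate <- pg$growth_rate
  x$doublings <- pg$doublings
  x$condition_nongrowing <- NA
  x$is_grower <- NA
  key <- interaction(x$strain_id, x$stress_agent, x$dose, drop = TRUE)
  for (i in split(seq_len(nrow(x)), key)) {
    cl <- classify_grower(x$growth_rate[i], x$doublings[i],
                          doubling_threshold = doubling_threshold,
                          zero_first = zero_first)
    x$growth_rate[i] <- cl$growth_rate
    x$doublings[i] <- cl$doublings
    x$condition_nongrowing[i] <- cl$condition_nongrowing
    x$is_grower[i] <- cl$is_grower
  }
  class(x) <- c("agar_fitness", "data.frame")
  x
}

#' Survival curves along stress gradients
#'
#' Proportion of grower strains at each dose of each stress agent, within
#' groups of strains (e.g. homozygotes versus heterozygotes, split by
#' origin class).
#'
#' @param fitness an [agar_fitness()] table.
#' @param groups data.frame `strain_id`, `group` assigning each strain to
#'   one group; strains absent from it are dropped.
#' @return A data.frame: `stress_agent`, `dose`, `group`, `n_strains`,
#'   `n_growers`, `proportion` (in `[0, 1]`), doses ascending. Empty
#'   group x dose cells are omitted with a warning.
#' @export
survival_curve <- function(fitness, groups) {
  stopifnot(all(c("strain_id", "group") %in% names(groups)))
  per_cond <- unique(fitness[, c("strain_id", "stress_agent", "dose",
                                 "is_grower")])
  per_cond <- merge(per_cond, groups, by = "strain_id")
  if (nrow(per_cond) == 0L) stop("no strains shared between fitness and groups")
  agg <- aggregate(is_grower ~ stress_agent + dose + group, per_cond,
                   function(z) c(n = length(z), g = sum(z)))
  out <- data.frame(stress_agent = agg$stress_agent, dose = agg$dose,
                    group = agg$group,
                    n_strains = agg$is_grower[, "n"],
                    n_growers = agg$is_grower[, "g"])
  out$proportion <- out$n_growers / out$n_strains
  n_cond <- nrow(unique(per_cond[, c("stress_agent", "dose")]))
  if (nrow(out) < n_cond * length(unique(per_cond$group))) {
    warning("some group x dose cells are empty and were omitted")
  }
  out[order(out$stress_agent, out$group, out$dose), , drop = FALSE]
}

#' Normalize stress fitness by the grower median
#'
#' For each stress condition, divides every strain's mean growth rate by
#' the median growth rate of that condition's growers, putting the three
#' stresses on a common scale; non-growers keep a normalized fitness of 0.
#'
#' @param fitness an [agar_fitness()] table.
#' @param conditions data.frame `stress_agent`, `dose` selecting one
#'   condition per agent; default: the highest (most extreme) dose of each
#'   agent.
#' @return A data.frame: `strain_id`, `stress_agent`, `dose`, `rate`
#'   (strain-level mean growth rate, zeroed for non-growers),
#'   `normalized`, `is_grower`.
#' @export
normalize_fitness <- function(fitness, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- aggregate(dose ~ stress_agent, fitness, max)
  }
  rows <- list()
  for (k in seq_len(nrow(conditions))) {
    sub <- fitness[fitness$stress_agent == conditions$stress_agent[k] &
                     fitness$dose == conditions$dose[k], , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop(sprintf("no assays for condition %s dose %s",
                   conditions$stress_agent[k], conditions$dose[k]))
    }
    st <- aggregate(growth_rate ~ strain_id, sub, mean)
    names(st)[2L] <- "rate"
    gr <- unique(sub[, c("strain_id", "is_grower")])
    st <- merge(st, gr, by = "strain_id")
    med <- stats::median(st$rate[st$is_grower])
    if (!any(st$is_grower) || !is.finite(med) || med <= 0) {
      stop(sprintf("no viable growers under %s dose %s: cannot normalize",
                   conditions$stress_agent[k], conditions$dose[k]))
    }
    st$normalized <- ifelse(st$is_grower, st$rate / med, 0)
    st$stress_agent <- conditions$stress_agent[k]
    st$dose <- conditions$dose[k]
    rows[[k]] <- st[, c("strain_id", "stress_agent", "dose", "rate",
                        "normalized", "is_grower")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resampling null for cross-stress independence
#'
#' Builds the expected distribution of three-stress mean fitness under the
#' null that performance is uncorrelated across stresses: each draw picks
#' one normalized fitness value uniformly at random (with replacement,
#' zeros of non-growers included) from each stress's full value set and
#' records the mean of the three.
#'
#' @param values_by_stress list of numeric vectors, one per stress.
#' @param n_draws number of resampling draws (default 10000).
#' @param seed integer seed (required).
#' @return Numeric vector of `n_draws` resampled means.
#' @export
resample_null <- function(values_by_stress, n_draws = 10000L, seed) {
  stopifnot(is.list(values_by_stress), length(values_by_stress) >= 1L)
  if (missing(seed)) stop("resample_null() requires an explicit seed")
  for (v in values_by_stress) if (length(v) < 1L) {
    stop("every stress needs at least one value")
  }
  set.seed(seed)
  draws <- vapply(values_by_stress, function(v) {
    v[sample.int(length(v), n_draws, replace = TRUE)]
  }, numeric(n_draws))
  rowMeans(draws)
}

#' Per-strain mean fitness across stresses
#'
#' The empirical counterpart of [resample_null()]: each strain's mean
#' normalized fitness over the stresses it was assayed in (strains missing
#' any stress are dropped).
#'
#' @param normalized a [normalize_fitness()] table.
#' @return Named numeric vector of per-strain means.
#' @export
empirical_stress_means <- function(normalized) {
  n_stress <- length(unique(normalized$stress_agent))
  counts <- table(normalized$strain_id)
  keep <- names(counts)[counts == n_stress]
  sub <- normalized[normalized$strain_id %in% keep, , drop = FALSE]
  agg <- aggregate(normalized ~ strain_id, sub, mean)
  setNames(agg$normalized, agg$strain_id)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference of the two empirical
#' CDFs, evaluated at every pooled data point (so ties — ubiquitous here
#' because non-growers all sit at zero — are handled exactly). The
#' p-value uses the asymptotic Kolmogorov distribution at
#' `sqrt(n_eff) * D` with effective size `n_eff = n_a n_b / (n_a + n_b)`,
#' appropriate for the sample sizes of resampling comparisons.
#'
#' @param a,b the two samples (nonempty).
#' @return A `stat_test` with `statistic` = D (in `[0, 1]`) and the
#'   asymptotic two-sided p-value.
#' @examples
#' ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic  # 1
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  t <- sqrt(n_eff) * D
  p <- kolmogorov_sf(t)
  out <- stat_test("Two-sample Kolmogorov-Smirnov test (asymptotic)",
                   statistic = D, df = n_eff, p_value = p,
                   n = c(length(a), length(b)))
  out
}

# survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}
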