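#' Background-correct OD readings
#'
#' Subtracts a per-culture background estimate from the raw OD readings and
#' clips the result at `epsilon` so the log transform stays defined.
#' Methods: `"min_minus_eps"` (background = `min(od) - epsilon`, the
#' default, needing no blank), `"first_read"` (background = first reading
#' of the culture) and `"blank_well"` (background = median of the supplied
#' blank-well readings).
#'
#' @param plate a long-format plate table (columns `strain`, `environment`,
#'   `replicate`, `time_h`, `od`), e.g. from [read_plate_timeseries()] or
#'   [generate_od_curves()].
#' @param method background-correction method (see above).
#' @param blank numeric vector of blank-well OD readings; required for
#'   `method = "blank_well"`.
#' @param epsilon floor for corrected OD (default 0.005 OD units).
#' @return The plate table with an `od_corrected` column added. Cultures
#'   whose raw readings are all equal (uninformative under
#'   `min_minus_eps`) are flagged in the `"flagged"` attribute and a
#'   warning is raised.
#' @examples
#' plate <- data.frame(strain = "s", environment = "e", replicate = 1,
#'                     time_h = 0:2, od = c(0.10, 0.20, 0.40))
#' correct_background(plate, method = "first_read")$od_corrected
#' @export
correct_background <- function(plate,
                               method = c("min_minus_eps", "first_read",
                                          "blank_well"),
                               blank = NULL, epsilon = 0.005) {
  method <- match.arg(method)
  stopifnot(all(c("strain", "environment", "replicate", "time_h", "od") %in%
                  names(plate)))
  if (method == "blank_well" && is.null(blank)) {
    stop("method 'blank_well' requires blank-well readings")
  }
  ord <- order(plate$strain, plate$environment, plate$replicate,
               plate$time_h)
  plate <- plate[ord, , drop = FALSE]
  key <- interaction(plate$strain, plate$environment, plate$replicate,
                     drop = TRUE)
  corrected <- numeric(nrow(plate))
  flagged <- character()
  for (g in split(seq_len(nrow(plate)), key)) {
    od <- plate$od[g]
    b <- switch(method,
                min_minus_eps = min(od) - epsilon,
                first_read = od[1L],
                blank_well = stats::median(blank))
    if (method == "min_minus_eps" && length(unique(od)) == 1L) {
      flagged <- c(flagged, as.character(key[g[1L]]))
    }
    corrected[g] <- pmax(od - b, epsilon)
  }
  if (length(flagged)) {
    warning(sprintf("%d culture(s) have constant raw OD; background correction is uninformative: %s",
                    length(flagged), paste(flagged, collapse = ", ")))
  }
  plate$od_corrected <- corrected
  attr(plate, "background") <- list(method = method, epsilon = epsilon)
  attr(plate, "flagged") <- flagged
  rownames(plate) <- NULL
  plate
}

#' Select the shared exponential-phase OD window for one environment
#'
#' Finds lower and upper corrected-OD limits, shared by all cultures of an
#' environment, that maximise the mean (over cultures) Pearson correlation
#' between log corrected OD and time among the readings falling inside the
#' window. Candidate bounds are the `grid_size` quantiles of the pooled
#' corrected OD values (or every observed value when
#' `exhaustive = TRUE`). A candidate pair `(lo, hi)` is feasible only if
#' it lies inside every culture's observed OD span (the window is a range
#' every culture traverses) and every culture retains at least
#' `min_points` readings with `lo <= od_corrected <= hi` whose
#' correlation is defined; cultures occupying disjoint OD ranges therefore
#' raise the no-feasible-window error. Ties in the objective are broken by
#' the wider window, then the smaller lower bound.
#'
#' @param cultures a list of data.frames, one per culture, each with
#'   columns `time_h` and `od_corrected` (times strictly increasing).
#' @param grid_size number of quantile-based candidate bounds (default 25).
#' @param min_points minimum readings each culture must retain (default 5).
#' @param exhaustive use every observed OD value as a candidate bound
#'   (slow; intended as a reference mode).
#' @return A list of class `od_window`: `od_lower`, `od_upper`,
#'   `objective` (mean Pearson r attained), `n_candidates`.
#' @examples
#' cu <- data.frame(time_h = 0:9, od_corrected = 0.05 * exp(0.4 * 0:9))
#' select_window(list(cu))$objective  # exactly exponential: r = 1
#' @export
select_window <- function(cultures, grid_size = 25L, min_points = 5L,
                          exhaustive = FALSE) {
  stopifnot(length(cultures) >= 1L)
  for (cu in cultures) {
    stopifnot(all(c("time_h", "od_corrected") %in% names(cu)))
    if (nrow(cu) < min_points) {
      stop(sprintf("a culture has fewer than min_points = %d readings",
                   min_points))
    }
    if (any(cu$od_corrected <= 0)) {
      stop("od_corrected must be positive (run correct_background first)")
    }
  }
  pooled <- sort(unlist(lapply(cultures, function(cu) cu$od_corrected),
                        use.names = FALSE))
  cand <- if (exhaustive) unique(pooled) else
    unique(stats::quantile(pooled, probs = seq(0, 1, length.out = grid_size),
                           names = FALSE, type = 7))
  m <- length(cand)
  if (m < 2L) stop("not enough distinct OD values to form a window")
  lo <- rep(cand[-m], times = (m - 1L):1L)
  hi <- unlist(lapply(2:m, function(i) cand[i:m]), use.names = FALSE)
  npair <- length(lo)

  r_sum <- numeric(npair)
  feasible <- rep(TRUE, npair)
  for (cu in cultures) {
    ord <- order(cu$od_corrected, cu$time_h)
    odv <- cu$od_corrected[ord]
    tv <- cu$time_h[ord]
    yv <- log(odv)
    n <- length(odv)
    cs <- function(v) c(0, cumsum(v))
    St <- cs(tv); Sy <- cs(yv); Stt <- cs(tv * tv)
    Syy <- cs(yv * yv); Sty <- cs(tv * yv)
    a <- findInterval(lo, odv, left.open = TRUE)  # count of od < lo
    b <- findInterval(hi, odv)                     # count of od <= hi
    nn <- b - a
    ok <- nn >= min_points & lo >= odv[1L] & hi <= odv[n]
    feasible <- feasible & ok
    ia <- a + 1L; ib <- b + 1L
    st <- St[ib] - St[ia]; sy <- Sy[ib] - Sy[ia]
    stt <- Stt[ib] - Stt[ia]; syy <- Syy[ib] - Syy[ia]
    sty <- Sty[ib] - Sty[ia]
    covty <- sty - st * sy / nn
    vart <- pmax(stt - st * st / nn, 0)
    vary <- pmax(syy - sy * sy / nn, 0)
    denom <- sqrt(vart * vary)
    r <- ifelse(ok & denom > 1e-12, covty / denom, NA_real_)
    r <- pmin(pmax(r, -1), 1)
    feasible <- feasible & !is.na(r)
    r_sum <- r_sum + ifelse(is.na(r), 0, r)
  }
  if (!any(feasible)) {
    stop("no feasible OD window: no candidate range is shared by all ",
         "cultures with >= min_points readings each; lower min_points or ",
         "inspect the data")
  }
  obj <- ifelse(feasible, r_sum / length(cultures), -Inf)
  best <- max(obj)
  sel <- which(obj >= best - 1e-12)
  width <- hi[sel] - lo[sel]
  sel <- sel[width >= max(width) - 1e-12]
  sel <- sel[which.min(lo[sel])]
  structure(list(od_lower = lo[sel], od_upper = hi[sel],
                 objective = obj[sel], n_candidates = npair),
            class = "od_window")
}

#' @export
print.od_window <- function(x, ...) {
  cat(sprintf("OD window [%.4g, %.4g], mean Pearson r = %.6f (%d candidates searched)\n",
              x$od_lower, x$od_upper, x$objective, x$n_candidates))
  invisible(x)
}

#' Fit the maximum growth rate of one culture within an OD window
#'
#' Ordinary least squares of natural-log corrected OD on time over the
#' readings with `od_lower <= od_corrected <= od_upper`. The MGR is the
#' regression slope (per hour); `pearson_r` is the correlation of log OD
#' and time over the same points. The fit passes QC when it uses at least
#' `min_points` readings and attains `pearson_r >= qc_r_threshold`
#' (default 0.99, flagging the rare poorly linear fits).
#'
#' @param time_h,od_corrected the culture's readings.
#' @param window an `od_window` (or list with `od_lower`, `od_upper`).
#' @param min_points minimum readings for a QC pass (default 5).
#' @param qc_r_threshold minimum Pearson r for a QC pass (default 0.99).
#' @return A one-row data.frame: `mgr_per_h`, `pearson_r`, `n_points`,
#'   `od_lower`, `od_upper`, `qc_pass`. With fewer than 2 in-window points
#'   the MGR is `NA` and QC fails; with constant OD the slope is 0, the
#'   correlation undefined (`NA`) and QC fails.
#' @examples
#' t <- 0:5
#' od <- 0.05 * exp(0.5 * t)
#' fit_mgr(t, od, list(od_lower = min(od), od_upper = max(od)))
#' @export
fit_mgr <- function(time_h, od_corrected, window, min_points = 5L,
                    qc_r_threshold = 0.99) {
  keep <- od_corrected >= window$od_lower & od_corrected <= window$od_upper
  t <- time_h[keep]
  y <- log(od_corrected[keep])
  n <- length(t)
  if (n < 2L) {
    return(data.frame(mgr_per_h = NA_real_, pearson_r = NA_real_,
                      n_points = n, od_lower = window$od_lower,
                      od_upper = window$od_upper, qc_pass = FALSE))
  }
  vart <- sum((t - mean(t))^2)
  vary <- sum((y - mean(y))^2)
  covty <- sum((t - mean(t)) * (y - mean(y)))
  slope <- covty / vart
  r <- if (vary > 0) covty / sqrt(vart * vary) else NA_real_
  qc <- n >= min_points && !is.na(r) && r >= qc_r_threshold
  data.frame(mgr_per_h = slope, pearson_r = r, n_points = n,
             od_lower = window$od_lower, od_upper = window$od_upper,
             qc_pass = qc)
}

#' Estimate MGR for every culture of one environment
#'
#' Applies the cross-culture procedure to one environment: selects a single
#' OD window shared by all of the environment's cultures
#' ([select_window()]), then fits each culture within it ([fit_mgr()]).
#'
#' @param plate_env background-corrected plate table (one environment;
#'   must contain `od_corrected`).
#' @inheritParams select_window
#' @inheritParams fit_mgr
#' @return A data.frame with one row per culture (`strain`, `environment`,
#'   `replicate`, plus the [fit_mgr()] columns); the selected window is
#'   attached as attribute `"window"`.
#' @export
estimate_environment <- function(plate_env, grid_size = 25L, min_points = 5L,
                                 qc_r_threshold = 0.99, exhaustive = FALSE) {
  stopifnot("od_corrected" %in% names(plate_env))
  env <- unique(plate_env$environment)
  if (length(env) != 1L) stop("estimate_environment expects a single environment")
  grp <- interaction(plate_env$strain, plate_env$replicate, drop = TRUE)
  idx <- split(seq_len(nrow(plate_env)), grp)
  cultures <- lapply(idx, function(i)
    plate_env[i, c("time_h", "od_corrected")])
  win <- select_window(cultures, grid_size = grid_size,
                       min_points = min_points, exhaustive = exhaustive)
  fits <- lapply(idx, function(i) {
    cu <- plate_env[i, , drop = FALSE]
    cbind(data.frame(strain = cu$strain[1L], environment = env,
                     replicate = cu$replicate[1L],
                     stringsAsFactors = FALSE),
          fit_mgr(cu$time_h, cu$od_corrected, win,
                  min_points = min_points, qc_r_threshold = qc_r_threshold))
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  attr(out, "window") <- win
  out
}

#' Fit maximum growth rates for a whole plate experiment
#'
#' The top-level growth-rate estimator: background-corrects all OD
#' readings, then, independently for each environment, selects one shared
#' exponential-phase OD window and regresses log OD on time within it for
#' every culture.
#'
#' @inheritParams correct_background
#' @inheritParams select_window
#' @inheritParams fit_mgr
#' @param background background-correction method passed to
#'   [correct_background()].
#' @return An object of class `mgr_fit`: a list with `estimates` (one row
#'   per strain x environment x replicate), `windows` (one row per
#'   environment: bounds and attained mean r), `params` and `call`.
#'   Methods: [print.mgr_fit()], [summary.mgr_fit()], [coef.mgr_fit()]
#'   (strain x environment matrix of mean QC-passing MGR).
#' @examples
#' p <- sim_params(n_dom = 2, n_wild = 1, n_env = 1, n_rep = 2)
#' sim <- simulate_crosses(p, seed = 1, agar = FALSE)
#' fit <- fit_mgr_experiment(sim$plate)
#' fit
#' @export
fit_mgr_experiment <- function(plate,
                               background = c("min_minus_eps", "first_read",
                                              "blank_well"),
                               blank = NULL, epsilon = 0.005,
                               grid_size = 25L, min_points = 5L,
                               qc_r_threshold = 0.99, exhaustive = FALSE) {
  background <- match.arg(background)
  corrected <- correct_background(plate, method = background, blank = blank,
                                  epsilon = epsilon)
  envs <- unique(corrected$environment)
  ests <- list()
  wins <- list()
  for (e in envs) {
    est <- estimate_environment(corrected[corrected$environment == e, ,
                                          drop = FALSE],
                                grid_size = grid_size,
                                min_points = min_points,
                                qc_r_threshold = qc_r_threshold,
                                exhaustive = exhaustive)
    w <- attr(est, "window")
    wins[[length(wins) + 1L]] <- data.frame(
      environment = e, od_lower = w$od_lower, od_upper = w$od_upper,
      mean_r = w$objective, stringsAsFactors = FALSE)
    ests[[length(ests) + 1L]] <- est
  }
  structure(list(estimates = do.call(rbind, ests),
                 windows = do.call(rbind, wins),
                 params = list(background = background, epsilon = epsilon,
                               grid_size = grid_size,
                               min_points = min_points,
                               qc_r_threshold = qc_r_threshold),
                 call = match.call()),
            class = "mgr_fit")
}

#' @export
print.mgr_fit <- function(x, ...) {
  est <- x$estimates
  cat(sprintf("MGR fit: %d cultures, %d strains, %d environments\n",
              nrow(est), length(unique(est$strain)),
              length(unique(est$environment))))
  cat(sprintf("  QC pass: %d/%d (r >= %.3g, >= %d points)\n",
              sum(est$qc_pass), nrow(est), x$params$qc_r_threshold,
              x$params$min_points))
  cat(sprintf("  MGR range (QC-passing): %.4g to %.4g per hour\n",
              min(est$mgr_per_h[est$qc_pass]),
              max(est$mgr_per_h[est$qc_pass])))
  invisible(x)
}

#' @describeIn fit_mgr_experiment per-environment window bounds, mean
#'   Pearson r and QC failure counts.
#' @param object,x an `mgr_fit` object.
#' @param ... unused.
#' @export
summary.mgr_fit <- function(object, ...) {
  est <- object$estimates
  qc <- aggregate(qc_pass ~ environment, est,
                  function(z) c(fail = sum(!z), n = length(z)))
  out <- merge(object$windows,
               data.frame(environment = qc$environment,
                          n_cultures = qc$qc_pass[, "n"],
                          n_qc_fail = qc$qc_pass[, "fail"]),
               by = "environment")
  class(out) <- c("summary.mgr_fit", "data.frame")
  out
}

#' @export
print.summary.mgr_fit <- function(x, ...) {
  cat("Per-environment OD windows and QC\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn fit_mgr_experiment strain x environment matrix of mean
#'   QC-passing MGR (NA where no replicate passed).
#' @export
coef.mgr_fit <- function(object, ...) {
  fitness_matrix(object$estimates)
}

#' Mean fitness per strain and environment
#'
#' Averages replicate MGR estimates (QC-passing only, by default) into a
#' strain x environment matrix — the fitness table consumed by the
#' heterosis statistics.
#'
#' @param estimates a replicate-level MGR table with columns `strain`,
#'   `environment`, `mgr_per_h` and (optionally) `qc_pass`, e.g.
#'   `mgr_fit$estimates` or a table read with [read_mgr_table()].
#' @param qc_only drop QC-failing replicates first (default `TRUE`; if the
#'   table has no `qc_pass` column all rows are used).
#' @return A numeric matrix (strains in rows, environments in columns) with
#'   the replicate table retained in attribute `"replicates"`. Cells with
#'   no usable replicate are `NA`.
#' @export
fitness_matrix <- function(estimates, qc_only = TRUE) {
  stopifnot(all(c("strain", "environment", "mgr_per_h") %in% names(estimates)))
  keep <- estimates
  if (qc_only && "qc_pass" %in% names(estimates)) {
    keep <- estimates[estimates$qc_pass & !is.na(estimates$mgr_per_h), ,
                      drop = FALSE]
  }
  strains <- sort(unique(estimates$strain))
  envs <- sort(unique(estimates$environment))
  m <- matrix(NA_real_, length(strains), length(envs),
              dimnames = list(strains, envs))
  agg <- aggregate(mgr_per_h ~ strain + environment, keep, mean)
  m[cbind(match(agg$strain, strains), match(agg$environment, envs))] <-
    agg$mgr_per_h
  attr(m, "replicates") <- estimates
  m
}

#' Plot log OD trajectories and the selected window for one environment
#'
#' @param x an `mgr_fit` object.
#' @param plate the background-corrected plate table the fit was made from
#'   (pass the original table; it is re-corrected with the fit's settings).
#' @param environment which environment to show (default: the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mgr_fit <- function(x, plate, environment = NULL, ...) {
  if (missing(plate)) stop("plot.mgr_fit needs the plate table")
  if (is.null(environment)) environment <- x$windows$environment[1L]
  corrected <- correct_background(plate, method = x$params$background,
                                  epsilon = x$params$epsilon)
  pe <- corrected[corrected$environment == environment, , drop = FALSE]
  w <- x$windows[x$windows$environment == environment, ]
  grp <- interaction(pe$strain, pe$replicate, drop = TRUE)
  plot(range(pe$time_h), log(range(pe$od_corrected)), type = "n",
       xlab = "time (h)", ylab = "log corrected OD",
       main = sprintf("%s: window [%.3g, %.3g]", environment,
                      w$od_lower, w$od_upper), ...)
  for (i in split(seq_len(nrow(pe)), grp)) {
    lines(pe$time_h[i], log(pe$od_corrected[i]),
          col = grDevices::grey(0.4, 0.4))
  }
  abline(h = log(c(w$od_lower, w$od_upper)), col = 2, lty = 2)
  invisible(x)
}
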