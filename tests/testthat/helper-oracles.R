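# independent reference implementations used as oracles in tests

# brute-force OD window search: plain loops and cor(), no prefix sums
oracle_select_window <- function(cultures, grid_size = 25L, min_points = 5L) {
  pooled <- sort(unlist(lapply(cultures, function(cu) cu$od_corrected)))
  cand <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = grid_size),
                                 names = FALSE, type = 7))
  best <- NULL
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (cand[j] <= cand[i]) next
      lo <- cand[i]; hi <- cand[j]
      rs <- numeric(0)
      ok <- TRUE
      for (cu in cultures) {
        if (lo < min(cu$od_corrected) || hi > max(cu$od_corrected)) {
          ok <- FALSE; break
        }
        keep <- cu$od_corrected >= lo & cu$od_corrected <= hi
        if (sum(keep) < min_points) { ok <- FALSE; break }
        r <- suppressWarnings(stats::cor(cu$time_h[keep],
                                         log(cu$od_corrected[keep])))
        if (is.na(r)) { ok <- FALSE; break }
        rs <- c(rs, r)
      }
      if (!ok) next
      obj <- mean(rs)
      better <- is.null(best) ||
        obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
           (hi - lo > best$hi - best$lo + 1e-12 ||
              (abs((hi - lo) - (best$hi - best$lo)) <= 1e-12 && lo < best$lo)))
      if (better) best <- list(lo = lo, hi = hi, obj = obj)
    }
  }
  best
}

# brute-force two-sample KS distance over all pooled evaluation points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  D <- 0
  for (x in pts) {
    D <- max(D, abs(mean(a <= x) - mean(b <= x)))
  }
  D
}

# a clean exponential culture data.frame
exp_culture <- function(rate, od0 = 0.05, times = seq(0, 9, by = 0.5)) {
  data.frame(time_h = times, od_corrected = od0 * exp(rate * times))
}

# a small long-format plate with exponential growth plus noise
make_plate <- function(rates, env = "e1", od0 = 0.05, bg = 0.08,
                       times = seq(0, 9, by = 0.5), noise = 0) {
  do.call(rbind, lapply(seq_along(rates), function(i) {
    data.frame(strain = sprintf("s%02d", i), environment = env,
               replicate = 1L, time_h = times,
               od = od0 * exp(rates[i] * times) *
                 exp(stats::rnorm(length(times), 0, noise)) + bg)
  }))
}
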