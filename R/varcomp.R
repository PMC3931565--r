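#' Two-way random-effects variance components by expected mean squares
#'
#' Decomposes replicate-level fitness into environment, genotype,
#' genotype-by-environment and error variance using the method-of-moments
#' (expected mean squares) estimators for the balanced two-way random
#' model with interaction:
#' \deqn{\sigma^2_{err} = MS_{within}, \quad
#'       \sigma^2_{GE} = (MS_{GE} - MS_{within})/n, \quad
#'       \sigma^2_G = (MS_G - MS_{GE})/(e n), \quad
#'       \sigma^2_E = (MS_E - MS_{GE})/(g n)}
#' with `g` genotypes, `e` environments and `n` replicates per cell. Raw
#' estimates can be negative by sampling; both the raw values and their
#' absolute values (the conventional reporting scale for such displays)
#' are returned. On balanced data these estimators agree with REML for
#' this model.
#'
#' @param x data.frame with columns `genotype`, `environment`, `value`
#'   (replicate-level MGR); every genotype x environment cell must hold
#'   the same number `n >= 2` of replicates. Unbalanced input is an
#'   error — use [balance_replicates()] to subsample to balance.
#' @return An object of class `varcomp`: a data.frame with columns
#'   `component` (`environment`, `genotype`, `gxe`, `error`), `raw`,
#'   `reported` (= `abs(raw)`), plus attributes `mean_squares` and `dims`.
#' @examples
#' set.seed(1)
#' x <- expand.grid(genotype = letters[1:4], environment = LETTERS[1:3],
#'                  replicate = 1:2)
#' x$value <- rnorm(nrow(x))
#' varcomp_two_way(x)
#' @export
varcomp_two_way <- function(x) {
  stopifnot(all(c("genotype", "environment", "value") %in% names(x)))
  g <- factor(x$genotype)
  e <- factor(x$environment)
  counts <- table(g, e)
  if (any(counts == 0L)) stop("every genotype x environment cell needs data")
  n <- unique(as.vector(counts))
  if (length(n) != 1L) {
    stop("unbalanced design: replicate counts per cell differ; ",
         "use balance_replicates() to subsample to the minimum count")
  }
  if (n < 2L) {
    stop("need n >= 2 replicates per cell to separate interaction from error")
  }
  y <- x$value
  G <- nlevels(g); E <- nlevels(e)
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  em <- tapply(y, e, mean)
  cm <- tapply(y, list(g, e), mean)
  ss_g <- E * n * sum((gm - grand)^2)
  ss_e <- G * n * sum((em - grand)^2)
  ss_ge <- n * sum((sweep(sweep(cm, 1, gm), 2, em) + grand)^2)
  ss_w <- sum((y - cm[cbind(g, e)])^2)
  ms <- c(genotype = ss_g / (G - 1), environment = ss_e / (E - 1),
          gxe = ss_ge / ((G - 1) * (E - 1)), error = ss_w / (G * E * (n - 1)))
  raw <- c(environment = (ms["environment"] - ms["gxe"]) / (G * n),
           genotype = (ms["genotype"] - ms["gxe"]) / (E * n),
           gxe = (ms["gxe"] - ms["error"]) / n,
           error = ms["error"])
  names(raw) <- c("environment", "genotype", "gxe", "error")
  out <- data.frame(component = names(raw), raw = unname(raw),
                    reported = abs(unname(raw)), stringsAsFactors = FALSE)
  attr(out, "mean_squares") <- ms
  attr(out, "dims") <- c(g = G, e = E, n = n)
  class(out) <- c("varcomp", "data.frame")
  out
}

#' @export
print.varcomp <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("Variance components (EMS, %d genotypes x %d environments x %d replicates)\n",
              d["g"], d["e"], d["n"]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Subsample an unbalanced replicate table to balance
#'
#' Randomly keeps `min` replicates (the smallest cell count) in every
#' genotype x environment cell, so [varcomp_two_way()] can be applied.
#'
#' @inheritParams varcomp_two_way
#' @param seed integer seed for the subsampling (required, for
#'   reproducibility).
#' @return The balanced subset of `x`.
#' @export
balance_replicates <- function(x, seed) {
  stopifnot(all(c("genotype", "environment", "value") %in% names(x)))
  if (missing(seed)) stop("balance_replicates() requires an explicit seed")
  set.seed(seed)
  key <- interaction(x$genotype, x$environment, drop = TRUE)
  k <- min(table(key))
  keep <- unlist(lapply(split(seq_len(nrow(x)), key), function(i) {
    if (length(i) == k) i else sample(i, k)
  }), use.names = FALSE)
  x[sort(keep), , drop = FALSE]
}

#' One-way intraclass correlation of replicate measurements
#'
#' ICC(1) from the one-way random-effects ANOVA of replicate measurements
#' grouped by strain (within one environment):
#' \deqn{ICC = \frac{MS_{between} - MS_{within}}
#'                  {MS_{between} + (k - 1) MS_{within}}}
#' with `k` the replicate count per strain; for unbalanced data `k` is
#' replaced by Searle's adjusted mean count
#' `k0 = (N - sum(k_i^2) / N) / (s - 1)`. The reported value is truncated
#' below at 0; the raw value is kept in attribute `"raw"`.
#'
#' @param values replicate-level measurements.
#' @param strain grouping labels (>= 2 groups, each with >= 2 values for a
#'   meaningful ICC).
#' @return The ICC as a single number with attributes `raw`, `k` and (when
#'   degenerate) `flag`. All values identical returns 1 by convention.
#' @examples
#' icc_oneway(c(1, 1, 2, 2, 3, 3), rep(letters[1:3], each = 2))  # 1
#' @export
icc_oneway <- function(values, strain) {
  strain <- factor(strain)
  s <- nlevels(strain)
  if (s < 2L) stop("need at least 2 strains")
  N <- length(values)
  ki <- as.vector(table(strain))
  if (any(ki < 1L)) stop("empty strain group")
  if (stats::var(values) == 0) {
    out <- 1
    attr(out, "raw") <- 1
    attr(out, "k") <- mean(ki)
    attr(out, "flag") <- "all values identical: zero within- and between-variance"
    return(out)
  }
  k0 <- (N - sum(ki^2) / N) / (s - 1)
  gm <- tapply(values, strain, mean)
  grand <- mean(values)
  ss_b <- sum(ki * (gm - grand)^2)
  ss_w <- sum((values - gm[strain])^2)
  ms_b <- ss_b / (s - 1)
  ms_w <- ss_w / (N - s)
  raw <- (ms_b - ms_w) / (ms_b + (k0 - 1) * ms_w)
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  attr(out, "k") <- k0
  out
}

#' Average per-environment ICCs
#'
#' Arithmetic mean of one-way ICCs computed separately in each
#' environment — the experiment-level repeatability summary.
#'
#' @param iccs numeric vector of per-environment ICC values, or a
#'   replicate-level table (`strain`, `environment`, `mgr_per_h`) from
#'   which they are computed.
#' @return For a vector input, its mean. For a table input, a list with
#'   `per_environment` (named vector) and `average`.
#' @export
icc_average <- function(iccs) {
  if (is.numeric(iccs)) {
    stopifnot(length(iccs) >= 1L)
    return(mean(iccs))
  }
  stopifnot(all(c("strain", "environment", "mgr_per_h") %in% names(iccs)))
  df <- iccs
  if ("qc_pass" %in% names(df)) {
    df <- df[df$qc_pass & !is.na(df$mgr_per_h), , drop = FALSE]
  }
  per_env <- vapply(split(df, df$environment), function(g) {
    as.numeric(icc_oneway(g$mgr_per_h, g$strain))
  }, numeric(1))
  list(per_environment = per_env, average = mean(per_env))
}
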