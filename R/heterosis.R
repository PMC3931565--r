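#' Mid-parent and best-parent heterosis
#'
#' `midparent_heterosis()` is the hybrid's fitness minus the arithmetic
#' mean of its two parents' fitness. `bestparent_heterosis()` is the
#' hybrid's fitness minus the fitness of its fitter parent, so a positive
#' value means the hybrid outperforms even its best parent. Both are in
#' the units of the fitness measure (MGR per hour) and symmetric in the
#' parents, and `bph <= mph` always, with equality iff the parents are
#' equally fit.
#'
#' @param f_hybrid,f_p1,f_p2 fitness of the hybrid and its two parents
#'   (vectors recycle as usual).
#' @return Numeric vector of heterosis scores.
#' @examples
#' midparent_heterosis(0.55, 0.4, 0.6)  # 0.05
#' bestparent_heterosis(0.65, 0.4, 0.6) # 0.05
#' @export
midparent_heterosis <- function(f_hybrid, f_p1, f_p2) {
  f_hybrid - (f_p1 + f_p2) / 2
}

#' @rdname midparent_heterosis
#' @export
bestparent_heterosis <- function(f_hybrid, f_p1, f_p2) {
  f_hybrid - pmax(f_p1, f_p2)
}

#' Classify a cross by its parents' origins
#'
#' @param origin1,origin2 `"domesticated"` or `"wild"` (vectors recycle).
#' @return Character vector: `"DxD"` (both domesticated), `"WxW"` (both
#'   wild) or `"mixed"`. Symmetric in its arguments.
#' @examples
#' classify_cross("wild", "domesticated")  # "mixed"
#' @export
classify_cross <- function(origin1, origin2) {
  valid <- c("domesticated", "wild")
  if (!all(origin1 %in% valid) || !all(origin2 %in% valid)) {
    bad <- setdiff(unique(c(origin1, origin2)), valid)
    stop("unknown origin label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(origin1 == "domesticated" & origin2 == "domesticated", "DxD",
         ifelse(origin1 == "wild" & origin2 == "wild", "WxW", "mixed"))
}

#' Heterosis scores for every hybrid and environment
#'
#' Joins a strain x environment fitness table with the cross design and
#' computes MPH and BPH per hybrid x environment cell. Cells where the
#' hybrid or either parent has no usable fitness value (e.g. all
#' replicates failed QC) are excluded, with a message giving the count.
#'
#' @param fitness a strain x environment fitness matrix
#'   ([fitness_matrix()]) or a replicate-level MGR table (then averaged
#'   over QC-passing replicates first).
#' @param crosses cross design `data.frame(hybrid_id, parent1, parent2)`.
#' @param metadata strain metadata `data.frame(strain_id, origin)`; used to
#'   assign the cross class (omitted if `crosses` already carries a
#'   `cross_class` column).
#' @return A `data.frame` of class `heterosis_scores`: `hybrid_id`,
#'   `environment`, `cross_class`, `f_hybrid`, `f_p1`, `f_p2`, `mph`,
#'   `bph`, `parent1`, `parent2`.
#' @seealso [heterosis_summary()], [divergence_correlation()]
#' @export
heterosis_scores <- function(fitness, crosses, metadata = NULL) {
  if (!is.matrix(fitness)) fitness <- fitness_matrix(fitness)
  stopifnot(all(c("hybrid_id", "parent1", "parent2") %in% names(crosses)))
  if (!"cross_class" %in% names(crosses)) {
    if (is.null(metadata)) {
      stop("supply metadata (strain_id, origin) or a cross_class column")
    }
    org <- setNames(metadata$origin, metadata$strain_id)
    missing_par <- setdiff(unique(c(crosses$parent1, crosses$parent2)),
                           names(org))
    if (length(missing_par)) {
      stop("parents missing from metadata: ",
           paste(missing_par, collapse = ", "))
    }
    crosses$cross_class <- classify_cross(org[crosses$parent1],
                                          org[crosses$parent2])
  }
  envs <- colnames(fitness)
  n <- nrow(crosses) * length(envs)
  out <- data.frame(
    hybrid_id = rep(crosses$hybrid_id, times = length(envs)),
    environment = rep(envs, each = nrow(crosses)),
    cross_class = rep(crosses$cross_class, times = length(envs)),
    parent1 = rep(crosses$parent1, times = length(envs)),
    parent2 = rep(crosses$parent2, times = length(envs)),
    stringsAsFactors = FALSE)
  val <- function(id, env) {
    i <- match(id, rownames(fitness))
    j <- match(env, colnames(fitness))
    ifelse(is.na(i) | is.na(j), NA_real_, fitness[cbind(i, j)])
  }
  out$f_hybrid <- val(out$hybrid_id, out$environment)
  out$f_p1 <- val(out$parent1, out$environment)
  out$f_p2 <- val(out$parent2, out$environment)
  usable <- complete.cases(out[, c("f_hybrid", "f_p1", "f_p2")])
  if (any(!usable)) {
    message(sprintf("dropping %d hybrid x environment cell(s) with missing fitness",
                    sum(!usable)))
  }
  out <- out[usable, , drop = FALSE]
  out$mph <- midparent_heterosis(out$f_hybrid, out$f_p1, out$f_p2)
  out$bph <- bestparent_heterosis(out$f_hybrid, out$f_p1, out$f_p2)
  rownames(out) <- NULL
  class(out) <- c("heterosis_scores", "data.frame")
  out
}

#' Summarise heterosis by cross class
#'
#' Mean MPH and BPH and the proportions of strictly positive scores per
#' cross class (optionally also per environment). Exact zeros count as
#' non-positive and are reported separately.
#'
#' @param scores a [heterosis_scores()] table.
#' @param per_environment also stratify by environment.
#' @param unit `"cell"` (default): each hybrid x environment cell is one
#'   observation; `"hybrid"`: average each hybrid over its environments
#'   first, then summarise the per-hybrid means.
#' @return A data.frame with columns `cross_class` (and `environment`),
#'   `n`, `mean_mph`, `mean_bph`, `prop_mph_pos`, `prop_bph_pos`,
#'   `prop_mph_zero`, `prop_bph_zero`.
#' @export
heterosis_summary <- function(scores, per_environment = FALSE,
                              unit = c("cell", "hybrid")) {
  unit <- match.arg(unit)
  stopifnot(nrow(scores) >= 1L)
  df <- as.data.frame(scores)
  if (unit == "hybrid") {
    if (per_environment) {
      stop("unit = 'hybrid' averages over environments; cannot combine with per_environment")
    }
    df <- aggregate(cbind(mph, bph) ~ hybrid_id + cross_class, df, mean)
  }
  keys <- if (per_environment) c("cross_class", "environment") else
    "cross_class"
  idx <- split(seq_len(nrow(df)), df[keys], drop = TRUE)
  rows <- lapply(idx, function(i) {
    g <- df[i, , drop = FALSE]
    cbind(g[1L, keys, drop = FALSE],
          data.frame(n = nrow(g),
                     mean_mph = mean(g$mph), mean_bph = mean(g$bph),
                     prop_mph_pos = mean(g$mph > 0),
                     prop_bph_pos = mean(g$bph > 0),
                     prop_mph_zero = mean(g$mph == 0),
                     prop_bph_zero = mean(g$bph == 0)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$cross_class, c("DxD", "mixed", "WxW"))), ,
      drop = FALSE]
}

#' @export
print.heterosis_scores <- function(x, ...) {
  cat(sprintf("Heterosis scores: %d hybrid x environment cells (%d hybrids, %d environments)\n",
              nrow(x), length(unique(x$hybrid_id)),
              length(unique(x$environment))))
  print(heterosis_summary(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.heterosis_scores <- function(object, ...) heterosis_summary(object, ...)

# ---- statistical tests ------------------------------------------------

stat_test <- function(test_name, statistic, df, p_value, estimate = NULL,
                      n = NULL) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, n = n),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(x$test_name, "\n")
  if (!is.null(x$estimate)) cat(sprintf("  estimate = %.4g\n", x$estimate))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 6), collapse = " and "),
              x$p_value))
  invisible(x)
}

#' One-way ANOVA F test
#'
#' Classic fixed-effects one-way ANOVA (`F = MS_between / MS_within`,
#' df `k - 1` and `N - k`), fitted with [stats::aov()]. Used to compare
#' strain-level mean fitness between groups, e.g. heterozygotes versus
#' homozygotes, where each observation is one strain's MGR averaged over
#' all environments and replicates.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor; every level must be
#'   observed).
#' @return A `stat_test` with the F statistic, both df and the p-value.
#' @examples
#' oneway_anova_F(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
oneway_anova_F <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("every group needs at least one observation")
  if (length(values) - nlevels(groups) < 1L) stop("not enough residual df")
  fit <- stats::aov(values ~ groups)
  tab <- anova(fit)
  stat_test("one-way ANOVA F test",
            statistic = tab$`F value`[1L],
            df = c(tab$Df[1L], tab$Df[2L]),
            p_value = tab$`Pr(>F)`[1L],
            n = length(values))
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' via [stats::t.test()]. When both samples have zero variance and equal
#' means the statistic is 0 with p = 1 by convention.
#'
#' @param x,y the two samples (each of length >= 2).
#' @return A `stat_test` with the t statistic, fractional df and two-sided
#'   p-value.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    return(stat_test("Welch two-sample t test",
                     statistic = if (d == 0) 0 else sign(d) * Inf,
                     df = length(x) + length(y) - 2,
                     p_value = if (d == 0) 1 else 0,
                     n = c(length(x), length(y))))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  stat_test("Welch two-sample t test",
            statistic = unname(ht$statistic), df = unname(ht$parameter),
            p_value = ht$p.value, n = c(length(x), length(y)))
}

#' Correlate hybrid fitness metrics with parental sequence divergence
#'
#' Pearson correlation, within one environment and an optional cross-class
#' subset, between a hybrid fitness metric (absolute hybrid MGR, MPH or
#' BPH) and the sequence divergence between the hybrid's parents. The
#' two-sided p-value comes from the t transform of r
#' ([stats::cor.test()]); significance stars encode p < 0.05 / 0.01 /
#' 0.001.
#'
#' @param scores a [heterosis_scores()] table.
#' @param divergence labelled symmetric divergence matrix covering all
#'   parents ([read_divergence_matrix()] or a simulated one).
#' @param metric `"mph"`, `"bph"` or `"f_hybrid"`.
#' @param environment environment id to restrict to (required unless the
#'   scores table has a single environment).
#' @param cross_class optional subset: `"DxD"`, `"mixed"`, `"WxW"`, or a
#'   vector of classes.
#' @return A `stat_test` with `estimate` = r, t statistic, df = n - 2,
#'   p-value and a `stars` element (`""`, `"*"`, `"**"`, `"***"`). If
#'   either variable has zero variance the correlation is undefined and
#'   returned as `NA` with a flag.
#' @export
divergence_correlation <- function(scores, divergence,
                                   metric = c("mph", "bph", "f_hybrid"),
                                   environment = NULL, cross_class = NULL) {
  metric <- match.arg(metric)
  df <- as.data.frame(scores)
  if (is.null(environment)) {
    if (length(unique(df$environment)) > 1L) {
      stop("specify which environment to correlate within")
    }
  } else {
    df <- df[df$environment == environment, , drop = FALSE]
  }
  if (!is.null(cross_class)) {
    df <- df[df$cross_class %in% cross_class, , drop = FALSE]
  }
  if (nrow(df) < 3L) stop("need at least 3 hybrid pairs in the subset")
  miss <- setdiff(unique(c(df$parent1, df$parent2)), rownames(divergence))
  if (length(miss)) {
    stop("parents missing from divergence matrix: ",
         paste(miss, collapse = ", "))
  }
  d <- divergence[cbind(match(df$parent1, rownames(divergence)),
                        match(df$parent2, colnames(divergence)))]
  y <- df[[metric]]
  if (stats::var(y) == 0 || stats::var(d) == 0) {
    out <- stat_test("Pearson correlation with parental divergence",
                     statistic = NA_real_, df = nrow(df) - 2,
                     p_value = NA_real_, estimate = NA_real_, n = nrow(df))
    out$flag <- "zero variance: correlation undefined"
    out$stars <- ""
    return(out)
  }
  ct <- stats::cor.test(y, d, method = "pearson")
  out <- stat_test("Pearson correlation with parental divergence",
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value,
                   estimate = unname(ct$estimate), n = nrow(df))
  out$stars <- p_stars(ct$p.value)
  out
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Correlation grid: metrics x cross-class subsets x environments
#'
#' Runs [divergence_correlation()] for each combination of fitness metric
#' (hybrid MGR, MPH, BPH), strain subset (all crosses, domesticated only,
#' wild only) and environment, returning the full grid with raw p-values,
#' significance stars and a Benjamini-Hochberg adjusted column.
#'
#' @inheritParams divergence_correlation
#' @return A data.frame: `metric`, `subset`, `environment`, `n`, `r`, `p`,
#'   `stars`, `p_bh`.
#' @export
correlation_grid <- function(scores, divergence) {
  subsets <- list(all = c("DxD", "mixed", "WxW"), domesticated = "DxD",
                  wild = "WxW")
  envs <- unique(as.data.frame(scores)$environment)
  rows <- list()
  for (metric in c("f_hybrid", "mph", "bph")) {
    for (sub in names(subsets)) {
      for (e in envs) {
        res <- tryCatch(
          divergence_correlation(scores, divergence, metric = metric,
                                 environment = e,
                                 cross_class = subsets[[sub]]),
          error = function(err) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, subset = sub, environment = e, n = res$n,
          r = res$estimate, p = res$p_value, stars = res$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Strain-level mean fitness
#'
#' Averages a replicate-level MGR table (or a fitness matrix) into one
#' mean value per strain across all environments and replicates — the unit
#' of observation of the heterozygote-versus-homozygote ANOVA.
#'
#' @inheritParams fitness_matrix
#' @return Named numeric vector of per-strain means.
#' @export
strain_means <- function(estimates, qc_only = TRUE) {
  if (is.matrix(estimates)) {
    return(rowMeans(estimates, na.rm = TRUE))
  }
  keep <- estimates
  if (qc_only && "qc_pass" %in% names(estimates)) {
    keep <- estimates[estimates$qc_pass & !is.na(estimates$mgr_per_h), ,
                      drop = FALSE]
  }
  agg <- aggregate(mgr_per_h ~ strain, keep, mean)
  setNames(agg$mgr_per_h, agg$strain)
}
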