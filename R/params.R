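#' Simulation parameters for the synthetic cross experiment
#'
#' Bundles every tunable of the synthetic-data generator: the shape of the
#' two-clade strain phylogeny, clade-specific deleterious-mutation rates,
#' the distribution of mutational effects and their dominance, the
#' environment panel and noise model for liquid growth, the OD-trajectory
#' settings, and the agar stress-assay model.
#'
#' Defaults emulate the design of a 22-strain cross experiment: 13
#' domesticated and 9 wild founder strains, all 231 pairwise hybrids, 11
#' liquid environments with 4 replicates each, and three agar stress
#' gradients of four doses. Deleterious mutations accumulate only along the
#' domesticated clade by default (`lambda_wild = 0`), are fully recessive
#' (`h = 0`), and are numerous with individually small effects
#' (about ten per strain, exponentially distributed with mean
#' `s_mean = 0.008`), in line with the many candidate loss-of-function
#' variants seen in real strain panels. Each clade is shaped as an early
#' radiation (`radiation = 6`), so most within-clade divergence traces to
#' deep splits; together with the tree scale this calibrates the expected
#' mid-parent heterosis of a domesticated x domesticated cross to roughly
#' 5% of the environment baseline, exceeding that of mixed crosses.
#'
#' @param n_dom,n_wild number of domesticated / wild founder strains.
#' @param clade_height height of each clade subtree (branch-length units).
#' @param stem_length length of the stem branch joining each clade to the
#'   root.
#' @param radiation shape exponent of the clade trees: internal node
#'   depths (as fractions of clade height from the root) are raised to
#'   this power, so values above 1 concentrate splits near the clade root
#'   (an early radiation, as in real domesticated yeast lineages where
#'   most pairwise divergence traces back to deep splits); 1 keeps the
#'   plain coalescent shape.
#' @param lambda_dom,lambda_wild expected number of load-relevant
#'   deleterious mutations per unit branch length in each clade.
#' @param subst_per_unit expected nucleotide substitutions per unit
#'   patristic distance; scales the simulated divergence matrix. These
#'   background substitutions affect divergence only, not fitness.
#' @param s_mean mean homozygous selection coefficient (exponential).
#' @param h dominance coefficient in `[0, 1]`; 0 = fully recessive.
#' @param n_env number of liquid environments.
#' @param env_means baseline MGR (per hour) of a mutation-free strain in
#'   each environment; length `n_env`.
#' @param sigma_gxe standard deviation of the genotype-by-environment
#'   effect on log MGR (one draw per strain x environment).
#' @param sigma_rep standard deviation of replicate noise on log MGR.
#' @param n_rep replicates per strain x environment.
#' @param od0 inoculation OD of a culture.
#' @param od_K carrying-capacity OD of the logistic trajectory.
#' @param background_od additive plate/medium background OD.
#' @param sigma_od additive read noise per OD measurement (OD units).
#' @param sigma_od_rel multiplicative (lognormal) measurement noise per OD
#'   reading, capturing well-to-well optical irregularities that scale
#'   with density.
#' @param dt_h sampling interval (hours).
#' @param od_log_growth target natural-log fold growth of a baseline
#'   strain during the assay; each environment is run for
#'   `od_log_growth / env_mean` hours (rounded up to a `dt_h` multiple),
#'   emulating the practice of incubating slow conditions longer so every
#'   assay captures a comparable stretch of exponential growth.
#' @param t_max_h optional fixed assay duration (hours) for all
#'   environments, overriding `od_log_growth` when non-`NULL`.
#' @param stress_agents named list, one entry per stress agent, each a list
#'   with numeric vectors `doses`, `incubation_h` and `thresholds` (all the
#'   same length, doses increasing, thresholds decreasing).
#' @param sigma_robust standard deviation of the per-strain, per-agent
#'   robustness draw; independent across agents, which makes cross-stress
#'   performance uncorrelated by construction.
#' @param doubling_gain cell doublings gained per unit of growth margin for
#'   growing patches.
#' @param sigma_doubling trial-to-trial noise on doublings.
#' @param cal_slope,cal_intercept true linear law mapping patch intensity
#'   to cell counts (cells per intensity unit; cells).
#' @param cal_rel_noise relative noise of calibration cell counts.
#' @param n_cal number of calibration (intensity, cell count) pairs.
#' @param cells0_mean,cells0_cv mean and coefficient of variation of the
#'   initial cell number per patch.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_crosses()]
#' @examples
#' p <- sim_params(n_dom = 3, n_wild = 2, n_env = 2)
#' p$lambda_dom
#' @export
sim_params <- function(n_dom = 13L,
                       n_wild = 9L,
                       clade_height = 2.6,
                       stem_length = 0.3,
                       radiation = 6,
                       lambda_dom = 3.5,
                       lambda_wild = 0.0,
                       subst_per_unit = 2000,
                       s_mean = 0.008,
                       h = 0.0,
                       n_env = 11L,
                       env_means = NULL,
                       sigma_gxe = 0.04,
                       sigma_rep = 0.02,
                       n_rep = 4L,
                       od0 = 0.02,
                       od_K = 2.5,
                       background_od = 0.08,
                       sigma_od = 0.002,
                       sigma_od_rel = 0.02,
                       dt_h = 1 / 3,
                       od_log_growth = 3.6,
                       t_max_h = NULL,
                       stress_agents = NULL,
                       sigma_robust = 0.5,
                       doubling_gain = 1.0,
                       sigma_doubling = 0.8,
                       cal_slope = 2000,
                       cal_intercept = 0,
                       cal_rel_noise = 0.05,
                       n_cal = 40L,
                       cells0_mean = 5e5,
                       cells0_cv = 0.1) {
  if (is.null(env_means)) {
    env_means <- seq(0.25, 0.55, length.out = n_env)
  }
  if (is.null(stress_agents)) {
    # dose units and incubation times follow a typical NaCl / salicylate /
    # ZnSO4 gradient design; thresholds decline so that survival drops from
    # ~1 at the mildest dose to ~0.5 at the most extreme one
    thr <- c(2.0, 0.6, 0.3, 0.0)
    stress_agents <- list(
      NaCl       = list(doses = c(2, 8, 9, 10),
                        incubation_h = c(48, 72, 96, 120), thresholds = thr),
      salicylate = list(doses = c(2.5, 3.5, 4, 5),
                        incubation_h = c(24, 24, 48, 72), thresholds = thr),
      ZnSO4      = list(doses = c(0.5, 2, 2.5, 2.75),
                        incubation_h = c(24, 48, 72, 120), thresholds = thr)
    )
  }
  p <- list(
    n_dom = as.integer(n_dom), n_wild = as.integer(n_wild),
    clade_height = clade_height, stem_length = stem_length,
    radiation = radiation,
    lambda_dom = lambda_dom, lambda_wild = lambda_wild,
    subst_per_unit = subst_per_unit,
    s_mean = s_mean, h = h,
    n_env = as.integer(n_env), env_means = env_means,
    sigma_gxe = sigma_gxe, sigma_rep = sigma_rep, n_rep = as.integer(n_rep),
    od0 = od0, od_K = od_K, background_od = background_od,
    sigma_od = sigma_od, sigma_od_rel = sigma_od_rel,
    dt_h = dt_h, od_log_growth = od_log_growth, t_max_h = t_max_h,
    stress_agents = stress_agents, sigma_robust = sigma_robust,
    doubling_gain = doubling_gain, sigma_doubling = sigma_doubling,
    cal_slope = cal_slope, cal_intercept = cal_intercept,
    cal_rel_noise = cal_rel_noise, n_cal = as.integer(n_cal),
    cells0_mean = cells0_mean, cells0_cv = cells0_cv
  )
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_dom >= 0, p$n_wild >= 0)
  if (p$n_dom + p$n_wild < 3) {
    stop("need at least 3 strains in total (n_dom + n_wild >= 3)")
  }
  nonneg <- c("clade_height", "stem_length", "lambda_dom", "lambda_wild",
              "subst_per_unit", "s_mean", "sigma_gxe", "sigma_rep",
              "sigma_od", "sigma_od_rel", "sigma_robust", "sigma_doubling",
              "cal_rel_noise")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop(sprintf("parameter '%s' must be a single nonnegative number", nm))
    }
  }
  if (p$h < 0 || p$h > 1) stop("dominance coefficient h must be in [0, 1]")
  if (p$radiation <= 0) stop("radiation exponent must be positive")
  if (length(p$env_means) != p$n_env) {
    stop("env_means must have length n_env")
  }
  if (any(p$env_means <= 0)) stop("env_means must be positive")
  if (p$od0 <= 0 || p$od_K <= p$od0) stop("need 0 < od0 < od_K")
  if (p$dt_h <= 0) stop("dt_h must be positive")
  if (!is.null(p$t_max_h) && p$t_max_h <= p$dt_h) {
    stop("t_max_h must exceed dt_h")
  }
  if (p$od_log_growth <= 0) stop("od_log_growth must be positive")
  for (ag in names(p$stress_agents)) {
    a <- p$stress_agents[[ag]]
    if (!all(c("doses", "incubation_h", "thresholds") %in% names(a)) ||
        length(a$doses) != length(a$incubation_h) ||
        length(a$doses) != length(a$thresholds)) {
      stop(sprintf("stress agent '%s': doses, incubation_h and thresholds must have equal length", ag))
    }
    if (is.unsorted(a$doses, strictly = TRUE)) {
      stop(sprintf("stress agent '%s': doses must be strictly increasing", ag))
    }
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cross-experiment parameters\n")
  cat(sprintf("  strains: %d domesticated + %d wild (%d hybrids)\n",
              x$n_dom, x$n_wild, choose(x$n_dom + x$n_wild, 2)))
  cat(sprintf("  mutation rates (per unit branch): dom %.3g, wild %.3g; s ~ Exp(mean %.3g), h = %.2f\n",
              x$lambda_dom, x$lambda_wild, x$s_mean, x$h))
  cat(sprintf("  environments: %d (baseline MGR %.2f-%.2f/h), %d replicates\n",
              x$n_env, min(x$env_means), max(x$env_means), x$n_rep))
  cat(sprintf("  noise (log scale): GxE sd %.3g, replicate sd %.3g; OD read sd %.3g\n",
              x$sigma_gxe, x$sigma_rep, x$sigma_od))
  cat(sprintf("  stress agents: %s\n", paste(names(x$stress_agents), collapse = ", ")))
  invisible(x)
}
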