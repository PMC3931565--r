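#' Simulate a two-clade strain phylogeny and divergence matrix
#'
#' Draws a random coalescent tree for each clade (domesticated and wild),
#' rescales each to `clade_height`, and joins them at the root through stem
#' branches of length `stem_length`, giving an ultrametric tree of depth
#' `clade_height + stem_length`. Pairwise sequence divergence is then
#' simulated as Poisson-distributed substitution counts with mean
#' proportional to the patristic distance (`subst_per_unit` substitutions
#' per unit distance), drawn once per unordered pair so the matrix is
#' symmetric with a zero diagonal.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A list of class `tree_sim` with elements `tree` (an
#'   `ape::phylo`), `divergence` (labelled symmetric count matrix),
#'   `patristic` (the underlying distances) and `origin` (named character
#'   vector, `"domesticated"` or `"wild"` per tip).
#' @examples
#' ts <- simulate_tree(sim_params(n_dom = 3, n_wild = 2), seed = 1)
#' ts$divergence
#' @export
simulate_tree <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  nd <- params$n_dom
  nw <- params$n_wild
  nk_d <- clade_newick(nd, "D", params$clade_height, params$radiation)
  nk_w <- clade_newick(nw, "W", params$clade_height, params$radiation)
  nk <- sprintf("(%s:%g,%s:%g);", nk_d, params$stem_length,
                nk_w, params$stem_length)
  tree <- ape::read.tree(text = nk)
  labels <- c(sprintf("D%02d", seq_len(nd)), sprintf("W%02d", seq_len(nw)))
  pat <- ape::cophenetic.phylo(tree)[labels, labels, drop = FALSE]
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- stats::rpois(1L, params$subst_per_unit * pat[i, j])
    }
  }
  origin <- setNames(ifelse(startsWith(labels, "D"), "domesticated", "wild"),
                     labels)
  structure(list(tree = tree, divergence = d, patristic = pat,
                 origin = origin),
            class = "tree_sim")
}

# newick for one clade subtree (no trailing semicolon), rescaled to `height`
# with a radiation-shape transform: internal node depths d (as a fraction of
# clade height, measured from the clade root) are mapped to d^radiation, so
# radiation > 1 concentrates splits near the clade root (an early radiation,
# the shape of real domesticated yeast lineages); radiation = 1 leaves the
# coalescent shape untouched
clade_newick <- function(n, prefix, height, radiation = 1) {
  if (n < 1L) stop("each clade needs at least one strain")
  if (n == 1L) return(sprintf("%s01:%g", prefix, height))
  tr <- ape::rcoal(n, tip.label = sprintf("%s%02d", prefix, seq_len(n)))
  dep <- ape::node.depth.edgelength(tr)   # distance from clade root
  d <- dep / max(dep[seq_len(n)])         # ultrametric: tips at 1
  d <- d^radiation
  tr$edge.length <- height * (d[tr$edge[, 2L]] - d[tr$edge[, 1L]])
  sub(";$", "", ape::write.tree(tr))
}

#' Assign deleterious mutations along a simulated phylogeny
#'
#' On each branch the number of load-relevant mutations is Poisson with
#' mean `lambda_clade * branch_length`, where the clade of a branch is the
#' clade of the tips descending from it (the two stem branches belong to
#' their respective clades). Each mutation receives an independent
#' homozygous selection coefficient `s ~ Exponential(mean = s_mean)`,
#' resampled in the rare case `s >= 1`. A strain inherits every mutation on
#' its root-to-tip path, so strains sharing ancestry share mutation
#' identities — the substrate for complementation in hybrids.
#'
#' @inheritParams simulate_tree
#' @param tree_sim result of [simulate_tree()].
#' @return A list of class `mutation_set`: `mutations` (named list, one
#'   `data.frame(mutation_id, s)` per strain), `load` (named vector of
#'   summed homozygous effects) and `count` (mutations per strain).
#' @examples
#' p <- sim_params(n_dom = 3, n_wild = 2)
#' ts <- simulate_tree(p, seed = 1)
#' ms <- assign_mutations(ts, p, seed = 2)
#' ms$count
#' @export
assign_mutations <- function(tree_sim, params, seed = NULL) {
  stopifnot(inherits(tree_sim, "tree_sim"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  tree <- tree_sim$tree
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  tipsets <- edge_tipsets(tree)

  per_edge <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    tips <- tree$tip.label[tipsets[[edge[e, 2L]]]]
    clade <- unique(tree_sim$origin[tips])
    # with two monophyletic clades every branch is ancestral to one clade only
    lam <- if (identical(clade, "domesticated")) params$lambda_dom
           else if (identical(clade, "wild")) params$lambda_wild
           else mean(c(params$lambda_dom, params$lambda_wild))
    k <- stats::rpois(1L, lam * elen[e])
    if (k > 0L) {
      s <- stats::rexp(k, rate = 1 / params$s_mean)
      while (any(s >= 1)) s[s >= 1] <- stats::rexp(sum(s >= 1), 1 / params$s_mean)
      per_edge[[e]] <- data.frame(
        mutation_id = sprintf("e%03d_m%03d", e, seq_len(k)),
        s = s, stringsAsFactors = FALSE)
    }
  }

  muts <- vector("list", ntip)
  names(muts) <- tree$tip.label
  for (tip in seq_len(ntip)) {
    path <- tip_path_edges(edge, tip, ntip)
    dfs <- per_edge[path]
    dfs <- dfs[!vapply(dfs, is.null, logical(1))]
    muts[[tree$tip.label[tip]]] <- if (length(dfs)) do.call(rbind, dfs) else
      data.frame(mutation_id = character(), s = numeric(),
                 stringsAsFactors = FALSE)
  }
  load <- vapply(muts, function(m) sum(m$s), numeric(1))
  count <- vapply(muts, nrow, integer(1))
  structure(list(mutations = muts, load = load, count = count),
            class = "mutation_set")
}

# tip indices descending from each node (list indexed by node id)
edge_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  edge <- tree$edge
  ord <- rev(ape::postorder(tree))  # we accumulate children-first
  for (e in ape::postorder(tree)) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# indices of edges on the root-to-tip path
tip_path_edges <- function(edge, tip, ntip) {
  path <- integer()
  node <- tip
  repeat {
    e <- which(edge[, 2L] == node)
    if (length(e) == 0L) break
    path <- c(path, e)
    node <- edge[e, 1L]
  }
  path
}

#' Deterministic fitness of a homozygous strain
#'
#' Multiplicative fitness across loci: a homozygote expresses the full
#' homozygous effect of every mutation it carries, so its MGR is
#' `env_mean * prod(1 - s) * exp(gxe + noise)`.
#'
#' @param s numeric vector of homozygous selection coefficients carried by
#'   the strain (all in `[0, 1)`).
#' @param env_mean baseline MGR of a mutation-free strain in the
#'   environment.
#' @param gxe genotype-by-environment effect on the log scale (default 0).
#' @param noise replicate noise on the log scale (default 0).
#' @return MGR in per-hour units.
#' @examples
#' homozygote_fitness(c(0.1), env_mean = 0.5)  # 0.45
#' @export
homozygote_fitness <- function(s, env_mean, gxe = 0, noise = 0) {
  stopifnot(all(s >= 0), all(s < 1))
  env_mean * prod(1 - s) * exp(gxe + noise)
}

#' Deterministic fitness of an F1 hybrid under complementation
#'
#' Mutations present in both parents remain homozygous in the hybrid
#' (factor `1 - s`); mutations private to one parent become heterozygous
#' and contribute `1 - h * s`. With `h = 0` (fully recessive) private
#' mutations are completely complemented, which is the mechanism that
#' generates heterosis between divergent parents.
#'
#' @param mut1,mut2 `data.frame(mutation_id, s)` for each parent, as
#'   produced by [assign_mutations()].
#' @param h dominance coefficient in `[0, 1]`.
#' @inheritParams homozygote_fitness
#' @return MGR in per-hour units.
#' @examples
#' m1 <- data.frame(mutation_id = "a", s = 0.1)
#' m2 <- data.frame(mutation_id = "b", s = 0.1)
#' hybrid_fitness(m1, m2, env_mean = 1)          # 1: both complemented
#' hybrid_fitness(m1, m1, env_mean = 1)          # 0.9: shared stays homozygous
#' @export
hybrid_fitness <- function(mut1, mut2, env_mean, h = 0, gxe = 0, noise = 0) {
  shared <- intersect(mut1$mutation_id, mut2$mutation_id)
  s_shared <- mut1$s[match(shared, mut1$mutation_id)]
  s_priv <- c(mut1$s[!(mut1$mutation_id %in% shared)],
              mut2$s[!(mut2$mutation_id %in% shared)])
  env_mean * prod(1 - s_shared) * prod(1 - h * s_priv) * exp(gxe + noise)
}

# expressed load of a genotype under partial dominance (used by the agar
# stress model): shared mutations count fully, private ones at h * s
expressed_load <- function(mut1, mut2 = NULL, h = 0) {
  if (is.null(mut2)) return(sum(mut1$s))
  shared <- intersect(mut1$mutation_id, mut2$mutation_id)
  s_shared <- mut1$s[match(shared, mut1$mutation_id)]
  s_priv <- c(mut1$s[!(mut1$mutation_id %in% shared)],
              mut2$s[!(mut2$mutation_id %in% shared)])
  sum(s_shared) + h * sum(s_priv)
}

#' Simulate true fitness for all homozygotes and hybrids
#'
#' Builds the full cross design (every unordered pair of founder strains),
#' computes the deterministic multiplicative fitness of each genotype in
#' each environment, adds a lognormal genotype-by-environment effect (one
#' draw per genotype x environment) and lognormal replicate noise, and
#' returns the design tables together with the ground truth.
#'
#' @inheritParams assign_mutations
#' @param mut_set result of [assign_mutations()].
#' @param tree_sim result of [simulate_tree()].
#' @return A list of class `fitness_sim`:
#'   `metadata` (founder strain origins), `crosses` (hybrid design with
#'   cross classes), `truth` (per strain x environment deterministic MGR
#'   including the GxE effect), `replicates` (per strain x environment x
#'   replicate true MGR), `load_expressed` (named vector used by the agar
#'   stress model) and `is_hybrid` (named logical).
#' @export
simulate_fitness <- function(tree_sim, mut_set, params, seed = NULL) {
  stopifnot(inherits(tree_sim, "tree_sim"), inherits(mut_set, "mutation_set"),
            inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  founders <- names(mut_set$mutations)
  metadata <- data.frame(strain_id = founders,
                         origin = unname(tree_sim$origin[founders]),
                         stringsAsFactors = FALSE)
  pairs <- utils::combn(founders, 2L)
  crosses <- data.frame(
    hybrid_id = paste(pairs[1L, ], pairs[2L, ], sep = "x"),
    parent1 = pairs[1L, ], parent2 = pairs[2L, ],
    stringsAsFactors = FALSE)
  crosses$cross_class <- classify_cross(
    tree_sim$origin[crosses$parent1], tree_sim$origin[crosses$parent2])

  strains <- c(founders, crosses$hybrid_id)
  is_hybrid <- setNames(c(rep(FALSE, length(founders)),
                          rep(TRUE, nrow(crosses))), strains)

  w <- numeric(length(strains))
  names(w) <- strains
  loadx <- numeric(length(strains))
  names(loadx) <- strains
  for (f in founders) {
    w[f] <- prod(1 - mut_set$mutations[[f]]$s)
    loadx[f] <- expressed_load(mut_set$mutations[[f]])
  }
  for (k in seq_len(nrow(crosses))) {
    m1 <- mut_set$mutations[[crosses$parent1[k]]]
    m2 <- mut_set$mutations[[crosses$parent2[k]]]
    hid <- crosses$hybrid_id[k]
    w[hid] <- hybrid_fitness(m1, m2, env_mean = 1, h = params$h)
    loadx[hid] <- expressed_load(m1, m2, h = params$h)
  }

  env_ids <- sprintf("env%02d", seq_len(params$n_env))
  ns <- length(strains)
  ne <- params$n_env
  g <- matrix(stats::rnorm(ns * ne, 0, params$sigma_gxe), ns, ne,
              dimnames = list(strains, env_ids))
  det <- outer(w, params$env_means) * exp(g)
  dimnames(det) <- list(strains, env_ids)
  truth <- data.frame(
    strain = rep(strains, times = ne),
    environment = rep(env_ids, each = ns),
    mgr_det = as.vector(det), stringsAsFactors = FALSE)

  nr <- params$n_rep
  replicates <- truth[rep(seq_len(nrow(truth)), each = nr), ]
  replicates$replicate <- rep(seq_len(nr), times = nrow(truth))
  replicates$mgr_true <- replicates$mgr_det *
    exp(stats::rnorm(nrow(replicates), 0, params$sigma_rep))
  rownames(replicates) <- NULL

  structure(list(metadata = metadata, crosses = crosses, truth = truth,
                 replicates = replicates, w = w, load_expressed = loadx,
                 is_hybrid = is_hybrid),
            class = "fitness_sim")
}

#' Generate microplate OD trajectories from true growth rates
#'
#' Each culture follows a logistic trajectory
#' `OD(t) = K * od0 * exp(r t) / (K + od0 * (exp(r t) - 1))` with `r` the
#' culture's true MGR, multiplied by lognormal measurement noise
#' (`sigma_od_rel`), plus an additive plate background and additive
#' Gaussian read noise (`sigma_od`), sampled every `dt_h` hours up to
#' `t_max_h`. The logistic exposes a saturating tail (and the background a
#' flat early phase) that the OD window selector must learn to exclude.
#'
#' @param replicates data.frame with columns `strain`, `environment`,
#'   `replicate`, `mgr_true` (as in [simulate_fitness()]`$replicates`).
#' @inheritParams simulate_tree
#' @return A long-format `data.frame` (class `plate_data`) with columns
#'   `strain`, `environment`, `replicate`, `time_h`, `od`.
#' @export
generate_od_curves <- function(replicates, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"),
            all(c("strain", "environment", "replicate", "mgr_true") %in%
                  names(replicates)))
  if (any(replicates$mgr_true <= 0)) stop("true growth rates must be positive")
  if (!is.null(seed)) set.seed(seed)
  # assay duration per environment: slow conditions are incubated longer so
  # every assay captures a comparable stretch of exponential growth
  env_dur <- vapply(split(replicates$mgr_true, replicates$environment),
                    function(r) {
                      d <- if (!is.null(params$t_max_h)) params$t_max_h else
                        params$od_log_growth / stats::median(r)
                      ceiling(d / params$dt_h) * params$dt_h
                    }, numeric(1))
  nt_env <- setNames(as.integer(round(env_dur / params$dt_h)) + 1L,
                     names(env_dur))
  nt <- nt_env[replicates$environment]
  n <- nrow(replicates)
  idx <- rep(seq_len(n), times = nt)
  tt <- unlist(lapply(nt, function(k) seq(0, by = params$dt_h,
                                          length.out = k)),
               use.names = FALSE)
  r <- replicates$mgr_true[idx]
  K <- params$od_K
  od0 <- params$od0
  ert <- exp(r * tt)
  od <- K * od0 * ert / (K + od0 * (ert - 1)) *
    exp(stats::rnorm(length(tt), 0, params$sigma_od_rel)) +
    params$background_od + stats::rnorm(length(tt), 0, params$sigma_od)
  out <- data.frame(
    strain = replicates$strain[idx],
    environment = replicates$environment[idx],
    replicate = replicates$replicate[idx],
    time_h = tt,
    od = od,
    stringsAsFactors = FALSE)
  class(out) <- c("plate_data", "data.frame")
  out
}

#' Generate agar-patch stress assays and calibration pairs
#'
#' Implements a load-threshold survival model: a strain grows under agent
#' `a` at dose `k` iff `load + z_a < threshold_k`, where `load` is the
#' strain's expressed mutational load and `z_a ~ Normal(0, sigma_robust)`
#' is a robustness draw made once per strain x agent and shared across that
#' agent's doses (so survival is monotone along a gradient) but independent
#' across agents (so cross-stress performance is uncorrelated — the null of
#' the resampling analysis holds by construction). Growing patches make
#' `3 + doubling_gain * margin` cell doublings on average (margin =
#' threshold - load - z), non-growing patches a carry-over residue below 3
#' doublings; three trials per condition. Patch intensities follow the
#' inverse of the true linear cells-per-intensity law; a separate table of
#' noisy calibration pairs from the same law is returned.
#'
#' @param load_expressed named numeric vector of expressed loads (from
#'   [simulate_fitness()]).
#' @inheritParams simulate_tree
#' @return A list with `assays` (one row per strain x agent x dose x trial:
#'   `strain_id`, `stress_agent`, `dose`, `trial`, `intensity_initial`,
#'   `intensity_final`, `incubation_h`), `calibration` (`intensity`,
#'   `cell_count` pairs) and `truth` (per strain x condition: whether the
#'   model intended growth, and the mean doublings drawn).
#' @export
generate_agar_assays <- function(load_expressed, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  strains <- names(load_expressed)
  rows <- list()
  truth <- list()
  n_trial <- 3L
  for (ag in names(params$stress_agents)) {
    a <- params$stress_agents[[ag]]
    z <- stats::rnorm(length(strains), 0, params$sigma_robust)
    names(z) <- strains
    for (k in seq_along(a$doses)) {
      margin <- a$thresholds[k] - (load_expressed + z)
      grows <- margin > 0
      mean_dbl <- ifelse(grows,
                         3 + params$doubling_gain * margin,
                         stats::runif(length(strains), 0.3, 2.8))
      dbl <- matrix(pmax(stats::rnorm(length(strains) * n_trial,
                                      rep(mean_dbl, each = n_trial),
                                      params$sigma_doubling), 0),
                    nrow = n_trial)
      cells0 <- matrix(pmax(stats::rnorm(length(strains) * n_trial,
                                         params$cells0_mean,
                                         params$cells0_cv * params$cells0_mean),
                            1e4), nrow = n_trial)
      cells1 <- cells0 * 2^dbl
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = rep(strains, each = n_trial),
        stress_agent = ag,
        dose = a$doses[k],
        trial = rep(seq_len(n_trial), times = length(strains)),
        intensity_initial = as.vector((cells0 - params$cal_intercept) / params$cal_slope),
        intensity_final = as.vector((cells1 - params$cal_intercept) / params$cal_slope),
        incubation_h = a$incubation_h[k],
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        strain_id = strains, stress_agent = ag, dose = a$doses[k],
        grows = unname(grows), mean_doublings = colMeans(dbl),
        stringsAsFactors = FALSE)
    }
  }
  assays <- do.call(rbind, rows)
  # calibration pairs: carved patches of all sizes, log-uniform over the
  # observed intensity range so small patches anchor the intercept
  rng <- range(c(assays$intensity_initial, assays$intensity_final))
  intensity <- exp(stats::runif(params$n_cal, log(rng[1]), log(rng[2])))
  cells <- (params$cal_slope * intensity + params$cal_intercept) *
    (1 + stats::rnorm(params$n_cal, 0, params$cal_rel_noise))
  list(assays = assays,
       calibration = data.frame(intensity = intensity, cell_count = cells),
       truth = do.call(rbind, truth))
}

#' Simulate a complete synthetic cross experiment
#'
#' Runs the whole generator: phylogeny and divergence matrix, mutation
#' accumulation, true fitness of all homozygotes and hybrids, microplate OD
#' trajectories and agar stress assays. Output tables match the reader
#' schemas of the analysis functions, so the generated data can be written
#' out with the package writers and re-analysed end to end.
#'
#' @inheritParams simulate_tree
#' @param seed integer seed (required: the generator is fully seeded).
#' @param od_curves,agar generate the (comparatively large) OD trajectory
#'   table / the agar assay tables (`TRUE` by default).
#' @return A list of class `cross_sim` with elements `params`, `tree`,
#'   `divergence`, `mutations`, `metadata`, `crosses`, `truth`,
#'   `replicates`, `plate` (if requested), `agar`, `calibration`,
#'   `agar_truth` (if requested).
#' @examples
#' sim <- simulate_crosses(sim_params(n_dom = 3, n_wild = 2, n_env = 2),
#'                         seed = 1, od_curves = FALSE, agar = FALSE)
#' head(sim$replicates)
#' @export
simulate_crosses <- function(params = sim_params(), seed,
                             od_curves = TRUE, agar = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed) || is.null(seed)) {
    stop("simulate_crosses() requires an explicit seed")
  }
  set.seed(seed)
  ts <- simulate_tree(params)
  ms <- assign_mutations(ts, params)
  fs <- simulate_fitness(ts, ms, params)
  out <- list(params = params, tree = ts$tree, divergence = ts$divergence,
              patristic = ts$patristic, mutations = ms,
              metadata = fs$metadata, crosses = fs$crosses,
              truth = fs$truth, replicates = fs$replicates,
              w = fs$w, load_expressed = fs$load_expressed,
              is_hybrid = fs$is_hybrid)
  if (od_curves) {
    out$plate <- generate_od_curves(fs$replicates, params)
  }
  if (agar) {
    ag <- generate_agar_assays(fs$load_expressed, params)
    out$agar <- ag$assays
    out$calibration <- ag$calibration
    out$agar_truth <- ag$truth
  }
  class(out) <- "cross_sim"
  out
}

#' @export
print.cross_sim <- function(x, ...) {
  cat("Synthetic cross experiment\n")
  cat(sprintf("  %d founders (%d domesticated, %d wild), %d hybrids, %d environments\n",
              nrow(x$metadata), sum(x$metadata$origin == "domesticated"),
              sum(x$metadata$origin == "wild"), nrow(x$crosses),
              x$params$n_env))
  cat(sprintf("  mutations per founder: %s\n",
              paste(range(x$mutations$count), collapse = "-")))
  if (!is.null(x$plate)) {
    cat(sprintf("  plate table: %d OD readings\n", nrow(x$plate)))
  }
  if (!is.null(x$agar)) {
    cat(sprintf("  agar table: %d patch measurements\n", nrow(x$agar)))
  }
  invisible(x)
}
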