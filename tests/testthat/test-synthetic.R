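p_small <- sim_params(n_dom = 4, n_wild = 3, n_env = 2, n_rep = 2)

test_that("tree simulation is deterministic and clade-structured", {
  ts1 <- simulate_tree(p_small, seed = 1)
  ts2 <- simulate_tree(p_small, seed = 1)
  expect_identical(ts1$divergence, ts2$divergence)

  expect_equal(dim(ts1$divergence), c(7, 7))
  expect_true(all(diag(ts1$divergence) == 0))
  expect_true(all(ts1$divergence == t(ts1$divergence)))
  expect_true(all(ts1$divergence[upper.tri(ts1$divergence)] > 0))

  # within-clade distances are smaller than between-clade distances
  dom <- sprintf("D%02d", 1:4); wld <- sprintf("W%02d", 1:3)
  pat <- ts1$patristic
  expect_lt(mean(pat[dom, dom][upper.tri(pat[dom, dom])]),
            mean(pat[dom, wld]))
  expect_lt(mean(pat[wld, wld][upper.tri(pat[wld, wld])]),
            mean(pat[dom, wld]))

  # minimal 3-strain design
  ts3 <- simulate_tree(sim_params(n_dom = 2, n_wild = 1), seed = 2)
  expect_equal(dim(ts3$divergence), c(3, 3))
})

test_that("mutation counts follow the Poisson branch-length expectation", {
  ts <- simulate_tree(p_small, seed = 3)
  # lambda = 0 everywhere: no mutations at all
  p0 <- p_small; p0$lambda_dom <- 0; p0$lambda_wild <- 0
  ms0 <- assign_mutations(ts, p0, seed = 4)
  expect_true(all(ms0$count == 0))

  # expected count per tip = lambda * root-to-tip path length
  p1 <- p_small; p1$lambda_dom <- 1.2; p1$lambda_wild <- 1.2
  depth <- p_small$clade_height + p_small$stem_length
  reps <- 300
  counts <- replicate(reps, assign_mutations(ts, p1)$count[["D01"]])
  expect_lt(abs(mean(counts) - 1.2 * depth),
            3 * sd(counts) / sqrt(reps))

  # wild clade silent under the defaults
  ms <- assign_mutations(ts, p_small, seed = 5)
  expect_true(all(ms$count[sprintf("W%02d", 1:3)] == 0))
  expect_true(all(unlist(lapply(ms$mutations, function(m) m$s)) < 1))
})

test_that("shared ancestry means shared mutation identities", {
  set.seed(6)
  ts <- simulate_tree(p_small, seed = 6)
  p1 <- p_small; p1$lambda_dom <- 3; p1$lambda_wild <- 3
  ms <- assign_mutations(ts, p1, seed = 7)
  pat <- ts$patristic
  dom <- sprintf("D%02d", 1:4)
  ids <- lapply(ms$mutations[dom], `[[`, "mutation_id")
  # every pair: shared mutations are exactly those both inherited; the
  # count of private ones grows with patristic distance in expectation,
  # and identical ids imply identical effects
  for (i in 1:3) for (j in (i + 1):4) {
    shared <- intersect(ids[[i]], ids[[j]])
    si <- ms$mutations[[dom[i]]]
    sj <- ms$mutations[[dom[j]]]
    expect_equal(si$s[match(shared, si$mutation_id)],
                 sj$s[match(shared, sj$mutation_id)])
  }
})

test_that("private mutation counts scale linearly with patristic distance", {
  p1 <- sim_params(n_dom = 6, n_wild = 3)
  p1$lambda_dom <- 2; p1$lambda_wild <- 2
  reps <- 60
  xs <- NULL; ys <- NULL
  for (k in seq_len(reps)) {
    ts <- simulate_tree(p1, seed = 100 + k)
    ms <- assign_mutations(ts, p1)
    labs <- rownames(ts$patristic)
    pr <- combn(seq_along(labs), 2)
    for (c1 in seq_len(ncol(pr))) {
      a <- labs[pr[1, c1]]; b <- labs[pr[2, c1]]
      ids_a <- ms$mutations[[a]]$mutation_id
      ids_b <- ms$mutations[[b]]$mutation_id
      priv <- length(setdiff(ids_a, ids_b)) + length(setdiff(ids_b, ids_a))
      xs <- c(xs, ts$patristic[a, b]); ys <- c(ys, priv)
    }
  }
  fit <- lm(ys ~ xs)
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  # total private path length between two tips equals their patristic
  # distance, so the slope is lambda
  expect_lt(abs(slope - 2), 3 * se + 0.15)
})

test_that("fitness functions implement multiplicative complementation", {
  expect_equal(homozygote_fitness(numeric(0), 0.5), 0.5)
  expect_equal(homozygote_fitness(0.1, 0.5), 0.45)
  expect_equal(homozygote_fitness(c(0.1, 0.2), 1), 0.9 * 0.8)

  m1 <- data.frame(mutation_id = "a", s = 0.1)
  m2 <- data.frame(mutation_id = "b", s = 0.1)
  # disjoint single mutations, h = 0: full complementation
  f_h <- hybrid_fitness(m1, m2, env_mean = 0.5, h = 0)
  mid <- (homozygote_fitness(0.1, 0.5) + homozygote_fitness(0.1, 0.5)) / 2
  expect_equal(f_h, 0.5)
  expect_equal(f_h - mid, 0.05)  # MPH = s * env_mean when both sides complement

  # identical parents: no complementation possible, MPH = 0
  expect_equal(hybrid_fitness(m1, m1, env_mean = 0.5, h = 0),
               homozygote_fitness(0.1, 0.5))

  # h = 0.5: hybrid equals midparent to first order in s
  s <- 0.01
  m1s <- data.frame(mutation_id = "a", s = s)
  m2s <- data.frame(mutation_id = "b", s = s)
  f_h5 <- hybrid_fitness(m1s, m2s, env_mean = 1, h = 0.5)
  mid5 <- (1 - s + 1 - s) / 2
  expect_lt(abs(f_h5 - mid5), s^2)

  # noise enters on the log scale
  expect_equal(homozygote_fitness(0.1, 0.5, gxe = 0.1, noise = -0.1),
               0.45)
})

test_that("replicate noise averages out around the deterministic part", {
  ts <- simulate_tree(p_small, seed = 8)
  ms <- assign_mutations(ts, p_small, seed = 9)
  reps <- 800
  set.seed(10)
  p_noise <- p_small
  vals <- replicate(reps, {
    fs <- simulate_fitness(ts, ms, p_noise)
    fs$replicates$mgr_true[1]
  })
  fs0 <- local({p0 <- p_small; p0$sigma_gxe <- 0; p0$sigma_rep <- 0
                simulate_fitness(ts, ms, p0, seed = 11)})
  det <- fs0$replicates$mgr_det[1]
  # lognormal mean correction is ~exp(sigma^2): tiny at these sds
  expect_lt(abs(mean(vals) - det) / det, 3 * sd(vals) / sqrt(reps) / det + 0.01)
})

test_that("OD curves reduce to exact exponentials in the noise-free limit", {
  p0 <- sim_params(n_dom = 2, n_wild = 1, n_env = 1, n_rep = 1,
                   sigma_od = 0, sigma_od_rel = 0, od_K = 1e9)
  reps <- data.frame(strain = "D01", environment = "env01", replicate = 1L,
                     mgr_true = 0.42)
  plate <- generate_od_curves(reps, p0, seed = 12)
  y <- log(plate$od - p0$background_od)
  fit <- lm(y ~ plate$time_h)
  expect_equal(unname(coef(fit)[2]), 0.42, tolerance = 1e-9)
  # early readings sit at inoculum plus background
  expect_equal(plate$od[1], p0$od0 + p0$background_od, tolerance = 1e-9)
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_crosses(p_small, seed = 99)
  s2 <- simulate_crosses(p_small, seed = 99)
  expect_identical(s1$plate$od, s2$plate$od)
  expect_identical(s1$divergence, s2$divergence)
  expect_identical(s1$agar$intensity_final, s2$agar$intensity_final)
  expect_error(simulate_crosses(p_small), "seed")
})

test_that("agar truth is monotone in dose and the analysis tracks it", {
  sim <- simulate_crosses(sim_params(n_env = 1, n_rep = 1), seed = 14,
                          od_curves = FALSE)
  tr <- sim$agar_truth
  # shared robustness draw + declining thresholds: grower sets are nested
  for (ag in unique(tr$stress_agent)) {
    sub <- split(tr[tr$stress_agent == ag, ], tr$dose[tr$stress_agent == ag])
    props <- vapply(sub, function(d) mean(d$grows), numeric(1))
    expect_true(all(diff(props[order(as.numeric(names(props)))]) <= 0))
  }
  cal <- calibrate_intensity(sim$calibration$intensity,
                             sim$calibration$cell_count)
  fit <- agar_fitness(sim$agar, cal)
  per_cond <- unique(fit[, c("strain_id", "stress_agent", "dose",
                             "is_grower")])
  agg <- aggregate(is_grower ~ stress_agent + dose, per_cond, mean)
  for (ag in unique(agg$stress_agent)) {
    pr <- agg[agg$stress_agent == ag, ]
    pr <- pr[order(pr$dose), ]
    expect_true(all(diff(pr$is_grower) <= 0.08))  # monotone up to noise
  }
  # mildest dose: essentially everyone grows
  mild <- agg[agg$dose %in% c(0.5, 2, 2.5)[1], ]
  expect_true(all(agg$is_grower[agg$dose == min(agg$dose)] > 0.95))
})

test_that("equal clade mutation rates remove the class differences", {
  p_eq <- sim_params(lambda_wild = 3.5)  # same as lambda_dom
  sim <- simulate_crosses(p_eq, seed = 15, od_curves = FALSE, agar = FALSE)
  fm <- tapply(sim$replicates$mgr_true,
               list(sim$replicates$strain, sim$replicates$environment), mean)
  sc <- heterosis_scores(fm, sim$crosses, sim$metadata)
  su <- heterosis_summary(sc)
  mm <- setNames(su$mean_mph, su$cross_class)
  # all classes now carry load: WxW heterosis is no longer ~0 and the
  # DxD - WxW gap collapses relative to the default setting
  expect_gt(mm["WxW"], 0.005)
  expect_lt(abs(mm["DxD"] - mm["WxW"]), 0.015)
})
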