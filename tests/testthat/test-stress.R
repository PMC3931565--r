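test_that("calibration recovers an exact linear law and rejects bad input", {
  cal <- calibrate_intensity(1:10, 1000 * (1:10))
  expect_equal(cal$slope, 1000, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-6)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-12)
  expect_equal(intensity_to_cells(cal, 5), 5000, tolerance = 1e-6)

  expect_error(calibrate_intensity(1:2, c(10, 20)), "at least 3")
  expect_error(calibrate_intensity(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("noisy calibration at the study scale stays tightly linear", {
  set.seed(3)
  intensity <- exp(runif(40, log(200), log(20000)))
  cells <- 2000 * intensity * (1 + rnorm(40, 0, 0.05))
  cal <- calibrate_intensity(intensity, cells)
  expect_gt(cal$pearson_r, 0.98)
  expect_equal(cal$slope, 2000, tolerance = 0.1)
})

test_that("patch growth rate and doublings follow the log-ratio definitions", {
  res <- patch_growth_rate(1e5, 8e5, 24)
  expect_equal(res$doublings, 3)
  expect_equal(res$growth_rate, log(8) / 24)

  expect_equal(patch_growth_rate(5, 5, 10)$growth_rate, 0)
  expect_equal(patch_growth_rate(1, exp(0.1 * 48), 48)$growth_rate, 0.1)
  expect_error(patch_growth_rate(0, 10, 1), "positive")
  expect_error(patch_growth_rate(10, 10, 0), "positive")
})

test_that("grower classification zeroes before the one-positive test", {
  nong <- classify_grower(c(0.05, 0.06, 0.04), c(2, 3, 2))
  expect_false(nong$is_grower)
  expect_true(nong$condition_nongrowing)
  expect_equal(nong$growth_rate, c(0, 0, 0))

  grow <- classify_grower(c(0.1, 0.12, 0.09), c(5, 6, 4))
  expect_true(grow$is_grower)
  expect_equal(grow$growth_rate, c(0.1, 0.12, 0.09))

  # one good trial among failures: mean doublings ~1.17 <= 3, so the
  # zeroing precedes (and defeats) the one-positive test
  mixed <- classify_grower(c(0.08, 0, 0), c(3.5, 0, 0))
  expect_false(mixed$is_grower)
  expect_true(mixed$condition_nongrowing)

  # alternative order keeps the positive trial visible
  alt <- classify_grower(c(0.08, 0, 0), c(3.5, 0, 0), zero_first = FALSE)
  expect_true(alt$is_grower)
  expect_equal(alt$growth_rate, c(0, 0, 0))  # still zeroed afterwards
})

test_that("agar fitness pipeline classifies per strain x condition", {
  cal <- calibrate_intensity(1:10, 1000 * (1:10))
  assays <- data.frame(
    strain_id = rep(c("a", "b"), each = 3),
    stress_agent = "NaCl", dose = 8, trial = rep(1:3, 2),
    intensity_initial = rep(100, 6),
    intensity_final = c(100 * 2^5, 100 * 2^6, 100 * 2^4,   # a: grower
                        100 * 2^2, 100 * 2^1, 100 * 2^2),  # b: nongrower
    incubation_h = 48)
  fit <- agar_fitness(assays, cal)
  a <- fit[fit$strain_id == "a", ]
  b <- fit[fit$strain_id == "b", ]
  expect_true(all(a$is_grower))
  expect_equal(a$doublings, c(5, 6, 4), tolerance = 1e-9)
  expect_false(any(b$is_grower))
  expect_equal(b$growth_rate, rep(0, 3))
})

test_that("survival proportions are in [0,1] and group sizes are honest", {
  cal <- calibrate_intensity(1:10, 1000 * (1:10))
  assays <- expand.grid(strain_id = c("a", "b", "c"), trial = 1:3,
                        dose = c(1, 2), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  assays$stress_agent <- "NaCl"
  assays$intensity_initial <- 100
  # a grows at both doses, b only at dose 1, c never
  assays$intensity_final <- with(assays, ifelse(
    strain_id == "a", 100 * 2^5,
    ifelse(strain_id == "b" & dose == 1, 100 * 2^5, 100 * 2^1)))
  assays$incubation_h <- 48
  fit <- agar_fitness(assays, cal)
  groups <- data.frame(strain_id = c("a", "b", "c"), group = "all")
  sv <- survival_curve(fit, groups)
  expect_equal(sv$proportion[sv$dose == 1], 2 / 3)
  expect_equal(sv$proportion[sv$dose == 2], 1 / 3)
  expect_true(all(sv$proportion >= 0 & sv$proportion <= 1))

  one <- survival_curve(fit, data.frame(strain_id = "a", group = "solo"))
  expect_true(all(one$proportion %in% c(0, 1)))
})

test_that("normalization divides by the grower median and is scale-free", {
  fit <- data.frame(
    strain_id = rep(c("a", "b", "c"), each = 3),
    stress_agent = "Na", dose = 10, trial = rep(1:3, 3),
    growth_rate = c(0.10, 0.10, 0.10,  0.20, 0.20, 0.20,  0, 0, 0),
    doublings = c(5, 5, 5, 6, 6, 6, 0, 0, 0),
    condition_nongrowing = rep(c(FALSE, FALSE, TRUE), each = 3),
    is_grower = rep(c(TRUE, TRUE, FALSE), each = 3))
  norm <- normalize_fitness(fit, conditions = data.frame(stress_agent = "Na",
                                                         dose = 10))
  expect_equal(norm$normalized[norm$strain_id == "a"], 0.1 / 0.15)
  expect_equal(norm$normalized[norm$strain_id == "c"], 0)

  fit2 <- fit; fit2$growth_rate <- fit2$growth_rate * 2
  norm2 <- normalize_fitness(fit2, conditions = data.frame(stress_agent = "Na",
                                                           dose = 10))
  expect_equal(norm$normalized, norm2$normalized, tolerance = 1e-12)

  fit3 <- fit; fit3$is_grower <- FALSE; fit3$growth_rate <- 0
  expect_error(normalize_fitness(fit3, conditions = data.frame(
    stress_agent = "Na", dose = 10)), "no viable growers")
})

test_that("resampling null has the analytic mean and handles constants", {
  vals <- list(a = rep(1, 5), b = rep(1, 3), c = rep(1, 7))
  expect_equal(unique(resample_null(vals, 100, seed = 1)), 1)
  zeros <- list(a = 0, b = 0, c = 0)
  expect_equal(unique(resample_null(zeros, 50, seed = 1)), 0)

  set.seed(9)
  vals2 <- list(a = runif(30), b = runif(40), c = runif(20))
  draws <- resample_null(vals2, 10000, seed = 2)
  expected <- mean(vapply(vals2, mean, numeric(1)))
  se <- sqrt(sum(vapply(vals2, var, numeric(1))) / 3^2 / 10000)
  expect_lt(abs(mean(draws) - expected), 3 * se)

  # determinism under a fixed seed
  expect_identical(resample_null(vals2, 100, seed = 7),
                   resample_null(vals2, 100, seed = 7))
})

test_that("empirical per-strain stress means require all stresses", {
  norm <- data.frame(strain_id = c("a", "a", "a", "b", "b"),
                     stress_agent = c("x", "y", "z", "x", "y"),
                     normalized = c(1, 0.5, 0, 1, 1))
  em <- empirical_stress_means(norm)
  expect_equal(unname(em["a"]), 0.5)
  expect_false("b" %in% names(em))
})

test_that("KS statistic equals the brute-force ECDF oracle", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)

  set.seed(19)
  for (i in 1:10) {
    a <- sample(c(0, round(runif(4), 2)), 5, replace = TRUE)
    b <- sample(c(0, round(runif(4), 2)), 5, replace = TRUE)
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_D(a, b))
  }

  # heavy ties (the zero-inflated case the stress data produce)
  a <- c(0, 0, 0, 0.5, 1)
  b <- c(0, 1, 1, 1, 1)
  expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_D(a, b))
})

test_that("asymptotic KS p-value agrees with stats::ks.test on clean data", {
  set.seed(29)
  a <- rnorm(80)
  b <- rnorm(120, 0.2)
  mine <- ks_two_sample(a, b)
  ref <- ks.test(a, b, exact = FALSE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  expect_true(mine$statistic >= 0 && mine$statistic <= 1)
})
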