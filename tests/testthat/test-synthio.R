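test_that("synthetic constants realize the pigment-masking configuration deterministically", {
  cst1 <- desk_constants()
  cst2 <- desk_constants()
  expect_identical(cst1, cst2)
  K <- cst1$specific_absorption
  # carotenoid and anthocyanin support nested inside the chlorophyll band
  thr <- 1e-4 * max(K[, "CAR"])
  expect_true(all(K[K[, "CAR"] > thr, "CHL"] > 0))
  expect_true(all(K[K[, "ANT"] > 1e-4 * max(K[, "ANT"]), "CHL"] > 0))
  # zero-peak spec still yields valid constants
  spec0 <- constants_spec(desk_grid())
  for (v in names(spec0$bands)) spec0$bands[[v]]$peak[] <- 0
  cst0 <- synthetic_optical_constants(spec0)
  expect_equal(max(cst0$specific_absorption), 0)
  # bands outside the grid are refused
  bad <- default_absorption_bands()
  bad$CHL$center[1] <- 3000
  expect_error(constants_spec(desk_grid(), bands = bad), class = "leafoptics_spec")
})

test_that("trait populations honour their marginals, copula and seed", {
  spec <- archetype_population("wide", n_samples = 1500, seed = 91)
  pop1 <- sample_trait_population(spec)
  pop2 <- sample_trait_population(spec)
  expect_identical(pop1, pop2)
  # Kolmogorov-Smirnov agreement of the truncated-normal CHL marginal
  m <- spec$marginals$CHL
  plo <- pnorm(m$lower, m$mean, m$sd); phi <- pnorm(m$upper, m$mean, m$sd)
  theo <- function(q) (pnorm(q, m$mean, m$sd) - plo) / (phi - plo)
  emp <- ecdf(pop1$CHL)
  qs <- seq(m$lower + 0.1, m$upper - 0.1, length.out = 200)
  expect_lt(max(abs(emp(qs) - theo(qs))), 0.05)
  # CHL-CAR rank correlation close to the copula target
  expect_equal(cor(pop1$CHL, pop1$CAR, method = "spearman"), 0.8, tolerance = 0.1)
  # bounds respected
  expect_true(all(pop1$N >= 1.1 & pop1$N <= 3.4))
})

test_that("a bimodal marginal produces two density modes at large n", {
  spec <- population_spec(
    list(N = marg <- list(kind = "mix2", lower = 1, upper = 3.5, mean1 = 1.3,
                          sd1 = 0.08, mean2 = 2.5, sd2 = 0.12, weight = 0.5),
         CHL = list(kind = "point", lower = 0, upper = 120, value = 40),
         CAR = list(kind = "point", lower = 0, upper = 30, value = 10),
         ANT = list(kind = "point", lower = 0, upper = 40, value = 1),
         EWT = list(kind = "point", lower = 0, upper = 0.1, value = 0.01),
         LMA = list(kind = "point", lower = 0, upper = 0.05, value = 0.005)),
    chl_car_rho = 0, n_samples = 2000, seed = 8)
  pop <- sample_trait_population(spec)
  dens <- density(pop$N)
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
  modes <- dens$x[peaks][dens$y[peaks] > 0.25 * max(dens$y)]
  expect_length(modes, 2)
  expect_equal(sort(modes), c(1.3, 2.5), tolerance = 0.15)
  # point masses are degenerate draws
  expect_equal(var(pop$CHL), 0)
})

test_that("band-localized corruption depresses correlation only inside its bands", {
  cst <- desk_constants()
  d <- wide_population_dataset(50, seed = 15, constants = cst)
  ns <- noise_spec(bands = data.frame(lambda_start = 600, lambda_end = 725),
                   seed = 15)
  meas <- corrupt_to_measured(d$spectra, ns)
  expect_identical(meas$meta, d$spectra$meta)
  r <- pearson_profile(d$spectra, meas)
  wl <- as.numeric(cst$grid)
  inside <- wl >= 600 & wl <= 725
  expect_lt(max(r[inside]), 0.9)
  expect_gt(min(r[!inside]), 0.97)
  # zero noise is the identity
  silent <- noise_spec(band_sd = 0, band_jitter = 0, background_sd = 0)
  expect_equal(corrupt_to_measured(d$spectra, silent)$values, d$spectra$values)
  # heavy noise near zero reflectance still clips into [0, 1]
  dark <- spectral_dataset(matrix(0.001, 10, 51), cst$grid)
  loud <- corrupt_to_measured(dark, noise_spec(band_sd = 0.5, seed = 1))
  expect_true(all(loud$values >= 0 & loud$values <= 1))
})

test_that("the full noise + cycle pipeline reproduces the four-band error phenomenology", {
  cst <- desk_constants()
  d <- wide_population_dataset(30, seed = 19, constants = cst)
  ns <- noise_spec(seed = 19)
  meas <- corrupt_to_measured(d$spectra, ns)
  prof <- wavelength_error_profile(d$spectra, meas)
  bands <- flag_low_accuracy_bands(prof)
  # every injected band is rediscovered by an overlapping flagged band
  overlaps <- function(b1s, b1e, b2s, b2e) b1s <= b2e & b2s <= b1e
  for (i in seq_len(nrow(ns$bands)))
    expect_true(any(overlaps(bands$lambda_start, bands$lambda_end,
                             ns$bands$lambda_start[i], ns$bands$lambda_end[i])))
  for (i in seq_len(nrow(bands)))
    expect_true(any(overlaps(ns$bands$lambda_start, ns$bands$lambda_end,
                             bands$lambda_start[i], bands$lambda_end[i])))
})

test_that("trial simulation is deterministic and collapses without variance", {
  cst <- desk_constants()
  des <- trial_design(n_genotypes = 8)
  quiet <- simulate_population_trial(des, cst, sigma2_g = 2, sigma2_ge = 0,
                                     sigma2_eps = 0, env_effect_sd = 0, seed = 3)
  # without environment, GxE and residual variance all observations of a
  # genotype coincide
  split_rows <- split(seq_len(nrow(quiet$values)), quiet$meta$genotype_id)
  for (idx in split_rows)
    expect_equal(max(apply(quiet$values[idx, , drop = FALSE], 2, var)), 0)
  t1 <- simulate_population_trial(des, cst, seed = 9)
  t2 <- simulate_population_trial(des, cst, seed = 9)
  expect_identical(t1$values, t2$values)
  expect_identical(attr(t1, "trait_values"), attr(t2, "trait_values"))
  # unbalanced draws stay within the declared ranges
  tu <- simulate_population_trial(trial_design(n_genotypes = 6), cst,
                                  unbalanced = TRUE, seed = 4)
  reps <- tapply(tu$meta$replicate_id,
                 paste(tu$meta$genotype_id, tu$meta$environment_id),
                 function(x) length(unique(x)))
  expect_true(all(reps >= 1 & reps <= 2))
})
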