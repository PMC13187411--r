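test_that("variance components: noiseless genotype differences go entirely to sigma2_g", {
  d <- expand.grid(genotype = 1:6, env = 1:2, rep = 1:2)
  means <- c(10, 12, 14, 16, 18, 20)
  vals <- means[d$genotype]                       # identical within genotype
  vc <- variance_components(vals, d$genotype, d$env, d$rep)
  expect_equal(vc$sigma2_eps, 0)
  expect_equal(vc$sigma2_ge, 0)
  expect_equal(vc$sigma2_g, var(means))
  one <- d$genotype == 1
  expect_error(variance_components(vals[one], d$genotype[one], d$env[one]),
               class = "leafoptics_degenerate_design")
})

test_that("variance components: pure noise gives near-zero genotypic variance", {
  set.seed(17)
  n_g <- 150
  d <- expand.grid(genotype = 1:n_g, env = 1:2, rep = 1:2)
  d$y <- rnorm(nrow(d))
  vc <- variance_components(d$y, d$genotype, d$env, d$rep)
  expect_lt(vc$sigma2_g, 0.05)
  expect_equal(vc$sigma2_eps, 1, tolerance = 0.25)
})

test_that("balanced simulated trials recover the generative variance components", {
  est <- sapply(1:20, function(s) {
    d <- balanced_trial_values(s)
    vc <- variance_components(d$y, d$genotype, d$environment, d$replicate)
    c(g = vc$sigma2_g, ge = vc$sigma2_ge, eps = vc$sigma2_eps)
  })
  m <- rowMeans(est)
  expect_equal(unname(m["g"]), 2, tolerance = 0.15)
  expect_equal(unname(m["ge"]), 1, tolerance = 0.15)
  expect_equal(unname(m["eps"]), 2, tolerance = 0.15)
})

test_that("entry-mean identity holds exactly in every emitted component set", {
  for (s in 1:5) {
    d <- balanced_trial_values(s, ng = 60)
    vc <- variance_components(d$y, d$genotype, d$environment, d$replicate)
    expect_identical(vc$sigma2_p,
                     vc$sigma2_g + vc$sigma2_ge / vc$n_e_eff +
                       vc$sigma2_eps / (vc$n_e_eff * vc$n_r_eff))
  }
})

test_that("broad-sense heritability reproduces the worked example and its limits", {
  mk_vc <- function(g, ge, eps, ne = 2, nr = 2) structure(
    list(sigma2_g = g, sigma2_ge = ge, sigma2_eps = eps,
         sigma2_p = g + ge / ne + eps / (ne * nr), n_e_eff = ne, n_r_eff = nr,
         single_environment = FALSE), class = "variance_components")
  expect_equal(broad_sense_h2(mk_vc(2, 1, 2)), 2 / 3)
  expect_equal(broad_sense_h2(mk_vc(0, 1, 2)), 0)
  expect_equal(broad_sense_h2(mk_vc(3, 0, 0)), 1)
  expect_true(is.na(broad_sense_h2(mk_vc(0, 0, 0))))
  # monotone in genotypic variance with the others fixed
  h <- sapply(seq(0, 5, by = 0.5), function(g) broad_sense_h2(mk_vc(g, 1, 2)))
  expect_true(all(diff(h) > 0))
})

test_that("repeats are technical measurements: averaging them changes nothing when identical", {
  d <- balanced_trial_values(3, ng = 40)
  d2 <- rbind(d, d)                         # two identical repeats per plot
  d2$rep_q <- rep(1:2, each = nrow(d))
  vc1 <- variance_components(d$y, d$genotype, d$environment, d$replicate)
  vc2 <- variance_components(d2$y, d2$genotype, d2$environment, d2$replicate,
                             rep_id = d2$rep_q)
  expect_equal(vc1$sigma2_g, vc2$sigma2_g, tolerance = 1e-10)
  expect_equal(vc1$sigma2_eps, vc2$sigma2_eps, tolerance = 1e-10)
})

test_that("per-wavelength heritability localizes genotype signal and matches direct calls", {
  set.seed(23)
  ng <- 40
  wl <- seq(400, 2450, length.out = 11)
  d <- expand.grid(genotype = 1:ng, env = 1:2, rep = 1:2)
  g_eff <- rnorm(ng, 0, 0.05)
  vals <- matrix(0.3, nrow(d), length(wl))
  sig <- wl > 1000
  vals[, sig] <- vals[, sig] + g_eff[d$genotype]          # heritable only here
  vals <- vals + matrix(rnorm(length(vals), 0, 0.01), nrow(d))
  vals <- pmin(pmax(vals, 0), 1)
  ds <- spectral_dataset(vals, wavelength_grid(wl),
                         data.frame(sample_id = paste0("o", seq_len(nrow(d))),
                                    genotype_id = d$genotype,
                                    environment_id = d$env,
                                    replicate_id = d$rep))
  h2 <- h2_spectrum(ds)
  expect_lt(max(h2$h2[!sig]), 0.3)
  expect_gt(min(h2$h2[sig]), 0.6)
  # consistency with a direct per-wavelength call
  vc <- variance_components(ds$values[, 11], ds$meta$genotype_id,
                            ds$meta$environment_id, ds$meta$replicate_id)
  expect_equal(h2$h2[11], broad_sense_h2(vc))
  expect_equal(h2$sigma2_g[11], vc$sigma2_g)
  bad <- ds
  bad$meta$genotype_id <- NULL
  expect_error(h2_spectrum(bad), class = "leafoptics_schema")
})

test_that("a noiseless single-environment genotype signal is fully heritable", {
  ng <- 12
  wl <- c(500, 1500)
  g_eff <- seq(0.2, 0.5, length.out = ng)
  vals <- cbind(rep(0.3, 2 * ng), rep(g_eff, each = 2))   # signal only at 1500 nm
  ds <- spectral_dataset(vals, wavelength_grid(wl),
                         data.frame(sample_id = paste0("o", seq_len(2 * ng)),
                                    genotype_id = rep(1:ng, each = 2),
                                    environment_id = 1,
                                    replicate_id = rep(1:2, ng)))
  h2 <- h2_spectrum(ds)
  expect_equal(h2$sigma2_ge, c(0, 0))       # fixed at zero: single environment
  expect_equal(h2$h2[2], 1, tolerance = 1e-6)
})

test_that("heritability-spectrum plotting runs on a null device", {
  d <- balanced_trial_values(2, ng = 20)
  vals <- pmin(pmax(matrix(d$y / 40 + 0.3, nrow(d), 2), 0), 1)
  ds <- spectral_dataset(vals, wavelength_grid(c(500, 1500)),
                         data.frame(sample_id = paste0("o", seq_len(nrow(d))),
                                    genotype_id = d$genotype,
                                    environment_id = d$environment,
                                    replicate_id = d$replicate))
  h2 <- h2_spectrum(ds)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(h2))
})
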