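make_xy <- function(n = 40, p = 20, rank = NULL, seed = 2) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.05, 0.6), n, p)
  if (!is.null(rank)) {
    base <- matrix(runif(n * rank, 0.05, 0.6), n, rank)
    mix <- matrix(runif(rank * p), rank, p)
    X <- base %*% mix
    X <- (X - min(X)) / (max(X) - min(X)) * 0.8 + 0.05
  }
  spectral_dataset(X, wavelength_grid(seq_len(p) * 10 + 390))
}

test_that("PLSR fits a realizable linear map exactly on a rank-limited problem", {
  ds <- make_xy(n = 40, p = 20, rank = 5)
  beta <- runif(20, -1, 1)
  y <- as.numeric(ds$values %*% beta)   # lies in the rank-5 column space
  fit <- fit_plsr_trait_model(ds, y, n_components = 5)
  yhat <- predict(fit, ds)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("PLSR caps components at the feasibility bound and matches OLS at full rank", {
  ds <- make_xy(n = 10, p = 30)
  y <- rowMeans(ds$values) + rnorm(10, 0, 0.01)
  expect_warning(fit <- fit_plsr_trait_model(ds, y, n_components = 30),
                 "capped")
  expect_equal(fit$n_components, 9)
  # full-rank small problem: PLSR with ncomp = rank equals least squares
  ds2 <- make_xy(n = 30, p = 8, seed = 5)
  y2 <- as.numeric(ds2$values %*% runif(8)) + rnorm(30, 0, 0.05)
  fit2 <- fit_plsr_trait_model(ds2, y2, n_components = 8)
  ols <- lm.fit(cbind(1, ds2$values), y2)
  expect_equal(predict(fit2, ds2),
               as.numeric(cbind(1, ds2$values) %*% ols$coefficients),
               tolerance = 1e-8)
  expect_error(fit_plsr_trait_model(ds2, rep(1, 30)),
               class = "leafoptics_degenerate_response")
})

test_that("prediction scores reproduce the worked clamp example", {
  y <- c(0.2, 1.1, -0.7, 2.3, 0.5)
  expect_equal(prediction_scores(y, y), list(r = 1, r_squared = 1, r_squared_clamped = 1))
  null_pred <- prediction_scores(y, rep(mean(y), 5))
  expect_equal(null_pred$r_squared, 0)
  set.seed(3)
  yt <- rnorm(50)
  yt <- (yt - mean(yt)) / sd(yt)        # var exactly 1
  sc <- prediction_scores(yt, -3 * yt + 7)
  expect_equal(sc$r, -1)
  expect_lt(sc$r_squared, -1)
  expect_equal(sc$r_squared_clamped, -1)
  expect_true(all(is.na(unlist(prediction_scores(rep(1, 5), y)))))
  expect_error(prediction_scores(1:2, 1:2), class = "leafoptics_insufficient_samples")
})

test_that("transfer matrix is exchangeable for identical datasets and complete", {
  cst <- desk_constants()
  d <- wide_population_dataset(40, seed = 51, constants = cst)
  datasets <- list(a = list(spectra = d$spectra, traits = d$pop),
                   b = list(spectra = d$spectra, traits = d$pop))
  tm <- transfer_matrix(datasets, traits = c("CHL", "EWT"), n_components = 10)
  expect_equal(nrow(tm), 2 * 2 * 2)
  for (v in c("CHL", "EWT")) {
    sub <- tm[tm$trait == v, ]
    expect_equal(sub$r2[!sub$diagonal], sub$r2[sub$diagonal],
                 tolerance = 1e-9)
  }
  # grid mismatch is refused with both names
  d2 <- wide_population_dataset(10, seed = 5,
                                constants = synthetic_optical_constants(
                                  constants_spec(desk_grid(41))))
  expect_error(transfer_matrix(list(a = datasets$a,
                                    c = list(spectra = d2$spectra, traits = d2$pop))),
               class = "leafoptics_dimension")
})

test_that("sensitivity profiles isolate one trait at a time", {
  cst <- desk_constants()
  d <- wide_population_dataset(25, seed = 61, constants = cst)
  profs <- sensitivity_profiles(d$pop, cst)
  # CV equals sd/mean recomputed directly from a manual ensemble
  v <- "EWT"
  tm <- leafoptics:::as_traits_matrix(d$pop)
  mod <- matrix(rep(colMeans(tm), each = nrow(tm)), nrow(tm),
                dimnames = list(NULL, colnames(tm)))
  mod[, v] <- tm[, v]
  R <- leafoptics:::forward_reflectance_matrix(mod, cst)
  expect_equal(profs[[v]]$cv, apply(R, 2, sd) / colMeans(R), tolerance = 1e-12)
  # constant trait: zero variance everywhere
  pop_const <- d$pop
  pop_const$ANT <- 3
  profs2 <- sensitivity_profiles(pop_const, cst, traits = "ANT")
  expect_equal(max(profs2$ANT$sd), 0)
  expect_equal(max(profs2$ANT$cv, na.rm = TRUE), 0)
  # a constituent with no absorption pathway cannot move the spectrum
  spec <- constants_spec(desk_grid())
  spec$bands$ANT$peak[] <- 0
  cst0 <- synthetic_optical_constants(spec)
  profs3 <- sensitivity_profiles(d$pop, cst0, traits = "ANT")
  expect_equal(max(profs3$ANT$cv, na.rm = TRUE), 0)
  expect_error(sensitivity_profiles(d$pop[1, ], cst),
               class = "leafoptics_insufficient_samples")
})

test_that("masked pigments transfer worse than broad-band traits across archetypes", {
  # compact 3-dataset suite; the full-size ordering is asserted in the
  # acceptance suite
  cst <- desk_constants()
  sets <- list()
  for (arch in c("wide", "crop", "tropical")) {
    pop <- sample_trait_population(archetype_population(arch, n_samples = 120, seed = 71))
    sets[[arch]] <- list(spectra = simulate_population(pop, cst), traits = pop)
  }
  tm <- transfer_matrix(sets, traits = c("CHL", "EWT", "CAR", "ANT"))
  off <- !tm$diagonal
  for (tr_id in c("wide", "crop", "tropical")) for (te_id in c("wide", "crop", "tropical")) {
    if (tr_id == te_id) next
    pair <- tm$train_id == tr_id & tm$test_id == te_id
    broad <- min(tm$r2[pair & tm$trait %in% c("CHL", "EWT")])
    masked <- max(tm$r2[pair & tm$trait %in% c("CAR", "ANT")])
    expect_gt(broad, masked)
  }
  # diagonal (training-set) fit at least as good as mean off-diagonal transfer
  for (v in c("CHL", "EWT", "CAR", "ANT")) {
    sub <- tm[tm$trait == v, ]
    expect_gte(mean(sub$r2[sub$diagonal]), mean(sub$r2[!sub$diagonal]))
  }
})
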