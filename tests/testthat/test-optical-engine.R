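test_that("average transmissivity matches the Fresnel quadrature oracle", {
  expect_equal(average_transmissivity(40, 1), 1)
  expect_equal(average_transmissivity(90, 1.5), tav_quadrature(90, 1.5),
               tolerance = 1e-6)
  for (al in c(20, 40, 59, 90)) for (n in c(1.2, 1.45, 1.6))
    expect_equal(average_transmissivity(al, n), tav_quadrature(al, n),
                 tolerance = 1e-9)
  expect_true(average_transmissivity(40, 1.3) > average_transmissivity(40, 1.6))
  expect_error(average_transmissivity(0, 1.4), class = "leafoptics_domain")
  expect_error(average_transmissivity(95, 1.4), class = "leafoptics_domain")
  expect_error(average_transmissivity(40, 0.9), class = "leafoptics_domain")
})

test_that("elementary-layer transmission matches the isotropic-flux quadrature oracle", {
  expect_equal(layer_transmission(0), 1)
  expect_equal(layer_transmission(0.5), tau_quadrature(0.5), tolerance = 1e-8)
  expect_equal(layer_transmission(10), tau_quadrature(10), tolerance = 1e-8)
  expect_lt(layer_transmission(10), 1e-4)
  kk <- 10^seq(-6, log10(50), length.out = 40)
  expect_equal(layer_transmission(kk), tau_quadrature(kk), tolerance = 1e-8)
  expect_true(all(diff(layer_transmission(kk)) < 0))
  expect_error(layer_transmission(-0.1), class = "leafoptics_domain")
})

test_that("the hand-rolled exponential integral agrees with an established implementation", {
  skip_if_not_installed("pracma")
  x <- 10^seq(-6, log10(50), length.out = 60)
  expect_equal(leafoptics:::expint_e1(x), pracma::expint_E1(x), tolerance = 1e-12)
})

test_that("total absorption is linear in contents and inverse in N", {
  cst <- desk_constants()
  zero <- leaf_traits(N = 2, CHL = 0, CAR = 0, ANT = 0, EWT = 0, LMA = 0)
  expect_equal(total_absorption(zero, cst), rep(0, 51))
  tr <- leaf_traits(N = 2, CHL = 30, CAR = 8, ANT = 2, EWT = 0.01, LMA = 0.006)
  dbl <- leaf_traits(N = 2, CHL = 60, CAR = 16, ANT = 4, EWT = 0.02, LMA = 0.012)
  expect_equal(total_absorption(dbl, cst), 2 * total_absorption(tr, cst))
  deep <- leaf_traits(N = 4, CHL = 30, CAR = 8, ANT = 2, EWT = 0.01, LMA = 0.006)
  expect_equal(total_absorption(deep, cst), total_absorption(tr, cst) / 2)
})

test_that("single plate matches the ray-summation oracle and conserves energy", {
  # opaque plate
  p0 <- plate_single_layer(0, 1.4, 40)
  expect_equal(p0$transmittance, 0)
  expect_equal(p0$reflectance, 1 - average_transmissivity(40, 1.4))
  # no absorption: all light goes somewhere
  p1 <- plate_single_layer(1, 1.4, 40)
  expect_equal(p1$reflectance + p1$transmittance, 1, tolerance = 1e-12)
  # explicit sum over internal bounces
  p <- plate_single_layer(0.8, 1.4, 40)
  o <- plate_ray_oracle(0.8, 1.4, 40)
  expect_equal(unname(p$reflectance), unname(o["R"]), tolerance = 1e-10)
  expect_equal(unname(p$transmittance), unname(o["T"]), tolerance = 1e-10)
  expect_error(plate_single_layer(1.2, 1.4), class = "leafoptics_domain")
})

test_that("Stokes stack agrees with iterative layer adding for integer layer counts", {
  st1 <- stokes_stack(0.1, 0.7, 1)
  expect_equal(st1$reflectance, 0.1)
  expect_equal(st1$transmittance, 0.7)
  st2 <- stokes_stack(0.1, 0.7, 2)
  expect_equal(st2$reflectance, 0.1 + 0.7^2 * 0.1 / (1 - 0.1^2), tolerance = 1e-12)
  expect_equal(st2$transmittance, 0.7^2 / (1 - 0.1^2), tolerance = 1e-12)
  for (m in 2:5) {
    st <- stokes_stack(0.12, 0.63, m)
    o <- adding_oracle(0.12, 0.63, m)
    expect_equal(unname(st$reflectance), unname(o["R"]), tolerance = 1e-10)
    expect_equal(unname(st$transmittance), unname(o["T"]), tolerance = 1e-10)
  }
  std <- stokes_stack(0.3, 0, 3)
  expect_equal(std$transmittance, 0)
  expect_equal(std$reflectance, 0.3)
  expect_error(stokes_stack(0.6, 0.5, 2), class = "leafoptics_nonphysical")
})

test_that("forward spectra obey the energy budget over random draws", {
  cst <- desk_constants()
  set.seed(101)
  worst_sum <- 0; all_in_range <- TRUE
  for (i in 1:1000) {
    tr <- leaf_traits(N = runif(1, 1, 4), CHL = runif(1, 0, 120),
                      CAR = runif(1, 0, 30), ANT = runif(1, 0, 40),
                      EWT = runif(1, 0, 0.1), LMA = runif(1, 0, 0.05))
    sp <- forward_spectrum(tr, cst)
    all_in_range <- all_in_range &&
      all(sp$reflectance >= 0 & sp$reflectance <= 1) &&
      all(sp$transmittance >= 0 & sp$transmittance <= 1)
    worst_sum <- max(worst_sum, max(sp$reflectance + sp$transmittance))
  }
  expect_true(all_in_range)
  expect_lte(worst_sum, 1 + 1e-9)   # absorptance = 1 - R - T stays >= 0
})

test_that("forward spectrum has no spectral structure without absorption", {
  g <- desk_grid()
  K <- matrix(0, 51, 5, dimnames = list(NULL, c("CHL", "CAR", "ANT", "EWT", "LMA")))
  flat <- optical_constants(g, rep(1.45, 51), K)
  sp <- forward_spectrum(leaf_traits(N = 2, CHL = 0, CAR = 0, ANT = 0,
                                     EWT = 0, LMA = 0), flat)
  expect_equal(diff(range(sp$reflectance)), 0)
  expect_equal(diff(range(sp$transmittance)), 0)
})

test_that("reflectance decreases monotonically with chlorophyll where it absorbs", {
  cst <- desk_constants()
  base <- forward_spectrum(leaf_traits(CHL = 30), cst)
  more <- forward_spectrum(leaf_traits(CHL = 45), cst)
  absorbing <- cst$specific_absorption[, "CHL"] > 1e-6
  expect_true(all(more$reflectance[absorbing] <= base$reflectance[absorbing]))
})

test_that("forward spectrum is continuous in the real-valued structure parameter", {
  cst <- desk_constants()
  lo <- forward_spectrum(leaf_traits(N = 1.999, CHL = 40), cst)
  hi <- forward_spectrum(leaf_traits(N = 2.001, CHL = 40), cst)
  expect_lt(max(abs(lo$reflectance - hi$reflectance)), 1e-3)
  expect_lt(max(abs(lo$transmittance - hi$transmittance)), 1e-3)
})

test_that("optical constants reject a sixth absorber and bad tables", {
  g <- wavelength_grid(1:3)
  K <- matrix(0.1, 3, 5, dimnames = list(NULL, c("CHL", "CAR", "ANT", "EWT", "LMA")))
  K6 <- cbind(K, BROWN = rep(0.1, 3))
  expect_error(optical_constants(g, rep(1.4, 3), K6), class = "leafoptics_schema")
  expect_error(optical_constants(g, rep(0.9, 3), K), class = "leafoptics_domain")
  expect_error(optical_constants(g, rep(1.4, 3), -K), class = "leafoptics_domain")
})
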