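# shared fixtures, all generated in code

desk_constants <- function() synthetic_optical_constants(constants_spec(desk_grid()))

# tiny dataset builder for the per-wavelength statistics tests
tiny_ds <- function(values, wl = NULL, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(wl)) wl <- seq(500, by = 100, length.out = ncol(values))
  meta <- if (is.null(ids)) NULL else data.frame(sample_id = ids)
  spectral_dataset(values, wavelength_grid(wl), meta)
}

wide_population_dataset <- function(n, seed, constants = desk_constants()) {
  pop <- sample_trait_population(archetype_population("wide", n_samples = n, seed = seed))
  list(pop = pop, spectra = simulate_population(pop, constants))
}

# unpolarized Fresnel transmittance averaged over a cone: independent
# quadrature oracle for average_transmissivity
tav_quadrature <- function(alpha, n) {
  fres <- function(theta) {
    st <- sin(theta); ct <- cos(theta)
    ctt <- sqrt(1 - (st / n)^2)
    rs <- ((ct - n * ctt) / (ct + n * ctt))^2
    rp <- ((n * ct - ctt) / (n * ct + ctt))^2
    1 - (rs + rp) / 2
  }
  a <- alpha * pi / 180
  num <- integrate(function(th) fres(th) * sin(th) * cos(th), 0, a,
                   rel.tol = 1e-12)$value
  den <- integrate(function(th) sin(th) * cos(th), 0, a, rel.tol = 1e-12)$value
  num / den
}

# isotropic-flux slab transmission: independent quadrature oracle for
# layer_transmission
tau_quadrature <- function(k) {
  one <- function(kk) {
    for (tol in c(1e-12, 1e-11, 1e-10)) {
      v <- tryCatch(integrate(function(mu) mu * exp(-kk / mu), 0, 1,
                              rel.tol = tol, subdivisions = 500L)$value,
                    error = function(e) NULL)
      if (!is.null(v)) return(2 * v)
    }
    stop("quadrature failed at k = ", kk)
  }
  vapply(k, one, numeric(1))
}

# explicit ray summation inside a single plate (geometric series, truncated)
plate_ray_oracle <- function(tau, n, alpha, n_bounces = 1e4) {
  talf <- average_transmissivity(alpha, n)
  t21 <- average_transmissivity(90, n) / n^2
  r21 <- 1 - t21
  Tr <- 0; Rr <- 1 - talf
  amp <- talf * tau
  for (i in seq_len(n_bounces)) {
    Tr <- Tr + amp * t21
    amp <- amp * r21 * tau
    Rr <- Rr + amp * t21
    amp <- amp * r21 * tau
  }
  c(R = Rr, T = Tr)
}

# iterative two-stream adding of m identical layers: oracle for stokes_stack
adding_oracle <- function(r, t, m) {
  R <- r; T <- t
  for (i in seq_len(m - 1)) {
    den <- 1 - R * r
    T_new <- T * t / den
    R_new <- R + T^2 * r / den
    R <- R_new; T <- T_new
  }
  c(R = R, T = T)
}

# hand-built single-layer linear "network" F(x) = w . x + c for exact
# integrated-gradients checks
linear_surrogate <- function(w, c0 = 0, grid = NULL) {
  p <- length(w)
  if (is.null(grid)) grid <- wavelength_grid(seq(400, 2450, length.out = p))
  structure(list(weights = list(matrix(w, p, 1)), biases = list(c0),
                 loss_trace = 0,
                 hyperparams = surrogate_hyperparams(hidden_sizes = 1, epochs = 1),
                 trait_names = "linear", grid = grid),
            class = "leaf_surrogate")
}

balanced_trial_values <- function(seed, ng = 200, ne = 2, nr = 2,
                                  sg = 2, sge = 1, se = 2) {
  set.seed(seed)
  g <- rnorm(ng, 0, sqrt(sg))
  e <- rnorm(ne, 0, 1)
  ge <- matrix(rnorm(ng * ne, 0, sqrt(sge)), ng, ne)
  d <- expand.grid(genotype = seq_len(ng), environment = seq_len(ne),
                   replicate = seq_len(nr))
  d$y <- 10 + g[d$genotype] + e[d$environment] +
    ge[cbind(d$genotype, d$environment)] + rnorm(nrow(d), 0, sqrt(se))
  d
}
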