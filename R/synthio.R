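#' Specification for synthetic optical constants
#'
#' Describes a refractive-index curve (base level with a smooth wavelength
#' trend) and, per constituent, a list of Gaussian absorption bands
#' `(center nm, width nm, peak coefficient)`. The default band layout places
#' the carotenoid and anthocyanin bands wholly inside the support of the
#' dominant chlorophyll band — the pigment-masking configuration responsible
#' for their weak identifiability — and gives water and dry matter broad,
#' non-overlapping bands in the long-wavelength half.
#'
#' @param grid a [wavelength_grid()].
#' @param n_base,n_amplitude,n_scale refractive-index curve
#'   `n(lambda) = n_base + n_amplitude * exp(-(lambda - lambda_min)/n_scale)`.
#' @param bands named list (one entry per constituent `CHL, CAR, ANT, EWT,
#'   LMA`) of data frames with columns `center`, `width`, `peak`.
#' @return object of class `constants_spec`.
#' @export
constants_spec <- function(grid = desk_grid(),
                           n_base = 1.4, n_amplitude = 0.1, n_scale = 1200,
                           bands = default_absorption_bands()) {
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (!setequal(names(bands), CONSTITUENTS))
    stop_leafoptics("bands must name exactly the five constituents",
                    "leafoptics_spec")
  lo <- grid[1]; hi <- grid[length(grid)]
  for (cc in CONSTITUENTS) {
    b <- bands[[cc]]
    if (any(b$peak < 0))
      stop_leafoptics("band peak coefficients must be >= 0", "leafoptics_spec")
    if (any(b$center < lo | b$center > hi))
      stop_leafoptics(sprintf("%s band center outside the wavelength grid", cc),
                      "leafoptics_spec")
  }
  structure(list(grid = grid, n_base = n_base, n_amplitude = n_amplitude,
                 n_scale = n_scale, bands = bands),
            class = "constants_spec")
}

#' @rdname constants_spec
#' @export
default_absorption_bands <- function() {
  band <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], peak = m[, 3])
  }
  list(
    CHL = band(670, 60, 0.07, 480, 60, 0.04),
    CAR = band(500, 35, 0.08),              # inside the CHL 480-band support
    ANT = band(550, 25, 0.05),              # inside the CHL band span
    EWT = band(1450, 90, 30, 1940, 110, 45, 2400, 120, 10),
    LMA = band(1720, 80, 300, 2100, 90, 250, 2300, 120, 350, 1200, 200, 20)
  )
}

#' Generate synthetic optical constants
#'
#' Builds an [optical_constants()] table from Gaussian-sum absorption curves.
#' Deterministic given the spec (no randomness is involved).
#'
#' @param spec a [constants_spec()].
#' @return an [optical_constants()] object.
#' @export
synthetic_optical_constants <- function(spec = constants_spec()) {
  stopifnot(inherits(spec, "constants_spec"))
  wl <- as.numeric(spec$grid)
  K <- sapply(CONSTITUENTS, function(cc) {
    b <- spec$bands[[cc]]
    rowSums(sapply(seq_len(nrow(b)), function(i)
      b$peak[i] * exp(-0.5 * ((wl - b$center[i]) / b$width[i])^2)))
  })
  if (is.null(dim(K))) K <- matrix(K, nrow = 1, dimnames = list(NULL, CONSTITUENTS))
  n <- spec$n_base + spec$n_amplitude * exp(-(wl - wl[1]) / spec$n_scale)
  optical_constants(spec$grid, n, K)
}

#' Trait-population specifications and dataset archetypes
#'
#' A population spec gives each trait a marginal distribution — truncated
#' normal (`tnorm`), long-tailed log-normal (`lnorm`) or a two-component
#' normal mixture (`mix2`) — plus a non-negative Gaussian-copula rank
#' correlation between chlorophyll and carotenoid contents. Three bundled
#' archetypes emulate the qualitative structure of real leaf datasets:
#'
#' * `"wide"`: broad species-diverse coverage (herbarium-style collections);
#'   long-tailed CAR and ANT, strong CHL-CAR correlation.
#' * `"crop"`: narrow unimodal single-crop trial.
#' * `"tropical"`: bimodal marginals confined to a domain-shifted region —
#'   narrow coverage whose modes do not span the wide archetype's range.
#'
#' @param marginals named list (N, CHL, CAR, ANT, EWT, LMA) of lists with
#'   `kind` (`"tnorm"`, `"lnorm"`, `"mix2"`, `"point"`) and parameters:
#'   tnorm `mean, sd`; lnorm `meanlog, sdlog`; mix2 `mean1, sd1, mean2, sd2,
#'   weight`; point `value`. Each also carries `lower`, `upper` truncation
#'   limits.
#' @param chl_car_rho rank correlation between CHL and CAR in \[0, 1).
#' @param n_samples number of samples to draw.
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(marginals, chl_car_rho = 0.5, n_samples = 200, seed = 1) {
  stopifnot(is.list(marginals))
  if (!setequal(names(marginals), TRAIT_NAMES))
    stop_leafoptics("marginals must name exactly the six traits", "leafoptics_spec")
  if (chl_car_rho < 0 || chl_car_rho >= 1)
    stop_leafoptics("chl_car_rho must lie in [0, 1)", "leafoptics_spec")
  structure(list(marginals = marginals, chl_car_rho = chl_car_rho,
                 n_samples = n_samples, seed = seed),
            class = "population_spec")
}

marg <- function(kind, lower, upper, ...) c(list(kind = kind, lower = lower, upper = upper), list(...))

#' @rdname population_spec
#' @param archetype one of `"wide"`, `"crop"`, `"tropical"`.
#' @export
archetype_population <- function(archetype = c("wide", "crop", "tropical"),
                                 n_samples = 200, seed = 1) {
  archetype <- match.arg(archetype)
  m <- switch(archetype,
    wide = list(
      N   = marg("tnorm", 1.1, 3.4, mean = 1.9, sd = 0.5),
      CHL = marg("tnorm", 5, 100, mean = 45, sd = 22),
      CAR = marg("lnorm", 0.5, 25, meanlog = log(9), sdlog = 0.5),
      ANT = marg("lnorm", 0.01, 20, meanlog = log(1.5), sdlog = 0.9),
      EWT = marg("tnorm", 0.002, 0.05, mean = 0.018, sd = 0.009),
      LMA = marg("tnorm", 0.002, 0.025, mean = 0.009, sd = 0.004)),
    crop = list(
      N   = marg("tnorm", 1.1, 2.2, mean = 1.5, sd = 0.15),
      CHL = marg("tnorm", 20, 90, mean = 55, sd = 10),
      CAR = marg("tnorm", 2, 22, mean = 12, sd = 2.5),
      ANT = marg("lnorm", 0.01, 10, meanlog = log(0.8), sdlog = 0.7),
      EWT = marg("tnorm", 0.004, 0.025, mean = 0.012, sd = 0.003),
      LMA = marg("tnorm", 0.002, 0.01, mean = 0.005, sd = 0.0012)),
    tropical = list(
      N   = marg("mix2", 1.4, 3.2, mean1 = 2.0, sd1 = 0.08, mean2 = 2.5, sd2 = 0.10, weight = 0.5),
      CHL = marg("mix2", 8, 55, mean1 = 17, sd1 = 2.5, mean2 = 33, sd2 = 3.5, weight = 0.5),
      CAR = marg("lnorm", 0.5, 15, meanlog = log(5), sdlog = 0.5),
      ANT = marg("lnorm", 0.01, 25, meanlog = log(2), sdlog = 0.9),
      EWT = marg("mix2", 0.003, 0.02, mean1 = 0.0065, sd1 = 0.0008, mean2 = 0.011, sd2 = 0.0012, weight = 0.5),
      LMA = marg("mix2", 0.007, 0.022, mean1 = 0.012, sd1 = 0.0009, mean2 = 0.016, sd2 = 0.0011, weight = 0.5))
  )
  rho <- switch(archetype, wide = 0.8, crop = 0.5, tropical = 0.6)
  population_spec(m, chl_car_rho = rho, n_samples = n_samples, seed = seed)
}

# quantile function of one marginal (used to map copula normals to traits)
marginal_quantile <- function(m, p) {
  x <- switch(m$kind,
    tnorm = {
      plo <- pnorm(m$lower, m$mean, m$sd); phi <- pnorm(m$upper, m$mean, m$sd)
      qnorm(plo + p * (phi - plo), m$mean, m$sd)
    },
    lnorm = exp(qnorm(p, m$meanlog, m$sdlog)),
    mix2 = {
      # mixture quantile by inversion on a fine grid (monotone interpolation)
      gr <- seq(m$lower, m$upper, length.out = 2048)
      cdf <- m$weight * pnorm(gr, m$mean1, m$sd1) +
        (1 - m$weight) * pnorm(gr, m$mean2, m$sd2)
      stats::approx(cdf, gr, xout = pmin(pmax(p, min(cdf)), max(cdf)),
                    ties = "ordered")$y
    },
    point = rep(m$value, length(p)),
    stop_leafoptics(sprintf("unknown marginal kind '%s'", m$kind), "leafoptics_spec")
  )
  pmin(pmax(x, m$lower), m$upper)
}

#' Draw a trait population
#'
#' Seeded draws from a [population_spec()]: independent uniform scores per
#' trait except for the CHL--CAR pair, which shares a Gaussian copula with the
#' spec's rank correlation; marginal quantile maps are applied afterwards and
#' truncation to the marginal bounds is applied last.
#'
#' @param spec a [population_spec()].
#' @return `data.frame` with columns `sample_id`, `N`, `CHL`, `CAR`, `ANT`,
#'   `EWT`, `LMA`.
#' @export
sample_trait_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_samples
  with_op_seed("sample_trait_population", spec$seed, {
    z_chl <- rnorm(n)
    z_car <- spec$chl_car_rho * z_chl + sqrt(1 - spec$chl_car_rho^2) * rnorm(n)
    p <- list(CHL = pnorm(z_chl), CAR = pnorm(z_car))
    out <- data.frame(sample_id = paste0("s", seq_len(n)))
    for (tr in TRAIT_NAMES) {
      pp <- if (tr %in% names(p)) p[[tr]] else runif(n)
      out[[tr]] <- marginal_quantile(spec$marginals[[tr]], pp)
    }
    if (any(out$N < 1))
      stop_leafoptics("population spec places mass below N = 1", "leafoptics_spec")
    out
  })
}

#' Forward-simulate a whole trait population
#'
#' @param pop trait `data.frame` as from [sample_trait_population()].
#' @param constants an [optical_constants()] object.
#' @param role role label for the resulting dataset.
#' @param alpha top-surface incidence half-angle in degrees.
#' @return a [spectral_dataset()] of simulated reflectance, row-aligned with
#'   `pop`.
#' @export
simulate_population <- function(pop, constants, role = "simulated", alpha = 40) {
  R <- forward_reflectance_matrix(as_traits_matrix(pop), constants, alpha)
  meta <- pop[intersect(META_COLS, names(pop))]
  if (!nrow(meta) || !"sample_id" %in% names(meta))
    meta <- data.frame(sample_id = paste0("s", seq_len(nrow(R))))
  spectral_dataset(R, constants$grid, meta, role = role)
}

#' Band-localized measurement-noise specification
#'
#' Emulates the canonical discrepancy pattern between measured and simulated
#' leaf spectra: noise concentrated in wavebands where reflectance is low,
#' with a small background level elsewhere. Default bands are the four
#' problem regions 400--500, 600--725, 1860--2025 and 2325--2450 nm.
#'
#' @param bands `data.frame` with columns `lambda_start`, `lambda_end` (nm).
#' @param band_sd additive Gaussian noise sd inside the bands.
#' @param band_jitter multiplicative jitter sd inside the bands
#'   (`x * (1 + rnorm(.) * band_jitter)`).
#' @param background_sd additive noise sd outside the bands.
#' @param seed integer seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(bands = data.frame(
                         lambda_start = c(400, 600, 1860, 2325),
                         lambda_end = c(500, 725, 2025, 2450)),
                       band_sd = 0.04, band_jitter = 0.3,
                       background_sd = 0.001, seed = 1) {
  if (band_sd < 0 || band_jitter < 0 || background_sd < 0)
    stop_leafoptics("noise standard deviations must be >= 0", "leafoptics_spec")
  structure(list(bands = bands, band_sd = band_sd, band_jitter = band_jitter,
                 background_sd = background_sd, seed = seed),
            class = "noise_spec")
}

in_bands <- function(wl, bands) {
  hit <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(bands)))
    hit <- hit | (wl >= bands$lambda_start[i] & wl <= bands$lambda_end[i])
  hit
}

#' Corrupt a simulated dataset into a pseudo-measured one
#'
#' Applies the band-localized noise of a [noise_spec()] to a simulated
#' dataset, clips to \[0, 1\], preserves metadata, and relabels the role to
#' `"measured"`.
#'
#' @param hsr_sim a [spectral_dataset()].
#' @param spec a [noise_spec()].
#' @return a [spectral_dataset()] of the same shape.
#' @export
corrupt_to_measured <- function(hsr_sim, spec = noise_spec()) {
  stopifnot(inherits(hsr_sim, "spectral_dataset"), inherits(spec, "noise_spec"))
  wl <- as.numeric(hsr_sim$grid)
  lo <- wl[1]; hi <- wl[length(wl)]
  if (any(spec$bands$lambda_start > hi | spec$bands$lambda_end < lo))
    stop_leafoptics("noise bands lie outside the wavelength grid", "leafoptics_spec")
  band <- in_bands(wl, spec$bands)
  V <- hsr_sim$values
  with_op_seed("corrupt_to_measured", spec$seed, {
    add_sd <- ifelse(band, spec$band_sd, spec$background_sd)
    noise_add <- matrix(rnorm(length(V)), nrow(V)) *
      matrix(add_sd, nrow(V), ncol(V), byrow = TRUE)
    jit <- matrix(1, nrow(V), ncol(V))
    if (spec$band_jitter > 0 && any(band))
      jit[, band] <- 1 + matrix(rnorm(nrow(V) * sum(band), 0, spec$band_jitter), nrow(V))
    out <- pmin(pmax(V * jit + noise_add, 0), 1)
    spectral_dataset(out, hsr_sim$grid, hsr_sim$meta, role = "measured")
  })
}

#' Multi-environment trial design
#'
#' @param n_environments,n_replicates nominal counts (`>= 1`). For unbalanced
#'   data the effective counts entering the entry-mean phenotypic variance are
#'   harmonic means of per-genotype counts, computed downstream.
#' @param n_genotypes number of genotypes (used by the simulator).
#' @param replicate_range,repeat_range integer ranges from which per-genotype
#'   replicate and per-replicate repeat counts are drawn when simulating
#'   unbalanced trials.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_environments = 2, n_replicates = 2, n_genotypes = 200,
                         replicate_range = c(1, 2), repeat_range = c(1, 3)) {
  if (n_environments < 1 || n_replicates < 1)
    stop_leafoptics("need at least one environment and one replicate",
                    "leafoptics_spec")
  structure(list(n_environments = n_environments, n_replicates = n_replicates,
                 n_genotypes = n_genotypes, replicate_range = replicate_range,
                 repeat_range = repeat_range),
            class = "trial_design")
}

#' Simulate a genotype trial and propagate it through the forward model
#'
#' Genotype, environment, genotype-by-environment and residual effects are
#' injected on one trait axis (default chlorophyll) at the stated variances;
#' every observation's trait vector is then propagated through
#' [forward_spectrum()]. The base trait vector defaults to a point mass (the
#' crop-archetype means) so that the injected effects are the only source of
#' genotypic variance; supply a non-degenerate `base_population` to emulate a
#' diverse panel instead. With `unbalanced = TRUE`, per-genotype replicate and
#' per-replicate repeat counts are drawn from the design's ranges.
#'
#' @param design a [trial_design()].
#' @param constants an [optical_constants()] object.
#' @param sigma2_g,sigma2_ge,sigma2_eps genotype, genotype-by-environment and
#'   residual variances on the trait axis (trait units squared).
#' @param trait_axis which trait carries the effects.
#' @param base_traits named trait vector for the degenerate base population.
#' @param base_population optional [population_spec()] drawn per genotype
#'   instead of `base_traits`.
#' @param env_effect_sd sd of the environment main effect.
#' @param unbalanced draw unbalanced replicate/repeat counts.
#' @param seed integer seed.
#' @return a [spectral_dataset()] with full `genotype_id`, `environment_id`,
#'   `replicate_id`, `repeat_id` metadata; the realized per-observation trait
#'   values are attached as attribute `"trait_values"`.
#' @export
simulate_population_trial <- function(design = trial_design(), constants,
                                      sigma2_g = 2, sigma2_ge = 1, sigma2_eps = 2,
                                      trait_axis = "CHL",
                                      base_traits = c(N = 1.5, CHL = 55, CAR = 12,
                                                      ANT = 1, EWT = 0.012, LMA = 0.005),
                                      base_population = NULL,
                                      env_effect_sd = 1, unbalanced = FALSE, seed = 1) {
  stopifnot(inherits(design, "trial_design"), inherits(constants, "optical_constants"))
  if (any(c(sigma2_g, sigma2_ge, sigma2_eps) < 0))
    stop_leafoptics("variance components must be >= 0", "leafoptics_spec")
  ng <- design$n_genotypes; ne <- design$n_environments
  with_op_seed("simulate_population_trial", seed, {
    base <- if (is.null(base_population)) {
      m <- matrix(rep(base_traits[TRAIT_NAMES], each = ng), nrow = ng)
      colnames(m) <- TRAIT_NAMES
      m
    } else {
      bp <- base_population
      bp$n_samples <- ng
      as_traits_matrix(sample_trait_population(bp))
    }
    g_eff <- rnorm(ng, 0, sqrt(sigma2_g))
    e_eff <- rnorm(ne, 0, env_effect_sd)
    ge_eff <- matrix(rnorm(ng * ne, 0, sqrt(sigma2_ge)), ng, ne)
    rows <- list(); k <- 0
    for (g in seq_len(ng)) for (e in seq_len(ne)) {
      nr <- if (unbalanced)
        sample(seq(design$replicate_range[1], design$replicate_range[2]), 1)
      else design$n_replicates
      for (r in seq_len(nr)) {
        nrep <- if (unbalanced)
          sample(seq(design$repeat_range[1], design$repeat_range[2]), 1)
        else 1L
        eps <- rnorm(1, 0, sqrt(sigma2_eps))   # plot-level residual
        for (q in seq_len(nrep)) {
          k <- k + 1
          rows[[k]] <- data.frame(genotype = g, environment = e, replicate = r,
                                  rep_q = q, eps = eps)
        }
      }
    }
    obs <- do.call(rbind, rows)
    traits <- base[obs$genotype, , drop = FALSE]
    shift <- g_eff[obs$genotype] + e_eff[obs$environment] +
      ge_eff[cbind(obs$genotype, obs$environment)] + obs$eps
    traits[, trait_axis] <- pmax(traits[, trait_axis] + shift, 0)
    R <- forward_reflectance_matrix(traits, constants)
    meta <- data.frame(
      sample_id = paste0("g", obs$genotype, "_e", obs$environment,
                         "_r", obs$replicate, "_q", obs$rep_q),
      genotype_id = paste0("g", obs$genotype),
      environment_id = paste0("e", obs$environment),
      replicate_id = paste0("r", obs$replicate),
      repeat_id = paste0("q", obs$rep_q))
    ds <- spectral_dataset(R, constants$grid, meta, role = "measured")
    attr(ds, "trait_values") <- traits
    ds
  })
}
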