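#' Inversion settings
#'
#' Controls the bounded optimization used to invert reflectance spectra. The
#' default bounds span the physiological ranges of the plate-model literature;
#' the default initial point is a fixed mid-physiological leaf so that cycles
#' are reproducible. Optimization is bounded quasi-Newton (L-BFGS-B) with
#' numerical gradients on unit-scaled traits; `multi_start` restarts (the
#' mid-bounds point plus seeded perturbations) guard the nearly flat
#' carotenoid/anthocyanin directions. A finite-difference step of 1e-7 on the
#' unit scale is required for those flat directions to converge.
#'
#' @param bounds 2 x 6 matrix (rows `lower`, `upper`; columns the six traits).
#' @param init a [leaf_traits()] starting point, inside the bounds.
#' @param merit_tolerance stop a restart sweep early once the merit falls
#'   below this value.
#' @param max_evaluations optimizer iteration cap per restart.
#' @param multi_start number of restarts.
#' @param seed integer seed for the restart perturbations.
#' @return object of class `inversion_settings`.
#' @export
inversion_settings <- function(bounds = default_trait_bounds(),
                               init = leaf_traits(),
                               merit_tolerance = 1e-10,
                               max_evaluations = 5000,
                               multi_start = 3,
                               seed = 1) {
  if (any(bounds["lower", ] >= bounds["upper", ]))
    stop_leafoptics("each lower bound must be below its upper bound",
                    "leafoptics_spec")
  if (any(unclass(init) < bounds["lower", ]) || any(unclass(init) > bounds["upper", ]))
    stop_leafoptics("initial traits must lie within the bounds", "leafoptics_spec")
  structure(list(bounds = bounds, init = init,
                 merit_tolerance = merit_tolerance,
                 max_evaluations = max_evaluations,
                 multi_start = multi_start, seed = seed),
            class = "inversion_settings")
}

#' @rdname inversion_settings
#' @export
default_trait_bounds <- function() {
  b <- rbind(lower = c(1, 0, 0, 0, 0, 0),
             upper = c(4, 120, 30, 40, 0.1, 0.05))
  colnames(b) <- TRAIT_NAMES
  b
}

#' Inversion merit function
#'
#' Root mean square error over wavelengths between the forward-simulated
#' reflectance of `traits` and a target reflectance spectrum. Transmittance is
#' deliberately ignored: inversion here is reflectance-only, the common
#' practice when transmittance is not measured.
#'
#' @param traits a [leaf_traits()] vector.
#' @param target_reflectance numeric vector on the constants' grid.
#' @param constants an [optical_constants()] object.
#' @return non-negative scalar.
#' @export
merit <- function(traits, target_reflectance, constants) {
  if (length(target_reflectance) != length(constants$grid))
    stop_leafoptics("target reflectance not on the constants' wavelength grid",
                    "leafoptics_dimension")
  sp <- forward_spectrum(traits, constants)
  sqrt(mean((sp$reflectance - target_reflectance)^2))
}

# unit-scale merit against a precomputed forward engine
merit_scaled <- function(u, target, pre, lower_traits, span) {
  r <- forward_reflectance_fast(lower_traits + u * span, pre)
  sqrt(mean((r - target)^2))
}

#' Invert a single reflectance spectrum
#'
#' Bounded minimization of [merit()] over the six traits; the best restart is
#' returned, and a restart sweep stops early once the merit falls below
#' `settings$merit_tolerance`. The returned merit never exceeds the merit at
#' the initial point.
#'
#' @param target_reflectance numeric vector in \[0, 1\] on the constants' grid.
#' @param constants an [optical_constants()] object.
#' @param settings an [inversion_settings()].
#' @return list with elements `traits` (a [leaf_traits()] vector) and `merit`.
#' @export
invert_spectrum <- function(target_reflectance, constants,
                            settings = inversion_settings()) {
  if (length(target_reflectance) != length(constants$grid))
    stop_leafoptics("target reflectance not on the constants' wavelength grid",
                    "leafoptics_dimension")
  if (any(target_reflectance < 0) || any(target_reflectance > 1))
    stop_leafoptics("target reflectance must lie in [0, 1]", "leafoptics_domain")
  pre <- forward_precompute(constants)
  lower <- settings$bounds["lower", ]
  span <- settings$bounds["upper", ] - lower
  starts <- inversion_starts(settings, lower, span)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], merit_scaled, target = target_reflectance, pre = pre,
            lower_traits = lower, span = span,
            lower = rep(0, 6), upper = rep(1, 6),
            method = "L-BFGS-B",
            control = list(maxit = settings$max_evaluations,
                           factr = 1, pgtol = 0, ndeps = rep(1e-7, 6))),
      error = function(e) {
        stop_leafoptics(sprintf(
          "optimizer failed (start %d: %s); start traits: %s", s, conditionMessage(e),
          paste(signif(lower + starts[s, ] * span, 4), collapse = ", ")),
          "leafoptics_optimizer")
      })
    if (!is.finite(fit$value))
      stop_leafoptics(sprintf("non-finite merit at traits: %s",
                              paste(signif(lower + fit$par * span, 4), collapse = ", ")),
                      "leafoptics_optimizer")
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value <= settings$merit_tolerance) break
  }
  tr <- unname(lower + best$par * span)
  list(traits = leaf_traits(tr[1], tr[2], tr[3], tr[4], tr[5], tr[6]),
       merit = best$value)
}

inversion_starts <- function(settings, lower, span) {
  u0 <- (unclass(settings$init)[TRAIT_NAMES] - lower) / span
  starts <- matrix(u0, nrow = 1)
  if (settings$multi_start > 1) {
    with_op_seed("invert_spectrum", settings$seed, {
      extra <- matrix(runif((settings$multi_start - 1) * 6, -0.2, 0.2),
                      ncol = 6, byrow = TRUE)
      starts <- rbind(starts,
                      sweep(extra, 2, as.numeric(u0), "+"))
    })
  }
  pmin(pmax(starts, 0.001), 0.999)
}

#' Invert every sample of a dataset
#'
#' Row-wise [invert_spectrum()]; order-preserving and deterministic given
#' `settings$seed`. Per-sample failures are collected (with their
#' `sample_id`) while the remaining rows continue.
#'
#' @param ds a [spectral_dataset()].
#' @param constants an [optical_constants()] object.
#' @param settings an [inversion_settings()].
#' @return object of class `prospect_inversion`: list with `traits`
#'   (data.frame `sample_id` + six traits), `merit` (per-sample residual
#'   RMSE), `failures` (data.frame of `sample_id`, `message`), `settings`,
#'   `grid`.
#' @export
invert_dataset <- function(ds, constants, settings = inversion_settings()) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$values)
  traits <- matrix(NA_real_, n, 6, dimnames = list(NULL, TRAIT_NAMES))
  merits <- rep(NA_real_, n)
  fails <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(invert_spectrum(ds$values[i, ], constants, settings),
                    leafoptics_error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        sample_id = ds$meta$sample_id[i], message = conditionMessage(res))
    } else {
      traits[i, ] <- unclass(res$traits)
      merits[i] <- res$merit
    }
  }
  structure(list(
    traits = cbind(data.frame(sample_id = ds$meta$sample_id), as.data.frame(traits)),
    merit = merits,
    failures = if (length(fails)) do.call(rbind, fails)
               else data.frame(sample_id = character(0), message = character(0)),
    settings = settings, grid = ds$grid),
    class = "prospect_inversion")
}

#' @export
print.prospect_inversion <- function(x, ...) {
  cat(sprintf("<prospect_inversion> %d samples (%d failed), merit RMSE median %.3g\n",
              nrow(x$traits), nrow(x$failures), median(x$merit, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.prospect_inversion <- function(object, ...) {
  m <- as.matrix(object$traits[TRAIT_NAMES])
  rownames(m) <- object$traits$sample_id
  m
}

#' Regeneration cycle
#'
#' The measured-to-resimulated workflow: invert the measured dataset
#' (`p_inv`), forward-simulate the estimated traits (`hsr_sim`), re-invert the
#' simulation (`p_re`) and forward-simulate again (`hsr_re`) — exactly these
#' four arrows, with no smoothing or filtering in between. The per-wavelength
#' error statistics between any two stages come from
#' [wavelength_error_profile()].
#'
#' @param hsr_meas a [spectral_dataset()] of measured reflectance.
#' @param constants an [optical_constants()] object.
#' @param settings an [inversion_settings()].
#' @return object of class `regeneration_cycle`: list with `p_inv`, `hsr_sim`,
#'   `p_re`, `hsr_re`, `merit_inv`, `merit_re`; all row-aligned with
#'   `hsr_meas`.
#' @export
regeneration_cycle <- function(hsr_meas, constants,
                               settings = inversion_settings()) {
  inv <- invert_dataset(hsr_meas, constants, settings)
  if (nrow(inv$failures))
    stop_leafoptics(sprintf("inversion failed for %d sample(s), first: %s",
                            nrow(inv$failures), inv$failures$sample_id[1]),
                    "leafoptics_optimizer")
  hsr_sim <- simulate_population(inv$traits, constants, role = "simulated")
  hsr_sim$meta <- hsr_meas$meta
  re <- invert_dataset(hsr_sim, constants, settings)
  if (nrow(re$failures))
    stop_leafoptics("re-inversion failed", "leafoptics_optimizer")
  hsr_re <- simulate_population(re$traits, constants, role = "resimulated")
  hsr_re$meta <- hsr_meas$meta
  structure(list(p_inv = inv$traits, hsr_sim = hsr_sim,
                 p_re = re$traits, hsr_re = hsr_re,
                 merit_inv = inv$merit, merit_re = re$merit,
                 settings = settings),
            class = "regeneration_cycle")
}

#' @export
print.regeneration_cycle <- function(x, ...) {
  cat(sprintf("<regeneration_cycle> %d samples\n", nrow(x$p_inv)))
  cat(sprintf("  inversion merit RMSE:    median %.3g, max %.3g\n",
              median(x$merit_inv), max(x$merit_inv)))
  cat(sprintf("  re-inversion merit RMSE: median %.3g, max %.3g\n",
              median(x$merit_re), max(x$merit_re)))
  invisible(x)
}

#' @export
summary.regeneration_cycle <- function(object, hsr_meas = NULL, ...) {
  prof <- wavelength_error_profile(object$hsr_sim, object$hsr_re)
  out <- list(sim_re = prof)
  if (!is.null(hsr_meas)) out$meas_sim <- wavelength_error_profile(hsr_meas, object$hsr_sim)
  out
}

#' Serialize a regeneration cycle
#'
#' Writes the four cycle components as CSV tables sharing a run-id prefix
#' (`<prefix>_p_inv.csv`, `<prefix>_hsr_sim.csv`, `<prefix>_p_re.csv`,
#' `<prefix>_hsr_re.csv`) plus a YAML manifest with the resolved settings.
#'
#' @param cycle a [regeneration_cycle()] result.
#' @param dir output directory.
#' @param prefix run-id prefix.
#' @return invisibly, the manifest path.
#' @export
write_cycle <- function(cycle, dir, prefix = "cycle") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(nm) file.path(dir, paste0(prefix, "_", nm))
  write_traits_table(cbind(cycle$p_inv, merit = signif(cycle$merit_inv, 9)), p("p_inv.csv"))
  write_traits_table(cbind(cycle$p_re, merit = signif(cycle$merit_re, 9)), p("p_re.csv"))
  write_spectra_table(cycle$hsr_sim, p("hsr_sim.csv"))
  write_spectra_table(cycle$hsr_re, p("hsr_re.csv"))
  manifest <- list(
    run = prefix,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_samples = nrow(cycle$p_inv),
    settings = list(
      bounds_lower = as.numeric(cycle$settings$bounds["lower", ]),
      bounds_upper = as.numeric(cycle$settings$bounds["upper", ]),
      init = as.numeric(unclass(cycle$settings$init)),
      merit_tolerance = cycle$settings$merit_tolerance,
      max_evaluations = cycle$settings$max_evaluations,
      multi_start = cycle$settings$multi_start,
      seed = cycle$settings$seed))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(p("manifest.yaml"))
}
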