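#' Variance components of a multi-environment trial
#'
#' Restricted-maximum-likelihood fit of the all-random model
#' `value = mu + genotype + environment + genotype:environment + residual`
#' (the standard entry-mean heritability model). Technical repeats within a
#' replicate are averaged to one value per plot before fitting, since the
#' model has no repeat term. Component estimates are truncated at zero by the
#' REML estimator itself; with a single environment the interaction is not
#' estimable and is fixed at zero with a message. The entry-mean phenotypic
#' variance is
#' \deqn{\sigma^2_p = \sigma^2_g + \sigma^2_{ge}/n_e +
#'       \sigma^2_\epsilon/(n_e n_r),}
#' where for unbalanced data `n_e` and `n_r` are harmonic means of the
#' per-genotype environment and replicate counts.
#'
#' @param values numeric vector, one value per observation.
#' @param genotype,environment,replicate,rep_id observation labels; `rep_id`
#'   (technical repeat) is optional and triggers pre-averaging.
#' @return object of class `variance_components`: list with `sigma2_g`,
#'   `sigma2_ge`, `sigma2_eps`, `sigma2_p`, `n_e_eff`, `n_r_eff`,
#'   `single_environment`.
#' @export
variance_components <- function(values, genotype, environment,
                                replicate = NULL, rep_id = NULL) {
  d <- data.frame(y = as.numeric(values),
                  genotype = factor(genotype),
                  environment = factor(environment))
  d$replicate <- if (is.null(replicate)) factor(1) else factor(replicate)
  if (nlevels(d$genotype) < 2)
    stop_leafoptics("variance components need at least 2 genotypes",
                    "leafoptics_degenerate_design")
  if (!is.null(rep_id)) {   # average technical repeats to one value per plot
    key <- interaction(d$genotype, d$environment, d$replicate, drop = TRUE)
    agg <- tapply(d$y, key, mean)
    first <- !duplicated(key)
    d <- d[first, ]
    d$y <- as.numeric(agg[as.character(key[first])])
  }
  ne_g <- tapply(d$environment, d$genotype, function(e) length(unique(e)))
  n_e_eff <- harmonic_mean(ne_g)
  plot_key <- interaction(d$genotype, d$environment, drop = TRUE)
  nr_ge <- tapply(d$replicate, plot_key, length)
  n_r_eff <- harmonic_mean(nr_ge)
  single_env <- nlevels(d$environment) < 2
  # noiseless limit: every observation of a genotype identical. REML is
  # degenerate here, but the decomposition is exact: all variance is genotypic.
  within_var <- tapply(d$y, d$genotype, var)
  if (all(is.na(within_var) | within_var == 0)) {
    g_means <- tapply(d$y, d$genotype, mean)
    return(structure(list(sigma2_g = var(as.numeric(g_means)), sigma2_ge = 0,
                          sigma2_eps = 0,
                          sigma2_p = var(as.numeric(g_means)),
                          n_e_eff = n_e_eff, n_r_eff = n_r_eff,
                          single_environment = single_env),
                     class = "variance_components"))
  }
  if (single_env) {
    message("single environment: genotype-by-environment variance fixed at 0")
    fml <- y ~ (1 | genotype)
  } else {
    fml <- y ~ (1 | genotype) + (1 | environment) + (1 | genotype:environment)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  sigma2_g <- unname(v["genotype"])
  sigma2_ge <- if (single_env) 0 else unname(v["genotype:environment"])
  sigma2_eps <- unname(v["Residual"])
  structure(list(sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
                 sigma2_eps = sigma2_eps,
                 sigma2_p = sigma2_g + sigma2_ge / n_e_eff +
                   sigma2_eps / (n_e_eff * n_r_eff),
                 n_e_eff = n_e_eff, n_r_eff = n_r_eff,
                 single_environment = single_env),
            class = "variance_components")
}

harmonic_mean <- function(x) length(x) / sum(1 / as.numeric(x))

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> g %.4g | gxe %.4g | residual %.4g | entry-mean p %.4g (n_e %.3g, n_r %.3g)\n",
              x$sigma2_g, x$sigma2_ge, x$sigma2_eps, x$sigma2_p,
              x$n_e_eff, x$n_r_eff))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \frac{\sigma^2_g}
#'   {\sigma^2_g + \sigma^2_{ge}/n_e + \sigma^2_\epsilon/(n_e n_r)}.}
#' Returns 0 when the genotypic variance is zero with positive phenotypic
#' variance, and `NA` (undefined) when the phenotypic variance is zero.
#'
#' @param vc a [variance_components()] object.
#' @param n_e,n_r effective environment and replicate counts; default to the
#'   ones recorded in `vc`.
#' @return `H^2` in \[0, 1\], or `NA`.
#' @export
broad_sense_h2 <- function(vc, n_e = vc$n_e_eff, n_r = vc$n_r_eff) {
  stopifnot(inherits(vc, "variance_components"))
  sigma2_p <- vc$sigma2_g + vc$sigma2_ge / n_e + vc$sigma2_eps / (n_e * n_r)
  if (sigma2_p == 0) return(NA_real_)
  vc$sigma2_g / sigma2_p
}

#' Per-wavelength broad-sense heritability of reflectance
#'
#' Treats the reflectance at each wavelength as an individual trait and
#' applies [variance_components()] and [broad_sense_h2()] independently per
#' wavelength.
#'
#' @param ds a [spectral_dataset()] whose metadata includes `genotype_id` and
#'   `environment_id` (plus optional `replicate_id`, `repeat_id`).
#' @return object of class `h2_spectrum`: data.frame with columns
#'   `wavelength_nm`, `sigma2_g`, `sigma2_ge`, `sigma2_eps`, `sigma2_p`, `h2`,
#'   `n_e_eff`, `n_r_eff`.
#' @export
h2_spectrum <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  need <- c("genotype_id", "environment_id")
  miss <- setdiff(need, names(ds$meta))
  if (length(miss))
    stop_leafoptics(paste("missing metadata column(s):", paste(miss, collapse = ", ")),
                    "leafoptics_schema")
  repl <- if ("replicate_id" %in% names(ds$meta)) ds$meta$replicate_id else NULL
  repq <- if ("repeat_id" %in% names(ds$meta)) ds$meta$repeat_id else NULL
  rows <- lapply(seq_along(ds$grid), function(j) {
    vc <- suppressMessages(
      variance_components(ds$values[, j], ds$meta$genotype_id,
                          ds$meta$environment_id, repl, repq))
    data.frame(wavelength_nm = as.numeric(ds$grid)[j],
               sigma2_g = vc$sigma2_g, sigma2_ge = vc$sigma2_ge,
               sigma2_eps = vc$sigma2_eps, sigma2_p = vc$sigma2_p,
               h2 = broad_sense_h2(vc),
               n_e_eff = vc$n_e_eff, n_r_eff = vc$n_r_eff)
  })
  out <- suppressMessages(do.call(rbind, rows))
  class(out) <- c("h2_spectrum", "data.frame")
  out
}

#' @export
print.h2_spectrum <- function(x, ...) {
  cat(sprintf("<h2_spectrum> %d wavelengths, H2 in [%.3f, %.3f]\n",
              nrow(x), min(x$h2, na.rm = TRUE), max(x$h2, na.rm = TRUE)))
  invisible(x)
}

#' @rdname h2_spectrum
#' @param x an `h2_spectrum`.
#' @param path output CSV path.
#' @export
write_h2_spectrum <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a heritability spectrum
#'
#' @param x an [h2_spectrum()] result.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.h2_spectrum <- function(x, ...) {
  plot(x$wavelength_nm, x$h2, type = "l", ylim = c(0, 1),
       xlab = "wavelength (nm)", ylab = expression(H^2), ...)
  invisible(x)
}
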