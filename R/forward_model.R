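#' Average transmissivity of a plane dielectric interface
#'
#' Mean transmittance of unpolarized light through a plane interface between
#' air and a dielectric of refractive index `n`, averaged over incidence angles
#' from 0 to `alpha` with the usual projected-solid-angle weighting (the
#' `tav(alpha, n)` function of the plate-model lineage, closed form after
#' Stern and Allen). `alpha = 90` gives the hemispherical average used for the
#' interior layer interfaces; the conventional top-surface value is
#' `alpha = 40`.
#'
#' @param alpha incidence half-angle in degrees, in (0, 90].
#' @param n refractive index (scalar or vector), `>= 1`.
#' @return transmissivity fraction(s) in (0, 1]; exactly 1 when `n = 1`.
#' @export
average_transmissivity <- function(alpha, n) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 90)
    stop_leafoptics("alpha must lie in (0, 90] degrees", "leafoptics_domain")
  if (any(!is.finite(n)) || any(n < 1))
    stop_leafoptics("refractive index must be >= 1", "leafoptics_domain")
  out <- numeric(length(n))
  one <- n == 1
  out[one] <- 1
  if (any(!one)) {
    nn <- n[!one]
    theta <- alpha * pi / 180
    r2 <- nn^2
    rp <- r2 + 1
    rm <- r2 - 1
    a <- (nn + 1)^2 / 2
    k <- -(r2 - 1)^2 / 4
    ds <- sin(theta)
    k2 <- k^2
    rm2 <- rm^2
    b2 <- ds^2 - rp / 2
    b1 <- sqrt(pmax(b2^2 + k, 0))   # vanishes analytically at alpha = 90
    b <- b1 - b2
    ts <- (k2 / (6 * b^3) + k / b - b / 2) - (k2 / (6 * a^3) + k / a - a / 2)
    tp1 <- -2 * r2 * (b - a) / rp^2
    tp2 <- -2 * r2 * rp * log(b / a) / rm2
    tp3 <- r2 * (1 / b - 1 / a) / 2
    tp4 <- 16 * r2^2 * (r2^2 + 1) * log((2 * rp * b - rm2) / (2 * rp * a - rm2)) / (rp^3 * rm2)
    tp5 <- 16 * r2^3 * (1 / (2 * rp * b - rm2) - 1 / (2 * rp * a - rm2)) / rp^3
    out[!one] <- (ts + tp1 + tp2 + tp3 + tp4 + tp5) / (2 * ds^2)
  }
  out
}

# exponential integral E1 for x > 0: power series below 1, modified-Lentz
# continued fraction above; both branches uniformly accurate to ~1e-14 so no
# external special-function dependency is required
expint_e1 <- function(x) {
  out <- numeric(length(x))
  out[x == 0] <- Inf
  small <- x > 0 & x < 1
  if (any(small)) {
    xs <- x[small]
    s <- numeric(length(xs))
    term <- rep(1, length(xs))
    for (k in 1:30) {           # 30 terms: |term| < 1e-32/k! at x < 1
      term <- term * (-xs) / k
      s <- s - term / k
    }
    out[small] <- -0.577215664901532861 - log(xs) + s
  }
  big <- x >= 1
  if (any(big)) {
    xb <- x[big]
    b <- xb + 1
    c <- rep(1e308, length(xb))
    d <- 1 / b
    h <- d
    for (i in 1:60) {
      an <- -i * i
      b <- b + 2
      d <- 1 / (an * d + b)
      c <- b + an / c
      h <- h * c * d
    }
    out[big] <- h * exp(-xb)
  }
  out
}

#' Transmission of an elementary absorbing layer
#'
#' Transmission of isotropic diffuse flux through a homogeneous absorbing
#' layer of dimensionless absorption `k`:
#' \deqn{\tau(k) = (1-k)e^{-k} + k^2 E_1(k),}
#' with \eqn{E_1} the exponential integral. Equals 1 at `k = 0` and decreases
#' strictly with `k`.
#'
#' @param k dimensionless absorption, `>= 0` (scalar or vector).
#' @return transmission fraction(s) in (0, 1].
#' @export
layer_transmission <- function(k) {
  if (any(!is.finite(k)) || any(k < 0))
    stop_leafoptics("absorption k must be finite and >= 0", "leafoptics_domain")
  out <- rep(1, length(k))
  pos <- k > 0
  out[pos] <- (1 - k[pos]) * exp(-k[pos]) + k[pos]^2 * expint_e1(k[pos])
  out
}

#' Per-layer absorption from traits and optical constants
#'
#' \deqn{k(\lambda) = \frac{1}{N}\sum_c C_c K_c(\lambda)} over the five
#' constituents; the structure parameter `N` spreads the total absorber load
#' over the layers.
#'
#' @param traits a [leaf_traits()] vector.
#' @param constants an [optical_constants()] object.
#' @return numeric vector of per-wavelength `k` values.
#' @export
total_absorption <- function(traits, constants) {
  tr <- unclass(traits)
  traits <- leaf_traits(unname(tr["N"]), unname(tr["CHL"]), unname(tr["CAR"]),
                        unname(tr["ANT"]), unname(tr["EWT"]), unname(tr["LMA"]))
  as.vector(constants$specific_absorption %*% unclass(traits)[CONSTITUENTS]) /
    unname(traits["N"])
}

#' Reflectance and transmittance of a single plate
#'
#' One absorbing plate bounded by two dielectric interfaces. Light enters the
#' top surface through the conical average transmissivity at half-angle
#' `alpha`; the interior variant (both sides hemispherical, `alpha = 90`)
#' describes the layers below the first. Interior exit transmissivity is
#' `tav(90, n) / n^2` by reciprocity.
#'
#' @param tau elementary-layer transmission in \[0, 1\] (scalar or vector).
#' @param n refractive index (scalar or vector matching `tau`).
#' @param alpha top-surface incidence half-angle in degrees.
#' @return list with components `reflectance`, `transmittance` for the
#'   `alpha`-incidence plate and `reflectance_interior`,
#'   `transmittance_interior` for the hemispherically illuminated plate.
#' @export
plate_single_layer <- function(tau, n, alpha = 40) {
  if (any(tau < 0) || any(tau > 1))
    stop_leafoptics("tau must lie in [0, 1]", "leafoptics_domain")
  talf <- average_transmissivity(alpha, n)
  t12 <- average_transmissivity(90, n)
  t21 <- t12 / n^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * tau^2
  # r21 < 1 strictly for n > 1, so denom > 0; assert rather than guard
  stopifnot(all(denom > 0))
  Ta <- talf * tau * t21 / denom
  Ra <- (1 - talf) + r21 * tau * Ta
  Ti <- t12 * tau * t21 / denom
  Ri <- (1 - t12) + r21 * tau * Ti
  list(reflectance = Ra, transmittance = Ta,
       reflectance_interior = Ri, transmittance_interior = Ti)
}

#' Stack identical layers by the Stokes solution
#'
#' Reflectance and transmittance of `n_layers` identical layers of individual
#' reflectance `r` and transmittance `t`, for real-valued `n_layers >= 1`:
#' with \eqn{D = \sqrt{(1+r+t)(1+r-t)(1-r+t)(1-r-t)}},
#' \eqn{a = (1+r^2-t^2+D)/2r}, \eqn{b = (1-r^2+t^2+D)/2t} and `m = n_layers`,
#' \eqn{T = b^m (a^2-1)/(a^2 b^{2m} - 1)} and
#' \eqn{R = a (b^{2m}-1)/(a^2 b^{2m} - 1)}. The conservative branch
#' \code{r + t >= 1} and the limits \code{t = 0} / \code{r = 0} are handled
#' explicitly.
#'
#' @param r,t per-layer reflectance and transmittance, \code{r + t <= 1}
#'   (vectors allowed).
#' @param n_layers real number of layers, `>= 0`. The value 0 is the identity
#'   stack (R = 0, T = 1); fractional values below 1 arise when the Stokes
#'   solution covers the `N - 1` interior plates of a leaf with `N < 2`.
#' @return list with components `reflectance`, `transmittance`.
#' @export
stokes_stack <- function(r, t, n_layers) {
  if (any(r < 0) || any(t < 0) || any(r + t > 1 + 1e-12))
    stop_leafoptics("non-physical layer: need r, t >= 0 and r + t <= 1",
                    "leafoptics_nonphysical")
  if (n_layers < 0)
    stop_leafoptics("n_layers must be >= 0", "leafoptics_domain")
  m <- n_layers
  R <- numeric(length(r))
  T <- numeric(length(r))
  cons <- (r + t) >= 1          # conservative (no absorption) limit
  dark <- t == 0                # opaque layers
  flat <- r == 0 & !dark        # no per-layer reflection: pure attenuation
  gen <- !(cons | dark | flat)
  if (any(gen)) {
    rg <- r[gen]; tg <- t[gen]
    D <- sqrt(pmax((1 + rg + tg) * (1 + rg - tg) * (1 - rg + tg) * (1 - rg - tg), 0))
    a <- (1 + rg^2 - tg^2 + D) / (2 * rg)
    b <- (1 - rg^2 + tg^2 + D) / (2 * tg)
    bm <- exp(m * log(b))                # b^m for real m
    b2m <- bm^2
    den <- a^2 * b2m - 1
    T[gen] <- bm * (a^2 - 1) / den
    R[gen] <- a * (b2m - 1) / den
  }
  if (any(cons & !dark)) {
    tc <- t[cons & !dark]
    Tc <- tc / (tc + (1 - tc) * m)       # conservative Stokes limit; 1 at m = 0
    T[cons & !dark] <- Tc
    R[cons & !dark] <- 1 - Tc
  }
  if (any(flat)) {
    T[flat] <- t[flat]^m
    R[flat] <- 0
  }
  if (any(dark)) {
    T[dark] <- if (m == 0) 1 else 0
    R[dark] <- if (m == 0) 0 else r[dark]
  }
  list(reflectance = R, transmittance = T)
}

#' Forward simulation of a leaf spectrum
#'
#' Composes [total_absorption()], [layer_transmission()],
#' [plate_single_layer()] and [stokes_stack()] per wavelength: the first plate
#' (incidence half-angle `alpha`) is kept separate, the Stokes solution covers
#' the remaining `N - 1` interior plates, and the two systems are coupled by
#' the standard two-stream adding formulas using the interior-side reflectance
#' of the first plate.
#'
#' @param traits a [leaf_traits()] vector.
#' @param constants an [optical_constants()] object.
#' @param alpha top-surface incidence half-angle in degrees (default 40, the
#'   plate-model convention).
#' @return object of class `leaf_spectra`: list with `grid`, `reflectance`,
#'   `transmittance`.
#' @examples
#' cst <- synthetic_optical_constants(constants_spec(desk_grid()))
#' sp <- forward_spectrum(leaf_traits(N = 1.8, CHL = 40), cst)
#' range(sp$reflectance + sp$transmittance)  # never exceeds 1
#' @export
forward_spectrum <- function(traits, constants, alpha = 40) {
  k <- total_absorption(traits, constants)
  tau <- layer_transmission(k)
  n <- constants$refractive_index
  p <- plate_single_layer(tau, n, alpha)
  N <- unname(traits["N"])
  if (N > 1) {
    sub <- stokes_stack(p$reflectance_interior, p$transmittance_interior, N - 1)
    den <- 1 - sub$reflectance * p$reflectance_interior
    R <- p$reflectance + p$transmittance * sub$reflectance * p$transmittance_interior / den
    T <- p$transmittance * sub$transmittance / den
  } else {
    R <- p$reflectance
    T <- p$transmittance
  }
  structure(list(grid = constants$grid, reflectance = R, transmittance = T),
            class = "leaf_spectra")
}

#' @export
print.leaf_spectra <- function(x, ...) {
  cat(sprintf("<leaf_spectra> %d wavelengths, R in [%.3f, %.3f], T in [%.3f, %.3f]\n",
              length(x$grid), min(x$reflectance), max(x$reflectance),
              min(x$transmittance), max(x$transmittance)))
  invisible(x)
}

# internal fast path: forward reflectance for many trait rows sharing constants.
# tav values depend only on (alpha, n) and are cached per constants object.
forward_reflectance_matrix <- function(traits_mat, constants, alpha = 40) {
  pre <- forward_precompute(constants, alpha)
  t(apply(traits_mat, 1, function(tr) forward_reflectance_fast(tr, pre)))
}

forward_precompute <- function(constants, alpha = 40) {
  n <- constants$refractive_index
  talf <- average_transmissivity(alpha, n)
  t12 <- average_transmissivity(90, n)
  t21 <- t12 / n^2
  list(K = constants$specific_absorption, talf = talf, t12 = t12,
       t21 = t21, r21 = 1 - t21, grid = constants$grid)
}

forward_reflectance_fast <- function(tr, pre) {
  N <- tr[[1]]
  k <- as.vector(pre$K %*% tr[2:6]) / N
  tau <- layer_transmission(k)
  denom <- 1 - pre$r21^2 * tau^2
  Ta <- pre$talf * tau * pre$t21 / denom
  Ra <- (1 - pre$talf) + pre$r21 * tau * Ta
  Ti <- pre$t12 * tau * pre$t21 / denom
  Ri <- (1 - pre$t12) + pre$r21 * tau * Ti
  if (N <= 1) return(Ra)
  st <- stokes_stack(Ri, Ti, N - 1)
  den <- 1 - st$reflectance * Ri
  Ra + Ta * st$reflectance * Ti / den
}
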