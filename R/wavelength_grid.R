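#' Wavelength grid
#'
#' An ordered set of wavelengths (nm) shared by spectra, optical constants and
#' all per-wavelength statistics. The default grid is the full 1-nm range
#' 400--2450 nm (2051 points); a coarser 51-point desk grid with identical span
#' is available via [desk_grid()] and is what the synthetic-data generator and
#' the test suite use.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing,
#'   all positive. Defaults to `400:2450`.
#' @return an object of class `wavelength_grid` (a validated numeric vector).
#' @examples
#' length(wavelength_grid())   # 2051
#' desk_grid()                 # 51 points, 400 to 2450 nm
#' @export
wavelength_grid <- function(wavelengths = 400:2450) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) == 0L)
    stop_leafoptics("wavelength grid is empty", "leafoptics_empty_input")
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0))
    stop_leafoptics("wavelengths must be finite and positive", "leafoptics_domain")
  if (any(diff(wavelengths) <= 0))
    stop_leafoptics("wavelengths must be strictly increasing", "leafoptics_domain")
  structure(wavelengths, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param n number of points for the desk grid.
#' @export
desk_grid <- function(n = 51) {
  wavelength_grid(seq(400, 2450, length.out = n))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d points, %g to %g nm\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) < 1e-9)
}

check_same_grid <- function(a, b, what = "datasets") {
  if (!same_grid(a, b))
    stop_leafoptics(sprintf("wavelength grids of the two %s differ", what),
                    "leafoptics_dimension")
  invisible(TRUE)
}
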