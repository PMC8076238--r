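#' Fit the scattering power law to a reduced-scattering spectrum
#'
#' Nonlinear least squares of `mu_s'(lambda) = a * lambda^-b` (lambda in nm,
#' mu_s' in mm^-1) over the in-band points, initialised from the log-log
#' linear regression (which is already exact for noiseless power-law data)
#' and refined with Levenberg-Marquardt.  The exponent `b` tracks average
#' scatterer size, the magnitude `a` scatterer number density.
#'
#' @param x a scattering [spectrum()] with positive in-band values.
#' @param bd a [band()].
#' @return A list of class `power_law_fit`: `a`, `b`, `fit_rms` (mm^-1),
#'   `n_points`.
#' @export
fit_power_law <- function(x, bd) {
  stopifnot(inherits(x, "spectrum"), inherits(bd, "band"))
  sel <- x$wavelength >= bd$range[1] & x$wavelength <= bd$range[2] &
    is.finite(x$value)
  wl <- x$wavelength[sel]
  y <- x$value[sel]
  if (length(y) < 5)
    stop("insufficient data: need >= 5 finite in-band points, have ",
         length(y))
  if (any(y <= 0))
    stop("nonpositive mu_s' in band at wavelength(s) ",
         paste(wl[y <= 0], collapse = ", "), " nm")
  ols <- lm(log(y) ~ log(wl))
  a0 <- exp(coef(ols)[[1]])
  b0 <- -coef(ols)[[2]]
  a <- a0; b <- b0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * wl^(-b), start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    a <- coef(fit)[["a"]]
    b <- coef(fit)[["b"]]
  }
  r <- y - a * wl^(-b)
  structure(list(a = a, b = b, fit_rms = sqrt(mean(r^2)),
                 n_points = length(y)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law mu_s' = a * lambda^-b: a = %.6g, b = %.6g (rms %.3g mm^-1, n = %d)\n",
              x$a, x$b, x$fit_rms, x$n_points))
  invisible(x)
}
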