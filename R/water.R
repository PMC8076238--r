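#' Analysis bands at the water absorption overtones
#'
#' The second-overtone band spans 940--1000 nm around the 970 nm absorption
#' peak; the first-overtone band spans 1230--1380 nm on the shoulder of the
#' ~1450 nm peak (skin reflectance beyond 1380 nm is too attenuated to use).
#' The `peak` element is the reference wavelength about which the bound-water
#' perturbation remaps the spectrum.
#'
#' @param name `"second_overtone"` (or `"second"`) or `"first_overtone"`
#'   (or `"first"`).
#' @return A list with `name`, `range` (nm) and `peak` (nm), class `band`.
#' @export
band <- function(name = c("second_overtone", "first_overtone",
                          "second", "first")) {
  name <- match.arg(name)
  name <- if (startsWith(name, "second")) "second_overtone" else "first_overtone"
  if (name == "second_overtone")
    structure(list(name = name, range = c(940, 1000), peak = 970),
              class = "band")
  else
    structure(list(name = name, range = c(1230, 1380), peak = 1380),
              class = "band")
}

#' Bundled pure-water absorption reference
#'
#' Absorption coefficient of pure liquid water at 25 C on a 1 nm grid from
#' 900 to 1500 nm, in mm^-1.  This is a synthetic spline reconstruction
#' through landmark values of published NIR water tabulations (see the file
#' header of `extdata/water_absorption_synthetic.tsv`), adequate for the
#' shape-based analyses here; it is not a measured dataset.
#'
#' @return An absorption [spectrum()].
#' @export
water_reference <- function() {
  path <- system.file("extdata", "water_absorption_synthetic.tsv",
                      package = "skindrs", mustWork = TRUE)
  ref <- read_spectrum(path)
  stopifnot(all(ref$value > 0))
  ref
}

#' Bound-water perturbation parameters
#'
#' Phenomenological model of how hydrogen bonding to macromolecules deforms
#' the water absorption bands: a signed shift of the band about its peak
#' (red shift at the second overtone, blue shift at the first) and a
#' broadening factor, mixed in with weight `f_b` (the bound fraction).
#'
#' @param shift_nm signed wavelength shift about the band peak, nm.
#' @param width_factor peak broadening scale, >= 1.
#' @param f_b bound-water mixing fraction in `[0, 1]`.
#' @return A list of class `bound_water_perturbation`.
#' @export
bound_water_perturbation <- function(shift_nm = 0, width_factor = 1,
                                     f_b = 0) {
  if (width_factor < 1) stop("width_factor must be >= 1")
  if (f_b < 0 || f_b > 1) stop("f_b must lie in [0, 1]")
  structure(list(shift_nm = shift_nm, width_factor = width_factor, f_b = f_b),
            class = "bound_water_perturbation")
}

#' Apply the bound-water perturbation to the water reference
#'
#' The bound component is the reference resampled at
#' `lambda' = peak + (lambda - peak - shift) / width`, i.e. shifted by
#' `shift_nm` and broadened by `width_factor` about the band peak; the output
#' is `(1 - f_b) * ref + f_b * bound`.  With `f_b = 0`, or with zero shift
#' and unit width, the reference is returned unchanged.  Remapped wavelengths
#' outside the reference domain are clamped to the edge values.
#'
#' @param ref the water reference [spectrum()].
#' @param pert a [bound_water_perturbation()].
#' @param bd a [band()].
#' @param wavelengths evaluation grid, nm; defaults to the reference grid
#'   restricted to the band.
#' @return An absorption [spectrum()].
#' @export
apply_bound_water_model <- function(ref, pert, bd, wavelengths = NULL) {
  stopifnot(inherits(ref, "spectrum"), inherits(pert, "bound_water_perturbation"),
            inherits(bd, "band"))
  if (is.null(wavelengths))
    wavelengths <- ref$wavelength[ref$wavelength >= bd$range[1] &
                                    ref$wavelength <= bd$range[2]]
  base <- approx(ref$wavelength, ref$value, xout = wavelengths, rule = 2)$y
  lam_b <- bd$peak + (wavelengths - bd$peak - pert$shift_nm) / pert$width_factor
  bound <- approx(ref$wavelength, ref$value, xout = lam_b, rule = 2)$y
  spectrum(wavelengths, (1 - pert$f_b) * base + pert$f_b * bound,
           kind = "absorption")
}

#' Pure-water fitting residual of an absorption spectrum
#'
#' Least-squares fit of a scaled pure-water spectrum `c * mu_a_water` to the
#' in-band absorption spectrum, amplitude constrained to `c >= 0`.  The
#' residual statistic is `rho = 100 * sum(residual^2) / N` -- the mean
#' squared deviation per spectral point, times 100 -- which grows as the
#' measured band shape departs from free water (the bound-water signature).
#' An optional free constant baseline can be co-fitted; the headline
#' statistic uses the amplitude-only model.
#'
#' @param x an absorption [spectrum()] covering the band with >= 10 points.
#' @param bd a [band()].
#' @param ref the water reference [spectrum()], linearly resampled onto `x`'s
#'   grid.
#' @param baseline fit an additive constant as well (default off).
#' @return A list of class `water_fit_result`: `amplitude`, `baseline`,
#'   `rho`, `n_points`, `band`.
#' @export
fit_pure_water <- function(x, bd, ref = water_reference(), baseline = FALSE) {
  stopifnot(inherits(x, "spectrum"), inherits(bd, "band"))
  sel <- x$wavelength >= bd$range[1] & x$wavelength <= bd$range[2] &
    is.finite(x$value)
  if (sum(sel) < 10)
    stop("insufficient data: need >= 10 finite in-band points, have ",
         sum(sel))
  wl <- x$wavelength[sel]
  y <- x$value[sel]
  w <- approx(ref$wavelength, ref$value, xout = wl)$y
  if (anyNA(w)) stop("band not covered by the water reference")
  if (baseline) {
    fit <- lm(y ~ w)
    cc <- max(0, coef(fit)[["w"]])
    b0 <- if (coef(fit)[["w"]] >= 0) coef(fit)[["(Intercept)"]] else mean(y)
  } else {
    cc <- max(0, sum(y * w) / sum(w * w))
    b0 <- 0
  }
  r <- y - cc * w - b0
  structure(list(amplitude = cc, baseline = b0,
                 rho = 100 * sum(r^2) / length(r),
                 n_points = length(r), band = bd$name),
            class = "water_fit_result")
}

#' @export
print.water_fit_result <- function(x, ...) {
  cat(sprintf("Pure-water fit (%s): amplitude c = %.4g, rho = %.4g (n = %d)\n",
              x$band, x$amplitude, x$rho, x$n_points))
  invisible(x)
}
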