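#' Fiber-probe geometry
#'
#' Describes the three-fiber contact probe: one source fiber and collection
#' fibers at the given source-to-detector separations (SDS).  Defaults match
#' a 400 um core, NA 0.22 probe with detectors at 1 and 2 mm, in optical
#' contact with tissue of refractive index 1.45.  With
#' `n_ambient == n_tissue` the surface is treated as index matched (a fused
#' silica probe face nearly matches skin at 1.45); setting a different
#' `n_ambient` switches on the unpolarised Fresnel boundary.
#'
#' @param fiber_diameter fiber core diameter, mm.
#' @param fiber_na numerical aperture (specified in air).
#' @param sds_list source-to-detector separations, mm, strictly increasing.
#' @param n_tissue tissue refractive index.
#' @param n_ambient refractive index above the surface.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(fiber_diameter = 0.4, fiber_na = 0.22,
                           sds_list = c(1.0, 2.0),
                           n_tissue = 1.45, n_ambient = 1.45) {
  stopifnot(is.numeric(fiber_diameter), length(fiber_diameter) == 1)
  if (fiber_diameter <= 0) stop("fiber_diameter must be > 0")
  if (fiber_na <= 0 || fiber_na >= n_ambient)
    stop("fiber_na must lie in (0, n_ambient)")
  if (any(sds_list <= fiber_diameter))
    stop("all source-detector separations must exceed the fiber diameter")
  if (is.unsorted(sds_list, strictly = TRUE))
    stop("sds_list must be strictly increasing")
  if (n_tissue <= 1 || n_ambient < 1) stop("invalid refractive indices")
  structure(list(fiber_diameter = fiber_diameter, fiber_na = fiber_na,
                 sds_list = as.numeric(sds_list),
                 n_tissue = n_tissue, n_ambient = n_ambient),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("Fiber probe: diameter", x$fiber_diameter, "mm, NA", x$fiber_na,
      "\n  SDS:", paste(x$sds_list, collapse = ", "), "mm",
      "\n  n_tissue:", x$n_tissue, " n_ambient:", x$n_ambient,
      if (x$n_ambient == x$n_tissue) "(index matched)" else "(Fresnel boundary)",
      "\n")
  invisible(x)
}

#' Optical properties of the homogeneous medium
#'
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0 unless
#'   modelling a pure absorber, where 0 is allowed).
#' @param g Henyey-Greenstein anisotropy factor in `[0, 1)`; the scattering
#'   coefficient used by the kernel is `mu_s = mu_s_prime / (1 - g)`.
#' @return An object of class `medium_optics` with the derived `mu_s`.
#' @export
medium_optics <- function(mu_a, mu_s_prime, g = 0.8) {
  if (!is.numeric(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (!is.numeric(mu_s_prime) || mu_s_prime < 0)
    stop("mu_s_prime must be >= 0")
  if (g < 0 || g >= 1) stop("g must lie in [0, 1)")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g,
                 mu_s = mu_s_prime / (1 - g)),
            class = "medium_optics")
}

#' Monte Carlo run configuration
#'
#' @param n_photons number of launched photons.
#' @param seed integer seed for the kernel's own PRNG; a fixed seed gives a
#'   bit-identical result.
#' @param roulette_threshold weight below which Russian roulette is played.
#' @param roulette_survival survival probability of the roulette.
#' @param record_paths record per-detected-photon path length and maximum
#'   depth (needed for the white-Monte-Carlo path database).
#' @param r_max,z_max lateral / depth bounds (mm) beyond which a photon is
#'   terminated and booked as lost; generous relative to the 2 mm probe.
#' @param split_factor geometric-splitting factors applied at the planes
#'   `z_split` during zero-absorption (white) runs: a photon crossing a
#'   plane toward the surface is split into that many copies of
#'   proportionally smaller weight, and a split copy diving back plays
#'   Russian roulette -- an exact-in-expectation variance reduction that
#'   concentrates work in the near-surface region the detectors sample.
#'   Set to 1 to disable.
#' @param z_split splitting plane depths, mm (same length as
#'   `split_factor`).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_photons = 1e5, seed = 1,
                      roulette_threshold = 1e-4, roulette_survival = 0.1,
                      record_paths = FALSE, r_max = 20, z_max = 20,
                      split_factor = 4, z_split = 0.5) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)")
  if (length(split_factor) != length(z_split))
    stop("split_factor and z_split must have the same length")
  if (any(split_factor < 1) || any(split_factor != round(split_factor)))
    stop("split_factor entries must be positive integers")
  if (any(z_split <= 0) || anyDuplicated(z_split))
    stop("z_split depths must be positive and distinct")
  o <- order(z_split)
  structure(list(n_photons = as.integer(n_photons), seed = as.numeric(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 record_paths = isTRUE(record_paths),
                 r_max = r_max, z_max = z_max,
                 split_factor = as.integer(split_factor)[o],
                 z_split = as.numeric(z_split)[o]),
            class = "mc_config")
}

#' Short provenance string identifying a probe geometry
#'
#' Used to stamp path databases and reflectance grids so that mismatched
#' geometries are refused at load time.
#' @param probe a [probe_geometry()].
#' @return A single character string.
#' @export
geometry_hash <- function(probe) {
  stopifnot(inherits(probe, "probe_geometry"))
  paste0("fd", format(probe$fiber_diameter), "|na", format(probe$fiber_na),
         "|sds", paste(format(probe$sds_list), collapse = ","),
         "|nt", format(probe$n_tissue), "|namb", format(probe$n_ambient))
}
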