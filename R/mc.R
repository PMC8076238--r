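#' Sample Henyey-Greenstein deflection cosines
#'
#' Deterministic inverse-CDF transform of uniform variates to single-scatter
#' deflection cosines of the Henyey-Greenstein phase function.  At `g = 0` the
#' transform reduces to `2 u - 1` (isotropic scattering).
#'
#' @param g anisotropy factor in `[0, 1)`.
#' @param u uniform variates in `[0, 1)`.
#' @return Numeric vector of cosines in `[-1, 1]`.
#' @export
sample_hg_cosine <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1 || g < 0 || g >= 1)
    stop("g must lie in [0, 1)")
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  .hg_cosine(g, as.numeric(u))
}

.cone_cosine <- function(probe) {
  # NA is specified in air; at the (near) matched face the cone in tissue has
  # half-angle asin(NA / n_tissue)
  cos(asin(probe$fiber_na / probe$n_tissue))
}

.run_kernel <- function(medium, probe, config, record_paths) {
  .mc_kernel(medium$mu_a, medium$mu_s, medium$g,
             probe$fiber_diameter / 2, probe$fiber_diameter / 2,
             probe$sds_list, .cone_cosine(probe),
             config$n_photons, config$seed,
             config$roulette_threshold, config$roulette_survival,
             record_paths, config$r_max, config$z_max,
             probe$n_tissue / probe$n_ambient,
             config$split_factor, config$z_split)
}

#' Simulate diffuse reflectance collected by the fiber probe
#'
#' Launches photons uniformly over the source-fiber face within the NA cone
#' into a homogeneous semi-infinite medium and scores the weight collected by
#' each detector fiber (exit point on the fiber face, exit direction within
#' the NA acceptance cone).  Reflectance is detected weight per launched
#' photon.  Deterministic for a fixed seed.
#'
#' @param medium a [medium_optics()].
#' @param probe a [probe_geometry()].
#' @param config an [mc_config()].
#' @return An object of class `mc_result` with elements `reflectance`,
#'   `standard_error`, `n_detected` (per detector), the weight budget
#'   (`absorbed`, `escaped`, `lost`), and `zero_detected` flag.
#' @export
simulate_reflectance <- function(medium, probe = probe_geometry(),
                                 config = mc_config()) {
  stopifnot(inherits(medium, "medium_optics"),
            inherits(probe, "probe_geometry"), inherits(config, "mc_config"))
  k <- .run_kernel(medium, probe, config, FALSE)
  zero <- all(k$n_detected == 0L)
  if (zero) warning("no photons detected at any separation")
  structure(list(reflectance = as.numeric(k$reflectance),
                 standard_error = as.numeric(k$se),
                 n_detected = as.integer(k$n_detected),
                 absorbed = k$absorbed, escaped = k$escaped, lost = k$killed,
                 split_net = k$split_net,
                 n_photons = config$n_photons, seed = config$seed,
                 sds_list = probe$sds_list, zero_detected = zero),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo reflectance (", x$n_photons, " photons, seed ", x$seed,
      ")\n", sep = "")
  for (j in seq_along(x$sds_list))
    cat(sprintf("  SDS %.2f mm: R = %.4g (SE %.2g, n = %d)\n",
                x$sds_list[j], x$reflectance[j], x$standard_error[j],
                x$n_detected[j]))
  invisible(x)
}

#' Build a white-Monte-Carlo path database
#'
#' Runs the kernel at zero absorption and records, for every detected photon,
#' its detector, total path length, maximum depth and exit weight.  Absorption
#' is later applied analytically with [rescale_reflectance()] (Beer-Lambert
#' reweighting), which is exact in expectation and lets one scatter-only run
#' serve every absorption value on a grid.
#'
#' @param medium a [medium_optics()] with `mu_a == 0`.
#' @inheritParams simulate_reflectance
#' @return An object of class `path_database`.
#' @export
build_path_database <- function(medium, probe = probe_geometry(),
                                config = mc_config()) {
  stopifnot(inherits(medium, "medium_optics"))
  if (medium$mu_a != 0)
    stop("path database must be built at mu_a = 0 (white Monte Carlo)")
  cfg <- config
  cfg$record_paths <- TRUE
  k <- .run_kernel(medium, probe, cfg, TRUE)
  structure(list(detector_id = as.integer(k$path_detector),
                 primary_id = as.integer(k$path_primary),
                 path_length = as.numeric(k$path_length),
                 max_depth = as.numeric(k$path_max_depth),
                 weight = as.numeric(k$path_weight),
                 n_photons = config$n_photons, seed = config$seed,
                 mu_s_prime = medium$mu_s_prime, g = medium$g,
                 sds_list = probe$sds_list,
                 geometry_hash = geometry_hash(probe)),
            class = "path_database")
}

#' @export
print.path_database <- function(x, ...) {
  cat("White-MC path database: mu_s' =", x$mu_s_prime, "mm^-1, g =", x$g,
      "\n ", length(x$path_length), "detected paths from", x$n_photons,
      "photons; geometry", x$geometry_hash, "\n")
  invisible(x)
}

#' Rescale a white-Monte-Carlo database to a given absorption
#'
#' Reweights every detected photon by `exp(-mu_a * path_length)` and returns
#' the implied reflectance per detector with its standard error.  Monotone
#' non-increasing in `mu_a`.
#'
#' @param db a [build_path_database()] result.
#' @param mu_a absorption coefficient, mm^-1 (scalar, >= 0).
#' @return List with `reflectance` and `standard_error` vectors (one entry
#'   per detector).
#' @export
rescale_reflectance <- function(db, mu_a) {
  stopifnot(inherits(db, "path_database"))
  if (!is.numeric(mu_a) || length(mu_a) != 1 || mu_a < 0)
    stop("mu_a must be a single value >= 0")
  # contributions from copies of one launched photon are correlated:
  # the batch kernel aggregates per primary before estimating the variance
  out <- .rescale_batch(db$detector_id, db$primary_id, db$path_length,
                        db$weight, db$n_photons, length(db$sds_list),
                        as.numeric(mu_a))
  list(reflectance = as.numeric(out$reflectance[1, ]),
       standard_error = as.numeric(out$se[1, ]))
}

#' Interrogation depth of the detected photons
#'
#' Weighted statistic of the maximum depths reached by detected photons, with
#' weights `exit_weight * exp(-mu_a * path_length)` -- i.e. the depth
#' distribution the probe actually samples at the given absorption.  Depth
#' decreases with `mu_a` because deep paths are long and hence attenuated.
#'
#' @inheritParams rescale_reflectance
#' @param statistic `"mean"`, `"median"` or `"percentile"`.
#' @param p percentile in `(0, 1)` when `statistic = "percentile"`.
#' @return Depth in mm per detector (`NA` with a warning where a detector has
#'   no recorded paths).
#' @export
interrogation_depth <- function(db, mu_a,
                                statistic = c("mean", "median", "percentile"),
                                p = 0.9) {
  stopifnot(inherits(db, "path_database"))
  statistic <- match.arg(statistic)
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (statistic == "median") { statistic <- "percentile"; p <- 0.5 }
  nd <- length(db$sds_list)
  out <- rep(NA_real_, nd)
  w_all <- db$weight * exp(-mu_a * db$path_length)
  for (j in seq_len(nd)) {
    sel <- db$detector_id == j
    if (!any(sel)) { warning("no recorded paths for detector ", j); next }
    w <- w_all[sel]; d <- db$max_depth[sel]
    if (statistic == "mean") {
      out[j] <- sum(w * d) / sum(w)
    } else {
      o <- order(d)
      cw <- cumsum(w[o]) / sum(w)
      out[j] <- d[o][which(cw >= p)[1]]
    }
  }
  out
}

#' Diffusion-approximation spatially resolved reflectance
#'
#' Closed-form steady-state reflectance of a pencil source on a semi-infinite
#' medium with an extrapolated boundary (dipole solution), used as an
#' independent physics check of the Monte Carlo kernel at high transport
#' albedo.  For an index-matched boundary the internal-reflection parameter
#' `A = 1`.
#'
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param rho source-detector distances, mm.
#' @param A internal reflection parameter (1 for a matched boundary).
#' @return Reflectance per unit area (mm^-2) at each `rho`.
#' @export
diffusion_reflectance <- function(mu_a, mu_s_prime, rho, A = 1) {
  mu_t <- mu_a + mu_s_prime
  z0 <- 1 / mu_t
  D <- 1 / (3 * mu_t)
  zb <- 2 * A * D
  mu_eff <- sqrt(3 * mu_a * mu_t)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
     (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2) / (4 * pi)
}
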