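#' Configuration of the synthetic psoriasis/normal study
#'
#' Encodes the study conditions the pipeline is exercised under: 21 psoriasis
#' subjects measured at three sites (lesion, adjacent uninvolved, uninvolved
#' upper inner arm) and 21 normal subjects at one arm site, five replicate
#' reflectance measurements per site, with group-dependent bound-water
#' fraction, hemoglobin-like absorption offset, power-law scattering
#' (lesions: lower magnitude, larger spread) and multiplicative measurement
#' noise.  Band-specific perturbation defaults give the bound-water signature
#' a strong first-overtone and a weak second-overtone expression, matching
#' the observed band asymmetry.  All distributions are configurable; the
#' defaults are this package's chosen effect sizes (direction and
#' significance, not magnitudes, are constrained by the clinical findings).
#'
#' @param n_psoriasis,n_normal cohort sizes.
#' @param replicates_per_site replicate measurements per site.
#' @param seed cohort generation seed.
#' @param noise_cv multiplicative lognormal reflectance noise CV.
#' @param water_fraction mean/sd of the tissue water volume fraction.
#' @param f_b named per-group mean/sd of the bound-water fraction (draws are
#'   clipped to `[0, 1]`).
#' @param offset named per-group mean/sd of the flat hemoglobin-like
#'   absorption offset, mm^-1 (clipped to >= 0).
#' @param musp_970 named per-group mean/sd of the reduced scattering
#'   coefficient at 970 nm, mm^-1.  The power-law magnitude is derived as
#'   `a = musp_970 * 970^b`, so `a` and `b` are strongly correlated (as fit
#'   parameters of smooth spectra are) while the physical scattering level
#'   stays controlled; the lesion group's doubled `b` spread then produces
#'   the larger spread of fitted `a`/`b` at lesion sites.
#' @param pl_b named per-group mean/sd of the power-law wavelength exponent.
#' @param perturbation per-band bound-water shift/width defaults.
#' @param nuisance_tilt per-band SD (mm^-1 per 100 nm) of a zero-mean,
#'   group-independent linear spectral tilt added to each site's absorption,
#'   emulating site-to-site variability of non-water chromophores (residual
#'   hemoglobin, lipids, collagen tails).  The second-overtone band sits on
#'   much weaker water absorption, so chromophore variability dominates its
#'   fitting residual and masks group structure there -- the observed band
#'   asymmetry -- while leaving the strongly water-dominated first overtone
#'   discriminative.
#' @param pasi_link coefficients tying the erythema / thickness / scaling
#'   subscores to (offset, a, f_b), plus score noise SDs.
#' @param wavelength_step spectral sampling, nm.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_psoriasis = 21, n_normal = 21, replicates_per_site = 5, seed = 42,
    noise_cv = 0.02,
    water_fraction = c(mean = 0.70, sd = 0.05),
    f_b = list(lesion = c(mean = 0.55, sd = 0.15),
               adjacent_uninvolved = c(mean = 0.35, sd = 0.10),
               psoriasis_arm = c(mean = 0.25, sd = 0.08),
               normal_arm = c(mean = 0.25, sd = 0.08)),
    offset = list(lesion = c(mean = 0.0035, sd = 0.002),
                  adjacent_uninvolved = c(mean = 0.003, sd = 0.002),
                  psoriasis_arm = c(mean = 0.0028, sd = 0.002),
                  normal_arm = c(mean = 0.0028, sd = 0.002)),
    musp_970 = list(lesion = c(mean = 1.08, sd = 0.18),
                    adjacent_uninvolved = c(mean = 1.35, sd = 0.12),
                    psoriasis_arm = c(mean = 1.35, sd = 0.12),
                    normal_arm = c(mean = 1.35, sd = 0.12)),
    pl_b = list(lesion = c(mean = 0.80, sd = 0.10),
                adjacent_uninvolved = c(mean = 0.80, sd = 0.05),
                psoriasis_arm = c(mean = 0.80, sd = 0.05),
                normal_arm = c(mean = 0.80, sd = 0.05)),
    perturbation = list(second_overtone = c(shift_nm = 1.5, width_factor = 1.0),
                        first_overtone = c(shift_nm = -8, width_factor = 1.15)),
    nuisance_tilt = c(second_overtone = 0.018, first_overtone = 0.004),
    pasi_link = list(erythema = c(intercept = 0.8, coef_offset = 600,
                                  noise_sd = 0.8),
                     thickness = c(intercept = 2.0, coef_musp = -1.5,
                                   ref_musp = 1.08, noise_sd = 0.8),
                     scaling = c(intercept = 0.0, coef_f_b = 4.5,
                                 noise_sd = 0.5)),
    wavelength_step = 1) {
  stopifnot(n_psoriasis >= 2, n_normal >= 2, replicates_per_site >= 1,
            noise_cv >= 0, water_fraction[["sd"]] >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

.site_groups <- c("lesion", "adjacent_uninvolved", "psoriasis_arm",
                  "normal_arm")

#' Compose a synthetic tissue absorption spectrum
#'
#' `mu_a(lambda) = water_fraction * [(1 - f_b) * ref + f_b * bound] + offset`,
#' where the bound component comes from [apply_bound_water_model()].  The
#' flat offset stands in for residual chromophores (chiefly hemoglobin) that
#' raise lesion absorption without water-band structure.
#'
#' @param water_fraction water volume fraction in `(0, 1]`.
#' @param f_b bound-water fraction in `[0, 1]`.
#' @param shift_nm,width_factor perturbation parameters (see
#'   [bound_water_perturbation()]).
#' @param offset flat absorption offset, mm^-1 (>= 0).
#' @param bd a [band()].
#' @param ref the water reference [spectrum()].
#' @param wavelengths evaluation grid, nm.
#' @return An absorption [spectrum()].
#' @export
compose_absorption <- function(water_fraction, f_b, shift_nm, width_factor,
                               offset, bd, ref = water_reference(),
                               wavelengths = NULL) {
  if (water_fraction <= 0 || water_fraction > 1)
    stop("water_fraction must lie in (0, 1]")
  if (offset < 0) stop("offset must be >= 0")
  pert <- bound_water_perturbation(shift_nm, width_factor, f_b)
  mix <- apply_bound_water_model(ref, pert, bd, wavelengths)
  spectrum(mix$wavelength, water_fraction * mix$value + offset,
           kind = "absorption")
}

.draw_clipped <- function(n, ms, lo = -Inf, hi = Inf)
  pmin(pmax(rnorm(n, ms[["mean"]], ms[["sd"]]), lo), hi)

.band_grid <- function(bd, step) seq(bd$range[1], bd$range[2], by = step)

#' Generate the synthetic cohort
#'
#' Draws per-subject, per-site tissue parameters from the configured group
#' distributions, composes absorption and power-law scattering spectra over
#' both overtone bands, pushes them through the forward reflectance surrogate
#' ([forward_interpolate()] on the supplied database) and applies independent
#' multiplicative lognormal noise per replicate and wavelength.  PASI
#' subscores (psoriasis subjects only) are rounded, clipped linear functions
#' of the lesion's offset, power-law magnitude and bound fraction plus noise.
#' Fully reproducible from `config$seed`.  A subject whose optical properties
#' fall outside the database grid is redrawn (up to 20 retries, then an
#' error).
#'
#' @param config a [cohort_config()].
#' @param db a `reflectance_db` used as the forward model.
#' @param ref the water reference [spectrum()].
#' @return A list of class `cohort` of subject records; each record carries
#'   `subject_id`, `cohort`, `pasi` and a named `sites` list whose elements
#'   hold the true parameters and per-band replicate reflectance matrices.
#' @export
generate_cohort <- function(config = cohort_config(), db,
                            ref = water_reference()) {
  stopifnot(inherits(config, "cohort_config"), inherits(db, "reflectance_db"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  bands <- list(second_overtone = band("second"), first_overtone = band("first"))
  grids <- lapply(bands, .band_grid, step = config$wavelength_step)
  sigma <- sqrt(log(1 + config$noise_cv^2))

  draw_site <- function(group) {
    b <- .draw_clipped(1, config$pl_b[[group]], 0.05, Inf)
    musp970 <- .draw_clipped(1, config$musp_970[[group]], 0.15, Inf)
    list(group = group,
         water_fraction = .draw_clipped(1, config$water_fraction, 0.05, 1),
         f_b = .draw_clipped(1, config$f_b[[group]], 0, 1),
         offset = .draw_clipped(1, config$offset[[group]], 0, Inf),
         musp_970 = musp970,
         a = musp970 * 970^b,
         b = b)
  }

  site_spectra <- function(site) {
    out <- list()
    for (bn in names(bands)) {
      wl <- grids[[bn]]
      pert <- config$perturbation[[bn]]
      mua <- compose_absorption(site$water_fraction, site$f_b,
                                pert[["shift_nm"]], pert[["width_factor"]],
                                site$offset, bands[[bn]], ref, wl)$value
      tilt <- rnorm(1, 0, config$nuisance_tilt[[bn]])
      mua <- pmax(mua + tilt * (wl - mean(bands[[bn]]$range)) / 100, 1e-3)
      musp <- site$a * wl^(-site$b)
      R <- forward_interpolate(db, mua, musp)  # errors if out of bounds
      reps_R1 <- reps_R2 <- matrix(0, config$replicates_per_site, length(wl))
      for (r in seq_len(config$replicates_per_site)) {
        reps_R1[r, ] <- R[, 1] * rlnorm(length(wl), -sigma^2 / 2, sigma)
        reps_R2[r, ] <- R[, 2] * rlnorm(length(wl), -sigma^2 / 2, sigma)
      }
      out[[bn]] <- list(wavelength = wl, R1 = reps_R1, R2 = reps_R2,
                        true_mu_a = mua, true_mu_sp = musp)
    }
    out
  }

  make_subject <- function(id, cohort_name, groups) {
    for (try in 1:20) {
      sites <- lapply(groups, draw_site)
      names(sites) <- groups
      specs <- tryCatch(lapply(sites, site_spectra), error = function(e) NULL)
      if (!is.null(specs)) {
        for (g in groups) sites[[g]]$spectra <- specs[[g]]
        return(list(subject_id = id, cohort = cohort_name, sites = sites))
      }
    }
    stop("could not draw subject ", id,
         " inside the database grid after 20 retries")
  }

  subjects <- list()
  for (i in seq_len(config$n_psoriasis)) {
    s <- make_subject(sprintf("P%02d", i), "psoriasis",
                      c("lesion", "adjacent_uninvolved", "psoriasis_arm"))
    les <- s$sites$lesion
    pl <- config$pasi_link
    e <- pl$erythema[["intercept"]] + pl$erythema[["coef_offset"]] * les$offset +
      rnorm(1, 0, pl$erythema[["noise_sd"]])
    th <- pl$thickness[["intercept"]] +
      pl$thickness[["coef_musp"]] * (les$musp_970 - pl$thickness[["ref_musp"]]) +
      rnorm(1, 0, pl$thickness[["noise_sd"]])
    sc <- pl$scaling[["intercept"]] + pl$scaling[["coef_f_b"]] * les$f_b +
      rnorm(1, 0, pl$scaling[["noise_sd"]])
    s$pasi <- c(erythema = min(4, max(0, round(e))),
                thickness = min(4, max(0, round(th))),
                scaling = min(4, max(0, round(sc))))
    subjects[[length(subjects) + 1]] <- s
  }
  for (i in seq_len(config$n_normal)) {
    s <- make_subject(sprintf("N%02d", i), "normal", "normal_arm")
    s$pasi <- c(erythema = NA_real_, thickness = NA_real_,
                scaling = NA_real_)
    subjects[[length(subjects) + 1]] <- s
  }
  structure(list(subjects = subjects, config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  nsite <- sum(vapply(x$subjects, function(s) length(s$sites), 0L))
  cat("Synthetic cohort:", length(x$subjects), "subjects,", nsite,
      "measured sites,", x$config$replicates_per_site,
      "replicates per site (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Run the full analysis pipeline on a cohort
#'
#' For each subject, site and band: average the replicate reflectance
#' spectra, invert them to absorption and reduced-scattering spectra with the
#' trained model, compute the pure-water fitting residual, fit the scattering
#' power law and read off mu_s' at 970 nm (second-overtone band) or 1300 nm
#' (first-overtone band) by linear interpolation.  Then run one-way ANOVA and
#' Scheffe tests across the four site groups for each derived metric, and
#' Pearson correlations of the first-overtone residual at the lesion site
#' with the three PASI subscores.
#'
#' @param cohort a [generate_cohort()] result.
#' @param model a trained [train_inverse_model()].
#' @param ref the water reference [spectrum()].
#' @return A list of class `cohort_results` with `site_table` (one row per
#'   subject x site x band), `anova`, `scheffe` (per metric), `pearson`, and
#'   `n_failed`.
#' @export
run_pipeline <- function(cohort, model, ref = water_reference()) {
  stopifnot(inherits(cohort, "cohort"), inherits(model, "inverse_model"))
  bands <- list(second_overtone = band("second"),
                first_overtone = band("first"))
  rows <- list()
  n_failed <- 0L
  for (s in cohort$subjects) {
    for (g in names(s$sites)) {
      site <- s$sites[[g]]
      for (bn in names(bands)) {
        sp <- site$spectra[[bn]]
        row <- tryCatch({
          R1 <- colMeans(sp$R1)
          R2 <- colMeans(sp$R2)
          rec <- invert_reflectance(model, R1, R2, wavelength = sp$wavelength)
          mua_sp <- spectrum(rec$wavelength[!rec$out_of_domain],
                             rec$mu_a[!rec$out_of_domain], kind = "absorption")
          musp_sp <- spectrum(rec$wavelength[!rec$out_of_domain],
                              rec$mu_sp[!rec$out_of_domain],
                              kind = "scattering")
          wf <- fit_pure_water(mua_sp, bands[[bn]], ref)
          pl <- fit_power_law(musp_sp, bands[[bn]])
          lam0 <- if (bn == "second_overtone") 970 else 1300
          musp_at <- approx(musp_sp$wavelength, musp_sp$value, xout = lam0)$y
          data.frame(subject_id = s$subject_id, cohort = s$cohort,
                     group = g, band = bn, rho = wf$rho,
                     amplitude = wf$amplitude, a = pl$a, b = pl$b,
                     musp_at = musp_at, readout_nm = lam0,
                     n_out_of_domain = sum(rec$out_of_domain),
                     erythema = s$pasi[["erythema"]],
                     thickness = s$pasi[["thickness"]],
                     scaling = s$pasi[["scaling"]])
        }, error = function(e) NULL)
        if (is.null(row)) n_failed <- n_failed + 1L else
          rows[[length(rows) + 1]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  metric_groups <- function(values, groups) {
    keep <- is.finite(values)
    split(values[keep], factor(groups[keep], levels = .site_groups))
  }
  metrics <- list(
    rho_second_overtone = with(tab[tab$band == "second_overtone", ],
                               metric_groups(rho, group)),
    rho_first_overtone = with(tab[tab$band == "first_overtone", ],
                              metric_groups(rho, group)),
    musp_970 = with(tab[tab$band == "second_overtone", ],
                    metric_groups(musp_at, group)),
    musp_1300 = with(tab[tab$band == "first_overtone", ],
                     metric_groups(musp_at, group)))
  anova_res <- lapply(metrics, one_way_anova)
  scheffe_res <- lapply(metrics, scheffe_test)

  les <- tab[tab$band == "first_overtone" & tab$group == "lesion" &
               is.finite(tab$rho), ]
  safe_r <- function(y) tryCatch(pearson_correlation(les$rho, y),
                                 error = function(e) NA_real_)
  pearson <- c(erythema = safe_r(les$erythema),
               thickness = safe_r(les$thickness),
               scaling = safe_r(les$scaling))

  structure(list(site_table = tab, metrics = metrics, anova = anova_res,
                 scheffe = scheffe_res, pearson = pearson,
                 n_failed = n_failed),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat("Cohort pipeline results:", nrow(x$site_table),
      "subject x site x band rows (", x$n_failed, "failures )\n")
  for (m in names(x$anova))
    cat(sprintf("  %-20s ANOVA p = %.3g\n", m, x$anova[[m]]$p_value))
  cat("  Pearson r (lesion first-overtone rho vs PASI):",
      sprintf("erythema %.2f, thickness %.2f, scaling %.2f\n",
              x$pearson[["erythema"]], x$pearson[["thickness"]],
              x$pearson[["scaling"]]))
  invisible(x)
}
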