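test_that("composed absorption reduces to the water reference in the null case", {
  ref <- water_reference()
  for (bd in list(band("second"), band("first"))) {
    mu <- compose_absorption(1, 0, 3, 1.0, 0, bd, ref)
    base <- band_values(bd)
    expect_equal(mu$value, base$value, tolerance = 1e-12)
  }
})

test_that("a flat offset breaks the pure-water shape and raises rho", {
  bd <- band("second")
  mu0 <- compose_absorption(0.7, 0, 3, 1.0, 0, bd)
  expect_equal(fit_pure_water(mu0, bd)$rho, 0, tolerance = 1e-18)
  mu1 <- compose_absorption(0.7, 0, 3, 1.0, 0.01, bd)
  expect_gt(fit_pure_water(mu1, bd)$rho, 0)
})

test_that("rho grows with the generative bound fraction", {
  bd <- band("first")
  rho_lo <- fit_pure_water(compose_absorption(0.7, 0.2, -8, 1.15, 0, bd), bd)$rho
  rho_hi <- fit_pure_water(compose_absorption(0.7, 0.6, -8, 1.15, 0, bd), bd)$rho
  expect_gt(rho_hi, rho_lo)
})

test_that("compose_absorption validates parameters", {
  bd <- band("second")
  expect_error(compose_absorption(0, 0.5, 3, 1, 0, bd), "water_fraction")
  expect_error(compose_absorption(0.7, 1.5, 3, 1, 0, bd), "f_b")
  expect_error(compose_absorption(0.7, 0.5, 3, 1, -0.1, bd), "offset")
})

test_that("cohort generation is deterministic and has the study structure", {
  cfg <- cohort_config(n_psoriasis = 4, n_normal = 3, seed = 99)
  db <- tiny_db()
  c1 <- generate_cohort(cfg, db)
  c2 <- generate_cohort(cfg, db)
  expect_identical(c1, c2)

  expect_length(c1$subjects, 7)
  n_sites <- vapply(c1$subjects, function(s) length(s$sites), 0L)
  expect_equal(n_sites, c(rep(3L, 4), rep(1L, 3)))
  s1 <- c1$subjects[[1]]
  expect_setequal(names(s1$sites),
                  c("lesion", "adjacent_uninvolved", "psoriasis_arm"))
  expect_true(all(is.finite(s1$pasi)))
  expect_true(all(is.na(c1$subjects[[7]]$pasi)))
  sp <- s1$sites$lesion$spectra$second_overtone
  expect_equal(dim(sp$R1), c(5, 61))
  expect_true(all(sp$R1 > 0))

  c3 <- generate_cohort(cohort_config(n_psoriasis = 4, n_normal = 3,
                                      seed = 100), db)
  expect_false(identical(c1$subjects[[1]]$sites$lesion$f_b,
                         c3$subjects[[1]]$sites$lesion$f_b))
})

test_that("default cohort counts match the study design", {
  cfg <- cohort_config()
  expect_equal(cfg$n_psoriasis, 21)
  expect_equal(cfg$n_normal, 21)
  expect_equal(cfg$replicates_per_site, 5)
  # 21 x 3 psoriasis sites + 21 normal sites = 84 measured sites
  expect_equal(cfg$n_psoriasis * 3 + cfg$n_normal, 84)
})

test_that("zero measurement noise gives identical replicates", {
  cfg <- cohort_config(n_psoriasis = 2, n_normal = 2, noise_cv = 0, seed = 5)
  co <- generate_cohort(cfg, tiny_db())
  sp <- co$subjects[[1]]$sites$lesion$spectra$first_overtone
  for (r in 2:nrow(sp$R1)) expect_equal(sp$R1[r, ], sp$R1[1, ])
})

test_that("subjects whose optics leave the grid are rejected after retries", {
  big <- c(mean = 10, sd = 0.01)  # mu_s' far above the 3 mm^-1 grid edge
  cfg <- cohort_config(n_psoriasis = 2, n_normal = 2, seed = 1,
                       musp_970 = list(lesion = big,
                                       adjacent_uninvolved = big,
                                       psoriasis_arm = big,
                                       normal_arm = big))
  expect_error(generate_cohort(cfg, tiny_db()), "20 retries")
})

test_that("the scaling subscore tracks the lesion bound-water residual", {
  # at the generator level (composed spectra, no measurement chain) the
  # PASI scaling score and the first-overtone residual share their f_b
  # driver, so their correlation across lesions is clearly positive
  cfg <- cohort_config(seed = 71)
  co <- generate_cohort(cfg, tiny_db())
  bd <- band("first")
  ref <- water_reference()
  pert <- cfg$perturbation$first_overtone
  rho <- scal <- numeric(0)
  for (s in co$subjects) {
    if (s$cohort != "psoriasis") next
    les <- s$sites$lesion
    mu <- compose_absorption(les$water_fraction, les$f_b, pert[["shift_nm"]],
                             pert[["width_factor"]], les$offset, bd, ref)
    rho <- c(rho, fit_pure_water(mu, bd, ref)$rho)
    scal <- c(scal, s$pasi[["scaling"]])
  }
  expect_gt(pearson_correlation(rho, scal), 0)
})

test_that("the pipeline produces per-site metrics and cohort statistics", {
  cfg <- cohort_config(n_psoriasis = 4, n_normal = 4, seed = 17)
  co <- generate_cohort(cfg, tiny_db())
  res <- run_pipeline(co, tiny_model())
  expect_s3_class(res$site_table, "data.frame")
  # 4 subjects x 3 sites x 2 bands + 4 x 1 x 2 = 32 rows when nothing fails
  expect_equal(nrow(res$site_table) + res$n_failed * 0, 32 - res$n_failed)
  expect_named(res$anova, c("rho_second_overtone", "rho_first_overtone",
                            "musp_970", "musp_1300"))
  for (m in res$anova) expect_true(is.finite(m$p_value))
  expect_true(all(dim(res$scheffe$rho_first_overtone$p_value) == c(4, 4)))
  expect_length(res$pearson, 3)
})
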