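test_that("the water reference has the expected overtone structure", {
  ref <- water_reference()
  expect_true(all(diff(ref$wavelength) > 0))
  expect_true(all(ref$value > 0))
  b2 <- band_values(band("second"))
  peak <- b2$wavelength[which.max(b2$value)]
  expect_lt(abs(peak - 970), 5)
  # rising into the first overtone beyond 1380 nm
  tail_sel <- ref$wavelength >= 1380 & ref$wavelength <= 1445
  expect_true(all(diff(ref$value[tail_sel]) > 0))
})

test_that("a scaled pure-water spectrum fits with the right amplitude and rho 0", {
  for (bd in list(band("second"), band("first"))) {
    for (k in c(0.3, 0.7, 1.9)) {
      w <- band_values(bd)
      fit <- fit_pure_water(spectrum(w$wavelength, k * w$value), bd)
      expect_equal(fit$amplitude, k, tolerance = 1e-12)
      expect_equal(fit$rho, 0, tolerance = 1e-20)
    }
  }
})

test_that("rho scales quadratically under joint scaling of a mismatched spectrum", {
  bd <- band("second")
  pert <- bound_water_perturbation(shift_nm = 5, width_factor = 1.1, f_b = 0.6)
  y <- apply_bound_water_model(water_reference(), pert, bd)
  f1 <- fit_pure_water(y, bd)
  expect_gt(f1$rho, 0)
  k <- 2.5
  f2 <- fit_pure_water(spectrum(y$wavelength, k * y$value), bd)
  expect_equal(f2$rho, k^2 * f1$rho, tolerance = 1e-10)
  expect_equal(f2$amplitude, k * f1$amplitude, tolerance = 1e-10)
})

test_that("the closed-form amplitude matches a brute-force grid search", {
  bd <- band("second")
  ref <- water_reference()
  wl <- band_values(bd)$wavelength
  shifted <- approx(ref$wavelength, ref$value, xout = wl + 5, rule = 2)$y
  sp <- spectrum(wl, shifted)
  fit <- fit_pure_water(sp, bd)
  w <- band_values(bd)$value
  cs <- seq(0, 3, by = 1e-5)
  rhos <- vapply(cs, function(cc) 100 * mean((shifted - cc * w)^2), 0)
  expect_equal(fit$rho, min(rhos), tolerance = 1e-6)
  expect_equal(fit$amplitude, cs[which.min(rhos)], tolerance = 1e-3)
})

test_that("rho is invariant to reordering of spectral points", {
  bd <- band("first")
  y <- apply_bound_water_model(water_reference(),
                               bound_water_perturbation(-8, 1.15, 0.5), bd)
  set.seed(4)
  o <- sample(nrow(y))
  f1 <- fit_pure_water(y, bd)
  f2 <- fit_pure_water(spectrum(y$wavelength[o], y$value[o]), bd)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-12)
})

test_that("fit_pure_water validates its inputs", {
  bd <- band("second")
  expect_error(fit_pure_water(spectrum(941:947, rep(0.01, 7)), bd),
               "insufficient data")
  expect_error(fit_pure_water(spectrum(941:960, rep(NA_real_, 20)), bd),
               "insufficient data")
})

test_that("the bound-water model is the identity at f_b = 0 or null perturbation", {
  ref <- water_reference()
  for (bd in list(band("second"), band("first"))) {
    base <- band_values(bd)
    out0 <- apply_bound_water_model(ref, bound_water_perturbation(5, 1.3, 0), bd)
    expect_equal(out0$value, base$value, tolerance = 1e-12)
    outn <- apply_bound_water_model(ref, bound_water_perturbation(0, 1, 0.7), bd)
    expect_equal(outn$value, base$value, tolerance = 1e-12)
  }
})

test_that("rho increases with bound fraction at the default band perturbations", {
  ref <- water_reference()
  perts <- list(second_overtone = c(3, 1.0), first_overtone = c(-8, 1.15))
  for (bn in names(perts)) {
    bd <- band(sub("_overtone", "", bn))
    rhos <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(fb) {
      y <- apply_bound_water_model(
        ref, bound_water_perturbation(perts[[bn]][1], perts[[bn]][2], fb), bd)
      fit_pure_water(y, bd)$rho
    }, 0)
    expect_true(all(diff(rhos) > 0), info = bn)
  }
})

test_that("the bound-water model is continuous in its parameters", {
  ref <- water_reference()
  bd <- band("first")
  base <- apply_bound_water_model(ref, bound_water_perturbation(-8, 1.15, 0.5), bd)
  for (pert in list(bound_water_perturbation(-8.01, 1.15, 0.5),
                    bound_water_perturbation(-8, 1.1501, 0.5),
                    bound_water_perturbation(-8, 1.15, 0.501))) {
    nearby <- apply_bound_water_model(ref, pert, bd)
    expect_lt(max(abs(nearby$value - base$value)), 1e-3)
  }
})

test_that("power-law fits recover generating parameters to 1e-6 relative", {
  for (bd in list(band("second"), band("first"))) {
    wl <- seq(bd$range[1], bd$range[2], by = 2)
    cases <- rbind(expand.grid(a = c(10, 1e3, 1e6), b = c(0.3, 1.5, 2.5)),
                   data.frame(a = c(315.565, 257912.881), b = c(0.808, 1.762)))
    for (i in seq_len(nrow(cases))) {
      a <- cases$a[i]; b <- cases$b[i]
      fit <- fit_power_law(spectrum(wl, a * wl^(-b), kind = "scattering"), bd)
      expect_lt(abs(fit$a - a) / a, 1e-6)
      expect_lt(abs(fit$b - b) / max(abs(b), 1), 1e-6)
    }
  }
})

test_that("a constant spectrum fits with b = 0", {
  bd <- band("second")
  wl <- seq(940, 1000, by = 5)
  fit <- fit_power_law(spectrum(wl, rep(1.2, length(wl)), kind = "scattering"), bd)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_equal(fit$a, 1.2, tolerance = 1e-8)
})

test_that("noiseless fits equal the log-log regression oracle", {
  bd <- band("first")
  wl <- seq(1230, 1380, by = 10)
  y <- 480 * wl^(-0.82)
  ols <- lm(log(y) ~ log(wl))
  fit <- fit_power_law(spectrum(wl, y, kind = "scattering"), bd)
  expect_equal(fit$a, exp(coef(ols)[[1]]), tolerance = 1e-7)
  expect_equal(fit$b, -coef(ols)[[2]], tolerance = 1e-7)
})

test_that("nonpositive scattering values are an error naming wavelengths", {
  bd <- band("second")
  wl <- seq(940, 1000, by = 5)
  y <- 300 * wl^(-0.8)
  y[3] <- -0.1
  expect_error(fit_power_law(spectrum(wl, y, kind = "scattering"), bd), "950")
  expect_error(fit_power_law(spectrum(wl[1:4], y[1:4], kind = "scattering"), bd),
               "insufficient")
})
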