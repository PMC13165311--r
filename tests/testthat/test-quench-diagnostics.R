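# quench_diagnostics: Stern-Volmer fits, lifetime profiles, overlap,
# inner-filter attenuation, temperature trends, mechanism cascade

sv_data <- function(q, ratio, lifetimes = NULL, tau0 = NULL) {
  titration_dataset(q, 1000 / ratio, i0 = 1000, lifetimes = lifetimes,
                    tau0 = tau0)
}

test_that("stern_volmer_fit recovers noiseless linear data exactly", {
  q <- c(0, 1e-3, 2e-3, 3e-3, 4e-3)
  fit <- stern_volmer_fit(sv_data(q, 1 + 100 * q))
  expect_equal(fit$k_sv, 100, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_false(fit$curvature_flag)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("combined static+dynamic data flags curvature with K_D*K_S", {
  q <- seq(0, 0.02, length.out = 9)
  ratio <- (1 + 50 * q) * (1 + 50 * q)  # quadratic coefficient 2500 /M^2
  fit <- stern_volmer_fit(sv_data(q, ratio))
  expect_true(fit$curvature_flag)
  expect_equal(fit$quad_coeff, 2500, tolerance = 1e-6)
})

test_that("stern_volmer_fit validates its input", {
  expect_error(stern_volmer_fit(sv_data(c(0, 1e-3, 2e-3), c(1, 1.1, 1.2))),
               class = "cqd_insufficient_data_error")
  expect_error(titration_dataset(c(0, 1e-3), c(100, -5)),
               class = "cqd_validation_error")
  expect_error(titration_dataset(c(0, 1e-3, 1e-3), c(1, 1, 1)),
               class = "cqd_validation_error")
})

test_that("lifetime_profile discriminates the canonical signatures", {
  q <- c(0, 1e-3, 2e-3, 3e-3)
  ratio <- 1 + 300 * q
  # tau0/tau equal to I0/I at every point -> dynamic signature
  expect_equal(lifetime_profile(sv_data(q, ratio, lifetimes = 5 / ratio,
                                        tau0 = 5)), "changed")
  # flat lifetime while intensity falls -> static/IFE signature
  expect_equal(lifetime_profile(sv_data(q, ratio,
                                        lifetimes = rep(5, length(q)),
                                        tau0 = 5)), "unchanged")
  # lifetime rises but does not track the intensity -> combined signature
  expect_equal(lifetime_profile(sv_data(q, ratio * (1 + 300 * q),
                                        lifetimes = 5 / ratio,
                                        tau0 = 5)), "partial")
  expect_equal(lifetime_profile(sv_data(q, ratio)), "absent")
  expect_error(titration_dataset(q, 1000 / ratio, i0 = 1000,
                                 lifetimes = c(5, 4)),
               class = "cqd_validation_error")
})

test_that("spectral_overlap_fraction matches geometry and the quadrature oracle", {
  grid <- seq(250, 700, by = 1)
  band <- function(center, width = 20) {
    data.frame(wavelength = grid,
               value = exp(-(grid - center)^2 / (2 * width^2)))
  }
  sb <- function(abs_c, ex_c = 360) {
    spectra_bundle(band(abs_c), band(ex_c), band(450))
  }
  # disjoint bands
  expect_equal(spectral_overlap_fraction(sb(650), "excitation"), 0,
               tolerance = 1e-6)
  # identical curves
  expect_equal(spectral_overlap_fraction(sb(360), "excitation"), 1,
               tolerance = 1e-6)

  # two unit Gaussians one sigma apart vs a fine-grid quadrature oracle
  sigma <- 20
  frac <- spectral_overlap_fraction(sb(360 + sigma), "excitation")
  fine <- seq(200, 800, by = 0.01)
  g1 <- exp(-(fine - 360)^2 / (2 * sigma^2))
  g2 <- exp(-(fine - 360 - sigma)^2 / (2 * sigma^2))
  oracle <- sum(pmin(g1, g2)) / sum(g1)
  expect_equal(frac, oracle, tolerance = 1e-3)

  # symmetry when both curves are normalized to unit height
  f_ab <- spectral_overlap_fraction(
    spectra_bundle(band(380), band(360), band(450)), "excitation")
  f_ba <- spectral_overlap_fraction(
    spectra_bundle(band(360), band(380), band(450)), "excitation")
  expect_equal(f_ab, f_ba, tolerance = 1e-6)

  expect_true(frac >= 0 && frac <= 1)
})

test_that("ife_attenuation follows the half-path correction", {
  expect_equal(ife_attenuation(0, 0), 1)
  expect_equal(ife_attenuation(1, 0), 10^-0.5)
  expect_equal(ife_attenuation(1, 1), 0.1)
  expect_error(ife_attenuation(-0.1, 0), class = "cqd_validation_error")

  # strictly decreasing in each argument; correction inverts attenuation
  a <- seq(0, 2, by = 0.25)
  expect_true(all(diff(ife_attenuation(a, 0.3)) < 0))
  expect_true(all(diff(ife_attenuation(0.3, a)) < 0))
  expect_equal(ife_attenuation(a, rev(a)) * ife_correction(a, rev(a)),
               rep(1, length(a)))
})

test_that("temperature_trend reads the slope change", {
  expect_equal(temperature_trend(120, 80), "static_hint")
  expect_equal(temperature_trend(80, 120), "dynamic_hint")
  expect_equal(temperature_trend(100, 101), "flat")
})

test_that("classify_mechanism applies the documented rule cascade", {
  q <- seq(0, 0.02, length.out = 9)
  lin <- stern_volmer_fit(sv_data(q, 1 + 100 * q))

  # lifetime evidence dominates: dynamic regardless of overlap
  call <- classify_mechanism(lin, "changed", overlap_ex = 0.9)
  expect_equal(call$call, "dynamic")
  expect_true(length(call$evidence_used) > 0)

  curved <- stern_volmer_fit(sv_data(q, (1 + 60 * q) * (1 + 60 * q)))
  expect_equal(classify_mechanism(curved, "unchanged", overlap_ex = 0.6,
                                  dilution_reversible = TRUE)$call, "ife")
  # dilution veto blocks the IFE call
  expect_false(classify_mechanism(curved, "unchanged", overlap_ex = 0.6,
                                  dilution_reversible = FALSE)$call == "ife")

  expect_equal(classify_mechanism(lin, "unchanged", overlap_ex = 0.05,
                                  new_absorption_band = TRUE)$call, "static")
  expect_equal(classify_mechanism(lin, "unchanged",
                                  temp = "static_hint")$call, "static")
  expect_equal(classify_mechanism(curved, "partial")$call, "mixed")
  expect_equal(classify_mechanism(lin, "absent")$call, "indeterminate")

  ind <- classify_mechanism(lin, "absent")
  expect_length(ind$evidence_used, 0L)
  expect_gt(length(ind$rationale), 0L)
})
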