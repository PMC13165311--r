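# Quenching-mechanism diagnostics: Stern-Volmer fits, lifetime-ratio
# profiles, spectral overlap, inner-filter attenuation, temperature trends,
# and the rule cascade discriminating dynamic, static, inner-filter and
# mixed quenching.

#' Construct a titration dataset
#'
#' @param q_conc Quencher concentrations (M), strictly increasing; the first
#'   may be 0.
#' @param intensity Fluorescence intensities aligned to `q_conc`, all > 0.
#' @param i0 Intensity at zero quencher; defaults to the intensity at
#'   `q_conc == 0` when present.
#' @param lifetimes Optional lifetimes (ns) aligned to `q_conc`.
#' @param tau0 Lifetime at zero quencher; defaults to the lifetime at
#'   `q_conc == 0`.
#' @param temperature_c Optional temperature (degrees C).
#' @param dilution_series Optional second `titration_dataset` recorded after
#'   dilution.
#' @param dilution_factor Dilution factor of `dilution_series`.
#' @return A `titration_dataset`.
#' @export
titration_dataset <- function(q_conc, intensity, i0 = NULL, lifetimes = NULL,
                              tau0 = NULL, temperature_c = NULL,
                              dilution_series = NULL, dilution_factor = NA) {
  q_conc <- as.numeric(q_conc)
  intensity <- as.numeric(intensity)
  if (length(q_conc) != length(intensity)) {
    cqd_error("cqd_validation_error",
              "q_conc and intensity must have equal length")
  }
  if (any(diff(q_conc) <= 0)) {
    cqd_error("cqd_validation_error", "q_conc must be strictly increasing")
  }
  if (any(q_conc < 0)) {
    cqd_error("cqd_validation_error", "q_conc must be nonnegative")
  }
  if (any(intensity <= 0)) {
    cqd_error("cqd_validation_error", "intensities must be positive")
  }
  if (is.null(i0)) {
    if (q_conc[1] != 0) {
      cqd_error("cqd_validation_error",
                "i0 required when the series lacks a zero-quencher point")
    }
    i0 <- intensity[1]
  }
  if (i0 <= 0) cqd_error("cqd_validation_error", "i0 must be positive")
  if (!is.null(lifetimes)) {
    lifetimes <- as.numeric(lifetimes)
    if (length(lifetimes) != length(q_conc)) {
      cqd_error("cqd_validation_error",
                "lifetimes misaligned with concentrations")
    }
    if (any(lifetimes <= 0)) {
      cqd_error("cqd_validation_error", "lifetimes must be positive")
    }
    if (is.null(tau0)) {
      if (q_conc[1] != 0) {
        cqd_error("cqd_validation_error",
                  "tau0 required when the series lacks a zero-quencher point")
      }
      tau0 <- lifetimes[1]
    }
  }
  structure(
    list(q_conc = q_conc, intensity = intensity, i0 = i0,
         lifetimes = lifetimes, tau0 = tau0, temperature_c = temperature_c,
         dilution_series = dilution_series,
         dilution_factor = dilution_factor),
    class = "titration_dataset"
  )
}

#' Construct a spectra bundle
#'
#' @param analyte_absorbance Data.frame with columns `wavelength`, `value`
#'   (absorbance, >= 0), wavelengths ascending.
#' @param cqd_excitation,cqd_emission Data.frames with columns `wavelength`,
#'   `value` (normalized amplitude in \[0, 1\]).
#' @return A `spectra_bundle`.
#' @export
spectra_bundle <- function(analyte_absorbance, cqd_excitation, cqd_emission) {
  check_curve <- function(df, name, unit_range = FALSE) {
    if (!is.data.frame(df) || !all(c("wavelength", "value") %in% names(df))) {
      cqd_error("cqd_validation_error", sprintf(
        "%s must be a data.frame with wavelength and value columns", name))
    }
    if (!nrow(df)) {
      cqd_error("cqd_validation_error", sprintf("%s is empty", name))
    }
    if (any(diff(df$wavelength) <= 0)) {
      cqd_error("cqd_validation_error", sprintf(
        "%s wavelengths must be ascending", name))
    }
    if (any(df$value < 0)) {
      cqd_error("cqd_validation_error", sprintf(
        "%s values must be nonnegative", name))
    }
    if (unit_range && any(df$value > 1)) {
      cqd_error("cqd_validation_error", sprintf(
        "%s amplitudes must lie in [0, 1]", name))
    }
    df
  }
  structure(
    list(
      analyte_absorbance = check_curve(analyte_absorbance,
                                       "analyte_absorbance"),
      cqd_excitation = check_curve(cqd_excitation, "cqd_excitation", TRUE),
      cqd_emission = check_curve(cqd_emission, "cqd_emission", TRUE)
    ),
    class = "spectra_bundle"
  )
}

#' Stern-Volmer fit
#'
#' Least-squares line of I0/I versus quencher concentration.  Upward
#' curvature is assessed by nested comparison against a quadratic model:
#' the curvature flag is set when adding the quadratic term improves AIC by
#' at least `aic_margin` (default 2) and the quadratic coefficient is
#' positive.  Exactly linear (machine-precision) data never flags curvature;
#' an exactly quadratic fit over a linear one always does.
#'
#' @param data A `titration_dataset`.
#' @param aic_margin Required AIC improvement for accepting curvature.
#' @return An `sv_fit`: list with `k_sv` (1/M), `intercept`, `r_squared`,
#'   `curvature_flag`, `quad_coeff` (1/M^2).
#' @examples
#' q <- c(0, 1e-3, 2e-3, 3e-3, 4e-3)
#' d <- titration_dataset(q, 100 / (1 + 100 * q))
#' stern_volmer_fit(d)$k_sv  # 100
#' @export
stern_volmer_fit <- function(data, aic_margin = 2) {
  stopifnot(inherits(data, "titration_dataset"))
  q <- data$q_conc
  y <- data$i0 / data$intensity
  nz <- q > 0
  if (length(unique(q[nz])) < 3L) {
    cqd_error("cqd_insufficient_data_error",
              "need at least 3 distinct nonzero concentrations")
  }
  fit1 <- stats::lm(y ~ q)
  fit2 <- stats::lm(y ~ q + I(q^2))
  rss1 <- sum(stats::residuals(fit1)^2)
  rss2 <- sum(stats::residuals(fit2)^2)
  scale <- sum(y^2)
  eps <- .Machine$double.eps^0.5 * max(scale, 1)
  curvature <- if (rss1 <= eps) {
    FALSE                       # linear model already exact
  } else if (rss2 <= eps) {
    stats::coef(fit2)[[3]] > 0  # quadratic exact, linear not
  } else {
    (stats::AIC(fit1) - stats::AIC(fit2)) >= aic_margin &&
      stats::coef(fit2)[[3]] > 0
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= eps) 1 else 1 - rss1 / tss
  structure(
    list(
      k_sv = stats::coef(fit1)[[2]],
      intercept = stats::coef(fit1)[[1]],
      r_squared = r2,
      curvature_flag = isTRUE(curvature),
      quad_coeff = stats::coef(fit2)[[3]]
    ),
    class = "sv_fit"
  )
}

#' Lifetime-ratio profile
#'
#' Compares tau0/tau with I0/I.  Dynamic quenching shortens the lifetime in
#' proportion to the intensity loss; static quenching and the inner filter
#' effect leave it untouched.
#'
#' @param data A `titration_dataset`.
#' @param track_tol Relative tolerance for tau0/tau tracking I0/I
#'   (default 0.10).
#' @param unity_tol Tolerance around 1 for "unchanged" (default 0.05).
#' @return One of `"changed"` (tracks I0/I and exceeds unity: the dynamic
#'   signature), `"unchanged"`, `"partial"` (lifetime rises but does not
#'   track the full intensity loss, as in combined static + dynamic
#'   quenching), or `"absent"` (no lifetimes supplied).
#' @export
lifetime_profile <- function(data, track_tol = 0.10, unity_tol = 0.05) {
  stopifnot(inherits(data, "titration_dataset"))
  if (is.null(data$lifetimes)) return("absent")
  ratio <- data$tau0 / data$lifetimes
  iratio <- data$i0 / data$intensity
  if (all(abs(ratio - 1) <= unity_tol)) return("unchanged")
  tracks <- all(abs(ratio - iratio) <= track_tol * iratio)
  exceeds <- any(ratio > 1 + unity_tol)
  if (tracks && exceeds) "changed" else "partial"
}

#' Fractional spectral overlap
#'
#' Quantitative overlap between the analyte absorbance and a CQD band:
#' integral of the pointwise minimum of the two normalized curves divided by
#' the band integral, on the union wavelength grid by trapezoidal
#' integration.  Absorbance is normalized to its maximum over the band's
#' support.
#'
#' @param spectra A `spectra_bundle` (see [spectra_bundle()]).
#' @param band `"excitation"` or `"emission"`.
#' @return Fraction in \[0, 1\].
#' @export
spectral_overlap_fraction <- function(spectra,
                                      band = c("excitation", "emission")) {
  band <- match.arg(band)
  stopifnot(inherits(spectra, "spectra_bundle"))
  ab <- spectra$analyte_absorbance
  bd <- spectra[[paste0("cqd_", band)]]
  if (is.null(ab) || !nrow(ab) || is.null(bd) || !nrow(bd)) {
    cqd_error("cqd_validation_error", "empty spectra")
  }
  if (all(bd$value == 0)) {
    cqd_error("cqd_validation_error",
              sprintf("%s band is zero everywhere", band))
  }
  grid <- sort(unique(c(ab$wavelength, bd$wavelength)))
  interp <- function(df) {
    y <- stats::approx(df$wavelength, df$value, xout = grid, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  a <- interp(ab)
  b <- interp(bd)
  supp <- b > 0
  amax <- max(a[supp])
  a_norm <- if (amax > 0) a / amax else a
  b_norm <- b / max(b)
  trap <- function(y) sum(diff(grid) * (utils::head(y, -1) + y[-1]) / 2)
  trap(pmin(a_norm, b_norm)) / trap(b_norm)
}

#' Inner-filter attenuation factor
#'
#' Standard half-path correction for the inner filter effect: transmitted
#' fraction `10^(-(A_ex + A_em)/2)` for absorbances at the excitation
#' (primary IFE) and emission (secondary IFE) wavelengths, assuming a
#' centered detection window.
#'
#' @param a_ex Absorbance at the excitation wavelength (>= 0).
#' @param a_em Absorbance at the emission wavelength (>= 0).
#' @return Attenuation factor in (0, 1].
#' @seealso [ife_correction()] for the inverse multiplier.
#' @export
ife_attenuation <- function(a_ex, a_em) {
  if (any(a_ex < 0) || any(a_em < 0)) {
    cqd_error("cqd_validation_error", "absorbance must be nonnegative")
  }
  10^(-(a_ex + a_em) / 2)
}

#' Inner-filter correction multiplier
#'
#' Inverse of [ife_attenuation()]: multiply an observed intensity by this to
#' recover the intensity free of inner-filter attenuation.
#'
#' @inheritParams ife_attenuation
#' @return Correction multiplier >= 1.
#' @export
ife_correction <- function(a_ex, a_em) 1 / ife_attenuation(a_ex, a_em)

#' Temperature trend of the Stern-Volmer slope
#'
#' Static quenching weakens on heating (ground-state complexes dissociate);
#' dynamic quenching strengthens (faster diffusion).
#'
#' @param k_sv_low_t Slope at the lower temperature (1/M).
#' @param k_sv_high_t Slope at the higher temperature (1/M).
#' @param flat_tol Relative band within which the trend counts as flat
#'   (default 0.05).
#' @return `"static_hint"`, `"dynamic_hint"` or `"flat"`.
#' @export
temperature_trend <- function(k_sv_low_t, k_sv_high_t, flat_tol = 0.05) {
  if (abs(k_sv_high_t - k_sv_low_t) <= flat_tol * abs(k_sv_low_t)) {
    return("flat")
  }
  if (k_sv_high_t < k_sv_low_t) "static_hint" else "dynamic_hint"
}

#' Classify the quenching mechanism
#'
#' Rule cascade, first match wins, with lifetime evidence ranked above all
#' other observables:
#' \enumerate{
#'   \item lifetime ratio tracks I0/I (`"changed"`) -> dynamic;
#'   \item lifetime unchanged, spectral overlap at excitation or emission at
#'     least `theta_overlap`, and dilution does not refute reversibility ->
#'     inner filter effect;
#'   \item lifetime unchanged and a new ground-state absorption band ->
#'     static;
#'   \item lifetime unchanged and the Stern-Volmer slope falls on heating ->
#'     static;
#'   \item upward Stern-Volmer curvature together with conflicting lifetime
#'     evidence (a partial lifetime change) -> mixed;
#'   \item otherwise indeterminate.
#' }
#' The rationale records every rule inspected.  Upward curvature is reported
#' as "mixed" rather than being ascribed to a specific photophysical cause.
#'
#' @param sv An `sv_fit` from [stern_volmer_fit()].
#' @param lifetimes Output of [lifetime_profile()]: `"changed"`,
#'   `"unchanged"`, `"partial"` or `"absent"`.
#' @param overlap_ex,overlap_em Spectral overlap fractions, or `NA`.
#' @param dilution_reversible `TRUE`/`FALSE`/`NA`: did dilution to low
#'   absorbance restore the linear response?  `FALSE` vetoes the IFE call.
#' @param new_absorption_band `TRUE`/`FALSE`/`NA`: new UV-vis band on
#'   quencher addition.
#' @param temp Output of [temperature_trend()], or `NA`.
#' @param theta_overlap Minimum overlap fraction for the IFE rule
#'   (default 0.2).
#' @return A `mechanism_call`: list with `call` (one of `"dynamic"`,
#'   `"static"`, `"ife"`, `"mixed"`, `"indeterminate"`), `evidence_used`,
#'   `rationale`.
#' @export
classify_mechanism <- function(sv, lifetimes,
                               overlap_ex = NA, overlap_em = NA,
                               dilution_reversible = NA,
                               new_absorption_band = NA,
                               temp = NA, theta_overlap = 0.2) {
  stopifnot(inherits(sv, "sv_fit"))
  lifetimes <- match.arg(lifetimes,
                         c("changed", "unchanged", "partial", "absent"))
  rationale <- character()
  note <- function(msg) rationale <<- c(rationale, msg)
  done <- function(call, evidence) {
    structure(list(call = call, evidence_used = evidence,
                   rationale = rationale),
              class = "mechanism_call")
  }

  max_overlap <- suppressWarnings(max(c(overlap_ex, overlap_em), na.rm = TRUE))
  if (!is.finite(max_overlap)) max_overlap <- NA_real_

  if (lifetimes == "changed") {
    note("rule 1 fired: lifetime ratio tracks I0/I -> dynamic")
    return(done("dynamic", "lifetime_changed"))
  }
  note("rule 1 failed: lifetime profile not 'changed'")

  if (lifetimes == "unchanged" && !is.na(max_overlap) &&
      max_overlap >= theta_overlap && !isFALSE(dilution_reversible)) {
    note(sprintf(
      "rule 2 fired: lifetime unchanged, overlap %.2f >= %.2f, dilution not refuted -> ife",
      max_overlap, theta_overlap))
    return(done("ife", c("lifetime_unchanged", "spectral_overlap",
                         if (isTRUE(dilution_reversible)) "dilution_reversible")))
  }
  note("rule 2 failed: ife conditions not met")

  if (lifetimes == "unchanged" && isTRUE(new_absorption_band)) {
    note("rule 3 fired: lifetime unchanged, new ground-state absorption band -> static")
    return(done("static", c("lifetime_unchanged", "new_absorption_band")))
  }
  note("rule 3 failed: no new absorption band with unchanged lifetime")

  if (lifetimes == "unchanged" && identical(temp, "static_hint")) {
    note("rule 4 fired: lifetime unchanged, K_sv falls on heating -> static")
    return(done("static", c("lifetime_unchanged", "temperature_static_hint")))
  }
  note("rule 4 failed: no static temperature trend with unchanged lifetime")

  if (sv$curvature_flag && lifetimes == "partial") {
    note("rule 5 fired: upward curvature with partial lifetime change -> mixed")
    return(done("mixed", c("sv_curvature", "lifetime_partial")))
  }
  note("rule 5 failed: no curvature with conflicting lifetime evidence")

  note("no rule fired -> indeterminate")
  done("indeterminate", character())
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (evidence: %s)\n", x$call,
              paste(x$evidence_used, collapse = ", ")))
  invisible(x)
}
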