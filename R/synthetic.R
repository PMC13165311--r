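# Synthetic data generators: selectivity corpora with known per-ion
# detectability (Bernoulli challenge/detection events, the event model the
# failure-ratio statistic assumes), and titration/lifetime/spectra bundles
# with known quenching mechanism.

#' Specify a synthetic ion panel
#'
#' @param canonical_id Ion identities (`"El(Roman)"` form, e.g. `"Fe(III)"`).
#' @param detect_prob Per-ion probability that a study challenging the ion
#'   reports it as detected.
#' @param challenge_prob Per-ion probability that the ion appears in a
#'   study's challenge panel (default 1).
#' @return An `ion_panel_spec` data.frame.
#' @export
ion_panel_spec <- function(canonical_id, detect_prob, challenge_prob = 1) {
  if (!length(canonical_id)) {
    cqd_error("cqd_parameter_error", "panel must contain at least one ion")
  }
  detect_prob <- rep_len(detect_prob, length(canonical_id))
  challenge_prob <- rep_len(challenge_prob, length(canonical_id))
  if (any(detect_prob < 0 | detect_prob > 1) ||
      any(challenge_prob < 0 | challenge_prob > 1)) {
    cqd_error("cqd_parameter_error", "probabilities must lie in [0, 1]")
  }
  structure(
    data.frame(canonical_id = canonical_id, detect_prob = detect_prob,
               challenge_prob = challenge_prob, stringsAsFactors = FALSE),
    class = c("ion_panel_spec", "data.frame")
  )
}

# "Fe(III)" -> "Fe^3+"
canonical_to_token <- function(canonical_id) {
  m <- regmatches(canonical_id,
                  regexec("^([A-Z][a-z]?)\\((-?)([IVX]+)\\)$", canonical_id))[[1]]
  if (!length(m)) {
    cqd_error("cqd_parameter_error", sprintf(
      "cannot derive a token for panel id '%s'", canonical_id))
  }
  n <- match(m[4], ROMAN)
  sign <- if (m[3] == "-") "-" else "+"
  if (n == 1L) paste0(m[2], "^", sign) else paste0(m[2], "^", n, sign)
}

#' Generate a synthetic selectivity corpus
#'
#' Each synthetic study draws its challenge panel by independent coin flips
#' (`challenge_prob` per ion); each challenged ion is then detected with
#' `detect_prob`, becoming an analyte with a placeholder LOD (log-uniform
#' over `lod_range`), or otherwise listed as non-interfering.  The expected
#' failure ratio of an ion is therefore `1 - detect_prob`.
#'
#' @param panel An [ion_panel_spec()].
#' @param n_studies Number of studies to generate (>= 1).
#' @param seed Integer seed; the generator is deterministic given the seed
#'   and the global RNG state is restored afterwards.
#' @param lod_range Range (uM) for placeholder LODs.
#' @return A `cqd_corpus`.
#' @export
gen_selectivity_corpus <- function(panel, n_studies, seed = 1L,
                                   lod_range = c(1e-3, 10)) {
  if (!inherits(panel, "ion_panel_spec") || !nrow(panel)) {
    cqd_error("cqd_parameter_error", "panel must be a nonempty ion_panel_spec")
  }
  if (n_studies < 1L) {
    cqd_error("cqd_parameter_error", "n_studies must be >= 1")
  }
  tokens <- vapply(panel$canonical_id, canonical_to_token, "")
  studies <- with_seed(seed, {
    lapply(seq_len(n_studies), function(i) {
      challenged <- stats::runif(nrow(panel)) < panel$challenge_prob
      detected <- challenged & (stats::runif(nrow(panel)) < panel$detect_prob)
      lods <- exp(stats::runif(nrow(panel), log(lod_range[1]),
                               log(lod_range[2])))
      analytes <- lapply(which(detected), function(j) {
        list(species = parse_species_token(tokens[j]),
             lod_um = lods[j], lod_verbatim = format(lods[j]))
      })
      non_interfering <- lapply(which(challenged & !detected), function(j) {
        parse_species_token(tokens[j])
      })
      new_sensing_study(
        study_id = sprintf("SYN%04d", i),
        ref = "synthetic",
        precursors = "synthetic precursor",
        synthesis_method = "synthetic",
        conditions = "",
        analytes = analytes,
        non_interfering = non_interfering
      )
    })
  })
  new_corpus(studies, provenance = sprintf("synthetic(seed=%d)", seed))
}

#' Specify a synthetic quenching mechanism
#'
#' Generative forms: dynamic `I0/I = 1 + k_dynamic [Q]` with
#' `tau0/tau = I0/I`; static `I0/I = 1 + k_static [Q]` with unchanged
#' lifetime; combined `(1 + k_dynamic [Q]) (1 + k_static [Q])` with the
#' lifetime following only the dynamic factor; ife attenuation
#' `10^(-(A_ex + A_em)/2)` with absorbance proportional to `[Q]` and
#' unchanged lifetime.
#'
#' @param mechanism `"dynamic"`, `"static"`, `"combined"` or `"ife"`.
#' @param k_dynamic,k_static Quenching constants (1/M, >= 0).
#' @param abs_center,abs_width,abs_peak Analyte absorbance band: center and
#'   width (nm) and the peak absorbance reached at the highest quencher
#'   concentration (ife only).
#' @param tau0 Unquenched lifetime (ns).
#' @param noise_sd Relative (multiplicative Gaussian) intensity noise.
#' @param seed Integer seed.
#' @return A `mechanism_spec`.
#' @export
mechanism_spec <- function(mechanism = c("dynamic", "static", "combined",
                                         "ife"),
                           k_dynamic = 100, k_static = 100,
                           abs_center = 360, abs_width = 30, abs_peak = 1,
                           tau0 = 5, noise_sd = 0, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (k_dynamic < 0 || k_static < 0) {
    cqd_error("cqd_parameter_error", "rate constants must be >= 0")
  }
  if (noise_sd < 0) {
    cqd_error("cqd_parameter_error", "noise_sd must be >= 0")
  }
  structure(
    list(mechanism = mechanism, k_dynamic = k_dynamic, k_static = k_static,
         abs_center = abs_center, abs_width = abs_width, abs_peak = abs_peak,
         tau0 = tau0, noise_sd = noise_sd, seed = seed),
    class = "mechanism_spec"
  )
}

gaussian_band <- function(grid, center, width, height) {
  height * exp(-(grid - center)^2 / (2 * width^2))
}

#' Generate synthetic spectra components
#'
#' Gaussian bands sampled on a wavelength grid.
#'
#' @param peaks List of `c(center, width, height)` triplets (nm, nm,
#'   amplitude); widths must be positive.
#' @param grid Wavelength grid (nm).
#' @return Data.frame with columns `wavelength`, `value` (sum of bands).
#' @export
gen_spectra <- function(peaks, grid = seq(250, 700, by = 1)) {
  if (!length(peaks)) {
    cqd_error("cqd_parameter_error", "need at least one peak")
  }
  vals <- rep(0, length(grid))
  for (p in peaks) {
    if (p[2] <= 0) {
      cqd_error("cqd_parameter_error", "peak width must be positive")
    }
    vals <- vals + gaussian_band(grid, p[1], p[2], p[3])
  }
  data.frame(wavelength = grid, value = vals)
}

#' Generate a synthetic titration
#'
#' Produces a titration dataset (intensities with multiplicative Gaussian
#' noise, lifetimes consistent with the mechanism) together with the
#' auxiliary evidence a complete mechanistic workup would supply: an analyte
#' absorbance spectrum and CQD excitation/emission bands (overlapping for
#' ife, remote for the other mechanisms), a dilution-reversibility flag
#' (`TRUE` for ife, `FALSE` for static, `NA` otherwise), a new-absorption-
#' band flag (`TRUE` for static) and the temperature trend implied by the
#' mechanism.
#'
#' @param spec A [mechanism_spec()].
#' @param q_grid Quencher concentrations (M), ascending, nonnegative; a zero
#'   point is prepended when absent.
#' @return List with elements `titration` (`titration_dataset`), `spectra`
#'   (`spectra_bundle`), `evidence` (list `dilution_reversible`,
#'   `new_absorption_band`, `temp`), and `mechanism` (the generating truth).
#' @export
gen_titration <- function(spec, q_grid = seq(0, 0.02, length.out = 9)) {
  stopifnot(inherits(spec, "mechanism_spec"))
  q <- as.numeric(q_grid)
  if (any(diff(q) <= 0) || any(q < 0)) {
    cqd_error("cqd_validation_error",
              "q_grid must be ascending and nonnegative")
  }
  if (q[1] != 0) q <- c(0, q)
  i0 <- 1000
  tau0 <- spec$tau0
  ex_wl <- 360; em_wl <- 450
  qmax <- max(q)

  spectra_for <- function(abs_center) {
    grid <- seq(250, 700, by = 2)
    spectra_bundle(
      analyte_absorbance = data.frame(
        wavelength = grid,
        value = gaussian_band(grid, abs_center, spec$abs_width,
                              spec$abs_peak)),
      cqd_excitation = data.frame(
        wavelength = grid, value = gaussian_band(grid, ex_wl, 25, 1)),
      cqd_emission = data.frame(
        wavelength = grid, value = gaussian_band(grid, em_wl, 30, 1))
    )
  }

  ratio <- switch(spec$mechanism,
    dynamic  = 1 + spec$k_dynamic * q,
    static   = 1 + spec$k_static * q,
    combined = (1 + spec$k_dynamic * q) * (1 + spec$k_static * q),
    ife = {
      a_ex <- spec$abs_peak * (q / max(qmax, .Machine$double.eps)) *
        gaussian_band(ex_wl, spec$abs_center, spec$abs_width, 1)
      a_em <- spec$abs_peak * (q / max(qmax, .Machine$double.eps)) *
        gaussian_band(em_wl, spec$abs_center, spec$abs_width, 1)
      1 / ife_attenuation(a_ex, a_em)
    })
  tau_ratio <- switch(spec$mechanism,
    dynamic  = 1 + spec$k_dynamic * q,
    static   = rep(1, length(q)),
    combined = 1 + spec$k_dynamic * q,
    ife      = rep(1, length(q)))

  noisy <- with_seed(spec$seed, {
    mult <- if (spec$noise_sd > 0) {
      1 + stats::rnorm(length(q), 0, spec$noise_sd)
    } else {
      rep(1, length(q))
    }
    mult[1] <- 1  # the reference point defines I0
    pmax(mult, 0.05)
  })
  intensity <- (i0 / ratio) * noisy
  lifetimes <- tau0 / tau_ratio

  # ife: absorbance band sits on the excitation band; otherwise remote
  spectra <- spectra_for(if (spec$mechanism == "ife") spec$abs_center
                         else 620)
  evidence <- list(
    dilution_reversible = switch(spec$mechanism, ife = TRUE, static = FALSE,
                                 NA),
    new_absorption_band = spec$mechanism == "static",
    temp = switch(spec$mechanism, dynamic = "dynamic_hint",
                  static = "static_hint", ife = "flat", NA_character_)
  )
  list(
    titration = titration_dataset(q, intensity, i0 = i0,
                                  lifetimes = lifetimes, tau0 = tau0),
    spectra = spectra,
    evidence = evidence,
    mechanism = spec$mechanism
  )
}

#' Full diagnostic workup of a generated bundle
#'
#' Convenience wrapper running [stern_volmer_fit()], [lifetime_profile()],
#' [spectral_overlap_fraction()] and [classify_mechanism()] on the output of
#' [gen_titration()] (or on equivalent observed data).
#'
#' @param bundle List with `titration`, optionally `spectra` and `evidence`.
#' @param theta_overlap Passed to [classify_mechanism()].
#' @return A `mechanism_call`.
#' @export
diagnose_bundle <- function(bundle, theta_overlap = 0.2) {
  sv <- stern_volmer_fit(bundle$titration)
  lt <- lifetime_profile(bundle$titration)
  ov_ex <- ov_em <- NA
  if (!is.null(bundle$spectra)) {
    ov_ex <- spectral_overlap_fraction(bundle$spectra, "excitation")
    ov_em <- spectral_overlap_fraction(bundle$spectra, "emission")
  }
  ev <- bundle$evidence
  if (is.null(ev)) {
    ev <- list(dilution_reversible = NA, new_absorption_band = NA, temp = NA)
  }
  classify_mechanism(sv, lt, overlap_ex = ov_ex, overlap_em = ov_em,
                     dilution_reversible = ev$dilution_reversible,
                     new_absorption_band = ev$new_absorption_band,
                     temp = ev$temp, theta_overlap = theta_overlap)
}
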