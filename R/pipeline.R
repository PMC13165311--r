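# End-to-end pipeline and report generation: the negative-chemical-space run
# (tally -> filter -> rank -> correlate -> plot) and the quenching-mechanism
# diagnosis from titration/spectra files.

#' Build a pipeline run configuration
#'
#' All defaults resolve without user input; the configuration is echoed (with
#' an md5 hash) into the output directory so a run is reproducible from its
#' artifacts.
#'
#' @param corpus Corpus source: a path or the fixture name `"table1"`.
#' @param scope Tally scope, `"ions_only"` or `"all_species"`.
#' @param min_tested Inclusion threshold (strict), default 10.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param n_boot,level,seed Bootstrap settings (0 `n_boot` disables CIs).
#' @param out_dir Output directory.
#' @param panel_file Optional annotation-panel override CSV.
#' @param redox_threshold Redox-activity threshold (V) for profiles.
#' @return A `run_config`.
#' @export
run_config <- function(corpus = "table1",
                       scope = c("ions_only", "all_species"),
                       min_tested = 10L,
                       method = c("pearson", "spearman"),
                       n_boot = 0L, level = 0.95, seed = 1L,
                       out_dir = tempfile("negspace_run_"),
                       panel_file = NULL, redox_threshold = 0) {
  structure(
    list(corpus = corpus, scope = match.arg(scope),
         min_tested = as.integer(min_tested), method = match.arg(method),
         n_boot = as.integer(n_boot), level = level, seed = as.integer(seed),
         out_dir = out_dir, panel_file = panel_file,
         redox_threshold = redox_threshold),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the negative-chemical-space pipeline
#'
#' Loads the corpus, tallies outcomes, applies the inclusion filter, ranks
#' the negative space, computes the potential/failure correlation and writes
#' all artifacts (outcome table CSV, ranked listing CSV, correlation JSON, a
#' potential-versus-failure-ratio plot colored by HSAB class, run log) into
#' the configured output directory.  Re-running with the same configuration
#' reproduces identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects (`table`, `filtered`,
#'   `ranked`, `correlation`) and `artifacts` (file paths).
#' @export
run_negspace_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  corpus <- stage("load_corpus",
                  suppressWarnings(load_corpus(config$corpus)))
  panel <- stage("ion_panel", cqd_ion_panel(config$panel_file))
  tab <- stage("tally", tally_outcomes(corpus, config$scope))
  filt <- stage("filter", filter_min_tested(tab, config$min_tested))
  ranked <- stage("rank", rank_negative_space(filt))
  corr <- stage("correlate",
                correlate_potential_failure(filt, config$method, panel))

  ci <- NULL
  if (config$n_boot > 0L) {
    ci <- stage("bootstrap", {
      rows <- lapply(seq_len(nrow(filt)), function(i) {
        interval <- bootstrap_failure_ci(
          corpus, filt$canonical_id[i], n_boot = config$n_boot,
          level = config$level, seed = config$seed, scope = config$scope)
        data.frame(canonical_id = filt$canonical_id[i],
                   ci_low = interval[["low"]], ci_high = interval[["high"]],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }

  paths <- list(
    outcome_table = file.path(config$out_dir, "outcome_table.csv"),
    ranking = file.path(config$out_dir, "negative_space_ranking.csv"),
    correlation = file.path(config$out_dir, "correlation.json"),
    plot = file.path(config$out_dir, "negspace_plot.pdf"),
    config = file.path(config$out_dir, "config.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  stage("write_outputs", {
    write_outcome_csv(filt, paths$outcome_table, ci = ci)
    write_outcome_csv(ranked, paths$ranking)
    writeLines(jsonlite::toJSON(
      list(config_hash = hash, r = corr$r, n_ions = corr$n_ions,
           method = corr$method, pairs = corr$pairs),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"),
      paths$correlation)
    writeLines(jsonlite::toJSON(c(unclass(config),
                                  list(config_hash = hash)),
                                auto_unbox = TRUE, null = "null",
                                pretty = TRUE), paths$config)
    writeLines(c(
      sprintf("config_hash: %s", hash),
      sprintf("corpus_provenance: %s", corpus$provenance),
      sprintf("n_studies: %d", length(corpus$studies)),
      sprintf("seed: %d", config$seed),
      sprintf("r_version: %s", as.character(getRversion())),
      sprintf("package_version: %s",
              as.character(utils::packageVersion("cqdnegspace")))
    ), paths$log)
  })
  stage("plot", {
    grDevices::pdf(paths$plot, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_negative_space(filt, panel,
                        main = sprintf("Negative chemical space [%s]", hash))
  })
  invisible(list(table = tab, filtered = filt, ranked = ranked,
                 correlation = corr, ci = ci, artifacts = paths))
}

#' Plot failure ratio against reduction potential
#'
#' Scatter of per-ion failure ratio versus standard reduction potential,
#' colored by HSAB class.  Advisory output; the analysis artifacts are the
#' CSV/JSON tables.
#'
#' @param table An `ion_outcome_table` (filtered).
#' @param panel Annotation table.
#' @param main Plot title.
#' @return Invisibly, the plotted data.frame.
#' @export
plot_negative_space <- function(table, panel = cqd_ion_panel(),
                                main = "Negative chemical space") {
  df <- merge(as.data.frame(table), panel, by = "canonical_id")
  cols <- c(hard = "#D55E00", borderline = "#0072B2", soft = "#009E73",
            not_applicable = "grey50")
  graphics::plot(df$e0_volts, df$failure_ratio,
                 pch = 19, col = cols[df$hsab_class],
                 xlab = "Standard reduction potential E0 (V vs SHE)",
                 ylab = "Failure ratio", ylim = c(0, 1.05), main = main)
  graphics::text(df$e0_volts, df$failure_ratio, df$canonical_id,
                 pos = 3, cex = 0.7)
  graphics::legend("bottomleft", legend = names(cols)[1:3],
                   col = cols[1:3], pch = 19, bty = "n")
  invisible(df)
}

#' Read a titration CSV
#'
#' Expected columns: `q_molar`, `intensity`, optional `lifetime_ns`,
#' optional constant `temperature_c`.
#'
#' @param path CSV path.
#' @return A `titration_dataset`.
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) {
    cqd_error("cqd_io_error", sprintf("titration file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("q_molar", "intensity")
  if (!all(need %in% names(df))) {
    cqd_error("cqd_validation_error", sprintf(
      "%s: titration CSV needs columns %s", path,
      paste(need, collapse = ", ")))
  }
  titration_dataset(
    df$q_molar, df$intensity,
    lifetimes = if ("lifetime_ns" %in% names(df)) df$lifetime_ns else NULL,
    temperature_c = if ("temperature_c" %in% names(df))
      df$temperature_c[1] else NULL
  )
}

#' Read a spectra CSV
#'
#' Expected long format: columns `wavelength_nm`, `value`, `series` with
#' series values `absorbance`, `excitation`, `emission`.
#'
#' @param path CSV path.
#' @return A `spectra_bundle`.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) {
    cqd_error("cqd_io_error", sprintf("spectra file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "value", "series")
  if (!all(need %in% names(df))) {
    cqd_error("cqd_validation_error", sprintf(
      "%s: spectra CSV needs columns %s", path, paste(need, collapse = ", ")))
  }
  get_series <- function(name) {
    sub <- df[df$series == name, , drop = FALSE]
    data.frame(wavelength = sub$wavelength_nm, value = sub$value)
  }
  spectra_bundle(get_series("absorbance"), get_series("excitation"),
                 get_series("emission"))
}

#' Diagnose the quenching mechanism from files
#'
#' Reads a titration CSV (and optionally a spectra CSV), runs the
#' Stern-Volmer fit, lifetime profile and overlap assessment, applies the
#' rule cascade and writes a mechanism report JSON with the full evidence
#' trail.
#'
#' @param titration_path Titration CSV (see [read_titration_csv()]).
#' @param spectra_path Optional spectra CSV (see [read_spectra_csv()]).
#' @param out Optional path for the report JSON.
#' @param dilution_reversible,new_absorption_band,temp Extra evidence flags
#'   (see [classify_mechanism()]).
#' @param theta_overlap IFE overlap threshold.
#' @return The report as a list (invisibly written to `out` when given).
#' @export
run_quench_diagnosis <- function(titration_path, spectra_path = NULL,
                                 out = NULL, dilution_reversible = NA,
                                 new_absorption_band = NA, temp = NA,
                                 theta_overlap = 0.2) {
  titr <- read_titration_csv(titration_path)
  sv <- stern_volmer_fit(titr)
  lt <- lifetime_profile(titr)
  ov_ex <- ov_em <- NA
  if (!is.null(spectra_path)) {
    spectra <- read_spectra_csv(spectra_path)
    ov_ex <- spectral_overlap_fraction(spectra, "excitation")
    ov_em <- spectral_overlap_fraction(spectra, "emission")
  }
  call <- classify_mechanism(sv, lt, overlap_ex = ov_ex, overlap_em = ov_em,
                             dilution_reversible = dilution_reversible,
                             new_absorption_band = new_absorption_band,
                             temp = temp, theta_overlap = theta_overlap)
  report <- list(
    call = call$call,
    evidence_used = call$evidence_used,
    rationale = call$rationale,
    k_sv = sv$k_sv,
    intercept = sv$intercept,
    r_squared = sv$r_squared,
    curvature_flag = sv$curvature_flag,
    quad_coeff = sv$quad_coeff,
    lifetime_profile = lt,
    overlap_excitation = ov_ex,
    overlap_emission = ov_em
  )
  if (!is.null(out)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"), out)
  }
  invisible(report)
}
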