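# Ion annotation (HSAB class, standard reduction potential, electronic
# pathway flags), precursor donor chemistry, the potential/failure-ratio
# correlation and the coordination-plus-electronic detectability rule.

#' Built-in ion reference panel
#'
#' Loads the packaged annotation table: HSAB class after the classical
#' Pearson classification, standard reduction potential in V vs SHE with the
#' couple used (the couple to the stable lower aqueous oxidation state where
#' one exists, otherwise reduction to the metal), ground-state paramagnetism
#' of the aqua ion, and a heavy-atom flag (period >= 5).
#'
#' @param file Optional path to an override CSV with the same columns.
#' @return A data.frame with columns `canonical_id`, `hsab_class`,
#'   `e0_volts`, `couple`, `paramagnetic`, `heavy_atom`, `source_note`.
#' @export
cqd_ion_panel <- function(file = NULL) {
  path <- if (is.null(file)) {
    system.file("extdata", "ion_panel.csv", package = "cqdnegspace",
                mustWork = TRUE)
  } else {
    file
  }
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("canonical_id", "hsab_class", "e0_volts", "couple",
            "paramagnetic", "heavy_atom")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    cqd_error("cqd_validation_error", sprintf(
      "ion panel lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  panel$paramagnetic <- as.logical(panel$paramagnetic)
  panel$heavy_atom <- as.logical(panel$heavy_atom)
  panel
}

#' Annotate an ion
#'
#' Looks the ion up in the reference panel; unknown ions error (never a
#' silent default) with the known panel listed.
#'
#' @param canonical_id Ion identity, e.g. `"Fe(III)"`.
#' @param panel Annotation table, by default [cqd_ion_panel()].
#' @return An `annotated_ion`: list with `canonical_id`, `hsab_class`,
#'   `e0_volts`, `couple`, `paramagnetic`, `heavy_atom`.
#' @examples
#' annotate_ion("Hg(II)")$heavy_atom  # TRUE
#' @export
annotate_ion <- function(canonical_id, panel = cqd_ion_panel()) {
  i <- match(canonical_id, panel$canonical_id)
  if (is.na(i)) {
    cqd_error("cqd_lookup_error", sprintf(
      "ion '%s' not in the annotation panel (known: %s)",
      canonical_id, paste(panel$canonical_id, collapse = ", ")))
  }
  structure(
    list(
      canonical_id = panel$canonical_id[i],
      hsab_class = panel$hsab_class[i],
      e0_volts = panel$e0_volts[i],
      couple = panel$couple[i],
      paramagnetic = panel$paramagnetic[i],
      heavy_atom = panel$heavy_atom[i]
    ),
    class = "annotated_ion"
  )
}

# precursor keyword lexicon -> donor classes; matched case-insensitively
donor_lexicon <- function() {
  list(
    oxygen_hard = c(
      "citric acid", "citrate", "tartaric", "salicylic", "succinic",
      "glycolic", "gallic", "ascorbic", "glutamic", "acid",
      "glucose", "fructose", "lactose", "sucrose", "xylan", "cellulose",
      "starch", "cyclodextrin", "polysaccharide", "chitosan",
      "glycol", "glycerol", "borax", "boric",
      "juice", "peel", "leaves", "leaf", "seeds", "seed", "flower",
      "biomass", "powder", "apple", "pepper", "chickpea", "apricot",
      "watermelon", "pomegranate", "barberry", "gelatin", "keratin",
      "fish scale", "walnut", "carbon rod", "rods", "cqd"
    ),
    nitrogen_borderline = c(
      "urea", "carbamide", "thiourea", "melamine", "ammonia", "ammonium",
      "amine", "amino", "diamino", "ethylenediamine", "triethylamine",
      "triethylenetetramine", "phenylenediamine", "polyethyleneimine",
      "pei", "edta", "pyridine", "taurine", "tryptophan", "phenylalanine",
      "arginine", "glutamine", "glutamic", "cysteine", "cystiene",
      "chitosan", "gelatin", "keratin", "amikacin", "acetamide", "amide",
      "aniline", "thiosemicarbazone"
    ),
    sulfur_soft = c(
      "thiourea", "cysteine", "cystiene", "sulfide", "sulphide", "thiol",
      "thio", "taurine", "keratin", "mercapto", "thiosemicarbazone"
    )
  )
}

#' Classify precursor donor chemistry
#'
#' Matches each precursor against an embedded lexicon: carbohydrates, organic
#' acids and oxygen-rich biomass mark hard O-donor surface sites; urea,
#' amines and amino-acid nitrogen mark borderline N-donor sites; thiourea,
#' cysteine and sulfide chemistry mark soft S-donor sites.  Unmatched
#' precursors are recorded as unresolved.
#'
#' @param study A `sensing_study`, or a character vector of precursor names.
#' @return A `donor_profile`: list with `donor_classes` (subset of
#'   `c("oxygen_hard", "nitrogen_borderline", "sulfur_soft")`) and `evidence`
#'   (data.frame `precursor`, `matched_class`).
#' @examples
#' classify_precursor_donors(c("Citric acid", "thiourea"))$donor_classes
#' @export
classify_precursor_donors <- function(study) {
  precursors <- if (inherits(study, "sensing_study")) {
    study$precursors
  } else {
    as.character(study)
  }
  if (!length(precursors)) {
    cqd_error("cqd_parameter_error", "precursor list is empty")
  }
  lex <- donor_lexicon()
  evid <- list()
  classes <- character()
  for (p in precursors) {
    pl <- tolower(p)
    hit <- FALSE
    for (cls in names(lex)) {
      if (any(vapply(lex[[cls]], function(kw) grepl(kw, pl, fixed = TRUE),
                     TRUE))) {
        evid[[length(evid) + 1L]] <- data.frame(
          precursor = p, matched_class = cls, stringsAsFactors = FALSE)
        classes <- union(classes, cls)
        hit <- TRUE
      }
    }
    if (!hit) {
      evid[[length(evid) + 1L]] <- data.frame(
        precursor = p, matched_class = "unresolved",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(classes)) {
    warning("no precursor matched the donor lexicon; donor profile is empty",
            call. = FALSE)
  }
  structure(
    list(donor_classes = classes, evidence = do.call(rbind, evid)),
    class = "donor_profile"
  )
}

#' Correlate reduction potential with failure ratio
#'
#' Joins an (already filtered) outcome table with the annotation panel and
#' correlates the standard reduction potential with the per-ion failure
#' ratio.  Ions absent from the panel are dropped and listed in the result
#' for audit.
#'
#' @param table An `ion_outcome_table`, typically after
#'   [filter_min_tested()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param panel Annotation table, by default [cqd_ion_panel()].
#' @return A `cqd_correlation`: list with `r`, `n_ions`, `method`, `pairs`
#'   (data.frame `canonical_id`, `e0_volts`, `failure_ratio`) and
#'   `dropped` (ids not in the panel).
#' @export
correlate_potential_failure <- function(table,
                                        method = c("pearson", "spearman"),
                                        panel = cqd_ion_panel()) {
  method <- match.arg(method)
  stopifnot(inherits(table, "ion_outcome_table"))
  keep <- table$canonical_id %in% panel$canonical_id
  dropped <- table$canonical_id[!keep]
  df <- merge(as.data.frame(table)[keep, c("canonical_id", "failure_ratio")],
              panel[, c("canonical_id", "e0_volts")], by = "canonical_id")
  df <- df[order(df$canonical_id), c("canonical_id", "e0_volts",
                                     "failure_ratio")]
  if (nrow(df) < 3L) {
    cqd_error("cqd_undefined_value_error",
              "fewer than 3 annotated ions with outcomes")
  }
  if (stats::sd(df$e0_volts) == 0 || stats::sd(df$failure_ratio) == 0) {
    cqd_error("cqd_undefined_value_error",
              "zero variance on one correlation axis")
  }
  r <- stats::cor(df$e0_volts, df$failure_ratio, method = method)
  structure(
    list(r = r, n_ions = nrow(df), method = method, pairs = df,
         dropped = dropped),
    class = "cqd_correlation"
  )
}

#' @export
print.cqd_correlation <- function(x, ...) {
  cat(sprintf("<cqd_correlation> %s r = %.3f over %d ions\n",
              x$method, x$r, x$n_ions))
  invisible(x)
}

#' Detectability profile of an annotated ion
#'
#' Implements the two-stage detectability rule: Lewis acid-base
#' complementarity between the ion's HSAB class and the precursor-derived
#' donor sites is necessary (hard ions need O-donors, borderline ions
#' N-donors, soft ions S-donors), but a measurable fluorescence response
#' additionally requires at least one electronic pathway - redox activity
#' (potential above `redox_threshold`), paramagnetism, or a heavy-atom
#' effect.
#'
#' @param ion An `annotated_ion` from [annotate_ion()].
#' @param donors A `donor_profile` from [classify_precursor_donors()].
#' @param redox_threshold Potential (V vs SHE) above which an ion counts as
#'   redox-active; default 0.
#' @return A `detectability_profile`: list with `coordination_match`,
#'   `electronic_pathways` (subset of `c("redox_active", "paramagnetic",
#'   "heavy_atom")`) and `predicted_responsive`.
#' @export
detectability_profile <- function(ion, donors, redox_threshold = 0) {
  stopifnot(inherits(ion, "annotated_ion"), inherits(donors, "donor_profile"))
  complement <- c(hard = "oxygen_hard", borderline = "nitrogen_borderline",
                  soft = "sulfur_soft")
  match_class <- if (ion$hsab_class %in% names(complement)) {
    complement[[ion$hsab_class]]
  } else {
    NA_character_
  }
  coordination_match <- !is.na(match_class) &&
    match_class %in% donors$donor_classes
  pathways <- character()
  if (!is.na(ion$e0_volts) && ion$e0_volts > redox_threshold) {
    pathways <- c(pathways, "redox_active")
  }
  if (isTRUE(ion$paramagnetic)) pathways <- c(pathways, "paramagnetic")
  if (isTRUE(ion$heavy_atom)) pathways <- c(pathways, "heavy_atom")
  structure(
    list(
      coordination_match = coordination_match,
      electronic_pathways = pathways,
      predicted_responsive = coordination_match && length(pathways) > 0L
    ),
    class = "detectability_profile"
  )
}
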