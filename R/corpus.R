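# Corpus data model and JSON (de)serialization.
#
# A corpus is a list of sensing studies, each one literature record: the CQD
# precursors, synthesis route, detected analytes (with LOD in uM as printed)
# and the list of species explicitly reported as non-interfering.

new_sensing_study <- function(study_id, ref = "", precursors = character(),
                              synthesis_method = "", conditions = "",
                              analytes = list(), non_interfering = list(),
                              note = "") {
  structure(
    list(
      study_id = study_id,
      ref = ref,
      precursors = as.character(precursors),
      synthesis_method = synthesis_method,
      conditions = conditions,
      analytes = analytes,
      non_interfering = non_interfering,
      note = note
    ),
    class = "sensing_study"
  )
}

new_corpus <- function(studies, provenance = "") {
  structure(list(studies = studies, provenance = provenance),
            class = "cqd_corpus")
}

validate_study <- function(study) {
  sid <- study$study_id
  if (!nzchar(sid)) {
    cqd_error("cqd_validation_error", "study with empty study_id")
  }
  an_ids <- vapply(study$analytes, function(a) a$species$canonical_id, "")
  ni_ids <- unlist(lapply(study$non_interfering,
                          function(s) s$canonical_id))
  overlap <- intersect(an_ids, ni_ids)
  if (length(overlap)) {
    cqd_error("cqd_validation_error", sprintf(
      "study '%s': species %s appear both as analyte and non-interfering",
      sid, paste(overlap, collapse = ", ")))
  }
  for (a in study$analytes) {
    if (!is.null(a$lod_um) && !is.na(a$lod_um)) {
      if (a$lod_um <= 0) {
        cqd_error("cqd_validation_error", sprintf(
          "study '%s': non-positive LOD %g for %s",
          sid, a$lod_um, a$species$canonical_id))
      }
      if (a$lod_um >= 1e5) {
        # the corpus transcribes LODs verbatim; implausible magnitudes
        # (such as a printed "10^6" uM) are flagged, not corrected
        warning(sprintf(
          "study '%s': implausible LOD %g uM for %s (transcribed verbatim)",
          sid, a$lod_um, a$species$canonical_id),
          call. = FALSE)
      }
    }
  }
  invisible(study)
}

validate_corpus <- function(corpus) {
  ids <- vapply(corpus$studies, `[[`, "", "study_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    cqd_error("cqd_validation_error",
              sprintf("duplicate study_id: %s", paste(dup, collapse = ", ")))
  }
  for (s in corpus$studies) validate_study(s)
  invisible(corpus)
}

study_from_record <- function(rec, idx) {
  need <- c("id", "analytes", "non_interfering")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    cqd_error("cqd_validation_error", sprintf(
      "corpus record %s ('%s') lacks field(s): %s",
      idx, if (is.null(rec$id)) "?" else rec$id,
      paste(missing, collapse = ", ")))
  }
  parse_or_rethrow <- function(token, field) {
    tryCatch(expand_joint_tokens(token), cqd_parse_error = function(e) {
      cqd_error("cqd_validation_error", sprintf(
        "study '%s', field %s: %s", rec$id, field, conditionMessage(e)))
    })
  }
  analytes <- list()
  for (a in rec$analytes) {
    if (is.null(a$species)) {
      cqd_error("cqd_validation_error", sprintf(
        "study '%s': analyte without species token", rec$id))
    }
    for (sp in parse_or_rethrow(a$species, "analytes")) {
      analytes[[length(analytes) + 1L]] <- list(
        species = sp,
        lod_um = if (is.null(a$lod_um)) NA_real_ else as.numeric(a$lod_um),
        lod_verbatim = if (is.null(a$lod_verbatim)) "" else a$lod_verbatim
      )
    }
  }
  non_interfering <- list()
  for (tok in rec$non_interfering) {
    for (sp in parse_or_rethrow(tok, "non_interfering")) {
      non_interfering[[length(non_interfering) + 1L]] <- sp
    }
  }
  new_sensing_study(
    study_id = rec$id,
    ref = if (is.null(rec$ref)) "" else rec$ref,
    precursors = unlist(rec$precursors),
    synthesis_method = if (is.null(rec$synthesis_method)) "" else
      rec$synthesis_method,
    conditions = if (is.null(rec$conditions)) "" else rec$conditions,
    analytes = analytes,
    non_interfering = non_interfering,
    note = if (is.null(rec$note)) "" else rec$note
  )
}

#' Load a selectivity corpus
#'
#' Reads a corpus from a JSON file in the corpus schema, or resolves the name
#' `"table1"` to the packaged 60-study literature fixture.  All species
#' tokens are parsed and study invariants validated on load.
#'
#' @param source Path to a corpus JSON file, or the fixture name `"table1"`.
#' @return A `cqd_corpus` object (fields `studies`, `provenance`).
#' @examples
#' corp <- load_corpus("table1")
#' length(corp$studies)  # 60
#' @export
load_corpus <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- source
  if (source == "table1") {
    path <- system.file("extdata", "table1.json", package = "cqdnegspace",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    cqd_error("cqd_io_error", sprintf("corpus file not found: %s", path))
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$studies)) {
    cqd_error("cqd_validation_error", "corpus JSON lacks a 'studies' array")
  }
  studies <- lapply(seq_along(doc$studies), function(i) {
    study_from_record(doc$studies[[i]], i)
  })
  corpus <- new_corpus(studies, provenance = source)
  validate_corpus(corpus)
  corpus
}

#' Write a corpus to JSON
#'
#' Serializes in the corpus JSON schema with species tokens rendered in
#' normalized `^n+` notation; `load_corpus()` on the result reproduces the
#' corpus.
#'
#' @param corpus A `cqd_corpus`.
#' @param dest Destination file path.
#' @return `dest`, invisibly.
#' @export
write_corpus <- function(corpus, dest) {
  stopifnot(inherits(corpus, "cqd_corpus"))
  validate_corpus(corpus)
  recs <- lapply(corpus$studies, function(s) {
    list(
      id = s$study_id,
      ref = s$ref,
      precursors = as.list(s$precursors),
      synthesis_method = s$synthesis_method,
      conditions = s$conditions,
      analytes = lapply(s$analytes, function(a) {
        list(
          species = render_species(a$species),
          lod_um = if (is.na(a$lod_um)) NULL else a$lod_um,
          lod_verbatim = a$lod_verbatim
        )
      }),
      non_interfering = lapply(s$non_interfering, render_species),
      note = s$note
    )
  })
  json <- jsonlite::toJSON(list(studies = recs), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  ok <- tryCatch({
    writeLines(json, dest, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    cqd_error("cqd_io_error", sprintf("cannot write corpus to '%s'", dest))
  }
  invisible(dest)
}

#' Flatten a corpus into a per-event table
#'
#' One row per explicit challenge event: a detected analyte or a
#' non-interfering listing.  A species listed more than once in the same
#' study and outcome counts once.
#'
#' @param corpus A `cqd_corpus`.
#' @return A data.frame with columns `study_id`, `species_raw`,
#'   `canonical_id`, `kind`, `outcome` (`"detected"`/`"non_interfering"`) and
#'   `lod_um`.
#' @export
corpus_events <- function(corpus) {
  stopifnot(inherits(corpus, "cqd_corpus"))
  rows <- list()
  for (s in corpus$studies) {
    seen <- character()
    for (a in s$analytes) {
      key <- paste0("D:", a$species$canonical_id)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = s$study_id, species_raw = a$species$raw_token,
        canonical_id = a$species$canonical_id, kind = a$species$kind,
        outcome = "detected", lod_um = a$lod_um,
        stringsAsFactors = FALSE)
    }
    for (sp in s$non_interfering) {
      key <- paste0("N:", sp$canonical_id)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = s$study_id, species_raw = sp$raw_token,
        canonical_id = sp$canonical_id, kind = sp$kind,
        outcome = "non_interfering", lod_um = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(study_id = character(), species_raw = character(),
                      canonical_id = character(), kind = character(),
                      outcome = character(), lod_um = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Export the flat per-event table as CSV
#'
#' @param corpus A `cqd_corpus`.
#' @param dest Destination CSV path.
#' @return `dest`, invisibly.
#' @export
write_events_csv <- function(corpus, dest) {
  ev <- corpus_events(corpus)
  utils::write.csv(
    ev[, c("study_id", "species_raw", "canonical_id", "outcome", "lod_um")],
    dest, row.names = FALSE)
  invisible(dest)
}

corpus_equal <- function(a, b) {
  if (length(a$studies) != length(b$studies)) return(FALSE)
  for (i in seq_along(a$studies)) {
    sa <- a$studies[[i]]; sb <- b$studies[[i]]
    if (!identical(sa$study_id, sb$study_id)) return(FALSE)
    if (!identical(sa$precursors, sb$precursors)) return(FALSE)
    if (length(sa$analytes) != length(sb$analytes)) return(FALSE)
    for (j in seq_along(sa$analytes)) {
      aa <- sa$analytes[[j]]; ab <- sb$analytes[[j]]
      if (!species_equal(aa$species, ab$species)) return(FALSE)
      if (!isTRUE(all.equal(aa$lod_um, ab$lod_um))) return(FALSE)
    }
    if (length(sa$non_interfering) != length(sb$non_interfering)) return(FALSE)
    for (j in seq_along(sa$non_interfering)) {
      if (!species_equal(sa$non_interfering[[j]], sb$non_interfering[[j]])) {
        return(FALSE)
      }
    }
    if (!identical(sa$note, sb$note)) return(FALSE)
  }
  TRUE
}

#' @export
print.cqd_corpus <- function(x, ...) {
  n_an <- sum(vapply(x$studies, function(s) length(s$analytes), 0L))
  n_ni <- sum(vapply(x$studies, function(s) length(s$non_interfering), 0L))
  cat(sprintf("<cqd_corpus> %d studies (%d analyte, %d non-interfering listings); provenance: %s\n",
              length(x$studies), n_an, n_ni, x$provenance))
  invisible(x)
}
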