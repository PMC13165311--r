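# Independent brute-force tally oracle: iterates raw species strings in the
# corpus JSON, canonicalizes them with standalone regexes, and counts
# outcomes.  Deliberately shares no code with the package's parser or type
# system.

ORACLE_ROMAN <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

oracle_canon <- function(tok) {
  t <- gsub("−|–|—", "-", tok)
  t <- gsub("_", "", t)
  t <- gsub("[∙•·]", "", t)
  t <- sub("\\^(.*)\\^", "^\\1", t)
  t <- gsub("\\^\\.", "^", t)
  t <- trimws(gsub("\\s+\\^", "^", t))
  oxo <- c(CR2O7 = "Cr(VI)", CRO4 = "Cr(VI)", MNO4 = "Mn(VII)")
  if (grepl("^(.*?)\\^([0-9]*)([+-])$", t)) {
    m <- regmatches(t, regexec("^(.*?)\\^([0-9]*)([+-])$", t))[[1]]
    core <- m[2]
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    sgn <- m[4]
  } else if (grepl("^(.*?)\\^([+-])([0-9]+)$", t)) {
    m <- regmatches(t, regexec("^(.*?)\\^([+-])([0-9]+)$", t))[[1]]
    core <- m[2]; n <- as.integer(m[4]); sgn <- m[3]
  } else if (grepl("^[A-Za-z0-9()]+[+-]$", t)) {
    core <- sub("[+-]$", "", t)
    n <- 1L
    sgn <- substr(t, nchar(t), nchar(t))
  } else {
    return(list(id = tolower(t), ion = FALSE))
  }
  if (sgn == "-" && toupper(core) %in% names(oxo)) {
    return(list(id = unname(oxo[toupper(core)]), ion = TRUE))
  }
  if (grepl("^[A-Z][a-z]?$", core)) {
    id <- if (sgn == "+") {
      sprintf("%s(%s)", core, ORACLE_ROMAN[n])
    } else {
      sprintf("%s(-%s)", core, ORACLE_ROMAN[n])
    }
    return(list(id = id, ion = TRUE))
  }
  list(id = sprintf("%s(%d%s)", core, n, sgn), ion = TRUE)
}

# path -> named list: id -> c(detected, noninterfering); ions only
oracle_tally <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  det <- new.env(); non <- new.env()
  bump <- function(envir, id) {
    assign(id, (if (exists(id, envir)) get(id, envir) else 0L) + 1L, envir)
  }
  for (s in doc$studies) {
    seen_d <- character(); seen_n <- character()
    for (an in s$analytes) {
      for (part in strsplit(an$species, "/", fixed = TRUE)[[1]]) {
        c0 <- oracle_canon(part)
        if (c0$ion && !(c0$id %in% seen_d)) {
          seen_d <- c(seen_d, c0$id); bump(det, c0$id)
        }
      }
    }
    for (tok in s$non_interfering) {
      for (part in strsplit(tok, "/", fixed = TRUE)[[1]]) {
        c0 <- oracle_canon(part)
        if (c0$ion && !(c0$id %in% seen_n)) {
          seen_n <- c(seen_n, c0$id); bump(non, c0$id)
        }
      }
    }
  }
  ids <- sort(union(ls(det), ls(non)))
  out <- lapply(ids, function(id) {
    c(detected = if (exists(id, det)) get(id, det) else 0L,
      noninterfering = if (exists(id, non)) get(id, non) else 0L)
  })
  names(out) <- ids
  out
}

expect_tally_matches_oracle <- function(corpus) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  suppressWarnings(write_corpus(corpus, tmp))
  oracle <- oracle_tally(tmp)
  tab <- tally_outcomes(corpus, scope = "ions_only")
  expect_setequal(tab$canonical_id, names(oracle))
  for (i in seq_len(nrow(tab))) {
    o <- oracle[[tab$canonical_id[i]]]
    expect_identical(
      c(tab$detected_count[i], tab$noninterfering_count[i]),
      unname(as.integer(o)),
      label = sprintf("counts for %s", tab$canonical_id[i]))
  }
}
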