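# In-code fixtures shared across test files.

load_table1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(load_corpus("table1"))
    cache
  }
})

toy_study <- function(id, detects, challenges) {
  new_study_tokens(id, detects, challenges)
}

# build a study from plain tokens
new_study_tokens <- function(id, detects, challenges, lod = 1) {
  analytes <- lapply(detects, function(tok) {
    list(species = parse_species_token(tok), lod_um = lod,
         lod_verbatim = as.character(lod))
  })
  ni <- lapply(challenges, parse_species_token)
  structure(
    list(study_id = id, ref = id, precursors = "toy", synthesis_method = "",
         conditions = "", analytes = analytes, non_interfering = ni,
         note = ""),
    class = "sensing_study")
}

toy_corpus <- function() {
  structure(
    list(studies = list(
      new_study_tokens("S1", "Fe^3+", c("Zn^2+", "K^+")),
      new_study_tokens("S2", "Zn^2+", "Fe^3+"),
      new_study_tokens("S3", "Fe^3+", "Zn^2+")
    ), provenance = "toy"),
    class = "cqd_corpus")
}

random_corpus <- function(seed, n_studies = 8) {
  panel <- ion_panel_spec(
    c("Fe(III)", "Cu(II)", "Zn(II)", "Hg(II)", "Na(I)", "Cd(II)"),
    detect_prob = c(0.8, 0.5, 0.1, 0.6, 0.0, 0.3),
    challenge_prob = c(0.9, 0.7, 0.8, 0.5, 0.6, 0.4))
  gen_selectivity_corpus(panel, n_studies, seed = seed)
}
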