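# corpus_io: species grammar, fixture integrity, serialization round trips

test_that("parse_species_token handles the table notation", {
  fe <- parse_species_token("Fe^3+")
  expect_equal(fe$element, "Fe")
  expect_equal(fe$charge, 3L)
  expect_equal(fe$kind, "cation")
  expect_equal(fe$canonical_id, "Fe(III)")

  # unicode/subscript markup as extracted from the table
  cr <- parse_species_token("Cr_2_O_7_^2−^")
  expect_equal(cr$element, "Cr")
  expect_equal(cr$oxidation_state, 6L)
  expect_equal(cr$kind, "anion")
  expect_equal(cr$canonical_id, "Cr(VI)")
  # chromate merges with the cationic notation
  expect_equal(parse_species_token("CrO4^2-")$canonical_id, "Cr(VI)")
  expect_equal(parse_species_token("Cr^6+")$canonical_id, "Cr(VI)")

  glu <- parse_species_token("glucose")
  expect_equal(glu$kind, "molecule")
  expect_equal(glu$charge, 0L)
  expect_equal(glu$canonical_id, "glucose")

  # assorted printed variants
  expect_equal(parse_species_token("Fe^+2")$canonical_id, "Fe(II)")
  expect_equal(parse_species_token("Na^1+")$canonical_id, "Na(I)")
  expect_equal(parse_species_token("Mn^+")$canonical_id, "Mn(I)")
  expect_equal(parse_species_token("NH4^+")$canonical_id, "NH4(1+)")
  expect_equal(parse_species_token("Cl^-")$canonical_id, "Cl(-I)")
  expect_equal(parse_species_token("NO3^-")$kind, "anion")
  expect_equal(parse_species_token("O2^.-")$kind, "anion")
  expect_equal(parse_species_token("H2O2")$kind, "molecule")

  expect_error(parse_species_token(""), class = "cqd_parse_error")
  expect_error(parse_species_token("   "), class = "cqd_parse_error")
  expect_error(parse_species_token("Fe^3+-"), class = "cqd_parse_error")
})

test_that("expand_joint_tokens splits redox alternatives", {
  pair <- expand_joint_tokens("Fe^2+/Fe^3+")
  expect_length(pair, 2L)
  expect_equal(vapply(pair, `[[`, "", "canonical_id"),
               c("Fe(II)", "Fe(III)"))
  single <- expand_joint_tokens("K^+")
  expect_length(single, 1L)
  expect_equal(single[[1]]$canonical_id, "K(I)")
  expect_error(expand_joint_tokens("a/b/"), class = "cqd_parse_error")
  expect_error(expand_joint_tokens("a//b"), class = "cqd_parse_error")
})

test_that("canonicalization is idempotent over every fixture token", {
  corp <- load_table1()
  toks <- unique(unlist(lapply(corp$studies, function(s) {
    c(vapply(s$analytes, function(a) a$species$raw_token, ""),
      vapply(s$non_interfering, `[[`, "", "raw_token"))
  })))
  expect_gt(length(toks), 80)
  for (t in toks) {
    sp1 <- parse_species_token(t)
    sp2 <- parse_species_token(render_species(sp1))
    expect_identical(sp1[setdiff(names(sp1), "raw_token")],
                     sp2[setdiff(names(sp2), "raw_token")],
                     label = sprintf("idempotence for '%s'", t))
  }
})

test_that("the packaged table1 fixture has the documented shape", {
  expect_warning(load_corpus("table1"), "implausible LOD")  # the 10^6 entry
  corp <- load_table1()
  expect_s3_class(corp, "cqd_corpus")
  expect_length(corp$studies, 60L)
  expect_identical(anyDuplicated(vapply(corp$studies, `[[`, "", "study_id")),
                   0L)

  ev <- corpus_events(corp)
  ionic <- ev[ev$kind %in% c("cation", "anion"), ]
  expect_true(all(nzchar(ionic$canonical_id)))

  # verbatim LOD bookkeeping: the printed "10^6" and the absent "-----"
  b154 <- Filter(function(s) s$study_id == "B154", corp$studies)[[1]]
  expect_equal(b154$analytes[[1]]$lod_um, 1e6)
  expect_equal(b154$analytes[[1]]$lod_verbatim, "10^6")
  b182 <- Filter(function(s) s$study_id == "B182", corp$studies)[[1]]
  expect_true(is.na(b182$analytes[[1]]$lod_um))

  # the free-text interference cell maps to a note, not species
  b193 <- Filter(function(s) s$study_id == "B193", corp$studies)[[1]]
  expect_length(b193$non_interfering, 0L)
  expect_match(b193$note, "reduced interference")
})

test_that("write/load round trips are the identity", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))

  corp <- load_table1()
  suppressWarnings(write_corpus(corp, tmp))  # B154 fidelity warning
  expect_true(cqdnegspace:::corpus_equal(corp,
                                         suppressWarnings(load_corpus(tmp))))

  empty <- structure(list(studies = list(), provenance = "empty"),
                     class = "cqd_corpus")
  write_corpus(empty, tmp)
  expect_true(cqdnegspace:::corpus_equal(empty, load_corpus(tmp)))

  write_corpus(toy_corpus(), tmp)
  expect_true(cqdnegspace:::corpus_equal(toy_corpus(), load_corpus(tmp)))
})

test_that("round-trip identity holds for random synthetic corpora", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  for (seed in 1:8) {
    corp <- random_corpus(seed)
    write_corpus(corp, tmp)
    back <- load_corpus(tmp)
    expect_true(cqdnegspace:::corpus_equal(corp, back),
                label = sprintf("round trip, seed %d", seed))
  }
})

test_that("schema violations are reported with the offending record", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines('{"studies": [
    {"id": "OK1", "precursors": ["x"], "analytes":
      [{"species": "Fe^3+", "lod_um": 1, "lod_verbatim": "1"}],
     "non_interfering": ["K^+"]},
    {"id": "BAD1", "precursors": ["y"], "non_interfering": ["K^+"]}
  ]}', tmp)
  expect_error(load_corpus(tmp), "BAD1", class = "cqd_validation_error")

  writeLines('{"studies": [
    {"id": "DUP", "analytes": [], "non_interfering": []},
    {"id": "DUP", "analytes": [], "non_interfering": []}
  ]}', tmp)
  expect_error(load_corpus(tmp), "duplicate", class = "cqd_validation_error")

  writeLines('{"studies": [
    {"id": "S1", "analytes":
      [{"species": "Fe^3+", "lod_um": 1, "lod_verbatim": "1"}],
     "non_interfering": ["Fe^3+"]}
  ]}', tmp)
  expect_error(load_corpus(tmp), "both as analyte",
               class = "cqd_validation_error")

  expect_error(load_corpus(tempfile()), class = "cqd_io_error")
})
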