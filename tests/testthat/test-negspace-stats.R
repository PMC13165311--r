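# negspace_stats: tallies, failure ratios, filtering, bootstrap, ranking

test_that("tally_outcomes matches hand enumeration on the toy corpus", {
  empty <- structure(list(studies = list(), provenance = "empty"),
                     class = "cqd_corpus")
  expect_equal(nrow(tally_outcomes(empty)), 0L)

  tab <- tally_outcomes(toy_corpus())
  fe <- tab[tab$canonical_id == "Fe(III)", ]
  zn <- tab[tab$canonical_id == "Zn(II)", ]
  expect_equal(c(fe$detected_count, fe$noninterfering_count), c(2L, 1L))
  expect_equal(c(zn$detected_count, zn$noninterfering_count), c(1L, 2L))
  expect_equal(fe$failure_ratio, 1 / 3)

  # conservation: events in equal events out
  ev <- corpus_events(toy_corpus())
  expect_equal(sum(tab$detected_count), sum(ev$outcome == "detected"))
  expect_equal(sum(tab$noninterfering_count),
               sum(ev$outcome == "non_interfering"))
})

test_that("scope drops molecules but keeps anions", {
  corp <- structure(list(studies = list(
    new_study_tokens("S1", "Fe^3+", c("glucose", "NO3^-", "TC", "Cl^-"))
  ), provenance = "toy"), class = "cqd_corpus")
  ions <- tally_outcomes(corp, "ions_only")
  expect_setequal(ions$canonical_id, c("Fe(III)", "NO3(1-)", "Cl(-I)"))
  all_sp <- tally_outcomes(corp, "all_species")
  expect_setequal(all_sp$canonical_id,
                  c("Fe(III)", "NO3(1-)", "Cl(-I)", "glucose", "tc"))
})

test_that("within-study duplicates count once", {
  corp <- structure(list(studies = list(
    new_study_tokens("S1", "Fe^3+", c("Zn^2+", "Zn^2+"))
  ), provenance = "toy"), class = "cqd_corpus")
  tab <- tally_outcomes(corp)
  expect_equal(tab$noninterfering_count[tab$canonical_id == "Zn(II)"], 1L)
})

test_that("failure_ratio follows the definition and guards zero totals", {
  expect_equal(failure_ratio(list(noninterfering_count = 0L,
                                  tested_total = 5L)), 0)
  expect_equal(failure_ratio(list(noninterfering_count = 1L,
                                  tested_total = 3L)), 1 / 3)
  expect_error(failure_ratio(list(noninterfering_count = 0L,
                                  tested_total = 0L)),
               class = "cqd_undefined_value_error")
  tab <- tally_outcomes(toy_corpus())
  expect_true(all(tab$failure_ratio >= 0 & tab$failure_ratio <= 1))
  expect_equal(tab$failure_ratio,
               1 - tab$detected_count / tab$tested_total)
})

test_that("filter_min_tested is strict and monotone", {
  tab <- tally_outcomes(toy_corpus())
  expect_equal(nrow(filter_min_tested(tab, 100L)), 0L)

  mk <- function(ids, tot) {
    structure(data.frame(
      canonical_id = ids, detected_count = 0L,
      noninterfering_count = as.integer(tot),
      tested_total = as.integer(tot), failure_ratio = 1),
      scope = "ions_only", corpus_provenance = "toy",
      class = c("ion_outcome_table", "data.frame"))
  }
  t2 <- mk(c("A(I)", "B(I)"), c(11L, 10L))
  expect_equal(filter_min_tested(t2, 10L)$canonical_id, "A(I)")

  full <- tally_outcomes(load_table1())
  prev <- full
  for (thr in c(0L, 5L, 10L, 20L, 40L)) {
    cur <- filter_min_tested(full, thr)
    expect_true(all(cur$canonical_id %in% prev$canonical_id))
    prev <- cur
  }
})

test_that("tally_outcomes agrees with the string-level oracle", {
  expect_tally_matches_oracle(load_table1())
  for (seed in 1:10) {
    expect_tally_matches_oracle(random_corpus(seed))
  }
})

test_that("bootstrap_failure_ci is deterministic and degenerate-safe", {
  corp <- random_corpus(3, n_studies = 20)
  ci1 <- bootstrap_failure_ci(corp, "Fe(III)", n_boot = 199, seed = 42)
  ci2 <- bootstrap_failure_ci(corp, "Fe(III)", n_boot = 199, seed = 42)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_failure_ci(corp, "Fe(III)", n_boot = 199, seed = 43)
  expect_false(identical(ci1, ci3))

  # an ion that always fails has a point-mass interval
  ci_na <- bootstrap_failure_ci(corp, "Na(I)", n_boot = 99, seed = 1)
  expect_equal(unname(ci_na), c(1, 1))

  expect_error(bootstrap_failure_ci(corp, "Fe(III)", n_boot = 0),
               class = "cqd_parameter_error")
  expect_error(bootstrap_failure_ci(corp, "Xx(I)"),
               class = "cqd_undefined_value_error")
})

test_that("bootstrap percentile interval has near-nominal coverage", {
  # truth: failure probability 0.5; cluster bootstrap over 40 studies
  panel <- ion_panel_spec("Fe(III)", detect_prob = 0.5, challenge_prob = 1)
  hits <- vapply(1:120, function(rep) {
    corp <- gen_selectivity_corpus(panel, 40, seed = 1000 + rep)
    ci <- bootstrap_failure_ci(corp, "Fe(III)", n_boot = 299, level = 0.95,
                               seed = rep)
    ci[["low"]] <= 0.5 && 0.5 <= ci[["high"]]
  }, TRUE)
  expect_gte(mean(hits), 0.88)
})

test_that("rank_negative_space orders by ratio, total, then id", {
  tab <- structure(data.frame(
    canonical_id = c("B(I)", "A(I)", "C(I)", "D(I)"),
    detected_count = c(0L, 0L, 2L, 0L),
    noninterfering_count = c(12L, 20L, 2L, 12L),
    tested_total = c(12L, 20L, 4L, 12L),
    failure_ratio = c(1, 1, 0.5, 1)),
    scope = "ions_only", corpus_provenance = "toy",
    class = c("ion_outcome_table", "data.frame"))
  ranked <- rank_negative_space(tab)
  expect_equal(ranked$canonical_id, c("A(I)", "B(I)", "D(I)", "C(I)"))

  single <- rank_negative_space(tab[tab$canonical_id == "C(I)", ])
  expect_equal(single$canonical_id, "C(I)")
})
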