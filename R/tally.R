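# Negative-chemical-space statistics: per-ion outcome tallies, failure
# ratios, inclusion filtering, cluster-bootstrap uncertainty and ranking.
#
# Every species reported in a study is an experimental event with two
# outcomes: detected (positive fluorescence response) or non-interfering
# (explicitly tested, no significant response).  For each ion,
#   tested_total  = detected + non-interfering challenges, and
#   failure_ratio = non-interfering / tested_total.

new_outcome_table <- function(df, scope, provenance) {
  rownames(df) <- NULL
  structure(df, scope = scope, corpus_provenance = provenance,
            class = c("ion_outcome_table", "data.frame"))
}

#' Tally detection outcomes per ion
#'
#' Counts, for every canonical species identity in the corpus, how many
#' studies detected it and how many explicitly reported it as
#' non-interfering.  With `scope = "ions_only"` (the default unit of analysis)
#' molecular and neutral-radical challenges are dropped; anions count as
#' ions.
#'
#' @param corpus A `cqd_corpus`.
#' @param scope `"ions_only"` or `"all_species"`.
#' @return An `ion_outcome_table`: a data.frame with columns `canonical_id`,
#'   `detected_count`, `noninterfering_count`, `tested_total` and
#'   `failure_ratio`, sorted by `canonical_id`.
#' @examples
#' tab <- tally_outcomes(load_corpus("table1"))
#' tab[tab$canonical_id == "Fe(III)", ]
#' @export
tally_outcomes <- function(corpus, scope = c("ions_only", "all_species")) {
  scope <- match.arg(scope)
  ev <- corpus_events(corpus)
  if (scope == "ions_only") {
    ev <- ev[ev$kind %in% c("cation", "anion"), , drop = FALSE]
  }
  empty <- new_outcome_table(
    data.frame(canonical_id = character(), detected_count = integer(),
               noninterfering_count = integer(), tested_total = integer(),
               failure_ratio = numeric(), stringsAsFactors = FALSE),
    scope, corpus$provenance)
  if (!nrow(ev)) return(empty)
  ids <- sort(unique(ev$canonical_id))
  det <- vapply(ids, function(id) {
    sum(ev$canonical_id == id & ev$outcome == "detected")
  }, 0L)
  non <- vapply(ids, function(id) {
    sum(ev$canonical_id == id & ev$outcome == "non_interfering")
  }, 0L)
  tot <- det + non
  new_outcome_table(
    data.frame(canonical_id = ids, detected_count = det,
               noninterfering_count = non, tested_total = tot,
               failure_ratio = ifelse(tot > 0, non / tot, NA_real_),
               stringsAsFactors = FALSE),
    scope, corpus$provenance)
}

#' Failure ratio of an outcome entry
#'
#' @param entry One row of an `ion_outcome_table` (or any list/data.frame row
#'   with `noninterfering_count` and `tested_total`).
#' @return The fraction of explicit challenges reported as non-interfering.
#' @export
failure_ratio <- function(entry) {
  tot <- entry$tested_total
  if (is.null(tot) || length(tot) != 1L || is.na(tot) || tot == 0) {
    cqd_error("cqd_undefined_value_error",
              "failure ratio undefined for tested_total = 0")
  }
  entry$noninterfering_count / tot
}

#' Filter ions by number of explicit challenges
#'
#' Retains ions challenged strictly more than `min_tested` times, the
#' inclusion rule used to keep single-case reports out of the negative-space
#' map.
#'
#' @param table An `ion_outcome_table`.
#' @param min_tested Threshold; an entry is kept iff
#'   `tested_total > min_tested`.  Default 10.
#' @return A filtered `ion_outcome_table` (input unmodified).
#' @export
filter_min_tested <- function(table, min_tested = 10L) {
  stopifnot(inherits(table, "ion_outcome_table"), min_tested >= 0)
  new_outcome_table(table[table$tested_total > min_tested, , drop = FALSE],
                    attr(table, "scope"), attr(table, "corpus_provenance"))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cluster-bootstrap confidence interval for a failure ratio
#'
#' Resamples studies (not events) with replacement, respecting within-study
#' dependence between the challenges reported by one article, and returns a
#' percentile interval for the per-ion failure ratio.
#'
#' @param corpus A `cqd_corpus`.
#' @param canonical_id Ion identity, e.g. `"Fe(III)"`.
#' @param n_boot Number of bootstrap resamples (default 1999).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param scope Tally scope, see [tally_outcomes()].
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_failure_ci <- function(corpus, canonical_id, n_boot = 1999L,
                                 level = 0.95, seed = 1L,
                                 scope = c("ions_only", "all_species")) {
  scope <- match.arg(scope)
  if (n_boot < 1L) {
    cqd_error("cqd_parameter_error", "n_boot must be >= 1")
  }
  ev <- corpus_events(corpus)
  if (scope == "ions_only") {
    ev <- ev[ev$kind %in% c("cation", "anion"), , drop = FALSE]
  }
  ev <- ev[ev$canonical_id == canonical_id, , drop = FALSE]
  if (!nrow(ev)) {
    cqd_error("cqd_undefined_value_error", sprintf(
      "ion '%s' has no challenges in this corpus", canonical_id))
  }
  sids <- vapply(corpus$studies, `[[`, "", "study_id")
  det <- vapply(sids, function(s) {
    sum(ev$study_id == s & ev$outcome == "detected")
  }, 0L)
  non <- vapply(sids, function(s) {
    sum(ev$study_id == s & ev$outcome == "non_interfering")
  }, 0L)
  n_stud <- length(sids)
  ratios <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_stud, n_stud, replace = TRUE)
      d <- sum(det[idx]); n <- sum(non[idx])
      if (d + n == 0) NA_real_ else n / (d + n)
    }, 0)
  })
  ratios <- ratios[!is.na(ratios)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(ratios, c(alpha, 1 - alpha), names = FALSE, type = 6)
  c(low = ci[1], high = ci[2])
}

#' Rank the negative chemical space
#'
#' Orders ions by decreasing failure ratio (ties: decreasing `tested_total`,
#' then lexicographic `canonical_id`), so the species most resistant to CQD
#' fluorescence modulation come first.
#'
#' @param table An `ion_outcome_table`, typically already filtered with
#'   [filter_min_tested()].
#' @return The reordered `ion_outcome_table`.
#' @export
rank_negative_space <- function(table) {
  stopifnot(inherits(table, "ion_outcome_table"))
  ord <- order(-table$failure_ratio, -table$tested_total, table$canonical_id)
  new_outcome_table(table[ord, , drop = FALSE],
                    attr(table, "scope"), attr(table, "corpus_provenance"))
}

#' Write an outcome table as CSV
#'
#' @param table An `ion_outcome_table`.
#' @param dest Destination path.
#' @param ci Optional data.frame with columns `canonical_id`, `ci_low`,
#'   `ci_high` to merge in.
#' @return `dest`, invisibly.
#' @export
write_outcome_csv <- function(table, dest, ci = NULL) {
  df <- as.data.frame(table)
  if (!is.null(ci)) {
    df <- merge(df, ci, by = "canonical_id", all.x = TRUE, sort = TRUE)
  }
  utils::write.csv(df, dest, row.names = FALSE)
  invisible(dest)
}
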