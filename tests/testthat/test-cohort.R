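toy_lexicon <- function() {
  tibble::tibble(
    cancer = c("breast", "lung", "melanoma"),
    synonyms = list(c("breast cancer"), c("lung cancer"), c("skin melanoma")),
    incidence_per_100k = c(125, 57, 22),
    survival_5yr_pct = c(90, 18, 92),
    median_age_dx = c(61, 70, 63))
}

ev_row <- function(user, day, text, category) {
  tibble::tibble(user_id = user, day = day, query_text = text,
                 cancers = "", page_id = "p", category = category)
}

test_that("query matching is word-bounded and case-insensitive", {
  lex <- toy_lexicon()
  ev <- dplyr::bind_rows(
    ev_row("u1", 0, "Breast cancer symptoms", "symptoms"),
    ev_row("u2", 1, "cancun hotels", NA))
  out <- match_cancer_queries(ev, lex)
  expect_equal(nrow(out), 1L)
  expect_equal(out$cancers_matched[[1]], "breast")
})

test_that("a printed six-row toy log retains exactly its matching rows", {
  lex <- toy_lexicon()
  ev <- dplyr::bind_rows(
    ev_row("u1", 0, "lung cancer treatment", "treatment"),
    ev_row("u1", 1, "cheap flights", NA),
    ev_row("u2", 2, "best pizza near me", NA),
    ev_row("u2", 3, "skin melanoma pictures", "other"),
    ev_row("u3", 4, "lungfish aquarium", NA),
    ev_row("u3", 5, "breastfeeding tips", NA))
  out <- match_cancer_queries(ev, lex)
  expect_equal(nrow(out), 2L)
  expect_setequal(unlist(out$cancers_matched), c("lung", "melanoma"))
  expect_error(match_cancer_queries(ev, lex[0, ]), "non-empty")
})

test_that("severity partition uses a strict below-median rule", {
  mk <- function(surv) {
    tibble::tibble(cancer = paste0("c", seq_along(surv)),
                   synonyms = replicate(length(surv), character(0)),
                   incidence_per_100k = 1, survival_5yr_pct = surv,
                   median_age_dx = 60)
  }
  expect_equal(as.character(partition_severity(mk(c(10, 20, 60, 80)))$severity),
               c("aggressive", "aggressive", "indolent", "indolent"))
  expect_equal(as.character(partition_severity(mk(c(50, 50, 50)))$severity),
               rep("indolent", 3))
  expect_equal(as.character(partition_severity(mk(c(10, 50, 90)))$severity),
               c("aggressive", "indolent", "indolent"))
  expect_error(partition_severity(mk(c(10, NA, 30))), "missing")
  expect_error(partition_severity(mk(50)), "at least two")
})

cohort_events <- function() {
  lex <- toy_lexicon()
  ev <- dplyr::bind_rows(
    # u_small: 4 categorized visits -> page gate
    purrr::map_dfr(1:4, function(i) {
      ev_row("u_small", i, "breast cancer symptoms", "symptoms")
    }),
    # u_mono: 6 visits, single category -> category gate
    purrr::map_dfr(1:6, function(i) {
      ev_row("u_mono", i, "lung cancer prognosis", "information")
    }),
    # u_in: 3 breast + 2 lung visits over days 3..12, two categories
    ev_row("u_in", 3, "breast cancer symptoms", "symptoms"),
    ev_row("u_in", 5, "breast cancer treatment", "treatment"),
    ev_row("u_in", 7, "lung cancer treatment", "treatment"),
    ev_row("u_in", 9, "lung cancer symptoms", "symptoms"),
    ev_row("u_in", 12, "breast cancer stages", "information"),
    # u_na: 5 visits but one uncategorized -> page gate (4 counted)
    ev_row("u_na", 1, "skin melanoma pictures", "other"),
    ev_row("u_na", 2, "skin melanoma forum", "social_media"),
    ev_row("u_na", 3, "skin melanoma care", NA),
    ev_row("u_na", 4, "skin melanoma news", "other"),
    ev_row("u_na", 5, "skin melanoma signs", "symptoms"))
  match_cancer_queries(ev, lex)
}

test_that("inclusion gates, dominant disease and span follow the rules", {
  lex <- partition_severity(toy_lexicon())
  res <- build_profiles(cohort_events(), lex)
  expect_equal(res$exclusions$n_users, 4L)
  expect_equal(res$exclusions$excluded_page_gate, 2L)    # u_small, u_na
  expect_equal(res$exclusions$excluded_category_gate, 1L) # u_mono
  expect_equal(res$exclusions$n_included, 1L)
  p <- res$profiles
  expect_equal(p$user_id, "u_in")
  expect_equal(p$dominant_disease, "breast")   # 3 breast vs 2 lung
  expect_equal(p$severity, "indolent")
  expect_equal(p$n_pages, 5L)
  expect_equal(p$n_categories, 3L)
  expect_equal(p$search_period_days, 10)       # days 3..12 inclusive
  expect_equal(p$category_sequence[[1]],
               c("symptoms", "treatment", "treatment", "symptoms",
                 "information"))
})

test_that("the two gates commute", {
  lex <- partition_severity(toy_lexicon())
  ev <- cohort_events()
  joint <- build_profiles(ev, lex)$profiles$user_id
  # category gate first (min_pages = 1), then page gate on the survivors
  first_cat <- build_profiles(ev, lex, cohort_config(1, 2))$profiles
  reversed <- first_cat$user_id[first_cat$n_pages >= 5]
  expect_setequal(joint, reversed)
})

test_that("dominant disease ignores within-day event order", {
  lex <- partition_severity(toy_lexicon())
  ev <- cohort_events()
  same_day <- ev[sample(nrow(ev)), ]
  same_day <- dplyr::arrange(same_day, user_id, day)
  res <- build_profiles(same_day, lex)
  expect_equal(res$profiles$dominant_disease, "breast")
  expect_setequal(res$profiles$user_id, "u_in")
})

test_that("dominant-disease ties break alphabetically", {
  lex <- partition_severity(toy_lexicon())
  ev <- match_cancer_queries(dplyr::bind_rows(
    ev_row("u", 1, "lung cancer risk", "causes"),
    ev_row("u", 2, "breast cancer risk", "causes"),
    ev_row("u", 3, "lung cancer stages", "information"),
    ev_row("u", 4, "breast cancer stages", "information"),
    ev_row("u", 5, "breast cancer forum", "social_media"),
    ev_row("u", 6, "lung cancer forum", "social_media")), lex)
  res <- build_profiles(ev, lex)
  expect_equal(res$profiles$dominant_disease, "breast")
})

test_that("empty input yields empty profiles and a zero tally", {
  lex <- partition_severity(toy_lexicon())
  ev <- match_cancer_queries(ev_row("u", 0, "nothing relevant", NA), lex)
  res <- build_profiles(ev, lex)
  expect_equal(nrow(res$profiles), 0L)
  expect_equal(res$exclusions$n_included, 0L)
})
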