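mk_profile <- function(user_id, first_day, last_day, n_pages = 10,
                       dominant = "breast", severity = "indolent",
                       cancers = dominant,
                       sequence = rep("information", n_pages)) {
  tibble::tibble(
    user_id = user_id, dominant_disease = dominant, severity = severity,
    category_sequence = list(sequence), cancers_all = list(cancers),
    n_pages = n_pages, n_categories = length(unique(sequence)),
    first_day = first_day, last_day = last_day,
    search_period_days = last_day - first_day + 1)
}

test_that("pair construction orders searchers and computes lags", {
  profiles <- dplyr::bind_rows(
    mk_profile("a", 3, 10),
    mk_profile("b", 12, 20, dominant = "lung", severity = "aggressive",
               cancers = c("lung", "breast")))
  edges <- tibble::tibble(user_a = "b", user_b = "a")  # orientation reversed
  pairs <- find_pairs(profiles, edges)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$first_searcher, "a")
  expect_equal(pairs$lag_days, 9)
  expect_equal(pairs$severity, "indolent")     # first searcher's severity
  expect_true(pairs$overlap)                   # both queried breast
  expect_equal(pairs$first_duration_days, 8)
  expect_equal(pairs$second_duration_days, 9)
})

test_that("edges touching non-cohort users yield no pair", {
  profiles <- mk_profile("a", 0, 5)
  edges <- tibble::tibble(user_a = "a", user_b = "stranger")
  expect_equal(nrow(find_pairs(profiles, edges)), 0L)
})

test_that("a five-edge fixture yields its three qualifying pairs", {
  profiles <- dplyr::bind_rows(
    mk_profile("a", 0, 4), mk_profile("b", 2, 9),
    mk_profile("c", 5, 6, dominant = "lung", severity = "aggressive"),
    mk_profile("d", 1, 30))
  edges <- tibble::tibble(
    user_a = c("a", "a", "b", "x", "c"),
    user_b = c("b", "c", "d", "y", "z"))
  pairs <- find_pairs(profiles, edges)
  expect_equal(nrow(pairs), 3L)
  expect_setequal(paste(pairs$first_searcher, pairs$second_searcher),
                  c("a b", "a c", "d b"))
  expect_equal(sort(pairs$lag_days), c(1, 2, 5))
  # shuffled edge order and flipped orientation give identical pairs
  flipped <- tibble::tibble(user_a = edges$user_b, user_b = edges$user_a)
  expect_identical(pairs, find_pairs(profiles, flipped[sample(5), ]))
})

test_that("the window-overlap restriction drops disjoint episodes", {
  profiles <- dplyr::bind_rows(
    mk_profile("a", 0, 4),
    mk_profile("b", 10, 20))
  edges <- tibble::tibble(user_a = "a", user_b = "b")
  expect_equal(nrow(find_pairs(profiles, edges)), 1L)
  expect_equal(nrow(find_pairs(profiles, edges,
                               require_window_overlap = TRUE)), 0L)
  touching <- dplyr::bind_rows(mk_profile("a", 0, 10),
                               mk_profile("b", 10, 20))
  expect_equal(nrow(find_pairs(touching, edges,
                               require_window_overlap = TRUE)), 1L)
})

test_that("ties on first day go to the searcher with more pages", {
  profiles <- dplyr::bind_rows(
    mk_profile("a", 5, 10, n_pages = 6),
    mk_profile("b", 5, 12, n_pages = 9))
  pairs <- find_pairs(profiles, tibble::tibble(user_a = "a", user_b = "b"))
  expect_equal(pairs$first_searcher, "b")
  expect_equal(pairs$lag_days, 0)
})

test_that("the permutation null is calibrated on null data", {
  set.seed(55)
  g <- simulate_contact_graph(2000, -0.99, 6, seed = 55)
  included <- sample(g$node_ids, 300)
  profiles <- purrr::map_dfr(included, function(u) mk_profile(u, 0, 9))
  pairs <- find_pairs(profiles, g$edges)
  enr <- enrichment_vs_chance(pairs, profiles, g$edges,
                              n_permutations = 1000, seed = 56)
  expect_lt(abs(enr$fold - 1), 0.2)
  expect_gt(enr$p_value, 0.01)
})

test_that("enrichment guards its inputs", {
  profiles <- mk_profile("a", 0, 5)
  empty_edges <- tibble::tibble(user_a = character(0), user_b = character(0))
  expect_error(enrichment_vs_chance(0, profiles, empty_edges), "no contact")
  edges <- tibble::tibble(user_a = "a", user_b = "b")
  expect_error(enrichment_vs_chance(0, profiles, edges,
                                    n_permutations = 10), "at least 100")
})

test_that("overlap statistics cover both extremes", {
  profiles <- dplyr::bind_rows(
    mk_profile("a", 0, 5, cancers = "breast"),
    mk_profile("b", 1, 6, cancers = "breast"))
  pairs <- find_pairs(profiles, tibble::tibble(user_a = "a", user_b = "b"))
  res <- overlap_stats(pairs, profiles, seed = 1)
  expect_equal(res$observed_overlap, 1)
  expect_equal(res$random_overlap, 1)

  unique_prof <- purrr::map_dfr(1:6, function(i) {
    mk_profile(paste0("u", i), i, i + 5,
               dominant = default_lexicon()$cancer[i],
               cancers = default_lexicon()$cancer[i])
  })
  res2 <- overlap_stats(find_pairs(unique_prof,
                                   tibble::tibble(user_a = "u1",
                                                  user_b = "u2")),
                        unique_prof, seed = 2)
  expect_equal(res2$observed_overlap, 0)
  expect_equal(res2$random_overlap, 0)
})

test_that("degenerate contrasts give null p-values", {
  pairs <- tibble::tibble(
    first_searcher = c("a", "c", "e", "g"),
    second_searcher = c("b", "d", "f", "h"),
    lag_days = 7,
    first_duration_days = c(4, 4, 9, 9),
    second_duration_days = c(4, 4, 9, 9),
    severity = c("aggressive", "aggressive", "indolent", "indolent"),
    overlap = TRUE, first_n_diseases = 1L, second_n_diseases = 1L)
  res <- lag_duration_contrasts(pairs)
  tests <- res$tests
  lag_p <- tests$p.value[grepl("lag", tests$test)]
  expect_equal(lag_p, 1)
  dur_p <- tests$p.value[grepl("sign test", tests$test)]
  expect_true(all(dur_p == 1))
  expect_true(tests$skipped[grepl("signed-rank", tests$test)])
})

test_that("small strata are skipped with a flag", {
  pairs <- tibble::tibble(
    first_searcher = "a", second_searcher = "b", lag_days = 3,
    first_duration_days = 10, second_duration_days = 5,
    severity = "indolent", overlap = TRUE,
    first_n_diseases = 2L, second_n_diseases = 1L)
  res <- lag_duration_contrasts(pairs)
  expect_true(all(res$tests$skipped[res$tests$stratum == "aggressive"]))
  expect_true(res$tests$skipped[grepl("lag", res$tests$test)])
})

test_that("category preference ratios recover a constructed contrast", {
  # first searchers view treatment twice as often as second searchers
  profiles <- dplyr::bind_rows(
    purrr::map_dfr(1:20, function(i) {
      mk_profile(sprintf("f%02d", i), 0, 5,
                 sequence = c(rep("treatment", 4), rep("information", 6)))
    }),
    purrr::map_dfr(1:20, function(i) {
      mk_profile(sprintf("s%02d", i), 3, 9,
                 sequence = c(rep("treatment", 2), rep("information", 8)))
    }))
  edges <- tibble::tibble(user_a = sprintf("f%02d", 1:20),
                          user_b = sprintf("s%02d", 1:20))
  pairs <- find_pairs(profiles, edges)
  expect_true(all(pairs$first_searcher == sprintf("f%02d", 1:20)))
  pref <- category_preference_contrast(pairs, profiles)
  expect_equal(pref$ratio_first_vs_second[pref$category == "treatment"], 2)
  expect_equal(pref$pct_difference[pref$category == "treatment"], 100)
  expect_true(pref$undefined[pref$category == "pets"])
  expect_true(is.na(pref$ratio_first_vs_second[pref$category == "pets"]))

  # identical viewing profiles in both roles: all defined ratios are 1
  sym_profiles <- dplyr::bind_rows(
    mk_profile("p", 0, 5, sequence = c("causes", "symptoms")),
    mk_profile("q", 2, 8, sequence = c("causes", "symptoms")))
  sym_pairs <- find_pairs(sym_profiles,
                          tibble::tibble(user_a = "p", user_b = "q"))
  sym <- category_preference_contrast(sym_pairs, sym_profiles)
  defined <- sym[!sym$undefined, ]
  expect_true(all(defined$ratio_first_vs_second == 1))
})
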