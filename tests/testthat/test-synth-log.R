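test_that("config validation enforces the documented invariants", {
  expect_error(synthetic_config(pageview_exponent = 0.5), "negative")
  expect_error(synthetic_config(mean_search_days = -1), "day parameters")
  expect_error(synthetic_config(overlap_prob = 1.4), "probabilities")
  expect_error(synthetic_config(n_users = 1), "at least 2")
  expect_error(synthetic_config(degree_exponent = -0.9, xmax = Inf),
               "non-integrable")
})

test_that("an empty configuration gives empty tables with valid headers", {
  sim <- simulate_log(synthetic_config(n_users = 0, seed = 1))
  expect_equal(nrow(sim$events), 0L)
  expect_named(sim$events, c("user_id", "day", "query_text", "cancers",
                             "page_id", "category"))
  expect_equal(nrow(sim$contacts), 0L)
  expect_gt(nrow(sim$lexicon), 0L)
})

test_that("the same configuration and seed reproduce identical outputs", {
  cfg <- synthetic_config(n_users = 300, seed = 99)
  a <- simulate_log(cfg)
  b <- simulate_log(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$contacts, b$contacts)
  expect_identical(a$truth$included, b$truth$included)
  # a different seed changes the draw
  c <- simulate_log(synthetic_config(n_users = 300, seed = 100))
  expect_false(identical(a$events, c$events))
})

test_that("event days stay inside the study window and spans match windows", {
  sim <- simulate_log(synthetic_config(n_users = 400, seed = 3))
  expect_true(all(sim$events$day >= 0 & sim$events$day < 92))
  roles <- sim$truth$roles
  spans <- sim$events |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(span = max(.data$day) - min(.data$day) + 1, n = dplyr::n())
  joined <- dplyr::inner_join(spans[spans$n >= 2, ], roles,
                              by = "user_id")
  expect_equal(joined$span, joined$window_days)
})

test_that("pooled sequence emissions converge to the stationary mixture", {
  # long chains so the initial-distribution transient washes out
  truth <- hmm_truth_indolent()
  seqs <- simulate_hmm_sequences(truth, 40, 500, seed = 8)
  emp <- tabulate(match(unlist(seqs), page_categories()), nbins = 10) /
    length(unlist(seqs))
  # stationary mixture computed independently by power iteration
  pi0 <- rep(1 / 5, 5)
  for (i in 1:500) pi0 <- as.numeric(pi0 %*% truth$transition)
  expected <- as.numeric(pi0 %*% truth$emission)
  expect_true(all(abs(emp - expected) < 0.02))
})

test_that("the contact graph hits its degree median and slope", {
  g <- simulate_contact_graph(20000, -0.99, 6, seed = 13)
  expect_equal(distribution_median(g$degrees), 6)
  fit <- fit_loglog_slope(g$degrees)
  expect_lt(abs(fit$slope - (-0.99)), 0.1)
  expect_equal(nrow(dedupe_edges(g$edges)), nrow(g$edges))
})

test_that("planted pairs reach the analytic enrichment target", {
  sim <- simulate_log(synthetic_config(n_users = 4000, seed = 17))
  matched <- match_cancer_queries(sim$events, sim$lexicon)
  prof <- build_profiles(matched, sim$lexicon)$profiles
  pairs <- find_pairs(prof, sim$contacts)
  expect_equal(nrow(pairs), sim$truth$target_pairs)
  expect_gt(sim$truth$target_pairs,
            2 * sim$truth$expected_chance_pairs)
  # planted disease overlap lands near the configured probability
  expect_lt(abs(mean(pairs$overlap) - 0.56), 0.1)
})

test_that("multi-category fraction among threshold passers is calibrated", {
  sim <- simulate_log(synthetic_config(n_users = 10000, seed = 23))
  matched <- match_cancer_queries(sim$events, sim$lexicon)
  counts <- matched |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n = dplyr::n(),
                     k = dplyr::n_distinct(.data$category))
  passing <- counts[counts$n >= 5, ]
  frac <- mean(passing$k >= 2)
  expect_lt(abs(frac - 0.415), 0.03)
})

test_that("configurations round-trip through JSON with a seed override", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- synthetic_config(n_users = 500, pair_enrichment = 4, seed = 9)
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_identical(simulate_log(back)$events, simulate_log(cfg)$events)
  expect_equal(back$pair_enrichment, 4)
  expect_equal(read_synthetic_config(path, seed = 77)$seed, 77L)
})

test_that("perfect labelers are unanimous and engineered pages ambiguous", {
  truth <- tibble::tibble(page_id = sprintf("p%d", 1:50),
                          category = sample(page_categories(), 50,
                                            replace = TRUE))
  lab <- simulate_labelers(truth, accuracy = 1, ambiguous_fraction = 0,
                           seed = 1)
  agg <- aggregate_labels(lab)
  expect_true(all(!agg$ambiguous))
  expect_equal(agg$decided, truth$category)
  expect_true(all(agg$max_votes == 5))

  lab2 <- simulate_labelers(truth, accuracy = 1, ambiguous_fraction = 1,
                            seed = 2)
  agg2 <- aggregate_labels(lab2)
  expect_true(all(agg2$ambiguous))
})

test_that("majority rate at accuracy 0.8 matches the exact multinomial", {
  truth <- tibble::tibble(page_id = sprintf("p%04d", 1:1000),
                          category = sample(page_categories(), 1000,
                                            replace = TRUE))
  lab <- simulate_labelers(truth, accuracy = 0.8, ambiguous_fraction = 0,
                           seed = 5)
  agg <- aggregate_labels(lab)
  expect_lt(abs(mean(!agg$ambiguous) - exact_majority_prob(0.8)), 0.05)
})

test_that("labeler arguments are validated", {
  truth <- tibble::tibble(page_id = "p1", category = "causes")
  expect_error(simulate_labelers(truth, accuracy = 1.2), "accuracy")
  expect_error(simulate_labelers(truth, n_labelers = 0), "n_labelers")
})
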