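cats <- page_categories()

test_that("category_hmm validates its stochastic structure", {
  expect_s3_class(hmm_truth_aggressive(), "category_hmm")
  expect_error(category_hmm(c(0.5, 0.6), diag(2), matrix(0.1, 2, 10)),
               "summing to 1")
  bad_trans <- rbind(c(0.9, 0.2), c(0.5, 0.5))
  expect_error(category_hmm(c(0.5, 0.5), bad_trans, matrix(0.1, 2, 10)),
               "sum to 1")
})

test_that("a single-state fit reduces to pooled category frequencies", {
  seqs <- list(c("causes", "causes", "symptoms"),
               c("symptoms", "other"),
               c("causes", "information"))
  fit <- train_hmm(seqs, K = 1, seed = 1)
  pooled <- tabulate(match(unlist(seqs), cats), nbins = 10)
  # EM fixed point with the Dirichlet pseudo-count of 1e-3 per symbol
  expected <- (pooled + 1e-3) / (sum(pooled) + 10e-3)
  expect_equal(as.numeric(fit$emission[1, ]), expected, tolerance = 1e-9)
})

test_that("alternating sequences force near-deterministic cross transitions", {
  seqs <- replicate(40, rep(c("symptoms", "treatment"), 10),
                    simplify = FALSE)
  fit <- train_hmm(seqs, K = 2, seed = 3)
  off <- c(fit$transition[1, 2], fit$transition[2, 1])
  expect_true(all(off > 0.95))
})

test_that("parameters of a 3-state model are recovered from its samples", {
  truth <- category_hmm(
    c(0.6, 0.3, 0.1),
    rbind(c(0.8, 0.15, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.15, 0.8)),
    rbind(c(0.7, 0.2, rep(0.1 / 8, 8)),
          c(0.05, 0.05, 0.7, 0.1, rep(0.1 / 6, 6)),
          c(rep(0.04, 5), 0.5, 0.2, rep(0.1 / 3, 3))))
  seqs <- simulate_hmm_sequences(truth, 1000, 20, seed = 9)
  best <- NULL
  for (r in 1:4) {
    fit <- train_hmm(seqs, K = 3, seed = 100 + r)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # align states greedily by emission similarity, then compare rows
  perm <- apply(best$emission %*% t(truth$emission), 2, which.max)
  expect_equal(sort(perm), 1:3)
  aligned <- permute_hmm(best, perm)
  for (i in 1:3) {
    expect_lt(tv_dist(aligned$emission[i, ], truth$emission[i, ]), 0.1)
    expect_lt(tv_dist(aligned$transition[i, ], truth$transition[i, ]), 0.1)
  }
})

test_that("EM log-likelihood is monotone non-decreasing", {
  seqs <- simulate_hmm_sequences(hmm_truth_indolent(), 120, 12, seed = 5)
  for (K in c(2, 4, 6)) {
    fit <- train_hmm(seqs, K, seed = K)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("one-step predictions match exhaustive path enumeration", {
  set.seed(77)
  for (K in 1:3) {
    model <- random_category_hmm(K)
    for (plen in 0:4) {
      prefix <- sample(cats, plen, replace = TRUE)
      expect_equal(predict_next_category(model, prefix),
                   brute_force_predict(model, prefix), tolerance = 1e-12)
    }
  }
})

test_that("degenerate prediction cases follow symmetry", {
  det <- category_hmm(1, matrix(1, 1, 1),
                      matrix(c(0, 0, 0, 1, rep(0, 6)), 1, 10))
  p <- predict_next_category(det, c("information", "information"))
  expect_equal(unname(p["information"]), 1, tolerance = 1e-12)

  unif <- category_hmm(c(0.3, 0.7),
                       rbind(c(0.2, 0.8), c(0.6, 0.4)),
                       matrix(0.1, 2, 10))
  p <- predict_next_category(unif, c("causes", "pets", "other"))
  expect_equal(unname(p), rep(0.1, 10), tolerance = 1e-12)
  expect_error(predict_next_category(unif, c("causes", "bogus")),
               "unknown category")
})

test_that("holdout error is 0 for a deterministic cycle and ~0.9 for noise", {
  cyc_emis <- matrix(0, 3, 10)
  cyc_emis[1, 1] <- 1; cyc_emis[2, 2] <- 1; cyc_emis[3, 3] <- 1
  cyc <- category_hmm(c(1, 0, 0),
                      rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)), cyc_emis)
  seqs <- replicate(10, cats[rep(1:3, 5)], simplify = FALSE)
  expect_equal(holdout_prediction_error(cyc, seqs)$error, 0)

  unif <- category_hmm(1, matrix(1, 1, 1), matrix(0.1, 1, 10))
  set.seed(12)
  noise <- replicate(60, sample(cats, 25, replace = TRUE), simplify = FALSE)
  err <- holdout_prediction_error(unif, noise)$error
  expect_lt(abs(err - 0.9), 0.03)
})

test_that("the generating model dominates a mismatched model on its samples", {
  truth <- hmm_truth_aggressive()
  mismatched <- hmm_truth_indolent()
  seqs <- simulate_hmm_sequences(truth, 500, 15, seed = 21)
  e_truth <- holdout_prediction_error(truth, seqs)$error
  e_wrong <- holdout_prediction_error(mismatched, seqs)$error
  expect_lt(e_truth, e_wrong)
})

test_that("state relabeling leaves predictions and signatures unchanged", {
  model <- hmm_truth_indolent()
  perm <- c(3, 1, 5, 2, 4)
  permuted <- permute_hmm(model, perm)
  seqs <- simulate_hmm_sequences(model, 40, 10, seed = 31)
  expect_equal(holdout_prediction_error(model, seqs)$error,
               holdout_prediction_error(permuted, seqs)$error)
  sig_a <- signature_states(model)
  sig_b <- signature_states(permuted)
  # same signature content per matched state
  for (s in 1:5) {
    a <- sig_a[sig_a$state == perm[s], c("category", "probability")]
    b <- sig_b[sig_b$state == s, c("category", "probability")]
    expect_equal(a, b)
  }
})

test_that("select_num_states handles trivial and analytic cases", {
  seqs <- simulate_hmm_sequences(hmm_truth_aggressive(), 40, 8, seed = 2)
  sel <- select_num_states(seqs, 1, n_restarts = 2, seed = 2)
  expect_equal(sel$best_K, 1L)

  alt <- replicate(60, rep(c("symptoms", "treatment"), 8), simplify = FALSE)
  sel <- select_num_states(alt, 1:3, n_restarts = 3, seed = 4)
  expect_equal(sel$best_K, 2L)
  res <- sel$results
  # one state cannot beat 50% argmax error on alternating data; two can
  expect_gt(res$error[res$K == 1], 0.45)
  expect_lt(res$error[res$K == 2], 0.05)
})

test_that("infeasible candidates are flagged, not dropped", {
  seqs <- replicate(8, c("causes", "other"), simplify = FALSE)
  sel <- select_num_states(seqs, c(1, 500), n_restarts = 1, seed = 1)
  res <- sel$results
  expect_false(res$feasible[res$K == 500])
  expect_true(res$feasible[res$K == 1])
  expect_equal(sel$best_K, 1L)
  expect_error(select_num_states(seqs[1:4], 1:2), "at least 8")
})

test_that("signature tables honor the strict 0.05 threshold and tie order", {
  em <- matrix(0, 2, 10)
  em[1, ] <- c(0.96, 0.04, rep(0, 8))
  em[2, ] <- rep(0.1, 10)
  m <- category_hmm(c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)), em)
  sig <- signature_states(m)
  s1 <- sig[sig$state == 1, ]
  expect_equal(nrow(s1), 1L)           # 0.04 excluded, strictly > 0.05
  expect_equal(s1$category, "causes")
  s2 <- sig[sig$state == 2, ]
  expect_equal(s2$category, cats)      # uniform ties keep canonical order
  expect_true(all(s2$tied))
})

test_that("default truths carry the reported signature asymmetry", {
  sig_agg <- signature_states(hmm_truth_aggressive())
  sig_ind <- signature_states(hmm_truth_indolent())
  expect_false("support" %in% sig_agg$category)
  expect_true("support" %in% sig_ind$category)
})

test_that("stability ranking orders states by self-transition", {
  m <- category_hmm(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.5, 0.5)),
                    matrix(0.1, 2, 10))
  r <- stability_ranking(m)
  expect_equal(r$state, c(1L, 2L))
  expect_equal(r$self_transition, c(0.9, 0.5))

  tied <- category_hmm(c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)),
                       matrix(0.1, 2, 10))
  rt <- stability_ranking(tied)
  expect_equal(rt$state, c(1L, 2L))
  expect_true(all(rt$tied))

  # default truths: aggressive journeys are most stable early,
  # indolent journeys late
  expect_setequal(stability_ranking(hmm_truth_aggressive())$state[1:2],
                  c(1L, 2L))
  expect_setequal(stability_ranking(hmm_truth_indolent())$state[1:3],
                  c(3L, 4L, 5L))
})

test_that("model JSON round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- hmm_truth_aggressive()
  write_hmm_json(m, path)
  m2 <- read_hmm_json(path)
  expect_equal(m2$transition, m$transition, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2$emission, m$emission, tolerance = 1e-12,
               ignore_attr = TRUE)
})
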