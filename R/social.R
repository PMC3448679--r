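#' Identify co-searching acquaintance pairs
#'
#' Returns one pair for every contact edge whose two endpoints are both
#' included cohort members. The first searcher is the endpoint whose
#' first cancer query came earlier (ties resolve to the endpoint with
#' more pages, then to the lexicographically smaller user id); the lag
#' is the difference between the two first-query days. The pair's
#' severity group is that of the first searcher's dominant disease, and
#' `overlap` records whether the two users queried at least one common
#' cancer. The result is independent of edge orientation and edge
#' order.
#'
#' @param profiles Included-user profile tibble from [build_profiles()].
#' @param edges Contact edge tibble (`user_a`, `user_b`), undirected and
#'   deduplicated.
#' @param require_window_overlap Keep only pairs whose search windows
#'   (first to last active day) intersect; by default both merely have
#'   to search within the study period.
#' @return A tibble of `CoSearchPair` records: `first_searcher`,
#'   `second_searcher`, `lag_days`, `first_duration_days`,
#'   `second_duration_days`, `severity`, `overlap`, `first_n_diseases`,
#'   `second_n_diseases`.
#' @export
find_pairs <- function(profiles, edges, require_window_overlap = FALSE) {
  stopifnot(all(c("user_a", "user_b") %in% names(edges)))
  empty <- tibble::tibble(
    first_searcher = character(0), second_searcher = character(0),
    lag_days = numeric(0), first_duration_days = numeric(0),
    second_duration_days = numeric(0), severity = character(0),
    overlap = logical(0), first_n_diseases = integer(0),
    second_n_diseases = integer(0))
  if (nrow(edges) == 0 || nrow(profiles) == 0) return(empty)

  idx <- stats::setNames(seq_len(nrow(profiles)), profiles$user_id)
  ia <- idx[edges$user_a]
  ib <- idx[edges$user_b]
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) return(empty)
  ia <- unname(ia[keep]); ib <- unname(ib[keep])
  if (require_window_overlap) {
    ld <- profiles$last_day
    fd0 <- profiles$first_day
    keep2 <- fd0[ia] <= ld[ib] & fd0[ib] <= ld[ia]
    ia <- ia[keep2]; ib <- ib[keep2]
    if (length(ia) == 0) return(empty)
  }

  fd <- profiles$first_day
  np <- profiles$n_pages
  uid <- profiles$user_id
  a_first <- (fd[ia] < fd[ib]) |
    (fd[ia] == fd[ib] & np[ia] > np[ib]) |
    (fd[ia] == fd[ib] & np[ia] == np[ib] & uid[ia] < uid[ib])
  f <- ifelse(a_first, ia, ib)
  s <- ifelse(a_first, ib, ia)

  overlap <- vapply(seq_along(f), function(k) {
    length(intersect(profiles$cancers_all[[f[k]]],
                     profiles$cancers_all[[s[k]]])) > 0
  }, logical(1))

  tibble::tibble(
    first_searcher = uid[f],
    second_searcher = uid[s],
    lag_days = as.numeric(fd[s] - fd[f]),
    first_duration_days = profiles$search_period_days[f],
    second_duration_days = profiles$search_period_days[s],
    severity = profiles$severity[f],
    overlap = overlap,
    first_n_diseases = lengths(profiles$cancers_all[f]),
    second_n_diseases = lengths(profiles$cancers_all[s])
  ) |>
    dplyr::arrange(.data$first_searcher, .data$second_searcher)
}

#' Fold enrichment of co-search pairs over a permutation null
#'
#' The chance expectation is the mean number of qualifying pairs when
#' the "included searcher" labels are randomly reassigned across the
#' contact graph's users, preserving the number of included users and
#' the graph itself. Fold enrichment is the observed count over this
#' expectation, with a one-sided permutation p-value (probability of a
#' null count at least as large as observed). An alternative null that
#' rewires edges while preserving degrees is available.
#'
#' @param observed_pairs Pair tibble from [find_pairs()] or an observed
#'   pair count.
#' @param profiles Included-user profiles.
#' @param edges Contact edge tibble.
#' @param n_permutations Number of permutations (>= 100, default 1000).
#' @param seed Optional integer seed.
#' @param null `"label"` (default) or `"rewire"`.
#' @return A `cosearch_enrichment` object: list with `observed`,
#'   `expected`, `fold` (NA when the expectation is 0), `p_value`,
#'   `n_permutations`, `null`.
#' @export
enrichment_vs_chance <- function(observed_pairs, profiles, edges,
                                 n_permutations = 1000, seed = NULL,
                                 null = c("label", "rewire")) {
  null <- match.arg(null)
  if (nrow(edges) == 0) stop("no contact edges", call. = FALSE)
  if (n_permutations < 100) {
    stop("n_permutations must be at least 100", call. = FALSE)
  }
  observed <- if (is.data.frame(observed_pairs)) {
    nrow(observed_pairs)
  } else as.numeric(observed_pairs)

  nodes <- unique(c(edges$user_a, edges$user_b, profiles$user_id))
  ea <- match(edges$user_a, nodes)
  eb <- match(edges$user_b, nodes)
  inc <- match(intersect(profiles$user_id, nodes), nodes)
  I <- length(inc)
  N <- length(nodes)

  with_seed(seed, {
    null_counts <- numeric(n_permutations)
    if (null == "label") {
      for (p in seq_len(n_permutations)) {
        flag <- logical(N)
        flag[sample.int(N, I)] <- TRUE
        null_counts[p] <- sum(flag[ea] & flag[eb])
      }
    } else {
      flag <- logical(N)
      flag[inc] <- TRUE
      m <- length(ea)
      for (p in seq_len(n_permutations)) {
        # degree-preserving rewire: shuffle one endpoint column
        perm_b <- eb[sample.int(m)]
        ok <- ea != perm_b
        null_counts[p] <- sum(flag[ea[ok]] & flag[perm_b[ok]])
      }
    }
    expected <- mean(null_counts)
    structure(list(
      observed = observed,
      expected = expected,
      fold = if (expected > 0) observed / expected else NA_real_,
      p_value = (1 + sum(null_counts >= observed)) / (n_permutations + 1),
      null_counts = null_counts,
      n_permutations = n_permutations,
      null = null,
      n_included = I, n_nodes = N, n_edges = length(ea)
    ), class = "cosearch_enrichment")
  })
}

#' @export
print.cosearch_enrichment <- function(x, ...) {
  cat(sprintf(
    "Co-search pairs: %d observed vs %.1f expected by chance (%s null)\n",
    x$observed, x$expected, x$null))
  if (is.na(x$fold)) {
    cat("fold enrichment undefined (expected count 0)\n")
  } else {
    cat(sprintf("fold enrichment %.2f, one-sided permutation p = %.3g\n",
                x$fold, x$p_value))
  }
  invisible(x)
}

#' @export
glance.cosearch_enrichment <- function(x, ...) {
  tibble::tibble(observed = x$observed, expected = x$expected,
                 fold = x$fold, p.value = x$p_value,
                 n_permutations = x$n_permutations, null = x$null)
}

#' Disease overlap of co-search pairs versus random matching
#'
#' @param pairs Pair tibble from [find_pairs()] (>= 1 row).
#' @param profiles Included-user profiles.
#' @param n_draws Random pairings for the baseline (default 10000).
#' @param seed Optional integer seed.
#' @return A tibble with `observed_overlap` (fraction of pairs sharing a
#'   queried cancer), `random_overlap` (same statistic over uniformly
#'   random pairings of included users) and `n_pairs`.
#' @export
overlap_stats <- function(pairs, profiles, n_draws = 10000, seed = NULL) {
  if (nrow(pairs) == 0) stop("no pairs", call. = FALSE)
  with_seed(seed, {
    base <- if (nrow(profiles) >= 2) {
      i <- sample.int(nrow(profiles), n_draws, replace = TRUE)
      j <- sample.int(nrow(profiles), n_draws, replace = TRUE)
      ok <- i != j
      mean(mapply(function(a, b) {
        length(intersect(profiles$cancers_all[[a]],
                         profiles$cancers_all[[b]])) > 0
      }, i[ok], j[ok]))
    } else NA_real_
    tibble::tibble(observed_overlap = mean(pairs$overlap),
                   random_overlap = base,
                   n_pairs = nrow(pairs))
  })
}

# exact two-sided sign test on paired differences (ties dropped)
sign_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) < 1) return(list(p.value = 1, n = 0))
  bt <- stats::binom.test(sum(d > 0), length(d), 0.5)
  list(p.value = bt$p.value, n = length(d))
}

#' Lag and duration contrasts across severity groups
#'
#' Summarizes co-search pairs per severity stratum (mean and SD of the
#' lag and of both searchers' durations) and runs the study's
#' nonparametric contrasts: a rank-sum test comparing lags between
#' severity groups, a per-stratum sign test of the paired difference
#' between the second and first searcher's durations, and a signed-rank
#' test of the number of distinct diseases queried by the first versus
#' the second searcher (reported with the mean percentage difference).
#' Strata with fewer than 2 pairs have their tests skipped and flagged.
#'
#' @param pairs Pair tibble from [find_pairs()].
#' @return A `pair_contrasts` object: list with `summary` (per-severity
#'   tibble) and `tests` (tibble of test, stratum, statistic, p, flag).
#' @export
lag_duration_contrasts <- function(pairs) {
  if (nrow(pairs) == 0) stop("no pairs", call. = FALSE)
  summary <- pairs |>
    dplyr::group_by(.data$severity) |>
    dplyr::summarise(
      n = dplyr::n(),
      lag_mean = mean(.data$lag_days), lag_sd = sd(.data$lag_days),
      first_duration_mean = mean(.data$first_duration_days),
      first_duration_sd = sd(.data$first_duration_days),
      second_duration_mean = mean(.data$second_duration_days),
      second_duration_sd = sd(.data$second_duration_days),
      .groups = "drop"
    )

  tests <- list()
  agg <- pairs[pairs$severity == "aggressive", ]
  ind <- pairs[pairs$severity == "indolent", ]
  if (nrow(agg) >= 2 && nrow(ind) >= 2) {
    p <- if (length(unique(c(agg$lag_days, ind$lag_days))) == 1) 1 else {
      suppressWarnings(stats::wilcox.test(agg$lag_days, ind$lag_days,
                                          exact = FALSE)$p.value)
    }
    tests$lag <- tibble::tibble(
      test = "lag rank-sum (aggressive vs indolent)", stratum = "both",
      statistic = mean(agg$lag_days) - mean(ind$lag_days),
      p.value = p, skipped = FALSE)
  } else {
    tests$lag <- tibble::tibble(
      test = "lag rank-sum (aggressive vs indolent)", stratum = "both",
      statistic = NA_real_, p.value = NA_real_, skipped = TRUE)
  }

  for (sev in c("aggressive", "indolent")) {
    strat <- pairs[pairs$severity == sev, ]
    if (nrow(strat) >= 2) {
      st <- sign_test(strat$second_duration_days, strat$first_duration_days)
      tests[[paste0("dur_", sev)]] <- tibble::tibble(
        test = "duration sign test (second vs first searcher)",
        stratum = sev,
        statistic = mean(strat$second_duration_days) -
          mean(strat$first_duration_days),
        p.value = st$p.value, skipped = FALSE)
    } else {
      tests[[paste0("dur_", sev)]] <- tibble::tibble(
        test = "duration sign test (second vs first searcher)",
        stratum = sev, statistic = NA_real_, p.value = NA_real_,
        skipped = TRUE)
    }
  }

  d <- pairs$first_n_diseases - pairs$second_n_diseases
  if (nrow(pairs) >= 2 && any(d != 0)) {
    p <- suppressWarnings(stats::wilcox.test(
      pairs$first_n_diseases, pairs$second_n_diseases, paired = TRUE,
      exact = FALSE)$p.value)
    pct <- 100 * (mean(pairs$first_n_diseases) /
                    mean(pairs$second_n_diseases) - 1)
    tests$diseases <- tibble::tibble(
      test = "diseases searched signed-rank (first vs second, % more)",
      stratum = "both", statistic = pct, p.value = p, skipped = FALSE)
  } else {
    tests$diseases <- tibble::tibble(
      test = "diseases searched signed-rank (first vs second, % more)",
      stratum = "both", statistic = NA_real_, p.value = NA_real_,
      skipped = TRUE)
  }

  structure(list(summary = summary, tests = dplyr::bind_rows(tests)),
            class = "pair_contrasts")
}

#' @export
print.pair_contrasts <- function(x, ...) {
  cat("Co-search pair lag/duration summary by severity\n")
  print(x$summary)
  cat("\nNonparametric contrasts\n")
  print(x$tests)
  invisible(x)
}

#' @export
tidy.pair_contrasts <- function(x, ...) x$tests

#' @export
glance.pair_contrasts <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary, names_from = "severity",
    values_from = setdiff(names(x$summary), "severity"))
}

#' Category preferences of first versus second searchers
#'
#' For each page category, computes each pair member's share of page
#' views in that category, then contrasts the mean share of first
#' searchers with that of second searchers: the ratio of means, the
#' corresponding percentage difference, and a two-sided rank-sum test of
#' the per-user shares. Categories viewed by neither role are flagged
#' with an undefined ratio.
#'
#' @param pairs Pair tibble from [find_pairs()].
#' @param profiles Included-user profiles carrying `category_sequence`.
#' @return A tibble with `category`, `first_mean_share`,
#'   `second_mean_share`, `ratio_first_vs_second`, `pct_difference`,
#'   `p.value`, `undefined`.
#' @export
category_preference_contrast <- function(pairs, profiles) {
  if (nrow(pairs) == 0) stop("no pairs", call. = FALSE)
  cats <- page_categories()
  shares_of <- function(ids) {
    seqs <- profiles$category_sequence[match(ids, profiles$user_id)]
    t(vapply(seqs, function(s) {
      tabulate(match_categories(s), nbins = length(cats)) / length(s)
    }, numeric(length(cats))))
  }
  first_sh <- shares_of(pairs$first_searcher)
  second_sh <- shares_of(pairs$second_searcher)
  purrr::map_dfr(seq_along(cats), function(ci) {
    f <- first_sh[, ci]; s <- second_sh[, ci]
    undefined <- all(f == 0) && all(s == 0)
    ratio <- if (undefined || mean(s) == 0) NA_real_ else mean(f) / mean(s)
    p <- if (undefined) NA_real_ else {
      suppressWarnings(stats::wilcox.test(f, s, exact = FALSE)$p.value)
    }
    tibble::tibble(
      category = cats[ci],
      first_mean_share = mean(f),
      second_mean_share = mean(s),
      ratio_first_vs_second = ratio,
      pct_difference = if (is.na(ratio)) NA_real_ else 100 * (ratio - 1),
      p.value = p,
      undefined = undefined
    )
  })
}
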