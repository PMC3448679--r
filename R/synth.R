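#' Configuration for the synthetic query-log generator
#'
#' Bundles every parameter of [simulate_log()]. The defaults reproduce
#' the statistical structure reported for the source cohort: heavy-tailed
#' pages-per-user (slope -2.19) and users-per-page (-2.25) distributions,
#' a contact-degree distribution with slope -0.99 and median 6, a mean
#' search period of 10.0 (sd 14.5) days, co-searching acquaintance pairs
#' enriched 6-fold over chance with disease overlap 0.56, acquaintance
#' lags of 15 (indolent) and 9 (aggressive) days, acquaintance search
#' durations of 5.1 +/- 8.1 (indolent) and 12.5 +/- 17.3 (aggressive)
#' days, proband durations of 13.9 +/- 18.9 (indolent) and 11.0 +/- 14.7
#' (aggressive) days, and a 41.5% multi-category fraction among users
#' passing the five-page threshold.
#'
#' @param n_users Number of searcher users (default 20000).
#' @param pageview_exponent,pagepop_exponent,degree_exponent Negative
#'   power-law slopes for pages per user, users per page and contacts per
#'   user.
#' @param target_degree_median Target lower median of contact degrees;
#'   fixes the degree-distribution truncation point.
#' @param hmm_truth_aggressive,hmm_truth_indolent Ground-truth
#'   `category_hmm` objects per severity group.
#' @param mean_search_days,sd_search_days Mean/sd of the generic search
#'   period (days).
#' @param pair_enrichment Fold enrichment of co-searching acquaintance
#'   pairs over the label-permutation chance expectation.
#' @param lag_aggressive_days,lag_indolent_days Mean lag (days) between
#'   proband and acquaintance first searches, per severity.
#' @param acq_duration_aggressive_days,acq_duration_aggressive_sd,acq_duration_indolent_days,acq_duration_indolent_sd
#'   Acquaintance search-duration mean/sd per severity (days).
#' @param proband_duration_aggressive_days,proband_duration_aggressive_sd,proband_duration_indolent_days,proband_duration_indolent_sd
#'   Proband search-duration mean/sd per severity (days).
#' @param overlap_prob Probability that a co-search pair shares a queried
#'   cancer.
#' @param multi_category_fraction Fraction of threshold-passing users who
#'   browse two or more page categories.
#' @param background_factor Background (non-searcher) contact-graph users
#'   per searcher. Searchers' messenger contacts are mostly people who
#'   never query about cancer; the background keeps co-search pairs as
#'   rare, relative to the cohort, as they are in real logs.
#' @param incidence_noise_sd Lognormal sd of the disease-popularity noise
#'   around incidence-proportional query shares.
#' @param noise_query_fraction Fraction of additional non-cancer noise
#'   rows appended to the log.
#' @param unknown_category_fraction Fraction of cancer page visits whose
#'   category is withheld (`NA`), emulating uncategorized pages.
#' @param study_days Length of the observation window in days (92).
#' @param xmax Truncation point of the page-count power laws.
#' @param seed Integer seed; the full output is a pure function of the
#'   configuration including this seed.
#' @return A `synthetic_config` object (validated list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_users = 500, seed = 1)
#' sim <- simulate_log(cfg)
#' head(sim$events)
synthetic_config <- function(n_users = 20000,
                             pageview_exponent = -2.19,
                             pagepop_exponent = -2.25,
                             degree_exponent = -0.99,
                             target_degree_median = 6,
                             hmm_truth_aggressive = infoseekr::hmm_truth_aggressive(),
                             hmm_truth_indolent = infoseekr::hmm_truth_indolent(),
                             mean_search_days = 10.0,
                             sd_search_days = 14.5,
                             pair_enrichment = 6,
                             lag_aggressive_days = 9,
                             lag_indolent_days = 15,
                             acq_duration_aggressive_days = 12.5,
                             acq_duration_aggressive_sd = 17.3,
                             acq_duration_indolent_days = 5.1,
                             acq_duration_indolent_sd = 8.1,
                             proband_duration_aggressive_days = 11.0,
                             proband_duration_aggressive_sd = 14.7,
                             proband_duration_indolent_days = 13.9,
                             proband_duration_indolent_sd = 18.9,
                             overlap_prob = 0.56,
                             multi_category_fraction = 0.415,
                             background_factor = 4,
                             incidence_noise_sd = 0.5,
                             noise_query_fraction = 0.05,
                             unknown_category_fraction = 0,
                             study_days = 92,
                             xmax = 1e4,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  expo <- c(cfg$pageview_exponent, cfg$pagepop_exponent, cfg$degree_exponent)
  if (any(expo >= 0)) stop("all exponents must be negative", call. = FALSE)
  if (!is.finite(cfg$xmax) && any(expo >= -1)) {
    stop("exponent >= -1 with unbounded support is non-integrable",
         call. = FALSE)
  }
  days <- c(cfg$mean_search_days, cfg$sd_search_days,
            cfg$lag_aggressive_days, cfg$lag_indolent_days,
            cfg$acq_duration_aggressive_days, cfg$acq_duration_indolent_days,
            cfg$proband_duration_aggressive_days,
            cfg$proband_duration_indolent_days)
  if (any(days < 0)) stop("day parameters must be >= 0", call. = FALSE)
  probs <- c(cfg$overlap_prob, cfg$multi_category_fraction,
             cfg$noise_query_fraction, cfg$unknown_category_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_users != 0 && cfg$n_users < 2) {
    stop("n_users must be 0 (empty log) or at least 2", call. = FALSE)
  }
  stopifnot(inherits(cfg$hmm_truth_aggressive, "category_hmm"),
            inherits(cfg$hmm_truth_indolent, "category_hmm"),
            cfg$pair_enrichment > 0, cfg$study_days >= 1,
            cfg$background_factor >= 0)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d users (background x%g), seed %d\n",
    x$n_users, x$background_factor, as.integer(x$seed)))
  cat(sprintf(
    "  slopes: pages/user %.2f, users/page %.2f, degree %.2f (median %d)\n",
    x$pageview_exponent, x$pagepop_exponent, x$degree_exponent,
    x$target_degree_median))
  cat(sprintf("  search period %.1f +/- %.1f days; enrichment x%g; overlap %.2f\n",
              x$mean_search_days, x$sd_search_days, x$pair_enrichment,
              x$overlap_prob))
  invisible(x)
}

# lognormal draws parameterized by method of moments to (mean, sd)
rlnorm_mom <- function(n, mean, sd) {
  if (mean <= 0) stop("lognormal mean must be positive", call. = FALSE)
  if (sd <= 0) return(rep(mean, n))
  sig2 <- log(1 + sd^2 / mean^2)
  rlnorm(n, log(mean) - sig2 / 2, sqrt(sig2))
}

# Lognormal day-window draws whose mean, after capping at the D-day
# observation window, still equals `mean`: the scale is inflated by the
# factor that exactly offsets the truncation loss
# (E[min(cX, D)] = mean, solved for c).
rlnorm_window <- function(n, mean, sd, D) {
  if (sd <= 0 || mean >= D) return(rep(pmin(mean, D), n))
  sig2 <- log(1 + sd^2 / mean^2)
  sig <- sqrt(sig2)
  mu <- log(mean) - sig2 / 2
  capped_mean <- function(cc) {
    z <- (log(D / cc) - mu) / sig
    cc * mean * stats::pnorm(z - sig) + D * stats::pnorm(z, lower.tail = FALSE)
  }
  cc <- if (capped_mean(1) >= mean) 1 else {
    stats::uniroot(function(x) capped_mean(x) - mean, c(1, D / mean),
                   tol = 1e-10)$root
  }
  pmin(cc * rlnorm(n, mu, sig), D)
}

# stationary distribution of a row-stochastic matrix
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# truncation point making the lower median of a discrete power law equal
# to `target`, with the most comfortable margin on both sides
degree_truncation <- function(exponent, target) {
  best <- NULL
  for (xmax in seq.int(target + 1, 5000)) {
    p <- (1:xmax)^exponent
    Fc <- cumsum(p) / sum(p)
    margin <- min(0.5 - Fc[target - 1], Fc[target] - 0.5)
    if (!is.null(best) && margin < best$margin - 1e-12 && best$margin > 0) break
    if (is.null(best) || margin > best$margin) {
      best <- list(xmax = xmax, margin = margin)
    }
  }
  if (is.null(best) || best$margin <= 0) {
    stop("no truncation point achieves the requested degree median",
         call. = FALSE)
  }
  best$xmax
}

#' Generate a heavy-tailed contact graph
#'
#' Draws a degree sequence from a truncated discrete power law whose
#' truncation point is chosen so the lower median equals
#' `target_median`, then realizes an undirected simple graph by random
#' stub matching (self-loops and duplicate edges are dropped, which
#' perturbs realized degrees only marginally at these densities).
#'
#' @param n_nodes Number of nodes.
#' @param exponent Negative degree-distribution slope.
#' @param target_median Target lower median degree.
#' @param seed Optional integer seed.
#' @param node_ids Optional character vector of node identifiers.
#' @return A list with `edges` (tibble `user_a`, `user_b`, deduplicated,
#'   `user_a < user_b`), `degrees` (realized degree per node) and
#'   `node_ids`.
#' @export
#' @examples
#' g <- simulate_contact_graph(2000, -0.99, 6, seed = 1)
#' distribution_median(g$degrees)
simulate_contact_graph <- function(n_nodes, exponent = -0.99,
                                   target_median = 6, seed = NULL,
                                   node_ids = NULL) {
  stopifnot(n_nodes >= 0)
  if (is.null(node_ids)) {
    node_ids <- sprintf("u%07d", seq_len(n_nodes))
  }
  stopifnot(length(node_ids) == n_nodes)
  empty <- tibble::tibble(user_a = character(0), user_b = character(0))
  if (n_nodes < 2) {
    return(list(edges = empty, degrees = integer(n_nodes),
                node_ids = node_ids))
  }
  with_seed(seed, {
    xmax <- degree_truncation(exponent, target_median)
    drawn <- rpower_law(n_nodes, exponent, 1, xmax)
    stubs <- rep.int(seq_len(n_nodes), drawn)
    stubs <- stubs[sample.int(length(stubs))]
    if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
    a <- stubs[seq(1, length(stubs), by = 2)]
    b <- stubs[seq(2, length(stubs), by = 2)]
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- (lo - 1) * n_nodes + hi
    dedup <- !duplicated(key)
    lo <- lo[dedup]; hi <- hi[dedup]
    degrees <- tabulate(c(lo, hi), nbins = n_nodes)
    list(
      edges = tibble::tibble(user_a = node_ids[lo], user_b = node_ids[hi]),
      degrees = degrees,
      node_ids = node_ids
    )
  })
}

empty_log_tables <- function(lexicon) {
  list(
    events = tibble::tibble(user_id = character(0), day = integer(0),
                            query_text = character(0), cancers = character(0),
                            page_id = character(0), category = character(0)),
    contacts = tibble::tibble(user_a = character(0), user_b = character(0)),
    lexicon = lexicon,
    truth = list(included = character(0), roles = tibble::tibble(),
                 pairs_planted = tibble::tibble(),
                 expected_chance_pairs = 0, target_pairs = 0)
  )
}

#' Simulate a synthetic query log, contact graph and lexicon
#'
#' Generates the three tables consumed by the analysis pipeline with the
#' statistical structure described in [synthetic_config()]:
#'
#' * per-user cancer page-view counts follow a truncated discrete power
#'   law; users at or above five categorized page views are potential
#'   cohort members, and a configured fraction of them browse two or
#'   more categories;
#' * category sequences of multi-category users are emitted by the
#'   severity-matched ground-truth journey model of their dominant
#'   disease; single-category users repeat one category drawn from that
#'   model's stationary output mixture;
#' * each user's visits span a whole-day window whose length is drawn
#'   from a lognormal matched to the configured mean/sd; the first and
#'   last visits sit on the window boundaries;
#' * page identifiers are assigned within each category so that
#'   views-per-page follow the configured popularity power law;
#' * the contact graph covers searchers plus background users, with
#'   power-law degrees hitting the target median; co-searching
#'   acquaintance pairs are topped up to `pair_enrichment` times the
#'   analytic label-permutation chance expectation, with severity-specific
#'   lags and durations, disease overlap calibrated to `overlap_prob`,
#'   and the first searcher querying more diseases and more
#'   treatment/information pages than the second.
#'
#' The output is a pure function of the configuration (including its
#' seed): identical configurations give identical tables.
#'
#' @param config A [synthetic_config()].
#' @param lexicon Optional lexicon tibble (defaults to
#'   [default_lexicon()]).
#' @return A list with `events`, `contacts`, `lexicon` (severity
#'   annotated) and `truth` (generator-side ground truth for round-trip
#'   evaluation: included user ids, role table, planted pairs, analytic
#'   chance expectation and planted target).
#' @export
simulate_log <- function(config = synthetic_config(), lexicon = NULL) {
  validate_synthetic_config(config)
  lex <- partition_severity(lexicon %||% default_lexicon())
  if (config$n_users == 0) return(empty_log_tables(lex))

  with_seed(config$seed, {
    n <- config$n_users
    D <- config$study_days
    cats <- page_categories()
    user_ids <- sprintf("u%07d", seq_len(n))

    ## -- disease assignment ------------------------------------------
    w <- lex$incidence_per_100k *
      exp(rnorm(nrow(lex), 0, config$incidence_noise_sd))
    dominant <- sample(lex$cancer, n, replace = TRUE, prob = w)
    sev_of <- stats::setNames(as.character(lex$severity), lex$cancer)
    severity <- sev_of[dominant]

    # extra (non-dominant) diseases queried by each user
    n_extra <- stats::rpois(n, 0.3)
    extras <- lapply(seq_len(n), function(i) {
      if (n_extra[i] == 0) return(character(0))
      sample(setdiff(lex$cancer, dominant[i]), min(n_extra[i], 3))
    })

    ## -- page counts and cohort structure ----------------------------
    n_pages <- rpower_law(n, config$pageview_exponent, 1, config$xmax)
    passes <- n_pages >= 5
    multi <- passes & (runif(n) < config$multi_category_fraction)
    included <- which(multi)

    ## -- contact graph over searchers + background -------------------
    n_bg <- round(config$background_factor * n)
    node_ids <- c(user_ids, sprintf("b%07d", seq_len(n_bg)))
    graph <- simulate_contact_graph(length(node_ids), config$degree_exponent,
                                    config$target_degree_median,
                                    node_ids = node_ids)
    edge_a <- match(graph$edges$user_a, node_ids)
    edge_b <- match(graph$edges$user_b, node_ids)
    n_nodes <- length(node_ids)

    ## -- co-search pair planting -------------------------------------
    is_inc <- logical(n_nodes)
    is_inc[included] <- TRUE
    nat <- which(is_inc[edge_a] & is_inc[edge_b])
    C0 <- length(nat)
    I <- length(included)
    m <- length(edge_a)
    kappa <- if (n_nodes > 1) I * (I - 1) / (n_nodes * (n_nodes - 1)) else 0
    pe <- config$pair_enrichment
    target <- if (kappa > 0 && pe * kappa < 1) {
      max(C0, round(pe * kappa * (m - C0) / (1 - pe * kappa)))
    } else C0
    n_plant <- target - C0

    role <- rep(NA_character_, n)        # searchers only can have roles
    link <- rep(NA_integer_, n)          # acq -> proband user index

    # natural qualifying edges first: orient by page count
    for (e in nat) {
      x <- edge_a[e]; y <- edge_b[e]
      rx <- role[x]; ry <- role[y]
      if (is.na(rx) && is.na(ry)) {
        if (n_pages[y] > n_pages[x]) { tmp <- x; x <- y; y <- tmp }
        role[x] <- "proband"; role[y] <- "acq"; link[y] <- x
      } else if (identical(rx, "proband") && is.na(ry)) {
        role[y] <- "acq"; link[y] <- x
      } else if (identical(ry, "proband") && is.na(rx)) {
        role[x] <- "acq"; link[x] <- y
      } else if (identical(rx, "acq") && is.na(ry)) {
        role[y] <- "acq"; link[y] <- link[x]
      } else if (identical(ry, "acq") && is.na(rx)) {
        role[x] <- "acq"; link[x] <- link[y]
      } # both already roled: leave as-is
    }

    planted_a <- integer(0); planted_b <- integer(0)
    if (n_plant > 0 && I >= 2) {
      pool <- included[is.na(role[included])]
      pool <- pool[sample.int(length(pool))]
      n_new <- min(n_plant, floor(length(pool) / 2))
      if (n_new > 0) {
        probands <- pool[seq_len(n_new)]
        acqs <- pool[n_new + seq_len(n_new)]
        role[probands] <- "proband"; role[acqs] <- "acq"
        link[acqs] <- probands
        # drop planted edges that already exist in the graph
        key_existing <- (pmin(edge_a, edge_b) - 1) * n_nodes +
          pmax(edge_a, edge_b)
        key_new <- (pmin(probands, acqs) - 1) * n_nodes + pmax(probands, acqs)
        fresh <- !(key_new %in% key_existing)
        planted_a <- probands[fresh]; planted_b <- acqs[fresh]
        edge_a <- c(edge_a, planted_a); edge_b <- c(edge_b, planted_b)
      }
    }

    ## -- disease overlap calibration ---------------------------------
    disease_sets <- lapply(seq_len(n), function(i) c(dominant[i], extras[[i]]))
    acq_idx <- which(!is.na(role) & role == "acq")
    q_hat <- 0
    if (I >= 2) {
      draw_i <- sample(included, 4000, replace = TRUE)
      draw_j <- sample(included, 4000, replace = TRUE)
      ok <- draw_i != draw_j
      q_hat <- mean(mapply(function(i, j) {
        length(intersect(disease_sets[[i]], disease_sets[[j]])) > 0
      }, draw_i[ok], draw_j[ok]))
    }
    # Only proband-acquaintance pairs can carry a planted match; pairs
    # arising from tangled components overlap merely by chance. The
    # per-acquaintance match probability is solved so the expected
    # overlap over all qualifying pairs hits the configured value:
    #   target = f_pa * (o* + (1 - o*) q) + (1 - f_pa) * q
    qual <- which(is_inc[edge_a] & is_inc[edge_b])
    f_pa <- if (length(qual) > 0) {
      a <- edge_a[qual]; b <- edge_b[qual]
      pa <- (!is.na(role[a]) & role[a] == "proband" &
               !is.na(role[b]) & role[b] == "acq" & link[b] == a) |
            (!is.na(role[b]) & role[b] == "proband" &
               !is.na(role[a]) & role[a] == "acq" & link[a] == b)
      mean(pa)
    } else 1
    o_star <- if (f_pa > 0) {
      (config$overlap_prob - q_hat) / (f_pa * max(1e-9, 1 - q_hat))
    } else 0
    o_star <- max(0, min(1, o_star))
    if (length(acq_idx) > 0) {
      match_flag <- runif(length(acq_idx)) < o_star
      for (k in seq_along(acq_idx)) {
        if (match_flag[k]) {
          a <- acq_idx[k]
          dominant[a] <- dominant[link[a]]
          severity[a] <- sev_of[dominant[a]]
          extras[[a]] <- setdiff(extras[[a]], dominant[a])
          disease_sets[[a]] <- c(dominant[a], extras[[a]])
        }
      }
    }

    # first searchers query more distinct diseases than second searchers
    pro_idx <- which(!is.na(role) & role == "proband")
    if (length(pro_idx) > 0) {
      add <- stats::rpois(length(pro_idx), 0.15)
      for (k in seq_along(pro_idx)) {
        if (add[k] > 0) {
          i <- pro_idx[k]
          extra_new <- sample(setdiff(lex$cancer, disease_sets[[i]]),
                              min(add[k], 2))
          extras[[i]] <- c(extras[[i]], extra_new)
          disease_sets[[i]] <- c(dominant[i], extras[[i]])
        }
      }
    }

    ## -- search windows ----------------------------------------------
    draw_window <- function(mean, sd, len) {
      pmax(1, round(rlnorm_window(len, mean, sd, D)))
    }
    W <- draw_window(config$mean_search_days, config$sd_search_days, n)
    start <- integer(n)
    plain <- which(is.na(role))
    start[plain] <- vapply(W[plain], function(w) {
      sample.int(D - w + 1, 1) - 1L
    }, integer(1))

    for (i in pro_idx) {
      sev <- severity[i]
      W[i] <- draw_window(
        if (sev == "aggressive") config$proband_duration_aggressive_days
        else config$proband_duration_indolent_days,
        if (sev == "aggressive") config$proband_duration_aggressive_sd
        else config$proband_duration_indolent_sd, 1)
      # probands start early so the acquaintance's episode fits the window
      start[i] <- sample.int(max(1, min(floor(D / 2), D - W[i] + 1)), 1) - 1L
    }
    for (i in acq_idx) {
      p <- link[i]
      sev <- severity[p]    # pair severity follows the first searcher
      W[i] <- draw_window(
        if (sev == "aggressive") config$acq_duration_aggressive_days
        else config$acq_duration_indolent_days,
        if (sev == "aggressive") config$acq_duration_aggressive_sd
        else config$acq_duration_indolent_sd, 1)
      lag <- max(1, round(stats::rexp(
        1, 1 / max(0.5, if (sev == "aggressive") config$lag_aggressive_days
                   else config$lag_indolent_days))))
      start[i] <- min(start[p] + lag, D - 1L)
      # keep the drawn duration when the episode overruns the window by
      # starting earlier (shortening the lag), never before the proband
      if (start[i] + W[i] > D) {
        start[i] <- max(start[p] + 1L, D - W[i])
      }
      W[i] <- min(W[i], D - start[i])
    }

    ## -- category sequences ------------------------------------------
    truth_hmm <- list(aggressive = config$hmm_truth_aggressive,
                      indolent = config$hmm_truth_indolent)
    tilt_emission <- function(model, factors) {
      em <- model$emission
      for (cat in names(factors)) {
        em[, cat] <- em[, cat] * factors[[cat]]
      }
      category_hmm(model$initial, model$transition, em / rowSums(em))
    }
    tilted <- list(
      proband = lapply(truth_hmm, tilt_emission,
                       factors = list(treatment = 1.25, information = 1.14)),
      acq = lapply(truth_hmm, tilt_emission,
                   factors = list(causes = 2.16, social_media = 1.75))
    )
    stationary_mix <- lapply(truth_hmm, function(mdl) {
      as.numeric(stationary_distribution(mdl$transition) %*% mdl$emission)
    })

    sample_sequence <- function(model, L, need_multi) {
      for (attempt in 1:50) {
        s <- simulate_hmm_sequences(model, 1, L)[[1]]
        if (!need_multi || L < 2 || length(unique(s)) >= 2) return(s)
      }
      s[1] <- setdiff(page_categories(), s[2])[1]  # force a second category
      s
    }

    sequences <- vector("list", n)
    for (i in seq_len(n)) {
      sev <- if (!is.na(role[i]) && role[i] == "acq") {
        severity[link[i]]
      } else severity[i]
      L <- n_pages[i]
      if (passes[i] && !multi[i]) {
        cat_one <- sample(cats, 1, prob = stationary_mix[[sev]])
        sequences[[i]] <- rep(cat_one, L)
      } else {
        mdl <- if (is.na(role[i])) truth_hmm[[sev]] else tilted[[role[i]]][[sev]]
        sequences[[i]] <- sample_sequence(mdl, L, need_multi = multi[i])
      }
    }

    ## -- event days ---------------------------------------------------
    day_list <- vector("list", n)
    for (i in seq_len(n)) {
      L <- n_pages[i]
      if (L == 1) {
        day_list[[i]] <- start[i]
      } else {
        mid <- if (L > 2) {
          sort(sample.int(W[i], L - 2, replace = TRUE)) + start[i] - 1L
        } else integer(0)
        day_list[[i]] <- c(start[i], mid, start[i] + W[i] - 1L)
      }
    }

    ## -- query text and cancers per event ----------------------------
    topic_words <- category_topic_words()
    ev_user <- rep.int(seq_len(n), n_pages)
    ev_day <- unlist(day_list, use.names = FALSE)
    ev_cat <- unlist(sequences, use.names = FALSE)
    ev_disease <- unlist(lapply(seq_len(n), function(i) {
      L <- n_pages[i]
      n_dom <- ceiling(0.6 * L)
      c(rep(dominant[i], n_dom),
        sample(disease_sets[[i]], L - n_dom, replace = TRUE))
    }), use.names = FALSE)
    ev_topic <- vapply(ev_cat, function(cc) {
      pool <- topic_words[[cc]]
      pool[sample.int(length(pool), 1)]
    }, character(1))

    ## -- page ids within categories -----------------------------------
    ev_page <- character(length(ev_cat))
    for (cc in cats) {
      sel <- which(ev_cat == cc)
      n_ev <- length(sel)
      if (n_ev == 0) next
      pops <- integer(0)
      while (sum(pops) < n_ev) {
        pops <- c(pops, rpower_law(max(64, n_ev %/% 2), config$pagepop_exponent,
                                   1, config$xmax))
      }
      pops <- pops[seq_len(which(cumsum(pops) >= n_ev)[1])]
      ids <- rep.int(seq_along(pops), pops)[seq_len(n_ev)]
      ev_page[sel] <- sprintf("p_%s_%05d", cc, ids)
      ev_page[sel] <- ev_page[sel][sample.int(n_ev)]
    }

    if (config$unknown_category_fraction > 0) {
      hide <- runif(length(ev_cat)) < config$unknown_category_fraction
      ev_cat[hide] <- NA_character_
    }

    events <- tibble::tibble(
      user_id = user_ids[ev_user],
      day = as.integer(ev_day),
      query_text = paste(ev_disease, "cancer", ev_topic),
      cancers = ev_disease,
      page_id = ev_page,
      category = ev_cat
    )

    ## -- non-cancer noise rows ----------------------------------------
    n_noise <- round(config$noise_query_fraction * nrow(events))
    if (n_noise > 0) {
      noise_terms <- c("cancun hotels", "weather forecast", "football scores",
                       "pasta recipes", "used cars")
      noise <- tibble::tibble(
        user_id = user_ids[sample.int(n, n_noise, replace = TRUE)],
        day = as.integer(sample.int(D, n_noise, replace = TRUE) - 1L),
        query_text = sample(noise_terms, n_noise, replace = TRUE),
        cancers = "",
        page_id = sprintf("p_noise_%05d", sample.int(2000, n_noise,
                                                     replace = TRUE)),
        category = NA_character_
      )
      events <- dplyr::bind_rows(events, noise)
    }
    events <- dplyr::arrange(events, .data$user_id, .data$day)

    contacts <- tibble::tibble(user_a = node_ids[pmin(edge_a, edge_b)],
                               user_b = node_ids[pmax(edge_a, edge_b)])

    roles <- tibble::tibble(
      user_id = user_ids,
      role = role,
      linked_proband = ifelse(is.na(link), NA_character_, user_ids[link]),
      dominant_disease = dominant,
      severity = severity,
      n_pages = n_pages,
      multi_category = multi,
      window_start = start,
      window_days = W
    )

    list(
      events = events,
      contacts = contacts,
      lexicon = lex,
      truth = list(
        included = user_ids[included],
        roles = roles,
        pairs_planted = tibble::tibble(
          proband = user_ids[planted_a], acquaintance = user_ids[planted_b]),
        n_natural_pairs = C0,
        expected_chance_pairs = kappa * length(edge_a),
        target_pairs = target,
        overlap_match_prob = o_star,
        chance_overlap = q_hat,
        n_nodes = n_nodes,
        config = config
      )
    )
  })
}

#' Simulate crowd labelers for a page-category truth table
#'
#' Each page receives `n_labelers` votes. Unflagged pages get the true
#' category with probability `accuracy`, otherwise a uniformly random
#' other category. Pages flagged ambiguous (a `ambiguous_fraction` random
#' subset) receive votes engineered to reach no three-vote majority: the
#' votes cycle through the true category and two random distractors two
#' at a time.
#'
#' @param truth A tibble with columns `page_id` and `category` (true
#'   labels over [page_categories()]).
#' @param n_labelers Votes per page (default 5).
#' @param accuracy Probability a labeler reports the true category.
#' @param ambiguous_fraction Fraction of pages engineered to be
#'   ambiguous.
#' @param seed Optional integer seed.
#' @return A tibble with `page_id`, vote columns `v1..vN`, and the
#'   engineered `ambiguous` flag.
#' @export
#' @examples
#' truth <- tibble::tibble(page_id = c("p1", "p2"),
#'                         category = c("symptoms", "treatment"))
#' simulate_labelers(truth, accuracy = 1, ambiguous_fraction = 0, seed = 1)
simulate_labelers <- function(truth, n_labelers = 5, accuracy = 0.8,
                              ambiguous_fraction = 0, seed = NULL) {
  stopifnot(is.data.frame(truth), all(c("page_id", "category") %in% names(truth)))
  if (n_labelers < 1) stop("n_labelers must be >= 1", call. = FALSE)
  if (accuracy < 0 || accuracy > 1) {
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  }
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1) {
    stop("ambiguous_fraction must lie in [0, 1]", call. = FALSE)
  }
  cats <- page_categories()
  match_categories(truth$category)
  with_seed(seed, {
    n <- nrow(truth)
    amb <- runif(n) < ambiguous_fraction
    votes <- matrix(NA_character_, nrow = n, ncol = n_labelers)
    for (i in seq_len(n)) {
      true_cat <- truth$category[i]
      if (amb[i]) {
        distract <- sample(setdiff(cats, true_cat),
                           max(2, ceiling(n_labelers / 2)))
        pool <- rep(c(true_cat, distract), each = 2)
        votes[i, ] <- pool[seq_len(n_labelers)]
      } else {
        correct <- runif(n_labelers) < accuracy
        v <- rep(true_cat, n_labelers)
        n_err <- sum(!correct)
        if (n_err > 0) {
          v[!correct] <- sample(setdiff(cats, true_cat), n_err, replace = TRUE)
        }
        votes[i, ] <- v
      }
    }
    out <- tibble::as_tibble(as.data.frame(votes, stringsAsFactors = FALSE))
    names(out) <- paste0("v", seq_len(n_labelers))
    dplyr::bind_cols(tibble::tibble(page_id = truth$page_id), out,
                     tibble::tibble(ambiguous = amb))
  })
}
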