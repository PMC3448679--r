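# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647) + 1L
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Orchestrates every stage in dependency order: simulate (or load) the
#' query log, contact graph and lexicon; construct the cohort; simulate
#' and aggregate crowd labels for the visited pages; fit the power-law
#' slopes (pages per user, users per page, contact degrees); select the
#' number of hidden journey states by holdout and train per-severity
#' models with their signature and stability tables; analyze co-search
#' pairs (enrichment, overlap, lag/duration and category contrasts); and
#' regress disease query shares on the lexicon covariates. Each stage
#' receives a seed derived deterministically from the global seed and
#' the stage name, so stages can be re-run independently; the report is
#' stamped with a configuration hash and identical configurations yield
#' identical reports. A stage whose preconditions fail (e.g. an empty
#' cohort under an extreme page gate) is reported with explicit zero
#' counts instead of aborting downstream stages that do not depend on
#' it; a hard failure aborts with the failing stage named.
#'
#' @param synth A [synthetic_config()], or `NULL` when `data` is given.
#' @param cohort A [cohort_config()].
#' @param candidate_Ks Hidden-state counts scanned by the selection
#'   stage.
#' @param n_restarts Restarts per K.
#' @param n_permutations Permutations for the enrichment null.
#' @param labeler_accuracy Accuracy of the simulated crowd labelers.
#' @param seed Global seed (overrides `synth$seed`).
#' @param data Optional list with `events`, `contacts`, `lexicon` to use
#'   instead of simulating.
#' @param out_dir Optional directory; when given, stage artifacts
#'   (query log, contacts, profiles, models, JSON summaries and the
#'   Markdown report) are written there.
#' @return A `pipeline_report` object: list of stage results plus
#'   `report` (character vector of Markdown lines) and `stamp`.
#' @export
run_pipeline <- function(synth = synthetic_config(),
                         cohort = cohort_config(),
                         candidate_Ks = 2:8,
                         n_restarts = 5,
                         n_permutations = 1000,
                         labeler_accuracy = 0.8,
                         seed = NULL,
                         data = NULL,
                         out_dir = NULL) {
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(seed) && !is.null(synth)) synth$seed <- as.integer(seed)
  seed <- as.integer(seed %||% synth$seed %||% 1L)

  ## simulate ---------------------------------------------------------
  sim <- run_stage("simulate", {
    if (!is.null(data)) {
      list(events = data$events, contacts = data$contacts,
           lexicon = partition_severity(data$lexicon), truth = NULL)
    } else {
      simulate_log(synth)
    }
  })

  ## cohort -----------------------------------------------------------
  cohort_res <- run_stage("cohort", {
    matched <- match_cancer_queries(sim$events, sim$lexicon)
    build_profiles(matched, sim$lexicon, cohort)
  })
  profiles <- cohort_res$profiles

  ## labels -----------------------------------------------------------
  labels_res <- run_stage("labels", {
    page_truth <- sim$events |>
      dplyr::filter(!is.na(.data$category)) |>
      dplyr::distinct(.data$page_id, .data$category)
    if (nrow(page_truth) == 0) {
      list(n_pages = 0L, n_decided = 0L, decided_fraction = NA_real_)
    } else {
      ballots <- simulate_labelers(page_truth, 5, labeler_accuracy,
                                   ambiguous_fraction = 0.05,
                                   seed = stage_seed(seed, "labels"))
      agg <- aggregate_labels(ballots)
      list(n_pages = nrow(agg), n_decided = sum(!agg$ambiguous),
           decided_fraction = mean(!agg$ambiguous),
           patterns = dplyr::count(agg[agg$ambiguous, ], .data$pattern))
    }
  })

  ## heavy-tail fits --------------------------------------------------
  heavytail_res <- run_stage("heavytail", {
    cancer_events <- sim$events[!is.na(sim$events$category), ]
    fits <- list()
    if (nrow(cancer_events) > 0) {
      per_user <- dplyr::count(cancer_events, .data$user_id)$n
      per_page <- dplyr::count(cancer_events, .data$page_id)$n
      if (length(unique(per_user)) >= 2) {
        fits$pages_per_user <- fit_loglog_slope(per_user)
      }
      if (length(unique(per_page)) >= 2) {
        fits$users_per_page <- fit_loglog_slope(per_page)
      }
    }
    if (nrow(sim$contacts) > 0) {
      deg <- c(table(c(sim$contacts$user_a, sim$contacts$user_b)))
      fits$contact_degree <- fit_loglog_slope(deg)
      fits$degree_median <- distribution_median(deg)
    }
    fits
  })

  ## journey models ---------------------------------------------------
  statehmm_res <- run_stage("statehmm", {
    if (nrow(profiles) < 8) {
      list(selection = NULL, models = NULL,
           note = "cohort too small for holdout selection")
    } else {
      sel <- select_num_states(profile_sequences(profiles), candidate_Ks,
                               n_restarts = n_restarts,
                               seed = stage_seed(seed, "statehmm"))
      models <- lapply(c(aggressive = "aggressive", indolent = "indolent"),
                       function(sev) {
        seqs <- profile_sequences(profiles, sev)
        if (length(seqs) < 2) return(NULL)
        fit <- train_hmm(seqs, sel$best_K,
                         seed = stage_seed(seed, paste0("hmm_", sev)))
        list(model = fit, signature = signature_states(fit),
             stability = stability_ranking(fit))
      })
      list(selection = sel, models = models, note = NULL)
    }
  })

  ## social -----------------------------------------------------------
  social_res <- run_stage("social", {
    pairs <- find_pairs(profiles, sim$contacts)
    if (nrow(pairs) == 0 || nrow(sim$contacts) == 0) {
      list(pairs = pairs, n_pairs = nrow(pairs), enrichment = NULL,
           overlap = NULL, contrasts = NULL, preferences = NULL)
    } else {
      list(
        pairs = pairs, n_pairs = nrow(pairs),
        enrichment = enrichment_vs_chance(
          pairs, profiles, sim$contacts, n_permutations,
          seed = stage_seed(seed, "social")),
        overlap = overlap_stats(pairs, profiles,
                                seed = stage_seed(seed, "overlap")),
        contrasts = lag_duration_contrasts(pairs),
        preferences = category_preference_contrast(pairs, profiles)
      )
    }
  })

  ## regression -------------------------------------------------------
  epi_res <- run_stage("regress", {
    if (nrow(profiles) < 5) NULL else {
      incidence_regression(disease_frequency_table(profiles, sim$lexicon))
    }
  })

  stamp <- list(seed = seed,
                config_hash = rlang::hash(list(synth, cohort, candidate_Ks,
                                               n_restarts, n_permutations,
                                               labeler_accuracy)),
                n_users = length(unique(sim$events$user_id)))

  report <- c(
    "# Information-seeking pipeline report",
    sprintf("config hash: %s  seed: %d", stamp$config_hash, stamp$seed),
    "",
    "## Cohort",
    sprintf("- users with events: %d", cohort_res$exclusions$n_users),
    sprintf("- excluded at page gate: %d",
            cohort_res$exclusions$excluded_page_gate),
    sprintf("- excluded at category gate: %d",
            cohort_res$exclusions$excluded_category_gate),
    sprintf("- included: %d", cohort_res$exclusions$n_included),
    "",
    "## Heavy-tailed distributions",
    if (!is.null(heavytail_res$pages_per_user)) {
      sprintf("- pages/user slope %.2f (R2 %.2f)",
              heavytail_res$pages_per_user$slope,
              heavytail_res$pages_per_user$r2)
    } else "- pages/user: not fitted",
    if (!is.null(heavytail_res$users_per_page)) {
      sprintf("- users/page slope %.2f (R2 %.2f)",
              heavytail_res$users_per_page$slope,
              heavytail_res$users_per_page$r2)
    } else "- users/page: not fitted",
    if (!is.null(heavytail_res$contact_degree)) {
      sprintf("- contact degree slope %.2f (R2 %.2f), median %d",
              heavytail_res$contact_degree$slope,
              heavytail_res$contact_degree$r2,
              heavytail_res$degree_median)
    } else "- contact degrees: not fitted",
    "",
    "## Crowd labels",
    sprintf("- %d pages, %d decided (fraction %.3f)",
            labels_res$n_pages, labels_res$n_decided,
            labels_res$decided_fraction),
    "",
    "## Journey model selection",
    if (!is.null(statehmm_res$selection)) {
      sprintf("- best K = %d (holdout error %.3f)",
              statehmm_res$selection$best_K,
              statehmm_res$selection$results$error[
                statehmm_res$selection$results$K ==
                  statehmm_res$selection$best_K])
    } else sprintf("- skipped: %s", statehmm_res$note %||% "no data"),
    "",
    "## Co-search pairs",
    sprintf("- pairs: %d", social_res$n_pairs),
    if (!is.null(social_res$enrichment)) {
      sprintf("- fold enrichment %.2f (p = %.3g)",
              social_res$enrichment$fold, social_res$enrichment$p_value)
    } else "- enrichment: not computed",
    if (!is.null(social_res$overlap)) {
      sprintf("- disease overlap %.2f vs %.2f random",
              social_res$overlap$observed_overlap,
              social_res$overlap$random_overlap)
    } else "- overlap: not computed",
    "",
    "## Query share regression",
    if (!is.null(epi_res)) {
      sprintf("- R2 = %.3f, incidence p = %.2g", epi_res$r_squared,
              glance(epi_res)$incidence_p)
    } else "- skipped: cohort too small"
  )

  result <- structure(
    list(sim = sim, cohort = cohort_res, labels = labels_res,
         heavytail = heavytail_res, statehmm = statehmm_res,
         social = social_res, epi = epi_res, report = report,
         stamp = stamp),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_query_log(sim$events, file.path(out_dir, "query_log.tsv"))
    write_contacts(sim$contacts, file.path(out_dir, "contacts.tsv"))
    write_lexicon(sim$lexicon, file.path(out_dir, "lexicon.csv"))
    if (nrow(profiles) > 0) {
      write_profiles(profiles, file.path(out_dir, "profiles.tsv"))
    }
    jsonlite::write_json(cohort_res$exclusions,
                         file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE)
    if (!is.null(statehmm_res$selection)) {
      readr::write_tsv(statehmm_res$selection$results,
                       file.path(out_dir, "selection_errors.tsv"))
      for (sev in names(statehmm_res$models)) {
        if (!is.null(statehmm_res$models[[sev]])) {
          write_hmm_json(statehmm_res$models[[sev]]$model,
                         file.path(out_dir, paste0("hmm_", sev, ".json")))
        }
      }
    }
    summary_json <- list(
      stamp = stamp,
      exclusions = cohort_res$exclusions,
      n_pairs = social_res$n_pairs,
      fold_enrichment = if (!is.null(social_res$enrichment)) {
        social_res$enrichment$fold
      },
      best_K = if (!is.null(statehmm_res$selection)) {
        statehmm_res$selection$best_K
      },
      regression_r2 = if (!is.null(epi_res)) epi_res$r_squared
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(report, file.path(out_dir, "report.md"))
  }

  result
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
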