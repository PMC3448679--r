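#' Cohort-construction thresholds
#'
#' @param min_pages Minimum categorized cancer page visits for inclusion
#'   (default 5).
#' @param min_categories Minimum distinct page categories (default 2).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(min_pages = 5, min_categories = 2) {
  stopifnot(min_pages >= 1, min_categories >= 1)
  structure(list(min_pages = min_pages, min_categories = min_categories),
            class = "cohort_config")
}

lexicon_patterns <- function(lexicon) {
  vapply(seq_len(nrow(lexicon)), function(i) {
    terms <- tolower(unique(c(lexicon$cancer[i], lexicon$synonyms[[i]])))
    terms <- terms[nzchar(terms)]
    # longest-first so alternation prefers full synonyms
    terms <- terms[order(-nchar(terms))]
    paste0("\\b(", paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", terms),
                         collapse = "|"), ")\\b")
  }, character(1))
}

#' Retain cancer-specific query events
#'
#' Keeps events whose query text contains the name (or any synonym) of a
#' lexicon cancer as a case-insensitive, word-boundary match — "breast
#' cancer symptoms" matches the breast entry, while "cancun hotels" does
#' not match a lexicon built from cancer terms. No stemming is applied.
#' Events matching several cancers are annotated with all of them.
#'
#' @param events Query-event table with a `query_text` column.
#' @param lexicon Lexicon tibble (see [default_lexicon()]).
#' @return The retained rows with a `cancers_matched` list column of
#'   matched cancer names.
#' @export
#' @examples
#' ev <- tibble::tibble(query_text = c("breast cancer symptoms",
#'                                     "cancun hotels"))
#' match_cancer_queries(ev, default_lexicon())
match_cancer_queries <- function(events, lexicon) {
  stopifnot(is.data.frame(events), "query_text" %in% names(events))
  if (!is.data.frame(lexicon) || nrow(lexicon) == 0) {
    stop("lexicon must be a non-empty table", call. = FALSE)
  }
  texts <- stringr::str_to_lower(events$query_text)
  pats <- lexicon_patterns(lexicon)
  hit <- matrix(FALSE, nrow = nrow(events), ncol = nrow(lexicon))
  for (i in seq_along(pats)) {
    hit[, i] <- stringr::str_detect(texts, pats[i])
  }
  any_hit <- rowSums(hit) > 0
  out <- events[any_hit, , drop = FALSE]
  hits <- hit[any_hit, , drop = FALSE]
  out$cancers_matched <- lapply(seq_len(nrow(out)), function(r) {
    lexicon$cancer[hits[r, ]]
  })
  tibble::as_tibble(out)
}

#' Build per-user search profiles with inclusion gates
#'
#' Derives one profile per user from cancer-specific events: the
#' dominant disease (the cancer queried most frequently, counting each
#' matched cancer of an event once; ties resolve alphabetically), its
#' severity group, the day-ordered category sequence (stable within a
#' day in input order), page/category counts and the inclusive day span
#' of cancer-specific activity. Events with unknown (`NA`) category are
#' dropped before any counting, keeping the observable alphabet of the
#' journey models closed. Users must reach `min_pages` categorized
#' visits and `min_categories` distinct categories to be included; the
#' two gates commute, and the tally reports how many users each gate
#' removed (page gate first).
#'
#' @param events Output of [match_cancer_queries()]: rows with
#'   `user_id`, `day`, `category` and `cancers_matched`.
#' @param lexicon Severity-annotated lexicon ([partition_severity()] is
#'   applied if the `severity` column is absent).
#' @param config A [cohort_config()].
#' @return A list with `profiles` (tibble: `user_id`,
#'   `dominant_disease`, `severity`, `category_sequence` list column,
#'   `cancers_all` list column, `n_pages`, `n_categories`, `first_day`,
#'   `last_day`, `search_period_days`) and `exclusions` (named list:
#'   `n_users`, `excluded_page_gate`, `excluded_category_gate`,
#'   `n_included`).
#' @export
build_profiles <- function(events, lexicon, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!"severity" %in% names(lexicon)) lexicon <- partition_severity(lexicon)
  if (!"cancers_matched" %in% names(events)) {
    stop("events must carry cancers_matched; run match_cancer_queries() first",
         call. = FALSE)
  }
  if (nrow(events) == 0) {
    return(list(
      profiles = tibble::tibble(
        user_id = character(0), dominant_disease = character(0),
        severity = character(0), category_sequence = list(),
        cancers_all = list(), n_pages = integer(0), n_categories = integer(0),
        first_day = integer(0), last_day = integer(0),
        search_period_days = numeric(0)),
      exclusions = list(n_users = 0L, excluded_page_gate = 0L,
                        excluded_category_gate = 0L, n_included = 0L)))
  }

  ev <- events |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$user_id, .data$day, .data$.row)
  match_categories(ev$category)

  base <- ev |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      category_sequence = list(.data$category),
      n_pages = dplyr::n(),
      n_categories = dplyr::n_distinct(.data$category),
      first_day = min(.data$day),
      last_day = max(.data$day),
      cancers_all = list(sort(unique(unlist(.data$cancers_matched)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(search_period_days = .data$last_day - .data$first_day + 1)

  dom <- ev |>
    dplyr::select("user_id", "cancers_matched") |>
    tidyr::unnest_longer("cancers_matched", values_to = "cancer") |>
    dplyr::count(.data$user_id, .data$cancer) |>
    dplyr::arrange(.data$user_id, dplyr::desc(.data$n), .data$cancer) |>
    dplyr::distinct(.data$user_id, .keep_all = TRUE) |>
    dplyr::select("user_id", dominant_disease = "cancer")

  sev <- stats::setNames(as.character(lexicon$severity), lexicon$cancer)
  profiles_all <- base |>
    dplyr::left_join(dom, by = "user_id") |>
    dplyr::mutate(severity = unname(sev[.data$dominant_disease])) |>
    dplyr::select("user_id", "dominant_disease", "severity",
                  "category_sequence", "cancers_all", "n_pages",
                  "n_categories", "first_day", "last_day",
                  "search_period_days")

  n_users_with_events <- length(unique(events$user_id))
  pass_pages <- profiles_all$n_pages >= config$min_pages
  pass_cats <- profiles_all$n_categories >= config$min_categories
  # users whose events were all uncategorized fail the page gate too
  n_no_cat <- n_users_with_events - nrow(profiles_all)
  exclusions <- list(
    n_users = n_users_with_events,
    excluded_page_gate = sum(!pass_pages) + n_no_cat,
    excluded_category_gate = sum(pass_pages & !pass_cats),
    n_included = sum(pass_pages & pass_cats)
  )
  list(profiles = profiles_all[pass_pages & pass_cats, , drop = FALSE],
       exclusions = exclusions)
}
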