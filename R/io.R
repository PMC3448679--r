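#' Read and write the package's tabular dialects
#'
#' Query logs are UTF-8 tab-separated files with a header row and
#' columns `user_id day query_text cancers page_id category`; `cancers`
#' is a comma-joined list and `category` one of [page_categories()] or
#' `NA`. Contacts are two-column TSVs (`user_a`, `user_b`), undirected,
#' deduplicated, without self-loops. Profiles are TSVs with
#' `category_sequence` and `cancers_all` comma-joined. Ballots are CSVs
#' `page_id,v1,...,v5`.
#'
#' @param path File path.
#' @param events,contacts,profiles,ballots Tables to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name log_io
NULL

#' @rdname log_io
#' @export
read_query_log <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    user_id = readr::col_character(),
                    day = readr::col_integer(),
                    query_text = readr::col_character(),
                    cancers = readr::col_character(),
                    page_id = readr::col_character(),
                    category = readr::col_character()))
}

#' @rdname log_io
#' @export
write_query_log <- function(events, path) {
  readr::write_tsv(events[, c("user_id", "day", "query_text", "cancers",
                              "page_id", "category")], path)
  invisible(path)
}

#' @rdname log_io
#' @export
read_contacts <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = "cc")
  dedupe_edges(edges)
}

#' @rdname log_io
#' @export
write_contacts <- function(contacts, path) {
  readr::write_tsv(dedupe_edges(contacts), path)
  invisible(path)
}

# canonical undirected edge list: user_a < user_b, no loops, no duplicates
dedupe_edges <- function(edges) {
  stopifnot(all(c("user_a", "user_b") %in% names(edges)))
  a <- pmin(edges$user_a, edges$user_b)
  b <- pmax(edges$user_a, edges$user_b)
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  tibble::tibble(user_a = a[keep], user_b = b[keep])
}

#' @rdname log_io
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles |>
    dplyr::mutate(
      category_sequence = purrr::map_chr(.data$category_sequence, paste,
                                         collapse = ","),
      cancers_all = purrr::map_chr(.data$cancers_all, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname log_io
#' @export
read_profiles <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      category_sequence = strsplit(.data$category_sequence, ",", fixed = TRUE),
      cancers_all = strsplit(.data$cancers_all, ",", fixed = TRUE))
}

#' @rdname log_io
#' @export
read_ballots <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname log_io
#' @export
write_ballots <- function(ballots, path) {
  vote_cols <- grep("^v[0-9]+$", names(ballots), value = TRUE)
  readr::write_csv(ballots[, c("page_id", vote_cols)], path)
  invisible(path)
}

#' Serialize a journey model to or from JSON
#'
#' @param model A `category_hmm`.
#' @param path JSON file path.
#' @return `write_hmm_json()` returns `path` invisibly;
#'   `read_hmm_json()` returns a `category_hmm`.
#' @export
write_hmm_json <- function(model, path) {
  stopifnot(inherits(model, "category_hmm"))
  jsonlite::write_json(
    list(K = model$K, categories = model$categories,
         initial = model$initial,
         transition = model$transition, emission = model$emission,
         loglik = model$loglik),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  category_hmm(x$initial, x$transition, x$emission,
               loglik = x$loglik %||% NA_real_)
}

#' Serialize a generator configuration to or from JSON
#'
#' The JSON document mirrors [synthetic_config()] field for field; the
#' two ground-truth journey models are embedded as their initial,
#' transition and emission tables. An explicit `seed` argument to the
#' reader overrides the stored one.
#'
#' @param config A `synthetic_config`.
#' @param path JSON file path.
#' @param seed Optional seed overriding the stored value on read.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns a validated `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  for (f in c("hmm_truth_aggressive", "hmm_truth_indolent")) {
    m <- x[[f]]
    x[[f]] <- list(initial = m$initial, transition = m$transition,
                   emission = m$emission)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("hmm_truth_aggressive", "hmm_truth_indolent")) {
    x[[f]] <- category_hmm(x[[f]]$initial, x[[f]]$transition,
                           x[[f]]$emission)
  }
  if (!is.null(seed)) x$seed <- as.integer(seed)
  do.call(synthetic_config, x)
}

#' Extract category sequences from profiles
#'
#' Convenience accessor returning the list of category-token vectors
#' (one per included user) consumed by [train_hmm()] and
#' [select_num_states()].
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param severity Optional severity filter (`"aggressive"` or
#'   `"indolent"`).
#' @return List of character vectors.
#' @export
profile_sequences <- function(profiles, severity = NULL) {
  if (!is.null(severity)) {
    profiles <- profiles[profiles$severity == severity, , drop = FALSE]
  }
  profiles$category_sequence
}
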