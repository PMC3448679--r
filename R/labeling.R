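#' Aggregate five-way crowd labels into page categories
#'
#' A page's category is decided when at least three of its five votes
#' agree (with five votes at most one category can reach three, so the
#' decision is unique). Pages without a three-vote majority are flagged
#' ambiguous and classified by their vote pattern: `2+2+1` (two
#' categories with two votes each), `2+1+1+1` (one category with two
#' votes), or `other` (all five votes distinct). The result is invariant
#' to vote order.
#'
#' @param ballots Either a tibble with a `page_id` column and exactly
#'   five vote columns `v1..v5`, or a single character vector of five
#'   votes.
#' @return A tibble with `page_id`, `decided` (category or `NA`),
#'   `ambiguous` (logical), `pattern` (vote pattern string) and
#'   `max_votes`.
#' @export
#' @examples
#' aggregate_labels(c("causes", "symptoms", "causes", "symptoms", "other"))
aggregate_labels <- function(ballots) {
  cats <- page_categories()
  if (is.character(ballots)) {
    ballots <- tibble::tibble(page_id = NA_character_,
                              !!!stats::setNames(as.list(ballots),
                                                 paste0("v", seq_along(ballots))))
  }
  vote_cols <- grep("^v[0-9]+$", names(ballots), value = TRUE)
  if (length(vote_cols) != 5) {
    stop("ballots must have exactly 5 votes per page", call. = FALSE)
  }
  votes <- as.matrix(ballots[, vote_cols])
  if (anyNA(votes)) stop("ballots contain missing votes", call. = FALSE)
  idx <- matrix(match(votes, cats), nrow = nrow(votes))
  if (anyNA(idx)) {
    stop("ballots contain unknown category tokens", call. = FALSE)
  }
  n <- nrow(idx)
  counts <- matrix(0L, nrow = n, ncol = length(cats))
  for (j in seq_len(ncol(idx))) {
    ij <- cbind(seq_len(n), idx[, j])
    counts[ij] <- counts[ij] + 1L
  }
  max_votes <- apply(counts, 1, max)
  winner <- cats[max.col(counts, ties.method = "first")]
  decided <- ifelse(max_votes >= 3, winner, NA_character_)
  pattern <- vapply(seq_len(n), function(r) {
    if (max_votes[r] >= 3) return(NA_character_)
    cc <- sort(counts[r, counts[r, ] > 0], decreasing = TRUE)
    p <- paste(cc, collapse = "+")
    if (p %in% c("2+2+1", "2+1+1+1")) p else "other"
  }, character(1))
  tibble::tibble(
    page_id = if ("page_id" %in% names(ballots)) ballots$page_id else NA,
    decided = decided,
    ambiguous = is.na(decided),
    pattern = pattern,
    max_votes = as.integer(max_votes)
  )
}

# small English stop-word list for the vector space model
label_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "has",
    "have", "in", "is", "it", "its", "of", "on", "or", "that", "the", "this",
    "to", "was", "were", "will", "with", "you", "your")
}

#' Term-frequency vectors for page texts
#'
#' Lowercases, strips non-letter characters, removes a small stop-word
#' list and counts remaining terms, giving each page a sparse
#' term-frequency vector in long (tidy) form.
#'
#' @param pages Tibble with `page_id` and `text` columns.
#' @return A tibble with `page_id`, `term`, `weight` (term count).
#' @export
build_term_vectors <- function(pages) {
  stopifnot(all(c("page_id", "text") %in% names(pages)))
  toks <- pages |>
    dplyr::mutate(term = stringr::str_extract_all(
      stringr::str_to_lower(.data$text), "[a-z]+")) |>
    dplyr::select("page_id", "term") |>
    tidyr::unnest_longer("term") |>
    dplyr::filter(!.data$term %in% label_stopwords())
  toks |>
    dplyr::count(.data$page_id, .data$term, name = "weight") |>
    tibble::as_tibble()
}

# long term vectors -> dense page x term matrix
term_matrix <- function(vectors) {
  pages <- sort(unique(vectors$page_id))
  terms <- sort(unique(vectors$term))
  m <- matrix(0, nrow = length(pages), ncol = length(terms),
              dimnames = list(pages, terms))
  m[cbind(match(vectors$page_id, pages), match(vectors$term, terms))] <-
    vectors$weight
  m
}

#' Cosine distances from pages to category centroids
#'
#' Each category's centroid is the arithmetic mean of the term vectors
#' of its decided pages; the distance from a page to a centroid is the
#' cosine distance (1 minus the cosine of the angle between the raw
#' term-frequency vectors). A page identical to its category's only
#' member is at distance 0; a page sharing no vocabulary with a centroid
#' is at distance 1. Categories without any decided page have no
#' centroid; they are reported and skipped.
#'
#' @param vectors Long term-vector tibble from [build_term_vectors()].
#' @param labels Tibble with `page_id` and `category` for decided pages.
#' @return A tibble `page_id` x `category` with `distance`, covering all
#'   pages in `vectors` and all categories with a centroid; the skipped
#'   categories are kept in the `skipped_categories` attribute.
#' @export
centroid_distances <- function(vectors, labels) {
  stopifnot(all(c("page_id", "term", "weight") %in% names(vectors)),
            all(c("page_id", "category") %in% names(labels)))
  m <- term_matrix(vectors)
  labels <- labels[!is.na(labels$category), , drop = FALSE]
  labels <- labels[labels$page_id %in% rownames(m), , drop = FALSE]
  if (nrow(labels) == 0) {
    stop("no decided pages with term vectors; centroids undefined",
         call. = FALSE)
  }
  present <- intersect(page_categories(), unique(labels$category))
  skipped <- setdiff(page_categories(), present)
  if (length(skipped) > 0) {
    message("no decided pages for: ", paste(skipped, collapse = ", "),
            " (centroids skipped)")
  }
  centroids <- t(vapply(present, function(cc) {
    rows <- labels$page_id[labels$category == cc]
    colMeans(m[rows, , drop = FALSE])
  }, numeric(ncol(m))))
  norm_rows <- function(x) {
    n <- sqrt(rowSums(x^2))
    n[n == 0] <- 1
    x / n
  }
  sim <- norm_rows(m) %*% t(norm_rows(centroids))
  out <- tidyr::expand_grid(page_id = rownames(m), category = present) |>
    dplyr::mutate(distance = 1 - as.vector(t(sim)))
  attr(out, "skipped_categories") <- skipped
  out
}

#' Contrast distance spread of decided and ambiguous pages
#'
#' For each page, the relative spread of its distances to the categories
#' its labelers voted for — `(max - min) / mean` — measures how sharply
#' the vector space separates the candidate categories. Genuinely
#' ambiguous pages sit roughly equidistant from their voted categories
#' (small spread) while decided pages sit clearly closer to one (large
#' spread). Pages with fewer than two voted categories carrying a
#' centroid have no spread and are dropped. The two groups are compared
#' with a two-sided Wilcoxon rank-sum test.
#'
#' @param distances Output of [centroid_distances()].
#' @param ballots Ballot tibble (`page_id`, `v1..v5`).
#' @return An `ambiguity_contrast` object: list with `by_page` (page,
#'   group, relative gap), `summary` (group means and sizes), `p_value`
#'   (rank-sum, `NA` with a flag if either group has fewer than 2
#'   pages), and `flagged`.
#' @export
ambiguity_contrast <- function(distances, ballots) {
  agg <- aggregate_labels(ballots)
  vote_cols <- grep("^v[0-9]+$", names(ballots), value = TRUE)
  voted <- lapply(seq_len(nrow(ballots)), function(r) {
    unique(as.character(unlist(ballots[r, vote_cols])))
  })
  rows <- purrr::map_dfr(seq_len(nrow(ballots)), function(r) {
    d <- distances[distances$page_id == ballots$page_id[r] &
                     distances$category %in% voted[[r]], ]
    if (nrow(d) < 2) return(NULL)
    tibble::tibble(
      page_id = ballots$page_id[r],
      group = ifelse(agg$ambiguous[r], "ambiguous", "decided"),
      relative_gap = (max(d$distance) - min(d$distance)) /
        mean(d$distance)
    )
  })
  if (nrow(rows) == 0 || dplyr::n_distinct(rows$group) < 2) {
    stop("need at least one decided and one ambiguous page with >= 2 voted ",
         "categories", call. = FALSE)
  }
  summary <- rows |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_gap = mean(.data$relative_gap),
                     .groups = "drop")
  flagged <- any(summary$n < 2)
  p <- if (flagged) {
    NA_real_
  } else if (length(unique(rows$relative_gap)) == 1) {
    1  # identical spreads in both groups: no evidence of a difference
  } else {
    suppressWarnings(stats::wilcox.test(
      relative_gap ~ group, data = rows, exact = FALSE)$p.value)
  }
  structure(list(by_page = rows, summary = summary, p_value = p,
                 flagged = flagged),
            class = "ambiguity_contrast")
}

#' @export
print.ambiguity_contrast <- function(x, ...) {
  cat("Relative distance spread to voted categories\n")
  print(x$summary)
  if (x$flagged) {
    cat("rank-sum p undefined (a group has < 2 pages)\n")
  } else {
    cat(sprintf("two-sided rank-sum p = %.3g\n", x$p_value))
  }
  invisible(x)
}

#' @export
tidy.ambiguity_contrast <- function(x, ...) x$summary

#' @export
glance.ambiguity_contrast <- function(x, ...) {
  s <- tidyr::pivot_wider(x$summary, names_from = "group",
                          values_from = c("n", "mean_gap"))
  dplyr::bind_cols(s, tibble::tibble(p.value = x$p_value,
                                     flagged = x$flagged))
}
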