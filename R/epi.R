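#' Disease frequency records for the epidemiological regression
#'
#' Computes each cancer's share of the query log, by default as the
#' percentage of included users whose dominant disease it is; the
#' per-query alternative counts every cancer-matched event instead.
#' Shares cover the whole lexicon (diseases never queried get 0) and
#' sum to 100.
#'
#' @param profiles Included-user profiles from [build_profiles()].
#' @param lexicon Lexicon tibble with covariates.
#' @param events Optional matched event table, required for
#'   `weight = "queries"`.
#' @param weight `"users"` (default) or `"queries"`.
#' @return A tibble with `cancer`, `query_share` (percent),
#'   `incidence_per_100k`, `survival_5yr_pct`, `median_age_dx`.
#' @export
disease_frequency_table <- function(profiles, lexicon, events = NULL,
                                    weight = c("users", "queries")) {
  weight <- match.arg(weight)
  counts <- if (weight == "users") {
    if (nrow(profiles) == 0) stop("no included users", call. = FALSE)
    dplyr::count(profiles, cancer = .data$dominant_disease)
  } else {
    if (is.null(events) || !"cancers_matched" %in% names(events)) {
      stop("weight = \"queries\" needs a matched event table", call. = FALSE)
    }
    events |>
      dplyr::select("cancers_matched") |>
      tidyr::unnest_longer("cancers_matched", values_to = "cancer") |>
      dplyr::count(.data$cancer)
  }
  lexicon |>
    dplyr::select("cancer", "incidence_per_100k", "survival_5yr_pct",
                  "median_age_dx") |>
    dplyr::left_join(counts, by = "cancer") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  query_share = 100 * .data$n / sum(.data$n)) |>
    dplyr::select("cancer", "query_share", "incidence_per_100k",
                  "survival_5yr_pct", "median_age_dx")
}

#' Regress query-log disease frequency on epidemiological covariates
#'
#' Ordinary least squares of the query share on age-adjusted incidence,
#' 5-year relative survival and median age at diagnosis, entered
#' jointly. Reports the model R-squared and two-sided coefficient
#' p-values. A near-singular design (condition number above 1e8) is
#' flagged with a warning rather than an error, as is a constant
#' response (whose R-squared is reported as 0).
#'
#' @param records Output of [disease_frequency_table()] (>= 5 rows).
#' @return An `incidence_fit` object: list with `fit` (the `lm`),
#'   `r_squared`, `coefficients` (tibble of term, estimate, p.value),
#'   `flagged`, `n`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' rec <- tibble::tibble(cancer = lex$cancer,
#'                       query_share = 100 * lex$incidence_per_100k /
#'                         sum(lex$incidence_per_100k),
#'                       incidence_per_100k = lex$incidence_per_100k,
#'                       survival_5yr_pct = lex$survival_5yr_pct,
#'                       median_age_dx = lex$median_age_dx)
#' glance(incidence_regression(rec))
incidence_regression <- function(records) {
  req <- c("query_share", "incidence_per_100k", "survival_5yr_pct",
           "median_age_dx")
  stopifnot(all(req %in% names(records)))
  records <- records[complete.cases(records[, req]), , drop = FALSE]
  if (nrow(records) < 5) stop("need at least 5 records", call. = FALSE)
  covs <- records[, c("incidence_per_100k", "survival_5yr_pct",
                      "median_age_dx")]
  if (any(vapply(covs, function(x) length(unique(x)) == 1, logical(1)))) {
    stop("covariates must be non-constant", call. = FALSE)
  }
  fit <- stats::lm(query_share ~ incidence_per_100k + survival_5yr_pct +
                     median_age_dx, data = records)
  cond <- kappa(stats::model.matrix(fit), exact = TRUE)
  flagged <- cond > 1e8
  if (flagged) {
    warning(sprintf("near-collinear covariates (condition number %.2g)",
                    cond), call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))  # exact relations are legal input
  r2 <- if (stats::var(records$query_share) == 0) 0 else sm$r.squared
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    std.error = sm$coefficients[, "Std. Error"],
    p.value = sm$coefficients[, "Pr(>|t|)"]
  )
  structure(list(fit = fit, r_squared = r2, coefficients = coefs,
                 flagged = flagged, condition_number = cond,
                 n = nrow(records), data = tibble::as_tibble(records)),
            class = "incidence_fit")
}

#' @export
print.incidence_fit <- function(x, ...) {
  cat(sprintf(
    "Query-share regression on incidence, survival, age at diagnosis (n = %d)\n",
    x$n))
  cat(sprintf("R-squared: %.3f%s\n", x$r_squared,
              if (x$flagged) "  [flagged: near-collinear design]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.incidence_fit <- function(x, ...) x$coefficients

#' @export
glance.incidence_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    incidence_p = x$coefficients$p.value[
      x$coefficients$term == "incidence_per_100k"],
    n = x$n, flagged = x$flagged)
}

#' @describeIn incidence_regression Query share against incidence with
#'   the marginal least-squares line.
#' @param object An `incidence_fit`.
#' @param x,... Unused / passed on.
#' @export
autoplot.incidence_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$incidence_per_100k,
                               y = .data$query_share)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "age-adjusted incidence per 100,000",
                  y = "share of cancer queries (%)",
                  title = sprintf("Query share vs incidence (model R² = %.2f)",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
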