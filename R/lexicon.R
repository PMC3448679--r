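#' Built-in cancer lexicon
#'
#' A lexicon of 35 common specific cancers with name synonyms and
#' registry-style statistics: age-adjusted incidence per 100,000,
#' age-adjusted 5-year relative survival (percent) and median age at
#' diagnosis. The bundled values are synthetic stand-ins with realistic
#' magnitudes (the package does not redistribute registry tables); supply
#' your own lexicon via [read_lexicon()] for real analyses.
#'
#' @return A tibble with columns `cancer`, `synonyms` (list column of
#'   character vectors), `incidence_per_100k`, `survival_5yr_pct`,
#'   `median_age_dx`.
#' @seealso [partition_severity()], [read_lexicon()]
#' @export
#' @examples
#' default_lexicon()
default_lexicon <- function() {
  path <- system.file("extdata", "cancer_lexicon_synthetic.csv",
                      package = "infoseekr", mustWork = TRUE)
  read_lexicon(path)
}

#' Read or write a cancer lexicon CSV
#'
#' The lexicon dialect is a CSV with columns
#' `cancer,synonyms,incidence_per_100k,survival_5yr_pct,median_age_dx`,
#' where `synonyms` is a `|`-joined list of alternative names.
#'
#' @param path File path.
#' @return `read_lexicon()` returns a lexicon tibble with `synonyms` split
#'   into a list column; `write_lexicon()` returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("cancer", "synonyms", "incidence_per_100k", "survival_5yr_pct",
           "median_age_dx")
  missing_cols <- setdiff(req, names(lex))
  if (length(missing_cols) > 0) {
    stop("lexicon is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lex |>
    dplyr::mutate(synonyms = strsplit(as.character(.data$synonyms),
                                      "|", fixed = TRUE)) |>
    tibble::as_tibble()
}

#' @rdname read_lexicon
#' @param lexicon A lexicon tibble as returned by [read_lexicon()].
#' @export
write_lexicon <- function(lexicon, path) {
  out <- lexicon |>
    dplyr::mutate(synonyms = purrr::map_chr(.data$synonyms, paste,
                                            collapse = "|"))
  readr::write_csv(out[, c("cancer", "synonyms", "incidence_per_100k",
                           "survival_5yr_pct", "median_age_dx")], path)
  invisible(path)
}

#' Partition cancers into aggressive and indolent severity groups
#'
#' Diseases with 5-year relative survival strictly below the median
#' survival across the lexicon are labeled `aggressive`; all others
#' (including those exactly at the median) are `indolent`. With all
#' survivals equal nothing lies strictly below the median, so every entry
#' is indolent.
#'
#' @param lexicon A lexicon tibble with a `survival_5yr_pct` column.
#' @return The lexicon with a `severity` factor column
#'   (`aggressive`/`indolent`) added.
#' @export
#' @examples
#' partition_severity(default_lexicon())
partition_severity <- function(lexicon) {
  if (nrow(lexicon) < 2) {
    stop("severity partition needs at least two lexicon entries", call. = FALSE)
  }
  surv <- lexicon$survival_5yr_pct
  if (anyNA(surv)) {
    stop("missing 5-year survival values in lexicon", call. = FALSE)
  }
  med <- stats::median(surv)
  lexicon |>
    dplyr::mutate(
      severity = factor(ifelse(surv < med, "aggressive", "indolent"),
                        levels = c("aggressive", "indolent"))
    )
}
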