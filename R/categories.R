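#' Canonical page categories
#'
#' The ten thematic categories used to label cancer-related web pages:
#' causes of cancer, preventive medicine, symptoms, general disease
#' information, treatment, social media (question-and-answer groups),
#' support organizations, celebrity news, pet cancer, and a residual
#' "other" class. All category sequences, emission matrices and label
#' ballots in this package are defined over this fixed alphabet, in this
#' canonical order (which is also the tie-breaking order wherever ties
#' arise).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' page_categories()
page_categories <- function() {
  c("causes", "prevention", "symptoms", "information", "treatment",
    "social_media", "support", "celebrity", "pets", "other")
}

# topic words used to template synthetic query text, one pool per category
category_topic_words <- function() {
  list(
    causes       = c("causes", "risk factors", "hereditary"),
    prevention   = c("prevention", "screening", "vaccine"),
    symptoms     = c("symptoms", "early signs", "warning signs"),
    information  = c("what is", "prognosis", "stages"),
    treatment    = c("treatment", "chemotherapy", "new drugs"),
    social_media = c("forum", "questions", "community answers"),
    support      = c("support group", "awareness", "charity"),
    celebrity    = c("celebrity", "famous people with"),
    pets         = c("in dogs", "in cats"),
    other        = c("news", "pictures", "statistics")
  )
}

match_categories <- function(x, arg = "category") {
  cats <- page_categories()
  bad <- setdiff(unique(x[!is.na(x)]), cats)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s token(s): %s", arg, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  factor(x, levels = cats)
}
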