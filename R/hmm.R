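#' Construct a discrete-emission hidden Markov model over page categories
#'
#' A `category_hmm` couples a latent K-state Markov chain (initial
#' distribution and row-stochastic transition matrix) with a K x 10
#' row-stochastic emission matrix over the canonical page categories.
#' All rows must sum to one within 1e-9 and contain no negative entries.
#'
#' @param initial Numeric K-vector of initial state probabilities.
#' @param transition K x K row-stochastic matrix.
#' @param emission K x 10 row-stochastic matrix; columns follow
#'   [page_categories()].
#' @param loglik Optional log-likelihood to attach (set by [train_hmm()]).
#' @param loglik_trace Optional per-iteration log-likelihood trace.
#' @return A `category_hmm` object.
#' @export
category_hmm <- function(initial, transition, emission,
                         loglik = NA_real_, loglik_trace = numeric(0)) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  K <- length(initial)
  cats <- page_categories()
  if (!all(dim(transition) == c(K, K))) {
    stop("transition must be K x K", call. = FALSE)
  }
  if (nrow(emission) != K || ncol(emission) != length(cats)) {
    stop("emission must be K x 10", call. = FALSE)
  }
  check_rows <- function(m, what) {
    if (any(m < 0)) stop(what, " has negative entries", call. = FALSE)
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-9)) {
      stop(what, " rows must sum to 1 (tolerance 1e-9)", call. = FALSE)
    }
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a probability vector summing to 1", call. = FALSE)
  }
  check_rows(transition, "transition")
  check_rows(emission, "emission")
  colnames(emission) <- cats
  structure(
    list(K = K, initial = initial, transition = transition,
         emission = emission, categories = cats,
         loglik = loglik, loglik_trace = loglik_trace),
    class = "category_hmm"
  )
}

#' @export
print.category_hmm <- function(x, ...) {
  cat(sprintf("category_hmm: %d hidden states over %d categories\n",
              x$K, length(x$categories)))
  if (is.finite(x$loglik)) cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  cat("  self-transitions:", paste(sprintf("%.2f", diag(x$transition)),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Default ground-truth journey models
#'
#' Five-state reference models used by the synthetic generator, one per
#' disease-severity group. The aggressive-disease model is string-like:
#' probability mass flows forward along the state chain, the first two
#' states are the most stable (highest self-transition), treatment-heavy
#' emissions appear late in the chain and the support category never
#' exceeds the 0.05 signature threshold. The indolent-disease model is
#' densely interconnected with roughly symmetric transitions, its last
#' three states are the most stable, and support is a signature output.
#' The exact probabilities are package choices that realize this
#' qualitative structure.
#'
#' @return A `category_hmm` with 5 states.
#' @export
#' @examples
#' signature_states(hmm_truth_indolent())
hmm_truth_aggressive <- function() {
  transition <- rbind(
    c(0.88, 0.09, 0.01, 0.01, 0.01),
    c(0.02, 0.84, 0.11, 0.02, 0.01),
    c(0.01, 0.03, 0.70, 0.24, 0.02),
    c(0.01, 0.02, 0.04, 0.63, 0.30),
    c(0.02, 0.02, 0.04, 0.17, 0.75)
  )
  #            caus  prev  symp  info  trea  socm  supp  cele  pets  othr
  emission <- rbind(
    c(0.04, 0.03, 0.60, 0.20, 0.04, 0.02, 0.01, 0.01, 0.01, 0.04),
    c(0.04, 0.02, 0.09, 0.62, 0.11, 0.03, 0.02, 0.01, 0.01, 0.05),
    c(0.03, 0.02, 0.04, 0.15, 0.60, 0.06, 0.02, 0.01, 0.01, 0.06),
    c(0.55, 0.15, 0.04, 0.08, 0.06, 0.04, 0.02, 0.01, 0.01, 0.04),
    c(0.03, 0.02, 0.02, 0.07, 0.05, 0.28, 0.02, 0.12, 0.08, 0.31)
  )
  category_hmm(c(0.70, 0.14, 0.08, 0.05, 0.03), transition, emission)
}

#' @rdname hmm_truth_aggressive
#' @export
hmm_truth_indolent <- function() {
  transition <- rbind(
    c(0.55, 0.17, 0.10, 0.09, 0.09),
    c(0.15, 0.55, 0.11, 0.10, 0.09),
    c(0.04, 0.05, 0.78, 0.07, 0.06),
    c(0.03, 0.03, 0.05, 0.84, 0.05),
    c(0.03, 0.03, 0.06, 0.07, 0.81)
  )
  #            caus  prev  symp  info  trea  socm  supp  cele  pets  othr
  emission <- rbind(
    c(0.05, 0.04, 0.62, 0.16, 0.04, 0.02, 0.02, 0.01, 0.01, 0.03),
    c(0.04, 0.03, 0.05, 0.11, 0.64, 0.04, 0.03, 0.01, 0.01, 0.04),
    c(0.03, 0.03, 0.03, 0.66, 0.05, 0.06, 0.07, 0.01, 0.01, 0.05),
    c(0.03, 0.02, 0.02, 0.07, 0.04, 0.13, 0.58, 0.02, 0.01, 0.08),
    c(0.03, 0.02, 0.02, 0.06, 0.04, 0.54, 0.11, 0.04, 0.02, 0.12)
  )
  category_hmm(c(0.45, 0.30, 0.10, 0.08, 0.07), transition, emission)
}

# ---- sequence coercion ------------------------------------------------

# Accept a list of character vectors of category tokens (or a single
# vector) and return a list of 0-based integer vectors.
as_category_index_list <- function(sequences) {
  cats <- page_categories()
  if (is.character(sequences)) sequences <- list(sequences)
  if (!is.list(sequences) || length(sequences) == 0) {
    stop("sequences must be a non-empty list of category-token vectors",
         call. = FALSE)
  }
  lapply(sequences, function(s) {
    if (length(s) == 0) stop("empty sequence", call. = FALSE)
    idx <- match(s, cats)
    if (anyNA(idx)) {
      stop("unknown category token(s): ",
           paste(unique(s[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    as.integer(idx - 1L)
  })
}

#' Simulate category sequences from a journey model
#'
#' @param model A `category_hmm`.
#' @param n Number of sequences (users).
#' @param lengths Integer vector of sequence lengths, recycled to `n`.
#' @param seed Optional integer seed.
#' @return A list of `n` character vectors of category tokens.
#' @export
simulate_hmm_sequences <- function(model, n, lengths, seed = NULL) {
  stopifnot(inherits(model, "category_hmm"), n >= 0)
  lengths <- rep_len(as.integer(lengths), n)
  with_seed(seed, {
    cats <- model$categories
    K <- model$K
    lapply(seq_len(n), function(i) {
      L <- lengths[i]
      states <- integer(L)
      states[1] <- sample.int(K, 1, prob = model$initial)
      if (L > 1) {
        for (t in 2:L) {
          states[t] <- sample.int(K, 1, prob = model$transition[states[t - 1], ])
        }
      }
      obs <- vapply(states, function(s) {
        sample.int(length(cats), 1, prob = model$emission[s, ])
      }, integer(1))
      cats[obs]
    })
  })
}

# Run code with a temporary RNG state when seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# ---- training ---------------------------------------------------------

# Random EM starting points: emission rows are drawn sparse (Dirichlet
# concentration < 1) so restarts break the state-permutation symmetry
# decisively, and transition rows carry a sticky diagonal, the natural
# prior for browsing journeys; both choices mainly speed convergence.
random_hmm_init <- function(K, M) {
  rdirichlet_row <- function(conc) {
    g <- stats::rgamma(length(conc), shape = conc)
    g <- g + 1e-8
    g / sum(g)
  }
  transition <- t(vapply(seq_len(K), function(i) {
    conc <- rep(1, K)
    conc[i] <- conc[i] + 4
    rdirichlet_row(conc)
  }, numeric(K)))
  emission <- t(vapply(seq_len(K), function(i) {
    rdirichlet_row(rep(0.4, M))
  }, numeric(M)))
  list(initial = rdirichlet_row(rep(1, K)),
       transition = transition,
       emission = emission)
}

#' Fit a journey model by Baum-Welch expectation-maximization
#'
#' Estimates initial, transition and emission probabilities of a K-state
#' hidden Markov model from category sequences, using the scaled
#' forward-backward recursions. Emission rows receive a small Dirichlet
#' pseudo-count (`smoothing`) at each M-step so that symbols unseen in
#' training never acquire exactly zero probability, which would lock out
#' held-out sequences during model selection. The initial distribution
#' is estimated freely, so sequences whose true beginning was not
#' observed are handled without pinning a designated start state.
#' Iteration stops when the relative log-likelihood change drops below
#' `tol` or after `max_iter` iterations; the per-iteration trace is kept
#' on the fitted object so monotonicity can be audited.
#'
#' @param sequences List of character vectors of category tokens.
#' @param K Number of hidden states (>= 1).
#' @param seed Optional integer seed for the random initialization.
#' @param max_iter,tol EM stopping rule (defaults 500 and 1e-6 relative).
#' @param smoothing Emission pseudo-count per M-step (default 1e-3).
#' @param init Optional list with `initial`, `transition`, `emission` to
#'   start from instead of a random draw.
#' @return A fitted `category_hmm` with `loglik` and `loglik_trace`.
#' @export
#' @examples
#' seqs <- simulate_hmm_sequences(hmm_truth_indolent(), 50, 10, seed = 1)
#' fit <- train_hmm(seqs, K = 3, seed = 1)
#' glance(fit)
train_hmm <- function(sequences, K, seed = NULL, max_iter = 500, tol = 1e-6,
                      smoothing = 1e-3, init = NULL) {
  stopifnot(K >= 1)
  idx <- as_category_index_list(sequences)
  n_events <- sum(lengths(idx))
  if (K > n_events) {
    stop(sprintf("K = %d exceeds the total event count (%d)", K, n_events),
         call. = FALSE)
  }
  M <- length(page_categories())
  if (is.null(init)) {
    init <- with_seed(seed, random_hmm_init(K, M))
  }
  fit <- baum_welch_cpp(idx, init$initial, init$transition, init$emission,
                        as.integer(max_iter), tol, smoothing)
  category_hmm(fit$initial, fit$transition, fit$emission,
               loglik = fit$loglik, loglik_trace = fit$loglik_trace)
}

#' Log-likelihood of sequences under a journey model
#'
#' @inheritParams train_hmm
#' @param model A `category_hmm`.
#' @return Total log-likelihood (sum over sequences).
#' @export
hmm_loglik <- function(model, sequences) {
  stopifnot(inherits(model, "category_hmm"))
  hmm_loglik_cpp(as_category_index_list(sequences), model$initial,
                 model$transition, model$emission)
}

# ---- prediction -------------------------------------------------------

#' One-step-ahead predictive category distribution
#'
#' Runs the forward recursion over `prefix` and returns the exact
#' filtered predictive distribution of the next page category. An empty
#' prefix uses the initial state distribution directly (no transition is
#' applied before the first emission).
#'
#' @param model A `category_hmm`.
#' @param prefix Character vector of category tokens (possibly empty).
#' @return Named numeric vector over the 10 categories, summing to 1.
#' @export
#' @examples
#' predict_next_category(hmm_truth_aggressive(), c("symptoms", "information"))
predict_next_category <- function(model, prefix = character(0)) {
  stopifnot(inherits(model, "category_hmm"))
  cats <- model$categories
  if (length(prefix) == 0) {
    state <- model$initial
  } else {
    obs <- as_category_index_list(list(prefix))[[1]]
    alpha <- hmm_filter_cpp(obs, model$initial, model$transition,
                            model$emission)
    state <- as.numeric(alpha[nrow(alpha), ] %*% model$transition)
  }
  pred <- as.numeric(state %*% model$emission)
  stats::setNames(pred / sum(pred), cats)
}

#' Holdout one-step-ahead prediction error
#'
#' For every position t >= 2 of every test sequence, the next category is
#' predicted as the argmax of [predict_next_category()] on the true
#' prefix; the error is the fraction of mismatches over all scored
#' positions. Argmax ties resolve in canonical category order. A
#' predictive log-loss per scored event is also reported for use as an
#' alternative metric.
#'
#' @param model A `category_hmm`.
#' @param sequences Test sequences (list of token vectors), each of
#'   length >= 2 to be scored.
#' @param metric `"argmax"` (default, 0/1 error) or `"logloss"`.
#' @return A list with `error`, `mean_logloss`, `n_scored`, `n_wrong`,
#'   and `value` (the requested metric).
#' @export
holdout_prediction_error <- function(model, sequences,
                                     metric = c("argmax", "logloss")) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "category_hmm"))
  idx <- as_category_index_list(sequences)
  res <- holdout_error_cpp(idx, model$initial, model$transition,
                           model$emission)
  if (res$n_scored == 0) {
    stop("no scorable positions: all test sequences have length < 2",
         call. = FALSE)
  }
  res$value <- if (metric == "argmax") res$error else res$mean_logloss
  res
}

# ---- model selection --------------------------------------------------

#' Select the number of hidden states by holdout prediction error
#'
#' Users (not events) are split once into a training and a test set; for
#' each candidate K the model is fitted `n_restarts` times from random
#' initializations, the restart with the best training log-likelihood is
#' retained (selection on training likelihood avoids leaking the test
#' set into restart choice), and its one-step-ahead prediction quality
#' is measured on the held-out users. The selected K minimizes the
#' chosen holdout metric, with ties resolved toward the smaller (more
#' parsimonious) K.
#'
#' Both the 0/1 argmax error and the predictive log-loss are computed
#' for every candidate; selection uses the log-loss by default. The two
#' agree about gross underfitting, but around the optimum the argmax
#' error flattens into a plateau — predicting the single most likely
#' category barely changes once the dominant structure is captured — and
#' cannot resolve which state count generalizes best, whereas the
#' log-loss retains a clear minimum because it is sensitive to the
#' calibration of the whole predictive distribution. Set
#' `metric = "argmax"` to select on the raw error fraction instead.
#'
#' @param sequences List of category-token vectors, one per user (>= 8).
#' @param candidate_Ks Integer vector of state counts to scan.
#' @param train_fraction Fraction of users used for training (default 0.75).
#' @param n_restarts Random restarts per K (default 5).
#' @param seed Optional integer seed controlling the split and restarts.
#' @param metric Holdout metric minimized by the selection:
#'   `"logloss"` (default) or `"argmax"`.
#' @param resplit Draw a fresh train/test split for every restart
#'   (default `FALSE`: restarts vary only the initialization).
#' @param ... Passed to [train_hmm()] (e.g. `max_iter`, `smoothing`).
#' @return A `state_selection` object: list with `results` (tibble of
#'   K, error, train log-likelihood, feasibility), `best_K`, `best_model`,
#'   and the call settings.
#' @export
#' @examples
#' seqs <- simulate_hmm_sequences(hmm_truth_aggressive(), 80, 8, seed = 2)
#' sel <- select_num_states(seqs, 1:3, n_restarts = 2, seed = 2)
#' sel$best_K
select_num_states <- function(sequences, candidate_Ks, train_fraction = 0.75,
                              n_restarts = 5, seed = NULL,
                              metric = c("logloss", "argmax"),
                              resplit = FALSE, ...) {
  metric <- match.arg(metric)
  if (length(sequences) < 8) {
    stop("need at least 8 users so both splits are non-empty", call. = FALSE)
  }
  if (length(candidate_Ks) == 0) stop("candidate_Ks is empty", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1, n_restarts >= 1)

  with_seed(seed, {
    n <- length(sequences)
    n_train <- max(1, min(n - 1, round(train_fraction * n)))
    base_split <- sample.int(n, n_train)
    train_events <- sum(lengths(sequences[base_split]))

    rows <- list()
    models <- list()
    for (K in sort(unique(as.integer(candidate_Ks)))) {
      feasible <- K <= train_events
      if (!feasible) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          K = K, error = NA_real_, mean_logloss = NA_real_,
          train_loglik = NA_real_, n_iter = NA_integer_, feasible = FALSE)
        next
      }
      best <- NULL
      for (r in seq_len(n_restarts)) {
        split <- if (resplit && r > 1) sample.int(n, n_train) else base_split
        fit <- train_hmm(sequences[split], K, ...)
        if (is.null(best) || fit$loglik > best$fit$loglik) {
          best <- list(fit = fit, split = split)
        }
      }
      err <- holdout_prediction_error(best$fit, sequences[-best$split],
                                      metric = metric)
      rows[[length(rows) + 1]] <- tibble::tibble(
        K = K, error = err$error, mean_logloss = err$mean_logloss,
        train_loglik = best$fit$loglik,
        n_iter = length(best$fit$loglik_trace), feasible = TRUE)
      models[[as.character(K)]] <- best$fit
    }

    results <- dplyr::bind_rows(rows)
    scored <- if (metric == "argmax") results$error else results$mean_logloss
    ok <- which(results$feasible & !is.na(scored))
    if (length(ok) == 0) stop("no feasible candidate K", call. = FALSE)
    best_row <- ok[which.min(scored[ok])]  # ties -> smaller K (sorted)
    best_K <- results$K[best_row]

    structure(
      list(results = results, best_K = best_K,
           best_model = models[[as.character(best_K)]],
           train_fraction = train_fraction, n_restarts = n_restarts,
           metric = metric, n_users = n, seed = seed),
      class = "state_selection"
    )
  })
}

#' @export
print.state_selection <- function(x, ...) {
  cat(sprintf(
    "Holdout selection of hidden-state count (%d users, %.0f%%/%.0f%% split, %d restarts)\n",
    x$n_users, 100 * x$train_fraction, 100 * (1 - x$train_fraction),
    x$n_restarts))
  print(x$results)
  cat("best K:", x$best_K, "\n")
  invisible(x)
}

#' @export
tidy.state_selection <- function(x, ...) x$results

#' @export
glance.state_selection <- function(x, ...) {
  tibble::tibble(best_K = x$best_K,
                 best_error = x$results$error[x$results$K == x$best_K],
                 n_users = x$n_users, n_restarts = x$n_restarts,
                 train_fraction = x$train_fraction)
}

#' @describeIn select_num_states Prediction-error curve over candidate K.
#' @param object A `state_selection`.
#' @export
autoplot.state_selection <- function(object, ...) {
  df <- object$results[object$results$feasible, ]
  df$error <- if (object$metric == "logloss") df$mean_logloss else df$error
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$error)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = df[df$K == object$best_K, ],
                        colour = "firebrick", size = 3) +
    ggplot2::scale_x_continuous(breaks = df$K) +
    ggplot2::labs(x = "number of hidden states",
                  y = if (object$metric == "logloss") {
                    "holdout predictive log-loss"
                  } else "holdout prediction error",
                  title = "Holdout error by number of hidden states") +
    ggplot2::theme_minimal()
}

# ---- interpretation ---------------------------------------------------

#' Signature output categories of each hidden state
#'
#' Lists, per hidden state, the categories whose emission probability
#' strictly exceeds `threshold`, ordered by decreasing probability; ties
#' keep the canonical category order and are flagged.
#'
#' @param model A `category_hmm`.
#' @param threshold Minimum emission probability (default 0.05, strict).
#' @return A tibble with columns `state`, `category`, `probability`,
#'   `rank`, `tied`.
#' @export
#' @examples
#' signature_states(hmm_truth_indolent())
signature_states <- function(model, threshold = 0.05) {
  stopifnot(inherits(model, "category_hmm"))
  purrr::map_dfr(seq_len(model$K), function(s) {
    p <- model$emission[s, ]
    keep <- which(p > threshold)
    if (length(keep) == 0) {
      return(tibble::tibble(state = integer(0), category = character(0),
                            probability = numeric(0), rank = integer(0),
                            tied = logical(0)))
    }
    ord <- keep[order(-p[keep], keep)]
    tibble::tibble(
      state = s,
      category = model$categories[ord],
      probability = unname(p[ord]),
      rank = seq_along(ord),
      tied = duplicated(p[ord]) | duplicated(p[ord], fromLast = TRUE)
    )
  })
}

#' Rank hidden states by stability
#'
#' Orders states by decreasing self-transition probability — the
#' probability of remaining in the state at the next step. Exact ties
#' keep the canonical state order and are flagged.
#'
#' @param model A `category_hmm`.
#' @return A tibble with columns `state`, `self_transition`, `rank`,
#'   `tied`.
#' @export
stability_ranking <- function(model) {
  stopifnot(inherits(model, "category_hmm"))
  d <- diag(model$transition)
  ord <- order(-d, seq_along(d))
  tibble::tibble(
    state = ord,
    self_transition = unname(d[ord]),
    rank = seq_along(ord),
    tied = duplicated(d[ord]) | duplicated(d[ord], fromLast = TRUE)
  )
}

#' @export
tidy.category_hmm <- function(x, ...) {
  cats <- x$categories
  dplyr::bind_rows(
    tibble::tibble(matrix = "initial", from = NA_integer_,
                   to = as.character(seq_len(x$K)),
                   probability = x$initial),
    tidyr::expand_grid(from = seq_len(x$K), to_i = seq_len(x$K)) |>
      dplyr::mutate(matrix = "transition", to = as.character(.data$to_i),
                    probability = as.vector(t(x$transition))[
                      (.data$from - 1) * x$K + .data$to_i]) |>
      dplyr::select("matrix", "from", "to", "probability"),
    tidyr::expand_grid(from = seq_len(x$K), to_i = seq_along(cats)) |>
      dplyr::mutate(matrix = "emission", to = cats[.data$to_i],
                    probability = as.vector(t(x$emission))[
                      (.data$from - 1) * length(cats) + .data$to_i]) |>
      dplyr::select("matrix", "from", "to", "probability")
  )
}

#' @export
glance.category_hmm <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik,
                 n_iter = length(x$loglik_trace))
}

#' @describeIn category_hmm Transition-matrix heatmap with emission
#'   signatures in the subtitle.
#' @param object A `category_hmm`.
#' @param x,... Unused / passed on.
#' @export
autoplot.category_hmm <- function(object, ...) {
  df <- tidyr::expand_grid(from = seq_len(object$K), to = seq_len(object$K))
  df$probability <- mapply(function(i, j) object$transition[i, j],
                           df$from, df$to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$probability)), size = 3) +
    ggplot2::scale_y_reverse(breaks = seq_len(object$K)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$K)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "to state", y = "from state",
                  title = "Hidden-state transition probabilities") +
    ggplot2::theme_minimal()
}
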