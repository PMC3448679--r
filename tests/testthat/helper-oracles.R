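# Independent oracles used across the suite. These deliberately avoid the
# package's forward recursion and EM code paths.

# one-step predictive distribution by exhaustive enumeration over all
# hidden state paths of length |prefix| + 1
brute_force_predict <- function(model, prefix) {
  cats <- page_categories()
  K <- model$K
  if (length(prefix) == 0) {
    p <- as.numeric(model$initial %*% model$emission)
    return(stats::setNames(p / sum(p), cats))
  }
  obs <- match(prefix, cats)
  Tn <- length(obs) + 1
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  pred <- numeric(length(cats))
  norm <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    w <- model$initial[st[1]] * model$emission[st[1], obs[1]]
    if (Tn > 1) {
      for (t in 2:Tn) {
        w <- w * model$transition[st[t - 1], st[t]]
        if (t < Tn) w <- w * model$emission[st[t], obs[t]]
      }
    }
    pred <- pred + w * model$emission[st[Tn], ]
    norm <- norm + w
  }
  stats::setNames(pred / norm, cats)
}

# random valid category_hmm for property-style tests
random_category_hmm <- function(K) {
  rdir <- function(n) {
    g <- stats::rgamma(n, shape = 1) + 1e-6
    g / sum(g)
  }
  category_hmm(
    rdir(K),
    t(vapply(seq_len(K), function(i) rdir(K), numeric(K))),
    t(vapply(seq_len(K), function(i) rdir(10), numeric(10)))
  )
}

# total-variation distance between two probability vectors
tv_dist <- function(p, q) sum(abs(p - q)) / 2

# permute the hidden states of a model
permute_hmm <- function(model, perm) {
  category_hmm(model$initial[perm],
               model$transition[perm, perm, drop = FALSE],
               model$emission[perm, , drop = FALSE])
}

# exact P(a 5-vote ballot reaches a >= 3 majority) for a labeler that is
# correct with probability `accuracy` and otherwise uniform over the
# other 9 categories: enumerate all vote-count compositions
exact_majority_prob <- function(accuracy) {
  probs <- c(accuracy, rep((1 - accuracy) / 9, 9))
  total <- 0
  comps <- compositions_of(5, 10)
  for (r in seq_len(nrow(comps))) {
    if (max(comps[r, ]) >= 3) {
      total <- total + stats::dmultinom(comps[r, ], prob = probs)
    }
  }
  total
}

# all compositions of n into k non-negative parts
compositions_of <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions_of(n - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}
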