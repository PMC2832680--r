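#' Split a histogram's events into cross-validation folds
#'
#' Events (not channels) are partitioned: each event is assigned to
#' exactly one test fold uniformly at random, so for every fold the train
#' and test counts add up channel-wise to the original histogram, and the
#' test histograms of all folds sum to the original. Reproducible given
#' `seed`.
#'
#' @param h A [channel_histogram()] with at least `n_folds` events.
#' @param n_folds Number of folds (at least 2).
#' @param seed Integer seed.
#' @return List of `n_folds` elements, each a list with `train` and
#'   `test` [channel_histogram()]s.
#' @export
split_folds <- function(h, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(h, "channel_histogram"))
  if (n_folds < 2L) stop("'n_folds' must be at least 2")
  counts <- h$counts
  if (sum(counts) < n_folds)
    stop("histogram has fewer events than folds")
  set.seed(seed)
  nch <- length(counts)
  fold_counts <- matrix(0, nrow = n_folds, ncol = nch)
  occ <- which(counts > 0)
  for (c in occ)
    fold_counts[, c] <- stats::rmultinom(1, counts[c],
                                         rep(1 / n_folds, n_folds))
  lapply(seq_len(n_folds), function(f) {
    test <- fold_counts[f, ]
    list(train = channel_histogram(counts - test, h$concentration,
                                   h$replicate, h$pregrowth),
         test = channel_histogram(test, h$concentration,
                                  h$replicate, h$pregrowth))
  })
}

#' Choose the number of mixture components by 10-fold cross-validation
#'
#' Starting from `K = 1`, fits `K` and `K + 1` Gaussian-component mixtures
#' on the training 90% of each fold and scores each by the mean (per
#' event) held-out log-likelihood of the remaining 10%. The step to
#' `K + 1` components is accepted if and only if its mean fold score
#' exceeds the `K`-component mean fold score by more than `alpha` times
#' the standard deviation (across folds) of the `K + 1` scores; the
#' search stops at the first rejection or at `k_max`. `alpha` sets the
#' stringency: larger values demand stronger evidence before splitting a
#' subpopulation, and the chosen `K` is non-increasing in `alpha`.
#'
#' @inheritParams split_folds
#' @param alpha Stringency multiplier (non-negative).
#' @param k_max Largest component count considered.
#' @param restarts Random restarts per fold fit (passed to
#'   [fit_em_restarts()]).
#' @param comparator Either `"cv"` (default: compare against the
#'   `K`-component model's cross-validation mean on the same folds) or
#'   `"train"` (compare against the `K`-component model's training score).
#' @param ... Further arguments passed to [fit_em_restarts()].
#' @return An object of class `"cv_decision"`: list with `chosen_k`,
#'   `per_k_fold_scores` (one vector of fold scores per tested `K`),
#'   `per_k_mean`, `per_k_sd`, `alpha`, `n_folds`.
#' @export
select_num_components <- function(h, alpha = 1.0, k_max = 6L,
                                  n_folds = 10L, restarts = 100L,
                                  seed = 1L, comparator = c("cv", "train"),
                                  ...) {
  stopifnot(alpha >= 0, k_max >= 1L)
  comparator <- match.arg(comparator)
  folds <- split_folds(h, n_folds = n_folds, seed = seed)
  cv_scores <- function(K) {
    vapply(seq_along(folds), function(f) {
      fit <- fit_em_restarts(folds[[f]]$train, K, n_restarts = restarts,
                             seed = restart_seed(seed, K * 1000L + f), ...)
      n_test <- sum(folds[[f]]$test$counts)
      if (n_test == 0) return(NA_real_)
      mixture_loglik(fit$model, folds[[f]]$test)$loglik / n_test
    }, numeric(1))
  }
  train_score <- function(K) {
    fit <- fit_em_restarts(h, K, n_restarts = restarts,
                           seed = restart_seed(seed, K), ...)
    -fit$mean_nll
  }
  scores <- list()
  scores[[1]] <- cv_scores(1L)
  K <- 1L
  while (K + 1L <= k_max) {
    s_next <- tryCatch(cv_scores(K + 1L), error = function(e) {
      warning("cross-validation fits failed at K = ", K + 1L, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(s_next)) break
    scores[[K + 1L]] <- s_next
    ref <- if (comparator == "cv") mean(scores[[K]], na.rm = TRUE)
           else train_score(K)
    improve <- mean(s_next, na.rm = TRUE) - ref
    if (!is.finite(improve) ||
        improve <= alpha * stats::sd(s_next, na.rm = TRUE)) break
    K <- K + 1L
  }
  names(scores) <- paste0("K", seq_along(scores))
  structure(list(chosen_k = K,
                 per_k_fold_scores = scores,
                 per_k_mean = vapply(scores, mean, numeric(1),
                                     na.rm = TRUE),
                 per_k_sd = vapply(scores, stats::sd, numeric(1),
                                   na.rm = TRUE),
                 alpha = alpha, n_folds = n_folds),
            class = "cv_decision")
}

#' @export
print.cv_decision <- function(x, ...) {
  cat(sprintf(
    "cross-validated component selection: chose K = %d (alpha = %g)\n",
    x$chosen_k, x$alpha))
  print(data.frame(K = seq_along(x$per_k_mean),
                   mean_heldout_ll = round(x$per_k_mean, 5),
                   sd_across_folds = round(x$per_k_sd, 5)),
        row.names = FALSE)
  invisible(x)
}
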