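#' Fit a Gaussian-plus-uniform mixture to a histogram by EM
#'
#' Expectation-maximization on binned channel counts. The E-step computes
#' responsibilities over the uniform outlier component and the `K`
#' Gaussians; the M-step updates the Gaussian weights (renormalized to
#' `1 - uniform_weight`, the uniform weight itself is held fixed), the
#' means (unless `fix_means`) and the variances. A component whose
#' variance falls below `variance_floor` is focussed on a single channel,
#' does not represent a real subpopulation, and is eliminated; the
#' remaining Gaussian weights are renormalized. Iteration stops when the
#' relative log-likelihood change drops below `tol` or after `max_iter`
#' iterations.
#'
#' @param h A [channel_histogram()] with positive total count.
#' @param K Number of Gaussian components (at least 1, at most the number
#'   of occupied channels).
#' @param init Optional initial [mixture_model()]; if `NULL`, means are
#'   placed at the count-weighted quantiles of the data, standard
#'   deviations at 50 and Gaussian weights at `(1 - uniform_weight)/K`.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param fix_means If `TRUE`, component means are never updated (used by
#'   the mode-anchored pipeline, [fit_me_em()]).
#' @param variance_floor Elimination threshold on component variance
#'   (channels squared).
#' @param uniform_weight Fixed weight of the uniform outlier component;
#'   set to 0 for a pure Gaussian mixture.
#' @return An object of class `"mixem_fit"`: list with the fitted `model`,
#'   `loglik`, `mean_nll` (nats/event), `n_iterations`, `converged`,
#'   `eliminated_components`, `degenerate`, and the per-iteration
#'   `loglik_trace`.
#' @seealso [fit_em_restarts()] for the random-restart wrapper.
#' @export
fit_em <- function(h, K, init = NULL, max_iter = 500L, tol = 1e-8,
                   fix_means = FALSE, variance_floor = 1.0,
                   uniform_weight = 0.02) {
  stopifnot(inherits(h, "channel_histogram"), K >= 1L)
  counts <- h$counts
  nch <- length(counts)
  total <- sum(counts)
  if (total <= 0) stop("histogram has zero total count")
  occ <- which(counts > 0)
  if (K > length(occ))
    stop("K = ", K, " exceeds the number of occupied channels (",
         length(occ), ")")
  u <- uniform_weight
  if (is.null(init)) {
    probs <- seq_len(K) / (K + 1)
    cum <- cumsum(counts[occ]) / total
    means <- vapply(probs, function(p) occ[which.max(cum >= p)], numeric(1))
    means <- means + seq_len(K) * 1e-3  # break exact ties between means
    sds <- rep(50, K)
    w <- rep((1 - u) / K, K)
  } else {
    stopifnot(inherits(init, "mixture_model"), length(init$means) == K)
    if (abs(init$uniform_weight - u) > 1e-12)
      u <- init$uniform_weight
    means <- init$means; sds <- init$sds; w <- init$weights
  }

  ch <- seq_len(nch)
  wcounts <- counts[occ]
  trace <- numeric(0)
  eliminated <- 0L
  converged <- FALSE
  prev_ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # component densities at occupied channels, weighted
    dmat <- vapply(seq_along(means), function(i)
      w[i] * stats::dnorm(occ, means[i], sds[i]), numeric(length(occ)))
    dmat <- matrix(dmat, nrow = length(occ))
    tot <- .rowSums(dmat, length(occ), ncol(dmat)) + u / nch
    tot <- pmax(tot, .Machine$double.xmin)
    ll <- sum(wcounts * log(tot))
    trace <- c(trace, ll)
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) <= tol * (abs(prev_ll) + 1e-300)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    prev_ll <- ll
    # M-step
    resp <- dmat / tot                      # Gaussian responsibilities
    Nk <- colSums(wcounts * resp)
    dead <- Nk < 1e-12
    if (!fix_means)
      means <- ifelse(dead, means, colSums(wcounts * resp * occ) / Nk)
    dev2 <- (matrix(occ, length(occ), length(means)) -
               matrix(means, length(occ), length(means), byrow = TRUE))^2
    vars <- ifelse(dead, 0, colSums(wcounts * resp * dev2) / pmax(Nk, 1e-300))
    keep <- !dead & vars >= variance_floor
    if (!all(keep)) {
      eliminated <- eliminated + sum(!keep)
      means <- means[keep]; vars <- vars[keep]; Nk <- Nk[keep]
      if (length(means) == 0L) {
        # all components gone: degenerate uniform-only model
        model <- mixture_model(numeric(0), numeric(0), numeric(0),
                               uniform_weight = 1, n_channels = nch)
        ll <- mixture_loglik(model, h)$loglik
        fit <- structure(list(model = model, loglik = ll,
                              mean_nll = -ll / total,
                              n_iterations = iter, converged = TRUE,
                              degenerate = TRUE,
                              eliminated_components = eliminated,
                              loglik_trace = trace, method = "EM"),
                         class = "mixem_fit")
        return(fit)
      }
      prev_ll <- -Inf  # model changed discontinuously; reset convergence
    }
    sds <- sqrt(vars)
    w <- (1 - u) * Nk / sum(Nk)
  }
  model <- mixture_model(means, sds, w, uniform_weight = u,
                         n_channels = nch)
  ll <- mixture_loglik(model, h)$loglik
  structure(list(model = model, loglik = ll, mean_nll = -ll / total,
                 n_iterations = iter, converged = converged,
                 degenerate = FALSE, eliminated_components = eliminated,
                 loglik_trace = trace, method = "EM"),
            class = "mixem_fit")
}

# deterministic per-restart seed derived from a root seed; depends only on
# (seed, index) so increasing n_restarts never reshuffles earlier restarts
restart_seed <- function(seed, index) {
  as.integer((((as.numeric(seed) %% 1000003) + 1) * 2017 +
                as.numeric(index) * 7919) %% 2147483629)
}

# random initialization rule: means uniform between the lowest and highest
# occupied channel, sds 50, Gaussian weights (1-u)/K
random_init <- function(h, K, seed, uniform_weight = 0.02, init_sd = 50) {
  occ <- which(h$counts > 0)
  set.seed(seed)
  mixture_model(means = stats::runif(K, min(occ), max(occ)),
                sds = rep(init_sd, K),
                weights = rep((1 - uniform_weight) / K, K),
                uniform_weight = uniform_weight,
                n_channels = length(h$counts))
}

#' EM with random restarts
#'
#' Runs [fit_em()] from `n_restarts` random initializations (component
#' means drawn uniformly between the lowest and highest occupied channel,
#' standard deviations 50, equal Gaussian weights) and returns the restart
#' with the highest final log-likelihood; ties are broken by the lowest
#' restart index. The default of 100 restarts guards against stopping at
#' locally optimal solutions. Fully deterministic given `seed`; each
#' restart uses a substream derived from `(seed, restart index)`, so
#' changing `n_restarts` does not reshuffle earlier restarts.
#'
#' @inheritParams fit_em
#' @param n_restarts Number of random restarts.
#' @param seed Integer root seed.
#' @param ... Further arguments passed to [fit_em()].
#' @return A `"mixem_fit"` (see [fit_em()]) with additional element
#'   `n_restarts_used` and `restart_index` of the winning restart.
#' @export
fit_em_restarts <- function(h, K, n_restarts = 100L, seed = 1L,
                            uniform_weight = 0.02, ...) {
  stopifnot(n_restarts >= 1L)
  best <- NULL
  for (i in seq_len(n_restarts)) {
    init <- random_init(h, K, restart_seed(seed, i),
                        uniform_weight = uniform_weight)
    fit <- fit_em(h, K, init = init, uniform_weight = uniform_weight, ...)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart_index <- i
    }
  }
  best$n_restarts_used <- n_restarts
  best
}

#' @export
print.mixem_fit <- function(x, ...) {
  cat(sprintf("%s mixture fit: %d Gaussian component%s\n",
              x$method, length(x$model$means),
              if (length(x$model$means) == 1) "" else "s"))
  cat(sprintf("  loglik %.4f, mean NLL %.6f nats/event, %d iteration%s%s\n",
              x$loglik, x$mean_nll, x$n_iterations,
              if (x$n_iterations == 1) "" else "s",
              if (x$converged) " (converged)" else ""))
  if (x$eliminated_components > 0)
    cat(sprintf("  %d component(s) eliminated at the variance floor\n",
                x$eliminated_components))
  print(x$model)
  invisible(x)
}

#' @export
summary.mixem_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.mixem_fit <- function(object, ...) {
  m <- object$model
  cbind(mean = m$means, sd = m$sds, weight = m$weights)
}

#' @export
logLik.mixem_fit <- function(object, ...) {
  K <- length(object$model$means)
  npar <- if (object$method == "ME+EM") 2 * K else 3 * K - 1
  structure(object$loglik, df = npar, class = "logLik")
}

#' @export
predict.mixem_fit <- function(object, channels = NULL, ...) {
  if (is.null(channels)) channels <- seq_len(object$model$n_channels)
  mixture_density(object$model, channels)
}

#' @export
plot.mixem_fit <- function(x, h = NULL, ...) {
  m <- x$model
  ch <- seq_len(m$n_channels)
  dens <- mixture_density(m, ch)
  if (!is.null(h)) {
    graphics::plot(ch, to_density(h), type = "h", col = "grey80",
                   xlab = "fluorescence channel", ylab = "density", ...)
    graphics::lines(ch, dens, col = "firebrick", lwd = 2)
  } else {
    graphics::plot(ch, dens, type = "l", col = "firebrick", lwd = 2,
                   xlab = "fluorescence channel", ylab = "density", ...)
  }
  for (i in seq_along(m$means))
    graphics::abline(v = m$means[i], lty = 3, col = "grey40")
  invisible(x)
}
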