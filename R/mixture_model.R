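#' Gaussian-plus-uniform mixture model on channel support
#'
#' The density family used throughout: `K` Gaussian components in channel
#' (log-intensity) coordinates plus one uniform component over the whole
#' channel range. The uniform component carries a fixed weight (0.02 by
#' default) and absorbs outlier events such as contaminating particles or
#' sample carry-over; the Gaussian weights share the remaining mass.
#' Components are stored sorted by ascending mean.
#'
#' @param means Numeric vector of component means (channel coordinates).
#' @param sds Numeric vector of component standard deviations (channels,
#'   positive).
#' @param weights Numeric vector of component weights (non-negative); must
#'   sum to `1 - uniform_weight` within `1e-9`.
#' @param uniform_weight Fixed weight of the uniform outlier component.
#' @param n_channels Number of channels of the support.
#' @return An object of class `"mixture_model"`.
#' @examples
#' m <- mixture_model(c(250, 700), c(40, 80), c(0.49, 0.49))
#' sum(m$weights) + m$uniform_weight  # 1
#' @export
mixture_model <- function(means, sds, weights, uniform_weight = 0.02,
                          n_channels = 1024L) {
  K <- length(means)
  stopifnot(length(sds) == K, length(weights) == K,
            length(uniform_weight) == 1L, uniform_weight >= 0,
            uniform_weight <= 1)
  if (K > 0) {
    if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds <= 0))
      stop("component sds must be positive and finite")
    if (any(weights < -1e-12))
      stop("component weights must be non-negative")
  }
  if (abs(sum(weights) + uniform_weight - 1) > 1e-9)
    stop("weights plus uniform_weight must sum to 1")
  ord <- order(means)
  structure(list(means = as.numeric(means[ord]),
                 sds = as.numeric(sds[ord]),
                 weights = pmax(as.numeric(weights[ord]), 0),
                 uniform_weight = as.numeric(uniform_weight),
                 n_channels = as.integer(n_channels)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  K <- length(x$means)
  cat(sprintf("Gaussian+uniform mixture: %d component%s, uniform weight %g\n",
              K, if (K == 1) "" else "s", x$uniform_weight))
  if (K > 0)
    print(data.frame(mean = round(x$means, 2), sd = round(x$sds, 2),
                     weight = round(x$weights, 4)), row.names = FALSE)
  invisible(x)
}

#' Mixture density evaluated at channel coordinates
#'
#' Densities are evaluated at bin centers (integer channels), i.e.
#' `p(c) = uniform_weight / n_channels + sum_i w_i Normal(c; mu_i, sd_i)`.
#'
#' @param model A [mixture_model()].
#' @param channels Numeric vector of channel coordinates (defaults to all
#'   integer channels).
#' @return Numeric vector of densities.
#' @export
mixture_density <- function(model, channels = seq_len(model$n_channels)) {
  stopifnot(inherits(model, "mixture_model"))
  d <- rep(model$uniform_weight / model$n_channels, length(channels))
  for (i in seq_along(model$means))
    d <- d + model$weights[i] *
      stats::dnorm(channels, model$means[i], model$sds[i])
  d
}

#' Log-likelihood of a histogram under a mixture model
#'
#' Sums `counts(c) * log p(c)` over channels, with densities at bin
#' centers. With a positive uniform weight the density is bounded away from
#' zero, so the log-likelihood is always finite; with `uniform_weight = 0`
#' the density is floored at the smallest positive double before taking
#' logs.
#'
#' @param model A [mixture_model()].
#' @param h A [channel_histogram()] with positive total count, on the same
#'   support as `model`.
#' @return List with elements `loglik` (total, nats) and `mean_nll`
#'   (per-event negative log-likelihood, nats/event).
#' @export
mixture_loglik <- function(model, h) {
  stopifnot(inherits(model, "mixture_model"),
            inherits(h, "channel_histogram"))
  if (length(h$counts) != model$n_channels)
    stop("histogram support does not match model support")
  total <- sum(h$counts)
  if (total <= 0) stop("histogram has zero total count")
  occ <- which(h$counts > 0)
  d <- pmax(mixture_density(model, occ), .Machine$double.xmin)
  ll <- sum(h$counts[occ] * log(d))
  list(loglik = ll, mean_nll = -ll / total)
}
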