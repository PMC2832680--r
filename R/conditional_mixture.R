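#' Conditional mixture model across a dose gradient
#'
#' A two-Gaussian-plus-uniform mixture whose parameters are explicit
#' functions of the dose `g` (galactose concentration, percent w/v):
#' the low and high component means are affine in `g`
#' (`mu_low(g) = a_low + b_low g`, `mu_high(g) = a_high + b_high g`), the
#' standard deviations are dose-independent, and the low-component weight
#' is constant at `1 - uniform_weight` up to a threshold dose `g0`, above
#' which it decays exponentially at rate `r`. The high weight is the
#' complement within the Gaussian mass. This parameterization encodes the
#' empirical switching behaviour of a bistable network: an abrupt
#' establishment of the high-expressing subpopulation near `g0`, then a
#' gradual fade-out of the low subpopulation.
#'
#' The default parameter values are the ground truth used by the synthetic
#' data generator (see [default_galactose_spec()]).
#'
#' @param a_low,b_low Intercept (channels) and slope (channels per % gal)
#'   of the low-component mean.
#' @param a_high,b_high Same for the high-component mean.
#' @param sigma_low,sigma_high Component standard deviations (channels).
#' @param g0 Threshold concentration (% w/v) below which the population is
#'   entirely low-expressing.
#' @param r Exponential decay rate of the low weight above `g0` (per % gal).
#' @param uniform_weight Fixed weight of the uniform outlier component.
#' @param n_channels Number of channels of the support.
#' @return An object of class `"conditional_mixture"`.
#' @export
conditional_mixture_model <- function(a_low = 150, b_low = 500,
                                      a_high = 550, b_high = 4000,
                                      sigma_low = 40, sigma_high = 80,
                                      g0 = 0.003, r = 150,
                                      uniform_weight = 0.02,
                                      n_channels = 1024L) {
  stopifnot(sigma_low > 0, sigma_high > 0, r >= 0, g0 >= 0,
            uniform_weight >= 0, uniform_weight < 1)
  structure(list(a_low = a_low, b_low = b_low, a_high = a_high,
                 b_high = b_high, sigma_low = sigma_low,
                 sigma_high = sigma_high, g0 = g0, r = r,
                 uniform_weight = uniform_weight,
                 n_channels = as.integer(n_channels)),
            class = "conditional_mixture")
}

#' @export
print.conditional_mixture <- function(x, ...) {
  cat("conditional mixture model (two Gaussians + uniform outlier)\n")
  cat(sprintf("  low  mean: %.4g + %.4g g   sd %.4g\n",
              x$a_low, x$b_low, x$sigma_low))
  cat(sprintf("  high mean: %.4g + %.4g g   sd %.4g\n",
              x$a_high, x$b_high, x$sigma_high))
  cat(sprintf("  low weight: %.3g below g0 = %.4g, decaying at r = %.4g\n",
              1 - x$uniform_weight, x$g0, x$r))
  invisible(x)
}

#' Low-subpopulation weight as a function of dose
#'
#' Returns `1 - uniform_weight` (0.98 by default) for doses at or below
#' the threshold `g0`, and `(1 - uniform_weight) * exp(-r (g - g0))` above
#' it. The high-component weight is the complement,
#' `(1 - uniform_weight) - weight_low(g)`.
#'
#' @param model A [conditional_mixture_model()].
#' @param g Numeric vector of non-negative doses.
#' @return Numeric vector of low-component weights.
#' @export
weight_low <- function(model, g) {
  stopifnot(inherits(model, "conditional_mixture"), all(g >= 0))
  wmax <- 1 - model$uniform_weight
  ifelse(g <= model$g0, wmax, wmax * exp(-model$r * (g - model$g0)))
}

#' Evaluate a conditional mixture at one dose
#'
#' Instantiates the snapshot [mixture_model()] predicted at dose `g`: two
#' Gaussians with means `a + b g`, the dose-independent standard
#' deviations, weights `(weight_low(g), 0.98 - weight_low(g))`, and the
#' fixed uniform component.
#'
#' @param model A [conditional_mixture_model()].
#' @param g A single non-negative dose.
#' @return A [mixture_model()].
#' @export
predict_mixture <- function(model, g) {
  stopifnot(inherits(model, "conditional_mixture"), length(g) == 1L, g >= 0)
  wl <- weight_low(model, g)
  mixture_model(means = c(model$a_low + model$b_low * g,
                          model$a_high + model$b_high * g),
                sds = c(model$sigma_low, model$sigma_high),
                weights = c(wl, 1 - model$uniform_weight - wl),
                uniform_weight = model$uniform_weight,
                n_channels = model$n_channels)
}
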