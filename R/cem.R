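#' Fit a conditional mixture model across a dose gradient (CEM)
#'
#' Fits the [conditional_mixture_model()] to all histograms of one
#' replicate jointly by a single run of EM (further runs do not improve
#' accuracy for this family, since the initialization is deterministic).
#' The E-step computes responsibilities at every (dose, channel) cell
#' under the current dose-dependent mixture. The M-step updates, in turn:
#' (i) the affine mean coefficients by responsibility-weighted least
#' squares of channel on dose; (ii) the variances by the
#' responsibility-weighted mean squared residual, floored at
#' `variance_floor`; and (iii) the weight-curve parameters `(g0, r)` by
#' maximizing the responsibility-weighted weight log-likelihood over a
#' coarse grid (linear in `g0`, log-spaced in `r`) followed by local
#' univariate refinement, accepting only improving steps. The total
#' log-likelihood is non-decreasing across iterations; a guard reverts
#' any `(g0, r)` step that would lower it.
#'
#' Initialization: means constant in dose at 200 (low) and 700 (high)
#' channels, standard deviations 50, and a first E-step with flat mixture
#' probabilities of 0.49 per Gaussian; the threshold-exponential weight
#' curve is first fitted in the first M-step and used thereafter.
#'
#' @param histograms List of [channel_histogram()]s of one replicate at
#'   three or more distinct doses (an [fc_dataset()] is also accepted and
#'   must contain a single replicate).
#' @param seed Unused (the fit is deterministic); accepted for interface
#'   uniformity with the other fitters.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param variance_floor Lower bound on component variances (channels
#'   squared).
#' @param r_max Upper bound of the decay-rate search grid (per % gal).
#' @param grid_size Grid resolution per axis for the `(g0, r)` search.
#' @param uniform_weight Fixed weight of the uniform outlier component.
#' @return An object of class `"cem_fit"`: list with the fitted `model`
#'   (a [conditional_mixture_model()]), `loglik` (summed over doses),
#'   `mean_nll` (nats/event), `n_iterations`, `converged`,
#'   `loglik_trace`, and the training `concentrations`.
#' @export
fit_cem <- function(histograms, seed = NULL, max_iter = 1000L, tol = 1e-8,
                    variance_floor = 1.0, r_max = 1e4, grid_size = 50L,
                    uniform_weight = 0.02) {
  if (inherits(histograms, "fc_dataset")) histograms <- histograms$histograms
  stopifnot(is.list(histograms), length(histograms) >= 1L)
  ok <- vapply(histograms, inherits, logical(1), "channel_histogram")
  if (!all(ok)) stop("all elements must be channel_histogram objects")
  g <- vapply(histograms, `[[`, numeric(1), "concentration")
  if (length(unique(g)) < 3L)
    stop("need histograms at >= 3 distinct concentrations to identify ",
         "affine means and the weight curve")
  nch <- length(histograms[[1]]$counts)
  C <- vapply(histograms, function(h) {
    if (length(h$counts) != nch) stop("histograms differ in channel count")
    if (sum(h$counts) <= 0) stop("histogram with zero total count")
    h$counts
  }, numeric(nch))
  J <- length(g)
  N <- sum(C)
  ch <- seq_len(nch)
  u <- uniform_weight
  wmax <- 1 - u
  eps <- 1e-12

  # init: means constant in dose, sds 50; weight curve fitted in first M-step
  a_low <- 200; b_low <- 0; a_high <- 700; b_high <- 0
  s_low <- 50; s_high <- 50
  g0 <- NA_real_; r <- NA_real_

  qfun <- function(g0c, rc, Nl, Nh) {
    wl <- ifelse(g <= g0c, wmax, wmax * exp(-rc * (g - g0c)))
    wl <- pmin(pmax(wl, eps), wmax - eps)
    sum(Nl * log(wl) + Nh * log(wmax - wl))
  }
  dens_at <- function(wl_j) {
    dl <- vapply(seq_len(J), function(j)
      wl_j[j] * stats::dnorm(ch, a_low + b_low * g[j], s_low),
      numeric(nch))
    dh <- vapply(seq_len(J), function(j)
      (wmax - wl_j[j]) * stats::dnorm(ch, a_high + b_high * g[j], s_high),
      numeric(nch))
    list(dl = dl, dh = dh,
         tot = pmax(dl + dh + u / nch, .Machine$double.xmin))
  }

  trace <- numeric(0)
  converged <- FALSE
  prev_ll <- -Inf
  prev_g0 <- NA_real_; prev_r <- NA_real_
  iter <- 0L
  ll <- NA_real_
  repeat {
    iter <- iter + 1L
    wl_j <- if (iter == 1L) rep(0.49, J)
            else {
              w <- ifelse(g <= g0, wmax, wmax * exp(-r * (g - g0)))
              pmin(w, wmax)
            }
    d <- dens_at(wl_j)
    ll <- sum(C * log(d$tot))
    if (iter > 1L && is.finite(prev_ll) && ll < prev_ll - 1e-9 * abs(prev_ll) &&
        !is.na(prev_g0)) {
      # ascent guard: revert the (g0, r) step and re-evaluate
      g0 <- prev_g0; r <- prev_r
      wl_j <- pmin(ifelse(g <= g0, wmax, wmax * exp(-r * (g - g0))), wmax)
      d <- dens_at(wl_j)
      ll <- sum(C * log(d$tot))
    }
    if (iter > 1L) trace <- c(trace, ll)
    if (iter > 2L && is.finite(prev_ll) &&
        abs(ll - prev_ll) <= tol * (abs(prev_ll) + 1e-300)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    if (iter > 1L) prev_ll <- ll

    # E-step responsibilities, count-weighted
    vl <- C * d$dl / d$tot
    vh <- C * d$dh / d$tot

    # M-step (i): affine means by weighted least squares of channel on dose
    wls <- function(v) {
      colw <- colSums(v)
      colwy <- colSums(v * ch)
      Sw <- sum(colw)
      xbar <- sum(colw * g) / Sw
      ybar <- sum(colwy) / Sw
      Sxx <- sum(colw * (g - xbar)^2)
      Sxy <- sum((colwy - colw * ybar) * (g - xbar))
      b <- if (Sxx > 1e-300) Sxy / Sxx else 0
      c(a = ybar - b * xbar, b = b, Sw = Sw)
    }
    cl <- wls(vl); chh <- wls(vh)
    a_low <- cl[["a"]]; b_low <- cl[["b"]]
    a_high <- chh[["a"]]; b_high <- chh[["b"]]

    # M-step (ii): dose-independent variances, floored
    var_of <- function(v, a, b, Sw) {
      mu <- a + b * g
      dev2 <- (matrix(ch, nch, J) - matrix(mu, nch, J, byrow = TRUE))^2
      max(sum(v * dev2) / Sw, variance_floor)
    }
    s_low <- sqrt(var_of(vl, a_low, b_low, cl[["Sw"]]))
    s_high <- sqrt(var_of(vh, a_high, b_high, chh[["Sw"]]))

    # M-step (iii): (g0, r) by grid search + univariate refinement
    Nl <- colSums(vl); Nh <- colSums(vh)
    g0s <- seq(0, max(g), length.out = grid_size)
    rs <- c(0, 10^seq(log10(1e-2), log10(r_max),
                      length.out = grid_size - 1L))
    qmat <- outer(g0s, rs, Vectorize(function(a0, r0) qfun(a0, r0, Nl, Nh)))
    best <- arrayInd(which.max(qmat), dim(qmat))
    g0_new <- g0s[best[1]]; r_new <- rs[best[2]]
    # local refinement, one golden-section pass per coordinate
    dg <- diff(range(g0s)) / (grid_size - 1L)
    opt_g0 <- stats::optimize(function(x) qfun(x, r_new, Nl, Nh),
                              c(max(0, g0_new - dg), min(max(g), g0_new + dg)),
                              maximum = TRUE)
    if (opt_g0$objective > qfun(g0_new, r_new, Nl, Nh))
      g0_new <- opt_g0$maximum
    r_lo <- if (best[2] > 1L) rs[max(2L, best[2] - 1L)] / 2 else 0
    r_hi <- min(r_max, r_new * 2 + 1)
    opt_r <- stats::optimize(function(x) qfun(g0_new, x, Nl, Nh),
                             c(r_lo, r_hi), maximum = TRUE)
    if (opt_r$objective > qfun(g0_new, r_new, Nl, Nh))
      r_new <- opt_r$maximum
    prev_g0 <- g0; prev_r <- r
    if (is.na(g0) || qfun(g0_new, r_new, Nl, Nh) >= qfun(g0, r, Nl, Nh)) {
      g0 <- g0_new; r <- r_new
    }
    if (iter == 1L) prev_ll <- -Inf  # flat-weight loglik is not comparable
  }

  model <- conditional_mixture_model(a_low = a_low, b_low = b_low,
                                     a_high = a_high, b_high = b_high,
                                     sigma_low = s_low, sigma_high = s_high,
                                     g0 = g0, r = r,
                                     uniform_weight = u, n_channels = nch)
  structure(list(model = model, loglik = ll, mean_nll = -ll / N,
                 n_iterations = iter, converged = converged,
                 loglik_trace = trace, concentrations = sort(unique(g)),
                 method = "CEM"),
            class = "cem_fit")
}

#' @export
print.cem_fit <- function(x, ...) {
  cat(sprintf("conditional mixture fit (CEM): %d doses, %d iteration%s%s\n",
              length(x$concentrations), x$n_iterations,
              if (x$n_iterations == 1) "" else "s",
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  loglik %.4f, mean NLL %.6f nats/event\n",
              x$loglik, x$mean_nll))
  print(x$model)
  invisible(x)
}

#' @export
summary.cem_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.cem_fit <- function(object, ...) {
  m <- object$model
  c(a_low = m$a_low, b_low = m$b_low, a_high = m$a_high,
    b_high = m$b_high, sigma_low = m$sigma_low, sigma_high = m$sigma_high,
    g0 = m$g0, r = m$r)
}

#' @export
logLik.cem_fit <- function(object, ...)
  structure(object$loglik, df = 8, class = "logLik")

#' Predicted snapshot mixture at a dose
#'
#' @param object A `"cem_fit"`.
#' @param g A single non-negative dose.
#' @param ... Ignored.
#' @return A [mixture_model()] (see [predict_mixture()]).
#' @export
predict.cem_fit <- function(object, g, ...) predict_mixture(object$model, g)

#' Simulate a dataset from a fitted conditional mixture
#'
#' Uses the fitted model as the ground truth of a [synthetic_spec()] and
#' generates one dataset per requested simulation.
#'
#' @param object A `"cem_fit"`.
#' @param nsim Number of datasets.
#' @param seed Integer seed for the first dataset (incremented per
#'   simulation).
#' @param ... Further arguments passed to [synthetic_spec()] (e.g.
#'   `events_per_condition`, `concentrations`).
#' @return A list of `nsim` [fc_dataset()]s (a single dataset if
#'   `nsim = 1`).
#' @export
simulate.cem_fit <- function(object, nsim = 1, seed = 1L, ...) {
  args <- list(...)
  if (is.null(args$concentrations))
    args$concentrations <- object$concentrations
  out <- lapply(seq_len(nsim), function(i) {
    sp <- do.call(synthetic_spec,
                  c(list(truth = object$model, seed = seed + i - 1L), args))
    generate_dataset(sp)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.cem_fit <- function(x, ...) {
  m <- x$model
  g <- seq(0, max(x$concentrations), length.out = 200)
  wl <- weight_low(m, g)
  mu_l <- m$a_low + m$b_low * g
  mu_h <- m$a_high + m$b_high * g
  graphics::plot(g, mu_h, type = "l", col = "firebrick", lwd = 2,
                 ylim = range(c(mu_l, mu_h)),
                 xlab = "galactose concentration (% w/v)",
                 ylab = "fluorescence channel", ...)
  thr <- 0.01
  graphics::lines(g[wl > thr], mu_l[wl > thr], col = "navy", lwd = 2)
  graphics::abline(v = m$g0, lty = 3)
  graphics::legend("topleft", c("high subpopulation", "low subpopulation"),
                   col = c("firebrick", "navy"), lwd = 2, bty = "n")
  invisible(x)
}
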