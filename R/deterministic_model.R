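#' Parameters of the deterministic auto-activation switch
#'
#' A single gene activated by an external signal and by its own protein
#' product, modelled by the ordinary differential equation
#' `dP/dt = basal + vmax * (s P)^n / (K^n + (s P)^n) - gamma * P`:
#' a basal production rate, Hill-type auto-activation whose strength is
#' modulated by the signal `s`, and first-order degradation/dilution.
#' For suitable parameters the system is bistable over an intermediate
#' range of `s`, producing the classical S-shaped bifurcation diagram
#' with two saddle-node (fold) points.
#'
#' The default parameters (`basal = 0.1`, `vmax = 10`, `K = 1`, `n = 2`,
#' `gamma = 1`) are bistable for signals roughly in `s = 0.2` to `0.5`
#' (basal production about 1% of maximal, a typical regime for strongly
#' induced promoters); with a larger basal rate relative to `vmax` the
#' fold disappears and the response becomes graded.
#'
#' @param basal Basal production rate (concentration/time, positive).
#' @param vmax Maximal regulated production (concentration/time,
#'   non-negative; 0 switches regulation off).
#' @param K Activation half-saturation constant (signal x protein units,
#'   positive).
#' @param n Hill coefficient (>= 1; default 2).
#' @param gamma First-order decay rate (1/time, positive).
#' @return An object of class `"switch_params"`.
#' @export
switch_params <- function(basal = 0.1, vmax = 10, K = 1, n = 2, gamma = 1) {
  stopifnot(basal > 0, vmax >= 0, K > 0, n >= 1, gamma > 0)
  structure(list(basal = basal, vmax = vmax, K = K, n = n, gamma = gamma),
            class = "switch_params")
}

switch_rate <- function(P, s, p) {
  a <- (s * P)^p$n
  p$basal + p$vmax * a / (p$K^p$n + a) - p$gamma * P
}

switch_rate_dP <- function(P, s, p) {
  a <- (s * P)^p$n
  d <- ifelse(P > 0 & s > 0,
              p$vmax * p$n * a / P * p$K^p$n / (p$K^p$n + a)^2,
              0)
  d - p$gamma
}

#' Steady states of the auto-activation switch at one signal level
#'
#' Finds all roots of the production-minus-decay rate on
#' `[0, (basal + vmax)/gamma]` by a dense sign scan followed by
#' bisection, and classifies each by the sign of the rate derivative
#' (negative slope = stable). For this system the root count is 1, 2
#' (at a fold) or 3.
#'
#' @param s Non-negative signal level.
#' @param params A [switch_params()].
#' @param n_grid Number of scan points.
#' @return Data frame with columns `P` (steady state), `stable`
#'   (logical), `residual` (rate at the root).
#' @export
steady_states <- function(s, params = switch_params(), n_grid = 4001L) {
  stopifnot(inherits(params, "switch_params"), s >= 0)
  p_max <- (params$basal + params$vmax) / params$gamma
  grid <- seq(0, p_max * (1 + 1e-9), length.out = n_grid)
  f <- switch_rate(grid, s, params)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    if (f[i] == 0) roots <- c(roots, grid[i])
    else if (f[i] * f[i + 1L] < 0) {
      rt <- stats::uniroot(switch_rate, c(grid[i], grid[i + 1L]), s = s,
                           p = params, tol = 1e-12)
      roots <- c(roots, rt$root)
    }
  }
  if (f[n_grid] == 0) roots <- c(roots, grid[n_grid])
  roots <- sort(unique(roots))
  data.frame(P = roots,
             stable = switch_rate_dP(roots, s, params) < 0,
             residual = switch_rate(roots, s, params))
}

#' Bifurcation diagram of the auto-activation switch
#'
#' Computes the steady states over a grid of signal values and locates
#' the fold (saddle-node) points where the root count changes, refining
#' each by bisection on the signal. For a bistable parameter set the
#' count changes 1 -> 3 -> 1 and exactly two fold points bound the
#' three-root interval.
#'
#' @param s_grid Increasing numeric vector of signal values.
#' @param params A [switch_params()].
#' @param n_grid Scan resolution passed to [steady_states()].
#' @param fold_tol Bisection tolerance on the fold-point signal values.
#' @return An object of class `"bifurcation_diagram"`: list with
#'   `states` (data frame: `s`, `P`, `stable`) and `fold_points`
#'   (numeric vector of refined fold signal values).
#' @export
bifurcation_diagram <- function(s_grid, params = switch_params(),
                                n_grid = 4001L, fold_tol = 1e-8) {
  stopifnot(all(diff(s_grid) > 0))
  per_s <- lapply(s_grid, steady_states, params = params, n_grid = n_grid)
  counts <- vapply(per_s, nrow, integer(1))
  states <- do.call(rbind, lapply(seq_along(s_grid), function(i)
    data.frame(s = s_grid[i], P = per_s[[i]]$P,
               stable = per_s[[i]]$stable)))
  folds <- numeric(0)
  for (i in seq_len(length(s_grid) - 1L)) {
    if (counts[i] != counts[i + 1L]) {
      lo <- s_grid[i]; hi <- s_grid[i + 1L]
      c_lo <- counts[i]
      while (hi - lo > fold_tol * max(1, abs(hi))) {
        mid <- (lo + hi) / 2
        c_mid <- nrow(steady_states(mid, params, n_grid))
        if (c_mid == c_lo) lo <- mid else hi <- mid
      }
      folds <- c(folds, (lo + hi) / 2)
    }
  }
  structure(list(states = states, fold_points = folds, params = params),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation diagram: %d signal levels, %d fold point%s",
              length(unique(x$states$s)), length(x$fold_points),
              if (length(x$fold_points) == 1) "" else "s"))
  if (length(x$fold_points))
    cat(" at s = ", paste(signif(x$fold_points, 6), collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  st <- x$states
  graphics::plot(st$s, st$P, pch = 19, cex = 0.4,
                 col = ifelse(st$stable, "black", "grey60"),
                 xlab = "input signal s", ylab = "steady-state P", ...)
  for (fp in x$fold_points) graphics::abline(v = fp, lty = 3)
  invisible(x)
}
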