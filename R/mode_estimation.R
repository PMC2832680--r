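#' Running-average smoothing of channel counts
#'
#' Centered moving average over a window of `window` channels, applied to
#' counts normalized to the counts-per-10,000-events scale
#' (`counts * 1e4 / total`), which makes the downstream derivative
#' threshold independent of sample size. Near the edges the window
#' truncates to the available channels and renormalizes.
#'
#' @param counts Non-negative numeric vector of channel counts.
#' @param window Odd window width in channels (default 71).
#' @return Smoothed numeric vector on the per-10,000-events scale.
#' @export
smooth_counts <- function(counts, window = 71L) {
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window < 3 || window > length(counts))
    stop("'window' must be between 3 and length(counts)")
  total <- sum(counts)
  if (total <= 0) stop("zero total count")
  s <- counts * 1e4 / total
  n <- length(s)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(s))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Centered finite-difference derivative estimate
#'
#' `d(c) = (x(c + h) - x(c - h)) / (2 h)` with `h = (span - 1)/2`.
#' Positions within `h` of either edge are undefined, filled with 0 and
#' reported in attribute `"valid"` (the index range where the estimate is
#' defined). Exact for affine series in the interior, and exact for the
#' second difference of quadratics when applied twice.
#'
#' @param series Numeric vector.
#' @param span Odd span in channels (default 71, same as the smoothing
#'   window).
#' @return Numeric vector of derivative estimates with attribute
#'   `"valid"`.
#' @export
central_difference <- function(series, span = 71L) {
  if (span %% 2 == 0) stop("'span' must be odd")
  n <- length(series)
  if (span >= n) stop("'span' must be smaller than the series length")
  h <- (span - 1L) %/% 2L
  d <- numeric(n)
  idx <- (h + 1L):(n - h)
  d[idx] <- (series[idx + h] - series[idx - h]) / (2 * h)
  attr(d, "valid") <- c(h + 1L, n - h)
  d
}

#' Detect density modes by smoothed derivatives
#'
#' The peak detector: smooth the histogram ([smooth_counts()]), estimate
#' first and second derivatives by centered differences of the same span,
#' and scan for downward zero crossings of the first derivative
#' (`d1(c) > 0` followed by `d1(c + 1) <= 0`). A crossing is accepted as a
#' mode if and only if the curvature there is convincingly negative:
#' `d2(c) <= theta` (the default criterion). Real subpopulation peaks
#' produce second derivatives two orders of magnitude below the default
#' threshold on the normalized scale, while sampling-noise wiggles and
#' very broad low-weight bumps stay two orders of magnitude above it.
#' `criterion = "product"` instead thresholds the combined quantity
#' `max(d1) over the half-window before the crossing, times d2(c)`;
#' small bumps have both small first and second derivatives in the
#' vicinity of a mode, so the product also discriminates peak size, but
#' its scale is less well matched to the default `theta` (see the
#' methods vignette). The reported mode location is the argmax of the
#' smoothed series over the two channels flanking the crossing. Channels
#' within a full span of either edge are never eligible. Because the
#' smoothed series is normalized per 10,000 events, `theta` is
#' sample-size-free.
#'
#' @param h A [channel_histogram()] with positive total count.
#' @param window Odd smoothing/differencing window (channels).
#' @param theta Acceptance threshold on the combined derivative
#'   (negative; default -0.0002 on the per-10,000-events scale).
#' @param criterion `"d2"` (default) or `"product"`.
#' @return An object of class `"mode_set"`: list with `modes` (ascending
#'   channel coordinates; may be empty), `smoothed`, `d1`, `d2`, and the
#'   per-crossing diagnostic table `crossings`.
#' @export
detect_modes <- function(h, window = 71L, theta = -2e-4,
                         criterion = c("d2", "product")) {
  stopifnot(inherits(h, "channel_histogram"))
  criterion <- match.arg(criterion)
  sm <- smooth_counts(h$counts, window)
  d1 <- central_difference(sm, window)
  d2 <- central_difference(as.numeric(d1), window)
  n <- length(sm)
  hh <- (window - 1L) %/% 2L
  elig <- (2L * hh + 1L):(n - 2L * hh - 1L)  # d2 defined, crossing inspectable
  cand <- elig[d1[elig] > 0 & d1[elig + 1L] <= 0]
  crit <- if (criterion == "product")
    vapply(cand, function(c) max(d1[(c - hh):c]) * d2[c], numeric(1))
  else d2[cand]
  acc <- cand[crit <= theta]
  modes <- vapply(acc, function(c) if (sm[c + 1L] > sm[c]) c + 1L else c,
                  integer(1))
  structure(list(modes = as.numeric(sort(modes)),
                 smoothed = sm, d1 = d1, d2 = d2,
                 crossings = data.frame(channel = cand, criterion = crit,
                                        accepted = crit <= theta),
                 window = window, theta = theta),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode detection (window %d, theta %g): %d mode%s",
              x$window, x$theta, length(x$modes),
              if (length(x$modes) == 1) "" else "s"))
  if (length(x$modes))
    cat(" at channel(s) ", paste(x$modes, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Mode-estimation-plus-EM mixture fit
#'
#' The mode-anchored pipeline: detect density modes with [detect_modes()],
#' introduce one Gaussian component per mode with its mean pinned at the
#' mode location, and run a single pass of EM ([fit_em()] with
#' `fix_means = TRUE`) to fit the mixture coefficients and variances
#' (standard deviations initialized at 50, Gaussian weights equal).
#'
#' @inheritParams detect_modes
#' @param ... Further arguments passed to [fit_em()].
#' @return A `"mixem_fit"` (see [fit_em()]) with `method = "ME+EM"` and
#'   the `mode_set` attached as element `modes`.
#' @export
fit_me_em <- function(h, window = 71L, theta = -2e-4, ...) {
  ms <- detect_modes(h, window = window, theta = theta)
  K <- length(ms$modes)
  if (K == 0L)
    stop("no modes detected; fall back to fit_em_restarts() with K = 1")
  dots <- list(...)
  u <- if (!is.null(dots$uniform_weight)) dots$uniform_weight else 0.02
  init <- mixture_model(means = ms$modes, sds = rep(50, K),
                        weights = rep((1 - u) / K, K),
                        uniform_weight = u,
                        n_channels = length(h$counts))
  fit <- fit_em(h, K, init = init, fix_means = TRUE, ...)
  fit$method <- "ME+EM"
  fit$modes <- ms
  fit
}
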