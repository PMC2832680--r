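#' Specification of a synthetic dose-gradient experiment
#'
#' Describes both the ground-truth generative model (a
#' [conditional_mixture_model()]) and the acquisition design (dose levels,
#' replicates, pregrowth arms, events collected, scatter-gate retention,
#' replicate-level jitter). [generate_dataset()] turns a spec into data.
#'
#' Pregrowth history enters the generative model only through the weight
#' threshold: under raffinose (uninduced) pregrowth the switching threshold
#' `g0` is multiplied by `raf_threshold_scale`, emulating the transition
#' occurring over a slightly higher dose range when starting uninduced.
#'
#' @param truth Ground-truth [conditional_mixture_model()].
#' @param concentrations Numeric vector of distinct non-negative doses
#'   (% w/v galactose).
#' @param n_replicates Biological replicates per pregrowth arm.
#' @param pregrowths Character vector, subset of `c("gal", "raf")`.
#' @param events_per_condition Events collected per condition before
#'   gating.
#' @param gate_fraction Probability that an event survives the scatter
#'   gate (gating is independent of fluorescence).
#' @param replicate_jitter_sd Standard deviation (channels) of a
#'   per-replicate shift added to both mean intercepts, emulating
#'   replicate-to-replicate variability.
#' @param raf_threshold_scale Multiplier applied to `g0` in the raffinose
#'   pregrowth arm.
#' @param seed Integer seed making generation fully reproducible.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(truth = conditional_mixture_model(),
                           concentrations = galactose_concentrations(),
                           n_replicates = 4L,
                           pregrowths = c("gal", "raf"),
                           events_per_condition = 60000L,
                           gate_fraction = 0.5,
                           replicate_jitter_sd = 10,
                           raf_threshold_scale = 1.5,
                           seed = 1L) {
  stopifnot(inherits(truth, "conditional_mixture"),
            all(pregrowths %in% c("gal", "raf")),
            length(pregrowths) >= 1L,
            n_replicates >= 1L,
            events_per_condition > 0,
            gate_fraction > 0, gate_fraction <= 1,
            replicate_jitter_sd >= 0, raf_threshold_scale > 0)
  concentrations <- as.numeric(concentrations)
  if (any(concentrations < 0) || anyDuplicated(concentrations))
    stop("'concentrations' must be distinct and non-negative")
  structure(list(truth = truth, concentrations = concentrations,
                 n_replicates = as.integer(n_replicates),
                 pregrowths = unique(pregrowths),
                 events_per_condition = as.integer(events_per_condition),
                 gate_fraction = gate_fraction,
                 replicate_jitter_sd = replicate_jitter_sd,
                 raf_threshold_scale = raf_threshold_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic dose-gradient experiment spec\n")
  cat(sprintf("  %d concentrations x %d replicates x {%s} pregrowth\n",
              length(x$concentrations), x$n_replicates,
              paste(x$pregrowths, collapse = ", ")))
  cat(sprintf("  %d events/condition, gate fraction %.2f, jitter sd %g\n",
              x$events_per_condition, x$gate_fraction,
              x$replicate_jitter_sd))
  invisible(x)
}

#' The 17 galactose concentrations of the emulated experiment
#'
#' The dose ladder analysed in the emulated experiment: 17 galactose
#' concentrations (% w/v) spanning 0 to 0.08, densest around the switching
#' threshold.
#'
#' @return Numeric vector of length 17.
#' @export
galactose_concentrations <- function() {
  c(0.0, 0.0015, 0.0022, 0.0033, 0.0038, 0.0043, 0.0050, 0.0057, 0.0066,
    0.0076, 0.0087, 0.0100, 0.0115, 0.0132, 0.0174, 0.020, 0.080)
}

#' Default spec replicating the emulated galactose experiment
#'
#' 17 galactose concentrations, 4 replicates in each of the two pregrowth
#' arms, 60,000 events per condition, a 50% scatter gate, and the default
#' ground-truth conditional mixture.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
default_galactose_spec <- function(seed = 1L) synthetic_spec(seed = seed)

#' Generate a synthetic flow-cytometry dataset
#'
#' For each (pregrowth, replicate, concentration) condition: a
#' per-replicate jitter shift is drawn and added to both mean intercepts;
#' each of `events_per_condition` events is assigned to the low Gaussian,
#' high Gaussian, or uniform outlier component with probabilities
#' `(w_low(g), 0.98 - w_low(g), 0.02)`; channel values are drawn from the
#' component distribution, thinned by the scatter gate independently of
#' their value, rounded to the nearest integer channel, clipped to the
#' channel range (emulating cytometer rail channels), and binned.
#' Generation is fully reproducible given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param keep_labels If `TRUE`, attach a per-condition table of true
#'   component tallies among retained events as attribute `"labels"` of the
#'   returned dataset (used for generator self-checks).
#' @return An [fc_dataset()].
#' @examples
#' sp <- synthetic_spec(events_per_condition = 1000,
#'                      concentrations = c(0, 0.005, 0.08),
#'                      n_replicates = 1, pregrowths = "gal")
#' ds <- generate_dataset(sp)
#' length(ds$histograms)  # 3
#' @export
generate_dataset <- function(spec, keep_labels = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- spec$truth
  nch <- truth$n_channels
  u <- truth$uniform_weight
  set.seed(spec$seed)
  hists <- list()
  labels <- list()
  for (pg in sort(spec$pregrowths)) {
    g0 <- truth$g0 * if (pg == "raf") spec$raf_threshold_scale else 1
    for (rep_i in seq_len(spec$n_replicates)) {
      jitter <- stats::rnorm(1, 0, spec$replicate_jitter_sd)
      for (g in spec$concentrations) {
        wl <- if (g <= g0) 1 - u else (1 - u) * exp(-truth$r * (g - g0))
        n <- spec$events_per_condition
        comp <- sample.int(3L, n, replace = TRUE,
                           prob = c(wl, 1 - u - wl, u))
        x <- numeric(n)
        i1 <- comp == 1L; i2 <- comp == 2L; i3 <- comp == 3L
        x[i1] <- stats::rnorm(sum(i1), truth$a_low + jitter +
                                truth$b_low * g, truth$sigma_low)
        x[i2] <- stats::rnorm(sum(i2), truth$a_high + jitter +
                                truth$b_high * g, truth$sigma_high)
        x[i3] <- stats::runif(sum(i3), 1, nch)
        keep <- stats::runif(n) < spec$gate_fraction
        ch <- pmin(pmax(round(x[keep]), 1), nch)
        h <- channel_histogram(tabulate(ch, nbins = nch),
                               concentration = g,
                               replicate = as.character(rep_i),
                               pregrowth = pg)
        hists[[length(hists) + 1L]] <- h
        if (keep_labels)
          labels[[length(labels) + 1L]] <- data.frame(
            key = histogram_key(h),
            n_low = sum(i1 & keep), n_high = sum(i2 & keep),
            n_outlier = sum(i3 & keep), n_retained = sum(keep))
      }
    }
  }
  ds <- fc_dataset(hists, channel_transform(n_channels = nch))
  if (keep_labels)
    attr(ds, "labels") <- do.call(rbind, labels)
  ds
}
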