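#' Assemble the stochastic bifurcation structure from per-dose fits
#'
#' The stochastic bifurcation structure summarizes, as a function of the
#' dose: the number of distinguishable subpopulations, their locations
#' (Gaussian means), their within-subpopulation variability (Gaussian
#' standard deviations), and the fractions of the population they
#' represent (Gaussian weights renormalized by the Gaussian mass
#' `1 - uniform_weight` so they sum to 1).
#'
#' For conditional-mixture fits the low component formally exists at
#' every dose with exponentially vanishing size; it is reported only
#' while its mixture coefficient exceeds `low_report_threshold`
#' (components whose weight is at or below the threshold are omitted).
#'
#' @param fits For the default method: a named list mapping dose (as a
#'   decimal string or numeric names) to [mixture_model()] or
#'   `"mixem_fit"` objects. For the `"cem_fit"` method: the fitted CEM.
#' @param ... Passed between methods.
#' @return An object of class `"bifurcation_structure"`: a data frame
#'   with columns `concentration`, `n_subpops`, `subpop` (component index
#'   by ascending mean), `location`, `spread`, `fraction`.
#' @export
extract_structure <- function(fits, ...) UseMethod("extract_structure")

#' @rdname extract_structure
#' @param concentrations Doses at which to evaluate a `"cem_fit"`.
#' @param low_report_threshold Minimum mixture coefficient for a
#'   component of a conditional fit to be reported (default 0.01).
#' @export
extract_structure.cem_fit <- function(fits,
                                      concentrations = fits$concentrations,
                                      low_report_threshold = 0.01, ...) {
  models <- lapply(concentrations, function(g) {
    m <- predict_mixture(fits$model, g)
    keep <- m$weights > low_report_threshold
    if (!any(keep)) keep[which.max(m$weights)] <- TRUE
    mixture_model(m$means[keep], m$sds[keep],
                  m$weights[keep] * (1 - m$uniform_weight) /
                    sum(m$weights[keep]),
                  uniform_weight = m$uniform_weight,
                  n_channels = m$n_channels)
  })
  names(models) <- format_concentration(concentrations)
  extract_structure.default(models)
}

#' @rdname extract_structure
#' @export
extract_structure.default <- function(fits, ...) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  rows <- lapply(names(fits), function(key) {
    m <- fits[[key]]
    if (inherits(m, "mixem_fit")) m <- m$model
    stopifnot(inherits(m, "mixture_model"))
    K <- length(m$means)
    if (K == 0L) return(NULL)
    gmass <- sum(m$weights)
    data.frame(concentration = as.numeric(key),
               n_subpops = K,
               subpop = seq_len(K),
               location = m$means,
               spread = m$sds,
               fraction = m$weights / gmass)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$concentration, out$subpop), ]
  rownames(out) <- NULL
  class(out) <- c("bifurcation_structure", "data.frame")
  out
}

#' @export
print.bifurcation_structure <- function(x, ...) {
  cat("stochastic bifurcation structure\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.bifurcation_structure <- function(x, ...) {
  graphics::plot(x$concentration, x$location, pch = 19,
                 col = ifelse(x$subpop == 1 & x$n_subpops > 1, "navy",
                              "firebrick"),
                 xlab = "dose", ylab = "subpopulation location (channel)",
                 ...)
  invisible(x)
}

# evaluate any fitted object on a histogram: per-event mean NLL
model_mean_nll <- function(model_obj, h) {
  if (inherits(model_obj, "cem_fit"))
    model_obj <- predict_mixture(model_obj$model, h$concentration)
  else if (inherits(model_obj, "mixem_fit"))
    model_obj <- model_obj$model
  stopifnot(inherits(model_obj, "mixture_model"))
  mixture_loglik(model_obj, h)$mean_nll
}

# fetch the model applying to histogram h from one replicate's fit record:
# a cem_fit applies to all doses; a list of per-dose fits is keyed by
# format_concentration(dose)
replicate_model_for <- function(rep_models, h) {
  if (inherits(rep_models, "cem_fit")) return(rep_models)
  key <- format_concentration(h$concentration)
  m <- rep_models[[key]]
  if (is.null(m))
    stop("no model for concentration ", key, " in replicate fit record")
  m
}

#' Training and testing goodness-of-fit across replicates
#'
#' For every method and replicate, the training score is the mean
#' negative log-likelihood (nats/event) of the model on the replicate it
#' was fit to, averaged over doses; the testing score evaluates the same
#' model on the corresponding histograms of the other replicates with the
#' same pregrowth condition. Conditional fits are evaluated at each dose
#' through their predicted snapshot mixtures. 95% confidence intervals on
#' the method-level means are obtained by a seeded percentile bootstrap
#' over conditions.
#'
#' @param models Nested list: `models[[method]][[replicate_key]]` where
#'   `replicate_key` is `"pregrowth:replicate"` and the value is either a
#'   `"cem_fit"` or a named list of per-dose [mixture_model()] /
#'   `"mixem_fit"` objects keyed by the decimal dose string.
#' @param dataset The [fc_dataset()] the models were fit to; all
#'   replicates of a pregrowth must share doses.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `"nll_scores"`: list with `scores` (one row
#'   per method and replicate, columns `train` and `test`) and `summary`
#'   (per method and split: mean, `ci_lo`, `ci_hi`).
#' @export
train_test_nll <- function(models, dataset, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(dataset, "fc_dataset"), is.list(models))
  hs <- dataset$histograms
  meta <- data.frame(
    key = names(hs),
    pregrowth = vapply(hs, `[[`, character(1), "pregrowth"),
    replicate = vapply(hs, `[[`, character(1), "replicate"),
    concentration = vapply(hs, `[[`, numeric(1), "concentration"),
    stringsAsFactors = FALSE)
  score_rows <- list()
  cond_scores <- list()  # per method/split: per-condition score vectors
  for (method in names(models)) {
    cond_scores[[method]] <- list(train = numeric(0), test = numeric(0))
    for (rep_key in names(models[[method]])) {
      parts <- strsplit(rep_key, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("replicate keys must be 'pregrowth:replicate', got ", rep_key)
      pg <- parts[1]; rep_id <- parts[2]
      own <- meta$pregrowth == pg & meta$replicate == rep_id
      others <- meta$pregrowth == pg & meta$replicate != rep_id
      own_g <- sort(meta$concentration[own])
      for (r2 in unique(meta$replicate[others])) {
        g2 <- sort(meta$concentration[others & meta$replicate == r2])
        if (!isTRUE(all.equal(own_g, g2)))
          stop("replicates ", rep_id, " and ", r2,
               " do not share concentrations")
      }
      rm_ <- models[[method]][[rep_key]]
      tr <- vapply(meta$key[own], function(k)
        model_mean_nll(replicate_model_for(rm_, hs[[k]]), hs[[k]]),
        numeric(1))
      te <- vapply(meta$key[others], function(k)
        model_mean_nll(replicate_model_for(rm_, hs[[k]]), hs[[k]]),
        numeric(1))
      cond_scores[[method]]$train <- c(cond_scores[[method]]$train, tr)
      cond_scores[[method]]$test <- c(cond_scores[[method]]$test, te)
      score_rows[[length(score_rows) + 1L]] <-
        data.frame(method = method, pregrowth = pg, replicate = rep_id,
                   train = mean(tr), test = mean(te),
                   stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, score_rows)
  set.seed(seed)
  summ <- do.call(rbind, lapply(names(cond_scores), function(method) {
    do.call(rbind, lapply(c("train", "test"), function(split) {
      v <- cond_scores[[method]][[split]]
      boots <- vapply(seq_len(n_boot), function(b)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      data.frame(method = method, split = split, mean_nll = mean(v),
                 ci_lo = unname(stats::quantile(boots, 0.025)),
                 ci_hi = unname(stats::quantile(boots, 0.975)),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(scores = scores, summary = summ), class = "nll_scores")
}

#' @export
print.nll_scores <- function(x, ...) {
  cat("train/test mean negative log-likelihood (nats/event)\n")
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Decompose landmark-location variability into replicate and method parts
#'
#' Given subpopulation-location estimates arranged as a complete
#' method x replicate x landmark array, estimates biological variability
#' per landmark as the standard deviation across replicates of the
#' method-averaged locations, and method variability as the standard
#' deviation across methods of the replicate-averaged locations (sample
#' standard deviations, `n - 1` denominator).
#'
#' @param locations Numeric 3-d array with dimensions
#'   (method, replicate, landmark); dimnames are used in the output when
#'   present. Missing values are rejected.
#' @return An object of class `"variability_report"`: data frame with
#'   columns `landmark`, `bio_sd`, `method_sd` (channels).
#' @export
variability_decomposition <- function(locations) {
  stopifnot(is.array(locations), length(dim(locations)) == 3L)
  if (anyNA(locations)) {
    idx <- which(is.na(locations), arr.ind = TRUE)[1, ]
    dn <- dimnames(locations)
    lab <- vapply(1:3, function(d)
      if (!is.null(dn[[d]])) dn[[d]][idx[d]] else as.character(idx[d]),
      character(1))
    stop("missing location estimate at (method = ", lab[1],
         ", replicate = ", lab[2], ", landmark = ", lab[3], ")")
  }
  rep_by_lm <- apply(locations, c(2, 3), mean)   # mean over methods
  meth_by_lm <- apply(locations, c(1, 3), mean)  # mean over replicates
  lm_names <- dimnames(locations)[[3]]
  if (is.null(lm_names)) lm_names <- paste0("P", seq_len(dim(locations)[3]))
  out <- data.frame(landmark = lm_names,
                    bio_sd = apply(rep_by_lm, 2, stats::sd),
                    method_sd = apply(meth_by_lm, 2, stats::sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("variability_report", "data.frame")
  out
}

#' @export
print.variability_report <- function(x, ...) {
  cat("location variability (channels): replicates vs methods\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Estimate landmark subpopulation locations by all three methods
#'
#' Runs the three estimators (per-dose EM with cross-validated component
#' count, mode-estimation-plus-EM, and the conditional mixture model) on
#' every replicate of one pregrowth arm and records the locations of four
#' landmark subpopulations: the low (and only) subpopulation at the
#' lowest dose (P1), the low and high subpopulations at an intermediate
#' dose where both coexist (P2, P3; default the 11th dose), and the high
#' (and only) subpopulation at the largest dose (P4). The result feeds
#' [variability_decomposition()].
#'
#' @param dataset An [fc_dataset()].
#' @param pregrowth Pregrowth arm to analyse.
#' @param landmark_idx Integer vector of three dose indices (low-only,
#'   coexistence, high-only); defaults to the first, 11th and last dose.
#' @param restarts Random restarts for the EM fits.
#' @param alpha,k_max Passed to [select_num_components()].
#' @param seed Integer seed.
#' @return Numeric array (3 methods x replicates x 4 landmarks), with an
#'   `NA` where a method did not report the landmark's subpopulation.
#' @export
estimate_landmarks <- function(dataset, pregrowth = "gal",
                               landmark_idx = NULL, restarts = 10L,
                               alpha = 1.0, k_max = 3L, seed = 1L) {
  stopifnot(inherits(dataset, "fc_dataset"))
  hs <- dataset_subset(dataset, pregrowth = pregrowth)
  if (!length(hs)) stop("no histograms for pregrowth ", pregrowth)
  gs <- sort(unique(vapply(hs, `[[`, numeric(1), "concentration")))
  if (is.null(landmark_idx))
    landmark_idx <- c(1L, min(11L, length(gs)), length(gs))
  stopifnot(length(landmark_idx) == 3L)
  g_lm <- gs[landmark_idx]
  reps <- sort(unique(vapply(hs, `[[`, character(1), "replicate")))
  methods <- c("EM", "ME+EM", "CEM")
  arr <- array(NA_real_, dim = c(3L, length(reps), 4L),
               dimnames = list(method = methods, replicate = reps,
                               landmark = paste0("P", 1:4)))
  low_high <- function(model) {
    K <- length(model$means)
    if (K == 0L) return(c(NA_real_, NA_real_))
    c(model$means[1], model$means[K])  # sorted ascending
  }
  for (ri in seq_along(reps)) {
    rh <- dataset_subset(dataset, pregrowth = pregrowth,
                         replicate = reps[ri])
    # EM and ME+EM at the three landmark doses
    for (li in seq_along(g_lm)) {
      h <- dataset_subset(dataset, pregrowth = pregrowth,
                          replicate = reps[ri],
                          concentration = g_lm[li])[[1]]
      dec <- select_num_components(h, alpha = alpha, k_max = k_max,
                                   restarts = restarts,
                                   seed = restart_seed(seed, ri * 10L + li))
      em <- fit_em_restarts(h, dec$chosen_k, n_restarts = restarts,
                            seed = restart_seed(seed, ri * 100L + li))
      me <- tryCatch(fit_me_em(h), error = function(e) NULL)
      em_lh <- low_high(em$model)
      me_lh <- if (is.null(me)) c(NA_real_, NA_real_)
               else low_high(me$model)
      assign_lm <- function(row, lh, li, K) {
        if (li == 1L) arr[row, ri, 1L] <<- lh[1]
        if (li == 2L && K >= 2L) {
          arr[row, ri, 2L] <<- lh[1]; arr[row, ri, 3L] <<- lh[2]
        }
        if (li == 3L) arr[row, ri, 4L] <<- lh[2]
      }
      assign_lm("EM", em_lh, li, length(em$model$means))
      if (!is.null(me)) assign_lm("ME+EM", me_lh, li,
                                  length(me$model$means))
    }
    # CEM over the whole replicate, landmarks from the reported structure
    cem <- fit_cem(rh)
    st <- extract_structure(cem, concentrations = g_lm)
    p <- st[abs(st$concentration - g_lm[1]) < 1e-12, ]
    arr["CEM", ri, 1L] <- p$location[1]
    p <- st[abs(st$concentration - g_lm[2]) < 1e-12, ]
    if (nrow(p) >= 2L) {
      arr["CEM", ri, 2L] <- p$location[1]
      arr["CEM", ri, 3L] <- p$location[nrow(p)]
    }
    p <- st[abs(st$concentration - g_lm[3]) < 1e-12, ]
    arr["CEM", ri, 4L] <- p$location[nrow(p)]
  }
  arr
}
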