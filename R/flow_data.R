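#' Channel-to-intensity transform of a logarithmic flow cytometer
#'
#' Flow cytometers of the class emulated here record fluorescence on a
#' logarithmic scale: `n_channels` bins span `decades` orders of magnitude of
#' relative intensity, so channel 1024 of a 1024-channel, 4-decade instrument
#' represents 10,000 times the intensity of channel 1. All model fitting in
#' this package operates directly in channel (log-intensity) coordinates;
#' the transform exists for reporting on the intensity scale.
#'
#' @param n_channels Number of fluorescence channels (at least 2).
#' @param decades Log10 dynamic range covered by the channels (positive).
#' @return An object of class `"channel_transform"`.
#' @examples
#' tr <- channel_transform()
#' channel_to_intensity(1024, tr) / channel_to_intensity(1, tr)  # 10000
#' @export
channel_transform <- function(n_channels = 1024L, decades = 4) {
  n_channels <- as.integer(n_channels)
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels < 2L)
    stop("'n_channels' must be a single integer >= 2")
  if (length(decades) != 1L || !is.finite(decades) || decades <= 0)
    stop("'decades' must be a single positive number")
  structure(list(n_channels = n_channels, decades = decades),
            class = "channel_transform")
}

#' Convert channel coordinates to relative fluorescence intensity
#'
#' Computes `I(c) = 10^(decades * (c - 1) / (n_channels - 1))`, the relative
#' intensity represented by (possibly fractional) channel coordinate `c`,
#' normalized so that `I(1) = 1`.
#'
#' @param channel Numeric vector of channel coordinates in
#'   `[1, n_channels]`; fractional values are allowed.
#' @param transform A [channel_transform()].
#' @return Numeric vector of relative intensities (dimensionless).
#' @export
channel_to_intensity <- function(channel, transform = channel_transform()) {
  stopifnot(inherits(transform, "channel_transform"))
  if (any(!is.finite(channel)) ||
      any(channel < 1 | channel > transform$n_channels))
    stop("channel coordinates must lie in [1, n_channels]")
  10^(transform$decades * (channel - 1) / (transform$n_channels - 1))
}

#' Single-condition channel-count histogram
#'
#' The unit of data in this package: event counts over the fluorescence
#' channels of one flow-cytometry acquisition, i.e. one (pregrowth,
#' replicate, dose) condition of a dose-gradient experiment.
#'
#' @param counts Non-negative integer vector of event counts per channel.
#' @param concentration Non-negative scalar dose (percent weight/volume
#'   galactose in the emulated experiment).
#' @param replicate Replicate label (coerced to character).
#' @param pregrowth Pregrowth condition, `"gal"` (induced start) or
#'   `"raf"` (uninduced start).
#' @return An object of class `"channel_histogram"`.
#' @export
channel_histogram <- function(counts, concentration = 0, replicate = "1",
                              pregrowth = c("gal", "raf")) {
  pregrowth <- match.arg(pregrowth)
  if (length(counts) < 2L) stop("'counts' must cover at least 2 channels")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("'counts' must be non-negative integers")
  if (length(concentration) != 1L || !is.finite(concentration) ||
      concentration < 0)
    stop("'concentration' must be a single non-negative number")
  structure(list(counts = as.numeric(counts),
                 concentration = as.numeric(concentration),
                 replicate = as.character(replicate),
                 pregrowth = pregrowth),
            class = "channel_histogram")
}

#' @export
print.channel_histogram <- function(x, ...) {
  cat(sprintf(
    "channel histogram: %s pregrowth, replicate %s, %s%% galactose\n",
    x$pregrowth, x$replicate, format_concentration(x$concentration)))
  cat(sprintf("  %d channels, %d events\n",
              length(x$counts), round(sum(x$counts))))
  invisible(x)
}

# canonical decimal printing of a concentration; round-trips through
# as.numeric exactly
format_concentration <- function(g) {
  vapply(g, function(gi) {
    s <- sprintf("%.15g", gi)
    if (as.numeric(s) != gi) s <- sprintf("%.17g", gi)
    s
  }, character(1))
}

histogram_key <- function(h)
  paste(h$pregrowth, h$replicate, format_concentration(h$concentration),
        sep = ":")

#' Collection of channel histograms from one experiment
#'
#' Bundles the histograms of a dose-gradient experiment, keyed by
#' `pregrowth:replicate:concentration`, together with the channel transform
#' of the instrument.
#'
#' @param histograms List of [channel_histogram()] objects (keys are derived
#'   from their metadata and must be unique).
#' @param transform A [channel_transform()] shared by all histograms.
#' @return An object of class `"fc_dataset"`.
#' @export
fc_dataset <- function(histograms, transform = channel_transform()) {
  stopifnot(is.list(histograms), inherits(transform, "channel_transform"))
  if (length(histograms)) {
    ok <- vapply(histograms, inherits, logical(1), "channel_histogram")
    if (!all(ok)) stop("all elements must be channel_histogram objects")
    nch <- vapply(histograms, function(h) length(h$counts), numeric(1))
    if (any(nch != transform$n_channels))
      stop("all histograms must have 'n_channels' channels")
    keys <- vapply(histograms, histogram_key, character(1))
    if (anyDuplicated(keys))
      stop("duplicate (pregrowth, replicate, concentration) keys")
    names(histograms) <- keys
    histograms <- histograms[order(keys, method = "radix")]
  }
  structure(list(histograms = histograms, transform = transform),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("flow-cytometry dataset: %d histograms, %d channels\n",
              length(x$histograms), x$transform$n_channels))
  if (length(x$histograms)) {
    pg <- vapply(x$histograms, `[[`, character(1), "pregrowth")
    g <- vapply(x$histograms, `[[`, numeric(1), "concentration")
    cat(sprintf("  pregrowths: %s; %d concentration levels\n",
                paste(sort(unique(pg)), collapse = ", "),
                length(unique(g))))
  }
  invisible(x)
}

#' Write a dataset to a tab-separated histogram table
#'
#' Writes the plain-text exchange format: a header row
#' `channel<TAB>pregrowth:replicate:concentration...` followed by one row
#' per channel. Columns are sorted lexicographically by key so repeated
#' writes are byte-identical.
#'
#' @param dataset An [fc_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fc_dataset"))
  keys <- names(dataset$histograms) %||% character(0)
  keys <- keys[order(keys, method = "radix")]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("channel", keys), collapse = "\t"), con)
  if (length(keys)) {
    mat <- vapply(dataset$histograms[keys], function(h) h$counts,
                  numeric(dataset$transform$n_channels))
    tab <- cbind(seq_len(dataset$transform$n_channels), mat)
    utils::write.table(format(tab, trim = TRUE, scientific = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset from a tab-separated histogram table
#'
#' @param path Path to a file written in the format of [write_dataset()].
#' @param transform Optional [channel_transform()]; defaults to one with as
#'   many channels as the table has rows (4 decades).
#' @return An [fc_dataset()].
#' @export
read_dataset <- function(path, transform = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "numeric")
  if (names(tab)[1] != "channel")
    stop("malformed histogram table: first column must be 'channel'")
  keys <- names(tab)[-1]
  if (anyDuplicated(keys)) stop("duplicate condition keys in header")
  if (length(keys) == 0L && nrow(tab) == 0L)
    return(fc_dataset(list(), transform %||% channel_transform()))
  if (is.null(transform)) {
    if (nrow(tab) == 0) stop("cannot infer channel count from empty table")
    transform <- channel_transform(n_channels = nrow(tab))
  }
  if (nrow(tab) != transform$n_channels)
    stop("table has ", nrow(tab), " rows but transform expects ",
         transform$n_channels, " channels")
  hists <- lapply(keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("malformed column key (want pregrowth:replicate:concentration): ",
           k)
    cnt <- tab[[k]]
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
      stop("column ", k, " contains negative or non-integer counts")
    channel_histogram(cnt, concentration = as.numeric(parts[3]),
                      replicate = parts[2], pregrowth = parts[1])
  })
  fc_dataset(hists, transform)
}

#' Normalize a histogram to per-channel event fractions
#'
#' @param h A [channel_histogram()] with positive total count.
#' @return Numeric vector of fractions summing to 1.
#' @export
to_density <- function(h) {
  stopifnot(inherits(h, "channel_histogram"))
  total <- sum(h$counts)
  if (total <= 0) stop("histogram has zero total count")
  h$counts / total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: subset an fc_dataset by metadata; returns list of histograms
dataset_subset <- function(dataset, pregrowth = NULL, replicate = NULL,
                           concentration = NULL) {
  hs <- dataset$histograms
  keep <- rep(TRUE, length(hs))
  if (!is.null(pregrowth))
    keep <- keep & vapply(hs, `[[`, character(1), "pregrowth") %in% pregrowth
  if (!is.null(replicate))
    keep <- keep & vapply(hs, `[[`, character(1), "replicate") %in%
      as.character(replicate)
  if (!is.null(concentration)) {
    g <- vapply(hs, `[[`, numeric(1), "concentration")
    keep <- keep & vapply(g, function(x)
      any(abs(x - concentration) < 1e-12), logical(1))
  }
  hs[keep]
}
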