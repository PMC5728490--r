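# Flow-cytometry event filtering, gating, and competition-fitness
# estimation.

#' Remove acquisition-carryover artifacts from an event stream
#'
#' Events are split into `n_bins` equal-count bins by acquisition order.
#' Reference statistics (mean and SD per channel) come from the last
#' `reference_tail` fraction of events. Starting from the first bin, a
#' maximal contiguous prefix of bins is removed while each bin's mean on
#' either channel deviates from the reference mean by more than `sd_mult`
#' reference SDs; removal never reaches into the reference tail, so at
#' least `reference_tail` of the acquired events are always retained.
#'
#' @param stream an [event_stream()] (or data.frame with `acq_time_s`,
#'   `marker_au`, `reporter_au`).
#' @param n_bins number of acquisition-order bins (default 100).
#' @param sd_mult deviation threshold in reference SDs (default 3).
#' @param reference_tail fraction of trailing events defining the reference
#'   (default 0.60).
#' @return A list: `stream` (retained events), `removed` (number of events
#'   removed), `removed_bins`, `retained_fraction`, `reference` (per-channel
#'   mean/sd).
#' @export
filter_acquisition_artifacts <- function(stream, n_bins = 100, sd_mult = 3,
                                         reference_tail = 0.60) {
  stopifnot(is.data.frame(stream))
  need <- c("acq_time_s", "marker_au", "reporter_au")
  if (!all(need %in% names(stream)))
    stop_param("stream must have columns ", paste(need, collapse = ", "))
  n <- nrow(stream)
  if (!n) stop("cannot filter an empty event stream")
  check_scalar(n_bins, "n_bins", lower = 1)
  check_scalar(sd_mult, "sd_mult", lower = 0)
  check_scalar(reference_tail, "reference_tail", 0.05, 1)
  ord <- order(stream$acq_time_s)
  stream <- stream[ord, , drop = FALSE]
  bin <- ceiling(seq_len(n) / n * n_bins)
  tail_idx <- seq.int(floor(n * (1 - reference_tail)) + 1L, n)
  chans <- c("marker_au", "reporter_au")
  ref_mean <- vapply(chans, function(ch) mean(stream[[ch]][tail_idx]), 0)
  ref_sd <- vapply(chans, function(ch) stats::sd(stream[[ch]][tail_idx]), 0)
  ref_sd[!is.finite(ref_sd) | ref_sd == 0] <- .Machine$double.eps
  first_tail_bin <- bin[tail_idx[1L]]
  removed_bins <- 0L
  for (b in seq_len(n_bins)) {
    if (b >= first_tail_bin) break      # never remove into the reference
    idx <- which(bin == b)
    if (!length(idx)) break
    dev <- vapply(chans, function(ch)
      abs(mean(stream[[ch]][idx]) - ref_mean[ch]) / ref_sd[ch], 0)
    if (any(dev > sd_mult)) removed_bins <- b else break
  }
  removed_idx <- if (removed_bins > 0L) which(bin <= removed_bins)
                 else integer(0)
  retained <- if (length(removed_idx)) stream[-removed_idx, , drop = FALSE]
              else stream
  retained$event_index <- seq_len(nrow(retained))
  class(retained) <- c("event_stream", "data.frame")
  list(stream = retained, removed = length(removed_idx),
       removed_bins = removed_bins,
       retained_fraction = nrow(retained) / n,
       reference = data.frame(channel = chans, mean = ref_mean, sd = ref_sd,
                              row.names = NULL))
}

#' Fraction of marker-positive events
#'
#' Gates the marker channel at an explicit threshold, or automatically at
#' the minimum-density point between the two marker modes (kernel density
#' estimate). A unimodal channel with `threshold = "auto"` is a gating
#' failure and raises an error asking for an explicit threshold.
#'
#' @param stream a filtered [event_stream()].
#' @param threshold numeric cut (au) or `"auto"` (default).
#' @return A list: `fraction` (events above the cut / total), `threshold`
#'   (the cut used), `n_events`.
#' @export
gate_marker_populations <- function(stream, threshold = "auto") {
  stopifnot(is.data.frame(stream), "marker_au" %in% names(stream))
  x <- stream$marker_au
  if (!length(x)) stop("cannot gate an empty event stream")
  if (identical(threshold, "auto")) {
    d <- stats::density(x, n = 512)
    dy <- diff(d$y)
    modes <- which(diff(sign(dy)) == -2) + 1L
    modes <- modes[d$y[modes] > 0.05 * max(d$y)]   # ignore stray ripples
    if (length(modes) < 2L)
      stop("marker channel looks unimodal; automatic gating failed - ",
           "supply an explicit threshold")
    span <- seq(min(modes), max(modes))
    cut <- d$x[span[which.min(d$y[span])]]
  } else {
    cut <- check_scalar(threshold, "threshold")
  }
  list(fraction = mean(x > cut), threshold = cut, n_events = length(x))
}

odds <- function(f) f / (1 - f)

#' Relative abundance normalized to the phase start
#'
#' Converts mutant fractions to log2 odds ratios against the phase's own
#' initial time point: depletion and recovery phases are normalized
#' separately, each to its first sample.
#'
#' @param trajectory a `competition_trajectory` data.frame with columns
#'   `sample_time_h`, `mutant_fraction`, `phase` (and optionally
#'   `generations`).
#' @return The trajectory with an added `log2_relative_abundance` column.
#' @export
relative_abundance <- function(trajectory) {
  stopifnot(is.data.frame(trajectory),
            all(c("sample_time_h", "mutant_fraction", "phase") %in%
                  names(trajectory)))
  out <- trajectory
  out$log2_relative_abundance <- NA_real_
  for (ph in unique(trajectory$phase)) {
    idx <- which(trajectory$phase == ph)
    f0 <- trajectory$mutant_fraction[idx[1L]]
    if (f0 <= 0 || f0 >= 1)
      stop("phase '", ph, "' starts at fraction ", f0,
           "; log-odds normalization needs 0 < f0 < 1")
    f <- trajectory$mutant_fraction[idx]
    out$log2_relative_abundance[idx] <- log2(odds(f) / odds(f0))
  }
  out
}

#' Per-generation relative fitness from a competition time course
#'
#' The selection coefficient is the least-squares slope of the mutant's log
#' frequency-odds versus cumulative generations, divided by log(2):
#' doublings gained or lost per wild-type doubling. Odds are used so the
#' slope is exact under exponential competition. A seeded nonparametric
#' bootstrap over time points gives the confidence interval.
#'
#' @param trajectory a `competition_trajectory` with columns
#'   `mutant_fraction`, `generations`, `phase`.
#' @param phase which phase to fit (`"depletion"` or `"recovery"`); default
#'   uses all rows.
#' @param bootstrap number of bootstrap resamples (0 to skip; default
#'   1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A list: `s` (selection coefficient per generation), `ci`
#'   (bootstrap interval or `NULL`), `n_points`, `phase`.
#' @examples
#' tr <- data.frame(sample_time_h = 0:2,
#'                  mutant_fraction = c(1, 2, 4) / c(2, 3, 5),
#'                  generations = 0:2, phase = "depletion")
#' relative_fitness(tr, bootstrap = 0)$s  # +1: odds double each generation
#' @export
relative_fitness <- function(trajectory, phase = NULL, bootstrap = 1000,
                             conf = 0.95, seed = 1) {
  stopifnot(is.data.frame(trajectory),
            all(c("mutant_fraction", "generations") %in% names(trajectory)))
  rows <- trajectory
  if (!is.null(phase)) {
    if (!"phase" %in% names(rows)) stop_param("trajectory has no phase column")
    rows <- rows[rows$phase == phase, , drop = FALSE]
  }
  f <- rows$mutant_fraction
  g <- rows$generations
  ok <- is.finite(f) & is.finite(g) & f > 0 & f < 1
  f <- f[ok]; g <- g[ok]
  if (length(f) < 2L)
    stop("need at least 2 usable time points with fractions in (0, 1)")
  y <- log(odds(f))
  slope <- function(yy, gg) stats::cov(gg, yy) / stats::var(gg)
  s <- slope(y, g) / log(2)
  ci <- NULL
  if (bootstrap > 0) {
    bs <- with_seed(seed, vapply(seq_len(bootstrap), function(i) {
      k <- sample.int(length(y), replace = TRUE)
      if (length(unique(g[k])) < 2L) return(NA_real_)
      slope(y[k], g[k]) / log(2)
    }, 0))
    a <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  }
  list(s = s, ci = ci, n_points = length(y), phase = phase %||% "all")
}
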