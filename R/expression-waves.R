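# Two-wave transcription-response detection from expression time courses.

#' Construct an expression course
#'
#' A gene-by-time matrix of log2 expression ratios versus a named reference
#' sample. Below-detection entries are `NA` (they carry no numeric value and
#' are ignored downstream).
#'
#' @param log2_ratio numeric matrix, genes in rows, time points in columns.
#' @param time_points numeric vector of sampling times (hours), one per
#'   column, strictly increasing.
#' @param reference label of the reference sample the ratios are against.
#' @return A list of class `expression_course` with elements `log2_ratio`,
#'   `time_points`, `gene_ids`, `reference`.
#' @export
expression_course <- function(log2_ratio, time_points,
                              reference = "reference") {
  if (!is.matrix(log2_ratio) || !is.numeric(log2_ratio))
    stop_param("log2_ratio must be a numeric matrix (genes x time points)")
  if (length(time_points) != ncol(log2_ratio))
    stop_param("time_points must match the number of columns")
  if (any(diff(time_points) <= 0))
    stop_param("time_points must be strictly increasing")
  if (is.null(rownames(log2_ratio)))
    rownames(log2_ratio) <- paste0("gene", seq_len(nrow(log2_ratio)))
  colnames(log2_ratio) <- format(time_points, trim = TRUE)
  structure(list(log2_ratio = log2_ratio,
                 time_points = as.numeric(time_points),
                 gene_ids = rownames(log2_ratio),
                 reference = reference),
            class = "expression_course")
}

#' @export
print.expression_course <- function(x, ...) {
  cat("<expression_course>", nrow(x$log2_ratio), "genes x",
      length(x$time_points), "time points, vs", x$reference, "\n")
  cat("  times (h):", paste(x$time_points, collapse = ", "), "\n")
  cat("  below detection:", sum(is.na(x$log2_ratio)), "entries\n")
  invisible(x)
}

#' Log2 ratios of normalized counts against a reference sample
#'
#' Builds an [expression_course()] from per-sample gene count tables (as
#' produced by [normalize_and_threshold()]). Genes not detected in a given
#' sample are masked (`NA`) there; genes not detected in the reference are
#' masked everywhere, matching the display rule for reference-normalized
#' panels.
#'
#' @param tables named list of `gene_count_table` data.frames, one per
#'   sample, in time order.
#' @param reference name of the reference sample (must be in
#'   `names(tables)`).
#' @param time_points numeric sampling times, one per table (in list order).
#' @return An [expression_course()].
#' @export
log_ratio_to_reference <- function(tables, reference, time_points) {
  if (!is.list(tables) || is.null(names(tables)))
    stop_param("tables must be a named list of gene count tables")
  if (!reference %in% names(tables))
    stop("reference sample '", reference, "' not found among tables")
  genes <- tables[[reference]]$gene_id
  ref <- tables[[reference]]
  ref_val <- stats::setNames(ifelse(ref$detected, ref$normalized, NA_real_),
                             ref$gene_id)
  mat <- sapply(tables, function(tb) {
    v <- stats::setNames(ifelse(tb$detected, tb$normalized, NA_real_),
                         tb$gene_id)[genes]
    log2(v / ref_val)
  })
  rownames(mat) <- genes
  mat[is.na(ref_val), ] <- NA_real_
  expression_course(mat, time_points, reference = reference)
}

#' Pearson correlation matrix between time points
#'
#' Pairwise-complete Pearson correlation between time-point columns over a
#' gene subset; below-detection (`NA`) entries are simply dropped pair by
#' pair, so masked genes stay usable. Cells with fewer than 3 complete gene
#' pairs are masked.
#'
#' @param course an [expression_course()].
#' @param gene_subset optional character vector of gene ids (e.g. the
#'   Pho4-target panel); default all genes.
#' @param min_pairs minimum complete pairs for a cell (default 3).
#' @return A symmetric T x T correlation matrix with unit diagonal.
#' @export
timepoint_correlation <- function(course, gene_subset = NULL, min_pairs = 3) {
  stopifnot(inherits(course, "expression_course"))
  m <- course$log2_ratio
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(m))
    if (length(missing))
      stop("genes not in the course: ", paste(missing, collapse = ", "))
    m <- m[gene_subset, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need at least 2 time points")
  if (sum(rowSums(!is.na(m)) > 0) < 3L)
    stop("need at least 3 genes with data after masking")
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(m))          # complete pairs per cell
  cc[obs < min_pairs] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Detect the two transcription waves by clustering the correlation matrix
#'
#' Runs k-means (k = 2, best of `restarts` seeded initializations) on the
#' rows of the time-point Pearson correlation matrix: each time point is
#' described by its correlation profile. The cluster containing the first
#' time point is wave 1. The first onset is the earliest wave-2 time point;
#' the stable onset is the start of the last contiguous wave-2 run (these
#' differ when a transient second-wave episode precedes the stable one, as
#' at 0.06 mM Pi).
#'
#' @param corr T x T correlation matrix (from [timepoint_correlation()]);
#'   masked cells are treated as correlation 0 for clustering.
#' @param time_points numeric times for the rows; defaults to numeric
#'   rownames/colnames of `corr`.
#' @param k number of clusters (fixed at 2 for wave detection).
#' @param restarts number of seeded k-means restarts.
#' @param seed integer seed.
#' @return A list of class `wave_partition`: `time_points`, `labels` (1/2),
#'   `has_second_wave`, `wave2_first_onset`, `wave2_stable_onset`, `delay`.
#'   Degenerate matrices (all time points alike) give a no-second-wave
#'   outcome, not an error.
#' @export
detect_waves <- function(corr, time_points = NULL, k = 2, restarts = 50,
                         seed = 1) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop_param("corr must be a square matrix")
  n <- nrow(corr)
  if (n < 4L) stop("need at least 4 time points to partition")
  if (is.null(time_points))
    time_points <- suppressWarnings(as.numeric(colnames(corr)))
  if (anyNA(time_points) || length(time_points) != n)
    stop_param("time_points must give one numeric time per row of corr")
  time_points <- as.numeric(time_points)
  x <- corr
  x[is.na(x)] <- 0
  no_wave <- list(time_points = time_points, labels = rep(1L, n),
                  has_second_wave = FALSE, wave2_first_onset = NA_real_,
                  wave2_stable_onset = NA_real_, delay = NA_real_)
  class(no_wave) <- "wave_partition"
  if (max(stats::dist(x)) < 1e-9) return(no_wave)   # degenerate: one wave
  km <- with_seed(seed,
                  stats::kmeans(x, centers = k, nstart = restarts,
                                iter.max = 100))
  labels <- km$cluster
  wave1 <- labels[1L]                   # cluster of the first time point
  lab <- ifelse(labels == wave1, 1L, 2L)
  if (all(lab == 1L)) return(no_wave)
  is2 <- lab == 2L
  runs <- rle(is2)
  last_run_start <- sum(runs$lengths[seq_len(length(runs$lengths) - 1L)]) + 1L
  if (!runs$values[length(runs$values)]) {
    # last run is wave-1: stable onset is the start of the last wave-2 run
    idx <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(idx, -1L) + 1L)
    last_run_start <- max(starts[runs$values])
  }
  out <- list(time_points = time_points, labels = lab,
              has_second_wave = TRUE,
              wave2_first_onset = time_points[which(is2)[1L]],
              wave2_stable_onset = time_points[last_run_start],
              delay = time_points[which(is2)[1L]])
  class(out) <- "wave_partition"
  out
}

#' @export
print.wave_partition <- function(x, ...) {
  cat("<wave_partition>", length(x$time_points), "time points\n")
  if (x$has_second_wave) {
    cat("  wave-2 first onset:", x$wave2_first_onset, "h; stable onset:",
        x$wave2_stable_onset, "h\n")
  } else cat("  no second wave detected\n")
  invisible(x)
}

#' Delay between the transcription waves
#'
#' The first wave fires practically at transfer in low-Pi media, so the
#' inter-wave delay is the second wave's first onset measured from the
#' transfer (`origin = 0` by default).
#'
#' @param partition a `wave_partition` from [detect_waves()].
#' @param origin time the first wave is referenced to (hours); default 0,
#'   the transfer.
#' @return Delay in hours, or `NA` (with a warning) if no second wave was
#'   detected.
#' @export
wave_delay <- function(partition, origin = 0) {
  stopifnot(inherits(partition, "wave_partition"))
  if (!partition$has_second_wave) {
    warning("no second wave detected; delay is undefined")
    return(NA_real_)
  }
  partition$wave2_first_onset - origin
}

#' Order genes by their mean induction early in the course
#'
#' Genes are ranked by descending mean log2 ratio over the time points within
#' `window_h` hours of transfer; masked entries are ignored; genes with no
#' data in the window rank last. Ties break lexicographically by gene id.
#'
#' @param course an [expression_course()].
#' @param window_h width of the early window in hours (default 2).
#' @return Character vector of gene ids, most-induced first.
#' @export
order_genes_by_early_induction <- function(course, window_h = 2) {
  stopifnot(inherits(course, "expression_course"))
  check_scalar(window_h, "window_h", lower = 0)
  sel <- course$time_points <= window_h
  if (!any(sel)) stop("no time points within the first ", window_h, " h")
  m <- course$log2_ratio[, sel, drop = FALSE]
  means <- rowMeans(m, na.rm = TRUE)
  means[is.nan(means)] <- -Inf          # all-masked genes rank last
  ord <- order(-means, rownames(m))
  rownames(m)[ord]
}

#' Reporter level at which growth begins to decline
#'
#' For each condition, the decline onset is the earliest time at which the
#' reference-normalized growth rate falls below `decline_tol` and stays
#' below it for at least `persistence` consecutive measured points; the
#' activation threshold is the reporter level at that time (linearly
#' interpolated). Conditions that never decline (e.g. rich medium) are
#' excluded. Reports per-condition thresholds, their mean and coefficient of
#' variation.
#'
#' @param reporter_by_condition named list of data.frames with columns
#'   `time_h`, `reporter_au`.
#' @param rates_by_condition named list (same names) of data.frames with
#'   columns `time_h`, `normalized_rate` (doublings/hour, reference-
#'   subtracted).
#' @param decline_tol rate below which growth counts as declining
#'   (doublings/hour; default -0.05).
#' @param persistence consecutive points required below `decline_tol`.
#' @return A list: `per_condition` (data.frame with condition, onset time,
#'   threshold), `mean`, `cv` (NA with a single declining condition),
#'   `has_threshold`.
#' @export
activation_threshold <- function(reporter_by_condition, rates_by_condition,
                                 decline_tol = -0.05, persistence = 2) {
  stopifnot(is.list(reporter_by_condition), is.list(rates_by_condition))
  conds <- intersect(names(reporter_by_condition), names(rates_by_condition))
  if (!length(conds)) stop_param("no shared condition names between inputs")
  rows <- lapply(conds, function(cn) {
    ra <- rates_by_condition[[cn]]
    keep <- is.finite(ra$normalized_rate)
    tt <- ra$time_h[keep]
    rr <- ra$normalized_rate[keep]
    below <- rr < decline_tol
    onset <- NA_real_
    if (length(below) >= persistence) {
      run <- stats::filter(as.numeric(below), rep(1, persistence),
                           sides = 1)
      hit <- which(run == persistence)
      if (length(hit)) onset <- tt[hit[1L] - persistence + 1L]
    }
    if (!is.finite(onset)) return(NULL)
    rep_df <- reporter_by_condition[[cn]]
    thr <- stats::approx(rep_df$time_h, rep_df$reporter_au, xout = onset,
                         rule = 2)$y
    data.frame(condition = cn, onset_h = onset, threshold_au = thr)
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || !nrow(per)) {
    return(list(per_condition = data.frame(), mean = NA_real_, cv = NA_real_,
                has_threshold = FALSE))
  }
  mu <- mean(per$threshold_au)
  cv <- if (nrow(per) > 1L) stats::sd(per$threshold_au) / mu else NA_real_
  list(per_condition = per, mean = mu, cv = cv, has_threshold = TRUE)
}
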