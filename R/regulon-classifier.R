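# Rule-based classification of PHO-regulated genes and module display
# filters. Expression tables are matrices of normalized expression (library
# sum 1e6 scale) with below-detection entries as NA.

#' Classification criteria for PHO-regulated genes
#'
#' @param fold_threshold minimal induction ratio counting as up-regulation
#'   (default 2).
#' @param on_off_min_samples samples (of the ON/OFF design) in which a gene
#'   must be up-regulated (default 15 of 25).
#' @param wt_min_timepoints time points (of the wild-type no-Pi course) in
#'   which a gene must be up-regulated (default 6 of 8).
#' @param on_rescue_multiple if OFF cells are below detection, ON cells must
#'   exceed this multiple of the detection level (default 10).
#' @param detection_level normalized detection floor (default 10).
#' @return A validated list of class `classification_criteria`.
#' @export
classification_criteria <- function(fold_threshold = 2,
                                    on_off_min_samples = 15,
                                    wt_min_timepoints = 6,
                                    on_rescue_multiple = 10,
                                    detection_level = 10) {
  check_scalar(fold_threshold, "fold_threshold", lower = 1e-12)
  check_scalar(on_off_min_samples, "on_off_min_samples", lower = 1)
  check_scalar(wt_min_timepoints, "wt_min_timepoints", lower = 1)
  check_scalar(on_rescue_multiple, "on_rescue_multiple", lower = 1e-12)
  check_scalar(detection_level, "detection_level", lower = 1e-12)
  structure(list(fold_threshold = fold_threshold,
                 on_off_min_samples = on_off_min_samples,
                 wt_min_timepoints = wt_min_timepoints,
                 on_rescue_multiple = on_rescue_multiple,
                 detection_level = detection_level),
            class = "classification_criteria")
}

check_expr_matrix <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m) || is.null(rownames(m)))
    stop_param(name, " must be a numeric matrix with gene-id rownames")
  invisible(m)
}

#' Criterion 1: up-regulation in constitutive-ON versus pho4-null cells
#'
#' A gene counts as up-regulated in a sample if the ON/OFF expression ratio
#' is at least `fold_threshold`, or if OFF cells are below detection and ON
#' cells are at least `on_rescue_multiple` times the detection level. The
#' gene passes if up-regulated in at least `on_off_min_samples` of the
#' matched samples. Samples where the ON value is below detection count as
#' not up-regulated.
#'
#' @param on_table,off_table matched genes x samples matrices of normalized
#'   expression (NA = below detection), identical dimnames.
#' @param criteria a [classification_criteria()].
#' @return Named logical vector over the genes.
#' @export
criterion_constitutive_vs_null <- function(on_table, off_table,
                                           criteria =
                                             classification_criteria()) {
  check_expr_matrix(on_table, "on_table")
  check_expr_matrix(off_table, "off_table")
  if (!identical(dim(on_table), dim(off_table)) ||
      !identical(rownames(on_table), rownames(off_table)) ||
      !identical(colnames(on_table), colnames(off_table)))
    stop("ON and OFF tables must share genes and samples (matched design)")
  rescue_floor <- criteria$on_rescue_multiple * criteria$detection_level
  up <- (!is.na(on_table) & !is.na(off_table) &
           on_table / off_table >= criteria$fold_threshold) |
        (!is.na(on_table) & is.na(off_table) & on_table >= rescue_floor)
  rowSums(up) >= criteria$on_off_min_samples
}

#' Criterion 2: up-regulation in wild-type cells depleting phosphate
#'
#' A gene passes if its expression in the no-Pi course is at least
#' `fold_threshold` times the pre-transfer high-Pi reference in at least
#' `wt_min_timepoints` time points. Genes below detection in the high-Pi
#' reference are removed from the analysis entirely (neither pass nor
#' fail).
#'
#' @param wt_noPi_table genes x time-points matrix of normalized expression
#'   in the no-Pi course (NA = below detection).
#' @param highPi_reference named vector of normalized expression in the
#'   pre-transfer high-Pi sample (NA = below detection).
#' @param criteria a [classification_criteria()].
#' @return Named logical vector over the genes detected in the reference
#'   (genes removed from the analysis are absent).
#' @export
criterion_wildtype_depletion <- function(wt_noPi_table, highPi_reference,
                                         criteria =
                                           classification_criteria()) {
  check_expr_matrix(wt_noPi_table, "wt_noPi_table")
  if (is.null(names(highPi_reference)))
    stop("highPi_reference must be a named vector")
  genes <- rownames(wt_noPi_table)
  if (!all(genes %in% names(highPi_reference)))
    stop("highPi_reference is missing ",
         sum(!genes %in% names(highPi_reference)), " gene(s)")
  ref <- highPi_reference[genes]
  keep <- !is.na(ref)
  m <- wt_noPi_table[keep, , drop = FALSE]
  up <- !is.na(m) & m / ref[keep] >= criteria$fold_threshold
  rowSums(up) >= criteria$wt_min_timepoints
}

#' Classify PHO-regulated genes by the two-criterion rule
#'
#' A gene is PHO-regulated if it passes both the constitutive-ON versus
#' pho4-null criterion and the wild-type depletion criterion. Each
#' criterion's pass set is also reported for Venn-style summaries.
#'
#' @param on_table,off_table matched ON/OFF matrices (see
#'   [criterion_constitutive_vs_null()]).
#' @param wt_noPi_table,highPi_reference wild-type course and reference
#'   (see [criterion_wildtype_depletion()]).
#' @param criteria a [classification_criteria()].
#' @return A list: `regulon` (character vector of genes passing both),
#'   `criterion1`, `criterion2` (each criterion's pass set), `venn`
#'   (counts: criterion1-only, both, criterion2-only).
#' @export
classify_pho_regulon <- function(on_table, off_table, wt_noPi_table,
                                 highPi_reference,
                                 criteria = classification_criteria()) {
  c1 <- criterion_constitutive_vs_null(on_table, off_table, criteria)
  c2 <- criterion_wildtype_depletion(wt_noPi_table, highPi_reference,
                                     criteria)
  set1 <- names(c1)[c1]
  set2 <- names(c2)[c2]
  both <- sort(intersect(set1, set2))
  list(regulon = both, criterion1 = sort(set1), criterion2 = sort(set2),
       venn = c(criterion1_only = length(setdiff(set1, set2)),
                both = length(both),
                criterion2_only = length(setdiff(set2, set1))))
}

#' Display filter for stress / protein-synthesis module genes
#'
#' Module genes (externally supplied stress or ribosomal-protein lists) are
#' dropped from display if they are below detection at the phase's
#' reference time point: the first time point for the depletion phase, or
#' the last low-Pi time point (t = 0 of recovery) for the recovery phase.
#'
#' @param course an [expression_course()] whose columns cover the phase.
#' @param module_gene_list character vector of module gene ids.
#' @param phase `"depletion"` or `"recovery"`.
#' @param reference_time time point (hours) used as the phase reference;
#'   default: first column for depletion, last column for recovery.
#' @return The module gene ids that survive the filter.
#' @export
module_display_filter <- function(course, module_gene_list,
                                  phase = c("depletion", "recovery"),
                                  reference_time = NULL) {
  stopifnot(inherits(course, "expression_course"))
  phase <- match.arg(phase)
  tp <- course$time_points
  ref_t <- reference_time %||% if (phase == "depletion") tp[1L]
                               else tp[length(tp)]
  j <- which.min(abs(tp - ref_t))
  present <- intersect(module_gene_list, rownames(course$log2_ratio))
  keep <- present[!is.na(course$log2_ratio[present, j])]
  keep
}
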