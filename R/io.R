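# Plain-table readers and writers for the pipeline's interchange formats.
# OD series, expression courses, gene counts, annotations and alignment
# records travel as TSV; flow event streams as CSV.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write OD time series tables
#'
#' TSV with columns `time_h`, `od`, `condition`, `replicate`; one or more
#' culture series per file.
#'
#' @param path file path.
#' @param series an [od_series()] (or rbind of several).
#' @return `read_od_series()` returns a list of [od_series()] split by
#'   (condition, replicate); `write_od_series()` returns `path` invisibly.
#' @export
read_od_series <- function(path) {
  df <- read_tsv_plain(path)
  sp <- split(df, interaction(df$condition, df$replicate, drop = TRUE))
  lapply(sp, function(d)
    od_series(d$time_h, d$od, d$condition[1], d$replicate[1]))
}

#' @rdname read_od_series
#' @export
write_od_series <- function(series, path) write_tsv_plain(series, path)

#' Read / write an expression course
#'
#' TSV with a `gene_id` column and one numeric column per time point
#' (header = time in hours); empty cells are below-detection entries.
#'
#' @param path file path.
#' @param course an [expression_course()].
#' @param reference reference-sample label recorded on reading.
#' @return An [expression_course()] / `path` invisibly.
#' @export
read_expression_course <- function(path, reference = "reference") {
  df <- read_tsv_plain(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_course(m, as.numeric(colnames(m)), reference = reference)
}

#' @rdname read_expression_course
#' @export
write_expression_course <- function(course, path) {
  stopifnot(inherits(course, "expression_course"))
  df <- data.frame(gene_id = rownames(course$log2_ratio),
                   course$log2_ratio, check.names = FALSE)
  write_tsv_plain(df, path)
}

#' Read / write flow-cytometry event streams
#'
#' CSV with columns `event_index`, `acq_time_s`, `marker_au`,
#' `reporter_au`. The reader accepts any table carrying the three required
#' channel/time columns (conversion from FCS is upstream of this package).
#'
#' @param path file path.
#' @param stream an [event_stream()].
#' @return An [event_stream()] / `path` invisibly.
#' @export
read_event_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("acq_time_s", "marker_au", "reporter_au")
  if (!all(need %in% names(df)))
    stop_param("event table must have columns ", paste(need, collapse = ", "))
  event_stream(df$acq_time_s, df$marker_au, df$reporter_au)
}

#' @rdname read_event_stream
#' @export
write_event_stream <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write alignment records and 3'-end annotations
#'
#' Alignment records: TSV with columns `chrom`, `pos`, `strand`, `umi`,
#' `unique_flag`, `gene_hits`. Annotations: BED-like TSV with columns
#' `gene_id`, `chrom`, `strand`, `three_prime_pos`.
#'
#' @param path file path.
#' @param records,annotation the tables to write.
#' @return The table / `path` invisibly.
#' @export
read_alignments <- function(path) read_tsv_plain(path)

#' @rdname read_alignments
#' @export
write_alignments <- function(records, path) write_tsv_plain(records, path)

#' @rdname read_alignments
#' @export
read_annotation <- function(path) validate_annotation(read_tsv_plain(path))

#' @rdname read_alignments
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_plain(validate_annotation(annotation), path)
}
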