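# UMI-corrected 3'-window gene counting from simplified alignment records.
#
# Alignment records are plain tables with columns chrom, pos (0-based),
# strand (+/-), umi (4 letters over ACGT), unique_flag, gene_hits (one gene
# id, or two joined by ";" for reads mapping equally well to two genes).
# Coordinates are 0-based half-open throughout; windows are oriented by
# strand: for a + strand gene the counted interval is
# [three_prime_pos - 400, three_prime_pos + 200), for a - strand gene the
# mirror image [three_prime_pos - 199, three_prime_pos + 401).

UMI_ALPHABET_SIZE <- 256L  # 4-letter UMIs over {A, C, G, T}

window_upstream <- 400L
window_downstream <- 200L

# Strand-oriented half-open 3' window [start, end).
gene_window <- function(three_prime_pos, strand) {
  if (strand == "+") {
    c(three_prime_pos - window_upstream, three_prime_pos + window_downstream)
  } else {
    c(three_prime_pos - window_downstream + 1L,
      three_prime_pos + window_upstream + 1L)
  }
}

validate_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "strand", "three_prime_pos")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop_param("annotation must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stop_param("annotation must have one record per gene")
  if (!all(annotation$strand %in% c("+", "-")))
    stop_param("annotation strand must be '+' or '-'")
  invisible(annotation)
}

#' Down-sample alignment records to a fixed depth
#'
#' Keeps a uniform random subset of exactly `min(n, nrow(records))` records
#' (in original order), so all samples enter the pipeline at comparable
#' depth.
#'
#' @param records alignment record data.frame.
#' @param n target number of reads (default 400,000).
#' @param seed integer seed.
#' @return The down-sampled records.
#' @export
downsample_reads <- function(records, n = 400000, seed = 1) {
  stopifnot(is.data.frame(records))
  check_scalar(n, "n", lower = 0)
  if (nrow(records) <= n) return(records)
  keep <- with_seed(seed, sort(sample.int(nrow(records), n)))
  records[keep, , drop = FALSE]
}

#' Score genome positions by their number of distinct UMIs
#'
#' PCR-duplicate correction: every (chrom, pos, strand) position is scored
#' by the number of distinct 4-letter UMIs observed there, bounded by the
#' 256 possible UMIs. Records with malformed UMIs are dropped with a
#' warning.
#'
#' @param records alignment record data.frame with columns `chrom`, `pos`,
#'   `strand`, `umi`.
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `score`.
#' @export
umi_position_score <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), score = integer()))
  ok <- grepl("^[ACGT]{4}$", records$umi)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with malformed UMIs rejected")
    records <- records[ok, , drop = FALSE]
    if (!nrow(records))
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), score = integer()))
  }
  key <- paste(records$chrom, records$pos, records$strand, sep = "\r")
  dedup <- !duplicated(paste(key, records$umi, sep = "\r"))
  tab <- table(key[dedup])
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    strand = vapply(parts, `[`, "", 3L),
                    score = as.integer(tab))
  stopifnot(all(out$score <= UMI_ALPHABET_SIZE))
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Sum UMI position scores over each gene's 3' window
#'
#' For every annotated gene, sums position scores on the matching strand
#' within the strand-oriented window spanning 400 bp upstream to 200 bp
#' downstream of the 3' end. Genes without an annotation are absent from the
#' result (they are not reported as zero).
#'
#' @param position_scores data.frame from [umi_position_score()].
#' @param annotation data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `three_prime_pos` (0-based).
#' @return Named numeric vector of per-gene window counts.
#' @export
gene_window_counts <- function(position_scores, annotation) {
  validate_annotation(annotation)
  counts <- vapply(seq_len(nrow(annotation)), function(i) {
    w <- gene_window(annotation$three_prime_pos[i], annotation$strand[i])
    sel <- position_scores$chrom == annotation$chrom[i] &
      position_scores$strand == annotation$strand[i] &
      position_scores$pos >= w[1] & position_scores$pos < w[2]
    sum(position_scores$score[sel])
  }, 0)
  stats::setNames(counts, annotation$gene_id)
}

#' Allocate ambiguous read mass between gene pairs
#'
#' Reads mapping equally well to two genes (high 3'-window sequence
#' similarity) carry `gene_hits = "A;B"` and `unique_flag = FALSE`. Their
#' UMI-collapsed mass is split between the two genes in proportion to each
#' gene's uniquely-mapped window count; if both unique counts are zero the
#' mass is split equally. Total read mass is conserved exactly. Sharing
#' among more than two genes is rejected.
#'
#' @param window_counts named vector of uniquely-mapped window counts (from
#'   [gene_window_counts()] on unique records).
#' @param records alignment records; only rows with `unique_flag = FALSE`
#'   contribute.
#' @return Named numeric vector of adjusted counts.
#' @export
allocate_ambiguous <- function(window_counts, records) {
  stopifnot(is.numeric(window_counts), !is.null(names(window_counts)),
            is.data.frame(records))
  adjusted <- window_counts
  amb <- records[!records$unique_flag, , drop = FALSE]
  if (!nrow(amb)) return(adjusted)
  hits <- strsplit(amb$gene_hits, ";", fixed = TRUE)
  n_hits <- lengths(hits)
  if (any(n_hits > 2L))
    stop("ambiguity among more than two genes is not supported (",
         sum(n_hits > 2L), " record(s))")
  amb <- amb[n_hits == 2L, , drop = FALSE]
  hits <- hits[n_hits == 2L]
  if (!nrow(amb)) return(adjusted)
  pair_key <- vapply(hits, function(h) paste(sort(h), collapse = ";"), "")
  scored <- umi_position_score(
    data.frame(chrom = paste(amb$chrom, pair_key, sep = "|"),
               pos = amb$pos, strand = amb$strand, umi = amb$umi))
  pair_of <- vapply(strsplit(scored$chrom, "|", fixed = TRUE), `[`, "", 2L)
  for (pk in unique(pair_of)) {
    genes <- strsplit(pk, ";", fixed = TRUE)[[1L]]
    if (!all(genes %in% names(adjusted)))
      stop("ambiguous pair references unannotated gene(s): ", pk)
    mass <- sum(scored$score[pair_of == pk])
    u <- window_counts[genes]
    share <- if (sum(u) > 0) u / sum(u) else c(0.5, 0.5)
    adjusted[genes] <- adjusted[genes] + mass * share
  }
  adjusted
}

#' Normalize a count library and flag detection
#'
#' Scales per-gene counts so the library sums to 1,000,000 and flags genes
#' whose normalized expression falls below the detection level (default 10
#' units) as not detected; downstream analyses treat those entries as
#' below-detection (`NA`) values.
#'
#' @param counts named numeric vector of per-gene counts.
#' @param detection_level normalized detection floor (default 10).
#' @return A data.frame of class `gene_count_table` with columns `gene_id`,
#'   `raw_count`, `normalized`, `detected`.
#' @export
normalize_and_threshold <- function(counts, detection_level = 10) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 0)) stop_param("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("cannot normalize an all-zero library")
  normalized <- counts / total * 1e6
  structure(
    data.frame(gene_id = names(counts), raw_count = as.numeric(counts),
               normalized = as.numeric(normalized),
               detected = as.numeric(normalized) >= detection_level,
               row.names = NULL),
    class = c("gene_count_table", "data.frame"))
}

#' Full counting pipeline from alignment records to a normalized table
#'
#' Convenience wrapper: down-sample to `depth` reads, score positions by
#' distinct UMIs (unique and ambiguous records separately), sum scores over
#' 3' windows, allocate ambiguous mass, and normalize to 1,000,000 with
#' detection flagging.
#'
#' @param records alignment record data.frame.
#' @param annotation gene 3'-end annotation table.
#' @param depth down-sampling depth (default 400,000).
#' @param seed integer seed for the down-sampling draw.
#' @param detection_level normalized detection floor.
#' @return A `gene_count_table` (see [normalize_and_threshold()]).
#' @export
count_pipeline <- function(records, annotation, depth = 400000, seed = 1,
                           detection_level = 10) {
  validate_annotation(annotation)
  records <- downsample_reads(records, n = depth, seed = seed)
  uniq <- records[records$unique_flag, , drop = FALSE]
  scores <- umi_position_score(uniq)
  counts <- gene_window_counts(scores, annotation)
  counts <- allocate_ambiguous(counts, records)
  normalize_and_threshold(counts, detection_level = detection_level)
}
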