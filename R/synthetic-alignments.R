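# Synthetic UMI-tagged alignment records near gene 3' ends.

random_umis <- function(n) {
  m <- matrix(sample(c("A", "C", "G", "T"), 4L * n, replace = TRUE), ncol = 4L)
  apply(m, 1L, paste0, collapse = "")
}

#' Build a toy 3'-end gene annotation
#'
#' Lays out `n_genes` genes on one chromosome with alternating strands and
#' regular spacing, for use with [simulate_alignments()] and the counting
#' pipeline.
#'
#' @param n_genes number of genes.
#' @param gene_ids optional ids (default `g001`, `g002`, ...).
#' @param spacing distance between consecutive 3' ends (bp); the default
#'   2000 keeps windows disjoint.
#' @param chrom chromosome name.
#' @return Annotation data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `three_prime_pos`.
#' @export
toy_annotation <- function(n_genes, gene_ids = NULL, spacing = 2000,
                           chrom = "chrI") {
  check_scalar(n_genes, "n_genes", lower = 1)
  ids <- gene_ids %||% sprintf("g%03d", seq_len(n_genes))
  stopifnot(length(ids) == n_genes)
  data.frame(gene_id = ids, chrom = chrom,
             strand = rep(c("+", "-"), length.out = n_genes),
             three_prime_pos = 1000L +
               as.integer(spacing) * (seq_len(n_genes) - 1L))
}

#' Simulate UMI-tagged alignment records from ground-truth expression
#'
#' Places `depth` reads into gene 3' windows (400 bp upstream to 200 bp
#' downstream of each 3' end, strand-oriented) in proportion to the truth
#' counts, each read carrying a random 4-letter UMI. A configurable fraction
#' of reads is made ambiguous between a gene and its designated partner
#' (modeling high 3' sequence similarity): those records list both genes in
#' `gene_hits` and are flagged non-unique.
#'
#' @param truth data.frame with columns `gene_id` and `count` (relative
#'   expression truth; any non-negative weights).
#' @param annotation 3'-end annotation covering every truth gene (see
#'   [toy_annotation()]).
#' @param depth number of reads (> 0).
#' @param shared_frac fraction of reads rendered two-gene ambiguous.
#' @param paralog_pairs optional two-column matrix/data.frame of gene-id
#'   pairs eligible for ambiguity; default pairs each gene with the next
#'   annotation row.
#' @param seed integer seed.
#' @return Alignment records: data.frame with columns `chrom`, `pos`,
#'   `strand`, `umi`, `unique_flag`, `gene_hits`.
#' @export
simulate_alignments <- function(truth, annotation, depth, shared_frac = 0,
                                paralog_pairs = NULL, seed = 1) {
  stopifnot(is.data.frame(truth),
            all(c("gene_id", "count") %in% names(truth)))
  validate_annotation(annotation)
  check_scalar(depth, "depth", lower = 1)
  check_scalar(shared_frac, "shared_frac", 0, 1)
  missing <- setdiff(truth$gene_id, annotation$gene_id)
  if (length(missing))
    stop("truth gene(s) without 3' annotation: ",
         paste(missing, collapse = ", "))
  if (any(truth$count < 0)) stop_param("truth counts must be non-negative")
  if (sum(truth$count) <= 0) stop_param("truth counts must not all be zero")
  ann <- annotation[match(truth$gene_id, annotation$gene_id), ]
  partner_of <- function(g) {
    if (!is.null(paralog_pairs)) {
      pp <- as.matrix(paralog_pairs)
      i <- which(pp[, 1] == g)
      if (length(i)) return(pp[i[1], 2])
      i <- which(pp[, 2] == g)
      if (length(i)) return(pp[i[1], 1])
      return(NA_character_)
    }
    j <- match(g, annotation$gene_id) %% nrow(annotation) + 1L
    annotation$gene_id[j]
  }
  with_seed(seed, {
    depth <- as.integer(depth)
    gi <- sample.int(nrow(truth), depth, replace = TRUE,
                     prob = truth$count / sum(truth$count))
    w_start <- integer(nrow(truth)); w_end <- integer(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      w <- gene_window(ann$three_prime_pos[i], ann$strand[i])
      w_start[i] <- w[1]; w_end[i] <- w[2]
    }
    pos <- w_start[gi] + floor(stats::runif(depth) * (w_end[gi] - w_start[gi]))
    ambig <- stats::runif(depth) < shared_frac
    gene_hits <- truth$gene_id[gi]
    if (any(ambig)) {
      partners <- vapply(gene_hits[ambig], partner_of, "")
      drop <- is.na(partners)
      ambig[ambig][drop] <- FALSE
      gene_hits[ambig] <- paste(gene_hits[ambig],
                                partners[!drop], sep = ";")
    }
    data.frame(chrom = ann$chrom[gi], pos = as.integer(pos),
               strand = ann$strand[gi], umi = random_umis(depth),
               unique_flag = !ambig, gene_hits = gene_hits)
  })
}
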