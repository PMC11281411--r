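#' RPKM normalisation of contig read counts
#'
#' Reads per kilobase of contig per million mapped reads:
#' \deqn{RPKM = reads / ((length/10^3) (library/10^6))}
#' computed per contig and sample.
#'
#' @param mapped_reads numeric matrix of mapped-read counts, contigs x
#'   samples, with contig row names and sample column names.
#' @param lengths contig lengths in bases (>= 1), in row order or named by
#'   contig id.
#' @param total_mapped per-sample library sizes (total mapped reads);
#'   defaults to the column sums of \code{mapped_reads}. Must be positive.
#' @return an [abundance_table()] of layer \code{"virome"}.
#' @export
compute_rpkm <- function(mapped_reads, lengths,
                         total_mapped = colSums(mapped_reads)) {
  if (!is.matrix(mapped_reads) || any(mapped_reads < 0))
    stop("mapped_reads must be a non-negative contigs x samples matrix")
  if (!is.null(names(lengths)))
    lengths <- lengths[rownames(mapped_reads)]
  if (length(lengths) != nrow(mapped_reads) || any(lengths < 1))
    stop("one length >= 1 required per contig")
  if (any(total_mapped <= 0))
    stop("total mapped reads must be positive for every sample; zero in: ",
         paste(colnames(mapped_reads)[total_mapped <= 0], collapse = ", "))
  if (any(mapped_reads > rep(total_mapped, each = nrow(mapped_reads))))
    stop("mapped_reads exceed the per-sample library size")
  rpkm <- sweep(mapped_reads / (lengths / 1e3), 2, total_mapped / 1e6, `/`)
  abundance_table(rpkm, "virome")
}

#' Convert a table to relative abundance
#'
#' Divides each sample column by its sum so columns sum to one. Idempotent.
#'
#' @param table an [abundance_table()].
#' @return an [abundance_table()] with unit column sums.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  cs <- colSums(table$values)
  if (any(cs <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(colnames(table$values)[cs <= 0], collapse = ", "))
  abundance_table(sweep(table$values, 2, cs, `/`), table$layer,
                  table$annotations)
}

#' Retain the most abundant fraction of features
#'
#' Implements the retention filter applied before network construction
#' (e.g. top 15% of bacterial OTUs, top 5% of virome contigs) that guards
#' against spurious correlations driven by zeros. Features are ranked by
#' mean relative abundance pooled across all samples; the top
#' \code{ceiling(fraction * n)} are kept. Ties at the cut are broken by
#' lexicographic feature id (smaller id wins); surviving features keep their
#' original order.
#'
#' @param table an [abundance_table()].
#' @param fraction fraction of features to keep, in (0, 1].
#' @param rank_by \code{"abundance"} (mean relative abundance, default) or
#'   \code{"prevalence"} (fraction of samples with non-zero abundance).
#' @return the filtered [abundance_table()].
#' @export
top_fraction <- function(table, fraction, rank_by = c("abundance", "prevalence")) {
  stopifnot(inherits(table, "abundance_table"))
  rank_by <- match.arg(rank_by)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  v <- table$values
  if (!nrow(v)) stop("empty abundance table")
  score <- if (rank_by == "abundance")
    rowMeans(to_relative(table)$values)
  else
    rowMeans(v > 0)
  n_keep <- ceiling(fraction * nrow(v))
  ord <- order(-score, rownames(v))       # ties: lexicographically smaller id first
  keep <- sort(match(rownames(v)[ord[seq_len(n_keep)]], rownames(v)))
  ann <- table$annotations
  if (!is.null(ann)) ann <- ann[ann$feature_id %in% rownames(v)[keep], , drop = FALSE]
  abundance_table(v[keep, , drop = FALSE], table$layer, ann)
}
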