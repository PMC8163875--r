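#' Splicing-adjusted count for one gene in one sample
#'
#' \code{adjusted = raw x prod(PCS_k)} over the gene's CDS introns. Missing
#' PCS values (introns with zero informative coverage in that sample) are
#' skipped, i.e. contribute a factor of 1; callers can track how often this
#' happens via the \code{"n_missing"} attribute.
#'
#' @param raw Non-negative raw gene count.
#' @param pcs_list Numeric vector of PCS values in [0, 1]; may contain
#'   \code{NA} (skipped) or be empty (intronless gene).
#' @return Adjusted count (real), never exceeding \code{raw}; the number of
#'   skipped missing values is attached as attribute \code{n_missing}.
#' @export
splicing_adjusted_counts <- function(raw, pcs_list) {
  stopifnot(length(raw) == 1L, raw >= 0)
  pcs <- pcs_list[!is.na(pcs_list)]
  if (any(pcs < 0 | pcs > 1)) stop("PCS values must lie in [0, 1]")
  structure(raw * prod(pcs), n_missing = sum(is.na(pcs_list)))
}

#' Splicing-adjusted counts for a gene-by-sample matrix
#'
#' Multiplies each raw gene count by the product of PCS values of the gene's
#' CDS introns in the same sample. Genes absent from the intron map pass
#' through unchanged; a mapped intron missing a PCS in some sample is
#' skipped with a logged warning.
#'
#' @param gene_counts data.frame or matrix of raw counts, genes in rows
#'   (rownames = gene ids), samples in columns.
#' @param metrics Per-sample metrics table from
#'   \code{\link{compute_splicing_metrics}}.
#' @param intron_map Named list mapping gene id to the character vector of
#'   its CDS-intron \code{segment_id}s (see \code{\link{map_cds_introns}}).
#' @return Numeric matrix of adjusted counts with the input dimnames.
#' @export
adjust_table <- function(gene_counts, metrics, intron_map) {
  m <- as.matrix(gene_counts)
  out <- m * 0
  n_missing <- 0L
  pcs_key <- paste(metrics$segment_id, metrics$sample_id)
  for (g in rownames(m)) {
    segs <- intron_map[[g]]
    for (s in colnames(m)) {
      if (is.null(segs) || length(segs) == 0L) {
        out[g, s] <- m[g, s]
        next
      }
      pcs <- metrics$pcs[match(paste(segs, s), pcs_key)]
      adj <- splicing_adjusted_counts(m[g, s], pcs)
      n_missing <- n_missing + attr(adj, "n_missing")
      out[g, s] <- as.numeric(adj)
    }
  }
  if (n_missing > 0L) {
    warning(n_missing, " missing PCS value(s) skipped (treated as 1)")
  }
  out
}

#' Map genes to the intron segments inside their CDS
#'
#' An intron counts as "inside the CDS" when its coordinates fall within the
#' CDS span of its gene (minimum CDS start to maximum CDS end across the
#' gene's transcripts). UTR introns are excluded.
#'
#' @param segments Segment table from \code{\link{extract_intron_segments}}.
#' @param annotation GFF3/GTF path or \code{GRanges} containing CDS features
#'   with \code{gene_id} or \code{Parent} attribution.
#' @return Named list: gene id -> character vector of segment ids.
#' @export
map_cds_introns <- function(segments, annotation) {
  gr <- load_annotation(annotation)
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) return(list())
  tx <- exon_transcript_ids(cds)
  gene <- exon_gene_ids(cds, tx)
  span <- data.frame(gene_id = gene,
                     start = GenomicRanges::start(cds) - 1L,
                     end = GenomicRanges::end(cds))
  lo <- tapply(span$start, span$gene_id, min)
  hi <- tapply(span$end, span$gene_id, max)

  out <- lapply(stats::setNames(nm = segments$gene_id), function(g) character())
  for (i in seq_len(nrow(segments))) {
    g <- segments$gene_id[i]
    if (!g %in% names(lo)) next
    if (segments$intron_start[i] >= lo[[g]] &&
        segments$intron_end[i] <= hi[[g]]) {
      out[[g]] <- c(out[[g]], segments$segment_id[i])
    }
  }
  out[lengths(out) > 0L]
}
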