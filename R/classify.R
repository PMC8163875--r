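#' Classify one spliced alignment against one intron segment
#'
#' Assigns exactly one of the five junction-read classes (or \code{"NONE"})
#' to an alignment/segment pair:
#' \describe{
#'   \item{CSR}{an N-gap whose boundaries equal the annotated intron, with at
#'     least \code{min_overhang} aligned nucleotides flanking the gap.}
#'   \item{EIJR}{a contiguous (ungapped at that boundary) stretch across the
#'     transcriptional 5' splice site with \code{min_overhang} on both sides.}
#'   \item{IEJR}{likewise across the 3' splice site.}
#'   \item{A5R}{an N-gap using the annotated 3' splice site but an
#'     alternative 5' site within the segment.}
#'   \item{A3R}{an N-gap using the annotated 5' splice site but an
#'     alternative 3' site within the segment.}
#' }
#' The transcriptional 5' splice site is \code{intron_start} for plus-strand
#' and \code{intron_end} for minus-strand segments, so counts are invariant
#' under reverse-complementing the locus. When several rules match (e.g. a
#' long read contiguous over both boundaries of a short intron) the
#' precedence CSR > A5R > A3R > EIJR > IEJR makes the label unique.
#'
#' @param alignment A list with elements \code{chrom}, \code{start} (0-based
#'   leftmost reference position) and \code{cigar} (SAM CIGAR string), or a
#'   length-1 \code{GAlignments}.
#' @param segment A single-row segment data.frame from
#'   \code{\link{extract_intron_segments}}.
#' @param min_overhang Minimum aligned nucleotides required on each side of a
#'   junction (default 8).
#' @return One of \code{"EIJR", "IEJR", "CSR", "A5R", "A3R", "NONE"}.
#' @export
classify_alignment <- function(alignment, segment, min_overhang = 8L) {
  stopifnot(min_overhang >= 1L)
  if (methods::is(alignment, "GAlignments")) {
    stopifnot(length(alignment) == 1L)
    alignment <- list(
      chrom = as.character(GenomicAlignments::seqnames(alignment)),
      start = GenomicAlignments::start(alignment) - 1L,
      cigar = GenomicAlignments::cigar(alignment)
    )
  }
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", alignment$cigar)) {
    stop("malformed CIGAR: ", alignment$cigar)
  }
  if (!identical(alignment$chrom, segment$chrom)) {
    return("NONE")
  }
  bl <- GenomicAlignments::extractAlignmentRangesOnReference(
    alignment$cigar, pos = as.integer(alignment$start) + 1L)[[1L]]
  classify_blocks(IRanges::start(bl) - 1L, IRanges::end(bl), segment,
                  min_overhang)
}

# core rule on 0-based half-open aligned blocks
classify_blocks <- function(bs, be, segment, min_overhang) {
  is <- segment$intron_start
  ie <- segment$intron_end
  plus <- segment$strand == "+"
  j5 <- if (plus) is else ie  # transcriptional 5' splice site
  j3 <- if (plus) ie else is
  n <- length(bs)
  if (n > 1L) {
    gs <- be[-n]   # gap starts
    ge <- bs[-1L]  # gap ends
    lo <- be[-n] - bs[-n]       # left flank widths
    ro <- be[-1L] - bs[-1L]     # right flank widths
    ok <- lo >= min_overhang & ro >= min_overhang
    if (any(ok & gs == is & ge == ie)) return("CSR")
    within <- gs >= segment$seg_start & ge <= segment$seg_end
    if (plus) {
      if (any(ok & within & ge == ie & gs != is)) return("A5R")
      if (any(ok & within & gs == is & ge != ie)) return("A3R")
    } else {
      if (any(ok & within & gs == is & ge != ie)) return("A5R")
      if (any(ok & within & ge == ie & gs != is)) return("A3R")
    }
  }
  spans <- function(j) any(bs <= j - min_overhang & be >= j + min_overhang)
  if (spans(j5)) return("EIJR")
  if (spans(j3)) return("IEJR")
  "NONE"
}

#' Count junction-read classes per intron segment
#'
#' Streams primary alignments over the segments and tabulates the five
#' junction-read classes per (segment, sample). Every retained alignment
#' contributes at most once to each overlapping segment; unmapped, secondary
#' and supplementary alignments are skipped; each mate of a pair is counted
#' independently. The derived \code{total} column is
#' \code{(eijr + iejr)/2 + a5r + a3r + csr}.
#'
#' @param alignments Path to a BAM or SAM file, or a \code{GAlignments}
#'   object. SAM input is converted on the fly.
#' @param segments Segment table from \code{\link{extract_intron_segments}}.
#' @param sample_id Sample label recorded in the output.
#' @param min_overhang Passed to the per-alignment classifier.
#' @return A data.frame with one row per segment: \code{segment_id, gene_id,
#'   intron_index, chrom, strand, intron_start, intron_end, sample_id, eijr,
#'   iejr, csr, a5r, a3r, total}. Segments with no informative reads have
#'   all-zero counts.
#' @export
count_junctions <- function(alignments, segments, sample_id = "sample",
                            min_overhang = 8L) {
  galn <- load_alignments(alignments)
  classes <- c("eijr", "iejr", "csr", "a5r", "a3r")
  counts <- matrix(0L, nrow = nrow(segments), ncol = length(classes),
                   dimnames = list(segments$segment_id, classes))

  if (length(galn) > 0L && nrow(segments) > 0L) {
    seg_gr <- GenomicRanges::GRanges(
      segments$chrom,
      IRanges::IRanges(segments$seg_start + 1L, segments$seg_end))
    hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(galn), seg_gr,
                                        ignore.strand = TRUE)
    if (length(hits) > 0L) {
      blk <- GenomicAlignments::extractAlignmentRangesOnReference(
        GenomicAlignments::cigar(galn), pos = GenomicAlignments::start(galn))
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (k in seq_along(qh)) {
        b <- blk[[qh[k]]]
        lab <- classify_blocks(IRanges::start(b) - 1L, IRanges::end(b),
                               segments[sh[k], ], min_overhang)
        if (lab != "NONE") {
          j <- match(tolower(lab), classes)
          counts[sh[k], j] <- counts[sh[k], j] + 1L
        }
      }
    }
  }

  out <- data.frame(
    segment_id = segments$segment_id,
    gene_id = segments$gene_id,
    intron_index = segments$intron_index,
    chrom = segments$chrom,
    strand = segments$strand,
    intron_start = segments$intron_start,
    intron_end = segments$intron_end,
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(counts, row.names = NULL))
  out$total <- total_coverage(out$eijr, out$iejr, out$csr, out$a5r, out$a3r)
  rownames(out) <- NULL
  out
}

load_alignments <- function(alignments) {
  if (methods::is(alignments, "GAlignments")) return(alignments)
  path <- alignments
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag))
}
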