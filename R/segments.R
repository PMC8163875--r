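#' Build intron segments from an exon annotation and a genome
#'
#' Every pair of consecutive exons of a transcript defines one segment:
#' the intervening intron together with its two flanking exons. Segments
#' arising identically from several transcripts are collapsed to a single
#' record. All coordinates are internal 0-based half-open; GFF3/GTF input
#' (1-based inclusive) is converted on read.
#'
#' @param annotation Path to a GFF3/GTF file, or a \code{GRanges} as returned
#'   by \code{rtracklayer::import} containing \code{exon} features grouped by
#'   \code{Parent} (GFF3) or \code{transcript_id} (GTF).
#' @param genome Path to a FASTA file, or a \code{Biostrings::DNAStringSet}.
#'   Sequence names are truncated at the first whitespace.
#' @param K Number of leading intron nucleotides to record (coding strand);
#'   must be at least 6 so that the fourth-nucleotide and +1..+6 donor window
#'   are always available.
#' @return A data.frame with one row per distinct intron segment and columns
#'   \code{segment_id, gene_id, transcript_id, intron_index, chrom, strand,
#'   seg_start, exon1_end, intron_start, intron_end, exon2_start, seg_end,
#'   donor_dinucleotide, acceptor_dinucleotide, intron_seq_5prime,
#'   exon_triplet}. \code{intron_index} is 1-based in transcript (5' to 3')
#'   orientation; \code{seg_start}/\code{seg_end} are the outer bounds of the
#'   two flanking exons. Donor/acceptor dinucleotides, the leading intron
#'   sequence and the 5'-exon terminal triplet (positions -3..-1) are
#'   reported on the coding strand (reverse-complemented for minus-strand
#'   genes).
#' @export
extract_intron_segments <- function(annotation, genome, K = 6L) {
  stopifnot(K >= 6L)
  gr <- load_annotation(annotation)
  dna <- load_genome(genome)

  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) {
    return(empty_segments())
  }
  tx <- exon_transcript_ids(ex)
  gene <- exon_gene_ids(ex, tx)

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    # 0-based half-open
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    transcript_id = tx,
    gene_id = gene,
    stringsAsFactors = FALSE
  )
  if (any(df$strand == "*")) {
    stop("exon features must be stranded (+/-)")
  }
  if (!all(df$chrom %in% names(dna))) {
    stop("chromosome not present in genome: ",
         paste(unique(setdiff(df$chrom, names(dna))), collapse = ","))
  }
  chrlen <- stats::setNames(Biostrings::width(dna), names(dna))
  if (any(df$start < 0L | df$end > chrlen[df$chrom])) {
    stop("exon outside chromosome bounds")
  }

  segs <- consecutive_exon_pairs(df)
  if (nrow(segs) == 0L) {
    return(empty_segments())
  }

  # collapse duplicates (same intron from several transcripts); first record
  # in (chrom, intron_start, gene_id, transcript_id) sorted order wins
  segs <- segs[order(segs$chrom, segs$intron_start, segs$intron_end,
                     segs$gene_id, segs$transcript_id), , drop = FALSE]
  key <- paste(segs$chrom, segs$strand, segs$intron_start, segs$intron_end)
  segs <- segs[!duplicated(key), , drop = FALSE]

  ilen <- segs$intron_end - segs$intron_start
  if (any(ilen < 4L)) {
    warning(sum(ilen < 4L), " intron(s) shorter than 4 nt dropped")
    segs <- segs[ilen >= 4L, , drop = FALSE]
  }
  if (nrow(segs) == 0L) {
    return(empty_segments())
  }

  seqs <- segment_sequences(segs, dna, K)
  segs$donor_dinucleotide <- seqs$donor
  segs$acceptor_dinucleotide <- seqs$acceptor
  segs$intron_seq_5prime <- seqs$intron5p
  segs$exon_triplet <- seqs$triplet
  segs$segment_id <- sprintf("%s:%d-%d:%s", segs$chrom, segs$intron_start,
                             segs$intron_end, segs$strand)
  rownames(segs) <- NULL
  segs[, c("segment_id", "gene_id", "transcript_id", "intron_index", "chrom",
           "strand", "seg_start", "exon1_end", "intron_start", "intron_end",
           "exon2_start", "seg_end", "donor_dinucleotide",
           "acceptor_dinucleotide", "intron_seq_5prime", "exon_triplet")]
}

# consecutive exon pairs of every transcript -> intron segment coordinates
consecutive_exon_pairs <- function(df) {
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  n <- nrow(df)
  i <- which(df$transcript_id[-n] == df$transcript_id[-1L])  # pair (i, i+1)
  out <- data.frame(
    gene_id = df$gene_id[i],
    transcript_id = df$transcript_id[i],
    chrom = df$chrom[i],
    strand = df$strand[i],
    seg_start = df$start[i],
    exon1_end = df$end[i],
    intron_start = df$end[i],
    intron_end = df$start[i + 1L],
    exon2_start = df$start[i + 1L],
    seg_end = df$end[i + 1L],
    stringsAsFactors = FALSE
  )
  # transcript orientation: first intron is leftmost on +, rightmost on -
  ord <- stats::ave(seq_along(i), out$transcript_id, FUN = seq_along)
  ntx <- stats::ave(seq_along(i), out$transcript_id, FUN = length)
  out$intron_index <- ifelse(out$strand == "+", ord, ntx - ord + 1L)
  out
}

# coding-strand sequence context for each segment (vectorized per chromosome)
segment_sequences <- function(segs, dna, K) {
  n <- nrow(segs)
  donor <- acceptor <- intron5p <- triplet <- character(n)
  for (cn in unique(segs$chrom)) {
    str <- as.character(dna[[cn]])
    idx <- which(segs$chrom == cn)
    s <- segs$intron_start[idx]
    e <- segs$intron_end[idx]
    k <- pmin(K, e - s)
    plus <- segs$strand[idx] == "+"
    p <- idx[plus]
    m <- idx[!plus]
    if (length(p) > 0L) {
      sp <- s[plus]; ep <- e[plus]; kp <- k[plus]
      donor[p] <- substring(str, sp + 1L, sp + 2L)
      acceptor[p] <- substring(str, ep - 1L, ep)
      intron5p[p] <- substring(str, sp + 1L, sp + kp)
      has3 <- sp - segs$seg_start[p] >= 3L
      triplet[p] <- ifelse(has3, substring(str, sp - 2L, sp), NA_character_)
    }
    if (length(m) > 0L) {
      sm <- s[!plus]; em <- e[!plus]; km <- k[!plus]
      donor[m] <- revcomp(substring(str, em - 1L, em))
      acceptor[m] <- revcomp(substring(str, sm + 1L, sm + 2L))
      intron5p[m] <- revcomp(substring(str, em - km + 1L, em))
      has3 <- segs$seg_end[m] - em >= 3L
      triplet[m] <- ifelse(has3, revcomp(substring(str, em + 1L, em + 3L)),
                           NA_character_)
    }
  }
  list(donor = donor, acceptor = acceptor, intron5p = intron5p,
       triplet = triplet)
}

revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x[ok])))
  out
}

empty_segments <- function() {
  data.frame(
    segment_id = character(), gene_id = character(),
    transcript_id = character(), intron_index = integer(),
    chrom = character(), strand = character(), seg_start = integer(),
    exon1_end = integer(), intron_start = integer(), intron_end = integer(),
    exon2_start = integer(), seg_end = integer(),
    donor_dinucleotide = character(), acceptor_dinucleotide = character(),
    intron_seq_5prime = character(), exon_triplet = character(),
    stringsAsFactors = FALSE
  )
}

load_annotation <- function(annotation) {
  if (methods::is(annotation, "GRanges")) return(annotation)
  rtracklayer::import(annotation)
}

load_genome <- function(genome) {
  dna <- if (methods::is(genome, "DNAStringSet")) genome
    else Biostrings::readDNAStringSet(genome)
  names(dna) <- sub("\\s.*$", "", names(dna))
  dna
}

exon_transcript_ids <- function(ex) {
  m <- S4Vectors::mcols(ex)
  if ("transcript_id" %in% names(m) && !all(is.na(m$transcript_id))) {
    return(as.character(m$transcript_id))
  }
  if ("Parent" %in% names(m)) {
    p <- m$Parent
    if (methods::is(p, "CharacterList") || methods::is(p, "List")) {
      if (any(lengths(p) != 1L)) {
        stop("each exon must have exactly one Parent transcript")
      }
      return(unlist(p, use.names = FALSE))
    }
    return(as.character(p))
  }
  stop("annotation lacks transcript grouping (Parent or transcript_id)")
}

exon_gene_ids <- function(ex, tx) {
  m <- S4Vectors::mcols(ex)
  if ("gene_id" %in% names(m) && !all(is.na(m$gene_id))) {
    return(as.character(m$gene_id))
  }
  # fall back to the transcript id with a trailing .N / -N version stripped
  sub("[.-][0-9]+$", "", tx)
}
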