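# in-code fixtures: tiny genomes and annotations built deterministically

# random genome with specific subsequences planted at 0-based positions
toy_genome <- function(len = 400L, plant = list(), seed = 101L,
                       chrom = "chr1") {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (p in plant) {
    s[(p$at + 1L):(p$at + nchar(p$seq))] <- strsplit(p$seq, "")[[1L]]
  }
  Biostrings::DNAStringSet(stats::setNames(paste(s, collapse = ""), chrom))
}

# exon annotation for one transcript; exons as list of 0-based [start, end)
toy_annotation <- function(exons, strand = "+", tx = "t1", gene = "g1",
                           chrom = "chr1") {
  n <- length(exons)
  GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(vapply(exons, `[`, 0L, 1L) + 1L,
                     vapply(exons, `[`, 0L, 2L)),
    strand = strand,
    type = "exon",
    Parent = tx,
    gene_id = gene,
    transcript_id = tx
  )
}

# standard two-exon plus-strand fixture: exons [0,100) and [200,300),
# GT..AG intron [100,200), exon triplet ACC, intron starts GTAAGT
toy_reference <- function(strand = "+") {
  if (strand == "+") {
    plant <- list(list(at = 97L, seq = "ACC"),
                  list(at = 100L, seq = "GTAAGT"),
                  list(at = 198L, seq = "AG"))
  } else {
    # coding-strand motifs reverse-complemented onto the plus strand
    plant <- list(list(at = 200L, seq = "GGT"),           # rc("ACC")
                  list(at = 194L, seq = "ACTTAC"),        # rc("GTAAGT")
                  list(at = 100L, seq = "CT"))            # rc("AG")
  }
  list(genome = toy_genome(400L, plant),
       annotation = toy_annotation(list(c(0L, 100L), c(200L, 300L)),
                                   strand = strand))
}

# alignment stub for classify_alignment
aln <- function(start, cigar, chrom = "chr1") {
  list(chrom = chrom, start = start, cigar = cigar)
}

# write a SAM file from alignment stubs (sequence = all A, matching lengths)
write_sam <- function(alns, genome, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  recs <- vapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(a$cigar)
    paste(sprintf("r%04d", i), 0L, a$chrom, a$start + 1L, 60L, a$cigar,
          "*", 0L, 0L, strrep("A", qlen), strrep("I", qlen), sep = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  path
}

# independent base-R reverse complement (oracle; no Biostrings)
rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}
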