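plus_seg <- function() {
  ref <- toy_reference("+")
  extract_intron_segments(ref$annotation, ref$genome)[1L, ]
}
minus_seg <- function() {
  ref <- toy_reference("-")
  extract_intron_segments(ref$annotation, ref$genome)[1L, ]
}

test_that("the five classes are assigned by junction geometry (+ strand)", {
  seg <- plus_seg()
  cases <- list(
    list(aln(92L, "16M"), "EIJR"),              # contiguous over 5'SS, 8/8
    list(aln(192L, "16M"), "IEJR"),             # contiguous over 3'SS
    list(aln(92L, "8M100N8M"), "CSR"),          # gap exactly [100,200)
    list(aln(87L, "8M105N8M"), "A5R"),          # gap [95,200): alt donor
    list(aln(92L, "8M110N8M"), "A3R"),          # gap [100,210): alt acceptor
    list(aln(120L, "20M"), "NONE"),             # wholly intronic
    list(aln(10L, "20M"), "NONE")               # wholly exonic
  )
  for (cs in cases) {
    expect_identical(classify_alignment(cs[[1]], seg, min_overhang = 8L),
                     cs[[2]])
  }
})

test_that("min_overhang is enforced on both sides of a junction", {
  seg <- plus_seg()
  short <- aln(93L, "15M")   # 7 nt on the exon side of the 5'SS
  expect_identical(classify_alignment(short, seg, min_overhang = 8L), "NONE")
  expect_identical(classify_alignment(short, seg, min_overhang = 7L), "EIJR")
  gap7 <- aln(93L, "7M100N9M")
  expect_identical(classify_alignment(gap7, seg, min_overhang = 8L), "NONE")
  expect_identical(classify_alignment(gap7, seg, min_overhang = 7L), "CSR")
})

test_that("classification is strand-aware at the 5'/3' splice sites", {
  seg <- minus_seg()
  # on the minus strand the transcriptional 5'SS is at intron_end = 200
  expect_identical(classify_alignment(aln(192L, "16M"), seg), "EIJR")
  expect_identical(classify_alignment(aln(92L, "16M"), seg), "IEJR")
  expect_identical(classify_alignment(aln(92L, "8M100N8M"), seg), "CSR")
  # alternative donor (genomic right) with canonical acceptor -> A5R
  expect_identical(classify_alignment(aln(92L, "8M95N8M"), seg), "A5R")
  # canonical donor with alternative acceptor (genomic left) -> A3R
  expect_identical(classify_alignment(aln(87L, "8M105N8M"), seg), "A3R")
})

test_that("every (alignment, segment) pair yields exactly one label", {
  seg <- plus_seg()
  set.seed(42)
  labels <- c("EIJR", "IEJR", "CSR", "A5R", "A3R", "NONE")
  for (i in 1:50) {
    start <- sample(0:250, 1L)
    cig <- sample(c(sprintf("%dM", sample(10:40, 1L)),
                    sprintf("%dM%dN%dM", sample(8:20, 1L),
                            sample(50:110, 1L), sample(8:20, 1L))), 1L)
    out <- classify_alignment(aln(start, cig), seg)
    expect_length(out, 1L)
    expect_true(out %in% labels)
  }
  # a short-intron segment spanned contiguously at both junctions resolves
  # deterministically to the 5' class
  genome <- toy_genome(300L)
  ann <- toy_annotation(list(c(0L, 100L), c(106L, 200L)))
  seg2 <- extract_intron_segments(ann, genome)[1L, ]
  expect_identical(classify_alignment(aln(90L, "26M"), seg2), "EIJR")
})

test_that("wrong chromosome gives NONE and malformed CIGAR errors", {
  seg <- plus_seg()
  expect_identical(classify_alignment(aln(92L, "16M", chrom = "chrX"), seg),
                   "NONE")
  expect_error(classify_alignment(aln(92L, "16Q"), seg))
})

test_that("count_junctions reproduces a hand-counted read mixture", {
  ref <- toy_reference("+")
  segs <- extract_intron_segments(ref$annotation, ref$genome)
  csr_read <- function(s) aln(s, sprintf("%dM100N%dM", 100L - s, s - 76L))
  reads <- c(
    lapply(c(88L, 89L, 90L, 91L, 92L, 88L, 89L, 90L, 91L, 92L), csr_read),
    lapply(c(88L, 89L, 90L, 91L), function(s) aln(s, "20M")),
    lapply(c(188L, 189L, 190L, 191L), function(s) aln(s, "20M"))
  )
  sam <- write_sam(reads, ref$genome)
  out <- count_junctions(sam, segs, sample_id = "s1")
  expect_identical(out$eijr, 4L)
  expect_identical(out$iejr, 4L)
  expect_identical(out$csr, 10L)
  expect_identical(out$a5r, 0L)
  expect_identical(out$a3r, 0L)
  # total by direct evaluation of the coverage formula
  expect_identical(out$total, (4 + 4) / 2 + 0 + 0 + 10)
  expect_identical(out$sample_id, "s1")
})

test_that("an empty alignment stream yields an all-zero table", {
  ref <- toy_reference("+")
  segs <- extract_intron_segments(ref$annotation, ref$genome)
  sam <- write_sam(list(), ref$genome)
  out <- count_junctions(sam, segs)
  expect_identical(out$csr + out$eijr + out$iejr + out$a5r + out$a3r, 0L)
  expect_identical(out$total, 0)
})

test_that("one read spanning two adjacent segments is counted in each", {
  genome <- toy_genome(400L)
  ann <- toy_annotation(list(c(0L, 100L), c(150L, 250L), c(300L, 400L)))
  segs <- extract_intron_segments(ann, genome)
  # gaps over both introns: CSR for both segments
  sam <- write_sam(list(aln(92L, "8M50N100M50N8M")), genome)
  out <- count_junctions(sam, segs)
  expect_identical(out$csr, c(1L, 1L))
})

test_that("class counts are invariant under strand mirroring", {
  # plus-strand locus with reads of every class, versus the same locus
  # reverse-complemented (coordinates remapped x -> L - x, strand flipped)
  L <- 400L
  ref <- toy_reference("+")
  segs_p <- extract_intron_segments(ref$annotation, ref$genome)
  reads_p <- list(aln(92L, "16M"), aln(190L, "14M"), aln(90L, "10M100N10M"),
                  aln(85L, "10M105N10M"), aln(90L, "10M110N10M"))
  out_p <- count_junctions(write_sam(reads_p, ref$genome), segs_p)

  genome_m <- Biostrings::DNAStringSet(stats::setNames(as.character(
    Biostrings::reverseComplement(ref$genome[["chr1"]])), "chr1"))
  ann_m <- toy_annotation(list(c(100L, 200L), c(300L, 400L)), strand = "-")
  segs_m <- extract_intron_segments(ann_m, genome_m)
  expect_identical(segs_m$donor_dinucleotide, segs_p$donor_dinucleotide)
  expect_identical(segs_m$exon_triplet, segs_p$exon_triplet)
  mirror <- function(a) {
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(a$cigar)
    ops <- rev(strsplit(gsub("([MN])", "\\1 ", a$cigar), " ")[[1L]])
    aln(L - (a$start + w), paste(ops, collapse = ""))
  }
  out_m <- count_junctions(write_sam(lapply(reads_p, mirror), genome_m),
                           segs_m)
  for (cl in c("eijr", "iejr", "csr", "a5r", "a3r")) {
    expect_identical(out_m[[cl]], out_p[[cl]])
  }
})
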