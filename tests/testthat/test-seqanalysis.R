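test_that("splice-site windows concatenate exon and intron context", {
  ref <- toy_reference("+")
  segs <- extract_intron_segments(ref$annotation, ref$genome)
  w <- splice_site_windows(segs, ref$genome)
  expect_identical(unname(w$five_prime), "ACCGTAAGT")  # exon -3..-1 + +1..+6
  expect_identical(nchar(unname(w$three_prime)), 9L)
  expect_identical(substr(unname(w$three_prime), 5, 6), "AG")
  # a minus-strand mirror of the same locus gives identical coding windows
  refm <- toy_reference("-")
  segsm <- extract_intron_segments(refm$annotation, refm$genome)
  wm <- splice_site_windows(segsm, refm$genome)
  expect_identical(substr(unname(wm$five_prime), 4, 9), "GTAAGT")
})

test_that("segments too short for the window are skipped with a warning", {
  genome <- toy_genome(300L)
  ann <- toy_annotation(list(c(0L, 100L), c(104L, 200L)))  # 4 nt intron
  segs <- extract_intron_segments(ann, genome)
  expect_warning(w <- splice_site_windows(segs, genome), "too short")
  expect_length(w$five_prime, 0L)
})

test_that("position frequency matrices count columns exactly", {
  pfm <- position_frequency(c("AC", "AG"))
  expect_identical(unname(pfm$counts["A", 1L]), 2L)
  expect_identical(unname(pfm$counts["C", 2L]), 1L)
  expect_identical(unname(pfm$counts["G", 2L]), 1L)
  expect_identical(pfm$n, c(2L, 2L))
  expect_error(position_frequency(character(0)), "no sequences")
  expect_error(position_frequency(c("AC", "A")), "equal length")
  uni <- position_frequency(rep("GTAAGT", 100))
  expect_true(all(uni$n == 100L))
  expect_true(all(apply(uni$counts, 2, max) == 100L))
  # N is excluded from its column with n adjusted
  amb <- position_frequency(c("AN", "AC"))
  expect_identical(amb$n, c(2L, 1L))
})

test_that("information logo heights follow 2 - H", {
  uniform <- position_frequency(c("AA", "CC", "GG", "TT"))
  expect_equal(colSums(information_logo(uniform)), c(0, 0),
               tolerance = 1e-12)
  single <- position_frequency(rep("A", 5))
  expect_equal(unname(information_logo(single)["A", 1L]), 2,
               tolerance = 1e-12)
  half <- position_frequency(c("A", "C"))
  il <- information_logo(half)
  expect_equal(sum(il[, 1L]), 1, tolerance = 1e-12)   # 2 - H(1/2,1/2)
  expect_equal(unname(il["A", 1L]), 0.5, tolerance = 1e-12)
  expect_equal(unname(il["C", 1L]), 0.5, tolerance = 1e-12)
})

test_that("difference logos are zero on equal inputs and antisymmetric", {
  a <- position_frequency(c("ACGT", "AGGT", "ACTT"))
  d0 <- difference_logo(a, a)
  expect_true(all(d0$contribution == 0))
  expect_true(all(d0$divergence == 0))

  hi <- position_frequency(rep("A", 4))
  lo <- position_frequency(rep("T", 4))
  d <- difference_logo(hi, lo)
  expect_equal(d$divergence[1L], 1, tolerance = 1e-12)  # JSD of point masses
  expect_gt(d$contribution[d$nucleotide == "A"], 0)
  expect_lt(d$contribution[d$nucleotide == "T"], 0)
  expect_equal(sum(abs(d$contribution)), 1, tolerance = 1e-12)

  swapped <- difference_logo(lo, hi)
  expect_equal(swapped$contribution, -d$contribution, tolerance = 1e-12)
  expect_equal(swapped$divergence, d$divergence, tolerance = 1e-12)

  b <- position_frequency(c("AC", "GT"))
  expect_error(difference_logo(a, b), "position")
})

test_that("positional Fisher test reproduces exact enumeration", {
  expect_equal(positional_fisher(c(A = 8, C = 2), c(A = 2, C = 8), "A"),
               4252 / 184756, tolerance = 1e-12)
  expect_identical(positional_fisher(c(A = 5, C = 5), c(A = 5, C = 5), "A"),
                   1)
  expect_equal(positional_fisher(c(A = 10, G = 0), c(A = 0, G = 10), "A"),
               2 / choose(20, 10), tolerance = 1e-12)
  # empty margin convention
  expect_identical(positional_fisher(c(A = 0, C = 0), c(A = 3, C = 2), "A"),
                   1)
  # counts for non-focal nucleotides pool together
  expect_equal(
    positional_fisher(c(A = 8, C = 1, G = 1), c(A = 2, C = 4, T = 4), "A"),
    positional_fisher(c(A = 8, C = 2), c(A = 2, C = 8), "A"),
    tolerance = 1e-15)
})

test_that("positional Fisher agrees with stats::fisher.test", {
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(sample(0:25, 4, replace = TRUE), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 || sum(tab[, 1]) == 0 ||
          sum(tab[, 2]) == 0) next
    p1 <- positional_fisher(c(A = tab[1, 1], C = tab[1, 2]),
                            c(A = tab[2, 1], C = tab[2, 2]), "A")
    p2 <- stats::fisher.test(tab)$p.value
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("fourth-nucleotide groups follow intron position +4", {
  segs <- data.frame(intron_seq_5prime = c("GTAAGT", "GTATGT", "GTANGT",
                                           "GTACGT", "GTAGGT"))
  g <- classify_fourth_nucleotide(segs)
  expect_identical(as.character(g),
                   c("A4", "T4", NA, "C4", "G4"))
})

test_that("exon triplet patterns encode the AAG consensus match", {
  expect_identical(as.character(classify_exon_triplet("AAG")), "AAG")
  expect_identical(as.character(classify_exon_triplet("ACC")), "ABH")
  expect_identical(as.character(classify_exon_triplet("TCT")), "BBH")
  expect_identical(as.character(classify_exon_triplet("ANG")), NA_character_)
  # the eight patterns partition all 64 triplets
  nt <- c("A", "C", "G", "T")
  all64 <- apply(expand.grid(nt, nt, nt), 1, paste, collapse = "")
  g <- classify_exon_triplet(all64)
  expect_false(anyNA(g))
  expect_identical(sum(table(g)), 64L)
  expect_identical(length(unique(g)), 8L)
})

test_that("delta IRS is the difference of condition means", {
  samples <- sim_sample_sheet(replicates = 2L)
  met <- data.frame(segment_id = "s1", sample_id = samples$sample_id,
                    irs = c(0.4, 0.6, 1.5, 2.5))
  d <- delta_irs(met, samples)
  expect_equal(d$delta, 1.5, tolerance = 1e-12)
  # identical conditions give zero; replicate order is irrelevant
  met0 <- met
  met0$irs <- c(1, 2, 2, 1)
  expect_equal(delta_irs(met0, samples)$delta, 0, tolerance = 1e-12)
  met_perm <- met[c(2, 1, 4, 3), ]
  expect_equal(delta_irs(met_perm, samples)$delta, d$delta,
               tolerance = 1e-12)
})

test_that("group comparison provides CDFs, box stats and rank-sum tests", {
  delta <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("a", "b"), each = 3)
  gc <- group_compare(delta, grp)
  # exact two-sided enumeration: 2 of the 20 orderings are this extreme
  expect_equal(gc$pvalues$p, 0.1, tolerance = 1e-12)
  for (g in c("a", "b")) {
    f <- gc$cdf$cum_fraction[gc$cdf$group == g]
    expect_true(all(diff(f) >= 0))
    expect_identical(utils::tail(f, 1), 1)
  }
  expect_identical(gc$box$median, c(2, 11))

  same <- group_compare(rep(c(5, 6, 7), 2), rep(c("a", "b"), each = 3))
  expect_gte(same$pvalues$p, 0.99)

  expect_warning(
    group_compare(c(1, 2, 3), factor(c("a", "a", "b"),
                                     levels = c("a", "b", "c"))),
    "excluded")
})
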