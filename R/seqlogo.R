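#' Aligned splice-site windows for a set of segments
#'
#' Extracts fixed-width coding-strand windows around the two splice sites:
#' the 5'SS window spans the last \code{exon_up} exonic nucleotides
#' (positions -exon_up..-1) plus the first \code{intron_down} intron
#' nucleotides (+1..+intron_down); the 3'SS window spans the last
#' \code{intron_up} intron nucleotides plus the first \code{exon_down}
#' nucleotides of the downstream exon. Segments whose intron or flanking
#' exons are too short for the window are skipped with a warning.
#'
#' @param segments Segment table from \code{\link{extract_intron_segments}}.
#' @param genome FASTA path or \code{DNAStringSet}.
#' @param exon_up,intron_down 5'SS window widths (defaults 3 and 6).
#' @param intron_up,exon_down 3'SS window widths (defaults 6 and 3).
#' @return list with character vectors \code{five_prime} and
#'   \code{three_prime}, named by \code{segment_id}.
#' @export
splice_site_windows <- function(segments, genome, exon_up = 3L,
                                intron_down = 6L, intron_up = 6L,
                                exon_down = 3L) {
  dna <- load_genome(genome)
  n <- nrow(segments)
  five <- three <- rep(NA_character_, n)
  ilen <- segments$intron_end - segments$intron_start
  up_exon <- segments$intron_start - segments$seg_start  # genomic-left exon
  dn_exon <- segments$seg_end - segments$intron_end      # genomic-right exon
  plus <- segments$strand == "+"
  e5 <- ifelse(plus, up_exon, dn_exon)                   # 5' exon width
  e3 <- ifelse(plus, dn_exon, up_exon)
  ok5 <- ilen >= intron_down & e5 >= exon_up
  ok3 <- ilen >= intron_up & e3 >= exon_down

  for (cn in unique(segments$chrom)) {
    str <- as.character(dna[[cn]])
    onchr <- segments$chrom == cn
    is0 <- segments$intron_start
    ie0 <- segments$intron_end
    sel <- which(onchr & ok5 & plus)
    if (length(sel)) {
      five[sel] <- substring(str, is0[sel] - exon_up + 1L,
                             is0[sel] + intron_down)
    }
    sel <- which(onchr & ok5 & !plus)
    if (length(sel)) {
      five[sel] <- revcomp(substring(str, ie0[sel] - intron_down + 1L,
                                     ie0[sel] + exon_up))
    }
    sel <- which(onchr & ok3 & plus)
    if (length(sel)) {
      three[sel] <- substring(str, ie0[sel] - intron_up + 1L,
                              ie0[sel] + exon_down)
    }
    sel <- which(onchr & ok3 & !plus)
    if (length(sel)) {
      three[sel] <- revcomp(substring(str, is0[sel] - exon_down + 1L,
                                      is0[sel] + intron_up))
    }
  }
  skipped <- is.na(five) | is.na(three)
  if (any(skipped)) {
    warning(sum(skipped), " segment(s) too short for the requested window")
  }
  list(five_prime = stats::setNames(five[!is.na(five)],
                                    segments$segment_id[!is.na(five)]),
       three_prime = stats::setNames(three[!is.na(three)],
                                     segments$segment_id[!is.na(three)]))
}

#' Position frequency matrix of aligned sequences
#'
#' @param sequences Character vector of equal-length sequences over
#'   \code{A,C,G,T,N}. \code{N}s are excluded from their column, with the
#'   per-column sequence count adjusted accordingly.
#' @return An object of class \code{pfm}: list with \code{counts} (4 x L
#'   integer matrix, rows A/C/G/T), \code{n} (per-column counts) and
#'   \code{positions} (column labels).
#' @export
position_frequency <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length")
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sequences))
  counts <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  present <- intersect(rownames(mat), rownames(counts))
  counts[present, ] <- mat[present, , drop = FALSE]
  bad <- setdiff(rownames(mat)[rowSums(mat) > 0], c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) stop("unexpected characters: ",
                             paste(bad, collapse = ","))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, n = as.integer(colSums(counts)),
                 positions = seq_len(L)),
            class = "pfm")
}

#' Per-position probabilities of a pfm
#' @param pfm A \code{pfm} object.
#' @return 4 x L matrix of column probabilities (0 where a column is empty).
#' @export
pfm_probabilities <- function(pfm) {
  p <- sweep(pfm$counts, 2L, pmax(pfm$n, 1L), "/")
  p[, pfm$n == 0L] <- 0
  p
}

#' Information-content sequence logo heights
#'
#' Classic Shannon logo: column height is \code{2 - H} bits, where H is the
#' column's Shannon entropy (log base 2), and each letter's height is its
#' probability times the column height. No small-sample correction is
#' applied; zero-probability letters have zero height.
#'
#' @param pfm A \code{pfm} object with at least one sequence.
#' @return 4 x L matrix of letter heights in bits.
#' @export
information_logo <- function(pfm) {
  stopifnot(sum(pfm$n) > 0L)
  p <- pfm_probabilities(pfm)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)          # 2 - H
  ic[pfm$n == 0L] <- 0
  sweep(p, 2L, ic, "*")
}

#' Difference logo between two position frequency matrices
#'
#' For each position, the column divergence is the Jensen-Shannon divergence
#' (base 2) between the two probability vectors; per-nucleotide signed
#' contributions are \code{p_high - p_low} rescaled so that the absolute
#' contributions sum to the divergence (enriched letters positive, depleted
#' negative). Symmetric up to sign: swapping the inputs flips every
#' contribution and leaves divergences unchanged.
#'
#' @param pfm_high,pfm_low \code{pfm} objects over identical positions.
#' @return data.frame with columns \code{position, nucleotide, contribution,
#'   divergence}.
#' @export
difference_logo <- function(pfm_high, pfm_low) {
  if (!identical(pfm_high$positions, pfm_low$positions)) {
    stop("position sets differ between the two matrices")
  }
  ph <- pfm_probabilities(pfm_high)
  pl <- pfm_probabilities(pfm_low)
  L <- ncol(ph)
  out <- vector("list", L)
  for (j in seq_len(L)) {
    div <- js_divergence(ph[, j], pl[, j])
    d <- ph[, j] - pl[, j]
    scale <- if (sum(abs(d)) > 0) div / sum(abs(d)) else 0
    out[[j]] <- data.frame(position = pfm_high$positions[j],
                           nucleotide = rownames(ph),
                           contribution = d * scale,
                           divergence = div,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Jensen-Shannon divergence, log base 2, with 0 log 0 = 0
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Two-sided Fisher exact test for nucleotide enrichment at one position
#'
#' Tests focal-vs-other nucleotide counts at a single logo position between
#' a high-Z and a low-Z intron set: exact two-sided p-value by summation of
#' all hypergeometric table probabilities not exceeding the observed table's
#' probability (with the conventional 1e-7 relative tolerance for numerical
#' ties). An empty margin gives p = 1.
#'
#' @param high_counts,low_counts Named integer vectors of nucleotide counts
#'   (names include \code{focal_nt}) at the position of interest.
#' @param focal_nt The nucleotide tested for enrichment (e.g. \code{"A"}).
#' @return Two-sided p-value in (0, 1].
#' @export
positional_fisher <- function(high_counts, low_counts, focal_nt) {
  a <- sum(high_counts[names(high_counts) == focal_nt])
  b <- sum(high_counts[names(high_counts) != focal_nt])
  c <- sum(low_counts[names(low_counts) == focal_nt])
  d <- sum(low_counts[names(low_counts) != focal_nt])
  fisher_2x2(a, b, c, d)
}

#' Two-sided Fisher exact p-value for the 2x2 table [[a, b], [c, d]]
#'
#' The primitive behind \code{\link{positional_fisher}}: sums hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("table entries must be non-negative")
  m <- a + b          # high-set size
  n <- c + d          # low-set size
  k <- a + c          # focal-nucleotide margin
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Draw a sequence logo or difference logo with base graphics
#'
#' Minimal renderer: letter heights from \code{\link{information_logo}} or
#' signed contributions from \code{\link{difference_logo}}, stacked per
#' position (positive up, negative down).
#'
#' @param heights 4 x L matrix (rows A/C/G/T) of stack heights; may contain
#'   negative values for difference logos.
#' @param positions Optional x-axis labels.
#' @param ylab Axis label.
#' @export
plot_logo <- function(heights, positions = seq_len(ncol(heights)),
                      ylab = "bits") {
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  L <- ncol(heights)
  ymax <- max(colSums(pmax(heights, 0)), 0.1)
  ymin <- min(-colSums(pmax(-heights, 0)), 0)
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(ymin, ymax * 1.05),
                 xlab = "position", ylab = ylab, xaxt = "n")
  graphics::axis(1, at = seq_len(L), labels = positions)
  graphics::abline(h = 0, col = "grey60")
  for (j in seq_len(L)) {
    up <- sort(heights[heights[, j] > 0, j], decreasing = FALSE)
    y <- 0
    for (nt in names(up)) {
      graphics::rect(j - 0.4, y, j + 0.4, y + up[nt], col = cols[nt],
                     border = NA)
      graphics::text(j, y + up[nt] / 2, nt, cex = 0.7, col = "white")
      y <- y + up[nt]
    }
    dn <- sort(-heights[heights[, j] < 0, j], decreasing = FALSE)
    y <- 0
    for (nt in names(dn)) {
      graphics::rect(j - 0.4, y - dn[nt], j + 0.4, y, col = cols[nt],
                     border = NA)
      graphics::text(j, y - dn[nt] / 2, nt, cex = 0.7, col = "white")
      y <- y - dn[nt]
    }
  }
  invisible(NULL)
}
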