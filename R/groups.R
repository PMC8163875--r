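#' Group introns by their fourth nucleotide
#'
#' The fourth intron nucleotide (coding strand) faces the m6A of the U6
#' snRNA ACAGA box during catalysis; introns are grouped as A4/T4/C4/G4
#' accordingly. Ambiguous bases yield \code{NA} (excluded from groups).
#'
#' @param segments Segment table (uses \code{intron_seq_5prime}).
#' @return Factor with levels \code{A4, T4, C4, G4}, one per segment.
#' @export
classify_fourth_nucleotide <- function(segments) {
  nt4 <- substr(segments$intron_seq_5prime, 4L, 4L)
  lab <- ifelse(nt4 %in% c("A", "C", "G", "T"), paste0(nt4, "4"),
                NA_character_)
  factor(lab, levels = c("A4", "T4", "C4", "G4"))
}

#' Group introns by the 5'-exon terminal triplet pattern
#'
#' The last three nucleotides of the 5' exon (positions -3..-1) pair with
#' loop I of U5 snRNA; the consensus is AAG. Each position is encoded
#' against the consensus: position -3 and -2 as \code{A} (matching) or
#' \code{B} (any other base), position -1 as \code{G} or \code{H}, giving
#' the eight patterns AAG, BAG, ABG, AAH, BBG, BAH, ABH, BBH. Triplets with
#' ambiguous bases yield \code{NA}.
#'
#' @param segments Segment table (uses \code{exon_triplet}), or a character
#'   vector of triplets.
#' @return Factor with the eight pattern levels.
#' @export
classify_exon_triplet <- function(segments) {
  trip <- if (is.character(segments)) segments else segments$exon_triplet
  ok <- !is.na(trip) & grepl("^[ACGT]{3}$", trip)
  p1 <- ifelse(substr(trip, 1L, 1L) == "A", "A", "B")
  p2 <- ifelse(substr(trip, 2L, 2L) == "A", "A", "B")
  p3 <- ifelse(substr(trip, 3L, 3L) == "G", "G", "H")
  lab <- ifelse(ok, paste0(p1, p2, p3), NA_character_)
  factor(lab, levels = c("AAG", "BAG", "ABG", "AAH", "BBG", "BAH", "ABH",
                         "BBH"))
}

#' Per-intron IRS difference between conditions
#'
#' \code{delta = mean IRS(treatment) - mean IRS(reference)} over replicates.
#' Segments absent from either condition are omitted.
#'
#' @inheritParams summarize_zscores
#' @return data.frame with \code{segment_id} and \code{delta}.
#' @export
delta_irs <- function(metrics, samples, reference = "WT", treatment = "KO") {
  cond <- samples$condition[match(metrics$sample_id, samples$sample_id)]
  m <- metrics[!is.na(cond), , drop = FALSE]
  cond <- cond[!is.na(cond)]
  mw <- tapply(m$irs[cond == reference], m$segment_id[cond == reference],
               mean)
  mk <- tapply(m$irs[cond == treatment], m$segment_id[cond == treatment],
               mean)
  ids <- sort(intersect(names(mw), names(mk)))
  data.frame(segment_id = ids, delta = unname(mk[ids] - mw[ids]),
             stringsAsFactors = FALSE)
}

#' Compare IRS differences across intron groups
#'
#' Produces, per group: empirical cumulative distribution points on a shared
#' grid, box-plot summaries (quartiles and 1.5 x IQR whiskers), and pairwise
#' two-sided Wilcoxon rank-sum p-values (exact when both groups have at most
#' 50 tie-free observations, normal approximation with continuity and tie
#' correction otherwise). Empty groups are dropped with a warning.
#'
#' @param delta Numeric vector of per-intron IRS differences.
#' @param group Factor (or character) of group labels, parallel to
#'   \code{delta}.
#' @return list with elements \code{sizes}, \code{medians}, \code{box}
#'   (data.frame group/q1/median/q3/whisker_lo/whisker_hi), \code{cdf}
#'   (data.frame group/x/cum_fraction on the shared grid of observed deltas)
#'   and \code{pvalues} (data.frame group1/group2/p).
#' @export
group_compare <- function(delta, group) {
  stopifnot(length(delta) == length(group))
  if (!is.factor(group)) group <- factor(group)
  keep <- !is.na(group) & !is.na(delta)
  delta <- delta[keep]
  group <- group[keep]
  sizes <- table(group)
  if (any(sizes == 0L)) {
    warning("empty group(s) excluded: ",
            paste(names(sizes)[sizes == 0L], collapse = ","))
    group <- droplevels(group)
    sizes <- table(group)
  }
  lev <- levels(group)

  grid <- sort(unique(delta))
  cdf <- do.call(rbind, lapply(lev, function(g) {
    data.frame(group = g, x = grid,
               cum_fraction = stats::ecdf(delta[group == g])(grid),
               stringsAsFactors = FALSE)
  }))

  box <- do.call(rbind, lapply(lev, function(g) {
    x <- delta[group == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    in_lo <- x[x >= q[1] - 1.5 * iqr]
    in_hi <- x[x <= q[3] + 1.5 * iqr]
    data.frame(group = g, q1 = q[1], median = q[2], q3 = q[3],
               whisker_lo = min(in_lo), whisker_hi = max(in_hi),
               stringsAsFactors = FALSE)
  }))

  pv <- NULL
  if (length(lev) >= 2L) {
    pairs <- utils::combn(lev, 2L)
    pv <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(pairs))) {
      x <- delta[group == pairs[1L, i]]
      y <- delta[group == pairs[2L, i]]
      use_exact <- length(x) <= 50L && length(y) <= 50L &&
        !anyDuplicated(c(x, y))
      pv$p[i] <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)$p.value)
    }
  }

  list(sizes = sizes, medians = tapply(delta, group, stats::median),
       box = box, cdf = cdf, pvalues = pv)
}
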