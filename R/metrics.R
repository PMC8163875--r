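#' Informative junction coverage of a segment
#'
#' \code{cov(Total) = (cov(EIJR) + cov(IEJR))/2 + cov(A5R) + cov(A3R) +
#' cov(CSR)}: the two boundary-spanning classes each see only one of the two
#' intron boundaries, so their mean estimates retained-isoform coverage.
#'
#' @param eijr,iejr,csr,a5r,a3r Non-negative read counts (vectorized).
#' @return Numeric vector of total informative coverage.
#' @export
total_coverage <- function(eijr, iejr, csr, a5r = 0, a3r = 0) {
  check_counts(eijr, iejr, csr, a5r, a3r)
  (eijr + iejr) / 2 + a5r + a3r + csr
}

#' Intron retention score (IRS)
#'
#' \code{IRS = log2((cov(EIJR) + cov(IEJR) + 0.1) / (2 cov(CSR) + 0.1))}.
#' The 0.1 pseudocount keeps the score finite at zero counts and is fixed
#' (not a tuning knob) so that scores remain comparable across analyses.
#' IRS is 0 exactly at the balance point \code{eijr + iejr = 2 csr}.
#'
#' @param eijr,iejr,csr Non-negative read counts (vectorized).
#' @return Numeric vector of log2 retention scores.
#' @export
intron_retention_score <- function(eijr, iejr, csr) {
  check_counts(eijr, iejr, csr)
  log2((eijr + iejr + 0.1) / (2 * csr + 0.1))
}

#' Proportion of canonical splicing (PCS)
#'
#' \code{PCS = cov(CSR) / cov(Total)}, the fraction of a segment's
#' informative coverage carried by canonical splice-junction reads. Undefined
#' (returned as \code{NA}, never imputed) when the total coverage is zero.
#'
#' @inheritParams total_coverage
#' @return Numeric vector in [0, 1], \code{NA} where \code{cov(Total) == 0}.
#' @export
proportion_canonical_splicing <- function(eijr, iejr, csr, a5r = 0, a3r = 0) {
  tot <- total_coverage(eijr, iejr, csr, a5r, a3r)
  ifelse(tot > 0, csr / tot, NA_real_)
}

#' Per-sample splicing metrics for a junction count table
#'
#' @param counts Count table from \code{\link{count_junctions}} (rows may mix
#'   samples; columns \code{segment_id, sample_id, eijr, iejr, csr, a5r,
#'   a3r} required).
#' @return data.frame with \code{segment_id, sample_id, irs, pcs, cov_total}.
#' @export
compute_splicing_metrics <- function(counts) {
  data.frame(
    segment_id = counts$segment_id,
    sample_id = counts$sample_id,
    irs = intron_retention_score(counts$eijr, counts$iejr, counts$csr),
    pcs = proportion_canonical_splicing(counts$eijr, counts$iejr, counts$csr,
                                        counts$a5r, counts$a3r),
    cov_total = total_coverage(counts$eijr, counts$iejr, counts$csr,
                               counts$a5r, counts$a3r),
    stringsAsFactors = FALSE
  )
}

#' Eligibility filter for the condition comparison
#'
#' Retains GY-AG introns (donor G followed by C/T, acceptor AG on the coding
#' strand) with \code{cov(Total) > min_total} in every replicate of both
#' conditions and mean CSR \code{> min_mean_csr} in at least one condition.
#' Both thresholds are strict. A segment missing counts for some sample fails
#' the coverage filter.
#'
#' @param counts Junction count table covering all samples.
#' @param segments Segment table (for donor/acceptor dinucleotides).
#' @param samples data.frame with columns \code{sample_id} and
#'   \code{condition}; exactly two conditions must be present.
#' @param min_total,min_mean_csr Strict lower thresholds (default 10).
#' @return Character vector of eligible \code{segment_id}s.
#' @export
filter_introns <- function(counts, segments, samples, min_total = 10,
                           min_mean_csr = 10) {
  stopifnot(min_total >= 0, min_mean_csr >= 0)
  conds <- unique(samples$condition)
  if (length(conds) != 2L) stop("exactly two conditions are required")
  if (anyDuplicated(samples$sample_id)) {
    stop("each sample must be assigned to exactly one condition")
  }

  gyag <- grepl("^G[CT]$", segments$donor_dinucleotide) &
    segments$acceptor_dinucleotide == "AG"
  candidates <- segments$segment_id[gyag]

  cnt <- counts[counts$sample_id %in% samples$sample_id &
                  counts$segment_id %in% candidates, , drop = FALSE]
  cond_of <- samples$condition[match(cnt$sample_id, samples$sample_id)]
  f <- factor(cnt$segment_id, levels = candidates)

  n_obs <- as.vector(table(f))
  min_tot <- tapply(cnt$total, f, min)
  mean_csr <- tapply(cnt$csr, list(f, factor(cond_of)), mean)
  csr_ok <- apply(mean_csr > min_mean_csr, 1L, any, na.rm = TRUE)

  keep <- n_obs == nrow(samples) &                  # missing sample: fail
    !is.na(min_tot) & min_tot > min_total & csr_ok
  unname(candidates[keep])
}

#' Two-sample Z-score for a difference in IRS between conditions
#'
#' \code{Z = (mean(trt) - mean(ref)) / sqrt(var(trt)/n_trt + var(ref)/n_ref)}
#' with sample (n-1) variances; for quadruplicates on both sides this is the
#' \code{sigma^2/4 + sigma^2/4} form. Antisymmetric under swapping the two
#' conditions. When both variances are zero: 0 if the means agree, otherwise
#' a signed infinity sentinel (sorts to the extreme end).
#'
#' @param irs_ref,irs_trt Numeric vectors of per-replicate IRS values
#'   (reference, e.g. WT, and treatment, e.g. knockout); each of length >= 2.
#' @return A single Z value.
#' @export
zscore <- function(irs_ref, irs_trt) {
  stopifnot(length(irs_ref) >= 2L, length(irs_trt) >= 2L)
  d <- mean(irs_trt) - mean(irs_ref)
  se <- sqrt(stats::var(irs_trt) / length(irs_trt) +
             stats::var(irs_ref) / length(irs_ref))
  if (se == 0) {
    if (d == 0) return(0)
    return(sign(d) * Inf)
  }
  d / se
}

#' Replicate-aggregated Z-scores per segment
#'
#' @param metrics Per-sample metrics from
#'   \code{\link{compute_splicing_metrics}}.
#' @param samples Sample sheet (\code{sample_id}, \code{condition}).
#' @param reference,treatment Condition labels; Z is oriented treatment minus
#'   reference.
#' @param eligible Optional character vector of segment ids (e.g. from
#'   \code{\link{filter_introns}}); defaults to all segments present.
#' @return data.frame with \code{segment_id, mu_wt, mu_ko, sigma_wt,
#'   sigma_ko, n_wt, n_ko, z} where "wt" is the reference and "ko" the
#'   treatment condition.
#' @export
summarize_zscores <- function(metrics, samples, reference = "WT",
                              treatment = "KO", eligible = NULL) {
  stopifnot(all(c(reference, treatment) %in% samples$condition))
  cond <- samples$condition[match(metrics$sample_id, samples$sample_id)]
  m <- metrics[!is.na(cond), , drop = FALSE]
  cond <- cond[!is.na(cond)]
  if (is.null(eligible)) eligible <- unique(m$segment_id)
  keep <- m$segment_id %in% eligible
  m <- m[keep, , drop = FALSE]
  cond <- cond[keep]

  stat <- function(which) {
    x <- m[cond == which, , drop = FALSE]
    f <- factor(x$segment_id, levels = eligible)
    list(mu = as.vector(tapply(x$irs, f, mean)),
         sd = as.vector(tapply(x$irs, f, stats::sd)),
         n = as.vector(table(f)))
  }
  wt <- stat(reference)
  ko <- stat(treatment)
  d <- ko$mu - wt$mu
  se <- sqrt(ko$sd^2 / ko$n + wt$sd^2 / wt$n)
  z <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  out <- data.frame(
    segment_id = eligible,
    mu_wt = wt$mu, mu_ko = ko$mu,
    sigma_wt = wt$sd, sigma_ko = ko$sd,
    n_wt = wt$n, n_ko = ko$n,
    z = z,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Partition segments by Z-score quartiles
#'
#' Segments with Z strictly above the top-quartile boundary (the 75th
#' percentile of Z) are labelled \code{high}, those strictly below the 25th
#' percentile \code{low}, the remainder \code{mid}. Strict comparison makes
#' the split deterministic under ties: values equal to a boundary fall into
#' \code{mid}, and a fully tied input yields empty high/low sets.
#'
#' @param z Named numeric vector of Z-scores (names are segment ids), or a
#'   data.frame with columns \code{segment_id} and \code{z}.
#' @return data.frame with \code{segment_id, z, quartile_class} ordered by
#'   \code{segment_id}.
#' @export
quartile_partition <- function(z) {
  if (is.data.frame(z)) {
    zz <- stats::setNames(z$z, z$segment_id)
  } else {
    zz <- z
  }
  stopifnot(length(zz) >= 4L, !is.null(names(zz)))
  finite <- zz
  # infinity sentinels sort to the extremes; place them beyond the data range
  # for quantile computation
  if (any(is.infinite(finite))) {
    rng <- range(finite[is.finite(finite)], 0)
    finite[finite == Inf] <- rng[2] + 1
    finite[finite == -Inf] <- rng[1] - 1
  }
  hi <- stats::quantile(finite, 0.75, names = FALSE, type = 7)
  lo <- stats::quantile(finite, 0.25, names = FALSE, type = 7)
  cls <- ifelse(finite > hi, "high", ifelse(finite < lo, "low", "mid"))
  out <- data.frame(segment_id = names(zz), z = unname(zz),
                    quartile_class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' IRS from isoform abundances (RT-qPCR / minigene style)
#'
#' The binary logarithm of retained-isoform abundance over spliced-isoform
#' abundance, as quantified from band intensities or qPCR standard curves.
#'
#' @param retained_abundance,spliced_abundance Positive abundances.
#' @return \code{log2(retained/spliced)}.
#' @export
qpcr_irs <- function(retained_abundance, spliced_abundance) {
  if (any(retained_abundance <= 0) || any(spliced_abundance <= 0)) {
    stop("abundances must be positive")
  }
  log2(retained_abundance / spliced_abundance)
}

check_counts <- function(...) {
  vals <- c(...)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("read counts must be non-negative")
  }
  invisible(TRUE)
}
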