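#' Configuration for the synthetic splicing data generator
#'
#' Defaults emulate the quadruplicate wild-type / knockout design of a
#' fission-yeast-like transcriptome: one GT(/GC)..AG intron per gene, a
#' fourth-nucleotide composition of A/T/C/G = 0.50/0.36/0.10/0.04 matching
#' the relative sizes of the A4/T4/C4/G4 intron groups, an AAG 5'-exon
#' triplet fraction of 0.11, a mean informative depth of 500 fragments per
#' intron with negative-binomial dispersion 0.1, and knockout retention-odds
#' effects of x6 (A4), x3 (C4), x1.2 (G4) and x1 (T4) applied only to
#' non-AAG introns (AAG introns are protected).
#'
#' @param n_genes Number of genes (one intron each by default).
#' @param introns_per_gene Introns per gene.
#' @param exon_length,intron_length Lengths in nt (intron >= 6).
#' @param p4 Named probabilities of A/T/C/G at intron position +4.
#' @param aag_fraction Probability that a 5' exon ends in AAG.
#' @param gc_donor_fraction Probability of a GC (vs GT) donor.
#' @param effects Named multiplicative knockout retention-odds factors per
#'   fourth nucleotide (names A, T, C, G).
#' @param aag_protected If TRUE, AAG-triplet introns keep effect 1.
#' @param expression_mean,expression_sdlog Lognormal informative depth per
#'   intron (mean on the natural scale, sdlog spread).
#' @param dispersion Negative-binomial dispersion of per-replicate depth.
#' @param baseline_odds_meanlog,baseline_odds_sdlog Lognormal baseline
#'   retention odds per intron (default median 0.05, i.e. well-spliced).
#' @param replicates Replicates per condition.
#' @param minus_strand_fraction Probability that a gene is on the minus
#'   strand.
#' @param alt_rate Rate of alternative-splice-site reads (A5R/A3R); 0 by
#'   default.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, introns_per_gene = 1L,
                       exon_length = 300L, intron_length = 60L,
                       p4 = c(A = 0.50, T = 0.36, C = 0.10, G = 0.04),
                       aag_fraction = 0.11, gc_donor_fraction = 0.02,
                       effects = c(A = 6, T = 1, C = 3, G = 1.2),
                       aag_protected = TRUE,
                       expression_mean = 500, expression_sdlog = 0.25,
                       dispersion = 0.1,
                       baseline_odds_meanlog = log(0.05),
                       baseline_odds_sdlog = 0.5,
                       replicates = 4L, minus_strand_fraction = 0.5,
                       alt_rate = 0) {
  if (intron_length < 6L) stop("intron_length must be at least 6")
  stopifnot(exon_length >= 3L, n_genes >= 1L, introns_per_gene >= 1L,
            abs(sum(p4) - 1) < 1e-8, replicates >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic genome, annotation and ground-truth table
#'
#' Builds a single-chromosome genome of spaced genes, each with
#' \code{introns_per_gene} GY-AG introns whose fourth nucleotide and 5'-exon
#' terminal triplet are drawn from the configured compositions, plus a
#' ground-truth table of per-intron retention odds, knockout effects and
#' expected depth. Deterministic given \code{seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed for all randomness.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{annotation}
#'   (\code{GRanges} with mRNA/exon/CDS features), \code{truth} (data.frame:
#'   gene_id, segment_id, chrom, strand, seg_start, intron_start,
#'   intron_end, seg_end, fourth_nt, exon_triplet, is_aag, baseline_odds,
#'   effect, expression, dispersion), \code{config} and \code{seed}.
#' @export
generate_reference <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  spacer <- 20L
  E <- config$exon_length
  I <- config$intron_length
  n_exons <- config$introns_per_gene + 1L
  gene_len <- n_exons * E + config$introns_per_gene * I

  genes <- sprintf("g%05d", seq_len(config$n_genes))
  strand <- ifelse(stats::runif(config$n_genes) <
                     config$minus_strand_fraction, "-", "+")
  offsets <- spacer + (seq_len(config$n_genes) - 1L) * (gene_len + spacer)
  chrom_len <- config$n_genes * (gene_len + spacer) + spacer

  n_int <- config$n_genes * config$introns_per_gene
  fourth <- sample(names(config$p4), n_int, replace = TRUE,
                   prob = config$p4)
  donors <- ifelse(stats::runif(n_int) < config$gc_donor_fraction, "GC",
                   "GT")
  is_aag <- stats::runif(n_int) < config$aag_fraction
  other_trip <- setdiff(
    apply(expand.grid(nt, nt, nt), 1L, paste, collapse = ""), "AAG")
  triplet <- ifelse(is_aag, "AAG",
                    sample(other_trip, n_int, replace = TRUE))

  chrom_seq <- sample(nt, chrom_len, replace = TRUE)
  # per-intron truth fields, filled in transcript order
  t_gene <- t_strand <- character(n_int)
  t_seg_start <- t_is <- t_ie <- t_seg_end <- t_index <- integer(n_int)
  # annotation features: mRNA + exons + CDS per gene
  n_feat <- 1L + 2L * n_exons
  f_start <- f_end <- integer(config$n_genes * n_feat)
  f_phase <- rep(NA_integer_, config$n_genes * n_feat)
  f_strand <- f_type <- f_id <- f_parent <- f_gene <- f_tx <-
    character(config$n_genes * n_feat)
  # CDS phase from cumulative coding length in transcript order
  cds_phase_tx <- (3L - ((seq_len(n_exons) - 1L) * E) %% 3L) %% 3L
  k <- 0L
  for (g in seq_len(config$n_genes)) {
    # coding-orientation gene sequence: exons and introns alternating
    parts <- character(2L * n_exons - 1L)
    gene_introns <- integer(config$introns_per_gene)
    for (j in seq_len(n_exons)) {
      ex <- sample(nt, E, replace = TRUE)
      if (j < n_exons) {
        k <- k + 1L
        gene_introns[j] <- k
        ex[(E - 2L):E] <- strsplit(triplet[k], "")[[1L]]
        intr <- sample(nt, I, replace = TRUE)
        intr[1:2] <- strsplit(donors[k], "")[[1L]]
        intr[4L] <- fourth[k]
        intr[(I - 1L):I] <- c("A", "G")
        parts[2L * j] <- paste(intr, collapse = "")
      }
      parts[2L * j - 1L] <- paste(ex, collapse = "")
    }
    coding <- paste(parts, collapse = "")
    placed <- if (strand[g] == "+") coding else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    off <- offsets[g]
    chrom_seq[(off + 1L):(off + gene_len)] <- strsplit(placed, "")[[1L]]

    # exon boundaries in coding orientation, relative to the gene start
    b <- cumsum(c(0L, rep(c(E, I), config$introns_per_gene), E))
    rel_s <- b[seq(1L, length(b) - 1L, by = 2L)]
    rel_e <- b[seq(2L, length(b), by = 2L)]
    if (strand[g] == "-") {
      # the coding layout was reverse-complemented into the genome, so
      # boundaries mirror within the gene
      tmp <- gene_len - rev(rel_e)
      rel_e <- gene_len - rev(rel_s)
      rel_s <- tmp
    }
    exon_s <- off + rel_s
    exon_e <- off + rel_e
    for (j in seq_len(config$introns_per_gene)) {
      idx <- if (strand[g] == "+") gene_introns[j] else
        gene_introns[config$introns_per_gene - j + 1L]
      t_gene[idx] <- genes[g]
      t_strand[idx] <- strand[g]
      t_seg_start[idx] <- exon_s[j]
      t_is[idx] <- exon_e[j]
      t_ie[idx] <- exon_s[j + 1L]
      t_seg_end[idx] <- exon_e[j + 1L]
      t_index[idx] <- if (strand[g] == "+") j else
        config$introns_per_gene - j + 1L
    }
    tx <- paste0(genes[g], ".1")
    fi <- (g - 1L) * n_feat + seq_len(n_feat)
    f_start[fi] <- c(off + 1L, exon_s + 1L, exon_s + 1L)
    f_end[fi] <- c(off + gene_len, exon_e, exon_e)
    f_strand[fi] <- strand[g]
    f_type[fi] <- c("mRNA", rep("exon", n_exons), rep("CDS", n_exons))
    f_id[fi] <- c(tx, rep(NA_character_, 2L * n_exons))
    f_parent[fi] <- c(NA_character_, rep(tx, 2L * n_exons))
    f_gene[fi] <- genes[g]
    f_tx[fi] <- tx
    cds_phase <- if (strand[g] == "+") cds_phase_tx else rev(cds_phase_tx)
    f_phase[fi[(n_exons + 2L):n_feat]] <- cds_phase
  }

  truth <- data.frame(
    gene_id = t_gene,
    segment_id = sprintf("chrS:%d-%d:%s", t_is, t_ie, t_strand),
    chrom = "chrS", strand = t_strand,
    seg_start = t_seg_start, intron_start = t_is, intron_end = t_ie,
    seg_end = t_seg_end, intron_index = t_index,
    fourth_nt = fourth, exon_triplet = triplet, is_aag = is_aag,
    stringsAsFactors = FALSE
  )
  truth$baseline_odds <- stats::rlnorm(n_int, config$baseline_odds_meanlog,
                                       config$baseline_odds_sdlog)
  eff <- config$effects[truth$fourth_nt]
  if (config$aag_protected) eff[truth$is_aag] <- 1
  truth$effect <- unname(eff)
  truth$expression <- stats::rlnorm(
    n_int, log(config$expression_mean) - config$expression_sdlog^2 / 2,
    config$expression_sdlog)
  truth$dispersion <- config$dispersion
  rownames(truth) <- NULL

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chrom_seq, collapse = ""), "chrS"))
  annotation <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(f_start, f_end), strand = f_strand,
    type = f_type, ID = f_id, Parent = f_parent, gene_id = f_gene,
    transcript_id = f_tx, phase = f_phase)

  list(genome = genome, annotation = annotation, truth = truth,
       config = config, seed = seed)
}

#' Write a synthetic reference to disk
#'
#' @param reference Output of \code{\link{generate_reference}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the FASTA, GFF3 and truth TSV written.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  tsv <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(reference$genome, fa)
  rtracklayer::export(reference$annotation, gff, format = "gff3")
  utils::write.table(reference$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, truth = tsv))
}

#' Sample sheet for a simulated two-condition design
#'
#' @param replicates Replicates per condition.
#' @param conditions Condition labels (reference first).
#' @return data.frame with \code{sample_id, condition, replicate}.
#' @export
sim_sample_sheet <- function(replicates = 4L, conditions = c("WT", "KO")) {
  data.frame(
    sample_id = paste(rep(conditions, each = replicates),
                      seq_len(replicates), sep = "_"),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), 2L),
    stringsAsFactors = FALSE
  )
}

#' Simulate junction counts under the ground-truth retention model
#'
#' Per intron, condition and replicate: the informative fragment total T is
#' negative-binomial with the intron's expected depth and the configured
#' dispersion; with retention odds o (baseline, times the knockout effect in
#' the treatment condition) and retention fraction r = o/(1+o), the spliced
#' count is \code{csr = T - R} with \code{R ~ Binomial(T, r)}; each retained
#' pre-mRNA contributes one read at each intron boundary, split
#' \code{Binomial(2R, 1/2)} between EIJR and IEJR. Under this model
#' \code{cov(Total) = T} exactly and \code{(EIJR+IEJR)/2 / CSR} estimates
#' the odds, so IRS concentrates at \code{log2(o)} with depth. Alternative
#' splice reads are added at \code{alt_rate} if configured.
#'
#' @param reference Output of \code{\link{generate_reference}} (or a list
#'   with elements \code{truth} and \code{config}).
#' @param seed Integer seed.
#' @param conditions Condition labels (reference first; effects apply to the
#'   second).
#' @return data.frame with one row per (intron, condition, replicate):
#'   segment_id, gene_id, sample_id, condition, replicate, eijr, iejr, csr,
#'   a5r, a3r, total, retention_fraction.
#' @export
simulate_junction_counts <- function(reference, seed = 1L,
                                     conditions = c("WT", "KO")) {
  truth <- reference$truth
  config <- reference$config
  set.seed(seed)
  reps <- config$replicates
  n <- nrow(truth)
  grid <- expand.grid(intron = seq_len(n), replicate = seq_len(reps),
                      condition = conditions, stringsAsFactors = FALSE)
  odds <- truth$baseline_odds[grid$intron] *
    ifelse(grid$condition == conditions[2L], truth$effect[grid$intron], 1)
  r <- odds / (1 + odds)
  total <- stats::rnbinom(nrow(grid), mu = truth$expression[grid$intron],
                          size = 1 / config$dispersion)
  retained <- stats::rbinom(nrow(grid), total, r)
  csr <- total - retained
  eijr <- stats::rbinom(nrow(grid), 2L * retained, 0.5)
  iejr <- 2L * retained - eijr
  a5r <- a3r <- integer(nrow(grid))
  if (config$alt_rate > 0) {
    a5r <- stats::rbinom(nrow(grid), total, config$alt_rate / 2)
    a3r <- stats::rbinom(nrow(grid), total, config$alt_rate / 2)
  }
  out <- data.frame(
    segment_id = truth$segment_id[grid$intron],
    gene_id = truth$gene_id[grid$intron],
    sample_id = paste(grid$condition, grid$replicate, sep = "_"),
    condition = grid$condition,
    replicate = grid$replicate,
    eijr = eijr, iejr = iejr, csr = csr, a5r = a5r, a3r = a3r,
    retention_fraction = r,
    stringsAsFactors = FALSE
  )
  out$total <- total_coverage(out$eijr, out$iejr, out$csr, out$a5r, out$a3r)
  out
}

#' Emit spliced SAM alignments realizing given junction counts
#'
#' For every counted read of every class, writes one primary SAM alignment
#' whose CIGAR realizes that class for its segment: an N-gap over the intron
#' for CSR, a contiguous match across the transcriptional 5' (EIJR) or 3'
#' (IEJR) splice site, and gaps using one annotated plus one alternative
#' boundary for A5R/A3R. Overhangs are sampled with at least
#' \code{min_overhang} aligned nt on each side, and junction reads are kept
#' inside the segment so each read classifies uniquely.
#'
#' @param reference Output of \code{\link{generate_reference}}; supplies the
#'   genome for read sequences.
#' @param counts data.frame with columns \code{segment_id, eijr, iejr, csr,
#'   a5r, a3r} (one sample), plus segment coordinates (\code{chrom, strand,
#'   seg_start, intron_start, intron_end, seg_end}) either in \code{counts}
#'   or joinable from \code{reference$truth} by \code{segment_id}.
#' @param path Output SAM path.
#' @param read_length Read length (>= 2 x \code{min_overhang}).
#' @param min_overhang Minimum aligned nt flanking any junction.
#' @param seed Integer seed for placement jitter.
#' @return Invisibly, \code{path}.
#' @export
emit_reads <- function(reference, counts, path, read_length = 50L,
                       min_overhang = 8L, seed = 1L) {
  if (read_length < 2L * min_overhang) {
    stop("read_length must be at least 2 x min_overhang")
  }
  set.seed(seed)
  need <- c("chrom", "strand", "seg_start", "intron_start", "intron_end",
            "seg_end")
  if (!all(need %in% names(counts))) {
    counts <- merge(counts,
                    reference$truth[, c("segment_id", need)],
                    by = "segment_id", sort = FALSE)
  }
  dna <- reference$genome
  rl <- as.integer(read_length)
  mo <- as.integer(min_overhang)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(dna), Biostrings::width(dna)))
  recs <- character(0)
  for (i in seq_len(nrow(counts))) {
    s <- counts[i, ]
    ilen <- s$intron_end - s$intron_start
    if (min(s$intron_start - s$seg_start, s$seg_end - s$intron_end) <
          mo || ilen < mo) {
      stop("segment too short for read_length/min_overhang: ", s$segment_id)
    }
    plus <- s$strand == "+"
    j5 <- if (plus) s$intron_start else s$intron_end
    j3 <- if (plus) s$intron_end else s$intron_start
    chr <- dna[[s$chrom]]
    add <- function(class, n, maker) {
      if (n > 0L) {
        for (q in seq_len(n)) {
          recs[[length(recs) + 1L]] <<- maker(
            sprintf("%s_%s_%d", s$segment_id, class, q))
        }
      }
    }
    # confine a junction read between the far end of its exon and the other
    # splice site, so it can never also span the other junction
    bounds <- function(j) {
      if (j == s$intron_start) c(s$seg_start, s$intron_end)
      else c(s$intron_start, s$seg_end)
    }
    add("EIJR", s$eijr, function(q) contiguous_read(
      chr, s$chrom, j5, rl, mo, bounds(j5)[1L], bounds(j5)[2L], q))
    add("IEJR", s$iejr, function(q) contiguous_read(
      chr, s$chrom, j3, rl, mo, bounds(j3)[1L], bounds(j3)[2L], q))
    add("CSR", s$csr, function(q) gapped_read(
      chr, s$chrom, s$intron_start, s$intron_end, rl, mo, s$seg_start,
      s$seg_end, q))
    shift_max <- max(3L, min(10L, ilen - 4L))
    add("A5R", s$a5r, function(q) {
      sh <- sample(3:shift_max, 1L)
      if (plus) gapped_read(chr, s$chrom, s$intron_start + sh,
                            s$intron_end, rl, mo, s$seg_start, s$seg_end, q)
      else gapped_read(chr, s$chrom, s$intron_start, s$intron_end - sh, rl,
                       mo, s$seg_start, s$seg_end, q)
    })
    add("A3R", s$a3r, function(q) {
      sh <- sample(3:shift_max, 1L)
      if (plus) gapped_read(chr, s$chrom, s$intron_start,
                            s$intron_end - sh, rl, mo, s$seg_start,
                            s$seg_end, q)
      else gapped_read(chr, s$chrom, s$intron_start + sh, s$intron_end, rl,
                       mo, s$seg_start, s$seg_end, q)
    })
  }
  writeLines(c(header, unlist(recs)), path)
  invisible(path)
}

# ungapped read across junction j, confined to [left_min, right_max]
contiguous_read <- function(chr, chrom, j, rl, mo, left_min, right_max,
                            qname) {
  a_lo <- max(mo, j + rl - right_max)   # start0 = j - a, end = j - a + rl
  a_hi <- min(rl - mo, j - left_min)
  if (a_lo > a_hi) stop("segment too short for read_length")
  a <- if (a_lo == a_hi) a_lo else sample(a_lo:a_hi, 1L)
  start0 <- j - a
  seq <- as.character(Biostrings::subseq(chr, start0 + 1L, start0 + rl))
  sam_record(qname, chrom, start0, sprintf("%dM", rl), seq)
}

# read with one N-gap [gs, ge), flanks inside [lo, hi)
gapped_read <- function(chr, chrom, gs, ge, rl, mo, lo, hi, qname) {
  a_lo <- max(mo, rl - (hi - ge))     # right flank rl - a must fit in [ge, hi]
  a_hi <- min(rl - mo, gs - lo)       # left flank a must fit in [lo, gs]
  if (a_lo > a_hi) stop("segment too short for read_length")
  a <- if (a_lo == a_hi) a_lo else sample(a_lo:a_hi, 1L)
  b <- rl - a
  start0 <- gs - a
  seq <- paste0(
    as.character(Biostrings::subseq(chr, start0 + 1L, gs)),
    as.character(Biostrings::subseq(chr, ge + 1L, ge + b)))
  sam_record(qname, chrom, start0,
             sprintf("%dM%dN%dM", a, ge - gs, b), seq)
}

sam_record <- function(qname, chrom, start0, cigar, seq) {
  paste(qname, 0L, chrom, start0 + 1L, 60L, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
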