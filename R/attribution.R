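#' Attribute TE-family piRNAs to their source loci
#'
#' Assigns each aligned read to a transposon family when its placement
#' overlaps an annotated insertion of that family by at least half the
#' read length, then apportions every family's reads among sources:
#' individually named clusters, all remaining clusters, and
#' outside-clusters. Percentages per family sum to 100. In all-mapper
#' mode reads are weighted 1/n_genomic_hits. Telomeric families can be
#' excluded (the default drops Het-A, TAHRE and TART).
#'
#' @param alignments an \code{alignment_set}.
#' @param te_annotation TE insertions with \code{family}.
#' @param clusters cluster data.frame with \code{cluster_id}.
#' @param named_clusters cluster_ids reported as individual columns;
#'   default all.
#' @param min_read_overlap minimum fraction of the read covered by the
#'   insertion (default 0.5).
#' @param exclude_families families dropped from the matrix.
#' @return matrix (families x sources) of percentages, with attribute
#'   \code{"omitted"} listing families with zero matching reads.
#' @export
family_source_matrix <- function(alignments, te_annotation, clusters,
                                 named_clusters = clusters$cluster_id,
                                 min_read_overlap = 0.5,
                                 exclude_families = c("Het-A", "TAHRE",
                                                      "TART")) {
  rec <- alignments$records
  te <- te_annotation[!(te_annotation$family %in% exclude_families), ,
                      drop = FALSE]
  if (nrow(rec) == 0 || nrow(te) == 0)
    return(structure(matrix(numeric(0), 0, 0), omitted = character(0)))
  w <- .read_weights(rec, alignments$mode)
  # read -> family by >= min_read_overlap genomic overlap
  hits <- IRanges::findOverlaps(.as_ir(rec), .as_ir(te))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same_ct <- rec$contig[qh] == te$contig[sh]
  ovl <- pmin(rec$end[qh], te$end[sh]) - pmax(rec$start[qh], te$start[sh])
  ok <- same_ct & ovl >= min_read_overlap * rec$length[qh]
  qh <- qh[ok]; sh <- sh[ok]
  # first qualifying insertion wins (one family per placement)
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  fam <- te$family[sh]
  # source of each placement: named cluster / other cluster / outside
  p5 <- .five_prime(rec)[qh]
  src <- rep("outside_clusters", length(qh))
  for (i in seq_len(nrow(clusters))) {
    inside <- rec$contig[qh] == clusters$contig[i] &
      p5 >= clusters$start[i] & p5 < clusters$end[i]
    lab <- if (clusters$cluster_id[i] %in% named_clusters)
      clusters$cluster_id[i] else "other_clusters"
    src[inside] <- lab
  }
  sources <- c(intersect(clusters$cluster_id, named_clusters),
               "other_clusters", "outside_clusters")
  agg <- tapply(w[qh], list(factor(fam), factor(src, levels = sources)),
                sum, default = 0)
  omitted <- setdiff(unique(te$family), rownames(agg))
  if (length(omitted) > 0)
    message(sprintf("%d family(ies) with no matching reads omitted",
                    length(omitted)))
  pct <- 100 * agg / rowSums(agg)
  structure(as.matrix(pct), omitted = omitted)
}

#' Log2 fold change of normalized counts
#'
#' Both samples are first scaled to reads per million miRNA-matching
#' reads; the fold change is log2((mutant_rpm + c) / (control_rpm + c))
#' with pseudo-count c (default 1 rpm) so that total losses are bounded.
#' Entries where both raw counts are zero are NA.
#'
#' @param mutant_counts,control_counts named numeric vectors on a shared
#'   name space (names are aligned; missing names count 0).
#' @param mutant_mirna,control_mirna miRNA ledgers of the two libraries.
#' @param pseudo pseudo-count in rpm units.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mutant_counts, control_counts,
                             mutant_mirna, control_mirna, pseudo = 1) {
  keys <- union(names(mutant_counts), names(control_counts))
  m <- stats::setNames(rep(0, length(keys)), keys)
  ct <- m
  m[names(mutant_counts)] <- mutant_counts
  ct[names(control_counts)] <- control_counts
  mr <- normalize_rpm(m, mutant_mirna)
  cr <- normalize_rpm(ct, control_mirna)
  out <- log2((mr + pseudo) / (cr + pseudo))
  out[m == 0 & ct == 0] <- NA_real_
  out
}

#' Families exceeding a strict threshold
#'
#' Returns the families whose value strictly exceeds the threshold --
#' used both for the >50\% single-source attribution count and the >75\%
#' piRNA-loss count (a family at exactly the threshold is excluded).
#'
#' @param values named numeric vector (shares or losses, as fractions or
#'   percentages -- the caller picks the scale).
#' @param threshold strict lower bound.
#' @return list with \code{families} and \code{count}.
#' @export
families_over_threshold <- function(values, threshold) {
  fams <- names(values)[!is.na(values) & values > threshold]
  list(families = fams, count = length(fams))
}

#' Total loss of TE-matching piRNAs
#'
#' 100 * (1 - mutant_total / control_total) on miRNA-normalized
#' all-mapper TE-matching totals, floored at 0.
#'
#' @param mutant_total,control_total normalized TE-matching read totals.
#' @return percentage lost.
#' @export
total_te_loss <- function(mutant_total, control_total) {
  .stopifnot_scalar(mutant_total, "mutant_total")
  .stopifnot_scalar(control_total, "control_total")
  if (control_total <= 0) stop("control total must be positive")
  max(0, 100 * (1 - mutant_total / control_total))
}

#' Genomic TE copy number from DNA-seq counts
#'
#' copies = read_count * 300 / consensus_length / coverage_depth: each
#' paired-end read pair contributes 300 sequenced base pairs (2 x 150
#' nt), so family base pairs divided by consensus length and coverage
#' estimate the haploid copy number.
#'
#' @param read_count family-matching read (pair) count, vectorized.
#' @param consensus_length_bp family consensus length (bp).
#' @param coverage_depth genomic coverage (x).
#' @return estimated copy number(s).
#' @export
te_copy_number <- function(read_count, consensus_length_bp, coverage_depth) {
  if (any(consensus_length_bp <= 0)) stop("consensus length must be > 0")
  if (any(coverage_depth <= 0)) stop("coverage depth must be > 0")
  read_count * 300 / consensus_length_bp / coverage_depth
}

#' Specify a chromosomal deletion
#'
#' Coordinates are ingested in the 1-based inclusive convention genome
#' browsers print and stored 0-based half-open, so
#' \code{length_bp = end - start} after conversion (= printed end -
#' printed start + 1).
#'
#' @param label deletion name.
#' @param contig contig/chromosome name.
#' @param start,end printed 1-based inclusive coordinates.
#' @return list of class \code{deletion_spec} with 0-based half-open
#'   \code{start}, \code{end} and \code{length_bp}.
#' @export
deletion_spec <- function(label, contig, start, end) {
  stopifnot(end >= start, start >= 1)
  structure(list(label = label, contig = contig,
                 start = as.integer(start - 1L), end = as.integer(end),
                 length_bp = as.integer(end - start + 1L)),
            class = "deletion_spec")
}

#' Apply an in-silico chromosomal deletion
#'
#' Removes the deletion interval from the genome sequence and every
#' annotation layer: features wholly inside are dropped, features
#' straddling a deletion edge are truncated, features downstream are
#' shifted left by the deletion length. Alignment records overlapping
#' the interval are dropped (their sequence no longer exists). The
#' report gives the deletion length and its overlap with every cluster.
#'
#' @param dataset list with \code{genome} (DNAStringSet) and any of
#'   \code{genes}, \code{te_insertions}, \code{clusters} (interval
#'   data.frames) and \code{alignments} (an \code{alignment_set}).
#' @param spec a \code{\link{deletion_spec}}.
#' @return list with the modified \code{dataset} and a \code{report}
#'   data.frame (cluster overlaps, lengths).
#' @export
apply_deletion <- function(dataset, spec) {
  stopifnot(inherits(spec, "deletion_spec"))
  genome <- dataset$genome
  if (!spec$contig %in% names(genome)) stop("unknown contig in deletion spec")
  clen <- Biostrings::width(genome[spec$contig])
  if (spec$start < 0 || spec$end > clen)
    stop("deletion spec overlaps a contig boundary")
  # report before modifying
  report <- data.frame(label = spec$label, length_bp = spec$length_bp,
                       length_kb = round(spec$length_bp / 1000, 1),
                       stringsAsFactors = FALSE)
  if (!is.null(dataset$clusters) && nrow(dataset$clusters) > 0) {
    cl <- dataset$clusters
    ov <- vapply(seq_len(nrow(cl)), function(i)
      if (cl$contig[i] == spec$contig)
        max(0, min(cl$end[i], spec$end) - max(cl$start[i], spec$start))
      else 0, numeric(1))
    report <- cbind(report[rep(1, nrow(cl)), , drop = FALSE],
                    cluster_id = if ("cluster_id" %in% names(cl))
                      cl$cluster_id else sprintf("c%02d", seq_len(nrow(cl))),
                    cluster_overlap_bp = ov,
                    cluster_fraction_removed = ov / (cl$end - cl$start))
    rownames(report) <- NULL
  }
  s <- spec$start; e <- spec$end; L <- e - s
  seq <- genome[[spec$contig]]
  genome[[spec$contig]] <- Biostrings::xscat(
    Biostrings::subseq(seq, 1, s), Biostrings::subseq(seq, e + 1, clen))
  dataset$genome <- genome
  shift_df <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    on <- df$contig == spec$contig
    keep <- !(on & df$start >= s & df$end <= e)
    df <- df[keep, , drop = FALSE]
    on <- df$contig == spec$contig
    # truncate straddlers, then shift anything beyond the cut
    df$end[on] <- ifelse(df$start[on] < s & df$end[on] > s & df$end[on] <= e,
                         s, df$end[on])
    df$start[on] <- ifelse(df$start[on] >= s & df$start[on] < e &
                             df$end[on] > e, e, df$start[on])
    df$start[on] <- ifelse(df$start[on] >= e, df$start[on] - L, df$start[on])
    df$end[on] <- ifelse(df$end[on] > e, df$end[on] - L,
                         ifelse(df$end[on] > s, pmin(df$end[on], s),
                                df$end[on]))
    rownames(df) <- NULL
    df
  }
  for (nm in c("genes", "te_insertions", "clusters"))
    dataset[[nm]] <- shift_df(dataset[[nm]])
  if (!is.null(dataset$alignments)) {
    aln <- dataset$alignments
    rec <- aln$records
    hit <- rec$contig == spec$contig & rec$end > s & rec$start < e
    rec <- rec[!hit, , drop = FALSE]
    on <- rec$contig == spec$contig & rec$start >= e
    rec$start[on] <- rec$start[on] - L
    rec$end[on] <- rec$end[on] - L
    aln$records <- rec
    aln$total_mapped <- if (nrow(rec) == 0) 0 else
      sum(rec$copies[!duplicated(rec$read_id)])
    aln$genome_lengths[spec$contig] <- aln$genome_lengths[spec$contig] - L
    dataset$alignments <- aln
  }
  list(dataset = dataset, report = report)
}

#' Total weight of TE-matching reads
#'
#' Sums the (multiplicity-weighted) reads whose genomic placement overlaps
#' an annotated TE insertion by at least half the read length -- the
#' quantity entering the total piRNA-loss comparison. Optionally restricted
#' to an interval.
#'
#' @param alignments an \code{alignment_set}.
#' @param te_annotation TE insertions.
#' @param min_read_overlap minimum read-length fraction covered.
#' @param region optional one-row data.frame (contig, start, end): count
#'   only reads whose placement overlaps this interval.
#' @param exclude_families families ignored (default telomeric).
#' @return weighted read total.
#' @export
te_matching_count <- function(alignments, te_annotation,
                              min_read_overlap = 0.5, region = NULL,
                              exclude_families = c("Het-A", "TAHRE",
                                                   "TART")) {
  rec <- alignments$records
  te <- te_annotation[!(te_annotation$family %in% exclude_families), ,
                      drop = FALSE]
  if (nrow(rec) == 0 || nrow(te) == 0) return(0)
  w <- .read_weights(rec, alignments$mode)
  hits <- IRanges::findOverlaps(.as_ir(rec), .as_ir(te))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ovl <- pmin(rec$end[qh], te$end[sh]) - pmax(rec$start[qh], te$start[sh])
  ok <- rec$contig[qh] == te$contig[sh] &
    ovl >= min_read_overlap * rec$length[qh]
  match_idx <- unique(qh[ok])
  if (!is.null(region)) {
    inr <- rec$contig[match_idx] == region$contig &
      rec$end[match_idx] > region$start & rec$start[match_idx] < region$end
    match_idx <- match_idx[inr]
  }
  sum(w[match_idx])
}
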