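#' Parameters for piRNA cluster identification
#'
#' Defaults follow the published procedure: minimum cluster size 5 kb,
#' minimum 1U-or-10A composition 30\% (evaluated ignoring strand), read
#' density significant at p < 0.05 under a Poisson null evaluated in
#' sliding windows, and a >95\% major-strand share for the uni-strand
#' call. Window/step sizes parameterize the density scan.
#'
#' @param min_size_bp minimum cluster span after merging (bp).
#' @param min_1U_or_10A composition floor, inclusive (a candidate passes
#'   at exactly this value).
#' @param density_p Poisson tail threshold, exclusive (requires p <
#'   \code{density_p}).
#' @param window_bp,step_bp sliding-window geometry of the density scan.
#' @param uni_strand_threshold strict major-strand share above which a
#'   cluster is uni-strand.
#' @return list of class \code{cluster_call_params}.
#' @export
cluster_call_params <- function(min_size_bp = 5000L, min_1U_or_10A = 0.30,
                                density_p = 0.05, window_bp = 1000L,
                                step_bp = 500L, uni_strand_threshold = 0.95) {
  stopifnot(min_1U_or_10A > 0, min_1U_or_10A <= 1,
            density_p > 0, density_p <= 1,
            uni_strand_threshold > 0, uni_strand_threshold <= 1,
            min_size_bp >= window_bp, step_bp <= window_bp)
  structure(list(min_size_bp = as.integer(min_size_bp),
                 min_1U_or_10A = min_1U_or_10A, density_p = density_p,
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 uni_strand_threshold = uni_strand_threshold),
            class = "cluster_call_params")
}

#' Identify piRNA clusters from uniquely mapping reads
#'
#' Scans each contig in sliding windows and keeps windows whose weighted
#' read 5'-end count k is significant under a Poisson null with rate
#' lambda = N * window / G (N total mapped read weight, G total genome
#' length), rejecting when P(X >= k) < \code{density_p}. Overlapping
#' significant windows are chained, each candidate is trimmed to the span
#' of its reads, candidates below the size floor or below the strict
#' strand-agnostic 1U-or-10A composition floor are discarded, and the
#' survivors are merged with \code{\link{merge_clusters}}.
#'
#' @param alignments an \code{alignment_set} in \code{unique} mode.
#' @param params a \code{\link{cluster_call_params}}.
#' @return data.frame with contig, start, end, unique_read_count (0-based
#'   half-open), sorted by contig and start.
#' @export
call_clusters <- function(alignments, params = cluster_call_params()) {
  stopifnot(inherits(alignments, "alignment_set"))
  if (alignments$mode != "unique")
    stop("call_clusters requires a unique-mode alignment set")
  rec <- alignments$records
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), unique_read_count = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(rec) == 0) return(empty)
  G <- sum(alignments$genome_lengths)
  w <- .read_weights(rec, alignments$mode)
  N <- sum(w)
  lambda <- N * params$window_bp / G
  p5 <- .five_prime(rec)
  out <- list()
  for (ct in names(alignments$genome_lengths)) {
    sel <- rec$contig == ct
    if (!any(sel)) next
    pos <- p5[sel]; wt <- w[sel]
    clen <- alignments$genome_lengths[[ct]]
    starts <- seq(0L, max(0L, clen - params$window_bp), by = params$step_bp)
    k <- vapply(starts, function(s)
      sum(wt[pos >= s & pos < s + params$window_bp]), numeric(1))
    sig <- stats::ppois(ceiling(k) - 1, lambda, lower.tail = FALSE) <
      params$density_p & k > 0
    if (!any(sig)) next
    cand <- IRanges::reduce(IRanges::IRanges(starts[sig] + 1L,
                                             starts[sig] + params$window_bp))
    for (j in seq_along(cand)) {
      cs <- IRanges::start(cand)[j] - 1L; ce <- IRanges::end(cand)[j]
      inside <- pos >= cs & pos < ce
      if (!any(inside)) next
      # trim to the extent of contributing reads
      rs <- min(rec$start[sel][inside]); re <- max(rec$end[sel][inside])
      if (re - rs < params$min_size_bp) next
      comp <- .composition_1u10a(rec[sel, , drop = FALSE][inside, ,
                                                          drop = FALSE],
                                 wt[inside])
      if (comp < params$min_1U_or_10A) next
      out[[length(out) + 1]] <- data.frame(
        contig = ct, start = rs, end = re,
        unique_read_count = sum(wt[inside]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  merge_clusters(do.call(rbind, out))
}

# strand-agnostic max(1U fraction, 10A fraction), weighted
.composition_1u10a <- function(records, w) {
  max(sum(w[records$first_nt == "T"]) / sum(w),
      sum(w[records$tenth_nt == "A"]) / sum(w))
}

#' Merge closely adjacent clusters
#'
#' Two neighbouring loci are merged when the gap between them is smaller
#' than their combined length; overlapping loci count as gap 0 and are
#' always merged. Applied per contig and iterated to a fixed point; read
#' counts are summed into the merged span.
#'
#' @param clusters data.frame with contig, start, end and (optionally)
#'   unique_read_count.
#' @return merged data.frame, disjoint intervals per contig.
#' @export
merge_clusters <- function(clusters) {
  if (nrow(clusters) <= 1) return(clusters)
  if (!"unique_read_count" %in% names(clusters))
    clusters$unique_read_count <- 0
  res <- list()
  for (ct in unique(clusters$contig)) {
    cl <- clusters[clusters$contig == ct, , drop = FALSE]
    cl <- cl[order(cl$start), , drop = FALSE]
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < nrow(cl)) {
        gap <- max(0, cl$start[i + 1] - cl$end[i])
        if (gap < (cl$end[i] - cl$start[i]) +
            (cl$end[i + 1] - cl$start[i + 1])) {
          cl$end[i] <- max(cl$end[i], cl$end[i + 1])
          cl$unique_read_count[i] <- cl$unique_read_count[i] +
            cl$unique_read_count[i + 1]
          cl <- cl[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else i <- i + 1
      }
      if (!merged_any) break
    }
    res[[ct]] <- cl
  }
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a cluster as uni- or dual-strand
#'
#' A cluster is uni-strand when strictly more than the threshold share
#' (default 95\%) of its uniquely mapping reads come from one strand;
#' exactly at the threshold it is dual.
#'
#' @param cluster one-row data.frame (contig, start, end).
#' @param alignments an \code{alignment_set}.
#' @param threshold strict major-strand share.
#' @return \code{"uni"} or \code{"dual"}.
#' @export
classify_strand <- function(cluster, alignments, threshold = 0.95) {
  rec <- alignments$records
  p5 <- .five_prime(rec)
  sel <- rec$contig == cluster$contig & p5 >= cluster$start & p5 < cluster$end
  if (!any(sel)) stop("cluster contains no reads")
  w <- .read_weights(rec, alignments$mode)[sel]
  plus <- sum(w[rec$strand[sel] == "+"]) / sum(w)
  if (max(plus, 1 - plus) > threshold) "uni" else "dual"
}

#' Ping-pong signature z-score of a region
#'
#' For opposite-strand read pairs, counts weighted 5'-5' overlaps c(o)
#' for o = 1..20 nt; the z-score contrasts the 10 nt bin against the
#' background bins (1-9, 11-20): z = (c(10) - mean(bg)) / sd(bg) with
#' population sd. Returns NA when the region has reads on only one
#' strand, no opposite-strand pairing signal, or zero background sd.
#'
#' @param alignments an \code{alignment_set}.
#' @param contig,start,end region (0-based half-open); \code{NULL} region
#'   uses all records.
#' @return z-score (numeric) or NA.
#' @export
pingpong_z <- function(alignments, contig = NULL, start = NULL, end = NULL) {
  rec <- alignments$records
  if (!is.null(contig)) {
    p5 <- .five_prime(rec)
    rec <- rec[rec$contig == contig & p5 >= start & p5 < end, , drop = FALSE]
  }
  if (nrow(rec) == 0) return(NA_real_)
  w <- .read_weights(rec, alignments$mode)
  ov <- numeric(20)
  for (ct in unique(rec$contig)) {
    sel <- rec$contig == ct
    plus <- rec$strand[sel] == "+"
    if (!any(plus) || all(plus)) next
    p5 <- .five_prime(rec[sel, , drop = FALSE])
    wp <- tapply(w[sel][plus], p5[plus], sum)
    wm <- tapply(w[sel][!plus], p5[!plus], sum)
    ppos <- as.integer(names(wp))
    for (o in 1:20) {
      q <- as.character(ppos + o - 1L)
      hit <- q %in% names(wm)
      if (any(hit))
        ov[o] <- ov[o] + sum(as.numeric(wp[hit]) * as.numeric(wm[q[hit]]))
    }
  }
  if (sum(ov) == 0) return(NA_real_)
  bg <- ov[-10]
  s <- .pop_sd(bg)
  if (is.na(s) || s == 0) {
    # perfectly flat signature has no excess at 10 nt: z = 0 by continuity;
    # a nonzero excess over a zero-variance background is undefined
    return(if (ov[10] == mean(bg)) 0 else NA_real_)
  }
  (ov[10] - mean(bg)) / s
}

#' Fill cluster-level metrics
#'
#' Adds expression and content metrics to called clusters: weighted
#' unique read count, rpm (per million miRNA-matching reads), rpkm (reads
#' per cluster kilobase per million genome-mapped 23-29 nt reads),
#' plus-strand read fraction, uni/dual type, ping-pong z-score(s) and the
#' fraction of cluster base pairs under TE and coding annotations.
#'
#' @param clusters data.frame from \code{\link{call_clusters}}.
#' @param alignments unique-mode \code{alignment_set}.
#' @param te_annotation data.frame (contig, start, end, ...) of TE
#'   insertions.
#' @param gene_annotation data.frame (contig, start, end, ...) of coding
#'   annotations.
#' @param mirna_count miRNA ledger; defaults to the alignment set's.
#' @param total_mapped genome-mapped read total for the rpkm denominator;
#'   defaults to the alignment set's.
#' @param alignments_all optional all_best-mode set for
#'   \code{pingpong_z_all}.
#' @return the clusters data.frame with metric columns appended.
#' @export
cluster_metrics <- function(clusters, alignments, te_annotation,
                            gene_annotation,
                            mirna_count = alignments$mirna_count,
                            total_mapped = alignments$total_mapped,
                            alignments_all = NULL) {
  if (nrow(clusters) == 0) return(clusters)
  rec <- alignments$records
  w <- .read_weights(rec, alignments$mode)
  p5 <- .five_prime(rec)
  len <- clusters$end - clusters$start
  n <- nrow(clusters)
  cnt <- plusfrac <- ppu <- ppa <- numeric(n)
  type <- character(n)
  for (i in seq_len(n)) {
    sel <- rec$contig == clusters$contig[i] & p5 >= clusters$start[i] &
      p5 < clusters$end[i]
    cnt[i] <- sum(w[sel])
    plusfrac[i] <- if (cnt[i] > 0)
      sum(w[sel & rec$strand == "+"]) / cnt[i] else NA_real_
    type[i] <- if (cnt[i] > 0)
      classify_strand(clusters[i, ], alignments) else NA_character_
    ppu[i] <- pingpong_z(alignments, clusters$contig[i], clusters$start[i],
                         clusters$end[i])
    ppa[i] <- if (!is.null(alignments_all))
      pingpong_z(alignments_all, clusters$contig[i], clusters$start[i],
                 clusters$end[i]) else NA_real_
  }
  clusters$unique_read_count <- cnt
  clusters$rpm <- normalize_rpm(cnt, mirna_count)
  clusters$rpkm <- if (total_mapped > 0)
    cnt * 1e9 / (len * total_mapped) else NA_real_
  clusters$plus_strand_read_fraction <- plusfrac
  clusters$type <- type
  clusters$pingpong_z_unique <- ppu
  clusters$pingpong_z_all <- ppa
  clusters$te_bp_fraction <- .overlap_bp_by_contig(clusters, te_annotation) / len
  clusters$cds_bp_fraction <- .overlap_bp_by_contig(clusters, gene_annotation) / len
  clusters
}

#' Rank clusters by expression and keep the top n
#'
#' Sorts by accumulated unique read count (descending), breaking ties by
#' (contig, start), assigns ranks and returns the first \code{n} (all if
#' fewer).
#'
#' @param clusters metric-filled cluster data.frame.
#' @param n number of clusters to keep (default 20).
#' @return ranked subset with a \code{rank} column.
#' @export
rank_top <- function(clusters, n = 20L) {
  if (nrow(clusters) == 0) return(cbind(clusters, rank = integer(0)))
  ord <- order(-clusters$unique_read_count, clusters$contig, clusters$start)
  out <- clusters[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, n)
}
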