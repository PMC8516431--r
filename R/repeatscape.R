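#' Kimura two-parameter divergence
#'
#' K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)) from the proportions of
#' transitions (P) and transversions (Q) between a repeat copy and its
#' family consensus. Returned as a proportion (multiply by 100 for
#' percent). The formula saturates when 1 - 2P - Q <= 0 or 1 - 2Q <= 0;
#' that raises an explicit error rather than returning a silent NaN.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return divergence K (proportion).
#' @export
kimura2p <- function(P, Q) {
  stopifnot(is.numeric(P), is.numeric(Q))
  if (any(P < 0 | Q < 0 | P + Q > 1))
    stop("P and Q must be non-negative with P + Q <= 1")
  if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0))
    stop("Kimura divergence saturated: 1-2P-Q and 1-2Q must be positive")
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# window layout shared by the border profiles: for each cluster border,
# `n_flank` windows outside and `n_int` inside, ordered from the most
# distal flank window (index 1) to the most internal window. Returns NULL
# when the flank would leave the contig.
.border_windows <- function(cluster, contig_len, window, flank, internal) {
  n_flank <- flank %/% window; n_int <- internal %/% window
  left <- list(out = cluster$start - rev(seq_len(n_flank)) * window,
               inn = cluster$start + (seq_len(n_int) - 1) * window)
  right <- list(out = cluster$end + (rev(seq_len(n_flank)) - 1) * window,
                inn = cluster$end - seq_len(n_int) * window)
  # drop borders whose flank leaves the contig
  res <- list()
  if (min(left$out) >= 0) {
    starts <- c(left$out, left$inn)
    keep_in <- c(rep(TRUE, n_flank), left$inn + window <= cluster$end)
    res$left <- data.frame(index = seq_len(n_flank + n_int), start = starts,
                           end = starts + window, valid = keep_in)
  }
  if (max(right$out) + window <= contig_len) {
    starts <- c(right$out, right$inn)
    keep_in <- c(rep(TRUE, n_flank), right$inn >= cluster$start)
    res$right <- data.frame(index = seq_len(n_flank + n_int), start = starts,
                            end = starts + window, valid = keep_in)
  }
  res
}

#' Annotation content profile at cluster borders
#'
#' For each cluster border the flanking region (default 10 kb, outside)
#' and the internal cluster margin (default 5 kb) are tiled in windows
#' (default 500 bp) and the fraction of base pairs covered by TE and
#' coding (CDS) annotations is averaged across all borders per window
#' index. Window index 1 is the most distal flank window; the border sits
#' between indices \code{flank/window} and \code{flank/window + 1}.
#' Borders whose flank leaves the contig are dropped; internal windows
#' reaching beyond the opposite border of a short cluster are dropped for
#' that cluster.
#'
#' @param clusters cluster data.frame (contig, start, end).
#' @param te_annotation,gene_annotation interval data.frames.
#' @param contig_lengths named vector of contig lengths.
#' @param window,flank,internal window geometry in bp.
#' @return data.frame with window index, offset_bp (window start relative
#'   to the border, negative outside), mean te_fraction and cds_fraction,
#'   and n (borders contributing).
#' @export
border_content_profile <- function(clusters, te_annotation, gene_annotation,
                                   contig_lengths, window = 500L,
                                   flank = 10000L, internal = 5000L) {
  n_win <- (flank + internal) %/% window
  te_mat <- cds_mat <- NULL
  for (i in seq_len(nrow(clusters))) {
    wins <- .border_windows(clusters[i, ], contig_lengths[[clusters$contig[i]]],
                            window, flank, internal)
    for (side in wins) {
      te_row <- cds_row <- rep(NA_real_, n_win)
      te_sub <- te_annotation[te_annotation$contig == clusters$contig[i], ,
                              drop = FALSE]
      cds_sub <- gene_annotation[gene_annotation$contig == clusters$contig[i], ,
                                 drop = FALSE]
      for (j in which(side$valid)) {
        te_row[side$index[j]] <- .overlap_bp(side$start[j], side$end[j],
                                             te_sub) / window
        cds_row[side$index[j]] <- .overlap_bp(side$start[j], side$end[j],
                                              cds_sub) / window
      }
      te_mat <- rbind(te_mat, te_row)
      cds_mat <- rbind(cds_mat, cds_row)
    }
  }
  if (is.null(te_mat))
    return(data.frame(index = integer(), offset_bp = integer(),
                      te_fraction = numeric(), cds_fraction = numeric(),
                      n = integer()))
  data.frame(index = seq_len(n_win),
             offset_bp = (seq_len(n_win) - 1L - flank %/% window) * window,
             te_fraction = colMeans(te_mat, na.rm = TRUE),
             cds_fraction = colMeans(cds_mat, na.rm = TRUE),
             n = colSums(!is.na(te_mat)))
}

# length-weighted mean divergence of insertions overlapping [s,e);
# NA when no TE bp overlaps
.window_divergence <- function(s, e, te) {
  if (nrow(te) == 0) return(NA_real_)
  ov <- pmax(0, pmin(te$end, e) - pmax(te$start, s))
  if (sum(ov) == 0) return(NA_real_)
  sum(ov * te$divergence_pct) / sum(ov)
}

#' Transposon divergence profile at cluster borders
#'
#' Window divergence is the length-weighted mean \code{divergence_pct} of
#' overlapping insertions; windows with no TE base pairs are skipped in
#' the cross-cluster average (per-cluster window means first, then the
#' mean over clusters). Two layouts: \code{absolute_500bp} uses fixed
#' windows as in \code{\link{border_content_profile}};
#' \code{percent_halves} rescales each cluster to its own length, tiling
#' from -50\% (flank of half the cluster length) to +50\% (internal half)
#' of the cluster length around each border in 5\%-of-length bins.
#'
#' @param clusters cluster data.frame.
#' @param te_annotation TE insertions with \code{divergence_pct}.
#' @param contig_lengths named vector of contig lengths.
#' @param mode \code{"absolute_500bp"} or \code{"percent_halves"}.
#' @param window,flank,internal geometry of the absolute mode.
#' @return data.frame with window index, offset (bp or percent of cluster
#'   length), mean_divergence and n.
#' @export
divergence_border_profile <- function(clusters, te_annotation, contig_lengths,
                                      mode = c("absolute_500bp",
                                               "percent_halves"),
                                      window = 500L, flank = 10000L,
                                      internal = 5000L) {
  mode <- match.arg(mode)
  mat <- NULL
  if (mode == "absolute_500bp") {
    n_win <- (flank + internal) %/% window
    offs <- (seq_len(n_win) - 1L - flank %/% window) * window
    for (i in seq_len(nrow(clusters))) {
      te_sub <- te_annotation[te_annotation$contig == clusters$contig[i], ,
                              drop = FALSE]
      wins <- .border_windows(clusters[i, ],
                              contig_lengths[[clusters$contig[i]]],
                              window, flank, internal)
      for (side in wins) {
        row <- rep(NA_real_, n_win)
        for (j in which(side$valid))
          row[side$index[j]] <- .window_divergence(side$start[j], side$end[j],
                                                   te_sub)
        mat <- rbind(mat, row)
      }
    }
  } else {
    # 10 bins outside (-50%..0) and 10 inside (0..+50%) of cluster length
    n_win <- 20L
    offs <- seq(-50, 45, by = 5) + 2.5
    for (i in seq_len(nrow(clusters))) {
      te_sub <- te_annotation[te_annotation$contig == clusters$contig[i], ,
                              drop = FALSE]
      len <- clusters$end[i] - clusters$start[i]
      bin <- len / 20
      clen <- contig_lengths[[clusters$contig[i]]]
      for (border in c("left", "right")) {
        b <- if (border == "left") clusters$start[i] else clusters$end[i]
        dir <- if (border == "left") 1 else -1
        edges <- b + dir * seq(-len / 2, len / 2, by = bin)
        if (min(edges) < 0 || max(edges) > clen) next
        row <- vapply(seq_len(n_win), function(j)
          .window_divergence(min(edges[j], edges[j + 1]),
                             max(edges[j], edges[j + 1]), te_sub),
          numeric(1))
        mat <- rbind(mat, row)
      }
    }
  }
  if (is.null(mat))
    return(data.frame(index = integer(), offset = numeric(),
                      mean_divergence = numeric(), n = integer()))
  data.frame(index = seq_len(ncol(mat)), offset = offs,
             mean_divergence = colMeans(mat, na.rm = TRUE),
             n = colSums(!is.na(mat)))
}

#' Partition contigs into heterochromatin and euchromatin
#'
#' Computes TE bp density in fixed windows; maximal runs of windows with
#' density at least twice the genomic average that reach a contig end are
#' labeled heterochromatin, everything else euchromatin. The partition
#' tiles every contig exactly once.
#'
#' @param te_annotation TE insertion intervals.
#' @param contig_lengths named vector of contig lengths.
#' @param density_window window size (default 50 kb); contigs shorter
#'   than one window are handled as a single window.
#' @return data.frame contig, start, end, class
#'   (\code{"heterochromatin"} / \code{"euchromatin"}).
#' @export
call_heterochromatin <- function(te_annotation, contig_lengths,
                                 density_window = 50000L) {
  total_te <- if (nrow(te_annotation) == 0) 0 else
    sum(te_annotation$end - te_annotation$start)
  avg <- total_te / sum(contig_lengths)
  out <- list()
  for (ct in names(contig_lengths)) {
    clen <- contig_lengths[[ct]]
    starts <- seq(0L, max(0L, clen - 1L), by = density_window)
    ends <- pmin(starts + density_window, clen)
    te_sub <- te_annotation[te_annotation$contig == ct, , drop = FALSE]
    dens <- vapply(seq_along(starts), function(j)
      .overlap_bp(starts[j], ends[j], te_sub) / (ends[j] - starts[j]),
      numeric(1))
    hot <- avg > 0 & dens >= 2 * avg
    lab <- rep("euchromatin", length(starts))
    r <- rle(hot)
    idx_end <- cumsum(r$lengths); idx_start <- idx_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] &&
          (idx_start[k] == 1L || idx_end[k] == length(starts)))
        lab[idx_start[k]:idx_end[k]] <- "heterochromatin"
    }
    r2 <- rle(lab)
    e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
    out[[ct]] <- data.frame(contig = ct, start = starts[s2],
                            end = ends[e2], class = r2$values,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation between TE insertion strand and piRNA strand
#'
#' For each cluster, the fraction of TE insertions on the plus strand
#' (insertions assigned by midpoint) and the weighted fraction of
#' uniquely mapping reads on the plus strand; the Pearson correlation is
#' computed over clusters when at least three clusters with defined
#' fractions and nonzero variance are available, otherwise \code{r} is
#' NA.
#'
#' @param clusters cluster data.frame.
#' @param alignments unique-mode \code{alignment_set}.
#' @param te_annotation stranded TE insertions.
#' @return list with \code{per_cluster} (data.frame te_plus_fraction,
#'   read_plus_fraction) and \code{r}.
#' @export
strand_bias_correlation <- function(clusters, alignments, te_annotation) {
  rec <- alignments$records
  w <- .read_weights(rec, alignments$mode)
  p5 <- .five_prime(rec)
  mid <- (te_annotation$start + te_annotation$end) / 2
  tp <- rp <- rep(NA_real_, nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    te_in <- te_annotation$contig == clusters$contig[i] &
      mid >= clusters$start[i] & mid < clusters$end[i]
    if (any(te_in))
      tp[i] <- mean(te_annotation$strand[te_in] == "+")
    sel <- rec$contig == clusters$contig[i] & p5 >= clusters$start[i] &
      p5 < clusters$end[i]
    if (any(sel))
      rp[i] <- sum(w[sel & rec$strand == "+"]) / sum(w[sel])
  }
  per <- data.frame(te_plus_fraction = tp, read_plus_fraction = rp)
  ok <- stats::complete.cases(per)
  r <- if (sum(ok) >= 3 && stats::sd(tp[ok]) > 0 && stats::sd(rp[ok]) > 0)
    stats::cor(tp[ok], rp[ok]) else NA_real_
  list(per_cluster = per, r = r)
}

#' Divergence distribution by genomic compartment
#'
#' Assigns every TE insertion (by midpoint) to one of three classes --
#' piRNA cluster, heterochromatin, euchromatin -- and returns the mean
#' divergence and a 1\%-bin histogram per class.
#'
#' @param te_annotation TE insertions with \code{divergence_pct}.
#' @param clusters cluster intervals.
#' @param partition output of \code{\link{call_heterochromatin}}.
#' @return list with \code{means} (named numeric) and \code{histogram}
#'   (data.frame class, bin, count).
#' @export
divergence_class_summary <- function(te_annotation, clusters, partition) {
  if (nrow(te_annotation) == 0)
    return(list(means = c(cluster = NA_real_, heterochromatin = NA_real_,
                          euchromatin = NA_real_),
                histogram = data.frame(class = character(), bin = integer(),
                                       count = integer())))
  mid <- floor((te_annotation$start + te_annotation$end) / 2)
  cls <- rep("euchromatin", nrow(te_annotation))
  hc <- partition[partition$class == "heterochromatin", , drop = FALSE]
  for (i in seq_len(nrow(hc)))
    cls[te_annotation$contig == hc$contig[i] & mid >= hc$start[i] &
          mid < hc$end[i]] <- "heterochromatin"
  for (i in seq_len(nrow(clusters)))
    cls[te_annotation$contig == clusters$contig[i] &
          mid >= clusters$start[i] & mid < clusters$end[i]] <- "cluster"
  means <- vapply(c("cluster", "heterochromatin", "euchromatin"), function(k)
    if (any(cls == k)) mean(te_annotation$divergence_pct[cls == k])
    else NA_real_, numeric(1))
  bins <- floor(te_annotation$divergence_pct)
  hist <- as.data.frame(table(class = cls, bin = bins),
                        stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0, , drop = FALSE]
  names(hist)[3] <- "count"
  hist$bin <- as.integer(hist$bin)
  rownames(hist) <- NULL
  list(means = means, histogram = hist)
}
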