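#' Build a signed permutation from two ortholog-tagged gene orders
#'
#' Writes the subject species' gene order in the coordinate and
#' orientation frame of the query: genes shared between the two arrays
#' are renumbered 1..n by query position; each subject gene contributes
#' its query number with a positive sign when its strand matches the
#' query strand and a negative sign otherwise. Genes absent from either
#' array are dropped; a duplicated ortholog group in either array is an
#' error (the correspondence must be one-to-one).
#'
#' @param subject_order data.frame with \code{ortholog_group} and
#'   \code{strand}, in subject genomic order.
#' @param query_order data.frame with \code{ortholog_group} and
#'   \code{strand}, in query genomic order.
#' @return integer vector: the signed permutation.
#' @export
build_signed_permutation <- function(subject_order, query_order) {
  so <- subject_order$ortholog_group
  qo <- query_order$ortholog_group
  if (anyDuplicated(so) || anyDuplicated(qo))
    stop("duplicated ortholog group: correspondence must be one-to-one")
  shared <- intersect(so, qo)
  if (length(shared) == 0) stop("no shared ortholog groups")
  q <- query_order[qo %in% shared, , drop = FALSE]
  s <- subject_order[so %in% shared, , drop = FALSE]
  qrank <- stats::setNames(seq_len(nrow(q)), q$ortholog_group)
  qstrand <- stats::setNames(q$strand, q$ortholog_group)
  val <- unname(qrank[s$ortholog_group])
  sign <- ifelse(s$strand == qstrand[s$ortholog_group], 1L, -1L)
  as.integer(val * sign)
}

#' Find breakpoints of a signed permutation
#'
#' Pads the permutation with 0 and n+1 and reports every adjacency whose
#' signed difference p[i+1] - p[i] differs from 1. An adjacency is
#' additionally flagged as an inversion breakpoint when the two elements
#' differ in sign (padding counts as positive).
#'
#' @param perm integer vector whose absolute values are a permutation of
#'   1..n.
#' @return data.frame with one row per breakpoint: \code{adjacency} (i,
#'   the padded left-element index starting at 0), \code{left},
#'   \code{right} (the two elements) and \code{inversion}.
#' @export
find_breakpoints <- function(perm) {
  n <- length(perm)
  if (!setequal(abs(perm), seq_len(n)))
    stop("absolute values must be a permutation of 1..n")
  p <- c(0L, as.integer(perm), n + 1L)
  d <- diff(p)
  bp <- which(d != 1L)
  sgn <- function(x) ifelse(x >= 0, 1L, -1L)  # padding is positive
  data.frame(adjacency = bp - 1L, left = p[bp], right = p[bp + 1L],
             inversion = sgn(p[bp]) != sgn(p[bp + 1L]))
}

#' Genomic positions of breakpoints
#'
#' Maps each breakpoint of \code{\link{find_breakpoints}} to a genomic
#' position in the subject: the midpoint of the intergenic span between
#' the two genes anchoring the disordered adjacency. Terminal
#' adjacencies (against the padding) use the outer edge of the terminal
#' gene.
#'
#' @param breakpoints data.frame from \code{\link{find_breakpoints}}.
#' @param subject_genes data.frame (contig, start, end) aligned with the
#'   permutation elements, in subject genomic order.
#' @return the breakpoints data.frame with contig and position columns.
#' @export
breakpoint_positions <- function(breakpoints, subject_genes) {
  n <- nrow(subject_genes)
  pos <- numeric(nrow(breakpoints))
  for (j in seq_len(nrow(breakpoints))) {
    i <- breakpoints$adjacency[j]   # between padded elements i and i+1
    pos[j] <- if (i == 0) subject_genes$start[1]
    else if (i == n) subject_genes$end[n]
    else (subject_genes$end[i] + subject_genes$start[i + 1]) / 2
  }
  breakpoints$contig <- subject_genes$contig[1]
  breakpoints$position <- pos
  breakpoints
}

#' Breakpoint frequency profile around loci
#'
#' Bins breakpoint events by distance to the nearest border of each
#' locus: events inside a locus fall in the between-flanks bin (bin 0,
#' the x0 window of the enrichment z-score); events outside fall in
#' consecutive flank windows (bin k covers ((k-1)*window, k*window] bp
#' from the border, on either side). Frequencies are events per window
#' averaged over loci; a flank side truncated by a contig end is
#' excluded from the averaging.
#'
#' @param events data.frame with contig and position.
#' @param loci data.frame (contig, start, end).
#' @param contig_lengths named vector of contig lengths.
#' @param window flank window size (default 15 kb).
#' @param extent profiled flank extent per side (default 150 kb).
#' @return data.frame bin (0 = between flanks), dist_lo, dist_hi,
#'   frequency, n_loci.
#' @export
profile_breakpoints <- function(events, loci, contig_lengths,
                                window = 15000L, extent = 150000L) {
  n_bins <- extent %/% window
  counts <- matrix(NA_real_, nrow = nrow(loci), ncol = n_bins + 1)
  for (i in seq_len(nrow(loci))) {
    ev <- events[events$contig == loci$contig[i], , drop = FALSE]
    inside <- ev$position >= loci$start[i] & ev$position < loci$end[i]
    counts[i, 1] <- sum(inside)
    dist <- ifelse(ev$position < loci$start[i], loci$start[i] - ev$position,
                   ev$position - loci$end[i])
    left_ok <- loci$start[i] - extent >= 0
    right_ok <- loci$end[i] + extent <= contig_lengths[[loci$contig[i]]]
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * window; hi <- b * window
      n_sides <- left_ok + right_ok
      if (n_sides == 0) next
      sel <- !inside & dist > lo & dist <= hi &
        ((ev$position < loci$start[i] & left_ok) |
           (ev$position >= loci$end[i] & right_ok))
      counts[i, b + 1] <- sum(sel) / n_sides
    }
  }
  data.frame(bin = 0:n_bins,
             dist_lo = c(NA, (seq_len(n_bins) - 1) * window),
             dist_hi = c(NA, seq_len(n_bins) * window),
             frequency = colMeans(counts, na.rm = TRUE),
             n_loci = colSums(!is.na(counts)))
}

#' Random background locus sets
#'
#' Generates \code{n_sets} sets of random genomic intervals, one per
#' observed locus, with lengths matched to the observed loci and
#' placement uniform over the contigs (weighted by the room each contig
#' offers). Reproducible by seed.
#'
#' @param contig_lengths named vector of contig lengths.
#' @param locus_lengths lengths of the observed loci (bp).
#' @param n_sets number of sets (default 10).
#' @param seed integer seed.
#' @return list of data.frames (contig, start, end).
#' @export
sample_background <- function(contig_lengths, locus_lengths, n_sets = 10L,
                              seed = 1L) {
  if (any(locus_lengths > max(contig_lengths)))
    stop("a locus is longer than every contig")
  set.seed(seed)
  lapply(seq_len(n_sets), function(k) {
    rows <- lapply(locus_lengths, function(L) {
      room <- pmax(0, contig_lengths - L)
      ct <- sample(names(contig_lengths), 1, prob = room)
      s <- sample(seq(0L, contig_lengths[[ct]] - L), 1)
      data.frame(contig = ct, start = s, end = s + L,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Breakpoint enrichment z-score
#'
#' Z0 = (x0 - mu) / sigma, where x0 is the breakpoint frequency in the
#' between-flanks window, and mu and sigma are the mean and population
#' standard deviation of the flank-window frequencies. The p-value is
#' the one-sided upper-tail normal probability.
#'
#' @param x0 between-flanks breakpoint frequency.
#' @param flank_frequencies numeric vector of flank-window frequencies
#'   (length >= 2).
#' @return list with x0, mu, sigma, Z0 and p; Z0 and p are NA when
#'   sigma is 0.
#' @export
enrichment_zscore <- function(x0, flank_frequencies) {
  .stopifnot_scalar(x0, "x0")
  if (length(flank_frequencies) < 2)
    stop("need at least 2 flank windows")
  mu <- mean(flank_frequencies)
  sigma <- .pop_sd(flank_frequencies)
  if (is.na(sigma) || sigma == 0)
    return(list(x0 = x0, mu = mu, sigma = sigma, Z0 = NA_real_,
                p = NA_real_))
  z <- (x0 - mu) / sigma
  list(x0 = x0, mu = mu, sigma = sigma, Z0 = z, p = normal_upper_p(z))
}

#' One-sided upper-tail normal probability
#'
#' p = 1 - Phi(z) for the standard normal distribution function Phi.
#'
#' @param z z-score(s).
#' @return upper-tail probability.
#' @export
normal_upper_p <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

#' Inversion breakpoint events between two species
#'
#' For every subject contig, expresses the subject gene order as a
#' signed permutation in the query frame (shared ortholog groups only,
#' query order by contig then coordinate), detects breakpoints and maps
#' them to subject genomic positions.
#'
#' @param query_genes,subject_genes gene data.frames with
#'   \code{ortholog_group} and \code{strand}.
#' @param inversion_only keep only inversion-flagged breakpoints
#'   (default TRUE, matching the inversion-breakpoint profile; set FALSE
#'   to profile all breakpoints).
#' @return data.frame contig, position, inversion.
#' @export
inversion_breakpoint_events <- function(query_genes, subject_genes,
                                        inversion_only = TRUE) {
  q <- query_genes[order(query_genes$contig, query_genes$start), ,
                   drop = FALSE]
  q <- q[!duplicated(q$ortholog_group), , drop = FALSE]
  out <- list()
  for (ct in unique(subject_genes$contig)) {
    sub <- subject_genes[subject_genes$contig == ct, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    sub <- sub[!duplicated(sub$ortholog_group), , drop = FALSE]
    shared <- intersect(sub$ortholog_group, q$ortholog_group)
    if (length(shared) < 2) next
    subs <- sub[sub$ortholog_group %in% shared, , drop = FALSE]
    qs <- q[q$ortholog_group %in% shared, , drop = FALSE]
    perm <- build_signed_permutation(subs[, c("ortholog_group", "strand")],
                                     qs[, c("ortholog_group", "strand")])
    bps <- find_breakpoints(perm)
    if (nrow(bps) == 0) next
    bps <- breakpoint_positions(bps, subs[, c("contig", "start", "end")])
    out[[length(out) + 1]] <- bps[, c("contig", "position", "inversion")]
  }
  if (length(out) == 0)
    return(data.frame(contig = character(), position = numeric(),
                      inversion = logical()))
  res <- do.call(rbind, out)
  if (inversion_only) res <- res[res$inversion, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Between-flank-gene windows of clusters
#'
#' Extends each cluster interval to the inner edges of its nearest
#' flanking genes: the window within which a rearrangement breakpoint is
#' counted as lying "between the flanks" (the x0 window).
#'
#' @param clusters cluster data.frame.
#' @param genes gene data.frame.
#' @param contig_lengths named vector of contig lengths.
#' @return data.frame contig, start, end.
#' @export
interflank_loci <- function(clusters, genes, contig_lengths) {
  out <- clusters[, c("contig", "start", "end"), drop = FALSE]
  for (i in seq_len(nrow(out))) {
    g <- genes[genes$contig == out$contig[i], , drop = FALSE]
    left <- g$end[g$end <= out$start[i]]
    right <- g$start[g$start >= out$end[i]]
    out$start[i] <- if (length(left) > 0) max(left) else 0
    out$end[i] <- if (length(right) > 0) min(right) else
      contig_lengths[[out$contig[i]]]
  }
  out
}
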