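# Internal helpers. All genomic intervals in this package are 0-based
# half-open (BED convention) unless a function documents otherwise.

#' @importFrom IRanges IRanges findOverlaps reduce width pintersect
#'   countOverlaps start end
NULL

# IRanges from a 0-based half-open data.frame (columns start, end)
.as_ir <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# total bp of [qs,qe) covered by the union of intervals in `df` (same contig
# rows must be pre-filtered by the caller)
.overlap_bp <- function(qs, qe, df) {
  if (qe <= qs || nrow(df) == 0L) return(0L)
  q <- IRanges::IRanges(qs + 1L, qe)
  s <- IRanges::reduce(.as_ir(df))
  hits <- IRanges::findOverlaps(q, s)
  if (length(hits) == 0L) return(0L)
  sum(IRanges::width(IRanges::pintersect(rep(q, length(hits)), s[S4Vectors::subjectHits(hits)])))
}

# per-interval union-overlap bp of query df against subject df, contig-aware
.overlap_bp_by_contig <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sub <- subject[subject$contig == query$contig[i], , drop = FALSE]
    as.numeric(.overlap_bp(query$start[i], query$end[i], sub))
  }, numeric(1))
}

# population standard deviation
.pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

.stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

#' Jaccard index of two genomic intervals
#'
#' Intersection over union of two 0-based half-open intervals on the same
#' contig; the overlap criterion used when matching called clusters to
#' planted truth.
#'
#' @param s1,e1 first interval.
#' @param s2,e2 second interval.
#' @return Jaccard index in [0, 1].
#' @export
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  if (uni <= 0) return(0)
  inter / uni
}

# empty data.frame constructors keep column types stable
.empty_intervals <- function(extra = character()) {
  base <- data.frame(contig = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  for (col in extra) base[[col]] <- character()
  base
}
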