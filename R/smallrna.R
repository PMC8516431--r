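#' Collapse raw reads to unique sequences
#'
#' Reads are collapsed to unique sequences with a \code{copies} count
#' before filtering and mapping; U is converted to T at ingest so a single
#' DNA alphabet is used internally.
#'
#' @param sequences character vector (or named character / DNAStringSet)
#'   of raw read sequences.
#' @return data.frame with columns \code{read_id}, \code{sequence},
#'   \code{copies}.
#' @export
collapse_reads <- function(sequences) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (length(sequences) == 0)
    return(data.frame(read_id = character(), sequence = character(),
                      copies = integer(), stringsAsFactors = FALSE))
  sequences <- toupper(gsub("U", "T", sequences, fixed = FALSE))
  tab <- table(sequences)
  data.frame(read_id = sprintf("seq%06d", seq_along(tab)),
             sequence = names(tab), copies = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter small-RNA reads against annotation sequence sets
#'
#' Removes reads matching any annotation sequence set (non-coding RNA,
#' miRNA, gene, pseudogene) with up to \code{max_mismatch} mismatches on
#' either strand, then restricts survivors to the piRNA size range.
#' Reads matching the miRNA set are counted (weighted by \code{copies})
#' into the normalization ledger used for cross-sample comparison; the
#' miRNA set is checked first so a read matching several categories is
#' attributed to miRNAs.
#'
#' @param reads data.frame from \code{\link{collapse_reads}} (columns
#'   read_id, sequence, copies).
#' @param annotation_sequences named list of \code{DNAStringSet} (or
#'   character vectors); the element named \code{"miRNA"} feeds the
#'   normalization ledger. May be empty.
#' @param size_range length-2 integer vector, default \code{c(23, 29)}.
#' @param max_mismatch mismatches tolerated in annotation matching.
#' @return list with \code{reads} (surviving rows) and \code{mirna_count}.
#' @export
filter_reads <- function(reads, annotation_sequences = list(),
                         size_range = c(23L, 29L), max_mismatch = 2L) {
  stopifnot(all(c("read_id", "sequence", "copies") %in% names(reads)))
  if (nrow(reads) == 0)
    return(list(reads = reads, mirna_count = 0))
  reads$sequence <- toupper(gsub("U", "T", reads$sequence))
  sets <- lapply(annotation_sequences, function(x)
    if (inherits(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x))
  # miRNA first: first-match-wins and the ledger uses miRNA matches only
  ord <- c(intersect("miRNA", names(sets)),
           setdiff(names(sets), "miRNA"))
  drop <- rep(FALSE, nrow(reads))
  mirna_count <- 0
  for (nm in ord) {
    set <- sets[[nm]]
    if (length(set) == 0) next
    todo <- which(!drop)
    if (length(todo) == 0) break
    hit <- vapply(todo, function(i)
      .matches_any(reads$sequence[i], set, max_mismatch), logical(1))
    if (nm == "miRNA") mirna_count <- sum(reads$copies[todo][hit])
    drop[todo[hit]] <- TRUE
  }
  keep <- !drop & nchar(reads$sequence) >= size_range[1] &
    nchar(reads$sequence) <= size_range[2]
  list(reads = reads[keep, , drop = FALSE], mirna_count = mirna_count)
}

# does `seq` align within any sequence of `set` with <= mm mismatches,
# on either strand?
.matches_any <- function(seq, set, mm) {
  pat <- Biostrings::DNAString(seq)
  if (any(Biostrings::vcountPattern(pat, set, max.mismatch = mm) > 0))
    return(TRUE)
  any(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), set,
                                max.mismatch = mm) > 0)
}

#' Map small-RNA reads to a genome by exact matching
#'
#' Places each read on both strands of the genome allowing no mismatches
#' (exact substring search via a position dictionary, grouped by read
#' length). Contigs shorter than \code{min_contig} are removed before
#' matching. In \code{unique} mode only reads with exactly one genomic hit
#' are kept; in \code{all_best} mode all exact hits are kept and
#' \code{n_genomic_hits} records the multiplicity.
#'
#' @param reads data.frame (read_id, sequence, copies).
#' @param genome \code{DNAStringSet} of contigs.
#' @param mode \code{"unique"} or \code{"all_best"}.
#' @param min_contig minimum contig length retained (default 50 kb).
#' @param mirna_count miRNA-matching read count carried into the
#'   normalization ledger of the returned alignment set.
#' @return an \code{alignment_set}: list with \code{records} (data.frame
#'   read_id, contig, start, end, strand, length, first_nt, tenth_nt,
#'   n_genomic_hits, copies; 0-based half-open), \code{mode},
#'   \code{mirna_count}, \code{total_mapped} (copies of mapped reads) and
#'   \code{genome_lengths}.
#' @export
map_reads <- function(reads, genome, mode = c("unique", "all_best"),
                      min_contig = 50000L, mirna_count = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "DNAStringSet"))
  genome <- genome[Biostrings::width(genome) >= min_contig]
  if (length(genome) == 0) stop("no contig passes the minimum length filter")
  bad <- grepl("[^ACGT]", reads$sequence)
  if (any(bad)) {
    warning(sprintf("skipping %d read(s) with non-ACGT symbols", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  recs <- list()
  if (nrow(reads) > 0) {
    for (w in sort(unique(nchar(reads$sequence)))) {
      sub <- reads[nchar(reads$sequence) == w, , drop = FALSE]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub$sequence))
      pdr <- Biostrings::PDict(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(sub$sequence)))
      for (ct in names(genome)) {
        for (str in c("+", "-")) {
          mp <- Biostrings::matchPDict(if (str == "+") pd else pdr,
                                       genome[[ct]])
          cnt <- S4Vectors::elementNROWS(mp)
          if (sum(cnt) == 0) next
          ir <- unlist(mp)
          idx <- rep(seq_len(nrow(sub)), cnt)
          recs[[length(recs) + 1]] <- data.frame(
            read_id = sub$read_id[idx], contig = ct,
            start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
            strand = str, copies = sub$copies[idx],
            sequence = sub$sequence[idx], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(recs) == 0) {
    records <- data.frame(read_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          first_nt = character(), tenth_nt = character(),
                          n_genomic_hits = integer(), copies = integer(),
                          stringsAsFactors = FALSE)
  } else {
    records <- do.call(rbind, recs)
    hits <- table(records$read_id)
    records$n_genomic_hits <- as.integer(hits[records$read_id])
    records$length <- nchar(records$sequence)
    records$first_nt <- substr(records$sequence, 1, 1)
    records$tenth_nt <- substr(records$sequence, 10, 10)
    if (mode == "unique")
      records <- records[records$n_genomic_hits == 1L, , drop = FALSE]
    records <- records[order(records$contig, records$start, records$read_id),
                       c("read_id", "contig", "start", "end", "strand",
                         "length", "first_nt", "tenth_nt", "n_genomic_hits",
                         "copies"), drop = FALSE]
    rownames(records) <- NULL
  }
  total_mapped <- if (nrow(records) == 0) 0 else
    sum(records$copies[!duplicated(records$read_id)])
  structure(list(records = records, mode = mode,
                 mirna_count = mirna_count, total_mapped = total_mapped,
                 genome_lengths = stats::setNames(Biostrings::width(genome),
                                                  names(genome))),
            class = "alignment_set")
}

#' Normalize a read count by the miRNA ledger
#'
#' Cross-sample normalization divides by the number of miRNA-matching
#' reads of the library: \code{count * 1e6 / mirna_count} (reads per
#' million miRNA reads).
#'
#' @param count raw read count (vectorized).
#' @param mirna_count miRNA-matching read count of the library; must be
#'   strictly positive.
#' @return normalized value(s).
#' @export
normalize_rpm <- function(count, mirna_count) {
  if (!is.numeric(mirna_count) || length(mirna_count) != 1L ||
      is.na(mirna_count) || mirna_count <= 0)
    stop("mirna_count must be a single positive number")
  count * 1e6 / mirna_count
}

# weighted 5' position table of an alignment_set's records;
# weight = copies (unique mode) or copies / n_genomic_hits (all_best)
.read_weights <- function(records, mode) {
  if (mode == "all_best") records$copies / records$n_genomic_hits
  else as.numeric(records$copies)
}

# 5' position (0-based) of each record
.five_prime <- function(records) {
  ifelse(records$strand == "+", records$start, records$end - 1L)
}
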