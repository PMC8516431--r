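# Readers and writers for the package's on-disk formats. Coordinates are
# converted between the internal 0-based half-open convention and each
# format's own convention (GFF3 1-based inclusive, BED 0-based half-open).

#' Write gene annotations as GFF3
#'
#' @param genes gene data.frame (contig, start, end, strand, gene_id,
#'   ortholog_group), 0-based half-open.
#' @param path output file.
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    attrs <- sprintf("ID=%s;ortholog_group=%s", genes$gene_id,
                     genes$ortholog_group)
    writeLines(sprintf("%s\tpiclust\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       genes$contig, genes$start + 1L, genes$end,
                       genes$strand, attrs), con)
  }
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Expects \code{gene} features with \code{ID} and \code{ortholog_group}
#' attributes, as written by \code{\link{write_genes_gff3}}.
#'
#' @param path GFF3 file.
#' @return gene data.frame, 0-based half-open.
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), ortholog_group = character(),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(sprintf("%s=[^;]+", key), a))
    sub(sprintf("^%s=", key), "", m)
  }
  data.frame(contig = f[, 1], start = as.integer(f[, 4]) - 1L,
             end = as.integer(f[, 5]), strand = f[, 7],
             gene_id = attr_get(f[, 9], "ID"),
             ortholog_group = attr_get(f[, 9], "ortholog_group"),
             stringsAsFactors = FALSE)
}

#' Write TE insertions as BED6 plus a TSV side table
#'
#' The BED6 carries family as name and divergence as score; the TSV
#' carries all columns and is what \code{\link{read_te_annotation}}
#' reads back.
#'
#' @param te TE data.frame.
#' @param prefix path prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}.
#' @export
write_te_annotation <- function(te, prefix) {
  bed <- data.frame(te$contig, te$start, te$end, te$family,
                    round(te$divergence_pct, 2), te$strand)
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(te, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read TE insertions from the TSV side table
#' @param path the \code{.tsv} written by
#'   \code{\link{write_te_annotation}}.
#' @return TE data.frame.
#' @export
read_te_annotation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an alignment set as extended BED
#'
#' BED6 columns (name = read id, score = copies) extended with length,
#' first/tenth nucleotide and hit count; the normalization ledger goes
#' to a JSON sidecar.
#'
#' @param alignments an \code{alignment_set}.
#' @param prefix path prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.ledger.json}.
#' @export
write_alignments_bed <- function(alignments, prefix) {
  rec <- alignments$records
  bed <- data.frame(rec$contig, rec$start, rec$end, rec$read_id,
                    rec$copies, rec$strand, rec$length, rec$first_nt,
                    rec$tenth_nt, rec$n_genomic_hits)
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(mode = alignments$mode, mirna_count = alignments$mirna_count,
         total_mapped = alignments$total_mapped,
         genome_lengths = as.list(alignments$genome_lengths)),
    paste0(prefix, ".ledger.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an alignment set from extended BED
#' @param prefix prefix used by \code{\link{write_alignments_bed}}.
#' @return an \code{alignment_set}.
#' @export
read_alignments_bed <- function(prefix) {
  led <- jsonlite::read_json(paste0(prefix, ".ledger.json"),
                             simplifyVector = TRUE)
  tab <- utils::read.table(paste0(prefix, ".bed"), sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer",
                                          "character", "integer",
                                          "character", "character",
                                          "integer"))
  names(tab) <- c("contig", "start", "end", "read_id", "copies", "strand",
                  "length", "first_nt", "tenth_nt", "n_genomic_hits")
  records <- tab[, c("read_id", "contig", "start", "end", "strand",
                     "length", "first_nt", "tenth_nt", "n_genomic_hits",
                     "copies")]
  structure(list(records = records, mode = led$mode,
                 mirna_count = led$mirna_count,
                 total_mapped = led$total_mapped,
                 genome_lengths = unlist(led$genome_lengths)),
            class = "alignment_set")
}

#' Write one synthetic species to disk
#'
#' Emits genome FASTA, genes GFF3, TE BED+TSV and a truth TSV of planted
#' clusters; reads (if supplied) go to FASTA plus a truth TSV.
#'
#' @param truth a \code{species_truth}.
#' @param dir output directory.
#' @param reads optional result of \code{\link{simulate_small_rna}}.
#' @return named list of written paths.
#' @export
write_species_truth <- function(truth, dir, reads = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- truth$species
  paths <- list(
    genome = file.path(dir, paste0(sp, ".genome.fa")),
    genes = file.path(dir, paste0(sp, ".genes.gff3")),
    te = file.path(dir, paste0(sp, ".te")),
    clusters = file.path(dir, paste0(sp, ".true_clusters.tsv")),
    events = file.path(dir, paste0(sp, ".inversions.tsv")))
  Biostrings::writeXStringSet(truth$genome, paths$genome)
  write_genes_gff3(truth$genes, paths$genes)
  write_te_annotation(truth$te_insertions, paths$te)
  utils::write.table(truth$true_clusters, paths$clusters, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$inversion_events, paths$events, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(reads)) {
    paths$reads <- file.path(dir, paste0(sp, ".reads.fa"))
    paths$read_truth <- file.path(dir, paste0(sp, ".read_truth.tsv"))
    rs <- Biostrings::DNAStringSet(reads$reads$sequence)
    names(rs) <- reads$reads$read_id
    Biostrings::writeXStringSet(rs, paths$reads)
    utils::write.table(reads$truth, paths$read_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths
}
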