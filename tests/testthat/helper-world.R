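# Shared synthetic worlds, built once per test run and memoized.
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, n_species = 3, seed = 42, inversion_rate = 1.5,
                         hotspot_bias = 0.5, ...) {
  if (is.null(.world_cache[[key]])) {
    cfg <- world_config(n_species = n_species, seed = seed,
                        inversion_rate = inversion_rate,
                        hotspot_bias = hotspot_bias, ...)
    anc <- generate_ancestor(cfg)
    .world_cache[[key]] <- list(config = cfg, ancestor = anc,
                                world = evolve_species(anc, cfg))
  }
  .world_cache[[key]]
}

# one species mapped end to end (reads simulated, unique-mode alignments)
cached_mapped_species <- function(key = "default", sp_index = 1,
                                  pingpong_fraction = 0.3, seed = 7) {
  ck <- paste0("mapped_", key, "_", sp_index, "_", pingpong_fraction)
  if (is.null(.world_cache[[ck]])) {
    w <- cached_world(key)
    truth <- w$world$species[[sp_index]]
    sim <- simulate_small_rna(truth, pingpong_fraction = pingpong_fraction,
                              seed = seed)
    reads <- collapse_reads(sim$reads$sequence)
    aln <- map_reads(reads, truth$genome, "unique", mirna_count = 1e6)
    .world_cache[[ck]] <- list(truth = truth, sim = sim, reads = reads,
                               aln = aln)
  }
  .world_cache[[ck]]
}

empty_records <- function() {
  data.frame(read_id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), length = integer(),
             first_nt = character(), tenth_nt = character(),
             n_genomic_hits = integer(), copies = integer(),
             stringsAsFactors = FALSE)
}

# hand-built alignment_set from a record table (fills derived columns)
make_alignment_set <- function(records, genome_lengths,
                               mode = "unique", mirna_count = 1e6) {
  n <- nrow(records)
  if (is.null(records$read_id)) records$read_id <- sprintf("r%05d", seq_len(n))
  if (is.null(records$copies)) records$copies <- 1L
  if (is.null(records$n_genomic_hits)) records$n_genomic_hits <- 1L
  if (is.null(records$length)) records$length <- records$end - records$start
  if (is.null(records$first_nt)) records$first_nt <- "T"
  if (is.null(records$tenth_nt)) records$tenth_nt <- "A"
  structure(list(records = records, mode = mode, mirna_count = mirna_count,
                 total_mapped = sum(records$copies[!duplicated(records$read_id)]),
                 genome_lengths = genome_lengths),
            class = "alignment_set")
}

# naive independent re-derivation of breakpoints from the definition
naive_breakpoints <- function(perm) {
  p <- c(0L, perm, length(perm) + 1L)
  res <- NULL
  for (i in seq_len(length(p) - 1)) {
    if (p[i + 1] - p[i] != 1) {
      inv <- (p[i] < 0) != (p[i + 1] < 0)
      res <- rbind(res, c(i - 1L, inv))
    }
  }
  if (is.null(res)) return(data.frame(adjacency = integer(),
                                      inversion = logical()))
  data.frame(adjacency = res[, 1], inversion = as.logical(res[, 2]))
}

# pooled inversion-breakpoint enrichment Z0 of a 4-species world with 20
# planted clusters spread over 8 contigs
enrichment_world_z <- function(seed, hotspot_bias) {
  cfg <- world_config(
    n_species = 4, contig_lengths = rep(400000L, 8), n_genes = 320,
    n_te_families = 4,
    cluster_specs = data.frame(
      length_bp = rep(c(6000L, 8000L, 10000L, 7000L), 5),
      strand_mode = "dual", read_budget = 1000L),
    inversion_rate = 3, hotspot_bias = hotspot_bias, seed = seed)
  anc <- generate_ancestor(cfg)
  world <- evolve_species(anc, cfg)
  profs <- list()
  for (s in names(world$species)) {
    st <- world$species[[s]]
    clens <- setNames(Biostrings::width(st$genome), names(st$genome))
    ev <- do.call(rbind, lapply(setdiff(names(world$species), s), function(q)
      inversion_breakpoint_events(world$species[[q]]$genes, st$genes)))
    loci <- interflank_loci(st$true_clusters, st$genes, clens)
    if (is.null(ev) || nrow(ev) == 0) next
    profs[[s]] <- profile_breakpoints(ev, loci, clens, 15000L, 150000L)
  }
  m <- do.call(cbind, lapply(profs, `[[`, "frequency"))
  if (is.null(m)) return(NA_real_)
  freq <- rowMeans(m, na.rm = TRUE)
  enrichment_zscore(freq[1], freq[-1])$Z0
}

# planted truth with the caller's own merge rule applied: planted clusters
# that drifted within merging distance of each other count as one locus
merged_planted_truth <- function(planted) {
  df <- planted[, c("contig", "start", "end")]
  df$unique_read_count <- 1
  m <- merge_clusters(df)
  m$n_members <- m$unique_read_count
  m$strand_mode <- vapply(seq_len(nrow(m)), function(i) {
    mem <- planted$contig == m$contig[i] & planted$start >= m$start[i] &
      planted$end <= m$end[i]
    if (sum(mem) == 1) planted$strand_mode[mem] else NA_character_
  }, character(1))
  m
}
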