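# Pipeline orchestration: end-to-end runs driven by a YAML (or list)
# config, plus a bundled demo world generator.

#' Run the full comparative pipeline
#'
#' Executes the stages in dependency order for every species in the
#' config -- read filtering and mapping, cluster calling and metrics,
#' repeat-landscape profiling, cross-species synteny tracing,
#' inversion-breakpoint profiling and enrichment, and TE-family
#' attribution -- and writes TSV/BED/JSON outputs plus a provenance
#' manifest to the output directory. Reruns with the same config and
#' seed are byte-identical.
#'
#' @param config path to a YAML config or an equivalent list. Required
#'   fields: \code{out_dir} and \code{species} (a named list; each
#'   species lists \code{genome}, \code{genes}, \code{te},
#'   \code{reads} paths and optionally \code{mirna}, a FASTA of mature
#'   miRNA sequences used for the normalization ledger). Optional:
#'   \code{tree} (newick, branch lengths in My), \code{seed} and a
#'   \code{params} block (\code{min_contig}, \code{top_n}, \code{call},
#'   \code{synteny}, \code{breaks} subsections).
#' @return (invisibly) a list with per-species results, synteny calls,
#'   homology groups, enrichment and the manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir) || is.null(config$species))
    stop("pipeline config needs 'out_dir' and 'species'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prm <- config$params
  min_contig <- prm$min_contig %||% 50000L
  top_n <- prm$top_n %||% 20L
  call_params <- do.call(cluster_call_params, as.list(prm$call))
  span <- prm$synteny$span %||% 200000L
  bwin <- prm$breaks$window %||% 15000L
  bext <- prm$breaks$extent %||% 150000L

  species_res <- list()
  for (sp in names(config$species)) {
    paths <- config$species[[sp]]
    res <- tryCatch(
      .run_species(sp, paths, min_contig, call_params, top_n,
                   file.path(out_dir, sp)),
      error = function(e) stop(sprintf("stage failure in species '%s': %s",
                                       sp, conditionMessage(e)), call. = FALSE))
    species_res[[sp]] <- res
  }

  # cross-species stages need >= 2 species
  calls <- groups <- ages <- NULL
  enrich <- NULL
  if (length(species_res) >= 2) {
    sdata <- lapply(species_res, function(r)
      list(clusters = r$top_clusters, genes = r$genes,
           contig_lengths = r$contig_lengths))
    calls <- pairwise_table(sdata, span = span)
    utils::write.table(calls, file.path(out_dir, "synteny_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    groups <- link_groups(calls)
    utils::write.table(groups, file.path(out_dir, "homology_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tree <- NULL
    if (!is.null(config$tree) && file.exists(config$tree))
      tree <- ape::read.tree(config$tree)
    if (is.null(tree)) {
      warning("no tree supplied: homology-group age assignment skipped")
    } else {
      ages <- do.call(rbind, lapply(split(groups, groups$group), function(g) {
        a <- assign_age(g, tree)
        data.frame(group = g$group[1], n_species = length(unique(g$species)),
                   age_My = a$age_My, category = a$category)
      }))
      utils::write.table(ages, file.path(out_dir, "group_ages.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    enrich <- .run_breaks(species_res, bwin, bext, out_dir)
  }

  manifest <- list(
    package = "piclust",
    version = as.character(utils::packageVersion("piclust")),
    seed = config$seed %||% NA,
    params = list(min_contig = min_contig, top_n = top_n,
                  call = unclass(call_params), synteny_span = span,
                  breaks = list(window = bwin, extent = bext)),
    species = lapply(config$species, function(p) lapply(p, as.character)),
    outputs = setdiff(list.files(out_dir, recursive = TRUE),
                      "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(species = species_res, synteny_calls = calls,
                 homology_groups = groups, group_ages = ages,
                 enrichment = enrich,
                 manifest = file.path(out_dir, "manifest.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_species <- function(sp, paths, min_contig, call_params, top_n, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- Biostrings::readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- read_genes_gff3(paths$genes)
  te <- read_te_annotation(paths$te)
  raw <- Biostrings::readDNAStringSet(paths$reads)
  reads <- collapse_reads(raw)
  ann <- list()
  if (!is.null(paths$mirna) && file.exists(paths$mirna))
    ann$miRNA <- Biostrings::readDNAStringSet(paths$mirna)
  filt <- filter_reads(reads, ann)
  mirna <- if (filt$mirna_count > 0) filt$mirna_count else 1e6
  aln_u <- map_reads(filt$reads, genome, "unique", min_contig, mirna)
  aln_a <- map_reads(filt$reads, genome, "all_best", min_contig, mirna)
  write_alignments_bed(aln_u, file.path(dir, "alignments.unique"))
  write_alignments_bed(aln_a, file.path(dir, "alignments.all_best"))
  clusters <- call_clusters(aln_u, call_params)
  clusters <- cluster_metrics(clusters, aln_u, te, genes,
                              alignments_all = aln_a)
  if (nrow(clusters) > 0)
    clusters$cluster_id <- sprintf("%s_pic%02d", sp, seq_len(nrow(clusters)))
  top <- rank_top(clusters, top_n)
  utils::write.table(clusters, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(top, file.path(dir, "clusters.top.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clens <- stats::setNames(Biostrings::width(genome), names(genome))
  # repeat landscape
  prof <- border_content_profile(top, te, genes, clens)
  utils::write.table(prof, file.path(dir, "border_content.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dvg <- divergence_border_profile(top, te, clens)
  utils::write.table(dvg, file.path(dir, "border_divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  part <- call_heterochromatin(te, clens)
  utils::write.table(part, file.path(dir, "chromatin_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dsum <- divergence_class_summary(te, top, part)
  utils::write.table(
    data.frame(class = names(dsum$means), mean_divergence = dsum$means),
    file.path(dir, "divergence_by_class.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sbias <- strand_bias_correlation(top, aln_u, te)
  # attribution
  fsm <- family_source_matrix(aln_u, te, top)
  if (nrow(fsm) > 0)
    utils::write.table(data.frame(family = rownames(fsm), fsm,
                                  check.names = FALSE),
                       file.path(dir, "family_sources.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(species = sp, genes = genes, te = te, clusters = clusters,
       top_clusters = top, alignments_unique = aln_u,
       alignments_all = aln_a, contig_lengths = clens,
       strand_bias = sbias, family_sources = fsm)
}

# inversion-breakpoint profile + enrichment pooled over subject species
.run_breaks <- function(species_res, window, extent, out_dir) {
  sp <- names(species_res)
  profs <- list()
  for (s in sp) {
    subj <- species_res[[s]]
    ev <- do.call(rbind, lapply(setdiff(sp, s), function(q)
      inversion_breakpoint_events(species_res[[q]]$genes, subj$genes)))
    loci <- interflank_loci(subj$top_clusters, subj$genes,
                            subj$contig_lengths)
    if (nrow(loci) == 0 || is.null(ev) || nrow(ev) == 0) next
    profs[[s]] <- profile_breakpoints(ev, loci, subj$contig_lengths,
                                      window, extent)
  }
  if (length(profs) == 0) return(NULL)
  freq <- rowMeans(do.call(cbind, lapply(profs, `[[`, "frequency")),
                   na.rm = TRUE)
  prof <- profs[[1]]
  prof$frequency <- freq
  utils::write.table(prof, file.path(out_dir, "breakpoint_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- enrichment_zscore(freq[1], freq[-1])
  jsonlite::write_json(enr, file.path(out_dir, "breakpoint_enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  enr
}

#' Write a bundled synthetic demo dataset and config
#'
#' Builds a small multi-species world (default 5 species, two contigs,
#' three planted clusters), simulates reads for every species (spiking
#' in miRNA reads so the normalization ledger is exercised), writes all
#' inputs in standard formats and returns the path of a ready-to-run
#' YAML config.
#'
#' @param out_dir directory to populate.
#' @param seed integer seed.
#' @param n_species number of species.
#' @return path of the written YAML config.
#' @export
make_demo <- function(out_dir, seed = 1L, n_species = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- world_config(n_species = n_species, seed = seed)
  anc <- generate_ancestor(cfg)
  world <- evolve_species(anc, cfg)
  set.seed(seed + 101L)
  mirnas <- vapply(1:5, function(i) .rand_dna(22L), character(1))
  species_cfg <- list()
  for (sp in names(world$species)) {
    truth <- world$species[[sp]]
    reads <- simulate_small_rna(truth, seed = seed + match(sp, names(world$species)))
    # spike in miRNA reads to feed the normalization ledger
    n_mirna <- 200L
    mseq <- sample(mirnas, n_mirna, replace = TRUE)
    reads$reads <- rbind(reads$reads,
                         data.frame(read_id = sprintf("%s_mir%04d", sp,
                                                      seq_len(n_mirna)),
                                    sequence = mseq, copies = 1L,
                                    stringsAsFactors = FALSE))
    paths <- write_species_truth(truth, file.path(out_dir, sp), reads)
    species_cfg[[sp]] <- list(
      genome = paths$genome, genes = paths$genes,
      te = paste0(paths$te, ".tsv"), reads = paths$reads,
      mirna = file.path(out_dir, "mirna.fa"))
  }
  mset <- Biostrings::DNAStringSet(mirnas)
  names(mset) <- sprintf("mir%d", seq_along(mirnas))
  Biostrings::writeXStringSet(mset, file.path(out_dir, "mirna.fa"))
  tree_path <- file.path(out_dir, "tree.nwk")
  ape::write.tree(world$tree, tree_path)
  utils::write.table(world$ortholog_map, file.path(out_dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  config <- list(out_dir = file.path(out_dir, "results"),
                 seed = seed, tree = tree_path,
                 species = species_cfg,
                 params = list(min_contig = 50000L, top_n = 20L))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
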