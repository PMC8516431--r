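#' Configuration for a synthetic multi-species world
#'
#' Defines the shape of a simulated clade: contig lengths, gene and
#' transposon-family counts, planted piRNA clusters, and the inversion
#' process applied along the branches of a dated species tree. The defaults
#' emulate a small clade of fly-like genomes with TE-dense germline piRNA
#' clusters, sized so a full multi-species pipeline run takes seconds.
#'
#' @param n_species number of extant species (tree leaves).
#' @param tree an \code{ape::phylo} with branch lengths in million years
#'   (My) and \code{n_species} tips, or \code{NULL} to build a default
#'   ladder tree with split times spanning roughly 2-35 My.
#' @param contig_lengths integer vector of contig lengths (bp).
#' @param n_genes total number of ancestral genes, distributed across
#'   contigs proportionally to length. Ortholog identity is the ancestral
#'   gene number.
#' @param n_te_families number of transposon families.
#' @param cluster_specs data.frame with columns \code{length_bp},
#'   \code{strand_mode} (\code{"uni"} or \code{"dual"}) and
#'   \code{read_budget}: the piRNA clusters planted in the ancestor.
#' @param inversion_rate expected (Poisson mean) number of inversions per
#'   tree branch.
#' @param hotspot_bias fraction of inversions whose breakpoints are drawn
#'   from hotspot windows at planted cluster borders (both breakpoints of
#'   such an inversion fall in hotspot windows).
#' @param seed integer seed; all generator output is deterministic in it.
#' @return a list of class \code{world_config}.
#' @export
world_config <- function(n_species = 5,
                         tree = NULL,
                         contig_lengths = c(400000L, 300000L),
                         n_genes = 60,
                         n_te_families = 5,
                         cluster_specs = data.frame(
                           length_bp = c(8000L, 10000L, 6000L),
                           strand_mode = c("dual", "dual", "uni"),
                           read_budget = c(3000L, 4000L, 2000L)),
                         inversion_rate = 1.5,
                         hotspot_bias = 0.5,
                         seed = 1L) {
  if (is.null(tree)) tree <- .default_ladder_tree(n_species)
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  if (length(tree$tip.label) != n_species)
    stop("tree leaf count must equal n_species")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  if (hotspot_bias < 0 || hotspot_bias > 1)
    stop("hotspot_bias must be in [0, 1]")
  if (n_genes < 0 || n_te_families < 0) stop("counts must be non-negative")
  cluster_specs <- as.data.frame(cluster_specs)
  if (nrow(cluster_specs) > 0) {
    stopifnot(all(c("length_bp", "strand_mode", "read_budget") %in%
                    names(cluster_specs)))
    if (any(cluster_specs$length_bp <= 0)) stop("cluster lengths must be > 0")
    if (!all(cluster_specs$strand_mode %in% c("uni", "dual")))
      stop("strand_mode must be 'uni' or 'dual'")
  }
  structure(list(n_species = n_species, tree = tree,
                 contig_lengths = as.integer(contig_lengths),
                 n_genes = as.integer(n_genes),
                 n_te_families = as.integer(n_te_families),
                 cluster_specs = cluster_specs,
                 inversion_rate = inversion_rate,
                 hotspot_bias = hotspot_bias,
                 seed = as.integer(seed)),
            class = "world_config")
}

# ladder tree sp1..spN with split times emulating a young fly clade
.default_ladder_tree <- function(n) {
  if (n == 1) stop("need at least 2 species for a tree")
  times <- c(1.9, 7.3, 14, 25, 36.9, 45, 54, 62, 73)[seq_len(n - 1)]
  tips <- paste0("sp", seq_len(n))
  nwk <- sprintf("%s:%g", tips[1], times[1])
  for (k in seq_len(n - 1)) {
    inc <- if (k < n - 1) times[k + 1] - times[k] else 0
    nwk <- sprintf("(%s,%s:%g):%g", nwk, tips[k + 1], times[k], inc)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the ancestral genome of a synthetic world
#'
#' Builds one ancestral species: random 4-letter contig sequences, ordered
#' non-overlapping genes whose ortholog group is their ancestral rank,
#' planted TE-dense piRNA clusters, a TE-dense terminal
#' (heterochromatin-like) block per contig, and dispersed background
#' insertions. Cluster insertions receive low sequence divergence (~3%),
#' terminal-block insertions intermediate (~8%) and euchromatic background
#' high (~15%), mirroring the age layering of germline cluster repeats.
#'
#' @param config a \code{\link{world_config}}.
#' @return a \code{species_truth} list with elements \code{species},
#'   \code{genome} (DNAStringSet), \code{genes}, \code{te_insertions},
#'   \code{true_clusters}, \code{inversion_events}, \code{te_families}.
#'   All coordinates 0-based half-open.
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  lens <- config$contig_lengths
  contigs <- paste0("chr", seq_along(lens))
  specs <- config$cluster_specs

  # cluster placement: each cluster needs edge margins so flank genes exist
  edge <- pmin(15000L, as.integer(floor(lens * 0.1)))
  clusters <- .empty_intervals()
  clusters$strand_mode <- character(); clusters$cluster_id <- character()
  clusters$read_budget <- integer(); clusters$major_strand <- character()
  if (nrow(specs) > 0) {
    assign_contig <- integer(nrow(specs))
    used <- lapply(seq_along(lens), function(i) integer(0))
    placed <- list()
    for (i in seq_len(nrow(specs))) {
      L <- specs$length_bp[i]
      fits <- which(lens - 2L * edge >= L)
      if (length(fits) == 0L)
        stop(sprintf("cluster of %d bp does not fit on any contig", L))
      ok <- FALSE
      for (attempt in seq_len(200)) {
        ci <- if (length(fits) == 1L) fits else sample(fits, 1)
        s <- sample(seq(edge[ci], lens[ci] - edge[ci] - L), 1)
        # keep >= 25 kb between clusters: below twice the combined length
        # of two planted clusters, the merge rule would join them
        clash <- any(vapply(placed, function(p)
          p$ci == ci && s < p$e + 25000 && p$s < s + L + 25000, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place planted clusters without collision")
      placed[[i]] <- list(ci = ci, s = s, e = s + L)
      assign_contig[i] <- ci
    }
    clusters <- data.frame(
      contig = contigs[assign_contig],
      start = vapply(placed, function(p) p$s, numeric(1)),
      end = vapply(placed, function(p) p$e, numeric(1)),
      strand_mode = specs$strand_mode,
      cluster_id = sprintf("cl%02d", seq_len(nrow(specs))),
      read_budget = as.integer(specs$read_budget),
      major_strand = sample(c("+", "-"), nrow(specs), replace = TRUE),
      stringsAsFactors = FALSE)
  }

  # heterochromatin-like terminal block: last 15% of each contig,
  # skipped where it would collide with a planted cluster
  hc <- data.frame(contig = contigs,
                   start = as.integer(floor(lens * 0.85)), end = lens,
                   stringsAsFactors = FALSE)
  if (nrow(clusters) > 0) {
    bad <- vapply(seq_len(nrow(hc)), function(i) {
      cl <- clusters[clusters$contig == hc$contig[i], , drop = FALSE]
      any(cl$end > hc$start[i] - 2000)
    }, logical(1))
    hc <- hc[!bad, , drop = FALSE]
  }

  # gene placement in free space (outside clusters +- 1 kb margin)
  genes <- .place_genes(contigs, lens, clusters, config$n_genes)

  # TE families and insertions
  fams <- data.frame(family = sprintf("fam%02d", seq_len(config$n_te_families)),
                     consensus_length = if (config$n_te_families > 0)
                       sample(1000:6000, config$n_te_families, replace = TRUE)
                     else integer(0),
                     stringsAsFactors = FALSE)
  te <- .place_tes(contigs, lens, clusters, hc, genes, fams)

  genome <- Biostrings::DNAStringSet(vapply(lens, .rand_dna, character(1)))
  names(genome) <- contigs

  structure(list(species = "ancestor", genome = genome, genes = genes,
                 te_insertions = te, true_clusters = clusters,
                 inversion_events = data.frame(contig = character(),
                                               start = integer(),
                                               end = integer(),
                                               stringsAsFactors = FALSE),
                 te_families = fams),
            class = "species_truth")
}

# distribute genes across contigs proportionally to length and place them
# non-overlapping in space free of clusters (+- 1 kb)
.place_genes <- function(contigs, lens, clusters, n_genes) {
  out <- list()
  quota <- .proportional_quota(lens, n_genes)
  for (i in seq_along(contigs)) {
    m <- quota[i]
    if (m == 0) next
    segs <- .free_segments(lens[i],
                           clusters[clusters$contig == contigs[i], , drop = FALSE],
                           margin = 1000L)
    segs <- segs[segs$end - segs$start >= 3000, , drop = FALSE]
    if (nrow(segs) == 0) next
    seg_quota <- .proportional_quota(segs$end - segs$start, m)
    for (j in seq_len(nrow(segs))) {
      k <- seg_quota[j]
      if (k == 0) next
      slot <- (segs$end[j] - segs$start[j]) / k
      glen <- pmin(round(stats::runif(k, 500, 2000)), floor(slot) - 200L)
      glen <- pmax(glen, 300L)
      gs <- segs$start[j] + round((seq_len(k) - 1) * slot) +
        vapply(seq_len(k), function(x)
          sample(seq(0, max(1, floor(slot - glen[x] - 1))), 1), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        contig = contigs[i], start = gs, end = gs + glen,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      ortholog_group = character(), stringsAsFactors = FALSE))
  g <- do.call(rbind, out)
  g <- g[order(match(g$contig, contigs), g$start), , drop = FALSE]
  g$gene_id <- sprintf("anc_g%04d", seq_len(nrow(g)))
  g$ortholog_group <- sprintf("og%04d", seq_len(nrow(g)))
  rownames(g) <- NULL
  g
}

.proportional_quota <- function(weights, total) {
  if (total == 0 || length(weights) == 0) return(rep(0L, length(weights)))
  q <- floor(total * weights / sum(weights))
  rem <- total - sum(q)
  if (rem > 0) {
    add <- order(weights, decreasing = TRUE)[seq_len(rem)]
    q[add] <- q[add] + 1L
  }
  as.integer(q)
}

# complement of (intervals +- margin) within [0, len)
.free_segments <- function(len, intervals, margin = 0L) {
  if (nrow(intervals) == 0)
    return(data.frame(start = 0L, end = len))
  iv <- intervals[order(intervals$start), , drop = FALSE]
  s <- pmax(0L, iv$start - margin); e <- pmin(len, iv$end + margin)
  segs <- data.frame(start = c(0L, e), end = c(s, len))
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

# tile part of [s,e) with non-overlapping insertions reaching target_frac
.fill_with_tes <- function(contig, s, e, target_frac, fams, div_mean, div_sd) {
  rows <- list(); pos <- s; filled <- 0; span <- e - s
  while (filled / span < target_frac && pos < e - 300) {
    gap <- round(stats::runif(1, 50, 0.35 * span * (1 - target_frac) /
                                max(1, span / 1200) + 200))
    pos <- pos + gap
    len <- round(stats::runif(1, 300, 2500))
    if (pos + len > e) len <- e - pos
    if (len < 150) break
    rows[[length(rows) + 1]] <- data.frame(
      contig = contig, start = pos, end = pos + len,
      strand = sample(c("+", "-"), 1),
      family = sample(fams$family, 1),
      divergence_pct = max(0, stats::rnorm(1, div_mean, div_sd)),
      full_length = stats::runif(1) < 0.2, stringsAsFactors = FALSE)
    pos <- pos + len
    filled <- filled + len
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

.place_tes <- function(contigs, lens, clusters, hc, genes, fams) {
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), family = character(),
                      divergence_pct = numeric(), full_length = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(fams) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(clusters)))   # young, dense cluster repeats
    out[[length(out) + 1]] <- .fill_with_tes(
      clusters$contig[i], clusters$start[i], clusters$end[i], 0.6, fams, 3, 1)
  for (i in seq_len(nrow(hc)))         # intermediate-age terminal blocks
    out[[length(out) + 1]] <- .fill_with_tes(
      hc$contig[i], hc$start[i], hc$end[i], 0.45, fams, 8, 1.5)
  # dispersed old euchromatic background, avoiding genes/clusters/hc
  for (i in seq_along(contigs)) {
    blocked <- rbind(
      clusters[clusters$contig == contigs[i], c("start", "end"), drop = FALSE],
      hc[hc$contig == contigs[i], c("start", "end"), drop = FALSE],
      genes[genes$contig == contigs[i], c("start", "end"), drop = FALSE])
    blocked$contig <- contigs[i]
    segs <- .free_segments(lens[i], blocked, margin = 1000L)
    for (j in seq_len(nrow(segs))) {
      if (segs$end[j] - segs$start[j] < 4000) next
      out[[length(out) + 1]] <- .fill_with_tes(
        contigs[i], segs$start[j], segs$end[j], 0.05, fams, 15, 2)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  te <- do.call(rbind, out)
  te <- te[order(match(te$contig, contigs), te$start), , drop = FALSE]
  rownames(te) <- NULL
  te
}

# hotspot windows: up to 1 kb immediately outside each planted cluster
# border, intersected with feature-free space
.hotspot_windows <- function(truth, width = 1000L) {
  cl <- truth$true_clusters
  if (nrow(cl) == 0) return(.empty_intervals())
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    clen <- Biostrings::width(truth$genome[cl$contig[i]])
    rows[[length(rows) + 1]] <- data.frame(
      contig = cl$contig[i],
      start = c(max(0L, cl$start[i] - width), cl$end[i]),
      end = c(cl$start[i], min(clen, cl$end[i] + width)),
      stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, rows)
  w[w$end > w$start, , drop = FALSE]
}

# apply one inversion of [b1,b2) to a species_truth; features are assumed
# never to straddle b1/b2 (breakpoints are sampled in feature-free gaps)
.apply_inversion <- function(truth, contig, b1, b2) {
  seq <- truth$genome[[contig]]
  inv <- Biostrings::reverseComplement(Biostrings::subseq(seq, b1 + 1, b2))
  Biostrings::subseq(seq, b1 + 1, b2) <- inv
  truth$genome[[contig]] <- seq
  flipmap <- function(df, has_strand = TRUE) {
    if (nrow(df) == 0) return(df)
    idx <- which(df$contig == contig & df$start >= b1 & df$end <= b2)
    if (length(idx) > 0) {
      s <- df$start[idx]; e <- df$end[idx]
      df$start[idx] <- b1 + b2 - e
      df$end[idx] <- b1 + b2 - s
      if (has_strand && "strand" %in% names(df))
        df$strand[idx] <- ifelse(df$strand[idx] == "+", "-", "+")
      if ("major_strand" %in% names(df))
        df$major_strand[idx] <- ifelse(df$major_strand[idx] == "+", "-", "+")
    }
    df[order(match(df$contig, names(truth$genome)), df$start), , drop = FALSE]
  }
  truth$genes <- flipmap(truth$genes)
  truth$te_insertions <- flipmap(truth$te_insertions)
  truth$true_clusters <- flipmap(truth$true_clusters)
  truth$inversion_events <- rbind(truth$inversion_events,
                                  data.frame(contig = contig, start = b1,
                                             end = b2, stringsAsFactors = FALSE))
  truth
}

# sample a breakpoint position from feature-free gaps; `within` optionally
# restricts to given windows (hotspots)
.safe_gaps <- function(truth, contig) {
  clen <- Biostrings::width(truth$genome[contig])
  feats <- rbind(truth$genes[truth$genes$contig == contig,
                             c("contig", "start", "end"), drop = FALSE],
                 truth$te_insertions[truth$te_insertions$contig == contig,
                                     c("contig", "start", "end"), drop = FALSE],
                 truth$true_clusters[truth$true_clusters$contig == contig,
                                     c("contig", "start", "end"), drop = FALSE])
  .free_segments(clen, feats)
}

.sample_pos_in <- function(segs) {
  w <- segs$end - segs$start
  j <- sample.int(nrow(segs), 1, prob = w)
  sample(seq(segs$start[j], segs$end[j] - 1L), 1)
}

#' Evolve a synthetic ancestor along a species tree
#'
#' Walks the dated tree from root to tips; on each branch a
#' Poisson-distributed number of inversions is applied. An inversion
#' reverses a genomic segment (sequence reverse-complemented, contained
#' genes/TEs/clusters reversed in order and flipped in strand); breakpoints
#' are sampled from intergenic feature-free gaps so no gene, insertion or
#' cluster is ever split. With probability \code{hotspot_bias} both
#' breakpoints are drawn from hotspot windows flanking planted cluster
#' borders, emulating recurrent rearrangement at cluster loci.
#'
#' @param ancestor output of \code{\link{generate_ancestor}}.
#' @param config the same \code{\link{world_config}}.
#' @return list with \code{species} (named list of \code{species_truth},
#'   one per tree tip), \code{ortholog_map} (data.frame species, gene_id,
#'   ortholog_group) and \code{tree}.
#' @export
evolve_species <- function(ancestor, config) {
  stopifnot(inherits(ancestor, "species_truth"),
            inherits(config, "world_config"))
  set.seed((config$seed * 373L + 7919L) %% 2147483647L)
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- list(); states[[root]] <- ancestor
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    st <- states[[par]]
    n_inv <- stats::rpois(1, config$inversion_rate)
    for (v in seq_len(n_inv)) {
      use_hot <- stats::runif(1) < config$hotspot_bias
      bp <- .draw_breakpoints(st, use_hot)
      if (is.null(bp)) next
      st <- .apply_inversion(st, bp$contig, bp$b1, bp$b2)
    }
    states[[child]] <- st
  }
  species <- list()
  omap <- list()
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    st <- states[[i]]
    st$species <- sp
    if (nrow(st$genes) > 0)
      st$genes$gene_id <- sprintf("%s_%s", sp, sub("^anc_", "", st$genes$gene_id))
    species[[sp]] <- st
    omap[[sp]] <- data.frame(species = sp, gene_id = st$genes$gene_id,
                             ortholog_group = st$genes$ortholog_group,
                             stringsAsFactors = FALSE)
  }
  omap <- do.call(rbind, omap)
  rownames(omap) <- NULL
  list(species = species, ortholog_map = omap, tree = config$tree)
}

.draw_breakpoints <- function(truth, use_hotspots) {
  contigs <- names(truth$genome)
  if (use_hotspots) {
    hot <- .hotspot_windows(truth)
    if (nrow(hot) > 0) {
      # restrict hotspot windows to feature-free space
      safe <- do.call(rbind, lapply(unique(hot$contig), function(ct) {
        g <- .safe_gaps(truth, ct)
        h <- hot[hot$contig == ct, , drop = FALSE]
        ir <- IRanges::findOverlaps(.as_ir(h), .as_ir(g))
        if (length(ir) == 0) return(NULL)
        ph <- h[S4Vectors::queryHits(ir), , drop = FALSE]
        pg <- g[S4Vectors::subjectHits(ir), , drop = FALSE]
        data.frame(contig = ct, start = pmax(ph$start, pg$start),
                   end = pmin(ph$end, pg$end), stringsAsFactors = FALSE)
      }))
      safe <- safe[!is.na(safe$start) & safe$end > safe$start, , drop = FALSE]
      tab <- table(safe$contig)
      ok <- names(tab)[tab >= 2]
      if (length(ok) > 0) {
        ct <- if (length(ok) == 1) ok else sample(ok, 1)
        segs <- safe[safe$contig == ct, , drop = FALSE]
        two <- sample.int(nrow(segs), 2, prob = segs$end - segs$start)
        p1 <- .sample_pos_in(segs[two[1], , drop = FALSE])
        p2 <- .sample_pos_in(segs[two[2], , drop = FALSE])
        return(list(contig = ct, b1 = min(p1, p2), b2 = max(p1, p2)))
      }
    }
    # no usable hotspots: fall through to uniform placement
  }
  ct <- sample(contigs, 1, prob = Biostrings::width(truth$genome))
  gaps <- .safe_gaps(truth, ct)
  if (nrow(gaps) < 2) return(NULL)
  two <- sample.int(nrow(gaps), 2, prob = gaps$end - gaps$start)
  p1 <- .sample_pos_in(gaps[two[1], , drop = FALSE])
  p2 <- .sample_pos_in(gaps[two[2], , drop = FALSE])
  list(contig = ct, b1 = min(p1, p2), b2 = max(p1, p2))
}

#' Simulate small-RNA reads from planted piRNA clusters
#'
#' Draws 23-29 nt reads from each planted cluster up to its read budget.
#' A fraction \code{u1_bias} of cluster reads start at genomic positions
#' giving a 5' U; in dual-strand clusters a fraction
#' \code{pingpong_fraction} of the budget is emitted as opposite-strand
#' pairs whose 5' ends overlap by exactly 10 nt (the responder read then
#' carries the complementary 10A). Uni-strand clusters emit
#' \code{uni_share} of reads from their major strand. Noise reads are
#' uniform over the genome. Total read count is exactly
#' \code{sum(read_budget) + round(noise_fraction * sum(read_budget))}.
#'
#' @param truth a \code{species_truth} with planted clusters.
#' @param pingpong_fraction fraction of dual-cluster reads emitted as
#'   10-nt-overlap ping-pong pairs; must lie in [0, 1].
#' @param u1_bias probability a cluster read is forced to begin with U.
#' @param noise_fraction noise reads as a fraction of the cluster budget.
#' @param uni_share strand share of the major strand in uni clusters.
#' @param seed integer seed.
#' @return list with \code{reads} (data.frame read_id, sequence, copies)
#'   and \code{truth} (read_id, origin, contig, start, end, strand).
#' @export
simulate_small_rna <- function(truth, pingpong_fraction = 0.3, u1_bias = 0.75,
                               noise_fraction = 0.05, uni_share = 0.98,
                               seed = 1L) {
  stopifnot(inherits(truth, "species_truth"))
  if (pingpong_fraction < 0 || pingpong_fraction > 1)
    stop("pingpong_fraction must be in [0, 1]")
  if (u1_bias < 0 || u1_bias > 1) stop("u1_bias must be in [0, 1]")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  cl <- truth$true_clusters
  if (nrow(cl) == 0) stop("no planted clusters in this species_truth")
  set.seed(seed)
  chars <- lapply(as.character(truth$genome), function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    ct <- cl$contig[i]; s <- cl$start[i]; e <- cl$end[i]
    budget <- cl$read_budget[i]
    bs <- chars[[ct]]
    t5 <- which(bs == "T") - 1L   # plus-strand 5' positions giving 1U
    a5 <- which(bs == "A") - 1L   # minus-strand 5' positions giving 1U
    n_pairs <- if (cl$strand_mode[i] == "dual")
      floor(pingpong_fraction * budget / 2) else 0L
    if (n_pairs > 0) {
      # initiator 5' at p (1U needs T), responder 5' at p+9 (1U needs A);
      # the same constraint gives the initiator its 10A
      pp <- intersect(t5, a5 - 9L)
      pool <- pp[pp >= s + 19 & pp <= e - 31]
      unif <- seq(s + 19, e - 31)
      p <- .biased_draw(n_pairs, u1_bias, pool, unif)
      l1 <- sample(23:29, n_pairs, replace = TRUE)
      l2 <- sample(23:29, n_pairs, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        origin = cl$cluster_id[i], contig = ct,
        start = p, end = p + l1, strand = "+", stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        origin = cl$cluster_id[i], contig = ct,
        start = p + 10L - l2, end = p + 10L, strand = "-",
        stringsAsFactors = FALSE)
    }
    n_single <- budget - 2L * n_pairs
    if (n_single > 0) {
      if (cl$strand_mode[i] == "uni") {
        maj <- cl$major_strand[i]
        strands <- ifelse(stats::runif(n_single) < uni_share, maj,
                          setdiff(c("+", "-"), maj))
      } else {
        strands <- sample(c("+", "-"), n_single, replace = TRUE)
      }
      L <- sample(23:29, n_single, replace = TRUE)
      is_p <- strands == "+"
      p <- integer(n_single)
      if (any(is_p))
        p[is_p] <- .biased_draw(sum(is_p), u1_bias,
                                t5[t5 >= s & t5 <= e - 29], seq(s, e - 29))
      if (any(!is_p)) {
        q <- .biased_draw(sum(!is_p), u1_bias,
                          a5[a5 >= s + 28 & a5 <= e - 1], seq(s + 28, e - 1))
        p[!is_p] <- q - L[!is_p] + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        origin = cl$cluster_id[i], contig = ct,
        start = p, end = p + L, strand = strands, stringsAsFactors = FALSE)
    }
  }
  n_noise <- round(noise_fraction * sum(cl$read_budget))
  if (n_noise > 0) {
    clens <- Biostrings::width(truth$genome)
    ci <- sample(seq_along(clens), n_noise, replace = TRUE, prob = clens)
    L <- sample(23:29, n_noise, replace = TRUE)
    p <- vapply(seq_len(n_noise), function(k)
      sample(seq(0L, clens[ci[k]] - L[k]), 1), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      origin = "noise", contig = names(truth$genome)[ci],
      start = p, end = p + L,
      strand = sample(c("+", "-"), n_noise, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$read_id <- sprintf("%s_r%06d", truth$species, seq_len(nrow(tab)))
  seqs <- vapply(seq_len(nrow(tab)), function(k) {
    sub <- paste(chars[[tab$contig[k]]][(tab$start[k] + 1):tab$end[k]],
                 collapse = "")
    if (tab$strand[k] == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    sub
  }, character(1))
  list(reads = data.frame(read_id = tab$read_id, sequence = seqs,
                          copies = 1L, stringsAsFactors = FALSE),
       truth = tab[, c("read_id", "origin", "contig", "start", "end", "strand")])
}

# draw n positions: with prob `bias` from `pool` (1U-compatible starts),
# otherwise uniform from `unif`; falls back to uniform if pool is empty
.biased_draw <- function(n, bias, pool, unif) {
  useb <- stats::runif(n) < bias & length(pool) > 0
  out <- integer(n)
  if (any(useb)) out[useb] <- sample(pool, sum(useb), replace = TRUE)
  if (any(!useb)) out[!useb] <- sample(unif, sum(!useb), replace = TRUE)
  out
}

#' Simulate whole-genome DNA-seq family read counts
#'
#' Per transposon family, paired-end read counts are Poisson-distributed
#' around total family base pairs times coverage divided by 300 (the base
#' pairs contributed by one 150 nt paired-end read pair), the quantity the
#' genomic copy-number estimator inverts.
#'
#' @param truth a \code{species_truth} with TE insertions.
#' @param coverage_depth mean genomic coverage (x); must be > 0.
#' @param seed integer seed.
#' @return data.frame family, genomic_bp, consensus_length, read_count,
#'   coverage_depth.
#' @export
simulate_te_dnaseq <- function(truth, coverage_depth = 30, seed = 1L) {
  stopifnot(inherits(truth, "species_truth"))
  if (coverage_depth <= 0) stop("coverage_depth must be > 0")
  te <- truth$te_insertions
  if (nrow(te) == 0) stop("no TE insertions in this species_truth")
  set.seed(seed)
  bp <- tapply(te$end - te$start, te$family, sum)
  fam <- truth$te_families
  fam <- fam[fam$family %in% names(bp), , drop = FALSE]
  gbp <- as.numeric(bp[fam$family])
  data.frame(family = fam$family, genomic_bp = gbp,
             consensus_length = fam$consensus_length,
             read_count = stats::rpois(nrow(fam), gbp * coverage_depth / 300),
             coverage_depth = coverage_depth, stringsAsFactors = FALSE)
}
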