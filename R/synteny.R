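#' Extract ortholog-tagged flanking gene arrays of a cluster
#'
#' Collects the genes lying wholly within \code{span} bp upstream and
#' downstream of the cluster borders, ordered outward from the border
#' (innermost gene first). A flank truncated by a contig end is returned
#' as-is and flagged.
#'
#' @param cluster one-row data.frame (contig, start, end).
#' @param gene_annotation gene data.frame with \code{ortholog_group}.
#' @param contig_lengths named vector of contig lengths.
#' @param span flank span in bp (default 200 kb).
#' @return list with \code{left}, \code{right} (gene data.frames with a
#'   \code{distance} column, innermost first) and truncation flags.
#' @export
extract_flanks <- function(cluster, gene_annotation, contig_lengths,
                           span = 200000L) {
  stopifnot("ortholog_group" %in% names(gene_annotation))
  g <- gene_annotation[gene_annotation$contig == cluster$contig, ,
                       drop = FALSE]
  lo <- cluster$start - span
  hi <- cluster$end + span
  left <- g[g$start >= max(0, lo) & g$end <= cluster$start, , drop = FALSE]
  right <- g[g$start >= cluster$end &
               g$end <= min(contig_lengths[[cluster$contig]], hi), ,
             drop = FALSE]
  left$distance <- cluster$start - left$end
  right$distance <- right$start - cluster$end
  left <- left[order(left$distance), , drop = FALSE]
  right <- right[order(right$distance), , drop = FALSE]
  rownames(left) <- rownames(right) <- NULL
  list(left = left, right = right,
       left_truncated = lo < 0,
       right_truncated = hi > contig_lengths[[cluster$contig]])
}

#' Locate the homologous locus of a cluster in a subject species
#'
#' Looks up the flank genes' ortholog groups in the subject annotation
#' and proposes the interval between the innermost matched anchors.
#' Candidate placements are ranked by, in order: (1) both flanks on the
#' same subject contig, (2) innermost anchors closest to the cluster in
#' the query, (3) longest contiguous run of collinear orthologs around
#' the anchors. Ortholog groups duplicated in the subject are ignored
#' (one-to-one correspondence required).
#'
#' @param flanks output of \code{\link{extract_flanks}}.
#' @param subject_annotation subject gene data.frame with
#'   \code{ortholog_group}.
#' @return list with \code{status} (\code{"located"} or
#'   \code{"unresolved"}), \code{contig}, \code{start}, \code{end},
#'   anchors and diagnostics; locus coordinates are the span between the
#'   inner edges of the two anchor genes.
#' @export
locate_homolog <- function(flanks, subject_annotation) {
  unresolved <- list(status = "unresolved", contig = NA_character_,
                     start = NA_real_, end = NA_real_, diagnostics = "")
  sub <- subject_annotation
  dup <- names(table(sub$ortholog_group))[table(sub$ortholog_group) > 1]
  sub <- sub[!(sub$ortholog_group %in% dup), , drop = FALSE]
  lm <- sub[sub$ortholog_group %in% flanks$left$ortholog_group, ,
            drop = FALSE]
  rm_ <- sub[sub$ortholog_group %in% flanks$right$ortholog_group, ,
             drop = FALSE]
  if (nrow(lm) == 0 || nrow(rm_) == 0) {
    unresolved$diagnostics <- "flank ortholog(s) missing in subject"
    return(unresolved)
  }
  shared <- intersect(lm$contig, rm_$contig)
  if (length(shared) == 0) {
    unresolved$diagnostics <- "flanks on different subject contigs"
    return(unresolved)
  }
  cands <- lapply(shared, function(ct) {
    l <- lm[lm$contig == ct, , drop = FALSE]
    r <- rm_[rm_$contig == ct, , drop = FALSE]
    # innermost anchor: the matched gene closest to the cluster in the query
    li <- l[which.min(flanks$left$distance[match(l$ortholog_group,
                                                 flanks$left$ortholog_group)]), ]
    ri <- r[which.min(flanks$right$distance[match(r$ortholog_group,
                                                  flanks$right$ortholog_group)]), ]
    qdist <- flanks$left$distance[match(li$ortholog_group,
                                        flanks$left$ortholog_group)] +
      flanks$right$distance[match(ri$ortholog_group,
                                  flanks$right$ortholog_group)]
    run <- .collinear_run_length(flanks, sub[sub$contig == ct, , drop = FALSE])
    locus <- sort(c(min(li$end, ri$end), max(li$start, ri$start)))
    list(contig = ct, start = locus[1], end = locus[2], qdist = qdist,
         run = run, left_anchor = li$ortholog_group,
         right_anchor = ri$ortholog_group)
  })
  ord <- order(vapply(cands, `[[`, numeric(1), "qdist"),
               -vapply(cands, `[[`, numeric(1), "run"))
  best <- cands[[ord[1]]]
  list(status = "located", contig = best$contig, start = best$start,
       end = best$end, left_anchor = best$left_anchor,
       right_anchor = best$right_anchor,
       diagnostics = sprintf("%d same-contig candidate(s)", length(cands)))
}

# longest run of query-consecutive ortholog groups in subject gene order
.collinear_run_length <- function(flanks, sub_genes) {
  qorder <- c(rev(flanks$left$ortholog_group), flanks$right$ortholog_group)
  qidx <- match(sub_genes$ortholog_group[order(sub_genes$start)], qorder)
  qidx <- qidx[!is.na(qidx)]
  if (length(qidx) == 0) return(0L)
  best <- run <- 1L
  for (i in seq_along(qidx)[-1]) {
    run <- if (abs(qidx[i] - qidx[i - 1]) == 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Classify the homologous locus of a cluster in a subject species
#'
#' A located locus is an \code{active_piC} when a piRNA cluster called in
#' the subject overlaps it and passes all five activity thresholds
#' (>= 100 rpm, >= 10 rpkm, >= 5 kb, >= 25\% TE bp, <= 25\% gene bp).
#' Otherwise the flank gene arrangement decides: if the adjacency between
#' the two flank arrays is intact in the subject (the innermost left and
#' right flank genes are neighbours in collinear order) the call is
#' \code{synteny}; if that junction is disrupted the call is
#' \code{inversion_break}; when the locus could not be located the call
#' is \code{unresolved}.
#'
#' @param locus output of \code{\link{locate_homolog}}.
#' @param flanks output of \code{\link{extract_flanks}} (query side).
#' @param subject_clusters metric-filled subject cluster data.frame.
#' @param subject_annotation subject gene data.frame.
#' @param thresholds list of activity thresholds.
#' @return list with \code{status} and the subject locus coordinates.
#' @export
classify_locus <- function(locus, flanks, subject_clusters,
                           subject_annotation,
                           thresholds = list(rpm = 100, rpkm = 10,
                                             min_size = 5000,
                                             te_frac = 0.25,
                                             gene_frac = 0.25)) {
  if (locus$status != "located")
    return(list(status = "unresolved", contig = NA_character_,
                start = NA_real_, end = NA_real_))
  res <- list(contig = locus$contig, start = locus$start, end = locus$end)
  if (nrow(subject_clusters) > 0) {
    sc <- subject_clusters[subject_clusters$contig == locus$contig &
                             subject_clusters$end > locus$start &
                             subject_clusters$start < locus$end, ,
                           drop = FALSE]
    active <- nrow(sc) > 0 &&
      any(sc$rpm >= thresholds$rpm & sc$rpkm >= thresholds$rpkm &
            (sc$end - sc$start) >= thresholds$min_size &
            sc$te_bp_fraction >= thresholds$te_frac &
            sc$cds_bp_fraction <= thresholds$gene_frac)
    if (active) return(c(list(status = "active_piC"), res))
  }
  junction <- .junction_intact(flanks, subject_annotation, locus$contig)
  if (is.na(junction))
    return(list(status = "unresolved", contig = NA_character_,
                start = NA_real_, end = NA_real_))
  c(list(status = if (junction) "synteny" else "inversion_break"), res)
}

# is the adjacency between the innermost left and right flank genes
# preserved in the subject? Uses the signed permutation of shared flank
# genes: intact iff the elements bracketing the junction are adjacent
# with signed difference +1 (allowing the whole locus to be inverted).
.junction_intact <- function(flanks, subject_annotation, subject_contig) {
  qgenes <- rbind(flanks$left[rev(seq_len(nrow(flanks$left))), , drop = FALSE],
                  flanks$right)
  sub <- subject_annotation[subject_annotation$contig == subject_contig, ,
                            drop = FALSE]
  sub <- sub[order(sub$start), , drop = FALSE]
  sub <- sub[!duplicated(sub$ortholog_group) &
               !duplicated(sub$ortholog_group, fromLast = TRUE), ,
             drop = FALSE]
  shared <- intersect(qgenes$ortholog_group, sub$ortholog_group)
  kq <- sum(flanks$left$ortholog_group %in% shared)
  if (kq == 0 || !any(flanks$right$ortholog_group %in% shared))
    return(NA)
  perm <- build_signed_permutation(sub[, c("ortholog_group", "strand")],
                                   qgenes[, c("ortholog_group", "strand")])
  k <- kq  # query index of the innermost shared left-flank gene
  pos_k <- which(abs(perm) == k)
  pos_k1 <- which(abs(perm) == k + 1)
  if (abs(pos_k - pos_k1) != 1) return(FALSE)
  lo <- min(pos_k, pos_k1)
  perm[lo + 1] - perm[lo] == 1
}

#' All pairwise synteny calls of a species set
#'
#' For every ordered pair of species (S species give S*(S-1) pairs) and
#' every top cluster of the query species, extracts flanks, locates the
#' homologous locus in the subject and classifies it.
#'
#' @param species_data named list; each element a list with
#'   \code{clusters} (metric-filled, ranked), \code{genes} and
#'   \code{contig_lengths}.
#' @param span flank span (bp).
#' @param thresholds activity thresholds, see
#'   \code{\link{classify_locus}}.
#' @return data.frame of synteny calls (query, subject, cluster_id,
#'   status, subject locus coordinates).
#' @export
pairwise_table <- function(species_data, span = 200000L,
                           thresholds = list(rpm = 100, rpkm = 10,
                                             min_size = 5000,
                                             te_frac = 0.25,
                                             gene_frac = 0.25)) {
  sp <- names(species_data)
  rows <- list()
  for (q in sp) for (s in setdiff(sp, q)) {
    qd <- species_data[[q]]; sd_ <- species_data[[s]]
    if (is.null(qd) || is.null(sd_)) {
      warning(sprintf("missing data for pair %s-%s; skipped", q, s))
      next
    }
    cl <- qd$clusters
    for (i in seq_len(nrow(cl))) {
      fl <- extract_flanks(cl[i, ], qd$genes, qd$contig_lengths, span)
      loc <- locate_homolog(fl, sd_$genes)
      call <- classify_locus(loc, fl, sd_$clusters, sd_$genes, thresholds)
      rows[[length(rows) + 1]] <- data.frame(
        query = q, subject = s,
        cluster_id = if ("cluster_id" %in% names(cl)) cl$cluster_id[i]
        else sprintf("%s_c%02d", q, i),
        query_contig = cl$contig[i], query_start = cl$start[i],
        query_end = cl$end[i],
        status = call$status, subject_contig = call$contig,
        subject_start = call$start, subject_end = call$end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(query = character(), subject = character(),
                      cluster_id = character(), query_contig = character(),
                      query_start = numeric(), query_end = numeric(),
                      status = character(), subject_contig = character(),
                      subject_start = numeric(), subject_end = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Link pairwise synteny calls into cross-species homology groups
#'
#' Builds a graph whose nodes are loci (the query cluster locus and every
#' resolved subject locus); edges connect the two loci of each call and
#' any two same-species loci that overlap by at least one base pair.
#' Connected components are the homology groups.
#'
#' @param calls data.frame from \code{\link{pairwise_table}}.
#' @return data.frame with group, species, contig, start, end, active
#'   (whether the species shows an active cluster at the locus).
#' @export
link_groups <- function(calls) {
  nodes <- list()
  edges <- list()
  key <- function(sp, ct, s, e) sprintf("%s:%s:%d-%d", sp, ct, round(s),
                                        round(e))
  add_node <- function(sp, ct, s, e, active) {
    k <- key(sp, ct, s, e)
    if (is.null(nodes[[k]]))
      nodes[[k]] <<- list(species = sp, contig = ct, start = s, end = e,
                          active = active)
    else nodes[[k]]$active <<- nodes[[k]]$active || active
    k
  }
  for (i in seq_len(nrow(calls))) {
    qk <- add_node(calls$query[i], calls$query_contig[i],
                   calls$query_start[i], calls$query_end[i], TRUE)
    if (calls$status[i] %in% c("active_piC", "synteny")) {
      sk <- add_node(calls$subject[i], calls$subject_contig[i],
                     calls$subject_start[i], calls$subject_end[i],
                     calls$status[i] == "active_piC")
      edges[[length(edges) + 1]] <- c(qk, sk)
    }
  }
  if (length(nodes) == 0)
    return(data.frame(group = integer(), species = character(),
                      contig = character(), start = numeric(),
                      end = numeric(), active = logical()))
  ndf <- do.call(rbind, lapply(names(nodes), function(k)
    data.frame(name = k, species = nodes[[k]]$species,
               contig = nodes[[k]]$contig, start = nodes[[k]]$start,
               end = nodes[[k]]$end, active = nodes[[k]]$active,
               stringsAsFactors = FALSE)))
  # same-species overlapping loci are the same locus
  for (sp in unique(ndf$species)) {
    sub <- ndf[ndf$species == sp, , drop = FALSE]
    for (ct in unique(sub$contig)) {
      ss <- sub[sub$contig == ct, , drop = FALSE]
      if (nrow(ss) < 2) next
      hits <- IRanges::findOverlaps(.as_ir(ss), .as_ir(ss))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      for (j in which(qh < sh))
        edges[[length(edges) + 1]] <- c(ss$name[qh[j]], ss$name[sh[j]])
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (length(edges) > 0)
      as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character()),
    vertices = ndf, directed = FALSE)
  comp <- igraph::components(g)
  ndf$group <- comp$membership[ndf$name]
  out <- ndf[order(ndf$group, ndf$species), c("group", "species", "contig",
                                              "start", "end", "active")]
  rownames(out) <- NULL
  out
}

#' Assign an evolutionary age to a homology group
#'
#' The age is the divergence time (My) of the most recent common
#' ancestor of all species where the locus is an active piRNA cluster;
#' a group active in a single species is species-specific (age 0).
#'
#' @param group data.frame rows of one group from
#'   \code{\link{link_groups}}.
#' @param tree dated \code{ape::phylo}; tip labels must cover the group's
#'   species.
#' @return list with \code{age_My} and \code{category}
#'   (\code{"species_specific"} or \code{"conserved"}).
#' @export
assign_age <- function(group, tree) {
  active_sp <- unique(group$species[group$active])
  missing <- setdiff(unique(group$species), tree$tip.label)
  if (length(missing) > 0)
    stop(sprintf("species absent from tree: %s",
                 paste(missing, collapse = ", ")))
  if (length(active_sp) <= 1)
    return(list(age_My = 0, category = "species_specific"))
  mrca <- ape::getMRCA(tree, active_sp)
  bt <- ape::branching.times(tree)
  list(age_My = unname(bt[as.character(mrca)]),
       category = "conserved")
}
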