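# small deterministic gene layout: 5 genes each side of a cluster at
# [250000, 300000) on a 800 kb contig, so both 200 kb flank spans fit
.toy_genes <- function(contig = "chr1", offset = 0) {
  data.frame(contig = contig,
             start = offset + 150000 + c(1:5 * 10000, 200000 + 1:5 * 10000),
             end = offset + 150000 + c(1:5 * 10000 + 2000,
                                       200000 + 1:5 * 10000 + 2000),
             strand = rep("+", 10),
             gene_id = sprintf("g%02d", 1:10),
             ortholog_group = sprintf("og%02d", 1:10),
             stringsAsFactors = FALSE)
}
.toy_cluster <- function() data.frame(contig = "chr1", start = 250000,
                                      end = 300000)

test_that("flank extraction keeps genes wholly within the span, ordered outward", {
  genes <- .toy_genes()
  clens <- c(chr1 = 800000)
  fl <- extract_flanks(.toy_cluster(), genes, clens)
  expect_equal(nrow(fl$left), 5)
  expect_equal(nrow(fl$right), 5)
  expect_equal(fl$left$ortholog_group[1], "og05")    # innermost first
  expect_equal(fl$right$ortholog_group[1], "og06")
  expect_false(fl$left_truncated || fl$right_truncated)

  # cluster at position 0: empty left flank, flagged
  cl0 <- data.frame(contig = "chr1", start = 0, end = 5000)
  fl0 <- extract_flanks(cl0, genes, clens)
  expect_equal(nrow(fl0$left), 0)
  expect_true(fl0$left_truncated)

  # a gene straddling the span limit is excluded (wholly-within rule)
  g2 <- rbind(genes, data.frame(contig = "chr1", start = 490000,
                                end = 510000, strand = "+",
                                gene_id = "gX", ortholog_group = "ogX"))
  fl2 <- extract_flanks(.toy_cluster(), g2, clens)  # span ends at 500000
  expect_false("ogX" %in% fl2$right$ortholog_group)
})

test_that("homolog location follows the ranked placement preferences", {
  genes <- .toy_genes()
  clens <- c(chr1 = 800000)
  fl <- extract_flanks(.toy_cluster(), genes, clens)

  # identity: the unrearranged subject returns the inter-anchor interval
  loc <- locate_homolog(fl, genes)
  expect_equal(loc$status, "located")
  expect_equal(loc$contig, "chr1")
  expect_equal(loc$start, 202000)  # end of innermost left gene og05
  expect_equal(loc$end, 360000)    # start of innermost right gene og06

  # preference 1: a single-contig placement beats split flanks
  split <- genes
  split$contig <- ifelse(genes$ortholog_group %in% c("og05", "og06"),
                         c("cA", "cB")[match(genes$ortholog_group,
                                             c("og05", "og06"))], "cC")
  locp <- locate_homolog(fl, split)
  expect_equal(locp$contig, "cC")

  # preference 2: anchors nearest the query cluster win
  outer_only <- genes[genes$ortholog_group %in%
                        c("og01", "og02", "og09", "og10"), ]
  outer_only$contig <- "far"
  inner_only <- genes[genes$ortholog_group %in% c("og05", "og06"), ]
  inner_only$contig <- "near"
  locn <- locate_homolog(fl, rbind(outer_only, inner_only))
  expect_equal(locn$contig, "near")

  # no resolvable flank gene: unresolved
  none <- genes; none$ortholog_group <- paste0("zz", 1:10)
  expect_equal(locate_homolog(fl, none)$status, "unresolved")
})

test_that("locus classification separates active, synteny and inversion break", {
  genes <- .toy_genes()
  clens <- c(chr1 = 800000)
  fl <- extract_flanks(.toy_cluster(), genes, clens)
  loc <- locate_homolog(fl, genes)
  no_clusters <- data.frame(contig = character(), start = numeric(),
                            end = numeric(), rpm = numeric(),
                            rpkm = numeric(), te_bp_fraction = numeric(),
                            cds_bp_fraction = numeric())

  # all five thresholds met: active piRNA cluster
  active <- data.frame(contig = "chr1", start = 250000, end = 256000,
                       rpm = 150, rpkm = 12, te_bp_fraction = 0.4,
                       cds_bp_fraction = 0.1)
  expect_equal(classify_locus(loc, fl, active, genes)$status, "active_piC")

  # one threshold failing in turn: not active, collinear flanks -> synteny
  for (col in c("rpm", "rpkm", "te_bp_fraction")) {
    weak <- active
    weak[[col]] <- c(rpm = 99, rpkm = 9, te_bp_fraction = 0.2)[[col]]
    expect_equal(classify_locus(loc, fl, weak, genes)$status, "synteny")
  }
  geney <- active; geney$cds_bp_fraction <- 0.3
  expect_equal(classify_locus(loc, fl, geney, genes)$status, "synteny")
  small <- active; small$end <- small$start + 4000   # below 5 kb floor
  expect_equal(classify_locus(loc, fl, small, genes)$status, "synteny")

  # collinear flanks with no piRNA signal at all
  expect_equal(classify_locus(loc, fl, no_clusters, genes)$status, "synteny")

  # a whole-locus inversion in the subject still preserves the junction
  inv_all <- genes
  inv_all[, c("start", "end")] <- 800000 - inv_all[, c("end", "start")]
  inv_all$strand <- "-"
  inv_all <- inv_all[order(inv_all$start), ]
  loc2 <- locate_homolog(fl, inv_all)
  expect_equal(classify_locus(loc2, fl, no_clusters, inv_all)$status,
               "synteny")

  # an inversion with one breakpoint between the flank arrays breaks the
  # junction (og05 is pulled away from og06)
  broken <- genes
  seg <- broken$ortholog_group %in% c("og03", "og04", "og05")
  a <- min(broken$start[seg]); b <- max(broken$end[seg])
  ns <- a + b - broken$end[seg]; ne <- a + b - broken$start[seg]
  broken$start[seg] <- ns; broken$end[seg] <- ne
  broken$strand[seg] <- "-"
  broken <- broken[order(broken$start), ]
  loc3 <- locate_homolog(fl, broken)
  expect_equal(classify_locus(loc3, fl, no_clusters, broken)$status,
               "inversion_break")
})

test_that("the pairwise table enumerates S(S-1) ordered pairs", {
  mk_species <- function(sp) {
    list(clusters = data.frame(contig = "chr1", start = 250000, end = 300000,
                               cluster_id = paste0(sp, "_c1"), rpm = 200,
                               rpkm = 20, te_bp_fraction = 0.5,
                               cds_bp_fraction = 0),
         genes = .toy_genes(),
         contig_lengths = c(chr1 = 800000))
  }
  ten <- setNames(lapply(sprintf("s%02d", 1:10), mk_species),
                  sprintf("s%02d", 1:10))
  calls <- pairwise_table(ten)
  expect_equal(nrow(calls), 90)
  expect_equal(nrow(unique(calls[, c("query", "subject")])), 90)
  expect_true(all(calls$status == "active_piC"))

  two <- ten[1:2]
  expect_equal(nrow(pairwise_table(two)), 2)
  one <- ten[1]
  expect_equal(nrow(pairwise_table(one)), 0)
})

test_that("homology groups link overlapping loci transitively", {
  base <- data.frame(query_contig = "chr1", query_start = 100000,
                     query_end = 150000, subject_contig = "chr1",
                     subject_start = 95000, subject_end = 155000,
                     status = "active_piC", stringsAsFactors = FALSE)
  ab <- cbind(query = "A", subject = "B", cluster_id = "A_c1", base)
  ba <- cbind(query = "B", subject = "A", cluster_id = "B_c1", base)
  g <- link_groups(rbind(ab, ba))
  expect_equal(length(unique(g$group)), 1)

  # chained A<->B, B<->C gives one group of three species
  bc <- cbind(query = "B", subject = "C", cluster_id = "B_c1", base)
  g3 <- link_groups(rbind(ab, ba, bc))
  expect_equal(length(unique(g3$group)), 1)
  expect_setequal(unique(g3$species), c("A", "B", "C"))

  # non-overlapping loci stay separate
  far <- ab
  far$cluster_id <- "A_c2"
  far[, c("query_start", "query_end")] <- c(400000, 450000)
  far[, c("subject_start", "subject_end")] <- c(400000, 450000)
  g4 <- link_groups(rbind(ab, far))
  expect_equal(length(unique(g4$group)), 2)
})

test_that("group ages are MRCA divergence times", {
  tree <- ape::read.tree(text = "((A:1.9,B:1.9):5.4,C:7.3);")
  two <- data.frame(group = 1, species = c("A", "B"), contig = "c",
                    start = 0, end = 10, active = TRUE)
  a <- assign_age(two, tree)
  expect_equal(a$age_My, 1.9)
  expect_equal(a$category, "conserved")

  solo <- two[1, ]
  expect_equal(assign_age(solo, tree)$category, "species_specific")
  expect_equal(assign_age(solo, tree)$age_My, 0)

  all3 <- data.frame(group = 1, species = c("A", "B", "C"), contig = "c",
                     start = 0, end = 10, active = TRUE)
  expect_equal(assign_age(all3, tree)$age_My, 7.3)

  # inactive members do not push the age up
  mixed <- all3; mixed$active <- c(TRUE, TRUE, FALSE)
  expect_equal(assign_age(mixed, tree)$age_My, 1.9)

  bad <- data.frame(group = 1, species = "Z", contig = "c", start = 0,
                    end = 1, active = TRUE)
  expect_error(assign_age(bad, tree), "absent")
})

test_that("unrearranged clades give perfect identity recovery", {
  cfg <- world_config(n_species = 3, inversion_rate = 0, seed = 77)
  anc <- generate_ancestor(cfg)
  world <- evolve_species(anc, cfg)
  clens <- setNames(Biostrings::width(anc$genome), names(anc$genome))
  sdata <- lapply(world$species, function(st)
    list(clusters = cbind(st$true_clusters[, c("contig", "start", "end")],
                          cluster_id = st$true_clusters$cluster_id,
                          rpm = 500, rpkm = 50, te_bp_fraction = 0.6,
                          cds_bp_fraction = 0),
         genes = st$genes, contig_lengths = clens))
  calls <- pairwise_table(sdata)
  expect_equal(nrow(calls), 6 * nrow(anc$true_clusters))
  expect_true(all(calls$status == "active_piC"))
  # every locus call overlaps the planted cluster in the subject
  planted <- anc$true_clusters
  for (i in seq_len(nrow(calls))) {
    p <- planted[planted$cluster_id ==
                   sub("^sp\\d+_", "", calls$cluster_id[i]) |
                   planted$cluster_id == calls$cluster_id[i], ]
    expect_true(calls$subject_start[i] < p$end[1] + 1 &&
                  calls$subject_end[i] > p$start[1] - 1)
  }
  # cluster death on one branch: locus still collinear -> synteny
  dead <- sdata
  dead$sp2$clusters <- dead$sp2$clusters[-1, ]
  calls2 <- pairwise_table(dead)
  gone <- calls2$subject == "sp2" &
    calls2$cluster_id %in% paste0(c("sp1_", "sp3_"),
                                  sdata$sp1$clusters$cluster_id[1])
  expect_true(all(calls2$status[gone] == "synteny"))
})
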