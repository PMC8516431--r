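# helper: n reads with 5' positions uniform in [s, e) on one contig
.uniform_records <- function(n, s, e, contig = "chr1", len = 26L,
                             frac_1u = 0.4, frac_10a = 0, seed = 1) {
  if (n == 0) return(empty_records())
  set.seed(seed)
  start <- sample(seq(s, e - len), n, replace = TRUE)
  data.frame(read_id = sprintf("u%05d", seq_len(n)), contig = contig,
             start = start, end = start + len, strand = "+",
             length = len,
             first_nt = ifelse(seq_len(n) <= frac_1u * n, "T", "A"),
             tenth_nt = ifelse(seq_len(n) <= frac_10a * n, "A", "C"),
             n_genomic_hits = 1L, copies = 1L, stringsAsFactors = FALSE)
}

test_that("a dense region is called as one cluster under the Poisson null", {
  rec <- .uniform_records(500, 100000, 106000)
  aln <- make_alignment_set(rec, c(chr1 = 1000000))
  # oracle: the window null rejects windows in the region and nowhere else
  lambda <- 500 * 1000 / 1e6
  k_in <- 500 * 1000 / 6000
  expect_lt(ppois(k_in - 1, lambda, lower.tail = FALSE), 1e-10)
  cl <- call_clusters(aln)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$contig, "chr1")
  # spans the region (trimmed to read extents)
  expect_lt(abs(cl$start - 100000), 200)
  expect_lt(abs(cl$end - 106000), 200)
  expect_equal(cl$unique_read_count, 500)
})

test_that("composition and size floors discard candidates", {
  # same density but only 10% 1U and 10% 10A: below the 30% floor
  rec <- .uniform_records(500, 100000, 106000, frac_1u = 0.1,
                          frac_10a = 0.1)
  aln <- make_alignment_set(rec, c(chr1 = 1000000))
  expect_equal(nrow(call_clusters(aln)), 0)
  # composition exactly at the floor passes (inclusive threshold)
  rec2 <- .uniform_records(500, 100000, 106000, frac_1u = 0.3)
  expect_equal(nrow(call_clusters(make_alignment_set(rec2,
                                                     c(chr1 = 1000000)))), 1)
  # a dense 4 kb region stays below the 5 kb size floor
  rec3 <- .uniform_records(400, 100000, 104000)
  expect_equal(nrow(call_clusters(make_alignment_set(rec3,
                                                     c(chr1 = 1000000)))), 0)
  # empty alignment set
  empty <- make_alignment_set(.uniform_records(0, 0, 100),
                              c(chr1 = 1000000))
  expect_equal(nrow(call_clusters(empty)), 0)
})

test_that("raising the composition floor never increases the cluster count", {
  m <- cached_mapped_species()
  counts <- vapply(c(0.1, 0.3, 0.6, 0.9, 0.99), function(th)
    nrow(call_clusters(m$aln, cluster_call_params(min_1U_or_10A = th))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster merging follows the combined-length gap rule", {
  two <- data.frame(contig = "chr1", start = c(0, 10000),
                    end = c(6000, 16000), unique_read_count = c(10, 20))
  m <- merge_clusters(two)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 16000))
  expect_equal(m$unique_read_count, 30)

  far <- data.frame(contig = "chr1", start = c(0, 20000),
                    end = c(5000, 25000), unique_read_count = c(1, 2))
  expect_equal(nrow(merge_clusters(far)), 2)

  one <- data.frame(contig = "chr1", start = 5, end = 6000,
                    unique_read_count = 3)
  expect_identical(merge_clusters(one), one)

  # overlapping inputs are treated as gap 0 and merged
  ovl <- data.frame(contig = "chr1", start = c(0, 3000),
                    end = c(5000, 9000), unique_read_count = c(1, 1))
  expect_equal(nrow(merge_clusters(ovl)), 1)

  # merged output intervals are disjoint
  set.seed(2)
  s <- sort(sample(0:200000, 20)) ; e <- s + sample(2000:9000, 20, TRUE)
  res <- merge_clusters(data.frame(contig = "chr1", start = s, end = e,
                                   unique_read_count = 1))
  expect_true(all(res$start[-1] >= res$end[-nrow(res)]))
})

test_that("strand classification applies the strict >95% rule", {
  mk <- function(n_plus, n_minus) {
    rec <- data.frame(contig = "chr1",
                      start = seq_len(n_plus + n_minus) * 30,
                      strand = rep(c("+", "-"), c(n_plus, n_minus)))
    rec$end <- rec$start + 26L
    make_alignment_set(rec, c(chr1 = 100000))
  }
  cl <- data.frame(contig = "chr1", start = 0, end = 100000)
  expect_equal(classify_strand(cl, mk(98, 2)), "uni")
  expect_equal(classify_strand(cl, mk(50, 50)), "dual")
  expect_equal(classify_strand(cl, mk(95, 5)), "dual")   # exactly 95%: dual
  expect_equal(classify_strand(cl, mk(96, 4)), "uni")
  expect_error(classify_strand(data.frame(contig = "chrX", start = 0,
                                          end = 10), mk(5, 5)), "no reads")
})

test_that("ping-pong z-score contrasts the 10 nt overlap against background", {
  # flat signature: one plus read, minus 5' ends at every offset 1..20
  flat <- data.frame(contig = "chr1",
                     start = c(100, rep(NA, 20)), strand = c("+", rep("-", 20)))
  flat$start[2:21] <- (100 + 0:19) - 25   # minus read start so 5' = 100+o-1
  flat$end <- ifelse(flat$strand == "+", flat$start + 26L, flat$start + 26L)
  aln <- make_alignment_set(flat, c(chr1 = 10000))
  expect_equal(pingpong_z(aln), 0)

  # dominant 10 nt overlap over sparse background noise
  plus <- data.frame(contig = "chr1", start = 100 + 40 * (0:24), strand = "+")
  minus <- data.frame(contig = "chr1",
                      start = plus$start + 10L - 26L, strand = "-")
  noise <- data.frame(contig = "chr1",
                      start = c(100 + 4 - 26, 100 + 40 + 17 - 26), strand = "-")
  rec <- rbind(plus, minus, noise)
  rec$end <- rec$start + 26L
  z <- pingpong_z(make_alignment_set(rec, c(chr1 = 10000)))
  expect_gt(z, 4)

  # degenerate cases are NA, not 0: single strand, or zero background sd
  single <- plus; single$end <- single$start + 26L
  expect_true(is.na(pingpong_z(make_alignment_set(single, c(chr1 = 1e4)))))
  pure <- rbind(plus, minus); pure$end <- pure$start + 26L
  expect_true(is.na(pingpong_z(make_alignment_set(pure, c(chr1 = 1e4)))))
})

test_that("simulated ping-pong pairing yields a strong z-score", {
  m <- cached_mapped_species(pingpong_fraction = 0.5)
  dual <- m$truth$true_clusters[m$truth$true_clusters$strand_mode == "dual", ]
  for (i in seq_len(nrow(dual))) {
    z <- pingpong_z(m$aln, dual$contig[i], dual$start[i], dual$end[i])
    expect_gt(z, 3)
  }
})

test_that("cluster metrics compute expression and content at reference values", {
  rec <- .uniform_records(100, 20000, 30000)
  aln <- make_alignment_set(rec, c(chr1 = 1000000))
  aln$total_mapped <- 1e6
  cl <- data.frame(contig = "chr1", start = 20000, end = 30000)
  te <- data.frame(contig = "chr1", start = 20000, end = 30000)
  genes <- data.frame(contig = character(), start = integer(),
                      end = integer())
  out <- cluster_metrics(cl, aln, te, genes, mirna_count = 1e6,
                         total_mapped = 1e6)
  expect_equal(out$rpm, 100)
  expect_equal(out$rpkm, 10)
  expect_equal(out$te_bp_fraction, 1.0)
  expect_equal(out$cds_bp_fraction, 0)
  expect_equal(out$unique_read_count, 100)
})

test_that("ranking keeps the top n by read count with coordinate tie-breaks", {
  cl <- data.frame(contig = c("chr2", "chr1", "chr1"),
                   start = c(100, 500, 100), end = c(200, 600, 200),
                   unique_read_count = c(10, 20, 30))
  expect_equal(rank_top(cl, 20)$unique_read_count, c(30, 20, 10))
  expect_equal(rank_top(cl, 2)$unique_read_count, c(30, 20))
  ties <- data.frame(contig = c("chr2", "chr1"), start = c(1, 5),
                     end = c(10, 15), unique_read_count = c(7, 7))
  expect_equal(rank_top(ties, 2)$contig, c("chr1", "chr2"))
  expect_equal(rank_top(ties, 2)$rank, c(1, 2))
})

test_that("planted clusters are recovered and total counts are conserved", {
  m <- cached_mapped_species()
  cl <- call_clusters(m$aln)
  cl <- cluster_metrics(cl, m$aln, m$truth$te_insertions, m$truth$genes)
  planted <- m$truth$true_clusters
  jac <- vapply(seq_len(nrow(planted)), function(i) {
    same <- cl[cl$contig == planted$contig[i], , drop = FALSE]
    if (nrow(same) == 0) return(0)
    max(vapply(seq_len(nrow(same)), function(j)
      interval_jaccard(same$start[j], same$end[j],
                       planted$start[i], planted$end[i]), numeric(1)))
  }, numeric(1))
  expect_true(all(jac >= 0.5))
  # planted uni-strand clusters are classified uni
  for (i in which(planted$strand_mode == "uni")) {
    hit <- which.max(vapply(seq_len(nrow(cl)), function(j)
      interval_jaccard(cl$start[j], cl$end[j], planted$start[i],
                       planted$end[i]) *
        (cl$contig[j] == planted$contig[i]), numeric(1)))
    expect_equal(cl$type[hit], "uni")
  }
  expect_lte(sum(cl$unique_read_count), m$aln$total_mapped)
})
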