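test_that("Kimura two-parameter divergence matches the closed form", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.1, 0.05), 0.1702, tolerance = 1e-3)
  expect_equal(kimura2p(0.1, 0.05),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_error(kimura2p(0.5, 0), "saturated")
  expect_error(kimura2p(0.3, 0.5), "saturated")
  expect_error(kimura2p(-0.1, 0), "non-negative")
})

test_that("Kimura divergence recovers the true distance of simulated pairs", {
  # site-counting oracle: evolve a 40 kb sequence under the two-parameter
  # substitution process for expected distance d (transition rate alpha,
  # two transversion rates beta, kappa = alpha/beta = 2), count observed
  # transition/transversion proportions, and compare kimura2p against d
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  n <- 40000
  for (d in c(0.1, 0.2, 0.3)) {
    kappa <- 2
    beta_t <- d / (kappa + 2)       # beta*t; alpha*t = kappa*beta*t
    alpha_t <- kappa * beta_t
    # K80 site substitution probabilities at time t
    p_ts <- 0.25 + 0.25 * exp(-4 * beta_t) -
      0.5 * exp(-2 * (alpha_t + beta_t))
    p_tv <- 0.5 - 0.5 * exp(-4 * beta_t)   # both transversions combined
    anc <- sample(bases, n, replace = TRUE)
    u <- runif(n)
    der <- anc
    ts <- u < p_ts
    tv <- !ts & u < p_ts + p_tv
    der[ts] <- transition[anc[ts]]
    der[tv] <- vapply(anc[tv], function(b)
      sample(setdiff(bases, c(b, transition[[b]])), 1), character(1))
    P <- mean(der == transition[anc])
    Q <- mean(der != anc & der != transition[anc])
    expect_equal(kimura2p(P, Q), d, tolerance = 0.05)
  }
})

test_that("border content profiles separate cluster interior from flanks", {
  cl <- data.frame(contig = "chr1", start = 50000, end = 60000)
  te <- data.frame(contig = "chr1", start = 50000, end = 60000)
  genes <- data.frame(contig = character(), start = integer(),
                      end = integer())
  clens <- c(chr1 = 200000)
  prof <- border_content_profile(cl, te, genes, clens)
  expect_equal(nrow(prof), 30)  # (10000 + 5000) / 500 windows per border
  flank <- prof$offset_bp < 0
  expect_true(all(prof$te_fraction[flank] == 0))
  expect_true(all(prof$te_fraction[!flank] == 1))
  expect_true(all(prof$cds_fraction == 0))
  # profile is invariant to cluster input order
  cl2 <- rbind(cl, data.frame(contig = "chr1", start = 120000, end = 130000))
  expect_equal(border_content_profile(cl2, te, genes, clens),
               border_content_profile(cl2[2:1, ], te, genes, clens))
  # empty annotation: all-zero profile
  none <- border_content_profile(cl, genes, genes, clens)
  expect_true(all(none$te_fraction == 0))
})

test_that("divergence profiles average length-weighted window divergence", {
  clens <- c(chr1 = 200000)
  cl <- data.frame(contig = "chr1", start = 50000, end = 60000)
  te_flat <- data.frame(contig = "chr1", start = 30000, end = 80000,
                        divergence_pct = 5)
  prof <- divergence_border_profile(cl, te_flat, clens)
  expect_true(all(abs(prof$mean_divergence - 5) < 1e-9))
  # low-divergence interior vs high-divergence flanks
  te_mix <- data.frame(contig = "chr1",
                       start = c(50000, 30000, 60000),
                       end = c(60000, 50000, 80000),
                       divergence_pct = c(3, 10, 10))
  p2 <- divergence_border_profile(cl, te_mix, clens)
  expect_true(all(abs(p2$mean_divergence[p2$offset < 0] - 10) < 1e-9))
  expect_true(all(abs(p2$mean_divergence[p2$offset >= 0] - 3) < 1e-9))
  p3 <- divergence_border_profile(cl, te_mix, clens, mode = "percent_halves")
  expect_equal(nrow(p3), 20)
  expect_true(all(abs(p3$mean_divergence[p3$offset < 0] - 10) < 1e-9))
  expect_true(all(abs(p3$mean_divergence[p3$offset > 0] - 3) < 1e-9))
  # a TE-free cluster contributes nothing (windows skipped, not zeroed)
  cl2 <- rbind(cl, data.frame(contig = "chr1", start = 120000, end = 130000))
  p4 <- divergence_border_profile(cl2, te_mix, clens)
  expect_equal(p4$mean_divergence, p2$mean_divergence)
  expect_equal(p4$n, p2$n)
})

test_that("heterochromatin designation needs a dense run touching a contig end", {
  clens <- c(chr1 = 500000)
  uniform <- data.frame(contig = "chr1", start = seq(0, 490000, 10000),
                        end = seq(0, 490000, 10000) + 1000)
  part <- call_heterochromatin(uniform, clens)
  expect_true(all(part$class == "euchromatin"))

  # terminal 20% at ~3x the genomic average density
  terminal <- data.frame(contig = "chr1",
                         start = c(seq(0, 390000, 10000),
                                   seq(400000, 495000, 2500)),
                         end = c(seq(0, 390000, 10000) + 800,
                                 seq(400000, 495000, 2500) + 2000))
  p2 <- call_heterochromatin(terminal, clens)
  hc <- p2[p2$class == "heterochromatin", ]
  expect_equal(nrow(hc), 1)
  expect_equal(hc$end, 500000)
  expect_lte(hc$start, 400000)

  # the same dense block in the interior stays euchromatic
  interior <- terminal
  shift <- interior$start >= 400000
  interior$start[shift] <- interior$start[shift] - 200000
  interior$end[shift] <- interior$end[shift] - 200000
  p3 <- call_heterochromatin(interior, clens)
  expect_true(all(p3$class == "euchromatin"))

  # partition tiles every contig exactly once
  for (p in list(part, p2, p3)) {
    expect_equal(sum(p$end - p$start), 500000)
    expect_true(all(p$start[-1] == p$end[-nrow(p)]))
  }
})

test_that("strand bias correlation recovers antisense TE orientation", {
  # clusters alternate: reads all plus & TEs all minus, or the reverse
  n <- 10
  cl <- data.frame(contig = "chr1", start = (0:(n - 1)) * 20000,
                   end = (0:(n - 1)) * 20000 + 10000)
  read_plus <- rep(c(TRUE, FALSE), length.out = n)
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(contig = "chr1", start = cl$start[i] + (1:20) * 100,
               strand = ifelse(read_plus[i], "+", "-"))
  }))
  rec$end <- rec$start + 26L
  te <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(contig = "chr1", start = cl$start[i] + (1:5) * 1500,
               end = cl$start[i] + (1:5) * 1500 + 1000,
               strand = ifelse(read_plus[i], "-", "+"))
  }))
  aln <- make_alignment_set(rec, c(chr1 = 1000000))
  res <- strand_bias_correlation(cl, aln, te)
  expect_true(abs(res$r) >= 0.99)
  expect_equal(res$per_cluster$te_plus_fraction,
               1 - res$per_cluster$read_plus_fraction)

  # zero variance: r undefined
  te_same <- te; te_same$strand <- "+"
  rec_same <- rec; rec_same$strand <- "+"
  res2 <- strand_bias_correlation(cl, make_alignment_set(rec_same,
                                                         c(chr1 = 1e6)),
                                  te_same)
  expect_true(is.na(res2$r))

  # independent random fractions decorrelate
  set.seed(33)
  n2 <- 100
  cl3 <- data.frame(contig = "chr1", start = (0:(n2 - 1)) * 10000,
                    end = (0:(n2 - 1)) * 10000 + 5000)
  rec3 <- do.call(rbind, lapply(seq_len(n2), function(i)
    data.frame(contig = "chr1", start = cl3$start[i] + (1:10) * 100,
               strand = sample(c("+", "-"), 10, replace = TRUE))))
  rec3$end <- rec3$start + 26L
  te3 <- do.call(rbind, lapply(seq_len(n2), function(i)
    data.frame(contig = "chr1", start = cl3$start[i] + (1:10) * 400,
               end = cl3$start[i] + (1:10) * 400 + 300,
               strand = sample(c("+", "-"), 10, replace = TRUE))))
  res3 <- strand_bias_correlation(cl3, make_alignment_set(rec3,
                                                          c(chr1 = 2e6)),
                                  te3)
  expect_lt(abs(res3$r), 0.3)
})

test_that("divergence class summary orders cluster < HC < EC on planted data", {
  te <- data.frame(
    contig = "chr1",
    start = c(10000, 12000, 100000, 110000, 400000, 410000),
    end = c(11000, 13000, 101000, 111000, 401000, 411000),
    divergence_pct = c(3, 3.5, 15, 14, 8, 8.5))
  cl <- data.frame(contig = "chr1", start = 9000, end = 14000)
  part <- data.frame(contig = "chr1", start = c(0, 390000),
                     end = c(390000, 500000),
                     class = c("euchromatin", "heterochromatin"))
  s <- divergence_class_summary(te, cl, part)
  expect_lt(s$means[["cluster"]], s$means[["heterochromatin"]])
  expect_lt(s$means[["heterochromatin"]], s$means[["euchromatin"]])
  expect_equal(sum(s$histogram$count), nrow(te))
  # single populated class
  s2 <- divergence_class_summary(te[1:2, ], cl, part)
  expect_true(is.na(s2$means[["heterochromatin"]]))
  expect_true(is.na(s2$means[["euchromatin"]]))
  # equal divergences give identical means
  te_eq <- te; te_eq$divergence_pct <- 7
  s3 <- divergence_class_summary(te_eq, cl, part)
  expect_true(all(s3$means == 7))
})

test_that("planted divergence layering is visible in generated species", {
  w <- cached_world("default")
  anc <- w$ancestor
  clens <- setNames(Biostrings::width(anc$genome), names(anc$genome))
  part <- call_heterochromatin(anc$te_insertions, clens)
  expect_true("heterochromatin" %in% part$class)
  s <- divergence_class_summary(anc$te_insertions, anc$true_clusters, part)
  expect_lt(s$means[["cluster"]], s$means[["heterochromatin"]])
  expect_lt(s$means[["heterochromatin"]], s$means[["euchromatin"]])
})
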