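test_that("Z-score standardization and clustering recover planted archetypes", {
  z <- zscore_cluster(rbind(a = c(1, 2, 3), b = c(5, 1, 3)), k = 1)
  expect_equal(unname(z$zscores["a", ]), c(-1, 0, 1))
  # affine invariance of the standardization
  m <- matrix(rnorm(30), 10)
  z1 <- zscore_cluster(m, 2, seed = 5)$zscores
  z2 <- zscore_cluster(m * 3.7 + 11, 2, seed = 5)$zscores
  expect_equal(z1, z2)

  expect_error(zscore_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3)), 1), "a")

  # two well-separated archetypes: perfect recovery, labels by size
  set.seed(30)
  truth_lab <- rep(c(1, 2), c(60, 40))
  prof <- t(vapply(truth_lab, function(g)
    (if (g == 1) c(0, 1, 0) else c(1, 0, 1)) + rnorm(3, 0, 0.05),
    numeric(3)))
  cl <- zscore_cluster(prof, 2, seed = 7)
  expect_identical(unname(cl$labels[truth_lab == 1]), rep(1L, 60))
  expect_identical(unname(cl$labels[truth_lab == 2]), rep(2L, 40))
})

test_that("metagene binning follows the 5/22/18 layout and conserves percentages", {
  ann <- simple_annotation("tx1", len = 900L, u5 = 100L, cds = 440L)
  mk <- function(pos) data.frame(transcript_id = "tx1", pos = pos)
  expect_identical(which(metagene_profile(mk(1), ann)$counts > 0), 1L)
  # CDS relative position 0.5 -> bin 5 + floor(0.5 * 22) + 1 = 17
  expect_identical(which(metagene_profile(mk(321), ann)$counts > 0), 17L)
  # first base of the 3'UTR -> bin 28
  expect_identical(which(metagene_profile(mk(541), ann)$counts > 0), 28L)

  set.seed(40)
  mp <- metagene_profile(mk(sample(900, 3000, replace = TRUE)), ann)
  expect_equal(sum(mp$percent), 100)
  # segment lengths proportional to the bin split: near-uniform occupancy
  expect_lt(max(abs(mp$percent - 100 / 45)), 5 * sqrt(100 / 45))
  expect_identical(sum(mp$counts), 3000L)

  # non-mRNA transcripts are excluded but counted
  ann2 <- rbind(ann, data.frame(transcript_id = "nc1", gene_id = "nc1",
                                strand = "+", length = 500L, utr5_end = 0L,
                                cds_end = 0L, is_spike_in = FALSE))
  mp2 <- metagene_profile(data.frame(transcript_id = c("tx1", "nc1"),
                                     pos = c(50L, 50L)), ann2)
  expect_identical(mp2$n_excluded, 1L)
  expect_identical(mp2$n_sites, 1L)

  expect_error(metagene_profile(mk(901), ann), "outside")
})

test_that("context matrices are centered on C and recover a planted GGG motif", {
  seqs <- c(tx1 = "AAAACGGGAAAAA")
  pfm <- motif_pfm(data.frame(transcript_id = "tx1", pos = 5), seqs)
  expect_identical(unname(pfm$counts["C", "0"]), 1L)
  expect_identical(unname(pfm$counts["G", c("1", "2", "3")]), rep(1L, 3))
  expect_true(all(colSums(pfm$counts) + pfm$gaps == 1L))

  # many sites in a C-GGG context: downstream G enrichment >= 2x background
  set.seed(41)
  n <- 120
  chunks <- vapply(seq_len(n), function(i)
    paste0(paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
           "CGGG"), character(1))
  seq2 <- c(tx2 = paste(chunks, collapse = ""))
  sites <- data.frame(transcript_id = "tx2", pos = 12 * (seq_len(n) - 1) + 9)
  pfm2 <- motif_pfm(sites, seq2)
  g_down <- mean(pfm2$counts["G", c("1", "2", "3")]) / n
  g_bg <- mean(pfm2$counts["G", c("-5", "-4", "-3", "-2")]) / n
  expect_gte(g_down / g_bg, 2)

  expect_error(motif_pfm(data.frame(transcript_id = "tx1", pos = 2), seqs),
               "not a cytosine")

  # edge truncation reported as gaps
  pfm3 <- motif_pfm(data.frame(transcript_id = "tx1", pos = 5),
                    c(tx1 = "AAAACGG"))
  expect_identical(unname(pfm3$gaps[c("3", "4", "5")]), rep(1L, 3))
})

test_that("methylation-expression correlation and its sign categories behave", {
  rec <- data.table::data.table(
    transcript_id = paste0("tx", 1:5), pos = 1L,
    gene_id = paste0("g", 1:5),
    delta_m = c(0.5, 0.3, 0.1, -0.1, -0.3),
    direction = c("hyper", "hyper", "hyper", "hypo", "hypo"))
  de <- data.table::data.table(
    gene_id = paste0("g", 1:5),
    log2fc = c(-2, -1.2, -0.4, 0.4, 1.2),
    direction = c("down", "down", "ns", "up", "up"))
  ct <- correlate_meth_expr(rec, de)
  expect_equal(ct$r, -1, tolerance = 1e-9)   # exact descending relationship
  expect_identical(ct$n, 5L)
  expect_error(correlate_meth_expr(rec[1:2, ], de), "fewer than 3")

  cats <- categorize_correlation(rec, de)
  expect_identical(cats$category[cats$gene_id == "g1"], "negative")
  expect_identical(cats$category[cats$gene_id == "g3"], "neutral")
  expect_identical(cats$category[cats$gene_id == "g4"], "negative")
  counts <- attr(cats, "counts")
  expect_identical(sum(counts), nrow(cats))          # categories partition

  # positive pairing: hyper DMS on an up-regulated gene
  de2 <- data.table::copy(de)[gene_id == "g1", `:=`(direction = "up")]
  cats2 <- categorize_correlation(rec, de2)
  expect_identical(cats2$category[cats2$gene_id == "g1"], "positive")
})
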