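make_counts <- function(n_genes = 100, mu = 200, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * 4, size = 20, mu = mu), n_genes, 4)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  m
}

test_that("identical conditions give null fold changes and no significance", {
  m <- make_counts()
  res <- de_test(m[, 1:2], m[, 1:2], quiet = TRUE)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$padj > 0.05 | is.na(res$padj)))
})

test_that("a four-fold gene recovers log2fc near 2 under size-factor normalization", {
  m <- make_counts(mu = 300, seed = 2)
  a <- m[, 1:2]; b <- m[, 3:4]
  a["g001", ] <- c(100, 100); b["g001", ] <- c(400, 400)
  res <- de_test(a, b, quiet = TRUE)
  expect_lt(abs(res$log2fc[res$gene_id == "g001"] - 2), 0.1)
  # all-zero genes are excluded with a log line
  a["g002", ] <- 0L; b["g002", ] <- 0L
  res2 <- de_test(a, b, quiet = TRUE)
  expect_false("g002" %in% res2$gene_id)
})

test_that("DEG calls apply strict fold-change and inclusive padj thresholds", {
  res <- data.table::data.table(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(log2(2.5), 1, log2(10), -log2(3)),
    padj = c(0.01, 0.01, 0.06, 0.05))
  d <- call_degs(res)
  expect_identical(d$direction[d$gene_id == "a"], "up")
  expect_identical(d$direction[d$gene_id == "b"], "ns")   # FC exactly 2
  expect_identical(d$direction[d$gene_id == "c"], "ns")   # padj 0.06
  expect_identical(d$direction[d$gene_id == "d"], "down")
})

test_that("DEG calls are invariant under rescaling one library", {
  m <- make_counts(mu = 400, seed = 3)
  a <- m[, 1:2]; b <- m[, 3:4]
  idx <- 1:10
  b[idx, ] <- b[idx, ] * 6L
  base <- call_degs(de_test(a, b, quiet = TRUE))
  b2 <- b; b2[, 1] <- b2[, 1] * 3L
  scaled <- call_degs(de_test(a, b2, quiet = TRUE))
  expect_identical(base$direction, scaled$direction)
})

test_that("early and late response genes are classified disjointly from the three comparisons", {
  mk <- function(genes, dirs) data.table::data.table(gene_id = genes,
                                                     direction = dirs)
  genes <- c("e1", "l1", "only02", "x")
  d02 <- mk(genes, c("up", "ns", "up", "ns"))
  d06 <- mk(genes, c("ns", "up", "ns", "down"))
  d26 <- mk(genes, c("down", "up", "ns", "ns"))
  el <- classify_early_late(d02, d06, d26)
  expect_identical(el$early, "e1")     # up at 2 h, down again by 6 h
  expect_identical(el$late, "l1")      # up at 6 h and still rising
  expect_false("only02" %in% c(el$early, el$late))
  expect_length(intersect(el$early, el$late), 0)
})

test_that("planted early/late archetypes are recovered from simulated counts", {
  hits <- vapply(1:2, function(seed) {
    cfg <- sim_config(n_transcripts = 200, seed = seed)
    tx <- generate_transcriptome(cfg)
    truth <- plant_truth(tx, cfg)
    cnt <- simulate_counts(truth, cfg)
    dsn <- attr(cnt, "design")
    de <- lapply(list(c(0, 2), c(0, 6), c(2, 6)), function(pr)
      call_degs(de_test(cnt[, dsn$timepoint == pr[1]],
                        cnt[, dsn$timepoint == pr[2]], quiet = TRUE)))
    el <- classify_early_late(de[[1]], de[[2]], de[[3]])
    g <- truth$genes
    pe <- g$gene_id[g$archetype == "early"]
    pl <- g$gene_id[g$archetype == "late"]
    c(mean(pe %in% el$early), mean(pl %in% el$late))
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.8)
  expect_gte(mean(hits[2, ]), 0.8)
})
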