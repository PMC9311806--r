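test_that("transcriptome generation is deterministic and validates input", {
  cfg <- sim_config(n_transcripts = 10, seed = 1)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$seq, b$seq)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$hairpins, b$hairpins)

  expect_error(sim_config(n_transcripts = 0), "n_transcripts")
  expect_error(sim_config(cds_len = -5), "cds_len")
  expect_error(sim_config(conversion_rate = 1.2), "conversion_rate")
  expect_error(sim_config(dms_archetype_weights = rep(0, 5)), "weights")
})

test_that("mean segment lengths follow the 5:22:18 ratio", {
  cfg <- sim_config(n_transcripts = 500, seed = 11)
  tx <- generate_transcriptome(cfg)
  ann <- tx$annotation[!tx$annotation$is_spike_in, ]
  u5 <- mean(ann$utr5_end)
  cds <- mean(ann$cds_end - ann$utr5_end)
  u3 <- mean(ann$length - ann$cds_end)
  expect_lt(abs(u5 / cds - 5 / 22), 0.1 * 5 / 22)
  expect_lt(abs(u3 / cds - 18 / 22), 0.1 * 18 / 22)
})

test_that("planted sites sit on cytosines with median level near 0.2 and spare the spike-in", {
  cfg <- sim_config(n_transcripts = 250, seed = 5)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  expect_gt(nrow(truth$sites), 400)
  base_at <- mapply(function(id, p) substr(tx$seq[[id]], p, p),
                    truth$sites$transcript_id, truth$sites$pos)
  expect_true(all(base_at == "C"))
  lv <- as.matrix(truth$sites[, c("level_t1", "level_t2", "level_t3")])
  expect_true(all(lv >= 0 & lv <= 1))
  expect_lt(abs(median(truth$sites$level_t1) - 0.2), 0.05)
  expect_identical(sum(truth$sites$transcript_id == "spikein"), 0L)
  # resistant-region intervals stay inside their transcripts
  ann <- tx$annotation
  hp <- truth$resistant_regions
  expect_true(all(hp$start >= 1 &
                    hp$end <= ann$length[match(hp$transcript_id,
                                               ann$transcript_id)]))
})

test_that("zero planted coupling leaves methylation and expression shifts uncorrelated", {
  cfg <- sim_config(n_transcripts = 500, dms_fraction = 1,
                    coupling_rho = 0, seed = 21)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  d <- truth$sites[truth$sites$type == "dms", ]
  d <- d[!duplicated(d$gene_id), ]
  g <- truth$genes[match(d$gene_id, truth$genes$gene_id), ]
  dm <- d$level_t2 - d$level_t1
  dlfc <- log2(g$mult_t2)
  expect_gte(length(dm), 450)
  expect_lt(abs(cor(dm, dlfc)), 0.1)
})

test_that("read simulation is seeded, in-bounds, and perfectly converted at r = 1", {
  cfg <- sim_config(n_transcripts = 8, depth = 20, conversion_rate = 1,
                    incomplete_read_fraction = 0, sites_per_transcript = 0,
                    dms_fraction = 0, resistant_fraction = 0, seed = 3)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  rd <- simulate_reads(tx, truth, cfg, 1, 1)
  rd2 <- simulate_reads(tx, truth, cfg, 1, 1)
  expect_identical(rd$calls, rd2$calls)
  expect_identical(rd$reads, rd2$reads)
  # no methylation, perfect conversion, no failed reads: everything converted
  expect_identical(sum(rd$calls$unconverted), 0L)
  # positions within bounds and binary states
  len <- tx$annotation$length[match(rd$calls$transcript_id,
                                    tx$annotation$transcript_id)]
  expect_true(all(rd$calls$pos >= 1 & rd$calls$pos <= len))
  expect_type(rd$calls$unconverted, "logical")
  # conservation: per-read summaries match the call table
  expect_identical(sum(rd$reads$n_c), nrow(rd$calls))
})

test_that("spike-in read fraction matches its configured 0.5% and site levels are recovered", {
  cfg <- sim_config(n_transcripts = 40, depth = 100,
                    incomplete_read_fraction = 0, seed = 9)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  rd <- simulate_reads(tx, truth, cfg, 1, 1)
  n <- nrow(rd$reads)
  frac <- mean(rd$reads$is_spike_in)
  expect_lt(abs(frac - 0.005), 4 * sqrt(0.005 * 0.995 / n))
  # observed M/C within 3 binomial SE of the planted level for >= 95% of sites
  obs <- rd$calls[, .(C = .N, M = sum(unconverted)),
                  by = .(transcript_id, pos)]
  key <- paste(obs$transcript_id, obs$pos)
  s <- truth$sites
  i <- match(paste(s$transcript_id, s$pos), key)
  ok <- !is.na(i) & obs$C[i] >= 30
  lv <- s$level_t1[ok]
  se <- sqrt(lv * (1 - lv) / obs$C[i][ok])
  within <- abs(obs$M[i][ok] / obs$C[i][ok] - lv) <= 3 * se
  expect_gte(mean(within), 0.95)
})

test_that("count simulation is seeded with flat null genes and early genes peaking at 2 h", {
  cfg <- sim_config(n_transcripts = 300, seed = 13)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  cnt <- simulate_counts(truth, cfg)
  expect_identical(cnt, simulate_counts(truth, cfg))
  g <- truth$genes
  # early archetype in truth parameters: up at 2 h, down again at 6 h
  e <- g[g$archetype == "early", ]
  expect_true(all(e$mult_t2 > e$mult_t1 & e$mult_t3 < e$mult_t2))
  # null genes: empirical fold changes stay near zero at decent depth
  dsn <- attr(cnt, "design")
  nul <- g$gene_id[g$archetype == "null" & g$base_mean >= 500]
  m0 <- rowMeans(cnt[nul, dsn$timepoint == 0, drop = FALSE])
  m2 <- rowMeans(cnt[nul, dsn$timepoint == 2, drop = FALSE])
  expect_lt(median(abs(log2((m2 + 0.5) / (m0 + 0.5)))), 0.3)
})
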