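test_that("eligibility needs coverage 10 in every replicate and high confidence somewhere", {
  pu <- function(cov) make_pileup("tx1", 1L, clean_cov = cov, meth_count = 2L)
  hc_at_site <- make_pileup("tx1", 1L, 20, 8)
  hc_empty <- hc_at_site[0, ]
  elig <- select_eligible_sites(list(pu(12), pu(15)), list(pu(11), pu(30)),
                                hc_at_site, hc_empty)
  expect_identical(nrow(elig), 1L)
  # one replicate at coverage 9: ineligible
  elig2 <- select_eligible_sites(list(pu(12), pu(9)), list(pu(11), pu(30)),
                                 hc_at_site, hc_empty)
  expect_identical(nrow(elig2), 0L)
  # high-confidence in neither condition: ineligible
  elig3 <- select_eligible_sites(list(pu(12), pu(15)), list(pu(11), pu(30)),
                                 hc_empty, hc_empty)
  expect_identical(nrow(elig3), 0L)
})

test_that("Fisher test handles identity, symmetry and the enumerated oracle table", {
  ft <- fisher_dm_test(6, 14, 6, 14)
  expect_equal(ft$p, 1.0)
  expect_equal(ft$or, 1.0)

  a <- fisher_dm_test(10, 5, 3, 12)
  b <- fisher_dm_test(3, 12, 10, 5)      # conditions swapped
  expect_equal(a$p, b$p)
  expect_equal(a$or, 1 / b$or)

  # frozen from exhaustive enumeration of tables with margins (20, 20, 6, 34)
  z <- fisher_dm_test(6, 14, 0, 20)
  expect_equal(z$p, 0.020196020196, tolerance = 1e-10)
  # Haldane correction keeps the odds ratio finite on zero cells
  expect_equal(z$or, (6.5 * 20.5) / (14.5 * 0.5))

  expect_error(fisher_dm_test(0, 0, 0, 0), "zero")
  expect_error(fisher_dm_test(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0)) next
    mine <- fisher_dm_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p
    ref <- stats::fisher.test(t(tab))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("DMS classification thresholds and directions partition the records", {
  rec <- dm_records(
    data.table::data.table(transcript_id = "tx1", pos = c(1L, 2L, 3L)),
    list(make_pileup("tx1", 1:3, 50, c(5, 10, 25))),
    list(make_pileup("tx1", 1:3, 50, c(25, 11, 5))))
  out <- classify_dms(rec, quiet = TRUE)
  expect_identical(out$direction[out$pos == 1], "hyper")   # level rose
  expect_identical(out$direction[out$pos == 3], "hypo")    # level fell
  expect_identical(out$direction[out$pos == 2], "ns")
  expect_identical(sum(out$direction %in% c("hyper", "hypo")),
                   sum(out$padj <= 0.05 & out$delta_m != 0))
  expect_equal(out$delta_m, out$m_b - out$m_a)
})

test_that("a planted level shift of 0.3 at coverage 50 is detected with power >= 0.8", {
  pow <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200
    m_a <- rbinom(n, 50, 0.2)
    m_b <- rbinom(n, 50, 0.5)
    ft <- fisher_dm_test(m_a, 50 - m_a, m_b, 50 - m_b)
    mean(p.adjust(ft$p, "BH") <= 0.05)
  }, numeric(1))
  expect_gte(mean(pow), 0.8)
})
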