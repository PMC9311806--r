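test_that("3C filter partitions reads at the more-than-3 boundary", {
  rd <- make_reads(list(
    list(id = "a", tx = "tx1", pos = c(1, 5, 9, 13), unconv = rep(TRUE, 4)),
    list(id = "b", tx = "tx1", pos = c(1, 5, 9, 13), unconv = c(TRUE, TRUE, TRUE, FALSE)),
    list(id = "c", tx = "tx1", pos = integer(), unconv = logical()),
    list(id = "d", tx = "tx1", pos = c(2, 4), unconv = c(FALSE, FALSE))))
  f <- three_c_filter(rd)
  expect_identical(f$noise$reads$read_id, "a")          # 4 unconverted: noise
  expect_setequal(f$clean$reads$read_id, c("b", "c", "d"))  # exactly 3: clean
  # exhaustive + disjoint
  expect_identical(sort(c(f$clean$reads$read_id, f$noise$reads$read_id)),
                   sort(rd$reads$read_id))
  # idempotent
  f2 <- three_c_filter(f$clean)
  expect_identical(f2$clean$reads, f$clean$reads)
  expect_identical(nrow(f2$noise$reads), 0L)
})

test_that("conversion-rate estimate is the spike-in proportion with Clopper-Pearson interval", {
  one_uc <- c(TRUE, rep(FALSE, 39))
  rd <- make_reads(lapply(1:50, function(i)
    list(id = paste0("s", i), tx = "spike", pos = seq(1, 160, 4),
         unconv = if (i == 1) one_uc else rep(FALSE, 40), spike = TRUE)))
  est <- estimate_conversion_rate(rd)
  expect_equal(est$r, 1999 / 2000)
  expect_identical(est$n_total_c, 2000L)
  # frozen from the exact binomial interval for 1999/2000
  expect_equal(est$ci95, c(0.99721736, 0.99998734), tolerance = 1e-6)
  expect_true(est$ci95[1] <= est$r && est$r <= est$ci95[2])

  # all converted: r = 1 with upper bound exactly 1
  rd2 <- make_reads(list(list(id = "s", tx = "spike", pos = 1:20,
                              unconv = rep(FALSE, 20), spike = TRUE)))
  est2 <- estimate_conversion_rate(rd2)
  expect_equal(est2$r, 1)
  expect_equal(est2$ci95[2], 1)

  # no spike-in control: explicit error naming it
  rd3 <- make_reads(list(list(id = "x", tx = "tx1", pos = 1:5,
                              unconv = rep(FALSE, 5))))
  expect_error(estimate_conversion_rate(rd3), "spike-in")
})

test_that("failed-conversion spike reads are excluded from the calibration", {
  # one globally failed read would drag the estimate far below truth
  rd <- make_reads(c(
    lapply(1:40, function(i) list(id = paste0("s", i), tx = "spike",
                                  pos = 1:25, unconv = rep(FALSE, 25),
                                  spike = TRUE)),
    list(list(id = "bad", tx = "spike", pos = 1:25,
              unconv = rep(c(TRUE, FALSE), c(12, 13)), spike = TRUE))))
  est <- estimate_conversion_rate(rd)
  expect_identical(est$n_total_c, 1000L)
  expect_equal(est$r, 1)
})

test_that("pileups carry coverage, level and signal-to-noise arithmetic", {
  ann <- simple_annotation("tx1")
  # 18 clean reads (6 unconverted at the site) + 2 noise reads (4 extra
  # unconverted Cs each) covering the same site
  spec <- c(site_reads(n = 18, n_unconv = 6),
            site_reads(n = 2, n_unconv = 2, extra_unconv_per_read = 4,
                       id_prefix = "noise"))
  rd <- make_reads(spec)
  f <- three_c_filter(rd)
  pile <- build_pileups(f$clean, rd, ann)
  s <- pile[pile$pos == 10, ]
  expect_identical(s$total_cov, 20L)
  expect_identical(s$clean_cov, 18L)
  expect_identical(s$meth_count, 6L)
  expect_equal(s$level, 6 / 18)
  expect_equal(s$sn_ratio, 0.90)
  # clean 20 reads, 6 unconverted: level 0.30
  rd2 <- make_reads(site_reads(n = 20, n_unconv = 6))
  pile2 <- build_pileups(rd2, rd2, ann)
  expect_equal(pile2$level[pile2$pos == 10], 0.30)
  # conservation and ordering invariants
  expect_identical(sum(pile$total_cov), nrow(rd$calls))
  expect_true(all(pile$clean_cov <= pile$total_cov))
  expect_true(all(pile$level >= 0 & pile$level <= 1, na.rm = TRUE))

  # degenerate and error cases
  empty <- make_reads(list())
  expect_identical(nrow(build_pileups(empty, empty, ann)), 0L)
  bad <- make_reads(list(list(id = "x", tx = "nope", pos = 3,
                              unconv = FALSE)))
  expect_error(build_pileups(bad, bad, ann), "nope")
})
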