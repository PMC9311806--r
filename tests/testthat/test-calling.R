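test_that("non-conversion p-values match the exact binomial tail", {
  pile <- make_pileup("tx1", c(10, 20, 30), clean_cov = c(20, 20, 15),
                      meth_count = c(6, 0, 3))
  st <- call_site_pvalues(pile, 0.9995)
  # frozen oracle: direct summation of C(20,k) 0.0005^k 0.9995^(20-k), k>=6
  expect_equal(st$p[st$pos == 10], 6.0200156513e-16, tolerance = 1e-9)
  expect_equal(st$p[st$pos == 20], 1.0)     # M = 0: upper tail at zero
  expect_true(all(st$p > 0 & st$p <= 1))

  # r = 1 with M >= 1: impossible under the null, floored and flagged
  st2 <- call_site_pvalues(make_pileup("tx1", 1, 10, 2), 1)
  expect_equal(st2$p, .Machine$double.xmin)
  expect_true(st2$p_underflow)

  # zero clean coverage is skipped with a warning
  pz <- make_pileup("tx1", c(1, 2), clean_cov = c(0, 10), meth_count = c(0, 1))
  pz$level[1] <- NA
  expect_warning(stz <- call_site_pvalues(pz, 0.9995), "zero clean coverage")
  expect_identical(nrow(stz), 1L)

  expect_error(call_site_pvalues(pile, 0), "conversion rate")
})

test_that("the filter cascade applies the stated inequalities", {
  pile <- make_pileup(
    "tx1", pos = 1:5,
    clean_cov  = c(20, 19, 60, 20, 20),
    meth_count = c(6,  6,  6,  5,  6),
    total_cov  = c(21, 20, 63, 21, 20))
  # pos 5 has sn exactly 20/20 = 1.0; overwrite to hit the 0.9 boundary
  pile$sn_ratio[5] <- 0.9
  st <- apply_site_filters(call_site_pvalues(pile, 0.9995))
  get <- function(col, i) st[[col]][match(i, st$pos)]
  expect_true(get("pass_standard", 1))   # C=20, M=6, m=0.3
  expect_false(get("pass_standard", 2))  # C=19 fails coverage
  expect_true(get("pass_standard", 3))   # m exactly 0.1 passes (inclusive)
  expect_false(get("pass_standard", 4))  # M=5 fails methylated depth
  expect_false(get("pass_sn", 5))        # S/N exactly 0.9 fails (strict)
  expect_true(get("pass", 1))
  # BH universe is the standard-passing set; others carry NA padj
  expect_true(is.na(get("padj", 2)))
  expect_false(is.na(get("padj", 1)))
})

test_that("single-site BH equals the raw p and padj is monotone", {
  one <- apply_site_filters(call_site_pvalues(
    make_pileup("tx1", 1, 30, 9), 0.9995))
  expect_equal(one$padj, one$p)
  many <- apply_site_filters(call_site_pvalues(
    make_pileup("tx1", 1:30, clean_cov = 40, meth_count = 4 + (1:30) %% 9),
    0.999))
  tested <- many[!is.na(many$padj), ]
  o <- order(tested$p)
  expect_true(all(diff(tested$padj[o]) >= -1e-12))
  expect_true(all(tested$padj >= tested$p))
})

test_that("raising any threshold never adds a passing site", {
  set.seed(4)
  pile <- make_pileup("tx1", 1:200,
                      clean_cov = 15 + rpois(200, 20),
                      meth_count = rbinom(200, 10, 0.5),
                      total_cov = 15 + rpois(200, 20) + rbinom(200, 3, 0.5))
  pile$clean_cov <- pmin(pile$clean_cov, pile$total_cov)
  pile$level <- pile$meth_count / pile$clean_cov
  pile$sn_ratio <- pile$clean_cov / pile$total_cov
  called <- call_site_pvalues(pile, 0.9995)
  base <- apply_site_filters(called)
  passing <- function(st) paste(st$transcript_id, st$pos)[st$pass]
  for (tweak in list(filter_thresholds(min_cov = 30),
                     filter_thresholds(min_level = 0.3),
                     filter_thresholds(min_meth = 8),
                     filter_thresholds(min_sn = 0.95),
                     filter_thresholds(max_fdr = 0.01))) {
    expect_true(all(passing(apply_site_filters(called, tweak)) %in%
                      passing(base)))
  }
})

test_that("replicate intersection pools counts and keeps only shared sites", {
  r1 <- make_pileup("tx1", c(5, 9), clean_cov = c(20, 25),
                    meth_count = c(6, 10))
  r2 <- make_pileup("tx1", c(5, 14), clean_cov = c(30, 22),
                    meth_count = c(12, 7))
  m <- merge_replicates(r1, r2)
  expect_identical(m$pos, 5L)                 # rep1-only and rep2-only absent
  expect_equal(m$level, 18 / 50)              # pooled (6+12)/(20+30)
  expect_identical(m$clean_cov, 50L)
  # identity: identical inputs give the full set and 100% overlap
  mi <- merge_replicates(r1, r1)
  expect_identical(mi$pos, r1$pos)
  expect_equal(unname(attr(mi, "overlap_pct")), c(100, 100))
  # merged set is a subset of each replicate
  expect_true(all(m$pos %in% r1$pos) && all(m$pos %in% r2$pos))
})

test_that("three-way overlap partition matches brute-force set algebra", {
  ident <- make_pileup("tx1", 1:4, 20, 8)
  v <- condition_overlap(list(t0 = ident, t2 = ident, t6 = ident))
  expect_identical(unname(v[["t0&t2&t6"]]), 4L)
  expect_identical(sum(v), 4L)

  d1 <- make_pileup("tx1", 1:3, 20, 8)
  d2 <- make_pileup("tx1", 4:6, 20, 8)
  d3 <- make_pileup("tx1", 7:9, 20, 8)
  vd <- condition_overlap(list(a = d1, b = d2, c = d3))
  expect_identical(unname(vd[["a&b&c"]]), 0L)
  expect_identical(sum(vd), 9L)

  # randomized subsets against an independent membership enumeration
  set.seed(8)
  for (i in 1:5) {
    sets <- lapply(1:3, function(j)
      make_pileup("tx1", sample(1:30, sample(5:20, 1)), 20, 8))
    names(sets) <- c("x", "y", "z")
    v <- condition_overlap(sets)
    keys <- lapply(sets, function(s) s$pos)
    uni <- sort(unique(unlist(keys)))
    oracle <- integer(7)
    for (k in uni) {
      inx <- vapply(keys, function(ks) k %in% ks, logical(1))
      code <- sum(inx * c(1, 2, 4))
      slot <- match(code, c(1, 2, 4, 3, 5, 6, 7))
      oracle[slot] <- oracle[slot] + 1L
    }
    expect_identical(unname(as.integer(v)), oracle)
    expect_identical(sum(v), length(uni))
    expect_identical(attr(v, "union"), length(uni))
  }
})
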