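test_that("the threshold peak caller finds, merges and filters runs", {
  tr <- strand_track(c(1, 5, 5, 1, 5), "c1")
  p0 <- call_peaks(tr, 3, min_width = 1, merge_gap = 0)
  expect_equal(p0$start, c(1, 4))
  expect_equal(p0$end, c(3, 5))
  expect_equal(p0$score, c(5, 5))

  p1 <- call_peaks(tr, 3, min_width = 1, merge_gap = 1)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$start, p1$end), c(1, 5))

  expect_equal(nrow(call_peaks(strand_track(rep(2, 50), "c1"), 3)), 0)
  expect_equal(nrow(call_peaks(tr, 3, min_width = 3, merge_gap = 0)), 0)
})

test_that("overlap counting matches hand counts and a per-base oracle", {
  iv <- function(s, e) intervals("c1", s, e)
  n <- 5
  a <- iv(seq(0, 400, 100), seq(0, 400, 100) + 50)
  expect_equal(overlap_count(a, a), c(n, n))
  b <- iv(seq(0, 400, 100) + 60, seq(0, 400, 100) + 90)
  expect_equal(overlap_count(a, b), c(0, 0))

  a2 <- iv(0, 10)
  b2 <- iv(c(9, 15), c(20, 30))
  # [15,30) shares no base with [0,10): brute-force enumeration gives (1, 1)
  expect_equal(overlap_count(a2, b2), c(1, 1))
  expect_equal(overlap_count(a2, b2), overlap_count_oracle(a2, b2, 100))

  # brute-force per-base oracle + IRanges cross-check on random sets
  set.seed(11)
  for (rep in 1:20) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    as <- sample.int(900, na); bs <- sample.int(900, nb)
    a3 <- iv(as, as + sample.int(80, na))
    b3 <- iv(bs, bs + sample.int(80, nb))
    expect_equal(overlap_count(a3, b3), overlap_count_oracle(a3, b3, 1000))
    ir_hits <- IRanges::countOverlaps(
      IRanges::IRanges(a3$start + 1, a3$end),
      IRanges::IRanges(b3$start + 1, b3$end))
    expect_equal(overlap_count(a3, b3)[1], sum(ir_hits > 0))
  }
})

test_that("the circular overlap counter agrees with a per-base oracle", {
  set.seed(19)
  L <- 2000
  for (rep in 1:20) {
    nb <- sample(3:8, 1); na <- sample(3:12, 1)
    bs <- sort(sample.int(L - 100, nb))
    be <- bs + sample.int(90, nb)
    s <- sample.int(L, na) - 1
    e <- s + sample.int(150, na)          # may wrap past L
    fast <- toposeqr:::count_overlaps_circular(s, e, bs, cummax(be), L)
    bcov <- rep(FALSE, L)
    for (j in seq_len(nb)) bcov[(bs[j] + 1):be[j]] <- TRUE
    slow <- sum(vapply(seq_len(na), function(i)
      any(bcov[(s[i]:(e[i] - 1)) %% L + 1]), logical(1)))
    expect_equal(fast, slow)
  }
})

test_that("Monte-Carlo overlap test matches closed-form placement probability", {
  # b covers the whole genome -> saturated null, p = 1
  a <- intervals("c1", c(100, 500), c(150, 560))
  ball <- intervals("c1", 0, 10000)
  expect_equal(montecarlo_overlap_test(a, ball, 10000, 200, seed = 1)$p, 1)

  # single 10 bp peak pair on a 10 kb circle: overlap probability 19/10000
  one <- intervals("c1", 4000, 4010)
  res <- montecarlo_overlap_test(one, one, 10000, 999, seed = 2)
  q <- 19 / 10000
  expect_equal(res$statistic, 1)
  expect_lt(abs(res$p - (1 + 999 * q) / 1000),
            3 * sqrt(999 * q * (1 - q)) / 1000 + 1e-9)

  expect_error(montecarlo_overlap_test(intervals("c1", 0, 20000), one,
                                       10000, 100, seed = 1), "wider")
})

test_that("null-drawn peak sets give uniform Monte-Carlo p-values", {
  # the statistic must be well spread for empirical p to approach U(0,1):
  # many placed peaks, moderate per-peak hit probability
  set.seed(12)
  L <- 50000
  bs <- sort(sample.int(L - 300, 60))
  b <- intervals("c1", bs, bs + 250)
  ps <- vapply(1:100, function(i) {
    as <- sample.int(L, 150) - 1
    a <- intervals("c1", as, as + 150)
    montecarlo_overlap_test(a, b, L, 199, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(100))   # 1% critical value
  # super-uniformity: P(p <= alpha) <= alpha + 1/(iterations + 1)
  expect_lte(mean(ps <= 0.1), 0.1 + 1 / 200 + 3 * sqrt(0.1 * 0.9 / 100))
})

test_that("Welch's t-test matches the reference implementation", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  mine <- welch_t_test(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)

  swapped <- welch_t_test(b, a)
  expect_equal(swapped$statistic, -mine$statistic)
  expect_equal(swapped$p, mine$p)

  set.seed(13)
  for (i in 1:25) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    mine <- welch_t_test(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }

  deg <- welch_t_test(c(5, 5, 5), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_lte(deg$p, .Machine$double.xmin)
  expect_error(welch_t_test(c(2, 2), c(2, 2)), "undefined")
})

test_that("inside/outside comparison separates planted enrichment", {
  flat <- strand_track(rep(3, 1000), "c1")
  pk <- intervals("c1", 100, 200)
  r0 <- enrichment_inside_outside(flat, pk)
  expect_equal(r0$p, 1)
  expect_equal(r0$statistic, 0)

  v <- rep(1, 1000); v[101:200] <- 10
  r1 <- enrichment_inside_outside(strand_track(v, "c1"), pk)
  expect_true(r1$degenerate)
  expect_lte(r1$p, 1e-300)

  # analytic expectation: t = (2-1)/sqrt(2/1e4) = 10 sqrt(50)
  set.seed(14)
  v2 <- c(rnorm(10000, 2), rnorm(10000, 1))
  r2 <- enrichment_inside_outside(strand_track(v2, "c1"),
                                  intervals("c1", 0, 10000))
  expect_lt(abs(r2$statistic - 10 * sqrt(50)), 3 * sqrt(2))
  expect_error(enrichment_inside_outside(flat, intervals("c1", 0, 1000)),
               "partition")
})

test_that("peak composition reports GC, width and the AT/score correlation", {
  g <- genome_seq("GGCCAATTNNGGAATT", "c1")
  pk <- intervals("c1", c(0, 4), c(4, 8), name = c("p1", "p2"), score = c(2, 4))
  comp <- peak_composition(pk, g)
  expect_equal(comp$per_peak$gc, c(1, 0))
  expect_equal(comp$median_width, 4)
  expect_error(peak_composition(intervals("c1", 10, 20), g), "bounds")

  # peaks planted in AT-rich islands are more AT-rich than the genome
  set.seed(15)
  base <- make_genome(20000, 0.6, seed = 15)
  chars <- strsplit(base$sequence, "")[[1]]
  starts <- seq(1000, 19000, 2000)
  for (s in starts) {
    chars[(s + 1):(s + 200)] <- sample(c("A", "T"), 200, replace = TRUE,
                                       prob = c(0.45, 0.45) / 0.9)
  }
  g2 <- genome_seq(paste(chars, collapse = ""), "chr")
  pk2 <- intervals("chr", starts, starts + 200)
  comp2 <- peak_composition(pk2, g2)
  expect_lt(comp2$mean_gc, 0.6)
})
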