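test_that("random genomes hit the requested GC content and are reproducible", {
  g <- make_genome(100000, 0.5, seed = 1)
  b <- strsplit(g$sequence, "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)   # 3 sigma of Binomial(1e5, .5) is ~0.0047
  expect_true(g$circular)

  g0 <- make_genome(10000, 0, seed = 1)
  expect_false(grepl("[GC]", g0$sequence))

  expect_identical(make_genome(20000, 0.4, seed = 9)$sequence,
                   make_genome(20000, 0.4, seed = 9)$sequence)
})

test_that("TU placement is disjoint with both strands and wide expression", {
  g <- make_genome(100000, 0.5, seed = 2)
  tus <- make_tu_annotation(g, 20, 2, seed = 1)
  expect_equal(nrow(tus), 20)
  ord <- tus[order(tus$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-20] + 1000))
  expect_setequal(unique(tus$strand), c("+", "-"))
  expect_true(all(tus$end - tus$start >= 500 & tus$end - tus$start <= 5000))

  sorted <- sort(tus$fpkm, decreasing = TRUE)
  expect_gte(sorted[1] / sorted[20], 100)

  flat <- make_tu_annotation(g, 10, 0, seed = 3)
  expect_equal(length(unique(flat$fpkm)), 1)

  small <- make_genome(10000, 0.5, seed = 1)
  expect_error(make_tu_annotation(small, 50, 2, seed = 1), "too small")
})

test_that("planted cleavage sites reproduce the consensus on both strands", {
  fx <- small_planted_fixture()
  spec <- fx$motif_spec
  cons <- strsplit(spec$consensus, "")[[1]]
  ci <- spec$cleavage_index
  Lm <- length(cons)
  # window on the cleaved strand, flank 10: consensus column j sits at
  # window column 11 + (j - ci)
  win <- extract_tcs_windows(
    data.frame(contig = "chr", position = fx$truth$position,
               strand = fx$truth$strand, n3e = 1), fx$genome, flank = 10)
  for (k in seq_along(win)) {
    wchars <- strsplit(win[k], "")[[1]]
    for (j in seq_len(Lm)) {
      if (cons[j] == "N") next
      expect_identical(wchars[11 + j - ci], cons[j])
    }
  }
  # both strands carry about half the sites
  expect_equal(sum(fx$truth$strand == "+"), 10)
})

test_that("Topo-Seq simulation matches its Poisson construction", {
  fx <- small_planted_fixture()
  cs <- simulate_toposeq(fx$genome, fx$truth, depth = 20000, S = 50,
                         replicates = 2, seed = 5)
  # background track totals within 3 sigma of Poisson(depth)
  for (cond in c("plusAra_minusIP", "minusAra_plusIP", "minusAra_minusIP")) {
    for (r in 1:2) {
      expect_lt(abs(track_total(cs[[cond]][[r]]$fw) - 20000), 3 * sqrt(20000))
      expect_lt(abs(track_total(cs[[cond]][[r]]$rv) - 20000), 3 * sqrt(20000))
    }
  }
  # null contrast at planted positions averages ~0
  fw_idx <- fx$truth$position[fx$truth$strand == "+"] + 1
  d <- cs$minusAra_plusIP[[1]]$fw$values[fw_idx] -
    cs$minusAra_minusIP[[1]]$fw$values[fw_idx]
  lam <- 20000 / genome_length(fx$genome)
  expect_lt(abs(mean(d)), 3 * sqrt(2 * lam / length(fw_idx)))
  # planted positions in the induced+IP condition carry the spike
  spike <- cs$plusAra_plusIP[[1]]$fw$values[fw_idx]
  expect_gt(mean(spike), 0.9 * 50 * lam)
  # determinism
  cs2 <- simulate_toposeq(fx$genome, fx$truth, depth = 20000, S = 50,
                          replicates = 2, seed = 5)
  expect_identical(cs$plusAra_plusIP[[1]]$fw$values,
                   cs2$plusAra_plusIP[[1]]$fw$values)
})

test_that("ChIP simulation lays down the exponential upstream decay", {
  # sparse all-plus layout so components of neighbouring TUs cannot overlap
  L_up <- 2000
  tus <- tu_df(start = 60000 * (1:20), end = 60000 * (1:20) + 2000,
               strand = "+", fpkm = 100)
  sim <- simulate_chip_fe(tus, 1.3e6, L_up = L_up, seed = 4, noise_sd = 0)
  v <- sim$ip$values
  # component above baseline at distance d upstream of TSS
  comp <- function(d) mean(v[tus$start - d + 1]) - 1
  ratio <- comp(L_up) / comp(250)
  expect_lt(abs(ratio / exp(-(L_up - 250) / L_up) - 1), 0.1)

  # zero-expression TU adds nothing above baseline
  tus0 <- tu_df(start = c(10000, 60000), end = c(12000, 62000),
                strand = "+", fpkm = c(0, 100))
  sim0 <- simulate_chip_fe(tus0, 2e5, L_up = L_up, seed = 4, noise_sd = 0)
  expect_equal(sim0$ip$values[10001:12000], rep(1, 2000))

  s1 <- simulate_chip_fe(tus0, 2e5, L_up = L_up, seed = 8)
  s2 <- simulate_chip_fe(tus0, 2e5, L_up = L_up, seed = 8)
  expect_identical(s1$ip$values, s2$ip$values)
})

test_that("DRIP simulation plants coding-strand signal only when asked", {
  g <- make_genome(100000, 0.5, seed = 6)
  tus <- make_tu_annotation(g, 12, 1, seed = 7)

  null <- simulate_drip(tus, 1e5, rloop_fraction = 0, seed = 8,
                        coverage_depth = 5)
  expect_length(null$planted, 0)
  # experimental and control differ only by Poisson noise
  expect_lt(abs(mean(null$exp$fw$values) - mean(null$ctrl$fw$values)),
            3 * sqrt(2 * 5 / 1e5))

  d <- simulate_drip(tus, 1e5, rloop_fraction = 1, seed = 9,
                     coverage_depth = 5, rloop_strength = 2)
  expect_gt(length(d$planted), 0)
  plus <- tus[tus$id %in% d$planted & tus$strand == "+", ]
  if (nrow(plus) > 0) {
    tu <- plus[1, ]
    body <- (tu$start + 1):tu$end
    expect_gt(mean(d$exp$fw$values[body]), mean(d$exp$rv$values[body]))
  }

  # control tracks carry no TU-body excess (type-I control at alpha = 0.01)
  outside <- rep(TRUE, 1e5)
  for (i in seq_len(nrow(tus))) outside[(tus$start[i] + 1):tus$end[i]] <- FALSE
  bg <- d$ctrl$fw$values[outside]
  set.seed(10)
  p <- vapply(seq_len(nrow(tus)), function(i) {
    body <- d$ctrl$fw$values[(tus$start[i] + 1):tus$end[i]]
    welch_t_test(body, sample(bg, 2000))$p
  }, numeric(1))
  expect_gte(mean(p > 0.01), 0.95)
})
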