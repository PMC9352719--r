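test_that("HETU/LETU selection ranks, tie-breaks and excludes", {
  tab <- data.frame(id = sprintf("g%02d", 1:10), fpkm = c(10:6, 5:1) * 1.0)
  s <- select_tu_sets(tab, n = 3)
  expect_equal(s$hetu, c("g01", "g02", "g03"))
  expect_equal(sort(s$letu), c("g08", "g09", "g10"))
  expect_length(intersect(s$hetu, s$letu), 0)

  ties <- data.frame(id = sprintf("g%02d", 10:1), fpkm = rep(2, 10))
  st <- select_tu_sets(ties, n = 3)
  expect_equal(st$hetu, c("g01", "g02", "g03"))   # id lexicographic tie-break
  expect_length(st$letu, 3)

  ex <- select_tu_sets(tab, n = 3, exclude_ids = c("g01", "g10"))
  expect_false("g01" %in% ex$hetu)
  expect_false("g10" %in% ex$letu)
  expect_error(select_tu_sets(tab, n = 6), "at least")

  set.seed(22)
  big <- data.frame(id = sprintf("t%03d", 1:500),
                    fpkm = 10^rnorm(500, 1, 1.5))
  sb <- select_tu_sets(big, n = 200)
  expect_gt(min(big$fpkm[big$id %in% sb$hetu]),
            max(big$fpkm[big$id %in% sb$letu]))
})

test_that("metagene profiles reproduce constants, steps and the SEM oracle", {
  tus <- tu_df(start = c(3000, 9000), end = c(5000, 11000), strand = c("+", "-"))
  flat <- strand_track(rep(4, 20000), "chr")
  p <- metagene_profile(flat, tus, us_length = 1000, ds_length = 1000,
                        body_bins = 10, circular = FALSE)
  expect_equal(unname(p$mean), rep(4, length(p$mean)))
  expect_equal(unname(p$sem), rep(0, length(p$sem)))

  v <- rep(1, 20000); v[3001:5000] <- 2
  p2 <- metagene_profile(strand_track(v, "chr"), tus[1, ], us_length = 500,
                         ds_length = 500, body_bins = 5, circular = FALSE)
  expect_equal(unname(p2$mean[p2$region == "body"]), rep(2, 5))
  expect_equal(unname(p2$mean[p2$region != "body"]), rep(1, 1000))

  # SEM against the explicit per-TU loop oracle (plus-strand TUs)
  set.seed(23)
  starts <- seq(2000, 38000, 4000)
  tus3 <- tu_df(start = starts, end = starts + sample(900:1500, 10),
                strand = "+")
  vals <- rnorm(40000, 5)
  p3 <- metagene_profile(strand_track(vals, "chr"), tus3, us_length = 300,
                         ds_length = 300, body_bins = 7, circular = FALSE)
  m <- metagene_oracle_matrix(vals, tus3, 300, 300, 7)
  expect_equal(unname(p3$mean), unname(colMeans(m)))
  expect_equal(unname(p3$sem), unname(apply(m, 2, sd) / sqrt(nrow(m))))
})

test_that("metagene profiles are mirror- and order-invariant and linear", {
  set.seed(24)
  L <- 30000
  vals <- rpois(L, 3) + rnorm(L, 0, 0.1)
  tus <- tu_df(start = c(4000, 12000, 21000), end = c(6000, 15000, 23000),
               strand = c("+", "-", "+"))
  args <- list(us_length = 1500, ds_length = 1500, body_bins = 9,
               circular = FALSE)
  p <- do.call(metagene_profile, c(list(strand_track(vals, "chr"), tus), args))

  # mirror the layout: reverse coordinates, flip strands, reverse the track
  mir <- tu_df(start = L - tus$end, end = L - tus$start,
               strand = ifelse(tus$strand == "+", "-", "+"))
  pm <- do.call(metagene_profile,
                c(list(strand_track(rev(vals), "chr"), mir), args))
  expect_equal(unname(pm$mean), unname(p$mean))
  expect_equal(unname(pm$sem), unname(p$sem))

  # TU order is irrelevant
  pp <- do.call(metagene_profile,
                c(list(strand_track(vals, "chr"), tus[c(3, 1, 2), ]), args))
  expect_equal(unname(pp$mean), unname(p$mean))
  expect_equal(unname(pp$sem), unname(p$sem))

  # linearity of the mean
  vals2 <- rpois(L, 2)
  pa <- do.call(metagene_profile, c(list(strand_track(vals2, "chr"), tus), args))
  pab <- do.call(metagene_profile,
                 c(list(strand_track(vals + vals2, "chr"), tus), args))
  expect_equal(unname(pab$mean), unname(p$mean + pa$mean))
})

test_that("TSS regions include both endpoints and quantification is strand-aware", {
  L <- 30000
  tu <- tu_df(start = 10000, end = 12000, strand = "+")
  v <- rep(0, L)
  v[(10000 - 200 + 1):(10000 + 200 + 1)] <- 1   # exactly TSS +/- 200
  q <- quantify_tu_regions(strand_track(v, "chr"), tu, circular = FALSE)
  expect_equal(q$tss, 1)                       # 401 of 401 positions
  expect_equal(q$us, 200 / 5000)               # [tss-200, tss) only
  expect_equal(q$body, 201 / 2000)             # [tss, tss+200] inside the body

  flat <- strand_track(rep(2, L), "chr")
  tus <- tu_df(start = c(8000, 20000), end = c(10000, 22000),
               strand = c("+", "-"))
  qf <- quantify_tu_regions(flat, tus, circular = FALSE)
  expect_equal(unlist(qf[c("us", "tss", "body", "ds")], use.names = FALSE),
               rep(2, 8))
  cmp <- compare_tu_regions(qf, qf)
  expect_equal(cmp$p, rep(1, 4))
  expect_equal(cmp$p_adj, rep(1, 4))
})

test_that("upstream range inverts a noise-free exponential at the 5% level", {
  # two identical plus-strand TUs with an exponential upstream component
  L <- 80000
  Lu <- 1500
  v <- rep(1, L)
  for (s in c(30000, 60000)) {
    d <- seq_len(10000)
    v[s - d + 1] <- v[s - d + 1] + 2 * exp(-d / Lu)
  }
  tus <- tu_df(start = c(30000, 60000), end = c(32000, 62000), strand = "+")
  prof <- metagene_profile(strand_track(v, "chr"), tus, us_length = 10000,
                           ds_length = 1000, body_bins = 5, flank_bin = 100,
                           circular = FALSE)
  d <- upstream_signal_range(prof, background_level = 1 + 0.05 * 2,
                             consecutive_bins = 3)
  expect_lt(abs(d - 3 * Lu), 150)   # within +/- 1 flank bin + rounding

  flatp <- metagene_profile(strand_track(rep(1, L), "chr"), tus,
                            us_length = 10000, ds_length = 1000,
                            body_bins = 5, flank_bin = 100, circular = FALSE)
  expect_equal(upstream_signal_range(flatp, 1), 0)
  # never dropping below background -> full upstream length
  expect_equal(upstream_signal_range(prof, background_level = 0.5), 10000)
})
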