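test_that("TCS calling fires on point signal and stays silent on nulls", {
  fw <- strand_track(c(rep(0, 400), 50, rep(0, 599)), "c1", "+")
  rv <- strand_track(c(rep(0, 999), 1), "c1", "-")
  tc <- call_tcs(fw, rv, k = 3, floor = 5)
  expect_equal(nrow(tc), 1)
  expect_equal(tc$position, 400)
  expect_equal(tc$strand, "+")
  expect_equal(tc$n3e, 50)

  const <- strand_track(rep(7, 100), "c1", "+")
  expect_equal(nrow(call_tcs(const, const)), 0)

  neg <- strand_track(rep(-1, 100), "c1", "+")
  expect_error(call_tcs(neg, neg), "no positive")
})

test_that("window extraction matches a substring oracle and wraps", {
  g <- genome_seq("AAACTTAAAA", "c1", circular = TRUE)
  w <- extract_tcs_windows(
    data.frame(contig = "c1", position = 5, strand = "+", n3e = 1), g,
    flank = 3)
  # window = genome[position - flank, position + flank); oracle by substring
  expect_equal(w, substr("AAACTTAAAA", 5 - 3 + 1, 5 + 3))
  expect_equal(w, "ACTTAA")

  # minus-strand window straddles the same bond, read 5'->3' on the
  # reverse strand
  wm <- extract_tcs_windows(
    data.frame(contig = "c1", position = 4, strand = "-", n3e = 1), g,
    flank = 3)
  expect_equal(wm, revcomp(substr("AAACTTAAAA", 4 - 3 + 2, 4 + 3 + 1)))

  # circular wrap past either end
  ww <- extract_tcs_windows(
    data.frame(contig = "c1", position = 1, strand = "+", n3e = 1), g,
    flank = 5)
  expect_equal(nchar(ww), 10)
  expect_equal(ww, paste0(substr(g$sequence, 7, 10), substr(g$sequence, 1, 6)))
})

test_that("minus-strand planted sites return the consensus, not its complement", {
  fx <- small_planted_fixture()
  minus <- fx$truth[fx$truth$strand == "-", ]
  w <- extract_tcs_windows(
    data.frame(contig = "chr", position = minus$position, strand = "-",
               n3e = 1), fx$genome, flank = 10)
  core <- vapply(w, function(s) substr(s, 6, 11), character(1),
                 USE.NAMES = FALSE)
  expect_true(all(grepl("^TC[ACGT]TTA$", core)))
})

test_that("PFM construction obeys frequency and information bounds", {
  pfm <- build_pfm(rep("ACGTAC", 100), cleavage_index = 3)
  expect_true(all(pfm$ic > 1.9 & pfm$ic <= 2))
  expect_equal(unname(colSums(pfm$freq)), rep(1, 6), tolerance = 1e-9)
  expect_equal(pfm$consensus, "ACGTAC")

  set.seed(16)
  seqs <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    character(1))
  pfm2 <- build_pfm(seqs, 4)
  expect_lte(mean(pfm2$ic), 0.02)
  expect_true(all(pfm2$ic >= 0))
  expect_equal(pfm2$consensus, "NNNNNNNN")

  expect_error(build_pfm(c("ACGT", "ACG"), 2), "equal length")
})

test_that("the cleavage offset is found by maximal conserved-C scoring", {
  # single C column 4 nt 5' of cleavage
  seqs <- rep("AACATTAT", 50)   # C at column 3, cleavage at column 7
  pfm <- build_pfm(seqs, cleavage_index = 7)
  expect_equal(find_cleavage_offset(pfm), 4)

  pfm1 <- build_pfm(rep("AACTTTT", 50), cleavage_index = 4)  # C just 5'
  expect_equal(find_cleavage_offset(pfm1), 1)

  # two C-rich columns with different conservation: brute-force oracle
  set.seed(17)
  seqs2 <- vapply(1:300, function(i) {
    x <- sample(c("A", "C", "G", "T"), 9, replace = TRUE)
    x[2] <- sample(c("C", "A"), 1, prob = c(0.7, 0.3))
    x[5] <- "C"
    paste(x, collapse = "")
  }, character(1))
  pfm2 <- build_pfm(seqs2, cleavage_index = 9)
  up <- 1:8
  score <- pfm2$ic[up] * pfm2$freq["C", up]
  modal_c <- vapply(up, function(j)
    rownames(pfm2$freq)[which.max(pfm2$freq[, j])] == "C", logical(1))
  score[!(modal_c & pfm2$ic[up] >= 0.5)] <- -Inf
  expect_equal(find_cleavage_offset(pfm2), 9 - which.max(score))

  pfm3 <- build_pfm(rep("AATTTTAA", 20), cleavage_index = 5)
  expect_error(find_cleavage_offset(pfm3), "no conserved C")
})

test_that("motif scanning scores its own consensus maximally and is strand-aware", {
  pfm <- build_pfm(rep("ACGTACGTT", 30), cleavage_index = 5)
  g <- genome_seq(paste0(strrep("T", 30), "ACGTACGTT", strrep("T", 30)), "c1")
  hits <- scan_motif(g, pfm, score_threshold = 10)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start[which.max(fwd$score)], 30)

  # palindromic motif: forward and reverse hits coincide
  pal <- build_pfm(rep("ACGCGT", 30), cleavage_index = 3)
  g2 <- genome_seq(paste0(strrep("A", 20), "ACGCGT", strrep("A", 20)), "c1")
  h2 <- scan_motif(g2, pal, score_threshold = 8)
  expect_setequal(h2$start[h2$strand == "+"], h2$start[h2$strand == "-"])

  # planted-site recovery at the 5th percentile of planted-site scores
  fx <- small_planted_fixture()
  truth_w <- extract_tcs_windows(
    data.frame(contig = "chr", position = fx$truth$position,
               strand = fx$truth$strand, n3e = 1), fx$genome, flank = 7)
  pfm3 <- build_pfm(truth_w, cleavage_index = 8)
  L <- genome_length(fx$genome)
  expected_start <- ifelse(fx$truth$strand == "+",
                           (fx$truth$position - 7) %% L,
                           (fx$truth$position - 6) %% L)
  h_all <- scan_motif(fx$genome, pfm3, score_threshold = -Inf)
  site_scores <- h_all$score[match(paste(expected_start, fx$truth$strand),
                                   paste(h_all$start, h_all$strand))]
  thr <- stats::quantile(site_scores, 0.05)
  hits3 <- scan_motif(fx$genome, pfm3, score_threshold = thr)
  key <- paste(hits3$start, hits3$strand)
  found <- mean(paste(expected_start, fx$truth$strand) %in% key)
  expect_gte(found, 0.95)
})

test_that("PFM text round-trips through write/read", {
  pfm <- build_pfm(c("ACGTAA", "ACGTTA", "ACCTAA", "ACGTAT"), 4)
  f <- tempfile(fileext = ".pfm")
  write_pfm(pfm, f)
  back <- read_pfm(f)
  expect_equal(back$freq, pfm$freq, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$cleavage_index, pfm$cleavage_index)
  expect_equal(back$consensus, pfm$consensus)
  expect_equal(back$n_sequences, pfm$n_sequences)
})

test_that("the TCS-to-motif pipeline is strand-symmetric end to end", {
  g <- make_genome(40000, 0.5, seed = 21)
  mk <- function(strand) {
    pos <- seq(1000, 39000, length.out = 20)
    g2 <- g
    chars <- strsplit(g$sequence, "")[[1]]
    spec <- default_motif_spec()
    cons <- strsplit(spec$consensus, "")[[1]]
    cons[cons == "N"] <- "A"
    truth <- integer(0)
    for (p in pos) {
      fill <- if (strand == "-")
        strsplit(revcomp(paste(cons, collapse = "")), "")[[1]] else cons
      chars[(p + 1):(p + length(cons))] <- fill
      truth <- c(truth, if (strand == "+") p + spec$cleavage_index - 1 else
        p + length(cons) - spec$cleavage_index)
    }
    g2$sequence <- paste(chars, collapse = "")
    w <- extract_tcs_windows(
      data.frame(contig = "chr", position = truth, strand = strand, n3e = 1),
      g2, flank = 10)
    build_pfm(w, 11)
  }
  plus <- mk("+")
  minus <- mk("-")
  # the consensus core is identical regardless of planting strand
  expect_equal(substr(plus$consensus, 5, 11), substr(minus$consensus, 5, 11))
  expect_equal(find_cleavage_offset(plus), find_cleavage_offset(minus))
})
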