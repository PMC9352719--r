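# shared fixtures and independent brute-force oracles

# small deterministic genome/annotation/planting fixture for motif tests
small_planted_fixture <- function(genome_bp = 50000, n_tus = 10, n_sites = 20,
                                  seed = 101) {
  g <- make_genome(genome_bp, 0.5, seed = seed)
  tus <- make_tu_annotation(g, n_tus, 2, seed = seed + 1)
  pl <- plant_cleavage_sites(g, n_sites, seed = seed + 2, tus = tus)
  list(genome0 = g, tus = tus, genome = pl$genome, truth = pl$truth,
       motif_spec = pl$motif_spec)
}

# per-base set-intersection oracle for overlap counting (linear intervals)
overlap_count_oracle <- function(a, b, genome_length) {
  cover <- function(x) {
    v <- rep(FALSE, genome_length)
    for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
    v
  }
  bv <- cover(b)
  av <- cover(a)
  n_a <- sum(vapply(seq_len(nrow(a)), function(i)
    any(bv[(a$start[i] + 1):a$end[i]]), logical(1)))
  n_b <- sum(vapply(seq_len(nrow(b)), function(i)
    any(av[(b$start[i] + 1):b$end[i]]), logical(1)))
  c(n_a, n_b)
}

# recall/precision of called TCSs against planted truth at exact
# position + strand
tcs_recovery <- function(called, truth) {
  key <- function(d) paste(d$position, d$strand)
  tp <- sum(key(called) %in% key(truth))
  c(recall = tp / nrow(truth),
    precision = if (nrow(called) > 0) tp / nrow(called) else 1)
}

# hand-build a TU annotation data.frame
tu_df <- function(start, end, strand, fpkm = 1, contig = "chr") {
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             strand = strand, id = sprintf("TU%03d", seq_along(start)),
             fpkm = fpkm, stringsAsFactors = FALSE)
}

# independent slow metagene oracle for plus-strand TUs on a linear layout:
# returns the per-TU bin matrix computed with explicit loops
metagene_oracle_matrix <- function(values, tus, us, ds, body_bins) {
  rows <- list()
  for (i in seq_len(nrow(tus))) {
    s <- tus$start[i]; e <- tus$end[i]
    stopifnot(tus$strand[i] == "+")
    usv <- values[(s - us + 1):s]
    len <- e - s
    b <- len %/% body_bins
    sizes <- c(rep(b, body_bins - 1), len - (body_bins - 1) * b)
    bodyv <- numeric(body_bins)
    off <- s
    for (j in seq_len(body_bins)) {
      bodyv[j] <- mean(values[(off + 1):(off + sizes[j])])
      off <- off + sizes[j]
    }
    dsv <- values[(e + 1):(e + ds)]
    rows[[i]] <- c(usv, bodyv, dsv)
  }
  do.call(rbind, rows)
}
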