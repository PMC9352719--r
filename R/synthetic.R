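#' Deterministic child seed for a pipeline stage
#'
#' One global seed plus the stage name gives every stochastic stage its own
#' reproducible stream, independent of which other stages run.
#'
#' @param seed integer global seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 104729L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Default cleavage-motif specification
#'
#' The consensus carries the conserved core `TCNTTA` in an AT-rich context:
#' a single conserved C followed, four nucleotides downstream, by the TA
#' dinucleotide at which type-IA topoisomerase I cleaves. The cleavage index
#' (1-based column) points at the first base 3' of the scissile bond, i.e. the
#' A of the TA step. `N` columns are filled at planting time according to the
#' local AT content of the genome.
#'
#' @return list with `consensus` and `cleavage_index`.
#' @export
default_motif_spec <- function() {
  list(consensus = "NNNNTCNTTANNNN", cleavage_index = 10L)
}

#' Generate a random circular genome
#'
#' @param length_bp genome length (>= 10 kb).
#' @param gc_fraction target GC content in (0, 1); G and C (and A and T) are
#'   equiprobable within their class. Boundary values 0 and 1 are allowed for
#'   degenerate test genomes.
#' @param seed integer seed.
#' @return a circular `genome_seq`.
#' @export
make_genome <- function(length_bp, gc_fraction = 0.5, seed = 1L) {
  stopifnot(length_bp >= 10000, gc_fraction >= 0, gc_fraction <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), length_bp, replace = TRUE, prob = p)
  genome_seq(paste(bases, collapse = ""), contig = "chr", circular = TRUE)
}

#' Place non-overlapping transcription units with log-normal expression
#'
#' TUs get random strands, lengths in `tu_len_range`, inter-TU gaps of at
#' least `min_gap` bp, and FPKM-scale expression values drawn log-normally:
#' `fpkm = 10^rnorm(n, log10(5), expr_spread)`, so `expr_spread = 2` spans
#' several orders of magnitude as bacterial transcriptomes do.
#'
#' @param genome a `genome_seq` (circular layout supported).
#' @param n_tus number of TUs (>= 4).
#' @param expr_spread standard deviation of log10 expression.
#' @param seed integer seed.
#' @param min_gap minimum gap between neighbouring TUs in bp.
#' @param tu_len_range length range (bp) TU lengths are drawn from.
#' @return data.frame with columns contig, start, end, strand, id, fpkm
#'   (0-based half-open coordinates).
#' @export
make_tu_annotation <- function(genome, n_tus, expr_spread = 2, seed = 1L,
                               min_gap = 1000, tu_len_range = c(500, 5000)) {
  stopifnot(n_tus >= 4)
  set.seed(seed)
  L <- genome_length(genome)
  len <- round(stats::runif(n_tus, tu_len_range[1], tu_len_range[2]))
  slack <- L - sum(len) - n_tus * min_gap
  if (slack < 0)
    stop("genome too small to place ", n_tus, " TUs with min_gap ", min_gap)
  cuts <- sort(stats::runif(n_tus, 0, slack))
  extra <- diff(c(0, cuts))
  pos <- 0
  start <- integer(n_tus)
  for (i in seq_len(n_tus)) {
    pos <- pos + min_gap + extra[i]
    start[i] <- round(pos)
    pos <- pos + len[i]
  }
  strand <- sample(c("+", "-"), n_tus, replace = TRUE)
  if (length(unique(strand)) == 1L) strand[n_tus] <- setdiff(c("+", "-"), strand[1])
  fpkm <- 10^stats::rnorm(n_tus, log10(5), expr_spread)
  data.frame(contig = genome$contig, start = start, end = start + len,
             strand = strand, id = sprintf("TU%03d", seq_len(n_tus)),
             fpkm = fpkm, stringsAsFactors = FALSE)
}

#' Overwrite genome sequence with cleavage-motif instances
#'
#' Sites are placed (biased with probability `p_up` toward the regions
#' upstream of highly-expressed TUs when an annotation is supplied, otherwise
#' uniformly), alternating strands so each strand carries about half of them.
#' The consensus is written into the genome (reverse-complemented for minus
#' strand sites); `N` columns are drawn according to the AT content of the
#' surrounding 100 bp. The returned truth records, per site, the cleavage
#' position: the first base 3' of the scissile bond on the cleaved strand
#' (the A of the TA step for the default motif).
#'
#' @param genome a `genome_seq`.
#' @param n_sites number of sites to plant.
#' @param motif_spec list with `consensus` (may contain N) and 1-based
#'   `cleavage_index`; see [default_motif_spec()].
#' @param seed integer seed.
#' @param tus optional TU annotation (with `fpkm`) used for upstream bias.
#' @param p_up probability that a site goes upstream of a high-expression TU.
#' @param upstream_window size of the upstream placement window per TU (bp).
#' @return list with elements `genome` (modified), `truth` (data.frame
#'   position/strand, 0-based) and `motif_spec`.
#' @export
plant_cleavage_sites <- function(genome, n_sites, motif_spec = default_motif_spec(),
                                 seed = 1L, tus = NULL, p_up = 0.7,
                                 upstream_window = 5000) {
  cons <- toupper(motif_spec$consensus)
  Lm <- nchar(cons)
  ci <- as.integer(motif_spec$cleavage_index)
  stopifnot(Lm <= 30, ci >= 1, ci <= Lm)
  set.seed(seed)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  cons_chars <- strsplit(cons, "", fixed = TRUE)[[1]]
  high_tus <- NULL
  if (!is.null(tus)) {
    high_tus <- tus[tus$fpkm >= stats::median(tus$fpkm), , drop = FALSE]
  }
  strands <- sample(rep(c("+", "-"), length.out = n_sites))
  anchors <- integer(0)
  attempts <- 0L
  circ_dist <- function(a, b) pmin((a - b) %% L, (b - a) %% L)
  while (length(anchors) < n_sites) {
    attempts <- attempts + 1L
    if (attempts > 100L * n_sites)
      stop("failed to place ", n_sites, " sites without collision")
    if (!is.null(high_tus) && stats::runif(1) < p_up) {
      tu <- high_tus[sample.int(nrow(high_tus), 1), ]
      tss <- if (tu$strand == "+") tu$start else tu$end - 1L
      d <- sample.int(upstream_window, 1)
      g0 <- if (tu$strand == "+") (tss - d) %% L else (tss + d) %% L
    } else {
      g0 <- sample.int(L, 1) - 1L
    }
    if (length(anchors) > 0 && any(circ_dist(g0, anchors) < Lm)) next
    anchors <- c(anchors, g0)
  }
  truth_pos <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    g0 <- anchors[i]
    ctx <- chars[(((g0 - 50):(g0 + Lm + 49)) %% L) + 1L]
    at_local <- mean(ctx %in% c("A", "T"))
    fill <- cons_chars
    nn <- fill == "N"
    if (any(nn)) {
      fill[nn] <- sample(c("A", "T", "C", "G"), sum(nn), replace = TRUE,
                         prob = c(at_local / 2, at_local / 2,
                                  (1 - at_local) / 2, (1 - at_local) / 2))
    }
    if (strands[i] == "-") {
      fill <- strsplit(revcomp(paste(fill, collapse = "")), "", fixed = TRUE)[[1]]
      truth_pos[i] <- (g0 + Lm - ci) %% L
    } else {
      truth_pos[i] <- (g0 + ci - 1L) %% L
    }
    chars[((g0 + 0:(Lm - 1L)) %% L) + 1L] <- fill
  }
  list(genome = genome_seq(paste(chars, collapse = ""), contig = genome$contig,
                           circular = genome$circular),
       truth = data.frame(position = truth_pos, strand = strands,
                          stringsAsFactors = FALSE)[order(truth_pos), ],
       motif_spec = motif_spec)
}

#' Simulate strand-specific Topo-Seq N3E tracks for all four conditions
#'
#' Background 3'-end counts are Poisson with rate `depth / genome_length` at
#' every position, strand and condition. At each planted cleavage site the
#' induced, immunoprecipitated condition (`plusAra_plusIP`) additionally
#' receives `Poisson(S * lambda_bg)` counts at the exact cleavage position on
#' the cleaved strand; no other condition carries planted signal.
#'
#' @param genome a `genome_seq` (only its length and contig are used).
#' @param truth data.frame with `position` (0-based) and `strand`.
#' @param depth expected background 3'-end count per strand per sample.
#' @param S signal-to-background ratio at planted sites.
#' @param replicates biological replicates per condition.
#' @param seed integer seed.
#' @return nested list `set[[condition]][[replicate]]` of `fw`/`rv`
#'   `strand_track` pairs (a "condition set").
#' @export
simulate_toposeq <- function(genome, truth, depth = 2e5, S = 50,
                             replicates = 2, seed = 1L) {
  stopifnot(depth > 0, replicates >= 1)
  set.seed(seed)
  L <- genome_length(genome)
  lambda <- depth / L
  fw_idx <- truth$position[truth$strand == "+"] + 1L
  rv_idx <- truth$position[truth$strand == "-"] + 1L
  out <- lapply(condition_labels, function(cond) {
    lapply(seq_len(replicates), function(r) {
      fw <- stats::rpois(L, lambda)
      rv <- stats::rpois(L, lambda)
      if (cond == "plusAra_plusIP") {
        fw[fw_idx] <- fw[fw_idx] + stats::rpois(length(fw_idx), S * lambda)
        rv[rv_idx] <- rv[rv_idx] + stats::rpois(length(rv_idx), S * lambda)
      }
      list(fw = strand_track(fw, contig = genome$contig, strand = "+"),
           rv = strand_track(rv, contig = genome$contig, strand = "-"))
    })
  })
  names(out) <- condition_labels
  out
}

#' Simulate a ChIP fold-enrichment track with TU-linked structure
#'
#' The factor signal is a baseline of 1 plus, per TU and scaled by its
#' normalized log expression: a promoter peak over TSS +/- `tss_halfwidth`,
#' a body gradient decreasing linearly from the TSS to the TU end, and an
#' upstream exponential decay `exp(-d / L_up)` extending 5' of the TSS (the
#' signature of transcription-generated negative supercoiling accumulating
#' upstream). Multiplicative log-normal noise is applied; the matched input
#' track is flat with the same noise.
#'
#' @param tus TU annotation with `fpkm` (see [make_tu_annotation()]).
#' @param genome_length contig length in bp.
#' @param L_up upstream decay length in bp.
#' @param seed integer seed.
#' @param noise_sd standard deviation of log-normal noise.
#' @param amp_tss,amp_body,amp_up component amplitudes (fold units above
#'   baseline, at maximum expression).
#' @param tss_halfwidth promoter peak half width in bp.
#' @param up_extent how far upstream the decay is laid down (default 5 L_up).
#' @param circular wrap coordinates on a circular contig.
#' @return list with `ip` and `input` `strand_track`s (unstranded).
#' @export
simulate_chip_fe <- function(tus, genome_length, L_up = 10000, seed = 1L,
                             noise_sd = 0.1, amp_tss = 3, amp_body = 2,
                             amp_up = 2, tss_halfwidth = 200,
                             up_extent = 5 * L_up, circular = TRUE) {
  stopifnot(L_up > 0)
  set.seed(seed)
  L <- genome_length
  w <- log2(1 + tus$fpkm)
  if (max(w) > 0) w <- w / max(w)
  sig <- rep(1, L)
  add <- function(pos, val) {
    idx <- (pos %% L) + 1L
    sig[idx] <<- sig[idx] + val
  }
  for (i in seq_len(nrow(tus))) {
    if (w[i] == 0) next
    len <- tus$end[i] - tus$start[i]
    if (tus$strand[i] == "+") {
      tss <- tus$start[i]
      body <- tss + 0:(len - 1L)
      up <- tss - seq_len(up_extent)
    } else {
      tss <- tus$end[i] - 1L
      body <- tss - 0:(len - 1L)
      up <- tss + seq_len(up_extent)
    }
    add(body, amp_body * w[i] * (1 - (0:(len - 1L)) / len))
    add(tss + (-tss_halfwidth):tss_halfwidth, amp_tss * w[i])
    add(up, amp_up * w[i] * exp(-seq_len(up_extent) / L_up))
  }
  ip <- sig * exp(stats::rnorm(L, 0, noise_sd))
  input <- exp(stats::rnorm(L, 0, noise_sd))
  list(ip = strand_track(ip, contig = tus$contig[1], strand = "."),
       input = strand_track(input, contig = tus$contig[1], strand = "."))
}

#' Simulate an RNA-Seq coverage track from known expression
#'
#' Plumbing generator used to exercise FPKM computation: per-base Poisson
#' counts over TU bodies with rates proportional to each TU's FPKM, plus a
#' small uniform background (1% of depth).
#'
#' @param tus TU annotation with `fpkm`.
#' @param genome_length contig length.
#' @param depth expected total fragment count.
#' @param seed integer seed.
#' @param circular wrap TU extents on circular contigs.
#' @return a `strand_track` of per-base fragment counts.
#' @export
simulate_rnaseq <- function(tus, genome_length, depth = 1e6, seed = 1L,
                            circular = TRUE) {
  set.seed(seed)
  L <- genome_length
  lam <- rep(0.01 * depth / L, L)
  norm <- sum(tus$fpkm * (tus$end - tus$start))
  for (i in seq_len(nrow(tus))) {
    pos <- circ_positions(tus$start[i], tus$end[i], L, circular)
    lam[pos + 1L] <- lam[pos + 1L] + 0.99 * depth * tus$fpkm[i] / norm
  }
  strand_track(stats::rpois(L, lam), contig = tus$contig[1], strand = ".")
}

#' Simulate strand-specific DRIP-Seq tracks with an RNase HI control
#'
#' R-loops are planted in a fraction of the eligible (by default the most
#' expressed quartile of) TUs: extra coverage is added over the TU body on the
#' TU's coding strand only, emulating immunoprecipitated RNA:DNA hybrids. The
#' control pair (RNase HI treated, hybrids degraded) carries background only.
#'
#' @param tus TU annotation with `fpkm`.
#' @param genome_length contig length.
#' @param rloop_fraction fraction of eligible TUs that receive an R-loop.
#' @param seed integer seed.
#' @param coverage_depth mean background per-base coverage.
#' @param rloop_strength planted signal in multiples of `coverage_depth`.
#' @param eligible_ids TU ids eligible for planting; default is the top
#'   expression quartile.
#' @param circular wrap TU extents.
#' @return list with `exp` and `ctrl` (each `fw`/`rv` `strand_track` pairs)
#'   and `planted` (ids of TUs carrying an R-loop).
#' @export
simulate_drip <- function(tus, genome_length, rloop_fraction = 0.5, seed = 1L,
                          coverage_depth = 5, rloop_strength = 2,
                          eligible_ids = NULL, circular = TRUE) {
  stopifnot(rloop_fraction >= 0, rloop_fraction <= 1)
  set.seed(seed)
  L <- genome_length
  if (is.null(eligible_ids))
    eligible_ids <- tus$id[tus$fpkm >= stats::quantile(tus$fpkm, 0.75)]
  n_plant <- round(rloop_fraction * length(eligible_ids))
  planted <- if (n_plant > 0) sample(eligible_ids, n_plant) else character(0)
  mk <- function() stats::rpois(L, coverage_depth)
  exp_fw <- mk(); exp_rv <- mk(); ctrl_fw <- mk(); ctrl_rv <- mk()
  for (id in planted) {
    tu <- tus[tus$id == id, ]
    pos <- circ_positions(tu$start, tu$end, L, circular)
    extra <- stats::rpois(length(pos), rloop_strength * coverage_depth)
    if (tu$strand == "+") exp_fw[pos + 1L] <- exp_fw[pos + 1L] + extra
    else exp_rv[pos + 1L] <- exp_rv[pos + 1L] + extra
  }
  ct <- tus$contig[1]
  list(exp = list(fw = strand_track(exp_fw, ct, "+"),
                  rv = strand_track(exp_rv, ct, "-")),
       ctrl = list(fw = strand_track(ctrl_fw, ct, "+"),
                   rv = strand_track(ctrl_rv, ct, "-")),
       planted = sort(planted))
}
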