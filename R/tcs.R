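#' Call single-base topoisomerase cleavage sites from enriched N3E tracks
#'
#' A cleavage site is a position whose enriched N3E exceeds both a
#' distributional threshold `mu + k * sigma` (moments over positions with
#' positive enriched signal on that strand) and an absolute floor in scaled
#' counts. Each qualifying position is emitted as one single-base TCS; no
#' merging is performed, because the assay resolves cleavage to one base.
#'
#' @param enriched_fw,enriched_rv enriched `strand_track`s from
#'   [toposeq_enrichment()].
#' @param k multiplier on the positive-signal standard deviation.
#' @param floor absolute minimum enriched N3E (scaled counts).
#' @param clip_negative if `TRUE`, negative enriched values are set to 0
#'   before thresholding (moments are unchanged: they already use only
#'   positive support).
#' @return data.frame with columns contig, position (0-based), strand, n3e.
#' @export
call_tcs <- function(enriched_fw, enriched_rv, k = 3, floor = 5,
                     clip_negative = FALSE) {
  one <- function(track, strand) {
    v <- track$values
    if (clip_negative) v <- pmax(v, 0)
    pos_support <- v[v > 0]
    if (length(pos_support) == 0)
      stop("no positive enriched signal on strand ", strand)
    # with a single positive position there is no background distribution to
    # estimate; only the absolute floor applies
    if (length(pos_support) >= 2) {
      mu <- mean(pos_support)
      sigma <- stats::sd(pos_support)
      thr <- mu + k * sigma
    } else {
      thr <- -Inf
    }
    idx <- which(v > thr & v >= floor)
    if (length(idx) == 0)
      return(data.frame(contig = character(), position = integer(),
                        strand = character(), n3e = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(contig = track$contig, position = idx - 1L, strand = strand,
               n3e = v[idx], stringsAsFactors = FALSE)
  }
  out <- rbind(one(enriched_fw, "+"), one(enriched_rv, "-"))
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Extract strand-oriented sequence windows around cleavage sites
#'
#' Windows are read 5' to 3' on the cleaved strand and have length
#' `2 * flank`; the cleavage falls between columns `flank` and `flank + 1`
#' (1-based), i.e. the stored TCS coordinate (first base 3' of the scissile
#' bond) sits at column `flank + 1`. Minus-strand windows are
#' reverse-complemented. Circular contigs wrap.
#'
#' @param tcs_list TCS data.frame from [call_tcs()].
#' @param genome a `genome_seq`.
#' @param flank half-window in bp.
#' @return character vector of sequences, one per TCS.
#' @export
extract_tcs_windows <- function(tcs_list, genome, flank = 10) {
  stopifnot(flank >= 1)
  vapply(seq_len(nrow(tcs_list)), function(i) {
    p <- tcs_list$position[i]
    if (tcs_list$strand[i] == "+") {
      seq_window(genome, p - flank, p + flank)
    } else {
      revcomp(seq_window(genome, p - flank + 1, p + flank + 1))
    }
  }, character(1))
}

#' Build a position-frequency matrix from aligned sequences
#'
#' Column base frequencies use a pseudocount of 0.25 per base; `N` characters
#' contribute 0.25 to every base (uninformative). Information content per
#' column is `2 + sum(f * log2(f))` bits against a uniform background; the
#' consensus shows `N` where IC falls below `min_ic`.
#'
#' @param sequences character vector of equal-length sequences (>= 2).
#' @param cleavage_index 1-based column holding the cleavage position.
#' @param pseudocount per-base pseudocount.
#' @param min_ic IC cutoff (bits) below which the consensus letter is N.
#' @return object of class `motif_matrix`: list with `freq` (4 x L matrix,
#'   rows ACGT), `ic`, `consensus`, `cleavage_index`, `n_sequences`.
#' @export
build_pfm <- function(sequences, cleavage_index, pseudocount = 0.25,
                      min_ic = 0.5) {
  stopifnot(length(sequences) >= 2)
  len <- unique(nchar(sequences))
  if (length(len) != 1) stop("sequences must have equal length")
  stopifnot(cleavage_index >= 1, cleavage_index <= len)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
                nrow = length(sequences), byrow = TRUE)
  counts <- sapply(seq_len(len), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    n_amb <- sum(!mat[, j] %in% bases)
    as.numeric(tab) + n_amb * 0.25
  })
  counts <- counts + pseudocount
  freq <- sweep(counts, 2, colSums(counts), "/")
  rownames(freq) <- bases
  ic <- apply(freq, 2, function(f) 2 + sum(f * log2(f)))
  cons <- vapply(seq_len(len), function(j)
    if (ic[j] < min_ic) "N" else bases[which.max(freq[, j])], character(1))
  structure(list(freq = freq, ic = ic, consensus = paste(cons, collapse = ""),
                 cleavage_index = as.integer(cleavage_index),
                 n_sequences = length(sequences)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %d columns, %d sequences, cleavage at column %d\n",
              ncol(x$freq), x$n_sequences, x$cleavage_index))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Distance from the conserved C to the cleavage position
#'
#' Scans the columns 5' of the cleavage index for the column maximizing
#' `IC * f(C)` among columns where C is the modal base with IC at or above
#' `min_ic`, and returns its distance (nt) to the cleavage position. For the
#' topoisomerase I cleavage motif this recovers the 4 nt spacing between the
#' conserved C and the cleaved TA step.
#'
#' @param motif a `motif_matrix`.
#' @param min_ic minimum IC (bits) for a column to qualify.
#' @return integer offset in nt.
#' @export
find_cleavage_offset <- function(motif, min_ic = 0.5) {
  ci <- motif$cleavage_index
  if (ci < 2) stop("no columns upstream of the cleavage index")
  up <- seq_len(ci - 1)
  modal_c <- vapply(up, function(j)
    rownames(motif$freq)[which.max(motif$freq[, j])] == "C", logical(1))
  ok <- modal_c & motif$ic[up] >= min_ic
  if (!any(ok))
    stop("no conserved C column found upstream of the cleavage position")
  score <- motif$ic[up] * motif$freq["C", up]
  score[!ok] <- -Inf
  ci - up[which.max(score)]
}

#' Scan a genome for motif occurrences by log-odds score
#'
#' Every window on both strands is scored as the sum of
#' `log2(f[base, column] / 0.25)`; windows at or above `score_threshold` are
#' returned as intervals (strand set to the matching orientation; the
#' interval start is the 0-based position of the window's first base on the
#' forward strand). Circular contigs wrap.
#'
#' @param genome a `genome_seq`.
#' @param motif a `motif_matrix`.
#' @param score_threshold minimum log-odds score (bits).
#' @return interval data.frame with `score` = log-odds.
#' @export
scan_motif <- function(genome, motif, score_threshold) {
  L <- genome_length(genome)
  W <- ncol(motif$freq)
  stopifnot(W <= L)
  logodds <- log2(pmax(motif$freq, 1e-12) / 0.25)
  score_strand <- function(seqstr) {
    chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    code <- match(chars, c("A", "C", "G", "T"))   # N -> NA, scores 0
    n <- length(code) - W + 1L
    sc <- numeric(n)
    for (j in seq_len(W)) {
      contrib <- logodds[cbind(code[j:(j + n - 1L)], j)]
      contrib[is.na(contrib)] <- 0
      sc <- sc + contrib
    }
    sc
  }
  ext <- if (genome$circular) paste0(genome$sequence,
                                     substr(genome$sequence, 1, W - 1)) else
    genome$sequence
  fw <- score_strand(ext)[seq_len(if (genome$circular) L else L - W + 1L)]
  rv_full <- score_strand(revcomp(ext))
  n_ext <- nchar(ext) - W + 1L
  # reverse-strand window starting (fw coords) at s spans [s, s+W); on the
  # reverse-complemented extended sequence it begins at n_ext - s
  idx <- if (genome$circular) seq_len(L) else seq_len(L - W + 1L)
  rv <- rv_full[n_ext - (idx - 1L)]
  hits <- function(sc, strand) {
    h <- which(sc >= score_threshold)
    if (length(h) == 0) return(NULL)
    intervals(contig = genome$contig, start = h - 1L, end = h - 1L + W,
              strand = strand, name = NA_character_, score = sc[h])
  }
  out <- rbind(hits(fw, "+"), hits(rv, "-"))
  if (is.null(out)) return(intervals(character(), integer(), integer())[0, ])
  out
}

#' Write a motif matrix as a text PFM
#'
#' Four tab-separated rows (A, C, G, T) of column frequencies, preceded by
#' header comment lines naming the cleavage index, sequence count and
#' consensus.
#'
#' @param motif a `motif_matrix`.
#' @param path output file.
#' @export
write_pfm <- function(motif, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# cleavage_index=%d", motif$cleavage_index),
               sprintf("# n_sequences=%d", motif$n_sequences),
               sprintf("# consensus=%s", motif$consensus)), con)
  utils::write.table(format(motif$freq, digits = 10), con, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a text PFM written by [write_pfm()]
#' @param path PFM file.
#' @return a `motif_matrix`.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, "="), "",
                           hdr[startsWith(hdr, paste0("# ", key, "="))])
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            row.names = 1)
  freq <- as.matrix(body)
  colnames(freq) <- NULL
  ic <- apply(freq, 2, function(f) 2 + sum(f * log2(f)))
  structure(list(freq = freq, ic = ic, consensus = get("consensus"),
                 cleavage_index = as.integer(get("cleavage_index")),
                 n_sequences = as.integer(get("n_sequences"))),
            class = "motif_matrix")
}
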