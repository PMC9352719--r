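#' Scale a track to a target total
#'
#' Depth normalization: the track is multiplied by `target_total / total` so
#' that samples of different sequencing depth become comparable. The default
#' target of 1e6 gives counts-per-million.
#'
#' @param track a `strand_track` with positive total.
#' @param target_total desired total signal.
#' @return scaled `strand_track`.
#' @export
scale_track <- function(track, target_total = 1e6) {
  tot <- track_total(track)
  if (tot <= 0) stop("cannot scale an all-zero track")
  strand_track(track$values * (target_total / tot),
               contig = track$contig, strand = track$strand)
}

#' Positionwise mean of replicate tracks
#' @param tracks list of `strand_track`s of equal length and strand.
#' @return a `strand_track`.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  n <- length(tracks[[1]]$values)
  for (t in tracks) {
    if (length(t$values) != n) stop("track length mismatch in average_tracks")
    if (t$strand != tracks[[1]]$strand) stop("strand mismatch in average_tracks")
  }
  v <- Reduce(`+`, lapply(tracks, `[[`, "values")) / length(tracks)
  strand_track(v, contig = tracks[[1]]$contig, strand = tracks[[1]]$strand)
}

#' Positionwise track subtraction (a - b)
#'
#' Negative values are retained: whether to clip is a decision of downstream
#' callers, not of the arithmetic.
#'
#' @param a,b `strand_track`s of equal length.
#' @return a `strand_track`.
#' @export
subtract_tracks <- function(a, b) {
  check_same_shape(a, b)
  strand_track(a$values - b$values, contig = a$contig, strand = a$strand)
}

condition_labels <- c("plusAra_plusIP", "plusAra_minusIP",
                      "minusAra_plusIP", "minusAra_minusIP")

#' Topo-Seq enrichment: scale, average replicates, double subtraction
#'
#' Per strand, replicate tracks of all four conditions (induction +/-Ara
#' crossed with immunoprecipitation +/-IP) are scaled to a common total,
#' averaged within condition, and combined as
#' `(plusAra_plusIP - plusAra_minusIP) - (minusAra_plusIP - minusAra_minusIP)`:
#' the -IP track removes library background, the -Ara track removes
#' induction-independent signal. The stage order is fixed:
#' scale, then average, then subtract.
#'
#' @param condition_set nested list `set[[condition]][[replicate]]`, each
#'   element a list with `fw` and `rv` `strand_track`s; conditions must be
#'   named `plusAra_plusIP`, `plusAra_minusIP`, `minusAra_plusIP`,
#'   `minusAra_minusIP`.
#' @param scale_target common total to scale every sample to; the default
#'   (`NULL`) uses the mean total over all samples so enriched values stay in
#'   read-count units.
#' @param average_first if `FALSE`, subtraction is applied per replicate pair
#'   and the differences averaged (sensitivity-analysis mode; the two orders
#'   agree when replicate counts match).
#' @return list with `fw` and `rv` enriched `strand_track`s.
#' @export
toposeq_enrichment <- function(condition_set, scale_target = NULL,
                               average_first = TRUE) {
  missing <- setdiff(condition_labels, names(condition_set))
  if (length(missing) > 0)
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  # sample total = fw + rv of one replicate (a library is one sample)
  totals <- unlist(lapply(condition_labels, function(cond)
    vapply(condition_set[[cond]], function(r) track_total(r$fw) + track_total(r$rv),
           numeric(1))))
  if (any(totals <= 0)) stop("sample with zero total signal")
  if (is.null(scale_target)) scale_target <- mean(totals)
  scaled <- lapply(condition_labels, function(cond) {
    lapply(condition_set[[cond]], function(r) {
      f <- scale_target / (track_total(r$fw) + track_total(r$rv))
      list(fw = strand_track(r$fw$values * f, r$fw$contig, "+"),
           rv = strand_track(r$rv$values * f, r$rv$contig, "-"))
    })
  })
  names(scaled) <- condition_labels
  one_strand <- function(strand_key) {
    if (average_first) {
      avg <- lapply(scaled, function(reps)
        average_tracks(lapply(reps, `[[`, strand_key)))
      subtract_tracks(
        subtract_tracks(avg$plusAra_plusIP, avg$plusAra_minusIP),
        subtract_tracks(avg$minusAra_plusIP, avg$minusAra_minusIP))
    } else {
      nrep <- min(vapply(scaled, length, integer(1)))
      diffs <- lapply(seq_len(nrep), function(i)
        subtract_tracks(
          subtract_tracks(scaled$plusAra_plusIP[[i]][[strand_key]],
                          scaled$plusAra_minusIP[[i]][[strand_key]]),
          subtract_tracks(scaled$minusAra_plusIP[[i]][[strand_key]],
                          scaled$minusAra_minusIP[[i]][[strand_key]])))
      average_tracks(diffs)
    }
  }
  list(fw = one_strand("fw"), rv = one_strand("rv"))
}

#' Fold enrichment of an IP track over an input track
#'
#' Both tracks are scaled to a common total (by default the mean of their two
#' totals, keeping count units), then the positionwise ratio
#' `(ip + pseudocount) / (input + pseudocount)` is taken. The pseudocount
#' guards positions with zero input coverage.
#'
#' @param ip_track,input_track `strand_track`s of equal length.
#' @param pseudocount positive guard added to both numerator and denominator.
#' @param scale_target common total; `NULL` for the mean of the two totals.
#' @return `strand_track` of fold-enrichment values.
#' @export
fold_enrichment <- function(ip_track, input_track, pseudocount = 1,
                            scale_target = NULL) {
  check_same_shape(ip_track, input_track)
  stopifnot(pseudocount > 0)
  if (is.null(scale_target))
    scale_target <- mean(c(track_total(ip_track), track_total(input_track)))
  ip <- scale_track(ip_track, scale_target)
  inp <- scale_track(input_track, scale_target)
  strand_track((ip$values + pseudocount) / (inp$values + pseudocount),
               contig = ip_track$contig, strand = ip_track$strand)
}

#' Compute FPKM per transcription unit from a coverage/count track
#'
#' FPKM(TU) = C / (L_kb * M) with C the fragments assigned to the TU (summed
#' track counts over its extent), L_kb the TU length in kb and M the total
#' fragments in millions.
#'
#' @param tu_list TU data.frame (columns contig, start, end, strand, id).
#' @param coverage_track `strand_track` of per-base fragment counts.
#' @param circular whether the contig is circular (TU extents may wrap).
#' @return data.frame with columns `id`, `fpkm`.
#' @export
compute_fpkm <- function(tu_list, coverage_track, circular = TRUE) {
  v <- coverage_track$values
  L <- length(v)
  M <- sum(v) / 1e6
  if (M <= 0) stop("coverage track has zero total")
  widths <- tu_list$end - tu_list$start
  if (any(widths <= 0)) stop("zero-length TU in annotation")
  fpkm <- vapply(seq_len(nrow(tu_list)), function(i) {
    pos <- circ_positions(tu_list$start[i], tu_list$end[i], L, circular)
    if (is.null(pos)) return(NA_real_)
    sum(v[pos + 1L]) / ((widths[i] / 1000) * M)
  }, numeric(1))
  data.frame(id = tu_list$id, fpkm = fpkm, stringsAsFactors = FALSE)
}

#' Binned correlation between two tracks
#'
#' Tracks are averaged over non-overlapping windows of `bin_width` bp (the
#' final partial window is kept) and the correlation computed on the binned
#' vectors.
#'
#' @param a,b `strand_track`s of equal length.
#' @param bin_width window size in bp.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p`, `method`, `n_bins`.
#' @export
track_correlation <- function(a, b, bin_width = 1000,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_same_shape(a, b)
  stopifnot(bin_width >= 1)
  f <- (seq_along(a$values) - 1L) %/% bin_width
  av <- tapply(a$values, f, mean)
  bv <- tapply(b$values, f, mean)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("correlation undefined for a constant binned track")
  ct <- suppressWarnings(stats::cor.test(av, bv, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method,
       n_bins = length(av))
}
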