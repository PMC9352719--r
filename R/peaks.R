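#' Threshold peak caller
#'
#' Plumbing caller for fold-enrichment tracks: maximal runs of positions with
#' signal at or above `fe_threshold`, runs separated by at most `merge_gap`
#' bases merged, runs shorter than `min_width` discarded. The peak score is
#' the mean signal over the final peak. Externally-called peak lists (e.g.
#' MACS2 output) can be read with [read_intervals()] instead.
#'
#' @param fe_track `strand_track` of fold-enrichment values.
#' @param fe_threshold calling threshold (> 1).
#' @param min_width minimum peak width in bp.
#' @param merge_gap maximal gap (bp) between runs that are merged.
#' @return interval data.frame (0-based half-open) with scores.
#' @export
call_peaks <- function(fe_track, fe_threshold = 3, min_width = 1, merge_gap = 0) {
  stopifnot(fe_threshold > 1)
  v <- fe_track$values
  r <- rle(v >= fe_threshold)
  e0 <- cumsum(r$lengths)
  s0 <- e0 - r$lengths
  keep <- r$values
  if (!any(keep)) return(intervals(character(), integer(), integer())[0, ])
  s <- s0[keep]; e <- e0[keep]
  if (merge_gap > 0 && length(s) > 1) {
    ms <- s[1]; me <- e[1]; outs <- integer(0); oute <- integer(0)
    for (i in 2:length(s)) {
      if (s[i] - me <= merge_gap) {
        me <- e[i]
      } else {
        outs <- c(outs, ms); oute <- c(oute, me)
        ms <- s[i]; me <- e[i]
      }
    }
    s <- c(outs, ms); e <- c(oute, me)
  }
  wide <- (e - s) >= min_width
  s <- s[wide]; e <- e[wide]
  if (length(s) == 0) return(intervals(character(), integer(), integer())[0, ])
  score <- vapply(seq_along(s), function(i) mean(v[(s[i] + 1):e[i]]), numeric(1))
  intervals(contig = fe_track$contig, start = s, end = e, strand = ".",
            name = sprintf("peak%d", seq_along(s)), score = score)
}

#' Count reciprocal peak overlaps
#'
#' A peak of set `a` counts as overlapping if it shares at least one base with
#' any peak of set `b` (and is counted once however many partners it has);
#' symmetrically for `b`.
#'
#' @param peaks_a,peaks_b interval data.frames.
#' @return integer vector `c(a_in_b, b_in_a)`.
#' @export
overlap_count <- function(peaks_a, peaks_b) {
  hit <- function(x, y) {
    if (nrow(x) == 0 || nrow(y) == 0) return(0L)
    n <- 0L
    for (ct in unique(x$contig)) {
      xs <- x[x$contig == ct, ]; ys <- y[y$contig == ct, ]
      if (nrow(ys) == 0) next
      m <- outer(xs$start, ys$end, `<`) & outer(xs$end, ys$start, `>`)
      n <- n + sum(rowSums(m) > 0)
    }
    n
  }
  c(hit(peaks_a, peaks_b), hit(peaks_b, peaks_a))
}

# count how many of the (possibly wrapping) placed peaks [s, e) hit any b
# interval; bs sorted ascending, prefmax_be = running max of b ends in that
# order. A peak covers [s, min(e, L)) plus, when it wraps, [0, e - L).
count_overlaps_circular <- function(s, e, bs, prefmax_be, L) {
  eL <- pmin(e, L)
  # last b (in sorted order) starting before the peak end
  j <- findInterval(eL - 0.5, bs)
  hit <- j > 0 & prefmax_be[pmax(j, 1)] > s
  wrapped <- e > L
  if (any(wrapped)) {
    jw <- findInterval(e[wrapped] - L - 0.5, bs)
    hit[wrapped] <- hit[wrapped] | jw > 0
  }
  sum(hit)
}

#' Monte-Carlo test for genomic interval overlap enrichment
#'
#' The observed statistic is the number of `peaks_a` overlapping any
#' `peaks_b`. The null re-places every a-peak uniformly at random on the
#' circular genome, preserving widths (placed peaks may overlap each other),
#' and recounts. The one-sided empirical p-value uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (1 + iterations)` so it is never zero.
#'
#' @param peaks_a,peaks_b interval data.frames on one contig.
#' @param genome_length circular genome length in bp.
#' @param iterations number of random placements (>= 100).
#' @param seed integer seed.
#' @return list with `statistic` (observed count), `n_a`, `p`, `iterations`,
#'   and `null` summary (mean, sd, max).
#' @export
montecarlo_overlap_test <- function(peaks_a, peaks_b, genome_length,
                                    iterations = 10000, seed = 1L) {
  stopifnot(iterations >= 100)
  w <- peaks_a$end - peaks_a$start
  if (any(w > genome_length)) stop("peak wider than the genome")
  observed <- overlap_count(peaks_a, peaks_b)[1]
  ord <- order(peaks_b$start)
  bs <- peaks_b$start[ord]
  prefmax_be <- cummax(peaks_b$end[ord])
  set.seed(seed)
  n_a <- length(w)
  null <- integer(iterations)
  for (it in seq_len(iterations)) {
    s <- sample.int(genome_length, n_a, replace = TRUE) - 1L
    null[it] <- count_overlaps_circular(s, s + w, bs, prefmax_be,
                                        genome_length)
  }
  p <- (1 + sum(null >= observed)) / (1 + iterations)
  list(statistic = observed, n_a = n_a, p = p, iterations = iterations,
       null = c(mean = mean(null), sd = stats::sd(null), max = max(null)))
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean_x - mean_y) / sqrt(s2x/nx + s2y/ny)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. When both
#' groups are constant with different means the statistic is infinite; the
#' result is then flagged `degenerate` and p reported at the smallest positive
#' double rather than raising, because near-constant genomic windows do occur.
#'
#' @param x_values,y_values numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p`, group means and sizes, and
#'   `degenerate` flag.
#' @export
welch_t_test <- function(x_values, y_values) {
  nx <- length(x_values); ny <- length(y_values)
  stopifnot(nx >= 2, ny >= 2)
  mx <- mean(x_values); my <- mean(y_values)
  vx <- stats::var(x_values); vy <- stats::var(y_values)
  if (vx == 0 && vy == 0) {
    if (mx == my) stop("Welch t undefined: both groups constant with equal means")
    return(list(statistic = sign(mx - my) * Inf, df = NA_real_,
                p = .Machine$double.xmin, mean_x = mx, mean_y = my,
                n_x = nx, n_y = ny, degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p = p, mean_x = mx, mean_y = my,
       n_x = nx, n_y = ny, degenerate = FALSE)
}

# Welch test tolerating the fully degenerate case (both groups constant with
# equal means -> no evidence of difference: t = 0, p = 1)
welch_pair <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(list(statistic = 0, df = NA_real_, p = 1, mean_x = mean(x),
                mean_y = mean(y), n_x = length(x), n_y = length(y),
                degenerate = TRUE))
  }
  welch_t_test(x, y)
}

#' Compare signal inside vs outside a peak set
#'
#' Partitions every genomic position into inside/outside the peaks and runs a
#' two-sided Welch t-test on the per-position values (position-level
#' distributions, as in violin-plot comparisons of occupancy inside and
#' outside enriched regions).
#'
#' @param track a `strand_track`.
#' @param peaks interval data.frame; must cover neither none nor all of the
#'   genome.
#' @return [welch_t_test()] result plus `n_inside`/`n_outside`.
#' @export
enrichment_inside_outside <- function(track, peaks) {
  v <- track$values
  inside <- rep(FALSE, length(v))
  for (i in seq_len(nrow(peaks))) {
    if (peaks$end[i] > length(v)) stop("peak outside track bounds")
    inside[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
  }
  if (!any(inside) || all(inside)) stop("inside/outside partition is empty")
  res <- welch_pair(v[inside], v[!inside])
  res$n_inside <- res$n_x
  res$n_outside <- res$n_y
  res
}

#' Peak width and base composition summaries
#'
#' Per-peak GC fraction (`(G + C) / width`, N ignored) and width, plus set
#' summaries (median width, mean GC) and, when peak scores are present, the
#' Spearman correlation between log score and AT fraction.
#'
#' @param peaks interval data.frame within genome bounds.
#' @param genome a `genome_seq`.
#' @return list with `per_peak` data.frame, `median_width`, `mean_gc`, and
#'   (when scores exist) `spearman_log_score_at` with `p`.
#' @export
peak_composition <- function(peaks, genome) {
  L <- genome_length(genome)
  if (any(peaks$start < 0 | peaks$end > L)) stop("peak outside genome bounds")
  gc <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- seq_window(genome, peaks$start[i], peaks$end[i])
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    b <- b[b != "N"]
    gc[i] <- if (length(b) == 0) NA_real_ else mean(b %in% c("G", "C"))
  }
  per_peak <- data.frame(name = peaks$name, width = peaks$end - peaks$start,
                         gc = gc, stringsAsFactors = FALSE)
  out <- list(per_peak = per_peak,
              median_width = stats::median(per_peak$width),
              mean_gc = mean(per_peak$gc, na.rm = TRUE))
  if (!all(is.na(peaks$score)) && nrow(peaks) >= 3 && all(peaks$score > 0)) {
    ct <- suppressWarnings(
      stats::cor.test(log(peaks$score), 1 - gc, method = "spearman"))
    out$spearman_log_score_at <- unname(ct$estimate)
    out$spearman_p <- ct$p.value
  }
  out
}

#' Bonferroni adjustment over an emitted comparison family
#'
#' @param p numeric vector of p-values forming one family.
#' @return adjusted p-values (capped at 1).
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
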