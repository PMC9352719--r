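#' Select highly- and least-expressed TU sets
#'
#' HETU = top `n` TUs by FPKM, LETU = bottom `n`, after removing `exclude_ids`
#' (e.g. rRNA operons, whose extreme expression would otherwise dominate).
#' Ties are broken by lexicographic TU id so selection is deterministic.
#'
#' @param expression_table data.frame with `id` and `fpkm`.
#' @param n set size.
#' @param exclude_ids ids removed before ranking.
#' @return list with `hetu`, `letu`, `all` (character id vectors).
#' @export
select_tu_sets <- function(expression_table, n = 200, exclude_ids = NULL) {
  tab <- expression_table[!expression_table$id %in% exclude_ids, , drop = FALSE]
  if (nrow(tab) < 2 * n)
    stop("need at least ", 2 * n, " TUs after exclusions, have ", nrow(tab))
  ord_hi <- order(-tab$fpkm, tab$id)
  ord_lo <- order(tab$fpkm, tab$id)
  list(hetu = tab$id[ord_hi[seq_len(n)]],
       letu = tab$id[ord_lo[seq_len(n)]],
       all = tab$id)
}

# oriented per-TU vector of track values: upstream (far -> TSS), body
# (TSS -> end), downstream; NULL if the windows leave a linear contig
tu_oriented_values <- function(values, tu, us_length, ds_length, circular) {
  L <- length(values)
  if (tu$strand == "+") {
    us <- if (us_length > 0) circ_positions(tu$start - us_length, tu$start, L, circular)
    body <- circ_positions(tu$start, tu$end, L, circular)
    ds <- if (ds_length > 0) circ_positions(tu$end, tu$end + ds_length, L, circular)
  } else {
    us <- if (us_length > 0) rev(circ_positions(tu$end, tu$end + us_length, L, circular))
    body <- rev(circ_positions(tu$start, tu$end, L, circular))
    ds <- if (ds_length > 0) rev(circ_positions(tu$start - ds_length, tu$start, L, circular))
  }
  if ((us_length > 0 && is.null(us)) || is.null(body) ||
      (ds_length > 0 && is.null(ds)))
    return(NULL)
  list(us = values[us + 1L], body = values[body + 1L], ds = values[ds + 1L])
}

bin_means <- function(v, width) {
  if (length(v) == 0) return(numeric(0))
  colMeans(matrix(v, nrow = width))
}

# body partitioned into equal-size bins of floor(len / bins) bp, the last bin
# absorbing the remainder
body_bin_means <- function(v, bins) {
  len <- length(v)
  b <- len %/% bins
  if (b == 0) return(NULL)
  sizes <- c(rep(b, bins - 1), len - (bins - 1) * b)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  vapply(seq_len(bins), function(i) mean(v[starts[i]:ends[i]]), numeric(1))
}

#' Metagene profile over a TU set
#'
#' Per TU: a fixed upstream window 5' of the TSS, the TU body rescaled to
#' `body_bins` equal-fraction bins, and a fixed downstream window 3' of the
#' TU end. Minus-strand TUs have all axes reversed so "upstream" is always 5'
#' of the TSS. The profile is the across-TU mean per bin with its standard
#' error (SEM over TUs, not replicates).
#'
#' @param track a `strand_track`.
#' @param tu_list TU data.frame (contig, start, end, strand, id).
#' @param us_length,ds_length flank lengths in bp (must be multiples of
#'   `flank_bin`).
#' @param body_bins number of body bins.
#' @param flank_bin bin width (bp) for the flanks; 1 = single-base resolution.
#' @param circular wrap windows on circular contigs; on linear contigs TUs
#'   whose windows leave the contig are skipped (count reported in the
#'   `n_skipped` field).
#' @param weights optional per-TU multiplier (e.g. +1/-1 strand projection),
#'   named by TU id or in `tu_list` order.
#' @return object of class `metagene_profile`: list with `mean`, `sem`,
#'   `region` (us/body/ds per bin), `coord` (bin center coordinates: bp
#'   relative to TSS/end for flanks, fraction for body), `n`, `n_skipped`,
#'   `flank_bin`, `us_length`, `ds_length`, `body_bins`, and the per-TU
#'   matrix `per_tu`.
#' @export
metagene_profile <- function(track, tu_list, us_length = 15000,
                             ds_length = 15000, body_bins = 100,
                             flank_bin = 1, circular = TRUE, weights = NULL) {
  stopifnot(nrow(tu_list) >= 1, body_bins >= 1,
            us_length %% flank_bin == 0, ds_length %% flank_bin == 0)
  if (is.null(weights)) weights <- rep(1, nrow(tu_list))
  if (!is.null(names(weights))) weights <- weights[tu_list$id]
  nb_us <- us_length %/% flank_bin
  nb_ds <- ds_length %/% flank_bin
  rows <- list()
  ids <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(tu_list))) {
    vals <- tu_oriented_values(track$values, tu_list[i, ], us_length,
                               ds_length, circular)
    if (is.null(vals)) { n_skipped <- n_skipped + 1L; next }
    body <- body_bin_means(vals$body, body_bins)
    if (is.null(body)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <-
      weights[i] * c(bin_means(vals$us, flank_bin), body,
                     bin_means(vals$ds, flank_bin))
    ids <- c(ids, tu_list$id[i])
  }
  if (length(rows) == 0) stop("no usable TU in metagene_profile")
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  region <- c(rep("us", nb_us), rep("body", body_bins), rep("ds", nb_ds))
  coord <- c(-rev(seq_len(nb_us) * flank_bin - flank_bin / 2),
             (seq_len(body_bins) - 0.5) / body_bins,
             seq_len(nb_ds) * flank_bin - flank_bin / 2)
  sem <- if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m)) else
    rep(0, ncol(m))
  structure(list(mean = colMeans(m),
                 sem = sem,
                 region = region, coord = coord, n = nrow(m),
                 n_skipped = n_skipped, flank_bin = flank_bin,
                 us_length = us_length, ds_length = ds_length,
                 body_bins = body_bins, per_tu = m),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d TUs (%d skipped), %d bins (us %d / body %d / ds %d)\n",
              x$n, x$n_skipped, length(x$mean), sum(x$region == "us"),
              x$body_bins, sum(x$region == "ds")))
  invisible(x)
}

#' Write a metagene profile as TSV (bin, region, coord, mean, sem, n)
#' @param profile a `metagene_profile`.
#' @param path output file.
#' @export
write_metagene_tsv <- function(profile, path) {
  df <- data.frame(bin = seq_along(profile$mean), region = profile$region,
                   coord = profile$coord, mean = profile$mean,
                   sem = profile$sem, n = profile$n)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean signal in US / TSS / TU body / DS regions per TU
#'
#' Strand-aware region means: US = `us_length` bp 5' of the TSS, TSS region =
#' TSS plus/minus `tss_halfwidth` bp inclusive of both endpoints (401
#' positions at the default 200), TU = the TU body, DS = `ds_length` bp 3' of
#' the TU end.
#'
#' @param track a `strand_track`.
#' @param tu_list TU data.frame.
#' @param tss_halfwidth half-width of the TSS region in bp.
#' @param us_length,ds_length flank lengths in bp.
#' @param circular wrap on circular contigs; TUs with off-contig regions on
#'   linear contigs are skipped.
#' @return data.frame with columns tu_id, us, tss, body, ds.
#' @export
quantify_tu_regions <- function(track, tu_list, tss_halfwidth = 200,
                                us_length = 5000, ds_length = 5000,
                                circular = TRUE) {
  v <- track$values
  L <- length(v)
  out <- lapply(seq_len(nrow(tu_list)), function(i) {
    tu <- tu_list[i, ]
    tss <- if (tu$strand == "+") tu$start else tu$end - 1L
    regs <- tu_oriented_values(v, tu, us_length, ds_length, circular)
    tss_pos <- circ_positions(tss - tss_halfwidth, tss + tss_halfwidth + 1L,
                              L, circular)
    if (is.null(regs) || is.null(tss_pos)) return(NULL)
    data.frame(tu_id = tu$id, us = mean(regs$us), tss = mean(v[tss_pos + 1L]),
               body = mean(regs$body), ds = mean(regs$ds),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no usable TU in quantify_tu_regions")
  res
}

#' Compare region means between two TU sets
#'
#' Two-sided Welch t-tests per region with Bonferroni correction over the
#' emitted comparison family.
#'
#' @param regions_a,regions_b outputs of [quantify_tu_regions()].
#' @param regions which region columns to compare.
#' @return data.frame with one row per region: means, t, df, p, p_adj.
#' @export
compare_tu_regions <- function(regions_a, regions_b,
                               regions = c("us", "tss", "body", "ds")) {
  rows <- lapply(regions, function(r) {
    w <- welch_pair(regions_a[[r]], regions_b[[r]])
    data.frame(region = r, mean_a = w$mean_x, mean_b = w$mean_y,
               n_a = w$n_x, n_b = w$n_y, t = w$statistic, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p)
  out
}

#' How far upstream of the TSS does signal stay above background?
#'
#' Scans the upstream part of a metagene profile for runs (of at least
#' `consecutive_bins` bins) where `mean - SEM` exceeds `background_level`,
#' and returns the distance (bp) of the far edge of the farthest such run.
#' Returns 0 when the profile never rises above background and the full
#' upstream length when it never falls back to it. For a noise-free
#' exponential decay `b + A exp(-d/L)` evaluated against
#' `background_level = b + 0.05 A` this returns approximately `3 L`.
#'
#' @param profile a `metagene_profile`.
#' @param background_level detection level in track units.
#' @param consecutive_bins minimum run length (bins) counted as real signal.
#' @return distance in bp.
#' @export
upstream_signal_range <- function(profile, background_level,
                                  consecutive_bins = 3) {
  us <- profile$region == "us"
  stopifnot(any(us))
  above <- (profile$mean[us] - profile$sem[us]) > background_level
  # bins are ordered far -> TSS; distance of bin i's far edge:
  nb <- sum(us)
  dist_far <- (nb:1) * profile$flank_bin
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= consecutive_bins
  if (!any(ok)) return(0)
  dist_far[min(starts[ok])]
}
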