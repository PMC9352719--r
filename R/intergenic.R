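#' Extract intergenic regions between adjacent transcription units
#'
#' One IR per adjacent TU pair whose gap length falls in
#' `[min_len, max_len]`; on circular genomes the wrap-around gap between the
#' last and first TU is included (its `end` then exceeds the genome length
#' and coordinates are taken modulo the length downstream). Overlapping TUs
#' are merged first (merge count reported as an attribute).
#'
#' @param tu_list TU data.frame (contig, start, end, strand, id).
#' @param min_len,max_len IR length bounds in bp.
#' @param genome_length contig length (required for the wrap gap).
#' @param circular include the wrap-around gap?
#' @return data.frame with columns contig, start, end, left_id, left_strand,
#'   right_id, right_strand, length; attribute `n_merged`.
#' @export
extract_irs <- function(tu_list, min_len = 1, max_len = 10000,
                        genome_length = NULL, circular = TRUE) {
  if (nrow(tu_list) < 2) stop("need at least 2 TUs to extract IRs")
  tus <- tu_list[order(tu_list$start), , drop = FALSE]
  # merge overlapping TUs (keeps the first id and strand of each merged run)
  n_merged <- 0L
  keep <- list(tus[1, ])
  for (i in 2:nrow(tus)) {
    last <- keep[[length(keep)]]
    if (tus$start[i] < last$end) {
      last$end <- max(last$end, tus$end[i])
      keep[[length(keep)]] <- last
      n_merged <- n_merged + 1L
    } else {
      keep[[length(keep) + 1L]] <- tus[i, ]
    }
  }
  tus <- do.call(rbind, keep)
  n <- nrow(tus)
  left <- seq_len(n)
  right <- c(seq_len(n)[-1], 1L)
  ir_start <- tus$end[left]
  ir_end <- tus$start[right]
  if (circular) {
    if (is.null(genome_length)) stop("genome_length required for circular IRs")
    ir_end[n] <- tus$start[1] + genome_length
  } else {
    left <- left[-n]; right <- right[-n]
    ir_start <- ir_start[-n]; ir_end <- ir_end[-n]
  }
  len <- ir_end - ir_start
  sel <- len >= min_len & len <= max_len
  out <- data.frame(contig = tus$contig[left][sel],
                    start = ir_start[sel], end = ir_end[sel],
                    left_id = tus$id[left][sel],
                    left_strand = tus$strand[left][sel],
                    right_id = tus$id[right][sel],
                    right_strand = tus$strand[right][sel],
                    length = len[sel], stringsAsFactors = FALSE)
  attr(out, "n_merged") <- n_merged
  out
}

#' Classify intergenic regions by flanking-gene geometry and annotation
#'
#' Orientation: divergent when the left TU is on the minus and the right TU
#' on the plus strand (promoters inside the IR), convergent for plus/minus
#' (terminators inside), tandem otherwise. `tf_flag` marks IRs overlapped by
#' at least one transcription-factor site; `membrane_flag` marks IRs where at
#' least one flanking TU encodes a membrane protein; `flank_expr` is the
#' larger FPKM of the two flanking TUs.
#'
#' @param irs IR data.frame from [extract_irs()].
#' @param tf_sites optional interval data.frame of TF sites.
#' @param membrane_gene_ids optional character vector of membrane TU ids
#'   (unknown ids trigger a warning and are ignored).
#' @param expression_table optional data.frame with `id`, `fpkm`.
#' @param genome_length needed to resolve wrap-around IRs against TF sites.
#' @return `irs` with added columns orientation, tf_flag, membrane_flag,
#'   flank_expr.
#' @export
classify_irs <- function(irs, tf_sites = NULL, membrane_gene_ids = NULL,
                         expression_table = NULL, genome_length = NULL) {
  orientation <- ifelse(irs$left_strand == "-" & irs$right_strand == "+",
                        "divergent",
                 ifelse(irs$left_strand == "+" & irs$right_strand == "-",
                        "convergent", "tandem"))
  tf_flag <- rep(FALSE, nrow(irs))
  if (!is.null(tf_sites) && nrow(tf_sites) > 0) {
    for (i in seq_len(nrow(irs))) {
      s <- irs$start[i]; e <- irs$end[i]
      hit <- any(tf_sites$start < e & tf_sites$end > s)
      if (!hit && !is.null(genome_length) && e > genome_length)
        hit <- any(tf_sites$start < e - genome_length)
      tf_flag[i] <- hit
    }
  }
  membrane_flag <- rep(FALSE, nrow(irs))
  if (!is.null(membrane_gene_ids)) {
    known <- unique(c(irs$left_id, irs$right_id))
    unknown <- setdiff(membrane_gene_ids, known)
    if (length(unknown) > 0)
      warning("membrane list ids not found among flanking TUs: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    membrane_flag <- irs$left_id %in% membrane_gene_ids |
      irs$right_id %in% membrane_gene_ids
  }
  flank_expr <- rep(NA_real_, nrow(irs))
  if (!is.null(expression_table)) {
    fp <- stats::setNames(expression_table$fpkm, expression_table$id)
    flank_expr <- pmax(fp[irs$left_id], fp[irs$right_id])
  }
  irs$orientation <- orientation
  irs$tf_flag <- tf_flag
  irs$membrane_flag <- membrane_flag
  irs$flank_expr <- unname(flank_expr)
  irs
}

#' Per-group IR signal statistics with pairwise Welch comparisons
#'
#' The per-IR statistic is the mean track value over the IR interval
#' (unstranded, wrap-aware). IRs are grouped by the requested keys
#' (`orientation`, `tf_flag`, `membrane_flag`, `expression` — the last
#' stratifies `flank_expr` at its median into low/high); group means and
#' medians are reported and all group pairs compared by Welch t-tests with
#' Bonferroni correction over the emitted family. Groups with fewer than two
#' IRs are dropped.
#'
#' @param track a `strand_track`.
#' @param irs classified IR data.frame.
#' @param grouping_keys subset of
#'   `c("orientation", "tf_flag", "membrane_flag", "expression")`.
#' @param circular wrap IR extents past the contig end.
#' @return list with `per_ir` (IR means + group label), `groups`
#'   (group/n/mean/median) and `comparisons` (pairwise tests).
#' @export
ir_group_stats <- function(track, irs,
                           grouping_keys = "orientation", circular = TRUE) {
  allowed <- c("orientation", "tf_flag", "membrane_flag", "expression")
  stopifnot(all(grouping_keys %in% allowed))
  v <- track$values
  L <- length(v)
  ir_mean <- vapply(seq_len(nrow(irs)), function(i) {
    pos <- circ_positions(irs$start[i], irs$end[i], L, circular)
    if (is.null(pos)) return(NA_real_)
    mean(v[pos + 1L])
  }, numeric(1))
  keys <- lapply(grouping_keys, function(k) {
    if (k == "expression") {
      ifelse(irs$flank_expr >= stats::median(irs$flank_expr, na.rm = TRUE),
             "ELhigh", "ELlow")
    } else if (k == "orientation") irs$orientation
    else ifelse(irs[[k]], paste0("+", toupper(substr(k, 1, 1))),
                paste0("-", toupper(substr(k, 1, 1))))
  })
  group <- do.call(paste, c(keys, sep = "/"))
  per_ir <- data.frame(irs[c("start", "end")], mean_signal = ir_mean,
                       group = group, stringsAsFactors = FALSE)
  per_ir <- per_ir[!is.na(per_ir$mean_signal), ]
  tab <- table(per_ir$group)
  kept <- names(tab)[tab >= 2]
  if (length(kept) < length(tab))
    message("dropping ", length(tab) - length(kept), " group(s) with < 2 IRs")
  per_ir <- per_ir[per_ir$group %in% kept, ]
  groups <- do.call(rbind, lapply(kept, function(g) {
    x <- per_ir$mean_signal[per_ir$group == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               median = stats::median(x), stringsAsFactors = FALSE)
  }))
  comparisons <- NULL
  if (length(kept) >= 2) {
    pairs <- utils::combn(sort(kept), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- per_ir$mean_signal[per_ir$group == pairs[1, j]]
      b <- per_ir$mean_signal[per_ir$group == pairs[2, j]]
      w <- tryCatch(welch_pair(a, b),
                    error = function(e) NULL)
      if (is.null(w)) return(NULL)
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 mean_a = w$mean_x, mean_b = w$mean_y, t = w$statistic,
                 df = w$df, p = w$p, stringsAsFactors = FALSE)
    }))
    if (!is.null(comparisons)) comparisons$p_adj <- bonferroni(comparisons$p)
  }
  list(per_ir = per_ir, groups = groups, comparisons = comparisons)
}

#' Meta-intergene profiles per orientation class
#'
#' IR bodies are rescaled to `body_bins` bins with fixed flanks reaching into
#' the adjacent TUs; IRs are unstranded, so no axis flipping is applied.
#' Profiles are computed separately for each orientation class and for the
#' pooled set (`all`).
#'
#' @param track a `strand_track`.
#' @param irs classified IR data.frame (needs `orientation`).
#' @param flank flank length into the adjacent TUs (bp).
#' @param body_bins number of IR body bins.
#' @param flank_bin flank bin width in bp.
#' @param circular wrap coordinates.
#' @return named list of `metagene_profile`s (`divergent`, `convergent`,
#'   `tandem` as present, plus `all`).
#' @export
meta_intergene_profile <- function(track, irs, flank = 1000, body_bins = 50,
                                   flank_bin = 1, circular = TRUE) {
  as_tus <- data.frame(contig = irs$contig, start = irs$start, end = irs$end,
                       strand = "+", id = sprintf("IR%04d", seq_len(nrow(irs))),
                       stringsAsFactors = FALSE)
  classes <- c(as.list(split(seq_len(nrow(irs)), irs$orientation)),
               list(all = seq_len(nrow(irs))))
  lapply(classes, function(idx)
    metagene_profile(track, as_tus[idx, , drop = FALSE], us_length = flank,
                     ds_length = flank, body_bins = body_bins,
                     flank_bin = flank_bin, circular = circular))
}
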