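#' Signed strand-specific DRIP-Seq signal
#'
#' All four tracks (experimental forward/reverse, RNase HI control
#' forward/reverse) are scaled to a common total; the reverse-strand coverage
#' is subtracted from the forward-strand coverage within each pair, and the
#' control difference is subtracted from the experimental difference:
#' `(exp_fw - exp_rv) - (ctrl_fw - ctrl_rv)`. Positive values mean
#' forward-strand excess of RNase-HI-sensitive (R-loop) signal. The two
#' subtraction steps commute; the order here follows the processing
#' convention of strand difference first.
#'
#' @param exp_fw,exp_rv,ctrl_fw,ctrl_rv `strand_track`s of equal length with
#'   positive totals. Replicates should be averaged upstream
#'   ([average_tracks()]).
#' @param scale_target common total; `NULL` for the mean of the four totals.
#' @return a `strand_track` (strand `"."`) of signed signal.
#' @export
drip_signal <- function(exp_fw, exp_rv, ctrl_fw, ctrl_rv, scale_target = NULL) {
  check_same_shape(exp_fw, exp_rv)
  check_same_shape(exp_fw, ctrl_fw)
  check_same_shape(exp_fw, ctrl_rv)
  totals <- c(track_total(exp_fw), track_total(exp_rv),
              track_total(ctrl_fw), track_total(ctrl_rv))
  if (any(totals <= 0)) stop("all four DRIP tracks need a positive total")
  if (is.null(scale_target)) scale_target <- mean(totals)
  sc <- function(t) scale_track(t, scale_target)$values
  v <- (sc(exp_fw) - sc(exp_rv)) - (sc(ctrl_fw) - sc(ctrl_rv))
  strand_track(v, contig = exp_fw$contig, strand = ".")
}

#' Coding- and template-strand DRIP metagene profiles
#'
#' The signed forward-minus-reverse signal is projected onto TU-relative
#' strands before metagene aggregation: for a plus-strand TU the coding
#' (mRNA-identical) strand value is `+signal`, for a minus-strand TU it is
#' `-signal`; the template profile is the exact negation. R-loops form on the
#' template strand with the nascent RNA, displacing the coding strand, so
#' planted R-loops appear as positive coding-strand signal regardless of TU
#' orientation.
#'
#' @param signal output of [drip_signal()].
#' @param tu_list TU data.frame.
#' @param us_length,ds_length,body_bins,flank_bin,circular passed to
#'   [metagene_profile()].
#' @return list with `coding` and `template` `metagene_profile`s.
#' @export
drip_metagene <- function(signal, tu_list, us_length = 2000, ds_length = 2000,
                          body_bins = 100, flank_bin = 1, circular = TRUE) {
  w <- ifelse(tu_list$strand == "+", 1, -1)
  coding <- metagene_profile(signal, tu_list, us_length = us_length,
                             ds_length = ds_length, body_bins = body_bins,
                             flank_bin = flank_bin, circular = circular,
                             weights = w)
  template <- coding
  template$mean <- -template$mean
  template$per_tu <- -template$per_tu
  list(coding = coding, template = template)
}

#' Per-TU R-loop detection from a signed DRIP signal
#'
#' For each TU the coding-strand projected signal over the body is tested:
#' a TU is called R-loop positive when its body mean exceeds
#' `sem_mult` standard errors (per-position SD over the body / sqrt(n)).
#'
#' @param signal output of [drip_signal()].
#' @param tu_list TU data.frame.
#' @param sem_mult detection multiple of the SEM.
#' @param circular wrap TU extents.
#' @return data.frame with tu_id, body_mean, sem, detected.
#' @export
detect_rloops <- function(signal, tu_list, sem_mult = 3, circular = TRUE) {
  v <- signal$values
  L <- length(v)
  rows <- lapply(seq_len(nrow(tu_list)), function(i) {
    tu <- tu_list[i, ]
    pos <- circ_positions(tu$start, tu$end, L, circular)
    if (is.null(pos)) return(NULL)
    x <- v[pos + 1L] * (if (tu$strand == "+") 1 else -1)
    sem <- stats::sd(x) / sqrt(length(x))
    data.frame(tu_id = tu$id, body_mean = mean(x), sem = sem,
               detected = mean(x) > sem_mult * sem, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
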