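#' Per-base strand-specific signal track
#'
#' Houses N3E (3'-end counts), coverage, fold enrichment or any other per-base
#' signal on one strand of one contig. Values on the reverse strand are stored
#' as non-negative magnitudes; orientation is carried by the `strand` field
#' (and the `.fw`/`.rv` file suffix on disk), not by sign.
#'
#' @param values numeric vector, one value per base (finite).
#' @param contig contig id.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return an object of class `strand_track`.
#' @export
strand_track <- function(values, contig = "chr", strand = ".") {
  stopifnot(is.numeric(values), length(values) > 0L)
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of +, -, .")
  if (any(!is.finite(values))) stop("strand_track values must be finite")
  structure(list(contig = contig, strand = strand, values = as.numeric(values)),
            class = "strand_track")
}

#' @export
print.strand_track <- function(x, ...) {
  cat(sprintf("<strand_track> %s(%s): %d bp, total %.6g\n",
              x$contig, x$strand, length(x$values), sum(x$values)))
  invisible(x)
}

#' Total signal of a track
#' @param track a `strand_track`.
#' @export
track_total <- function(track) sum(track$values)

check_same_shape <- function(a, b) {
  if (length(a$values) != length(b$values))
    stop("track length mismatch: ", length(a$values), " vs ", length(b$values))
  invisible(TRUE)
}

#' Read a bedGraph file into a dense per-base track
#'
#' bedGraph records are 0-based half-open; positions not covered by any record
#' are set to 0. Records must lie within `contig_length`.
#'
#' @param path bedGraph file.
#' @param contig_length length of the contig in bp.
#' @param strand strand label to attach (bedGraph itself is unstranded).
#' @return a `strand_track` of length `contig_length`.
#' @export
read_bedgraph <- function(path, contig_length, strand = ".") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  v <- numeric(contig_length)
  contig <- "chr"
  if (length(gr) > 0L) {
    s0 <- GenomicRanges::start(gr) - 1L        # to 0-based
    e0 <- GenomicRanges::end(gr)               # already exclusive in 0-based
    if (any(e0 > contig_length) || any(s0 < 0L))
      stop("bedGraph record exceeds contig length ", contig_length)
    sc <- S4Vectors::mcols(gr)$score
    for (i in seq_along(s0)) v[(s0[i] + 1L):e0[i]] <- sc[i]
    contig <- as.character(GenomicRanges::seqnames(gr))[1]
  }
  strand_track(v, contig = contig, strand = strand)
}

#' Write a track as run-length-encoded bedGraph
#'
#' Zero runs are omitted. Values are written at full double precision so that
#' a read-back reproduces the track to better than 1e-6 relative.
#'
#' @param track a `strand_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  v <- track$values
  if (any(!is.finite(v))) stop("refusing to write non-finite values")
  r <- rle(v)
  e0 <- cumsum(r$lengths)
  s0 <- e0 - r$lengths
  keep <- r$values != 0
  if (any(keep)) {
    df <- data.frame(chrom = track$contig, start = s0[keep], end = e0[keep],
                     value = format(r$values[keep], digits = 15, trim = TRUE,
                                    scientific = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}
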