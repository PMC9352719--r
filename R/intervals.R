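#' Construct an interval table
#'
#' Intervals are 0-based half-open throughout the package; BED is the native
#' convention and GFF3 is converted on read/write.
#'
#' @param contig,start,end,strand,name,score vectors (recycled) describing the
#'   intervals; `strand` in `+`, `-`, `.`.
#' @return data.frame with columns contig, start, end, strand, name, score.
#' @export
intervals <- function(contig, start, end, strand = ".", name = NA_character_,
                      score = NA_real_) {
  if (length(start) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
                   strand = strand, name = as.character(name),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  bad <- df$end <= df$start
  if (any(bad)) stop("end <= start for record(s): ", paste(which(bad), collapse = ", "))
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  df[order(df$contig, df$start), , drop = FALSE]
}

#' Read intervals from BED or GFF3
#'
#' BED is parsed as 0-based half-open; GFF3 is converted from 1-based inclusive
#' (start - 1, end unchanged). For GFF3 the `ID` attribute (falling back to
#' `Name`) becomes the interval name.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff3"`.
#' @return interval data.frame as from [intervals()].
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (length(gr) == 0L) return(intervals(character(), integer(), integer())[0, ])
  mc <- S4Vectors::mcols(gr)
  nm <- if (format == "bed") {
    if ("name" %in% names(mc)) as.character(mc$name) else NA_character_
  } else {
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
    alt <- if ("Name" %in% names(mc)) as.character(mc$Name) else NA_character_
    ifelse(is.na(id), alt, id)
  }
  sc <- if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  intervals(contig = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,   # 1-based -> 0-based
            end = GenomicRanges::end(gr),
            strand = st, name = nm, score = sc)
}

#' Write intervals to BED6 or GFF3
#'
#' @param x interval data.frame.
#' @param path output file.
#' @param format `"bed"` or `"gff3"`.
#' @param type GFF3 feature type for every record.
#' @export
write_intervals <- function(x, path, format = c("bed", "gff3"), type = "gene") {
  format <- match.arg(format)
  if (format == "bed") {
    df <- data.frame(chrom = x$contig, start = x$start, end = x$end,
                     name = ifelse(is.na(x$name), ".", x$name),
                     score = ifelse(is.na(x$score), 0, x$score),
                     strand = ifelse(x$strand == ".", ".", x$strand))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    attrs <- ifelse(is.na(x$name), paste0("ID=iv", seq_len(nrow(x))),
                    paste0("ID=", x$name, ";Name=", x$name))
    df <- data.frame(seqid = x$contig, source = "toposeqr", type = type,
                     start = x$start + 1L, end = x$end,
                     score = ifelse(is.na(x$score), ".", as.character(x$score)),
                     strand = ifelse(x$strand == ".", ".", x$strand),
                     phase = ".", attributes = attrs)
    con <- file(path, "w")
    writeLines("##gff-version 3", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(path)
}
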