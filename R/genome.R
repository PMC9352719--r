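#' Genome sequence container
#'
#' A minimal container for one contig: the sequence (uppercase ACGTN), its id,
#' and whether the molecule is circular. Bacterial chromosomes and plasmids are
#' circular; circularity controls coordinate wrap-around in window extraction,
#' metagene flanks and Monte-Carlo peak placement.
#'
#' @param sequence single character string over A/C/G/T/N.
#' @param contig contig id.
#' @param circular logical; is the molecule circular?
#' @return an object of class `genome_seq`.
#' @export
genome_seq <- function(sequence, contig = "chr", circular = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    warning("non-ACGTN characters replaced by N in contig ", contig)
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  structure(list(contig = contig, sequence = sequence, circular = isTRUE(circular)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp%s\n", x$contig, nchar(x$sequence),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Genome length in bp
#' @param genome a `genome_seq`.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Extract a genomic window, 0-based half-open
#'
#' Coordinates may run past either end of a circular contig; the window then
#' wraps. On a linear contig out-of-range coordinates are an error.
#'
#' @param genome a `genome_seq`.
#' @param start,end 0-based half-open window.
#' @return character string of length `end - start`.
#' @export
seq_window <- function(genome, start, end) {
  L <- genome_length(genome)
  stopifnot(end > start)
  if (start >= 0L && end <= L) return(substr(genome$sequence, start + 1L, end))
  if (!genome$circular)
    stop("window [", start, ",", end, ") outside linear contig of length ", L)
  pos <- (seq.int(start, end - 1L) %% L) + 1L
  # wrap: at most two contiguous pieces
  paste(substring(genome$sequence, pos, pos), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file
#'
#' Sequences are uppercased; any character outside A/C/G/T/N is mapped to N
#' with a warning. Duplicate contig ids or an empty file are format errors.
#'
#' @param path FASTA file.
#' @param circular logical flag applied to every record.
#' @return list of `genome_seq`, one per record.
#' @export
read_fasta <- function(path, circular = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  out <- lapply(seq_along(set), function(i)
    genome_seq(as.character(set[[i]]), contig = ids[i], circular = circular))
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#' @param genomes a `genome_seq` or list of them.
#' @param path output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence, character(1)))
  names(set) <- vapply(genomes, function(g) g$contig, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# 0-based positions of [start, end) with circular wrap; NULL if off a linear contig
circ_positions <- function(start, end, L, circular) {
  if (start >= 0 && end <= L) return(seq.int(start, end - 1L))
  if (!circular) return(NULL)
  seq.int(start, end - 1L) %% L
}
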