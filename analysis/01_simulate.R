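#!/usr/bin/env Rscript
# Stage 1: build the synthetic study and write its ground truth.
#
# Outputs: genome FASTA, TU annotation (GFF3), expression table, planted
# cleavage-site truth, and a summary of the study design.

source("analysis/00_common.R")

message("Building the synthetic study (seed ", STUDY_SEED, ") ...")
study <- build_study()

write_fasta(study$genome, file.path(RESULTS, "genome.fasta"))
write_intervals(
  data.frame(contig = study$tus$contig, start = study$tus$start,
             end = study$tus$end, strand = study$tus$strand,
             name = study$tus$id, score = NA_real_),
  file.path(RESULTS, "tus.gff3"), format = "gff3")
write_result_tsv(study$tus[c("id", "fpkm")], "expression.tsv")
write_result_tsv(study$truth, "truth_tcs.tsv")

expr <- sort(study$tus$fpkm, decreasing = TRUE)
message(sprintf("genome: %d bp circular, GC %.3f", genome_length(study$genome),
                mean(strsplit(study$genome$sequence, "")[[1]] %in% c("G", "C"))))
message(sprintf("TUs: %d (%d forward / %d reverse), FPKM %.2g-%.2g (ratio %.0f)",
                nrow(study$tus), sum(study$tus$strand == "+"),
                sum(study$tus$strand == "-"), min(expr), max(expr),
                max(expr) / min(expr)))
message(sprintf("planted cleavage sites: %d (%d forward / %d reverse), motif %s, cut at column %d",
                nrow(study$truth), sum(study$truth$strand == "+"),
                sum(study$truth$strand == "-"), study$motif_spec$consensus,
                study$motif_spec$cleavage_index))
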