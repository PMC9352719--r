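#!/usr/bin/env Rscript
# Stage 5: intergenic-region extraction, orientation/expression
# classification and per-group enrichment statistics.

source("analysis/00_common.R")

study <- build_study()
chip <- study_chip(study)
fe <- fold_enrichment(chip$ip, chip$input)
gl <- genome_length(study$genome)

irs <- extract_irs(study$tus, min_len = 1, max_len = 10000,
                   genome_length = gl)
irs <- classify_irs(irs, expression_table = study$tus[c("id", "fpkm")],
                    genome_length = gl)
tab <- table(irs$orientation)
message(sprintf("%d IRs within the 1 bp-10 kb length window: %s",
                nrow(irs),
                paste(names(tab), as.integer(tab), sep = " = ",
                      collapse = ", ")))
write_result_tsv(irs, "ir_table.tsv")

st <- ir_group_stats(fe, irs, grouping_keys = c("orientation", "expression"))
write_result_tsv(st$groups, "ir_groups.tsv")
write_result_tsv(st$comparisons, "ir_comparisons.tsv")
message("mean ChIP fold enrichment per IR group:")
for (i in order(-st$groups$mean)) {
  message(sprintf("  %-20s n = %2d  mean FE = %.2f", st$groups$group[i],
                  st$groups$n[i], st$groups$mean[i]))
}

mp <- meta_intergene_profile(fe, irs, flank = 1000, body_bins = 20,
                             flank_bin = 50)
for (cls in names(mp))
  write_metagene_tsv(mp[[cls]],
                     file.path(RESULTS, sprintf("meta_ir_%s.tsv", cls)))
message(sprintf("meta-intergene profiles written for: %s",
                paste(names(mp), collapse = ", ")))
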