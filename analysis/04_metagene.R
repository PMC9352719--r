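#!/usr/bin/env Rscript
# Stage 4: metagene analysis of ChIP enrichment over HETU and LETU sets,
# US/TSS/TU/DS region quantification with Welch/Bonferroni statistics, and
# the upstream extent of the enrichment signal.

source("analysis/00_common.R")

study <- build_study()
chip <- study_chip(study)
fe <- fold_enrichment(chip$ip, chip$input)

sets <- select_tu_sets(study$tus[c("id", "fpkm")], n = 20)
hetu <- study$tus[study$tus$id %in% sets$hetu, ]
letu <- study$tus[study$tus$id %in% sets$letu, ]
message(sprintf("HETU (top 20): FPKM >= %.3g; LETU (bottom 20): FPKM <= %.3g",
                min(hetu$fpkm), max(letu$fpkm)))

prof_h <- metagene_profile(fe, hetu, us_length = 15000, ds_length = 15000,
                           body_bins = 50, flank_bin = 100)
prof_l <- metagene_profile(fe, letu, us_length = 15000, ds_length = 15000,
                           body_bins = 50, flank_bin = 100)
write_metagene_tsv(prof_h, file.path(RESULTS, "metagene_hetu.tsv"))
write_metagene_tsv(prof_l, file.path(RESULTS, "metagene_letu.tsv"))

qh <- quantify_tu_regions(fe, hetu)
ql <- quantify_tu_regions(fe, letu)
cmp <- compare_tu_regions(qh, ql)
write_result_tsv(qh, "regions_hetu.tsv")
write_result_tsv(ql, "regions_letu.tsv")
write_result_tsv(cmp, "region_comparisons.tsv")
message("HETU vs LETU mean enrichment per region (Welch t, Bonferroni-adjusted p):")
for (i in seq_len(nrow(cmp))) {
  message(sprintf("  %-5s %.2f vs %.2f  t = %6.1f  p_adj = %s", cmp$region[i],
                  cmp$mean_a[i], cmp$mean_b[i], cmp$t[i],
                  format(cmp$p_adj[i], digits = 3)))
}

# how far upstream of the TSS does HETU enrichment persist above background?
bg <- median(prof_l$mean)
range_bp <- upstream_signal_range(prof_h, background_level = bg * 1.1,
                                  consecutive_bins = 3)
message(sprintf("HETU enrichment tracked up to ~%.1f kb upstream of the TSS (threshold: 110%% of the LETU background)",
                range_bp / 1000))
write_result_tsv(data.frame(upstream_range_bp = range_bp,
                            background_level = bg * 1.1),
                 "upstream_range.tsv")
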