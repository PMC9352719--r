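#!/usr/bin/env Rscript
# Stage 3: ChIP fold enrichment, peak calling, and colocalization of binding
# with cleavage by Monte-Carlo interval statistics.

source("analysis/00_common.R")

study <- build_study()
message("Simulating ChIP IP/input tracks ...")
chip <- study_chip(study)
fe <- fold_enrichment(chip$ip, chip$input)
write_bedgraph(fe, file.path(RESULTS, "chip_fe.bedgraph"))

peaks <- call_peaks(fe, fe_threshold = 2, min_width = 50, merge_gap = 100)
comp <- peak_composition(peaks, study$genome)
message(sprintf("called %d peaks (median width %d bp, mean GC %.3f)",
                nrow(peaks), comp$median_width, comp$mean_gc))
write_intervals(peaks, file.path(RESULTS, "chip_peaks.bed"), format = "bed")

# do peaks colocalize with planted cleavage sites?
tcs_iv <- intervals(contig = study$genome$contig,
                    start = study$truth$position,
                    end = study$truth$position + 1L,
                    strand = study$truth$strand)
ov <- overlap_count(peaks, tcs_iv)
mc <- montecarlo_overlap_test(peaks, tcs_iv, genome_length(study$genome),
                              iterations = 10000,
                              seed = derive_seed(study$seed, "mc"))
message(sprintf("%d/%d peaks overlap a cleavage site (null mean %.1f); Monte-Carlo p = %.2g at %d iterations",
                ov[1], nrow(peaks), mc$null["mean"], mc$p, mc$iterations))

io <- enrichment_inside_outside(fe, peaks)
message(sprintf("fold enrichment inside peaks %.2f vs outside %.2f (Welch t = %.1f, p %s)",
                io$mean_x, io$mean_y, io$statistic,
                format(io$p, digits = 3)))

ts <- study_toposeq(study)
rep_cor <- track_correlation(ts$plusAra_plusIP[[1]]$fw,
                             ts$plusAra_plusIP[[2]]$fw, bin_width = 1000)
message(sprintf("replicate Pearson correlation (1 kb bins): %.3f (background-dominated Poisson tracks share only the planted spikes)",
                rep_cor$estimate))

write_result_tsv(data.frame(
  n_peaks = nrow(peaks), median_width = comp$median_width,
  mean_gc = comp$mean_gc, peaks_overlapping_tcs = ov[1],
  mc_null_mean = unname(mc$null["mean"]), mc_p = mc$p,
  inside_mean = io$mean_x, outside_mean = io$mean_y,
  welch_t = io$statistic, welch_p = io$p,
  replicate_pearson = rep_cor$estimate), "peak_stats.tsv")
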