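#!/usr/bin/env Rscript
# Stage 6: strand-specific DRIP-Seq processing: forward-minus-reverse
# coverage, RNase HI control subtraction, coding/template metagenes and
# per-TU R-loop detection against the planted truth.

source("analysis/00_common.R")

study <- build_study()
message("Simulating DRIP experiment + RNase HI control ...")
d <- study_drip(study, rloop_fraction = 0.5)

sig <- drip_signal(d$exp$fw, d$exp$rv, d$ctrl$fw, d$ctrl$rv)
write_bedgraph(sig, file.path(RESULTS, "drip_signal.bedgraph"))

sets <- select_tu_sets(study$tus[c("id", "fpkm")], n = 20)
hetu <- study$tus[study$tus$id %in% sets$hetu, ]
letu <- study$tus[study$tus$id %in% sets$letu, ]
ph <- drip_metagene(sig, hetu, us_length = 2000, ds_length = 2000,
                    body_bins = 50, flank_bin = 50)
pl <- drip_metagene(sig, letu, us_length = 2000, ds_length = 2000,
                    body_bins = 50, flank_bin = 50)
write_metagene_tsv(ph$coding, file.path(RESULTS, "drip_coding_hetu.tsv"))
write_metagene_tsv(ph$template, file.path(RESULTS, "drip_template_hetu.tsv"))
write_metagene_tsv(pl$coding, file.path(RESULTS, "drip_coding_letu.tsv"))
message(sprintf("HETU coding-strand body mean %.2f vs template %.2f; LETU coding %.2f",
                mean(ph$coding$mean[ph$coding$region == "body"]),
                mean(ph$template$mean[ph$template$region == "body"]),
                mean(pl$coding$mean[pl$coding$region == "body"])))

calls <- detect_rloops(sig, study$tus)
calls$planted <- calls$tu_id %in% d$planted
write_result_tsv(calls, "rloop_calls.tsv")
message(sprintf("R-loops planted in %d TUs; detected in %d of them (%.0f%%) and in %d/%d unplanted TUs",
                length(d$planted), sum(calls$detected & calls$planted),
                100 * mean(calls$detected[calls$planted]),
                sum(calls$detected & !calls$planted),
                sum(!calls$planted)))
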