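# Shared study definition for the analysis scripts.
#
# The synthetic study emulates the signal structure of strand-specific
# topoisomerase I mapping on a bacterial chromosome: a 1 Mb circular genome,
# 100 transcription units with a log-normal expression spread, 200 planted
# cleavage-motif instances (biased upstream of highly-expressed TUs), four
# Topo-Seq conditions (induction x immunoprecipitation) with two replicates
# at 2e5 3'-ends per strand and signal-to-background 50, ChIP enrichment with
# a 10 kb upstream decay, RNA-Seq coverage, and strand-specific DRIP with an
# RNase HI control. Every script regenerates the pieces it needs from the
# same global seed, so the scripts are independent and deterministic.

library(toposeqr)

STUDY_SEED <- 1L
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

build_study <- function(seed = STUDY_SEED) {
  genome0 <- make_genome(1e6, 0.5, seed = derive_seed(seed, "genome"))
  tus <- make_tu_annotation(genome0, 100, 2, seed = derive_seed(seed, "tus"))
  planted <- plant_cleavage_sites(genome0, 200,
                                  seed = derive_seed(seed, "sites"), tus = tus)
  list(seed = seed, genome = planted$genome, tus = tus,
       truth = planted$truth, motif_spec = planted$motif_spec)
}

study_toposeq <- function(study, S = 50, replicates = 2) {
  simulate_toposeq(study$genome, study$truth, depth = 2e5, S = S,
                   replicates = replicates,
                   seed = derive_seed(study$seed, "toposeq"))
}

study_chip <- function(study, L_up = 10000) {
  simulate_chip_fe(study$tus, genome_length(study$genome), L_up = L_up,
                   seed = derive_seed(study$seed, "chip"))
}

study_drip <- function(study, rloop_fraction = 0.5) {
  simulate_drip(study$tus, genome_length(study$genome),
                rloop_fraction = rloop_fraction,
                seed = derive_seed(study$seed, "drip"))
}

write_result_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 8, trim = TRUE,
                                                scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
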