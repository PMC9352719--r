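#' Default pipeline configuration
#'
#' Returns the full configuration list with every parameter at its default.
#' The defaults define the standard synthetic study: a 1 Mb circular genome,
#' 100 TUs with a log-normal expression spread of two orders of magnitude,
#' 200 planted cleavage sites following the default motif, Topo-Seq depth of
#' 2e5 3'-ends per strand with signal-to-background 50 and two replicates,
#' a 10 kb upstream ChIP decay length, and DRIP R-loops in half of the top
#' expression quartile.
#'
#' @param out_dir output directory.
#' @param seed global seed; every stochastic stage derives its own child seed
#'   from it via [derive_seed()].
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = "toposeqr_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, tracks = TRUE, peaks = TRUE, tcs = TRUE,
                  motif = TRUE, metagene = TRUE, ir = TRUE, drip = TRUE),
    simulate = list(genome_length = 1e6, gc_fraction = 0.5, n_tus = 100,
                    expr_spread = 2, n_sites = 200, depth = 2e5, S = 50,
                    replicates = 2, L_up = 10000, rloop_fraction = 0.5,
                    rnaseq_depth = 1e6),
    inputs = list(genome_fasta = NULL, tu_gff = NULL, expression_tsv = NULL),
    tcs = list(k = 3, floor = 5, flank = 10),
    peaks = list(fe_threshold = 2, min_width = 50, merge_gap = 100,
                 mc_iterations = 1000),
    metagene = list(n_sets = 20, us_length = 15000, ds_length = 15000,
                    body_bins = 50, flank_bin = 100,
                    tss_halfwidth = 200, quant_us = 5000, quant_ds = 5000),
    ir = list(min_len = 1, max_len = 10000, flank = 1000, body_bins = 20,
              flank_bin = 50),
    drip = list(us_length = 2000, ds_length = 2000, body_bins = 50,
                flank_bin = 50))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [default_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 10, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic Topo-Seq / ChIP / DRIP analysis pipeline
#'
#' Executes the enabled stages in order (simulate, tracks, peaks, tcs, motif,
#' metagene, ir, drip), writing tables as TSV, tracks as bedGraph, the motif
#' as a text PFM and a provenance log recording every parameter, the seed and
#' the configuration hash. Re-running with the same configuration and seed
#' produces byte-identical tables. Stage inputs are validated before any
#' computation: with the simulate stage disabled, genome/annotation/
#' expression inputs must be supplied in `config$inputs`.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @return (invisibly) the output directory; side effect: files under it.
#' @export
run_pipeline <- function(config = default_config()) {
  st <- config$stages
  if (!isTRUE(st$simulate)) {
    need <- c("genome_fasta", "tu_gff", "expression_tsv")
    missing <- need[vapply(config$inputs[need], is.null, logical(1))]
    if (any(vapply(st[c("metagene", "ir")], isTRUE, logical(1))) &&
        (length(missing) > 0 || is.null(config$inputs$fe_bedgraph)))
      stop("simulate disabled but required inputs missing: ",
           paste(c(missing,
                   if (is.null(config$inputs$fe_bedgraph)) "fe_bedgraph"),
                 collapse = ", "))
    if (any(vapply(st[c("tracks", "peaks", "tcs", "motif", "drip")],
                   isTRUE, logical(1))))
      stop("stages tracks/peaks/tcs/motif/drip operate on simulated raw ",
           "tracks; enable the simulate stage or disable them")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  prov <- c(sprintf("config_hash: %s", config_hash(config)),
            sprintf("seed: %d", seed),
            sprintf("run_at: <deterministic omitted>"),
            paste0("config: ", deparse(config)))
  writeLines(prov, file.path(out, "provenance.log"))

  sim <- NULL
  if (isTRUE(st$simulate)) {
    p <- config$simulate
    genome0 <- make_genome(p$genome_length, p$gc_fraction,
                           derive_seed(seed, "genome"))
    tus <- make_tu_annotation(genome0, p$n_tus, p$expr_spread,
                              derive_seed(seed, "tus"))
    planted <- plant_cleavage_sites(genome0, p$n_sites,
                                    seed = derive_seed(seed, "sites"),
                                    tus = tus)
    genome <- planted$genome
    cs <- simulate_toposeq(genome, planted$truth, depth = p$depth, S = p$S,
                           replicates = p$replicates,
                           seed = derive_seed(seed, "toposeq"))
    chip <- simulate_chip_fe(tus, genome_length(genome), L_up = p$L_up,
                             seed = derive_seed(seed, "chip"))
    rna <- simulate_rnaseq(tus, genome_length(genome), depth = p$rnaseq_depth,
                           seed = derive_seed(seed, "rnaseq"))
    drip_sim <- simulate_drip(tus, genome_length(genome),
                              rloop_fraction = p$rloop_fraction,
                              seed = derive_seed(seed, "drip"))
    write_fasta(genome, file.path(out, "genome.fasta"))
    write_intervals(data.frame(contig = tus$contig, start = tus$start,
                               end = tus$end, strand = tus$strand,
                               name = tus$id, score = NA_real_),
                    file.path(out, "tus.gff3"), format = "gff3")
    write_tsv(tus[c("id", "fpkm")], file.path(out, "expression.tsv"))
    write_tsv(planted$truth, file.path(out, "truth_tcs.tsv"))
    write_tsv(data.frame(id = drip_sim$planted),
              file.path(out, "truth_rloops.tsv"))
    sim <- list(genome = genome, tus = tus, truth = planted$truth,
                motif_spec = planted$motif_spec, cs = cs, chip = chip,
                rna = rna, drip = drip_sim)
  } else {
    genome <- read_fasta(config$inputs$genome_fasta, circular = TRUE)[[1]]
    tu_iv <- read_intervals(config$inputs$tu_gff, format = "gff3")
    expr <- utils::read.delim(config$inputs$expression_tsv,
                              stringsAsFactors = FALSE)
    tus <- data.frame(contig = tu_iv$contig, start = tu_iv$start,
                      end = tu_iv$end, strand = tu_iv$strand,
                      id = tu_iv$name, stringsAsFactors = FALSE)
    tus$fpkm <- expr$fpkm[match(tus$id, expr$id)]
    fe <- read_bedgraph(config$inputs$fe_bedgraph, genome_length(genome))
    sim <- list(genome = genome, tus = tus, fe = fe)
  }

  enriched <- NULL
  if (isTRUE(st$tracks)) {
    enriched <- toposeq_enrichment(sim$cs)
    write_bedgraph(enriched$fw, file.path(out, "enriched_n3e.fw.bedgraph"))
    write_bedgraph(enriched$rv, file.path(out, "enriched_n3e.rv.bedgraph"))
    fe <- fold_enrichment(sim$chip$ip, sim$chip$input)
    write_bedgraph(fe, file.path(out, "chip_fe.bedgraph"))
    fpkm <- compute_fpkm(sim$tus, sim$rna)
    write_tsv(fpkm, file.path(out, "fpkm.tsv"))
    corr <- track_correlation(
      sim$cs$plusAra_plusIP[[1]]$fw,
      sim$cs$plusAra_plusIP[[min(2, length(sim$cs$plusAra_plusIP))]]$fw,
      bin_width = 1000, method = "pearson")
    write_tsv(data.frame(comparison = "plusAra_plusIP_rep1_vs_rep2_fw",
                         method = corr$method, estimate = corr$estimate,
                         p = corr$p, n_bins = corr$n_bins),
              file.path(out, "replicate_correlation.tsv"))
    sim$fe <- fe
  }

  peaks <- NULL
  if (isTRUE(st$peaks)) {
    p <- config$peaks
    peaks <- call_peaks(sim$fe, fe_threshold = p$fe_threshold,
                        min_width = p$min_width, merge_gap = p$merge_gap)
    write_intervals(peaks, file.path(out, "chip_peaks.bed"), format = "bed")
    # colocalization of ChIP peaks with planted cleavage positions
    tcs_iv <- intervals(contig = sim$genome$contig,
                        start = sim$truth$position,
                        end = sim$truth$position + 1L,
                        strand = sim$truth$strand)
    mc <- montecarlo_overlap_test(peaks, tcs_iv,
                                  genome_length(sim$genome),
                                  iterations = p$mc_iterations,
                                  seed = derive_seed(seed, "mc"))
    comp <- peak_composition(peaks, sim$genome)
    io <- enrichment_inside_outside(sim$fe, peaks)
    write_tsv(data.frame(
      n_peaks = nrow(peaks), median_width = comp$median_width,
      mean_gc = comp$mean_gc, mc_overlap = mc$statistic, mc_p = mc$p,
      inside_mean = io$mean_x, outside_mean = io$mean_y,
      welch_t = io$statistic, welch_p = io$p),
      file.path(out, "peak_stats.tsv"))
  }

  tcs <- NULL
  if (isTRUE(st$tcs)) {
    p <- config$tcs
    if (is.null(enriched)) enriched <- toposeq_enrichment(sim$cs)
    tcs <- call_tcs(enriched$fw, enriched$rv, k = p$k, floor = p$floor)
    write_intervals(intervals(contig = tcs$contig, start = tcs$position,
                              end = tcs$position + 1L, strand = tcs$strand,
                              name = sprintf("tcs%d", seq_len(nrow(tcs))),
                              score = tcs$n3e),
                    file.path(out, "tcs.bed"), format = "bed")
    write_tsv(data.frame(strand = c("+", "-"),
                         n = c(sum(tcs$strand == "+"), sum(tcs$strand == "-"))),
              file.path(out, "tcs_counts.tsv"))
  }

  if (isTRUE(st$motif)) {
    p <- config$tcs
    if (is.null(tcs)) stop("motif stage requires the tcs stage")
    win <- extract_tcs_windows(tcs, sim$genome, flank = p$flank)
    pfm <- build_pfm(win, cleavage_index = p$flank + 1L)
    offset <- tryCatch(find_cleavage_offset(pfm), error = function(e) NA_integer_)
    write_pfm(pfm, file.path(out, "cleavage_motif.pfm"))
    write_tsv(data.frame(consensus = pfm$consensus, n_sequences = pfm$n_sequences,
                         cleavage_offset_nt = offset),
              file.path(out, "motif_report.tsv"))
  }

  if (isTRUE(st$metagene)) {
    p <- config$metagene
    sets <- select_tu_sets(sim$tus[c("id", "fpkm")], n = p$n_sets)
    hetu <- sim$tus[sim$tus$id %in% sets$hetu, ]
    letu <- sim$tus[sim$tus$id %in% sets$letu, ]
    prof_h <- metagene_profile(sim$fe, hetu, us_length = p$us_length,
                               ds_length = p$ds_length,
                               body_bins = p$body_bins,
                               flank_bin = p$flank_bin)
    prof_l <- metagene_profile(sim$fe, letu, us_length = p$us_length,
                               ds_length = p$ds_length,
                               body_bins = p$body_bins,
                               flank_bin = p$flank_bin)
    write_metagene_tsv(prof_h, file.path(out, "metagene_hetu.tsv"))
    write_metagene_tsv(prof_l, file.path(out, "metagene_letu.tsv"))
    qh <- quantify_tu_regions(sim$fe, hetu, tss_halfwidth = p$tss_halfwidth,
                              us_length = p$quant_us, ds_length = p$quant_ds)
    ql <- quantify_tu_regions(sim$fe, letu, tss_halfwidth = p$tss_halfwidth,
                              us_length = p$quant_us, ds_length = p$quant_ds)
    write_tsv(qh, file.path(out, "regions_hetu.tsv"))
    write_tsv(ql, file.path(out, "regions_letu.tsv"))
    write_tsv(compare_tu_regions(qh, ql),
              file.path(out, "region_comparisons.tsv"))
  }

  if (isTRUE(st$ir)) {
    p <- config$ir
    irs <- extract_irs(sim$tus, min_len = p$min_len, max_len = p$max_len,
                       genome_length = genome_length(sim$genome))
    irs <- classify_irs(irs, expression_table = sim$tus[c("id", "fpkm")],
                        genome_length = genome_length(sim$genome))
    stats_ir <- ir_group_stats(sim$fe, irs, grouping_keys = "orientation")
    write_tsv(irs, file.path(out, "ir_table.tsv"))
    write_tsv(stats_ir$groups, file.path(out, "ir_groups.tsv"))
    if (!is.null(stats_ir$comparisons))
      write_tsv(stats_ir$comparisons, file.path(out, "ir_comparisons.tsv"))
  }

  if (isTRUE(st$drip)) {
    p <- config$drip
    d <- sim$drip
    sig <- drip_signal(d$exp$fw, d$exp$rv, d$ctrl$fw, d$ctrl$rv)
    write_bedgraph(sig, file.path(out, "drip_signal.bedgraph"))
    prof <- drip_metagene(sig, sim$tus, us_length = p$us_length,
                          ds_length = p$ds_length, body_bins = p$body_bins,
                          flank_bin = p$flank_bin)
    write_metagene_tsv(prof$coding, file.path(out, "drip_coding.tsv"))
    write_metagene_tsv(prof$template, file.path(out, "drip_template.tsv"))
    write_tsv(detect_rloops(sig, sim$tus), file.path(out, "rloop_calls.tsv"))
  }
  invisible(out)
}
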