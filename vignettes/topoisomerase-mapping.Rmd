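---
title: "Mapping topoisomerase I binding and cleavage from strand-specific tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping topoisomerase I binding and cleavage from strand-specific tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Type-IA DNA topoisomerase I (TopoI) relaxes negative supercoils by passing
one DNA strand through a transient single-strand break. During the reaction
the enzyme is covalently attached to the 5′ end of the break and leaves the
3′ end free. A poisoned mutant that stalls in this covalent state can be
crosslink-purified together with its attached DNA, and strand-specific
sequencing of that DNA pinpoints the break: a spike in the number of
fragment 3′ ends (N3E) at a single genomic position on a single strand marks
a topoisomerase cleavage site (TCS). Around these sites lies a sequence
motif; over transcription units (TUs) the enzyme's ChIP occupancy follows
transcription, accumulating near promoters and — the signature of
transcription-driven negative supercoiling in the twin-domain model — for
kilobases *upstream* of active TSSs. This package implements the
computational side of that mapping: the track arithmetic, the single-base
TCS caller, motif derivation, metagene and intergenic-region statistics,
Monte-Carlo interval-overlap tests, and strand-specific DRIP-Seq (R-loop)
processing, together with a synthetic-data generator that emulates the
signal structure of each assay so every stage is testable without external
data.

# The Topo-Seq model

Each sample yields two per-base N3E tracks (forward and reverse strand).
Four conditions are crossed: induction of the poisoned enzyme (+Ara/−Ara)
and immunoprecipitation (+IP/−IP). The enriched cleavage signal is

```
enriched = (plusAra_plusIP − plusAra_minusIP) − (minusAra_plusIP − minusAra_minusIP)
```

computed per strand with a fixed stage order: every sample is **scaled** to
a common total (a sample is one library, so the forward + reverse total is
scaled jointly), replicates are **averaged** within a condition, and the two
control **subtractions** are applied. The −IP subtraction removes
library/background structure, the −Ara subtraction removes any
induction-independent signal. Negative values are retained — clipping is a
caller decision, not an arithmetic one (`clip_negative` in `call_tcs()`
exposes the alternative).

**Scaling units.** `scale_track()` defaults to a counts-per-million target,
the conventional realization of depth normalization. Inside
`toposeq_enrichment()` (and `fold_enrichment()`, `drip_signal()`) the common
total instead defaults to the *mean of the input totals*: the enriched track
then stays commensurate with read counts, which keeps the TCS caller's
absolute floor (5 scaled counts) meaningful at any sequencing depth. A CPM
target would re-express the same floor as depth-dependent arbitrary units;
with count-scale totals the floor is interpretable as "at least ~5 enriched
3′ ends".

## TCS calling

A position is called a TCS when its enriched N3E exceeds both

* a distributional threshold `mu + k * sigma`, with the moments estimated
  over positions with *positive* enriched signal on that strand
  (`k = 3` by default) — negative and zero positions are subtraction
  residue, not background support; and
* an absolute floor (default 5 scaled counts), which protects against
  degenerate moment estimates on sparse tracks.

When fewer than two positions carry positive signal there is no background
distribution to estimate and only the floor applies. Each qualifying
position is emitted as one single-base TCS with no merging: the assay's
claim is single-base precision, and the generator plants point masses for
the same reason. Real libraries smear 3′ ends over a few bases; on real
data a light pre-smoothing or post-merging step may be warranted, and the
threshold policy parameters are recorded in the pipeline provenance log so
any such change is visible.

## Motif derivation

Windows of `2 * flank` bases (default ±10 bp) are read 5′→3′ on the cleaved
strand — reverse-strand windows are reverse-complemented — so that the
stored TCS coordinate (the first base 3′ of the scissile bond) sits at
column `flank + 1` and the bond itself falls between columns `flank` and
`flank + 1`. The position-frequency matrix uses a 0.25-per-base pseudocount;
information content per column is `2 + sum(f log2 f)` bits against a uniform
background, and consensus letters below 0.5 bits are written `N`. The
cleavage offset is the distance from the cleavage column to the upstream
column maximizing `IC × f(C)` among columns where C is modal with IC ≥ 0.5
bits — the "conserved C" of the type-IA cleavage motif. On the default
synthetic motif (consensus core `TCNTTA`, cut at the TA step) this offset is
4 nt. `scan_motif()` validates a derived motif by log-odds scanning of both
strands.

# The synthetic study

The generator produces, from one seed:

* a circular i.i.d. genome (default 1 Mb, GC 0.5);
* 100 non-overlapping TUs, lengths 0.5–5 kb, gaps ≥ 1 kb, random strands,
  FPKM drawn as `10^rnorm(n, log10(5), 2)` — a log-normal spread covering
  the several orders of magnitude seen in bacterial transcriptomes;
* 200 cleavage-motif instances written into the genome (70% placed upstream
  of highly-expressed TUs, mirroring the recruitment of the enzyme to
  transcribed regions; `N` columns filled according to local AT content;
  half of the sites per strand), with the true cleavage position recorded;
* Topo-Seq tracks: independent per-position Poisson background with
  `lambda = depth / genome_length` (default depth 2e5 per strand, so
  `lambda = 0.2`) in all four conditions, plus `Poisson(S * lambda)` extra
  counts (default S = 50) at each planted position, on the cleaved strand,
  in the induced+IP condition only;
* ChIP factor/input tracks: baseline 1 plus, per TU and scaled by
  normalized log expression, a promoter peak (TSS ± 200 bp), a linear body
  gradient, and an upstream exponential `exp(−d / L_up)` with
  `L_up = 10 kb` by default — chosen so the pipeline exercises detection of
  upstream signal on the 10 kb scale; multiplicative log-normal noise
  (σ = 0.1);
* strand-specific DRIP tracks with an RNase-HI-style control: Poisson
  coverage everywhere, plus extra coverage over the bodies of a fraction of
  highly-expressed TUs on the **coding strand only** (the strand displaced
  by the RNA:DNA hybrid), absent from the control;
* RNA-Seq-style coverage proportional to FPKM, used to exercise the FPKM
  computation (`FPKM = C / (L_kb × M)`).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: positional autocorrelation of background
(real Topo-Seq background is not i.i.d. Poisson), 3′-end smearing around
cleavage sites, GC or mappability bias, copy-number gradients from
replication, overlapping/nested TUs, and operon structure. The generator's
role is to verify the *logic* of the pipeline (recovery, strand handling,
statistics) under a known truth, not to benchmark sensitivity on real
libraries.

# Metagene and intergenic statistics

Metagene profiles align TUs at TSS and end, rescale bodies to equal-fraction
bins (bin size `floor(len / bins)`, last bin absorbing the remainder), and
attach fixed-length upstream/downstream flanks; minus-strand TUs are fully
reversed so "upstream" is always 5′ of the TSS. Confidence bands are ±SEM
across TUs. Profile extent defaults to 15 kb while quantification windows
default to 5 kb (US/DS) — two independent parameters. The TSS region is
TSS ± 200 bp *inclusive of both endpoints* (401 positions); the convention
is stated because "± 200 bp" alone does not pin it down. Region comparisons
use a two-sided Welch t-test with Bonferroni correction over the emitted
family of comparisons. Overlapping neighbour TUs are not masked from flanks
by default; on the sparse synthetic layout this is immaterial, and a
masking option would be the first thing to add for dense real annotations.

`upstream_signal_range()` operationalizes "signal tracked up to X kb
upstream": the distance of the far edge of the farthest run (≥
`consecutive_bins` bins) where `mean − SEM` exceeds a background level. For
a noise-free exponential `b + A exp(−d/L)` evaluated against `b + 0.05 A`
this returns ≈ 3L, which is how the recovery tests calibrate it.

Intergenic regions (IRs) are the gaps between adjacent TUs (wrap gap
included on circular genomes), length-filtered to 1 bp–10 kb by default so
a pathological wrap gap cannot dominate. Orientation follows flanking-gene
geometry: left −/right + is divergent (promoters inside the IR), +/− is
convergent, anything else tandem; "not divergent" two-way groupings are the
union of the latter two. TF-site and membrane-gene flags and the flanking
expression maximum are annotations joined from input lists, not predicted.

# Monte-Carlo interval overlap

The observed statistic is the number of query peaks sharing ≥ 1 base with
any reference peak. The null re-places query peaks uniformly on the circular
genome preserving widths (placed peaks may overlap each other — the simplest
exchangeable null; the scheme is deliberately pluggable since published
analyses rarely specify theirs). The empirical p uses the add-one estimator
`(1 + #{null ≥ obs}) / (1 + iterations)`, never exactly zero and slightly
super-uniform by construction. Two numerical caveats are built into the
tests: the closed-form check on a circle (a single w-bp peak pair overlaps
with probability `(2w − 1) / L`), and the observation that empirical p can
only approach U(0,1) when the overlap count is well spread — with a handful
of peaks the statistic is so discrete that most repeats return p = 1.

# DRIP-Seq processing

The signed signal is `(exp_fw − exp_rv) − (ctrl_fw − ctrl_rv)` after common
scaling; the two subtractions commute, and the order follows the
strand-difference-first convention. For metagenes the signed track is
projected onto TU-relative strands: coding-strand signal is `+signal` for
plus-strand TUs and `−signal` for minus-strand TUs, template is the exact
negation — the only orientation-consistent projection, which makes
coding + template ≡ 0 a structural invariant rather than an empirical one.
Negative strand-difference values are kept signed throughout.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere; BED is native, GFF3
  converts on read/write (start − 1). Single-base positions (TCSs) are
  0-based.
* Strand tracks store non-negative magnitudes; orientation lives in the
  strand field and the `.fw`/`.rv` file suffix, not in signs (the signed
  DRIP track is the one deliberate exception and is labelled unstranded).
* One global seed; each stochastic stage derives a child seed from the seed
  and the stage name (`derive_seed()`), so disabling a stage does not shift
  the streams of the others.
* Welch tests with both groups constant: equal means give t = 0, p = 1
  inside group-comparison wrappers (a constant region pair is evidence of
  no difference, not an error), while `welch_t_test()` itself errors on the
  fully undefined case and flags the infinite-t case with
  `p = .Machine$double.xmin`.
* Ties in TU-set selection break lexicographically by id, making HETU/LETU
  sets deterministic.
* Body-bin remainders go to the last bin; TUs shorter than the bin count
  are skipped and counted.
* `fold_enrichment` guards zero-input positions with a pseudocount
  (default 1 count) added to both numerator and denominator after scaling.

# Problem sizes used by the test suite

The test suite runs the full chain at the default study scale (1 Mb genome,
200 sites, three signal-to-background settings), ChIP upstream-range
recovery on a sparse 1.375 Mb layout at `L_up` ∈ {2, 5, 10} kb, Monte-Carlo
uniformity over 200 repeats of 199 iterations, and the end-to-end pipeline
twice at a 100 kb scale for byte-level determinism. These sizes were chosen
as the smallest at which each property is statistically clean: recovery
rates at S = 50 sit far from their thresholds, and the upstream-range
checks need flanks of ≥ 3 L_up.

# Known limitations

* The Poisson background is a stand-in; the caller's μ + 3σ policy was
  validated against it, not against autocorrelated real background.
* The plumbing peak caller is a threshold-run-merge device, not a
  MACS2-style model; import externally-called peaks for real data.
* De-novo motif discovery is out of scope: motifs come from TCS alignment
  and are validated by scanning.
* IR extraction works from the TU annotation it is given; IR counts are a
  property of the annotation, not of this code.
* `run_pipeline()` with the simulate stage disabled supports
  genome/annotation/expression/fold-enrichment inputs (metagene and IR
  stages); raw condition-track input from files is deliberately not
  plumbed — use the package functions directly for that.
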