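# toposeqr

Strand-specific track analysis for mapping bacterial topoisomerase I
binding and cleavage genome-wide — Topo-Seq N3E arithmetic, single-base
cleavage-site calling, cleavage-motif derivation, ChIP metagene and
intergenic-region statistics, Monte-Carlo interval-overlap tests, and
strand-specific DRIP-Seq (R-loop) processing — plus a synthetic-data
generator that makes the whole pipeline testable on a desk-scale toy
genome.

## The science

Type-IA topoisomerase I relaxes negative supercoils through a transient
single-strand break, binding covalently to the 5′ side and leaving the 3′
end free. Trapping a poisoned mutant in this state and sequencing the
attached DNA strand-specifically turns cleavage into a countable signal:
the number of fragment 3′ ends per position and strand (N3E). A cleavage
site (TCS) is a single-base N3E spike that survives a two-stage control
chain,

```
enriched = (+Ara+IP − +Ara−IP) − (−Ara+IP − −Ara−IP)
```

(scale to a common total → average replicates → subtract, per strand).
Positions with enriched N3E above μ + 3σ of the positive signal (and an
absolute floor) are called as TCSs; ±10 bp windows around them, read 5′→3′
on the cleaved strand, give a position-frequency matrix whose information
content exposes the cleavage motif — an AT-rich context with a conserved C
followed 4 nt downstream by the cleaved TA dinucleotide. Around
transcription units, ChIP fold enrichment (IP/input after depth scaling) is
profiled as metagenes with ±SEM bands, quantified in US / TSS ± 200 bp /
TU body / DS regions (Welch t-tests, Bonferroni), and tested for overlap
with other interval sets by Monte-Carlo placement on the circular
chromosome. DRIP-Seq R-loop signal is the strand difference of coverage
minus the RNase HI control difference, projected onto coding/template
strands per TU.

The methods vignette (`vignettes/topoisomerase-mapping.Rmd`) describes the
models, parameters and design choices in full.

## Worked example

The numbered scripts under `analysis/` run the whole study; the core chain
in a few lines:

```r
library(toposeqr)

genome0 <- make_genome(1e6, 0.5, seed = derive_seed(1, "genome"))
tus     <- make_tu_annotation(genome0, 100, 2, seed = derive_seed(1, "tus"))
planted <- plant_cleavage_sites(genome0, 200, seed = derive_seed(1, "sites"),
                                tus = tus)

cs  <- simulate_toposeq(planted$genome, planted$truth, depth = 2e5, S = 50,
                        replicates = 2, seed = derive_seed(1, "toposeq"))
en  <- toposeq_enrichment(cs)
tcs <- call_tcs(en$fw, en$rv, k = 3, floor = 5)
pfm <- build_pfm(extract_tcs_windows(tcs, planted$genome, flank = 10),
                 cleavage_index = 11)
pfm
find_cleavage_offset(pfm)
```

Running `Rscript analysis/02_cleavage_sites.R` (which performs exactly this
chain and validates it against the planted truth) prints:

```
called 198 TCSs: 98 on the forward and 100 on the reverse strand
recovery vs planted truth: recall 0.990, precision 1.000
cleavage motif consensus: NNNNNTCNTTANNNNNNNNN
conserved C sits 4 nt upstream of the cleavage position
motif scan at the 5% planted-score threshold recovers 95.0% of planted sites
```

That is the package's headline readout: of 200 planted single-base cleavage
sites, 198 are recovered at exact position and strand with no false calls;
aligning the called sites re-derives the planted consensus core `TCNTTA`
(low-information columns print as `N`), and the most conserved C column
sits 4 nt upstream of the cleavage position — the motif geometry of type-IA
topoisomerase cleavage. The other scripts add ChIP peak/colocalization
statistics (`03`), HETU/LETU metagenes with region tests and the upstream
signal range (`04`), intergenic-region orientation/expression statistics
(`05`), and DRIP coding/template profiles with R-loop detection (`06`);
each writes its tables under `results/`.

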