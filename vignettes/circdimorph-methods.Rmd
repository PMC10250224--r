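---
title: "circdimorph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circdimorph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circular RNAs arise when the spliceosome joins an upstream 3' splice site to
a downstream 5' splice site (back-splicing), producing a covalently closed
exonic circle (circRNA), or when an intron lariat escapes debranching
(ciRNA). Because circles have no free ends, the only read-level evidence that
distinguishes them from their linear host transcript is the back-spliced
junction (BSJ): a read whose two halves map in "reversed" order around the
circle boundary. circdimorph implements a desk-scale pipeline for a
fractionated experimental design with three libraries per biological sample —
poly(A)-selected mRNA (`polyA`), rRNA/mRNA-depleted total RNA (`Rminus`), and
the same after RNase R digestion (`Rplus`) — across a 2 sexes x 3 tissues
grid, plus a PAR-CLIP arm that maps the binding sites of an RNA-binding
protein (SXL in the motivating system) relative to the circles. Every stage
is driven by a seeded synthetic-data generator with planted ground truth, so
the whole analysis is verifiable end to end without external data.

## BSJ detection: junction library + exact scan

Chimeric read alignment is replaced by a *junction library* scan. For every
gene we take the canonical transcript (longest CDS, ties broken by exonic
length, then transcript id) and build one probe per ordered pair of exon
boundaries `(start of exon i, end of exon j)`, `i <= j`: the probe is the
last `L` nt of the circle's mature sequence concatenated with its first `L`
nt in transcript orientation, `L = read_length - min_anchor`. Lariat-derived
circles get probes joining each intron's 5' end to branch-point offsets 15-50
nt upstream of its 3' end (step 5). A read is assigned to a junction when
some probe alignment places the junction with at least `min_anchor` nt on
each side and at most `max_mm` mismatches over the whole read; the
fewest-mismatch junction wins, and ties — including equal-quality contiguous
matches to the linear genome — disqualify the read from counting.

* `min_anchor = 10` mirrors the chimeric-segment minimum a chimeric aligner
  would use. Reads whose junction falls within 10 nt of either read end are
  therefore invisible by design; at the default 100-nt read length that is
  18/99 of junction placements, which matters for read-level recall but not
  for junction-level recall at any reasonable depth.
* `max_mm = 1` by default (configurable). The scanner seeds on the exact
  10-mers immediately left and right of the junction, so a read with one
  mismatch anywhere is still found (the mismatch can spoil at most one of
  the two seeds); with `max_mm = 0` a single seed suffices. The same
  seed-and-verify scheme backs the linear aligner (non-overlapping 20-mer
  windows; detection is exhaustive up to 4 total mismatches per 100-nt read,
  which covers the configured error and conversion rates).
* Probes are only built within one gene and a 100 kb span; circles between
  genes are out of scope.
* Junction identity is genomic — `(contig, strand, acceptor, donor)` with
  `acceptor < donor`, 0-based half-open. All internal coordinates follow the
  BED convention; GTF conversion happens only at the I/O boundary.

A call is typed `exonic` when both boundaries coincide exactly with
annotated exon boundaries of one gene, `ciRNA` when it starts at an intron
5' end (strand-aware) and ends within the 15-50 nt branch-point window, and
`unassigned` otherwise; unassigned calls are retained in output but excluded
from all downstream statistics.

## Normalization and the back-splicing level

* **Reliability.** A junction is *reliable* in a sample when its `Rplus`
  count is at least twice its matched `Rminus` count; we add an `Rplus >= 2`
  floor so the rule is total when the `Rminus` count is zero. Globally
  reliable = reliable in at least one sample. Only reliable junctions enter
  the differential statistics.
* **Size factors.** `Rminus` BSJ counts are normalized by median-of-ratios
  size factors (geometric-mean reference over rows nonzero in every sample,
  median taken in log space, factors rescaled to geometric mean 1). BSJ count
  matrices are sparse at realistic depths, so when fewer than 10 rows are
  informative the estimator falls back to adjusted library sizes — total
  reads minus mRNA and rRNA reads — and records which method ran. Both
  estimators are exposed; a unit test cross-checks the median-of-ratios path
  against an independent implementation.
* **TPM.** Gene expression is quantified from the polyA libraries by exact
  transcript-space alignment against the canonical mature mRNA (a spliced
  read is contiguous in transcript space, not genome space); effective length
  is the canonical exonic length, with no fragment-length correction since
  reads are fixed-length.
* **Back-splicing level.** `level = (BSJ_Rplus + 0.5) / max(TPM_cognate, 1)`.
  The 0.5 pseudocount sits on the *read* scale, where it stabilizes zero
  counts; fold changes between levels are then plain ratios. Putting the
  pseudocount (or a fixed floor) on the level scale itself would tie the
  rule's behaviour to the size of the annotation universe, because TPM is
  compositional: with 40 genes a typical TPM is ~25,000 and any fixed
  level-scale constant is either negligible or overwhelming. For the same
  reason the detection floor for differential back-splicing defaults to raw
  read support (`min_support = 15` BSJ reads on the stronger side, the same
  floor the sex-specificity rule uses) rather than a floor on the normalized
  level; a `min_level` floor on the level scale is implemented and can be
  enabled where TPMs are on a genome-like scale. The TPM denominator is
  floored at 1 to keep ratios bounded when the cognate gene is barely
  expressed; junctions whose cognate TPM is below the floor in every sample
  are flagged and excluded.

## Classification rules

All rules are deterministic thresholds — the design has one library per
(sex, tissue, fraction), so there is no replicate variance to model.

* **Differential expression** toward side a:
  `(Rplus_a + 0.5)/(Rplus_b + 0.5) >= 4` and the size-factor-normalized
  `Rminus` counts strictly agree in direction.
* **Sex-specific**: at least 15 BSJ reads in some `Rplus` sample of one sex
  and zero reads in every opposite-sex sample; "every sample" covers both
  `Rplus` and `Rminus` by default (the strictest defensible reading), with an
  `Rplus`-only switch.
* **Differential back-splicing** uses the TPM-normalized levels with the same
  4-fold rule, the `Rminus` direction check, and the read-support floor.
  Between-sex calls map onto six groups on a fixed tissue x direction grid:
  G1 head F>M, G2 head M>F, G3 body F>M, G4 body M>F, G5 gonad M>F (testis
  over ovary), G6 gonad F>M.
* **Alternative back-splicing**: within a gene, junctions sharing the
  back-splice 3' splice site while differing at the 5' splice site form one
  alt5 event, and symmetrically for alt3. Splice-site roles are
  strand-aware: on the minus strand the 3'SS is the *high* genomic
  coordinate, so grouping by the genomic acceptor alone would swap alt5 and
  alt3 for half the genes. An event is observed in a sample when at least
  two members have an `Rplus` read there.

## PAR-CLIP arm

Reads are aligned by exact scan with up to 2 non-T>C mismatches; T>C
mismatches in transcript orientation (genomic A>G on the minus strand) are
unlimited and recorded as conversions, because 4SU crosslinking leaves them
as the diagnostic signature. Candidate peaks are maximal runs of SXL coverage
`>= 5`, merging runs closer than 10 nt. Enrichment against the IgG control is
scored as the library-size-normalized ratio
`(sxl/N_sxl) / ((igg + 1)/N_igg)` with a one-sided Poisson tail p-value at
mean `(igg + 1) x N_sxl / N_igg` — the simplest defensible null for count
enrichment; the heavier machinery this stands in for (a generative HMM
peak caller) is out of scope. Crosslink-induced mutation sites (CIMS) are
reference-T positions with at least 2 conversions; their FDR comes from a
within-peak permutation in which each overlapping read redistributes its
conversions uniformly over the reference-T positions it covers. Final
significance is the two-branch rule: ratio >= 10 with p < 1e-4 *and* a CIMS
site at FDR <= 0.3, or ratio >= 100 with p < 1e-4 regardless of CIMS.

Peaks are annotated by genomic region (midpoint rule, precedence exon >
intron > intergenic, coding exons refined to 5'UTR/CDS/3'UTR by the canonical
transcript, densities as peaks per kb of category) and assigned to
circRNA-relative categories by overlap: back-spliced exon, flanking intron
(immediately adjacent to the circle boundary), flanking exon (the nearest
exon beyond that intron). One peak may receive several categories across
circles, so category percentages can sum above 100%. Motif content is
summarized by k-mer z-scores against dinucleotide-preserving shuffles
(random Eulerian re-walks of the dinucleotide graph), a deliberately plain
stand-in for PWM-based motif discovery.

## The synthetic-data generator

The generator emulates the *structure* of the fractionated experiment, not
fly biology:

* Toy genome: one contig, uniform base composition, genes of 3-8 exons
  (80-300 nt) separated by 60-2000 nt introns carrying GT..AG splice
  dinucleotides in transcript orientation, intergenic gaps >= 500 nt, with
  rRNA and noncoding biotypes included. Coding genes carry a CDS leaving
  20-60 nt UTRs in the terminal exons.
* Planted circles sit exactly on canonical exon boundaries (or at intron
  5' ends with the branch point fixed 25 nt upstream of the intron 3' end
  for ciRNAs), only on coding hosts — the level denominator comes from polyA
  libraries, which cannot measure noncoding genes — and only where the mature
  circle is at least one read length long, so a read crosses the junction at
  most once. Classes: null, female- or male-biased at a configurable fold
  (default 8, applied in one tissue, default head), and female- or
  male-specific (rate zero in the opposite sex).
* Libraries are compositional: each sample's reads are one multinomial draw
  over linear fragments (expression x mature length), residual rRNA (2% in
  `Rminus`/`Rplus`), circle BSJ fragments and circle-internal fragments
  (1:1 by default). `polyA` sees only coding mRNA; `Rplus` multiplies all
  linear mass by the RNase-R survival fraction (default 0.02) and
  renormalizes — what survives digestion is what gets sequenced. Circles are
  0.5% of `Rminus` mass by default (a realistic share for ribodepleted
  libraries), which makes them ~20% of `Rplus`. Because composition is
  honest, a strong planted effect slightly deflates every other rate in that
  sample; at the default circle mass this distortion stays below ~15% and the
  recovery experiments pass with the planted 8-fold effects. Sequencing
  errors are uniform substitutions at 0.1% per base. Circle abundances are
  log-normal (sdlog 0.4) — the real abundance distribution is unknown, so
  this is an explicit placeholder and fully configurable.
* BSJ reads place the junction uniformly with at least 1 nt on each side;
  true per-read junction probabilities are exposed
  (`sample_composition()`, `true_bsj_prob()`) so tests can use exact
  binomial oracles, and `depth_for_min_bsj()` turns "every circle should
  expect at least K junction reads" into a depth.
* PAR-CLIP: per-site signal mass is
  `enrichment x affinity x (site_width + read_length) / genome_length` of
  the library — i.e. the expected library-size-normalized SXL:IgG read-count
  ratio over the site window, the quantity peak calling measures. Signal
  reads are centered on the site with Gaussian jitter (sd 10 nt) and convert
  each covered site T with probability 0.25; the IgG library is uniform
  background. Sites are placed only where the 21-nt site carries at least 4
  Ts (4SU crosslinks need uridines), kept 80 nt clear of feature edges so
  the resulting peak overlaps its planted feature and no neighbouring one,
  and circRNA-role sites are drawn from genes hosting a single circle so the
  planted category is unambiguous.

What passing these tests does *not* show about real data: the generator has
no repeat structure or homologous gene families (so multi-mapping is rare),
no fragment-length or coverage bias, no PCR duplication, one isoform per
gene, uniform base composition, and a single contig. The detector's
exactness results are statements about the junction-library algorithm, not
about alignment against a real genome.

## Study sizes used by the tests and the acceptance script

Chosen as the package's standard desk-scale experiments: detection exactness
on 40 genes / 150 circles (20 ciRNAs) with an error-free 200k-read `Rplus`
library and exact scan; group recovery on 20 female-head-biased (8-fold) plus
40 null circles with `Rplus` depth set so every circle expects >= 30 junction
reads (polyA 20k, `Rminus` 30k); null calibration on all-null experiments at
equal depths; PAR-CLIP recovery on a 120-gene (~0.8 Mb) genome with 100
planted sites at 20x enrichment and 50k-read SXL and IgG libraries (equal
depths keep the scaled IgG window counts stable, which is what bounds the
ratio's variance); CIMS checks at 1000 permutation rounds.

## Known limitations

* Circles shorter than the read length are not modelled or detectable (a
  read would wrap the junction twice).
* EIciRNAs (circles with retained introns) and annotation-free circle
  discovery are out of scope; detection is bounded by the annotation.
* The peak p-value model is a Poisson substitution, not a reconstruction of
  an HMM peak caller; CIMS FDR permutes within peaks rather than genome-wide.
* With one library per condition, all differential calls are threshold
  rules; no uncertainty is attached to them.
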