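---
title: "Methods: CNV calling and burden analysis for hotspot-targeted aCGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling and burden analysis for hotspot-targeted aCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

`cnvburden` turns per-probe log2 intensity ratios from a two-color
comparative genomic hybridization array into copy-number-variant calls,
annotates them, and compares cohorts. This vignette explains the model,
its tunable parameters, the synthetic-data generator used for testing,
and the design decisions taken where the underlying procedure left the
choice open.

## Coordinates and formats

All internal coordinates are 0-based half-open, so `size = end − start`
and BED files round-trip unchanged. Published CNV tables conventionally
print 1-based starts while their size columns still equal
`end − start`; the `one_based` dialect of the readers shifts the start
down by one and recomputes the end from the preserved size, so printed
sizes ingest exactly. A reader cannot distinguish the two conventions
from a single row, which is why the dialect is an explicit flag rather
than a guess; the `size` column, when present, is validated against
`end − start` after ingestion. Overlap between intervals on different
chromosomes is defined as zero (not an error), which keeps all-vs-all
scans branch-free.

## Segmentation model

**Chromosome-wise z-scoring.** For each sample and chromosome,
`z = (x − μ_c)/σ_c` with `μ_c`, `σ_c` the mean and sample SD over *all*
probes of the chromosome, CNV probes included. This is the simplest
reading of a chromosome-normalized transform and removes per-chromosome
baseline offsets (dye and hybridization artifacts). Its known weakness
is self-masking: an event covering a large fraction of a chromosome's
probes inflates `σ_c` and drags `μ_c` toward itself, attenuating its own
z-scores. On real genomes (chromosomes of 50–250 Mbp) this is rarely
material; a median/MAD fit is available behind `robust_zscore = TRUE`
for atypical inputs. A chromosome with zero variance is an error naming
the chromosome, not a silent NaN.

**Three-state HMM.** Probes are classified
decreased / normal / increased by Viterbi decoding with Gaussian
emissions on the z scale. The original analysis tool's parameter values
are not recoverable, so the defaults here are explicit and
configurable: emission means (−3, 0, +2.5) with unit SDs — deletions
sit deeper than duplications on z because a single-copy loss is a
log2-ratio of −1 against a duplication's +0.585 — self-transition
probability 0.999 with the off-diagonal mass split evenly, and an
initial distribution (0.001, 0.998, 0.001). Decoding runs on the probe
*index* sequence per chromosome and deliberately ignores genomic
distance: distance enters only afterwards, at assembly and bridging,
mirroring the two-stage description the procedure follows.

**Assembly, bridging, filtering.** Consecutive same-state probes merge
into a segment only when the inter-probe gap is strictly below 50 kbp.
Two same-state non-normal segments whose intervening sequence contains
at most 5 probes *and* spans at most 10 kbp are bridged — with the
intervening probes — into a single variant, iterating left-to-right to
a fixed point; bridging never joins a deletion to a duplication. A
variant is kept iff `|mean z| > 1.5`, probe count `> 10` (strictly),
size `> 50 kbp`, and additionally size `> 300 kbp` when it is not
hotspot-associated — the backbone's 36 kbp probe spacing cannot support
confident smaller calls. All comparison strictness follows the stated
rules exactly (a 10-probe variant fails; mean z of exactly 1.5 fails;
two probes exactly 50 kbp apart do not merge). Rejected variants are
retained with `qc_pass = FALSE` and a reason code, because filtered-out
calls are data for threshold diagnostics.

**Homozygous deletions.** The published call sets distinguish
"homozygous deletion" without stating a rule; here a deletion segment is
labelled `homozygous_deletion` when its mean z falls below a
configurable threshold (default −6, i.e. far beyond a single-copy
loss). For control-map and trio matching, homozygous deletions match
single-copy deletions (a proband's homozygous loss is assembled from two
carrier parents), never duplications.

**Sample QC.** The quality criteria behind array studies' per-sample
pass rates are platform-specific and not recoverable, so the rule here
is an explicit stand-in: a sample fails when its autosomal log2-ratio SD
exceeds 0.35 (strictly), or when its raw variant count exceeds 3× the
cohort median raw count (floored at one so that sparse, clean cohorts do
not flag every carrier). Both knobs live in `analysis_config()`.

## Annotation

**Hotspot class.** `HS` when the call overlaps hotspot sequence by at
least half its own length; `HS_assoc` when it is not `HS` but a
breakpoint falls inside a hotspot or one of its segmental-duplication
flank intervals; `non_HS` otherwise. The exact region set behind
published "HS assoc" labels is not available, so this three-way rule is
a documented reconstruction over the layout's hotspot + flank intervals.

**Rarity.** A call matches a control-map event when the reciprocal
overlap is at least 50% *in both directions* (the phrase "of their
length" is ambiguous; the symmetric reading is the stricter and is
adopted) and the types agree (`type_blind_matching = TRUE` disables the
type requirement; frequency maps are type-specific in practice, which is
why type-matched is the default). Matching is per control event — no
merging of fragmented control calls. Strict rarity keeps calls with
control count 0; relaxed rarity implements "frequency < 0.1%" as a
strict inequality on `count / n_controls`, so with 8,635 controls a
count of 8 passes (8/8635 ≈ 0.00093) and 9 fails (≈ 0.00104).

**Genes.** `gene_count` counts ≥ 1 bp overlaps; `breaks_gene` is true
only when a gene body strictly contains a breakpoint coordinate — a CNV
that swallows genes whole does not "break" them.

**Inheritance.** With both parents genotyped, a call is `de_novo` when
neither parent's own (same pipeline, same config) call set contains a
type-matched call at ≥ 50% reciprocal overlap; one match gives
`maternal`/`paternal`, two give `both`. With a single genotyped parent a
match yields that parent's label and a non-match stays `NA` — a
compound "paternal or de novo" cannot be resolved, and the
`parents_available` column preserves the information needed to
reconstruct that uncertainty. No parents, `NA`.

## Burden statistics

Every cohort comparison is a 2×2 Fisher exact test. The reported odds
ratio is the unconditional cross-product `ad/bc` — this is the quantity
that reproduces the odds ratios printed by burden studies of this design
(e.g. 11.2 from the table (4,5,4,56)) where the conditional MLE that
`stats::fisher.test` reports does not. Zero-cell tables report `Inf`
(no continuity correction by default; Haldane–Anscombe behind a flag).
The two-sided p-value follows the point-probability rule — the sum of
hypergeometric probabilities of all tables with the observed margins
whose point probability does not exceed the observed one (with the
customary `1 + 1e-7` tolerance factor against ties lost to floating
point); the test suite verifies it against exhaustive enumeration and
against `stats::fisher.test`. No multiple-testing correction is applied
by default, matching how such studies report raw p-values; a Bonferroni
helper (`adjust_burden_results`) is provided.

The largest-CNV survivor function reports, per size, the fraction of a
cohort whose largest call is at least that size; individuals without
calls never count as carriers, so the value at size 0 equals the
fraction of individuals with ≥ 1 call and the curve is non-increasing
by construction. The "large CNV" carrier definition is strictly greater
than 1 Mbp. Units are: individuals for rare-carrier and two-hit tests,
rare CNVs with resolved inheritance for the de novo test (NA inheritance
excluded). The two-proportion power calculation uses the
unpooled-variance normal approximation, whose `delta = 0` limit is
exactly `alpha`.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
not the biology of hybridization:

* **Layout**: by default 4 chromosomes × 50 Mbp with 27 hotspots of
  300–900 kbp, giving a hotspot genome fraction near 8% — the same
  order as ~251 Mbp of hotspot sequence in a ~3.1 Gbp genome — each
  hotspot flanked by 25 kbp segmental-duplication proxy intervals.
* **Probes**: jittered placement with median start-to-start spacing
  2.6 kbp inside hotspots and 36 kbp in the backbone, mirroring the
  targeted design's densities at about one-twelfth of its 135,000
  probes.
* **Cohorts**: per-cohort carrier probabilities, log-uniform planted
  sizes, deletion:duplication balance, de novo fractions and two-hit
  probabilities default to the observed cohort profiles (carrier rates
  ~2% for controls/dyslexia up to ~17% for ID; de novo fractions 0,
  0.40, 0.64; two-hit up to 0.44 for ID with congenital anomalies),
  with size windows whose medians track the observed cohort medians.
  Planted CNVs sit at hotspot loci with probability 0.5 by default —
  hotspot enrichment is real but both classes must stay exercised.
* **Intensities**: probe value ~ `N(m_state + δ_c, σ)` with
  `δ_c ~ N(0, τ)` fixed per chromosome per sample. The state means are
  the single-copy expectations −1.0 (deletion), +0.585 = log2(3/2)
  (duplication), with homozygous deletions floored at −3.0. No noise
  magnitude is published for the platform; σ = 0.15 is a choice of
  realistic aCGH probe noise, and τ = 0.1 exists precisely to exercise
  the chromosome-wise normalization. One global seed drives every
  sub-generator through deterministically derived child seeds, so all
  artifacts are byte-reproducible.
* **Not modelled**: dye-swap and wave artifacts, GC bias, mosaicism.
  Passing tests on this generator therefore demonstrate the calling
  logic and statistics, not robustness to correlated array artifacts.

Test and verification runs use a 4 × 50 Mbp genome (~11,000 probes) with
tens of samples per scenario; unit tests of interval and segment logic
use even smaller hand-built designs. Planted events are kept small
relative to chromosome length because the non-robust z-score fit is
part of the modelled procedure: a multi-megabase event on a toy 20 Mbp
chromosome can cover enough probes to mask itself, which is a property
of the procedure, not a bug, and is documented above.

## Pipeline runs

`run_simulate` / `run_call` / `run_annotate` / `run_burden` / `run_all`
wire the stages into on-disk runs: every writer emits a comment header
with the config hash and seed, and each stage writes a manifest
recording the config hash, seed and artifact paths. Manifest paths are
stored relative to the run directory and timestamps are off by default,
so identical seeds produce byte-identical output trees — reproducibility
was preferred over wall-clock provenance, which can be enabled
explicitly. The thin CLI in `inst/cli/cnvburden.R` exposes the same
runners with exit codes 0/1/2 (ok/validation/runtime).

## Known limitations

* HMM parameters are assumptions, not recovered values; conclusions
  about marginal calls (near 10 probes, |z| near 1.5) depend on them.
* The pipeline performs no EM re-estimation, no wavelet smoothing, no
  mosaic states and no sex-chromosome baseline adjustment; X/Y calls in
  mixed-sex cohorts need external care.
* The genomic-disorder region list is whatever the user supplies; the
  package ships no curated coordinate set.
* Aggregate array-scale results (total call counts, per-cohort average
  sizes, sample pass rates) depend on the raw arrays and are out of
  reach of the synthetic generator; the tests assert the properties the
  pipeline can guarantee (recovery of adequately covered planted
  events, exactness of the statistics, strictness of every threshold)
  and the desk-scale quantities recomputable from published counts and
  tables.
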