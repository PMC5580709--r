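---
title: "Scoring pooled Bar-seq screens for toxicity modifiers"
author: "bartox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled Bar-seq screens for toxicity modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bartox)
```

## The experiment this package models

A pooled human–yeast genetic interaction screen expresses a toxic human
"query" gene in a mixed culture of barcoded homozygous yeast deletion
strains and asks which deletions modify the toxicity. Every strain in the
knockout collection carries a unique 20-base *uptag* barcode; the pool is
grown with the query switched off (glucose, GLU) or on (galactose, GAL),
barcodes are PCR-amplified with composite primers carrying a 6-mer inline
index tag per (query, condition) sample, the amplicons are sequenced, and
per-strain read counts report each strain's relative abundance. A deletion
strain that becomes relatively more abundant under induction is a
*toxicity suppressor* — the deleted yeast gene is needed for the query's
toxicity — and one that becomes depleted is a *toxicity enhancer*.

`bartox` implements the downstream half of this experiment — demultiplexing,
barcode counting, normalization, Z-scoring with error propagation, hit
classification, and ortholog-level network construction — together with a
synthetic-data generator that emulates the wet half so every stage can be
tested end to end with known ground truth.

## The read structure and demultiplexing

Each forward read is the concatenation

```
G + NNNNNN + GATGTCCACGAGGTCTCT + <20-mer uptag>
 fixed  6-mer tag    18-base common primer    strain barcode
```

so coordinates are fixed: tag at positions 2–7, primer at 8–25, barcode
at 26–45 (1-based, inclusive). Because the amplicon structure is fixed by
the composite primers there is no sliding-window search. A read is
assigned to a sample when its tag has a unique best design match within
`tag_mismatch` (default 1) and its primer window is within
`primer_mismatch` (default 2) of the common primer. Barcodes are matched
to the catalog by unique best Hamming hit within `max_mismatch`
(default 2); equidistant best hits are counted as *ambiguous* and
excluded, reads with `N` in the barcode window as *unmatched*. These
tolerances are package defaults, chosen so that a catalog with minimum
pairwise barcode distance 3 keeps 1-mismatch assignment unambiguous;
they are tunable arguments throughout. Only the forward read is parsed:
the reverse tag of each sample's tag combination is validated in the
design file but does not appear in the sequenced bases.

A per-sample accounting ledger (`DemuxStats`) balances exactly:
`assigned + unassigned_tag + unassigned_primer = total reads`, and
`matched + ambiguous + unmatched = assigned`.

## Normalization and the modifier statistic

Counts are made comparable across samples by dividing each barcode count
by the average count of its sample, so every sample has mean normalized
abundance 1. (A true quantile-normalization mode, which forces identical
count distributions across samples, is available behind
`normalization = "quantile"` for comparison; the divide-by-average rule is
the default.)

For each query the per-strain statistic is the log2 ratio of normalized
induced to control abundance,

$$\mathrm{lr}_i = \log_2\frac{v^{\mathrm{GAL}}_i + c/\bar n_{\mathrm{GAL}}}
{v^{\mathrm{GLU}}_i + c/\bar n_{\mathrm{GLU}}},$$

with pseudocount $c = 0.5$ applied on the raw-count scale ($\bar n$ is the
sample's raw mean count), which keeps zero counts finite. The ratios are
standardised across strains into Z-scores,
$z_i = (\mathrm{lr}_i - \overline{\mathrm{lr}})/s$, with the usual
$n-1$ standard deviation (a median/MAD alternative sits behind
`robust = TRUE` for screens with heavy effect-laden tails). Scoring on
the GAL/GLU *ratio* — rather than on GAL abundance alone — controls for
strain-intrinsic abundance differences that are present in both
conditions; both pools are harvested at the end of the competition, so
the ratio is the natural per-strain contrast.

### Error propagation and the corrected Z-score

Barcode counting noise is modelled as Poisson: a count $n$ carries
relative error $1/\sqrt{n + c}$. Propagated through the log ratio this
gives an absolute error
$\delta_i = \frac{1}{\ln 2}\sqrt{\frac{1}{n^{\mathrm{GAL}}_i + c} +
\frac{1}{n^{\mathrm{GLU}}_i + c}}$, hence an absolute Z error
$\delta_i/s$ and a relative *error rate*
$e_i = (\delta_i/s)/|z_i|$ (defined as 1 when $z_i = 0$: a null score is
fully uncertain). The corrected Z-score is the pair
$(1 \pm e_i)\,z_i$: the low bound shrinks the score toward zero (capped
so it cannot cross zero when $e_i > 1$) and the high bound inflates it.
Classification uses the conservative low bound, so hit lists shrink, not
grow, under counting uncertainty. Strains with corrected Z above 1.96
are suppressors, below −1.96 enhancers, anything else no-effect — the
two-sided 5% standard-normal critical values, with strict inequalities.

No multiple-testing correction is applied by default (the fixed 1.96 cut
is the decision rule); `fdr = TRUE` reports Benjamini–Hochberg q-values
from two-sided normal p-values as a diagnostic.

## The synthetic pooled experiment

The generator (`sim_config()`, `simulate_screen()`) emulates the pooled
competition:

* **Library.** `build_library()` draws `n_strains` (default 4653, a
  genome-scale homozygous deletion collection) unique 20-mers by rejection
  sampling with minimum pairwise Hamming distance 3 and a cap of 10^6
  candidate draws, so single-mismatch assignment is provably unambiguous.
* **Effects.** Under GLU every strain has relative fitness 1. Under GAL
  the toxic query slows the whole pool to `baseline_gal` (default 0.5);
  designated suppressors gain `suppressor_effect` (default +0.3) and
  enhancers lose `enhancer_effect` (default 0.3). The defaults give
  clearly separated but not extreme effects on the doubling-rate scale.
* **Growth.** Deterministic exponential competition over `generations`
  doublings (default 10, standing in for a two-day induction):
  $a_i \propto 2^{f_i t}$, normalised to sum to 1. Stochastic drift is
  deliberately omitted — the monotone abundance–fitness link is the
  assumption the scoring relies on, and sequencing sampling supplies the
  noise.
* **Sequencing.** `depth` reads per sample (default 10^6, a typical
  Bar-seq depth; the source experiments do not report theirs) are drawn
  multinomially from the abundances; each base is substituted
  independently with probability `seq_error_rate` (default 0.001,
  Illumina-like; no indels, matching the Hamming-based assignment).
  Qualities are constant Q40 and never used. Identical configurations
  produce byte-identical FASTQ.

What the generator does *not* emulate — PCR jackpots and amplification
bias, transformation bottlenecks, strain dropout, growth-phase effects,
index hopping — bounds what passing tests show: they validate the
counting and scoring machinery under the model's own assumptions, not
robustness to every artefact of real pooled screens. Enhancer detection
in particular is intrinsically harder than suppressor detection: enhancer
strains are depleted into low counts where Poisson noise dominates, and
under strong toxicity the contrast saturates. The recovery analyses
therefore constrain suppressor performance only, mirroring the validated
behaviour of such screens.

## Numerical choices and degenerate inputs

* Samples whose counts are all zero are a hard error (normalization is
  undefined); zero spread of the log ratios (a degenerate screen) is a
  hard error rather than a silent division by zero.
* The error-rate ratio $e_i$ divides by $|z_i|$ and is ill-conditioned
  near $z_i = 0$; the classification never sees that instability because
  the low bound is capped at zero there.
* Abundances are computed as $2^{f_i t - \max_j f_j t}$ to avoid
  overflow at large generation counts; conservation to 1 within 1e−12 is
  a tested invariant.
* Barcode and tag matching break ties by reporting ambiguity (never
  first-wins); ambiguous assignments are excluded from counts but
  tallied, so the ledger still balances.
* Network exports sort nodes and edges lexicographically before writing,
  which makes GraphML output canonical: export → import → export is
  byte-stable.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script exercise the pipeline at
200 strains per screen (10 suppressors, 10 enhancers), 10^5–10^6 reads
per sample and 20 replicate seeds for the recovery study — sizes at which
every stage's behaviour is already asymptotic while a complete run stays
comfortably interactive. The full 4653-strain library is exercised where
the catalog itself is the object under test.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_strains = 200, n_suppressors = 10, n_enhancers = 10,
                  depth = 1e5, seq_error_rate = 0.001, seed = 42)
sim <- simulate_screen(cfg, queries = c("OPTN", "ANG"), outdir = "demo")
dx  <- count_barcodes(sim$design, sim$catalog)
fit <- score_screen(dx$counts, sim$catalog)
summary(fit)

omap <- load_ortholog_map(system.file("extdata", "example_orthologs.tsv",
                                      package = "bartox"))
mp   <- map_suppressors(fit$ztable, omap)
net  <- build_network(mp$interactions)
export_network(net, "screen.graphml")
```

`run_pipeline()` wires the same stages together from a single YAML
configuration with one global seed (split deterministically per stage)
and writes a manifest hashing every artifact, so a run is reproducible
byte for byte.

## Known limitations

* Single-end, fixed-position parsing only; no adapter trimming, quality
  filtering or paired-end merging.
* No replicate-aware variance model: the screen design has one GLU/GAL
  pair per query, so the across-strain spread is the only variance
  estimate.
* Ortholog expansion is many-to-many and source-tagged; the package does
  not arbitrate between ortholog databases, it records provenance and
  leaves filtering to the user.
* Enrichment is a generic hypergeometric test over user-supplied
  categories; it does not reproduce any proprietary annotation content.
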