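---
title: "Methods: germline panel classification and carrier-burden statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline panel classification and carrier-burden statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptvburden)
```

## Scope and shape

`ptvburden` implements the analytical core of a multi-gene germline panel
study in BRCA1/2-negative breast cancer: rule-based variant classification
followed by gene-level carrier-burden statistics against several control
cohorts and across phenotype strata. The repository is organised as an
analysis workflow — the numbered drivers under `analysis/` narrate the steps
(simulate, classify, case-control burden, phenotype strata) and write their
tables under `results/` — while every computation lives in the package
functions documented here, so the test suite and the acceptance script
exercise exactly the code the workflow runs. The workflow scripts are also
the package's command-line surface; there is no separate CLI binary.

## The classification model

Variants are assigned a five-tier class (1 benign, 2 likely benign, 3 VUS,
4 likely pathogenic, 5 pathogenic; classes 4/5 pooled as "deleterious").
The rules, in precedence order:

1. **Override list.** A per-variant override forces a class. The shipped
   default (`default_overrides()`) keeps the recurrent CHEK2 missense
   c.470C>T (p.I157T) at class 3, reflecting its lack of case-control
   association in the study population despite literature reports of a
   low-risk effect.
2. **Allele-frequency rule.** Any variant reported at MAF ≥ 1% in *any*
   configured reference population is benign (class 1). The maximum across
   populations is used because a variant common in any reference group
   fails the rarity expectation of a high-penetrance allele; an unobserved
   frequency counts as rare, since panel testing routinely produces novel
   variants.
3. **PTV rule.** Protein-truncating variants — nonsense, frameshift, or
   essential splice-site variants (the invariant ±1/±2 intronic
   dinucleotides, or the last exonic base on the donor side of an exon) —
   are class 5 when the truncation escapes the NMD-escape zone (below).
4. **NMD-escape demotion with domain rescue.** A PTV anchored in the last
   coding exon or the final 55 coding nucleotides of the penultimate coding
   exon likely escapes nonsense-mediated decay and is demoted to VUS
   (class 3) — unless the truncated region `[anchor, CDS end]` intersects
   an annotated functional domain, which restores class 5.
5. **Everything else** is VUS (class 3). Class 4 is reachable only through
   overrides: the source analysis pools classes 4/5 throughout and states
   no separate likely-pathogenic criterion, and we preferred not to invent
   one.

Independently of the class, rare missense variants (all reported MAFs
< 0.1%) called damaging by *both* configured in-silico predictors carry a
`damaging_missense` flag; which two annotation columns play the predictor
roles is configuration, not code.

### Coordinate and zone conventions

All genomic coordinates are 1-based closed (VCF/GFF3); coding coordinates
are 1-based from the A of ATG with the stop codon included (HGVS c.
numbering), so protein length is `cds_length/3 - 1`. The "last 55 bp of the
penultimate exon" is counted in *coding* nucleotides of the penultimate
CDS-bearing exon — the rule models NMD escape of a premature stop, a
property of the coding sequence — and non-coding exons are ignored for exon
counting. A transcript whose CDS sits in a single exon has no downstream
junction at all, so its whole CDS is treated as NMD-escape; the output
flags this so users can audit it.

Three further points the rule text leaves open, decided here:

* **Frameshift anchor.** The demotion anchor is the first altered codon,
  not the downstream novel stop: it is conservative and needs no sequence.
  When the coding sequence is available the premature-termination codon
  could be computed instead; we kept the anchor-based rule as the single
  behaviour rather than a switch, and note that for anchors already inside
  the zone the two coincide in effect.
* **Domain disruption** means the truncated tail `[anchor, CDS end]`
  *intersects* a domain (the weakest defensible reading — truncation
  removes everything downstream); `domain_mode = "contained"` offers the
  stricter reading that the whole domain must be lost.
* **Final-intron splice variants.** An essential splice variant upstream of
  the final coding junction always truncates ahead of the zone and stays
  class 5. One affecting the final junction is evaluated at the first
  coding base of the last coding exon; because this convention is not
  spelled out in the rule text, such calls carry an explicit note in the
  output instead of being applied silently.

## Burden statistics

Carrier counts are per patient, not per allele: a patient with several
qualifying variants in a gene counts once, and once in the any-gene row —
the simulated and fixture cohorts both contain dual-gene carriers to keep
this deduplication honest. Three carrier definitions are used:
`ptv_only` (deleterious PTVs, the case-control definition), `class45`
(all deleterious variants, the case-case definition) and
`damaging_missense`.

For a 2×2 table of carriers/non-carriers the odds ratio is the
cross-product, and its 95% interval the Wald interval
`exp(log(OR) ± z·sqrt(1/a + 1/b + 1/c + 1/d))` with `z = qnorm(0.975)`
(1.959964, not 1.96, so results are bit-reproducible). This is exactly the
exponentiated slope and Wald interval of a univariate logistic regression
on the same table — the identity that lets closed-form code reproduce
regression-derived published values, and which the test suite verifies
against an explicit `glm` fit on random tables. Any zero cell makes the
estimate undefined and it is rendered `n.a.`; no Haldane–Anscombe
continuity correction is applied, because the published tables use the same
convention and a corrected estimate would silently disagree with them.

Significance comes from the two-sided Fisher exact test
(point-probability method, via `stats::fisher.test`, enumeration-checked in
the tests) and, for age at first diagnosis, a pooled-variance Student t
test (Welch available via `var_equal = FALSE`). Age comparisons support two
reference constructions — the non-carrier remainder (`vs_rest`, the
default) and the overall sample including carriers (`vs_overall`) — because
the published wording ("compared with the overall sample") is ambiguous;
the workflow reports `vs_overall` to match the published table's framing.
No multiple-testing correction gates significance (the reference analysis
used raw p < 0.05); a Benjamini–Hochberg column is emitted alongside as
supplementary output.

Report tables round to 2 decimals, half away from zero, to match the
printed tables for regression testing; the JSON twins always carry machine
precision.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes. Its defaults are the study conditions: 5589 index cases; eight
panel genes at their observed deleterious-PTV carrier frequencies (from
71/5589 down to 3/5589); control cohorts of 27,173 (ExAC-like), 7325
(FLOSSIES-like) and 2189 (geographically matched) at their observed
per-gene frequencies; a recurrent CHEK2 founder frameshift (keyed
`c.1100del`, 79/103 of CHEK2 carriers); age at first diagnosis from a
truncated normal (mean 46.7, range 17–92 years; sd 11 chosen so the
published age-band fractions ~26% < 40 and ~38% 40–49 are approximately
reproduced — the source reports only mean/median/range); bilateral fraction
11.3%; receptor status known for 55.5% with ER+ 75.9%, PR+ 70.5%, HER2+
21.2% as independent margins (no joint distribution is published).

Stratum effects are odds multipliers on the per-gene carrier probability
(bilateral disease, ER-positive and HER2-positive status; defaults from the
published case-case odds ratios, e.g. 2.07 for PALB2 and 3.30 for TP53 in
bilateral disease), renormalised by their expectation so the configured
*marginal* prevalence is preserved — this keeps the overall 4.87% carrier
fraction a calibration target rather than a moving part. Per-gene age
shifts (e.g. −7.0 years for TP53) act additively on carrier ages.
Dual-gene carriers arise naturally from independent per-gene draws
(expectation ≈ 2–5 at these frequencies) rather than being forced to the
observed count of two.

Carriers receive concrete engineered variants on synthetic transcripts
(random exon partitions of realistic CDS lengths, random coding sequences
without internal stops, two annotated domains per protein): nonsense SNVs
built by mutating a codon to a stop, 1-bp frameshift deletions, and
invariant-site splice SNVs, with a configured fraction (default 8%) aimed
into the NMD-escape zone. Missense VUS, consensus-damaging rare missense
and one common benign allele per gene are generated alongside so that
every classification rule fires on simulated data. All randomness derives
from a single seed through per-component sub-seeds, so each artifact
(phenotypes, carriers, variants, controls) is individually reproducible
and the written VCF is byte-identical across runs.

What the generator does *not* emulate: realistic mutation spectra or
per-site mutation rates, haplotypes and linkage, receptor-status
correlation structure, ascertainment through family history, or sequencing
error. Passing tests on simulated data therefore demonstrate correctness
of the rules and estimators under the assumed sampling model, not
robustness to the messiness of real diagnostic data.

## The published-count fixture

`fixture_from_tables()` is the bridge to the published results: a
deterministic pseudo-cohort whose margins equal the published counts
exactly — per-gene deleterious and PTV carriers, founder sub-counts,
bilateral splits (including the zero bilateral NBN cell), the
receptor-status subgroup with its TNBC cell and nested founder sub-margins,
both dual carriers (unilateral, receptor status unavailable, as the
published totals imply), per-gene carrier mean ages, and the
damaging-missense prevalences. Receptor margins are realised by a nested
assignment that pins the all-negative (TNBC) cell and covers every
non-TNBC carrier with at least one positive marker. Running the real
pipeline on this fixture reproduces every defined published odds ratio and
CI to two decimals. Three published cells are knowingly not reproducible
from their own printed counts (the CHEK2 case-control ORs 2.93 and 3.02,
and the bilateral any-gene carrier OR 1.50, where the count cross-products
give 2.95, 3.05 and 1.47) — plausibly the original regression used
slightly adjusted denominators; the pipeline reports the count-derived
values and the discrepancy is asserted, not hidden.

## Numerical and degenerate-input choices

* Intron offsets are HGVS-style signed distances to the nearer exon
  boundary; exact midpoints resolve to the donor side.
* Multi-allelic VCF records are decomposed per alternate allele before
  classification; rules are allele-specific.
* SNV reference alleles are checked against the supplied coding sequence
  and mismatches are refused with the offending position named.
* Without a coding sequence, coding SNVs fall back to an HGVS p.
  annotation when present, else classify as `other`.
* Degenerate Fisher margins return p = 1 with a warning; empty groups and
  unknown patient or transcript identifiers are errors (unknown transcripts
  in VCF streaming are skipped, warned about, and counted).
* Age lists of length one return means but no p-value.

## Problem sizes used in verification

The deterministic acceptance checks run on the full published counts
(5589 cases against cohorts of 27,173 / 7325 / 2189) and cost seconds.
Property checks use: exhaustive coordinate verification on 300–600 nt toy
transcripts; 500 engineered PTVs per transcript geometry against a literal
restatement of the rules; 100 random tables against brute-force
hypergeometric enumeration and 50 against the logistic oracle; 200
simulated cohorts at full study scale for log-OR recovery (bias bound 0.05
on the log scale, about three Monte-Carlo standard errors at the
best-measured gene); and 1000 replicate tables at true OR 3.6 for Wald
coverage, with 93–97% accepted. These sizes were chosen to make
Monte-Carlo error small relative to the assertion bands.

## Known limitations

* No full HGVS parser: the `cdot` key and p. fallback are shorthands.
* Large genomic rearrangements and copy-number events are out of scope, as
  in the source analysis.
* One canonical transcript per gene; no isoform selection.
* The in-silico predictor verdicts are consumed as annotations; the tools
  themselves are never run.
* The MAF benign rule admits no exceptions beyond the override list ("
  generally considered benign" hints at unenumerated exceptions; none are
  implemented because none are specified).
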