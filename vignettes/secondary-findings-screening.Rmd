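---
title: "Screening exome cohorts for secondary findings: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exome cohorts for secondary findings: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfscreen)
```

## The screening problem

When an exome or genome is sequenced for one clinical question, the data
inevitably also cover genes in which a pathogenic variant predicts a
different, medically actionable disease. Variants of known or expected
pathogenicity in such genes, unrelated to the indication for sequencing, are
*secondary findings*. Reporting them is worthwhile exactly because the
conditions involved — hereditary cancer syndromes, cardiomyopathies and
arrhythmias, familial hypercholesterolemia, and a handful of metabolic
disorders — are ones where early awareness changes management.

`sfscreen` implements the screening side of that task for multi-sample
cohorts: an automatic filter cascade that reduces tens of thousands of calls
to a short candidate list, an evidence-combination engine for the manual
assessment step, a three-way reporting categorization, and cohort-level
aggregation. The package deliberately stops where curator judgment begins:
it never invents evidence codes beyond two clearly flagged advisory
suggestions, and it implements no benign-side classification at all.

## The gene policy list

Screening is restricted to an actionable-gene list with a per-gene reporting
policy. The shipped default transcribes the ACMG SF v2.0 recommendation of
59 genes. Each entry carries:

* `inheritance` — `AD`, `AR`, or `XL`. Only the two autosomal-recessive
  entries (`MUTYH`, `ATP7B`) change the filter's behaviour: a single
  pathogenic allele of a recessive gene is carrier status, not a reportable
  risk, so only homozygotes are screened there. The X-linked entries
  (`GLA`, `OTC`) are carried for bookkeeping and treated like `AD` by the
  zygosity filter; hemizygous male calls pass.
* `ep_eligible` — whether a *novel* protein-truncating variant is reportable
  in this gene. It is false for genes where pathogenicity works through
  gain of function or specific alleles (`APOB`, `PCSK9`, `RYR1`, `CACNA1S`,
  `RYR2` in the shipped table), because a truncating allele there does not
  imply the actionable phenotype. The published source table does not
  enumerate this split in the screening protocol itself, so the shipped
  flags are a best-effort transcription of the v2.0 recommendation; the
  table is plain data (`inst/extdata/acmg_sf2_gene_policies.tsv`) and any
  revision is a data edit, not a code change.

## The automatic filter cascade

Four per-call predicates, applied in protocol order; since each is a pure
predicate, the surviving set equals their conjunction and is independent of
stage order (a property the test suite checks against a brute-force oracle).

1. **Gene restriction** — only calls in policy-list genes continue.
2. **Zygosity** — in `AR` genes only homozygous calls continue; all
   zygosities continue elsewhere.
3. **Rarity** — the call's popmax MAF (the highest minor allele frequency
   in any reference population) must be at most `maf_threshold`
   (default 0.005). Homozygotes in `AR` genes are admitted up to
   `ar_hom_maf_threshold` (default 0.02): recessive pathogenic alleles
   circulate at appreciable carrier frequencies, and the screen only
   reports the much rarer homozygous state. Both comparisons are inclusive
   (`<=`), and a variant absent from the frequency table counts as
   frequency 0 — a variant never observed in population data cannot exceed
   a rarity ceiling.
4. **Retention** — a surviving call must be previously asserted (HGMD `DM`
   or `DM?`, or ClinVar pathogenic/likely pathogenic) or be
   protein-truncating (frameshift, stop-gain, start-loss, or splicing — the
   consequence classes in which a novel allele can still be interpretable).
   A ClinVar `conflicting` record does not satisfy retention. Novel
   missense variants are therefore never candidates, by design.

Every decision is logged: the audit trail records, per distinct variant and
stage, the calls in and out and the values compared, so an eliminated
variant can always be traced to the rule that removed it.

Rarity is evaluated per variant; the AR-homozygote exception is evaluated
per call. No conflict arises, because a heterozygous carrier of an AR-gene
variant has already left the cascade at the zygosity stage.

## Evidence combination and the three-category model

The manual-assessment step assigns each candidate a set of ACMG/AMP 2015
pathogenicity criteria. Codes carry their native strength (PVS1 very
strong; PS1–PS4 strong; PM1–PM6 moderate; PP1–PP5 supporting) unless a
modifier reassigns it — `PS4_Supporting`, `PP1_Strong` — which is how
expert-panel gene-specific adaptations (e.g. for MYH7-associated
cardiomyopathy) are expressed as input. The engine treats strength
reassignment uniformly: its output depends only on the counts of applied
strengths, never on which base codes realized them.

The combining rules are transcribed literally from the 2015 guideline
(pathogenic clauses checked first, so the highest achievable tier wins);
the test suite proves equivalence against an independently coded clause
list over the full grid of count vectors (up to 1 very strong, 4 strong,
6 moderate, 6 supporting). Two deliberate boundaries:

* Benign-side criteria are not implemented. Anything failing the
  pathogenic/likely-pathogenic rules is `uncertain`, which the reporting
  layer collapses into `others`. The three-category simplification is the
  point: a screening lab does not need to distinguish "uncertain" from
  "likely benign" for variants it will not report either way.
* A count vector with two very-strong criteria matches no printed clause
  and returns `uncertain`. It is reachable only through strength-promoted
  codes, which the engine accepts syntactically but the guideline never
  contemplated; the literal transcription is kept rather than inventing an
  extrapolation.

Categories follow from tier plus provenance: **KP** (known pathogenic) is a
previously reported variant — any non-absent ClinVar or HGMD record,
including a bare `DM?` — meeting pathogenic *or* likely-pathogenic
criteria; **EP** (expected pathogenic) is a novel protein-truncating
variant in an `ep_eligible` gene meeting the same criteria; everything
else is `others`. KP deliberately spans both tiers.

Dual curation is supported as a discordance flagger
(`check_concordance()`): it lists variants whose code sets or implied tiers
differ between two curators, or that only one curator assessed. Resolution
is a human conversation, not a function.

## The synthetic cohort generator

No genotype-level cohort data are distributed with the protocol this
package operationalizes, so correctness is established by construction:
`generate_cohort()` materializes a fully specified cohort — VCF, annotation
table, knowledge-base tables, group labels, curator evidence — together
with a derived truth table stating, for every variant, the stage that
should eliminate it (or none), the expected tier, and the expected
category. The closure property *pipeline(generate(config)) = truth* is a
standing test, at randomized configurations.

The default configuration is the study design the package's worked example
follows: 421 individuals in three groups (96 phenotypically normal, 96
juvenile obesity, 229 congenital heart disease), twelve carrier individuals
over eleven reportable variants, with one variant (the APOB missense)
shared by one normal and one CHD child. `table1_fixture()` emits the fully
deterministic version of that bundle, with the printed evidence sets, plus
engineered decoys: one variant per cascade stage that fails exactly that
stage, and candidates that survive filtering but fail classification (a
weakly supported AR homozygote admitted under the relaxed ceiling, a novel
truncating variant in a non-`ep_eligible` gene, a reported missense with
insufficient evidence, a reported synonymous variant with no evidence).

Planted carriers are distinct individuals within a group; sharing is
expressed as one variant with several carriers. This makes carrier counts
an exact function of the configuration rather than of collision luck in
the random draw.

What the generator does *not* emulate: linkage structure, realistic
site-frequency spectra, sequencing error, genotype-quality fields, or
multi-allelic complexity beyond what the parser itself constructs. Passing
tests therefore demonstrate the correctness of the decision logic on
well-formed inputs, not robustness to the full messiness of production
VCFs.

## Numerical and representational choices

* **Variant identity** is the normalized key `chrom:pos:ref:alt` after
  shared-suffix-then-shared-prefix trimming of the allele pair. This
  collapses padded spellings of the same indel and is idempotent. Full
  left-alignment across flanking reference context would require a genome
  FASTA the pipeline does not otherwise need; within one annotation
  convention the trimmed key is already unambiguous, and distinct-variant
  counts, knowledge joins and annotation joins all use it consistently.
* **Zygosity** comes from the `GT` field alone; phased and unphased
  genotypes are equivalent, haploid calls are `hemi`, and half-calls
  (`./1`) are kept as `het` with a warning — permissive-with-warning keeps
  a reviewable candidate rather than silently discarding it.
* **Percent rendering** is round-half-away-from-zero to two decimals
  (3 of 96 renders 3.13). All computation downstream of any rate uses the
  raw fraction; rounding exists only at the presentation boundary. A small
  epsilon guard absorbs binary floating-point error on exact decimal
  halves.
* **Tie-breaking** in the combining rules is pathogenic-first; within the
  likely-pathogenic clause "1 strong + 1–2 moderate", two or more strong
  criteria have already fired the pathogenic rule, so the clauses never
  compete.
* **Degenerate inputs**: an empty gene-policy table retains nothing; an
  empty cohort yields an empty candidate set and trail; knowledge-base
  lookups are total (absent keys return the absent-valued record);
  unknown consequence terms degrade to `other` with a warning.

## Problem sizes in the test suite

The suite favours many small randomized cases over few large ones: the
combining-rule equivalence enumerates all 490 count vectors; cascade/oracle
equivalence runs 200 randomized 12-variant cohorts plus 60 larger ones; the
closure property runs on full file bundles at the 421-sample study design
and at 30–76-sample randomized designs. These sizes exercise every rule
boundary (inclusive thresholds, AR exception, half-calls, multi-allelic
splits) while keeping the default run fast.

## Known limitations

* Compound heterozygotes and phase are out of scope; without family data
  the cascade cannot distinguish *cis* from *trans*, so AR genes are
  screened for homozygotes only.
* The policy table's `ep_eligible` split is a transcription of a published
  recommendation, not derived from mechanism annotations; users with a
  different reading edit the table.
* The engine accepts strength-promoted `PVS1` variants syntactically but
  the 2015 clause list it transcribes has no rule for two very-strong
  criteria (see above).
* Consequence classes are taken from the annotation table as given; the
  package does not recompute splice-region membership or transcript
  effects, and the choice of transcript set is the annotator's.
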