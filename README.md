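# sfscreen — secondary-findings screening for exome cohorts

When an exome is sequenced for one clinical question, the data also cover
genes in which a pathogenic variant predicts a *different*, medically
actionable disease. Such variants — known or expected pathogenic, in an
actionable gene, unrelated to the indication for sequencing — are
**secondary findings**. `sfscreen` is an R package for clinical
bioinformaticians and genetic-testing labs that screens multi-sample
cohorts for them:

* an **automatic filter cascade** over an ACMG SF v2.0-style actionable-gene
  policy list: gene restriction → autosomal-recessive homozygote rule →
  popmax allele-frequency rarity filter (MAF ≤ 0.005, relaxed to ≤ 0.02 for
  AR-gene homozygotes) → retention of variants asserted in HGMD (`DM`/`DM?`)
  or ClinVar (P/LP) or protein-truncating (frameshift, stop-gain,
  start-loss, splicing), with a complete per-variant audit trail;
* an **ACMG/AMP 2015 evidence-combining engine** with modified strength
  levels (`PS4_Supporting`, `PP1_Strong`, …). With *vs/s/m/p* the counts of
  very-strong/strong/moderate/supporting criteria met, a variant is
  **pathogenic** if `vs≥1 & (s≥1 | m≥2 | m+p≥2 with m≥1 | p≥2)`, or `s≥2`,
  or `s=1 & (m≥3 | m=2,p≥2 | m=1,p≥4)`; **likely pathogenic** under the
  corresponding weaker clauses; otherwise **uncertain** (benign-side rules
  are intentionally collapsed into the non-reportable category);
* the three-way reporting categorization — **KP** (known pathogenic:
  previously reported, meets P/LP), **EP** (expected pathogenic: novel
  protein-truncating variant in an EP-eligible gene, meets P/LP), and
  **others** — plus a dual-curator discordance checker;
* **cohort reporting**: per-group and overall reportable rates,
  consequence-class breakdown, candidates per individual;
* a **synthetic cohort generator** with derived ground truth, so the whole
  pipeline is testable end-to-end without access to gnomAD, ClinVar, or
  HGMD.

## Worked example

The package ships a deterministic worked-example bundle: a 421-sample
cohort (96 phenotypically normal, 96 juvenile-obesity, 229
congenital-heart-disease children) carrying eleven reportable variants in
twelve individuals, plus engineered decoys that must fail.

```r
library(sfscreen)

b <- table1_fixture(tempfile("bundle"))
res <- screen_cohort(b$vcf, b$annotations, b$genes, b$kb_freq,
                     b$kb_clinvar, b$kb_hgmd, b$groups, b$evidence)
res$summary
#> Cohort secondary-findings summary
#>   11 reportable variant(s) in 12 of 421 individuals (2.85%)
#>   normal     6 carriers /  96 individuals = 6.25%
#>   obesity    3 carriers /  96 individuals = 3.13%
#>   chd        3 carriers / 229 individuals = 1.31%

cls <- res$classified
cls[cls$category %in% c("KP", "EP"),
    c("gene", "hgvs_c", "codes", "tier", "category")]
#>   gene         hgvs_c                          codes              tier category
#>   APOB     c.10579C>T                    PS3,PS4,PP3        pathogenic       KP
#>  BRCA2 c.2806_2809del                   PVS1,PS4,PM2        pathogenic       KP
#>    DSP       c.268C>T                   PVS1,PM2,PP3        pathogenic       KP
#>   MYH7      c.1988G>A     PS4,PP1_Strong,PM1,PM2,PP3        pathogenic       KP
#>   MYH7      c.1207C>T PS4,PP1_Strong,PM1,PM2,PM5,PP3        pathogenic       KP
#>   PMS2     c.498+2T>C               PVS1,PS3,PM2,PP3        pathogenic       KP
#>   SDHB       c.724C>T PS4,PM2,PM5,PP3,PS3_Supporting        pathogenic       KP
#>   LDLR      c.459delC                       PVS1,PM2 likely_pathogenic       KP
#>   MYH7      c.2608C>T PM1,PM2,PM5,PP3,PS4_Supporting likely_pathogenic       KP
#>  BRCA2 c.2944_2945del                       PVS1,PM2 likely_pathogenic       EP
#>   FBN1     c.3042dupT                       PVS1,PM2 likely_pathogenic       EP
```

Reading the output: the cascade left 15 candidate variants for manual
assessment; evidence combination put seven in the pathogenic tier and four
in likely pathogenic; nine are KP (previously reported — note KP spans both
tiers) and two are EP (novel frameshifts in EP-eligible genes). The twelve
carrier individuals give group reportable rates of 6.25 %, 3.13 % and
1.31 %, and a cohort rate of 2.85 %. The four decoy candidates that
survived filtering all classify as `others`: a weakly supported ATP7B
homozygote, a novel RYR1 frameshift (gene not EP-eligible), a reported
missense with insufficient evidence, and a reported synonymous variant.

A shell front end wraps the same functions:

```sh
exec/sfscreen filter --vcf cohort.vcf --annotations ann.tsv \
    --kb-freq freq.tsv --kb-clinvar clinvar.tsv --kb-hgmd hgmd.tsv \
    --out candidates.tsv --audit audit.tsv
exec/sfscreen classify --candidates candidates.tsv --evidence ev.tsv \
    --evidence-b ev_second_curator.tsv --out classified.tsv
exec/sfscreen report --classified classified.tsv --candidates candidates.tsv \
    --groups groups.tsv --out summary.json
```

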