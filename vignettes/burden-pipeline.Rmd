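---
title: "Rare-variant filtering, segregation and Poisson burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant filtering, segregation and Poisson burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdburden)
```

## The problem

Neural tube defects (NTD) — myelomeningocele, anencephaly and related
closure defects — have high heritability but strongly heterogeneous
genetics: individually rare, incompletely penetrant variants scattered
over many genes. Exome studies of such traits typically combine two arms:
a *candidate-gene* arm that filters hard and then asks whether surviving
variants segregate with disease inside families, and an *unbiased burden*
arm that asks, gene by gene, whether affected individuals carry more
qualifying variants than controls. This package implements both arms over
standard inputs (annotated multi-sample VCF, PED pedigree, gene-list and
gene-model TSVs) plus a simulator for validating the statistics at desk
scale.

## The filter cascade

Records flow through four stages in a fixed order, with per-stage removal
counts in a funnel table:

1. **Consequence**: drop synonymous and noncoding variants. Records with
   an unrecognised consequence are kept with a warning rather than
   silently dropped.
2. **Frequency**: drop records whose allele frequency exceeds
   `max_pop_freq` (default 0.01, strict inequality) in *any* population
   source. A record absent from every source is treated as novel and
   kept; this matters because true pathogenic NTD alleles are typically
   absent from gnomAD/ExAC entirely.
3. **Genotype QC**: a record is retained only if at least one *relevant*
   carrier passes all of: GQ ≥ `min_gq` (default 99, the conventional cap,
   read as an inclusive bound), more than `min_strand_reads` (default 3,
   exclusive — i.e. at least 4) alternate reads on each strand, and an
   alternate-read fraction strictly above `min_alt_fraction` (default
   0.15). "Mutation frequency" here is the carrier's alternate-read
   fraction, not a population or cohort allele frequency — population
   frequency is already handled by stage 2. Zero or missing depth fails,
   since the fraction is undefined. Carriers that fail on an otherwise
   retained record are cleared to missing, so downstream segregation never
   leans on unsupported calls. With a pedigree the relevant carriers are
   the affected individuals; without one (a control cohort) every carrier
   counts. Whether the original analyses gated on *any* or on *all*
   carriers is not recoverable from their descriptions; gating on any
   affected carrier is the weakest rule consistent with "keeping
   high-quality mutations", and the carrier-clearing step keeps the
   surviving genotype data clean under it.
4. **Impact**: keep loss-of-function variants (stop-gained, frameshift,
   splice) and probably-damaging missense variants. The missense call uses
   the PolyPhen-2 categorical tag by default; a score-cutoff rule
   (default 0.80) exists for annotation sources that provide scores only.
   The default cutoff sits just below the smallest probably-damaging
   score in the packaged replication table (0.848), so both rules agree
   on the shipped fixtures.

Stages 1 and 2 commute; the order is fixed anyway so funnel reports are
reproducible. The cascade is idempotent, and on any input it equals a
record-by-record evaluation of the boolean rules (both facts are enforced
by property tests).

The *replication filter* used for targeted-resequencing cohorts is the
lighter published variant of the same rules: frequency < 1% plus a
probably-damaging/LOF impact, with no genotype-QC stage (MIP
pileup-derived calls carry different quality semantics than exome
genotypes).

## Candidate genes and segregation

The candidate list is the union of tagged source lists (mouse-NTD
orthologues and folate-pathway genes in the shipped configuration);
merging is commutative and associative, and tags accumulate. Gene matching
is case-insensitive exact symbol matching — alias resolution is
deliberately out of scope, as is computing annotations: the pipeline
consumes pre-annotated input.

Segregation is judged per family among the variant's carriers: a variant
is *shared* when every affected member with a non-missing genotype carries
it and at least one affected carrier exists. An affected member with a
missing genotype does not veto sharing (exome coverage gaps are routine);
such families are flagged `incomplete` instead. Unaffected carriers are
reported as a penetrance annotation, the transmitting parent is named when
exactly one genotyped parent carries, and a de novo flag is raised when
both parents are genotyped non-carriers. Trio probands run through the
same code path as multiplex families — a single affected carrier shares
trivially.

The compound-heterozygote scan emits all pairs of heterozygous variants a
sample carries in one gene, with phase support from parental genotypes:
`confirmed_trans` when the two variants trace to different single parents,
`excluded_cis` when both trace to the same parent, `possible` otherwise.
No statistical phasing is attempted.

## The burden test

The counting unit is the **carrier-observation**: an individual carrying a
variant counts once per variant, so a variant shared by two affected
contributes two. This is the convention under which the packaged exome
table (four case variant rows, two of them carried by two individuals
each) yields six case observations — and it is the unit the simulator
draws directly.

Rates are `k / (n * L * 2)`; in the two-cohort comparison the coding
length `L` cancels exactly, so the test runs on allele-count exposures
`E = n * 2` and never requires gene models (they only add per-bp rates to
the report). The test statistic is the exact Poisson upper tail
`P(X >= k_case)` at `lambda = k_ctrl * E_case / E_ctrl`. The analyses this
package reproduces describe the test as two-tailed, but both of their
printed p-values (1.228e-6 and 0.05265 = 1 − 7e⁻²) equal the one-sided
upper-tail probability to all printed digits, so `tail = "upper"` is the
default and a doubled two-sided option is provided and labelled.
Significance uses `alpha / n_genes` with `n_genes = 20389` by default;
both are configurable.

Two degeneracies are handled explicitly:

* `k_ctrl = 0` makes `lambda = 0` and any case count infinitely
  significant. `poisson_burden_p()` defaults to the raw behaviour
  (p = 0 with a warning) so published values reproduce unperturbed;
  `gene_burden_scan()` defaults to a 0.5 pseudocount added only when the
  control count is zero, always flagged in the `pseudocount_applied`
  column.
* Genes with mutation excess caused by read misalignment are removed via
  an explicit, editable blacklist. A heuristic (control count above the
  cross-gene 99.9th percentile) only warns — automatic exclusion of
  outliers would silently delete true signals in small cohorts.

## The simulator

`simulate_cohort()` draws, for each gene and cohort, qualifying
carrier-observations as `Poisson(rate * n * L * 2)` — the exact sampling
model the test assumes — rather than simulating a site-frequency spectrum:
the burden statistics see only counts and exposures, so count-level
realism is the property that matters. Each observation becomes a
heterozygous record with QC-passing genotype statistics assigned to a
random cohort member. Decoy records are injected per label — synonymous,
common (frequency drawn in (0.011, 0.2)), genotype-QC-failing (each
violating exactly one named rule, cycling through the four), and benign
missense when `polyphen_mix < 1` — and every record is labelled in a truth
table, so funnel removals can be checked against injected counts exactly.

Defaults are the study conditions: 61 cases structured as 18 familial
affected across 8 multiplex families plus 43 trio probands, 188 unrelated
controls, coding lengths 1–4 kb (the bulk of human coding genes), and a
base qualifying rate of 1e-6 per allele·bp — about one control
carrier-observation per 2.7 kb gene, a typical density for rare damaging
variants after the cascade. `polyphen_mix` defaults to 1 so that a
decoy-free configuration passes the cascade in its entirety. Enrichment is
specified as per-gene rate ratios applied to the case cohort only.

`simulate_family_variants()` complements the cohort generator with exact
small-pedigree scenarios (shared-by-affected, unshared, de novo,
compound-het) for validating the segregation logic; impossible
combinations (compound-het without two genotyped parents, unshared with a
single affected) are rejected.

What the generator does **not** emulate: linkage disequilibrium,
population structure, relatedness between carriers of the same variant
within the unrelated cohort arms, caller-specific QC artifacts, or a
realistic mutation spectrum. Passing tests therefore demonstrate the
correctness and calibration of the *statistics under their own sampling
assumptions*, not robustness to stratification or batch effects in real
cohorts.

## Evaluation and the choices behind the test problems

`evaluate_type1_power()` runs simulate → cascade (per arm) → scan per
replicate and reports, per significance level, the fraction of null-gene
tests with `p < alpha` (genes absent from the scan count as
non-significant), per-enriched-gene power, and the mean estimated rate
ratio `((k_case + 0.5)/E_case) / ((k_ctrl + 0.5)/E_ctrl)` — the 0.5
continuity correction keeps the ratio defined at zero counts and its bias
is a few percent once `E[k_ctrl]` reaches double digits, which is why the
recovery test problem uses `E[k_ctrl] = 15` and ratio 3
(`E[k_case] ≈ 14.6`).

The test problems are desk-scale by design: 2,000 genes (not the full
exome's 20,389 — the Bonferroni constant stays at 20,389 independently) at
a base rate giving `E[k_ctrl] ≈ 2`, 10 replicates for type-I, 200
replicates of a 5-gene cohort for recovery. At these sizes the full suite
runs in about a minute. Because λ is *estimated* from the control count
rather than known, the test is not uniformly conservative: its empirical
size at α = 0.05 sits a little above 0.06 under these conditions, driven
by low-count genes where a chance `k_ctrl = 0` or 1 makes a modest case
count look surprising. At the Bonferroni threshold the family-wise error
stays near zero (0–3 false positives in 20,000 null-gene tests).

## Numerical and design notes

* Tails come from `stats::ppois`; the test suite checks them against an
  independent summation of pmf terms
  `exp(k*log(lambda) - lambda - lgamma(k+1))` to 1e-12 over a 21×21 count
  grid, and the p-value is exposure-scale invariant by construction.
* VCF reading uses vcfR; multi-allelic sites are decomposed one record per
  ALT allele, with `Number=A`-style annotations split per allele and
  `Number=R` strand depths indexed by allele. Coordinates are 1-based
  (VCF); BED-style interval inputs would be half-open 0-based, converted
  at the I/O boundary. Writing emits plain-text VCF so outputs remain
  diffable and round-trip field-for-field.
* Genotype storage is sparse: only het/hom-alt/missing entries are kept,
  and a roster sample without an entry is an implicit genotyped
  homozygous-reference call. This keeps 2,000-gene × 249-sample cohorts
  small while preserving the carrier / genotyped-non-carrier / missing
  distinction segregation needs.
* Caller conventions differ, so the VCF field mapping is a configurable
  *dialect* (`vcf_dialect()`); the default expects `GQ`, `ADF`/`ADR`
  strand-split allele depths and `DP`, with annotations in INFO keys and
  population frequencies under an `AF_` prefix.
* The shipped 221- and 93-gene lists, the published-mutation table, the
  gene models and the pedigree fixtures are synthetic stand-ins carrying
  the real gene symbols the analyses name plus placeholder symbols to the
  documented sizes; curating the true historical lists is configuration,
  not code (their files are marked `synthetic`).

## Limitations

Single-variant-per-record decomposition means multi-nucleotide haplotypes
are not reassembled; no covariate adjustment, relatedness correction, or
collapsing tests beyond the Poisson rate comparison (SKAT-style methods
are out of scope); Bonferroni is the only multiplicity correction; and the
segregation logic assumes the pedigree's affection status is correct and
complete.
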