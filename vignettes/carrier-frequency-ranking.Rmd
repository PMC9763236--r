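---
title: "Estimating and ranking carrier frequencies of recessive disease genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and ranking carrier frequencies of recessive disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierrank)
library(dplyr)
```

## The problem

Autosomal recessive (AR) and X-linked (XL) Mendelian diseases are individually
rare but collectively a leading cause of neonatal and paediatric morbidity.
Unaffected carriers — heterozygous for one pathogenic allele — transmit these
diseases, and carrier frequencies differ sharply between populations. Panels
for newborn screening and expanded carrier screening should therefore be
anchored in population-specific carrier frequencies, yet for most genes and
most regions these have never been measured directly.

`carrierrank` estimates them from what *is* widely available: sites-only
population callsets that report, per variant and per population, the allele
count (AC), the number of called alleles (AN) and the number of homozygous
individuals (Hom). The pipeline

1. builds the catalog of known AR/XL disease genes from an OMIM
   genemap2-style table,
2. reads, quality-filters and merges population callsets,
3. classifies variants into four deleterious categories,
4. aggregates them into per-gene, per-population carrier rates and a
   predicted genetic prevalence, and ranks genes within each population,
5. compares cohorts by rank correlation, and
6. simulates complete synthetic cohorts with known ground truth so that every
   step above is testable without any external download.

## Gene catalog

A gene enters the catalog when at least one semicolon-separated sub-phenotype
of its `Phenotypes` annotation simultaneously (a) carries the `(3)` phenotype
mapping key (molecular basis known), (b) is annotated `Autosomal recessive`
or `X-linked` — where an annotation that is *only* `X-linked dominant` does
not count — and (c) does not begin with `?`, `{` or `[` (provisional,
susceptibility and non-disease entries). We evaluate the three rules per
sub-phenotype rather than on the whole cell: requiring them to co-occur in
one sub-phenotype is stricter and gives an auditable record of exactly which
annotation justified retention (the qualifying strings are kept in the
catalog). A gene annotated both X-linked dominant and X-linked recessive is
retained — only dominant-only annotations are excluded. Inheritance is
labelled from the chromosome (`XL` if and only if chromosome X). On the real
catalog this yields 2,699 genes: 2,525 autosomal and 174 X-linked.

Transcript models come from a genePred-style table; only `NM_`-prefixed
(protein-coding) transcripts are used. Coordinates are converted from the
0-based half-open file convention to 1-based inclusive at the reader
boundary, and everything downstream uses 1-based inclusive coordinates (the
VCF convention). A transcript's coding length is the number of exonic bases
inside the CDS; the gene-level value is the longest among its transcripts.

## Callset handling

Variants are kept when flagged `PASS` and covered in *more than* half of the
cohort (strict inequality at 0.5). Sites-only releases rarely expose per-site
call fractions directly, so when the cohort size is known we approximate
coverage as `AN / (2 * n_individuals)`; this is exact on autosomes when every
called individual is diploid, and it is the package's own choice, not part of
the formula. Exome and genome callsets are merged by summing AC, AN and Hom
per variant and population, recomputing allele frequencies from the merged
counts. Multiallelic sites are decomposed to one record per alternate allele.
A manually curated exclusion list (exact variant keys with a free-text
reason) is the vehicle for removing known low-penetrance or poor-quality
variants; nothing is hard-coded.

On chromosome X the source's homozygote convention (hemizygous males counted
in `Hom`) is taken as-is. No sex-stratified correction is attempted — a
documented limitation, discussed below.

## The four deleterious categories

Classification runs as a cascade; each variant lands in at most one category.

**Type 1 — known pathogenic.** ClinVar significance P or LP, or a conflicting
curation carried by at least 10 pathogenic submissions (conflicts driven by
one or two dissenting entries against an overwhelming pathogenic majority).
Including LP is the default (`include_lp = FALSE` restricts to P). Type 1
variants with allele frequency ≥ 0.005 in any population are *not*
auto-removed: they are emitted to a review report, because removing them is a
curation judgement (penetrance, risk-allele status) that belongs in the
exclusion list, not in code.

**Candidacy prefilter.** Variants that are not Type 1 move on only if they
are plausibly deleterious for a recessive disease in a healthy cohort: any
homozygous call in any population removes a variant (a healthy homozygote
contradicts severe recessive pathogenicity), as does an allele frequency
≥ 0.005 (inclusive) in any population whose AN is at least 1,000 — the AN
floor avoids calling a variant "common" from a handful of alleles.
Variants curated benign or likely benign are also barred here: only variants
of uncertain significance, conflicting curation or absent from the
annotation are candidate deleterious changes. Conflicting variants with
fewer than 10 pathogenic entries do fall through to candidacy.

**Type 2 — presumed loss of function.** Most severe consequence among stop
gained, start lost, frameshift, splice acceptor, splice donor (the
high-impact terms; when transcripts disagree, the most severe consequence
wins). Stop-gained variants additionally face the nonsense-mediated decay
(NMD) test: a premature stop in the final exon, or within 50 coding bases of
the final exon–exon junction, typically escapes NMD, yielding a truncated
protein rather than a degraded transcript — such stops are not confidently
loss-of-function and are excluded. Numerical choices, since the canonical
"50-nucleotide rule" leaves them open: the window is measured in *coding*
bases along the transcript strand, the boundary is inclusive at exactly 50,
and single-coding-exon transcripts always escape. A stop is excluded only
when it escapes on *every* protein-coding transcript harbouring it
(`nmd_mode = "any"` switches to single-transcript exclusion); a stop with no
covering transcript model is retained with a warning, since there is no
evidence of escape.

**Type 3 — predicted deleterious missense.** An ensemble of seven
prediction tools (CADD, DANN, fathmm_MKL_coding, phastCons, Polyphen2, SIFT,
VEST3) with per-tool cutoffs set to the mean score of ClinVar pathogenic
missense variants: CADD 28.04, DANN 0.99, fathmm_MKL_coding 0.90, phastCons
0.84, Polyphen2 0.90, SIFT 0.04, VEST3 0.78. Every tool calls a variant
deleterious at or above its cutoff except SIFT, where low scores are
deleterious. Only genes with at least one known pathogenic missense variant
are eligible; for those genes a gene-specific cutoff (the mean over the
gene's pathogenic missense variants) applies wherever it is *more* stringent
than the global one — the effective cutoff never relaxes. A variant is
Type 3 when it passes the five mandatory tools (CADD, DANN, Polyphen2, SIFT,
phastCons) and at least five of the seven overall; with all five mandatory
tools passing, the five-of-seven clause is automatically met, so the
mandatory rule is the binding one. The plain five-of-seven rule (no
mandatory subset) is available via `require_mandatory = FALSE`, because the
two readings genuinely differ — a variant passing CADD, DANN, fathmm_MKL,
phastCons and VEST3 but failing SIFT satisfies five-of-seven yet fails the
mandatory rule. Missing scores count as failing.

**Type 4 — harmful in-frame INDELs.** In-frame insertions/deletions that are
evolutionarily conserved (CADD strictly above 20) and fall in a protein
domain that also contains a known ClinVar P/LP in-frame INDEL of the same
gene. "Close proximity to known pathogenic INDELs" is operationalised as
same-domain co-occurrence, nothing fuzzier. Genes without a known pathogenic
in-frame INDEL yield no Type 4 calls; a missing CADD score excludes.

## Carrier rates and prevalence

For each deleterious variant and population, the variant carrier rate is

$$\mathrm{VCR} = \frac{AC - 2 \times Hom}{0.5 \times AN},$$

the fraction of individuals heterozygous for the allele (homozygotes are
subtracted; `0.5 × AN` is the number of individuals). When AN is 0 the rate
is 0. Assuming independent variants, the gene carrier rate is

$$\mathrm{GCR} = 1 - \prod_{i=1}^{n} (1 - \mathrm{VCR}_i),$$

the probability of carrying at least one of the gene's deleterious alleles,
and the predicted genetic prevalence at the gene level is

$$\mathrm{pGP_g} = \frac{\sum_i \sum_k \mathrm{VCR}_i \,\mathrm{VCR}_k}{4}
               = \frac{\left(\sum_i \mathrm{VCR}_i\right)^2}{4},$$

the expected affected-birth frequency when two random carriers mate and each
transmits a deleterious allele (Hardy–Weinberg random mating). The published
form of this equation is typographically garbled (its subscripts collapse);
the symmetric double sum over ordered variant pairs divided by four is the
reading consistent with random-mating carrier pairs, and the identity with
$(\sum_i \mathrm{VCR}_i)^2/4$ makes the implementation exact. This is a
documented interpretation, prominently flagged here because it cannot be
read off the printed equation.

Carrier rates above 1 are pathological (they can arise only from corrupt
counts); they are clamped into $[0,1]$ with a warning before the product, or
rejected with `clamp = FALSE`.

Within each population, all catalog genes — including those with zero
retained variants, which get GCR 0 — are ranked by descending GCR, ties
broken by ascending gene symbol. Keeping zero-GCR genes in the ranking keeps
rank vectors alignable across cohorts.

## Cohort comparison

Two cohorts are compared on the intersection of their gene catalogs,
restricted to genes with GCR > 0 in at least one cohort (genes invisible to
both carry no information and would flood the ranks with ties). Spearman's
rank correlation uses average ranks for ties; Pearson is computed on the raw
GCR values by default. Whether the published Pearson coefficients were
computed on GCR values or on integer ranks is not stated; raw values are the
default here because Spearman already covers rank space, and
`pearson_on = "ranks"` exists as a sensitivity switch. Correlation matrices
support row-wise Z-scaling for heatmap display (each row centred and scaled,
so each cohort's best-matching counterpart stands out regardless of its
overall correlation level).

## The synthetic cohort generator

`simulate_truth()` / `sample_callset()` / `simulate_cohort()` build complete
cohorts — catalog sources, transcript models, domains, ClinVar-style labels,
tool scores, per-population counts — with known ground truth. The generator
is first-class, tested code: it defines the study conditions under which the
pipeline's statistical behaviour is verified.

What it emulates, and the defaults chosen (each fixed once):

* **Genes.** 200 genes, each with one three-exon transcript (coding exon
  lengths 900/1000/900), alternating strands, 6.4% on chromosome X (the
  X share of the real catalog). One protein domain per gene (the middle
  exon).
* **Populations.** Seven populations of 10,000 diploids each, with
  per-population allele-frequency multipliers drawn log-normally
  (log-SD 0.5) around each variant's base frequency, creating realistic
  population differentiation.
* **Allele frequencies.** Deleterious variants draw base frequencies
  log-uniformly on $[10^{-5}, 5\times10^{-4}]$ — rare, as severe recessive
  alleles are, and safely below the 0.005 frequency filter so the filter
  never silently erases truth. Benign and uncertain variants draw from the
  wider $[10^{-5}, 0.05]$, and a planted "common missense" decoy class sits
  at 0.006–0.04, deliberately crossing the filter.
* **Class mixture.** type 1 / 2 / 3 / 4 / benign / VUS at
  0.15/0.15/0.15/0.05/0.35/0.15 — in-frame INDELs rarest, benign commonest.
  Variants per gene are Poisson with mean 8.
* **Evidence.** Pathogenic tool scores are drawn strictly beyond the cutoffs
  and benign scores strictly inside them, so classification of every
  non-borderline variant is determined by its true class; a `borderline`
  switch re-enables overlapping score distributions for stress testing.
  Stop-gained variants are placed on both sides of the NMD window on both
  strands; decoy stops sit inside the escape region. Decoy missense variants
  with fully deleterious scores are planted in genes *without* pathogenic
  missense anchors (they must not be called), and decoy in-frame INDELs sit
  outside anchored domains or below the conservation cutoff. Each eligible
  gene receives one anchor ClinVar pathogenic missense entry whose scores
  equal the global cutoffs, so the derived per-gene cutoff coincides with
  the global one — eligibility is exercised without moving any threshold.
* **Genotype sampling.** Benign variants follow full Hardy–Weinberg
  multinomial sampling, homozygotes included (exercising the homozygote
  filter). Truly deleterious variants are sampled *conditional on zero
  homozygotes*: carriers are Binomial$(n,\ 2q(1-q))$ and `Hom = 0`. This
  mirrors the ascertainment of the cohorts the method targets — individuals
  affected by severe childhood-onset recessive disease are excluded from
  them, so homozygotes for truly deleterious alleles are absent. It also
  makes the estimated VCR an exactly binomial estimator of the true carrier
  rate $2q(1-q)$, which is what the recovery checks assume.

What it does **not** emulate: realistic site-frequency spectra from
population-genetic models, linkage between variants (the GCR product form
itself assumes independence), sex-stratified chromosome X counts (X genes
are simulated with the autosomal machinery, matching the pipeline's uniform
treatment — a stress mode for the X limitation would need sex-aware
sampling), sequencing/annotation errors, and the long tail of real ClinVar
curation noise. Passing tests therefore demonstrate that the *pipeline
logic and estimators* are correct under the stated model; they do not
validate the biological accuracy of the classification rules on real data —
that is what the cross-cohort correlations and external-classifier
cross-checks in real studies are for.

## Statistical behaviour verified by the test suite

* The GCR and pGPg formulas match independent inclusion–exclusion and
  double-sum enumeration oracles to $10^{-12}$.
* The full classification cascade reproduces an independent brute-force
  rule evaluator *exactly* (set equality) on 100 randomized fixtures that
  include NMD-window positions 48–52 coding bases from the final junction,
  allele frequencies at exactly 0.005, CADD at exactly 20, and tool scores
  at exactly their cutoffs.
* On a simulated cohort (7 × 10,000 diploids, 200 genes), estimated GCR lies
  within 3 binomial standard errors of the true carrier frequency in ≥ 99%
  of gene–population cells. A note on this check: with expected carrier
  counts of 1–5 per variant, the binomial is right-skewed and the true
  two-sided 3-SE coverage is about 98.5–99.7% rather than the normal-theory
  99.7%; across seeds the per-cohort fraction fluctuates around 0.995, and
  cells that exceed 3 SEs were verified to carry exactly the correct
  classified variant sets (pure sampling noise).
* Two cohorts sampled from the same truth correlate (Spearman, on GCR
  rankings) more strongly than cohorts from independent truths in 100 of 100
  seeded replicates.
* Monotonicity: tightening any ensemble cutoff never adds a missense call;
  adding a positive-rate variant strictly increases GCR; rank vectors are
  exact permutations.

Problem sizes in the default test run — 200-gene cohorts, 10,000 diploids,
100 classification fixtures of ~250 variants, 100 comparison replicates at
5,000 diploids — were chosen as the smallest sizes at which the binomial
approximations and rank statistics are stable.

## Known limitations

* Chromosome X carrier rates apply the autosomal formula to counts that
  embed the source's hemizygote convention; female carrier frequency is the
  quantity of interest, and the uncorrected estimate conflates male
  hemizygotes with carriers.
* The GCR product assumes independent variants; in-phase variant pairs
  (haplotypes) inflate it slightly.
* Consequence annotation is consumed, not re-derived; errors in the upstream
  annotator propagate.
* Structural variants, repeat expansions and copy-number changes — major
  contributors for some diseases — are outside what sites-only SNV/INDEL
  callsets can support.
* No confidence intervals on GCR are produced; ranking stability across
  cohorts is the supported measure of reliability.
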