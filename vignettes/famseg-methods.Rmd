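---
title: "Methods: family-based rare-variant filtering, association and segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant filtering, association and segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The study design and what the package computes

`famseg` targets affected-sibling family designs: nuclear families
ascertained because they contain at least two siblings affected by the
index disease and at least one unaffected sibling, with one or both
parents sampled. In such a design a rare variant becomes interesting when
it tracks with disease *within* families (affected siblings carry it,
unaffected siblings do not) and does so *recurrently* across independent
families. The package implements the four analysis stages that follow a
jointly-called multi-sample VCF: relatedness/sex QC, affected-only
candidate filtering, allele-count association against reference
populations, and a Mendelian segregation test.

## Phenotype vocabulary

Pedigree phenotypes are four-way: `affected`, `unaffected`,
`other_diagnosis`, `unknown`. The third class exists because family
members with a psychiatric diagnosis other than the index disease can be
neither evidence for nor against co-segregation: treating such a relative
as unaffected would force the segregation probability of a carrier parent
with a different diagnosis to zero, and treating them as affected would
fabricate support. `other_diagnosis` and `unknown` members therefore
impose no constraint anywhere — not in the sibling filter and not in the
segregation test. On disk the class is PED code `-9`, keeping files
readable by standard tools (dialect recorded in a header comment, and
remappable for foreign files via `phenotype_coding`).

Missing genotypes are a first-class state (`NA` dosage), never silently
zero: an unaffected sibling with no DNA is recorded as missing in the
filter output (lenient default) or causes the variant to drop (strict
mode), and ungenotyped members are marginalised — not constrained — in the
segregation model.

## Relatedness QC

Kinship uses the centered, frequency-standardised genotype cross-product

$$K_{jk} = \frac{1}{M}\sum_m \frac{(g_{jm} - 2p_m)(g_{km} - 2p_m)}{2p_m(1-p_m)},$$

pairwise-complete over non-missing calls, with allele frequencies
estimated in-cohort (a founders-only option exists for strongly structured
cohorts). On this coefficient-of-relationship scale parent–offspring and
full-sib pairs sit near 0.5, second-degree pairs near 0.25 and unrelated
pairs near 0. Markers with in-cohort MAF below `maf_floor` (default 0.01)
are excluded because the standardisation denominator degenerates; fewer
than `min_markers` (default 1000) retained markers is an error rather than
a low-confidence estimate. Classification bands (`classify_pair`) default
to ≥0.8 duplicate/MZ, 0.35–0.8 first degree, 0.15–0.35 second degree;
these are conventional working thresholds, exposed as parameters because
array density and cohort structure shift the empirical clusters.

Family-assignment checking flags three failure modes observed in real
cohorts: a member unrelated to everyone in their recorded family, a member
whose mean kinship with another family exceeds their own family's by a
margin (default 0.2 — swapped samples), and a labelled parent–child pair
below the first-degree band (role errors such as a daughter recorded as
mother). Findings are advisory by default; `run_pipeline(qc_strict = TRUE)`
drops flagged individuals, but the default mirrors practice, where such
findings are resolved by reassignment, not deletion.

Sex inference uses X-heterozygosity only: males are hemizygous on the
non-pseudoautosomal X, so a male sample's called heterozygosity there is
near zero while diploid females show ordinary HWE heterozygosity
(expected rate $2p(1-p)$ per marker, well above 0.2 for common markers).
Thresholds default to <0.05 male, >0.20 female, ambiguous between — a wide
dead zone is deliberate, since contamination and low marker counts inflate
apparent male heterozygosity. Depth-based X/Y approaches need alignments,
which are upstream of this package's inputs.

## Candidate filtering

The filter retains, within each family, variants where **any** genotyped
affected sibling carries the alternate allele and **no** genotyped
unaffected sibling does. The any-quantifier matters: in a multiplex family
a risk variant need not be carried by every affected sibling (other
genetic and environmental causes coexist), and requiring all affected
carriers would discard exactly the recurrent-but-heterogeneous candidates
the design is built to find. Parents are excluded from this step —
ascertainment is on the sibship, and a carrier parent is expected for an
inherited variant. Candidates are then matched *exactly* on
(chrom, pos, ref, alt) across families — no fuzzy indel matching, since
upstream normalisation is assumed and fuzziness would silently merge
distinct alleles — and kept when seen in at least `min_families` (default
2) families. Functional restriction defaults to frameshift indels, with
loss-of-function ({frameshift, stop-gain, stop-loss, splicing}) and
LoF+missense presets.

Parental origin is mechanical: `inherited` if a genotyped parent of a
carrier child carries; `putative_de_novo` only when both parents are
genotyped non-carriers; otherwise `undetermined`. A variant recurring in
independent families is *presumably* inherited through an unsampled parent,
but that is an analyst's judgement, not a genotype fact, so the package
does not upgrade `undetermined`.

## Association: counting scheme and tests

Affected siblings share parents, so their alleles are not independent
draws; counting every carrier sibling would overstate the evidence. The
package therefore counts **one representative individual per family**
(first in pedigree order among eligible carriers — the choice is inert
when all carriers are heterozygous, which is the generic rare-variant
case):

* **Case scenario** — the affected children are the cases. Each of $N$
  families contributes 2 allele slots (one representative case), giving
  $2N$ total; a family with at least one affected carrier adds that
  carrier's dosage.
* **Carrier scenario** — the parents are a high-risk pool. Each family
  contributes 4 parental allele slots whether or not both parents were
  sampled ($4N$ total); a family where the variant segregates adds the
  dosage of one carrier parent, observed or obligate (a carrier child
  implies a carrier parent under Mendelian inheritance without de novo
  events — the assessment above guards that assumption).

For a 20-family cohort these denominators are 40 and 80. Each scenario's
counts form a 2×2 table against a reference population's (alt, total)
allele counts and are tested three ways:

1. **Yates-corrected chi-square**, $\sum (|O-E| - c)^2/E$ with
   $c = \min(0.5, |O-E|)$ — the clamp keeps the statistic at zero when the
   table sits at its expectation (in a 2×2 all four $|O-E|$ are equal, so
   it applies uniformly). The upper tail is computed with
   `pchisq(lower.tail = FALSE)`, which resolves p-values below 1e-300 —
   extreme-reference comparisons genuinely reach ~1e-75.
2. **Fixed-margins Monte-Carlo**: $B$ tables drawn with both margins fixed
   (the (1,1) cell is hypergeometric), the *uncorrected* Pearson statistic
   for each, and the estimator $(1+b)/(B+1)$, which never returns zero.
   This matches the behaviour of the standard simulated chi-square test in
   the reference statistical environment and is the honest test at counts
   where the χ² approximation is poor.
3. **Exact hypergeometric tail** — the $B \to \infty$ limit of (2) by
   enumeration over the (1,1) cell's support — used as the oracle for the
   simulation in the test suite and reported alongside it.

A statistic-comparison epsilon of 1e-9 absorbs floating-point ties between
the observed and resampled statistics.

## Segregation test

Under complete penetrance the phenotypes become hard genotype constraints:
affected ⇒ carrier (dosage ≥ 1, dominant coding — the motivating
observations are heterozygous), unaffected ⇒ non-carrier. The per-family
segregation probability is

$$p_i = P(\text{all affected carry} \wedge \text{no unaffected carries})$$

with founder genotypes independent HWE draws at population frequency $q$
and each child allele an independent fair draw from each parent. A child
listing only one parent receives one population allele — equivalent to
marginalising an implicit unconstrained founder, which the implementation
materialises so both evaluation paths share one pedigree normalisation.
$p_i$ is **unconditional** (not conditioned on the variant being present
in the family): at small $q$ it is of order $2q$ times a transmission
factor, which is the scale on which published per-family values of this
test sit. A `condition_on_presence` flag divides by the founder carrier
mass $1 - (1-q)^{2F}$ for the conditional reading. An `observed` argument
optionally clamps genotyped members to their observed dosages instead of
their phenotype constraint.

Two exact evaluators are implemented and cross-checked to 1e-12: full
enumeration over all $3^n$ genotype configurations (default for pedigrees
of ≤ 12 members) and sum-product variable elimination ("peeling") that
eliminates members leaf-first, rescaling each intermediate factor and
accumulating the scale in log space so large pedigrees cannot underflow.
The joint statistic is the product $\prod_i p_i$ over families
(independence under the null), and `gene_drop_p` estimates it by
simulation: founder genotypes drawn at HWE($q$), alleles dropped through
every pedigree, event = simultaneous segregation in all families, with the
same never-zero $(1 + \text{events})/(n_{\text{sims}}+1)$ estimator,
computed in memory-bounded chunks.

## The synthetic cohort generator

The generator emulates the study conditions so every stage can be tested
without external data: 20 families, 2–3 affected and 1–2 unaffected
siblings each, the first 8 families with both parents genotyped and the
remaining 12 with one randomly chosen parent ungenotyped (still present in
the pedigree, so segregation marginalises over them), a causal heterozygous
frameshift variant at population frequency $q = 0.00076$, ~5000 autosomal
background markers with MAF uniform on (0.05, 0.5) for kinship, and 500 X
markers (male calls hemizygous, emitted as homozygous diploid genotypes,
the common VCF convention) for sex inference.

At $q = 0.00076$ a naturally ascertained multiplex carrier family is
vanishingly rare, so the causal variant is **forced** into
`n_causal_families` (default 2) families: one parent is made a
heterozygous carrier, sibling transmissions are Mendelian draws
rejection-sampled until the family satisfies ascertainment (≥2 affected,
≥1 unaffected), and phenotypes follow carrier status through
`penetrance`/`phenocopy_rate` (defaults 1 and 0, so carrier ⇔ affected
within those families). The carrier parent is labelled `other_diagnosis` —
a carrier parent unaffected by the index disease is exactly the
configuration the phenotype vocabulary exists for. The remaining families
receive their affected labels by design, representing disease of other
genetic or environmental origin; this is the realistic reading of a cohort
in which the modeled variant explains a minority of families, and it is
what makes the filter-recovery property meaningful (the planted variant,
and only within-family-consistent variants, survive). Natural HWE draws
for the causal variant are available with `n_causal_families = 0`, which
is what `plant_frequency_check` uses to verify the founder allele
frequency calibrates to $q$ (mean over replicate cohorts within three
binomial standard errors).

Decoy variants exercise the filter's failure arms: single-family
affected-only hits (fail the recurrence requirement), variants carried by
an unaffected sibling in every family where they appear (must never
survive), and recurrent variants of non-qualifying functional class
(dropped by the class filter). The ledger records every placement, and the
test suite asserts the filter's behaviour against it.

What the generator does **not** model: linkage disequilibrium between
markers, population stratification, genotyping error, de novo mutation,
and age structure. Passing tests therefore demonstrate correctness of the
inference machinery under clean Mendelian sampling, not robustness to
array artefacts or admixture — the QC thresholds in particular should be
re-examined on real data.

## Numerical and design choices

* Chi-square tails via the survival function directly (never `1 - cdf`),
  stable to ~1e-300.
* Exact hypergeometric tails clamp to [0, 1] — enumeration over the whole
  support can exceed 1 by one ulp.
* Segregation probabilities clamp to [0, 1] after evaluation; the peeling
  path rescales factors and keeps the scale in log space.
* Monte-Carlo and gene-dropping estimators use $(1+b)/(B+1)$, never
  reporting zero; both are seed-reproducible, and gene-dropping runs in
  chunks (default 1e6 replicates) to bound memory.
* Ties between resampled and observed statistics are resolved inclusively
  (≥ with a 1e-9 epsilon), the conservative direction.
* Problem sizes in the test suite: kinship properties at 5000 markers with
  100–200 replicate pairs; gene-dropping convergence at 1e6 replicates;
  Monte-Carlo association at 1e5–1e6; end-to-end filter recovery over 20
  generator seeds. These sizes put every stochastic assertion at least
  three standard errors from its threshold under the generator's
  conditions.

## Known limitations

* The association counting scheme takes the first eligible carrier in
  pedigree order as the family representative; for families segregating a
  homozygous variant a max-dosage convention would differ — rare-variant
  designs make this moot, but it is a documented convention, not a law.
* The segregation model covers autosomal dominant-coded carriage with
  complete penetrance; incomplete-penetrance likelihoods and X-linked
  transmission are out of scope.
* Pedigrees with loops (consanguinity) are rejected by the cycle check in
  validation but would in any case violate the peeling path's conditional
  independence assumptions; the enumeration path would handle them, but
  the package does not target such designs.
* Multi-variant gene-level aggregation (several variants in one gene
  tested jointly) is not implemented; the segregation test takes one
  variant at a time.
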