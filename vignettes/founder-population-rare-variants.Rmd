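---
title: "Rare-variant analysis in founder populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant analysis in founder populations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderseq)
```

# The analysis problem

Isolated founder populations concentrate rare risk alleles: a variant
carried by one or two members of a small founding party can drift to an
appreciable frequency within a few generations, and a disorder that is
rare elsewhere can become common on the island. That concentration is
also what makes the statistics awkward — everyone is related to
everyone, so the cases and controls of an association study share
ancestry, and a naive chi-square test has a badly inflated type-I error.

`founderseq` implements the full analysis chain for this setting:

1. **Exome filter cascade** — reduce per-sample variant calls to novel,
   potentially deleterious variants shared among affected individuals.
2. **Pedigree kinship** — quantify relatedness for use by the
   association test and the simulator.
3. **Quasi-likelihood score association** — case-control association
   that corrects for relatedness, uses unaffected versus
   unknown-phenotype controls differently, and borrows information from
   phenotyped relatives who were never genotyped.
4. **Gene-drop simulation** — predict present-day allele frequencies
   from founder carriers or founder-pool frequencies.
5. **Burden comparisons** — exact tests of aggregated rare-variant
   counts against reference panels.
6. **Synthetic cohorts** — a generator with the statistical structure
   the pipeline assumes, so every stage is testable without restricted
   genotype data.

# Read-evidence model and the filter cascade

Each read covering a heterozygous site carries the variant allele with
probability 1/2 under an unbiased binomial read model, so the chance
that at least $m$ of $n$ reads support the variant is the upper tail of
$\mathrm{Binomial}(n, 1/2)$. Ten reads give a 98.9% chance of seeing the
variant at least twice, which is the origin of the common "10-fold for
99% detection" rule:

```{r}
hetDetectionProbability(10, 2)
minDepthForConfidence(2, 0.985)
```

The cascade applies, in order: a **quality** filter (at least 4 unique
variant-read start sites *and* a variant allele fraction of at least
15%, both thresholds inclusive because they are "at least" rules; zero
depth is a removal reason, not a division error), a **consequence**
filter (keep missense, nonsense, frameshift, canonical splice — the two
intronic bases at each exon boundary; consequence is taken from the
input annotation, not recomputed), a **novelty** filter against
user-supplied catalogues, and an **affected-sharing** filter (default: 3
of 5 samples). Survivors are annotated with linkage-region overlap
(1-based inclusive intervals; BED input is converted on read) and a
`validated` placeholder for downstream confirmatory sequencing results.

Two conventions deserve a note. Variant identity is *allele-aware*
(`chrom:pos:ref:alt`): a catalogued site with a different alternate
allele still counts as novel, which is the conservative choice for
downstream association. And because quality, consequence and novelty
are per-record predicates, their order cannot change which variants
survive — only the bookkeeping of removal reasons; the sharing filter
is applied last because it aggregates across samples. The
`FilterReport` object enforces count conservation (kept + removed =
input, chained across stages) in its validity method.

# Kinship

`kinshipMatrix()` implements the classical recursion in
ancestor-before-descendant order (topological sort by generation depth,
ties by input order): founders have $\phi_{ii} = 1/2$ and zero kinship
with other founders; an individual with parents $(f, m)$ has
$\phi_{ii} = (1 + \phi_{fm})/2$ and $\phi_{ij} = (\phi_{fj} +
\phi_{mj})/2$ for any earlier-processed $j$. Inbreeding is
$h_i = 2\phi_{ii} - 1$. The genotype correlation used by the
association test is $K = 2\Phi$ (diagonal $1 + h_i$).

The recursion is tested against classical identities (parent-offspring
1/4, half sibs 1/8, first cousins 1/16, the child of first cousins
$h = 1/16$), against positive semi-definiteness, and against an
independent Monte-Carlo oracle that drops uniquely labelled founder
alleles and estimates identity-by-descent directly.

# The quasi-likelihood score test

Genotypes are coded as half allele counts $y_i \in \{0, 1/2, 1\}$.
Affection status enters through a prevalence transform: affected
individuals get weight $T_i = 1$, unaffected ones
$T_i = -k_i/(1 - k_i)$ with $k_i$ the sex-specific prevalence (defaults
0.25 male, 0.27 female; the mean for unknown sex), unknown phenotype
$T_i = 0$. This is what distinguishes an unaffected control (actively
informative against carriage) from a control of unknown phenotype.

Relatives with phenotype but no genotype still contribute: with $N$ the
genotyped set and $M$ the ungenotyped-phenotyped set,

$$A = T_N + \Phi_{NN}^{-1}\,\Phi_{NM}\,T_M .$$

The allele frequency is estimated by generalised least squares (the
best linear unbiased estimator under the kinship correlation),
$\hat p = \mathbf{1}' K^{-1} y \,/\, \mathbf{1}' K^{-1} \mathbf{1}$,
and the statistic is

$$W = \frac{\left[A'(y - \hat p \mathbf{1})\right]^2}
        {\tfrac{\hat p (1 - \hat p)}{2}
         \left[A' K A - (A'\mathbf{1})^2 / \mathbf{1}'K^{-1}\mathbf{1}\right]},$$

referred to $\chi^2_1$. This closed form is the package's normative
definition of the statistic, reconstructed from the quasi-likelihood
construction it follows; fidelity is asserted through its reduction and
calibration properties rather than numeric equality with any particular
historical implementation. With identity kinship, no enrichment and
complete phenotypes it reduces to the classical one-degree-of-freedom
allelic quasi-score test, which is checked exactly on a four-individual
worked example ($W = 4.8$, $p = 0.0285$):

```{r}
mqlsTest(y = c(1, 0.5, 0, 0), A = c(1, 1, -1/3, -1/3), K = diag(4))[c("W", "p")]
```

Conventions and numerics:

* **Monomorphic variants** ($\hat p \in \{0, 1\}$) and degenerate
  phenotype contrasts (zero variance term) are flagged untestable with
  $p = 1$ by convention rather than erroring a scan.
* **Missing genotypes** drop the individual from $y$, $K$ and $A$ for
  that variant only; their phenotype still enters via the enrichment
  term.
* **X-linked markers** are excluded from the default scan with a
  warning; the autosomal coding can be forced but is flagged
  approximate, because the male dosage model differs on X.
* **Linear algebra** uses a symmetric positive-definite Cholesky
  factorisation; a pivot-ratio condition estimate above $10^{12}$ is an
  error, never a silent pseudo-inverse. Scans against a fixed cohort
  can pass a precomputed factor (`Kchol`) since $K$ does not change
  across variants.
* A Bonferroni threshold $0.05/\text{n variants}$ is reported alongside
  a scan; the statistics themselves are never adjusted.

Calibration is asserted empirically in the test suite: on 50
simulated three-generation families (about 650 individuals) with
phenotypes independent of genotype, the fraction of $p < 0.05$ over
2,000 replicate gene-dropped variants must lie inside the exact
binomial 99% band around 0.05 — and must stay there when the supplied
prevalence is badly misspecified (true 0.25, supplied 0.10), the
robustness property that matters in practice because island prevalences
are never known precisely. These problem sizes keep the whole
calibration under a minute while leaving the binomial band tight enough
to catch meaningful miscalibration.

# Gene-drop simulation

`dropAlleles()` assigns founder genotypes either as designated
heterozygous **fixed carriers** (the scenario where specific founders
are inferred to have introduced the variant — carriers are set
heterozygous, never homozygous, matching a founder-carrier frequency of
0.5) or by a **random founder frequency** $q$ with independent alleles
(Hardy–Weinberg in the founder pool, the natural default in the absence
of founder-genotype information). Each non-founder then inherits one
uniformly chosen allele from each parent, and each replicate records
the variant-allele frequency in a target set — by default the
individuals without descendants, i.e. the "current" generation, since
real current-population membership is a study-specific choice the
caller can override with an explicit id list.

Two supporting tools make the simulation testable and interpretable:

* `enumerateExact()` computes the exact distribution of the target-set
  frequency by enumerating all $2^{2 \cdot \text{non-founders}}$
  transmission patterns (and founder configurations in random mode); it
  refuses pedigrees beyond 16 meioses. It is the oracle against which
  the Monte-Carlo engine is goodness-of-fit tested at 100,000
  replicates.
* `expectedFrequencySweep()` maps founder frequency to present-day
  frequency over a grid of $q$ values, optionally **conditioning** on
  designated individuals being carriers. Conditioning is on carrier
  status (at least one variant allele) — the event actually observed
  when a variant is traced back to founders. Unconditionally the mean
  present-day frequency equals $q$ (Mendelian transmission is a
  martingale), which is itself one of the test-suite properties;
  conditioning raises the mean among carrier descendants, and for a
  trio the conditional mean has the closed form
  $\big(1/(2-q) + q\big)/2$ used as a test oracle.

Replicates are reproducible for a fixed seed, and the generator
restores the caller's RNG state.

# Burden comparisons

Variant-level and aggregated comparisons against reference panels use a
two-tailed Fisher's exact test on allele counts. Two-sided conventions
for Fisher's test genuinely differ between tools, so the package pins
the **small-probability method**: the p-value sums the probabilities of
all tables with the observed margins whose point probability does not
exceed the observed one (with a $10^{-7}$ relative slack for
floating-point ties). This matches `stats::fisher.test`, which serves
as an independent oracle in the tests. Published figures computed under
other two-sided conventions (mid-p, doubled one-sided, different count
bookkeeping) will not in general match this definition; the package
always reports its own exact values.

Carrier counts are translated to allele counts assuming heterozygosity
(each carrier contributes one of two chromosomes), panels are summed
per variant (`panelTotals()`), and categories follow the usual
definitions: **private** (one case carrier, absent from all panels),
**rare** (panel frequency below 1% by default; private implies rare),
**common** otherwise. `selectForVerification()` mirrors standard pooled
sequencing practice: nonsynonymous variants and those with pooled VAF
below 5% go to confirmatory single-sample sequencing.

# The synthetic cohort generator

The generator exists so that every pipeline stage has inputs with known
truth. Its defaults are the study conditions it emulates, fixed once:

| parameter | default | rationale |
|---|---|---|
| founding couples | 8 | founding-party scale |
| generations | 5 | depth of the emulated genealogy |
| offspring per couple | Poisson, mean 2.2 | tuned jointly with marriage probability so the unconditioned genealogy averages ≈285 members and ≈85 founders |
| marriage probability | 0.85 | as above |
| census conditioning | 288 ± 30% | see below |
| consanguineous mate choice | 0.14 | reported fraction of consanguineous unions |
| carrier founders | 2 | a founder pair introducing the risk variant |
| carrier penetrance | 0.76 | observed penetrance being emulated |
| prevalence | 0.25 male / 0.27 female | target population prevalences |
| baseline (phenocopy) risk | calibrated | `calibrateBaselineRisk()`, see below |

A supercritical branching process started from eight couples has an
intrinsic coefficient of variation around 0.4, so no honest choice of
rates makes every realisation land near a fixed census count. Because
the genealogy being emulated has a *known* size, `simulatePedigree()`
conditions on it by rejection: attempts outside ±30% of the target are
discarded. This is ordinary conditioning on an observed demographic
total; it changes nothing about Mendelian transmission within accepted
pedigrees. Setting `targetSize = NULL` disables it (the statistical
calibration tests use small unconditioned families).

Carrier founders default to the two male founders with the most
descendants, mirroring the situation where a founder pair heads the
affected lineage. Phenotypes follow a two-penetrance Bernoulli model —
carriers affected with probability 0.76, non-carriers with a
sex-specific baseline — which is the minimal model consistent with
penetrance, phenocopy and prevalence arithmetic; a liability-threshold
model would add parameters nothing in the emulated summaries can
identify. The baseline solves
$k = c f + (1 - c)\, b$ for $b$ given prevalence $k$, carrier fraction
$c$ (0.125 by default) and penetrance $f$:

```{r}
calibrateBaselineRisk(0.25)   # male baseline
calibrateBaselineRisk(0.27)   # female baseline
```

The exome fixture generator plants a configurable number of novel,
deleterious, widely shared variants with passing read evidence, and
constructs every background variant with at least one disqualifying
property (catalogued, excluded consequence, under-shared, or failing
read evidence). Survival truth is therefore exact by construction,
which is what lets the cascade be tested for *exact* recovery rather
than approximate enrichment. Read depths are negative binomial with
mean 56 and size 3, at which ≈98% of sites reach 10-fold coverage.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: sequencing error and mapping
artefacts beyond the simple evidence model, linkage disequilibrium and
multi-locus haplotypes, overlapping generations and non-random mating
structure beyond a single consanguinity probability, ascertainment of
cohort membership through probands, and genotyping error. Results on
real cohorts inherit all of those complications.

# Reproducibility conventions

Every stochastic entry point takes a `seed` argument, uses it locally
and restores the caller's RNG state. Fixture bundles written by
`writeFixtureBundle()` are byte-identical for identical seeds and carry
a manifest with the generating configuration. File formats are the
field's plain-text standards: PED/FAM (PLINK dialect, 0 = missing,
extra columns ignored), VCF 4.2 with `DP`/`AD` genotype fields and a
`USS` INFO key for unique start sites, BED (converted to 1-based
inclusive on read), and TSV for variant and panel-count tables.

# Known limitations

* The association statistic is the package's reconstruction of the
  quasi-likelihood score; it is validated by reduction and calibration
  properties, not by numerical identity with any external program.
* X-linked dosage is not modelled; X markers are excluded by default.
* The gene dropper is single-locus: no linked markers, mutation, or
  overlapping-generation demography.
* Exact enumeration is limited to 16 meioses by design; beyond that the
  Monte-Carlo engine is the only route.
* Novelty filtering is only as good as the supplied catalogues;
  historical database memberships are not reproducible offline.
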