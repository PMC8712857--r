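---
title: "RHDO-based NIPD: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RHDO-based NIPD: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodose)
```

## The statistical model

Maternal plasma cfDNA is modelled as a two-component mixture: maternal DNA
with weight $1-f$ and fetal DNA with weight $f$, the *fetal fraction*. At a
SNP where the mother is heterozygous (genomic allele frequency $1/2$), the
expected plasma frequency of a given allele is

$$\mathrm{E}[AF_{\mathrm{cfDNA}}] = \tfrac12 (1-f) + f\,d_{\mathrm{fetal}},$$

where $d_{\mathrm{fetal}}$ is the fetal dose of that allele. When the fetus
is homozygous-equivalent for the tracked allele ($d = 1$) the per-SNP
dosage change $DC_i = AF_{\mathrm{cfDNA},i} - AF_{\mathrm{gDNA},i}$ has
expectation $+f/2$; when the fetus lacks it entirely, $-f/2$. Counts are
treated as exchangeable binomials at a Poisson per-SNP depth — no
fragment-size, GC or capture-efficiency structure is modelled, which is
also the assumption underlying the package's in-silico performance model.

Hap1 denotes the maternal haplotype carrying the pathogenic variant, Hap2
the wild-type one. Type 1 / Type 2 informative alleles track Hap1 / Hap2
respectively; for a male fetus every phased SNP contributes both alleles
(the paternal X never reaches a male fetus), while for a female fetus a SNP
is informative for a type only when that haplotype's allele coincides with
the paternal allele — only then is the fetus homozygous-equivalent and the
full $\pm f/2$ shift realized.

The genotype call is a likelihood ratio over the two inheritance
hypotheses,

$$BF = \frac{P(\text{counts} \mid H_1)}{P(\text{counts} \mid H_2)},\qquad
  H_1: DC = +f/2,\quad H_2: DC = -f/2,$$

with decision thresholds $BF \ge 10$ (inherits Hap1), $BF \le 0.1$
(inherits Hap2), and a no-call in between.

## Likelihood form

The clinical formulation states the hypotheses at the level of the
segment-mean dosage change but does not fix a distribution. The package's
default works at the count level: each informative SNP contributes a
binomial likelihood for its tracked-allele count at the observed cfDNA
depth, with success probability $0.5 + f/2$ for the type favoured by the
hypothesis and $0.5 - f/2$ for the other. This is exact under the binomial
mixture model, uses the per-SNP depths as they are, and is the same
primitive the in-silico model simulates, so predicted and realized
performance are directly comparable. An alternative `normal_dc` mode
reproduces the segment-level formulation literally: the observed $DC$ is
Gaussian with mean $\pm f/2$ and variance
$0.25/(n_1 \bar d_1) + 0.25/(n_2 \bar d_2)$ from binomial sampling around
allele frequency $1/2$.

Two consequences are worth noting. For a **male fetus** the Type 1 and
Type 2 entries at one SNP are the two orientations of the same counts, so
the count-level product uses each observation twice; this doubles
$\log BF$ but cannot change its sign, and matches the clinical convention
of reporting both type lists in full. For a **female fetus** the
non-favoured type's tracked allele sits at fetal dose $1/2$, so its true
shift is $0$ rather than $-f/2$; under the symmetric likelihood these SNPs
contribute zero expected evidence (the binomial variance term
$p(1-p)$ is identical under both hypotheses), so the call is driven by the
favoured type, at roughly half the male-fetus evidence. Bayes factors are
computed entirely in log space — observed magnitudes reach $10^{\pm 300}$
and beyond, so `log10_bf` is the authoritative output and `bf` may
overflow to `Inf`/`0` harmlessly.

## Fetal fraction: the factor-of-two mapping

At a qualifying autosomal locus (mother homozygous, fetus heterozygous for
a paternal-specific allele) the fetal-specific allele fraction
$a/(a+b)$ has expectation $f/2$, because only half the fetal molecules
carry the paternal allele. The printed clinical formula $f = a/(a+b)$
therefore estimates half the total fetal proportion. This package defines
$f$ as the *total* fetal proportion of cfDNA — the quantity that the
$\pm f/2$ dosage model and the simulator use — and estimates it as
$2\sum a / \sum(a+b)$ pooled over qualifying loci. An `as_printed` mode
returns the undoubled ratio, and a `mean` aggregation mode averages
per-locus ratios instead of pooling counts; whether published per-family
fetal fractions include the doubling is not stated, so both conventions
are exposed.

With paternal genotypes, qualifying loci are restricted to
mother-homozygous / father-homozygous-opposite SNPs, where the fetus is
heterozygous by necessity and the estimator is unbiased. Without a father
(six of the 21 clinical pedigrees), loci where the mother is homozygous
and the plasma minor-allele fraction lies in $(0.5\%, 20\%)$ are taken as
fetal-informative. The lower cut excludes noise-only loci but censors
low-count loci, which inflates the estimate by roughly 15–20% at
$f \approx 2\%$; the estimate remains adequate for QC gating and BF
scaling, and the father-based estimator is used whenever possible.
Per-locus gates: depth $\ge 100\times$ and base quality $\ge$ Q13 (carried
by the `base_quality_ok` flag; the simulator always sets it).

## Male-fetus X dosage

A male fetus contributes one X chromosome per genome copy, so on the X the
effective fetal fraction is $f/(2-f)$ and the per-type shift is close to
$\pm f/4$ — while the clinical model asserts $\pm f/2$ for both sexes
(consistent with $DC$ defined as the *difference* between type means,
which is $\approx f/2$ under either convention). The generator's default
follows the stated expectation — the fetal hemizygous allele enters at
full weight $f$ — so that the simulator realizes exactly the model the
caller assumes and validation isolates inference errors from model
mismatch. A `realistic_male_x = TRUE` flag applies the $f/(2-f)$
correction (with total X depth scaled by $1 - f/2$) for robustness
testing; it halves per-type shifts and therefore roughly halves
$\log_{10} BF$, without changing its sign.

## Sex call and chrY noise floor

Fetal sex is the mean chrY-site depth over the mean autosomal-SNP depth,
female iff the ratio is strictly below $0.3\%$. A male fetus yields an
expected ratio of $f/2$ (one Y per fetal genome copy), comfortably above
threshold for $f \ge 1\%$. No noise model for female pregnancies is stated
clinically beyond observed ratios $< 0.15\%$; the generator uses a Poisson
floor with mean $0.05\%$ of the sample's mean depth, below threshold with
wide margin. This floor is a stand-in, not a measurement.

## Phasing and Mendelian QC

Genotypes for phasing are hard calls from gDNA counts: alternate-allele
fraction $< 0.15$ homozygous reference, $> 0.85$ homozygous alternate,
otherwise heterozygous, requiring depth $\ge 30\times$ (upstream variant
calling is out of scope, and with error-free simulated counts the hard
calls are exact). Phasing uses the mother's heterozygous gene-region SNPs:
a hemizygous affected proband directly donates the Hap1 allele; a
daughter's maternally transmitted allele is $m = 2d - p$ (daughter dose
$d$, paternal hemizygous dose $p$) and is assigned to Hap1 for a carrier
daughter or to Hap2 — with the assignment swapped and flagged — for an
unaffected daughter. Mendelian-inconsistent SNPs (e.g. $m \notin \{0,1\}$,
or a heterozygous male X) are dropped rather than imputed; a drop rate
above 5% raises a sample-swap warning. Pedigrees with neither proband nor
daughter are unphaseable and rejected. A female fetus without a paternal
sample falls back to the male-fetus type rule; dosage shifts are then
attenuated at the SNPs where the (unobserved) paternal allele differs from
Hap-consistent expectation, so the call is reported with an explicit
reliability caveat when the Bayes factor is nonetheless definite.

## CBS recombination screening

A meiotic crossover between the phasing meioses makes the fetal X switch
source haplotype at some position, flipping the sign of the oriented
dosage signal ($+DC$ at Type 1, $-DC$ at Type 2 SNPs, one value per SNP —
for a male fetus the two orientations of one SNP are numerically
identical, and using both would break permutation exchangeability).
Circular binary segmentation recursively finds the arc maximizing the
standardized mean-difference statistic and accepts a split when its
permutation p-value is below $\alpha$. The specifics are not stated
clinically and are package choices: $\alpha = 0.01$, 1,000 permutations
per scan (with early termination once significance is unreachable),
minimum segment 10 SNPs, and a final merge pass rejoining adjacent
segments whose mean difference is below $f/4$ (half the expected
between-state gap). These values hold the null false-split rate at or
below the nominal level while resolving crossover-to-variant distances of
the order seen clinically (0.6–1.3 Mb at ~0.5 SNP/kb panel density).
Series shorter than 20 SNPs return a single segment with a warning. Only
the variant-containing segment (the one spanning the lesion midpoint, or
the nearest segment if the lesion lies off the series span) contributes to
the Bayes factor; other segments only inform the recombination flag and
switch positions.

## In-silico performance model

`predict_performance()` draws tracked-allele counts under each hypothesis
from the same binomial model the caller assumes and classifies each
replicate with the same Bayes factor. With a common depth the log Bayes
factor is a linear function of the per-type count totals, so the
implementation samples totals directly — numerically identical to the
per-SNP product (asserted in the tests) and fast enough for the full
$10^6$-replicate setting; the default is $10^4$ replicates, which bounds
the Monte-Carlo standard error of a sensitivity near 0.95 at about 0.2%.
Sensitivity is $P(BF \ge 10 \mid H_1)$ with no-calls counted as
non-sensitive (whether clinical practice excludes them is unstated; this
is the conservative choice), specificity is $P(BF \le 0.1 \mid H_2)$, and
an expected sensitivity below 95% flags a redraw recommendation.

## What the generator emulates — and what it does not

The generator reproduces: the panel geometry (1,511 gene-region SNPs with
MAF $> 0.10$ in the gene $\pm$ 0.5 Mb window on GRCh37, 203 chrX and 213
autosomal SNPs with MAF $> 0.45$, 35 chrY sites); the three pedigree
shapes observed clinically (complete, father-missing, daughter-phased);
binomial read counts at Poisson depths around the configured means
(defaults 290× cfDNA, 200× gDNA, matching reported ranges); the mixture
dosage model with optional crossover; and hemizygous male X/Y dosage in
gDNA. It does **not** model sequencing error, alignment or capture bias,
cfDNA fragment-length structure, maternal mosaicism/chimerism, or linkage
disequilibrium between panel SNPs (haplotype alleles are drawn
independently per SNP). Passing tests therefore demonstrate correctness of
the inference given the binomial mixture model, and calibration of the QC
gates under it — not robustness to artefacts absent from that model.

## Numerical and degenerate-input choices

- All likelihood work is in natural-log space; `log10_bf` is derived once.
- Balanced data (equal counts, equal depths) give $BF = 1$ exactly and a
  no-call; the $BF \ge 10$ / $\le 0.1$ comparisons are inclusive.
- A fetal fraction below 1% makes `bayes_factor()` refuse with a redraw
  recommendation rather than return an unreliable ratio.
- The chrY ratio threshold is strict (`< 0.3%` is female), so a ratio of
  exactly 0.3% calls male.
- Zero-depth loci are excluded by the per-locus depth gates everywhere;
  fetal-fraction estimation is invariant to SNP order and duplicated
  zero-depth rows.
- `fetal_fraction = 0` is accepted by the generator as the no-signal null.
- Cohort percentages are reported to 1 decimal place and SNP-count means
  integer-rounded, matching clinical reporting precision; gestational ages
  are averaged in days and truncated to completed days.

## Cohort conventions

The deletion hotspot fraction counts deletions whose exon range is fully
contained in exons 44–55. For duplications, "located in exons 8–12" is
ambiguous; the published 5/6 is reproduced only when membership means the
*start* exon lies in 8–12 (containment gives 4/6, overlap 6/6), so the
start-exon rule is the default and all three are selectable.

## Problem sizes used in the validation suite

The simulation-based tests run at desk scale chosen to keep Monte-Carlo
error well inside the asserted margins: 200 simulated families
($f \in [0.02, 0.12]$, 300× cfDNA, ≥ 200 informative SNPs) for end-to-end
concordance; 200 replicates at 213 autosomal loci for fetal-fraction
recovery; 100 seeds each for CBS crossover localization (~400 informative
SNPs, $f = 0.08$) and the null false-split rate; and $10^4$ replicates for
performance-model points.

## Known limitations

- Paternally inherited variants and autosomal-recessive RHDO are out of
  scope; the model is X-linked and maternal-haplotype-only.
- Published per-family Bayes-factor magnitudes are not reproducible
  without the raw sequencing data; validation is therefore
  simulation-based plus cohort-table statistics.
- The no-father female-fetus fall-back and the minor-allele-window
  fetal-fraction rule are heuristics with documented biases.
- Hard genotype calls assume error-free counts; real data would need an
  upstream caller and an error-aware phasing step.
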