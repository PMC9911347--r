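---
title: "Models and methods behind popkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popkin implements the statistical core of an ancient-DNA population
analysis on pseudo-haploid 1240K-style genotype data: f-statistics with
block-jackknife errors, qpWave/qpAdm admixture modelling, admixture
dating from ancestry-covariance decay, mismatch- and likelihood-based
kinship inference with pedigree reconstruction, and a runs-of-homozygosity
(ROH) HMM with pedigree-simulation-based consanguinity classification.
This vignette describes the models, their assumptions, the tunable
parameters and the numerical choices; everything quantitative stated here
is computed by the test suite or by `scripts/acceptance.R`, not asserted
from memory.

## The data model

A `pk_dataset` holds a SNP table (chromosome, genetic position in
Morgans, physical position, alleles), a sample table (id, sex, group
label) and a genotype matrix (SNPs x samples) coded as the count of the
reference allele: 2/1/0, with 9 for missing. Pseudo-haploid data - one
randomly sampled allele per site, the standard representation for
low-coverage ancient genomes - uses only the codes 0/2/9. The X
chromosome is stored as chromosome 23, and male X calls are hemizygous
(haploid codes) in either ploidy mode; group allele counts give male X
calls one allele and everything else one (pseudo-haploid) or two
(diploid) alleles.

## The synthetic-data generator

Every downstream method is exercised on data from a seeded generator
that emulates the statistical structure the methods assume, at desk
scale:

* **Allele frequencies.** Ancestral frequencies are uniform on
  [0.05, 0.95] (bounded away from fixation so likelihood-based kinship
  stays well-conditioned; configurable). Each population drifts from its
  parent node by a Balding-Nichols step: `p' ~ Beta(p(1-F)/F,
  (1-p)(1-F)/F)` with variance `F p(1-p)`. Populations can be nested
  into a tree, which is what gives qpAdm's reference populations their
  differential relationships to the sources.
* **Genetic map.** 35.2 Morgans of autosome (a conventional sex-averaged
  total; a configuration knob, not a fitted value) split over 22
  autosomes in proportion to approximate human chromosome lengths, plus
  1.8 M of X. Physical positions use 1 cM per Mb. Desk-scale runs use
  50k-250k SNPs; nothing in the methods depends on the full 1.1M panel
  beyond density.
* **Admixture.** A two-source pulse `g` generations ago is simulated per
  haploid chromosome as a segment process with breakpoints at rate `g`
  per Morgan and i.i.d. source assignment (probability `alpha` for source
  A), so truth-track tract lengths are Exponential with mean `1/g`
  Morgans and the marginal ancestry is `alpha`. Genotypes are drawn
  site-independently from the tract's source frequency: linkage
  disequilibrium enters only through ancestry tracts and pedigree
  transmission, which is exactly the LD that f-statistics, decay dating,
  kinship and ROH consume. Background LD within a source population is
  not simulated.
* **Pedigrees.** Founder haplotypes carry unique labels; each meiosis
  applies Poisson crossovers at 1 per Morgan without interference
  (expectations used by the classifications depend on map length, not
  interference, to first order). Haplotypes are piecewise-constant label
  vectors, so truth autozygosity (both labels identical by descent) and
  pairwise IBD sharing are computed exactly, independent of SNP density.
  Fathers pass their X to daughters unrecombined; sons are hemizygous
  maternal.
* **Pseudo-haploid downsampling.** One of the two alleles per covered
  site, uniformly; missingness i.i.d. per sample and SNP.

Because sites are in linkage equilibrium within populations and there is
no sequencing-error or damage model (damage handling is an upstream,
out-of-scope concern), passing tests demonstrate the statistical
machinery under the stated model, not robustness to reference bias or
contamination in real data.

## f-statistics and the block jackknife

Group frequencies are allele-count ratios. `f4(A,B;C,D)` is the mean
over complete-case SNPs of `(pA - pB)(pC - pD)`; `f3(A;B,C)` is
`(pA - pB)(pA - pC)` with the finite-sample correction
`- pA(1-pA)/(nA-1)` on the target (unbiased for pseudo-haploid or small
samples, needed for admixture-f3's negativity logic; off in outgroup
mode, where the uncorrected shared-drift measure is conventional);
`f2` subtracts the correction for both groups. Standard errors come from
a weighted delete-one block jackknife over contiguous 5 cM genetic-map
windows (block edges always at chromosome boundaries; a short last block
is kept), with weights equal to SNPs per block; `|Z| >= 3` is the
conventional annotation threshold. PCA computes components from
reference samples (mean-centred, `1/sqrt(p(1-p))`-normalised, mean
imputation of rare missing reference calls) and projects sparse targets
by least squares over each target's covered SNPs.

## qpWave and qpAdm

For left populations `L0..L(l-1)` and right populations `R0..R(r-1)` the
f4 matrix has entries `f4(L0, Li; R0, Rj)` with a jackknife covariance
over the shared 5 cM blocks. qpWave tests rank `k` by the
covariance-weighted quadratic form of the rank-constrained residual,
referred to chi-square with `(l-1-k)(r-1-k)` degrees of freedom; rank 0
with two lefts is the cladality test. qpAdm finds weights summing to 1
that null out the target's f4 relationships to the rights
(`e(w) = sum_i w_i f4(T, Si; R0, Rj)`), by iterated generalised least
squares with the covariance of `e(w)` re-estimated from the block sums;
the full-model p uses `r - n` degrees of freedom, nested models drop one
source at a time, weight standard errors are leave-one-block-out refits,
and weights outside [0,1] flag the model infeasible. This is the
quadratic-form/chi-square approximation of the original Wishart
likelihood-ratio machinery: p-values are calibration-tested against
uniformity on simulated clades rather than value-matched against the
original binaries. Near-singular covariances (small right sets at desk
scale) are conditioned by an escalating ridge `1e-6 tr(C)/dim` with a
warning. The competing-source rotation refits each candidate source set
with the remaining candidates moved to the right, flagging `p < 0.01`
or infeasible weights. Sex bias uses per-chromosome qpAdm coefficients:
`Z = (coef_A - coef_X)/sqrt(se_A^2 + se_X^2)` per autosome with the
`Z >= 3` threshold.

## Admixture dating

Each SNP gets weight `w = pA - pB` and, per target sample, residual
`z = dose - (pB + alpha_hat (pA - pB))`, where `alpha_hat` is the
sample's genome-wide ancestry estimated by regressing doses on `w`
(centring on the sample's own ancestry removes the constant offset an
unevenly admixed sample would contribute). The decay curve is the
binned ratio `c(d) = sum(z_s w_s z_t w_t) / sum(w_s^2 w_t^2)` over SNP
pairs at genetic distance `d` within chromosomes, whose expectation is
`alpha(1-alpha) exp(-g d)` times an ancestry-ploidy factor of 1/2 for
diploid or pseudo-haploid targets (the two homologous chromosomes carry
independent mosaics). Pairs are accumulated on a distance grid at the
bin width (default 0.001 M) by FFT autocorrelation per sample and
chromosome - distances are therefore resolved to the bin width, which is
also the original tool's resolution. The fit is weighted least squares
of `A exp(-g d) + c` over bins in [0.0045, 1] Morgans (the shortest
bins are excluded to avoid background-LD contamination; the affine `c`
absorbs what remains), and the error on `g` is a leave-one-chromosome-out
jackknife. Calendar conversion uses 28 years per generation, a
configurable conventional constant: the underlying study reports
calendar dates without stating its generation time, so calendar-level
comparisons are indicative only.

## Kinship

**Mismatch (READ-style).** `P0` is the fraction of overlapping
pseudo-haploid calls that differ, windowed over 1 Mb physical windows
(the original tool's default; the synthetic genome's 1 cM/Mb scale keeps
windows sensibly populated) with a weighted block jackknife for the
standard error. Normalising by `alpha` - the cohort's median pair `P0`,
or a user-supplied baseline when relatives dominate (a warning fires
when more than 30% of pairs fall below the second-degree cutoff) -
gives expected values 1, 0.875, 0.75 and 0.5 for unrelated, second-
degree, first-degree and identical pairs; the cutoffs 0.90625, 0.8125
and 0.625 are the midpoints, boundaries assigned to the closer class.

**Likelihood IBD.** `(k0,k1,k2)` maximise the product over SNPs of the
likelihood of the observed call pair given allele frequency and a
symmetric call error (default 0.01), by EM on the simplex. On diploid
calls - including sparse best-call genotypes, which is how the method is
used on low-coverage data - the full triple is identified (observed
heterozygotes and opposing homozygotes separate `k0` from `k1`). On
pseudo-haploid single-allele calls the per-site likelihood is exactly
linear along the `k1/2 + k2` ridge (an affine observation model cannot
distinguish the states beyond their mean sharing), so only
`r = k1/2 + k2` is interpretable on that path; this is stated in the
documentation rather than papered over. Degrees come from `r` on the
half-log2 grid; anything beyond the third degree degrades to unrelated.

**Opposing homozygotes** (one sample 0, the other 2) are Mendelian
impossibilities for error-free parent-offspring pairs and disambiguate
structures with equal IBD expectations; the rate is reported per
overlapping site.

**Pedigree reconstruction** grows hypotheses by attaching genotyped
samples to a scaffold of on-demand ungenotyped placeholders (new
founders, siblings, intermediate parents, and a two-level aunt/uncle
attachment needed when every genotyped sample is a leaf, as in an infant
burial). Pairwise kinship coefficients are maintained incrementally, so
every candidate attachment is screened in vector arithmetic before any
state is built. The search deepens iteratively first on tolerated
violations of the called degrees (plus mitochondrial/Y line
constraints), then on the number of placeholders, so the returned set is
exactly the most parsimonious maximal-score pedigrees; hypotheses with
identical pairwise `(k0,k1,k2)` among the genotyped samples are one
ambiguity class and reported once. Design restrictions that keep the
space honest and finite: the hypothesis space is outbred (no
consanguineous placeholder unions), placeholder siblings attach only to
genotyped individuals or parents of genotyped ones, and samples declared
`leaves` (for example perinatal infants) are never placed as parents -
age evidence of exactly this kind is what resolves parent-offspring
versus sibling orientation in practice. The search is exhaustive within
its caps (24 individuals, 4 generations, node budget) and flags an
exhausted budget instead of silently truncating.

## Runs of homozygosity and consanguinity

The caller is a two-state frequency-based HMM on sparse diploid calls -
deliberately not a haplotype-copying reference-panel HMM, since no
modern haplotype panel ships with the package; the preserved operating
surface is length recovery above 4 cM, F-proportionality and class
separation. Emissions: heterozygotes occur at `2p(1-p)(1-err)` outside
ROH and `err` inside (default 0.01); homozygote emissions follow allele
frequency inside ROH and Hardy-Weinberg outside. Transitions are the
exact two-state continuous-time kernel with entry rate `theta` per cM
(default 0.001, i.e. 0.1 expected entries per Morgan under outbreeding;
results are tested to be robust to threefold changes) and exit rate
`1/8 cM^-1`. Viterbi segments are filtered to at least 4 cM and 50
covered SNPs, with endpoints at the midpoint between the boundary SNP
and the first SNP outside - the unbiased convention for sparse data. A
consequence worth knowing: for a planted segment of exactly the minimum
reported length, an unbiased length estimate plus a hard threshold
yields roughly coin-flip detection; power is high only for segments
strictly longer than the threshold, which is how the operating claim is
phrased.

Consanguinity classification compares each sample's binned ROH profile
([4,8), [8,12), [12,20), [20,Inf) cM - the conventional reporting bins)
against pedigree-simulated profile distributions for candidate parental
relationships (first/second cousins, half-siblings, avuncular, double
first cousins, unrelated; truth autozygosity from the label simulator,
at least 100 simulations each). Matching uses a bin-wise Gaussian
log-likelihood with the simulated per-bin spread floored at 10 cM, which
absorbs single-genome recombination noise; `combine = TRUE` pools
profiles into the cumulative histogram, which sharpens the comparison
because bin means grow linearly while spreads grow as the square root.
A sample is flagged consanguineous when its best class is a close-kin
union (parental inbreeding coefficient at least 1/16) that beats the
unrelated hypothesis; second cousins are reported but not flagged.
Within-individual heterozygosity (`het sites / covered sites`) connects
to the mismatch baseline: under random mating it matches the `P0` of
unrelated pseudo-haploid pairs, the identity used to distinguish a
small drifted gene pool from a cohort of relatives.

## Problem sizes and determinism

The test suite runs the full pipeline at reduced scale: 50k-150k SNPs
for f-statistics, qpAdm and dating; 400 simulated pairs at 100k SNPs
for the cladality calibration; a single 1.5 M chromosome at 1240K
density (312 SNPs/cM) thinned to a 0.27 coverage fraction for ROH power;
250k SNPs over the full autosomal map for the consanguinity cohort.
These sizes were chosen so each method's signal-to-noise matches its
full-scale behaviour while a complete run stays in the minutes range.
All generators and analyses are deterministic under a seed; the pipeline
driver fans a master seed out to stable per-stage child seeds (hashes of
stage names) so adding a stage never perturbs another stage's draws.

## Known limitations

* Linkage equilibrium within source populations means background-LD
  effects on the decay fit are represented only by the affine offset.
* The ROH caller's frequency HMM has less information than a
  haplotype-copying HMM at equal sparsity; its 4 cM operating point is
  honest but not panel-boosted.
* Pseudo-haploid IBD decomposition beyond `r` is impossible in
  principle (see above), not merely unimplemented.
* The pedigree search space excludes consanguineous unions among
  placeholders; cohorts where close-kin unions produce the genotyped
  samples themselves need the ROH consanguinity module, not the
  pedigree search, to see it.
* Benchmark comparisons against the released archaeological dataset
  require an external download and are out of the package's test scope.
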