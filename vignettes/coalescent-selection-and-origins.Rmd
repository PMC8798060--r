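---
title: "Coalescent tests of selection and the repeated origins of resistance mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent tests of selection and the repeated origins of resistance mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepOrigins)
```

## The problem

Target-site resistance (TSR) mutations — amino-acid changes in the gene
encoding the protein a herbicide inhibits, such as ALS or PPO — arise
repeatedly in agricultural weed populations under intense selection.
Given phased haplotypes and local genealogies extracted from an
ancestral recombination graph (ARG), the questions this package
addresses are: how many times did the same resistance mutation arise
independently; has each mutational lineage spread faster than drift
allows, either since it arose or only recently; how old is each origin
on a contemporary timescale; and how do co-segregating resistance
haplotypes interact, both locally (repulsion between alternative
resistance alleles) and with unlinked loci across the genome.

`sweepOrigins` implements the full chain — genealogy handling, the
order-of-coalescence selection tests, origin clustering with monophyly
support and allele ages, effective-population-size summaries, signed-LD
machinery, haplotype sweep statistics — together with seeded coalescent
generators that produce every input with known ground truth, so each
step is testable end to end without any external data.

## The descendant-count null and the two selection tests

Under the neutral coalescent the present-day descendant counts of the
$k$ lineages that existed at any past time are exchangeable: the count
vector is a uniform ordered composition of $N$ (the sample size) into
$k$ positive parts. The probability that $j$ marked lineages leave
exactly $f$ descendants is

$$P(f \mid N, k, j) \;=\;
\frac{\binom{f-1}{j-1}\binom{N-f-1}{k-j-1}}{\binom{N-1}{k-1}},
\qquad j \le f \le N-(k-j),$$

a hypergeometric in the "stars and bars" cut positions
(`descendantCountPmf()`). Two one-sided tests follow.

**De novo test** (`testDenovo()`). Let $f_N$ be the number of carriers
of a focal mutation today and let $k_S$ be the number of susceptible
lineages present when the mutation increased from one copy to two — the
carrier-clade MRCA. The p-value is the upper tail
$\sum_{f \ge f_N} P(f \mid N,\, k_S+2,\, 2)$: the probability that two
exchangeable lineages among $k_S+2$ leave at least $f_N$ of $N$
descendants. Small values mean the lineage expanded faster than drift
explains over its whole history.

**Recent-timescale test** (`testRecent()`). For a cutoff time $t$ more
recent than the origin, count resistant and susceptible lineages
$k_R(t)$ and $k_S(t)$ and take
$\sum_{f \ge f_N} P(f \mid N,\, k_R(t)+k_S(t),\, k_R(t))$. This asks
whether the frequency change since $t$ alone is non-neutral — the
standing-variation / fluctuating-selection regime. The default cutoff
is the most recent 1% of tree height (`recent_fraction = 0.01`);
because sources differ on whether the intended fraction is 1% or
0.01%, the fraction is an explicit argument rather than a constant.

Both statistics depend only on the *order* of coalescences, never on
branch lengths, which makes them robust to a misspecified effective
population size during ARG inference; the suite asserts this
invariance by rescaling all node times. All probability arithmetic is
done in log-space via `lchoose` with log-sum-exp accumulation —
binomial coefficients at the sample sizes of interest (hundreds of
haplotypes) overflow doubles.

Two independent oracles pin the constants: an exhaustive enumeration
of compositions (exact, used for all $N \le 14$) and a Monte-Carlo
uniform-composition sampler (`neutralLabellingOracle()`). One
property worth flagging: at fixed $(N, f_N)$ the tail is
non-*increasing* in $k_S$ — a larger $k_S$ means a more recent origin,
making the same present-day frequency more surprising.

**Lineage counting convention.** A branch with child time $c$ and
parent time $p$ crosses time $t$ iff $c \le t < p$: a node at exactly
$t$ counts as already coalesced. $k_S$ for the de novo test is
evaluated at the carrier MRCA plus $\varepsilon = 10^{-9}\times$ tree
height, so the two nascent carrier lineages are counted as two and the
MRCA itself as coalesced.

**Multiple testing.** `runOriginTests()` tests one origin at a time,
pruning all other origins' carriers so each lineage is compared against
susceptible haplotypes only, and applies Benjamini–Hochberg correction
separately within the de novo and recent families.

## Origins, support, and allele ages

`clusterOrigins()` defines an independent origin as a *maximal clade
whose leaves are all carriers*. The rule is deterministic, depends only
on topology, partitions the carriers exactly, and counts isolated
carrier leaves as singleton origins. `monophylySupport()` reports the
fraction of genealogy samples (e.g. ARG MCMC iterations) in which an
origin's leaf set is exactly a clade; every provided tree is counted,
thinning being the caller's concern.

**Allele age** (`alleleAge()`). The mutation that defines an origin
lies on the branch between the carrier-clade MRCA and the node above
it, and is modelled as uniformly placed on that branch. Per tree the
point estimate is the branch midpoint (the mean of that uniform); the
aggregate point estimate is the mean of midpoints across genealogy
samples. For the 95% interval, each sampled tree contributes one
seeded uniform placement draw and the interval is the percentile range
of those draws. This propagates both the across-sample variation in
the branch endpoints and the placement uncertainty the model itself
states; a pure midpoint interval would collapse to a point for a
single tree and systematically miss origins that sit near one end of
the branch. With one tree the interval degenerates to the midpoint.
Trees in which the carriers fail to be monophyletic contribute the
smallest containing clade, with a warning counter — matching the
behaviour of ARG summary tools that can only age the oldest allele.
Recovery tests plant origins with generator-drawn uniform mutation
times and find the interval slightly conservative (coverage a little
above 95%), the regrafting and time jitter of the sample generator
widening the percentile range.

**Rescaling** (`rescaleAge()`). Genealogy-based ages scale linearly
with the Ne assumed during inference; an age inferred under an
assumed Ne is converted to a contemporary timescale by dividing by
`ne_contemporary / ne_assumed`. With an assumed 5 × 10⁵ and a
contemporary geometric-mean estimate of 83,294,700 the factor is
166.5894.

**Geographic structure** (`geoPermutation()`). Panmixia between two
regions is tested by shuffling region labels across haplotypes and
recomputing the fraction of an origin mapping to one region; an
observed fraction outside the 95% percentile interval of the permuted
values flags stratification. The test has little power for rare
origins, which is inherent, not a defect.

## Effective-population-size summaries

`readCoal()` parses both the coalescence-rate dialect (epoch
boundaries plus haploid rates; Ne $= 1/(2\,\mathrm{rate})$) and a
plain `start end ne` table. Windowed summaries use *duration*
weighting by default: the epochs of rate-based trajectories are
log-spaced (steps of $10^{0.25}$ years here), so equal epoch weights
would over-weight the recent past. Because upstream conventions are
not always stated, `weighting = "epoch"` is exposed as the
alternative. The geometric mean is the natural summary for recent,
expansion-dominated windows; the harmonic mean (which governs
long-term coalescence) for deep-time windows; the suite checks the
harmonic ≤ geometric inequality and invariance to splitting epochs.

## Signed LD, matched pairs, and permutation nulls

Signed $r$ (`signedR()`) is the Pearson correlation of allele
indicators (phased haplotypes) or 0/1/2 dosages (genotypes), with each
site polarized by rarity: the minor allele is coded 1, an exact 50%
frequency keeping the alternate-allele coding so ties are
deterministic. Minor alleles on the same haplotypes thus give positive
$r$ and repulsion gives negative $r$. Missingness is handled by
pairwise-complete deletion; sites with more than 10% missing
genotypes are dropped at load, matching the upstream phasing filter.

Windowed scans (`windowedMeanR()`) use half-open windows
$[kw+1, (k+1)w+1)$ anchored at position 1, averaging defined $r$
values of class-filtered (by default missense) sites; the focal site
is always excluded and genome-wide interaction scans can exclude the
focal chromosome entirely. `outlierWindows()` takes the
$\lceil 0.01 n\rceil$ most extreme windows per tail.

Two nulls are provided. The *matched-pair* null
(`matchedPairNull()`) compares a focal pair's $r$ with the empirical
distribution over same-chromosome pairs matched on frequency (MAF
> 0.20) and proximity (≤ 500 bp). The *individual-label permutation*
(`windowPermutationTest()`) shuffles the focal variant's genotype
vector across individuals, keeping the window intact, and uses the
add-one estimate $p = (\#\{|\bar r_{perm}| \ge |\bar r_{obs}|\}+1) /
(n_{perm}+1)$; the smallest reportable p is therefore
$1/(n_{perm}+1)$, and claims below that floor require more
permutations. Both are checked for uniformity under seeded nulls.

## Sweep statistics

EHH at distance $x$ from a core site is the fraction of haplotype
pairs within a set identical from the core out to $x$; iHH integrates
the curve over genetic distance by trapezoids, truncating at
EHH < 0.05; XPEHH is $\ln(\mathrm{iHH}_{carrier} /
\mathrm{iHH}_{susceptible})$, reported unstandardized since the
analyses of interest contrast two haplotype classes at one locus
rather than rank genome-wide scores. The truncation level and
integration rule are the conventional choices and are exposed as
arguments. Genetic maps come from `rhoToCm()` — per-bp distance
$100\rho/(4N_e)$ cM accumulated monotonically, interpolated piecewise
linearly — or default to 1 cM/Mb.

Pairwise diversity `piWindows()` reports the mean per-site pairwise
difference over the sites present in the matrix (matrices carry
segregating sites only, so the denominator is the site count; multiply
by `n_sites / L` for per-bp values). H12 pools the two most frequent
window haplotypes, $(p_1+p_2)^2 + \sum_{i>2} p_i^2$, and is computed
over fixed SNP-count windows (default 200 SNPs) in `h12Scan()`, the
convention under which the statistic is defined.

## The synthetic-data generators

All generators use diploid coalescent scaling — $k$ lineages wait an
exponential time with rate $k(k-1)/(4N_e)$ — with times in
generations (the motivating species is an annual, so one generation
equals one year). Every generator takes an explicit seed and is
bit-reproducible.

* `simNeutralTree()` is the plain Kingman coalescent.
* `simSweepTree()` conditions the structured coalescent on a
  *deterministic logistic* carrier-frequency trajectory with selection
  coefficient $s$: within-class pair rates are $1/(2N_e x(t))$ and
  $1/(2N_e(1-x(t)))$, stepped so each step's event probability stays
  below 0.05. The origin generation is where the trajectory hits
  $1/(2N_e)$ — deterministic given $s$ and the final frequency — and
  carrier lineages still separate there merge at the origin, making
  carriers monophyletic by construction. The deterministic trajectory
  is an approximation to the conditioned diffusion; it is adequate for
  power and recovery testing, which is all it is used for. At $s = 0$
  the model nests the neutral coalescent: the tree is Kingman and the
  carriers are the leaf set under a branch-length-weighted random
  branch (a neutral mutation), optionally conditioned to subtend at
  least two leaves so that every replicate yields a testable origin.
* `simMultioriginRegion()` plants disjoint carrier clades on a neutral
  genealogy, records each origin's true mutation time as a uniform
  draw on its subtending branch, and assigns two-region labels either
  uniformly (panmixia) or concentrated per origin (stratification
  with a gene-flow `mixing` fraction).
* `jitterTrees()` emulates MCMC genealogy samples by random leaf
  regrafts (at a uniform height on a random branch) and lognormal
  time scaling.
* `dropMutations()` places infinite-sites mutations
  (Poisson(branch × µL), unique uniform positions);
  `phaseSwitchNoise()` swaps an individual's two haplotypes from
  random switch points onward, the dominant phasing-error mode.
* `simNeTrajectory()` builds log-spaced epoch tables; the expansion
  kind jumps from an ancient Ne of 6.3 × 10⁴ to a recent 8.3 × 10⁷ at
  100 years before present — the magnitude of expansion the pipeline
  is designed to handle — and `writeFixtureSet()` writes a complete
  plain-text input set (newick, VCF, metadata TSV, map, coal table,
  JSON manifest with ground truth).

What the generators deliberately do *not* emulate: recombination
within a local genealogy (each local tree is one non-recombining
unit, exactly what ARG extraction supplies), population structure in
the coalescent itself (regions are labels, not demes), missing
genotypes, and sequencing error. Passing tests therefore demonstrate
correctness of the statistical machinery under its own model, not
robustness to every artefact of real data.

## Numerical choices and test conditions

* Ultrametricity tolerance: $\max(10^{-9}, 10^{-9}\times$ height$)$;
  newick is written with 12 significant digits so round-trips hold at
  that tolerance. Polytomies are rejected unless explicitly resolved
  with zero-length branches.
* Degenerate inputs: singleton origins return p = 1 with a flag
  rather than an error; monomorphic sites give NA sentinels excluded
  from window means; zero/non-finite coalescence-rate epochs are
  dropped with warnings.
* The type-I calibration runs 1000 neutral genealogies of n = 50 at
  Ne = 10⁴; the empirical rejection rate sits slightly below 0.05
  because the tail sum is discrete. The power grid
  (s ∈ {0, 0.05, 0.2, 0.5}, 200 replicates) runs at Ne = 10³: with a
  very large Ne the sweep is instantaneous relative to background
  coalescence and the p-value saturates at its combinatorial floor for
  all large s, so distinguishing grid points requires susceptible
  coalescence during the sweep. Age-recovery uses 200 replicates of
  25 genealogy samples each. These sizes make the whole suite run in
  a few minutes on one core while leaving Monte-Carlo error well
  inside the asserted bands.

## Known limitations

* The recent-timescale test requires the cutoff to be more recent than
  the origin; older cutoffs are the de novo test's regime and are
  rejected with a pointer.
* Allele ages inherit any bias in the Ne used for rescaling; the
  linear rescaling cannot undo a mis-specified *shape* of the
  expansion.
* The permutation p floor of $1/(n_{perm}+1)$ means 1000 permutations
  cannot substantiate p < 0.0001; use more permutations for such
  claims.
* Published two-locus independence statistics are not always
  reproducible from printed marginal counts;
  `haplotypeIndependenceChisq()` is the textbook Pearson test (Yates
  optional) and makes no attempt to match unexplained variants.
* XPEHH is unstandardized; comparing values across loci or studies
  requires the optional genome-wide normalization the field sometimes
  applies, which is out of scope here.
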