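---
title: "Models and methods: ROH/IBD analysis of consanguinity and endogamy"
author: "consangkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ROH/IBD analysis of consanguinity and endogamy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In populations that practise both *consanguinity* (unions between close
relatives) and *endogamy* (marriage within a social group sustained over
many generations), an individual's genome carries two distinguishable
signatures: long runs of homozygosity (ROH) produced by recent parental
relatedness, and an elevated background of identity-by-descent (IBD)
sharing between nominally unrelated individuals produced by generations of
within-group mating. Separating the two matters clinically — recessive
disease risk in a couple depends on both — and demographically, because
the IBD background encodes the group's effective size history.

`consangkit` implements the computational core of such an analysis as a
reusable, tested package: a pedigree/meiosis simulator for ten classes of
consanguineous union; a classifier of parental relatedness from ROH
patterns; conversion of inferred class counts into per-generation
consanguinity rates and parental kinship; a coalescent model for the
expected genomic footprint of ROH and IBD segments; an endogamy IBD score
with jackknife errors; and a carrier-pairing simulation of recessive
disease risk. A synthetic-data module generates all inputs, because the
motivating cohort data are access-restricted.

## The model

A population of $N_e$ reproducing couples renews each generation. A new
couple is a degree-$i$ relative pair (siblings $i=1$, first cousins
$i=2$, ...) with probability $r_i$, connected by a single path. The mean
parental kinship is

$$k = \sum_{i=1}^{5} \frac{r_i}{4^i}, \qquad k < \tfrac14 .$$

Two chromosomes in unrelated individuals coalesce, per generation $t$
back, with probability $1/S(t)$ where $S(t) = 4N_e(t)(1-3k)$; the factor
$(1-3k)$ absorbs the acceleration of background coalescence caused by
consanguineous unions. The TMRCA of the two homologues of one individual
(`tmrca_within()`) additionally has probability $k/(1-3k)$ of a rapid
within-family coalescence. The within distribution is computed by a
Monte-Carlo realisation of the family/population Markov chain for
$t \le T_{\text{switch}}$ (default 50) and is proportional to the
unrelated form beyond, with the constant fixed by normalisation;
`T_switch` anywhere in 10–50 changes footprints by less than $10^{-3}$
absolutely (asserted in the tests).

Given a TMRCA of $t$, the expected number of segments of length $l$ on a
chromosome of $L$ Morgans is $4t e^{-2tl}(1 + t(L-l))$ per Morgan, which
is exactly the gap-length census of a Poisson breakpoint process of rate
$2t$ (the $2t$ meioses on the connecting path). Integrating $l$ times
that density gives the closed-form coverage of a length window, and
summing over the TMRCA distribution and chromosomes, divided by total
genome length, gives the expected *footprint*: the genome fraction in
segments of each 1 cM length class (ROH under the within distribution,
IBD under the between one). When the $N_e$ trajectory comes from an
IBD-based estimator, the estimator already reports $N_e(t)(1-3k)$ in
diploid units, so after halving to pair units the effective scale is the
estimate divided by two, with no further $k$ correction
(`rescale_ne()`); beyond the estimated horizon the trajectory is extended
at its last value.

### What "a segment" means (an adjudicated subtlety)

Three segment definitions coexist in this literature, and they are *not*
interchangeable at the 5–30 cM scale:

* **Path-recombination segments** — ended by *every* recombination on the
  connecting lineage paths. This is the definition the density above
  counts, and the one `consangkit` extracts from simulations by default:
  mosaics retain every crossover breakpoint, and founder-identity runs
  are split at breakpoints present in exactly one of the two haplotypes
  (a breakpoint below the common ancestor lies on one path; breakpoints
  above it were inherited through the common ancestor by both).
* **MRCA-constant segments** (e.g. `tskit`'s `ibd_segments`) — not ended
  by "invisible" recombinations whose detached lineage re-coalesces into
  the same path. These are systematically longer; against an `msprime`
  discrete-time Wright–Fisher oracle we measured segments about twice the
  path-segment prediction at small TMRCA while the marginal TMRCA
  distribution agreed exactly.
* **Founder-identity runs** — maximal intervals descending from the same
  founder chromosome, which is what an idealised identity-based caller
  would report in mutation-free data. In deep genealogies these
  concatenate many co-ancestry tracts and overshoot the model footprint
  by tens of percent. They remain the right notion for *autozygosity
  tracts* (runs of homozygosity are not interrupted by path
  recombination), so truth tracts for F_ROH and the classifier use this
  definition (`segment_def = "identity"`), while footprint comparisons
  use `"path"`.

In real data, mutations accumulated on detour lineages break sequence
identity approximately where the path definition breaks segments, which
is why empirical caller output is commonly compared against this model.

## The synthetic world

`gen_founder_panel()` draws linkage-free phased founders (sites
independent, Hardy–Weinberg by construction) with a folded
Beta(0.5, 0.5) minor-allele-frequency spectrum truncated to MAF ≥ 0.01 —
a U-shaped spectrum resembling genotyping-array common variants; the
motivating study used real cohort haplotypes, so the spectrum is our
choice and is recorded per site. Founder LD is deliberately absent: all
ROH/IBD structure in this pipeline is created by the pedigree machinery.

`gen_endogamous_population()` renews `n_pairs` couples for `generations`
generations on a synthetic genome (default 22 autosomes, 3,500 cM over
2.8 Gbp at 1.25 cM/Mbp). Consanguineous couples are realised as children
of two *existing* couples connected by a degree-$(i-1)$ relative pair
located in the recorded pedigree; this keeps population size and
offspring-number variance Wright–Fisher-like. Two earlier designs were
rejected after measurement: instantiating connecting mini-pedigrees with
extra path individuals dilutes the gene pool (the realised coalescence
scale was ~20% too large), and a balanced two-children-per-couple output
suppresses the sib-pair (TMRCA = 1) mass (use `output = "random"` for
model comparisons). During the first generations the pedigree is too
shallow to realise deep degrees and such couples fall back to random
mating; with ≥ 50 simulated generations this burn-in is invisible in the
5–30 cM window. With ~100 generations the truncation of coalescences
older than the founding contributes < 0.5% to the 5 cM bin.

`gen_carrier_table()` assigns pathogenic-variant carriers per gene at a
chosen rate; `sharing_boost` $b$ makes a gene segregate within a group
with probability $1/b$ at rate $b p$ (capped at one), preserving the
marginal rate while concentrating carriers within groups — a
founder-effect caricature sufficient to exercise the intra/inter-group
risk contrast and the permutation test.

What a green test therefore establishes: internal consistency of
simulator, extraction, classifier and model on noise-free truth data at
human-genome scale. What it does not establish: robustness to genotyping
error, phasing error, caller artefacts, LD, or real mating structure.

## Classifying parental relatedness

Ten union classes are modelled: sibling; avuncular and first-cousin
unions repeated over one, two or three consecutive ancestral generations;
first cousins once removed; second cousins; unrelated. "Repeated over
$g$ generations" means each couple in the previous $g-1$ generations of
the connecting pedigree was itself a union of that type — the reading
under which the offspring of a generation-2 first-cousin union is also
the offspring of second cousins by two routes, and a generation-3 union
adds third-cousin routes (hence the doubled and tripled count terms when
converting class counts to $r$). The exact expected inbreeding
coefficients implied by our pedigrees, from the kinship recursion:
sibling 1/4, avuncular 1/8 (g2 1/4, g3 89/256), first cousin 1/16
(g2 3/32, g3 31/256), FCOR 1/32, second cousin 1/64, unrelated 0.

Each simulated offspring is summarised by 15 statistics of its ROH
profile above 10 cM: the summed length of the ten longest ROHs, and
counts in fourteen 10 cM bins from 10 to 150 cM (longer ROHs are counted
in the top bin rather than dropped — discarding the strongest signal
would only hurt). A single-hidden-layer network (10 logistic units,
softmax over the ten classes, BFGS, L2 penalty $10^{-4}$, at most 500
iterations) is trained on 400 examples per class; counts are
square-root transformed before standardisation (Poisson-like variance).
Ten models are trained on independent 400/class resamples of a 500/class
pool and vote on a held-out evaluation set of 100 per class; each
individual takes the modal class, ties broken toward the closer
relationship (conservative for clinical-style use). We deliberately
evaluate on individuals simulated separately from the training pool so
every evaluated individual receives ten votes without leakage; a literal
"vote only where held out" reading would give most individuals about two
votes and leave ~10% with none.

At this scale the three-category accuracy (first cousin or closer;
FCOR/second cousin; unrelated) averages ~92.5% with ~1% spread between
protocol replicates; the irreducible part is dominated by second-cousin
offspring that carry no ROH longer than 10 cM (Poisson-thinned tracts)
and are genuinely indistinguishable from unrelated offspring in this
feature space. The acceptance test asserts the ≥ 92% criterion on the
mean of three protocol replicates to keep the assertion from hinging on
one evaluation set's binomial noise.

Class counts convert to rates as: $r_1$ = sibling fraction; $r_2$ = the
three first-cousin generations summed; $r_3$ = FCOR + twice the gen-2
and gen-3 first-cousin fractions + second cousins; $r_4$ = three times
the gen-3 first-cousin fraction; $r_5 = 0$. The component sum may exceed
one (the classes overlap by construction); only $k < 1/4$ is required.

## IBD score and risk simulation

The endogamy score is the summed length of 5–30 cM IBD segments between
distinct retained individuals of a group divided by $\binom{2n}{2} - n =
2n(n-1)$ chromosome pairs, after removing one member of every pair
sharing a segment > 40 cM (greedy, highest-degree first — the paper
states the rule but no algorithm; greedy minimises removals and is
deterministic with an id tie-break). Scores are standardised by a
reference population's score, and standard errors use a weighted
delete-one-chromosome jackknife with chromosome map lengths as weights.
The published sensitivity variant (filter > 30 cM, count 3–20 cM) is the
same engine with different parameters.

Couple risk: a pair is at risk when both members carry a
pathogenic/likely-pathogenic variant in the same recessive-disease gene.
Intra- and inter-group means come with moment-based variances using the
empirical variance of the pair indicators and the empirical covariance
over index-sharing pairs, assuming no correlation between disjoint
couples. The group-label permutation test reports the fraction of
permutations with a difference at least the observed one (`p = 0`
reported as < 1/B). Simulated first-cousin couples are drawn by matching
a reference kinship histogram in eight 0.05-wide bins with
largest-remainder rounding (reproducing the worked 20/75 → 40/150
example), each individual in at most one couple per replicate; kinship
for synthetic pairs is the exact pedigree kinship, not a re-estimate.

## Numerical choices and limitations

* Coordinates: 1-based bp, half-open segments in bp, closed cM lengths;
  Morgans internally in the footprint model, cM at interfaces.
* Crossovers are Haldane (Poisson, no interference); sex-averaged map;
  no mutation, no genotype error; X chromosome out of scope.
* TMRCA horizons are chosen adaptively so the truncated tail mass is
  below $10^{-9}$, then renormalised; coverage sums truncate the $t$
  axis where $e^{-2tl}$ underflows the target precision.
* The ROH caller implements the sliding-window (PLINK-parameterised)
  algorithm with proportion-based scoring at chromosome ends; HMM-based
  callers are out of scope.
* The permutation test and the classifier are deterministic given a
  seed; every pipeline stage derives a child seed from one master seed
  via a multiplicative hash (`child_seed()`).
* The variance formulas for group risk assume zero covariance between
  disjoint couples; with strong group structure this underestimates
  uncertainty, which is why the permutation test, not the moment
  variance, carries the inference.
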