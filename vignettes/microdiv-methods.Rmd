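---
title: "Models and methods behind microdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdiv)
```

## The scientific question

Two opposing eco-evolutionary hypotheses make predictions about how the
diversity of a gut community should relate to the genetic diversity *within*
each of its member species. Under Diversity Begets Diversity (DBD), diverse
communities create niches that favour further intra-species diversification;
under Ecological Controls (EC), saturated niche space suppresses it. A third
force, the Black Queen dynamic, predicts that genes whose products are
supplied as leaky public goods by a diverse surrounding community are more
likely to be lost from a focal genome. `microdiv` implements the measurement
and modelling stack needed to test these predictions on shotgun-metagenome
cohorts profiled into MIDAS-style merged tables, and a synthetic cohort
generator that plants each regime as ground truth so the whole stack can be
verified end to end without any external data.

## Measurements

### Community diversity

Shannon diversity is computed in natural-log units over all taxa with
positive abundance (`vegan::diversity` does the arithmetic), richness is the
count of positive-abundance taxa, and both roll up to any rank of a
five-rank taxonomy by summing member-species abundances. Rarefied richness
subsamples each sample's species-labelled reads *without replacement*
(multivariate hypergeometric, via `vegan::rrarefy`) to a fixed depth —
20 million reads by default, matching deep stool metagenomes; samples below
the depth are excluded rather than upsampled, which preserves rarefaction
semantics. Per-species read counts are reconstructed as
`round(relative_abundance * read_count)`; whether presence calling happens
before or after rarefaction is not standardized in the field, and we rarefy
the species-labelled counts directly.

### Polymorphism rates

The within-sample polymorphism rate of a species is the proportion of
assayed sites of a degeneracy class (fourfold-degenerate sites proxy
synonymous variation, onefold nonsynonymous) whose alternate-allele
frequency `f = alt/depth` lies in the intermediate window `0.2 <= f <= 0.8`,
bounds inclusive. The window keeps low-frequency sequencing errors out of
the numerator; because it is symmetric about 0.5, folding the frequency
spectrum cannot change the result, so the choice of reference allele is
immaterial. The denominator includes monomorphic passing sites, making the
statistic a per-assayed-site rate.

Sites enter the computation only after a filter stack that mirrors standard
practice for within-host metagenomics:

* samples need median depth >= 5 over covered protein-coding sites
  (strictly-below excluded);
* per sample, a site needs depth within `[0.3, 3]` times that median —
  anomalous coverage usually means mismapping;
* the site's gene must be a *core gene* (prevalence >= 90% across samples
  with marker coverage >= 5, where "present" means copy number in
  `[0.3, 3]`), not blacklisted as shared across species, and never reach
  copy number 3 anywhere in the cohort;
* species are analyzed at all only with marker-gene coverage >= 10 in >= 10
  samples.

### Gene content over time

A gene's copy number is its coverage divided by the median coverage of the
species' single-copy marker genes. Presence calls use deliberately
conservative windows: absent when `c <= 0.05`, present (single copy) when
`0.6 <= c <= 1.2` *and* marker coverage is >= 20; everything else —
including the 0.05–0.6 zone that multi-species read stealing tends to
populate — is ambiguous. We additionally require marker coverage >= 5 for
*any* call (below that even an absence is uninformative; the literature the
thresholds come from leaves this case unstated). A gain is
absent-to-present between two time points of one host, a loss the reverse;
ambiguous at either endpoint removes the gene from both the event counts
and the assayed-gene denominator, and a "present" endpoint requires the
>= 20 marker floor at both ends, since a transition is only as confident as
its weaker endpoint.

### Strain number

Within one sample, a species' polymorphic sites are modelled as reads drawn
from a mixture of K discrete strains: strain k has a binary genotype
`g_ks` per site and frequency `pi_k`, the expected alternate-allele
fraction at site s is `p_s = sum_k pi_k g_ks`, and observed counts are
`Binomial(D_s, (1-eps) p_s + eps (1-p_s))` with a shared error rate
`eps <= 0.1`. Input sites are all multi-allelic sites
(`1 <= alt <= D-1`) with depth >= 20; species/sample pairs with fewer than
100 such sites are not analyzed (a switch lets the floor count all covered
sites instead, since "sites with 20x coverage" is ambiguous between the two
readings).

Fitting alternates an exact step — each site's genotype column is set to
the best of the `2^K` patterns by enumeration, ties broken toward fewer
alternate alleles — with a bounded quasi-Newton step over `(pi, eps)` using
analytic gradients on transformed coordinates (additive log-ratio for the
simplex, scaled logit for the error rate). Both steps are ascent steps, so
the log-likelihood is monotone within a run. Runs start from 10 random
initializations, a set of deterministic starts whose candidate frequencies
sit at quantiles of the empirical frequency spectrum (these rescue rare
cases where random starts miss a basin), and — inside the K-selection loop
— a warm start that extends the best (K-1)-strain fit by a low-frequency
copy of an existing strain, which also guarantees the maximized
log-likelihood is non-decreasing in K. A final tight-tolerance polish runs
the alternation to a joint fixed point; on instances small enough for
brute-force enumeration over all genotype matrices and a fine
frequency/error grid, the optimizer attains the global optimum to within
`1e-4` log-likelihood units (this is asserted in the test suite).

K in 1..4 is selected by BIC. The parameter count deserves a note, because
it is the one place we deviate from the obvious convention. Counting every
genotype entry as a free parameter (`nu = (K-1) + K*S + 1`) makes the
penalty for one extra strain grow linearly with the number of sites
(~`S ln S`), while the likelihood evidence for a real minor strain grows
only with its divergent-site count; at realistic depths that penalty is an
order of magnitude larger than the largest gain a 15%-frequency strain can
produce, so K >= 3 would never be selected — the classification-likelihood
BIC inconsistency familiar from model-based clustering, where latent
assignments are not counted as parameters. Our default instead counts the
continuous parameters plus the site-pattern-class proportions the
assignment implicitly estimates, `nu = (2^K - 1) + K`, and uses the total
read count over included sites as the BIC sample size (the binomial trials
are the observations). Under this convention, simulated mixtures at depth
~50x with 200 sites are recovered at ~100% (K=1), ~97% (K=2) and ~87%
(K=3). The genotype-counting convention remains available via
`bic = "classification"`.

## Diversity-slope models

The *diversity slope* is the fitted coefficient of community diversity
(standardized to zero mean, unit variance) in a hierarchical model of an
intra-species response. Per-sample read count always enters as a covariate,
since sequencing depth influences both sides of the relationship.

* **Polymorphism rates** use a beta family with logit link, with optionally
  smoothed terms (thin-plate splines, basis dimension 5 by default) and
  random intercepts for species, host and sample, fitted with `mgcv::gam`.
  Rates of exactly 0 or 1 are nudged onto the open interval by the standard
  `(y (n-1) + 0.5)/n` transform, recorded in the fit. Smoothing parameters
  are selected by marginal ML — not REML — because the resulting scores
  feed likelihood-ratio comparisons across fixed-effect structures, for
  which REML is invalid. For smooth fits the reported "slope" is the
  finite-difference `(eta(z=1) - eta(z=-1))/2` on the link scale.
* **Strain counts** are positive counts, so candidate families are
  zero-truncated Poisson and zero-truncated negative binomial in both the
  linear (NB1) and quadratic (NB2) parameterizations; the reported fit is
  the AIC-best among them unless the model spec pins a family. A Pearson
  overdispersion statistic is attached to every fit.
* **Gene gains and losses** use NB1/NB2 with AIC selection; temporal models
  regress the count between `t1` and `t2` on diversity at `t1`, optionally
  with a diversity-by-time-lag interaction. A constant lag makes that
  interaction inestimable and is reported as a fit failure naming the
  collinearity, never silently dropped.
* **Polymorphism change** (a signed difference) is modelled as Gaussian
  after a log-modulus transform `sign(x) log1p(|x|/1e-5)`, which respects
  the sign while compressing the heavy tails a log transform would need.

When random effects are requested, count models are fitted with `glmmTMB`;
with no random effects the package uses its own direct maximum-likelihood
path (the truncated-count log-likelihoods are closed-form), which agrees
with `glmmTMB` to numerical precision on identical data — the test suite
asserts this — and is roughly two orders of magnitude faster, which is what
makes 400-replicate calibration experiments affordable. Inference is by
drop-one likelihood-ratio tests, never Wald z-tests; confidence intervals
for the slope can be obtained by LRT inversion (`slope_ci`), consistent
with that choice. For mgcv fits the drop-one comparison uses ML-score
differences with the dropped term's effective degrees of freedom, because
penalized log-likelihoods are not comparable across fixed-effect
structures; this is approximate and stated as such. Every fit can also be
compared against its intercept-plus-random-effects null
(`null_model_comparison`).

## The synthetic cohort generator

The generator is first-class, tested code: it is how every downstream claim
in this package is verified. Its defaults describe a plausible longitudinal
stool cohort; none of them is derived from any particular study's fitted
values.

* Communities are host-level draws from an asymmetric Dirichlet over a
  100-species pool (concentration 0.5; focal species get a 10x weight boost
  so they stay deep enough to assay). ~20 million reads per sample with
  lognormal jitter (sd 0.2); a species' expected per-base depth is
  `abundance x reads x 5e-5` (a 150 bp read against a ~3 Mb genome).
* Focal-species strain counts are `1 + Binomial(3, plogis(logit(0.25) +
  beta_dbd * z))` where `z` is the cohort-standardized true Shannon
  diversity: `beta_dbd > 0` is the DBD regime, `< 0` EC, `0` neutral.
  Strain genotypes are i.i.d. Bernoulli per site with the success
  probability chosen so two strains differ at a fraction `d = 0.1` of sites
  by default — read as divergence *within the assayed polymorphic-site
  panel*, not genome-wide. Strain frequencies follow a logistic-normal
  random walk between time points (step 0.3 on the log-ratio scale).
* Site depths are Poisson at the species' expected coverage; alternate
  counts are binomial with sequencing error 0.005 folded in symmetrically.
* Each focal species carries 150 genes, 70% core (carried by every strain);
  accessory genes are carried per strain with probability 0.6. Per-gene
  coverage is Poisson around `true_copy_number x marker_median` with 100
  effective units per gene; marker medians come from 15 simulated
  single-copy markers. Between time points each (strain, gene) presence
  flips with hazard `base_loss_rate * exp(gamma_bq * z)` per day
  (`base_loss_rate = 1e-4`; `gamma_bq = 0.5` is the Black-Queen regime) and
  absent genes are regained at `2e-5` per day, so both deletion and
  strain-replacement flavours of community-level loss arise from one
  strain-level mechanism.

What the generator does *not* emulate: read-level artifacts (mapping bias,
chimeras), linkage between sites, recombination, selection within hosts,
cross-species read stealing (the filters that guard against it are
exercised with planted high-copy and blacklisted genes instead), or
compositional coupling between community and focal-species abundance.
Passing tests therefore demonstrate that the estimators recover the truth
*of this generative model* under realistic depths and noise — they cannot
certify behaviour on artifacts the generator does not produce.

## Verification experiments and problem sizes

The test suite regenerates everything from code under fixed seeds; the
sizes below were chosen to give the Monte-Carlo margins stated while
keeping the suite comfortably runnable on a laptop.

* Strain-number recovery: 200 instances, K in {1, 2, 3}, 200 sites, depth
  ~Poisson(50), error 0.01, minimum strain frequency 0.15.
* Optimizer global-optimality: 50 brute-force-checkable instances (3–6
  sites, K <= 2, depth 50), tolerance `1e-4`.
* Polymorphism oracle: balanced two-strain mixtures at divergence 0.002,
  0.01, 0.05, depth 10^4, 20 000 sites; the rate must sit within 3
  Monte-Carlo standard errors of the divergence.
* Gain/loss calling: planted events in single-strain cohorts at marker
  coverage >= 20 (precision and recall >= 0.95); no-event cohorts must show
  < 0.5 false events per species-pair at depth >= 30.
* Slope recovery: 100 cohorts of 200 hosts x 20 species with true slope
  +0.5 under truncated NB2 (95% CI coverage); 400 null cohorts under
  truncated Poisson for LRT type-I calibration (5% within twice the
  binomial SE). The recovery and calibration experiments generate responses
  directly at the regression scale with no species-level effects, and are
  fitted with the matching fixed-effects-only models via the fast ML path.
* Black-Queen sign recovery: 50 full-generator cohorts with
  `gamma_bq = 0.5` (positive fitted loss-slope in >= 90%), 50 with
  `gamma_bq = 0` for calibration.

## Numerical choices and degenerate inputs

Zero-depth cells encode missingness everywhere (no sentinel values);
all-zero abundance vectors raise an undefined-diversity error; constant
predictors refuse to standardize; a zero polymorphism denominator yields an
undefined record that downstream pairing skips with a logged message rather
than an exception. Strain-fit ties in the per-site genotype argmax resolve
toward fewer alternate alleles, BIC ties toward smaller K. The error-rate
search is capped at 0.1; its logistic transform is re-anchored inside
(-8, 8) at each alternation step because exactly at the cap the gradient
vanishes and the optimizer could otherwise never leave the boundary. Table
round-trips are lossless for integers and better than `1e-9` relative for
reals. All randomness flows from one user seed through per-stage substreams
derived with a polynomial rolling hash (a linear hash produced colliding
streams in early testing, which a uniformity check caught).

## Known limitations

The strain model treats sites independently (no linkage), is biallelic, and
caps K at 4; real co-colonization above four strains folds into the
dominant four. The gene gain/loss caller cannot distinguish deletion from
strain replacement — by design, matching its conservative copy-number
windows. The mgcv drop-one comparison is approximate in its degrees of
freedom. Mixed-model LRTs on variance components sit on the boundary of the
parameter space and are conservative. The reader consumes already-profiled
tables: mapping-stage artifacts upstream of those tables are out of scope,
and the species set is taken as the tables deliver it.
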