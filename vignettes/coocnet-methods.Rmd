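---
title: "Inferring taxon aggregation and segregation networks with coocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring taxon aggregation and segregation networks with coocnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Presence-absence surveys of microbial taxa across many environmental
samples contain a statistical signal about which taxa *aggregate*
(co-occur more often than chance) and which *segregate* (co-occur less
often than chance).  Such associations can arise from shared or opposed
habitat preferences, or from genuine ecological interactions —
cooperation, syntrophy, competition.  Separating the two requires a null
model that absorbs as much of the habitat signal as possible before any
pair is declared associated.  `coocnet` implements such a workflow for a
binary taxa-by-samples matrix $X_{ia} \in \{0, 1\}$ with samples
classified into a three-level environment hierarchy (subtype $\subset$
type $\subset$ supertype).

## The occupancy null model

Under the null hypothesis of non-interacting taxa, each cell is an
independent Bernoulli draw with

$$\pi_{ia} = 1 - \exp(-p_i\,q_a),$$

where $p_i$ measures the abundance (detectability) of taxon $i$ and
$q_a$ the diversity supported by sample $a$.  The exponential link keeps
probabilities in $[0, 1)$ for any non-negative parameters, and arises
naturally if detection is a Poisson sampling of an underlying abundance.
The $N + M$ parameters are chosen by maximising

$$\mathcal{L} = \sum_{ia}\big[X_{ia}\log \pi_{ia} +
  (1 - X_{ia})\log(1 - \pi_{ia})\big],$$

so the resulting null model is the hardest of its family to reject.

Habitat preferences enter by *stratification*: the taxon parameters are
refitted separately within every environmental subtype $A$, giving
$p_i(A)$, and a taxon never observed in a subtype gets $p_i(A) = 0$
exactly — the null model never places it there.  Aggregations explained
by a shared subtype preference are therefore absorbed into the null and
do not surface as associations.  The stratification level is
configurable (`"subtype"` by default, `"global"` for a single stratum,
which reproduces the unstratified model).

### Numerical choices

* **Identifiability.**  Only the products $p_i q_a$ matter, so within
  each stratum the mean of $q$ is constrained to 1 (the gauge).  Any
  rescaling $(p, q) \to (c\,p, q/c)$ leaves $\pi$ unchanged, which the
  test suite checks to $10^{-12}$.
* **Solver.**  Damped Newton on $(\log p, \log q)$ — the log
  parametrisation enforces positivity — with analytic gradient and
  Hessian.  The Hessian is diagonal-plus-cross-block, so the Newton
  system is solved through a Schur complement of the larger block,
  keeping the cost at $O(\min(N,M)^2 \max(N,M))$ per iteration.  Steps
  are accepted under an Armijo condition; if the system is singular or
  the step is not an ascent direction, one sweep of block coordinate
  ascent is taken instead (the likelihood is concave in each single
  parameter, so 1-D Newton steps are safe).  Convergence is declared
  when the gradient infinity-norm falls below `tol = 1e-8`
  (`max_iter = 500`).
* **Initialisation.**  Row and column occupancy fractions mapped
  through $-\log(1 - x)$, floored at $10^{-6}$ — the moment-matching
  start of the multiplicative predecessor model, which lands close to
  the optimum.
* **Saturation.**  A taxon present in *every* sample of a stratum (or a
  sample containing every observed taxon) pushes its parameter to
  $+\infty$; products $p_i q_a$ are capped at $-\log(10^{-12})$ so that
  $\pi \le 1 - 10^{-12}$, and the stratum is flagged.  The cap keeps all
  downstream scores finite; flagged strata are exempted from the
  stationarity check because their optimum genuinely lies on the
  boundary.
* **Degenerate margins.**  All-zero rows and columns are fixed at
  $p = 0$ / $q = 0$ exactly (their maximum-likelihood values) and
  excluded from the iteration.

## Association scores

For taxa $i, j$ the null co-occurrence count over $M$ samples is a sum
of independent Bernoulli draws with per-sample probability
$w_m = \pi_{im}\pi_{jm}$ — a Poisson-binomial variable whose exact
distribution follows the recursion

$$P(n \mid m) = P(n \mid m-1)(1 - w_m) + P(n-1 \mid m-1)\,w_m,
  \qquad P(0 \mid 0) = 1.$$

Scores are inclusive negative-log tails at the observed count $n_{ij}$:

$$S^{\mathrm{A}}_{ij} = -\log P(n \ge n_{ij}), \qquad
  S^{\mathrm{S}}_{ij} = -\log P(n \le n_{ij}),$$

in natural log throughout (a fair-coin joint presence scores
$\log 2 \approx 0.693$).  Because both tails include the observed count,
$e^{-S^{\mathrm{A}}} + e^{-S^{\mathrm{S}}} = 1 + P(n = n_{ij})$, an
identity the suite asserts on every scored pair.  Sample-axis scores
(how surprisingly two *samples* share taxa) use the same machinery with
the matrix transposed.

The recursion runs in linear space over the samples with $w_m > 0$; a
tail smaller than $10^{-280}$ is recomputed by a log-space recursion
with log-sum-exp, so scores of hundreds of nats remain finite without
ever overflowing.  The kernel is compiled (Rcpp), making all-pair
scoring of a $60 \times 600$ problem a matter of seconds.

### Z calibration

Raw scores correlate with prevalence, so they are standardised against
the null: draw $R$ random matrices from the fitted model, *refit the
null model on each replicate*, score all pairs under the replicate's own
model, and set

$$Z_{ij} = \frac{S^{\mathrm{obs}}_{ij} - \overline{S^{(r)}_{ij}}}
  {\mathrm{sd}_r\,S^{(r)}_{ij}}.$$

Refitting is what makes the calibration honest — the observed scores
were also computed under a model estimated from the scored matrix
itself.  A `refit = FALSE` fast path exists for exploration and is
non-canonical.  $R$ defaults to 100; the validation suite uses 10–25 to
keep runtimes short, which widens the Z noise but leaves the procedure
unchanged.  Pairs whose replicate scores have spread below
`sd_floor = 1e-9` (for example two taxa confined to disjoint subtypes,
which score exactly zero in every realization) are flagged
*non-evaluable* rather than being assigned an arbitrary Z.

## Thresholds, detectability, and the control network

Null realizations carry no interactions, so every association detected
in them is a false positive.  Counting detections against the threshold
$T$ gives $\mathrm{FPR}(T) = \overline{\#\mathrm{null}}/\#\mathrm{evaluable}$
and $\mathrm{PPV}(T) = \max\!\big(0, (\#\mathrm{obs} -
\overline{\#\mathrm{null}})/\#\mathrm{obs}\big)$ (undefined when nothing
is observed).  The PPV estimator is the standard empirical-null excess
form; note it is clamped at zero and hence positively biased on pure
noise — its null-data mean sits near 0.1 at the suite's problem sizes,
far below any genuine operating point.  By default the curve reuses the
calibration replicates, standardising each against the others
(leave-one-out), which makes it essentially free; a fresh-realization
mode with full nested recalibration is available.

A pair can reach a significant aggregation only if the probability that
the two taxa *always* co-occur is small enough, and a segregation only
if the probability that they *never* co-occur is small enough; the
per-pair limits $-\log P(n = n_{\max})$ and $-\log P(n = 0)$ are
computed in closed form and compared against the threshold mapped onto
the raw scale through each pair's null mean and spread.  The *consensus
set* — pairs detectable for both types — is where aggregation and
segregation counts are comparable.

The *control network* separates methodological artefacts from signal: a
single null matrix is drawn, treated exactly like the observed one
(refit, score, calibrate), and its thresholds lowered by rank until it
carries exactly the observed edge counts (ties broken toward the
lexicographically smallest pair).  Because prevalent taxa accumulate
associations as thresholds drop, even the control network shows mild
clustering; genuine community structure must exceed it.

When both Z scores of a pair clear their thresholds, the type with the
larger Z wins and the conflict is counted on the network object — the
case is not meaningfully interpretable and essentially never occurs
outside adversarial fixtures.

## Network statistics

* **Propensity.**  $\mathrm{Prop}(a,b) = \log P(a,b) - \log P(a) - \log
  P(b)$ from counts over a common universe; zero under independence,
  symmetric.  Standard errors use the delta method on the binomial
  proportions ($\sqrt{1/k_{ab} - 1/k_a + 1/k_b - 1/K}$); a zero count
  leaves the value undefined (flagged) rather than $-\infty$.
* **Triangle propensities.**  For every unordered triple with both
  conditioning edges at a centre $k$ (condition AA, AS or SS), the
  third pair contributes an aggregation, a segregation or nothing; the
  conditional type frequency is compared against the unconditional
  frequency among evaluable pairs.  Each triple is counted once per
  centre; the third pair enters the denominator only if evaluable.
* **Nestedness.**  $\nu_{ij} = \sum_k A_{ik}A_{jk} / \sqrt{\sum_k
  A_{ik}\sum_k A_{jk}}$ on the aggregation adjacency by default — 1 for
  identical neighbourhoods, 0 for disjoint ones, undefined for isolated
  nodes.
* **Habitat preference.**  A taxon prefers an environment when strictly
  more than 50% *and* at least 3 of its samples fall there; otherwise
  undefined.  Relatedness classes (Same / Und / Diff per level; deepest
  shared taxonomic rank with unknown ranks never matching) feed the
  class propensities, and classes under 10 pairs are suppressed as too
  noisy.
* **Cosmopolitanism.**  Environmental: the number of subtypes occupied.
  Community: $1 + 2\sum_{a<b} X_{ia}X_{ib}\,
  \theta(S_0 - S^{\mathrm{SA}}_{ab}) / m_i$, the effective number of
  significantly *different* communities a taxon inhabits, between 1 (all
  its communities alike) and its prevalence $m_i$ (all different).  The
  default threshold $S_0 = 4.92$ is the sample-aggregation score at
  which that score's PPV reaches 0.96; on other data it should be
  re-derived from the sample-axis calibration curve.
* **Effective environment count.**  The exponential of the Shannon
  entropy of the environment fractions of a pair's co-occurrence
  samples, which discounts rare environments; between 1 and the number
  of environments at the level.

## The synthetic generator

`generate_dataset()` emulates exactly the structure the analysis
assumes, with known ground truth:

* $p \sim$ log-normal(meanlog $-2.5$, sdlog $1$) and $q \sim$
  Gamma(shape 2, rate 2; mean 1), giving a heavy-tailed prevalence
  distribution and ~5–15% matrix fill — the sparsity regime of broad
  environmental surveys.
* Four subtypes by default, nested pairwise into types and supertypes;
  each taxon is allowed in each subtype with probability 0.7 (at least
  one), and its occupancy probability is exactly zero elsewhere —
  the habitat stratification the null model is built to absorb.
* **Planted positive couplings.**  All members of a connected component
  of the positive-coupling graph share one abundance parameter and one
  latent per-sample uniform $u_{a}$.  In each shared-habitat sample,
  with probability $\rho$ per pair, both indicators are redrawn as
  $X = \mathbb{1}[u_a < \pi]$.  This comonotone merge forces identical
  indicators in coupled samples (at $\rho = 1$ the occupancy vectors
  coincide within shared subtypes) while leaving every taxon's marginal
  exactly Bernoulli($\pi$) — planted structure changes co-occurrence,
  never prevalence, so the null model cannot absorb it by re-estimating
  abundances.  Routing the merge through a per-component uniform makes
  overlapping pairs (coupled cliques) reinforce rather than overwrite
  one another.  An earlier max-merge design was rejected because it
  inflates the marginals of coupled taxa roughly by
  $\rho\,(1-\pi_i)\pi_j$ per shared sample, confounding coupling
  strength with abundance.
* **Planted negative couplings.**  With probability $\rho$ per sample, a
  joint presence loses one member chosen by a fair coin; $\rho = 1$
  yields exactly zero co-occurrences.  This deflates marginals slightly
  (documented, not corrected).
* With no planted pairs the matrix is bit-identical to
  `sample_matrix()` run on the generator's own $\pi$ and recorded cell
  seed, so null-data tests and generator tests are exchangeable.

What the generator does **not** emulate: read counts, sequencing error,
primer or study bias, abundance information, spatial or temporal
autocorrelation between samples, and correlation between taxonomy and
habitat preference.  Passing recovery tests therefore demonstrate the
statistical machinery, not robustness to those real-data artefacts.

## Validation choices

The suite validates the recursion against exhaustive $2^M$ enumeration
($M \le 12$), the fit against an independent bounded coordinate-ascent
maximiser, the calibration against its own FPR prediction on null-drawn
data (50 taxa, 400 samples, 25 replicates, 10 seeds), planted-pair
recovery at 60 taxa, 600 samples, 4 subtypes, 15 couplings of
$\rho = 0.6$ (mean ranking AUC above 0.9 over 10 seeds), and the
community-structure contract on a two-group planted fixture (within-group
positive, between-group negative coupling at $\rho = 0.9$): the
conditional-association pattern — (A|AA) and (S|AS) favoured, (S|AA)
and (A|AS) suppressed — appears in the observed network and is strongly
attenuated in the count-matched control.  These problem sizes were
chosen so the whole suite runs in a few minutes on one core while
keeping every binomial consistency check well-powered.

## Known limitations

Binary presence-absence discards abundance, which limits power against
segregation in sparse data; pairs are scored independently, so the
$N(N-1)/2$ tests share the same fitted null and are not independent
draws; the Z transform assumes the replicate score distribution is
summarised well by mean and spread; and coarse environment labels leave
residual habitat structure that surfaces as aggregation — the
motivation for reading any observed network against its control.
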