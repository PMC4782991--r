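---
title: "Quantifying directional emotion entrainment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional emotion entrainment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emotrain)
```

## The problem

Users of an online community broadcast emotional signals — mood tags on a
blog post, the affective tone of a microblog message — and adjust their own
emotional state in response to the signals of others. *Entrainment* is the
tendency of two such processes to synchronize. `emotrain` quantifies it from
nothing more than per-user, time-binned ternary emotion series: each user
$v_i$ contributes a sequence $x_t \in \{-1, 0, +1\}$ (negative, neutral,
positive; `NA` where the user produced no classifiable post in a bin).

Three questions drive the design:

1. **Is entrainment directional?** Who adapts to whom, and how asymmetric is
   the adaptation within a dyad?
2. **How do dyadic entrainment patterns evolve** as a community ages, and how
   do they relate to emotional similarity?
3. **Does entrainment structure help predict a user's next emotion state?**

## Entrainment strength from transfer entropy

The core statistic is transfer entropy. For a target series $x$ and source
series $y$ with history orders $m$ and $n$:

$$TE(Y \to X) = H(x_{t+1} \mid x_t^m) - H(x_{t+1} \mid x_t^m, y_t^n),$$

the reduction in uncertainty about $x$'s next state from knowing $y$'s
recent history beyond $x$'s own. The entrainment strength with which user
$i$ adopts user $j$'s emotions is $Etr(i \to j) = TE(j \to i)$; this
direction convention is fixed package-wide (`etr(i, j)` asks "how strongly
does $i$ entrain *toward* $j$?"). Entropies are in bits (log base 2 — the
base is our choice; it only scales the statistic).

`transfer_entropy()` is a plug-in estimator over the observed
$(m{+}1)$-gram and $(m{+}n{+}1)$-gram frequencies. Grams are encoded as
base-3 integers and tabulated, so a single estimate at 5000 bins costs a
few milliseconds and the permutation-null machinery (200 circular-shift
surrogates per dyad, `te_circular_null()`) stays cheap. Bins with missing
observations are excluded from the counts rather than imputed — the
simplest defensible contract, and the exclusion is per-gram, so a single
missing bin invalidates only the grams that overlap it.

Defaults: $m = n = 3$; `min_samples = 30` aligned grams (dyads below it are
refused and reported, never silently dropped).

### Estimator order versus sample size

The plug-in estimator's upward bias grows with the number of occupied
gram cells relative to the sample size — at $m=n=3$ the joint alphabet has
$3^7 = 2187$ cells, and with only ~2000 aligned grams the bias is on the
order of 0.4 bits. That dwarfs weak true signals. Two practical
consequences, both visible in the test suite:

* Analyses that compare *directions within a dyad* (directionality, EnDis)
  are robust at $m=n=3$: the bias is common to both directions.
* Analyses that compare *strengths against an absolute threshold*
  (Dual/Single/None classification at modest sample sizes) should match the
  estimator order to the dynamics' memory. The synthetic generator is a
  first-order chain, so the planted-pattern validation runs at $m=n=1$,
  where the bias is ~0.004 bits and recovery is essentially perfect. On real
  data the order is a genuine modelling choice: higher order captures longer
  memory but demands exponentially more data.

### The quadrature-smoothed estimator

A composite Simpson quadrature operator is provided
(`simpson_quadrature()`), exact for cubics, and an alternative TE estimator
(`te_config(estimator = "simpson")`) built on it: the plug-in TE is exactly
the sample mean of the per-gram log-likelihood-ratio statistics
$\xi_t = \log_2 \frac{\hat p(x_{t+1}\mid x_t^m, y_t^n)}{\hat p(x_{t+1}\mid x_t^m)}$,
and the smoothed estimator integrates $x\,\hat f(x)$ over a kernel density
$\hat f$ of the $\xi_t$ by composite Simpson. There is no canonical way to
attach a quadrature rule to a discrete plug-in estimator — the choice of
integrand is ours — so the smoothed path is offered behind a flag and every
quantitative guarantee in the package binds to the plug-in path. Negative
smoothed estimates clamp to zero; exact plug-in values cannot be negative.

## Dyad patterns and peer-level statistics

For each unordered dyad at time $t$:

* **EnDis** $= |Etr_{ij} - Etr_{ji}| / \max(Etr_{ij}, Etr_{ji})$ — 0 for
  perfect reciprocity, 1 for one-sided entrainment. When both strengths are
  zero the ratio is 0/0; such dyads are recorded as undefined and excluded
  from averages rather than assigned a value.
* **Pattern** — against the time-varying community threshold $\theta_t$,
  the mean of all finite *directed* strengths at $t$ (ordered pairs; the
  choice of ordered over unordered averaging is ours and is configurable by
  construction since $\theta_t$ is just a number): `Dual` if both
  directions reach $\theta_t$, `Single` if exactly one does, `None`
  otherwise. The boundary is inclusive ($\geq$).

`build_network()` computes all ordered-pair strengths from history up to
$t$ — cumulative by default, optionally a sliding window; the source
material never states which window the original analyses used, and
cumulative is the more stable default. Runtime is quadratic in users, which
is the honest cost of an all-pairs directed statistic.

Peer-level summaries (`dyad_trajectories()` and friends) then deliver the
reciprocity correlation, per-pattern mean cross-entropy distances with a
two-sample t-test, the ratio $R_t = \#\mathrm{Dual}_t / \#\mathrm{Single}_t$
with its first-peak segmentation into relationship 'Develop' and 'Maintain'
stages (undefined ratios — no Single dyads — are missing, not infinite),
per-dyad signed lead times between first Dual and first Single
classification (onset = first bin with the label; dyads never reaching a
pattern are censored and counted separately), and the OLS regression of
dyadic distance on the *minor* reciprocal strength.

## Emotional distance

Per-user emotion distributions $p(v_i^t)$ are relative state frequencies
in the window ending at $t$, smoothed by adding $\varepsilon = 10^{-6}$
and renormalising so cross-entropies stay finite. Community distance is

$$\langle CE \rangle_t = \frac{1}{N^2} \sum_{i \neq j}
  CE\!\left(p(v_i^t), p(v_j^t)\right),
  \qquad CE(p, q) = -\sum_s p(s) \log_2 q(s),$$

with the $1/N^2$ normaliser kept exactly as defined (a homogeneous
community therefore scores $H(p)(N^2-N)/N^2$, not $H(p)$).

## The synthetic generator

No public corpus with per-post emotion labels and known coupling exists, so
validation rests on `generate_community()`: coupled ternary Markov chains
with planted ground truth. Each user follows a shared base transition
matrix; a directed coupling edge $(j \to i, \kappa)$ makes follower $i$
copy source $j$'s previous state with probability $\kappa$ instead of
drawing from the base chain. Updates are synchronous from the $t-1$ states
only, so mutual (Dual) coupling is well-defined and order-free. Planted
patterns: Dual iff both directions are coupled, Single iff exactly one,
None controls sampled among uncoupled pairs.

Defaults, chosen once as a realistic day-binned regime: state persistence
0.6 (emotions carry over from day to day, switching 0.2/0.2), one post per
user per bin in expectation (Poisson), no missingness unless requested.

What the generator *does* emulate: ternary day-binned series, directional
coupling of tunable strength, users joining/abandoning over a timeline
(`generate_community_timeline()`), Bernoulli missingness. What it does
*not*: user heterogeneity in baseline emotional disposition (everyone
shares one base chain), burstiness of posting, content. Passing tests
therefore demonstrate estimator correctness and recoverability of planted
structure — not that real platforms behave like the generator.

Two consequences of the copy dynamics worth knowing:

* Under strong *mutual* copying a dyad's partner history becomes largely
  redundant with one's own (your partner copied you a step ago), so the
  *order-3* conditional information in a Dual dyad is genuinely small even
  though the order-1 information is large. This is why pattern-recovery
  validation uses the order-matched estimator, as discussed above.
* Coupling disjoint pairs makes partners converge but lets pairs drift
  apart (copying suppresses base-chain mixing), so *community-level*
  convergence experiments use a connected coupling topology (a hub star),
  where onset of coupling visibly lowers $\langle CE \rangle_t$.

## Community lifecycle

A user joins at their first post and has abandoned the community if they
contribute nothing for at least six months (182 day-bins, configurable)
before the corpus end; users posting within the final six months are never
called abandoned. `lifecycle_breakdown()` produces the per-period
joined / joined-and-abandoned / abandoned / other-active partition, and
`fit_exponential_growth()` fits $y = a e^{b(t - t_0)}$ by least squares on
the log scale — the standard, stable fitter for this functional form —
optionally excluding trailing periods where growth visibly ceases.

## Polarity classification

Platforms without mood labels need per-post polarity. The package ships a
multinomial naive Bayes classifier over unigram and bigram token features
with Laplace ($\alpha = 1$) smoothing. Negation is handled by prefixing
`neg-` to tokens in a negator's scope; scope is the following $k = 2$
tokens, terminated by punctuation — a bounded forward scope is the standard
reading of prefix-negation feature schemes, and $k$ is configurable.
Tokenization is injected by the caller (the package takes token vectors),
since segmentation is language-specific. A self-training loop
(`nb_self_train()`) repeatedly absorbs unlabeled documents whose posterior
confidence reaches a threshold (default 0.9 — the "high confidence" level
is not standardised anywhere, so it is exposed as configuration), with
permanent additions and a non-decreasing training set. Ties in posteriors
break toward neutral.

## The entrainment-augmented factor graph

Prediction of each user's next (final-bin) emotion state uses a log-linear
pairwise model over $y_i \in \{\mathrm{NEG}, \mathrm{NEU}, \mathrm{POS}\}$:

$$\log P(\mathbf y) = \sum_i \sum_j \alpha_{js} \, g(y_i, m_{ij})
 + \sum_{e_{ij}} \beta \, g(Etr(v_i \to v_j))
 + \sum_{e_{ij}} \gamma \, g(G(v_i, v_j)) - \log Z$$

* **Modality factors** $g(y_i, m_{ij}) \in \{0,1\}$: n-gram encodings of
  the user's historical states (unigrams per bin, bigrams across adjacent
  bins) and of activity levels discretized at 1× and 2× the community mean
  posting count (low < 1×, medium ∈ [1×, 2×), high ≥ 2×), each feature
  tagged with its relative temporal index. One weight per (feature, state)
  pair, so a single-node model is exactly multinomial logistic regression
  (the tests verify the gradient reduction).
* **Association factors** $g(Etr) \in \{0,1\}$: does the adopter's strength
  reach $En_0$, the mean entrainment strength over the preceding seven
  day-bins?
* **Pattern factors** $g(G) \in \{0,1,2\}$ for None/Single/Dual.

Two design points were genuinely open and are resolved as follows:

* **Label coupling.** Read literally, the pairwise factors score the
  *graph*, not the labels — they are constants that cancel in inference and
  cannot inform prediction. The package's default (`variant = "coupled"`)
  applies an edge's factor value only to assignments with $y_i = y_j$,
  which is the reading under which entrainment can carry label information;
  the literal reading remains available (`variant = "literal"`) and the
  tests confirm its factors cancel.
* **Weight tying.** Per-edge $\beta_{ij}, \gamma_{ij}$ are unlearnable from
  a single prediction snapshot (one observation per edge), so $\beta$ and
  $\gamma$ are tied across edges.

**Inference** is exact enumeration up to 12 nodes and damped loopy
sum-product above (damping 0.5, ≤200 sweeps, convergence when the largest
message change drops below $10^{-6}$; non-convergence is reported with the
residual, and marginals are still returned). Loopy beliefs are
quantitatively trustworthy here only for weak pairwise couplings: measured
against enumeration on 8-node/3-loop models, the worst total-variation gap
is about $2\times10^{-4}$ at edge-weight scale 0.05 but grows to
$7\times10^{-3}$ by scale 0.15, which is why the inference-oracle tests
draw small edge weights (trees are exact at any scale).

**Learning** maximises the L2-penalised mean log-likelihood by gradient
ascent: gradient = observed − expected feature counts − $\lambda\theta$,
$\lambda = 0.1$ by default, initial step
$\min(0.5,\ 1/(1+\lambda))$ adapted by halving on gradient-norm growth,
convergence at norm $10^{-4}$, and an abort with diagnostics if the norm
grows for ten consecutive steps. On partially labelled communities the
parameters are learned on the labelled subgraph (nodes with observed
labels and the edges among them); prediction clamps the training labels
and reads the argmax marginal of each test node, ties toward NEU. Full
marginalisation over unlabeled nodes during learning was considered and
rejected as disproportionate for the model sizes involved.

`enfg_cv()` wraps the four-fold cross-validation protocol; folds come from
`make_folds()` so baseline comparisons can share the identical partition
(paired comparisons).

## Baseline encodings

Conventional classifiers cannot consume relational factors, so entrainment
is flattened for them: chain clustering (`chain_cluster()`) links users
with mutually over-threshold strengths and takes connected components as
Dual groups; `single_neighbour_profile()` averages the emotion
distributions of the top $K = 5$ solely-entrained neighbours weighted by
strength and discretizes each dimension (1 on $[0, 1/4)$, 2 on
$[1/4, 1/2)$ — closed on the left — 3 otherwise). `baseline_cv()` runs the
sequential feature-tier comparison (modality; + Dual group; + Single
profile) under a naive Bayes backend (`e1071`) or a maximum-entropy backend
(multinomial logistic regression, `nnet`). The threshold $En_0$ does double
duty as the association threshold and the chain-clustering similarity
threshold; the package uses the seven-day average for both, configurable at
each call.

## Validation scales and what the suite shows

The test and acceptance workloads were sized to make every stochastic check
reproducible and sharp: 200 random sequence pairs (length ≤ 50) for the
brute-force oracle comparison at $10^{-12}$; 50,000 bins for the
$\log_2 3$ closed form; 100 seeded replicates at 5000 bins for
directionality, surrogate-null coverage and the coupling-monotonicity
sweep; 200 dyads at 2000 bins for pattern recovery; 50 random ≤8-node
models for the inference oracle; a 6-node model with 2000 training samples
for parameter recovery; 80 users for the prediction ablation. The
generator's defaults are the study conditions; none of these sizes or the
acceptance thresholds were adjusted to the outcomes, with the two
documented exceptions above (estimator order for pattern recovery, cohort
size for the ablation) whose rationale is methodological, not numerical.

## Known limitations

* The plug-in TE estimator is biased upward at small samples; only the two
  specified estimators are provided, and no bias-corrected variants.
* $\theta_t$-based classification inherits that bias when samples are
  short; prefer order-matched estimation or longer windows.
* The generator's users are homogeneous; convergence effects at the
  community level are driven by correlated fluctuations and connected
  coupling topologies, not by heterogeneous baselines converging.
* Loopy BP marginals degrade with strong couplings; the exact engine caps
  at 12 nodes by design.
* The polarity stage models token multinomials only; no segmentation, no
  lexicon beyond what the caller supplies.
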