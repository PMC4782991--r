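# emotrain

Directional emotion entrainment analysis for social time series.

## What this package is for

People on social platforms adjust their emotional state in response to the
emotions their contacts broadcast — a synchronization process called
*entrainment*. `emotrain` quantifies that process from per-user, time-binned
ternary emotion series (state −1/0/+1 per user per day, `NA` where a user
posted nothing classifiable). It is aimed at computational social scientists
and affective-dynamics researchers who have event streams of the form
`(user, time, emotion)` — from mood tags, or from text run through the
included polarity classifier — and want to ask:

- **Who entrains to whom, and how strongly?** Entrainment strength is
  transfer entropy: `Etr(i → j) = TE(j → i) = H(x_{t+1} | x_t^m) −
  H(x_{t+1} | x_t^m, y_t^n)` in bits, the uncertainty about user *i*'s next
  state removed by user *j*'s history beyond *i*'s own (default orders
  `m = n = 3`). The measure is asymmetric, so direction is part of the
  answer; a circular-shift surrogate null separates signal from estimation
  noise.
- **How asymmetric is a dyad?** `EnDis = |Etr_ij − Etr_ji| / max(Etr_ij,
  Etr_ji)`, and each dyad is classified against the time-varying community
  threshold θ_t (the mean directed strength at *t*) as **Dual** (both
  directions ≥ θ_t), **Single** (exactly one), or **None**.
- **How do emotions converge?** Community distance
  `⟨CE⟩_t = (1/N²) Σ_{i≠j} CE(p(v_i^t), p(v_j^t))` with cross-entropy in
  bits; peer-level trajectories give the Dual/Single ratio R_t, its
  develop/maintain stage split, lead-time distributions, and the regression
  of distance on reciprocal strength.
- **Does entrainment predict the next emotion?** A log-linear factor-graph
  model (EnFG) combines per-user n-gram modality features with tied pairwise
  entrainment-association and entrainment-pattern factors, learned by
  penalised maximum likelihood with exact or loopy-BP inference, evaluated
  by four-fold cross-validation against naive Bayes / maximum-entropy
  baselines over flattened entrainment encodings.

Because no public corpus ships both emotion labels and known coupling, the
package includes a first-class synthetic generator: communities of coupled
ternary Markov chains in which a follower copies its source's previous state
with probability κ, with planted Dual/Single/None dyads, join/abandon
timelines, and missingness. All quantitative validation rests on recovering
that planted ground truth.

## Worked example

Plant nine dyads (3 Dual, 3 Single, 3 uncoupled controls) at coupling
strength κ = 0.8 over 2000 daily bins, build the entrainment network, and
compare recovered patterns with the planted truth:

```r
library(emotrain)

pd <- planted_dyad_community(n_dual = 3, n_single = 3, n_none = 3,
                             kappa = 0.8, n_steps = 2000, seed = 42)
net <- build_network(pd$community,
                     cfg = te_config(order_m = 1, order_n = 1),
                     dyads = pd$dyads[, c("i", "j")])
net
#> <entrainment_network> t = 2000 | 18 directed edges | theta_t = 0.399

res <- merge(net$dyads, pd$dyads, by = c("i", "j"),
             suffixes = c("", ".planted"))
res[, c("i", "j", "etr_ij", "etr_ji", "en_dis", "pattern", "pattern.planted")]
#>    i  j  etr_ij  etr_ji  en_dis pattern pattern.planted
#> 1  1  2 0.82060 0.82861 0.00966    Dual            Dual
#> 2 11 12 0.00310 0.82846 0.99626  Single          Single
#> 3 13 14 0.00578 0.00199 0.65505    None            None
#> ...
mean(res$pattern == res$pattern.planted)
#> [1] 1
```

Reading the output: a Dual dyad carries ~0.8 bits of transfer entropy in
*both* directions with near-zero disparity (`en_dis ≈ 0.01`); a Single dyad
carries ~0.8 bits only in the follower→source direction (`en_dis ≈ 1`,
fully one-sided); uncoupled controls sit at the estimator's noise floor
(~0.003–0.006 bits) below θ_t ≈ 0.4, and every dyad is classified as
planted. The estimator order here is 1 because the generator is a
first-order chain; see the methods vignette
(`vignettes/emotrain-methods.Rmd`) for the order-versus-sample-size
discussion and every other modelling choice.

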