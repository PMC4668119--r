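---
title: "Modelling avoidance in probabilistic reward and punishment learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling avoidance in probabilistic reward and punishment learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidrl)
```

## The task

Subjects see one of four abstract stimuli on each of 160 intermixed
trials and classify it as category "A" or "B", or press "skip" to avoid
the trial. Two stimuli are reward-based: a correct classification wins
+25 points, an incorrect one produces no feedback. Two are
punishment-based: an incorrect classification loses 25 points, a correct
one produces no feedback. Each stimulus's majority category is
trial-correct on exactly 80% of its 40 presentations (32/8, realized
exactly rather than by Bernoulli draws, so the 80% figure is a
deterministic property of every schedule). A skip never gains or loses
points. In the *no-feedback* condition a skip is merely acknowledged; in
the *feedback* condition the screen reveals the category that would have
produced feedback — the winning category on reward trials, the losing
one on punishment trials.

The no-feedback outcome is ambiguous: it is simultaneously a missed
reward (on reward trials) and a successfully avoided punishment (on
punishment trials). How a subject values that ambiguity, and how they
value the feedback that follows a skip, are the scientific quantities of
interest: skipping every punishment trial and classifying every reward
trial is the points-optimal policy, yet many human subjects never skip
at all.

## The model

Each (stimulus, response) pair carries an expectancy $Q[r,s]$,
initialized to 0. Choice follows a softmax over the presented stimulus's
three expectancies,

$$\Pr(r \mid s) = \frac{e^{Q[r,s]/T}}{\sum_{j \in \{A,B,\mathrm{skip}\}} e^{Q[j,s]/T}},$$

with temperature $T \in [0,1]$. After the outcome, only the chosen
entry is updated by a dual-learning-rate delta rule with prediction
error $PE = R - Q[r,s]$:

$$Q[r,s] \leftarrow Q[r,s] + PE \cdot LR^{+} \text{ if } PE > 0,
  \qquad Q[r,s] \leftarrow Q[r,s] + PE \cdot LR^{-} \text{ if } PE < 0,$$

and no change when $PE = 0$. The reinforcement $R$ is +1 for a win and
−1 for a loss (fixed), the free value $R_0 \in [-1,1]$ for the
ambiguous no-feedback outcome, and the free values
$RS_{rew}, RS_{pun} \in [-1,1]$ for the feedback following a skip on
reward- and punishment-based trials. Because the update is a convex
combination of the current expectancy and a reinforcement in
$[-1, 1]$, every expectancy stays in $[-1, 1]$ forever.

Two modelling commitments deserve emphasis:

* **Skips update the skip expectancy.** A skip generates a prediction
  error against $Q[\mathrm{skip}, s]$ with $R = RS_{rew}$ or
  $RS_{pun}$. In the variant that fixes both at 0 the skip expectancy
  never leaves its zero initialization, which is what makes that
  variant exactly equivalent to a model without skip learning.
* **No counterfactual updating.** The category displayed after an
  informational skip never updates that category's expectancy; only
  the chosen response's entry moves.

Fitting is by *teacher forcing*: the subject's logged responses and
outcomes are replayed, the expectancies evolve as the model says they
would, and the fit criterion is the negative log likelihood
$\mathrm{negLLE} = -\sum_{t=1}^{160} \log \Pr(r_t)$. A random
three-option policy gives $160 \ln 3 = 175.78$; perfect prediction
gives 0. The teacher-forced expectancy trajectory does not depend on
$T$, a factorization the fitter exploits (below).

## Parameters

| parameter | range | role |
|---|---|---|
| $LR^{+}$ | $[0,1]$ | learning rate after better-than-expected outcomes |
| $LR^{-}$ | $[0,1]$ | learning rate after worse-than-expected outcomes |
| $T$ | $[0,1]$ | softmax temperature (explore at high $T$, exploit at low) |
| $R_0$ | $[-1,1]$ | subjective value of the ambiguous no-feedback outcome |
| $RS_{rew}$ | $[-1,1]$ | value of post-skip feedback on reward trials |
| $RS_{pun}$ | $[-1,1]$ | value of post-skip feedback on punishment trials |

Six variants are fitted (`model_specs()`): the full model ($k=6$);
`no_RS` ($RS_{rew}=RS_{pun}=0$, $k=4$); `one_RS` (tied RS, $k=5$);
`one_LR` (tied learning rates, $k=5$); `fixed_T` ($T=0.23$, the
cohort-mean temperature under the full model, used exactly even though
it lies off the 0.05 lattice, $k=5$); and `no_R0`
($R_0=RS_{rew}=RS_{pun}=0$, $k=3$). For a subject with zero skips the
likelihoods of `full`, `no_RS` and `one_RS` are identical — the RS
parameters are never touched — so `no_RS` always wins on BIC among the
three for such subjects.

## Grid-search estimation

The estimator is exhaustive grid search, not continuous optimization:
the `standard` grid steps the rates and temperature by 0.05 (21 values)
and the outcome values by 0.1 (21 values); the `desk` default coarsens
rates and temperature to 0.1 steps (11 values) so that a full-model fit
sweeps $11^2 \cdot 11 \cdot 21^3 \approx 1.2\times10^7$ lattice points
in about two seconds of compiled code. Two exact reorganizations make
this cheap without changing the argmin:

1. the $Q$ trajectory is temperature-independent, so one trajectory
   serves all temperature values;
2. expectancy rows of different stimuli never interact, so the negLLE
   splits into a reward-stimulus part involving $RS_{rew}$ but not
   $RS_{pun}$, and a punishment-stimulus part involving $RS_{pun}$ but
   not $RS_{rew}$; the two RS dimensions can be swept separately and
   summed.

Both are asserted against a naive per-trial R loop in the test suite
(agreement to $10^{-9}$, and exact argmin-set agreement with a
brute-force enumeration on coarse lattices).

When several lattice points fit equally well (within $10^{-9}$ in
negLLE — ties in practice arise from exactly identical likelihoods,
e.g. untouched RS dimensions), each parameter reports the median of its
tie range, per parameter (marginally); with an even number of distinct
tied values the midpoint of the two central values is reported, which
can fall off the lattice. The full argmin set is retained in the
`fit_result` for audit.

$T = 0$ appears on the printed grids but makes the softmax undefined;
it is interpreted as the argmax limit with uniform tie-splitting. A
logged response the limit assigns probability 0 yields an infinite
negLLE — a legal value that simply loses the argmin. The softmax is
computed with max-subtraction before exponentiation, so no overflow
occurs anywhere on the grid.

Model comparison uses $BIC = k \ln(160) + 2\,\mathrm{negLLE}$ per
subject, then a random-effects Bayesian model selection over subjects:
log model evidence is approximated as $-BIC/2$ (the standard
Laplace-style bridge, declared explicitly since the evidence
approximation is a modelling choice), a variational fixed point
estimates the Dirichlet concentrations over model frequencies (uniform
prior $\alpha_0 = 1$, convergence at $\max|\Delta\alpha| < 10^{-6}$,
cap 10,000 iterations), and exceedance probabilities
$\varphi_i = \Pr(r_i > r_j\ \forall j \neq i)$ are estimated by seeded
Monte Carlo with $10^6$ Dirichlet draws. The sample tallies partition
the draw count exactly, so the probabilities sum to one by
construction. For two models the closed form via the regularized
incomplete beta function serves as an independent cross-check, never as
the estimator.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a human study on this
task: two conditions of 100 subjects, 160 trials over 4 stimuli with
exact 80/20 contingencies, and a phenotype mix. The defaults encode the
qualitative contrasts the model predicts between avoidance phenotypes:

* `non_avoider`: $R_0 = 0.9$, $LR^- = 0.05$, $LR^+ = 0.4$, $T = 0.23$,
  RS at 0 — successful categorization on punishment trials is itself
  nearly as good as a win, so skipping never takes hold;
* `avoider`: $R_0 = 0$, $LR^- = 0.4$, $LR^+ = 0.4$, $T = 0.23$,
  $RS_{rew} = -0.2$, $RS_{pun} = 0.5$ — neutral ambiguity valuation,
  fast loss learning, and rewarding post-skip feedback on punishment
  trials lock avoidance in;
* `uniform`: every parameter uniform over its grid values, the
  workhorse for parameter-recovery studies.

These are package defaults chosen once for the qualitative contrasts,
not estimates from any human cohort; all are overridable and logged
with the cohort. The default mix (45% non-avoider / 55% avoider) sits
inside the 38–50% non-avoider range seen across conditions in human
samples. The master seed spawns per-subject (parameter, schedule,
choice) seed triples sequentially, so growing a cohort never perturbs
subjects already generated.

**What the generator does not emulate.** Human non-avoiders make *zero*
skips in 160 trials. A softmax agent over zero-initialized expectancies
cannot do that: the first presentation of each stimulus is a three-way
tie, so the skip probability is exactly 1/3 there under any
parameterization (the $T=0$ limit splits ties uniformly too), bounding
the zero-skip probability at $(2/3)^4 \approx 0.20$ per session; at the
non-avoider preset the realized rate is well under 1%, with a median of
about 7 exploratory skips per session. Synthetic "non-avoiders" are
therefore *rare*-skippers rather than never-skippers, and passing tests
demonstrate the pipeline's internal correctness and the direction of
parameter–behavior relationships, not that the generator reproduces
human zero-skip rates. Human subjects presumably carry strong priors
against opting out that this model family has no slot for. The
generator also imputes no reaction times or demographics.

```{r}
cohort <- generate_cohort(cohort_spec(n_per_condition = 5, seed = 42))
summarize_cohort(cohort)[, c("subject_id", "skips_reward",
                             "skips_punishment", "avoider")]
```

## Numerical and design choices

* **Exact-proportion scheduling.** 32/8 per stimulus rather than
  i.i.d. draws: "80% of trials" is treated as a realized proportion,
  making the contingency a deterministic test target. Trial order is a
  single seeded uniform shuffle; no block structure is imposed, and
  equal presentation counts (40 per stimulus) are assumed.
* **Points are bookkeeping.** The agent consumes outcome classes,
  never point totals; ±25 only affects the logged score.
* **Tie tolerance.** $10^{-9}$ on negLLE for argmin-set membership;
  degenerate all-infinite fits (possible only on grids containing only
  $T=0$) keep their tie set but are capped at 500,000 stored points
  with the exact tie count reported.
* **Behavioral denominators.** Percent optimal uses all trials of a
  valence as denominator, so optimal, skip, and non-optimal
  classifications partition each valence exactly; skips depress
  percent optimal and (on punishment trials) raise percent adaptive.
  Both frequent-avoider thresholds are implemented — at least 10 skips
  (`count`, the default, matching the 88/36/75 partition of 199
  subjects) or at least 10% of trials (`percent`, i.e. 16 of 160).
* **Monte Carlo properties under common random numbers.** Where the
  test suite checks that mean punishment-trial skipping is monotone in
  $R_0$ (non-increasing) and $RS_{pun}$ (non-decreasing), the same 500
  simulation seeds are reused at every grid value of the swept
  parameter, so the comparison is paired and sampling noise cannot
  masquerade as non-monotonicity at feasible simulation counts.
* **Problem sizes.** The test suite fits single subjects on the desk
  grid (about 2 s per full-model fit), runs parameter recovery on 100
  uniform-phenotype subjects (Kendall $\tau_b$ between true and
  recovered values around 0.6–0.7 for $R_0$ and $LR^-$, comfortably
  above the 0.2 the soft identifiability of this family guarantees),
  and uses coarse 3-value-per-parameter lattices wherever an exhaustive
  brute-force oracle must be enumerated in R. The production-scale 21-value
  grids are available by configuration (`grid_spec("standard")`) for
  production fits.

## Limitations

* Grid estimates inherit lattice resolution; standard errors are not
  provided (the estimator is grid MLE, matching the procedure it
  implements, not a posterior).
* The $-BIC/2$ evidence bridge is an approximation; exceedance
  probabilities inherit it.
* No reaction-time model, eligibility traces, forgetting, or
  perseveration terms; no protected exceedance probabilities or
  family-level inference.
* Empirical cohort-level effect sizes from human data (condition
  differences, the dominance of the full model in a 199-subject
  cohort) are not reproduction targets at desk scale; the suite checks
  the properties that are derivable and deterministic instead.
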