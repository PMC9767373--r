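---
title: "Modelling go/no-go learning under intermittent reinforcement removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling go/no-go learning under intermittent reinforcement removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probegng)
```

## The scientific question

In instrumental learning experiments, performance is usually measured while
feedback is being delivered, which conflates what an agent has learnt with how
it expresses that knowledge. One way to separate the two is to intersperse
short *probe blocks* in which reinforcement is withheld while the agent keeps
responding. A striking observation in such designs is that performance — as
measured by the signal-detection sensitivity index d′ — *improves* when
reinforcement is removed. `probegng` implements the full computational
machinery needed to study this effect: the task, a family of
reinforcement-learning agents, the signal-detection analysis, model fitting
and comparison, and the recovery/validation harnesses — all runnable on
synthetic cohorts, so no human data is required.

The core finding the package lets you reproduce on synthetic data is that the
d′ improvement does not require any change in the *sensitivity* of choice to
learnt values. A mere reduction of a general action bias during probe blocks,
combined with a positive initialization of value estimates, is sufficient to
drive a larger drop in false alarms than in hits — and thereby an increase in
d′.

## The task

The default task is a deterministic go/no-go learning session of 588 trials:
12 stimuli (6 go, 6 no-go), each presented 49 times, in pseudo-random order
constrained so that every consecutive bin of 12 trials contains each stimulus
exactly once and no two consecutive trials repeat a stimulus. A go response to
a go stimulus earns reward (+1), a go response to a no-go stimulus earns
punishment (−1), and withholding earns nothing. Five contiguous probe blocks
of 36 trials are overlaid on the sequence; during probe trials no feedback is
delivered.

```{r schedule}
sched <- gng_schedule(seed = 1)
table(sched$block_type)
validate_schedule(sched)
```

The ordering algorithm draws one random permutation of the stimulus set per
12-trial bin and resamples a bin whenever its first stimulus would repeat the
previous bin's last — this satisfies both ordering constraints exactly with
bounded retries. The bin interpretation of "once per twelve trials" (rather
than a sliding window) is consistent with 588 = 49 × 12.

**Probe-block placement.** Where exactly the probe blocks fall is a free
design choice, and the packaged default is one reasonable stand-in: onsets at trials 72, 183, 294,
405 and 516 (0-based), i.e. equal spacing with the first onset late enough
that every probe block has a full 36-trial reinforced window both before and
after it. This guarantees the pre-probe/probe/post-probe contrast machinery is
well defined for every block. Custom onsets can be supplied via
`probe_onsets`.

## The model family

All four model variants share the same value dynamics. The value of the
displayed stimulus $i$ is updated only on reinforced trials with a go
response, by the delta rule with learning rate $\alpha$:

$$Q_{i,t+1} = Q_{i,t} + \alpha\,(r_t - Q_{i,t}),$$

where $r_t \in \{+1, -1\}$ is the outcome. On probe trials with a go response
no update occurs (no feedback is observed). On any trial without a go
response, the displayed stimulus undergoes passive forgetting with decay
$\theta \in [0,1]$:

$$Q_{i,t+1} = \theta\, Q_{i,t}.$$

All stimuli share one free initial value $Q_0$. Choices follow a biased
softmax: the probability of a go response to the displayed stimulus is

$$p_t = \frac{1}{1 + e^{-(Q_{i,t} + b_k)/\tau_k}},$$

with action bias $b$ and temperature $\tau$, where the subscript $k$ indexes
the block type (reinforced or probe). The four variants differ only in which
softmax parameters may differ between block types:

| model       | free parameters                                   | count |
|-------------|---------------------------------------------------|-------|
| baseline    | $\tau, b, Q_0, \theta$                            | 4     |
| temperature | $\tau_R, \tau_P, b, Q_0, \theta$                  | 5     |
| bias        | $\tau, b_R, b_P, Q_0, \theta$                     | 5     |
| full        | $\tau_R, \tau_P, b_R, b_P, Q_0, \theta$           | 6     |

The learning rate is never fit: under deterministic reinforcement, learning
rate and temperature are strongly anti-correlated and not jointly
identifiable, so $\alpha$ is fixed (default 0.06) and every model-selection
analysis can be repeated across a log-spaced grid of six alphas from 0.01 to
0.20 (`alpha_sweep()`, `learning_rate_sweep()`) to confirm the conclusion
does not depend on the choice.

Two notational decisions deserve a note. First, the temperature *divides* the
value term in the exponent, so larger $\tau$ means more stochastic choice.
Second, outcomes are +1 for go responses to go stimuli and −1 for go responses
to no-go stimuli, matching the task's reward rule; the package applies decay
only to the *displayed* stimulus on no-go-response trials, never to
non-displayed stimuli, and $Q_0$ is one scalar shared by all stimuli (the
per-model free-parameter counts admit only one).

## Signal-detection analysis

Hit rate (HR, go responses to go stimuli) and false-alarm rate (FAR, go
responses to no-go stimuli) in a trial window give

$$d' = z(HR) - z(FAR), \qquad c = \tfrac{1}{2}\left(z(HR) + z(FAR)\right),$$

with $z$ the standard-normal quantile. Perfect rates cannot be
probit-transformed, so exact-0 and exact-$n$ counts are corrected to
$\tfrac{1}{2n}$ and $1 - \tfrac{1}{2n}$ respectively (`corrected_rate()`);
interior counts are untouched. The correction is applied identically to HR
and FAR — FAR = 0 is common late in learning. Under this sign convention for
$c$, a lower $c$ means a reduced overall propensity to respond.

Learning curves use centred sliding windows (21 trials for d′, 5 for the
go-probability curves); edge positions without a full window are reported
missing rather than computed on a shrunken window, which keeps the curve's
lag symmetric. Probe contrasts compare each 36-trial probe block with the 36
reinforced trials immediately before (pre-probe) and after (post-probe) it;
per-participant deltas are averaged across the five blocks before group-level
one-sample t-tests (`group_test()`).

**The confound.** Windowed d′ rises during learning for purely positional
reasons: later windows contain better-trained behaviour. Any probe block is
therefore expected to beat its *pre*-probe window even if nothing about probe
trials differs mechanistically. The package demonstrates this by simulation:
agents with block-shared parameters (the baseline model) and learning enabled
show a strictly positive mean probe-minus-pre-probe Δd′. This is why model
comparison, not the SDT contrast, carries the mechanistic conclusion.

## Fitting and model comparison

`fit_session()` minimizes the session negative log-likelihood
$\mathrm{NLL} = -\sum_t \log p_t$ (where $p_t$ is the model's probability of
the response actually made) over each model's free parameters, and
`compare_models()` scores models by
$\mathrm{BIC} = 2\,\mathrm{NLL} + k \ln n$ with $k$ free parameters and
$n$ trials, summarised across participants by the median (an SEM computed as
$\mathrm{sd}/\sqrt{n}$ is reported alongside as a dispersion label).

Numerical choices:

* **Transforms.** Optimization is unconstrained (BFGS) in a transformed
  space: $\log \tau$ for positivity, $\mathrm{logit}\,\theta$ for the unit
  interval, $b$ and $Q_0$ raw. Back-transformed temperatures are clamped to
  $[10^{-12}, 10^{12}]$ so degenerate $\tau \to 0$ or $\tau \to \infty$
  optima (which arise for nearly deterministic responders) remain
  representable.
* **Starts.** Multi-start with $\log \tau \sim U[\ln 0.05, \ln 2]$,
  $b, Q_0 \sim U[-1.5, 1.5]$, $\theta \sim U[0.5, 0.999]$ (then logit). The
  default of 1000 starts is conventional for this model class; the package's own harnesses use 25–50,
  which for this likelihood reach the same optima (the suite checks that the
  best NLL is monotone non-increasing in the number of starts, and that
  nested models never fit worse than their restrictions). Start sets are
  prefix-nested under a fixed seed, so adding starts can only improve the
  fit.
* **Floors.** Per-trial probabilities are floored at $10^{-12}$ before the
  log; non-finite objective values met during line searches are replaced by a
  large penalty. Ties between starts are broken by lowest NLL, then lowest
  start index.

## The synthetic cohort

`generate_cohort()` replaces the human sample: each synthetic participant
gets true parameters drawn from a configurable population and a session
simulated with the bias model on the shared schedule. The defaults emulate
the published group statistics where printed values exist — $Q_0 \sim
N(0.37, 0.58)$ and a bias difference $b_P - b_R \sim N(-0.17, 0.12)$, both
treating the printed ± as SD — and use documented stand-ins where they do
not: $\tau$ log-normal around 0.3 (log-SD 0.2), $b_R \sim N(0.3, 0.3)$,
$\theta \sim N(0.95, 0.05)$ clipped to $[0,1]$. These stand-ins were chosen
once, to produce learning curves with the qualitative shape of the observed
behaviour (initial P(Go) around 0.65 and progressive no-go suppression), and
are not calibrated against any test outcome. The inclusion criterion mirrors
the experiment: participants must reach d′ ≥ 1 on the reinforced trials of
the second half of the session; excluded participants are retained with
`included = FALSE` so exclusion behaviour is itself testable.

What the generator does *not* emulate: reaction times, within-session
attention lapses, stimulus-specific difficulty (all greebles are exchangeable
here), the two-experiment split, and the Bayesian sequential stopping rule.
Passing tests on synthetic cohorts therefore show that the analysis machinery
is correct and that the proposed mechanism generates the observed signature —
not that human data contain no structure beyond the model.

```{r cohort, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_participants = 12, master_seed = 31),
                          sched)
cs <- contrast_summary(cohort_contrast(cohort$sessions))
group_test(cs$delta_d_prime)       # d' up in probe blocks
group_test(cs$delta_criterion_c)   # criterion down: fewer go responses
```

## Parameter recovery and what it can show

`parameter_recovery()` simulates sessions from known parameter sets, refits
them, and correlates truth with estimate per free parameter. Two correlations
are reported: pooled over every simulated dataset (each refit is one point),
and after averaging the recovered values within each generating set
(`pearson_setmean`).

The distinction matters. A single 588-trial session carries limited
information about some parameters: the softmax saturates, so for agents with
large $|Q_0|$ the likelihood is nearly flat in $Q_0$ beyond about 1, and
$\theta$ (decay, active only on no-go-response trials, with a narrow
population spread near 0.95) is estimated with noise comparable to its
population SD. Pooled single-refit correlations are therefore bounded by
single-session Fisher information and do not approach 1 at desk scale,
whereas set-mean correlations improve with the number of datasets per set —
at the reference scale of 500 refits per participant, per-participant
averaging shrinks estimation noise by a factor of ~22, which is how
correlations above 0.99 can arise. The recovery harness reports both so the
effect is visible rather than hidden. The package's default harness sizes
(60 sets × 10 datasets × 50 starts for recovery; 15 participants × 4 models ×
6 alphas for the selection sweep) were chosen as the package's own desk-scale
study conditions.

Model *recovery* (simulate from each variant, refit all four, compare by
BIC) selects the generating model for the baseline and bias variants; the
temperature and full variants are penalised for their unused or redundant
splits — consistent with the empirical finding that the temperature split is
unsupported.

## The mechanism in one picture

`mechanism_demo()` evaluates the two softmax curves (reinforced, with $b_R$;
probe, with $b_P < b_R$) over a grid of values. Their gap is the reduction in
go-probability during probe blocks. With a positive $Q_0$, no-go stimuli
travel from $Q_0$ toward −1 — through the region where the gap is large —
while go stimuli travel toward +1, where the curves converge. The integrated
gap over the no-go trajectory exceeds that over the go trajectory, which is
exactly the asymmetry (ΔFAR more negative than ΔHR) that produces the d′
increase without any change in choice sensitivity.

```{r mechanism}
p <- param_set(tau_R = 0.3, b_R = 0.3, b_P = 0.13, Q0 = 0.37, theta = 0.95)
demo <- mechanism_demo(p)
c(nogo = attr(demo, "gap_integral_nogo"), go = attr(demo, "gap_integral_go"))
```

## Known limitations

* Probe-block onsets are a packaged default, not the experiment's (unknown)
  onsets; analyses that depend on absolute probe timing inherit this choice.
* The population distributions for $\tau$, $b_R$ and $\theta$ are stand-ins;
  only $Q_0$ and $b_P - b_R$ have printed group anchors.
* Pooled recovery correlations at desk scale are information-limited (see
  above); they are not a defect of the optimizer, which the suite shows
  reaching optima at least as good as the generating truth.
* The likelihood assumes every trial yields a response category (go/no-go);
  omission handling beyond the response window is not modelled.
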