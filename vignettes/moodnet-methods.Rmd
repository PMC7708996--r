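---
title: "Modelling mood disorders in an iterated social interaction game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mood disorders in an iterated social interaction game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodnet)
```

## The model

`moodnet` simulates a society of agents playing an iterated Continuous
Prisoner's Dilemma (CPD) on a fixed social network. Four agent types are
distinguished by a single trait, the reward sensitivity $\beta$: rational
agents ($\beta = 1$), manic agents ($\beta \in (1, \beta_{\max}]$),
depressed agents ($\beta \in [0, 1)$, modelling anhedonia), and bipolar
agents, whose sensitivity is not a trait but tracks an intrinsically
oscillating mood.

One interaction between neighbours $A$ and $B$ at round $t$ proceeds as:

1. **Expectation.** $A$ recalls its memory traces about $B$ and expects
   $E_A(B)$, the mean of the cooperation levels those traces recorded.
   With nothing recalled, a cold-start expectation is used (see below).
2. **Cooperation.** $A$ cooperates at exactly its expectation,
   $c_A = E_A(B)$, and symmetrically for $B$; both levels are computed from
   pre-round state, so there is no first-mover advantage.
3. **Payoff.** The CPD payoff bilinearly interpolates the discrete matrix
   with corners $C$ (mutual cooperation), $T$ (temptation), $D$ (mutual
   defection), $S$ (sucker):
   $p_A = c_A c_B C + c_A \bar c_B S + \bar c_A c_B T + \bar c_A \bar c_B D$,
   $\bar c = 1 - c$.
4. **Emotion.** Appraisal against expectation with perceived reward scaled
   by the agent's current sensitivity:
   $\delta_A = \tanh(\beta_A^t c_B - c_A)$.
5. **Memory encoding.** The interaction is stored as a trace (counterpart,
   its cooperation level, the emotion felt) with initial strength
   $\phi_0 = -k_N\delta + c$ for $\delta \le 0$ and $k_P\delta + c$
   otherwise: emotionally charged events are encoded more strongly, and the
   gradient ratio $\xi = k_P/k_N$ models positive ($\xi>1$) or negative
   ($\xi<1$) encoding bias.
6. **Mood.** Non-bipolar agents integrate emotion leakily,
   $\nu^t = \tanh(\nu^{t-1} + \kappa(\delta - \nu^{t-1}))$; rational agents
   use $\kappa = 0$ and stay neutral.

Trace strength decays as $\phi_t = \phi_0 e^{-\theta \Delta t}$ with
$\Delta t$ measured from the last encoding *or* refresh; traces below
$\phi_{\min}$ are permanently deleted, and a successful retrieval resets
strength to $\phi_0$ (re-anchoring the clock is the only reading consistent
with decay-from-$\phi_0$ after refresh). Retrieval is mood-congruent: a
trace with stored emotion $e$ is recalled with probability
$\max(0, 1 - \gamma\,|e - \nu|)$, a triangular kernel centred on the current
mood. $\gamma = 0$ recalls everything; large $\gamma$ recalls only
mood-matching traces.

Mania and depression scale engagement as well as perception: the
participation drive $\zeta$ and the target network degree $\eta$ are both
min–max rescalings of the trait $\beta$ (rational: $\zeta = 0.5$,
$\eta = 0.5|\mathcal A|$). Bipolar mood follows
$\nu^t = \sin(\omega t) + \lambda$, clamped to $[-1, 1]$, with the offset
$\lambda \sim U[-1,1]$ fixing whether the agent is mostly manic or mostly
depressed, and $\omega$ resampled every 50 rounds from an exponential
distribution with an agent-constant mean. Current sensitivity maps from
mood continuously: $\beta^t = \nu + 1$ for $\nu<0$, $1$ at $0$, and
$1 + \nu(\beta_{\max}-1)$ for $\nu>0$.

After each interaction both participants broadcast a gist to their other
neighbours: the counterpart's cooperation level with neutral emotion,
encoded at the receiver's intercept strength. The broadcast mechanism is
deliberately minimal — reputationally useful but emotionally flat and
short-lived — and can be ablated with `broadcast = FALSE`.

## Parameters and defaults

| Parameter | Default | Meaning and rationale |
|---|---|---|
| $C,T,D,S$ | 4, 5, 1, 0 | Satisfy $T>C>D>S$ and $2C>T+D$; the textbook (5,3,1,0) violates the second condition and is rejected at load. |
| $\beta_{\max}$ | 10 | Upper sensitivity bound; manic traits sampled uniformly on $(1,10]$, depressed on $[0,1)$. |
| $\kappa$ | 0.1 (manic/depressed) | Slow mood integration; 0 for rational agents; unused for bipolar. |
| $k_N, k_P, c$ | 80, 80, 10 | Unbiased encoding with maximal strength $90 < 100$; bias presets halve one gradient ($\xi = 2$ or $1/2$). |
| $\phi_{\min}$ | 1 | Deletion threshold; a neutral trace then lives $\ln(10)/\theta$ rounds unrefreshed. |
| $\theta$ | 0.01 | Retention horizon of ~230 rounds (neutral) to ~450 (maximal) in a 2000-round run: long reputational memory with a recency effect, and an interior point of the sweep grid $\{10^{-4},\dots,10\}$. $\theta = 10^{-4}$ is effectively perfect memory (lifetime $\gg$ run length), $\theta = 10$ is no memory (lifetime $< 1$ round). |
| $\gamma$ | 1 | Log-midpoint of the sweep grid $\{10^{-2},\dots,100\}$ and the kernel width at which the triangular window spans exactly the emotion range. |
| $\pi$ | 0.25 | Depressed connection diversity; 0.25 is type-balanced under equal representation. Values implying more depressed partners than exist are rejected. |
| $\omega'$ | $U[0.01, 0.5]$ rad/round | Mean cycling rate per bipolar agent; cycles spanning ~12–600 rounds inside a 2000-round run. Resampled $\omega$ every 50 rounds. |
| cold start | `"uniform"` | See below. |

**The cold-start choice.** When retrieval returns nothing, the agent needs
an expectation out of thin air. With any *fixed* homogeneous cold-start
value $v$, cooperation is pinned at $v$ for every agent forever: every
stored trace records $v$, every mean is $v$, by induction nothing else can
ever be played, and the memory-side experiments become exact nulls. The
package therefore defaults to a fresh $U(0,1)$ draw per cold encounter,
which seeds the cooperation variance the memory machinery acts on; a fixed
value remains available (`cold_start = 0.5`) and is used in the
deterministic engine examples.

## The network generator

Degrees are targeted per agent ($\eta$ from the trait) and wired by seeded
random stub matching: each agent contributes $\eta$ stubs, stubs are
visited in random order and paired with a compatible partner chosen with
probability proportional to remaining capacity (i.e. uniformly over
partner *stubs*), subject to no self-loops, no duplicate edges, and
per-type quotas for depressed agents ($\pi$ depressed neighbours, the rest
split equally). Heterogeneous degree sequences are generally not exactly
graphical, so unpairable stubs are dropped; the builder retries the
matching a bounded number of times and keeps the attempt with the fewest
drops. Residuals are reported (`dropped_stubs`, `realized_degree`), and in
the default society mean relative degree residuals stay within 10% for
every type. The graph is static for a run.

## Scheduling and numerical choices

* One interaction per agent per round: active agents are matched (random
  visiting order, uniform choice among unmatched active neighbours).
  Unmatched active agents receive no payoff and no memory update, and idle
  moods do not drift.
* The bipolar rhythm runs on the global round clock, including rounds the
  agent sits out, and its sensitivity map is applied to the *clamped* mood
  (the map and the retrieval kernel are defined on $[-1,1]$ only).
* The positive branch of the trait-to-initial-mood map is
  $(\beta_0-1)/(\beta_{\max}-1)$, the min–max rescaling onto $(0,1]$ that
  keeps manic initial moods inside the mood domain; the depressed branch is
  $\beta_0 - 1$.
* Target degrees are rounded to the nearest integer and capped at
  $|\mathcal A| - 1$; the cap also closes the open endpoint of the degree
  map at $\beta_0 = \beta_{\max}$.
* Purging runs lazily on queried memory buckets plus a periodic global
  sweep; because deletion depends only on elapsed time, the schedules are
  result-identical.
* Retrieval draws are independent per trace per query; duplicate traces
  about the same counterpart are all kept and all enter the expectation
  mean.
* Determinism: the master seed fans out to fixed substreams (population,
  network, activity, pairing, retrieval/cold-start, rhythm); the same
  configuration and seed reproduce the event log exactly.
* The round loop is compiled (Rcpp); a pure-R reference engine
  (`engine = "reference"`) implements the identical model for small
  societies and is cross-checked against the compiled engine in the tests,
  along with exact recomputation of every logged payoff and emotion from
  the closed forms.

## What the experiments show — and what they cannot

The bundled experiments (`run_replicates()`, `run_sweep()`,
`bias_experiment()`) use the default society of 200 agents, equal type
proportions, and 2000 rounds; replicate counts are 10 for the type
comparison, 5 per point for the forgetting and bias contrasts, and 3 per
point for the mood-dependence grid, with sweeps sharing paired replicate
seeds. A full run takes a few seconds; the complete experiment battery a
few minutes.

Two structural properties of the model are worth understanding before
interpreting the outputs:

1. **Payoff contrasts between types are dominated by engagement.** Under
   matching-based pairing the dense active subgraph almost always finds a
   partner for every active agent, so interaction counts scale with drive
   ($\zeta$), and the manic/rational payoff ratio sits near
   $\zeta_{\text{manic}}/\zeta_{\text{rational}} = 1.5$; the depressed
   deficit mirrors it. Bipolar agents average the two regimes.
2. **Memory parameters couple only weakly to payoffs.** With the default
   constants $C - S - T + D = 0$, the payoff is exactly
   $p_A = 1 + 4c_B - c_A$, linear in the cooperation levels, so only shifts
   in type-mean cooperation can move mean payoffs. Mood-congruent retrieval
   shifts those means through the correlation between a trace's stored
   emotion and its stored cooperation, and that correlation saturates
   towards zero for manic agents ($\tanh(\beta c_B - c_A) \approx 1$ when
   $\beta \gg 1$) and is attenuated by $\beta$ for depressed agents. The
   forgetting, bias, and mood-dependence contrasts therefore come out
   within a few percent of zero under this model: the machinery is
   implemented and exercised, but its payoff consequences are small, and
   the tests report that honestly.

The synthetic society emulates trait heterogeneity, homophily of depressed
agents, engagement differences, and forgetful, mood-congruent memory. It
does not emulate strategy learning, reactive strategies, noise in action
execution, dynamic network rewiring, interference-based forgetting, or any
neural mechanism; passing tests say nothing about those, nor about fitting
real clinical populations.
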