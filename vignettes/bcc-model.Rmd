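---
title: "Bayesian contextual control: the model behind the simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian contextual control: the model behind the simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccsim)
```

## The model in one page

`bccsim` simulates an agent that chooses among *policies* — fixed-length
action sequences $\pi$ — and whose reaction times are a by-product of the
choice computation itself. Three ingredients combine per behavioral
episode:

1. **A goal-directed likelihood.** Each hidden *context* $c$ (a task set,
   a goal regime) owns a small Markov decision process: transition
   kernels, learnable reward-contingency pseudo counts $\varphi$, and an
   outcome preference. The predicted free energy
   $F(\pi \mid c)$ is the Kullback–Leibler divergence between the
   outcome distribution a policy is predicted to produce and the
   preferred outcome distribution, and the reward likelihood is
   $p(R \mid \pi, c) = \mathrm{softmax}(-F(\pi \mid c))$.
2. **A habit prior.** Per context, a Dirichlet count vector $\alpha$ over
   policies. Counting starts at $\alpha_{init} = 1/a$, where $a$ is the
   *automatization tendency*: with $a = 1$ each executed policy reshapes
   the prior strongly (an "automatism+value learner"); with $a = 0.001$
   counting starts at 1000 and the prior stays effectively uniform (a
   "value-only learner"). A forgetting factor $f$ contracts the counts
   toward $\alpha_{init}$ once per episode.
3. **Context inference.** The context is inferred, not observed: a cue
   model with uncertainty $\varepsilon$, a transition kernel
   parameterized by the assumed change probability $\gamma$ (stay with
   $1-\gamma$), and the likelihood of the episode's experienced outcomes
   under each context's contingencies. Action selection uses the
   pre-episode posterior (prediction $\times$ cue evidence); outcome
   evidence is folded in after the episode, and all learning updates are
   weighted by that post-episode posterior — within-trial computation
   stays causal.

The posterior over policies is proportional to the context-mixed prior
times the context-mixed likelihood. By default the sampler consumes this
*product* form (mixed prior as proposal, mixed likelihood in the
acceptance ratio); a `mixture_mode = "posterior"` switch instead targets
the mixture of per-context posteriors, because the two forms are not
algebraically identical and the main-text equations admit either
reading. The mode used is recorded on every record table.

## Reaction times from sampling

Planning is an independence Metropolis–Hastings chain: proposals are
i.i.d. draws from the prior over policies, accepted with probability
$\rho = \min\{L(\pi^\*)/L(\pi_{n-1}),\, 1\}$. The first draw starts the
chain unconditionally; if the previous sample has zero likelihood the
proposal is always accepted (this keeps the chain ergodic on the prior's
support). After every step — accepted or not — the Dirichlet pseudo count
$\eta$ of the *current chain entry* is incremented, giving an online
estimate $q(\pi) = \eta_\pi / (N_\pi + n)$ of the posterior.

Sampling stops when the differential entropy of the Dirichlet
$q(\vartheta \mid \eta)$ falls below

$$H_{thr} = H_{init} + (H_{init} - 1)\,s,$$

where $H_{init}$ is the entropy of the flat Dirichlet (all-ones $\eta$,
forced by the estimate's denominator $N_\pi + n$) and $s > 0$ is the
speed–accuracy trade-off. The $-s$ term keeps the threshold strictly
below $H_{init}$ even when the initial entropy is zero (two options).
The entropy is checked after every step; the closed form is maintained
incrementally, so a step costs $O(\log K)$. The last chain entry at
termination is executed, and

$$RT = t_{nd} + t_{sample} \cdot N_{samples}$$

with defaults $t_{sample} = 0.2$ ms and $t_{nd} = 100$ ms. A hard cap
(`max_samples`, default 200 000) guards termination; capped runs are
flagged, never silently truncated. Note that a useful $s$ depends on the
number of policies: the flat-Dirichlet entropy of 81 policies is about
$-274$, so the grid world operates around $s = 0.5$ while two-choice
tasks operate around $s = 2.5$.

Two consequences shape all simulated effects. When prior and likelihood
agree, pseudo counts concentrate quickly: fast, accurate responses. When
they conflict, the chain alternates between prior-favored and
likelihood-favored policies, concentration is slow, and responses are
slow; under tight deadlines (small $s$) the chain stops while still
dominated by prior draws, so fast conflict choices follow the habit —
the mechanism behind fast flanker errors.

## The three tasks

**Grid world.** A $4 \times 5$ grid, cells numbered bottom-up row-major;
every four-trial miniblock starts in cell 3 and one of two goals (cell
15, then cell 11 from miniblock 101) pays off at the final step. The 81
policies are all $3^4$ sequences of left/up/right; moves off the edge
leave the cell unchanged. Within a miniblock, at trial $t$ only policies
whose first $t-1$ actions match the executed history remain candidates
(a contiguous block, thanks to lexicographic ordering); their habit
counts are renormalized as the proposal. There are no cues; context
evidence comes from the experienced outcomes.

**Flanker.** Policies are single responses. Four compound stimuli: two
target identities per response, and the flanker identity acts as a
*context cue* for a left-response or right-response context. The habit
prior carries an a priori context–response association (`bias`); the
target drives a one-step MDP whose contingencies reward the correct
response (`target_strength` controls how sharp that evidence is). A
small forgetting factor re-learns the flanker–response association every
trial, which strengthens it after congruent trials and weakens it after
incongruent ones — the sequential (Gratton) modulation. Ablation flags
remove the bias, the habit updating, or the context inference; each
removal abolishes the Gratton interaction.

**Task switching.** Two task sets (contexts) over compound stimuli with
one feature per task; congruent trials are those whose two features
demand the same response. The cue uncertainty $\varepsilon$ stands in
for the cue–target interval (shorter interval = noisier cue) and the
change probability $\gamma$ for the response–stimulus interval (longer
interval = switches easier to accept). A value-only learner is used:
switch costs come from residual belief in the previous task set, which
mixes the old task's outcome rules into the likelihood.

## Default parameters and why

All defaults were fixed once, while reproducing the qualitative target
phenomena, and are exposed through `agent_config()` and the task specs.

| parameter | grid world | flanker | task switching | role |
|---|---|---|---|---|
| $a$ | 1.0 / 0.001 | 1.0 | 0.001 | automatization tendency |
| $s$ | 0.5 | 2.5 | 2.5 | speed–accuracy trade-off |
| $\varepsilon$ | — (no cues) | 0.05 | 0.05 | cue uncertainty |
| $\gamma$ | 0.01 | 0.5 | 0.1 | change probability |
| $f$ | 0 | 0.05 | 0 | forgetting |
| preference | (0.995, 0.005) | (0.99, 0.01) | (0.99, 0.01) | outcome preference |
| contingency init | 1 | (fixed rule) | 3 | learning speed |

Notes on the choices that were genuinely open:

* **Terminal preference.** Whether the outcome preference scores every
  time step or only the episode's final outcome is not determined by the
  task descriptions. We score the final step
  (`preference_mode = "terminal"`; `"per_step"` is available). With
  per-step scoring, well-explored non-rewarding cells are penalized far
  more than never-visited ones, so a trained agent's likelihood
  systematically prefers unexplored paths over its learned goal path and
  the learning curves collapse; with both goals reachable only at the
  final step, terminal scoring is the reading under which the task
  behaves as described. Outcome evidence for context inference uses the
  same step.
* **Grid-world $\gamma = 0.01$.** The change probability sets a
  permanent floor on the old context's weight. At $\gamma \gtrsim 0.05$
  that floor keeps the old goal's likelihood mixed into every choice
  while the new context absorbs the blame for failures, so the old
  context never unlearns and behavior locks onto the old goal. At
  $\gamma = 0.01$ agents detect the switch within a few miniblocks and
  recover fully, reproducing the learning-curve shapes (fast initial
  decline, plateau by ~50 miniblocks, a post-switch reaction-time spike,
  automatism+value faster and at least as accurate).
* **Preference sharpness** controls how strongly learned contingencies
  separate policies; (0.995, 0.005) gives a value-only plateau accuracy
  around 0.75 and an automatism plateau near 0.99 with paper-scale
  sample counts.
* **Flanker softness.** Fast errors require that a strongly biased trial
  can flip the posterior majority; with hard target evidence the
  goal-directed term always wins and accuracy saturates at 1. The
  frozen `target_strength = 1.75` and `bias = 3` put typical incongruent
  trials just on the correct side of the flip point, so that the
  trial-to-trial fluctuations induced by habit updates plus forgetting
  produce a minority of fast, wrong, strongly-biased trials — the
  below-chance head of the conditional accuracy function.
* **Task-switching `contingency_init = 3`.** With counts starting at 1
  even ten training trials saturate the two-by-two outcome rule, and the
  training-length effect vanishes; starting at 3 keeps rule strength
  growing across 10/20/40 training trials, as in the reference
  experiments. Sweep grids ($\varepsilon \in \{0.005, 0.04, 0.09\}$,
  $\gamma \in \{0.05, 0.2, 0.4\}$) were chosen to stay on one side of
  the cue-versus-prior balance point, where the interval effects are
  monotone; monotonicity is evaluated on switch-trial reaction times,
  the quantity the interval manipulations target.

## What the simulations do and do not show

The synthetic tasks emulate the *structure* of the behavioral paradigms:
cue-driven context uncertainty, congruency, goal switches, miniblock
episodes. They do not emulate perceptual dynamics (attention spotlights,
stimulus encoding time), motor noise, or trial-to-trial non-decision
variability; real data would add all three. Reaction-time *scales* are
therefore indicative only — effects are meaningful as orderings and
shapes, not milliseconds. Within a single input configuration and a
fixed $s$ the stopping-time distribution is narrow; the right-skewed,
log-normal-like shape characteristic of empirical data appears at the
level of task record pools, where inputs vary across trials (and across
the $s$ regimes of a demonstration panel).

The post-switch window (miniblocks 101–105) deserves a caveat: in this
reconstruction the unheralded goal switch takes about two failed
miniblocks to detect (the change probability must stay small, see
above), and during exploration a first visit to an unrewarded cell is
explained better by the well-learned old context than by the fresh one,
which transiently pulls belief back. Both effects depress success in the
five-miniblock window relative to the published account, while all the
orderings (automatism worse than value-only right after the switch,
spike, full recovery) reproduce.

## Numerical choices

Normalization checks use a tolerance of $10^{-10}$. The softmax uses
max-subtraction. The Dirichlet entropy is computed in closed form
(`lgamma`/`digamma`) and updated incrementally inside the compiled
sampler; a pure-R reference engine consumes the identical random stream
and is asserted equal in the tests. Proposals use inverse-CDF lookup on
the prior's cumulative sums. Zero-probability policies are never
proposed and keep their initial pseudo count. Reproducibility: every
experiment derives one RNG substream per agent from
`(master_seed, agent_index)`, so results are byte-identical for a given
seed and unchanged for existing agents when more agents are added.

## Problem sizes used in the checks

The packaged checks run 50 agents per learner type through the full
200-miniblock grid world, 50 agents through 400 flanker trials (plus the
three ablations), 50 agents per task-switching condition, 500 sampler
runs per input regime and speed–accuracy setting, and 200 runs per $s$
for the chain-similarity curves. These sizes match the published agent
counts while keeping a full check run in the minutes range.
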