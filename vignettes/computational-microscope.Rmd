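---
title: "A computational microscope for planning strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A computational microscope for planning strategies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planscope)
```

planscope infers, trial by trial, which planning strategy a person used in a
Mouselab-MDP process-tracing experiment. This vignette is the package's own
account of the underlying models: what is assumed, which knobs matter, how
the numerics are handled, and what the shipped simulations do and do not
show about real data.

## The task model

A Mouselab-MDP trial presents a rooted out-tree of locations whose rewards
are hidden. The participant may pay a fee (default $1) to click any
non-start node and reveal its reward, in any order, and then commits to one
start-to-leaf path; the score is the sum of rewards along that path minus
the click fees. The set of revealed rewards at any moment is the *belief
state*; every click is treated as one observable planning operation.

Four preset environments are built in. The three-step presets share one
layout — three first moves, a forced second move, and a binary final choice
(13 nodes, 6 paths) — and differ in where reward variance sits:
*increasing* (\{−4,−2,+2,+4\}, \{−8,−4,+4,+8\}, \{−48,−24,+24,+48\} at
depths 1–3), *decreasing* (the mirror image), and *constant*
(\{−10,−5,+5,+10\} everywhere). The five-step preset keeps the three-branch
trunk, splits binarily at the last two steps, and draws rewards from
zero-mean normals with sd 1, 2, 4, 8, 32 at depths 1–5. The exact branching
of larger environments is not canonical, so the constructor accepts any
custom rooted tree plus a per-depth reward model; the trunk-with-terminal-
splits default was chosen as the smallest tree that preserves the
"long-term outcomes matter most" structure at depth 5. Normal rewards are
discretised with 15-point Gauss–Hermite quadrature wherever an expectation
over a single reward is needed (value-of-information features); this is
exact for the polynomial parts and accurate to ~1e-10 for the maxima
involved.

## Strategies as stochastic click policies

A planning strategy is a procedure mapping a belief state to a probability
distribution over the available actions: the unclicked nodes plus the
decision to stop and act (`TERMINATE`). Strategies spread probability
uniformly over all clicks they treat as functionally equivalent at the
current step — a breadth-first searcher starting a trial is equally likely
to inspect any of the three immediate outcomes.

The built-in library has 16 strategies covering the behaviours the
literature names: no planning; uniform random clicking (termination is a
member of its choice set, so a fresh three-step belief gives probability
1/13 to each of the 13 actions); myopic inspection of immediate outcomes,
exhaustive and satisficing; breadth-first search; satisficing depth-first
search; best-first search in terminating, non-terminating, and
after-an-immediate-sweep variants; goal-setting strategies (satisficing
random search over final outcomes, maximizing goal-setting with limited
backward planning, exhaustive backward planning, frugal goal-setting, and
a consecutive-second-maximum stopping variant); local search around already
observed nodes; and middle-out planning. The registry accepts user-defined
strategies so the library can be extended toward a larger catalogue.

Satisficing rules use an aspiration level of $48 where the environment can
pay that much on a single path, and the environment's maximum path value
otherwise (the constant-variance preset tops out at $30). Because belief
states — not click histories — drive every policy, stopping rules are
formulated on the belief (e.g. "two observed final outcomes at or above the
second-highest possible value" rather than "two consecutive such clicks").
The simulator completes each trial by choosing the path with the highest
expected value under the final belief, breaking ties uniformly; path choice
is not part of the inference model, which conditions on clicks only.

## The observation model

Each strategy's click behaviour is summarised by a softmax over a bank of
29 features of the (belief, action) pair:

$$P(d_t \mid S) = \prod_i
  \frac{\exp\!\big(\tfrac{1}{\tau}\, w^{(S)}\!\cdot f(c_{t,i}, b_{t,i})\big)}
       {\sum_{c \in \mathcal{C}_b} \exp\!\big(\tfrac{1}{\tau}\, w^{(S)}\!\cdot f(c, b_{t,i})\big)}$$

where the product runs over the trial's actions including the terminal
stop, and the normalisation runs over every available action. Features are
raw (unstandardised); the weights absorb scale, so fitted weights are
interpretable only jointly with the feature manifest. Click-specific
features are zero on the termination row and stopping features are zero on
click rows, keeping a single shared vector space.

Each feature belongs to exactly one of five decision-system categories —
Pavlovian (attraction and repulsion by rewards observed on the node's own
paths), model-free values and heuristics (structural and relational
regularities such as depth, frontier membership, or proximity to observed
nodes), model-based metareasoning (myopic value of information and reward
uncertainty), mental-effort avoidance (the termination indicator, plus the
number of clicks already invested at the moment of stopping), and
satisficing/stopping criteria (aspiration satisfaction, the value of the
best known path, completion indicators). Each feature carries a sign saying
whether larger values reflect more or less influence of its system; the
loss-repulsion features are the negatively signed ones.

Weights are fitted once per strategy at $\tau = 1$ by maximum likelihood on
trials simulated from the strategy's generative policy (400 per strategy by
default, enough to cover rare belief states such as uniformly bad final
outcomes). At fixed temperature this is a convex multinomial-logit problem;
we solve it with BFGS on the penalised negative log-likelihood, with an L2
ridge of 1e-4 for identifiability of collinear features, all evaluations in
log-space. The inference-time $\tau$ then rescales all strategies'
propensities jointly, which matches treating the temperature as a single
inference hyperparameter rather than a per-strategy parameter; whether
weights should instead be fitted jointly with $\tau$ is underdetermined,
and the $\tau = 1$ convention keeps the fit convex.

## Sequence inference

The trial-by-trial strategy sequence is modelled as a hidden Markov chain:
uniform initial distribution over strategies, and an *abrupt* transition
prior under which the previous strategy is repeated with probability
$p_\text{stay}$ and otherwise replaced by a uniformly random different
strategy. The joint model is

$$P(\mathbf{d}, S_1,\dots,S_T) = \frac{1}{|\mathcal{S}|}
  \prod_{t=2}^{T} P(S_t \mid S_{t-1})\, P(d_t \mid S_t).$$

The MAP sequence is computed by the Viterbi algorithm in log-space
($O(T|\mathcal{S}|^2)$; no underflow for any realistic $T$). Ties are
broken toward the lowest strategy id at every backtrack step so that
decoding is deterministic and testable against exhaustive enumeration.

Hyperparameters are fitted per participant (a shared mode exists for
pooled fitting): $p_\text{stay}$ by grid search over \{0, 0.02, …, 1\}
(ties resolve to the smallest value, so a single-trial dataset yields 0),
and $\tau$ by a derivative-free search over $[10^{-2}, 10^2]$ on the log
scale with a 50-evaluation budget — a coarse log-grid scan followed by
golden-section refinement around the best point. The objective for both is
the joint log-probability of the MAP sequence. A global Bayesian optimiser
would also do; the deterministic scan was chosen because the objective is
one-dimensional and piecewise smooth, and determinism makes runs exactly
reproducible. The fitting schedule alternates once — $\tau$ at
$p_\text{stay} = 0.5$, then $p_\text{stay}$, then $\tau$ again — a choice
that is not canonical but stable in practice because the two parameters
interact weakly.

A *gradual* transition prior is available as a documented stand-in variant
for model comparison: transition probability proportional to
$\exp(-\Delta(s_i, s_j)/\beta)$ with $\Delta$ the strategy distance below.
`compare_priors()` ranks priors by AIC/BIC computed from the MAP-sequence
log-likelihood with the number of fitted hyperparameters as the parameter
count and the number of trials as $n$. Forward–backward posterior
smoothing and hierarchical group priors are deliberately out of scope; the
method reports MAP sequences only.

## Strategy space structure

Pairwise strategy distances are symmetrised Kullback–Leibler divergences
between the distributions of full trials (clicks plus termination, jointly
with the sampled ground truth) induced by the fitted softmax models at
$\tau = 1$, estimated by Monte-Carlo integration. Each direction averages
the log-likelihood ratio over trials sampled from one strategy's own model,
so the diagonal is exactly zero and the matrix exactly symmetric by
construction; negative finite-sample estimates are clamped at zero with a
logged count. Whether belief states should enter the divergence separately
from the click sequence that determines them is ambiguous; we sample
(ground truth, click sequence) jointly. Ward's method (`ward.D2`) on these
distances groups strategies into types. The built-in set ships with a
curated type label per strategy; the canonical 13-type grouping emerged
from a much larger catalogue and is not reproducible from 16 strategies,
so the cluster count is a parameter rather than a constant.

The relative influence of decision system $ds$ on a strategy is
$\text{RI}_{ds} = |w_{ds}| / \sum_{ds'} |w_{ds'}|$ where $w_{ds}$ sums the
strategy's signed weights over the system's features. Profiles are
non-negative and sum to one; an all-zero weight vector (which cannot occur
for fitted strategies) returns a uniform profile with a warning.

## Synthetic data and what the validations show

The validation module generates participants whose ground-truth strategy
sequences come from three generative models — independent uniform draws per
trial, abrupt Markov switching (default $p_\text{stay} = 0.8$), and
gradual drift through strategy space (Gaussian kernel over the distance
matrix, bandwidth defaulting to half the median off-diagonal distance) —
and whose clicks are sampled from the fitted softmax models at generation
temperature 1. These defaults are the study conditions the package
documents: 50 participants × 31 trials per generator for the recovery
experiment (a desk-scale version of the original 500-per-generator
design), with sequence length equal to the strategy count for the monotone
trend designs and 12–50 sequences per trend cell.

Recovery is scored as the fraction of trials whose MAP strategy (or its
type label) equals the generating one; the full pipeline including
hyperparameter fitting runs on every simulated participant. Trend recovery
constructs sequences whose relative influence of one decision system
increases, decreases, or stays constant (percentile-group sampling for the
constant case) and summarises the inferred influence curve by the Spearman
correlation with trial number; the package calls a constant trend
recovered when the mean correlation is within ±0.2.

Two caveats bound what these simulations show. First, clicks are generated
from the same observation model used for inference, so recovery accuracy
measures the separability of the strategy models and the correctness of
the decoding machinery — not how faithfully the softmax family captures
human execution noise. Second, human data contain strategies outside any
finite library, within-trial strategy mixtures, and timing structure that
the model ignores; passing these validations therefore supports the
inference machinery, not the completeness of the strategy catalogue.

## Numerical and degenerate-input conventions

All likelihood computation is in log-space with grouped log-sum-exp.
Zero-click trials contribute their single termination term. A single-trial
inference reduces to a per-trial argmax (the uniform initial prior
cancels). `p_stay` values of exactly 0 or 1 produce −Inf transition terms
that Viterbi handles exactly. Every stochastic function takes a seed and
derives per-unit sub-seeds with a Lehmer-style map kept inside 32-bit
range, so datasets, fits, and experiments are bit-reproducible. Output
tables are stamped with hashes of the feature and strategy manifests to
prevent silent drift between weight vectors and their orderings.

## Worked example

```{r example, eval = FALSE}
env <- build_environment("increasing_variance_3step")
strategies <- default_strategies()
obs_model <- fit_observation_model(strategies, env, n_sim = 400, seed = 1)

sim <- generate_participants("abrupt_markov", obs_model, env,
                             n = 5, n_trials = 31, seed = 7)
results <- infer_dataset(sim$dataset, obs_model, env)
results[[1]]

tc <- time_course(results, level = "type")
ri <- time_course(results, level = "influence", obs_model = obs_model)

report <- recovery_experiment(obs_model, env, n_per_generator = 50,
                              n_trials = 31, seed = 1)
report
```

The chunk is not evaluated while building the vignette because the
recovery experiment takes a couple of minutes; `scripts/acceptance.R` runs
exactly this computation end to end and writes the resulting accuracies to
JSON.
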