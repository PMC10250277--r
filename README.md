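# planscope

A computational microscope for planning strategies: model-based inference
of *which planning strategy a person used on each trial* of a Mouselab-MDP
process-tracing experiment, for cognitive scientists studying planning,
metacognitive learning, and cognitive plasticity.

In the Mouselab-MDP paradigm a participant plans a route through a tree of
hidden rewards, paying a small fee to reveal one node at a time before
committing to a path. The ordered clicks externalise planning operations.
planscope turns those click sequences into trial-by-trial measurements at
four levels: individual planning operations, planning strategies, strategy
types, and the relative influence of five decision systems (Pavlovian,
model-free values & heuristics, model-based metareasoning, mental-effort
avoidance, satisficing & stopping).

## The model

Each strategy $S$ is a stochastic click policy represented by a weight
vector $w^{(S)}$ over a bank of belief-state features $f(c, b)$; the
probability of a click sequence $d_t$ is a softmax over the available
actions (clicks and termination):

$$P(d_t \mid S) = \prod_i
  \frac{\exp\big(\tfrac{1}{\tau} w^{(S)} \cdot f(c_{t,i}, b_{t,i})\big)}
       {\sum_{c \in \mathcal{C}_b} \exp\big(\tfrac{1}{\tau} w^{(S)} \cdot f(c, b_{t,i})\big)}.$$

The trial-by-trial strategy sequence $S_1,\dots,S_T$ is a hidden Markov
chain with uniform initial distribution and a sticky "abrupt-switch"
transition prior,

$$P(S_{t+1}=s \mid S_t) = p_\text{stay}\,\mathbb{I}(s = S_t) +
  (1-p_\text{stay})\,\frac{\mathbb{I}(s \neq S_t)}{|\mathcal{S}|-1},$$

and the MAP sequence is decoded with the Viterbi algorithm;
$p_\text{stay}$ is fitted by grid search (resolution 0.02) and $\tau$ by a
50-evaluation derivative-free search, both maximising the joint
probability of the MAP sequence. Strategies are grouped into types by Ward
clustering on symmetrised-KL distances between their click-sequence
distributions, and each strategy's signed feature weights decompose into
the relative influence of the five decision systems.

## Worked example

```r
library(planscope)

env <- build_environment("increasing_variance_3step")
strategies <- default_strategies()          # 16 built-in click policies
obs_model <- fit_observation_model(strategies, env, n_sim = 400, seed = 1)

# simulate 5 participants whose strategies switch abruptly across 31 trials
sim <- generate_participants("abrupt_markov", obs_model, env,
                             n = 5, n_trials = 31, seed = 7)
results <- infer_dataset(sim$dataset, obs_model, env)
results[[1]]
#> MAP strategy sequence over 31 trials (p_stay = 0.70, tau = 1.6, log P = -289.88)
#>   2 2 5 5 5 15 15 4 4 4 4 4 4 4 2 12 16 16 16 16 16 2 15 15 15 15 15 15 15 10 10

mean(results[[1]]$sequence == sim$sequences[1, ])
#> [1] 1
```

The printed line is one participant's inferred trajectory: the fitted
stickiness (`p_stay`), the softmax noise level (`tau`), and the MAP
strategy id for each trial — here the participant is decoded as moving
from random clicking (2) through breadth-first search (5), local search
(15), satisficing myopic inspection (4), exhaustive backward planning
(12), and middle-out planning (16) to satisficing goal-setting (10),
matching all 31 generating strategies. `time_course()` aggregates such results into
per-trial strategy/type frequencies or decision-system influence curves,
and `write_results()` exports tables stamped with the feature- and
strategy-manifest hashes.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/microscope.R simulate --generator abrupt_markov --n 10 --seed 1 --out data.json
Rscript inst/cli/microscope.R infer --dataset data.json --out results
Rscript inst/cli/microscope.R analyze --results results.json --level type --out analysis
Rscript inst/cli/microscope.R validate --mode recovery --out recovery.json
```

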