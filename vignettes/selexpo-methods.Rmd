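---
title: "Methods: opinion dynamics with selective exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: opinion dynamics with selective exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexpo)
```

## The model

A group of $n$ agents must judge an unknown state of nature. Each agent $i$
starts with an i.i.d. opinion $x_i$ and observes a fixed-size pool of $k$
information sources $G(i)$, drawn uniformly at random and independently of
opinions. The communication network is therefore a directed graph with fixed
in-degree $k$ and binomially distributed out-degree; an edge $j \to i$ means
"information flows from $j$ to $i$" ($j \in G(i)$).

Each round, the agents act once each, in a fresh uniformly random order. An
acting agent tries to reduce its *discrepancy*
$\sum_{j \in G(i)} |x_i - x_j|$ in one of two ways:

* **Naive learning** (probability $1-\beta$): adopt the opinion minimizing
  the discrepancy, i.e. the *median* of the source opinions. For binary
  opinions encoded 1/0 with odd $k$ this is exactly the majority of the
  sources, which is why one update rule serves all four models.
* **Selective exposure** (probability $\beta$): drop the source whose
  opinion differs most from one's own (ties broken uniformly at random) and
  reconnect to a uniformly chosen non-source agent whose opinion is
  *strictly* closer than the dropped source's. Opinions never change.

The propensity $\beta \in [0,1]$ is the single behavioural dial: $\beta = 0$
is pure social learning (the group converges toward a consensus, destroying
opinion diversity), $\beta = 1$ is pure rewiring (opinions are frozen; the
network fragments into like-minded clusters, preserving diversity globally).

A run is *steady* when no drawable action can change anything: every agent's
opinion equals its source median (relevant when $\beta < 1$) and no agent has
a strictly-closer non-source than its worst source (relevant when
$\beta > 0$). Because the replacement-candidate set depends only on the
*value* of the maximal discrepancy, this fixed-point condition does not
depend on how ties among most-discrepant sources are broken. We adopt the
fixed-point condition rather than "no observed change for some rounds"
precisely because it is tie-breaking-robust; the two agree on every converged
run we have inspected.

## The four opinion models

`make_model_spec()` builds the study conditions; its defaults *are* the
experimental settings and are not meant to be tuned per analysis:

| model | $n$ | initial opinions | true state | aggregation | null SE $\sigma_{\bar x}$ |
|---|---|---|---|---|---|
| `condorcet` | 101 | Bernoulli$(p = .55)$ | True | majority | — (categorical) |
| `galton` | 100 | $N(0, 1)$ | 0 | mean | $0.1$ |
| `bimodal` | 100 | $\tfrac12 N(-2,1) + \tfrac12 N(2,1)$ | 0 | mean | $\sqrt{0.05} \approx 0.224$ |
| `exponential` | 101 | Exp$(\lambda = 1)$ | $\ln 2 \approx 0.6931$ | median | $0.1$ |

The bimodal variance follows the law of total variance,
$\sigma^2 = \sum_j q(\mu_j - \mu)^2 + \sum_j q\sigma_j^2 = 4 + 1 = 5$. The
exponential model aggregates by the median (robust under skew), so its null
standard error comes from the sample-median asymptotics
$\mathrm{Var}[\tilde x] \approx 1/(8 f(\tilde\mu)^2 m)$ with $m = (n-1)/2$:
$1/(8 \cdot (1/2)^2 \cdot 50) = 0.01$. Group sizes are odd wherever a median
or majority needs a unique middle element.

A decision is **good** when it is True (condorcet) or lies *strictly* within
two null standard errors of the true state,
$|x - \mu| < 2\sigma_{\bar x}$. The same standardized band is applied to
individual opinions and to the collective decision — including in the
exponential model, where we read the individual-good definition as using the
one $\sigma_{\bar x}$ the model defines. Standardizing by $\sigma_{\bar x}$
makes performance comparable across models and group sizes; without
influence, a collective decision is good with probability
$2\Phi(2) - 1 \approx 0.954$ in every continuous model, and with the exact
binomial tail probability $P(Y > n/2) = 0.844$ in the jury model.

```{r nulls}
condorcet_group_probability(101, 0.55)
aggregation_null(make_model_spec("exponential"))
```

## Measures

`summarize_state()` computes per run: individual performance $p_i$ (good
fraction of agents), the collective decision and its good flag, opinion
diversity $\sigma_x$ (the *population* standard deviation — the group is the
whole population, not a sample), the giant strongly connected component
fraction $|C_1|$, and modularity over the opinion dichotomy
(True/False, or above/below the true state with ties below).

Two modularity variants are reported. The default `newman_directed` is the
standard directed form
$\sum_d [L_d/m - k_d^{in} k_d^{out}/m^2]$, bounded in $[-1, 1]$. The `paper`
variant, $\sum_d [L_d/m - (k_d^{in} k_d^{out}/2m)^2]$, mixes undirected and
directed degree conventions and is unbounded below (a single-category
partition of a 10-edge graph scores $-24$); it is kept for transparency but
cannot be the quantity shown on a $[0, \tfrac12]$ modularity axis, so
summaries and plots should use the directed Newman form.

On $|C_1|$: with sources drawn uniformly, the expected number of agents whom
nobody observes is $n(1 - k/(n-1))^{n-1} \approx 0.6$ at $n = 101$, $k = 5$,
so roughly 45% of initial graphs are *not* spanned by one strongly connected
component, while the *mean* spanned fraction is
$1 - 0.598/101 \approx 0.994$. The per-$\beta$ summaries therefore report the
mean giant-SCC fraction across runs, which is the quantity that is stable and
comparable across conditions; the spanning *probability* is a different and
much smaller number under this graph model.

## Reproducibility and the sweep harness

All randomness flows through R's global RNG. `run_simulation(seed = s)` is
bit-reproducible, and the sweep harness derives one seed per replicate from a
single root seed via
`derive_seed(root, cell, rep) = (48271·root + 69621·cell + 16807·rep) mod (2^31 - 19)`,
so any cell or single replicate can be re-run in isolation. The compiled
round loop consumes the same seeded stream; a pure-R reference engine
(`engine = "r"`) implements the identical dynamics through the exported
per-action functions. The two engines draw random numbers in different
orders, so they are not sample-path identical, but each is deterministic and
both must satisfy the same fixed-point and conservation properties, which is
how they cross-validate each other in the test suite.

Default problem sizes: the full design uses a 51-point $\beta$ grid with
30,000 replicates per point; the package default is 2,000 replicates per
cell (`experiment_config(reps_per_beta = 2000)`), which puts a binomial
standard error of about $0.01$ on collective-performance fractions — tight
enough to resolve every effect discussed here. The full grid remains
available by raising `reps_per_beta` and widening `beta_grid`.

```{r sweep}
cfg <- experiment_config("condorcet", beta_grid = c(0, 1),
                         reps_per_beta = 200, root_seed = 1)
run_sweep(cfg)$aggregates[, c("beta", "mean_individual_performance",
                              "collective_performance",
                              "mean_opinion_diversity",
                              "mean_giant_scc_fraction")]
```

## Numerical and design choices

* **Sequential (asynchronous) updating.** Agents act one at a time in a
  fresh random permutation, each seeing earlier same-round updates. This
  matches acting "in a random order" and avoids the two-cycles that
  synchronous median updating can enter.
* **Action draw every round.** An agent draws its Bernoulli($\beta$) action
  whether or not the action turns out to be a no-op; no-ops count as "no
  change" for steadiness. An agent that draws selective exposure and finds
  an empty candidate set keeps its edge and does *not* fall back to
  learning.
* **Strict inequalities.** "More congruent" is strict, and the good-decision
  band is open ($|x - \mu| < 2\sigma_{\bar x}$): a decision exactly on the
  boundary is not good.
* **Even-$k$ medians.** Any point between the two central order statistics
  minimizes absolute deviation; we return their midpoint (deterministic,
  symmetric). The default $k = 5$ never exercises this branch, but $k$ is
  configurable.
* **Round cap.** `max_rounds = 1000` with an explicit `converged` flag and a
  warning; no run at the default settings has ever hit it (steady states
  arrive within a few dozen rounds).
* **Binary opinions as 0/1 reals.** $|x_i - x_j| \in \{0, 1\}$, so "most
  discrepant" is a uniformly random disagreeing source and the candidate set
  is all agreeing non-sources — the binary specialization of the general
  rule, not a separate rule.
* **Scale-free topology.** The alternative initial topology with fixed
  in-degree and heavy-tailed out-degree is generated by preferential
  attachment on current out-degree + 1. It is a synthetic stand-in intended
  for robustness checks, documented as such; `regular` is the deterministic
  directed circulant.

## What the generator does and does not emulate

The synthetic initial conditions realize the idealized study design:
independent opinions, uniformly random wiring, homogeneous competence, one
behavioural parameter. Real groups violate most of this — opinions are
correlated before anyone interacts, attention is not uniformly random,
competence and connectivity are heterogeneous, and opinions may keep moving
*after* rewiring (reinforcement). Passing tests therefore demonstrate the
internal logic of the mechanism — that selective exposure preserves opinion
diversity and thereby collective accuracy at the cost of fragmentation,
while naive learning improves individuals but degrades the collective — not
a calibrated prediction for any empirical group.

## Known limitations

* The exponential null is asymptotic: at $n = 101$ the exact mean of the
  sample median is $\sum_{i=51}^{101} 1/i \approx 0.698$, a $+0.005$ bias
  relative to $\ln 2$ that is visible at $10^4$ replicates. Tests compare
  simulations against the exact order-statistic moments and separately check
  that the asymptotic null is within that bias.
* Steady-state detection is $O(n^2)$ per round per run; fine at
  $n \le 401$, the largest size considered, but the engine is not tuned for
  $n \gg 10^3$.
* Only the four named opinion models are supported; the spec mechanism is
  not a general distribution plug-in.
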