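---
title: "cisnet: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cisnet: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisnet)
```

# The model

`cisnet` simulates the evolution of a small gene regulatory network
whose wiring is carried by explicit promoter DNA. It combines three
layers.

## Binding landscapes

Each of the $n$ transcription factors (TFs) has a binding score
$\varepsilon_x$ for every 8-mer $x$ (all $4^8 = 65{,}536$ of them;
lower $\varepsilon$ = stronger binding). Scores are referenced to the
consensus site:

$$\varepsilon'_x \;=\;
\frac{\varepsilon_{\min} - \varepsilon_x}
     {\varepsilon_{\min} - \varepsilon_{\max}} \in [0,1],$$

where $\varepsilon_{\max}$ is the (numerically lowest) consensus score
and $\varepsilon_{\min}$ the worst score, so the consensus maps to 1.
Binders are the 8-mers with $\varepsilon'_x \ge \varepsilon'_{opt}$,
with $\varepsilon'_{opt} = 0.209$ fixed. On the binder set the
specificity is

$$\kappa_x = e^{\lambda(\varepsilon'_x - 1)},\qquad
\lambda = \frac{\ln\gamma}{\varepsilon'_{opt}-1},$$

so $\kappa = 1$ at the consensus and $\kappa = \gamma$ at the weakest
binder; everything below the threshold has $\kappa = 0$. The jump from
$\gamma$ to 0 is the *specificity gap*: it models the discrete
discrimination between specific and non-specific binding (e.g. induced
conformational change on binding). $\gamma$ and $\lambda$ are not free
independently — they are linked through $\varepsilon'_{opt}$, so
choosing $\gamma \in \{0.05, 0.10, 0.20\}$ fixes the slope. Because the
binder set depends only on $\varepsilon'_{opt}$, it is identical across
$\gamma$ values, which the test suite checks.

### The synthetic landscape generator

Real landscapes in this model family come from structure-based scoring
of TF–DNA complexes. `cisnet` replaces that pipeline with a calibrated
synthetic generator ([generate_raw_landscape()]): scores are drawn from
an additive position-energy matrix (8 positions × 4 bases, deviations
with spread `additive_sd`) plus optional pairwise epistatic terms
(`epistasis_weight`), and finally passed through a monotone
piecewise-linear rescaling so that after normalization *exactly*
`n_binders` 8-mers clear the threshold. The knot of the rescaling is
placed halfway between the `n_binders`-th and the next-best normalized
score, so the binder count is floating-point-safe.

Two properties of real landscapes matter downstream and are emulated:

* a Boltzmann-like score distribution — only a small tail of the
  65,536 8-mers binds appreciably;
* correlated mutational neighbourhoods — because the model is (mostly)
  additive, strong sites tend to have strong single-point mutants, so
  binding-site conservation increases with $\kappa$. A purely i.i.d.
  assignment of scores to 8-mers would destroy this structure, and with
  it every conservation statistic. The suite verifies the positive
  rank correlation between $\kappa$ and conservation on an additive
  landscape.

Defaults: 10 TFs, per-TF binder counts drawn log-uniformly from
[60, 900] (the empirically calibrated per-factor range of mammalian
TFs; reported panels are heterogeneous across factors, so a log-uniform
draw is used rather than a fixed count), `additive_sd = 1` (pure scale
choice; only $\varepsilon'$ matters downstream), `epistasis_weight =
0.2` (mild non-additivity; position-weight-matrix additivity is known
to be only approximate).

## Expression dynamics

Genotypes are $n$ upstream regulatory regions (URRs) of length $L$
(50–300 bp), plus a fixed activator/repressor sign $v_j \in \{\pm 1\}$
per gene and a fixed binary initial state. All $L-7$ overlapping 8-mer
windows of URR $i$ are scanned against each factor $j$'s table (forward
strand only), and

$$w_{ij} = \sum_{\text{sites of } j \text{ in URR } i} \kappa_x .$$

Expression follows the discrete-time sigmoid map

$$s_i(t+1) = \sigma_\alpha\!\Big(\sum_j v_j\, w_{ij}\, s_j(t)\Big),
\qquad \sigma_\alpha(u) = \frac{1}{1+e^{-\alpha u}},$$

with $\alpha = 20$. From iteration $\tau = 10$ onward a variance-like
measure over the last $\tau$ states,
$V = \tfrac1\tau \sum_{t'} D(s(t'), \bar s)^2$, is evaluated; the
system is *stable* when $V < 10^{-4}$, with phenotype $\bar s$ (the
window mean). Individuals not stable within 100 iterations are
unviable. $D$ is the root-mean-square distance
$D(a,b) = \sqrt{\tfrac1n\sum_i (a_i-b_i)^2}$, normalized by $n$ so that
$D \in [0,1]$ and the selection strength $\sigma$ is scale-free in the
number of genes (the plain-Euclidean alternative differs only by the
constant $\sqrt n$, which would rescale $\sigma$).

There is no basal expression term: a gene with no input sits at
$\sigma(0) = 0.5$.

## Population model

A random viable *founder* defines the optimal phenotype
$s_{opt}$ and is cloned to $M = 500$ individuals. Each generation,
parent pairs are drawn uniformly with replacement; the offspring
inherits each URR from one parent with probability 1/2 (no
recombination *within* URRs); every base then mutates independently
with probability 0.01 (1 mutation per 100 bp of genome in expectation);
the offspring is developed and accepted with probability equal to its
fitness

$$F = \begin{cases} e^{-D(\bar s,\, s_{opt})/\sigma} & \text{stable} \\
0 & \text{unstable,} \end{cases}$$

until $M$ offspring are accepted ($\sigma = 0.001$: strong stabilizing
selection). Generations do not overlap. The accept-with-probability-$F$
operator is the standard choice for this model family (valid because
$F \le 1$); the per-base Bernoulli mutation model treats the "per
genome" rate as an expectation, which keeps offspring independent.

# The measurement suite

**Robustness.** Each individual receives `n_mut = 100` uniform random
single point mutations; each mutant is redeveloped and the phenotype
distance to the unperturbed phenotype recorded. Robustness is the mean
distance over *stable* mutants; unstable mutants (~1–3 % of probes) are
excluded from the mean and tracked as a separate fraction, because
their distances are quasi-random and uninformative.

**Event classification.** A point mutation is classified by diffing the
site annotations of the affected URR (only the ≤ 8 windows overlapping
the mutated base can change): site lost = deletion (*unique* if the
(gene, TF) input disappears, else *redundant*); site gained = creation
(*unique* if the input is new); site persisting with possibly changed
$\kappa$ = *preserved*; no change = *silent* (its phenotypic effect is
exactly 0 by construction); two or more elementary changes =
*combined*.

**Decomposition.** With $g_i$ the stable-normalized event frequencies
and $e_i$ the mean effects, robustness is $\sum_i e_i g_i$. Comparing
endpoints, the observed change is
$\rho_i = e_i^{0} g_i^{0} - e_i^{F} g_i^{F}$ and the
constant-frequency counterfactual
$\rho'_i = (e_i^{0} - e_i^{F})\, g_i^{0}$. The contribution of the
silent-frequency shift is
$CS = \sum_{i:\Delta g_i < 0} (\rho_i - \rho'_i) \,/\, \sum_i \rho_i$;
$1 - CS$ is the "other contributions" share. Since both $g$ vectors sum
to 1, $\sum_i \Delta g_i = 0$ exactly (tested). If every frequency is
unchanged, $\rho = \rho'$ and $CS = 0$; if nothing changed at all the
decomposition is undefined and an error is raised.

**Conservation, avoidance, de novo propensity.** TFBS conservation of a
site is the fraction of its 24 single-point mutants that remain binders
for the same factor. TFBS avoidance is the silent-event frequency
divided by the TFBS-free genome fraction (footprints of all sites
unioned per gene; a window bound by two TFs counts once in the
footprint union). De novo propensity averages, over all fully
TFBS-free windows, the fraction of their 24 mutants that bind any
factor.

**Rewiring.** $\Phi = 1 - |N_F \cap N_I| / |N_F \cup N_I|$ over the
nonzero patterns of two interaction matrices (Jaccard complement: 0 for
identical patterns, 1 for disjoint ones, symmetric; two empty networks
give 0 by convention). Because dense random networks share connections
by chance, a baseline line $\Phi_{rand} = a + b\,c$ is fitted on pairs
of unrelated random viable individuals across a connectivity grid, and
$\Phi_{corr} = (\Phi - \Phi_{rand})/(1 - \Phi_{rand})$, clipped to
[0, 1], so chance-level rewiring maps to 0 and total rewiring stays 1.

**Connectivity matching.** Both the $\Phi$ baseline and the redundancy
correction need random genotypes "at the same connectivity". Rather
than stochastic search over $L$, `cisnet` inverts the exact expectation
$\mathbb E[c](L) = \frac1n\sum_j \big(1-(1-p_j)^{L-7}\big)$ with
$p_j$ = binder fraction of factor $j$, by bisection; this is monotone
in $L$ and deterministic.

# Numerical and design choices

* **Indexing.** 8-mers are integers 1…65536 (base-4, A<C<G<T), so
  lexicographic and numeric order agree; consensus ties are broken by
  lexicographic order (determinism).
* **Coordinates.** 0-based site offsets, half-open windows
  $[o, o+8)$; forward strand only — reverse-complement scanning is not
  part of this model.
* **Exactness at the threshold.** The calibration knot halfway between
  the last binder and the first non-binder guarantees the binder count
  survives floating-point round-trips; the consensus has
  $\kappa = e^0 = 1$ exactly, and silent probes skip redevelopment, so
  their effect is exactly 0 rather than numerically small.
* **Fixed-point consistency.** Stability accepts windowed variance
  $V < 10^{-4}$, i.e. per-gene fluctuations up to $\sim 10^{-2}$;
  redeveloping from a recorded phenotype therefore reproduces it to
  $\sim 10^{-2}$ in the worst case and to $\sim 10^{-6}$ typically
  (most attractors are sharp fixed points). The test suite asserts the
  worst-case band and a much tighter median.
* **RNG discipline.** One master seed; the founder search, each
  generation, and each probing snapshot draw from seeds derived
  deterministically from it, so robustness probing never perturbs the
  evolutionary trajectory and trajectories are exactly reproducible.
* **Degenerate inputs.** All-equal landscapes refuse to normalize;
  `n_binders` outside [1, 65535] is rejected; parents must match in
  $n$, $L$, signs and initial state; founder search and offspring
  acceptance carry attempt caps (10^5 and 10^3 × M) to fail fast on
  pathological configurations.

# What the synthetic world does and does not establish

The generator reproduces the score-distribution shape, calibrated
binder counts, and additive neighbourhood structure of
structure-derived landscapes, but *not* their motif content: there is
no information-content structure along positions beyond what the
random position-energy matrix provides, no reverse strand, and no
relationship between different factors' consensus sites. A green test
therefore establishes that the evolutionary and analytic machinery
behaves as specified *given* landscapes with realistic coarse
statistics — not that any particular biological factor is modeled.

Scaled-down runs (smaller $M$, fewer generations, probe subsampling via
`robustness_sample`) preserve the model exactly but weaken statistical
power; the package's stochastic trend tests run at desk scale (minutes,
one CPU) and are chosen from runtime measurements, not from the
magnitude of the effects. The full protocol (100 simulations × 2000
generations × $M = 500$, all $L$–$\gamma$ combinations) is
cluster-scale; `scripts/full_decomposition.R` implements it for users
with the budget. At desk scale the slow second-order effects — the
robustness increase and the connectivity drop at small $\gamma$, which
at full scale need hundreds of generations at $M = 500$ to separate
from drift — are at the edge of detectability; the corresponding tests
run the model honestly at reduced scale and document their power in the
test file. One check is expected to stay red at desk scale: the
"connectivity unchanged at $\gamma = 0.20$ within 5 %" band compares
population means whose founder-to-founder spread is ~18 % relative;
each population regresses from its founder's connectivity draw toward
the mutational equilibrium, and that regression only cancels in the
mean over many founders (~50 replicates), not over the handful a
desk-scale suite can afford.

# Known limitations

* No TFBS positional effects, spacing, cooperativity, or
  distance-dependent repression; regulation is a plain sum of
  specificities.
* No within-URR recombination; no environmental perturbation (only
  genetic robustness is probed).
* Unstable mutants' phenotype distances are discarded, not modeled.
* The per-factor specificity transform assumes one shared
  $\varepsilon'_{opt}$ across factors.
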