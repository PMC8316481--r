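---
title: "Maximum-entropy configuration models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy configuration models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxentnet)
```

## The statistical problem

A null model for a network fixes a handful of *local* properties of an
observed graph — the degree of every node, or its strength, or both — and is
otherwise maximally random. Maximizing Shannon entropy subject to soft
(ensemble-average) constraints yields an exponential family over graphs,
$P(G\mid\theta) \propto e^{-\theta\cdot C(G)}$, with one Lagrange multiplier
per constraint. Maximizing the likelihood of the observed graph then fixes
the multipliers: the stationarity conditions say precisely that every
constrained quantity equals its ensemble expectation,
$C_i(G^*) = \langle C_i\rangle(\theta)$. Because the constraints are linear
in the graph and entropy is concave, the log-likelihood is concave and the
optimum is unique (up to the degeneracies discussed below); its Hessian is
minus the covariance matrix of the constraints (the fluctuation–response
relation), hence negative semidefinite everywhere.

The package implements the six model families in which the probability
factorizes over node pairs:

| model | graph type | constraints | pair law |
|---|---|---|---|
| `ubcm` | binary undirected | degrees $k_i$ | Bernoulli, $p_{ij} = \frac{e^{-\theta_i-\theta_j}}{1+e^{-\theta_i-\theta_j}}$ |
| `dbcm` | binary directed | $k^{out}_i, k^{in}_i$ | Bernoulli, $p_{ij} = \frac{e^{-\alpha_i-\beta_j}}{1+e^{-\alpha_i-\beta_j}}$ |
| `bicm` | bipartite binary | per-layer degrees | Bernoulli across layers |
| `uecm` | integer-weighted undirected | $k_i$ and $s_i$ | Bernoulli–geometric mixture |
| `decm` | integer-weighted directed | four sequences | directed analogue |
| `crem_und`/`crem_dir` | real-weighted | strengths, given edge marginals $f_{ij}$ | Bernoulli($f$) × Exponential($\theta_i+\theta_j$) |

plus the one-parameter degree-corrected gravity model,
$p_{ij} = z s_i s_j/(1+z s_i s_j)$, calibrated to a link count.

For the enhanced models the pair weight given a link is geometric on the
positive integers with parameter $v_{ij} = e^{-\beta_i-\beta_j}$ (resp.
$e^{-\gamma_i-\delta_j}$), so $\langle w_{ij}\rangle = p_{ij}/(1-v_{ij})$ and
admissibility requires $v_{ij} < 1$ on every constrained pair. The
conditional reconstruction models take the marginal matrix $f$ of *any*
binary model as input and place exponential weights conditionally on a link,
with $\langle w_{ij}\rangle = f_{ij}/(\theta_i+\theta_j)$.

## Hessians by fluctuation–response

The package needs exact Hessians for Newton's method. Rather than
transcribing formula sheets, every Hessian is assembled from the identity
$H = -\mathrm{Cov}[C_i, C_j]$ using the closed-form pair moments of the
Bernoulli, Bernoulli–geometric and conditional-exponential laws
($\mathrm{Var}[w] = (p(1+v)-p^2)/(1-v)^2$ for the geometric mixture, and so
on). Constraints of two nodes only ever share the single pair that joins
them, so each Hessian block is a pair-covariance matrix plus a diagonal
correction. The contract for correctness is validation, not derivation: the
test suite checks every gradient against central finite differences of the
likelihood (relative error below $10^{-6}$), every Hessian against finite
differences of the gradient (below $10^{-5}$), and, for the binary models on
up to four nodes, against a brute-force enumeration of the entire ensemble
(agreement to $10^{-12}$, including $\sum_G P(G) = 1$). The only exception
is the conditional model, whose objective is a conditional likelihood: its
curvature $-f_{ij}/(\theta_i+\theta_j)^2$ is obtained by direct
differentiation, and its *sampling* variances (used for ensemble validation)
are computed from the Bernoulli–exponential law instead.

## One algebra for full and reduced systems

Nodes with identical constraint tuples can share a multiplier, shrinking the
system from one equation per node to one per *distinct tuple* with a
multiplicity count. Internally every model is expressed over such classes
from the start: the pair structure is a matrix of ordered pair counts
between classes, and the full (unreduced) problem is the special case of
singleton classes. Reduced and full likelihoods therefore agree exactly by
construction, which the tests assert to $10^{-12}$.

Two conventions deserve a note. Within-class unordered pairs number
$m(m-1)/2$; the likelihood uses exactly this count so that the reduced and
full objectives are the same function (a within-class count of $m(m-1)$
would double the diagonal term and break the identity, while leaving the
per-node gradient unchanged). Second, classes are keyed by *exact* tuple
equality — real-valued strengths are never binned, since binning would change
the model — and ordered lexicographically so reduced outputs are
reproducible. The reduction coefficient `c_r` follows each model family's
conventional normalization (distinct degrees over $N$ for the undirected
binary model; distinct out/in pairs over $2N$ for the directed one; per-layer
distinct degrees over the total node count for the bipartite model), so its
value is comparable within a family but not across families. The conditional
models have no reduced form: their marginal matrix is pair-specific.

## Degenerate constraints

Multipliers of nodes with zero degree or strength diverge to $+\infty$
(empty row), and a node connected to everything pushes its multiplier to
$-\infty$ (full row). Such nodes are resolved *before* the numerical solve:
their probability rows are fixed at 0 or 1, neighbours' residual constraints
are decremented where a row is forced full, and the reduced system is built
on the remainder. The recursion covers the undirected and bipartite binary
models completely; for directed and weighted models a node degenerate on one
side only is dropped from that side (its row contributes exactly zero to
every other equation), while a *saturated* degree in the enhanced models
would change the conditional weight law and is rejected with an informative
error instead of being guessed.

Because the bare sentinel values cannot distinguish a forced link from a
forbidden one once both kinds of resolved node are present, the solver
records the analytically fixed probability entries, and `fitted_values()`
reconstructs exact probability and expected-weight matrices from them.

A subtler boundary case appears when a constraint sequence is realizable
only by graphs that all share some link: the classic example is four nodes
with degrees $(2,2,1,1)$, where every realization contains the link between
the two degree-2 nodes. The likelihood supremum then sits at the boundary
($p \to 1$) and the multipliers diverge *logarithmically*: Newton still
meets the gradient tolerance quickly along the ridge, while the linear
methods approach it slowly and simply need a larger iteration budget. The
package does not attempt to detect such forced substructures analytically.

## The three solvers

All methods iterate $\theta^{(n+1)} = \theta^{(n)} + \alpha\,\Delta\theta$
and stop when the Euclidean gradient norm or update norm drops below the
tolerance, or at the iteration cap. The per-model defaults are $10^{-8}$
with caps of 1000 (undirected binary), 1000 at $10^{-10}$ (bipartite) and
10000 otherwise; all are overridable. When both criteria trigger in one
iteration the gradient criterion is reported, as it is the stronger
statement.

**Newton.** $\Delta\theta = -(H + \Delta H)^{-1}\nabla\mathcal{L}$ with the
smallest uniform eigenvalue shift $\Delta H$ making the matrix safely
negative definite: the clip level is $\varepsilon = 10^{-10}(1 +
\max|H_{ij}|)$, small enough not to slow convergence and large enough to
absorb exact gauge null-modes (the directed and bipartite likelihoods are
invariant under a constant shift moved between the two multiplier blocks).
A singular system after shifting falls back to a pseudo-inverse solve with a
warning.

**Quasi-Newton.** The purely diagonal version of the same step: entries of
the Hessian diagonal are clipped to at most $-\varepsilon$ and the update is
the componentwise quotient. Cheap per iteration, linearly convergent.

**Fixed point.** The stationarity conditions rearranged as $\theta =
G(\theta)$ and iterated as printed: no line search, no damping by default
(an optional relaxation factor exists but is off). The map divides by the
observed constraints, so degenerate nodes must have been resolved. On the
enhanced models the plain map can leave the admissible region or blow up;
both are reported as a `diverged` status rather than erroring mid-fit,
mirroring the known fragility of this recipe on jointly constrained models.

**Line search.** Armijo backtracking from $\alpha = 1$ with sufficient
increase parameter $\gamma = 10^{-4}$ and shrink factor $\beta = 1/2$
(conservative values inside the admissible ranges $\gamma\in(0,0.5]$,
$\beta\in(0,1)$). Inadmissible trial points evaluate to $-\infty$ and simply
shrink the step. One regime needs care: near the optimum the predicted
increase $\gamma\alpha\,\nabla\mathcal{L}^\top\Delta\theta$ falls below the
floating-point resolution of the objective and the test compares rounding
noise. The search then takes the method's asymptotic step directly: the unit
step for Newton, a half step for the diagonal method. The half step matters:
the undamped diagonal iteration is Jacobi-like, and on the conditional model
the Hessian's off-diagonal row sums equal its diagonal, so the undamped
iteration matrix has an exactly non-contracting mode — the damped step
restores contraction and lets the diagonal method actually reach tight
gradient tolerances there.

**Coupled strategy.** Fixed point run to its stop, then quasi-Newton from
that warm start, with the combined trace and the final phase's stopping
cause. When phase one already meets the gradient tolerance, phase two exits
immediately. When comparing stopping behaviour across methods, the
comparison runs disable the step criterion (uniformly) so that termination
is attributable to the gradient criterion or the cap.

**CReM positivity and rescaling.** The undirected conditional model's
multipliers are kept strictly positive by projection to $10^{-12}$ after
each accepted step. The directed model is deliberately *not* projected:
its admissibility constraint is pairwise ($\alpha_i+\beta_j > 0$ where
$f_{ij} > 0$) and individual multipliers of high-strength nodes are
legitimately negative at the optimum — a per-parameter clip pins the iterate
at the boundary with a non-zero gradient. Strengths may also be rescaled by
a factor $\kappa$: the rescaled solution is exactly $\kappa$ times the
original one, so the solver divides the strengths, solves, and divides the
multipliers back. The stopping tolerances are mapped into the rescaled units
($\mathrm{tol}_\nabla/\kappa$, $\mathrm{tol}_{\Delta\theta}\cdot\kappa$ —
the rescaled gradient is exactly the original gradient over $\kappa$), so
the returned accuracy, and hence the $\kappa$-invariance, is independent of
$\kappa$.

## Initialization

Three schemes. `sparse` uses the closed-form sparse-limit solution,
$\theta_i^{(0)} = -\ln(k_i/\sqrt{2L})$ for the undirected degrees and the
per-model analogues ($\sqrt{L}$ for directed/bipartite degrees,
$\sqrt{2W}$/$\sqrt{W}$ for strengths); `sqrtN` replaces the denominator with
$\sqrt{N}$; `uniform` draws every entry from $U(0,1)$ and requires a seed.
Conditional-model starts are floored at $10^{-8}$ to respect positivity.
For the enhanced models the closed forms can start outside the admissible
region when two strengths are large; the strength multipliers are then
shifted uniformly so the smallest pair sum clears a margin of $10^{-2}$ —
this moves only the starting point, never the solution.

## Sampling and validation

Each pair is an independent Bernoulli trial on its link probability; present
links in the enhanced models add a geometric number of extra weight units,
and in the conditional models an exponential weight via inverse-CDF, so
weights are zero exactly where links are absent. One uniform variate is
consumed per ordered cell per layer, in fixed row-major order, making a
sample sequence a bit-reproducible function of (model, parameters, seed).
`validate_ensemble()` compares empirical constraint means to their analytic
expectations, normalized by analytic standard errors (from the
fluctuation–response variances, or the Bernoulli–exponential law for the
conditional models); analytically fixed constraints get an `NA` z-score.

## What the synthetic generators do and do not emulate

`generate_binary()` draws from a gravity-model link law with deterministic
power-spread latent fitnesses, calibrated to a target density; heterogeneity
0 collapses to an Erdős–Rényi-like graph. `generate_weighted()` adds a
geometric or exponential weight layer on the sampled support. This
reproduces the features that matter for the solvers — sparse graphs with
broad, graphical degree and strength sequences, including zero-degree nodes
at low density — because every fitted sequence is realized by an actual
graph. It does *not* emulate clustering, reciprocity, community structure,
degree–degree correlations beyond the fitness form, or the weight
distributions of any particular empirical system; passing tests therefore
demonstrate correctness and convergence of the estimation machinery on
realistic local structure, not fidelity of the models to any real network.

The study sizes used by the tests and the acceptance script are the
package's own choices: monopartite fixtures of 200 nodes (bipartite
50 × 80) for the convergence contract, four-node ensembles for exhaustive
enumeration, and ten-node fixtures with $10^4$ (tests) or $5\times10^3$
(script) samples for moment recovery.

## Worked example

```{r example}
g <- generate_weighted(60, density = 0.1, mean_weight = 4, seed = 2)
obs <- constraints(g, "uecm")
fit <- solve_model("uecm", obs)
fit
report <- fit_report(fit, obs)
report
```

The maximum absolute and relative errors are computed against the expected
constraints at the returned multipliers; `c_r` is the fraction of equations
surviving reduction and `c_v` the coefficient of variation of the degree
sequence.

## Known limitations

Saturated degrees in the enhanced models are rejected, not resolved;
reciprocity-constrained and discrete-conditional variants are out of scope;
the enumeration oracle is limited to binary models on a handful of nodes by
design; and forced-substructure boundary optima (see above) are handled by
iteration budget, not detected analytically. Dense problems are stored as
dense matrices throughout, which is the intended regime for the
hundreds-of-nodes fixtures the package targets.
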