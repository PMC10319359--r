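---
title: "Bisected graph matching: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bisected graph matching: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgmatch)
```

## The matching problem

A bilateral network is a single directed, possibly weighted network whose
nodes split into a left and a right side. Indexing the full adjacency
matrix by that split gives four blocks: the ipsilateral subgraphs $A_{LL}$
and $A_{RR}$ and the contralateral subgraphs $A_{LR}$ and $A_{RL}$. A
candidate pairing of right nodes to left nodes is a permutation matrix
$P$, and `bgmatch` minimizes the discrete edge-disagreement objective

$$f(P) \;=\; \sum_{k=1}^{K}\,\lVert A_{LL}^{(k)} - P A_{RR}^{(k)} P^\top\rVert_F^2
\;+\; \lVert A_{LR}^{(k)} P^\top - P A_{RL}^{(k)}\rVert_F^2,$$

summed over the $K$ edge-type layers of a multiplex network ($K = 1$ for a
simple network). The key structural point is that a permutation of the
right-side nodes permutes the *rows and columns* of $A_{RR}$ but only the
*columns* of $A_{LR}$ and only the *rows* of $A_{RL}$; this is what
distinguishes bisected matching from matching two independent multiplex
layers. Dropping the contralateral term (`useContralateral = FALSE`, or
contralateral blocks that are identically zero) recovers classic two-network
graph matching on the ipsilateral subgraphs, and the package treats that as
an exact reduction: objectives, gradients and solve trajectories coincide.

For an unweighted network the objective counts directed edge
disagreements; for weighted networks it is the squared Frobenius norm of
the weight differences. Weights are used raw — synapse counts are matched
as counts. `transformWeights()` offers `binarize` and `log1p` as explicit
opt-ins, off by default, because no transform is part of the method
itself. Self-loops on the diagonal of $A_{LL}$/$A_{RR}$ are ordinary
entries to the solver, while diagonal entries of $A_{LR}$/$A_{RL}$ are
contralateral edges between index-matched nodes, never loops.

## The solver

Exact minimization is a quadratic assignment problem and is NP-hard, so the
solver follows the Frank–Wolfe (conditional gradient) family: relax the
permutation set to its convex hull, the doubly stochastic matrices, and
iterate

1. compute the gradient at the current iterate $P_{(i)}$;
2. find the permutation direction $Q_{(i)}$ minimizing
   $\mathrm{tr}(Q^\top \nabla f(P_{(i)}))$ by a linear assignment solve;
3. find the exact step $\alpha \in [0,1]$ minimizing the objective on the
   segment $\alpha P_{(i)} + (1-\alpha) Q_{(i)}$;
4. step, and stop when $\lVert P_{(i+1)} - P_{(i)}\rVert_F / \sqrt{n}$
   falls below the tolerance or `maxIter` is reached;

then project the final doubly stochastic iterate back onto the
permutations with one more assignment solve, and evaluate the discrete
objective there.

On the relaxed set the solver works with the indefinite trace form

$$\tilde f(P) = -\sum_k \mathrm{tr}\!\big(A_{LL}^{(k)\top} P A_{RR}^{(k)} P^\top\big)
 + \mathrm{tr}\!\big(A_{RL}^{(k)} P A_{LR}^{(k)\top} P\big),$$

whose gradient is

$$\nabla \tilde f(P) = -\sum_k A_{LL}^{(k)} P A_{RR}^{(k)\top}
 + A_{LL}^{(k)\top} P A_{RR}^{(k)}
 + A_{LR}^{(k)} P^\top A_{RL}^{(k)\top}
 + A_{RL}^{(k)\top} P^\top A_{LR}^{(k)}.$$

On permutation matrices the discrete objective equals a data constant plus
twice $\tilde f$, so the two forms rank permutations identically; on the
relaxed set $\tilde f$ is the standard indefinite relaxation, and —
unlike the Frobenius form, which is quartic along a segment — it is an
exact quadratic in $\alpha$ along every Frank–Wolfe segment, which is what
makes the closed-form line search possible. Both forms are exported
(`bgmObjective()`, `relaxedObjective()`), the latter mainly so that the
gradient can be checked against finite differences. The test suite does
exactly that, and validates the line-search coefficients against a dense
grid search rather than trusting the algebra.

### Tunable parameters

* `maxIter = 30` — Frank–Wolfe iterations per restart. The relaxation
  typically converges in well under 30 iterations at the problem sizes the
  package targets.
* `tol = 0.03` — stopping threshold on
  $\lVert P_{(i+1)} - P_{(i)}\rVert_F/\sqrt n$ (dimensionless). The
  $\sqrt n$ scaling makes the criterion size-independent and matches the
  convention of the standard Frank–Wolfe matching implementations, so that
  "default parameters" here mean the same thing they mean in that
  ecosystem.
* `nRestarts = 1` — number of restarts; the matching with the lowest
  *discrete* objective wins, ties going to the lowest restart index. The
  per-restart solutions are kept on the returned object so that
  `matchFrequencies()` can turn restart agreement into a confidence score:
  pairs selected in every restart are flagged high-confidence.
* `init = "barycenter"` — the flat matrix $J/n$, the centroid of the
  doubly stochastic set. `"randomized-barycenter"` averages the barycenter
  with a random doubly stochastic matrix (uniform noise balanced by 10
  Sinkhorn sweeps). Restarts from the plain barycenter still differ
  because assignment ties are broken randomly (below); the randomized
  initialization adds a second, stronger source of restart diversity.
* `project = "solution"` — the final projection solves the assignment on
  the last iterate itself, i.e. finds the permutation nearest the relaxed
  solution; this is the classic behavior of the reference implementations
  and the default. `project = "gradient"` instead projects along the
  gradient at the final iterate (the direction one further Frank–Wolfe
  step would take). The two disagree only when the relaxed solution is far
  from a vertex; both are exposed because both appear in descriptions of
  the algorithm family.
* `seed` — one integer from which all solver randomness flows
  (tie-breaking and randomized initialization). Identical seeds give
  bitwise-identical results; the caller's RNG state is restored afterwards.

### Numerical choices

The linear assignment subproblems are solved exactly by a compiled
$O(n^3)$ shortest-augmenting-path solver (`src/lap.cpp`). Assignment
problems arising from binary networks are massively degenerate, so ties
are broken by drawing a random symmetric relabeling of rows and columns,
solving the relabeled problem, and undoing the relabeling — every LAP call
consumes one RNG draw, which is also what makes barycenter restarts
distinct. The exact line search evaluates the quadratic's coefficients
from the segment endpoints; when the quadratic is concave or linear
(possible, since the relaxation is indefinite) the better endpoint is
taken, and the degenerate segment $P = Q$ returns $\alpha = 1$ (stay) by
convention. Because every step minimizes the objective over a segment that
contains the current point, the recorded relaxed-objective trace is
non-increasing, and every iterate is a convex combination of doubly
stochastic matrices — both properties are asserted in the tests.

### Seeds

Known pairs are handled by reordering both sides so seeds come first and
optimizing only the nonseed-by-nonseed block of $P$. The reduced problem
keeps the quadratic terms of the nonseed blocks and gains constant
"seed-interaction" gradient terms — for the ipsilateral part
$A_{LL}^{ns} A_{RR}^{ns\top} + A_{LL}^{sn\top} A_{RR}^{sn}$, and
analogously for the contralateral part — which couple the unknown matches
to the connectivity of the seeds. The restricted relaxed objective remains
affinely tied to the seed-respecting discrete objective (asserted by
enumeration in the tests), so seeded solves optimize the right thing, and
the returned matching maps every seed to its stated partner exactly.

### Padding

Sides of unequal size are matched after naive zero-padding
(`padNetwork()`): the smaller side's ipsilateral block is embedded in the
top-left corner of a square zero matrix, and its contralateral blocks get
zero columns/rows appended. Padded node ids are synthetic sentinels
(`__pad1`, ...) recorded on the object; a left node matched to a sentinel
is reported as unmatched by `matchedPairs()`, and sentinel assignments are
excluded from accuracy denominators. The alternative "adopted" padding
scheme (centering around the mean weight) is out of scope.

## The simulator

`simulateBilateral()` draws one synthetic bilateral network from the
correlated Erdős–Rényi (CorrER) construction: a pair of binary matrices in
which every entry of the first is Bernoulli($p$) and the matched entry of
the second is Bernoulli($p + \rho(1-p)$) or Bernoulli($p(1-\rho)$)
conditional on the first being 1 or 0. This gives marginal density $p$ for
both matrices and Pearson correlation $\rho$ between index-aligned
entries. The ipsilateral pair $(A_{LL}, A_{RR})$ and, independently, the
contralateral pair $(A_{LR}, A_{RL})$ are drawn this way, assembled into
one network whose index-aligned pairing is the ground truth, and the right
side is then shuffled by a uniformly random permutation to hide the truth
from the matcher.

Defaults are the package's study conditions throughout: $n = 10$ nodes per
side, ipsilateral density $0.3$ with correlation $0.8$, contralateral
density $0.2$; the contralateral correlation is the quantity the sweep
experiment varies. Two conventions were open and are fixed as follows:
ipsilateral draws zero their diagonal (self-synapses are conventionally
excluded), while contralateral draws keep theirs, because a diagonal
contralateral entry is an ordinary edge between index-matched homologs,
not a loop. Each instance seed is split into three child seeds (ipsilateral
draw, contralateral draw, shuffle), so varying one correlation parameter
reuses comparable draws for everything else — the sweep exploits this as a
common-random-numbers design.

What the simulator does *not* emulate about real connectomes: weighted
synapse counts (it is binary), degree heterogeneity and community
structure (edges are i.i.d. within a block), hemisphere-specific density
differences, and unpaired or midline neurons. Passing tests on CorrER
instances therefore demonstrate correctness of the optimization and
calibration of the generator, not field performance on any particular
connectome; on real data the decisive quantity is the empirical
contralateral alignment correlation, which `alignmentCorrelation()`
estimates under any candidate or known pairing.

## Evaluation conventions

*Accuracy* is the proportion of evaluable left nodes whose predicted
partner equals the true partner. Seeds are excluded from numerator and
denominator (they are inputs, not predictions), as are padding sentinels
and nodes without truth information. *Alignment correlations* compare
off-diagonal ipsilateral entries of $A_{LL}$ against pairing-aligned
$A_{RR}$, and all entries of column-aligned $A_{LR}$ against row-aligned
$A_{RL}$. The contralateral comparison is direct (not transposed): mirror
symmetry maps the edge $L_i \to R_j$ onto $R_i \to L_j$, which is exactly
the entry the bisected objective compares at the true pairing, and it is
the convention under which the generator's $\rho_{contra}$ is recovered.
*Method comparison* uses a two-sided Mann–Whitney U test on per-restart
accuracies via `stats::wilcox.test()`.

## The scripted experiments

`runRhoSweep()` varies the contralateral correlation over a grid (default
$0, 0.1, \dots, 1$), simulating `nReps` instances per value and running GM
and BGM once each, from the barycenter, on the identical instance with the
same tie-break randomness. Means are reported with normal-approximation
95% intervals (mean $\pm 1.96\,$SEM), a deliberate, simple choice for
per-grid-value Monte-Carlo error. The phenomenon the sweep quantifies: at
zero contralateral correlation the contralateral term is pure noise and
BGM trails GM by a large margin; the BGM curve rises monotonically with the
correlation and overtakes the flat GM curve in the low-middle of the grid
(around $0.3$–$0.4$ at the default conditions; with 1000 replicates per
value the overtaking point is resolved to about one grid step), then
saturates near perfect accuracy, so that the high-correlation margin over
GM approaches one minus GM's accuracy.

`runRestartComparison()` runs both methods once per restart seed on one
fixed network, so each comparison is paired on initialization, and
summarizes with the U test. `runSeedCV()` emulates a seeded
cross-validation design: per fold, 20% of the known pairs are held out for
evaluation and never enter the seed set; each requested number of seeds is
drawn from the remainder; accuracy is computed on the holdout only. Folds
re-randomize the holdout independently, a choice made where the design was
open.

Problem sizes used by the test suite are the package's own: the full sweep
conditions ($n = 10$, 1000 replicates per grid value) for the end-to-end
accuracy profile, $n \le 6$ wherever an exhaustive $n!$ oracle verifies
optimality, and $n \approx 100$ Monte-Carlo draws for generator
calibration.

## Known limitations

* The relaxation is indefinite and Frank–Wolfe only finds local optima;
  restarts mitigate but do not remove this. Reported objectives are upper
  bounds on the true minimum (the tests verify they never fall below the
  exhaustive minimum at small $n$).
* Where BGM overtakes GM depends on everything about the instance
  distribution — densities, sizes, weight structure — not just the
  contralateral correlation; the sweep's crossing location is a property
  of the stated simulation, not a universal constant, and with realistic
  replicate counts it is only resolved to about one grid step.
* Including contralateral terms is a modeling decision: when the true
  contralateral correlation is low, BGM is actively worse than GM. On new
  data, estimate the alignment correlation on a trusted subset first.
* The solver is dense ($O(n^3)$ per iteration); it is comfortable at
  connectome-subset scales (thousands of nodes) but not designed for
  $10^5$-node graphs.
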