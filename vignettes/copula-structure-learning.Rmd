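---
title: "Learning decomposable dependence graphs with copula information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning decomposable dependence graphs with copula information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decopula)
```

## The model

decopula learns the structure of a decomposable (chordal) Markov random
field for a continuous random vector $X = (X_1, \dots, X_d)$. Decomposable
models are exactly the undirected models whose density factorizes along a
junction tree: with maximal cliques $K_1, \dots, K_m$ and separators
$S_2, \dots, S_m$ satisfying the running intersection property,

$$p(x) \;=\; \frac{\prod_l p(x_{K_l})}{\prod_l p(x_{S_l})}.$$

The same factorization holds for the copula density $c(u)$ of
$U_i = F_i(X_i)$, because component-wise strictly increasing transforms
preserve conditional independence. Taking logs and expectations, the mutual
information of $X$ decomposes into clique and separator *copula entropies*:
writing $\psi(A) = E[\log c_A(U_A)]$ (the negative copula entropy of the
margin $A$, i.e. the mutual information inside $A$),

$$I(X) \;=\; \sum_l \psi(K_l) \;-\; \sum_l \psi(S_l).$$

This is the quantity the learner maximizes, penalized for complexity in a
BIC-like way. For a candidate graph $G$ with clique tree $T$,

$$S_{\mathrm{CBIC}}(G) \;=\; n \, I(G) \;-\; \frac{\log n}{2} \, \Lambda(G),
\qquad
\Lambda(G) = \sum_l \lambda(K_l) - \sum_l \lambda(S_l),$$

with $\lambda(A) = |A|(|A|+1)/2$ by default (the parameter count of a
Gaussian margin of dimension $|A|$; `penalty = "linear"` gives
$\lambda(A) = |A|$). Because both the fit and penalty terms are
clique/separator-additive, the score change of a single admissible edge
edit has a closed four-term form. Inserting $\{i, j\}$ with admissibility
separator $S$ creates the new maximal clique $S \cup \{i, j\}$ and replaces
the separator $S$ by $S \cup \{i\}$ and $S \cup \{j\}$, so

$$\Delta_{ij} \;=\; \kappa(S \cup \{i,j\}) - \kappa(S \cup \{i\})
  - \kappa(S \cup \{j\}) + \kappa(S),
\qquad
\kappa(A) = n\,\psi(A) - \tfrac{\log n}{2}\lambda(A),$$

and a deletion is the negation. Every candidate move therefore costs four
cached set-functional evaluations, not a rescore of the whole graph.

Because $\psi$ depends only on the copula — in estimation, only on
within-sample ranks — the learned structure is invariant under strictly
increasing transforms of individual variables. That is the scientific point
of the method: dependence is scored on the copula scale, so marginal shape
(skewness, boundedness, heavy tails) cannot masquerade as structure. The
contrast score `ng_ll`, a cross-validated log-likelihood of raw-scale
clique/separator kernel density estimates under the identical search
machinery, deliberately lacks this invariance.

## The estimator

$\psi(A)$ is estimated nonparametrically in three steps, all confined to
the training sample.

1. **Fold-wise pseudo-observations.** The training rows are split into
   $k = 5$ folds. For fold $r$, each column's empirical CDF
   $\hat F_{i,-r}$ is fitted on the complementary rows, and every row is
   mapped to $\hat U_{i,r} = \mathrm{clamp}(\varepsilon, 1-\varepsilon,
   \frac{m}{m+1} \hat F_{i,-r}(X_i))$ with $m$ the fitting-row count. The
   $m/(m+1)$ factor is the usual rank-based pseudo-observation scaling; the
   truncation at $\varepsilon$ keeps the subsequent probit transform finite.
2. **Probit-transformed KDE.** Kernel smoothing directly on $(0,1)^{|A|}$
   suffers boundary bias, so estimation happens on the probit scale
   $\hat Z = \Phi^{-1}(\hat U)$ with a diagonal Gaussian kernel; the copula
   density follows by dividing by the Jacobian $\prod_{i \in A}
   \phi(z_i)$. Log-densities use the log-sum-exp identity and a density
   floor $\delta_{\mathrm{floor}}$ so that $\log \hat c$ is always finite.
3. **Out-of-fold log scores.** $\hat\psi(A)$ is the average predictive log
   copula density of held-out rows under their fold's fit — centers and
   marginals both come from the complementary rows, so no information leaks
   from scored points into the fit. The average is over all scored points,
   i.e. the full training-row count.

The bandwidth is a single global vector $\theta \in \mathbb{R}_+^d$ (one
variance per variable), selected **once** before the search by maximizing
the leave-one-out predictive log-score of the $d$-dimensional KDE on the
probit-transformed training sample, and projected to $\theta_A$ for every
subset afterwards. Optimization runs on $\xi = \log\theta$ with L-BFGS-B
and an analytic gradient, inside the box
$[\log(\widehat{\mathrm{Var}}(Z_j)/\beta_{\max}),
  \log(\widehat{\mathrm{Var}}(Z_j)/\beta_{\min})]$.
We use $\beta_{\min} = 1$ and $\beta_{\max} = n_{tr}^{2/5}$: the upper
bound caps the bandwidth at the coordinate variance, the lower bound sits
at the classical one-dimensional rate $n^{-2/5}$, so the box brackets the
usual KDE-rate bandwidths with room on both sides. (Note the orientation:
with $\beta_{\min} < \beta_{\max}$, the larger constant must sit in the
lower bound's denominator or the box would be empty.)

### Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| folds $k$ | 5 | standard CV; fixed-$k$ out-of-fold scoring is asymptotically equivalent to leave-one-out |
| $\varepsilon$ | $10^{-5}$ | far below $1/(m+1)$ for realistic $m$: the clamp only guards exact 0/1 |
| $\delta_{\mathrm{floor}}$ | $10^{-100}$ | $\log \delta \approx -230$, never binding for sane densities |
| $\beta_{\min}, \beta_{\max}$ | $1$, $n_{tr}^{2/5}$ | nonempty box bracketing rate-optimal bandwidths |
| penalty $\lambda$ | $\vert A\vert(\vert A\vert+1)/2$ | Gaussian-margin parameter count; clique/separator additive |
| $n_{\mathrm{eff}}$ | $n_{tr}$ | all $\hat\psi$ are estimated from the training rows, so they set the scale of both $n$ and $\log n$ |

## The search

Search starts from the empty graph and repeatedly applies the
best strictly improving admissible move ($\Delta > 0$, no slack), pooling
insertions and deletions in one argmax per iteration. Admissibility is
decided on a maintained clique tree:

* a **deletion** $\{i,j\}$ is admissible iff the edge lies in exactly one
  maximal clique $K$; it splits $K$ into $S \cup \{i\}$ and $S \cup \{j\}$
  around $S = K \setminus \{i,j\}$;
* an **insertion** $\{i,j\}$ is admissible iff, for the closest pair of
  cliques $K_k \ni i$, $K_l \ni j$ in the tree, the minimum separator
  weight on the path between them equals $|K_k \cap K_l|$; the move's
  separator is $S = K_k \cap K_l$.

Both criteria are verified in the test suite against the brute-force
oracle "apply the edit, then run the chordality test" on exhaustively
checked small graphs. After a move, the maximal-clique set is updated
incrementally (the new clique absorbs any clique it subsumes; a split part
is dropped when a neighbour contains it) and the tree over the updated
cliques is re-derived as a maximum-weight spanning tree with deterministic
lexicographic tie-breaks — the same construction used when building a tree
from scratch, so the maintained tree is always bit-identical to a rebuild.
At desk scale ($d$ up to a few hundred) this re-derivation is a negligible
$O(m^2 \log m)$ per accepted move; we deliberately do not implement
amortized dynamic-tree structures. Separators enter the score with their
multiplicity in this maintained tree, which is also the reference
representation for the $\Delta$ terms, so accumulated deltas reconcile
exactly with from-scratch global scores. Disconnected states are handled
as one tree with empty separators joining components; since
$\psi(\emptyset) = 0$ and $\lambda(\emptyset) = 0$ these junctions are
score-neutral.

Tie-breaks among equal-$\Delta$ moves prefer insertion over deletion, then
lexicographic $(i, j)$; candidate evaluation order is irrelevant because
each iteration evaluates all admissible moves. Non-finite $\Delta$s mark a
move inadmissible for that iteration only. A safety cap of $d(d-1)$
iterations guards numerical cycling; strict improvement makes the search
terminate well before it in practice.

## The synthetic benchmark

`simulate_benchmark()` generates the study conditions used throughout the
package's tests and in `scripts/acceptance.R`:

1. draw an Erdős–Rényi graph $G(d, \rho)$ and chordalize it by the
   elimination game with a minimum-degree heuristic (lexicographic
   tie-breaks) — a standard, deterministic triangulation with modest
   fill-in;
2. give each edge an independent $\mathrm{Gamma}(\alpha = 2, \beta = 1)$
   weight ($\beta$ a rate, so $E[Y] = 2$) and form the ridge-regularized
   Laplacian precision $Q = \nu I + D - W$, which is strictly diagonally
   dominant, hence positive definite with minimum eigenvalue at least
   $\nu$, and has off-diagonal support exactly on the edge set;
3. standardize $Q^{-1}$ to a correlation matrix $R$ and sample latent
   Gaussians $Z \sim N(0, R)$; the standardized precision $SQS$ keeps
   $Q$'s zero pattern, so the latent conditional independences are the
   non-edges of the truth;
4. map $U = \Phi(Z)$ and produce three marginal regimes by quantile
   transforms of the *same* $U$: standard normal (then $X = Z$ exactly),
   Exponential(1), and Beta(1/2, 1/2) — identical ranks, different
   supports.

One seed fixes the whole pipeline (graph, then weights, then latent
normals), so datasets are reproducible bit for bit. The ridge $\nu$ is the
main free signal-strength knob; we fix $\nu = 1$, which puts typical
latent partial correlations of a $\rho = 0.1$, $d = 30$ graph around
0.15–0.3 — strong enough to be detectable at $n = 2000$, weak enough that
recovery is not trivial.

What the generator does *not* emulate: non-Gaussian copulas (dependence is
always elliptical at the latent level), discrete or tied data, heavy-tailed
dependence, and model misspecification (the truth is always exactly
decomposable). Passing recovery tests on these data therefore demonstrates
correct behaviour *under* a Gaussian-copula decomposable truth, not
robustness beyond it.

The benchmark protocol (`run_benchmark()`) splits each dataset 70/30,
estimates everything on the training rows, and evaluates recovery against
the known truth with SHD, precision, recall and F1. The held-out rows feed
only an informational predictive log-score column (training-fitted
marginals applied to test rows). Because the copula learner is a function
of ranks alone and the marginal families share ranks by construction, its
learned graph is identical across families within a seed; `run_benchmark()`
therefore learns it once per seed and replicates the row — the bit-for-bit
identity claim itself is asserted by a dedicated test that runs the full
pipeline on transformed data.

## Numerical choices and degenerate inputs

* Empirical CDFs are right-continuous step functions; ties share a
  pseudo-observation value, and the estimator is well defined (though
  designed for continuous data).
* $\hat\psi(\emptyset) = 0$ by the empty-product convention, so empty
  separators are score-neutral.
* The density floor and $\varepsilon$-truncation jointly guarantee every
  $\hat\psi$ is finite; should a non-finite value still arise, the affected
  move is excluded for that iteration rather than aborting the search, and
  a search that cannot even score the empty graph returns it with a
  warning.
* Variances in the bandwidth box use the unbiased $n-1$ denominator
  (immaterial to a box constraint).
* Degenerate recovery ratios (empty learned or true edge set) are reported
  as 0 with explicit `*_defined` flags so aggregation stays total.
* Problem sizes in the tests are chosen for a single desk CPU: estimator
  accuracy checks run at $n = 1400$–$5000$ in one or two dimensions, the
  scaled benchmark at $d = 15$, $n = 800$ over 5 seeds, and exhaustive
  graph oracles at $d \le 7$; `scripts/acceptance.R` runs the full
  $d = 30$, $n = 2000$ protocol over 5 seeds.

## Known limitations

* Greedy single-edge search finds a local optimum; no restarts or
  sampling over junction trees are provided.
* Chordality is a modeling bias: non-decomposable truths are approximated
  by a chordal surrogate, typically through extra scaffolding edges.
* KDE-based $\hat\psi$ degrades as clique size grows; the complexity
  penalty discourages, but does not bound, clique growth.
* The estimator assumes continuous marginals; heavily tied or discrete
  columns break the uniqueness of the underlying copula.

## A worked example

```{r example, eval = FALSE}
library(decopula)

sim <- simulate_benchmark(d = 10, n = 1200, rho = 0.15, seed = 1)
fit <- learn_structure(sim$X$exponential) # skewed marginals, same copula
glance(fit)
graph_recovery(sim$truth, fit$graph)
autoplot(fit)
```
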