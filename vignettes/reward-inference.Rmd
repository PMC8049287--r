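---
title: "Inferring the objective of a recurrent network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the objective of a recurrent network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models behind `rewardnet`, the numerical choices
the implementation makes where the mathematics leaves freedom, and what the
test suite does and does not establish. Code chunks are illustrative and not
evaluated when the package is built; every quantitative statement below is
recomputed either by the test suite or by `scripts/acceptance.R`.

## The model

An agent occupies states $s$ of a finite Markov decision process, draws
actions from a policy $\pi(a\mid s)$, and collects a state reward $r(s)$.
Rather than maximising reward alone, the agent pays for the complexity of
its policy: the objective is the stationary average

$$L_\pi \;=\; \langle r(s)\rangle_{p_\pi(s)} \;-\; \lambda\, I_\pi(a; s)
\;=\; \big\langle r(s) - \lambda\, c_\pi(s)\big\rangle_{p_\pi(s)},$$

where $c_\pi(s) = D_{KL}\!\left[\pi(\cdot\mid s)\,\|\,p_\pi(\cdot)\right]$
is the *coding cost*: how far the state-conditional action distribution
departs from the marginal action distribution. $\lambda \ge 0$ (units:
reward per nat) sets the price of information. At $\lambda \to \infty$
actions ignore the state entirely; at small $\lambda$ the policy approaches
the deterministic optimum.

Policy evaluation solves the average-reward Bellman system
$(I - P_\pi)v = (r - r_0\mathbf 1) - \lambda(c - c_0\mathbf 1)$, with the
free constant fixed by anchoring the stationary-weighted mean of $v$ to
zero. The soft-greedy improvement
$\pi^*(a\mid s) \propto p_\pi(a)\, e^{\langle v(s')\rangle_{p(s'|s,a)}/\lambda}$
never decreases $L_\pi$, and alternating the two steps converges to the
regularised optimum (`solve_entropy_rl()`).

A binary recurrent network maps onto this scheme neuron by neuron: the
"state" is the joint (network, input) configuration $(\sigma, x)$, the
"action" is neuron $i$'s proposed update $\tilde\sigma_i$, and the
constraint sums each neuron's information
$\sum_i I(\tilde\sigma_i;\sigma,x)$. Dynamics are asynchronous: one
neuron, chosen uniformly at random, resamples its state per time step while
the input makes one Markov step. The per-neuron soft-greedy update takes
the logistic form

$$\pi_i(\tilde\sigma_i = 1 \mid \sigma, x) =
\mathrm{logistic}\!\left(\frac{\Delta_i(\sigma, x)}{n\lambda}
+ \mathrm{logit}\, p_i\right),$$

with $\Delta_i$ the expected next-step value advantage of spiking and
$p_i$ the reference spiking marginal. We note that one published rendering
of this update carries the reciprocal prefactor and a flipped sign in the
exponent, which would make spiking *less* likely as its value advantage
grows; the form above is the one consistent with the general soft-greedy
update and with the Gibbs steady state below, and it is what the package
implements.

For autonomous (input-free) networks the optimised dynamics satisfy
detailed balance with respect to
$p(\sigma) \propto \prod_i p_i(\sigma_i)\, e^{v(\sigma)/(\lambda n)}$ —
the network Gibbs-samples a Boltzmann distribution whose energy is its own
value function. Inverting that relation plus the Bellman identity yields a
closed-form reward,

$$r(\sigma) = \lambda \sum_{i=1}^n
\log\frac{p(\sigma_i\mid\sigma_{/i})}{p(\sigma_i)} + \text{const},$$

computable from the stationary law alone (`closed_form_reward()`). The
prefactor deserves a note: carrying the Gibbs relation through the Bellman
identity gives exactly $\lambda$, and the package's two independent
inference routes agree to $10^{-6}$ under this prefactor (a property the
test suite checks); renderings with an extra factor of $n$ or $n^2$ only
rescale the result, which the affine identifiability convention absorbs.
Since $\lambda$ itself is not identifiable — $(r, \lambda)$ and
$(cr, c\lambda)$ induce identical dynamics — inferred rewards use the
$\lambda = 1$ convention and are reported mean-centred.

## Inference with an external input

With input the stationary law is not Gibbs and the value function must be
reconstructed from transition statistics. The observable quantities are
the per-neuron flip log-odds; they determine the input-conditional expected
value $u(\sigma, x) = \langle v(\sigma, x')\rangle_{p(x'|x)}$ only through
its differences across single flips, so $v$ is identifiable *only up to an
additive function of $x$*. The estimator:

1. estimate each flip's log-odds from flip-rate ratios with
   Haldane–Anscombe smoothing (exact tables skip this step);
2. solve a weighted least-squares problem on the flip graph for
   $u(\cdot, x)$ (weights: inverse variances of the logit estimates; this
   is the quadratic surrogate of the transition likelihood, and coincides
   with its maximiser in the infinite-data limit);
3. recover $v = u\,(P_x^{\mathsf T})^{-1}$ and convert to a reward through
   the Bellman identity.

The unidentifiable $x$-wise offset cannot be removed, so every analysis
that must not depend on it works with reward *profiles* centred across
network states: `recover_feature_partition()` clusters inputs by their
centred profile, which is invariant to the degeneracy, and for an
efficiently-coding network groups inputs exactly by the encoded feature
value. States of the joint chain visited fewer than `min_visits` times
(default 10) are masked rather than imputed.

## The benchmark environments

* **Maze** (`maze_spec()`, `build_maze()`): a 15×15 grid, four moves, 5%
  slip, walls blocking edges, a single rewarded cell teleporting to the
  start. The published layout of the walls is not available, so the
  default fixture generates a connected random barrier set from a pinned
  seed; every quantitative check depends only on the printed parameters
  (size, slip, reward placement), not the wall geometry. Reward is paid
  for occupying the rewarded cell, matching the state-based objective.
* **Two-level spike-count coding**: 8 neurons, a slow binary input
  (switch rate 0.02), reward 1 for exactly 2 spikes at $x=-1$ and 6 at
  $x=+1$, $\lambda = 0.114$. Sources differ internally on which input
  level pairs with which count; the package follows the figure-caption
  orientation (2 spikes at $x=-1$), which is also what its recovery tests
  assert.
* **Coupled pixel stimulus** (`pixel_stimulus_chain()`): $m$ pixels,
  one pixel resampled per step with
  $p(x_i' = 1\mid x) = \mathrm{logistic}(J\sum_j x_j - J_0)$. With
  $J = 1.5$ this is a cohering (ferromagnetic) Glauber chain whose
  patterns dwell near mostly-on/mostly-off, so the threshold feature
  $y(x) = \mathrm{sign}(\#\text{active} \ge 4)$ is slow enough to encode;
  positive $J_0$ suppresses activity. A literal reading of one published
  form of this rule reverses the sign of $J$, which makes the pixel count
  hover at the threshold, $y$ flip every few steps, and the feature
  essentially unencodable by any causal network — inconsistent with the
  published efficient-coding results themselves — so the package uses the
  cohering orientation.
* **Ring** (`make_reward("ring_adjacent")`): 12 neurons on a circle,
  reward 1 iff exactly 4 circularly adjacent neurons are active.

Simulations requiring a stochastic, non-degenerate optimum use the
population-averaged coding cost (`coding_cost_mode = "population"`), as the
original simulations do; the per-neuron mode admits trivial frozen optima
(a subset of neurons permanently active has zero per-neuron cost), which
the solver will happily find.

## Efficient coding

Maximising $I(y(x); \sigma) - \lambda \sum_i I(\tilde\sigma_i; \sigma, x)$
is the same objective with reward $r(\sigma,x) = \log p_\pi(y(x)\mid\sigma)$,
so `efficient_coding_optimize()` alternates a posterior/reward update with
network optimisation. Two numerical points:

* The exactly-uniform initial network is a degenerate fixed point (a flat
  posterior makes the reward constant), and at the reference $\lambda$ the
  flat point is locally attracting, so the loop is seeded with a small
  feature-aligned tilt of the initial tables (`init_bias`, default 0.01).
  The direction of the tilt picks one of the two flip-symmetric solutions;
  everything reported is invariant to that choice.
* The alternation is not provably monotone; the information trajectory is
  recorded and the best iterate returned. In practice the trajectory rises
  steeply and saturates within ~7 outer iterations at the reference
  settings ($m = n = 7$, $J = 1.5$, $\lambda = 0.167$, a $2^{14}$-state
  joint chain).

With a biased stimulus ($J_0 > 0$) the pixel chain becomes metastable
(subdominant eigenvalue within $2\times10^{-5}$ of one), and the
matrix-free iterative solvers cannot converge on it; joint spaces of up to
300 states therefore use dense direct solves. The published
population-splitting prediction under biased statistics is reproducible in
principle through the drivers, but the full 7-pixel version sits outside
the test suite's computational envelope, and at the sizes where direct
solves are cheap the symmetric solution remains stable — this is a known,
documented limitation rather than a tested claim.

## The pairwise-Ising track

For larger autonomous networks the value function is approximated by
$v_\phi(\sigma) = \sum_{i\ne j} J_{ij}\sigma_i\sigma_j + \sum_i h_i\sigma_i$
and trained by sampled TD descent against a bootstrap target with frozen
target parameters ($n_{batch} = 40$ samples per gradient step, target
refresh every $n_{epoch} = 100$ batches). Choices the published recipe
leaves open, and what this implementation does:

* **Differential form.** The bootstrap target subtracts a running
  average-return estimate (updated per batch, standard average-reward TD).
  Without it the target drifts by the average return at every refresh and
  training diverges for all but very small learning rates.
* **Learning rate.** $\eta = 0.05$ with $1/\sqrt{\text{round}}$ decay and
  250 target refreshes. The stability ceiling is set by the feature norm
  ($\eta \|f\|^2 \lesssim 2$ with $\|f\|^2 = \binom{n}{2} + n$), not by
  the reward scale.
* **Sampling.** On-policy trajectories with 5% exploration, and — the
  load-bearing choice — a chain reset before every batch to a randomly
  chosen maximal-reward state. The ring reward occupies 12 of 4096 states;
  an unguided chain either never finds it or locks the couplings onto one
  attractor. Resets cycling over the rewarded states keep the sampled
  distribution symmetric, and the trained couplings come out approximately
  circulant (positive at distance 1, negative at distance ≥ 3) with an
  activity bump that hops between rotations. A uniformly-weighted fit was
  tried and rejected on principle: under a near-uniform measure the
  quadratic projection of a 12/4096-sparse reward is numerically nil
  (verified by exact fitted value iteration), so the alternation cannot
  bootstrap — on-policy emphasis is essential, not incidental.
* **Safeguards.** L2 weight decay ($5\times10^{-3}$ per update) damps
  growth along directions the sampled states do not constrain; training
  aborts if $\|J\|_\infty > 10^3$.

Because the trained dynamics satisfy detailed balance, their stationary
law has the closed Gibbs form (`ising_stationary()`), and simulations draw
their initial state from it — a random start can trap a trajectory in a
metastable unrewarded basin, which says nothing about the trained model.

**Inverse direction.** `fit_ising_from_raster()` maximises the exact
transition likelihood of the observed single-flip chain (aggregated to
per-state flip/stay counts, analytic gradients, L-BFGS-B); rows flipping
more than one neuron are rejected and counted.
`infer_parametric_reward()` evaluates the implied reward
$\hat r_\phi$ on the states visited by a fresh $10^6$-step on-policy
trajectory and fits a reward model through the optimality moment
conditions $\langle f\, g^{\mathsf T}\rangle_D\,\theta =
\langle f\, \hat r_\phi\rangle_D$. The trajectory is ten times longer
than a naive choice because after convergence the bump needs
$\sim 10^{5.5}$ steps to revisit enough rotations for the visited-state
statistics to stabilise. The sparse model minimises total reward mass
subject to non-negativity and the moment conditions within a band
$\pm\varepsilon$ (default $10^{-6}\max|\hat r_\phi|$), via `boot::simplex`
with penalised slack variables, so an infeasible system returns the
minimal-relaxation solution with its slack reported. The pairwise and
global models are least squares on the same moments (SVD pseudo-inverse,
tolerant of rank deficiency).

**Prediction under perturbations.** An inferred reward is identified only
jointly with $\lambda$, and value-fit shrinkage biases its absolute scale,
so `perturb_and_predict()` can first calibrate the *effective* $\lambda$
of the inferred reward against the original condition (grid search
minimising the KL divergence to the original stationary law) and then
scale it by the prescribed relative change. Structural perturbations
retrain with couplings masked beyond a ring distance (severed
connections) or with neurons clamped active (pinning, excluded from the
coding-cost sum); tabular perturbations (cell removal, altered input
statistics) re-optimise exactly at matched coding cost via
`match_coding_cost()` (bisection on $\log\lambda$ to 2%).

One caveat the tests state precisely: at $\lambda = 0.05$ the trained ring
laws are sharp enough that the KL divergence between two *independently
retrained true-reward* networks is itself of order 1–2 nats (it is
dominated by which rotations happen to carry mass), so KL-based transfer
comparisons are only made between reward models fitted to the same data
(the sparse model predicts the high-coding-cost condition better than the
global model), not against that noise floor.

## What the synthetic benchmarks do and do not show

All data are generated by the package's own environments, so the tests
establish internal correctness (oracle agreement, detailed-balance
identities, parameter recovery, qualitative reproductions of the published
phenomena) under exactly-Markov, exactly-binary, stationary dynamics with
a single global objective. They do not probe model mismatch: refractory
structure, non-stationarity, unobserved neurons, heterogeneous objectives,
or constraints other than the coding cost. The finite-data tests (recovery
$r^2$ rising with sample count over $10^3..10^6$ samples) are the closest
proxy for real-data conditions.

Problem sizes were chosen so the full suite runs on a single CPU in tens
of minutes: exact tabular pipelines up to $2^{14}$ joint states, TD
training at $10^6$ sampled transitions, simulations of $10^5$–$10^6$
steps, and 8–20 seed replicates for the stochastic trend tests.
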