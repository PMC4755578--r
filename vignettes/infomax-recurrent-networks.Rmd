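---
title: "Infomax learning of recurrent interactions: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infomax learning of recurrent interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package studies a two-layer sensory rate network: $N$ input neurons
$x$ drive $M \ge N$ output neurons $s$ through a fixed feedforward matrix
$W$ ($M \times N$), and the outputs interact through a learnable recurrent
matrix $K$ ($M \times M$). Activities follow

$$\tau \dot s_i = -s_i + g\Big(\sum_j W_{ij} x_j + \sum_k K_{ik} s_k\Big),$$

with $g$ the logistic function and $\tau = 1$. For each fixed input the
network is run to its steady state $s = g(Wx + Ks)$, and that steady state
is the network's representation of the stimulus.

Because the map from input to steady state is deterministic, the mutual
information between $x$ and $s$ is governed by how strongly the map expands
input volumes. With the susceptibility (Jacobian) matrix
$\chi_{ij} = \partial s_i / \partial x_j$, maximizing information is
equivalent to minimizing

$$\varepsilon = -\tfrac12\,\big\langle \ln\det(\chi^T\chi) \big\rangle_x ,$$

the average over the stimulus ensemble of the negative log volume gain. At a
fixed point, $\chi$ solves the linear system $(I - GK)\chi = GW$, where $G$
is the diagonal matrix of gains $g'_i$ at the operating point.

Gradient descent on $\varepsilon$ with respect to $K$ gives the learning
rule implemented in `gradient_K()`:

$$\Delta K = \eta\,\big\langle (\chi\Gamma)^T + \phi^T a\, s^T \big\rangle,
\qquad
\phi = (G^{-1}-K)^{-1},\quad
\Gamma = (\chi^T\chi)^{-1}\chi^T\phi,\quad
a_k = [\chi\Gamma]_{kk}\,\frac{g''_k}{(g'_k)^3}.$$

The first term is the direct dependence of the log-determinant on $K$; the
second tracks the shift of the operating point (and hence of the gains) when
$K$ changes. The rule was re-derived by hand during development and is
verified in the test suite against central finite differences of
$\varepsilon$, which is the strongest internal check the package has.

## The ring model and its critical point

The analytically tractable case is a ring ("hypercolumn") of $M$ neurons
with preferred angles $\theta_i = 2\pi i/M$ and unit feedforward vectors
$W_i = (\cos\theta_i, \sin\theta_i)$. Inputs are points in the plane:
uniform angle, Gaussian radius with mean $\langle r\rangle$ (the mean
contrast) and standard deviation $0.1\langle r\rangle$. In the
low-contrast limit, a translation-invariant interaction profile with first
cosine harmonic $k_1$ (normalization $K(\theta) = \frac1M\sum_n k_n
\cos n\theta$) changes the objective by

$$\varepsilon(k_1) - \varepsilon(0) = 2\ln\!\big(1 - \tfrac12\gamma_0 k_1\big),$$

with $\gamma_0 = g'(0) = 1/4$ for the logistic. The objective decreases
monotonically in $k_1$ and diverges to $-\infty$ at the critical value
$k_1^c = 2/\gamma_0 = 8$: the infomax optimum sits exactly at the phase
transition where the homogeneous state destabilizes. Beyond it the network
falls into a self-sustained "hill" of activity at an arbitrary angle — an
attractor that no longer reflects the stimulus. `optimal_ring_K()`,
`analytic_objective_shift()` and `analytic_susceptibility()` expose these
closed forms; the numerics are required to reproduce them in the tests.

At finite contrast the operating point moves off $g'(0)$ and the optimum is
no longer exactly critical: training at $\langle r\rangle = 0.9$ learns a
weaker profile (amplitude near 5) with measurable higher harmonics, because
stronger inputs saturate the gains and recurrent amplification pays off
less.

## Numerical choices

**Fixed points.** The solver iterates the damped map
$s \leftarrow (1-\alpha)s + \alpha\,g(Wx+Ks)$ with $\alpha = 0.5$,
equivalent to forward Euler on the rate equation with step $\alpha\tau$.
Convergence is declared when every neuron moves less than `tol` (default
$10^{-9}$) in one step; this same per-neuron criterion defines the
convergence-time metric. The homogeneous initial state is $g(0)$;
supercritical runs add seeded Gaussian noise of scale $10^{-6}$ so the
symmetry can break (the hill's location depends on that noise realization,
so it is always seeded).

**Critical slowing down affects the solver too.** The damped map contracts
at a rate $1 - O(\delta)$ at distance $\delta$ from criticality, so plain
iteration becomes useless exactly where learning spends its final phase.
Paths that only need steady states (the objective, the gradient, training)
therefore run the damped iteration to a coarse $10^{-5}$ criterion — enough
to select the dynamically stable branch — and finish each sample with
Newton iterations on $F(s) = s - g(Wx+Ks)$, which stay quadratic until
$I - GK$ is numerically singular. Dynamical timing metrics
(`convergence_time()`, the `steps` column of `scaling_sweep()`) use the
pure damped iteration, since there the slow relaxation is the measurement.

**Susceptibility.** $\chi$ and $\phi$ come from one LU factorization of
$I - GK$ with stacked right-hand sides; $G^{-1}$ is never formed, so tiny
gains are harmless. The reciprocal-condition estimate of $I-GK$ is
reported, and values above $10^{12}$ raise an error identifying the input
as at/beyond criticality. $\ln\det(\chi^T\chi)$ is computed by Cholesky on
the small $N\times N$ matrix.

**Subcritical validity constraint.** The objective's information reading
rests on a smooth, invertible input-to-output map with a well-defined
Jacobian. Once the zero-input homogeneous state destabilizes — spectral
radius of $\gamma_0 K$ reaching 1 — the network enters the attractor
regime: weak stimuli produce pinned hills, the output space fragments, and
$\ln\det(\chi^T\chi)$ evaluated at those attractors is no longer a
mutual-information surrogate (it is dominated by the soft rotation mode of
the hill and can decrease without any gain in information). Left
unconstrained, batch gradient descent at low contrast does exactly this:
it crosses the critical point and keeps "descending" inside the invalid
regime. Training therefore rejects any trial update whose $\gamma_0 K$
spectral radius reaches 1, treating it like an objective increase
(learning-rate halving); `scaling_sweep()` applies the same rule,
recording $\varepsilon$ as missing at supercritical scales while the
dynamical metrics (convergence steps, population vector) remain defined
there. With this constraint the low-contrast ring converges onto the
critical surface from below, reproducing the cosine profile at amplitude
8 rather than overshooting it.

**Lookahead halving.** With lookahead on, each training step evaluates the
objective that the trial update would produce on the *current batch*; an
upcoming increase rejects the step, halves $\eta$ and retries. Evaluating
on the same batch is the cheapest faithful estimator of the "expected value
of the objective before updating"; it also means a rejection always
reflects a genuinely too-large step (to first order a small step along the
batch gradient cannot increase the batch objective), so $\eta$ is not
consumed by sampling noise. Training stops at `max_steps` or when $\eta$
falls below $10^{-7}$.

**Training scale.** Learning is full-matrix: all $M^2$ entries of $K$ are
free and translation invariance of the learned ring profile emerges from
the input statistics; it is never imposed. Package defaults are desk-scale:
$M = 41$ ring (the closed-form predictions are $M$-independent in this
normalization), batches of 100 inputs, $\eta_0 = 0.02$, 1200 steps. These
runs land within a few percent of the analytic optimum; the residual gap is
dominated by the finite-contrast correction, not by the optimizer.

## The synthetic-texture generator

The ecological model trains on image patches. In place of photographs the
package generates random-phase textures whose radially averaged power
spectrum falls as $f^{-2}$, matching the canonical natural-image statistic,
with RMS pixel contrast set to 35% of the half-range so low contrasts
dominate. What the generator reproduces: the spatial correlation structure
that makes whitening and the low-contrast operating regime meaningful. What
it does not: higher-order structure of natural scenes (edges, occlusions,
phase alignments across scales). Consequently the package's ecological
results are the qualitative ones — a Mexican-hat interaction profile in
preferred-orientation difference, near-symmetric interactions, recurrent
amplification of matched probes — and nothing finer; passing tests say
nothing about exact interaction profiles under real photographs.

The pipeline follows the standard route: random $25\times25$ patches, PCA
reduction, whitening by $\lambda^{-1/2}$ scaling of the eigenvectors (with
an eigenvalue floor of $10^{-8}$ times the leading eigenvalue), and a bank
of $M$ Gabor filters sharing center, wavelength (8 px) and envelope
($\sigma = 4$ px), spanning orientations at $180^\circ/M$ spacing. The
feedforward matrix is the product of the filter bank with the PCA
reconstruction map. Gabor parameters are configurable; the defaults put
about two carrier cycles under the envelope of a 25-px patch.

One scale is genuinely open: the mapping from byte-valued pixels to network
input units. Raw whitened codes would saturate the logistic and the
literature leaves the choice implicit. The package fixes it by rescaling
the whitened codes with a single global factor so the mean RMS feedforward
drive per neuron is 0.1 — the same low-contrast regime in which the ring
model's infomax optimum is near-critical, and the regime that the contrast
statistics of natural images themselves favor. Oriented Gabor probes for
response curves are scaled to the mean norm of the training codes ("mean
training contrast"), and contrast sweeps multiply that probe.

A bank that shares center, frequency, envelope and phase is, as a linear
operator, of low effective rank: its filters span only the azimuthal
harmonics under the spectral annulus of the Gabor, about nine dimensions
for the default parameters. Since $\chi = \phi W$ can never exceed the rank
of $W$, the log-determinant objective is finite only when the whitened
input dimension stays at or below that rank; `image_network()` checks the
conditioning of the composed feedforward matrix and refuses rank-deficient
configurations. Desk-scale ecological runs therefore use $M = 60$
orientations over $d = 8$ whitened dimensions, a few thousand patches and
a few hundred training steps; the Mexican-hat shape appears early in
training, consistent with the observation that the profile's shape forms
before its scale finishes converging.

## Conventions and degenerate cases

* Ring angles are $2\pi(i-1)/M$, spanning $[0, 2\pi)$; the toy model uses
  full 360° periodicity. Orientation doubling (mapping a 180°-periodic
  preference onto the full circle) is applied only in population-vector
  computations for orientation data, and the resultant phase is halved
  back.
* In the Fourier normalization $K(\theta)=\frac1M\sum k_n\cos n\theta$,
  $k_0$ is the profile mean; the closed-form results involve only $k_1$.
  A non-circulant matrix is circularly averaged over its diagonals first
  and the relative RMS residual of that averaging is reported as the
  departure from translation invariance.
* `solve_fixed_point()` returns `converged = FALSE` at `max_iter` instead
  of raising, so scaling sweeps can record non-convergence near
  criticality; NaN during iteration (divergent dynamics) is an error.
* Exactly at $k_1 = 8$ with zero input the uniform state is an exact fixed
  point and all closed forms are evaluated there without a limit; with
  $\varepsilon$ undefined beyond the critical point, supercritical scales
  in a sweep record `NA` rather than failing the sweep.
* Self-connections $K_{ii}$ are learned like any other entry; a config
  flag can zero them.

## Known limitations

* The learning loop is O(batch × $M^3$) per step from the per-sample linear
  solves; it is comfortable up to a few hundred outputs but not tuned for
  the full 380-unit ecological network at long training horizons.
* Only the recurrent matrix is learned; the feedforward side (and its
  emergence as Gabor filters under ICA-style learning) is outside the
  package's scope.
* The deterministic rate model has no noise channel, so "mutual
  information" is always the deterministic-map volume term; entropy
  estimation from sampled outputs is deliberately absent.
* The lookahead estimator evaluates on the current batch only; with very
  small batches near criticality the accepted-step guarantee is per batch,
  not per ensemble.
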