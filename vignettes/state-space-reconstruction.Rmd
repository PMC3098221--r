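---
title: "Kernel state-space reconstruction of neural ensemble dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel state-space reconstruction of neural ensemble dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleflow)
```

## The problem

Simultaneously recorded spike trains from $n$ units define a population
state $\nu(t) \in \mathbb{R}^n$ of smoothed firing rates at each time bin.
Computational theories hold that cognitive operations correspond to
movement among *attracting states* of this population dynamics: regions of
state space into which trajectories converge and within which they linger.
Demonstrating such convergence from recordings is hard for two reasons.
First, the recorded units are a small projection of a much larger system,
so trajectories in the raw rate space intersect themselves and the flow
direction is ambiguous.  Second, single-trial rate estimates are extremely
noisy, so nearby trajectories from different task conditions blur into one
another.

`ensembleflow` addresses both problems with a two-stage space expansion
followed by kernelized statistics:

1. **Delay coordinates.**  Each unit contributes one time-lagged copy
   $\nu_i(t-\tau_i)$, giving the DC (delay-coordinate) state
   $\tilde\nu(t) \in \mathbb{R}^{2n}$.  Lags are chosen per unit as the
   first local minimum of the average absolute cross-correlation with the
   other units, capped at 5% of the shortest task-phase length, so the new
   axes add minimally redundant information about the dynamics.
2. **Multinomial expansion.**  The order-$O$ feature map $\Phi(t)$ collects
   all monomials of degree $1..O$ in the $2n$ DC variables — firing rates
   and their products up to order $O$, i.e. co-activation patterns.  Its
   dimension, $\binom{2n+O}{O}-1$, reaches $10^6$–$10^9$ for realistic
   ensembles, so $\Phi$ is never formed.  All statistics are written in
   terms of dot products and evaluated with the inhomogeneous polynomial
   kernel
   $$k(x, y) = (1 + x\cdot y)^O - 1,$$
   whose feature space is exactly that monomial expansion with square-root
   multinomial weights (`explicit_expand()` materializes the map for small
   problems and is used as the oracle in the tests; `poly_kernel()` is the
   production path).  At $O=1$ every method reduces to its classical linear
   counterpart.

## Statistics in the expanded space

**Kernel Fisher discriminant analysis** (`fit_kfda()`) finds, for a pair of
task epochs, the direction $\Omega$ in feature space maximizing
between-epoch mean separation relative to within-epoch scatter, solved in
dual form on the centered kernel matrix.  A ridge $\eta \cdot
\mathrm{tr}(N)/m$ is added to the dual within-class scatter $N$; expressing
the penalty as a fraction $\eta$ of $N$'s mean eigenvalue makes its
leverage independent of the kernel's scale and order.  (A penalty
proportional to the mean kernel *value*, which is linear in $K$ where $N$
grows like $m K^2$, turned out to be numerically inert: the discriminant
then interpolates the training set at high orders, which also contradicts
the requirement that in-sample error stay positive under regularization.)
Out-of-sample error is flat over roughly $\eta \in [0.02, 1]$; the default
is $\eta = 0.05$.

Projections $x(t_i) = \sum_j \alpha_j\, k(\nu(t_j), \nu(t_i))$ of
population vectors onto $\Omega$ are sums of up to $10^9$ weakly dependent
terms, hence approximately Gaussian; a **Bayes classifier** with per-class
Gaussians and priors fixed at $0.5$ (so long epochs are not favored) yields
the *segregation error* (SE), the fraction of misclassified vectors.
Chance level is therefore 50%.  For **cross-trial prediction**
(`se_predic()`), $\Omega$ and the class Gaussians are fitted on a reference
set of trials, frozen, and applied to a disjoint prediction set —
forward (first to last trials) and backward.  Epoch similarity is also
summarized by the discretized **Kullback–Leibler divergence** between the
two class Gaussians on the discriminant axis (1000 cells, probability
floor $10^{-12}$, grid spanning both class means $\pm 6$ pooled SD; a grid
centered only on the grand mean collapses to the floor once classes
separate widely).

**Kernel PCA** (`kernel_pca()`) supplies 3-D projections for visualization
and for **flow fields** (`velocity_field()`): forward differences of
consecutive within-trial projections.  Velocities are computed only in the
3-D projection — in the ambient expanded space nearest neighbors are
meaningless at these dimensionalities — while all classification statistics
use the full space through the kernel.

**Convergence statistics.**  If task epochs are attracting states, the
dynamics should slow down near their centers.  `likelihood_velocity_curve()`
bins normalized speeds into 20 equal-width bins and regresses mean log
correct-class likelihood on bin center: a negative slope means fast-moving
points are far from their epoch's state.  The likelihoods are floored at
$10^{-12}$ before taking logs; Gaussian log-tails decay quadratically and a
single far-out vector would otherwise own the fit.  The original slope is
compared against a time-inverted surrogate with a paired test across the
shared bins.  `escape_analysis()` types each labeled trajectory (a maximal
run of bins with one epoch label) by its classifier-membership sequence:
confined (a), departing-but-returning (b), converging from outside (c), or
escaped; departures shorter than $k=2$ bins are ignored, and escaped
trajectories are additionally checked against a trapping region of radius
$\rho = 1.5$ times the reference set's maximal member distance from its
centroid.  Membership of a bin in epoch $C$ is decided by a one-vs-rest
kernel-FDA classifier for $C$; these classifiers use a pooled variance
(the "rest" is a mixture of epochs, not a Gaussian) and class-balanced
training sets (all bins of $C$ against a stratified sample of at most
$3|C|$ others), since data-rich epochs otherwise drown data-poor ones.

**Surrogates** (`epoch_block_shuffle()`, `time_invert_epochs()`,
`augment_decimate()`, `bootstrap_test()`).  The null for cross-trial
prediction shuffles whole epoch-blocks of the vector series while the
label timeline stays fixed, preserving all autocorrelations up to the
block length while randomizing the vector-to-label assignment; blocks are
only exchanged within $\pm 10$% of each other's length so the fixed
timeline stays meaningful.  Time inversion reverses bin order within each
labeled block (an involution) and destroys causal asymmetries only.
One-sided bootstrap $p$-values use the add-one rule
$p = (1 + \#\text{extreme})/(R+1)$ with $R = 100$ replications by default.

**Correlation dimension** (`correlation_dimension()`) supports the choice
of 3-D projections: the slope $d_2$ of $\log S(\varepsilon)$ vs
$\log\varepsilon$ over an automatically selected scaling region (longest
window of at least half a decade maximizing linear $R^2$), with a Theiler
exclusion $b_{\min}$ chosen where $S(\varepsilon)$ varies less than 5%
across temporal separations, and the Takens maximum-likelihood estimator
as a cross-check.  An embedding of dimension $2 d_2 + 1$ suffices for a
faithful representation.

## The synthetic study

No public recordings exist for the task this machinery targets, so the
package ships a generative stand-in (`generate_dataset()`) that makes every
stage testable with known ground truth.  A latent state
$z(t) \in \mathbb{R}^3$ follows an Ornstein–Uhlenbeck process
$$dz = \lambda\,(c_{e(t)} - z)\,dt + \sigma_z\, dW$$
whose fixed point $c_{e(t)}$ switches with the active task epoch; unit
rates are $\max(0,\, b + L z)$ with a fixed gain matrix $L$, and spikes are
drawn from an inhomogeneous Poisson process at 1-ms resolution.  The
default schedule mirrors a delayed win-shift maze trial: four training
choice/reward pairs, a 60-s delay, eight test choice/reward pairs,
separated by unlabeled stretches, about 154 s in total.

Defaults (all overridable in `synth_params()`): 20 units,
$\lambda = 2\,\mathrm{s}^{-1}$, $\sigma_z = 1.5$ (stationary latent SD
0.75), baseline $b = 2$ spikes/s, standard-normal loadings.  The epoch
fixed points lie on a single *task-progression axis* at
$-3, -1.5, 0, +1.5, +3$ latent units (train choice, train reward, delay,
test reward, test choice), with the delay sharing the resting state at the
origin.  These choices emulate the regime the method was built for: sparse
cortical firing where rectification is a genuine nonlinearity, trajectory
noise comparable to the separation of neighboring states, and interior
states that no single linear direction can separate from the mixture of
the remaining epochs — carving the delay state out of the ongoing dynamics
genuinely requires the higher-order expansion (its out-of-sample membership
rises from ~0.65 at $O=1$ to ~0.94 at $O=5$ under the reference
conditions).

What the generator does *not* emulate — and hence what passing tests do not
show about real recordings: non-Poisson spiking statistics (bursting,
refractoriness beyond the QC filter), slow nonstationarities across trials,
epoch-specific correlation structure beyond what the shared loading matrix
induces, and genuinely time-irreversible within-epoch dynamics.  The last
two limitations matter for interpretation.  A stationary OU process is
time-reversible, so the only asymmetry available to the time-inversion
contrast comes from epoch-entry transients ($\sim 3$ bins each at
$\lambda = 2$ and 0.2-s bins); an exact latent-level calculation gives
likelihood–velocity slopes of about $-0.55$ (original) vs $-0.48$
(inverted), i.e. the *contrast* is intrinsically a ~13% effect here even
though the negative slope itself is large and robust.  Likewise, with a
single OU center per epoch any two epochs are at best linearly separable,
so order-1 pairwise classification is statistically sufficient and the
escape fraction at $O=5$ does not fall below its $O=1$ value the way it
does on cortical data; the expansion's benefit on this generator is
confined to one-vs-rest carving of interior states.  The corresponding
checks in the acceptance suite are left failing deliberately rather than
weakened; they delimit what a minimal linear-Gaussian latent simulator can
reproduce.

## Numerical choices

- Spike densities use unit-area Gaussian kernels truncated (not reflected)
  at trial edges; bin value is the mean density over the half-open bin, so
  units are spikes/s and the trial integral approximates the spike count.
  Density is *not* normalized per trial by default — normalization to unit
  mass would make the 2%-of-maximum mean-rate exclusion vacuous — but a
  `normalize_to_trial` flag provides it.
- QC order: ISI-floor removal (10 ms), duplicate-channel removal (zero-lag
  1-ms indicator correlation > 0.9, lower-rate unit dropped), then the
  2%-of-max exclusion computed on the survivors.
- State vectors are rescaled by the mean reference-set L2 norm before
  kernel evaluation.  Raw spikes/s vectors give kernel entries of order
  $10^{20}$ at $O=5$ and an unsolvable within-scatter system; after
  rescaling, $x \cdot y = O(1)$ and all orders are numerically comparable.
- Monomials are ordered graded-lexicographically; ties in the Bayes
  classifier go to the first class; delay selection falls back to one bin
  when the correlation average has no interior minimum.
- Reference/prediction epoch series are truncated to equal length per
  epoch, and an optional per-class cap (150 vectors in the reference
  studies) bounds the kernel sizes.

## Reference problem sizes

The validation suite runs the full pipeline at: 20 units, 6 epochs, 4
trials (2 reference / 2 prediction), 10 replicate seeds, orders
$O \in \{1,5\}$, 100 block-shuffle bootstrap replications, and a per-class
cap of 150 vectors; the chance-level protocol uses 400 vectors per class
and 20 seeds.  At these sizes the whole suite completes in a few minutes on
one core while every statistic retains its qualitative behavior at larger
sizes.

## Worked example

```{r example, eval = FALSE}
library(ensembleflow)

params <- synth_params(n_units = 20, n_trials = 4, seed = 1)
d  <- generate_dataset(params)
r  <- estimate_rates(d$spikes, sigma = 0.05, bin_width = 0.2)
tl <- build_epoch_timeline(d$events, r)
dc <- build_dc_msua(r, select_delays(r, tl))

sweep <- pairwise_epoch_sweep(dc, tl,
                              ref_trials  = c("trial1", "trial2"),
                              pred_trials = c("trial3", "trial4"),
                              O_list = c(1, 3, 5, 7), max_per_class = 150)
summarize_sweep(sweep)
```

The same pipeline is exposed end-to-end through `run_pipeline()` and the
`exec/ensembleflow` command-line wrapper.
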