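---
title: "Emergent receptive-field and lateral-connectivity geometry: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent receptive-field and lateral-connectivity geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, the numerical
choices, and the known limitations.

## The models

### Receptive profiles

Two closed-form receptive-profile models anchor the analysis. The
Laplacian of Gaussian

$$\psi_{\mathrm{LoG}}(x,y) = -\frac{1}{\pi\sigma^4}
  \Big[1 - \frac{x^2+y^2}{2\sigma^2}\Big]
  e^{-\frac{x^2+y^2}{2\sigma^2}}$$

models the radially symmetric center-surround profiles of LGN cells: a
band-pass filter with zero DC response, negative center (in this sign
convention) and a positive surround ring at radius $\sqrt{2}\,\sigma$.
The Gabor family

$$\psi(x,y) = A\, e^{-\tfrac{1}{2}\big(u^2/\sigma_x^2 + v^2/\sigma_y^2\big)}
  \cos(2\pi f u + \phi), \qquad
  (u,v) = R_{-\theta}(x-x_0,\, y-y_0)$$

models V1 simple cells: an oriented carrier of frequency $f$ under an
anisotropic Gaussian envelope. The phase $\phi$ fixes the parity: odd
profiles ($\pi/4 < |\phi| \le 3\pi/4$) respond to boundaries, even ones
to interiors. One deliberate parameterization choice: the carrier
frequency multiplies the *undilated* rotated coordinate, so $f$ and the
envelope scales are separately interpretable (the common convention in
the Gabor-fitting literature); with unit scales the canonical form above
is recovered literally.

**Coordinates.** Every $s\times s$ filter lives on the normalized grid
$x,y \in \{-1, \dots, 1\}$ with $s$ points per side; $x$ grows with the
column index, $y$ grows *upward*, and angles are counter-clockwise from
$+x$, $\pi$-periodic wherever they denote undirected orientation. This
single convention is used everywhere — fitting, kernel geometry,
rendering — so no axis flip ever happens mid-pipeline. Fitted $\sigma$
values are reported in these normalized units (an $11\times 11$ filter
spans 2 units, so one pixel is $2/10$ units).

### The sub-Riemannian geometry of association fields

The position-orientation space $\mathbb{R}^2 \times S^1$ carries the
contact structure generated by $X_1 = (\cos\theta, \sin\theta, 0)$ and
$X_2 = (0,0,1)$. Integral curves of $X_1 + k X_2$ project to circular
arcs of curvature $k$; the package's `integral_curve()` implements them
in closed form, switching to the analytic straight-line limit for
$|k| < 10^{-8}$ to avoid catastrophic cancellation in $\sin(kt)/k$.
These arcs serve three roles: the model that association fields are
compared against, the oracle for the arc-fitting code, and the contour
generator for synthetic images.

## The network

The classifier is a standard convolutional stack with two modifications.
A single-filter convolutional layer $\ell^0$ (filter $\Psi^0$, then ReLU
and batch normalization) precedes the stack, playing the role of the
LGN's single pre-filtering channel. The first standard layer $\ell^1$
carries, besides its filter bank, a lateral connectivity kernel
$K^1(i,j,f,g)$ over spatial displacements $(i,j) \in \{-r,\dots,r\}^2$
and filter pairs $(f,g)$, applied to the post-batch-norm activation
through the diffusion update

$$\tilde h = \tfrac{1}{2}\big(h + K^1 * h\big),$$

a discretized Wilson–Cowan step with linear activation. Iterating the
update once more gives
$\tfrac14\big(h + (2K^1 + K^1{*}K^1) * h\big)$: lateral propagation
*self-replicates* into a longer-range kernel $2K^1 + K^1{*}K^1$ on the
enlarged support. Under zero padding this is an **interior identity**:
it is exact wherever the activation vanishes within $2r$ of the border,
because the intermediate activation is cropped to the layer size between
the two steps. Tests therefore verify it on zero-margined activations,
where it holds to $10^{-10}$.

Design choices the architecture description leaves open, and how they
were resolved:

- *Update-rule reading.* The rule is implemented as
  $\tfrac12(h + K*h)$ — the only scaling consistent with the
  self-replication identity above.
- *Feedforward phase semantics.* In the pre-training phase the lateral
  step is skipped entirely ($\tilde h = h$, not $h/2$): the phase is
  defined by the absence of lateral connections, and a global $1/2$
  would anyway be absorbed by the following layer's batch
  normalization.
- *Placement.* The lateral update acts on $h^1 = \mathrm{ReLU}(z^1)$
  after batch normalization, i.e. on the layer's advertised output.
- *Borders.* $K*h$ uses zero padding, matching the zero padding that
  keeps spatial sizes constant throughout the stack.
- *Lateral dropout.* Dropping 20% of lateral connections per weight
  update is implemented as an elementwise Bernoulli mask on the kernel
  entries, with inverted-dropout rescaling of the surviving entries so
  the expected propagated activation is unchanged.
- *Initialization of $K^1$.* Zero-mean uniform entries scaled by
  $1/(n D^2)$ ($n$ filters, $D\times D$ support), so the initial
  propagated term is small relative to the feedforward one; the
  architecture description says only that it starts random.
- *Optimizer.* SGD with momentum 0.9, weight decay $5\times 10^{-4}$,
  batch 128 (64 at desk scale), 90/10 train/validation split — standard
  values, all exposed in `training_config()`, since none are specified
  by the study design. Early stopping *halts* a phase and the network
  keeps the weights it had at the stop; no best-epoch snapshot is
  restored, because on a small validation split the "best" epoch is
  often an early, noisy one, and restoring it would hand the geometric
  analyses a less-trained filter.

The networks are trained in two phases: all weights except $K^1$ first
(feedforward pre-training, emulating the maturation of feedforward
tuning before horizontal connections develop), then everything jointly
with the lateral kernel freshly initialized. Both phases use early
stopping on validation accuracy.

## Fitting learned filters

`fit_log()` profiles out a free *sign-free* amplitude multiplier
analytically and optimizes $\sigma$ by a coarse log-spaced scan plus
golden-section refinement. The amplitude is free because a trained
filter's scale is arbitrary under batch normalization, and sign-free
because either polarity can emerge; $\sigma$ is unaffected by the
multiplier.

`fit_gabor()` is a full nonlinear least-squares fit of all eight Gabor
parameters by Levenberg–Marquardt. The objective is nonconvex, so the
fit multi-starts over $\theta \in \{0, \pi/8, \dots, 7\pi/8\}$,
$\phi \in \{0, \pm\pi/2, \pi\}$ and $f \in \{0.5, 1, 2\}$ (clamped below
the Nyquist bound), initializing center and scales from intensity
moments, pre-screening starts by residual and refining the best eight.
Scales and frequency are optimized on the log scale to stay positive.
One bound matters: the carrier frequency is constrained below the
sampling grid's Nyquist frequency $(s-1)/4$ cycles per normalized unit.
Above it, aliased Gabors exist that reproduce the $s\times s$ samples
equally well at a spurious orientation — with the bound in place,
noiseless synthetic banks are recovered orientation-perfect, and the
frequency is interpretable.

Parity boundaries: the odd/even rule uses strict inequalities in its
source formulation, leaving $|\phi| \in \{0, \pi/4, 3\pi/4, \pi\}$
unassigned; the package closes the lower end of each interval
($\pi/4$ even, $3\pi/4$ odd), a measure-zero choice made testable.
"Central lobe" for even-filter sign normalization means the filter value
at the grid point nearest the fitted center. Filters whose best Gabor
correlation falls below 0.5 (configurable) are flagged "complex shape"
and excluded from kernel geometry — trained banks do contain such
filters, and no quantitative exclusion rule is given in the study
design, so the threshold is exposed rather than hidden.

## Kernel geometry

`reparameterize()` moves $K^1$ into relative position-orientation
coordinates: restrict to same-parity filter pairs, translate each
$(f,g)$ spatial slice by the rounded difference of fitted centers so
that displacement $(0,0)$ means coincident centers, and permute the
filter axes into ascending-$\theta$ order. Shifts are rounded to whole
cells — the support is only $13\times 13$ and fitted centers carry
sub-pixel noise, so interpolation would mostly smear; the absolute mass
shifted out of support is returned as a diagnostic rather than silently
lost.

The hypercolumn profile is the $(0,0)$ spatial slice as a function of
$\theta_g$, optionally smoothed by a centered moving average (window 5
samples) that wraps circularly because orientation is $\pi$-periodic.
The planar vector field takes, at each displacement, the kernel-weighted
sum of unit vectors $v_g = (\cos\theta_g, \sin\theta_g)$, normalized and
scaled by the fiber maximum. Because all $v_g$ live in the upper half
plane, weights concentrated near the $0/\pi$ seam can cancel; such
degenerate points receive the zero vector and terminate streamlines.
This is also why the analysis picks its reference filter near the
*median* orientation of the parity group: a reference at the seam would
sit exactly in the degenerate regime. Streamlines are integrated with
fixed-step RK4 (step 0.1 cells, at most $10^4$ steps per direction) on
the bilinearly interpolated direction field, forward and backward from
seeds placed along the trans-axial segment through the origin (7 seeds,
0.5 cells apart — the seed layout is unspecified in the study design and
fully configurable). The field is computed on the raw lattice and
interpolated, not recomputed on an upsampled kernel; upsampling is
display-only (`project_spatial()`, lattice-preserving bilinear
refinement).

`fit_arc()` fits the curvature $k$ of the integral-curve arc through a
curve's anchor with the reference orientation, matching points by
*signed arc length* from the anchor. Chord lengths are converted to arc
lengths under the candidate curvature ($2/k \cdot \mathrm{asin}(kc/2)$),
which makes the fit exact on curves sampled from true arcs;
$k$ is found by a 101-point scan on $[-5, 5]$ plus golden-section
refinement. Two-sided streamline curves are fitted with their interior
anchor (the seed), since the arc family is defined through that point.

## Synthetic generators

The generators are first-class, tested code: they define the conditions
under which every claim in the test suite is evaluated.

- `make_log_filter()` renders the LoG surface plus peak-scaled Gaussian
  noise.
- `make_gabor_bank()` samples Gabor parameters from ranges chosen to
  resemble a trained first layer: evenly spaced or uniform orientations,
  moderate anisotropy, frequencies in $[0.7, 1.35]$ cycles per unit —
  high enough to act as boundary detectors, strictly below the $7\times
  7$ grid's Nyquist band so the parameters are identifiable from the
  samples (the generator refuses super-Nyquist ranges). Phases keep a
  0.15 rad margin from the parity boundaries so parity ground truth is
  unambiguous.
- `make_cocircular_kernel()` builds a lateral kernel directly in
  relative position-orientation coordinates: spatial Gaussian decay,
  concentration along the reference orientation's axis, and preference
  for the orientation obtained by transporting $\theta_f$ co-circularly
  to the displaced position ($\theta^* = \theta_f + 2\beta(\varphi -
  \theta_f)$, $\beta \in [0,1]$ the co-circularity strength; $\beta = 0$
  is pure collinearity). At zero displacement the orientation profile is
  a difference of Gaussians — excitation at zero offset, inhibitory
  flank — so Mexican-hat extraction has analytic ground truth; off
  center the tuning is purely excitatory, keeping the vector field
  well defined. This is a parametric model inspired by edge
  co-occurrence statistics, not a solution of any diffusion equation:
  tests need analytic ground truth, and qualitative co-circular
  structure is the target. Fitted arc curvature grows with $\beta$ in
  the perturbative regime ($\beta \lesssim 0.5$) and saturates beyond
  it, as the transported orientations rotate out of the axial
  concentration band — the tests assert monotonicity where the
  construction implies it.
- `make_oriented_image_dataset()` renders antialiased circular-arc
  contours over 1/f background noise. Class = curvature regime
  (near-straight, $|k| \le 0.05$ px$^{-1}$, vs strongly curved,
  $|k| \in [0.25, 0.45]$); position and initial orientation are uniform,
  so the orientation marginal of contour tangents is uniform by
  construction. Two statistics of natural images are deliberately
  emulated because the LGN-filter result depends on them: *signed*
  stroke contrast (each arc is randomly bright or dark, as real
  boundaries are) and spatially correlated 1/f background (amplitude
  0.4 relative to unit strokes). A polarity-neutral, band-pass front
  end — i.e. a center-surround filter — is the efficient single-channel
  code for such stimuli; with unsigned strokes or white backgrounds that
  pressure disappears and the LGN filter has no reason to become
  LoG-like. The curvature gap between classes is wide enough that the
  reduced network can learn the discrimination from ~$10^3$ images.

What the generators do **not** emulate: occlusion, textures, luminance
gradients, class semantics, scale variation, or the full power spectrum
of photographs. Passing tests therefore show that the *pipeline* is
correct and that the emergence mechanism operates under controlled
statistics — not that any particular quantitative outcome transfers to
natural images.

## Problem sizes and study conditions

The package's own experiments run at desk scale, chosen once: training
uses 1200 images of $16\times 16$ px, a reduced stack (LGN filter
$7\times 7$, first layer 12 filters with a $7\times 7$ lateral kernel,
two more conv layers, 64-unit head), SGD at learning rate 0.02, batch
64, up to 40 epochs per phase with patience 15. The end-to-end geometry
analysis uses 32-orientation banks and kernels of radius 6. The
full-scale configuration (grayscale natural images such as CIFAR-10, 64
filters, $13\times 13$ kernel, 800-epoch phases) is expressible with the
same configuration objects but is not run by the tests: it requires an
external dataset and long training, and the package makes no
quantitative claims about its outcomes at desk scale.

## Known limitations

- The interior self-replication identity breaks within $2r$ of the
  border under zero padding; wider-field analyses should embed
  activations accordingly.
- Gabor fits on $7\times 7$ grids are near-degenerate for low-frequency,
  near-isotropic filters; the Nyquist bound removes frequency aliases
  but cannot manufacture identifiability where the data lack it.
- The vector field inherits the antiparallel-cancellation degeneracy of
  summing orientation unit vectors near the $0/\pi$ seam; analyses
  should (and by default do) use references away from the seam.
- Batch-norm scale invariance means the LGN filter's norm is
  meaningless; only its shape (and hence the LoG correlation) is
  interpretable.
- Training at desk scale is a smoke-scale demonstration: accuracies and
  emergence effects are real but small-sample, and run-to-run
  variability is substantial. In seed sweeps under the default
  conditions, whether the LGN filter's LoG correlation rises during
  training depends mainly on the *dataset realization* (for some
  1200-image samples every initialization gains, for others the filter
  converges to an oriented or irregular shape instead), and the LoG
  correlation of a random initial 7x7 filter is itself broadly
  distributed (~0.1–0.4). The smoke test demonstrates the mechanism at
  a fixed seed; the acceptance script reports the initial and trained
  correlations separately so that either outcome is visible. Only much
  larger natural-image training can show the effect as a population
  tendency.
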