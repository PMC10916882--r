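---
title: "The six-mass vocal-fold model and its neural inverse surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The six-mass vocal-fold model and its neural inverse surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The forward model

`sixmass` simulates a dimensionality-reduced, one-dimensional six-mass model
of vocal-fold (VF) oscillation. Each fold is a 3 (longitudinal: posterior,
medial, anterior) x 2 (vertical: lower, upper) grid of point masses whose
motion is restricted to the lateral direction — the direction in which a
high-speed camera above the glottis sees the fold edges move. Twelve masses
in total, with the glottal midline at lateral position zero, left masses
signed negative.

Five force families act laterally on each mass:

* **Anchor force.** A damped spring to a per-pair rest position $x^r$, with a
  cubic stiffening term: $F^a = -k_a\,\Delta x\,(1 + \eta\,\Delta x^2) -
  r_a\,\dot x$, where $\Delta x = x - x^r$. The cubic coefficient $\eta =
  100\,\mathrm{cm}^{-2}$ follows the classical two-mass-model convention in
  which the deflection is expressed in cm; the package converts internally.
* **Vertical and longitudinal coupling.** Springs with free lengths
  $\ell_v$ (between the two members of a vertical pair) and $\ell_l$
  (between longitudinally adjacent masses) transmit their *entire* response
  laterally: magnitude $k\,(\sqrt{d^2 + \ell^2} - \ell)$ for lateral offset
  $d$ between the spring's ends, directed to restore $d \to 0$. The sign of
  the direction is smoothed as $2\sigma(d/\varepsilon) - 1$ (default
  $\varepsilon = 1$ mm, configurable as `smooth_eps`) so the force is
  continuous — and exactly zero — at $d = 0$. Each longitudinal chain is
  `fixed--P--M--A--fixed`, with fixed lateral end positions $\pm 0.05$ mm
  (posterior) and $0$ (anterior); a chain-end spring uses twice its single
  adjacent anchor stiffness so that every longitudinal stiffness is
  $\xi_l \cdot (\text{summed adjacent anchor stiffnesses})$ with $\xi_l = 0.2$.
* **Collision force.** When the left mass of a (section, level) pair crosses
  its right partner by $p > 0$, a zero-free-length spring of stiffness
  $k_c = 3\,\xi_c\,\bar k_a$ pushes both back with force $k_c\,p/2$ (the
  half-penetration per side), equal magnitude and opposite sign. The factor
  3 is the classical collision-stiffness convention relating $k_c$ to the
  anchor stiffness; $\bar k_a$ is the mean of the two colliding masses'
  anchor stiffnesses so the force stays antisymmetric under asymmetric
  stiffness scalings.
* **Bernoulli driving force.** Subglottal pressure $P_S$ loads the *lower*
  mass of each longitudinal column over its plate area
  $(L/3) \times \ell_v$: full pressure below a closed upper section,
  $P_S\,(1 - (w_2/w_1)^2)$ in a convergent channel (lower gap $w_1$ wider
  than upper gap $w_2$), zero in a divergent channel and zero everywhere in
  a column whose lower gap is closed. Upper masses never feel pressure. This
  is the standard two-mass Bernoulli form applied per column; columns are
  treated as independent flow channels, a deliberate simplification (see
  Limitations).

The equation of motion $m \odot \ddot x = F^a + F^v + F^c + F^d + F^l$ is
integrated by classical fixed-step RK4 at $\Delta t = 0.25$ ms for 1000
steps (250 ms), in double precision, from the standard initial condition:
lower masses deflected 1 mm outward, upper masses at rest, zero velocities.
The *trajectories* $T(x)$ — what a camera sees — are the signed lateral
positions of whichever member of each vertical pair is closer to the
midline (ties go to the lower, flow-controlling mass): a 6 x 1000 matrix
in mm.

### Parameters and units

All interface units are mm / ms / g / N/m / Pa; internals are SI. The
model instance is defined by a 14-component positive scaling vector $q$:
six reciprocal mass factors (one per vertical pair; the pair's two masses
are the defaults *divided* by the factor), six anchor-stiffness factors,
one subglottal-pressure factor and one collision-proportionality factor.
$q = \mathbf 1$ reproduces the defaults of `phys_config()`:

| quantity | bottom | top | unit |
|---|---|---|---|
| mass (per section) | 0.125/3 | 0.025/3 | g |
| anchor stiffness | 80/3 | 8/3 | N/m |
| collision stiffness | $80\,\xi_c$ | $8\,\xi_c$ | N/m |
| $P_S$ | 800 | | Pa |
| $r_a$ | 0.0002/3 | | Ns/m |
| $\ell_l$, $\ell_v$ | 0.5, 0.2 | | cm |

### The vertical coupling constant

The vertical coupling stiffness `k_v` deserves its own section because the
value is the one genuinely open constant of the model. With weak coupling
(order 0.1 N/m) the lateral coupling response — which is *quadratically*
soft in the offset, $\approx k_v d^2 / 2\ell_v$ — cannot transmit the lower
masses' driven oscillation to the upper masses at all: the upper masses sit
still at their rest positions, and since the extracted edge trajectory is
the pair member nearest the midline, the "visible" trajectories degenerate
to flat lines a few hundredths of a millimetre wide while the lower masses
oscillate at full amplitude underneath. That is not a model of visible
vocal-fold vibration. We therefore identified `k_v` against the observable
behaviour the model is supposed to produce — millimetre-scale edge
amplitudes, fundamental frequencies in the 150–200 Hz band typical of
porcine phonation, and a physically sensible fraction of non-viable random
configurations — and fixed the default at `k_v = 1000` N/m (1 N/mm), which
slaves the upper masses to the lower ones through a stiff but
geometrically softened spring. The constant remains configurable.

A consequence worth knowing: with this coupling, roughly one in six
randomly scaled configurations (light masses and stiff springs at the top
of the sampled range) exceeds the stability region of fixed-step RK4 at
0.25 ms and blows up. These simulations are detected as non-finite, counted
as excluded, and treated exactly like non-oscillating samples by the
dataset builder — they are non-viable model configurations under the
prescribed integrator.

### The oscillation filter

A sample is kept when the mean over the six rows of the per-row standard
deviation, computed over the post-transient window (after 75 ms) with
trajectories expressed in cm, is at least $10^{-3}$ (i.e. a 10 um standard
deviation; values exactly at the threshold pass). The cm convention follows
the classical CGS usage of the two-mass-model lineage; both the unit, the
aggregation (`mean` vs `min`) and the window are arguments of
`is_oscillating()`. Under the default conditions the filter plus the
instability exclusion retain about 82% of generated samples — the shipped
`scripts/acceptance.R` recomputes this fraction from scratch. The anchor
damping is so light ($\zeta \approx 10^{-3}$, decay constant about 1.25 s)
that the 1 mm initial kick still rings audibly at 250 ms; genuinely *dead*
trajectories therefore essentially do not occur, and the exclusions are
dominated by the integrator-instability tail.

## Synthetic data generation

Training data are generated, never recorded:

* **Scaling vectors** are i.i.d. log-uniform on $[1/5, 5]$ per component:
  density $1/(q \log 25)$, median exactly 1 (the model defaults), mean
  $(b-a)/\log(b/a) \approx 1.49$. The reciprocal bounds make "scale up by
  less than $\lambda$" exactly as likely as "scale down by less than
  $\lambda$".
* **Rest positions** are drawn per side/section from shifted gamma
  marginals $\Gamma(\alpha_j, \beta_j) + c_j$ (shipped defaults fitted to
  time-averaged edge trajectories of ex vivo porcine high-speed recordings;
  skewness decreases posterior to anterior), joined by a normal copula
  whose correlation matrix is blended toward independence,
  $\tilde\rho = d I + (1-d)\rho$ with $d = 0.5$. The shipped $\rho$ is a
  documented reconstruction from the printed anchors of the observed
  correlation structure (medial-to-neighbour 0.31–0.63, opposite-side
  anti-correlation −0.8 posterior to −0.2 anterior, and the left-anterior
  anomaly: +0.46 to the opposite posterior, −0.39 to its own posterior);
  `estimate_rest_correlation()` recomputes $\rho$ from any set of
  trajectory CSV files. Left sides are signed negative; the tiny
  negative-magnitude tail admitted by a negative shift $c$ is clamped to
  zero so the sign convention always holds (this touches well under 1% of
  draws).
* Each draw is simulated, the edge trajectories extracted, and the record
  kept iff it passes the oscillation filter. The survival fraction, the
  instability count, seed and bounds are stored with the dataset.

What the generator does *not* emulate: camera calibration error,
segmentation noise, non-orthogonal viewing angles, non-stationary
phonation, and acoustic loading by a vocal tract. A surrogate that passes
every synthetic test can therefore still degrade on recordings; the
evaluation module's observable-space metrics (f0, amplitude, pressure) are
the right currency for that comparison, not the RMSLE validation loss.

## The inverse surrogate

The network maps a 6 x 512 trajectory window (128 ms) to the 14 scaling
factors.

**Preprocessing.** The first 75 ms (transient) are dropped; a 512-step
window is chosen uniformly at random in training (re-rolled every epoch,
a cheap data augmentation) and deterministically (first eligible window) at
evaluation; 10% additive Gaussian noise — relative to each trajectory's own
standard deviation, so the corruption is amplitude-invariant — is applied
in training only; finally the rows are zero-truncated (left clamped to
$\le 0$, right to $\ge 0$). The six pre-noise window means are kept
separately: they estimate the rest positions and seed the recurrent state.

**Architecture.** A shared sub-CNN compresses each trajectory row:
conv(kernel 3, stride 3, 10 channels) → max-pool 2 → conv(kernel 3,
stride 2, 5 channels) → max-pool 2, with ReLU after each convolution, so
512 steps become a 21-step sequence of 5 features per row, 30 jointly. A
two-layer bidirectional GRU (hidden 256) consumes the sequence; its initial
hidden state for every layer and direction is produced from the six window
means by one FC + ReLU. Two read-outs are merged: an attention branch (FC
to width 16 applied at every step, flattened to 21 x 16, FC to 16) and the
top layer's final hidden state (FC to 16); the merged 32-vector passes
FC(32→32) → ReLU → FC(32→14).

**Positivity.** The outputs must be strictly positive but are *not* shares
of a whole, so a literal softmax head (which constrains the sum to one)
would distort them; the default head is element-wise exponential — the
network regresses $\log q$ — with `softplus` and literal `softmax`
available behind the `positivity` switch for comparison.

**Loss.** RMSLE, $\sqrt{\tfrac1{14}\sum_j (\log q_j - \log\hat q_j)^2}$:
the natural scale-invariant loss for positive multiplicative quantities,
and with the exponential head it is plain RMSE in the network's own output
space. Training uses Adam, initial learning rate $5\times10^{-3}$ decayed
by 0.9 per epoch, batch size 512, a 90/10 train/validation split, and early
stopping with patience 5 on validation loss; the best-validation weights
are kept. One seed controls split, windows, noise and initialisation.

All layers, including the bidirectional GRU and its backward pass, are
implemented in the package in plain R matrix code (BLAS does the heavy
lifting); the analytic gradients are verified against central finite
differences in the test suite, which is the strongest correctness check a
reverse-mode implementation can get.

**Free choices.** Several head details are under-determined by the
architecture sketch above and were fixed as follows: the attention flatten
uses the actual 21-step compressed length (a padded length is configurable
via `attention_seq`); the sub-CNN weights are shared across the six rows
(the parameter-efficient reading; `share_subcnn = FALSE` gives per-row
weights); the merge head is FC(32→32) → ReLU → FC(32→14).

## Desk-scale study sizes

The shipped tests exercise the full pipeline at sizes a laptop handles in
minutes, chosen once and fixed: the learnability check trains on a
2000-sample dataset with GRU hidden size 64 for 30 epochs (about 3 minutes)
— large enough that the subglottal-pressure factor is learned to a
validation MAE well below 0.5 against the 0.994 optimal-guess bound, with
pressure the best-learned component and the collision proportionality
stuck near the bound, reproducing the qualitative learnability ordering at
a fraction of the full cost. The acceptance script simulates 10,000
samples for the survival fraction. Training at production scale
(50k–1M samples, hidden 256) uses the same code paths through
`train_surrogate()`; only the sizes differ.

## Evaluation in observable space

For data whose true parameters are unknown, predictions are judged by
three observables: the subglottal pressure (factor x 800 Pa), and — after
re-simulating the model at the predicted parameters — the fundamental
frequency and amplitude of each trajectory against the observed ones.
Frequencies are estimated as the arg-max, above 50 Hz, of the
reciprocally-weighted spectrum $|X(f)|/f$ of the mean-removed signal
(the 1/f weighting suppresses overtones; a $1/f^2$ option exists but the
linear weighting is the default), with one-bin resolution ($fs/n$).
Amplitude is the maximum of the positively-oriented trajectory. MAE, median
AE and MAPE are reported without outlier rejection; gross f0
mispredictions stay in the averages, which is why the median column is
there. Re-simulation rest positions default to the time-wise means of the
*observed* trajectories (the only estimate available for recordings);
for synthetic data the stored generating rest positions can be requested
(`rest_source = "labels"`), which turns an oracle predictor into an exact
fixed point — the property the test suite uses to validate the pipeline.

## Numerical choices and degenerate inputs

* Non-finite forces or states abort a simulation with the offending step
  index; dataset generation counts such samples as excluded rather than
  failing.
* The sign-smoothing length `smooth_eps` trades force smoothness at the
  midline against fidelity of the coupling direction; 1 mm (one interface
  length unit) keeps every force law $C^\infty$ so the integrator's
  fourth-order convergence is observable on collision-free intervals.
* Trajectory extraction breaks $|x|$ ties toward the lower mass; the raw
  signed value is recorded even during overlap, so left trajectories can
  transiently cross zero — file readers warn (but do not fail) on such
  sign-convention violations.
* The shifted-gamma fitter profiles the shift over $(\min x - 3\,\mathrm{sd},
  \min x)$ with an inner MLE gamma fit and checks itself with a KS test at
  the 1% level; constant samples are rejected.
* `rmsle()` rejects non-positive components rather than adding the +1
  offset some conventions use: the scaling factors are bounded away from
  zero by construction.

## Known limitations

* The per-column independence of the Bernoulli driving force ignores that
  the three longitudinal sections share one airflow; a closed posterior
  column does not gate the flow of its neighbours here.
* No vocal-tract acoustic coupling: phenomena like frequency jumps and
  subharmonics driven by source–filter interaction are out of scope.
* With the printed light anchor damping, "vanishing oscillation" in the
  strict sense hardly exists within 250 ms (transients outlive the
  simulation); the sample exclusions are dominated by the stiff-tail
  integrator instabilities described above.
* The surrogate's accuracy numbers in this package are measured on
  synthetic validation data; nothing here certifies accuracy on
  recordings.
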