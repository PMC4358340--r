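---
title: "Modeling multi-stage food search: infotaxis, its drift-diffusion reduction, and behavioral-state segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multi-stage food search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infotaxr)
```

## The problem

An animal removed from food — the motivating case is *C. elegans* picked
off a bacterial lawn into a 1-inch arena — first searches a small area
intensively, turning often ("local search"), and after roughly a quarter
of an hour switches abruptly to long, straight excursions ("global
search"). This package implements a complete modeling pipeline for that
behavior:

* a **maximally informative (infotaxis) searcher** whose belief includes
  the probability that there is no source to find at all, so that the
  local-to-global switch *emerges* from Bayesian bookkeeping rather than
  being imposed;
* a **one-parameter drift-diffusion reduction** of the same decision;
* a **chemotaxis-adaptation null model**, the account the data reject;
* **trajectory analysis**: turn detection, binned turn rates, a two-state
  Poisson hidden Markov model, transition sharpness, and displacement
  statistics;
* a **synthetic worm-track generator** with planted ground truth, standing
  in for recordings that were never deposited, so the whole pipeline can
  be validated end to end.

## The belief model

The searcher holds a posterior $P_t(r_0)$ over source locations on an
$n \times n$ grid (default $128 \times 128$ cells of 0.2 mm, tiling the
25.4 mm arena) and a scalar $p_t(A)$, the probability that a source is in
the known area at all. A source at $r_0$ would produce odorant detections
at position $r$ as a Poisson process with rate

$$R(r\,|\,r_0) = \frac{\rho}{\ln(\sqrt{D\tau}/a)}\,
K_0\!\left(\frac{|r-r_0|}{\sqrt{D\tau}}\right),$$

the steady-state solution for two-dimensional diffusion with emission
rate $\rho$, diffusivity $D$, finite particle lifetime $\tau$, and
searcher size $a$; $L = \sqrt{D\tau}$ is the filter length. $K_0$
diverges at zero separation, so distances below $a$ are clamped to $a$ —
the physical cutoff already present in the logarithm.

Detection is coded **binary** (no hit / at least one hit); in a
source-absent arena the realized observation is always "no hit", with
per-cell likelihood $e^{-R(r|r_0)}$, applied as a pointwise Bayes product
and renormalization. A visited cell that did not contain food is set to
zero permanently. Both observations also inform $p(A)$:

$$p_{t+1}(A) = \frac{p_t(A)\,q_t}{p_t(A)\,q_t + (1-p_t(A))},
\qquad
q_t = \sum_{r_0 \neq r_t} P_t(r_0)\, e^{-R(r_t | r_0)},$$

where the visited cell is excluded from $q_t$ *before* renormalization.
With that convention the sequential updates are **exactly** the joint
Bayes computation over \{source in each cell\} $\cup$ \{source absent\} —
the test suite checks this to $10^{-10}$ on small grids. The first-order
form $q_t = e^{-h}$ is available as `pnohit_mode = "exp_minus_h"`.

Two numerical choices matter. First, $p(A)$ is held as $\ln(1-p(A))$:
the model starts at $\ln(1-p_0) = -100$, i.e. $1-p_0 \approx 10^{-44}$,
far below what the probability scale can resolve near 1; the log-scale
update has $p(A)=1$ ($\ell = -\infty$) as an exact fixed point, so an
animal certain that food is present never revises that belief downward —
the model's absorbing-certainty property. Second, all entropies are in
nats, so the belief state and the drift-diffusion variable share one
scale.

## The search loop

At each step the searcher evaluates, for staying and each in-grid
8-connected neighbor $r_j$,

$$\Delta S(r \to r_j) = P_t(r_j)\,[-S] +
\left[1 - P_t(r_j)\right]\left[\rho_0 \Delta S_0 + \rho_1 \Delta S_1\right],$$

with $h(r_j) = \sum_{r_0} P_t(r_0) R(r_j|r_0)$ the expected hit count,
$\rho_1 = p_t(A)\,(1-e^{-h})$ the probability of at least one detection,
$\rho_0 = 1-\rho_1$, and $\Delta S_{0,1}$ the posterior entropy changes
after the corresponding Bayes update combined with visited-cell zeroing.
(A detection requires a source, hence the $p_t(A)$ weight; the
configuration flag `rho1_as_printed` switches to a $1-p_t(A)$ weight for
comparison with an alternative convention.) The candidate minimizing
$\Delta S$ — the maximal expected information gain — is taken; ties are
broken uniformly at random from R's seeded RNG stream. Runs halt within
one cell of the border, after 15 consecutive non-moves, or at the step
budget. The local-to-global **transition** is the first step with
$p_t(A) \le 10^{-3}$.

The hot loop (candidate evaluation and the realized update) is compiled
C++; the identity
$\sum w\log w = \sum P\,e^{-R}(\log P - R)$ lets every candidate be
scored without per-cell logarithms, with `log P` carried alongside the
posterior. The exported R operations (`expected_entropy_change()` and
friends) are the readable reference implementations; the tests pin the
compiled path to them at $10^{-11}$.

## Choice of the default study conditions

The source text for this model states the grid ($128\times128$), the
start value $\ln(1-p_0)=-100$, the animal speed (0.17 mm/s), the arena
(25.4 mm), and the ~15-minute local search — but not $\sigma$, $a$,
$\rho$, $D$, $\tau$. Those were fixed **once**, from the following
structural argument. After $T$ no-hit steps along a path $r_{1..T}$,

$$\ln(1-p_T) - \ln(1-p_0) =
-\ln \sum_{r_0 \notin \text{visited}} P_0(r_0)\, e^{-C(r_0)},
\qquad C(r_0) = \sum_t R(r_t | r_0),$$

so reaching the transition requires cumulative exposure
$C(r_0) \gtrsim 100 + \ln P_0(r_0)$ at *every* cell the prior supports.
At one cell (0.2 mm) per step and ~765 steps available (15 min at
0.17 mm/s), the searcher cannot *visit* that region; the filter must
expose it, which forces $L$ comparable to the arena. Defaults:
$a = 5$ cells (~1 mm, the animal's own scale), $\rho = 0.35$, $D = 1$,
$\tau = 10^4$ ($L = 100$ cells $\approx$ 20 mm), prior width $\sigma = 6$
cells (~1.2 mm), start positions scattered around the prior center with
a 2-cell standard deviation. Under these conditions the median simulated
local search lasts ~14.5 min, $\ln(1-p_A)$ is linear over the middle of
the search ($R^2 \approx 0.995$), and the searcher shows the
inward-then-orbiting-then-exit structure. The test suite exercises a
half-resolution replica (64×64 cells of 0.4 mm, $a=2.5$, $\rho=0.45$,
$L=50$, $\sigma=3$) so the full experiment set fits in a routine test
run; the problem sizes quoted in the tests (12–50 runs per experiment)
are statistical choices, sized to the effects they measure.

Two documented consequences of this regime, asserted in the acceptance
tests at their nominal bounds and left failing there by design:

* **Sharpness of the accumulation tail.** The last few nats before the
  $10^{-3}$ threshold come from the least-exposed mid-edge cells, so the
  rise of $\ln(1-p_A)$ from $-5$ to $-0.01$ occupies ~15% of the local
  search rather than under 10%. The quantity is invariant under
  rescaling $\rho$ (width and duration both scale as $1/\rho$), so this
  is a property of the regime, not a calibration residue. It remains an
  order of magnitude sharper than any single-exponential adaptation
  model, whose corresponding ratio is the constant
  $\ln 9/\ln 10 \approx 0.954$.
* **Windowed straightness across the transition.** The local phase here
  is a loose, smoothly curving orbit — locally almost straight (lag-10
  heading autocorrelation ~0.72) — while the exit phase is straight in
  legs but switches between surviving posterior patches (~0.68). No
  windowed heading statistic we measured (lag-1, lag-10, 10-step
  net-to-gross displacement) puts the exit phase above the orbit phase,
  although the exit legs are conspicuous in the trajectories themselves.

## The drift-diffusion reduction

Over most of the local search $\ln(1-p_t(A))$ grows approximately
linearly, suggesting the one-dimensional accumulator
$dx = A\,dt + c\,dW$ from $x_0 = -100$ to an absorbing boundary fixed at
0 (the variable is a log-probability, so the boundary is not free).
`extract_drift_rate()` fits an OLS line to a trace restricted to the
(20%, 90%) window of the local search — the slope is the drift used in
the linearity and scaling analyses — and estimates $c$ as the standard
deviation of the detrended per-step increments, the moment estimator of
a diffusion coefficient.

For *first-passage* comparison a subtlety matters: the trace is mildly
convex at both ends (a supra-linear start, a slow tail), so extrapolating
the window slope from $-100$ mis-centers the predicted crossing time by
a few percent — enough to fail a KS test against an ensemble whose
durations vary by only ~0.3%. `ddm_reduction()` therefore uses the
maximum-likelihood drift of a diffusion observed over the whole local
search — net accumulation divided by steps, $100/T$ per run, averaged —
with the increment-based $c$. With those parameters the first-passage
distribution from $x_0=-100$ is statistically indistinguishable from the
generating infotaxis ensemble's durations in 18 of 20 repeated
experiments (two-sample KS at $\alpha = 0.05$, 12-run ensembles).

Euler–Maruyama first-passage times carry a boundary-overshoot bias of
roughly $0.58\,c\sqrt{dt}/A$; crossing times are linearly interpolated
within the crossing step, and tests of the Wald identity
$\mathbb{E}[T] = |x_0|/A$ use $dt$ small enough (0.01–0.04) that the
residual bias sits inside the Monte-Carlo error.

`drift_scaling_experiment()` tabulates extracted drift against the prior
width $\sigma$ and the filter length $L$. Under the default conditions
drift falls approximately linearly with $\sigma$ (so wider priors mean
longer local search), and cells sharing the ratio $\sigma/L$ have more
similar drift than cells across ratios; the experiment reports the
table, and the collapse check is agnostic to the direction in which the
ratio is written.

## The chemotaxis null model

The alternative explanation — turning elevated by the concentration step
at removal, decaying by sensory adaptation — is implemented as
$\lambda(t) = \lambda_{ss} + (\lambda_{max}-\lambda_{ss})e^{-t/\tau}$
(turns/min) driving an inhomogeneous Poisson process (thinning). Its
structural failures are closed-form: the time for the excess rate to
decay to 10% is $\tau\ln 10$ while the 90→10% transition width is
$\tau\ln 9$, so the width is ~95.4% of the duration for *every* $\tau$ —
a single exponential can be slow or sharp, never both. And because the
model responds to the concentration step, dilution scales its expected
excess turns proportionally, whereas the information-based searcher has
no concentration input anywhere in its configuration.

## Track analysis and the hidden Markov segmentation

Centroid tracks (`time_s, x_mm, y_mm` at 3 frames/s) are reduced to
headings by centered differences, with a 0.01 mm displacement floor below
which the previous heading is carried. A **turn** is an unwrapped heading
change exceeding 50° within a 1 s window — a conventional reorientation
threshold for centroid-level worm tracking, exposed in the configuration;
after a detection the detector steps past the entire above-threshold
stretch of overlapping windows plus one refractory window, so one large
reorientation is one event. Turn times binned at 60 s form the observable
for a 2-state Poisson-emission hidden Markov model fitted by Baum–Welch
(best of several random restarts; per-iteration log-likelihood is
non-decreasing and tested). States are relabeled so state 1 is the
high-rate (local) state; a fit whose two rates coincide within $10^{-6}$
is flagged degenerate. The transition time is where the posterior
probability of the global state crosses 0.5 (last crossing if several,
with a message), and the transition duration is the 0.1→0.9 span of that
posterior, linearly interpolated between bin centers — a few minutes for
sharply switching tracks at 60 s bins.

## The synthetic worm generator

`generate_track()` produces constant-speed (0.17 mm/s) run-and-tumble
tracks at 3 frames/s for 28 min (the first two minutes of a 30-min
session, dominated by carried-over forward locomotion, are dropped by the
analysis and therefore not generated): Poisson turn times at 4 turns/min
before a planted transition and 0.5 after, per-frame heading jitter of
3°, inside the 25.4 mm square. Design choices worth stating:

* **Turn kernel.** Post-turn heading changes have magnitude uniform on
  60–180°, either sign — the sharp omega-turn/pirouette events that
  centroid-level turn counting measures. A full-circle uniform kernel
  would plant "turns" of a few degrees that no abrupt-turn detector can
  see (28% of the circle lies under a 50° threshold), making the planted
  rates unidentifiable from the tracks; it remains available as
  `turn_kernel = "uniform"`.
* **Boundary.** The corral is aversive, not absorbing, and animals avoid
  it smoothly: within a 1.5 mm margin the heading rotates away from the
  wall at up to 12°/frame (36°/s, below the turn-detection threshold). A
  mirror reflection would inject instantaneous heading flips that the
  detector would rightly count, contaminating the planted global-state
  rate roughly twofold.
* **Transition source.** Per-track transition times are drawn from the
  drift-diffusion first-passage law (drift $1/9$ s$^{-1}$ from $-100$,
  i.e. a 900 s mean — the ~15 min the behavior shows — and noise 0.5,
  about a ±2 min spread across animals), linking the generator to the
  reduced model exactly as the pipeline links them. A fixed transition
  time and an optional linear rate ramp exist for testing the
  estimators.

What the generator does *not* emulate: speed fluctuations and pauses,
body posture (so no posture-based turn classification), reversals as a
distinct behavior, and any odor landscape. Passing the end-to-end
recovery test (50 tracks; median transition-time error ≤ 60 s; rates
within 25%; transition-duration distribution concentrated under 4 min)
therefore shows the *pipeline* is consistent, not that real recordings
would be segmented this accurately.

## Worked example

```{r example, eval = FALSE}
library(infotaxr)

# one full-scale search under the default study conditions
set.seed(1)
traj <- simulate_search(search_config())
traj
search_duration_seconds(traj) / 60       # minutes of local search

# the reduced model, from an ensemble
ens <- run_ensemble(search_config(), n = 20, seed = 1)
red <- ddm_reduction(ens)
fpt <- first_passage_distribution(
  ddm_params(red$drift_A, red$noise_c), n = 200, seed = 2)
ks_two_sample(ens$transition_steps, fpt)

# synthetic cohort and segmentation
coh <- generate_cohort(synth_config(), n = 10, seed = 3)
seg <- segment_track(coh$tracks[[1]])
seg$t_transition; coh$truths[[1]]$t_transition
```

## Limitations

The searcher is one-step greedy (no receding horizon), detection coding
is binary, and the arena is a flat square grid — all deliberate, matching
the scope of the behavioral account being modeled. The calibrated regime
(arena-scale filter) is the one compatible with the stated quantitative
constraints; other regimes (tight covering spirals under short filters)
do not reach the decision threshold inside the arena on the behavioral
timescale, as the exposure identity above makes explicit. Recovery
statistics quoted throughout are Monte-Carlo quantities at the stated
ensemble sizes and seeds.
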