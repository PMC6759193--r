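---
title: "Loop analysis of blood pressure/volume homeostasis: models and methods"
author: "vasoloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop analysis of blood pressure/volume homeostasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoloop)
```

# The networks and the modelling convention

The package analyses two closed interaction networks drawn from the
physiology of blood pressure and volume control.

The **AAR network** (10 nodes) couples the arginine-vasopressin (AVP),
atrial-natriuretic-peptide (ANP) and renin–angiotensin–aldosterone
(RAAS) axes: adrenal cortex (ACO), juxtaglomerular cells (JGC), heart
myocytes (HMY), the supraoptic/paraventricular nuclei (SPN), the renal
distal tubule and collecting duct (DTC), vascular smooth muscle (VSM),
atrial (ASR) and aortic-arch/carotid (ACR) stretch receptors, the
nucleus tractus solitarii (NTS) and the subfornical organ (SFO).

The **AAV network** (20 nodes) zooms into vascular smooth muscle: the
intracellular contraction machinery (actomyosin, caldesmon, MLC, MLCP,
MLCK, calmodulin, PKG, CPI-17, RhoA/ROCK, IP3R, Gq/PLC, G12/13-GEF,
PMCA, the ANP receptor/guanylate-cyclase and the V1 receptor, labelled
`x_1` … `x_15`) closed through the systemic loop HMY, SPN, NTS, ASR,
ACR (`x_16` … `x_20`).

Every node obeys the same first-order convention
$$\Theta_i \dot x_i + x_i = \sum_k T_{ik}(x),$$
where $\Theta_i$ is a time constant in minutes (self-decay is implicit
in the left-hand side — this is why the interaction sign matrices carry
a $-1$ diagonal and the digraphs have no self-arcs) and every term
$T_{ik}$ is a monotone, saturating Hill interaction:
$$f(x) = \frac{\alpha x^{n}}{1+\beta x^{n}}, \quad
  g(x) = \frac{\gamma}{1+\delta x^{n}}, \quad
  h(x, y) = \frac{\sigma x^{n}}{1+\epsilon x^{n}+\eta y^{n}},$$
activation, inhibition, and mixed activation/inhibition respectively.
The qualitative results (cycle signs, monotonicity, influence classes,
the critical-gain bound) are independent of these particular functional
forms — they rely only on the monotonicity classes — so the Hill
parameterisation serves to *exercise* the theory numerically, not to
fit data.

# Structural influence analysis

For a sign pattern $\Sigma$ the structural influence matrix is
$M = \mathrm{sign}[\mathrm{adj}(-\Sigma)]$, each entry classified over
**all** positive magnitude assignments as `+`, `-`, `0` or `?`.  The
implementation expands every $(n-1)\times(n-1)$ cofactor into its
permutation terms and collects the term signs.  This is exact: with
free independent magnitudes, any single nonzero monomial of a
multilinear form can be made to dominate, so a mixed-sign expansion can
attain both signs, and a single-sign expansion cannot change sign.  At
the package's problem sizes ($n \le 6$, at most $5! = 120$ terms per
cofactor) exhaustive expansion is instantaneous, so no special-purpose
algorithm is needed.

The steady-state reading of $M$ — entry $(i,j)$ is the sign of the
response of variable $i$ to a persistent positive input on equation
$j$ — requires $\det(-\Sigma)$ to be structurally positive.  That holds
for both five-node regulation schemes (`sigmaDTC()`, `sigmaVSM()`), but
*not* for the unsplit six-variable network, whose determinant class is
`?`; `structuralInfluenceMatrix()` warns in such cases and returns the
adjugate classes anyway.  This is one reason the analysis proceeds on
the two split schemes.

Two independent cross-checks guard the exact computation: a
Monte-Carlo oracle that samples magnitudes log-uniformly from
$[10^{-2}, 10^{2}]$ (wide, to let different monomials dominate) and
classifies the numerical adjugate per sample with a zero tolerance of
$10^{-12}$ relative to the largest adjugate entry; and the empirical
influence experiment described below.

# Monotonicity, gauges and candidate oscillators

A gauge transformation flips the sign of selected variables, and with
them all incident arcs, preserving every cycle sign.  A subsystem is
equivalent to a cooperative system (all arcs activating) exactly when
its signed structure is balanced, which the package decides exactly by
two-colouring each connected component by arc sign; gauges come in
$\pm$ pairs per component, so the returned gauge is normalised with
$+1$ at the lowest-ordered node of each component.  For the AAR core
\{ACO, JGC, HMY, SPN\} the flip set is \{HMY\}; for the AAV cell
subsystem `x_1`…`x_15` it is \{`x_2`, `x_4`, `x_7`, `x_13`, `x_14`\}.

A network all of whose elementary cycles are negative is a *candidate
oscillator*: it admits a single equilibrium, either stable
(homeostasis) or surrounded by persistent oscillations.  Cycle
enumeration uses a depth-first elementary-circuit search restricted to
smallest-index start nodes (each cycle found once, in canonical
rotation); the fixture graphs are small ($\le 20$ nodes, 13 elementary
cycles in the AAV loop), so exhaustive enumeration is trivially cheap.

# Time-scale separation

The networks span four time-scale classes.  The synthetic parameter
generator draws each node's $\Theta$ from its class range:

| class          | range (min) | nodes                                  |
|----------------|-------------|----------------------------------------|
| endocrine      | 30–60       | ACO, JGC, HMY, SPN, DTC, VSM, `x_16`, `x_17` |
| stretch        | 2–4.5       | ASR, ACR, `x_19`, `x_20`               |
| nerve          | 0.1–1       | NTS, SFO, `x_18`                       |
| intracellular  | 0.01–0.5    | `x_1` … `x_15`                         |

The endocrine and stretch ranges are physiological estimates for
hormone-to-target response times and stretch-receptor dynamics; nerve
conduction is only bounded above by about a minute, so its lower end
(0.1 min) is a design choice, as is the intracellular range (signal
transduction is faster still; `x_1` defaults to 0.5 min in the bundled
topology because it doubles as the aggregate time constant of the
reduced vascular model, the value used for the propensity surfaces).

`reduceTimeScale()` eliminates fast nodes by substituting their
instantaneous steady state into downstream terms.  Because the
composition of monotone functions is monotone, nested composed terms
retain a definite sign structure, and the reduced interaction matrix is
computed by recursive sign propagation through the term trees.  The
elimination requires the fast nodes to be mutually acyclic (checked;
otherwise the composition would be ill-defined).  Reducing the four
fast AAR nodes yields the six-variable system whose matrix is
`sigmaAAR()`; since DTC and VSM do not interact, the system then splits
into the two five-node schemes.

The reduction's validity is tested side by side: with fast
$\Theta = 0.01$ min the slow trajectories of the full and reduced AAR
models agree within 2 % sup-norm after a 2-minute boundary layer, and
with all non-actomyosin time constants at $\Theta_1/100$ the
20-variable delayed AAV model agrees with its scalar reduction within
5 % after transient (measured errors are orders of magnitude smaller).

# Quantitative experiments

**Equilibria.**  `findEquilibrium()` runs damped fixed-point iteration
($x \leftarrow x/2 + T(x)/2$, which converges for these bounded
monotone-term maps) followed by a Newton polish on $T(x) - x$ with a
finite-difference Jacobian, from a deterministic bound-derived start
plus random nonnegative starts inside twice the saturation bound of
each right-hand side.  Solutions are clustered at relative distance
$10^{-6}$; the candidate-oscillator theory predicts (and the tests
confirm across seeds) a single cluster.

**Empirical influence.**  A persistent input $+\varepsilon$ with
$\varepsilon = 10^{-3}\times$ the equilibrium scale is added to one
equation at a time; the equilibrium is re-solved warm-started and the
response sign recorded, with changes below $10^{-9}$ relative counted
as zero.  Signs are invariant under $\varepsilon \to \varepsilon/10$.
Across 50 sampled parameterisations per scheme the empirical signs
never contradict a structural `+`, `-` or `0`.  Within the default
Hill-coefficient ranges ($[0.5, 2]$) only a subset of the `?` entries
realises both signs — the remaining `?` entries are parameter-dependent
in principle (the wide-range sampling oracle exhibits both signs) but
sign-stable inside this physiological parameter family; the acceptance
test therefore reports the coverage rather than demanding it.

**Simulation.**  Delay-free systems integrate with fixed-step RK4 by
default (step-halving changes fixtures by under $10^{-6}$), with
adaptive `lsoda` for stiff time-constant ratios such as the reduction
comparisons.  Delayed systems use `deSolve::dede` with interpolated
history (tolerances $10^{-8}/10^{-10}$) and constant pre-history.

# The reduced vascular loop and oscillation propensity

With all non-actomyosin nodes treated as instantaneous, the AAV loop
collapses to one state driven by three delayed monotone feedbacks: the
ANP route (delay $\tau_1$) and the two stretch-receptor AVP routes
(delays $\tau_2, \tau_3$).  The two AVP routes share the slow endocrine
step that dominates their latency, so the default configuration ties
$\tau_3 = \tau_2$ (the simulator supports three distinct delays).
Delays are sampled from 2–4 min, the physiological window for these
loops.

`linearizeAAV()` computes the loop gains $p = k_1\mu_1$ and
$q = k_2(\mu_2+\mu_3)$ by exact forward-mode differentiation of the
composed Hill cascades at the equilibrium (tested against central
differences to $10^{-6}$).  The deviation dynamics
$\Theta \dot y + y = -p\,y(t-\tau_1) - q\,y(t-\tau_2)$ have
characteristic function
$$c(\omega) = j\omega\Theta + 1 + p e^{j\tau_1\omega} + q e^{j\tau_2\omega}.$$

**Propensity.**  $\rho = \min_{\omega>0} |c(\omega)|$ is computed on a
dense grid over $(0, 20\pi/\min(\tau_1,\tau_2)]$ ($10^5$ points by
default — about ten curve revolutions, a thousand points per lobe)
with every local minimum refined by Brent search to $10^{-12}$;
$\rho < 10^{-8}$ is reported as an exact root, $J^* = \infty$.  The
refined minimum matches a $10^6$-point brute-force scan within
$10^{-6}$ on random specifications.  $\omega = 0$ is excluded (no
oscillation at zero frequency); its value $1+p+q$ is the curve's
starting point.

**Critical gain.**  A root at total gain $s$ (split
$p = rs,\ q = (1-r)s$) requires
$s\,D(\omega) = -(1+j\omega\Theta)$ with
$D(\omega) = r e^{j\tau_1\omega} + (1-r) e^{j\tau_2\omega}$, i.e.
$-(1+j\omega\Theta)/D(\omega)$ real positive.  Roots exist only at
isolated gain values — one complex equation in the two unknowns
$(\omega, s)$ — so a bisection on "$\rho(s) = 0$" is ill-posed;
instead the zeros of the imaginary part are bracketed on a $2\times
10^4$-point grid and refined by `uniroot`, and the smallest positive
real part over the crossings is $s^*$ (verified a posteriori by
$\rho \approx 0$ at $s^*$).  Since $|D| \le 1$ and
$|1+j\omega\Theta| \ge 1$, always $s^* \ge 1$; $s^* = 1$ exactly when
$\Theta = 0$ and $\tau_1 = \tau_2$ (root at $\omega = \pi/\tau$) — a
necessary total gain of at least unity for oscillation onset, attained
only with a vanishing time constant and homogeneous delays.  A
closed-form corner case pins the implementation down: at $\Theta = 0$,
$\tau = (2, 4)$, $r = 1/2$, $s^* = 2$ exactly.

**Surfaces.**  `propensitySurface()` maps $J^*$ over
$(\tau_1,\tau_2) \in [2,4]^2$ (41×41 grid for the canonical figures)
at $\Theta = 0.5$ min with $p + q = 1$.  The gains are normalised
because only the total gain and its split matter for the geometry, and
$p+q=1$ is the onset threshold scale.  The surfaces are symmetric under
delay swap when $p = q$, attain their global maximum on the equal-delay
diagonal, and decay monotonically as $|\tau_1-\tau_2|$ grows near the
maximum.  Two measured refinements temper the idealised picture: away
from the corner the ridge bends slightly off-diagonal (the
$j\omega\Theta$ term favours marginally longer second delays), and a
small secondary ripple appears near $\tau_1 = 2\tau_2$ (a harmonic
resonance).  The headline conclusion is unaffected: homogeneous delays
maximise oscillation propensity, and desynchronising the loops
suppresses it.

**Onset experiments.**  To compare the linear prediction with the
nonlinear model, `setGainScale()` rescales deviations of the delayed
state around the equilibrium by a factor $\kappa$, multiplying every
loop gain by exactly $\kappa$ while preserving the equilibrium.  Two
numerical safeguards matter here: the scaled state is clamped at zero
(concentrations are nonnegative; without the clamp the even Hill powers
lose monotonicity on negative excursions and admit a spurious
attractor), and the default history perturbation shrinks as $1/\kappa$
so it stays inside the responsive range of the saturating feedback.
`detectOscillation()` discards half the record, splits the rest into
two windows, and flags sustained oscillation when the final window's
peak-to-peak amplitude exceeds a threshold (default $10^{-4}$ of the
state scale; the onset tests pass an explicit smaller threshold because
the gain scaling compresses the limit cycle by $1/\kappa$) and is not
decaying (amplitude ratio $\ge 0.95$); the period comes from upward
midline crossings, which are robust to fast low-amplitude ripples from
secondary unstable modes.  On the test fixture the detected onset
brackets the linear critical gain within $\pm 5\%$.

# What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the physiology — topology,
interaction monotonicity, time-scale classes, delay windows — with
reproducible Mersenne-Twister sampling (seed echoed in every output).
It does not calibrate against measured hormone kinetics, predict blood
pressure in absolute units, model osmolality beyond the SFO node,
include sympathetic/parasympathetic coupling, or add stochastic
forcing.  Passing tests therefore certify the mathematical claims and
their numerical realisation across the stated parameter families, not
quantitative agreement with any measured pressure trace.

# Degenerate inputs and tie-breaks

Graphs reject duplicate labels, unknown endpoints, signs outside
$\pm 1$, self-arcs and parallel arcs (at most one arc per ordered
pair — the analysed schemes never need more).  An empty edge list is a
valid graph with zero cycles; a node without incoming arcs relaxes to
zero (or to its constant bias).  Cycle listings break rotation ties by
starting at the smallest label.  `reduceTimeScale(model, character(0))`
is the identity.  Equilibrium searches error loudly when no start
converges; DDE integration errors on non-finite states rather than
clipping.

# Problem sizes

The test suite runs the full pipeline at the sizes reported above —
50-seed influence batches, 41×41×4 propensity surfaces, 100-spec
brute-force oracle comparisons, and minute-scale DDE onset
experiments — in a few minutes of CPU time; the heavy knobs
(`nGrid`, grid sizes, seed counts) are exposed as arguments throughout.
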