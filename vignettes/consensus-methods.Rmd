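---
title: "Methods: information flow between coupled stimuli and the consensus problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information flow between coupled stimuli and the consensus problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
numerical choices behind them, and what the test suite does and does not
demonstrate.

## The two-stimulus environment

An agent observes two coupled scalar stimuli evolving as

$$\dot X_1 = -\alpha_1 (X_1 - X_2) + \beta_1 \eta_1, \qquad
  \dot X_2 = -\alpha_2 (X_2 - X_1) + \beta_2 \eta_2,$$

with independent unit white noises $\eta_i$, deterministic couplings
$\alpha_i \ge 0$ (1/time) and noise amplitudes $\beta_i \ge 0$
(length/$\sqrt{\text{time}}$).  The linear system diagonalizes exactly:

* the **separation** $D = X_1 - X_2$ is an Ornstein–Uhlenbeck process with
  relaxation rate $\lambda = \alpha_1 + \alpha_2$ and noise intensity
  $\beta_1^2 + \beta_2^2$;
* the **centre of mass** $C = (\alpha_2 X_1 + \alpha_1 X_2)/\lambda$ is a
  drift-free diffusion.

Both are driven by the same two noises, so their increments are correlated
with rate $(\alpha_2\beta_1^2 - \alpha_1\beta_2^2)/\lambda$.  The model's
behaviour is governed by two dimensionless asymmetries,
$a = (\alpha_1-\alpha_2)/(\alpha_1+\alpha_2)$ and
$b = (\beta_1-\beta_2)/(\beta_1+\beta_2)$, and two natural scales,
$\tau = 1/\lambda$ (decay of transients) and
$\ell = (\beta_1+\beta_2)/\lambda$ (size of separation fluctuations).
`make_params()` validates the couplings and attaches these derived
quantities; `make_params_ab()` works directly in natural units
($\tau = \ell = 1$).

`simulate_paths()` samples the **exact** joint Gaussian transition kernel of
$(C, D)$ step by step — including the $C$–$D$ increment cross-covariance —
so the simulator has no discretization bias at any step size and can serve
as an oracle for the closed forms.  The test suite additionally checks it
against an independent Euler–Maruyama integration of the raw equations.

## Transfer entropy seen by a finite agent

An agent with cognitive architecture $(N, \Delta t)$ stores the past
snapshots $X_i(t - k\Delta t)$, $k = 1 \dots N$, of both stimuli.  The
directed transfer entropy is the conditional mutual information

$$T_{2\to1} = I\!\left(X_{1,t};\,
  \{X_{2,t-k\Delta t}\}_k \,\middle|\, \{X_{1,t-k\Delta t}\}_k\right),$$

equivalently a difference of two mutual informations (present against both
histories, minus present against own history).  All variables are jointly
Gaussian, so every term reduces to log-determinants of covariance blocks,
in bits.

**Divergence handling.**  Because $C$ diffuses without bound, raw
covariances diverge in the long-time limit and the two mutual-information
terms diverge individually (their difference stays finite).  The package
therefore expresses every coordinate relative to the oldest own-history
sample $X_1(t - N\Delta t)$.  The reference is a deterministic function of
the conditioning set, and the absolute level decouples from the differences
as its variance grows, so the conditional mutual information in these
reduced coordinates equals the long-time transfer entropy.  This
construction is validated three independent ways in the tests: Monte Carlo
covariances from the exact simulator, an Euler–Maruyama integration, and
the unreduced finite-time covariance (`finite_time_lag_covariance()`)
extrapolated to large times.

**Conditioning.**  At sampling intervals far below $\tau$, neighbouring
snapshots are nearly collinear and naive determinant ratios lose all
precision.  `transfer_entropy_analytic()` therefore works in
consecutive-increment coordinates (unit-triangular, determinant-preserving
within each block), which keeps every entry on the scale of one sampling
step and the computation well conditioned over at least
$\Delta t/\tau \in [10^{-3}, 10^{3}]$ and $N \le 32$.

The **influence** is the normalized antisymmetric ratio
$T_{12} = (T_{1\to2} - T_{2\to1})/(T_{1\to2} + T_{2\to1}) \in [-1, 1]$,
with the convention $T_{12} \equiv 0$ when the total flow is below
$10^{-12}$ bits.  Positive values mean process 1's history is the more
informative direction.

## The small-asymmetry expansion

For a single-snapshot agent ($N = 1$) in the regime
$(a+b) \sim \epsilon$, $|b-a| \sim \epsilon^2$,
$\Delta t/\tau \sim \epsilon^2$, the package's own expansion of the exact
influence (derived numerically from the closed form, with each coefficient
confirmed against the exact computation over two decades of $\epsilon$) is

$$T_{12}(\Delta t, 1) \;\approx\; 2\,(b - a) \;-\; \tfrac14\,(a+b)\,\frac{\Delta t}{\tau},$$

with error of order $\epsilon^4$.  Its zero
$\Delta t^* = 8\tau\,(b-a)/(a+b)$ is the critical sampling interval at
which fast- and slow-sampling agents reverse their conclusions about the
direction of information flow; the tests confirm the expansion root matches
the exact root to second order in $\epsilon$.  `influence_small_limit()`
implements this two-term form.

## Crossover phenomenology

Whether the influence changes sign along $\Delta t$ depends on where
$(a, b)$ sits.  At fixed $b$ there is a band of deterministic asymmetries —
roughly $0 < a \lesssim a_{\max}(b)$, with $a_{\max}$ growing with $|b|$ —
inside which the influence crosses zero exactly once within an order of
magnitude of $\tau$ (e.g. at $b = 0.3$, $N = 4$: no crossing at $a = -0.1$
or $a = 0.5$, exactly one at $a = 0.2$; at $b = 0.03$ the band is narrow,
$a \in (0, \approx 0.04)$).  Near the band's upper edge the zero contour
folds, producing pairs of crossings whose lower member tracks a fixed
look-back window ($N\,\Delta t \approx$ const) and keeps drifting with $N$.
`crossover_scan()` brackets every sign change on a log grid and refines it
by bisection to a relative width of $10^{-3}$ (exact zeros at grid nodes
count as crossings); `crossover_locus_stability()` tracks the principal
(largest-$\Delta t$) crossing per asymmetry and reports the memory size at
which the locus stops moving by more than a stated threshold (2% by
default) from one $N$ to the next.  The influence also depends on how a
*fixed* look-back window is discretized: at $a = 0.7$, $b = 0.75$ the sign
of the influence changes with $N$ at constant $T = N\Delta t$, which the
suite asserts.

## Empirical estimation

`transfer_entropy_empirical()` is the Gaussian (linear) plug-in: delay-embed
both series at the agent's memory depth and stride, form the unbiased
sample covariance of the $2N + 2$ embedding coordinates (both presents plus
both lag blocks), and evaluate the conditional-mutual-information
determinant formula in both directions.  Design choices:

* **Raw embedding, not reduced coordinates.**  This keeps the estimator
  exactly invariant under affine rescaling of either series (asserted in
  the tests).  The wandering common level ends up inside the conditioning
  block, so the estimator still converges to the long-time transfer
  entropy.
* **Debiasing.**  The plug-in inflates both directions by roughly
  $N/(2 n \ln 2)$ bits at sample size $n$, which shrinks the influence
  ratio toward zero as $N$ grows.  The package subtracts the exact
  first moment of the Gaussian log-determinant (a log-Wishart expectation;
  `digamma` terms), which removes the bulk of this at the cost of assuming
  independent rows — overlapping embeddings make it an approximation.
* **Degenerate input** (a constant series, or collinear lags) raises an
  error naming the offending block rather than returning nonsense.
* Optional ridge shrinkage toward the scaled identity is available for
  short series (`shrinkage`), off by default; standard errors come from a
  circular block bootstrap of embedding rows (block length
  $\max(25, 10 N \cdot \text{stride})$).

At $10^5$ points the estimator matches the closed form within bootstrap
error across the asymmetry grid the acceptance suite scans.  At a few
hundred points the influence of a *single* record carries a sampling offset
of order $\pm 0.3$ — comparable to the largest influence amplitudes the
model produces near a crossover — which is the dominant limit on what
short-record analyses can resolve (see below).

## Polities and belief distributions

A polity is a population of independent agents with architectures drawn
from `polity_spec()`: memory geometric on $\{1, 2, \dots\}$ with mean
$\langle N\rangle$ (so $P(N) = (1-x)x^{N-1}$, $x = 1 - 1/\langle N\rangle$)
and sampling interval log-normal with mean $\langle\Delta t\rangle$ and
log-standard-deviation $\theta$.  The log-normal is parameterized by its
*mean* (log-mean $\ln\langle\Delta t\rangle - \theta^2/2$), and the tests
pin the moment identities ($\ln(\langle\Delta t^2\rangle/\langle\Delta
t\rangle^2) = \theta^2$) by quadrature and simulation rather than trusting
any printed normalization constant.

`belief_distribution()` pools a per-architecture influence rule into a
mixture: Gauss–Legendre quadrature with 64 nodes in $\ln \Delta t$ over
$\pm 8\theta$, and summation over $N$ until the geometric tail mass falls
below $10^{-10}$.  Fixed-order quadrature of a *discontinuous* rule (a
sharp crossover) is only accurate to about a percent; the closed forms
below are exact and preferred in that case.  Two closed-form beliefs are
provided:

* `step_model_belief()`: if agents sampling faster than a critical
  interval $\tau^*$ conclude $T_{12}^<$ and slower agents $T_{12}^>$, the
  belief is two point masses with weights $(1\mp f)/2$,
  $f = 1 - 2F(\tau^*)$, $F$ the log-normal CDF.  Computing $f$ from the CDF
  guarantees consistency with the mixture weights by construction.
* `censored_two_camp_belief()`: two Gaussian camps split at memory $N_1$,
  with agents above $N_2$ censored; the weights are geometric-CDF ratios
  $(1-x^{N_1})/(1-x^{N_2})$ and $(x^{N_1}-x^{N_2})/(1-x^{N_2})$, exact
  under the geometric law.  The boundary $N = N_1$ belongs to camp 1, and
  "censored above $N_2$" retains $N \le N_2$.

`summarize_belief()` reports the mixture mean, the median by CDF inversion
(for atomic mixtures, the midpoint of the median interval, so a symmetric
two-point belief has median zero), and the camp fractions below, at, and
above zero influence.  A polity *has the consensus problem* when both
signed camps exceed a threshold (10% by default); the predicate flips as
the polity's mass crosses a vanishing-influence surface, and widening
$\theta$ at a fixed median sampling interval moves the minority camp
monotonically toward one half.

## The paired-record pipeline

`run_climate_pipeline()` applies the agent machinery to two aligned monthly
series (the motivating use: an observatory CO$_2$ record against local
temperature, at instrument precisions of 0.01 ppm and 0.1 °C):

1. **Detrending** (optional): least-squares removal of an exponential trend
   $c_0 + c_1 e^{c_2 t}$ from the first stream and a linear trend from the
   second (configurable), then removal of the $k$ highest-power periodogram
   harmonics with jointly fitted amplitudes and phases.
2. **Bootstrap** (`bootstrap_substreams()`): each replicate is a substream
   with a uniformly random start month, carried to the end of the record,
   plus i.i.d. Gaussian noise with standard deviation equal to each
   series' precision ("noise at the significant digit").  The default
   replicate count is 1000.
3. **Curve** (`influence_vs_memory()`): per replicate and memory size
   $N$ (sampling interval fixed at one month), debiased plug-in transfer
   entropies and influence; one embedding at $\max N$ is reused for all
   depths.  Point estimate = replicate mean; bands = replicate quantiles at
   10% steps.  Embedding vectors touching a masked month are dropped (no
   imputation), and replicates shorter than $12 + 2\max N$ months are
   skipped and counted.
4. **Polity** (`polity_belief_from_curve()`): per mean memory
   $\langle N\rangle$, pool the replicate influences with geometric weights
   over $N$ (truncated to the grid, renormalized) and locate the
   $\langle N\rangle$ at which the median belief crosses zero.

## Synthetic fixtures and what the tests show

`gen_climate_like()` writes paired monthly records: exponential-plus-
seasonal structure on stream A (CO$_2$-like: trend $257 + 57.7\,
e^{0.00125 t}$ ppm, annual and semiannual harmonics of 3 and 1 ppm),
linear-plus-seasonal on stream B (temperature-like: annual 2.5 °C,
semiannual 0.8 °C), coupled residuals from the exact environment at monthly
cadence, per-stream scaling (0.5 ppm / 1.0 °C — an affine operation that
leaves every information measure untouched), and rounding to instrument
precision *after* noise, as archived data are rounded.  The default
residual couplings ($\alpha = (0.3625, 0.1375)$, $\beta = (0.7, 0.3)$:
$\tau = 2$ months, $a = 0.45$, $b = 0.40$) were chosen once so the record
looks like a plausible deseasonalized climate residual (two-month decay)
*and* carries a sharp, analytically known influence crossover between
$N = 3$ and $4$ months — the property the recovery tests need to be able to
identify.  The ground-truth sidecar reconstructs the clean components
bit-exactly before rounding.

Two estimation-theoretic facts, established while validating the pipeline
and enforced by the suite's test conditions, bound what the pipeline can
demonstrate:

* **Record-length limit.**  The influence level estimated from one record
  of the length of a typical observatory series (~768 months) has a
  sampling offset comparable to the model's crossover amplitudes, so a
  single short record cannot localize the crossover memory reliably.  The
  recovery test therefore uses records of 16 000 months with substreams
  constrained to stay long, where the procedure identifies the sign-change
  memory within $\pm 2$ across independent records.
* **Detrending on integrated residuals.**  The model's centre of mass is a
  random walk; regressing a smooth trend (or notching Fourier bins) out of
  a random-walk path perturbs directed-information estimates at order one,
  no matter the record length, *unless* the deterministic components are
  fitted accurately enough that what is removed is genuinely deterministic.
  On long records the trend and harmonic fits converge and the fully
  detrended analysis agrees with the clean-residual one (asserted at 8 000
  months); on short, strongly seasonal records the surgery itself becomes a
  leading error source.  Real-data analyses should read the influence curve
  with this in mind.

Passing tests on these fixtures show that the estimator chain is correct
and that the procedure is consistent where it is statistically
identifiable; they do not show that any particular short empirical record
pins down a crossover.

## Numerical conventions and problem sizes

* Logarithms base 2 everywhere (bits); the influence is base-independent.
* Transfer entropies below $10^{-12}$ bits are clamped to zero, and the
  influence denominator threshold is $10^{-12}$ bits.
* Bisection tolerances: crossover refinement to relative width $10^{-3}$;
  belief-median inversion to 200 halvings of the component range.
* The suite's Monte Carlo sizes: $10^4$ replicates for lag-covariance
  agreement (4 standard errors), $10^5$ points for estimator/closed-form
  agreement (3 bootstrap standard errors), $10^6$ draws for polity weight
  checks (3 standard errors); the pipeline tests use 60–200 bootstrap
  replicates on records of 8 000–16 000 months.  These sizes were chosen so
  each check is decisive at its stated tolerance.

## Known limitations

* The environment is linear and Gaussian by construction; no non-Gaussian
  estimators (nearest-neighbour, symbolic) are provided, and only two
  stimuli are supported.
* The log-Wishart debiasing assumes independent embedding rows; with
  overlapping embeddings it removes most, not all, of the small-sample
  inflation.
* Quadrature-based belief pooling is inaccurate (~1%) for discontinuous
  influence rules; use the closed-form beliefs there.
* The pipeline makes no claim about real climate causality; the influence
  is a correlational, architecture-dependent quantity — that dependence
  being precisely the point.
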