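---
title: "Normative decision thresholds in changing contexts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative decision thresholds in changing contexts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normbound)
```

## The decision problem

`normbound` models a two-alternative forced-choice (2AFC) observer in
environments whose reward or evidence quality changes *within* a single
trial.  A latent state $s \in \{s_+, s_-\}$ generates observations
$\xi \mid s_\pm \sim N(\pm\mu\,\delta t, \sigma^2 \delta t)$ in discrete
time.  The ideal observer tracks the log-likelihood ratio
$y_n = \ln \Pr(s_+ \mid \xi_{1:n}) / \Pr(s_- \mid \xi_{1:n})$, updated
additively ($y_n = y_{n-1} + 2\xi_n \mu / \sigma^2$), or equivalently the
state likelihood $p_n = 1/(1 + e^{-y_n})$.  Evidence quality is the scaled
signal-to-noise ratio $m = 2\mu^2/\sigma^2$.

The normative objective is the trial-averaged reward rate
$$\rho = \frac{\langle R\rangle - \langle C(T_d)\rangle}
              {\langle T_t\rangle + \langle t_i\rangle},$$
with reward $R$, accumulated evidence cost $C(T_d) = \int_0^{T_d} c(t)\,dt$
(we keep $c(t) = c$ constant so that threshold dynamics reflect the task,
not the cost function), trial length $T_t$ and inter-trial interval $t_i$.

## Bellman backward induction

At each timestep the observer chooses among committing to $s_+$, committing
to $s_-$, or sampling again.  With the reward-rate penalty absorbed into
the action values,
$$V(p;\rho) = \max\Big\{
  R_c p + R_i(1-p) - \langle t_i\rangle\rho,\;
  R_c(1-p) + R_i p - \langle t_i\rangle\rho,\;
  \langle V(p';\rho)\mid p\rangle - c\,\delta t - \rho\,\delta t \Big\}.$$
The expectation over the next-step likelihood uses the one-step transfer
density: the two-component Gaussian mixture (weights $p$ and $1-p$ over the
latent state) mapped through the monotone change of variables
$\xi = \tfrac{\sigma^2}{2\mu}(y' - y)$.  We discretize $p$ on a symmetric
grid, sample the density at the grid points, apply trapezoid quadrature
weights, and renormalize each row, which yields a row-stochastic transfer
matrix; backward induction is then a sequence of matrix–vector products.
Known schedule changes simply switch between per-piece transfer matrices.

Because $\rho$ appears inside the recursion, the solution is a
co-optimization: at the optimal $\rho^*$ consistency requires
$V(1/2, t = 0; \rho^*) = 0$.  The start value is decreasing and convex in
$\rho$, so we bracket the root and solve with an Illinois-type false
position iteration to an absolute start-value tolerance of $10^{-6}$ times
the reward scale, typically in 5–10 value-function evaluations.  Grid sweeps
warm-start each cell with the neighbouring cell's $\rho^*$.

Decision thresholds are read off the action map: at each timestep the upper
threshold is the smallest grid likelihood where committing to $s_+$ is
optimal.  When waiting is optimal at every belief the threshold is
*infinite* — the observer will not respond at that time — and the trace
records an `Inf` sentinel (serialized as the string `"inf"` in CSV).

Numerical choices, fixed once:

* **Belief grid**: 501 symmetric points on $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-4}$.  This resolves thresholds to two grid cells
  ($0.004$ in likelihood) at interactive cost; all formulation is in
  $p$-space to avoid truncating the unbounded LLR.
* **Timestep**: $\delta t = 0.01$ time units for the continuous tasks; the
  tokens task uses its native 200 ms step.
* **Horizon**: thresholds are reported on an analysis window $[0, T]$ with
  the backward induction run to $T_f = 5T$, far enough that the artificial
  end time does not distort the window (doubling $T_f$ moves window
  thresholds by at most one grid cell; this is checked in the test suite).
* **Tie-breaking**: at exact value ties commitment beats waiting, and the
  commitment whose half of belief space contains $p$ wins.  At the exact
  midpoint $p = 1/2$ both commitments are equal; the action map records
  $s_+$ but both threshold traces report $1/2$.
* **Stiff dynamics**: the inferred-reward task's belief obeys
  $dy_R = x\,m_R\,dt - 2h\sinh(y_R)\,dt + \sqrt{2m_R}\,dW$; the $\sinh$
  leak is clamped so an Euler step never overshoots $y_R = 0$, and
  saturated-belief rows that underflow fall back to point masses at their
  clamped destinations.

## Task families

* **Reward-change**: $R_c(t)$ steps from $R_1$ to $R_2$ at $t = 0.5$
  (right-continuous Heaviside, so $R_c(0.5) = R_2$), punishment $R_i = 0$,
  $m = 5$, $c = 1$, $t_i = 1$.
* **SNR-change**: $\mu(t)$ steps from $\mu_1$ to $\mu_2$ at $t = 0.5$ with
  constant $R_c = 5$.
* **Tokens task**: 15 tokens leave a center target one every 200 ms, each
  to the upper or lower target with probability 1/2; the subject predicts
  the majority side.  The state likelihood is the Binomial tail
  $p_n = \Pr(\mathrm{Bin}(C_n, 1/2) \le \min\{C_n, 7 - L_n\})$, and each
  token movement transfers to exactly two successors with weight 1/2.
  After a decision at movement $n$ the remaining tokens finish at 170 ms
  (slow) or 20 ms (fast) per movement, so the effective inter-trial
  interval $t_i(n)$ *decreases* with decision time — commitment value
  changes through $t_i$ rather than $R_c$.  The fixed component of the
  inter-trial delay is not dictated by the task screen itself; we default
  it to 500 ms (it scales $\rho^*$ without changing motif structure).
* **Inferred reward-change**: reward alternates between $R_H$ and $R_L$
  through a two-state Markov process with hazard $h$, observed only through
  an independent Gaussian evidence stream; the DP state is the pair
  $(p, q)$ of choice and reward beliefs, with commitment values using
  $R_H q + R_L(1 - q)$.  Default joint grid: $201 \times 101$.

## Threshold motifs

Single-change tasks produce a small set of qualitative threshold shapes.
The classifier operationalizes them with three features: infinite-threshold
epochs (at least two consecutive all-wait timesteps), collapse of the upper
threshold to within one grid cell of $p = 1/2$ shortly before a scheduled
change, and the number and sign of direction changes after compressing the
trace to moves larger than one grid cell (3-step smoothing suppresses
discretization chatter).  For the tokens task, reachable beliefs alternate
with step parity, so the trace is first reduced to a parity-free envelope
in token-lead coordinates; the degenerate start state and the forced final
step are dropped, steps where only an already-decided state would commit
count as effectively infinite, and labels follow the count of
threshold-increase episodes (none / one / several, or an initial all-wait
epoch).

Over the default grids — $R_1, R_2 \in \{1,\dots,10\}$,
$\mu_1, \mu_2 \in [0.4, 2.2]$, and tokens $R_c \in [1, 10]$,
$c \in [0.25, 5]$ with $R_i = -1$ — the reward-change family exhibits five
distinct labels, the SNR-change family three (all monotone), and the tokens
family four.  The grid spans are configurable; the counts are properties of
the task families across spans that include both low-to-high and
high-to-low switches, not of the particular axes.

## Observer models and simulators

Three observers are simulated on identical evidence streams so that
performance differences are attributable to their commitment rules alone:

* **Noisy Bayesian (NB)**: the DP thresholds applied to the belief
  corrupted by an independent sensory-noise Wiener process of strength
  $\sigma_y$.
* **Constant threshold (Const)**: the same noisy belief against
  $\pm\theta_0$.
* **Urgency gating (UGM)**: a low-pass filter
  $\tau\,dE = (-E + p - 1/2)\,dt + \sigma_y\,dW$ compared against the
  hyperbolically collapsing bound $\theta_0/(a t)$.  The printed form of
  the bound is typographically ambiguous; we implement $\theta_0/(a t)$
  (infinite at $t = 0$, hyperbolic in $t$) and expose
  $\theta_0/(1 + a t)$ behind a flag.

Observed response times pass through a Gaussian motor filter of SD
$\sigma_{mn}$, rejection-resampled into the simulation window; the response
is taken to occur physically at the filtered time, so motor noise affects
earned reward, not just the measured distribution.  Heuristic models are
tuned noise-free by grid search under common random numbers and then
corrupted *without retuning*.  Noise strength is summarized as
$(\sigma_y + \sigma_{mn}) / (\bar\sigma_y + \bar\sigma_{mn})$ with maxima
$\bar\sigma_y = 5$, $\bar\sigma_{mn} = 0.25$.

The forced choice at the end of the window uses the sign of the belief,
with exact zeros broken by a fair coin.  Simulations are Euler–Maruyama;
because a discrete walk overshoots its bound, absorption accuracy slightly
exceeds the continuous-time value $1/(1+e^{-\theta})$, and tests therefore
compare against a matched-step random-walk oracle rather than the
continuous formula.

## Fitting the tokens task

The fitting objective is the marginal response-time distribution over the
16 bins (responding after $i = 0, \dots, 15$ token movements).  A model's
distribution is estimated by Monte Carlo on fresh fair-coin token
sequences, floored at $10^{-6}$ and renormalized, so log-likelihoods stay
finite.  An alternative objective conditioning on each trial's token
sequence would use more information; we use the marginal because the
response-time distribution is the canonical summary for this task, and the
trial-wise RMSE metric covers the conditional view at evaluation time.

Posteriors come from random-walk Metropolis with a diagonal Gaussian
proposal under bounded flat priors wide enough to contain all threshold
motif regimes: $R_c \in (0, 50]$, $c \in [0, 10]$,
$\sigma_y \in [0, 5]$, $\sigma_{mn} \in [0, 0.25]$,
$\theta_0 \in (0, 10]$, $a \in (0, 10]$, $\tau \in (0.01, 2]$.  Parameter
counts: NB $k = 4$, Const $k = 3$, UGM $k = 5$.  One fixed simulation seed
serves the whole chain (common random numbers), making the pseudo-likelihood
surface deterministic within a chain at the price of small frozen
Monte-Carlo roughness; proposal scales were pre-tuned on a synthetic tuning
cohort toward the 20–25% acceptance this roughness permits.  Chains start
from the best cell of a coarse lattice over the prior box followed by a
two-sweep coordinate refinement — without this the random walk must cross
large near-flat ridges within its budget.  The first 10% of samples are
burn-in; the maximum-a-posteriori (MAP) estimate is the best post-burn-in
sample.  A chain that accepts nothing in its first 500 steps aborts with a
proposal-scale diagnostic; the fitting wrapper then retries with a halved
proposal.

Model comparison uses AICc
($2k - 2\ln\hat L + (2k^2+2k)/(n-k-1)$), the average trial-by-trial RMSE
between observed response times and the mean of noisy model replays on the
same token sequences, and the Kullback–Leibler divergence
$\sum_i RTD(i)\ln(RTD(i)/RTM(i))$ between empirical and model response
distributions.

### Identifiability

Two structural ridges matter when interpreting fits.  First, scaling
$(R_c, c)$ jointly changes NB thresholds only through the fixed punishment
anchor, so the identified threshold-governing quantity is the ratio
$R_c/c$; raw $R_c$ is recovered poorly even when the implied thresholds are
recovered well.  Second, the UGM bound enters only through
$\theta_0 / (a t)$, so $\theta_0/a$ is the identified bound scale.
Recovery analyses therefore correlate MAP and generating values of
$R_c/c$, $\theta_0$ (Const), and $\theta_0/a$ (UGM).

## The synthetic cohort

The synthetic-subject generator emulates the *structure* of a human tokens
dataset: slow/fast speed conditions, one response bin (0–15) per trial,
fair-coin token sequences, and around a thousand trials per subject, with
cohorts of 20 subjects per generator class.  Generator parameters draw
noise uniformly ($\sigma_y \in [0.5, 2.5]$ on the LLR scale,
$\sigma_{mn} \in [0.02, 0.12]$ s) and spread the threshold-governing
parameters widely ($R_c \in [1, 8]$, $c \in [0.2, 3]$,
$\theta_0 \in [0.5, 4]$).  Three choices are deliberate:

* UGM sensory noise is drawn on the scale of the filter output
  ($\sigma_y \in [0.05, 0.4]$), since $E$ lives in $[-1/2, 1/2]$ and
  LLR-scale noise there produces subjects who respond at random.
* UGM cohorts share the canonical filter constant $\tau = 0.2$ s; subject
  individuality lives in the bound parameters and noise.
* The UGM bound scale $\theta_0/a$ is sampled log-uniformly on
  $[0.02, 1.2]$, keeping the collapsing bound within reach of the filter
  output before the deadline; observers whose bound never comes within
  reach respond only at the forced deadline and carry no threshold
  information.

What passing tests on this cohort do **not** show about real data: human
subjects mix strategies across trials, have sequential dependencies,
lapses beyond the Gaussian response-time filter, and unequal trial counts;
none of these are in the generator, so recovery results bound what the
pipeline can do under its own assumptions, not under human misspecification.

## Problem sizes

The test suite and the acceptance script use: $10\times10$ parameter grids
for the motif maps; $10^5$ Monte-Carlo samples for the transfer-density and
reward-rate oracle checks; $2\times10^4$–$3\times10^4$ trials per model for
the reward-rate comparisons (3,000 per tuning cell); and fitting chains of
2,000 samples (a scaled-down chain length; longer chains sharpen the MAP
but do not change the structure of the results) with 1,500–4,000 simulated
trials per likelihood evaluation (most for the constant-threshold model,
whose $\theta_0$–$\sigma_y$ ridge is resolved by distribution tail shape;
least for the noisy Bayesian model, whose cost is dominated by the
per-proposal DP solve), on cohorts of 20 synthetic subjects per class with
1,000 trials each.

## Known limitations

* The continuous-task simulator forces a choice at the end of the analysis
  window; the solver's horizon extends five times further, so a tiny
  fraction of late-deciding trials is truncated.
* The pseudo-likelihood's frozen Monte-Carlo roughness biases MCMC
  acceptance low and makes the MAP an approximate maximizer; model
  *selection* is robust to this, per-parameter posteriors less so.
* Motif labels are a deterministic function of grid resolution and the
  classifier's tolerances; cells exactly on a regime boundary can move
  between adjacent labels under a different discretization.
* The inferred-reward solver reports thresholds on the $(p, q)$ grid but
  does not yet co-optimize over policies that anticipate hazard-driven
  reward switches beyond the belief dynamics themselves.
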