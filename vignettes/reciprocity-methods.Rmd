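---
title: "Reciprocal connectivity in a balanced cortical network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal connectivity in a balanced cortical network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(recipronet)
```

## The scientific question

Cortical microcircuits contain far more reciprocal (bidirectional) synaptic
pairs than an independent random graph would produce; between pyramidal cells
and fast-spiking interneurons the probability that a connection is
reciprocated is close to one.  Classical theory of balanced
excitatory-inhibitory networks assumes independent connections, so it is
silent on what this fine structure does to cortical dynamics.  `recipronet`
implements a strongly coupled, conductance-based spiking model of layer 2/3
of rodent V1 in which the amount of dyadic reciprocity in each connection
class (E-E, I-I, E-I) is a control parameter that can be moved without
changing any in-degree distribution, together with the spike-train and
tuning statistics needed to quantify the consequences: Fano factors,
inter-spike-interval CV and CV2, serial rank correlations, spike
autocorrelation functions with decorrelation times, and orientation
selectivity indices.

## The wiring rule

Every unordered pair of neurons (dyad) is assigned one of four states.
Within a population with connection probability $q = K/N$, a dyad is made
bidirectional with probability

$$P_{\leftrightarrow} = p\,q + (1-p)\,q^2,$$

unidirectional (each direction) with probability $(1-p)\,q(1-q)$, and left
unconnected otherwise.  Both marginal connection probabilities remain $q$
for every $p$, so the expected in-degree is $K$ regardless of reciprocity;
the expected number of reciprocated partners per neuron is
$pK + (1-p)K^2/N$, i.e. $\approx pK$ for $p \gg K/N$ versus $K^2/N$ by
chance.  At $p = 0$ the rule reduces exactly to the independent
(Erdős–Rényi) case — in this parametrization chance-level reciprocity is
$p = 0$, and any $p > 0$ is excess.  At $p = 1$ a within-population block is
exactly symmetric.

For the cross-population class with $N_E \neq N_I$ the two directions have
different marginals $q_1 = K/N_E$, $q_2 = K/N_I$ and the generalization is
not dictated by the within-population formula.  We use
$P_{\leftrightarrow} = p\sqrt{q_1 q_2} + (1-p)q_1 q_2$, the symmetric
geometric interpolation, because it preserves both marginals and reduces to
the within-population rule when $N_E = N_I$ (the default configurations use
equal population sizes, where the question does not arise).  Combinations
where $p\sqrt{q_1 q_2}$ would exceed a marginal are rejected at validation.

Each connection class draws from its own child RNG stream, and within a
block the same uniform variates are classified against $p$-dependent
thresholds.  Two consequences matter for experiments: changing `p_II` leaves
the EE/EI/IE blocks bit-identical, and realizations at different $p$ are
maximally coupled, so reciprocity sweeps compare matched networks rather
than independent draws.  Self-connections are excluded; only dyadic
(pairwise) structure is controlled, not triplet or higher-order motifs.

## Why reciprocity matters: the effective self-coupling

A neuron engaged in $pK$ reciprocated dyads receives delayed feedback from
its own spikes: a spike adds $J/\sqrt K$ to each target, elicits on average
$\xi J/\sqrt K$ extra spikes there ($\xi$ = mean gain), and $pK$ of those
targets project back.  The integrated self-feedback is $pK\xi J^2$ — with
the $G/\sqrt K$ scaling this equals $p\,\xi G^2$, *independent of K*.  This
is why the package's reduced-scale networks ($K = 100$ instead of 500)
preserve the reciprocity phenomenology: the loop strength survives the
reduction untouched.  The loop is positive for E-E (direct re-excitation)
and I-I (disinhibition: my spike silences interneurons that inhibit me) and
negative for the E-I loop (my spike recruits partners that suppress me).
`effective_self_coupling()` evaluates these integrals; with the model's
couplings the I-I loop is by far the strongest ($G_{II} = 3$ versus
$G_{EE} = 0.15$), which is why excess I-I reciprocity dominates the
dynamical effects while E-E reciprocity is nearly inert.

## Single-neuron model

Neurons are single-compartment conductance-based cells with instantaneous
sodium activation ($I_{Na} = g_{Na} m_\infty^3 h (V - V_{Na})$), delayed
rectifier ($I_K = g_K n^4 (V-V_K)$), leak, and — in excitatory cells only —
a slow adaptation current $g_{adapt}\, z\,(V - V_K)$ whose gate relaxes to
$z_\infty(V) = 1/(1+e^{-0.7(V+30)})$ with $\tau_{adapt} = 60$ ms.
Parameters: $g_{Na} = 100$, $g_K = 40$, $g_L = 0.1$ mS/cm²,
$V_{Na} = 55$, $V_K = -80$, $V_L = -65$ mV, $C_m = 1\,\mu$F/cm²,
$g_{adapt} = 0.5$ mS/cm².

The rate functions $\alpha_x, \beta_x$ for $h$ and $n$ are a design choice:
the model family this network descends from has been simulated with more
than one kinetics set.  We evaluated two candidates.  With Wang–Buzsáki
interneuron kinetics ($\phi = 5$) the combination $g_{Na} = 100$,
$g_L = 0.1$ produces a *tonically firing* cell at zero input (~20 Hz):
the window current destabilizes rest, which contradicts the quiescent
resting state this network requires.  The shifted-Hodgkin–Huxley kinetics of
the Shriki–Hansel–Sompolinsky cortical model — the model that uses exactly
these conductance values and exactly this adaptation gate — give a stable
rest near $V_L$ and a rheobase between 0.5 and 1 µA/cm².  The package
therefore
defaults to those (`kinetics = "hh_cortical"`), keeps Wang–Buzsáki available
as `kinetics = "wang_buzsaki"`, and treats the kinetics as pluggable.

Integration uses exponential-Euler updates for both the gates and the
conductance-linear membrane equation at `dt = 0.05` ms (convergence checks
use 0.01/0.005 ms: halving the step moves spike times by well under 0.5 ms
per spike over a 1-s constant-input trace; a `deSolve::lsoda` reference
solution reproduces the engine's spike count).  Gating functions are
tabulated on a 0.025 mV grid.  Spikes are upward crossings of −20 mV with a
2 ms detection lockout and linear interpolation of the crossing time;
synaptic jumps take effect on the following step.

## Synapses and inputs

Each spike adds $\bar g_{AB}/\tau_{syn}$ to the target's synaptic
conductance, which decays exponentially with $\tau_{syn} = 3$ ms, so one
transient integrates to exactly $\bar g_{AB} = G_{AB}/\sqrt K$ with
$G_{EE} = 0.15$, $G_{IE} = 0.45$, $G_{EI} = 2$, $G_{II} = 3$ ms·mS/cm².
Synaptic currents use a mixed driving force
$\rho\,(V - V_B) + (1-\rho)(V_L - V_B)$.

**The mixing fraction ρ.**  $\rho$ is not printed in the source model, and
it turned out to be the single most consequential free parameter: the
conductance fraction loads the membrane with the (large) inhibitory synaptic
conductance, shunting the neuronal gain $\xi$ — and the reciprocity-induced
self-coupling loop scales with $\xi$.  In matched-seed sweeps of I-I
reciprocity, moving $\rho$ from 0.5 to 0 increases the I-population CV and
Fano-factor responses severalfold.  Since the phenomena this model exists to
exhibit are strong reciprocity effects, the package defaults to $\rho = 0$
(current-dominated driving force; the synapses remain
exponential-conductance transients).  Any mixing can be restored with
`synapse_params(rho = ...)` and the sweep rerun with
`run_reciprocity_sweep()` to reproduce the comparison.

**Background.**  Input from other cortical areas is a conductance
$\bar g_b K (R_b + \sqrt{R_b/K}\,\eta(t))$ at the excitatory reversal, with
$\eta$ an exact-discretization Ornstein–Uhlenbeck process with correlation
time $\tau_{syn}$ and stationary variance $1/(2\tau_{syn})$.  That
normalization is not arbitrary: it makes the conductance variance equal
$\bar g_b^2 K R_b/(2\tau_{syn})$, exactly the variance of Poisson shot noise
from $K$ afferents at rate $R_b$ filtered by the unit-integral exponential
kernel.  Negative excursions are clipped at zero (rare at the default
parameters).

**Feedforward drive.**  Layer 4 is reduced to a per-neuron stationary rate
$$R^{tot}_i(\theta) = c_{ff}K\,(R_0 + R_1(C)) + \sqrt{c_{ff}K}\,
\big(x_i + R_1(C)\,[x_i + \xi_{L4}\, z_{1,i} \cos 2(\theta - \Delta_i)]\big),$$
with $R_1(C) = R_1 \log_{10}(C+1)$, quenched per-neuron disorder
$x_i \sim N(0,1)$, $z_{1,i}$ Rayleigh, $\Delta_i \sim U[0,\pi)$ (drawn once
per network, frozen across trials, orientations and reciprocity sweeps), and
$R_0 = 2$ Hz, $R_1 = 20$ Hz, $C = 100$, $\xi_{L4} = 0.8$.  The rate (clipped
at zero) is filtered by the synaptic kernel together with
square-root shot noise and scaled by
$\bar g_{ff} = G_{ff}/(c_{ff}\sqrt K)$.  Excitatory cells draw
$K^{ff}_E$ afferents and inhibitory cells $K^{ff}_I = 8 K^{ff}_E$ — more
but weaker inputs, so the tuned component is relatively smaller and
inhibitory neurons are less orientation selective.

**Calibration of unprinted strengths.**  $G_{ff}^A$ and the background
scale are not published.  They were fixed once so that the chance-level
($p = 0$) network reproduces the reference operating point (E ≈ 5.4 Hz,
I ≈ 8.7–9 Hz at full contrast): $G_{ff}^E = 0.0286$, $G_{ff}^I = 0.0162$,
$\bar g_b = 0.012$, $R_b = 5$ Hz; the acceptance runs measure E ≈ 5.4 /
I ≈ 8.9 Hz at the desk-scale defaults.  $V_E = 0$ mV and $V_I = -75$ mV (reversals are
likewise unprinted).  These values are the package's study conditions and
are not tuned per experiment.

## Problem sizes

The default profile is $N_E = N_I = 2000$, $K = 100$, with feedforward
in-degrees scaled to preserve $c_{ff} = K^{ff}/K$ (20 and 160).  Because the
self-coupling integral $p\xi G^2$ is K-invariant, the reciprocity effects
survive this reduction; what shrinks is statistical power (fewer neurons)
and the quenched heterogeneity ratio.  Reported experiments use ~2 s
measurement windows per trial with a 0.5 s discarded transient for
trial-repeat (Fano) protocols and up to 10 s for single long trials;
the transient comfortably covers the slowest intrinsic timescale
($\tau_{adapt} = 60$ ms).  Full-scale runs ($N = 2\times10^4$, $K = 500$,
100 trials, minutes of biological time) use the same code paths and are a
matter of wall-clock budget only.

## Spike-train statistics

* **Fano factor** — across-trial count variance over mean, with the plain
  (divide by $n$) variance convention matching the defining ensemble
  average; the $n-1$ convention is available via `unbiased = TRUE`.  The
  counting window is the full per-trial measurement window, stated in the
  outputs.
* **CV / CV2** — ISI standard deviation over mean (same variance
  convention), and the mean of $2|\Delta t_{i+1}-\Delta t_i| /
  (\Delta t_{i+1}+\Delta t_i)$ over adjacent pairs.  CV2 ≤ 2 always, and it
  is insensitive to slow rate modulation, which inflates CV.
* **Serial rank correlations** — every ISI is ranked once within its train
  (average ranks on ties); $SRC_i$ is the Pearson correlation of rank pairs
  $i$ apart.  For a renewal train the long-window Fano factor is $CV^2$;
  serial correlations modify it to $FF = CV^2(1 + 2\sum_i SRC_i)$
  (`ff_from_cv_src()`), the identity used to cross-check the count-based
  estimator.  Default truncation $m = 20$; the Markov fixtures have
  geometrically decaying SRCs, so the truncation error is
  $O(\rho_1^{21})$.
* **Autocorrelation** — spike trains binned at 1 ms; per neuron
  $\langle N(t)N(t+\tau)\rangle_t/\Delta t^2$ with the zero-lag peak
  removed, averaged over the population.  Each neuron's AC converges to its
  squared mean rate, so the stored estimator's asymptote is the population
  mean of $r_i^2$ (`normalization = "rate_squared"`); the display
  convention that converges to the mean rate is available as a view
  (`ac_normalize_rate()`), and every AC object carries its normalization
  tag.
* **Decorrelation time** — the excess $AC(\tau) - r^2$ is fit by linear
  regression of $\log|{\rm excess}|$ against lag over an automatically
  selected window, and $\tau_{dec} = -1/\mathrm{slope}$.  Two readings of
  the published recipe were possible: a log-log slope (a dimensionless
  power-law exponent) or a semilog decay constant (a time).  Since the
  quantity is reported in milliseconds and compared across conditions as a
  time, the semilog reading is the default; the literal log-log slope is
  available via `method = "loglog"`.  In this network the AC departs from
  its asymptote *from below* at short lags (a refractory/AHP trough) before
  relaxing, so the window starts at the largest absolute excess and follows
  the recovery while the sign is constant; a flat or non-decaying excess
  yields `NA` with a warning, never a fabricated time.
* **OSI** — $|\sum_k r(\theta_k) e^{2i\theta_k}| / \sum_k r(\theta_k)$ on a
  12-orientation grid by default; an all-zero curve gives `NA`, not 0.

## What the synthetic fixtures do and do not show

The `generate_train()` families (Poisson, gamma renewal, Markov-ISI via a
Gaussian-copula AR(1) on ISI quantiles, periodic, rate-modulated) carry
planted values for every statistic: CV $= 1/\sqrt{k}$ for gamma shape $k$,
$FF = CV^2$ for renewal trains, geometric SRC decay with first-order value
$\approx \rho_1$ ($(6/\pi)\arcsin(\rho_1/2)$ exactly, within 3% of
$\rho_1$), zero everything for clocks.  They validate the statistics suite
independently of the simulator — a passing oracle suite certifies the
measurement code, not the network model.  Conversely they lack every
feature that makes network data hard (refractory troughs in the AC,
oscillatory ringing, heterogeneous rates), which is why the decorrelation
fit is additionally exercised on planted exponentials *and* on simulated
network ACs.

## Design choices on degenerate inputs and numerics

Undefined statistics are signaled, not zeroed: OSI of an all-zero tuning
curve, FF of an all-zero count vector, and $\tau_{dec}$ of a non-decaying
AC all return `NA` with a warning.  Neurons need at least 5 ISIs to
contribute CV/CV2 (configurable).  Ties in ranks use average ranks.
Negative instantaneous rates or conductances arising from the Gaussian
noise approximations are clipped at zero.  Non-finite membrane potentials
abort the run with the neuron and time in the error, rather than
propagating NaNs.

## Known limitations

* The baseline irregularity at the calibrated operating point is
  CV ≈ 0.5 (E) / 0.6 (I): the strong delayed-rectifier AHP of this neuron
  model regularizes firing at these rates, and the network sits somewhat
  below the CV ≈ 1 regime reported for the full-scale model.  Directions
  and orderings of the reciprocity effects are robust to this; absolute
  Fano factors are sub-Poisson.
* The excitatory-population response to I-I reciprocity (slowed
  fluctuations leaking from I to E) is weak at desk scale — visible in the
  AC but marginal in E-population Fano factors over 2-s windows.
* Only dyadic reciprocity is controlled; triplet and higher-order motifs
  follow whatever the dyad rule implies.
* The layer-4 population is a filtered stochastic rate, not spiking
  neurons; stimulus dynamics (drift, flicker) are out of scope.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)              # 2 x 2000 neurons, K = 100
sw <- run_reciprocity_sweep(cfg, p_values = c(0, 0.5), class = "II",
                            n_fano_trials = 20)
print(sw)       # population rates, CV, CV2, FF, tau_dec per p
```

Smaller versions of every experiment (200-neuron populations) run in
seconds; see `tiny_network_fixture()` and the test suite.
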