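---
title: "Memory time scales of calcium-based synapses under background activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory time scales of calcium-based synapses under background activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casynapse)
```

## The model

A synapse is described by two variables. The postsynaptic calcium
concentration $c(t)$ is a shot-noise process: every presynaptic spike adds
$C_{pre}$ (after a short delay $D$ that stands in for the NMDA-receptor
rise time), every postsynaptic spike adds $C_{post}$, and between spikes
$c$ decays exponentially with time constant $\tau_{Ca}$. Calcium is
dimensionless; the plasticity thresholds set its scale.

The synaptic efficacy $\rho \in [0,1]$ evolves as

$$\tau_\rho \,\dot\rho = -U'(\rho)
  + \gamma_p (1-\rho)\,\Theta(c-\theta_p)
  - \gamma_d \,\rho \,\Theta(c-\theta_d)
  + \sigma \sqrt{\tau_\rho}\,
    \sqrt{\Theta(c-\theta_d) + \Theta(c-\theta_p)}\;\xi(t),$$

so depression (rate $\gamma_d$) is active whenever $c > \theta_d$,
potentiation (rate $\gamma_p > \gamma_d$) additionally whenever
$c > \theta_p > \theta_d$, and the noise is gated by the same thresholds,
growing by $\sqrt2$ when both are crossed. The bare potential $U$ is
either flat (every efficacy value is marginally stable) or the symmetric
double well $U(\rho) = \rho^2 (1-\rho)^2/4$, whose minima at $\rho = 0$
(DOWN) and $\rho = 1$ (UP) realise a bistable synapse with barrier at
$\rho^\star = 1/2$.

Two parameter presets ship with the package (`ca_preset()`): the
`in_vitro` set fitted to cortical slice plasticity data at 2.5 mM
extracellular calcium, and the `in_vivo` set obtained by scaling both
calcium amplitudes by $1.5/2.5 = 0.6$, the estimated ratio of in-vivo to
slice extracellular calcium (`scale_calcium()`). The linear scaling is an
assumption; nonlinear mappings between extracellular calcium and spine
influx would change the numbers but not the structure of the results.

## Exact event-based propagation

Between spikes the calcium trajectory is a known exponential, so the
inter-event interval splits into at most three epochs: above $\theta_p$,
between the thresholds, and below $\theta_d$
(`threshold_partition()`; the six possible crossing patterns are the sign
patterns of the clipped crossing times $\tau_{Ca}\ln(c_0/\theta)$).
Within each epoch the efficacy update is exact:

* **Above $\theta_p$** the drift is linear with fixed point
  $\gamma_p/(\gamma_p+\gamma_d)$ and relaxation rate
  $(\gamma_p+\gamma_d)/\tau_\rho$; together with the doubled noise this
  is an Ornstein-Uhlenbeck (OU) transition whose mean and variance are
  applied in one Gaussian draw. The quartic term is neglected during
  suprathreshold epochs because $\gamma_p, \gamma_d \gg 1$; the Euler
  cross-check below confirms the approximation is numerically invisible.
* **Between the thresholds** the same applies with fixed point 0, rate
  $\gamma_d/\tau_\rho$ and single noise.
* **Below $\theta_d$** the dynamics are deterministic: the identity for
  the flat potential, and for the double well the integrated quartic
  flow, which with $x = \rho - 1/2$ reads
  $x(t)^2 = \tfrac14 / (1 + q e^{-t/(2\tau_\rho)})$,
  $q = (\tfrac14 - x_0^2)/x_0^2$, sign conserved
  (`deterministic_update_double_well()`). The fixed points 0, 1/2, 1 are
  exact, and the formula remains valid (and contracting) slightly outside
  $[0,1]$.

In flat-potential mode $\rho$ is clipped to $[0,1]$ after every
stochastic epoch; this realises the truncation of the OU process that the
asymptotic theory below assumes. Coincident calcium events are merged
into one jump so that tie-breaking can neither change the trajectory nor
desynchronise the noise stream. The engine is validated pathwise (at
$\sigma = 0$, where both schemes are deterministic) against a forward
Euler integration of the full equation at 0.001 ms steps, and in
distribution (at $\sigma > 0$) against Euler transition moments; see
`run_synapse_euler()` and the test suite.

Randomness comes from a counter-seeded xoshiro256++ generator with one
substream per synapse (and per neuron in the network), keyed by
`(seed, entity id)`. Ensemble results are therefore bit-reproducible and
independent of execution order, and fixture generators that use R's RNG
(`generate_poisson_train()`, connectivity, tagging) save and restore
`.Random.seed`.

## Stationary calcium statistics

For independent Poisson spike trains the stationary law of the calcium
shot noise obeys a flux-balance (master) equation: the downward
probability flux $(c/\tau_{Ca}) p(c)$ through level $c$ equals the upward
jump flux $\sum_{ch} \nu_{ch} [F(c) - F(c - C_{ch})]$. The delay $D$
drops out — a time-shifted Poisson process is again Poisson — so the
stationary solvers ignore it.

`ca_stationary_pdf()` integrates this equation forward in $c$. On
$(0, C_{\min}]$ the solution is the exact power law
$F(c) \propto c^{a}$ with $a = (\nu_{pre}+\nu_{post})\tau_{Ca}$; at the
firing rates of interest $a \ll 1$, so the density has an integrable
divergence at the origin that is kept analytically rather than on a grid
(this is also why the object reports a `point_mass` below the first jump
scale: almost all probability sits at calcium values far below threshold).
Beyond $C_{\min}$ an integrating factor turns the lagged equation into an
explicit marching scheme; the singular factor $(c - C_{ch})^{a}$ that
appears while a lag crosses the analytic panel is absorbed exactly by the
substitution $u = s + d\,w^{1/(1+a)}$ under fixed Gauss–Legendre
quadrature. The default resolution is 400 grid steps per smallest
amplitude; threshold fractions are CDF differences, accurate to about
$10^{-7}$ absolute (checked against an independent Monte-Carlo event
simulation, `mc_alpha_fractions()`, and against the closed form below).
The returned density grid is refined geometrically around every
amplitude corner so that a plain trapezoid over it reproduces unit mass
to $10^{-6}$.

When $C_{pre} = C_{post} = C$ the law is piecewise analytic
(`ca_stationary_pdf_closed()`): a pure power on the first amplitude
panel, a hypergeometric-series term on the second
($S(w) = \sum_m w^{a+1+m}/(a+1+m)$, i.e.
$w^{a+1}/(a+1)\cdot{}_2F_1(1, a+1; a+2; w)$ with $w = 1 - 1/x$), and an
exact integrating-factor recursion continued panel by panel. This is an
independent computational route used to cross-check the master-equation
solver; the production path for the fitted (unequal) amplitudes is the
numeric solver, since the validity windows of the published low-$c$
piecewise forms for that case are not fully specified.

Two quantities summarise the law: the fractions of time
$\alpha_d, \alpha_p$ spent above the two thresholds. Low-rate expansions
(`alpha_low_rate()`) make the spike-count structure explicit: when one
spike clears the threshold, $\alpha \simeq \nu_{tot}\tau_{Ca}\ln(C/\theta)$;
when two are needed,
$\alpha \simeq (\nu_{tot}\tau_{Ca})^2 [L\ln(C/\theta) +
\mathrm{Li}_2(-e^{-L}) - \mathrm{Li}_2(-1)]$ with
$L = \ln(C/(\theta-C))$. In general $\alpha \propto \nu^{k}$ where $k$
(`min_spikes_to_cross()`) is the number of simultaneous spikes needed to
reach the threshold.

## Memory decay with a flat potential

Averaging the gated drift over the calcium statistics gives net rates
$\Gamma_p = \gamma_p \alpha_p$ and $\Gamma_d = \gamma_d \alpha_d$, an
effective OU process truncated to $[0,1]$, and hence

* decay time constant $\tau_{eff} = \tau_\rho / (\Gamma_p + \Gamma_d)$,
* asymptotic mean: the $[0,1]$-truncated Gaussian mean built from
  $\bar\rho_{ub} = \Gamma_p/(\Gamma_p+\Gamma_d)$ and the stationary
  standard deviation
  $\sigma\sqrt{(\alpha_d+\alpha_p) / (2(\Gamma_p+\Gamma_d))}$.

```{r}
ou_summary(1, 1, ca_preset("in_vitro"))
ou_summary(1, 1, ca_preset("in_vivo"))
```

At 1/s background firing the in-vitro synapse forgets with a time
constant of about 2.5 minutes and settles near 0.2; the in-vivo
amplitudes stretch the time constant to about two hours, because two
spikes must now summate within a calcium decay time to reach
$\theta_d$ — the origin of the $\tau_{eff} \propto \nu^{-k}$ power law
(`low_rate_power_law()`), with $k = 1$ in vitro and $k = 2$ in vivo.

## Memory retention with a bistable synapse

With the double well, background activity tilts the landscape into the
effective potential
$U_{eff}(\rho) = U(\rho) + \tfrac{\Gamma_d}{2}\rho^2 +
\tfrac{\Gamma_p}{2}(1-\rho)^2$ with effective noise
$\sigma_{eff} = \sigma\sqrt{\alpha_d + \alpha_p}$
(`effective_potential()`). The UP minimum disappears through a
saddle-node bifurcation at a critical rate $\nu_c$
(`bifurcation_rate()`): about 1.31/s for the in-vivo preset and about
0.038/s for the in-vitro one (the larger amplitudes destroy bistability
much earlier). Below $\nu_c$, memory loss is an escape over the barrier
$\Delta U$, with mean time

$$T = \frac{2\pi\,\tau_\rho}
  {\sqrt{U_{eff}''(\rho_{min})\,|U_{eff}''(\rho_{saddle})|}}
  \exp\!\left(\frac{2\,\Delta U}{\sigma_{eff}^2}\right)$$

(`kramers_escape_time()`). The standard double-well prefactor is used;
since $\alpha_d \propto \nu^k$ at low rates, $\ln T$ grows like
$\nu^{-k}$, and at 1/s the in-vivo escape time is of the order of one
month — an enormous extension over the two hours of the flat potential.
Because direct escape simulations at the published parameters would need
months of model time, the Kramers implementation is validated in an
elevated-noise regime ($\sigma \times 5$), where simulated mean
first-passage times are required to fall within a factor of three of the
prediction; weak-barrier corrections and the distinction between
reaching the saddle and completing the transition both live inside that
factor.

Two quantitative caveats, established numerically and reflected in the
tests: the flat/double-well equivalence of fitted decay times holds to
10% only from roughly $3\nu_c$ upward (at $2\nu_c$ the bare quartic still
inflates the fitted constant by tens of percent), and the position of the
supercritical minimum approaches $\bar\rho_{ub}$ to 5% only well above
$\nu_c$. Also note that the equilibrium (Fokker–Planck) efficacy
distribution at in-vivo parameters is almost entirely in the DOWN well at
1/s — the UP state is metastable, not equally occupied — so
stationary-CDF initialisation of a network puts unperturbed synapses in
the DOWN state, and a memory is implanted by explicitly tagging a subset
at $\rho = 1$.

## The scaled recurrent network

The network module implements a recurrent excitatory/inhibitory LIF
network with plastic E→E synapses ($w = J_{EE}^{max}\rho$, each synapse
updated event-wise by the exact scheme; presynaptic calcium delayed by
$D$; voltage jumps use the synapse's current $\rho$). Published
full-scale runs (8000 E + 2000 I, 120 minutes) are far beyond desk
scale, so the shipped default is a scaled design: 800 E + 200 I,
connection probability 0.1 (mean in-degree 100, autapses excluded),
$\tau_m = 20$ ms, $V_L = -70$ mV, $V_{th} = -50$ mV and the intermediate
reset $V_r = -60$ mV, with coupling strengths and external drive
($\mu_{ext} = 10.6$ mV, $\sigma_{ext} = 5$ mV,
$J_{EE}^{max} = 0.6$, $J_{EI} = J_{II} = -1.6$, $J_{IE} = 0.3$ mV)
chosen with the package's own mean-field solver to place the network in
an inhibition-dominated asynchronous irregular state near 1/s. All of
these are plain fields of `network_params()` and none of the analysis
depends on the specific defaults — only on the consistency between
simulation and mean-field theory at whatever operating point results.

Voltages are advanced with the exact OU transition over each step
(dt = 0.1 ms, also the transmission delay) plus a Brownian-bridge
threshold-crossing correction. The bridge term removes the
$O(\sqrt{dt})$ crossing bias of naive Euler sampling, which would
otherwise depress firing rates by several percent at this step size and
confound the comparison with the Siegert formula; with it, disconnected
neurons match the formula to well under 1%.

The mean-field fixed point (`solve_meanfield()`) couples the Siegert
transfer function $\nu_\alpha = \Phi(\mu_\alpha, \sigma_\alpha)$ (with
input moments from the expected in-degrees and the mean E→E weight
$J_{EE}^{max}\bar\rho$) with the Poisson-based efficacy asymptote
$\bar\rho(\nu_E)$, iterated with damping 0.5 to residual $10^{-8}$. The
Siegert integral uses the scaled complementary error function
$\mathrm{erfcx}$, which keeps the integrand finite where the raw form
overflows. Because LIF spike trains at a hyperpolarised-side reset have
fewer short interspike intervals than a Poisson process, calcium summates
less often than the theory assumes, so the predicted $\bar\rho$ — and
through recurrent excitation the predicted $\nu_E$ — sit slightly above
the simulation; this documented bias direction is asserted in the tests,
and `isi_statistics()` together with `simulate_lif_neurons()` reproduces
its mechanism (depolarised resets over-represent short ISIs and push
efficacies up; hyperpolarised resets do the opposite).

Experiment protocols at desk scale (`run_figure_protocol()`,
`memory_implant_experiment()`): a 5-minute scaled run with a tagged 5%
of synapses at $\rho = 1$ decays with the OU time constant evaluated at
the observed network rate (in vitro, flat); a 10-minute in-vivo
double-well run at about 1/s shows no well-to-well transition in either
direction, the scaled analogue of the full-size retention result. Every
protocol writes a manifest (configuration echo, seeds, package version,
desk-scale substitutions, outputs), and identical manifests reproduce
identical outputs.

## Numerical choices and problem sizes

Defaults were chosen once, as the study conditions, and the test suite
runs them unchanged: ensembles of 1000 synapses over 15 minutes of model
time at 1/s for the flat-potential comparison; rate grids of five points
per decade (0.01–0.1/s) for the power-law slopes; 500 elevated-noise
escape runs; scaled network runs of 5 and 10 minutes. Ensemble-mean
traces are binned at $\tau_{eff}/50$ and fitted by least squares to
$a + b\,e^{-t/\tau}$ (`fit_exponential()`, Levenberg–Marquardt with
log-linear starting values); dwell times are estimated by the censored
exponential MLE (total observed time over number of events), returning
`Inf` when nothing escapes within the horizon.

## What the synthetic data do and do not show

All inputs are synthetic: homogeneous Poisson trains for the single-
synapse theory, and LIF-generated spikes in the network. Passing tests
therefore demonstrate internal consistency of simulation and theory
under the model's own assumptions — stationary, uncorrelated background
activity, instantaneous calcium jumps with a single decay time, linear
scaling of calcium influx with extracellular concentration — not that
cortical synapses behave this way. Non-Poisson renewal statistics are
handled only empirically (via the LIF experiments), correlated pre/post
trains and nonstationary inputs are out of scope, and the escape-time
validation is performed at elevated noise because the published-parameter
regime is unsimulable by construction.
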