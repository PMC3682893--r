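---
title: "Quantifying bacterial persister fractions from biphasic kill curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial persister fractions from biphasic kill curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persisterfit)
```

## The problem

When a growing bacterial culture is exposed to a bactericidal antibiotic, the
viable count usually does not fall as a single exponential. After a fast
initial kill, a small subpopulation — *persister* cells — survives far longer,
producing a biphasic time-kill curve. Persistence is phenotypic and
transient, not genetic resistance: colonies grown from the survivors are as
susceptible as the original culture. The quantity of biological interest is
the **persister fraction**: the proportion of cells already in the protected
state at the moment of drug addition. Defining it through a dynamical model,
rather than as "survivors after *k* hours", makes estimates comparable across
antibiotics, strains and laboratories, because the model-based fraction does
not depend on the arbitrary choice of sampling time.

## The two-state model

`persisterfit` implements a two-state switching model of type-II persistence
(persisters generated by stochastic switching during growth). During
treatment, normal cells ($n$) die at rate $m$ and switch into the persister
state at rate $a$; persisters ($p$) neither die nor grow, and return to the
normal state at rate $b$ (all rates per hour):

$$
\frac{dn}{dt} = -(m + a)\,n + b\,p, \qquad
\frac{dp}{dt} = a\,n - b\,p .
$$

The total $N(t) = n(t) + p(t)$ is a sum of two exponentials,

$$
N(t) = c_1 e^{\lambda_1 t} + c_2 e^{\lambda_2 t},
\qquad \lambda_{1,2} = \tfrac{1}{2}\left[-(m+a+b) \mp
\sqrt{(m+a+b)^2 - 4mb}\right],
$$

with $\lambda_1 < \lambda_2 \le 0$: the fast phase is dominated by dying
normal cells, the slow tail by persisters. The discriminant equals
$(m-b)^2 + a(a + 2m + 2b)$, which is how the package evaluates it — the
rearrangement is exact and has no catastrophic cancellation when
$(m+a+b)^2 \approx 4mb$. Trajectories are evaluated in the form
$e^{\lambda_1 t}\,[y_0 + Q\,t\,\varphi(\Delta t)]$ with
$\varphi(x) = (e^x - 1)/x$ and $\Delta = \lambda_2 - \lambda_1$, which is
uniformly accurate and passes smoothly through the repeated-eigenvalue limit
($\varphi \to 1$), where the solution degenerates to
$(c_1 + c_2 t) e^{\lambda t}$. The repeated-eigenvalue boundary is excluded
from the *fitting* space (it is measure-zero and would break the
four-parameter likelihood parameterisation), but model evaluation handles it.

```{r model}
mech <- mech_params(m = 2, a = 0.01, b = 0.05)
init <- initial_state(N0 = 1e7, fp = 0.01)
eigenvalues(mech)
mech_to_obs(mech, init)
```

## What the data identify — and what they do not

A fitted biexponential provides four observables $(c_1, c_2, \lambda_1,
\lambda_2)$, but the mechanistic description has five unknowns
$(m, a, b, N_0, f_p)$. The data therefore constrain the persister fraction
$f_p$ only to an interval. Writing $D = -(c_1\lambda_1 +
c_2\lambda_2)/(c_1 + c_2)$ (the initial per-capita death rate, so $D =
m(1-f_p)$) and $u = 1 - f_p$, requiring $m, a, b \ge 0$ confines $u$ to
$[D/|\lambda_1|,\ \min(1, D/|\lambda_2|)]$. For a biphasic curve with
$c_1 > 0$ the lower fraction bound is always zero — a slow tail can always be
explained by cells switching *into* persistence during treatment — while the
upper bound $1 - D/|\lambda_1|$ corresponds to $a = 0$, all slow-phase cells
being present from the start.

```{r interval}
obs <- mech_to_obs(mech, init)
feasible_fp_interval(obs)
```

The package's point estimate is the interval midpoint `fp_mid`, with the
model-free slow-amplitude fraction $c_2/(c_1+c_2)$ reported alongside.  The
half-width of the interval is the honest identifiability cost of the model;
both endpoints are always reported. Note one convention trap in this
literature: the complementary quantity $u = 1 - f_p$ (the *normal*-cell
fraction, whose feasible values typically lie between 0.99 and 1) is also
displayed by the interval object, since published tables sometimes tabulate
that quantity under the name "initial fraction".

At a chosen $f_p$ the mechanistic rates are recovered exactly:

```{r invert}
obs_to_mech(obs, fp = 0.01)
```

## The likelihood

Counts from serial-dilution plating are small, so measurement error is
dominated by sampling, not pipetting: if a volume $\delta_t$ (plated volume
times dilution factor) of a culture at concentration $N(t)$ is plated, the
colony count is Poisson with mean $N(t)\,\delta_t$. The log-likelihood of a
curve is

$$
\ell = \sum_t \left[ x_t \log\!\big(N(t)\delta_t\big) - N(t)\delta_t -
\log x_t! \right],
$$

and a zero count contributes $-N(t)\delta_t$ — zeros are informative, not
censored. Fitting maximises $\ell$ over the transform $c_1 = e^{\theta_1}$,
$c_2 = e^{\theta_2}$, $\lambda_2 = -e^{\theta_3}$, $\lambda_1 = \lambda_2 -
e^{\theta_4}$, which enforces positivity and eigenvalue ordering by
construction. Each of `n_starts` (default 10) starting points — a heuristic
two-phase split of the data (early slope, late slope, intercepts), perturbed
on the log scale — is optimised by a Nelder–Mead simplex pass refined by
BFGS, and the best converged optimum is kept; a stochastic-annealing pass can
be enabled (`use_sann = TRUE`) as a cross-check but is off by default, since
on simulated data the two deterministic optimisers from ten starts reach the
same optimum. Fits are deterministic given `(curve, seed)`.

Two kinds of uncertainty are produced and labelled distinctly: per-replicate
(within-curve) 95% intervals from the observed information in the transformed
coordinates (`confidence_intervals()`), and the between-replicate standard
error of $\log_{10} f_p$ across biological replicates
(`summarize_strain()`), which is what study-level plots should carry.

When every late-phase count is zero the fraction is below the assay's
detection limit; the fit is flagged and the usable upper bound
$3/(\hat N_0 \cdot \max \delta_{\text{late}})$ — the ~95% Poisson bound
implied by observing no colonies — is reported, mirroring the
"less than 0.001%" convention of experimental reports.

```{r fit}
curve <- simulate_kill_curve(mech, init, seed = 42)
fit <- fit_replicate(curve, fit_config(seed = 7))
fit
```

Whether a curve is biphasic at all is decided against the nested
single-exponential model $N(t) = c\,e^{\lambda t}$ fitted with the same
likelihood; the biexponential must be favoured by more than 4 AIC units
(`compare_single_exponential()`), the conventional cutoff at which the weaker
model has considerably less support. The threshold is a package choice;
visual assessment is the field's usual practice and provides no rule.

## The synthetic-data generator

No raw CFU data accompany the study this design emulates, so the generator is
a first-class module, not a test fixture. It reproduces the experimental
design: exponential growth to $N_0 \sim 10^7\!-\!10^8$ CFU/ml, drug addition,
hourly sampling for 4 h plus samples at 20, 24, 28 and 48 h, serial 10-fold
dilutions spot-plated in 5 µl drops early, 100–500 µl plated directly late,
targeting 10–300 colonies per plate, 6 biological replicates. Dilutions are
chosen deterministically from the expected curve (`design_dilutions()`), and
counts are drawn Poisson — exactly the error model the likelihood assumes, so
generator and fitter are a matched pair by construction. What the generator
deliberately does *not* emulate: pre-treatment growth dynamics (entering only
through $N_0$ and $f_p$), antibiotic degradation or pharmacodynamics,
emergence of genetic resistance, plating-efficiency differences between cell
states, and colony overlap at high density. Passing tests therefore validate
the inference machinery under its own assumptions, not those real-data
complications.

Parameter choices in `study_scenario()` are the package's study conditions:
persister fractions log-uniform on $[10^{-5}, 0.1]$ (spanning the "<0.001% to
>10%" range reported for environmental isolates), kill rates $m \in [0.5, 5]$
/h, return rates $b \in [10^{-4}, 0.1]$ /h. The forward switching rate is not
drawn independently: during balanced exponential growth at rate $g$ the
persister fraction equilibrates at $f_p \approx a/(g + b)$, so the generator
sets $a = f_p/(1-f_p)\,(g + b)$ with $g = 1$/h (a ~40-minute doubling time,
consistent with glucose minimal medium and with ~100-fold regrowth in the 4 h
growth window). This makes the drawn $f_p$ the fraction actually present at
drug addition and — because $a$ is then strictly positive — places the truth
in the interior of the identifiability interval rather than on its $a = 0$
boundary.

An exact event-driven (Gillespie) simulator of the three elementary events
(death, $n \to p$, $p \to n$; `simulate_stochastic()`, implemented in C++) is
included as an independent oracle: the ensemble mean of the jump process is
exactly the ODE solution, so closed form, integrator and event simulator can
be cross-checked three ways without sharing code paths.

## Study-level analyses

* **Cross-antibiotic correlation** (`cross_antibiotic_correlations()`): if a
  single physiological change (dormancy) set each strain's persister level,
  per-strain fractions would correlate positively across antibiotics. The
  package rank-correlates per-strain mean $\log_{10} f_p$ between every pair
  of single drugs (Spearman, average ranks on ties), with permutation
  p-values: exact enumeration for $n \le 7$, seeded Monte Carlo (10,000
  permutations, add-one rule) above. Aggregation is on the log scale
  throughout, because fractions spanning four orders of magnitude would
  otherwise be dominated by single replicates; means of per-replicate
  $\log_{10}$ midpoints are used (the choice between means, medians or pooled
  fits is open in the source material — means are the documented choice
  here).

* **Combination treatments** (`classify_combination()`): under two drugs
  simultaneously, three hypotheses predict the combination fraction
  $f_{AB}$ from the single-drug fractions — *exclusive* (no cell tolerates
  both; $f_{AB}$ below detection), *independent* ($f_{AB} = f_A f_B$),
  *coincident* ($f_{AB} = \min(f_A, f_B)$: whoever survives the more lethal
  drug survives both). Classification is by $\log_{10}$ distance, accepting
  the nearer hypothesis within $\tau = 0.5$ (half an order of magnitude —
  small enough to separate the hypotheses over the observed fraction ranges,
  large enough to absorb replicate-level noise); otherwise *ambiguous*. The
  generator's convention for combination curves is that the pair inherits the
  kill and return rates of the more lethal member — a simulation convention
  recorded in the truth table, since no generative rule for combinations is
  established.

* **Determinants** (`parameter_determinants()`): rank correlations of
  $\log_{10} f_p$ with each of $\log_{10} a$, $\log_{10} b$, $\log_{10} m$
  across strain × treatment fits. Under the balanced-growth construction the
  fraction is a monotone function of the switching-in rate $a$, and nearly
  independent of $b$ and $m$ — the structure the analysis is designed to
  detect.

```{r study, eval = FALSE}
cfg <- pipeline_config(
  scenario = study_scenario(fraction_model = "independent", seed = 1),
  fit = fit_config(n_starts = 4, seed = 1),
  seed = 1)
res <- run_pipeline(cfg)
res$correlations
```

## Numerical and design notes

* **Problem sizes.** Simulation-based checks in the package's test-suite use
  12-strain, 3-antibiotic, 6-replicate studies (216 curves each) with
  `n_starts = 4` for study-scale fitting — the heuristic start makes extra
  starts redundant on clean synthetic curves — while single-curve analyses
  keep the default 10 starts.
* **Zero counts and floors.** Predicted Poisson means are floored at
  `1e-300` inside the optimiser so the objective stays finite; a genuinely
  zero mean with a positive count yields `-Inf` with a warning at the
  user-facing likelihood.
* **Ties and degeneracies.** Spearman uses average ranks; a constant vector
  gives a flagged, not erroring, result. A singular observed-information
  matrix flags intervals unavailable but returns the fit. An empty feasible
  fraction interval (possible only for inconsistent hand-built biexponential
  parameters, not for fitted ones) raises an explicit infeasibility error.
* **Fraction conventions.** `fp` is everywhere the *persister* fraction; the
  interval object also carries the complementary normal-fraction bounds
  (`u_min`, `u_max`) to interoperate with tables using the opposite
  convention.
* **Known limitations.** Type-I (stationary-phase-triggered) persistence is
  out of scope; the model assumes persisters neither die nor grow during
  treatment; overdispersion beyond Poisson (pipetting error, clumping) is not
  modelled; hierarchical pooling across replicates is deliberately absent —
  replicates are fitted independently and combined on the log scale.
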