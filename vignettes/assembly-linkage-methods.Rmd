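---
title: "Models and numerical methods for linked assembly equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods for linked assembly equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedlink)
```

# The system and the models

`sedlink` quantifies a coupled set of equilibria built around the *E. coli*
recombination mediator proteins RecR and RecO and the C-terminal acidic tip
of SSB (the 15-residue peptide P15):

1. RecR self-associates: two dimers (R2, 43.9 kDa) form a tetramer
   (R4, 87.8 kDa) with constant $L_{obs} = [R_4]/[R_2]^2$.
2. Tetramerization is linked to proton binding, so $L_{obs}$ depends
   steeply on pH.
3. RecO (O, 27.4 kDa) binds the tetramer in two steps
   ($K_3$: R4 + O, $K_4$: R4O + O), with a vestigial dimer pathway
   ($K_2$: R2 + O) retained in the network but fixed to a negligible value
   because the R2O species is not observed at equilibrium.
4. P15 binds RecO 1:1 ($K \approx 1.2\times10^7\,M^{-1}$) and switches the
   cooperativity of RecO binding to the tetramer.

Three measurement models expose these constants: sedimentation equilibrium
(SE), sedimentation velocity (SV) of the reacting mixture, and isothermal
titration calorimetry (ITC). Because the underlying raw data are not
public, every fitting stage is exercised against the package's own seeded
generators (`gen_se`, `gen_sv`, `gen_itc`), which reproduce the published
experimental designs with known ground truth. Passing those round trips
demonstrates that the estimators are consistent and correctly implemented
at realistic noise; it does not exercise systematic artifacts of real
instruments (baseline drifts, time-invariant noise, meniscus mislocation),
which the generators deliberately omit.

## Sedimentation equilibrium

At equilibrium the radial signal of species $i$ is exponential in
$r^2$ with reduced buoyant molar mass
$\sigma_i = M_i(1-\bar v_i\rho)\,\omega^2/(2RT)$:

$$A(r) = \sum_i A_{r_0,i}\, e^{\sigma_i (r^2 - r_0^2)} + b .$$

A reversibly associating dimer-tetramer system collapses to two terms with
the tetramer exponent exactly twice the dimer exponent and the tetramer
amplitude slaved to $L_{obs} C_{di,r_0}^2$; `fit_se` fits $\log_{10}
L_{obs}$ globally across all loadings and speeds with per-scan reference
concentrations and baselines. Choices that were genuinely open:

* **Reference radius**: each channel's meniscus, making amplitudes directly
  interpretable (the reference position is mathematically arbitrary).
* **Baseline**: one floated constant per scan. No functional form for a
  radius-dependent offset is available, and the synthetic designs only
  need a constant.
* **Mass conservation**: optionally enforced as a penalty tying the
  model-implied sector integral of scans from one channel together across
  speeds (`conservation_weight`); the generator itself is strictly
  conserving, so the default fit leaves the penalty off.
* **Optimizer**: Levenberg-Marquardt on log-scaled positive parameters
  with a small log-uniform multistart on $L_{obs}$ (fixed internal seed),
  keeping positivity without constrained optimization.

## pH linkage

Proton binding to $m$ sites on the tetramer and $n$ sites per dimer gives

$$L_{obs}(pH) = L_0 \frac{P_{tet}}{P_{di}^2},\qquad
P = (1+k[H^+])^{sites} \;\text{(independent)}\quad\text{or}\quad
1+(k[H^+])^{sites}\;\text{(cooperative)} .$$

The selected model is three cooperative tetramer sites and two independent
dimer sites, fit on $\log_{10} L_{obs}$ with parameters as $\log_{10}k$.
The pointwise slope $\partial \log L_{obs}/\partial pH$ is the net proton
uptake on tetramerization; `proton_uptake_slope` returns the analytic
derivative or an interval mean (both are reported because the published
$-2.5$ value does not state which convention was used).

**Identifiability.** With data confined to pH below the tetramer-site
pKa, only the product $L_0 k_{tet}^m$ and $k_{di}$ are determined: the
objective is flat along the ridge $\log L_0 + m\log k_{tet} =$ const, and
an unconstrained fit drifts arbitrarily far along it. `fit_linkage`
therefore fixes the normalization $L_0 = 1\,M^{-1}$ by default (floatable
via `fix_L0 = NULL`). On the five-point tabulated series this convention
reproduces the published protonation constants almost exactly, which is
strong evidence the original analysis used the same normalization. The
quoted standard error on $k_{tet}$ should be read conditionally on that
convention.

Weighting is uniform by default (the source analysis does not state
weights); `weighted = TRUE` propagates tabulated standard errors onto the
log scale as $\sigma/(L\ln 10)$. Upper-limit rows are excluded from the
residuals, with an optional one-sided penalty mode for sensitivity
analysis. `compare_linkage_models` refits all four cooperative /
independent combinations and ranks them by RMSD.

## Reaction-coupled sedimentation velocity

The six species sediment and diffuse in a sector-shaped cell while
interconverting through four reversible mass-action reactions
(forward rates $K \times k_{off}$, all $k_{off} = 0.01\,s^{-1}$ by
default). `simulate_lamm` solves

$$\frac{\partial c_i}{\partial t} =
\frac{1}{r}\frac{\partial}{\partial r}\!\left[r\left(D_i
\frac{\partial c_i}{\partial r} - s_i\omega^2 r^2 c_i\right)\right]
+ f_i(c)$$

with zero-flux walls. Numerical choices:

* **Finite volumes with Scharfetter-Gummel (exponential-fitting) face
  fluxes.** This scheme is monotone at vanishing diffusion, reduces to
  upwinding at $D=0$, reproduces the exact exponential steady state, and
  conserves the sector integral of every species to round-off by
  construction (the drift monitored over a run is $\sim 10^{-14}$,
  against a 0.1% acceptance bound).
* **Strang splitting**: half reaction step, $\theta$-scheme transport
  ($\theta = 0.5$) with one prefactored sparse LU per species, half
  reaction step. Default grid 400 cells, default $\Delta t = 2$ s; the
  step is halved automatically if conservation drift exceeds 0.1%.
* **Reaction substep**: a linearized L-stable (Rosenbrock-Euler) step
  solved simultaneously for all radial cells through a Woodbury rank-4
  identity, because material piling up near the cell bottom drives local
  relaxation rates to hundreds per second, far beyond what explicit
  substepping can afford. The step conserves both monomer totals exactly
  because the conservation vectors annihilate both the flux vector and
  its Jacobian. The splitting is first-order accurate in the reaction
  coupling; the fast-exchange limit test (weight-average $s$ invariant
  when $k_{off}$ is increased tenfold) bounds the consequence of that
  error at well under 1%.
* **Species transport coefficients**: sedimentation coefficients are the
  published in-buffer values (O 0.8, R2 1.2, R4 1.7, R2O 1.4, R4O 1.9,
  R4O2 2.5 S); diffusion coefficients follow from the Svedberg relation.
  The equilibrium starting composition comes from `equilibrium_composition`,
  which reduces the speciation problem to a monotone scalar root (free
  RecO) wrapped around a closed-form dimer quadratic.
* **Statistical factors**: the step-wise constants are applied exactly as
  given. The original figure stating the statistical-factor convention is
  not reproducible from text, so `reaction_network(statistical_factors =
  TRUE)` optionally applies the 2x / 0.5x site-statistics conversion
  without committing to a guess in the defaults.

## c(s)-style distributions and their oracle

`fit_cs` decomposes scans on a grid of non-reacting single-species Lamm
solutions (same solver), with diffusion tied to $s$ through a single
frictional ratio, and solves for nonnegative amplitudes with a
second-difference Tikhonov penalty (hand-rolled Lawson-Hanson NNLS; no
NNLS solver is available in the dependency stack). This is deliberately
simpler than full maximum-entropy c(s) machinery: the regularization
weight is a fixed user parameter (default `alpha = 0.1`, scaled by the
ratio of design-matrix to penalty norms) rather than F-test selected, and
the frictional ratio is either fixed or optimized by a coarse grid search
on RMSD (`optimize_f_ratio = TRUE`). Peak positions of well-separated,
non-reacting species are recovered within one grid step when the
frictional ratio matches; for the reacting mixture the complex peak sits
slightly below the 2.5 S of the pure R4O2 complex because species
exchange on the 100-second timescale partially averages the boundary.
Default analysis settings for the titration designs (s grid 0.2-3.6 S in
0.04 S steps, frictional ratio 1.65, the mean implied by the assembly
species) were chosen on the no-peptide fixture and then held fixed.

`transport_sw` provides the model-free cross-check: on the solver's own
grid, the depletion rate of the cell-mass sum landward of a plateau face
equals the flux through that face, so
$s_w = -\dot I/(\omega^2 r_f^2 c_p)$ reproduces a single-species $s$
essentially exactly and agrees with the c(s) integral within 2% on
reacting mixtures.

## ITC

For a ligand X binding n identical independent sites on M, the total heat
after injection $i$ is $Q^{tot}_i = V_0\,\Delta H\,n M_{tot}\,
K x/(1+Kx)$ with the free ligand $x$ from the mass-balance quadratic.
Integral heats convert to observed per-injection heats with the overflow
displacement correction
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$,
and cell concentrations follow the standard instantaneous-mixing
bookkeeping (dilution factor $(1-f/2)/(1+f/2)$ per injection,
$f = dV/V_0$). Documented assumptions, since the instrument schedule is
not published: cell volume 1.4 ml (VP-ITC class) and a schedule of 14
injections of 20 ul of 50 uM ligand into 2 uM macromolecule. The larger,
fewer injections were chosen over the conventional 28 x 10 ul because the
total available heat is small ($V_0\,\Delta H\,M_{tot} \approx -15$ ucal)
and concentrating it raises the per-injection signal-to-noise; a Monte
Carlo power check during design showed this halves the failure rate of
single-titration recovery at 0.1 ucal noise while leaving the estimator
unbiased. At these concentrations the c-value $K M_{tot} n \approx 24$ is
comfortably inside the informative range; `fit_itc` warns outside
[1, 1000]. The generator's titration contains no dilution-heat component,
so its blank fixture is pure noise and blank subtraction is exercised as
an invariance test rather than as a default correction.

## Hydrodynamic bookkeeping

Complex masses and partial specific volumes come from strict additivity
over monomer composition (RecO 27.4 kDa / 0.734 ml/g, RecR 21.95 kDa /
0.711 ml/g, both experimentally determined; the sequence-calculated
alternatives 0.743/0.731 are carried in `species_paper.yaml` for
sensitivity work). Standard-condition corrections use fixed reference
water constants ($\rho_{20,w} = 0.99823$ g/ml, $\eta_{20,w} = 1.002$ cP).
Working-buffer properties (25% v/v glycerol) come from a frozen
glycerol-water grid built from the Cheng viscosity mixing correlation and
an apparent-specific-volume density model anchored to standard water
densities, with bilinear interpolation and hard range errors instead of
extrapolation; dissolved salt adds a linear density increment (0.041
g ml$^{-1}$ M$^{-1}$) and its sub-percent viscosity effect at $\le$200 mM
is neglected. These tables reproduce the published RecO standard-condition
value within about 3% ($s^0_{20,w} = 2.26$ S here vs $2.32 \pm 0.05$ S);
exact agreement is not achievable without the original buffer-property
tables, which are not printed.

Units at the interface are Svedberg, kDa, ml/g, cm, cP, g/ml, ucal and
kcal/mol; conversions to CGS/SI happen once, inside the functions, and the
round trip is tested.

## Reproducibility

One integer seed drives every noise draw through counter-indexed
L'Ecuyer-CMRG substreams, so scan $k$ receives the same noise regardless
of how many scans precede it. Problem sizes used by the shipped test
suite and acceptance script - 300-400 radial cells, 30 scans per velocity
run, 2 s transport steps, 86-point s grids, 20-replicate recovery loops -
were chosen as the smallest designs at which the estimators' statistical
errors, not discretization, dominate the round-trip budgets.

## Known limitations

* The c(s) implementation is a regularized least-squares sketch of the
  full Bayesian/maximum-entropy machinery; peak *areas* in reacting
  mixtures are reaction-averaged and should not be read as species
  populations.
* Kinetic rate constants are forward-simulated, never fitted; the
  package follows the original strategy of comparing simulated c(s)
  profiles with data by eye.
* The linkage model's $k_{tet}$ is reported under the $L_0 = 1$
  normalization (see above) and is not separately identifiable from
  these data.
* No nonideality, compressibility, time-invariant noise, or meniscus
  uncertainty is modeled anywhere.

```{r example, eval = FALSE}
# the full linkage analysis in four lines
tab <- read_ph_series_csv(system.file("extdata", "table1_50mM.csv",
                                      package = "sedlink"))
fit <- fit_linkage(tab)
print(fit)
proton_uptake_slope(fit$model, interval = c(8, 9))
```
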