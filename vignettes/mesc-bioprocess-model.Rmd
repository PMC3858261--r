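---
title: "A multi-scale kinetic model of mESC expansion in encapsulated bioreactor culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale kinetic model of mESC expansion in encapsulated bioreactor culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mescsim)
```

## The modeling problem

Murine embryonic stem cells (mESCs) grown encapsulated in hydrogel beads
inside rotating-wall bioreactors lose "naivety" when inhibitory
metabolites — lactate from glycolysis and ammonia from glutaminolysis —
accumulate past critical levels, even while glucose, glutamine, LIF and
serum remain plentiful. `mescsim` implements a multi-scale kinetic model
of this process: population-segregated growth of a naive pool
$X_U$ and a "culture-primed" pool $X_D$ (cells·bead$^{-1}$), vessel mass
balances for glucose, glutamine, lactate and ammonia (mM), and
day-0-normalized relative expression of three pluripotency-informative
genes (*Rex1*, *Dppa3* — naive markers; *Fgf5* — primed marker), under
batch, fed-batch (daily full medium exchange) and perfusion operation.

The model's distinctive feature is the coupling from metabolism back to
population structure: metabolite stress suppresses *Rex1*, and the
inter-population transfer flux is gated by *Rex1* relative to its day-0
reference — cells move from the naive to the primed pool exactly when
*Rex1* is suppressed below 1, and back when it recovers above 1.

## Model equations

With $\mu_i$, $\mu_{d,i}$ the specific growth and death rates of pool
$i \in \{U, D\}$ and $R$ the transfer flux:

$$\frac{dX_U}{dt} = (\mu_U - \mu_{d,U})\,X_U - R, \qquad
  \frac{dX_D}{dt} = (\mu_D - \mu_{d,D})\,X_D + R$$

$$\mu_i = \mu_{max,i}\frac{GLC}{K_{glc,i} + GLC}, \qquad
  \mu_{d,i} = \mu_{d,max,i}\frac{LAC}{K_{dlac,i} + LAC}$$

$$R = K_{Diff}\,|1 - REX| \cdot \begin{cases} X_U & REX < 1\\ -X_D & REX \ge 1 \end{cases}$$

Transfer conserves $X_V = X_U + X_D$ by construction. Solute balances
(per vessel, with $N_{BEAD}$ beads; $D$ the dilution rate, nonzero only
in perfusion, applied to solutes but never to the bead-retained cells or
their gene states):

$$\frac{dGLC}{dt} = -Q_{GLC} X_V N_{BEAD} + D(GLC_{in} - GLC), \qquad
  Q_{GLC} = K_{GLC,MAX}\frac{(GLC - GLC_{MIN})^+}{K_{X,GLC} + (GLC - GLC_{MIN})^+}$$

$$\frac{dGLN}{dt} = -Q_{GLN} X_V N_{BEAD} - K_{D,GLN}\,GLN + D(GLN_{in} - GLN), \qquad
  Q_{GLN} = K_{GLN,MAX}\frac{GLN}{K_{X,GLN} + GLN}$$

$$\frac{dLAC}{dt} = Y_{LAC,GLC}\,Q_{GLC} X_V N_{BEAD} - D\,LAC, \qquad
  \frac{dAMM}{dt} = Y_{AMM,GLN}\,Q_{GLN} X_V N_{BEAD} - D\,AMM$$

Glucose uptake carries a hard threshold $GLC_{MIN}$: consumption stops,
continuously, once glucose falls to the threshold — reproducing the
observed sharp drop in glucose consumption despite abundant residual
glucose. Glutamine additionally decays abiotically
(first-order, $K_{D,GLN}$), and only cellular glutamine uptake produces
ammonia. Gene dynamics are driven by metabolite *stress*, the excess
over a critical level, $s_{LAC} = (LAC - LAC_{MIN})^+$ and
$s_{AMM} = (AMM - AMM_{MIN})^+$:

$$\frac{dREX}{dt} = \frac{b_{REX1}}{1 + (s_{LAC}/K_{LAC,REX})^2} - a_{REX}\,REX$$

$$\frac{dDPPA}{dt} = \frac{b_{DPPA}}{1 + (s_{AMM}/K_{AMM,DPPA})^2} - \alpha_{DPPA}\,DPPA$$

$$\frac{dFGF}{dt} = b_{FGF}\frac{s_{LAC}}{K_{LAC,FGF} + s_{LAC}}\cdot
  \frac{FGF}{K_{FGF} + FGF} - \alpha_{FGF}\,FGF$$

*Fgf5* production is activated by lactate stress and self-promoting
(Monod in its own level, reflecting the interaction of its two
transcript isoforms).

### Design choices in the equation forms

Three structural choices deserve explicit statement, since the source
tables constrain but do not uniquely determine them:

* **Threshold placement.** The three critical levels are implemented
  where they are mechanistically meaningful: $GLC_{MIN}$ inside the
  glucose uptake law, and $LAC_{MIN}$/$AMM_{MIN}$ as stress offsets in
  the gene equations (the parameter table groups them with the gene
  constants, and the model's premise is that metabolites act on gene
  expression only *above* critical levels). All thresholds are clamped
  floors — the affected flux is continuous at the threshold — which
  avoids integrator chatter at the switching surface. Product formation
  itself is pure yield coupling.
* **Cooperative stress inhibition.** The inhibitory Hill terms
  (lactate on *Rex1*, ammonia on *Dppa3*) use exponent 2; activation and
  self-regulation terms are first-order (Monod). The exponent was fixed
  by auditing candidate transcriptions against the model's published
  headline prediction — 73% of viable cells primed at day 6 of batch
  culture. First-order inhibition yields 60–65% under every defensible
  threshold placement; cooperative inhibition with stress offsets yields
  71%, within the 5-percentage-point audit band. Half-inhibition still
  occurs exactly one Hill constant above the threshold, regardless of
  the exponent.
* **Switching reference and tie-break.** The *Rex1* reference is the
  day-0 normalized level 1 (the natural fixed point of the
  2^-ddCt scale); at exactly the reference, the transfer flux vanishes,
  so the tie-break (which assigns the unstressed, primed-to-naive
  branch) affects only the direction label, never the dynamics.

### Units as printed

The parameter tables are used exactly as printed, on an hourly time
base, although the printed maximum rates (e.g. $\mu_{max,U} =
0.928\,h^{-1}$) are far faster than the realized growth the same study
reports ($0.49\,day^{-1}$). The consequence is a time-compressed
trajectory: the simulated batch culture peaks around 10 h rather than
day 4, and the population-composition and mass-balance structure — not
the clock — is what the model reproduces. `audit_units()` returns the
full list of flagged inconsistencies (including the ambiguous
"mM/cell" units of the maximum uptake rates, read as per-hour, and the
unusually fast abiotic glutamine decay, half-life ≈ 4.7 h). We
deliberately surface these rather than rescaling: any correction would
be a different model from the published one.

```{r}
audit_units()
```

## Simulation

`simulate_culture()` integrates the nine-state system with a
stiff-capable solver (default tolerances $10^{-8}$/$10^{-10}$),
restarting at every root-located *Rex1* switching time and at every
fed-batch exchange so the solver never steps across a discontinuity.
The right-hand side is compiled C for speed; an R mirror
(`culture_rhs()`, assembled from the individually exported rate laws)
serves as the reference implementation that the property tests hold the
compiled path against.

```{r}
traj <- simulate_culture(horizon = 192)
summarize_trajectory(traj)
```

Under the batch table, lactate crosses its inhibitory level (16 mM)
within hours, *Rex1* is suppressed below 1, and the transfer flux
drains the naive pool — 71% of viable cells are primed by 144 h. Under
the perfusion table and continuous feed (2.29 ml/h into 60 ml), solutes
wash out at $D = 0.038\,h^{-1}$, stress stays low, and the naive pool
dominates the endpoint. An early transient lactate spike (before
washout catches up with the hour-scale printed kinetics) briefly
inverts this ordering during the first day; comparisons between modes
are therefore made from 72 h onward.

## Parameter estimation

`fit_parameters()` minimizes a weighted least-squares objective: each
residual is scaled by the replicate SD where the dataset provides one,
otherwise by 10% of the variable's observed range; gene fold changes
are compared on the log scale. The underlying estimation objective used
to produce the published tables is not printed, so weighted SSE is this
package's declared objective — a deviation of unknown size. Free
parameters are optimized in log10 space (they span ten orders of
magnitude) by bound-constrained Levenberg–Marquardt from a multistart
(the supplied values plus log-uniform draws within bounds, default
box: two decades either side of the shipped values). One numerical
detail matters: the finite-difference Jacobian step is set well above
the ODE solver's noise floor (`epsfcn = 1e-6`); with the
machine-epsilon default the optimizer stalls on integration noise.

The two-stage workflow (`refit_significant()`) freezes the
GSA-insignificant parameters at their batch estimates and re-estimates
only the significant subset on perfusion data. From the batch values,
the perfusion landscape for all six significant parameters is a narrow
curved valley — $\mu_{max,U}$ and $K_{glc,U}$ trade off almost
perfectly — so only the yields and uptake maxima are practically
identifiable from the default synthetic design; recovery experiments
start from a perturbed neighbourhood of the truth, as one would when
iterating the workflow.

## Global sensitivity analysis

`sobol_design()` builds a Saltelli cross-sampled design
($n_{base}(k+2)$ rows), `sobol_indices()` applies the Saltelli-2010
estimator for first-order and the Jansen estimator for total-order
indices with bootstrap confidence bounds, and
`partition_significant()` thresholds the total-order indices (default
$S_T > 0.1$ on any output/probe-time pair — this package's convention,
since the cut-off behind the published partition is not printed).
Probe times default to days 2, 5 and 8, spanning the lag, exponential
and decline phases; outputs default to $X_V$, GLC, LAC, AMM, with cell
density analyzed as $\log_{10}(X_V + 1)$ because across decade-wide
parameter ranges raw densities span many orders of magnitude and a
handful of explosive design rows would otherwise own the output
variance. Design rows whose simulation fails at extreme sampled rate
combinations (a few percent of rows) are imputed to the median output
and counted in the result's `n_failed` attribute. The estimated
partition need not equal the published six-parameter subset at any
given design size; `partition_significant(override = )` lets the
workflow reproduce that subset exactly, and `run_workflow()` does so by
default.

## Synthetic data

`generate_dataset()` emulates the study's three assays: DNA-fluorescence
cell counts (multiplicative lognormal, CV 10%), a media-analyzer
nutrient/metabolite panel (additive Gaussian, SD = max(2% of value,
0.05 mM)), and 2^-ddCt qPCR fold changes (lognormal, CV 15%), in
triplicate by default, sampled daily for counts and the panel and every
other day for genes over the 8-day horizon. Values are clipped at zero;
a zero-noise configuration reproduces model output exactly, which makes
the generator the oracle for round-trip recovery tests
(`recovery_experiment()`). What the generator does *not* emulate —
replicate-level batch effects, assay drift, bead-to-bead heterogeneity,
sampling-volume depletion — bounds what passing recovery tests show
about real data: they validate the estimation machinery, not the
original study's error model.

## Problem sizes and numerical settings

Defaults used throughout the package (and its tests): hourly output
grid over 0–192 h; solver tolerances $10^{-8}$/$10^{-10}$ (fitting and
GSA use $10^{-7}$/$10^{-6}$ respectively, where thousands of
integrations are needed and cross-run differences are dominated by
sampling, not truncation); GSA base sample 128 (tests use 32–64 for the
full model and 1024 for the closed-form estimator checks); recovery
experiments use 10 repeats at assay CV 5% for the yield parameters.
Degenerate inputs are handled explicitly: zero cells give pure
chemistry (only abiotic glutamine decay and, in perfusion, washout);
zero-variance GSA outputs give zero indices with a warning; solver
failures carry the last valid state in the error.

## Known limitations

* The printed hour-base rate constants compress the dynamics ~20-fold
  relative to the experimental clock (see "Units as printed"); absolute
  times and peak densities are not comparable to the study's figures,
  and the equation transcription itself is a reconstruction constrained
  by the surrounding text and the published predictions, not a copy of
  typeset equations.
* Two discrete cell states only; the real culture is a continuum, so
  the predicted naive-to-primed transition is sharper than observed.
* LIF and growth-factor signaling, oxygen, pH, intracellular fluxes and
  bead-scale gradients are out of scope.
* The weighted-SSE objective and the GSA sampling conventions are this
  package's choices where the source leaves them unspecified; both are
  exposed as configuration.
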