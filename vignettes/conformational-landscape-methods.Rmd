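---
title: "Quantifying a fold-switching conformational landscape from NMR peak intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a fold-switching conformational landscape from NMR peak intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confex)
```

## The problem

A fold-switching (metamorphic) protein such as KaiB interconverts between
discrete conformations on timescales spanning nine orders of magnitude: an
hours-long exchange between the binding-incompetent Ground state and the
binding-competent fold-switched (FS) state, a seconds-scale excursion into a
partially disordered (PD) intermediate whose C-terminal half is random coil,
and a millisecond exchange between the Ground state and a sparsely populated
"Enigma" state consistent with a two-residue register shift of the β1–β3
sheet. No single NMR experiment covers that range, so the analysis combines
three observables:

* **Real-time HSQC intensity series** after a temperature jump quantify the
  slow Ground ↔ FS relaxation to equilibrium.
* **CEST profiles** (saturation transfer swept across offsets) expose
  millisecond-to-second exchange with invisible minor states, delivering
  their populations, shift positions and rates.
* **CPMG relaxation dispersion** reports the exchange contribution
  $R_\mathrm{ex}$ to transverse relaxation and, measured at two temperatures,
  the exchange regime.

`confex` implements each stage as reusable functions, plus a seeded
synthetic-data generator that emulates the corresponding experiments so the
whole pipeline can be exercised and validated by parameter recovery at desk
scale. The numbered scripts under `analysis/` run the stages in order and
write tidy tables under `results/`.

## Exchange models and forward simulation

An `exchange_model` holds $N$ states with first-order rates $k_{ij}$ on a set
of edges, stationary populations $p_i$, and per-state resonance positions and
relaxation rates. Detailed balance ($p_i k_{ij} = p_j k_{ji}$) is enforced at
construction, which makes the population vector the stationary state of the
rate matrix $K$ (columns sum to zero, $K p = 0$).

CEST profiles are simulated by propagating the $3N$-dimensional magnetization
(x, y, z per state) under exchange, relaxation and B$_1$ nutation for the
saturation period, starting from z-magnetization proportional to the
populations, and reading out the observed state's z-component normalized by
the $T_\mathrm{relax}=0$ reference:

```{r cest-demo}
m <- two_state_model(kex = 173, pb = 0.07, labels = c("G", "E"),
                     delta_omega = c(18, 22.1), r1 = c(1, 1), r2 = c(10, 10))
sch <- cest_scheme("C13", 800, b1_hz = 20, t_relax = 0.4,
                   offsets_ppm = seq(14, 26, by = 0.2))
prof <- cest_profile(m, sch, "G")
plot(prof$offset_ppm, prof$intensity, type = "l",
     xlab = "saturation offset (ppm)", ylab = "I / I0")
```

Two numerical choices matter here. First, the propagation uses the
*homogeneous* Bloch–McConnell form (relaxation toward zero, no $+R_1 M_0$
recovery term), with the initial z-magnetization at the stationary
populations; because profiles are normalized by the zero-saturation
reference, the recovery term would largely cancel from the reported
quantity, and generator and fitter share the identical forward model.
Second, the matrix exponential is evaluated by scaling-and-squaring
(Armadillo's `expmat` in compiled code); an explicit fixed-step Euler
integrator (`cest_profile_euler()`) provides an independent numerical
cross-check. Forward Euler applied to an oscillatory system is only stable
while $\omega^2 \Delta t/2$ stays below the relaxation damping, so the
oracle's default step is $10^{-7}$ s; the two propagators agree to better
than $10^{-3}$ in normalized intensity on all fixtures (in practice to
$\sim10^{-7}$).

CPMG dispersion propagates transverse magnetization as a complex $N$-vector
through ideal $\tau$–180°–2$\tau$–180°–$\tau$ cycles spanning a constant-time
period ($R_{2,\mathrm{eff}} = -\ln(I/I_0)/T_\mathrm{CT}$). Pulses are treated
as instantaneous, so one cycle is $E(\tau)\,\overline{E(2\tau)}\,E(\tau)$.
The Carver–Richards closed form is implemented *only* as an independent
cross-check (the two agree within 2% of $R_\mathrm{ex}$ across slow,
intermediate and fast regimes); it is never used for fitting, because in the
slow regime — where these data live — it cannot separate populations from
rates. The fast- and slow-limit expressions,
$R_\mathrm{ex} \approx p_A p_B \Delta\omega^2 / k_\mathrm{ex}$ (with an
optional $-\Delta R_2^2$ correction, off by default because $\Delta R_2$ is
small against $\Delta\omega$) and
$R_\mathrm{ex} \approx k_\mathrm{leave}$, serve as initializers and oracles.

Unit conventions live in one place (`nmr_constants`): field strengths are
given as the ¹H Larmor frequency in MHz and converted per nucleus with the
gyromagnetic-ratio fractions 0.101329 (¹⁵N) and 0.251450 (¹³C).

## What the synthetic data emulate — and what they do not

`default_fixtures()` encodes the study conditions:

| fixture | process | key truth values |
|---|---|---|
| `tjump20C` | 40→20 °C jump, real-time HSQC | $k_{G\to FS} = 0.09$, $k_{FS\to G} = 0.36$ h⁻¹; 45 Ground + 37 FS peaks |
| `tjump20C_cypa` | same with prolyl isomerase present | 0.24 / 0.98 h⁻¹; 1.25× brighter |
| `cest15N_20C` | linear E↔G↔PD, ¹⁵N CEST, B₁ 20 Hz / 0.4 s | $p_E = 8\%$, $p_{PD} = 3\%$, $k_{G\to E} = 12$, $k_{G\to PD} = 2$ s⁻¹ |
| `cest15N_4C` | same at 4 °C, B₁ 10 Hz / 0.5 s, G- and PD-observed | $p_E = 2\%$, $p_{PD} = 75\%$, $k_{G\to E} = 4$, $k_{G\to PD} = 2$ s⁻¹ |
| `cestMethyl_20C` | ¹³CH₃ CEST, two-state | $k_\mathrm{ex} = 173$ s⁻¹, $p_b = 7\%$ |
| `cest15N_beta1_20C` | slow two-state (β1 strand), both B₁ fields | $k_\mathrm{ex} = 6.4$ s⁻¹, $p_b = 5\%$ |
| `cpmg15N_25C/35C` | constant-time CPMG, two temperatures | leaving rates 12→24 and 2→4 s⁻¹ |
| `volumes_4C` | multi-state volume table | PD 75%, Ground 15%, FS 10% |

Values the source experiments do not pin down were chosen once as what a
practitioner would call realistic, and are deliberately not revisited:

* **Starting populations of the jump** (equilibrated at 40 °C) are taken as
  Ground 0.6 / FS 0.4; only the direction and size of the perturbation
  matter for recovering the relaxation rate, not its exact origin.
* **Noise**: 2% of the maximum amplitude for real-time series and volume
  tables; 1% of the reference intensity for CEST (four scans on a 1.2 mM
  sample are high-S/N data) and for CPMG volumes (32 scans).
* **Response factors**: log-normal with $\sigma = 0.3$, per peak for
  real-time series (the fitter must tolerate heterogeneous amplitudes) and
  per residue for volume tables (populations from volumes require the factor
  to cancel within a residue).
* **Time grid**: first point at 0.12 h (the ~7 min dead time), one spectrum
  every 0.33 h, 16 h horizon.
* **Acquisition grids**: ¹⁵N offsets 104–135 ppm in 25 Hz steps at an
  800 MHz ¹H field; 97 methyl offsets over 8–25 ppm; CPMG
  $n_\mathrm{cyc} \in \{1,2,3,4,6,8,10,14,18,24,30,38,48,60\}$ over 60 ms
  with repeat planes at 0, 30 and 60.
* **Per-residue shifts**: Ground positions uniform within the sweep; PD and
  Enigma separations of 2.5–4 and 4.5–6.5 ppm with random signs (¹⁵N), and a
  methyl separation set ranging from 0.5 to 4.1 ppm, matching the reported
  spread.
* At 4 °C the generator emits profiles observed from **both** the Ground and
  the PD peaks. With only Ground-observed profiles, a dominant exchange
  partner is almost indistinguishable from a minor one (the normalization
  cancels the observed population), and it is the reciprocated PD-observed
  dips that pin the Ground/PD balance — which is also how the real
  experiment distinguishes them. The 20 °C ¹⁵N and the slow β1 process carry
  both B₁ fields where the single-field data would leave
  $k_\mathrm{ex}$ and $p_b$ nearly degenerate.

What the generator does **not** emulate: 2D lineshapes, peak overlap,
B₁ inhomogeneity, off-resonance pulse imperfections, scalar couplings and
¹³CH₃ multiplet effects, temperature drift, and any systematic integration
error beyond i.i.d. Gaussian noise plus the reference-plane normalization
error. Passing recovery tests therefore demonstrates the estimators are
consistent and well-conditioned under realistic noise — not that every
systematic effect in real spectra is handled.

## Stage 1: real-time kinetics

Every peak relaxes as $I_i(t) = a_i + b_i e^{-k_\mathrm{obs} t}$ with the
*same* observable rate. Both the per-peak and the global fits profile the
linear parameters $(a_i, b_i)$ exactly at a trial rate and minimize the
profiled weighted residual sum of squares over $k$ by a bounded 1-D golden
search: no starting values, no divergence, and $k \ge 0$ by construction.
The global fit shares one $k_\mathrm{obs}$ across the Ground and FS peak
families jointly (interpreting the published "global fit" as one shared
observable rate; the two families relax with the same eigenvalue in a
two-state system, so this is also the statistically efficient choice).

Splitting $k_\mathrm{obs}$ into directional rates needs the equilibrium
minor population. Plateau ratios between matched Ground/FS peaks carry the
per-peak response-factor ratio and are therefore only asymptotically
unbiased; instead, within each state family every peak shares the same
amplitude fraction $b_i/a_i = (p_0 - p_\mathrm{eq})/p_\mathrm{eq}$
*independently of its response factor*, so with $r_G$ and $r_{FS}$ the
family medians, $p_G = r_{FS}/(r_{FS} - r_G)$ exactly — then
$k_{G\to FS} = k_\mathrm{obs}\, p_{FS}$ and
$k_{FS\to G} = k_\mathrm{obs}\, p_G$. Peaks enter the global fit only if
their fitted amplitude exceeds $4\times10^5$ (the fixture units reproduce
the published filter, retaining 45 Ground and 37 FS peaks).

Uncertainty comes from a bootstrap in which each replicate both re-draws
every point from its stated noise level and resamples peaks with replacement
within each state family; the default is 1000 replicates and a seed is
required. Over 20 seeded replicates of the jump fixture the mean recovered
rates sit within 10% of truth and the 95% intervals cover truth in at least
17 of 20 runs.

The CypA experiment is put on the first experiment's intensity scale by the
median ratio of matched (peak, plane) volumes — matched planes cancel the
kinetic time course, so the estimator sees the pure scale factor (1.25 in
the fixture) even though the two experiments relax at different rates.

## Stage 2: CEST fitting

`fit_exchange_model()` fits two- and three-state models globally across
residues by weighted least squares against the Bloch–McConnell forward
model: exchange rates and populations are shared, while each residue owns
its observed-state position, its shift separation to each minor state, one
$R_1$ (shared across states within the residue) and $R_2$ values. A minor
state's $R_2$ can be tied to the observed state's ($R_{2,E} = R_{2,G}$ in the
three-state fits, reported bit-exactly equal), which regularizes a state
whose linewidth the data barely constrain. Each profile additionally carries
an analytically profiled scale factor penalized by the known relative noise
of its reference plane — the reference normalization is a correlated
multiplicative error, and ignoring it biases populations when the observed
peak is weak.

The objective is multi-modal in the shift separations and has well-known
quasi-degeneracies, so the optimizer is built in layers:

1. **Transforms.** Rates are fit in log space; minor populations through an
   additive log-ratio. For tree (cycle-free) topologies the global block is
   optimized in *directed-rate* coordinates — $(\log k_\mathrm{fwd},
   \log k_\mathrm{rev})$ per edge with populations derived from detailed
   balance — because the dip depth constrains the leaving rate and the dip
   width the return rate, which decorrelates the notorious
   $k_\mathrm{ex}/p_b$ ridge. Populations are capped at a minor/observed
   ratio of 5 (a fainter "observed" peak would not be the one integrated).
2. **Initialization.** Dips located on a lightly smoothed profile seed the
   positions (`initialize_from_dips()`); minors that are below the detection
   threshold are located by a 1-D brute-force scan of their shift
   separation; a minor state that is itself observed (PD at 4 °C) has its
   position pinned by its own profile's global minimum, mirroring how known
   assignments are used in practice. Dip depths invert to leaving-rate
   estimates through $1 - e^{-k T_\mathrm{relax}}$ (measured as excess over
   the no-exchange prediction so direct-saturation shoulders do not
   masquerade as exchange). Because each step behaves differently across
   regimes, the whole pass is repeated under canonical slow, intermediate
   and fast settings plus a coarse global grid; single-edge (two-state)
   fits additionally run a profile-likelihood grid over both directed rates
   with the nuisance blocks re-settled at every node, which separates the
   distinct local minima of the $k_\mathrm{ex}/p_b$ ridge. The best
   complete initializations are carried through the alternation (and a
   post-alternation return-rate rescan) before choosing.
3. **Refinement.** Block-coordinate descent alternates the global kinetic
   block with the per-residue nuisance blocks (residues couple only through
   the globals, so per-residue steps are cheap), followed by a bounded
   full-space quasi-Newton polish whose iteration budget shrinks with the
   parameter count.

Reduced $\chi^2 = \chi^2/(n_\mathrm{points} - n_\mathrm{params})$ is the
model-comparison statistic. `compare_models()` ranks topologies, reports
pairs within a configurable 10% equivalence band as indistinguishable (the
published comparison gives no numeric band; 10% is this package's
convention), and flags edges whose fitted rate is consistent with zero —
the convention chosen here for "underdetermined" exchange such as a putative
Enigma↔PD connection.

Temperatures are fit independently (no van't Hoff linking), as in the
source analysis.

## Stage 3: CPMG

`compute_r2eff_profile()` inverts the constant-time decay, averages
duplicate planes and reports the larger of the noise-based and
duplicate-based uncertainty. `estimate_rex()` is deliberately simple —
$R_{2,\mathrm{eff}}(\nu_\mathrm{low}) - R_{2,\mathrm{eff}}(\nu = \infty)$
with the infinite-frequency value taken as the mean of the two
highest-frequency points ($\nu_\mathrm{low}$ = 50 Hz for backbone ¹⁵N,
25 Hz for methyls) — because in the slow regime full dispersion-curve
fitting is not meaningful. On noiseless slow-limit profiles the estimator
returns the leaving rate within 10%; at finite pulsing rates it
underestimates slightly (residual refocusing at the "infinite" points),
which is why the acceptance band for the 12 s⁻¹ fixture is 25%.

The source analysis names only "a nonparametric significance test" for
deciding whether $R_\mathrm{ex}$ rises or falls with temperature.
`classify_regime()` implements a Monte-Carlo resampling test: draw
$R_\mathrm{ex}$ replicates from each temperature's propagated uncertainty,
take the two-sided tail probability of a sign reversal of the difference,
and Bonferroni-correct across the residues measured at both temperatures. A
significant rise is `slow_intermediate`, a significant fall `fast`,
otherwise `undetermined`. This is a stated stand-in for the unpublished
test, not a claim about the original code.

## Stage 4: the free-energy landscape

Populations from peak volumes are per-residue normalized and averaged
(response factors cancel within a residue). CEST-visible populations are
merged with the real-time ones by rescaling them into the real-time anchor
state's mass — in real-time HSQC the Enigma state is invisible (fast
exchange averages it into the Ground peak) and PD is minor, so the Ground
peak carries the whole CEST-visible budget; states seen only in real time
(FS) pass through, and the merged set sums to one by construction.

State free energies are the Boltzmann inversion
$\Delta G_i = -RT \ln(p_i / p_\mathrm{ref})$ with Ground as the reference at
each temperature (the reference choice and the inversion convention are this
package's, since only the resulting diagram is published). Barriers use the
Eyring equation with transmission coefficient 1,
$\Delta G^\ddagger = -RT \ln(k h / k_B T)$, drawn as a single effective
barrier where only a composite rate is observed (Ground→FS via PD); no
microscopic PD→FS rate is invented. Because each temperature's diagram is
relative to its own reference, the absolute offset between the 4 °C and
20 °C diagrams is unidentified; assuming the shared rate-limiting barrier
cannot drop on cooling bounds it from below, and a constant 2 kcal/mol is
added to all 4 °C values (with a warning reporting the minimal compliant
offset if the constant were insufficient).

## Stage 5: chemical shifts

`coil_rmsd()` and `model_correlation()` compare experimental shift tables
against random-coil predictions (RMSD over selected atoms and residue
ranges) and structural-model predictions (Spearman rank correlation,
mid-ranked ties), and `rank_models()` assembles the state × model ×
predictor cross table with an argmax-per-predictor majority verdict.
Running the predictors themselves is out of scope; inputs are delimited
tables (plus a minimal NMR-STAR reader for assigned-shift deposits), matched
on residue number and normalized atom name.

## Problem sizes and degenerate inputs

The test suite fits thinned offset grids (every 2nd–3rd saturated plane) and
reduced bootstrap counts; the acceptance script fits the full grids. These
sizes are the package's own validation choices — estimates on thinned grids
agree with the full-grid fits well within the recovery tolerances.

Degenerate inputs are handled explicitly: zero-population states are pruned
before propagation (so a two-state model with $p_b = 0$ reproduces the
one-state profile exactly), `t_relax = 0` returns the all-ones reference
profile, `ncyc = 0` planes are reference-only and never divided by,
non-positive CPMG volumes are dropped with a log message, constant series
fit $k = 0$, constant predicted shift vectors flag an undefined correlation
rather than returning one, and every stochastic stage requires an explicit
seed.

## Known limitations

* The slow-regime $R_\mathrm{ex}$ estimator has a small negative bias at
  finite pulsing frequency; it is reported as-is rather than corrected.
* The PD arm of the 20 °C three-state fit is weakly identified (a 3%
  population whose dip rides on the Ground tail); its population can wander
  by tens of percentage points between noise realizations while the Enigma
  arm stays within a point or two. The 4 °C data, where PD is directly
  observed, are the right place to quantify PD — as in the source analysis.
* B₁ inhomogeneity is ignored (a single B₁ value per scheme).
* The bootstrap treats peaks as exchangeable within a state family;
  systematic per-peak integration errors would not be captured.
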