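---
title: "Distributed-parameter modelling of DCE-MRI: models, fitting, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed-parameter modelling of DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdce)
```

## The problem

Gliomas are classified molecularly by IDH mutation and 1p/19q codeletion,
and their proliferative activity is indexed by Ki-67. DCE-MRI probes the
tumour microvasculature non-invasively: a gadolinium bolus is tracked
through tissue by rapid T1-weighted imaging, and a tracer-kinetic model
converts the concentration dynamics into physiological parameters. This
package implements the complete analysis chain for two such models and the
cohort-level statistics that relate the fitted parameters to the molecular
markers.

## Models and assumptions

Both models are linear and stationary in the arterial input $c_p(t)$
(plasma concentration, mM), so tissue concentration is a convolution.

**Extended Tofts.** A well-mixed interstitium with volume fraction $v_e$
exchanges with plasma (fraction $v_p$) through the lumped transfer constant
$K^{trans}$ (1/min); the efflux rate is $k_{ep} = K^{trans}/v_e$. The model
conflates perfusion and permeability in $K^{trans}$ and has no notion of
transit time.

**Distributed parameter (Sangren–Sheppard).** The capillary is a plug-flow
tube with transit time $T_c = v_p/F$; tracer exchanges bidirectionally with
the interstitium along the capillary at rate $PS$. The residue function is
1 during first pass, drops to the extraction fraction $E = 1-e^{-PS/F}$ at
$T_c$, and decays through a Bessel-function tail as back-diffused tracer
washes out. Flow $F$ and permeability $PS$ are separately identified,
which is the point of using this model: blood flow carries the
1p/19q-codeletion signal that the Tofts family cannot express.

Assumptions shared by both: no water-exchange limitation, fast
vascular-interstitial mixing transverse to the capillary, a single
well-defined bolus arrival common to AIF and tissue (configurable fixed
delay; arrival is not fitted), and concentration linear in relaxation-rate
change.

Internal units are fractions and 1/min; reported values are ×100
(mL/100 mL, mL/min/100 mL) and percent for $E$, matching radiological
convention. Conversion happens only at ROI aggregation and config load.

## Numerical implementation

The residue integral has an integrable $1/\sqrt\tau$ endpoint singularity;
the substitution $\tau = u^2$ removes it, and the factor
$e^{-PS/F}$ is folded into the integrand so the exponentially scaled Bessel
function never overflows (`dp_residue` uses adaptive quadrature at
tolerance $10^{-8}$; the forward model uses a cumulative trapezoid in $u$).

Convolutions run on a uniform internal grid (default 0.5 s — half the 2 s
frame spacing) with trapezoid weights and FFT. The residue's jump at $T_c$
would alias badly there, so the kernel is split into a plug-flow boxcar —
evaluated exactly as differences of the cumulative AIF integral — plus the
continuous exchange tail shifted to $t - T_c$. Shifted series are
interpolated with natural cubic splines; with linear interpolation the
grid-refinement error is dominated by curvature at the bolus peak. Halving
the internal step changes the output by well under 0.1 %. A transit time
shorter than one internal step is clamped to one step with a classed
warning.

The forward model is validated against an independent brute-force solver:
upwind explicit finite differences of the two-region transport equations
with the capillary discretised into 200 axial segments. Agreement over a
3×3×3×3 parameter grid spanning the reported glioma ranges is better than
2 % of the curve peak (the comparison metric is the maximum absolute
difference divided by the oracle's peak, since pointwise ratios are
ill-defined around the pre-bolus zeros).

## Relaxometry

T1 mapping uses the linearised variable-flip-angle (DESPOT1) regression of
$S/\sin\alpha$ on $S/\tan\alpha$ at 3°/6°/9°, which is exact on noiseless
SPGR data and orders of magnitude faster than per-voxel nonlinear fitting;
at three angles nothing is gained by the latter. Voxels with slope outside
(0, 1) are flagged rather than raising errors. Signal-to-concentration
inversion rescales the fitted $M_0$ so the mean of the baseline frames maps
exactly to the fitted $T_{10}$, inverts the SPGR equation per frame, and
applies $C = (1000/r_1)(1/T_1 - 1/T_{10})$. Default relaxivity is
$r_1 = 3.6\ \mathrm{L\,mmol^{-1}s^{-1}}$, a configuration knob rather than
a constant because contrast-agent identity (hence relaxivity at 3 T) is
often ambiguous in published protocols. Negative concentrations are floored
at zero (magnitude logged); frames failing inversion are interpolated when
isolated and disqualify the voxel when contiguous. B1 inhomogeneity and
T2* decay (TE ≈ 1 ms) are out of scope.

## Fitting

Voxelwise estimation is bounded nonlinear least squares
(Levenberg–Marquardt, numeric Jacobian) on the concentration residuals.
Bounds — $K^{trans} \in [0,2]$, $v_e \in [10^{-4},1]$, $v_p \in [0,0.5]$,
$F \in [10^{-3},4]$, $PS \in [0,2]$ in fractional units — generously cover
reported glioma values. The DP objective is multimodal in $(F, PS)$ with a
degenerate short-transit ridge ($v_p \to 0$, $F$ inflated) and a
weak-extraction basin ($v_e \to 1$), so initialisation is a fixed lattice
of 3 geometrically spaced values per parameter. Geometric spacing is
deliberate for the volume fractions too: kinetic parameters vary over
orders of magnitude, and a linear span leaves no start near brain-tissue
$v_p \approx 0.005$, which empirically funnels every refinement into the
degenerate ridge. The six best-RSS starts are refined, skipping starts
whose initial RSS is within 5 % of an already-refined one (they sit on the
same objective plateau — typically the $F$-at-bound face of the lattice —
and duplicate the basin), with early exit once a start reaches
machine-precision RSS. Ties are broken by lattice order. Fits that do not
converge, exceed a configurable RSS threshold, or land on $v_e + v_p > 1$
are excluded from aggregation and counted.

ROI medians are taken per parameter over valid voxels, with $k_{ep}$ and
$E$ derived per voxel *before* the median — medians of voxelwise ratios
differ from ratios of medians, and the reported quantity is the former.

## The synthetic cohort

The generator emulates the study design the statistics assume: 48 patients
(24 IDH wild-type, 9 mutant/intact, 15 mutant/codeleted), 10 baseline + 180
dynamic frames at 2 s, SPGR with TR 3.03 ms and 3°/6°/9° pre-contrast
angles, bolus at 24 s. Group kinetics are log-normal, parameterised by
published median/IQR pairs via $\mu = \log(\mathrm{median})$,
$\sigma = \log(q_{75}/q_{25})/(2 z_{0.75})$ — this reproduces the median
and quartile *ratio* exactly; printed quartiles that are asymmetric on the
log scale are matched only approximately. The four DP parameters are the
generative truth, with a Gaussian copula giving $v_p$–$F$ rank correlation
0.56 within groups; extended Tofts truth is derived from the same
physiology ($K^{trans} = E\,F$, shared $v_e, v_p$), so both models are fit
to the same curves and only the DP marginals are exactly calibrated — the
derived Tofts/extraction medians land near, not on, their published
counterparts, which is the physically consistent choice. Ki-67 is coupled
to true interstitial volume by a Gaussian copula (target Spearman 0.62)
with a log-normal marginal truncated to [1, 90] %.

Within-ROI heterogeneity is multiplicative log-normal jitter
($\sigma = 0.15$) applied voxelwise around patient-level truth — enough to
make ROI medians meaningful without modelling spatial texture. Published
cohorts carry no within-ROI dispersion information, so recovered IQRs are
not claimed to match printed between-patient IQRs. Rendering produces a
6×6×3-voxel ROI inside a 10×10×5 volume (tests use 3×3×1 in 5×5×3),
VFA stacks and 4D dynamics with Rician (default) or Gaussian noise at a
baseline SNR of 20. What passing tests show is therefore internal
consistency of the whole chain under the stated noise model — not robustness
to motion, partial volume, B1 bias, AIF mis-selection or any other artefact
of real acquisitions, all deliberately outside the generator.

## Statistics

Group comparisons use the Mann–Whitney U test throughout (glioma kinetic
parameters are heavily right-skewed; no normality gating), exact when
$n_1+n_2 \le 12$ without ties, tie-corrected normal approximation with
continuity correction otherwise. U counts pairs in which the
mutation-group (or codeleted-group) member scores higher, ties 0.5, so
parameters elevated in the mutant group produce large U.
Benjamini–Hochberg runs within each 9-parameter comparison family — the
two families (IDH; 1p/19q within IDH-mutant) are corrected separately, the
natural reading of a per-table correction.

ROC orientation is fixed a priori per parameter by the class the parameter
is expected elevated in ($k_{ep}$ and $F$ on the mutant/codeleted side,
the leakage-related parameters on the wild-type/intact side), so AUC < 0.5
is possible and preserved rather than silently flipped. AUC variance is
DeLong's structural-components estimator; the paired DeLong test compares
each model's best-AUC parameter. Youden cut-offs search midpoints between
adjacent distinct scores (ties toward the smaller cut-off; an all-equal
score vector is flagged degenerate). Spearman p values are exact by full
rank-permutation enumeration for $n \le 10$ (chunked for $n \in \{9,10\}$)
and t-approximate above.

## Problem sizes and seeds

Every stochastic routine takes an explicit seed and the pipeline threads a
single master seed; identical (config, seed) reproduce outputs
byte-identically. The validation suite uses a 3×3×3×3 DP parameter grid
against the PDE oracle, 200 voxels per model for SNR-20 recovery, 50 seeded
cohort replicates for the end-to-end effect-structure check, and $10^4$
draws for copula calibration — sizes chosen so each check is statistically
meaningful at desk scale.

## Known limitations

* Fitting the extended Tofts model to DP-generated curves is a deliberate
  model mismatch (as in any real two-model analysis); Tofts estimates
  inherit bias, so closure tests bound only the DP estimates tightly.
* At 2 s resolution the vascular spike of low-$T_c$ voxels spans one or
  two frames; flow identifiability degrades as $T_c$ approaches the frame
  spacing, and single-voxel $F$ estimates can fall into transit-time
  trade-offs that the ROI median then absorbs.
* Group sizes of 9 vs 15 give the 1p/19q blood-flow comparison limited
  power once multiplicity-corrected: under the calibrated group
  distributions most seeded replicates do not reach adjusted significance
  for $F$, although the direction is almost always right. Single-cohort
  significance claims at this design size should be read accordingly.
* No motion correction, B1 mapping, DICOM ingestion, bolus-arrival
  fitting, or alternative kinetic models (2CXM, tissue homogeneity,
  Patlak).
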