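# dpdce

Tracer-kinetic analysis of dynamic contrast-enhanced (DCE) MRI for glioma
molecular phenotyping, built around two forward models fitted voxelwise to
gadolinium concentration curves:

* the **extended Tofts model**

  $$C_t(t) = v_p\,c_p(t) + K^{trans}\int_0^t c_p(s)\,
    e^{-(K^{trans}/v_e)(t-s)}\,ds,$$

* the **distributed-parameter (DP, Sangren–Sheppard) model**
  $C_t = F\,(c_p \otimes R)$, whose residue function separates plug-flow
  capillary transit (flow $F$, transit time $T_c = v_p/F$) from
  bidirectional capillary–interstitium exchange (permeability–surface
  product $PS$):

  $$R(t) = \begin{cases} 1 & 0 \le t < T_c\\[2pt]
  1 - e^{-PS/F}\Big[1 + \displaystyle\int_0^{t-T_c}
    e^{-\frac{PS}{v_e}\tau}\,
    \sqrt{\tfrac{(PS/v_e)(PS/F)}{\tau}}\;
    I_1\!\big(2\sqrt{(PS/v_e)(PS/F)\,\tau}\big)\,d\tau\Big] & t \ge T_c
  \end{cases}$$

  with derived first-pass extraction $E = 1 - e^{-PS/F}$.

Around the models the package provides the full study pipeline: Parker
population (or measured) arterial input function, variable-flip-angle
T1/M0 mapping, SPGR signal ↔ concentration conversion, bounded multi-start
Levenberg–Marquardt fitting, ROI-median aggregation into per-patient
records, and the cohort statistics used to relate kinetic parameters to
IDH mutation, 1p/19q codeletion and the Ki-67 proliferation index:
Mann–Whitney U with Benjamini–Hochberg correction, ROC analysis with
DeLong variance and Youden cut-offs, paired DeLong model comparison, and
Spearman correlation. A calibrated synthetic-cohort generator (48
patients: 24 IDH wild-type, 9 mutant/1p19q-intact, 15 mutant/codeleted,
with log-normal group kinetics and a Gaussian-copula Ki-67) makes every
stage testable without patient data.

Intended users: imaging scientists and biostatisticians who need a
transparent, scriptable reference implementation of DP-model DCE analysis
and its downstream statistics.

## Worked example

```r
library(dpdce)

# three reference cases (ROI-median Ex-Tofts Ve in mL/100 mL,
# DP blood flow in mL/min/100 mL) with histologically confirmed subtypes
cases <- example_cases()
cases$predicted <- classify_subtype(cases$tofts_ve, cases$dp_f)
cases
#> # A tibble: 3 x 5
#>   case  subtype            tofts_ve  dp_f predicted
#>   <chr> <chr>                 <dbl> <dbl> <chr>
#> 1 A     wild-type             16.1   9.21 wild-type
#> 2 B     mutation-intact        0.08  7    mutation-intact
#> 3 C     mutation-codeleted     1.34  8.82 mutation-codeleted
```

All three cases classify correctly: an interstitial volume fraction above
the 1.670 mL/100 mL cut-off calls IDH wild-type, and among IDH-mutant
cases a DP blood flow above 7.154 mL/min/100 mL calls 1p/19q codeletion.

A full synthetic study:

```r
co  <- sample_cohort(cohort_config(), seed = 1)   # 48 labelled patients
rep <- build_report(co)
glance(rep)
#> # A tibble: 1 x 5
#>       n n_significant_idh n_significant_codeletion best_auc_idh best_auc_codeletion
#>   <int>             <int>                    <int>        <dbl>               <dbl>
#> 1    48                 8                        0        0.944               0.830
```

Permeability-related parameters separate IDH genotypes strongly (8 of 9
reach adjusted p < 0.05 in this draw), while the 1p/19q comparison at
n = 9 vs 15 carries the right effect direction (best AUC 0.83, for blood
flow) but rarely survives multiplicity correction — the effect structure
and power the generator is calibrated to.

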