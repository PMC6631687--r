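# ivivepk

In vitro–in vivo extrapolation (IVIVE) of hepatic clearance for PET
radiotracers, with a complete in vivo pharmacokinetic analysis pipeline and
a synthetic-data generator for validation.

## The problem

PET radiotracers are injected in subnanomolar amounts — three or more
orders of magnitude below the concentrations used in standard microsomal
stability assays — which raises the question of whether in vitro metabolism
data can predict radiotracer clearance in vivo at all. This package
implements the quantitative workflow needed to answer that question in the
rat model, for compounds whose clearance is predominantly hepatic
(ECCS class 2): predict plasma clearance from microsomal depletion data,
estimate observed clearance from arterial plasma sampling, and quantify
prediction accuracy. It is written for PK/DMPK scientists and radiotracer
developers.

## The models

**In vitro.** A depletion time course is fitted to
`C(t) = C0·exp(−ln2·t/t½)`; the half-life is corrected for nonspecific
microsomal binding via the lipophilicity relationship

    f_mic = 1 / (1 + P·10^(0.072·logP² + 0.067·logP − 1.126))

and scaled to intrinsic clearance (unbound convention, standard rat
factors):

    CL_int = ln2/(t½·f_mic) · (mL incubation/mg protein) · 60 mg/g liver · 40 g liver/kg

**Prediction.** The well-stirred liver model with hepatic blood flow
Q = 55 mL/min/kg and plasma free fraction f_p:

    CL_p = Q·f_p·CL_int / (Q + f_p·CL_int)

**In vivo.** Decay- and metabolite-corrected plasma concentration curves
are fitted with a triexponential disposition model
`C_p(t) = ΣA_i·exp(−λ_i·t)`, giving

    CL_p = D / Σ(A_i/λ_i)    V_d = CL_p/λ₃    t½,term = ln2/λ₃

**Accuracy.** Fold error (predicted/observed), average fold error
(geometric mean; its inverse is the fold underprediction) and RMSE.

## Worked example

The package bundles reference data for three xanthine A1 adenosine receptor
radiotracers studied in rat (CBX, MCBX, CPFPX): measured log P and
microsomal half-lives, free fractions reconstructed from the reported
clearance pairs, and observed plasma clearances from mean-curve fits.

```r
library(ivivepk)
cfg <- pipeline_config(
  "tables",
  compounds = a1ar_reference_compounds(),
  observed  = a1ar_reference_compounds()[c("compound_id", "cl_p_observed")])
run_ivive(cfg)
```

```
== In vitro stability and predicted clearance ==
 compound_id log_p t_half_vitro     f_p cl_p_observed  f_mic cl_int
         CBX  2.19         35.1 0.02697          3.22 0.8959  105.8
        MCBX  2.82         19.8 0.04427          9.10 0.8224  204.3
       CPFPX  2.93         14.0 0.01742          7.10 0.8039  295.6
 cl_p_predicted
          2.713
          7.768
          4.709

Clearance prediction accuracy
 compound_id predicted observed fold_error
         CBX      2.71     3.22       0.84
        MCBX      7.77     9.10       0.85
       CPFPX      4.71     7.10       0.66
AFE = 0.78  (fold underprediction 1.3)   RMSE = 1.6 mL/min/kg
```

Reading the output: metabolic stability ranks CBX > MCBX > CPFPX in the
microsomal assay, but after accounting for plasma protein binding the
predicted in vivo clearance ranks CBX < CPFPX < MCBX — matching the
observed order. All three predictions fall within 1-fold of observation;
the AFE of 0.78 corresponds to a slight (1.3-fold) average underprediction,
in line with what microsomal IVIVE typically achieves for classical drugs.

A fully synthetic run — generating depletion assays, ultrafiltration counts
and an 8-animal plasma study per compound, then running every fitting stage —
is one call:

```r
run_ivive(pipeline_config("synthetic", noise = noise_config(seed = 42)))
```

A thin command-line wrapper with `simulate`, `invitro`, `invivo`, `predict`
and `report` subcommands is installed at `inst/cli/ivivepk.R`; small
synthetic example CSVs live in `inst/extdata/`. The scientific background,
estimator choices and generator design are documented in
`vignettes/ivive-methods.Rmd`.

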