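# fxsephys

Patch-clamp feature extraction, K⁺-current decomposition and a
conductance-based simulator for phenotyping layer-5 prefrontal pyramidal
neurons.

## The problem

Layer-5 pyramidal neurons split into pyramidal-tract (PT) and
intratelencephalic (IT) projection classes with distinct ion-channel
repertoires. Comparing wild-type and *fmr1* knockout cells class by class
requires a long chain of standard electrophysiology analyses: subthreshold
membrane properties from current-clamp step families and chirp stimuli,
action-potential threshold dynamics from just-threshold pulses, and a
voltage-clamp decomposition of the outside-out patch K⁺ current into
fast-inactivating (Kv4-like), slowly inactivating (Kv1-like) and sustained
components, followed by a t-test/ANOVA battery with Bonferroni correction.
`fxsephys` implements that chain as tested, reusable R functions, and pairs
it with a Hodgkin–Huxley-style neuron/patch simulator whose
genotype-by-class presets emulate the published phenotypes — so every
stage can be exercised, validated against closed-form oracles, and run
end-to-end with no experimental data.

The core quantities, in the field's notation:

* input resistance *R*<sub>N</sub> from the linear portion of the I–V
  relation; sag ratio (peak/steady-state deflection); rebound slope;
  functional membrane time constant (slow component of a double-exponential
  decay fit); impedance profile *Z*(*f*) = |FFT(*V*)|/|FFT(*I*)| with
  resonant frequency *f*<sub>R</sub> (cells with *f*<sub>R</sub> > 2.2 Hz
  classify as PT-like); temporal summation of 50-Hz simulated EPSC trains;
* spike threshold at the first 20 mV/ms crossing of d*V*/d*t*, with
  just-threshold currents found by bisection across pulse durations
  (strength–duration/accommodation curves);
* *I*<sub>K-total</sub> (step to +50 mV from −90 mV),
  *I*<sub>KA-fast</sub> = total − prepulsed (100-ms prepulse to −20 mV),
  *I*<sub>K-slow</sub> = prepulsed − sustained (−20 mV holding), Boltzmann
  activation fits *G*/*G*<sub>max</sub> = 1/(1+exp(−(*V*−*V*<sub>1/2</sub>)/*k*)),
  inactivation/recovery time constants, and the h-current step
  (−30 → −140 mV) with double-exponential activation kinetics.

## A worked example

Simulate one wild-type PT cell, run the step family and chirp, and extract
its subthreshold profile:

```r
library(fxsephys)

cell  <- neuron_preset("wt-pt")
steps <- run_step_family(cell)                 # -150..+50 pA, 1000 ms
chirp <- run_chirp(cell)                       # 1-15 Hz in 15 s

input_resistance(steps)$R_N_MOhm
#> [1] 79.77579
sag_ratio(steps)
#> [1] 1.39081
zap_profile(chirp)$f_R_Hz
#> [1] 4.066667
```

79.8 MΩ, a sag ratio of 1.39 and theta-band resonance at 4.1 Hz are the
calibrated wild-type PT soma. The knockout preset differs only by the
stated conductance scalings (h-current ×0.6, Kv4-like ×1.35, Kv1-like
×0.6) and lands at ~95 MΩ and ~3.1 Hz.

Decompose the K⁺ current of a simulated somatic patch:

```r
kch   <- patch_channels_from(cell, "soma", exclude = c("NaT", "K_DR", "H"))
patch <- patch_spec(area_fraction = 0.05, noise_pA_sd = 0)
dec   <- run_k_decomposition(kch, patch)
round(dec$fractions, 2)
#>      fast      slow sustained 
#>      0.43      0.48      0.17 
```

43% fast / 48% slow of the total somatic K⁺ peak for wild type; the same
call on a `"ko-pt"` cell gives ~60% / ~30% — the flipped contribution
pattern that defines the knockout K⁺ phenotype.

The full cohort pipeline (simulate four cohorts, extract the feature
battery, run the statistics, summarize directions):

```r
res <- run_pipeline(list(n_cells = 15, seed = 1, family_size = 1))
head(subset(res$directions, direction != "unchanged"))
```

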