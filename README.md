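# growthctrl

Coarse-grained kinetic submodels of growth rate control in *Escherichia
coli*, for systems biologists who want the stringent-response machinery —
amino-acid biosynthesis and transport kinetics, tRNA charging, RelA/SpoT
(p)ppGpp dynamics, ppGpp-dependent transcription, transcriptional
attenuation and NCA-based fold-change extraction — as standalone,
deterministic, desk-scale R functions rather than buried inside a full
whole-cell model.

## The model in brief

Amino-acid supply to translation is a balance of single-step synthesis,
loss and exchange per amino acid *i*:

    v_supply = v_synth - v_down - v_loss + v_exchange
    v_synth  = kcat_f * E * 1/(1 + AA/K_I) * prod_j AA_j/(AA_j + K_M_j)

with forward/loss rate constants fitted against steady-state mass balances
at two anchor conditions (minimal and rich media), weighting exchange
deviations from literature uptake 1000:1.  Charging and elongation follow
saturating bi-substrate and A-site-competition kinetics, relaxed to a
within-timestep steady state by a stiff implicit integrator.  ppGpp obeys

    d[ppGpp]/dt = v_RelA + v_SpoT,syn - v_SpoT,deg

where RelA senses ribosomes carrying uncharged tRNA and SpoT hydrolysis is
inhibited by uncharged tRNA; the SpoT constants derive analytically from a
30 s decay half-life and an 11.4 µM steady state at 0.1 µM SpoT.  ppGpp
binds RNA polymerase with Hill coefficient 2 (`f = C²/(K_M² + C²)`) and
partitions expression between free- and bound-polymerase programs per gene;
charged tRNA attenuates enzyme transcription
(`P_stop = 1 - exp(-Σ tRNA/K)`).  A reduced host cell couples everything
per timestep and runs nutrient shifts, ppGpp clamps (0.01 µM/s ramp) and
allosteric-removal mutants.

## Worked example

```r
library(growthctrl)

# SpoT calibration: half-life 30 s at 0.1 uM SpoT, steady state 11.4 uM
d <- derive_spot_constants(halflife_ref = 30, C_SpoT_ref = 0.1,
                           ppgpp_ss_ref = 11.4)
signif(d$k_SpoT_deg, 2)   # 0.23   (1/(uM*s))
signif(d$k_SpoT_syn, 2)   # 2.6    (1/s)

# round trip: the SpoT-only ODE finds the calibration steady state again
pp <- ppgpp_params("trna")
tr <- integrate_spot_ode(pp, ppgpp0 = 1, t_end = 600)
tail(tr$ppgpp, 1)         # 11.39999 uM

# fit a toy biosynthesis network and recover the planted constants
toy <- generate_toy_aa_network(4, "branch", seed = 17)
fit <- fit_kcats_and_exchange(toy$net, toy$constants,
                              toy$cond_minimal, toy$cond_rich)
max(abs(fit$kinetics$kcat_f - toy$kinetics$kcat_f) /
    toy$kinetics$kcat_f)  # ~2e-07
max(abs(fit$residuals$minimal))   # ~3e-14 uM/s (balances hold exactly)

# a rich -> minimal downshift with all regulation on
hp <- host_params()
sched <- data.frame(time = c(0, 400), media = c("rich", "minimal"))
r <- run_shift_experiment(hp, sim_options(seed = 1, dt = 2), sched,
                          t_end = 2400)
s <- r$series
min(s$growth[s$time > 400])       # ~1.5e-04 1/s: transient growth minimum
mean(s$growth[s$time > 2100])     # ~2.0e-04 1/s: post-shift steady value
max(s$ppgpp)                      # ~98 uM: stringent ppGpp spike
```

The downshift trace shows the stringent signature: ppGpp spikes from its
rich-media value (~11 µM) toward ~98 µM within a minute of amino-acid
removal, the growth rate dips below its post-shift steady value while
biosynthesis enzymes accumulate, and the mRNA:rRNA mass ratio rises
transiently as polymerase reallocates from stable-RNA operons to mRNA.

## Layout

- `R/aa_biosynthesis.R`, `R/aa_transport.R`, `R/aa_supply_pheno.R` — supply
  kinetics and their calibrations
- `R/trna_charging.R`, `R/ppgpp_kinetics.R` — charging/elongation and
  RelA/SpoT dynamics
- `R/ppgpp_transcription.R`, `R/attenuation.R`, `R/nca.R` — transcription
  regulation and fold-change extraction
- `R/host_cell.R` — the reduced host and shift experiments
- `R/fixtures.R` — synthetic generators and JSON/CSV serialization
- `inst/cli/growthctrl.R` — `fit-params`, `fixtures`, `simulate`, `shift`
  subcommands
- `vignettes/growth-rate-control.Rmd` — the methods vignette (models,
  assumptions, parameter choices, limitations)
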