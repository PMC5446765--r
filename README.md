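# thermodose

Kinetic modelling of heat stress in microalgal cultures: how fast do
cells die, and photosynthesis stop, when an outdoor culture overheats —
and what does that cost a production site over a year?

Outdoor photobioreactors routinely exceed 40 °C on summer afternoons.
For the commercial species *Dunaliella salina*, viability and
photosynthetic activity are unaffected below about 43 °C but collapse
within minutes to hours above it. `thermodose` implements the kinetic
framework describing this: a Weibull survival model driven by an
integrated **thermal dose**, its calibration from laboratory kinetics,
activity estimation from PAM fluorometry, viability estimation from
flow cytometry, and a full-scale culture-collapse simulator.

## The model

Survival of an exposure of duration *t* at temperature *T* follows a
Weibull law,

    V(t) / V0 = exp( −(t / λ(T))^n ),    λ(T) = exp( a (T − T0) ),

where λ(T) is the half-life (the exposure killing 63% of the
population), *a* (°C⁻¹, negative) sets how fast the half-life shrinks
with temperature, *T0* (°C) is the temperature of unit half-life and
*n* is a shape factor producing the observed shoulder before rapid
decay. Because the exponent depends on *t* and *T* only through the
dimensionless **thermal dose**

    d = ∫ exp( −a (T(t′) − T0) ) dt′,

arbitrary temperature histories reduce to `survival = exp(−d^n)`,
integrated only while the culture is at or above the lethal threshold
(43 °C by default). Separate parameter sets describe viability
(erythrosine or FDA staining) and photosynthetic activity (the initial
slope α of a rapid light curve, fitted with the reparameterised
Eilers–Peeters model).

Calibration is two-stage: per-temperature least-squares Weibull fits,
then a log-linear regression of fitted half-lives on temperature
(slope = *a*, −intercept/slope = *T0*), with the shape factor averaged
across temperatures and uncertainty from a duplicate-noise Monte-Carlo
bootstrap.

## Worked example

```r
library(thermodose)

# duplicate kinetics at the six bath temperatures, 3% measurement noise
dat <- gen_kinetics(gen_config(seed = 7, noise_sd = 0.03))
res <- calibrate(dat, mc_iter = 1000, seed = 7)
res
#> <calibration_result> endpoint = viability
#>   a  = -0.2166 1/degC
#>   T0 = 81.66 degC
#>   n  = 4.665
#>   half-life regression R^2 = 0.9999 over 4 temperatures (excluded: 41, 42 degC)
#>   Monte-Carlo 95% CIs:
#>     a   [-0.2185, -0.2146]
#>     T0  [81.39, 81.95]
#>     n   [4.442, 4.93]

# a year with four afternoon heatwaves above the lethal threshold
clim <- gen_climate(gen_config(seed = 7, heatwave_days = c(150, 185, 210, 240)))
sim  <- run_simulation(clim, config = sim_config(policy = "delay-days",
                                                 delay_days = 5))
sim
#> <sim_result> 365 days: 4 collapses, 4 deactivation days, 4 days over 43 degC, light loss 5.0%
```

The calibration recovers the generating half-life law (the 41/42 °C
curves show no decay, so they are excluded as unidentifiable — exactly
what happens with the real sub-lethal curves). Each simulated heatwave
day accumulates enough dose to push end-of-day viability below 1%, so
it is counted as a culture collapse; with re-inoculation delayed by
5 days, each collapse forfeits about six days of incident light, and
under the assumption that productivity is proportional to captured
light the annual loss here is 5.0%.

Fitted objects support `tidy()`, `glance()` and `autoplot()`;
`pipeline_calibrate()`, `pipeline_simulate()`, `pipeline_rlc()` and
`pipeline_gate()` run the same stages file-to-file on the package's CSV
dialects, and `write_synthetic_inputs()` emits example files for every
stage.

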