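# debyesim

Multipole Debye dispersion modelling and time-domain simulation of
biological tissue.

## What it is for

Biological tissue is a dispersive dielectric: its conductivity and
permittivity change by orders of magnitude between the low-frequency alpha
dispersion and the membrane-driven beta dispersion.  Impedance spectroscopy
characterises this in the *frequency* domain, but applications such as
pulsed-electric-field electroporation drive the tissue with square pulse
bursts whose response must be computed in the *time* domain — where the
usual Cole–Cole description has no direct representation.

`debyesim` is for bioimpedance and bioelectromagnetics practitioners who
need that bridge.  It represents a tissue's complex relative permittivity
as a multipole first-order Debye model

```
eps*_r(w) = sigma_s / (j w eps0) + eps_inf + sum_k  d_eps_k / (1 + j w tau_k)
```

fits the model to admittance spectra (Y = G + jB over a 40 Hz–10 MHz
sweep) with a tournament genetic algorithm minimising the log-space cost

```
CF = sum_f (log10 E_r - log10 D_r)^2 + (log10|E_i| - log10|D_i|)^2,
```

and converts each fitted pole into an auxiliary differential equation
(ADE), `tau_k de_k/dt = E - e_k`, so the terminal current

```
I(t) = S [ sigma_s E + eps0 eps_inf dE/dt
           + sum_k (eps0 d_eps_k / tau_k)(E - e_k) ]
```

can be simulated for arbitrary waveforms.  Both a lumped (uniform-field)
solver and a minimal axisymmetric finite-element solver are provided, plus
a synthetic-spectrum generator so the whole pipeline is testable without
laboratory data.

## Worked example

```r
library(debyesim)

model <- potato_debye_models()$n4          # 4-pole potato-tissue dispersion
geom  <- cylinder_geometry(radius = 9.25e-3, height = 5e-3)

# frequency domain: terminal current at 1 kHz under 50 V
I <- 50 * terminal_admittance(model, geom, 1e3)
sprintf("|I| = %.4f A, phase = %.2f deg", Mod(I), Arg(I) * 180 / pi)
#> "|I| = 0.0734 A, phase = 7.21 deg"

# time domain: five periods of a 50 V sine, ADE integration
sim <- simulate_lumped(model, geom, source_sine(50, 1e3), t_end = 5e-3)
extract_amplitude_phase(sim, 1e3)
#> amplitude phase_deg
#> 0.0733759 7.2138605

# both solvers, side by side
compare_domains(model, geom)
#>   freq mag_freq phase_freq mag_time phase_time       dmag     dphase
#>   1000 0.073391     7.2129 0.073376     7.2139 1.5208e-05 0.00099459
#>  1e+05 0.431257    55.8150 0.431232    55.8193 2.4665e-05 0.00430151
#>  1e+06 1.563482    32.8742 1.563253    32.8780 2.2951e-04 0.00372726
#> max |dI| = 0.0002295 A, max |dphase| = 0.004302 deg
```

The 1 kHz current magnitude (0.0734 A at 7.2°) is the reference value for
this sample geometry; the `dmag`/`dphase` columns show that the
frequency-to-time-domain transformation is faithful to a fraction of a
percent once the sinusoidal steady state is reached.

Fitting a model back from noisy synthetic measurements:

```r
spec <- synth_spectrum(model, geom, noise_cv = 0.02, n_replicates = 10, seed = 42)
fit  <- debye_fit(spec, n_poles = 4, seed = 1,
                  control = ga_config(population_size = 400, max_generations = 800))
fit
#> Genetic-algorithm Debye fit: 4 pole(s), cost 0.00220265 after 800 generations
#> Multipole Debye dispersion model, 4 pole(s)
#>   sigma_s = 0.02157 S/m, eps_inf = 171.1
#>   pole 1: delta_eps = 2.228e+06, tau = 0.003748 s
#>   pole 2: delta_eps = 2.91e+04, tau = 2.262e-05 s
#>   pole 3: delta_eps = 1.867e+04, tau = 9.618e-07 s
#>   pole 4: delta_eps = 1.008e+04, tau = 1.611e-07 s
```

The recovered curves of conductivity and permittivity lie within about 1%
of the truth across the whole band (`predict(fit, type = "properties")`);
individual poles with nearby relaxation times are only weakly identifiable,
which is expected.

Pulse-burst simulation and the static-conductivity comparator (flat-top
response versus the drooping dispersive response):

```r
src <- source_pulse_burst()     # 4 pulses, 100 us, 200 us period, 50 V, 8 us edges
disp <- simulate_lumped(model, geom, src, t_end = 800e-6)
flat <- simulate_static_conductivity(model$sigma_s, geom, src, t_end = 800e-6)
max(flat$I)
#> 0.05803446
```

A finite-element counterpart of every simulation is available through
`build_mesh()`, `solve_frequency()` and `solve_time()`, and a command-line
front end (`inst/cli/debyesim.R`) exposes the pipeline as
`synth | fit | freq | time | fem | compare` subcommands.

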