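# soakfit

Crystal-size-dependent ligand soaking models and electron-counting occupancy
estimation.

## The problem

In crystallographic fragment screening, each fragment must soak into a
protein crystal long enough to reach a crystallographically observable
occupancy — but high-throughput workflows (acoustic droplet ejection onto
micro-meshes, conveyor-belt delivery) limit how long a crystal can soak
before evaporative dehydration destroys it. The practical question is:
**how long must a crystal of a given size soak to reach a target
occupancy?**

`soakfit` implements the empirical answer: the time to half-maximal
occupancy is proportional to crystal length,

```
t_1/2 = L * tau
```

so occupancy follows the hyperbolic saturation curve

```
O(L, t) = O_max * t / (t + L * tau)
```

where `L` is the crystal length (µm), `t` the soak time (s), `O_max` the
limiting occupancy after an infinite soak, and `tau` (s/µm) a
system-specific constant. The limiting occupancy links to an
intra-crystalline dissociation constant through the fraction saturation
equation `O_max = C / (Kd + C)`, i.e. `Kd = C (1 − O_max) / O_max` at
soaking concentration `C`.

The package provides, for workers planning or analysing soak experiments:

* the model, its inversions and the `Kd` link (`occupancy_calc`,
  `half_occupancy_time`, `required_soak_time`, `kd_from_omax`);
* bounded least-squares fitting of `(O_max, tau)` from observation tables,
  with identity-line R², mean absolute residual, size-binned summaries and
  a residual-versus-size polynomial diagnostic (`fit_soak_model`,
  `fit_report`);
* a seeded generator of synthetic soak-experiment tables with the
  statistical structure of the original 457-crystal study
  (`soak_preset`, `generate_observations`);
* a toy crystallography sandbox — Gaussian-atom structures, absolute-scale
  density maps, Fourier structure factors, CCP4/MRC map I/O, simulated
  overload incompleteness and calculated-structure-factor filling
  (`render_map`, `structure_factors`, `write_ccp4_map`);
* an absolute-scale electron-counting occupancy estimator with F000
  leveling, ligand masking, displaced-water correction and three-model
  consensus (`three_model_occupancy`, `recover_toy_occupancy`).

## Worked example

```r
library(soakfit)

lys <- soak_params(o_max = 0.903, tau = 0.794)   # lysozyme + NAG

# occupancy of a 310 µm crystal soaked 750 s
occupancy_calc(crystal_length = 310, soak_time = 750, params = lys)
#> [1] 0.6798743        # i.e. 68%

# half-occupancy time of a 150 µm crystal
half_occupancy_time(150, lys)
#> [1] 119.1            # seconds

# soak time for 80% occupancy in a 100 µm crystal
required_soak_time(0.80, crystal_length = 100, params = lys)
#> [1] 616.699          # seconds

# dissociation constant implied by O_max at 50 mM ligand
kd_from_omax(0.903, ligand_conc = 50)
#> [1] 5.370986         # mM

# fit a synthetic 354-crystal table and report
obs <- generate_observations(soak_preset("lysozyme_nag"), seed = 42)
fit_report(obs, ligand_conc = 50)
#> System: lysozyme+NAG (n = 354)
#>   O_max = 0.900, tau = 0.824 s/um
#>   Kd^cryst = 5.5 mM (at 50 mM ligand)
#>   R^2 (identity line) = 79.3%, mean |residual| = 8.94%
#>   residual-vs-size diagnostic (degree 3): R^2 = 0.6%
#>   bin [0, 60): n = 66, mean size 27.8 um
#>   ...
```

The fitted `O_max = 0.900` and `tau = 0.824` recover the generating truth
(0.903, 0.794) from noisy data; the diagnostic R² near zero says the
residuals carry no unmodelled size trend, as they should for data generated
from the model itself.

The electron-counting path runs end to end on synthetic density maps with
known ground truth:

```r
recover_toy_occupancy(0.5)
#> Occupancy estimate: mean 0.501 (models: 0.500, 0.500, 0.503; sd 0.0014)
```

A thin command-line front end over the same functions is installed at
`inst/scripts/soakfit-cli.R` with `simulate`, `fit` and `plan` subcommands.

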