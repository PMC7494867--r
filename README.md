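# arbriver

Stochastic reactive-transport modelling of a fluoroquinolone antibiotic
and fluoroquinolone-resistant bacteria in a polluted river reach.

Polluted rivers are hotspots for the selection and spread of antibiotic
resistance, but the processes that govern it — transport, sorption,
growth, plasmid exchange — are all noisy. `arbriver` implements a
coupled water-column/sediment 1-D model for nine state variables
(antibiotic `A`, heavy metal `M`, suspended solids `TSS`, particulate
and dissolved organic matter `POM`/`DOM`, and four bacterial phenotypes
`n_f`, `n_p`, `n_c`, `n_cp`) and asks how three sources of
stochasticity — demographic, environmental and anthropogenic — shape the
distribution of plasmid-borne resistant bacteria in the sediment.

The deterministic backbone per water-column variable is

    dc/dt = D d²c/dx² − u dc/dx ± exchange(k_set, k_resus, k_diff) ± reactions

with Monod growth `μ_max·S/(K_s+S)` under antibiotic inhibition
`max(0, 1 − A/MIC)`, metal limitation `min(1, K_im/M)` and resistance
fitness costs; conjugation `β·n_d·n_r/(n_d+n_r)`; segregation `SA·n`;
first-order decay, hydrolysis and death. The stochastic mode integrates
the same balances by Euler–Maruyama with Poisson-diffusion noise: each
active process rate `r` contributes `√r · ξ · Δt` with `ξ = z/√Δt`,
`z ~ N(0,1)`, so its integrated variance equals `r·T`. It is aimed at
environmental modellers and quantitative microbiologists who want a
transparent, fully scriptable testbed for resistance-transport
questions.

## Worked example

```r
library(arbriver)

sc <- musi_scenario()            # polluted 100 km reach, 100 cells, dt = 1 h
run <- run_simulation(sc, stop = "steady")
run$time_h                       # 7900  -- steady state before the 5-y horizon
round(station_final(run, "n_p", "sed"), 5)
#     2km     5km    10km    99km   100km
# 0.22483 0.24548 0.28196 0.29385 0.29385
```

The deterministic plasmid-borne resistant population in the bed settles
near 0.2–0.3 mg/l biomass and grows mildly downstream as populations
mature along the reach. Comparing noise categories (here 30 generations
over a reduced 4000 h horizon):

```r
sc4 <- musi_scenario(t_end = 4000)
demo <- run_ensemble(sc4, "demographic", 30, base_seed = 100)
env  <- run_ensemble(sc4, "environmental", 30, base_seed = 200)
anth <- run_ensemble(sc4, "anthropogenic", 30, base_seed = 300)
print(compare_categories(list(demo, env, anth)), digits = 3)
#         category station_km  mean       sd sd_ratio
# 1    demographic          2 0.210 0.066806  1.00000
# 2    demographic          5 0.239 0.074325  1.00000
# 3    demographic         10 0.284 0.097636  1.00000
# 4    demographic         99 0.274 0.103227  1.00000
# ...
# 7  environmental          5 0.247 0.000442  0.00595
# 9  environmental         99 0.315 0.004007  0.03882
# 12 anthropogenic          5 0.247 0.000911  0.01226
# 14 anthropogenic         99 0.289 0.000543  0.00526
```

Demographic noise spreads the sediment resistant population by roughly
0.07–0.10 mg/l, uniformly along the reach; environmental noise reaches
it only indirectly and is two to three orders of magnitude weaker;
anthropogenic (upstream-boundary) noise is weak everywhere under the
reference loading because the antibiotic arrives far below its MIC. The
one-at-a-time sensitivity screen over the published parameter envelopes:

```r
sens <- classify_sensitive(run_oat_sensitivity(sc))
head(sens, 3)
#          parameter min max diff_mg_l status sensitive
# 1 beta_conjugation   0 1.0     42.7      ok      TRUE
# 2              c_p   0 1.2      3.30     ok      TRUE
# 3           x_cost   0 1.2      3.30     ok      TRUE
```

A command-line wrapper with `make-scenario`, `simulate`, `sensitivity`
and `ensemble` subcommands lives at `inst/cli/arbriver`; every command
writes a manifest JSON from which `rerun_manifest()` regenerates its
outputs byte-identically.

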