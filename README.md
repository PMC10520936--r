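# thzpore

Deterministic whole-cell simulator of what a terahertz unipolar
picosecond pulse train does to a spherical cell: it charges the membrane,
nucleates hydrophilic (conducting) pores by electroporation, drives large
transmembrane ion flows through those pores, and activates the
Na+,K+-ATPase, whose ATP turnover — and hence metabolic power dissipation
— the package accounts for explicitly. It is aimed at computational
membrane biophysicists and bioelectromagnetics researchers who want a
tested, scriptable implementation of this coupled model rather than a
one-off C code.

## The model

Four coupled subsystems are advanced on an axisymmetric spherical cell
(radius 3.3 μm inside a 9.9 μm conducting bath), discretised over the
polar angle θ:

1. **Quasi-static potential.** At THz repetition frequencies the
   wavelength in cytoplasm vastly exceeds the cell, so the potential
   obeys ∇²Φ = 0 in both media at each instant, with the membrane
   potential V\_m(θ) as an interface jump and the applied uniform field as
   the outer boundary condition. The membrane charges by current
   continuity:

   C\_m ∂V\_m/∂t + g₁(V\_m − V\_rest) + I\_p = J\_n.

2. **Electroporation (asymptotic pore model).** Pore density per angle
   obeys dN/dt = α e^{(V_m/V_ep)²}(1 − N/N\_eq), with
   N\_eq = N₀ e^{q_p (V_m/V_ep)²}; individual pore radii follow a
   force-balance ODE (electrical expansion, steric wall repulsion, line
   tension, surface tension), with the surface tension softened by the
   total open pore area of the whole cell:
   σ\_eff = 2σ′ − (2σ′ − σ₀)/(1 − A\_p/A\_cell)².

3. **Pore transport (modified PNP).** Na⁺, K⁺, Ca²⁺ and Cl⁻ fluxes
   through the open pore area follow a drift–diffusion law with a steric
   correction for finite hydrated-ion size:
   J_j = −D_j c_j F z_j/(R_u T)·∇Φ − D_j ∇c_j − D_j c_j (Σ_k N_A a_k³ ∇c_k)/(1 − Σ_k N_A a_k³ c_k).

4. **Na+,K+-ATPase.** A four-state kinetic cycle with voltage-dependent,
   saturating ion binding gives the steady-state cycle rate v\_cyc in
   closed form; pump current is I = F_c·v\_cyc, ion flows follow the
   exact 3 Na⁺ : 2 K⁺ stoichiometry, and power dissipation is the ATP
   consumption rate times the hydrolysis energy per molecule
   (Q\_ATP = 10 k_B T).

The simulator couples these with operator splitting at sub-picosecond
resolution during the stimulation and a geometrically relaxing step
afterwards. Everything is deterministic: identical configurations give
bit-identical trajectories.

## Worked example

```r
library(thzpore)

cfg <- default_config("rat_neostriatal")
train <- pulse_train(E0 = 5e7, f_rep = 0.5e12, duty = 0.5, t_on = 1.2e-9)
plan <- simulation_plan(train, t_end = 12.3e-9, n_frames = 300)
traj <- run_simulation(cfg, plan)

traj
#> <thz_trajectory> 'run': 300 frames to 12.3 ns, 13 theta nodes
#>   peak |Vm| = 1.66 V; final A_p/A_cell = 0.00271; mean pump power = 3.18e-12 W

detect_pore_activation(traj) * 1e9    # ns
#> [1] 0.90505
mean(traj$P_cell[traj$t > 1.2e-9])    # W
#> [1] 2.8778e-12
```

Read: the 0.5 THz, 5×10⁷ V/m train charges the membrane for ~0.9 ns
before the pore density explodes ("activation"); the open pores then
clamp the membrane voltage, large ion flows follow, and the pump
dissipates ~3×10⁻¹² W — the 10⁻¹¹ W scale — while restoring the Na⁺/K⁺
balance. `write_trajectory_csv(traj, "run")` exports the per-angle and
θ-averaged series.

Pump I-V curves and fitting:

```r
iv <- iv_curve(cfg$atpase, initial_concentrations(cfg))
ds <- make_iv_dataset(cfg$atpase, initial_concentrations(cfg),
                      noise_frac = 0.05, seed = 7)
fit <- fit_iv(ds$data, cfg$atpase, initial_concentrations(cfg),
              free = c("F_c", "kd_Nao0"))
```

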