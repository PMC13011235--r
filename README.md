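# poreflow

Pore-scale permeability and structural analysis of cellular solids in R.

Liquid uptake in porous foods — sauces soaking into bread crumb, syrup into
sponge — is controlled by the crumb's microstructure: how porous it is, how
its gas cells connect, how wide the throats between them are, and how
tortuous the flow paths become. `poreflow` is for researchers who have
binary pore-space images (e.g. segmented micro-CT slices or stacks, white =
pore, black = solid) and want to compute the intrinsic Darcy permeability of
that structure directly, together with the structural descriptors that
explain it.

The core is a central-moment lattice Boltzmann solver (D2Q9 in 2D, D3Q27 in
3D, written in C++) for steady creeping flow on the voxel grid. Central
moments k_{x^m y^n z^p} = Σᵢ fᵢ (c_i − u)^{mnp} are relaxed towards their
truncated-Maxwellian equilibria with per-moment frequencies: shear moments
at 1/τ (so ν = cs²(τ − ½)), third-order moments at the "magic" frequency
8(2 − 1/τ)/(8 − 1/τ), which places the half-way bounce-back wall exactly
mid-link and makes permeability independent of τ. Flow is driven by a body
force F (the periodic equivalent of a pressure gradient), iterated until
the per-iteration relative L2 change of the velocity field falls below
10⁻¹⁰, and permeability is extracted from Darcy's law, k = ρ̄ U_d ν / F,
with U_d the superficial velocity. Around the solver: benchmark geometries
with analytic references (plane Poiseuille, Gebart's hexagonal cylinder
array, the close-packed FCC sphere packing), a seeded synthetic bread-crumb
foam generator, image metrics (porosity, effective porosity, face-connected
component labelling, Hildebrand–Rüegsegger local thickness with D10/D50/D90,
topology-preserving skeletonisation with branch tortuosity and junction
counts), voxel coarsening, REV analysis, and Spearman
descriptor–permeability correlation workflows.

## Worked example

Generate a synthetic crumb-like foam, characterise it, and compute its
permeability along x:

```r
library(poreflow)

p <- foam_params(target_porosity = 0.70, bubble_radius_mm = 0.15,
                 perforation_prob = 0.8, shape = c(128, 128), seed = 42)
foam <- generate_foam(p)
foam
#> pore geometry: 128 x 128 voxels at 18.7 um, porosity 0.6985

pore_network_report(foam, flow_axis = 1)
#>   porosity effective_porosity n_components main_connectivity
#> 1    0.698              0.683            3                 1
#>   secondary_connectivity  D10   D50   D90 mean_tortuosity n_branches
#> 1                      1 0.28 0.542 0.744           1.131         52
#>   triple_points quadruple_points
#> 1            28                2

cfg <- simulation_config(tau = 1, force = 1e-6, flow_axis = 1)
sol <- run_to_steady_state(foam, cfg)
sol
#> flow solution: 128 x 128 grid, 11444 fluid nodes, 11700 iterations (converged)

darcy_permeability(sol, foam, cfg)
#>   direction           Ud k_lattice         k_SI  k_darcy         Re
#> 1        x+ 5.261149e-05  8.768581 3.066285e-09 3106.913 0.06772956
```

Reading the output: the foam reached the requested 70% porosity, of which
68.3% sits in spanning (flow-relevant) clusters; a percolating path exists
both along (main) and across (secondary) the flow axis; the median pore
diameter D50 is 0.54 mm; skeleton branches are on average 13% longer than
their straight-line chords. The converged flow gives a superficial velocity
of 5.3 × 10⁻⁵ lattice units under F = 10⁻⁶, i.e. a permeability of
8.77 lu² = 3.07 × 10⁻⁹ m² = 3107 Darcy at the 18.7 µm voxel size, with
Re ≈ 0.07 — safely inside the Darcy regime.

`autoplot(sol)` shows the velocity-magnitude field,
`plot_psd(local_thickness(foam))` the pore-size distribution, and
`directional_permeability(foam, cfg)` the anisotropy between axes.
`ensemble_study()` runs the whole pipeline over a seeded ensemble of foams
and correlates every descriptor with permeability (Spearman, with exact
small-sample p-values).

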