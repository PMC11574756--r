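# glycofel

Conformational and free-energy analysis for glycosidase mechanism studies:
Cremer–Pople ring-puckering coordinates and collective variables (CVs), a
standard metadynamics engine with free-energy-landscape reconstruction, a
multi-distance reaction coordinate, recrossing-cycle profile averaging with
uncertainty bands, and per-frame catalytic-geometry analysis. Everything runs
at desk scale on synthetic ring geometries and analytic toy potentials, so the
full analysis chain — the part that turns enhanced-sampling output into
conformational itineraries, free-energy profiles and barrier reports — can be
developed, validated and taught without QM/MM trajectories.

## Who this is for

Computational glycoscientists and enzymologists analysing (or emulating)
enhanced-sampling simulations of pyranose rings and glycoside hydrolysis:
puckering landscapes of the −1 sugar, catalytic itineraries such as
**¹,⁴B → [⁴E]‡ → ¹,⁴B**, His/Asp general-acid dyads with a shared proton, and
oxocarbenium-like transition states.

## The core machinery

**Cremer–Pople puckering.** For a six-membered ring with atoms ordered
O5, C1, …, C5, out-of-plane displacements `z_j` relative to the mean plane
give the puckering coordinates

    q2 cos φ2 = sqrt(1/3) Σ z_j cos(4π(j−1)/6)
    q2 sin φ2 = −sqrt(1/3) Σ z_j sin(4π(j−1)/6)
    q3        = sqrt(1/6) Σ (−1)^(j−1) z_j

with total amplitude `Q = sqrt(q2² + q3²)`, polar angle `θ = atan2(q2, q3)`
and azimuth `φ = φ2`. Chairs sit at the poles (⁴C₁ at θ = 0 with this atom
ordering), boats/twist-boats on the equator, envelopes/half-chairs on the
θ ≈ 54.7°/125.3° bands — 38 canonical conformers in total. The normalized
CVs used for conformational landscapes are `cv1 = qx/Q, cv2 = qy/Q,
cv3 = qz/Q`.

**Metadynamics.** Gaussian bias hills `h·exp(−Σ (x−c)²/2σ²)` deposited every
`stride` MD steps, with a two-level height schedule (an initial height
reduced once after a set hill count). The free-energy landscape estimate is
the negated accumulated bias, `F(x) = −V_bias(x)`, shifted to min 0; a basin
free-energy-difference trace against hill count serves as the convergence
diagnostic. An overdamped-Langevin integrator (Euler–Maruyama, compiled)
validates the whole loop on analytic potentials.

**Reaction coordinate and profiles.** The reaction CV is a signed sum of the
six bond distances that break (+) or form (−) during inverting glycosylation:
`d(Nδ–H) − d(H–O′) + d(C1–O′) − d(Ow–C1) + d(Ow–Hw) − d(Hw–OAsp90)`.
Biased trajectories are segmented into R → P → R recrossing cycles
(dwell-filtered basin visits), each cycle yields a free-energy profile from
the cumulative bias, and cycles are combined by the exponential average
`f_avg(s) = −kBT ln[(1/n) Σ exp(−F_i(s)/kBT)]` with pointwise SD and
SE = SD/√n bands. Barrier reports extract ΔG‡, ΔG_rxn and the TS position.

**Catalytic geometry.** Per-frame distances and signed torsions, shared-proton
(low-barrier hydrogen bond) statistics for an acid dyad, run-length-compressed
conformer itineraries, and the oxocarbenium descriptors (C1–O5 shortening,
C5–O5–C1–C2 flattening).

## Worked example

```r
library(glycofel)

# a boat-puckered ring and its classification
cremer_pople(ideal_ring(0.57, 90, 240))[, c("Q", "theta", "phi")]
#>       Q theta   phi
#> 1  0.57    90   240
classify_conformer(cremer_pople(ideal_ring(0.57, 90, 240)))$conformer
#> [1] "1,4B"

# deposit-time bookkeeping: 909 hills, one per 250 steps of 0.5 fs
hill_count_to_time(909, stride = 250, timestep = 0.5)$time_ps_rounded
#> [1] 113.63

# metadynamics on a 5 kcal/mol double well, stopped after two recrossings
run <- run_toy_metadynamics(toy_potential("double_well", barrier = 5),
                            x0 = -1, n_hills = 3000, width = 0.06,
                            seed = 7, stop_recross = 2)
cyc <- detect_recrossings(run$colvar, c(-1.3, -0.7), c(0.7, 1.3),
                          min_dwell = 0.05, hills = run$hills)
cyc
#>   cycle start_time end_time recross_hill_index
#> 1     1       0.04     13.6                108
#> 2     2      13.6     24.8                 198

grid  <- seq(-1.45, 1.45, length.out = 291)
profs <- lapply(seq_len(nrow(cyc)), function(i)
  profile_per_cycle(run$hills, cyc[i, ], grid, reactant_range = c(-1.3, -0.7)))
extract_barrier(exponential_average(profs), c(-1.3, -0.7), c(0.7, 1.3))
#> Free-energy barrier: 4.71 +/- 0.52 kcal/mol (SE at TS) at s = -0.160
#> Reaction free energy: -1.40 kcal/mol (exergonic)
```

The recovered barrier (4.71 kcal/mol) sits within the single-recrossing
uncertainty of the analytic 5 kcal/mol; `autoplot()` on the averaged profile
draws the red exponential average with green SD and blue SE ribbons.

Catalytic-geometry analysis on synthetic inputs:

```r
dyad <- measure_dyad(gen_dyad_ensemble(1.32, 0.21, 2.54, 0.09,
                                       n = 2000, seed = 11))
dyad_analysis(dyad)
#> Dyad geometry over 2000 frames:
#>   donor-H        1.32 +/- 0.21 A
#>   donor-acceptor 2.54 +/- 0.09 A
#>   proton shared in 53% of frames; low-barrier H-bond: yes

traj  <- gen_reaction_trajectory(n_recrossings = 1, frames_per_leg = 60,
                                 noise_sd = 0, seed = 11)
presc <- attr(traj, "prescribed")
fwd   <- presc$frame[seq_len(which.max(presc$xi >= 1) + 20)]
pk    <- pucker_trajectory(traj[traj$residue == "RNG1" & traj$frame %in% fwd, ])
itinerary(pk)$string
#> [1] "1,4B -> 4E -> 1,4B"
```

PDB/XYZ trajectories and PLUMED-style HILLS/COLVAR files are read and written
with `read_pdb_frames()`, `read_xyz_frames()`, `read_hills()`,
`read_colvar()` and their `write_*` counterparts.

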