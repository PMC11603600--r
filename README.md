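# vtst

Thermal gas-phase rate constants from electronic-structure data, for
chemical kineticists who have a transition state, an intrinsic reaction
coordinate (IRC) profile and frequency analyses, and want rate constants
that go beyond conventional transition state theory: canonical variational
TST (CVT) to handle recrossing, one-dimensional hindered-rotor models for
torsional modes, and Eckart tunneling for light-particle transfer.

## What it computes

The generalized rate constant at dividing-surface position *s* along the
minimum-energy path uses the thermodynamic formulation

    k_GT(s, T) = sigma_Rx * (k_B T / h) * (c0)^dn * exp(-dG_GT(s)^{1M} / RT)

where `dG_GT^{1M}` is the generalized Gibbs activation energy at the 1 M
standard state (obtained from `G_GTS - sum_i G_Ri` at 1 atm and shifted by
`dn RT ln(V_m c0)`, `dn = 0` unimolecular, `-1` bimolecular), and
`sigma_Rx = prod(sigma_i^R) / sigma_TS` carries all rotational symmetry.
The CVT rate constant is the minimum of `k_GT` over computed path points
(equivalently, the maximum of `dG_GT`):

    k_CVT(T) = min_s k_GT(s, T),      recrossing factor = k_TST / k_CVT >= 1

The path points that matter are found by reaction force analysis: the
force `F(s) = -dV/ds` has a minimum (alpha) and a maximum (gamma) at the
inflection points of `V(s)`, and only the IRC points with
`alpha <= s <= gamma` (the transition-state zone, typically 6-12% of the
path) need frequency analyses.

Torsional modes replace their harmonic-oscillator factors with
one-dimensional hindered-rotor partition functions for the periodic
potential `V0/2 (1 - cos M phi)`: Pitzer-Gwinn
(`q_PG = q_FR e^{-y/2} I0(y/2) * q_HO/q_CHO`, `y = V0/RT`) or a
rational-polynomial corrected variant in the style of Ayala and Schlegel,
calibrated in this package against an exact torsional eigensolver that
also ships as a validation oracle.  Tunneling multiplies the rate by the
Boltzmann-averaged transmission through an asymmetric Eckart barrier
fitted to the ZPE-corrected forward/reverse barriers and the imaginary
frequency.

## Worked example

```r
library(vtst)
spec <- synthetic_reaction_spec(barrier = 8, entropy_shift = 800, seed = 1)
dir  <- tempfile()
eif  <- write_fixture_tree(dir, spec, temperatures = c(298.15, 400, 600))
cmd_rate(eif, file.path(dir, "rates.tsv"))
#> <rate_result> CVT/HO, 3 temperature(s), k in cm^3 molecule^-1 s^-1
#>        T dG_TST_1M      k_TST s_star dG_CVT_1M      k_CVT recrossing
#> 1 298.15    20.968 4.4030e-24  -0.05    21.024 4.0049e-24     1.0994
#> 2 400.00    23.261 2.7040e-21  -0.05    23.331 2.4772e-21     1.0915
#> 3 600.00    27.822 1.5253e-18  -0.05    27.929 1.3936e-18     1.0945
```

This bimolecular toy reaction has an 8 kcal/mol barrier whose
transitional modes stiffen on the reactant side, so the Gibbs maximum
sits at `s* = -0.05` amu^1/2 bohr rather than at the saddle point: CVT is
about 9-10% slower than TST at every temperature (the recrossing factor),
and `dG_CVT > dG_TST` by the corresponding 0.06-0.11 kcal/mol.  Rate
constants are in cm^3 molecule^-1 s^-1 because the reaction is
bimolecular.

Selecting the path points worth a frequency job:

```r
cmd_select_points(eif, dry_run = TRUE)
#> TS zone: alpha = -0.25, gamma = 0.25 amu^1/2 bohr
#> selected 10 of 200 nonstationary IRC points (P_CVT = 5.0%)
```

Only 5% of this IRC needs further electronic-structure work.  A
hindered-rotor table for a methyl-like torsion (54 cm^-1, reduced moment
1.85 amu A^2, threefold):

```r
cmd_hr_thermo(nu_tau = 54, I_r = 1.85, M = 3, temperatures = c(298.15, 650))
#>       T     V0  q_FR  q_PG   U_PG  S_PG    G_PG  q_AS   U_AS  S_AS    G_AS
#> 1 298.1 0.1017 2.817 2.583 0.3482 3.054 -0.5623 2.590 0.3451 3.049 -0.5639
#> 2 650.0 0.1017 4.160 3.999 0.6972 3.827 -1.7902 4.001 0.6957 3.826 -1.7910
```

The barrier `V0` was derived from the torsional frequency through the
harmonic relation of the cosine well and echoed in the table; `U`/`G` in
kcal/mol, `S` in cal/mol/K.

A thin command-line wrapper is installed as `exec/vtst`
(`vtst rate --eif run.eif`, `vtst select-points`, `vtst hr-thermo`,
`vtst fixtures`).

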