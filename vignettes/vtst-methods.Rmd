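---
title: "Models and numerical choices in vtst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in vtst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtst)
```

`vtst` computes gas-phase thermal rate constants from electronic-structure
data.  This vignette records the models it implements, the conventions and
tunable parameters, what the synthetic fixtures do and do not emulate, and
the design choices made where several defensible options existed.

## The rate model

Conventional transition state theory places the dividing surface at the
saddle point; canonical variational TST (CVT) instead minimizes the
generalized rate constant over dividing surfaces that intersect the
minimum-energy path (MEP) at coordinate $s$ (in amu$^{1/2}$ bohr,
reactants at $s<0$):

$$k_\mathrm{GT}(s,T) = \sigma_\mathrm{Rx}\,\frac{k_BT}{h}\,
 (c^\circ)^{\Delta n^\ddagger}
 \exp\!\left(-\frac{\Delta G^{\ddagger,\mathrm{1M}}_\mathrm{GT}(s)}{RT}\right),
 \qquad k_\mathrm{CVT}(T)=\min_s k_\mathrm{GT}(s,T).$$

The thermodynamic formulation builds
$\Delta G^{\ddagger}_\mathrm{GT} = G_\mathrm{GTS}-\sum_i G_{R_i}$ from
canonical partition functions with the electronic energies included in
$G$, at 1 atm, and converts to the 1 M standard state through the
relation between pressure- and concentration-based equilibrium
constants, $\Delta G^{\ddagger,\mathrm{1M}} =
\Delta G^{\ddagger,\mathrm{1atm}} + \Delta n^\ddagger RT\ln(V_m c^\circ)$
with $\Delta n^\ddagger = 0$ (unimolecular) or $-1$ (bimolecular) and
$V_m = RT/P$.  At 298.15 K and 1 atm the bimolecular shift is
$-RT\ln 24.465 = -1.894$ kcal mol$^{-1}$; the 1 M activation energy (and
hence every rate constant) is invariant to the pressure used for the
intermediate 1 atm bookkeeping, which the test suite asserts.

Three conventions matter and are applied consistently:

* **Symmetry.** Partition functions are computed $\sigma$-free; all
  rotational symmetry enters once through
  $\sigma_\mathrm{Rx}=\prod_i\sigma_i^R/\sigma_\mathrm{TS}$, with the
  generalized TS inheriting the saddle-point symmetry number (constant in
  $s$).  An explicit override is honored when the reaction demands a
  hand-set factor (chirality, symmetric reactions).
* **Vibrational reference.** All mode partition functions are
  bottom-of-well referenced, so the zero-point energy emerges from $q$
  rather than being added separately.  This makes the hindered-rotor
  substitution a clean per-mode drop-in.
* **Dividing surfaces are computed points.** CVT minimizes discretely
  over the saddle point plus the supplied generalized-TS records; the
  reported $s^*_\mathrm{CVT}$ is always an actual computed geometry.  Ties
  break toward $s=0$, then toward the reactant side.  Because minimizing
  $k_\mathrm{GT}$ is the same as maximizing
  $\Delta G^{\ddagger}_\mathrm{GT}$, the test suite checks the two routes
  against each other.

Multi-pathway reactions are handled by summing pathway rate constants and
reporting branching ratios $\Gamma_i = 100\,k_i/\sum_j k_j$; the
recrossing factor $k_\mathrm{TST}/k_\mathrm{CVT}\ge 1$ quantifies the
variational effect.  For two-step mechanisms with reactant complexes,
rates are computed reactants $\to$ TS directly and the complexes are
carried for reporting only; no steady-state treatment is attempted.

## Statistical thermodynamics

Ideal-gas rigid-rotor/harmonic-oscillator partition functions with the
standard closed forms: translation with the per-molecule volume
$k_BT/P$ (which makes $G = E_\mathrm{elec} - RT\ln Q$ the standard-state
chemical potential and reproduces Sackur–Tetrode entropies), classical
rotation from the principal moments of inertia (linear or nonlinear),
bottom-referenced harmonic vibrations over the real frequencies, and a
Boltzmann sum over electronic levels (a single spin-multiplicity level by
default; excited levels are supported when supplied).  Temperature
derivatives of $\ln Q$ are analytic; the suite cross-checks them against
central finite differences at fixed volume to $10^{-6}$ relative.
Constants are pinned to CODATA 2018 in one table
(`vtst_constants()`); no other file contains physical constants.

## Hindered rotors

A torsion is the periodic problem
$V(\varphi)=\tfrac{V_0}{2}(1-\cos M\varphi)$ with reduced moment of
inertia $I_r$ (amu Å$^2$), $M$ minima and torsional symmetry number
$\sigma_\tau$ (defaulting to $M$: symmetric-top torsions such as –CH$_3$
dominate practice).  When no scanned barrier is supplied, $V_0$ follows
from the harmonic relation of the cosine well,
$V_0 = 8\pi^2c^2\nu_\tau^2 I_r/M^2$ per molecule; a supplied scan barrier
takes precedence, with a warning when the two disagree by more than a
factor of two.  Torsion-to-mode assignment is explicit (a `mode_index`,
or a frequency match within 1 cm$^{-1}$) — never a low-frequency
heuristic.  Independent rotors multiply.

Two models are implemented:

* **Pitzer–Gwinn:** $q_\mathrm{PG} = q_\mathrm{FR}\,e^{-y/2}I_0(y/2)
  \cdot q_\mathrm{HO}/q_\mathrm{CHO}$ with $y=V_0/RT$,
  $q_\mathrm{FR}=\sqrt{8\pi^3I_rk_BT}/(\sigma_\tau h)$.  The classical
  hindered factor and the $I_1/I_0$ Bessel ratio in its internal-energy
  row are evaluated with exponentially scaled Bessel functions, so deep
  wells ($y>700$) cannot overflow.
* **Polynomial-corrected (Ayala–Schlegel style):**
  $q_\mathrm{AS} = q_\mathrm{PG}\,
  \frac{1+P_2(x,y)e^{-y/2}}{1+P_1(x,y)e^{-y/2}}$ with fifth-order
  polynomials in $x=1/q_\mathrm{FR}$ and $y$, no constant terms (the
  correction tends to 1 in the free-rotor limit).  The published
  coefficient tables for this family of corrections were not available to
  this package, so $P_1,P_2$ were calibrated once against the package's
  own exact torsional eigensolver over $x\in[0.04,0.6]$, $y\in[0,12]$,
  $M=\sigma_\tau\in\{2,3\}$ (`tools/fit-as-coefficients.R`; maximum
  residual 0.16% on the fitted domain).  Outside the fitted box the
  correction is clamped with a warning.  With $M=\sigma_\tau$ the
  dimensionless problem depends only on $(x,y)$ — the torsional quantum
  $u = h c\nu_\tau/k_BT$ equals $x\sqrt{\pi y}$ — which is what makes a
  two-variable correction exact in principle.

Thermodynamic properties ($U$, $S$, $H$, $G$ per mode) come from analytic
temperature derivatives of $\ln q$, using $dx/dT=-x/2T$ and $dy/dT=-y/T$
for the correction polynomials; the suite requires agreement with
numerical differentiation to $10^{-5}$ relative over 200–1000 K, and the
per-row identity $G=H-TS$ to $10^{-9}$.

The **validation oracle** diagonalizes
$H=-\frac{\hbar^2}{2I_r}\frac{d^2}{d\varphi^2}+\frac{V_0}{2}(1-\cos M\varphi)$
in a truncated plane-wave basis of `n_grid` states (for a pure cosine
potential this is exactly the periodic Fourier-grid Hamiltonian), sums
Boltzmann factors referenced to the potential minimum and divides by
$\sigma_\tau$.  It converges spectrally — doubling `n_grid` moves the
result by less than $10^{-8}$ at the defaults — and reproduces the free
rotor at $V_0=0$ and the bottom-referenced harmonic oscillator in deep
wells, up to the anharmonic zero-point shift
$M^2\hbar^2/32I_r$, which is independent of $V_0$.  The oracle is a
validation tool, not a production method.  On the grid
$q_\mathrm{FR}\in[2,20]$, $y\in[0.5,10]$, Pitzer–Gwinn stays within ~4%
of the oracle and the corrected model within ~0.1%.

## Reaction force analysis

The MEP is assembled from IRC branch files (two-column $s$, $V$ text),
merged with the TS at $s=0$ and energies re-zeroed to the reactant
asymptote.  When branch files carry unsigned $|s|$, the branch whose far
endpoint is lower after re-zeroing is taken as the reactant side — a
documented heuristic, overridable by an argument.  The reaction force
$F=-dV/ds$ is obtained by analytic differentiation of an interpolating
cubic spline with Forsythe–Malcolm–Moler end conditions; this reproduces
cubic polynomials exactly and is empirically fourth-order on analytic
profiles (a natural spline's zero-curvature end condition would not be
exact even for $V=s^2$).  A central finite-difference mode is kept as a
cross-check.  IRC points are smooth and noise-free, so no smoothing is
applied.

$\alpha$ (force minimum, $s<0$) and $\gamma$ (force maximum, $s>0$) are
reported at grid points, not interpolated, because the selected points
must be geometries a frequency job can run on; ties break toward $s=0$.
Zones partition the path exhaustively: reactant ($s<\alpha$), TS
($\alpha\le s\le\gamma$), product ($s>\gamma$).  The TS-zone selection
excludes $s=0$ (the optimized saddle point is already in hand), and the
economy statistic $P_\mathrm{CVT} = 100\,n_\mathrm{zone}/n_\mathrm{IRC}$
is reported to one decimal.  A path truncated before the force returns
toward zero on one side is accepted with a warning, using the available
extremum.

## Eckart tunneling

The transmission coefficient is the Boltzmann average of the transmission
probability through the asymmetric Eckart function fitted to the
ZPE-corrected forward and reverse barriers $\Delta V_1,\Delta V_2$ and
the saddle-point imaginary frequency $\nu^\ddagger$.  With
$\alpha_i = 2\pi\Delta V_i/h\nu^\ddagger$ and $\xi=E/\Delta V_1$:

$$p(E)=\frac{\cosh(a{+}b)-\cosh(a{-}b)}{\cosh(a{+}b)+\cosh d},\quad
a=\frac{2\sqrt{\alpha_1\xi}}{\alpha_1^{-1/2}+\alpha_2^{-1/2}},\;
b=\frac{2\sqrt{(\xi-1)\alpha_1+\alpha_2}}{\alpha_1^{-1/2}+\alpha_2^{-1/2}},\;
d=2\sqrt{\alpha_1\alpha_2-\pi^2/4},$$

($\cosh d \to \cos|d|$ for thin barriers with $\alpha_1\alpha_2<\pi^2/4$)
and $\kappa(T)=e^{\Delta V_1/k_BT}\int p(E)\,e^{-E/k_BT}\,dE/k_BT$ from
the higher asymptote to $\Delta V_1+40k_BT$, by adaptive quadrature at
relative tolerance $10^{-8}$.  The hyperbolic ratios are computed in
max-normalized exponential form, so large $\alpha$ cannot overflow.  The
implementation is validated against the classical limit
($\kappa\to1$ as $\nu^\ddagger\to0$), Wigner's
$1+(h c\nu^\ddagger/k_BT)^2/24$ for small reduced frequency (within 1%
for $u\le0.3$), and monotone decrease with temperature.  Barrier heights
are taken at the saddle point by default, not at the variational TS; a
`barrier` argument isolates that choice.

## Synthetic fixtures: what they do and do not show

The fixture generator plants known answers: an analytic path potential
(symmetric $\Delta E^\ddagger\,\mathrm{sech}^2(s/L)$ or an asymmetric
Eckart function), smooth analytic transitional-mode frequency
trajectories $\nu_i(s)$ (optionally stiffening sigmoidally on the
reactant side across the five transitional modes, which moves the Gibbs
maximum to $s<0$ increasingly with temperature), and toy water/hydroxyl
reactant geometries for the rotational factors.  Ground truths are
computed by brute force — dense grid searches for the force inflections,
and an independent inline reimplementation of the ideal-gas $\ln Q$
algebra for the $\Delta G_\mathrm{GT}(s,T)$ maximizer — never by the code
under test.  Defaults: 100 IRC points per side at step 0.05
amu$^{1/2}$ bohr, barrier 8 kcal mol$^{-1}$, width 0.4 amu$^{1/2}$ bohr,
imaginary frequency 1500 cm$^{-1}$; the test suite scales `n_side` down
to 20–30 points where the full path adds nothing.  The degenerate
zero-barrier unimolecular fixture (TS $\equiv$ reactant plus the reaction
coordinate) makes $\Delta G^\ddagger=0$ exactly, so an end-to-end run
must return $k = k_BT/h = 6.2124\times10^{12}$ s$^{-1}$ at 298.15 K.

Passing these tests shows the machinery is self-consistent and recovers
planted variational structure; it does not show that any real reaction's
potential surface, mode couplings, torsional scans or vibrational
anharmonicity are well described — those enter through the user's
electronic-structure data, not through this package.  Fixtures make no
attempt at realistic PESs.

## Degenerate and edge inputs

Single atoms get $q_\mathrm{rot}=1$ with a warning; a claimed-nonlinear
species with a zero principal moment is a geometry error.  A TS record
must carry exactly one imaginary frequency; generalized-TS records must
carry none (a projected frequency analysis is the expected provenance)
and must carry their $s$ value.  Unknown run-control keywords warn and
are collected, never silently dropped.  Empty TS-zone selections advise a
smaller IRC step.  Rate tables are written at full precision alongside
two-significant-figure display columns, and round-trip to at least 12
significant digits.

## Known limitations

One-dimensional, uncoupled torsions only; no multistructural or
multidimensional torsion treatment.  No microcanonical or improved CVT,
no small-curvature tunneling, no pressure-dependent (master-equation)
kinetics, no condensed-phase standard states beyond 1 M.  CVT is a
discrete minimization over supplied points; an interpolated refinement is
deliberately not the default, so the answer can only be as fine as the
IRC step.
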