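---
title: "Methods: interaction-network microstructure of sticker-spacer condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction-network microstructure of sticker-spacer condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condnet)
```

# Scope and model

`condnet` analyzes the internal microstructure of single-component
biomolecular condensates formed by sticker-spacer polymers — prion-like
low-complexity domains (LCDs) and binary tyrosine/serine (YS) model
sequences. The pipeline goes from residue sequences and bead-resolution
configurations to:

1. chain-chain interaction energies under a residue-level coarse-grained
   (Mpipi-style) potential;
2. energy-thresholded, unweighted, undirected interaction graphs (one node
   per chain);
3. graph statistics: normalized betweenness centrality, small-world
   estimators $\sigma_{sw}$ and $\omega_{sw}$, hubs and maximal cliques;
4. spatial organization (radial density profiles, sigmoid interface fits,
   hub/clique radial distributions) and temporal organization (role
   lifetimes, center-of-mass displacements);
5. single-chain conformation (gyration tensor, $R_g$, shape anisotropy
   $\kappa^2$) and power-law fits of chain metrics against centrality;
6. material and packing properties (surface tension by two routes,
   coexistence-density critical fits, excluded volume, overlap
   concentration, $\phi_{rel}$).

Production-scale molecular dynamics (hundreds of chains, microseconds) is
out of scope. A synthetic-data module generates droplet and slab
configurations, short Langevin trajectories and reference graph families so
that every analysis stage can be exercised and validated at desk scale.

# Sequences and composition metrics

The four LCDs (A1-LCD, FUS-LCD, EWSR1-LCD, TIA1-LCD; n = 137, 163, 280, 97)
and the eleven YS variants (all n = 150, spanning sticker fractions 0.10 to
1.00 and a range of blockiness, plus a fixed scrambled diblock counterpart)
ship both as code constants and as a FASTA fixture.

The sticker (hydrophobic) fraction $f_h$ counts residues in a configurable
sticker set — $\{F, W, Y\}$ for LCDs (giving $f_h \approx 0.14$ for all
four), $\{Y\}$ for YS chains. Blockiness is
$f_B = 1 - B_{act}/B_{max}$ with $B_{act}$ the number of adjacent unlike
pairs. The maximum junction count is not uniquely pinned down by the
defining limits alone; we adopt

$$B_{max} = \min(2\,\min(n_Y, n_S),\; n - 1),$$

which is attained by maximally dispersed arrangements and reproduces both
stated limits: a strictly alternating sequence gives $f_B = 0$ and a diblock
gives $f_B \to 1$ ($1 - 1/60 \approx 0.983$ for S$_{120}$Y$_{30}$).
Homopolymers have $B_{max} = 0$; $f_B$ is then defined as 1 and flagged
degenerate.

# The energy model

The potential is $E = E_{bond} + E_{elec} + E_{pair}$:

* **Bonds**: harmonic, $E = k (r - r_0)^2$ with
  $k = 19.2$ kcal mol$^{-1}$ Å$^{-2}$ and $r_0 = 3.81$ Å. We follow the MD
  engine convention without the 1/2 factor, consistent with the unit the
  constant is quoted in; a 1/2-factor reading would halve bond energies.
* **Electrostatics**: Debye–Hückel screened Coulomb with
  $\varepsilon_r = 80$, screening length $7.95$ Å, hard cutoff 35 Å. Only
  D, E, K, R carry charges; LCDs have under ~5% charged residues and YS
  chains none, so this term is small by construction.
* **Short-range pairs**: the generalized Wang–Frenkel potential with
  per-pair $(\varepsilon, \sigma, \mu, \nu)$ and $R_c = 3\sigma$, normalized
  so the well depth is exactly $-\varepsilon$. With $\mu = \nu = 1$ the well
  minimum sits at $r_{min} = 3\sigma\sqrt{3/19} \approx 1.19\sigma$. The
  potential is zero at and beyond $R_c$ by construction.

**Parameter table.** The exact published per-pair Mpipi parameters live in
an external repository and are not redistributed here. The packaged table
(`mpipi_like_params_synthetic.tsv`, marked synthetic in its name) combines
standard residue masses and charges, the common residue-level
coarse-grained bead diameters, and per-residue interaction strengths chosen
to reflect the sticker hierarchy (aromatics strongest) and anchored so that
$\varepsilon_{YY} = 0.42$ kcal/mol exactly — the one strength quoted for the
model, slightly below the thermal energy $k_BT = 0.596$ kcal/mol at 300 K.
Pair values use Lorentz ($\sigma$, arithmetic) and Berthelot
($\varepsilon$, geometric) combining rules. Any user table with the same
columns can be passed to `mpipi_model()`, so the packaged values can be
swapped for the published ones without code changes.

# Interaction graphs and small-world statistics

An edge is drawn between chains $a$ and $b$ when their summed inter-chain
bead-pair energy satisfies $E_{ab} < -m\,k_BT$, with $m = 5$ by default: a
five-fold multiple of the strongest single sticker contact, selecting
long-lived associations. The threshold multiple is recorded on the graph
object and edge counts are monotonically non-increasing in $m$ (a tested
invariant).

Betweenness centrality is normalized by $\binom{N-1}{2}$ so values lie in
$[0, 1]$ and are comparable across system sizes. Hubs are the $n_h = 10$
highest-centrality chains (ties broken by ascending chain id). Maximal
cliques are enumerated, scanned in decreasing size (ties lexicographic), and
reported greedily while sharing at most 2 members with every previously
reported clique, up to $n_c = 10$.

Small-worldness is estimated as

$$\sigma_{sw} = \frac{C/C_{rand}}{L/L_{rand}}, \qquad
  \omega_{sw} = \frac{L_{rand}}{L} - \frac{C}{C_{latt}},$$

where $C$ is the mean local clustering coefficient (nodes of degree < 2
counted as zero) and $L$ the mean shortest pathlength. Because $L$ is
undefined across components, it is computed on the largest connected
component, with the component fraction reported; $C$ uses the same
component. Reference quantities are ensemble means (default 10 graphs,
seeded): Erdős–Rényi references match node and edge counts.

**Lattice reference.** Rewiring-based latticization (accepting double-edge
swaps that shorten total ring distance) is the historical construction, but
it converges extremely slowly on sparse graphs of a few thousand nodes and
transiently degrades near-lattice inputs. We instead build the lattice
reference constructively: nodes are placed on a ring in random order and
stubs are matched to nearest ring neighbors in increasing distance. This
preserves the degree sequence exactly, reproduces the exact
$k$-nearest-neighbor ring lattice for regular inputs (so a ring lattice is
its own reference, giving $\omega_{sw} \approx -1$), and for irregular
degree sequences yields the most local arrangement the degrees admit. On
sparse ER benchmarks this gives $\omega_{sw} \approx 1$ and
$\sigma_{sw} \approx 1$, and Watts–Strogatz graphs (n = 1000, k = 10,
p = 0.1) land inside the small-world band $-0.3 \le \omega_{sw} \le 0.3$.
The Watts–Strogatz generator rewires one endpoint per edge with probability
$p$ (the classic construction), keeping the edge count fixed.

# Spatial and temporal organization

Radial mass density profiles bin bead masses by distance from the
dense-phase center of mass (5 Å bins by default, densities in g/cm³ using
residue masses). The droplet is assumed not to straddle the periodic
boundary, which the synthetic generators guarantee by centering it. The
interface is fit with a logistic sigmoid
$\rho(r) = \rho_{dil} + (\rho_{dense} - \rho_{dil})/(1 + e^{(r - r_0)/w})$
(a tanh variant is selectable); bins are weighted by the square root of
their shell volume because shell densities are count-noise limited — the
thin central shells would otherwise dominate the fit. Interface bounds
$r_{95} < r_{05}$ are where the fitted curve crosses 95% and 5% of the
dense-phase plateau. Fits fail loudly (no silent defaults) when the profile
lacks a plateau at least twice the dilute level.

Hub and clique chain center-of-mass distances are normalized by the
dilute-side bound $r_{05}$ and histogrammed to unit area. Role lifetimes are
flagged-frame fractions over a continuous window (the convention is 20% of
a production trajectory). Instantaneous displacement at frame $t$ averages
the two center-of-mass leg lengths to the neighboring frames — the
alternative reading (half the end-to-end displacement over the two-frame
span) differs only for curved paths and is not used — and is normalized by
the contour length $(n-1) \times 3.81$ Å, our reading of the "linear chain
conformation" length.

# Conformation

The gyration tensor is mass-weighted by default (residue masses differ); an
equal-weight mode matches polymer-theory closed forms such as
$R_g^2 = b^2(N^2 - 1)/12$ for an $N$-bead rod. Shape anisotropy
$\kappa^2 = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
\lambda_3\lambda_1)/(\sum_i \lambda_i)^2$ is scale invariant, 0 for
isotropic and 1 for collinear mass distributions; freely jointed chains of
150 bonds average $\kappa^2 \approx 0.39$ (Monte-Carlo, $10^4$ chains).
Power-law relations between chain metrics and centrality are fit as least
squares in $\log_{10}$–$\log_{10}$ space on per-chain points pooled over
sampled frames; zero-centrality chains are excluded before the log
transform.

# Thermodynamics and packing

Surface tension comes from two routes that are cross-validated against each
other on synthetic slabs (within 2%):

* Kirkwood–Buff: $\gamma = (L_z/2)\,(\langle P_{zz}\rangle - \tfrac12
  (\langle P_{xx}\rangle + \langle P_{yy}\rangle))$;
* stress profile: the integral of $\sigma_N(z) - \sigma_T(z)$ over two
  equal-thickness interface windows, averaged over the two interfaces. The
  window thickness defaults to the fitted 95–5% span.

Per-bead virial stresses split each pairwise and bonded force contribution
symmetrically between partners; summed over beads and divided by the box
volume they reproduce the global virial pressure tensor (a tested
invariant). The single audited unit conversion is
1 kcal mol$^{-1}$ Å$^{-2}$ = 694.77 mN/m.

Coexistence densities are fit jointly to the law of coexisting densities
$\rho_d - \rho_l = A(1 - T/T_c)^\beta$ and the law of rectilinear diameters
$(\rho_d + \rho_l)/2 = \rho_c + s(T_c - T)$, sharing $T_c$, with
$\beta = 0.325$ (3-D Ising) as a configurable default.

Excluded volume sums spherical monomer volumes and subtracts the
sphere–sphere lens intersection for bonded neighbors only, clamped to the
smaller sphere when engulfed. The monomer "radius" in this formula is taken
as half the bead diameter $\sigma$ from the parameter table (the quantity
the model tabulates is a diameter). The overlap concentration is
$c^* = N/V_{ex}$ and the effective packing density $\phi_{rel} = \rho_n/c^*$
classifies dilute-like ($<1$), overlap onset ($\approx 1$) and semi-dilute
($>1$) regimes; $\rho_n$ counts beads in a sphere of radius $r_0$ (the
fitted interface center) around the dense-phase center of mass.

# The synthetic-data module: what it does and does not emulate

Generators are pure functions of (spec, seed):

* **Droplets**: self-avoiding random walks (bond length 3.81 Å, non-bonded
  beads rejected closer than 4 Å — roughly $0.8\sigma$, a cheap but
  sufficient self-avoidance for analysis fixtures) with centers of mass
  uniform in a sphere; dilute chains outside. Slabs confine chains to a
  z-interval with two planar interfaces.
* **Langevin dynamics**: BAOAB splitting under the full potential, friction
  0.01 fs$^{-1}$ (a stand-in; the reference protocol used an NVT
  thermostat), timestep guard at 10 fs. It passes equipartition (kinetic
  energy per degree of freedom within 5% of $k_BT/2$) and bond-statistics
  checks, and supplies single-chain conformations for $V_{ex}$.
* **Planted droplets**: parallel-rod chain bundles at the pair-minimum
  spacing (6.9 Å, just inside the Y–Y well) give guaranteed
  super-threshold contacts without steric clashes. Triangular bundles in a
  shell at 0.85 R act as interface cliques; a linear contact path through
  the center provides hub-like betweenness, with path membership re-drawn
  each frame so hub identities churn while clique membership persists.
  These fixtures validate the spatial (hubs inner, cliques at the
  interface) and temporal (clique lifetimes exceed hub lifetimes) analyses
  through the real graph machinery.

What passing these tests shows is that the *analysis chain* is correct:
thresholding, graph statistics, role identification, profiles and fits
recover structures that were built in by construction. It does **not** show
that equilibrium condensates of a given sequence develop those structures —
random (unequilibrated) droplet configurations produce sparse interaction
graphs, and reproducing the emergent small-world microstructure of real
condensates requires production-scale sampling outside this package's
scope.

# Numerical choices and problem sizes

* Desk-scale defaults: 30 chains of 50 beads for pipeline runs; graph
  benchmarks use n = 2000 (ER, ring lattice) and n = 1000 (Watts–Strogatz)
  with 10-graph reference ensembles, sizes at which the estimator limits are
  sharp but a run completes in seconds to minutes.
* The coexistence fit runs on Levenberg–Marquardt stacked residuals with
  $T_c$ bounded below by the largest input temperature; noise-free recovery
  is exact to numerical precision and 1% multiplicative noise yields under
  2% bias (tested over 100 seeds).
* Tie-breaks are deterministic everywhere (ascending chain id for hub ties,
  lexicographic member lists for clique ties) so repeated runs are
  byte-identical under a fixed seed.
* Degenerate inputs fail explicitly: empty profiles, flat profiles,
  inverted interfaces, all-zero gyration eigenvalues, graphs with fewer
  than 10 nodes in the analysis component.

# Known limitations

* The packaged interaction strengths are synthetic stand-ins anchored to a
  single published value; quantitative energies (beyond the Y–Y anchor and
  the structural/threshold logic) should not be read as the published
  model's.
* The Langevin integrator is for fixtures, not production thermodynamics;
  no barostat, no Ewald electrostatics, no triclinic boxes.
* Dense-phase centers of mass assume a non-wrapping droplet.
* $\sigma_{sw}$ and $\omega_{sw}$ inherit the known biases of
  clustering-based small-world estimators on spatially embedded graphs;
  they are comparative estimators, not sharp classifiers.
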