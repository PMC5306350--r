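---
title: "Cooperative motion Monte Carlo for 2D polymer-solvent systems: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative motion Monte Carlo for 2D polymer-solvent systems: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cma2d)
```

## The model

`cma2d` simulates athermal polymer solutions in strictly two dimensions.
Chains of $N$ beads connected by unbreakable unit bonds live on a
triangular lattice of $L \times L$ sites (coordination 6) with periodic
boundaries in both axial directions; every site not occupied by a bead
holds a solvent particle of the same size, so the lattice is *fully
occupied* at all times.  The polymer concentration is the site fraction
$\varphi = n_\mathrm{chains} N / (\mathrm{layers} \cdot L^2)$; $\varphi = 1$
is a melt.  A quasi-2D variant stacks two layers, each site gaining its
mirror site as a seventh neighbour, which lets solvent pass over a chain —
the control that isolates strictly-2D solvent-exclusion effects.

The system is athermal: there are no interaction energies, only excluded
volume and connectivity.  Every admissible configuration has the same
statistical weight, so the simulation's only job is to move through
configuration space without bias.

Coordinates are axial integers $(a, b)$ with the unit-bond Cartesian
embedding $x = a + b/2$, $y = b\sqrt{3}/2$ (and $z$ equal to the layer
index).  The periodic cell is a rhombus; minimum-image displacements are
taken over its nine periodic images, which is exact for this cell.  On
this lattice every squared inter-site distance $a^2+ab+b^2$ is an integer,
which the observables exploit to tabulate pair distances exactly.

## The cooperative motion algorithm

With no vacancies, no element can move alone.  A trial move is a
*displacement walk*: pick a uniform random start site, tentatively push
its element onto a uniformly chosen neighbour, let the displaced element
continue the walk with a fresh uniform neighbour choice, and close the
loop when the walk steps back onto the start site.  By construction the
displacements along a closed loop sum to zero — no site is created or
destroyed (the continuity condition).  Walks are rejected when they

* revisit any non-start site (the cyclic permutation along a
  self-intersecting walk would be ill-defined),
* exceed `max_len` sites (default 100),
* close with fewer than 3 sites (a two-site swap), or
* wind around the torus (the closure is only apparent; the raw
  displacement sum is $\pm L$ in some direction, violating continuity).

An accepted walk cyclically permutes the elements along it; the move is
kept iff every bond of every affected chain is still a nearest-neighbour
pair, and otherwise the state is restored bit-for-bit.  A loop and its
reverse have identical proposal probability (same start, same number of
uniform direction choices), so the chain satisfies detailed balance on the
uniform athermal ensemble.  The strongest correctness check in the test
suite follows from this: the long-run conformation frequencies of a
5-bead chain match the exhaustive enumeration of all 618 directed
self-avoiding walks (chi-square over all classes, plus exact first
moments).

Time is measured in units of one attempted displacement per lattice site:
the engine counts every tentative walk step, accepted or not, and one time
unit elapses when that count reaches the site count.  All randomness in
the compiled kernel flows through one seeded xoshiro256** generator, so a
`(state, seed)` pair reproduces a trajectory bitwise.

## Initial states, and why dense systems must start disordered

`build_initial()` offers four arrangements:

* `"extended"` (default): chains laid fully extended along the $a$ axis,
  folding back at a row end (or every `fold_width` columns), packed from
  the origin; the remainder is solvent.  Deterministic, and fine for
  dilute systems, which relax in solvent.
* `"spread"`: one extended chain per row, rows evenly spaced.
* `"random"`: a Hamiltonian path on the torus, randomised by a long
  sequence of backbite moves, is cut into consecutive $N$-bead chains —
  an exactly valid, disordered full packing.
* `"pivot"`: each chain's conformation is drawn by the pivot algorithm
  (asymptotically uniform over self-avoiding walks) and placed uniformly
  at random without overlap.

The `"random"` arrangement exists because the ordered packings are
*jammed* at high concentration.  In a melt of fully extended commensurate
chains, exhaustive search proves that **no** bond-preserving cooperative
loop of length $\le 12$ exists — not one — and longer admissible loops
(whole-row slides, full-chain slithers) have proposal probability of order
$6^{-N}$.  The ordered melt is a crystal from which loop moves cannot
nucleate disorder at any practical rate; a disordered packing of the same
chains is mobile from the first sweep (of order one accepted loop per
time unit on a $64^2$ melt).  Starting dense systems from the randomised
packing is therefore a correctness requirement, not a convenience.

For dilute systems the `"pivot"` start has a stronger property: the pivot
ensemble *is* the equilibrium distribution of an isolated athermal chain,
and the engine preserves it by detailed balance, so production sampling is
stationary from the first timestep.  The package validates this
internally: pivot-sample means agree with exhaustive enumeration at small
$N$, and CMA production means agree with pivot references at larger $N$.

## Observables

All single-chain quantities are computed on unwrapped coordinates (bead
$i+1$ placed at bead $i$ plus the minimum-image bond vector); inter-bead
and centre-of-mass distances use the minimum-image convention.  The
gyration tensor's trace equals $R_g^2$ to $10^{-12}$ for every measured
chain (a standing test).  The asphericity is the ratio of ensemble means
$A_2 = \langle(\lambda_2-\lambda_1)^2\rangle / \langle(\lambda_2+\lambda_1)^2\rangle$
— not a mean of per-chain ratios — accumulated from the per-measurement
sums the engine records.

The intramolecular correlation $\gamma(r)$ counts ordered same-chain bead
pairs (including the self pair, so its total weight is exactly $N$) on the
exact integer-$r^2$ distance table; binning is a reporting view only.
The structure factor applies the spherically averaged kernel
$\sin(qr)/qr$ to that exact table, giving $S(q\to 0) = N$; a strictly-2D
isotropic average would use a Bessel $J_0$ kernel, which is available via
`kernel = "bessel"` for sensitivity checks (the printed-form kernel is the
default for fidelity to the field's convention).  The default $q$ grid is
64 log-spaced points in $[2\pi/L, \pi]$.

The centre-of-mass pair correlation normalises pair counts by the
continuum annulus area over the box area so that an ideal-gas pattern has
$g(r) = 1$; on a lattice the per-bin values wobble by the granularity of
the distance shells at small $r$ (the test suite checks both the plateau
and the exact shell-count expectation).  Solvent domains are connected
components of solvent sites under lattice adjacency, found by flood fill
and cross-checked against an independent graph-component oracle.

## Scaling analyses

`fit_power_law()` is ordinary least squares of $\log y$ on $\log x$ inside
an explicit window, returning a classed fit with exponent, standard error,
$R^2$ and predict/confint methods.  On top of it:

* `estimate_2nu()`: $\langle R_g^2\rangle \propto N^{2\nu}$; 2D references
  are $2\nu = 3/2$ (dilute, good solvent) and $1$ (ideal/melt).
* `estimate_concentration_exponent()`: $\langle R_g^2\rangle \propto
  \varphi^{(1-2\nu)/(d\nu-1)}$, with the analytic reference
  `concentration_exponent_reference(nu, d)` ($-1$ for $\nu=3/4, d=2$).
* `sq_slope()`: the fractal slope $-1/\nu$ of $S(q)$, fitted in a window
  chosen to exclude the Guinier knee ($qR_g \ge 4$) and the monomer scale
  ($q \le 2$).
* `detect_crossover()`: two-segment piecewise-linear fit in log-log
  coordinates with the breakpoint searched on the discrete $q$ grid;
  slope differences below `delta_threshold` are reported as "no
  crossover" (a result, not an error), and $\xi = 2\pi/q^*$.

## Reference experiments and run-length choices

`reproduce_target()` reruns the package's desk-scale reference
experiments ($N \le 128$ on a $64^2$ box; the production problem sizes of
the full study, $N$ up to 1024 on $256^2$–$512^2$ boxes, are out of scope
here).  The choices, made once:

* **Dilute runs** ($2\nu \to 3/2$): 12/6/3 chains of $N = 16/32/64$, all
  at $\varphi = 0.0469$ (inside the $\varphi \le 0.06$ dilute band, which
  is also the lowest concentration the full study uses).  Pivot starts;
  warm-up $N^{2.5}$ time units; production $10\,N^{2.5}$ with about 1200
  measurements; 4 replicates.  The production window spans a few
  conformational relaxation times (measured on the $N = 64$ relaxation
  from an extended start, which decays on the $10^5$-time-unit scale).
* **Melt and semidilute runs** ($\varphi = 1$ and $0.3$): random-packing
  starts, warm-up $8N^2$, production $16N^2$, 4 replicates from
  independent packings.  Replication matters: dense 2D dynamics is slow
  enough that a single packing is never fully forgotten within a run (two
  packings of the $N = 64$ melt hold an $\approx\!10\%$ $R_g^2$ offset
  over $2\times10^5$ time units); averaging over packings removes that
  initialisation memory.
* **Melt structure factor**: $S(q)$ accumulated on every 4th measurement;
  slope fitted in $[4/R_g, 2]$.
* **Blob crossover sign test**: at desk scale the crossover needs the
  longest affordable chain for scale separation between the blob size
  $\xi \approx \varphi^{-3/2}$ and the coil size, so it runs at $N = 128$,
  $\varphi = 0.4$, comparing slopes below and above the parameter-free
  blob scale $q_\xi = 2\pi\varphi^{3/2}$.  At $N = 64$ the two scales
  coincide and $S(q)$ is a single power law with an intermediate slope
  near $-1.8$ — itself the expected signature of the intermediate regime,
  but without a resolvable slope change.

## What the synthetic stages do and do not show

The fixtures (rods, the hexagon disk, exhaustive SAW enumeration, ideal
walks, uniform point patterns, pivot samples) give every observable an
exact or distributionally known reference, so the observable suite and the
fits are tested without trusting the engine, and the engine is tested
against enumeration without trusting the observables.  What passing these
tests does **not** show: behaviour at production scale ($N \ge 256$, where
the full study reports anomalous stretching, microphase separation at
intermediate concentrations and asphericities above 0.8), finite-size
effects beyond $L = 64$, or dynamic (time-correlation) observables, which
are outside the package's scope.

## Numerical choices and degenerate inputs

* Concentration arithmetic is exact for the printed reference cases
  (dyadic rationals).  The cross-convention correction to off-lattice
  area-fraction concentrations multiplies by the circle close-packing
  constant $\pi/(2\sqrt 3) \approx 0.9069$.
* The melt ($\varphi = 1$) changes nothing in the engine: loops simply
  permute beads only.
* A chain longer than the box edge cannot be laid by the `"spread"` or
  single-row arrangements and unwrapping assumes chain extent below the
  box scale; the initializers enforce feasibility (capacity errors).
* Equilibration monitoring (`equilibrate()`) declares convergence when
  two consecutive block means of $\langle R_g^2\rangle$ agree within two
  combined standard errors; hitting the window cap raises a warning and
  returns the full history for diagnosis rather than an error.
* The engine rejects two-site swap loops ($k = 2$); the smallest loop is
  the lattice triangle, and loop-length statistics are recorded per run.

## Known limitations

The backbite-cut packing approximates, but is not exactly, the uniform
melt ensemble (consecutive path segments are weakly correlated); the
replicate-averaged CMA production relaxes the residual bias, and the melt
exponent and asphericity land on the field's reference values within the
stated tolerances.  Dense-system mobility relies on disordered starts —
the package deliberately refuses to pretend an ordered melt equilibrates.
The pivot initializer and the placement rejection loop use R's RNG (seeded
per replicate), separate from the engine's compiled RNG stream; both are
reproducible from the same seeds, but the two streams are independent by
design.
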