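---
title: "Modeling whisker deformation inside the follicle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling whisker deformation inside the follicle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follisim)
```

## The question

Rodent whiskers (vibrissae) transduce touch not at the whisker tip but deep
inside the skin, where mechanoreceptors lining the follicle sinus complex
(FSC) sense how the whisker shaft pushes and pulls against the surrounding
tissue. That deformation cannot be observed directly in a behaving animal.
`follisim` implements a quasi-static, "pseudo-3D" mechanical model that
estimates the shape the whisker takes inside the follicle when it is
deflected, and how that shape changes with tissue stiffness, muscle state
and blood pressure in the ring sinus (RS).

## The model

The whisker shaft is an Euler-Bernoulli beam (Young's modulus $E$, solid
circular cross-section of radius $R$, $I = \pi R^4/4$), and the follicle
wall is a second beam made effectively rigid by scaling its $EI$. Tissue is
lumped into six linear springs:

* four *internal* springs joining whisker to wall, at the hair bulb
  ($k_1$, $x = 0$), the cavernous sinus (CS, $k_2$), the ring sinus (RS,
  $k_3$) and the follicle entrance ($k_4$, $x = L$);
* two *external* springs joining the wall ends to ground ($k_5$ deep,
  $k_6$ superficial), standing in for intrinsic muscle and surrounding
  tissue.

Discretised, this gives 13 elements — four whisker beam segments (the
fourth protrudes beyond the entrance and is load-free), three wall
segments, six springs — and 20 degrees of freedom: translation/rotation
pairs at five whisker nodes and four wall nodes, plus two
translation-only ground attachments. A deflection is imposed as an
essential boundary condition on the rotation at the follicle entrance
(default $-10^\circ$, simulating a $10^\circ$ rostral deflection), with
the ground translations fixed at zero; all loading enters through these
prescribed displacements, never as applied forces.

Boundary conditions are enforced by the penalty method: a large number
$\beta$ is added to the constrained diagonal entries of the assembled
stiffness matrix $K$ and $\beta$ times the prescribed value to the load
vector. Solving $K_{tot}\,d = f$ yields the nodal displacements. From the
nodal translations and rotations the package reconstructs

* $u(x)$, the absolute whisker displacement, by elementwise cubic Hermite
  interpolation — exact here, because the only loads are point forces at
  nodes, so $EI\,u''' = V(x)$ with piecewise-constant shear $V$;
* $f(x)$, the wall displacement, by linear interpolation of wall nodes
  (the near-rigid wall moves affinely);
* $r(x) = u(x) - f(x)$, the relative displacement that loads the
  mechanoreceptor-bearing tissue.

```{r profile}
params <- follicle_params()
pr <- compute_profiles(params)
pr
classify_profile(pr)
feasibility_test(pr)
```

## Parameters, units and defaults

All user-facing values use convenient units (GPa, MPa, micrometres,
millimetres, N/m, degrees) and are converted exactly to SI at the
boundary; everything internal is Pa, m, N, rad.

| parameter | default | meaning |
|---|---|---|
| $E$ | 3.5 GPa | whisker Young's modulus |
| $R$ | 75 μm | whisker base radius (150 μm diameter) |
| $L$ | 1 mm | follicle length |
| $k_1, k_2, k_3, k_4$ | $10^3, 10^4, 10^5, 10^6$ N/m | internal springs (HB, CS, RS, entrance) |
| $k_5, k_6$ | $3\times10^3, 7\times10^3$ N/m | external springs; $k_5+k_6 = E_{skin} L \approx 10^4$ N/m, $k_6/k_5 = 7/3$ |
| spring positions | $0, 0.3, 0.6, 1$ (of $L$) | HB, CS, RS, entrance |
| wall rigidity factor | $10^4$ | multiplier on wall $EI$ |
| deflection | $-10^\circ$ | prescribed entrance rotation |

The anatomy constrains these choices: the skin modulus (8 MPa) times $L$
fixes $k_5 + k_6 \approx 10^4$ N/m; the entrance must clamp the whisker,
so $k_4 \ge 100\,(k_5+k_6)$; and histology implies the orderings
$k_1 \le k_2 < k_4$, $k_1 \le k_3 < k_4$ and $k_5 < k_6$.
`validate_anatomical_constraints()` reports violations without refusing to
simulate, since the sweeps intentionally explore beyond the anatomical
range.

The RS spring sits at $0.6\,L$ because RS-level quantities are quoted at
$x = 0.6$ mm with $L = 1$ mm. The CS position is **not** anatomically
pinned; $0.3\,L$ is this package's default, and results that depend on the
CS level are sensitive to it (see *Calibration sensitivity* below).

## Numerical choices

* **Penalty scaling.** Two published prescriptions for $\beta$ circulate
  for this system — $10^7$ times the mean diagonal of $K$, and $10^7 E$ —
  which differ dimensionally. Both are implemented (`beta_mode = "diag"`
  default, `"modulus"`); both agree with the exact elimination solve
  (`oracle_constrained_solve()`) to better than $10^{-5}$ relative, and
  the penalty error shrinks like $1/\beta$.
* **Equilibration.** The assembled matrix mixes translational
  ($\sim EI/L_e^3$) and rotational ($\sim EI/L_e$) scales across five
  orders of magnitude before the penalty is added, so the dense solve
  applies symmetric Jacobi equilibration ($D K D$ with
  $D = \mathrm{diag}(K)^{-1/2}$). This changes nothing mathematically and
  keeps the 20-by-20 solve well conditioned in double precision.
* **Profile sampling.** 201 equispaced points on $[0, L]$ by default; the
  RS ($0.6\,L$) falls exactly on the grid.
* **Zero-crossing detection.** Profiles are classed C/S$_1$/S$_2$ by the
  number of sign changes of $r(x)$ (0, 1 or 2). Samples with
  $|r| < 10^{-3}\max|r|$ are ignored, and the last 5% of $L$ next to the
  entrance is excluded: the entrance spring clamps the whisker
  ($|r(L)| < 5\%$ of $\max|r|$), and the residual sub-tolerance wiggle
  there would otherwise contribute a grid-dependent spurious crossing.
  On all sweep grids the genuine crossings lie at $x \le 0.6\,L$, far from
  the excluded margin, and classification agrees with brute-force
  recounts on grids 50 times denser.
* **Degenerate inputs.** A zero prescribed angle yields the exact zero
  solution; classification refuses identically-zero profiles rather than
  guessing a class.

## The feasibility test

Ex vivo imaging of labelled Merkel cells under a $10^\circ$ deflection
bounds the whisker's relative displacement at the RS: mean 4.8 μm (the
default bound; 12 μm, the recorded maximum, is the relaxed variant), with
no sign change observed near the RS. `feasibility_test()` therefore
requires $|r(0.6\,L)| < 4.8$ μm, a constant sign of $r$ across
$x \in [0.55\,L, 0.65\,L]$, and that this sign oppose the deflection
direction (the whisker pivots about the clamped entrance). Under these
constraints only S-shaped profiles survive; C-shapes — which put their
largest displacement right at the RS — are excluded.

One consequence worth noting: $|r(0.6\,L)|$ falls monotonically as $k_3$
grows, so the magnitude criterion alone would make feasibility an upper
set in $k_3$. But at high $k_3$ the S$_1$ crossing migrates upward into
the RS window and the sign-constancy criterion fails again: per $k_2$
column of the map, the feasible $k_3$ values form one contiguous band,
not a half-line.

## The four sweeps

All sweeps are deterministic (no randomness anywhere) and return tidy
tables with their full grid recorded.

1. **`k1_sensitivity_sweep()`** — for each of 16 $(k_2, k_3)$ pairs
   ($k_2$ over $[10^3, 10^6]$, $k_3$ over $[10^4, 10^6]$, 4 log-spaced
   values each), $k_1$ runs over a dense log grid on $[10^2, 10^6]$ N/m
   and the band spread $\max_{k_1} r(x) - \min_{k_1} r(x)$ is measured.
   The spread at the RS is tiny (mean ≈ 0.38 μm here) while near the CS it
   reaches ≈ 13 μm for the softest $k_2$ — which is why $k_1$ can be
   frozen at $10^3$ N/m for the other analyses. "Near the CS" is measured
   as the maximum spread within $\pm 0.05\,L$ of the CS spring, the same
   half-width convention as the RS feasibility window; the spread declines
   monotonically from ~28 μm at the hair bulb toward zero at the RS, so
   wider windows read larger values (≈ 10.3 μm at the spring itself,
   ≈ 18.6 μm at $\pm 0.15\,L$).
2. **`k2k3_feasibility_map()`** — 13 × 13 log grid on
   $[10^3, 10^6]^2$ N/m with $k_1 = 10^3$; classifies every profile and
   applies the feasibility test. C-shapes occupy the soft corner (low
   $k_2$ and low $k_3$); all feasible points are S-shaped; the feasibility
   boundary is governed by $k_3$, with $k_2$ mostly selecting S$_1$
   versus S$_2$.
3. **`external_support_sweep()`** — models passive touch versus active
   whisking. Raising the total support $k_5 + k_6$ from $10^4$ to $10^5$
   N/m (contracted muscle is stiff) increases $r$ at the RS to ≈ 128% of
   baseline; balancing the ratio $k_5/k_6$ at fixed total maximizes
   $r(0.6\,L)$, with the extreme ratios 1/20 and 20 retaining only ≈ 51%
   of the balanced value. (With a near-rigid wall, mirrored ratios $\rho$
   and $1/\rho$ give numerically identical RS displacement.)
4. **`blood_pressure_sweep()`** — hydrostatic pressure in the RS stiffens
   $k_3$; as $k_3$ runs from $10^5$ to $10^6$ N/m, $r(0.6\,L)$ falls to
   ≈ 11% of its base value while the internal force
   $k_3 \cdot r(0.6\,L)$ rises — smaller displacement, harder push.

```{r sweeps}
bp <- blood_pressure_sweep(k3_values = log_space(1e5, 1e6, 5))
bp$table
```

The Fig-7/8-style sweeps need a baseline $(k_2, k_3)$, which is not
anatomically determined; the defaults $(10^4, 10^5)$ N/m — an S-region,
feasible pair whose $k_3$ coincides with the pressure sweep's base state —
are a documented calibration choice, not a measured fact.

## Calibration sensitivity

Two quantities dominate calibration uncertainty:

* **CS spring position.** With the CS at $0.3\,L$ (default), the mean
  RS-level $k_1$ band spread is 0.383 μm and the CS-level maximum is
  12.9 μm. Moving the CS to $0.2\,L$ gives 0.340 μm and 15.6 μm; to
  $0.4\,L$, 0.439 μm and 9.2 μm. RS-level results (the feasibility map,
  support and pressure sweeps) are far less sensitive, since the RS
  position is pinned at $0.6\,L$.
* **$(k_2, k_3)$ baseline.** Scales the support- and pressure-sweep
  displacements roughly proportionally; the monotone directions are
  unaffected anywhere in the S region.

## What the model does and does not capture

The model is quasi-static and planar: no whisker collisions, vibrations,
texture-induced micromotion or airflow, and no out-of-plane mechanics
(tissue on all sides is folded into one-plane spring action). It predicts
whisker *displacement*; mechanoreceptor response depends additionally on
local tissue stiffness, so displacement maps to receptor drive only
jointly with the spring constants (e.g. the internal RS force
$k_3 \, r(0.6\,L)$). Magnitudes are order-of-magnitude estimates — the
springs lump continuously distributed tissue into six attachment points —
while profile *shapes* and monotone trends are robust across wide
parameter ranges. Because every simulation here is generated by this same
beam-and-spring idealisation, agreement between sweeps and tests validates
the implementation and the internal consistency of the parameter
constraints, not the model's fidelity to living tissue.
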