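---
title: "Growth-optimal ribosome composition in a self-fabricating cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-optimal ribosome composition in a self-fabricating cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocomp)
```

## The question

Ribosomes are the only major cellular catalyst that is mostly RNA: in
bacteria roughly 2/3 of the ribosome's mass is rRNA and 1/3 is protein
(x_rP ≈ 0.36 in *E. coli*), while archaea, eukaryotes and especially
mitochondria carry progressively protein-richer ribosomes. Because
ribosomes make all proteins — including their own proteins and the RNA
polymerase that makes their own rRNA — their composition sits inside two
coupled autocatalytic loops, and one can ask which composition maximizes
the steady-state growth rate.

`ribocomp` implements a coarse-grained resource balance analysis (RBA)
model of a self-fabricating cell to answer this. The cell imports a carbon
unit (C), synthesizes amino acids (AA) and nucleotides (NT) with two lumped
enzymes (EAA, ENT), transcribes rRNA with RNA polymerase (RNAP), translates
seven protein species with the ribosome (R), and assembles ribosomes from
rRNA and ribosomal protein (rP) with assembly factors (AF). An extended
variant adds an RNase that degrades rRNA back to nucleotides.

## The model

At steady state, fluxes determine growth rate and concentrations:
`N v_tot = mu c >= 0` with the dry-mass normalization `omega^T c = 1`, so
that `mu = omega^T N v_tot` and, because every internal reaction conserves
mass exactly, growth equals the carbon exchange `mu = omega_C v_IC`
(plus the imported-protein exchange in the mitochondrial variant — see
below). Each catalyst carries a capacity constraint (flux at most turnover
times catalyst concentration); eliminating concentrations through
`c_i = w_i/mu`, `c_R = v_AF/mu` turns the whole model into a linear system
*parameterized by* `mu`: 12 constraints on 11 fluxes in the base model, 14
on 13 in the extended one. `build_constraints()` assembles exactly this
table; `constraints_as_table()` dumps it for inspection.

Ribosome composition enters through the fixed ribosome mass
`omega_R = n_rRNA omega_NT + n_rP omega_AA`: the protein mass fraction
`x_rP` fixes `n_rRNA = (1 - x_rP) omega_R / omega_NT` and
`n_rP = x_rP omega_R / omega_AA`. Both counts are kept real-valued across
sweeps — the relation is continuous and rounding would create grid
artifacts.

rRNA degradation (extended model) is a minimum-activity constraint
`v_RNase >= k_deg(x_rP) (1 - x_rP) c_R`, with three scenarios for the rate
constant: `none` (base model), `constant` (`k_deg = kdeg_max`), and `hill`,

    k_deg(x) = kdeg_max * (1 - x^n / (K^n + x^n)),

modeling cooperative protection of rRNA by ribosomal proteins with
half-saturation `K` and Hill factor `n`. The RNase itself costs resources
through its own capacity constraint and synthesis.

## Parameters and fixtures

All rates are stored per hour (file loaders accept per-second values with
unit tags); masses in g/mmol, lengths in residues. The carbon
stoichiometries are tied to the masses (`n_AA = omega_AA/omega_C`,
`n_NT = (omega_NT - omega_AA)/omega_C`) so that `omega^T N` vanishes on
every internal column — the validator enforces this, which is what makes
the dry-mass row exact.

The packaged fixtures (`ecoli_fixture()`) emulate *E. coli* in six media.
Literature-anchored values: translation elongation 21 AA/s with 85% of
ribosomes active, transcription elongation 85 NT/s, RNase R turnover
88 NT/s, and a ribosome whose protein moiety at the observed x_rP = 0.36
is a 7400-AA complex, which pins `omega_R = 7400 * omega_AA / 0.36`
(≈ 2.2 MDa). The remaining constants (lumped enzyme lengths, importer and
assembly turnover, active RNAP fraction 0.20) are fixture-derived
plausible values, flagged in `$meta`. Nutrient quality is encoded as a
single per-condition turnover for the lumped synthesis pathways
(`kcat_EAA = kcat_ENT`, 0.30–2.70/s from poorest to richest medium),
chosen once so that base-model optima at x_rP = 0.36 span ≈ 0.4–2.1/h —
the physiological range the model is meant to cover. These fixtures are
synthetic stand-ins: `load_parameters()` is the injection point for users
with measured parameter sets.

The default degradation sub-model is the cooperative scenario with
`K = 0.2`, `n = 6`, and `kdeg_max = 86.6/h` — the value
`calibrate_kdeg_max()` returns when asked to place the glucose-medium
optimum at the observed x_rP = 0.36 (grid step 0.01). Calibration is the
model's one fitted degree of freedom, exactly as in the source analysis;
everything downstream (other media, archaeal and mitochondrial variants)
is prediction.

## Numerics

**Feasibility and bisection.** Maximum growth rate at fixed composition is
the supremum of `mu` for which the linear system is feasible; feasibility
is monotone in `mu`, so bisection applies. Each feasibility test solves a
minimum-norm quadratic program over the polytope with `quadprog`: the dual
active-set method either returns a feasible witness or proves the
constraints inconsistent, which is a cleaner oracle than a simplex phase-1
at this scale. Rows are scaled to unit max-abs coefficient and columns
likewise before solving — fluxes span ~6 orders of magnitude (carbon
import ~10 mmol/g/h versus ribosomal protein synthesis ~1e-5) and the
constraint matrix mixes counts ~1e4 with fractions ~1. Feasibility is
accepted at 1e-9 on scaled rows.

**The bisection bracket** must be a provable upper bound on feasible
growth. We use the tightest available autocatalytic-loop ceiling: the
assembly-factor loop gives `mu^2 <= kel_bar_R * kcat_AF / n_AF` at every
composition; for `x_rP > 0` the rP loop gives `mu <= kel_bar_R / n_rP` and
for `x_rP < 1` the RNAP loop gives
`mu^2 <= kel_bar_R * kel_bar_RNAP / (n_rRNA n_RNAP)`. (The simpler
candidate `kel_bar_R omega_AA / omega_R` is *not* an upper bound for all
parameter sets — sufficiently fast metabolism pushes the optimum above it,
which truncates bisection silently; the loop ceilings cannot.) Default
absolute tolerance 1e-6/h; a relative tolerance is available for oracle
comparisons at small growth rates.

**Vertex enumeration.** At fixed `mu` the solution set is a bounded
polytope (the inhomogeneous dry-mass row pins the scale). Its vertices —
the elementary growth vectors of the parameterized system — are enumerated
exhaustively: equality rows are always active, and every completion by
inequality rows and non-negativity bounds to a square nonsingular active
set is solved and filtered for feasibility. At ≤ 13 variables this is
exact and fast enough (~3 s per growth rate). Completeness is audited by a
convex-combination check: independently computed feasible points
(min-norm witness, randomly tilted QPs) must be convex combinations of the
enumerated vertices (`convex_hull_residual()`).

**Closed form.** For the base model, assuming all 12 constraints active at
the optimum, homogenizing to the square matrix `B` and setting
`det B = 0` yields a quadratic in the rescaled growth rate
`mu_hat = (mu / kel_bar_R) (omega_R / omega_AA)`:
`(alpha + beta (1 - x)) mu_hat^2 + (gamma + x) mu_hat - 1 = 0`, with
coefficients returned by `quadratic_coefficients()` (the carbon-unit mass
is used where the importer's substrate mass appears). The sign of
`epsilon = (alpha + beta)/beta^2 + gamma/beta - 1` classifies the curve:
decreasing (optimum at the RNA-only ribosome) for `epsilon > 0`,
increasing for `epsilon < 0`, constant at `epsilon = 0` (dead band 1e-12).
The root is evaluated in the cancellation-free form
`2/(b + sqrt(b^2 + 4a))`, stable as the quadratic coefficient vanishes
near `x -> 1` with small `alpha`. `determinant_residual()` checks the
determinant construction numerically after row/column equilibration; note
that equilibrated 12×12 determinants are intrinsically small, so "zero at
the root" is judged against the off-root magnitude (~1e-9), not against 1.

**Degenerate inputs.** At `x_rP = 1` the rows involving `n_rRNA` keep
their (zero) coefficients rather than being dropped, preserving fixed
shapes; at `x_rP = 0` the rP loop imposes no cost and the RNAP loop binds.
Ties at the optimum are not lexicographically broken: the solver's witness
plus the full active set are reported, and the branch analysis shows the
optimum is unique where it matters (all vertices converge at `mu_max`).

## Scenario variants

*Archaea*: harsher environments (temperature, pH) are modeled as a higher
degradation ceiling — `variant_archaea()` multiplies `kdeg_max` (2× is the
standard scenario). `thermococcus_fixture()` additionally overrides
masses/rates with archaeal-plausible *synthetic* values.

*Mitochondria*: `variant_mitochondria()` marks a fraction of rP as
imported free of synthesis cost; the AA balance and the ribosome capacity
row charge only `(1 - f) n_rP` per complex. The imported mass is added to
the dry-mass row as an exchange term riding on `w_rP`, so the
normalization `omega^T c = 1` — and with it the conservation test suite —
holds for every variant. (Without that term, imported protein would appear
in the biomass but not in growth, and the normalization would drift by
exactly the imported mass flux.)

## What the tests do and do not show

The synthetic fixtures reproduce the *structure* of the experimental
situation — six media spanning 0.4–2.1/h, printed elongation/turnover
rates, the observed composition as calibration target — but not the
measured values of the unpublished per-medium parameter table. Tests and
pipelines therefore assert the model's qualitative laws (RNA/protein ratio
linear in growth rate with near-zero intercept; three transcription-flux
branches converging at the optimum; endpoint optima without degradation
and interior optima with it; calibration self-consistency; optima shifting
protein-ward under harsher degradation or free import; degraded fraction
falling with growth rate and with cooperativity) and the model's exact
invariants (mass conservation, dry-mass normalization, allocation budget,
two-loop upper bounds, numeric-vs-analytic agreement to 1e-6 relative).
Quantitative flux values depend on the fixture constants and should not be
read as predictions for real *E. coli*.

Problem sizes used by the shipped suite: composition sweeps at grid step
0.01 (101 points); oracle equivalence on 50 seeded random parameter sets ×
5 compositions; calibrations bracketed over six decades of `kdeg_max`;
vertex enumeration on 4–5 growth rates per run.

## Known limitations

The model lumps all non-ribosomal RNA away (no mRNA/tRNA), has no energy
metabolism, treats RNAP allocation to rRNA as a fixed scalar, and holds
elongation rates constant in `mu` (a user-supplied `kel_R`-vs-`mu` hook is
deliberately out of scope). Degradation acts on the ribosome's rRNA
content as a proxy for nascent-rRNA turnover, which standard RBA cannot
resolve (non-catalyst concentrations vanish at the optimum). The extended
model has no closed form; its optima come from the numeric solver only.

## A worked example

```{r example, eval = FALSE}
p <- ecoli_fixture("glc")

# numeric optimum vs closed form at the observed composition
maximize_growth(p, x_rP = 0.36, variant = "base")$mu
analytic_mu_max(p, 0.36)

# where does the base model put the optimum?
sweep_composition(p, seq(0, 1, 0.01), "base")$argmax      # 0: RNA-only

# and with cooperative rRNA protection?
sweep_composition(p, seq(0, 1, 0.01), "extended")$argmax  # mixed ribosome
```
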