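---
title: "Methods: serial two-step fermentation simulation by FBA/FVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial two-step fermentation simulation by FBA/FVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialferm)
```

## The model and its assumptions

serialferm predicts product yields of fermentation processes in which one
or two organisms act **serially** on a feedstock. The core assumptions are
those of constraint-based modeling: the metabolic network is at steady
state (`S·v = 0`), fluxes are box-bounded, and the organism's regulation is
summarized by growth-rate maximization (FBA). Because many flux vectors
attain the growth optimum, product formation is reported as a range — the
FVA minimum and maximum of the product transporter flux with growth fixed
at its optimum. Only these LP optima are contractual results; witness flux
vectors depend on the solver path and are never used for reporting.

### The five-chamber envelope

Each organism model is wrapped before simulation. The wrapper partitions
the system into five chambers:

* **Media** — one metabolite per feedstock compound;
* **Internal** — the organism model itself;
* **Growth**, **Product**, **Waste** — terminal chambers, represented by
  sink transporters whose fluxes measure accumulation.

All inter-chamber transporters are unidirectional (`lb ≥ 0`), and no
reaction connects the Internal chamber directly to the outside: boundary
(exchange) reactions found in the base model are removed at wrap time and
replaced by envelope transporters. Their metabolites define which compounds
the organism may secrete to Waste — metabolites without an exchange
reaction in the base model cannot leave the cell. This was a genuinely open
design point (the permissive alternative gives every internal metabolite a
Waste path); the restrictive reading was chosen because published models
encode membrane transport deliberately, and a permissive default would
silently create mass exits that the original model forbids.

### Media dosing: a mass basis reconciled with molar stoichiometry

Media are dosed at 1 g dry weight of media per gDW of cells per hour. A
constraint equating a *sum of molar fluxes* to a *mass* is not dimensionally
meaningful as written, so the envelope realizes it compound-wise: the feed
transporter of compound *c* is fixed (equality bounds) at
`mass_c / MW_c` mmol·gDW⁻¹·h⁻¹, which makes the MW-weighted feed sum equal
the composition total (≤ 1000 mg) exactly. Uptake into the Internal chamber
is *bounded above* by the fed amount, not forced: residuals drain through
per-compound passthrough transporters to Waste. Compositions may be partial;
unaccounted mass is treated as inert (non-digestible fiber behaves this
way), and polymeric compounds are only digestible if the registry maps them
to a model metabolite — there is no implicit depolymerization.

Oxygen is dosed outside the mass basis, as a molar influx bound:
`anaerobic` (0), `bounded(x)` (up to x mmol·gDW⁻¹·h⁻¹; the validation sweep
range of interest is 0–2), or `open` (the default large bound, 1000).

### Serial transfer between steps

The inter-step coupling is the one place where alternate optima could leak
into results, so it is pinned down conservatively and kept behind a single
operation (`derive_transfer_media`):

1. For each chain (min and max) the step is solved: FBA, then product FVA.
2. Growth and the chain's product flux are fixed at their optima (with a
   relative slack of 1e-6 to absorb floating point).
3. The residual of each media compound is `fed − FVA-max(uptake)` under
   those fixes; secreted by-product masses are `FVA-min(secretion)`.
4. The transfer media is the transferable residuals plus transferable
   secreted compounds. The product itself is always removed between steps
   (physically, it is evaporated), volatiles (CO2, H2, O2, CH4) default to
   non-transferable, and the first organism's cell biomass is not fed to
   step 2 unless `transfer_biomass = TRUE` — "decomposed biomass" is read
   as feedstock, not cell mass.

Taking FVA-max of uptake (= minimal residual) and FVA-min of secretion
makes the transferred mass a lower bound over the optimal face: the
two-step totals cannot be inflated by an arbitrary witness. Step 2's feed
equality equals the transferred mass without renormalization to 1 g, so
the total yield denominator remains the original input mass — this is what
makes "percent of input converted" meaningful across steps. The min total
chains step minima, the max total step maxima; pairing min with max would
answer a different (adversarial) question and is not reported.

If an organism cannot grow (`BM_MAX = 0` within tolerance) the step reports
zero yields with a `no-growth` flag and passes its media through unchanged.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| default flux bound | ±1000 | mmol·gDW⁻¹·h⁻¹ | stands in for "unknown"; large but finite keeps LPs well-posed |
| media basis | 1000 | mg/gDW/h | the 1 g media per gDW cells per hour uptake assumption |
| FVA growth slack `epsilon` | 1e-6 | relative | exact fixing is numerically brittle; escalated ×10 twice on infeasibility |
| gradient `delta` | 1 | mg/gDW | small enough to read as a directional derivative, large enough to be robust at solver tolerance |
| product zero threshold | 1e-3 | mg/h | below the artifact scale of the growth slack (1e-6 of a ~1000 mg/h scale); used only when forming relative-yield ratios |
| oxygen `open` bound | 1000 | mmol·gDW⁻¹·h⁻¹ | same "effectively unbounded" convention as flux bounds |

## Numerical choices

The LP engine is a dense two-phase primal simplex operating on the shifted
problem `x = v − lb ∈ [0, ub − lb]`, with equality rows handled by phase-1
artificials and upper bounds as slack rows. Pivoting uses Bland's rule
throughout: it guarantees termination under the heavy degeneracy these
envelope LPs exhibit and makes repeated solves bit-identical, at the cost
of extra pivots — the right trade at this problem scale (tens to a few
hundred variables). Pivot tolerance is 1e-9, phase-1 feasibility tolerance
1e-7. Knockouts are bound nullification (`lb = ub = 0`), which the solver
exploits by dropping fixed variables before building the tableau.

Relative yields divide product masses, not percentages: removal scans
change the input-mass denominator, and Eq-style ratios must compare product
formation. A baseline of zero product yields `100` if the perturbed run is
also zero (the scenario equals the wild type) and `NA` with status
`undefined` otherwise — never a division by zero, never an infinity.

## What the synthetic generator emulates — and what it does not

`make_random_network()` produces substrate → intermediates →
{biomass precursor, product + by-product} chains with randomized molecular
weights, split ratios and growth caps, exactly mass-balanced by
construction and always growth-feasible on their companion media. They
exercise every code path the genome-scale case would (envelope wrapping,
degenerate optima, blocked reactions after knockouts) at LP sizes where an
independent oracle can be run on every instance. They do **not** emulate
cofactor coupling, compartmentalization, loops (so loopless-FVA issues
never arise), or the sheer degeneracy of genome-scale models. A green
oracle-equivalence suite therefore establishes solver correctness on this
network family, not genome-scale performance; the published genome-scale
numbers (e.g. knockout pairs reaching 146%/170% of wild type) require
external SBML models and cluster-scale compute and are out of desk scope.

The toy pair was additionally given explicit boundary reactions
(`EX_etoh`, `EX_co2`): under the restrictive secretion policy above, a
fermenter that cannot export CO2 would be blocked, which would contradict
the toys' documented hand-derived optima. Their molecular weights (glc 180,
xyl 150, etoh 46, co2 44) make every mass check an exact rational, e.g.
`180 = 2·46 + 2·44`.

One consequence of the symmetric toy pair is worth stating: A→B and B→A
produce different step-wise trajectories but identical totals on the mixed
media, because each sugar is exclusive to one organism. Order-dependence of
the *total* requires overlapping substrate ranges or transferable
intermediates, which the genome-scale case has and the minimal pair does
not.

## Degenerate inputs and tie-breaks

* Empty or zero-mass media: the pipeline short-circuits to zero yields
  with a `no-growth` flag instead of building an infeasible LP.
* A compound mapped by no organism: passthrough only; scans report it
  neutral (relative yield 100, gradient 0).
* Knockout of a blocked reaction: provably no effect (asserted against the
  oracle).
* Duplicate task payloads: rejected — task ids are content hashes and
  duplicates would alias under checkpointing.
* Alternate optima: all reported quantities are optima of explicit LPs;
  worker count and execution order provably do not change outputs.

## Known limitations

* Two steps maximum; no co-culture (competition and cross-feeding within
  one vessel are a different modeling problem).
* Reaction-level knockouts only — no gene–protein–reaction rules.
* Steady-state FBA: no dynamics, so "infinite time" digestion is assumed;
  experimentally this overestimates fast-growing organisms' consumption in
  a fixed-duration step.
* The simplex is dense and single-threaded; genome-scale models
  (thousands of reactions) will solve, but slowly — the design target for
  parallelism is scenario multiplicity, not single-LP speed.
* SBML support covers Level 3 + FBC flux bounds, species formulas and the
  active objective; kinetic laws, rules and annotations are ignored.
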