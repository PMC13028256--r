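---
title: "Constraint-based analysis of fruit ripening metabolism with fruitFBA"
author: "fruitFBA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of fruit ripening metabolism with fruitFBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitFBA)
```

## The modeling problem

Ripe climacteric fruit is a non-growing, heterotrophic sink tissue. Its
quality traits — phenolic content (chlorogenate), anthocyanin pigmentation
(cyanidin), the climacteric hormone ethylene, and cell-wall softening
(galacturonate from pectin breakdown) — are produced simultaneously during
ripening from remobilized reserves, while the tissue keeps paying a basal
energetic cost. `fruitFBA` models this regime with flux balance analysis
(FBA): steady-state reaction fluxes $v$ over a stoichiometric matrix $S$,

$$\max_v \; v_{RQS} \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

where the objective is not biomass (the tissue does not grow) but a
composite *ripening-quality sink* (RQS), an irreversible pseudo-reaction

$$\text{chlorogenate}_c + \text{cyanidin}_c + \text{ethylene}_c +
\text{galacturonate}_c \rightarrow \varnothing$$

whose flux forces simultaneous production of the four traits in fixed 1:1
proportion. Three constraint groups define the maintenance regime
(`ripeningConfig()`):

* **NGAM** — a non-growth-associated maintenance ATP hydrolysis with a
  strictly positive lower bound, 1.0 mmol gDW$^{-1}$ h$^{-1}$ by default.
  It represents cellular upkeep and guarantees that energy metabolism runs
  even at zero RQS flux.
* **Reserve mobilization pools** — exchange reactions releasing stored
  substrates (hexose, quinate, methionine, cysteine, pectin, cofactor
  moieties) up to a common cap, 10.0 by default. The cap applies to
  reactions in the `reserve mobilization` subsystem only; gas, water and
  proton exchange and demand sinks are not reserves and keep their own
  bounds, otherwise respiration would be throttled by an accounting
  convention.
* **Blocked pools** — citrate and chlorogenate mobilization are fixed at
  zero, so the RQS cannot be fed by stored chlorogenate and central carbon
  metabolism cannot be bypassed through stored citrate.

## Transcriptome integration and regulatory levers

Differential-expression contrasts (per-gene log2 fold-change plus a
significance flag, one table per variety $\times$ transition) enter as
*soft penalties*, never as hard on/off switches. Genes are classified
`up`/`down`/`neutral` at a $|\log_2 FC| \ge 1$ cutoff with significance
required (both exposed as parameters; the conventional cutoff is a package
default, chosen once). Classes propagate to reactions through
gene–protein–reaction (GPR) rules: `and` (complex subunits) takes the
most-penalized member, `or` (isoenzymes) the least-penalized, except that
strictly conflicting isoenzyme evidence (some up, some down) is treated
conservatively as `mixed`. Reactions without gene association — transport,
pools, NGAM, RQS — are always neutral.

Each class maps to a positive weight with the ordering
$w_{down} > w_{mixed} > w_{neutral} > w_{up}$; the default scheme is
$\{2.0, 1.5, 1.0, 0.5\}$. Only the ordering is meaningful: the lever calls
below are invariant under any admissible scheme (this is asserted by
test). The transcriptome-weighted parsimonious problem fixes the RQS flux
and minimizes weighted total flux,

$$\min \sum_i w_i (v_i^+ + v_i^-) \quad \text{s.t.} \quad S v = 0,\;
v = v^+ - v^-,\; v^\pm \ge 0,\; v_{RQS} = 1,$$

with reversible reactions split into nonnegative forward/reverse parts so
the weighted absolute value is linear.

A **regulatory lever** is a reaction that is transcriptionally disfavored
(`down`) yet *structurally required*: its minimum attainable $|v|$ over
all steady-state solutions sustaining the RQS target exceeds a small
activity threshold. Requiredness is decided by per-reaction flux-range LPs
(variability-style, two LPs per candidate), not by inspecting one optimal
vertex — FBA optima are degenerate, and a single solution is
solver-dependent. The penalized solution contributes only the reported
direction and the magnitude normalized per unit RQS flux.

Key numeric choices, all fixed in code:

* `rqs_target = 1` flux unit rather than the FBA maximum — this makes
  "normalized magnitude" well defined and independent of where the pool
  caps happen to bind; the FBA maximum is still computed as a feasibility
  gate and logged in the report metadata.
* activity threshold `eps = 1e-6`, matching the flux snap tolerance:
  reported fluxes below $10^{-6}$ are set to exact zero, two orders above
  the solver's $10^{-9}$ pivot tolerances.
* ties among equal-weight parallel routes are resolved deterministically
  by the solver's fixed pivoting order, but tests only assert min/max
  attainable per-reaction flux, never which twin of a degenerate pair
  carries it.

## The linear-programming core

No LP solver package is available in the target R environment, so the
package carries a dense two-phase primal simplex for box-constrained
variables (`R/simplex.R`). Design points: Dantzig pricing with
smallest-index tie-breaks, switching permanently to Bland's rule after a
long degenerate stall so termination is guaranteed; bound-flip handling
for nonbasic variables; refactorization at every iteration (the problems
here have at most a few hundred variables, so robustness is cheaper than
speed); primal feasibility declared at $10^{-7}$ relative to the
right-hand side. The same initial basis and pivot order make repeated
solves bitwise identical. Infinite user bounds are clamped to $\pm 10^6$,
far outside the $\pm 1000$ defaults of the reaction-table dialect.
Correctness is cross-checked in the test suite against an independent
constraint-based implementation (cobrapy/GLPK) on the reference model and
on three toy networks, with objective agreement to $10^{-6}$.

## The reduced reference model

The published curated list for peach mesocarp (185 reactions, 150
metabolites, 410 genes) lives in an appendix that is not reproduced in the
text, so the package ships a *reduced* reference network (74 reactions, 76
metabolites, 41 genes across 9 metabolic subsystems plus
pool/transport/exchange pseudo-reactions) built so that every benchmark
claim is structurally testable:

* the eight benchmark reactions (ACO_m, CAS_c, EPSPS_c, FUM_m, GR_c,
  HQT_c, PPA_AT_c, QDH_c) appear with their published stoichiometries;
* chlorogenate is reachable only via HQT (p-coumaroylquinate formation)
  followed by 3'-hydroxylation;
* the shikimate pathway is fed exclusively from vacuolar quinate reserves
  through quinate dehydrogenase (QDH) running in reverse (quinate
  $\rightarrow$ dehydroquinate + NADH). There is deliberately no
  DAHP-synthase entry from erythrose-4-P/PEP: with it, QDH would not be
  required and the quinate-lever behavior could not be expressed. The full
  published network may well contain that entry — its printed EPSPS
  magnitude (1) is smaller than the two-aromatic-unit count (2) this
  reduced topology forces — which is why EPSPS's magnitude is *not* a
  claim of this package, while HQT (1) and QDH (2) are;
* ethylene synthesis is a lumped Yang cycle (met + ATP $\to$ SAM $\to$ ACC;
  ACC + O$_2$ $\to$ ethylene + HCN + CO$_2$) whose HCN by-product can only
  be detoxified by β-cyanoalanine synthase (CAS);
* the two phenylpropanoid hydroxylations each oxidize 2 GSH to GSSG, and
  glutathione reductase (GR) is the only way back — a minimal stand-in for
  the full ascorbate–glutathione cycle;
* NADPH comes only from cytosolic NADP-isocitrate dehydrogenase fed by
  mitochondrial isocitrate export, and oxaloacetate for citrate synthase
  is regenerated only through the southern TCA arm. Together with the
  absence of any fermentative pyruvate overflow and of a cytosolic
  NADH sink other than the mitochondrial external dehydrogenase, this
  makes aconitase (ACO_m), fumarase (FUM_m) and the respiratory chain
  carry flux in every feasible solution — maintenance alone cannot be paid
  by substrate-level phosphorylation;
* cofactor pools (ATP, ADP, Pi, NAD(P), CoA) exist as capped mobilization
  reactions; because the network conserves each moiety, they carry zero
  net flux at steady state and only set pool sizes, exactly their
  physiological role.

With unit RQS flux the stoichiometry then forces HQT $= +1$ (one
quinate ester per chlorogenate) and QDH $= -2$ (one dehydroquinate for the
chlorogenate acyl moiety plus one for cyanidin's p-coumaroyl starter) in
*every* steady-state solution, which is what the lever report shows.

## What the synthetic contrasts emulate — and what they do not

`scenarioContrast()` generates the four variety-by-transition contrasts
(MG/RP $\times$ E1vsE2/E3vsE4; E1 harvest, E2 shelf-life, E3 cold-stored,
E4 cold-stored plus shelf-life). The class layout is fixed: each benchmark
reaction's gene is `down` exactly in the contrasts where that reaction
behaves as a lever; the QDH gene flips to `up` in RP E3vsE4 — the
post-chilling transition of the chilling-sensitive variety, where quinate
utilization relaxes and quinic acid accumulates; all other genes are
neutral. Log2 fold-changes are drawn per class from
$N(-2.0, 0.3)$ / $N(+2.0, 0.3)$ / $N(0, 0.2)$ with significance set for
up/down genes only. Effect sizes sit more than three standard deviations
from the $\pm 1$ cutoff, so classes are recovered at default thresholds
in essentially all draws (asserted at $\ge 95\%$), and the same seed
reproduces tables bit for bit without touching the caller's RNG stream.

The generator emulates the *class-conditional* structure of real contrast
tables, not their full complexity: real RNA-seq contrasts have
heavy-tailed fold-change distributions, correlated genes, dispersed
effect sizes straddling the cutoff, and thousands of genes outside the
model. Passing tests therefore demonstrate that the pipeline recovers a
known generating structure, not that the classification thresholds are
optimal for any particular RNA-seq data set.

## Degenerate inputs and edge behavior

Empty reaction tables parse to an empty model with a warning; an equation
whose two sides cancel entirely is rejected; exchange reactions (one empty
equation side) are flagged structurally and only those in the reserve
mobilization subsystem are treated as pools. Infeasible and unbounded LPs
are reported in the solution status, never as a silent zero; an RQS
target above the FBA optimum is an error naming the optimum. With the
NGAM floor at zero and the RQS fixed at zero, the all-zero flux vector is
feasible, and no reaction is required (`minRequiredFlux()` returns 0
everywhere) — the maintenance demand is the only thing that forces flux
in the absence of a quality objective.

## Problem sizes and runtime

All shipped analyses are desk-scale: the reference model has 74 reactions
(148 variables after splitting, 76 mass-balance rows), a full
four-contrast lever analysis solves a few dozen LPs in under ten seconds,
and the complete test suite — including the external oracle runs —
finishes in a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
model <- buildReferenceModel()
report <- runContrastAnalysis(model, scenarioContrast("MG_E1vsE2", seed = 1))
leverTable(report)
```

The report lists the contrast's levers with class `down`,
`required = TRUE`, the per-unit-RQS magnitude and the net direction; the
union across the four scenario contrasts is the eight-reaction benchmark
set. `relativeGrowthRate()` complements the flux pipeline with the
log-scale growth-rate descriptor used for fruit development curves.

## Known limitations

* The reference network is a reduced stand-in, not a reconstruction of
  the full published model; census quantities (reaction/gene counts) and
  the magnitudes printed for ACO_m/FUM_m (0.3) and EPSPS (1) depend on the
  full network's energetics and are out of scope here.
* No thermodynamic (loopless) constraints beyond the bound scheme; futile
  cycles are suppressed only by flux minimization.
* No quadratic pFBA variant and no MILP-style discrete expression
  integration (iMAT/GIMME); penalties are deliberately soft.
* Elemental and charge balancing are not checked — lumped reactions
  conserve the moieties the model tracks, nothing more.
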