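---
title: "A factorial model of the minimum metabolic demand for amino acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A factorial model of the minimum metabolic demand for amino acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aademand)
```

## The model

At maintenance, the dietary intake of an amino acid must replace its
obligatory losses: the amino acid that the body irreversibly oxidises,
secretes, sheds or converts over each 24-h period. `aademand` assembles those
losses into a *minimum metabolic demand* (MMD, mg per kg body weight per day)
for each of 16 amino acid categories -- nine indispensable (IAA) groups
(His, Ile, Leu, Lys, SAA = Met+Cys, AAA = Phe+Tyr, Thr, Trp, Val) and seven
dispensable (DAA) groups (Ala, Arg, Asx, Glx, Gly, Pro, Ser) -- in the
75-kg healthy young adult male.

Seven loss sources enter the sum:

* **PTO~PA~, PTO~PP~** -- oxidation tied to protein turnover in the
  postabsorptive and postprandial states (upstream estimates: 11% and 2.4% of
  the respective protein-breakdown rates; the package consumes the resulting
  per-amino-acid *values*, not the breakdown rates).
* **IO** -- inevitable oxidation: constitutive first-pass catabolism of a
  fixed fraction (default 29%) of each *absorbed* amino acid.
* **EGL** -- gut endogenous losses (secreted, not reabsorbed).
* **UFAAP** -- urinary free amino acids and peptides.
* **HSNM** -- hair, skin, nail and miscellaneous losses.
* **OL** -- other losses from irreversible modification (3-methylhistidine,
  hydroxylysine) and functional conversion (serotonin, catecholamines,
  creatine/purine backbones, pyrimidines).

Because IO is a proportion of the absorbed amount, which at maintenance
equals the demand itself, the demand is a fixed point. With $S$ the sum of
the six non-IO losses and $r$ the inevitable-oxidation rate,

$$\mathrm{MMD} = S + r\,\mathrm{MMD}
  \quad\Longleftrightarrow\quad
  \mathrm{MMD} = \frac{S}{1-r}, \qquad \mathrm{IO} = r\,\mathrm{MMD}.$$

The closed form is the limit of the intuitive iteration
$\mathrm{MMD}_{t+1} = S + r\,\mathrm{MMD}_t$ (a geometric series in $r$); the
test suite uses that iteration as an independent oracle. The solution is
homogeneous of degree 1 in the components, which the tests exercise as a
property.

```{r solve}
pack <- load_pack()
fit <- solve_mmd_table(pack$components, pack$constants)
fit
```

Demands aggregate by class and to total protein; the IAA share of the
protein demand is a headline quantity:

```{r share}
iaa_share(fit)
```

## Parameters that matter

`model_constants()` collects the scalars: `io_rate` (0.29, dimensionless;
must be strictly below 1 or the model is infeasible), `n_to_protein` (6.25 g
protein per g N), `body_weight` (75 kg), `creatinine_excretion`
(0.2 mmol/kgBW/d, used to convert creatinine-normalised urinary reference
ranges). The per-amino-acid loss components live in a *parameter pack*
(`load_pack()`), a directory of small CSVs that can be edited, written back
with `write_pack()` and re-solved -- e.g. scaling the postabsorptive
turnover-oxidation column emulates scenarios with a different assumed
turnover in body compartments.

## Uncertainty

Component estimates are means with standard deviations; sums propagate by
root-sum-of-squares (`propagate_sd()`), which assumes the component errors
are independent. The IO term's SD is taken from the pack's directly
estimated override column when present, otherwise scaled from the non-IO
root-sum-of-squares by $r/(1-r)$. Published aggregate SDs for this model are
not exactly recoverable from the published component SDs (their IO SDs'
provenance is unstated), so the package treats SD checks as structural
(non-negativity, permutation invariance, monotonicity, dominance over the
largest member SD) rather than as value reproduction.

## Deriving the minor components

The pack's HSNM, UFAAP and OL columns can themselves be derived from primary
inputs:

* `derive_hsnm()` splits a nitrogen total (5 ± 0.9 mg N/kgBW/d) into
  miscellaneous (1.8) and dermal (3.2, by difference) parts, converts each
  with the 6.25 factor and apportions by the amino acid composition of
  whole-body protein and of hair/skin/nail protein respectively.
* `derive_ufaap()` / `weighted_ufaap()` combine urinary excretion studies,
  dividing per-day excretions by body weight and weighting means and SDs by
  subject number; glutamine-type reference-range records arrive as mmol/mol
  creatinine and are converted via `creatinine_normalized_to_mass()`.
* `assemble_ol()` converts urinary metabolite excretions mol-to-mol (or at a
  stated stoichiometry) into parent-amino-acid losses via
  `metabolite_to_aa_loss()`, folding members (Met/Cys, Phe/Tyr, Asp/Asn,
  Glu/Gln) into their composite categories.

The packaged composition tables and excretion records marked `_synthetic`
are back-derived stand-ins: the primary appendix datasets behind those
columns are not published, so the fixtures were constructed to be
physiologically plausible *and* to reproduce the published per-amino-acid
loss columns through the same derivation code paths. They exercise the
machinery and pin the published outputs; they are not the original data. The
body-protein composition table mixes published IAA values with synthetic DAA
values constrained to the published DAA total (flagged in a `provenance`
column).

## Sensitivity analysis

`run_sensitivity()` perturbs one loss parameter of one target at a time over
-20%..+20% in 5% steps and fits the response slope by ordinary least squares;
`b` is the change in MMD per 1% parameter variation. The default treats IO
as an independent numeric parameter held at baseline while another parameter
varies, recomputing the demand as the simple sum of the seven values. That
reading makes the response exactly linear with slope `baseline/100`, which
is the only reading consistent with the reference slope for threonine's gut
endogenous losses (14.5/100 = 0.145 rather than 14.5/71 = 0.204). The
fixed-point-coupled alternative -- IO re-derived from each perturbed sum --
is available with `coupled = TRUE` for exploration. For aggregate targets
the aggregate component value is perturbed; under linearity this equals
perturbing every member simultaneously.

```{r sens}
run_sensitivity(fit, "Thr", "egl")
```

## Protein-quality scoring

A scoring pattern divides each IAA requirement (mg/kgBW/d) by the total
protein requirement (g/kgBW/d), giving mg IAA per g protein
(`build_pattern()`). Scoring a dietary protein source divides its digestible
IAA content by the pattern value per IAA; the minimum ratio is the DIAAS
(not truncated at 1), the amino acids attaining it are first-limiting (ties
are all reported), and the protein intake required to cover the demand is
the pattern's protein requirement divided by the DIAAS (`score_source()`,
`required_intake()`).

```{r diaas}
pats <- pack_patterns(pack)
srcs <- sources_from_ratios(pack$reference_ratios)
score_source(srcs$whole_milk, pats$MMD)
score_source(srcs$whole_milk, pats$FAO)
```

True ileal digestibility resolution for raw-composition sources follows a
fallback chain: per-amino-acid value, mean of available values, total-protein
proxy, total-N proxy; nothing resolvable is an error naming the amino acid.
Tryptophan composition must be supplied -- the package never falls back to an
external food-composition lookup. The packaged sources carry precomputed
digestible reference ratios (their raw composition/digestibility tables are
not published); raw-composition scoring is exercised on synthetic sources in
the tests.

## Numerical and design choices

* All computation is at full double precision; rounding happens only in the
  reporting layer (1 dp for mg/kgBW/d, integers for mg/g patterns, 2 dp for
  ratios, minimum taken before rounding). Reporting rounds half-up
  (22.5 -> 23), matching the source tables' convention, rather than R's
  round-half-even.
* The comparison report derives its integer scoring patterns from the
  integer-rounded demand column, reproducing the published derivation chain;
  from unrounded demands two cells (AAA, Trp) would differ by 1 mg/g, an
  artefact of cascaded rounding in the source, not of the model.
* The packaged component table carries the published per-cell-rounded
  values. Re-solving from them reproduces the published per-amino-acid
  demands to within about ±0.2 mg/kgBW/d and class totals to within about
  ±0.5; the residuals are the accumulated cell rounding of the unpublished
  unrounded components.
* The total-protein row treats HSNM at its aggregate nitrogen value
  (31.25 mg/kgBW/d) as the source table does; `solve_mmd_table()` computes
  both that variant and the per-amino-acid sum and reports the difference
  (-0.07 mg/kgBW/d with the packaged table).
* Zero demands make loss proportions undefined and raise an error rather
  than returning NaN; an `io_rate` of 1 or more is rejected as infeasible.
* A phrase-level ambiguity in the source's fixed-point preamble (a stray
  "MMR" symbol) is read as the demand itself; no alternative reading is
  implemented.

## What the tests do and do not show

The suite checks the algebraic invariants (fixed-point identity, oracle
equivalence, homogeneity, SD structure), the derivation operations on both
synthetic inputs and the pinned published columns, and end-to-end
reproduction of the published demand, sensitivity and quality-score numbers
from the packaged transcription. Problem sizes are those of the model itself
(16 categories, 9-point sensitivity grids, six protein sources), so the
whole suite runs in seconds. Because the `_synthetic` fixtures are
back-derived, their tests demonstrate correctness of the conversion and
weighting machinery, not independent confirmation of the published loss
estimates; and reproducing demands from per-cell-rounded inputs inherits
that rounding, as quantified above.

## Limitations

* The oxidation rates (29%, 11%, 2.4%) and gut endogenous losses are
  consumed as upstream parameters; the package does not re-derive them from
  tracer data.
* Scoring handles one protein source at a time; no mixed-diet DIAAS.
* Digestibility is an input; there is no prediction of true ileal
  digestibility.
* The reference subject is the healthy young adult male; other populations
  require a different parameter pack.
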