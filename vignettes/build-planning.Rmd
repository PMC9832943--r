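---
title: "Planning automated DNA assembly builds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning automated DNA assembly builds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buildplanr)
```

## The problem

Combinatorial DNA assembly designs — the kind produced by automated
design tools such as j5 — specify primers, PCR reactions, amplified
pieces and the ordered piece lists that make up each target construct.
Turning such a design into a bench run is mechanical but error-prone:
every primer and template must be diluted to a working concentration,
each reaction mixed to exact final concentrations, annealing
temperatures reconciled on a single gradient block, residual template
digested, fragments pooled in equimolar ratios, and the whole choreography
relayed to a liquid handler and its operator without a single misplaced
well. `buildplanr` generates that choreography as data — an ordered step
table — and *proves* it coherent by executing it on a virtual deck with
exact volume and amount bookkeeping before anything is rendered.

Four strategies are supported, reflecting common practice:

* **PCR only** (`build_pcr_workflow()`): amplification + optional
  template-removal digestion.
* **Golden Gate** (`build_goldengate_workflow()`): restriction–ligation
  assembly of pooled fragments with a type-IIS enzyme, cycled between
  digestion and ligation temperatures.
* **One-pot IVA** (`build_onepot_iva_workflow()`): both fragments of a
  two-part construct amplified in the same tube; the transformed host's
  recombination machinery performs the assembly.
* **AQUA** (`build_aqua_workflow()`): separate PCRs per fragment, pooled
  by length-proportional volumes and transformed directly.

## The annealing-gradient model

A gradient thermocycler block is modelled as `n_zones` columns (default
12) at linearly spaced temperatures with `rows_per_zone` tube positions
each (default 8), running cold on the left to hot on the right. For a
set of reactions with annealing optima $T_i$ and tolerances $\tau_i$,
the planner must choose endpoints $(T_{low}, T_{high})$ and a zone $z_i$
for each reaction such that the deviation
$d_i = |T_i - T_{zone}(z_i)|$ satisfies $d_i \le \tau_i$, where

$$T_{zone}(k) = T_{low} + (k-1)\,\frac{T_{high}-T_{low}}{n_{zones}-1}.$$

The default tolerance is 0.4 °C. A design file may carry a per-reaction
*delta* (the tolerable variance from the optimum); the effective
tolerance is $\tau_i = \min(\delta_i, 0.4)$, so a rigid sub-0.4 delta
tightens the requirement and a permissive one never loosens it.

Endpoints default to $(\min_i T_i, \max_i T_i)$ and each reaction takes
the nearest zone (ties to the colder zone). That already guarantees
success for the common case: with 12 zones and a spread of at most
8 °C, zone spacing is at most 8/11 ≈ 0.727 °C, so the worst nearest-zone
deviation is below 0.364 °C < 0.4 °C. When any reaction still exceeds
its tolerance (rigid deltas, awkward spacings), the endpoints are
re-optimized by exhaustive grid search: ±2.0 °C around each default in
0.1 °C steps, minimizing lexicographically (1) the worst clamped excess
$\max_i \max(d_i - \tau_i, 0)$, (2) the worst deviation, (3) the lower
endpoint, (4) the span. The deterministic tie-breaks make plans
reproducible byte-for-byte. Two infeasibility modes are distinguished
and raised as classed conditions: optima spanning more than the block
supports (`max_span_c`, default 24 °C — split the run), and tolerance
sets no endpoint pair can satisfy.

Within a zone, tubes fill rows A downward in ascending reaction id, so a
position string like `"A6"` means row A of the sixth (warmer) column.
The block orientation and zone count are configurable because
instruments differ; the test suite checks the invariant that relabeling
reaction ids permutes rows but never changes zone temperatures.

One extension time serves the whole run: the longest product at
30 s/kb, rounded up to 5 s, floored at 10 s (all configurable). The
amplification program is 30 s at 98 °C; then cycles (default 34) of
10 s at 98 °C, 30 s annealing across the gradient, extension at 72 °C;
then 5 min at 72 °C. The digestion program is 30 min at 37 °C, 20 min
at 65 °C. Golden Gate cycling defaults to 30 cycles of 37 °C/16 °C for
5 min each, a 5 min 50 °C hold and 10 min at 80 °C, all exposed as
configuration keys since published practice varies.

## Stoichiometry

All dilution arithmetic is exact $C_1V_1 = C_2V_2$; the unit tests
require conservation to a relative error of $10^{-9}$.

* **Primers** arrive at 100 µM and must contribute 0.1 µM to a 25 µL
  reaction from a 1 µL addition. The working concentration is therefore
  *derived*, not hard-coded: $C_w = C_{final} \cdot V_{rxn} / V_{add} =
  2.5\ \mu M$, prepared as 0.5 µL stock + 19.5 µL water.
* **Templates** are delivered by mass: 0.5 ng per reaction from a 1 µL
  addition, i.e. a 0.5 ng/µL working stock. Stocks already at or below
  that concentration are used directly with the add volume raised to
  deliver the target mass, rejected when that volume exceeds 10 % of the
  reaction.
* **The reaction body** is abstracted as a 2× master mix (half the
  reaction volume) plus the two primer adds, the template add, and water
  to volume — 12.5/1/1/1/9.5 µL at defaults. The master-mix abstraction
  keeps the printed final concentrations exact while leaving polymerase
  internals out of scope. Every component scales linearly with the
  reaction volume, so final concentrations are size-invariant.
* **Digestion** adds water/buffer/enzyme at 19/5/1 µL per 25 µL
  reaction (scaled proportionally), bringing a default reaction to
  50 µL.
* **Equimolar pooling** assumes equal mass yield per reaction, under
  which equal moles means volumes proportional to fragment length:
  $v_i = v_{ref}\, L_i / \max_j L_j$ with $v_{ref} = 4$ µL. Any $v_i$
  below the 1 µL minimum pipettable volume triggers a predilution by the
  smallest factor that raises the addition to exactly 1 µL, leaving
  delivered moles unchanged. A prediluted fragment shared by $k$
  constructs is seeded with $k \times 1$ µL of source so every draw
  stays pipettable.

Transfers that still fall below the minimum pipettable volume (e.g.
0.5 µL primer-stock draws) are never silently emitted: they are flagged
per step and collected into the run's `mix_report`.

## Deck model and artifacts

Placement is deterministic: template then primer stocks fill 24-tube
racks in bundle order (wells A1–D6, column-major, 1-based columns, extra
racks as needed), reagents get their own rack, working dilutions fill a
96-well plate in stock order, reactions sit in the thermocycler at their
gradient positions, and assembly pools take the first free thermocycler
wells. The thermocycler owns deck slot 7; other labware takes slots in a
fixed order, with one tip rack allocated per 96 transfers. Instruction
files are plain UTF-8 with `" | "` separators precisely so tests can
diff them byte-for-byte; `write_run_artifacts()` is required (and
tested) to be byte-deterministic, and the configuration snapshot
embedded in `runbundle.json` is sufficient to rebuild identical
artifacts.

## The virtual deck

`execute_run()` replays the step table against wells holding (volume,
per-species amounts). A transfer moves volume and proportional amounts;
primers are tracked in pmol, DNA templates and fragments in ng (with
pmol derived from declared lengths at 650 g/mol/bp); enzymes, buffers
and water by volume. Two thermal events have modelled side effects: the
digestion program zeroes template species in its wells, and the
amplification program deposits each reaction's product species at a
nominal equal-yield mass concentration (`frag_yield_ng_ul`, default
25 ng/µL — the value is arbitrary by design, since every claim checked
against it is a ratio or a conservation total, not an absolute yield).
Overdraws and well-capacity overflows are recorded as violations, never
dropped. `check_conservation()` closes the loop: for every species,
final + destroyed − created must equal the initial stock total to
$10^{-9}$ relative, and total liquid volume must be conserved.

Evaporation, dead volume and tip residue are not modelled (a
`dead_volume_ul` key exists, default 0). Fragment concentrations after
the manual clean-up pause are assumed unchanged, as the plan has no
measurement to propagate.

## The synthetic design generator

`generate_design()` writes fully parseable design files with a JSON
manifest of every generated value, which serves as the parser's ground
truth in tests. It emulates the *structure* of design-software output —
declared per-reaction annealing optima (uniform on a range, rounded to
0.1 °C), product lengths (uniform integers), per-construct piece order,
the 96 primer+template capacity — and deliberately not its substance:
sequences are random base filler and annealing optima are declared
rather than computed from sequence, since primer design is the upstream
tool's job. `chromoprotein_like_fixture()` reproduces the canonical
benchmark shape: four reporter constructs of four pieces each from
seven reactions, three of them backbone/selection pieces shared by all
constructs. Passing tests therefore demonstrate that the *planning
arithmetic and bookkeeping* are correct under the stated assumptions;
they say nothing about wet-lab success rates, which depend on sequence
content, yields and enzyme performance that the generator does not
model.

The `delta_policy = "mixed"` option assigns half the reactions a rigid
0.2 °C delta and half a permissive 1.0 °C one, specifically to exercise
the endpoint re-optimizer's tightened-tolerance branch.

## Numerical choices

* Comparisons against tolerances use an absolute guard of $10^{-12}$;
  conservation and C1V1 identities are asserted at $10^{-9}$ relative.
* The endpoint grid is generated in integer steps of 0.1 °C to avoid
  floating-point drift; objective keys are rounded to 9 decimals before
  lexicographic comparison.
* Zone temperatures are reported rounded to 0.1 °C in instruction files;
  deviations are computed before rounding.
* A degenerate flat gradient (all optima equal) with more reactions than
  one column holds spreads reactions across equal-temperature columns
  instead of overfilling column 1.
* Reported problem sizes: the property suites run the seven-reaction,
  four-construct benchmark end-to-end for both Golden Gate and AQUA, a
  100-design sweep (2–12 reactions each) for the gradient bound, and
  brute-force endpoint comparisons at up to 8 reactions, where
  exhaustive search over the 41×41 endpoint grid is cheap.

## Known limitations

* Single gradient run per plan: designs whose optima span more than the
  block's gradient range are refused rather than split automatically.
* The equal-yield assumption behind equimolar pooling is exactly that —
  an assumption; per-fragment concentration overrides after clean-up are
  a natural extension not yet exposed.
* One-pot IVA is restricted to two-fragment combinations by default,
  reflecting the reliability of that strategy; the override emits an
  explicit warning step into the plan.
* The emitted run bundle is vendor-neutral (JSON + picklist CSV); no
  robot-specific script renderer is included.
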