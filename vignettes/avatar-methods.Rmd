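---
title: "Virtual cell avatars: model, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual cell avatars: model, protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellavatar)
```

`cellavatar` simulates how a cancer cell line responds to targeted drugs
and micro-environment cytokines, by overlaying the cell's genomic
aberrations on a curated signaling network and running a staged,
deterministic protocol. This vignette is the package's own account of the
model: what is simulated, which conventions were chosen where the
underlying biology admits many parameterizations, and what the bundled
fixtures can and cannot show.

## 1. The dynamical model

Commercial predictive-simulation platforms in this space use very large
proprietary kinetic networks (thousands of species, tens of thousands of
rate parameters). A desk-scale reimplementation cannot reconstruct such a
network; it must replace it with a dynamics family that is small enough to
curate by hand yet expressive enough to carry the disease logic. We use
**normalized-Hill logic-based ODEs**, a standard formalism for signaling
networks whose activities are only semi-quantitative:

$$\frac{dx_i}{dt} = \frac{y_{max,i}\, p_i\, u_i\, m_i - x_i}{\tau_i}$$

* $x_i \in [0, y_{max,i}\,p_i]$ — normalized activity. "Concentration"
  language maps onto activity; phospho-forms (pSTAT5, pAKT, pERK) are the
  activity of the corresponding node, not separate species.
* $\tau_i$ — relaxation time constant, default 1,000 simulation seconds.
  Protein-level responses in signaling are minutes-to-hours; with stage
  horizons of 50,000–75,000 s this leaves a comfortable factor of ~50
  between the slowest time constant and the horizon.
* $u_i$ — net drive from incoming edges. Each edge applies a rescaled Hill
  transfer $f(x) = w\,(1+K^n)\,x^n/(x^n+K^n)$, anchored so that a silent
  source contributes nothing and a fully active source contributes exactly
  its weight $w$. Activators pool by noisy-OR; AND-gated co-regulators
  (the CDK–cyclin pairs) multiply before pooling; inhibitors attenuate
  multiplicatively. This keeps drives closed in $[0,1]$ and makes
  monotonicity provable edge by edge. Defaults: $K = 0.5$, $n = 1.4$,
  $w = 0.9$.
* $p_i$ (production scaler) and $m_i$ (activity multiplier) are the two
  independent axes on which perturbations act — transcription-level versus
  protein-activity-level — so a copy-number change and a mutation on the
  same gene compose naturally.

Amplified sources ($p > 1$) can exceed activity 1; downstream transfer is
evaluated on the same Hill curve and capped at 1 when pooled, preserving
closure.

Boundary ligands (IL6, TNFA, IFNG) are step inputs: when a cytokine
condition clamps them they hold a fixed value instead of obeying the
relaxation ODE.

Integration uses deSolve's `lsoda` (stiff-capable, adaptive) at
`rtol = 1e-8`, `atol = 1e-10`. Steady state is declared when every node's
relative change across the trailing 10% of a stage is at most `1e-6`
(nodes with near-zero scale are compared absolutely, floor `1e-3`, so
silent nodes cannot fail on round-off ratios). Degenerate inputs resolve
conservatively: nodes with no inputs and zero basal drive decay to zero;
duplicate edges are a validation error, never silently merged.

## 2. The staged protocol

1. **Control** (0 → 50,000 s): the unperturbed network settles; an error
   is raised if the steady-state criterion fails at the horizon.
2. **Disease** (50,000 → 125,000 s): the genomic profile is mapped to
   modifiers and overlaid; the system relaxes to the disease baseline.
3. **Treatment** (125,000 → 200,000 s): drug modifiers are composed on
   top; readouts are percent changes versus the disease baseline.
4. **Micro-environment variant**: cytokine clamps create a modified
   disease baseline before the drug.

Two conventions deserve explanation because the protocol's description
leaves them open:

* *When are cytokines applied?* We clamp them together with the
  aberrations at 50,000 s, so the "disease baseline variant with the
  micro-environment" is itself steady well before the drug arrives at
  125,000 s. Any re-equilibration window longer than a few $\tau$ gives
  the same variant baseline, so this choice is innocuous for steady
  readouts.
* *What is the reference for percent change under cytokines?* The
  cytokine-modified disease baseline. This keeps the drug effect and the
  cytokine effect separable: "TNFα potentiates G6" is a statement about
  the drug's relative effect in the TNFα context, not about TNFα's own
  baseline shift (which is reported separately by contrasting baselines).

Percent changes are guarded with $\varepsilon = 10^{-9}$ in the
denominator so readouts of silent biomarkers stay finite.

Treatments given as several aliquots of the *same* drug sum their doses
before conversion to modifiers — a compound obeys dose addition against
itself, which is exactly what makes the sham-combination test (a drug
"combined" with itself must come out Loewe-additive, CI = 1) a meaningful
guard against spurious synergy calls. Distinct drugs compose
multiplicatively on shared targets, the independent-binding convention.

## 3. Aberration overlay conventions

Qualitative genomics ("mutation", "deletion") must become quantitative
modifiers. The magnitudes below are conventions, exposed in
`overlay_params()` and documented rather than hidden:

| aberration | modifier | default |
|---|---|---|
| oncogenic (GOF) mutation | basal override | 0.9 |
| tumor-suppressor (LOF) mutation | activity multiplier | 0.1 |
| amplification | production scaler | × 2.0 |
| deletion | production scaler | × 0.0 |
| receptor absent | production scaler | 0 |

A GOF override of 0.9 makes the node constitutively driven and hence
ligand-independent: clamping an upstream cytokine across its full range
moves the JAK2-V617F node's steady activity by under 5% on the HEL
fixture. Zygosity is not modeled; a heterozygous deletion can be expressed
with a magnitude override (e.g. 0.5). The curated oncogene /
tumor-suppressor annotation covers exactly the fixture genes; anything
else requires an explicit functional call in the profile.

## 4. Pharmacology conventions

Dose–response is modeled at the point of mechanism: fractional inhibition
of each target node, $I(d) = d^h/(d^h + K_t^h)$. The package deliberately
makes no attempt at pharmacokinetics; doses are "post-ADME" abstractions.
Internal dose units are arbitrary — all public interfaces use multiples of
the **reference dose C**, defined by 60% inhibition of the primary target
and computed in closed form, $C = K_{primary}(0.6/0.4)^{1/h}$.

Selectivity rankings such as `JAK2>JAK3>>JAK1>>>TYK2` are ordinal; the
quantitative spacing is undefined in the public record. We expand them
with a configurable fold base of 5 per `>` (25 per `>>`, 125 per `>>>`),
cumulatively — so only the *order* of target engagement is a tested
contract, not the absolute secondary-target doses.

The viability IC50 is the *minimal dose achieving at least 50% reduction*
— a grid scan on the monotone-processed curve refined by bisection on
re-simulated doses (relative tolerance `1e-3`), not by interpolating curve
values, so the returned dose genuinely achieves the level when re-run.
Synergy follows Loewe additivity: the isobologram traces the 50%
iso-effect contour of a full-factorial combination grid (linear
interpolation along grid rows; rows past a single agent's axis intercept
contribute no contour point), and each pair gets
$CI = d_A/IC50_A + d_B/IC50_B$ with an additivity band of ±0.05. Bliss
independence is not used for verdicts.

## 5. Phenotype indices and weight calibration

The phenotype indices follow the platform convention: proliferation
averages the four active CDK–cyclin complex activities; viability is
survival ÷ apoptosis with the marker sets given in `index_definition()`.
The complexes are first-class AND-gated nodes so that the index markers
exist in the network; cleaved PARP and BIM are effector readouts
downstream of the caspase and AKT/ERK arms, not index members.

The original biomarker weights are not public. Uniform weights are the
shipped default, and `calibrate_weights()` reproduces the documented
*procedure*: an exhaustive search over a simplex lattice (step 0.1, plus
the exact uniform point) maximizing the count of correctly-signed
qualitative trends, ties broken toward uniform. Survival and apoptosis
weights are searched jointly so viability-direction rows can be scored.
The closed-loop test generates trends from hidden weights and verifies the
calibration recovers a weight vector reproducing every sign — sign
recovery, not weight identification, is the contract, since many weight
vectors can explain the same qualitative table.

A percent change within ±0.5 percentage points counts as "unchanged" when
directions are called.

## 6. The bundled MPN fixtures

The curated network (51 nodes, 81 edges) is the smallest closure
containing: the JAK2-driven arms (STAT5/STAT3/STAT1, PI3K–AKT, SHC1–MEK–ERK,
NF-κB), the tumor-suppressor/cell-cycle axis (TP53, CDKN2A, RB1–E2F1,
cyclins, CDK–cyclin complexes), the survival and apoptosis index markers
with their cross-talk (BCL2-family brakes on BAX; IAP-family brakes on
caspases; NOXA–MCL1), and the three cytokine receptor axes. HEL carries
JAK2 and TP53 mutations, CDKN2A and RB1 deletions and an E2F1
amplification; SET2 carries the seven documented mutations. Both lack the
IL-6 receptor. The SET2 copy-number list in the public record is not fully
printed; the bundled profile is deliberately partial.

Edge weights were calibrated once, in `scripts/build_fixtures.R`, until
the fixture reproduces the qualitative results pattern — both single
agents reach the 50% viability level inside the C/1000–10C sweep; the
sub-IC50 combination crosses (half of one IC50 plus a third of the other)
reach the level, i.e. CI ≤ 5/6; TNFα strictly potentiates the JAK2
inhibitor at mid-range doses; IFNγ and IL-6 do not — and then frozen
(hashes pinned in the tests). Two calibration choices are worth recording:

* **TNFα potentiation** required near-saturating, steep IAP-family brakes
  (BIRC2 ⊣ CASP8, XIAP ⊣ CASP3 with Hill 2). With weak brakes, TNFα
  merely raises the apoptosis baseline and *dilutes* the drug's relative
  effect; with strong brakes, TNFα's extrinsic drive stays masked at
  baseline and is unmasked precisely when JAK inhibition collapses the
  STAT5/AKT-driven survival arm — the interaction the potentiation claim
  is about.
* **IFNγ** is wired through wild-type JAK1/JAK2 to STAT1 with a weak
  survival contribution (STAT1 → MCL1, weight 0.2). Since the mutant JAK2
  is constitutively active, IFNγ has little room to add drive; its net
  effect is mild de-sensitization of single agents, and the tested claim
  is the conservative one — no potentiation.

The synthetic-network generator (`generate_random_network`) exists for
property testing: seeded, self-loop-free, spanning-connected topologies on
which boundedness, monotonicity and solver-equivalence properties are
exercised independently of the curated fixture.

## 7. What passing tests show — and what they do not

The fixtures emulate the *logic* of a JAK2-V617F disease network, not its
kinetics: activities are normalized, doses are in C-multiples, and no
quantitative statement about μM axes, absolute viability percentages of
cultured cells, or timing in wall-clock hours is made or tested. What the
test suite establishes is protocol conformance (dose convention, stage
horizons, steadiness, vehicle normalization), internal mathematical
soundness (bound preservation, solver cross-checks against closed forms
and a fixed-step Euler reference at `1e-3`, Loewe sham additivity), and
reproduction of the *sign structure* of the published cell-line results.
Real tumor profiles have hundreds of aberrations against a network three
orders of magnitude larger; conclusions from this desk-scale avatar should
be read as methodological, not clinical.

Problem sizes were chosen to keep the full suite interactive: the 51-node
network integrates a protocol stage in well under a second, dose sweeps
use 25 grid points, combination grids 6×6–7×7, and the acceptance checks
run in a few minutes end to end.

## 8. Known limitations

* The dynamics family is a declared stand-in; none of its parameters are
  fitted to data, so only directions and orderings are meaningful.
* Proliferation is reported as an independent readout and does not enter
  normalized viability; the underlying platforms are ambiguous on this.
* Epigenetics, metabolism, DNA-repair and ER-stress sub-networks are out
  of scope; their absence biases the avatar toward signaling-dominated
  explanations.
* Selectivity spacing (fold base 5) and overlay magnitudes are
  conventions; analyses that depend on their absolute values, rather than
  on orderings, are outside the package's claims.
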