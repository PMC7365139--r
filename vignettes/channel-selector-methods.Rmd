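---
title: "Models and methods behind csmux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind csmux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmux)
```

# The system being modeled

A genetic *channel selector* (CS) lets one diffusible signal carry several
transcriptional conversations. A multiplexer (MUX) strain reads two inducer
inputs and a SELECT line, forwards the selected input as LuxI expression,
and the resulting acyl-homoserine lactone (AHL) diffuses to a demultiplexer
(DEMUX) strain that routes the signal to one of two outputs under the same
SELECT. All logic is built from CRISPRi transcriptional gates: a promoter
repressed by one sgRNA is a NOT gate; adding a second input promoter
transcribing the same sgRNA makes it a NOR gate. `csmux` implements the
computational side of this design cycle: logic synthesis, transfer-function
modeling, circuit composition and co-culture simulation, orthogonal
sgRNA:promoter library design, and the population-level cytometry
statistics used for evaluation, with a synthetic-data generator standing in
for the wet-lab measurements.

# Logic synthesis

`synthesize_minimal()` performs exhaustive iterative-deepening search over
the total NOT/NOR gate count, so the returned network is provably minimal
under its conventions:

* **Basis.** NOT (one input) and NOR (two distinct inputs). NOR(a, a) is
  excluded: it computes NOT(a) at the same cost, and the declared
  tie-break (fewer NOR among equal-count, equal-depth solutions) always
  prefers the NOT form, so the restriction never changes results.
* **No constant signals.** An absent promoter reads as logic 0; there is no
  tie-to-1 wire in the biological setting, so constants must be computed if
  needed.
* **Terminal outputs.** Each circuit output is a dedicated gate whose
  signal is not reused internally (`outputs_terminal = TRUE`). The output
  promoter's job is to drive a payload — LuxI or a reporter — not further
  sgRNAs. This convention matters: if outputs may feed gates, a 3-gate
  2-output DEMUX exists (the second output computed from the first), one
  gate below the canonical 2 NOT + 2 NOR two-layer design. Under the
  terminal convention the canonical design is the provable minimum. The
  unconstrained search remains available via `outputs_terminal = FALSE`.
* **Determinism.** Among minimum-count solutions, ties break by fewer
  layers, then fewer NOR gates, then the lexicographically smallest
  serialized netlist.

```{r}
synthesize_minimal(tt_mux())$metrics # 1 NOT + 3 NOR, 3 layers
synthesize_minimal(tt_demux())$metrics # 2 NOT + 2 NOR, 2 layers
```

`build_cs_network()` constructs n-channel channel selectors in two styles —
a tree of 2-input cells (`recursive`) or flat minterm decoding
(`two_layer`) — and reports constructive metrics via `network_metrics()`.
Closed-form scaling laws are deliberately not asserted; the counts are
produced by building the network and measuring it. Within a strain one
inverter per distinct select line is shared; the MUX and DEMUX halves live
in different strains and share nothing.

# Gate and sensor models

Every node's signal is its *reporter-equivalent fluorescence* in
molecules-of-equivalent-fluorescein (MEFL), matching a measurement scheme
in which each promoter of interest is probed by a standard insulated
reporter. This one currency is what lets independently fitted gate models
compose into circuit predictions.

* NOT gate (repression): `y = y_min + (y_max - y_min) / (1 + (x/K)^n)`.
* NOR gate: both input promoters transcribe the same sgRNA, so fluxes add
  before the nonlinearity: `nor(x1, x2) = not(x1 + x2)`.
* Sensor (activation): `y = y_min + (y_max - y_min) (c/K)^n / (1 + (c/K)^n)`
  with `c` an inducer concentration in its own units.

`fit_transfer_function()` fits `log10(model)` to `log10(y)` because
fluorescence spans decades and both asymptotes matter equally. Numerical
choices: parameters are optimized on a log10 scale with bounds
`y_min` in [floor, min(y)], `y_max` in [max(y), 10 max(y)], `K` within one
decade of the observed inputs and `n` in [0.5, 4]; `K` is multi-started at
the data quartiles and (for free-n fits) `n` at 1 and 2, keeping
Levenberg-Marquardt off local minima; convergence tolerances are tightened
(`ftol = ptol = 1e-14`) so noiseless data are recovered to machine
precision. Flat datasets are returned as degenerate fits with `K` and `n`
flagged unidentifiable rather than fabricated. Because the n = 1 model is
nested in the free-n model, its residual error can never be smaller;
`compare_hill_fits()` exposes both fits with an AIC comparison rather than
hard-coding a preference rule.

# Circuit composition and dynamics

`steady_state()` evaluates a circuit in one topological pass. Dynamics use
one ordinary differential equation per node,

`dX/dt = lambda (f(upstream) - X)`,

where `f` is the node's Hill response and `lambda` the strain growth rate:
production balances dilution-by-growth, so the long-time limit under a
constant environment equals the topological steady state (a tested
invariant). Model assumptions follow the experimental regime: dCas9 is in
excess and dCas9:sgRNA complexes form quickly and are stable, so repression
depends only on the sgRNA-producing promoter's output; LuxI is stable and
tracks its driving promoter with the same first-order lag.

The AHL wire obeys `dA/dt = sum(k_prod * OD_sender * LuxI)` with the
production rate `k_prod` in nM/h per OD600 per MEFL (default 0.089 for the
full CS circuit) and no intrinsic degradation. Media-replacement events
scale ODs — and by default AHL, since fresh medium contains none — by the
retained volume fraction; a flag disables AHL dilution. Because pure
accumulation has no steady state, `steady_state()` reports a quasi-steady
wire level `k_prod * od_sender * LuxI * ahl_exposure_h`, by default the
amount accrued over one 1.5-h dilution interval at OD 0.2; both are
explicit arguments.

Integration uses deSolve's lsoda with relative tolerance 1e-6, restarted
at dilution events; at a boundary the recorded sample holds the
post-dilution state so trajectory times stay strictly increasing.
`activation_time()` reports the first upward crossing of
`y_min + f (y_max - y_min)` with linear interpolation; the threshold
fraction is a parameter because "activation" of a rising reporter is not
otherwise sharply defined. `estimate_ahl_rate()` inverts the biosensor's
activation Hill over its strictly monotone range (saturated readouts are
flagged and excluded) and regresses the inferred AHL against the
trapezoidal integral of OD x LuxI through the origin.

The shipped `cs_circuit()` uses synthetic but digitally consistent default
parameters (gates: y_min 50, y_max 20,000 MEFL, K 2,000 MEFL, n 2; AHL
receiver K 30 nM): every gate's low output lands well below the next
gate's repression threshold and the leaky sender's off-state AHL stays
well below the receiver threshold over one dilution interval. They are
fixture values for exercising the engine, not fitted constants. Known
limitations carried deliberately: no dCas9 competition or saturation term
(the experimentally observed receiver-saturation fault is representable
only as an alternative parameter set), no fluorophore maturation delay, no
growth-burden feedback, and a well-mixed AHL pool with no spatial effects.

# Orthogonal sgRNA:promoter library design

The design pipeline mirrors the library construction logic end to end:

1. **Pre-sequences** — 15-nt cores (14 operator nt + 1 degenerate PAM nt)
   drawn with 40% GC bias (G = C = 0.2, A = T = 0.3 per position).
2. **Construction** — the pre:GG insert sits between a scaffold's -35 and
   -10 hexamers; the sgRNA operator is the 6 -35 nt plus the 14 5'-most
   pre nt, followed by an 82-nt constant handle. The scaffold table ships
   sigma70-consensus-like hexamers for the strong synthetic scaffold and
   TTGACT/GATAAT for the lambda-PR scaffold, plus a 6-bp downstream
   context; all fields are user-replaceable, since the package does not
   curate plasmid sequences. Designs gaining more than one NGG or any NAG
   relative to the bare scaffold (both strands counted — dCas9 can engage
   a PAM on either strand) are rejected, as are designs containing a BsaI
   site; BsaI is reported first because a Golden Gate incompatibility is
   absolute and its site always also registers as a strand-reversed PAM
   gain. With both strands counted the acceptance rate is a few percent,
   so a large draw funnels down to the accepted library — the intended
   shape of the procedure.
3. **Off-target screen** — three ordered rules: a >= 10-nt 3' match of the
   operator:PAM overlapping an essential feature; a >= 12-nt 3' match
   anywhere; and a 13-nt seed match with at most one mismatch adjacent to
   NGG or NAG. Both strands are scanned (Biostrings), coordinates are
   0-based half-open, and the degenerate PAM position is matched literally
   as the concrete base each design carries. The full published scoring
   algorithm behind the seed rule is replaced by this operational rule,
   which is what the screen enforced in practice.
4. **Diversity selection** — the complete match graph weights every pair
   of pre-sequences by co-occurring nucleotides (0-15). A two-phase
   heuristic (ascending-edge vertex collection, then swap-in/discard-worst
   refinement passes whose total weight provably never increases) yields a
   low-similarity core; random expansion of all pairs with weight <= 5
   produces maximal candidate sets; a linear score with weights ascending
   toward the 3' end (default 1..15 — the exact published weights are not
   stated, so they are configuration) picks the most seed-divergent set,
   ties broken lexicographically.
5. **Insulation** — 70-nt random insulators are rejection-sampled against
   a forbidden-motif catalog (sigma70 hexamers, a strong Shine-Dalgarno,
   BsaI and common cloning sites, homopolymer runs — a documented starting
   catalog, not a regulatory-site database) on both strands, then
   truncated from the 5' end to bring each promoter to exactly 105 bp.

# Synthetic cytometry data

The generator reproduces the statistical structure the analysis relies on:
log-normal single-cell fluorescence spanning decades with an additive
autofluorescence floor on FL1, log-normal FL3 (MECY) for strain
classification, correlated log-normal FSC/SSC nuisance channels to
exercise density gating, default event counts of 20,000-30,000, inducer
dose grids at the characterization concentrations, two-strain mixtures at
specified ratios with true labels retained, and 9 x 9 orthogonality panels
(81 combinations). Population variance is not a published quantity; the
default 0.2-decade SD is a fixture choice. The generator does not emulate
instrument optics, detector saturation, calibration-bead processing,
day-to-day drift, or the growth-burden and dCas9-saturation effects seen
in real circuits — so green round-trip tests certify the estimators'
correctness on data satisfying the model assumptions, not performance on
real cytometry files.

# Evaluation rules

* **RMSE in MEFL decades**: root mean square of
  `log10(predicted) - log10(measured)` over pairs; any pair containing a
  zero is omitted, and an all-zero comparison is an explicit error.
* **Density gate**: a deterministic 64 x 64 histogram on (log FSC,
  log SSC) serves as the density estimate — reproducible where kernel
  choices are not — and exactly `round(fraction * n)` top-ranked events
  are retained (fraction 0.85 by default), ties broken by acquisition
  order.
* **FL3 classification**: events at or above the threshold take the high
  label (boundary equality high, a declared convention); per-class mean
  FL1 is the arithmetic mean of linear MEFL, as all means are here.
* **Binning**: 64 log bins over the sample's value range with the peak
  normalized to 0.5 (frequency mode), or 125 log bins from 10 to 1e6 MEFL
  (25 per decade) with `floor(0.01 n)` events trimmed from each tail and
  the mean computed before trimming (violin mode). Trimming is applied
  per sample, not per panel — the finer-grained reading of an ambiguous
  rule.
* **Fold repression** is reported as off/on (uninduced over induced), so
  values above 1 indicate repression.

# Test and simulation scale

The suite runs at desk scale by choice: synthesis searches stop at 5-6
gates (enough to certify the 4-gate minima by exhaustion), oracle genomes
are 4-50 kb with planted motifs rather than full genomes, library-design
pipeline tests draw a few thousand pre-sequences with cores of 12-20, and
ODE consistency checks use 3-gate circuits over 12-20 simulated hours.
The deposited measured/simulated fluorescence tables are not
redistributable with the package, so the printed model-vs-data RMSE values
are covered by a test that activates when the corresponding CSV is placed
under `inst/extdata/`; everything else is generated in code at run time.
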