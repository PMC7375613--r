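---
title: "Whole-cell translation with shared ribosome and tRNA pools: model and methods"
author: "ribopool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell translation with shared ribosome and tRNA pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ribopool` simulates mRNA translation for an entire cell at codon
resolution. Three levels are coupled:

* **Cell level.** The cell holds `N` mRNA molecules, a ribosome pool of
  fixed size `G_tot` and a tRNA pool of fixed size `H_tot` split over
  species `j` with totals `H_tot,j`. Pools are conserved exactly: at every
  tick, free + bound ribosomes equal `G_tot`, and for each species free +
  on-mRNA molecules equal `H_tot,j`. A released (deacylated) tRNA returns
  to the free pool instantly — re-aminoacylation kinetics are not modeled.

* **mRNA level.** Each mRNA is a lattice of codons on which ribosomes move
  5'→3' under a generalized deterministic TASEP: ribosomes have a footprint
  of `s` codons, never overlap (A-site gap ≥ `s`) and never overtake.
  Every translation step is governed by a count-down timer in units of the
  tick `ΔT`; a step whose timer has expired but whose physical conditions
  are unmet (no free ribosome, downstream ribosome too close, decoders
  exhausted) is delayed by exactly one tick and retried.

* **Codon level.** Each active position runs a small state machine:
  `AWAIT_TRNA` (the A-site codon needs a charged tRNA; the codon is counted
  in the live demand ledger), then tRNA incorporation, then `ELONGATING`
  (a fixed translocation delay), then the move, which releases the tRNA
  that has reached the E-site. Termination is instantaneous when the A-site
  leaves the last sense codon; both remaining bound tRNAs are released so
  the ledger never leaks. State transitions update all demand counters
  incrementally, never by rescanning.

Randomness enters in exactly three places, all driven by R's RNG (so
`set.seed()` gives bit-identical runs): the per-tick mRNA visiting order (a
fresh uniform permutation each tick, to avoid resource-allocation bias),
the choice among decoding tRNA species, and the fractional-copy Bernoulli
draw at transcriptome instantiation.

# Supply-demand ratios and timers

Two live statistics couple the lattices to the pools:

* **RSDR** (ribosomal supply-demand ratio): free ribosomes divided by the
  number of mRNAs currently awaiting an initiation complex.
* **ESDR** of codon `c`:

  $$\mathrm{ESDR}(c,t)=\sum_{j\in RT(c)}
    \frac{\alpha(c,j)\,H_j(t)}{\max(D_j(t),1)^{\,1-e^{-w d_c}}}$$

  where `RT(c)` is the set of tRNA species that decode `c`,
  `α(c,j) ∈ (0,1]` the interaction coefficient (1 for Watson-Crick, lower
  for wobble), `H_j` the free count, and `D_j = Σ_c α(c,j)·demand(c)` the
  interaction-weighted count of codons currently awaiting a tRNA that `j`
  could serve. The demand is floored at 1 so the expression is finite at
  zero demand; with exponent 0 the floor is inert.

The recycling term works through the per-codon distance score `d_c`: the
copy-weighted mean, over all occurrences of `c` in the transcriptome, of
the downstream distance to the nearest codon sharing a decoder, capped at
the inclusive distance to the ORF 3' end when none follows. Codons that
tend to sit near co-decoded codons can reuse just-released tRNAs, so their
effective demand is discounted (exponent near 0); isolated codons feel the
full per-species competition (exponent near 1). The normalization `w` is
fixed by requiring the median exponent over codons to be 1/2; codons absent
from the transcriptome receive the median observed score. Both the score
definition and `w` are package choices (the statistic is defined only
qualitatively at this level) and are exposed through `recycling_params()`.

Timers map ratios to waits by the simplest monotone form consistent with
"more supply per demand means shorter waits":
`T = scale / max(SDR, ε)` seconds, quantized to `max(1, round(T/ΔT))`
ticks (half-away-from-zero rounding, identical in R and C++). Initiation
uses the gene's local initiation time rescaled by `rsdr_ref / RSDR`, so at
the reference ratio an mRNA initiates at exactly its local time. The
deterministic-timer approximation assumes waits are short relative to pool
turnover; the engine counts waits exceeding `warn_wait` (default 30 s) and
reports them, rather than silently entering the regime where the
approximation degrades.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `ΔT` (`dt`) | 0.05 | s | resolves per-codon dynamics (~1–10 ticks/codon) |
| `s` | 10 | codons | standard ribosome footprint |
| `transloc_ticks` | 1 | ticks | fixed translocation delay |
| `scale_elong` | 25 | s·ESDR | places typical waits at 1–5 ticks in the toy cell |
| `rsdr_ref` | 10 | – | reference RSDR at which initiation runs at local time |
| `sdr_floor` | 1e-6 | – | keeps waits finite under total starvation |
| mean initiation time | 0.95 | s | full-cell preset value |
| `N` | 5,100 | molecules | full-cell preset |
| `G_tot` | 70,000 | ribosomes | full-cell preset |
| `H_tot` | 650,407 | tRNAs | full-cell preset; ribosome:tRNA ratio preserved under scaling |

The desk-scale fixture (`toy_cell()`) keeps the ribosome:tRNA ratio but
divides the pools by ten (`G_tot = 7,000`, `H_tot = 65,041`) and uses 50
gene types, 500 molecules and 30–60-codon ORFs, so whole runs finish in
seconds on one CPU. Conservation, exclusion and determinism are exact at
any scale, so the scaled tests establish the same invariants as a full
cell; only throughput-dependent quantities are scale-specific.

# Codon-tRNA recognition

The package ships a rule-generated eubacterial recognition table
(`default_wobble_rules()`): per amino acid and codon box, C/U-ending codons
are read by a G34 anticodon (Watson-Crick + G:U wobble), A-ending codons by
a U34 anticodon whose modified uridine also reads the G-ending codon of the
family, with a dedicated C34 isoacceptor sharing those G-ending codons in
split boxes; the Arg CGN box uses an inosine anticodon (I:U, I:C, I:A) plus
a C34 species for CGG, and Ile AUA has a lysidine-like dedicated reader.
Every sense codon is covered, and the canonical sharing structure holds
(e.g. tRNA-Gly-UCC reads GGA and GGG while tRNA-Gly-GCC reads GGU and GGC),
which is the structure that makes heterologous-variant competition
analyses interesting. The default per-class coefficients (`gu` 0.64, `ug`
0.41, `iu` 0.90, `ic` 0.72, `ia` 0.10, `k2c` 0.90) follow the relative
ordering of tAI-style constraints and keep every codon decodable at a
realistic relative efficiency; they are data, not dogma — any table can be
loaded from TSV, and `optimize_interaction_coefficients()` refits the
wobble-class coefficients against expression targets by per-class grid
search with coordinate ascent (Watson-Crick pinned at 1). Where two target
vectors are supplied the objective is the **sum of their Spearman
correlations** with per-gene tAI; this aggregation is a package choice and
is the default rather than the only option.

tAI weights follow the standard construction (interaction-weighted supply,
max-normalized, zero-supply codons get the geometric mean of nonzero
weights); CAI weights are within-family relative frequencies from a
reference set with a 0.5 pseudo-count for unseen codons. The start codon
is scored like any Met codon; stop codons carry no weight and are not part
of the lattice.

# Calibration

* **Pool sizes** (`calibrate_pools()`): bisection in log scale over one
  global factor multiplying `G_tot` and every tRNA species (the
  ribosome:tRNA ratio is held fixed; per-species rebalancing is out of
  scope), until the post-steady active-ribosome fraction
  `%AR = 1 − mean(G_free)/G_tot` reaches the 80% target. `%AR` is monotone
  nonincreasing in the scale over the bracket — fewer ribosomes chase the
  same lattice capacity — which the bisection relies on and the tests
  check. Each evaluation reseeds identically, making the objective a
  deterministic function of the scale.
* **Initiation times** (`calibrate_initiation()`): multiplicative
  normalization to a transcriptome mean of 0.95 s (exact, order-preserving),
  with an optional short pilot run that warns when ribosomal density falls
  outside 0.1–0.3 ribosomes per 10 codons (the configurable default for
  the "expected range").
* **Steady state**: the first tick at which the relative range of the free
  ribosome trajectory over a trailing window (300 ticks) is ≤ 1%. The
  definition is verbal in the source material; the trailing-window range is
  the package's concrete form, and non-steady runs are flagged while
  falling back to the trailing window so pilot statistics stay comparable.

# Heterologous expression and variants

A payload ORF is inserted at 20% of the post-insertion molecule count
(native levels untouched). Its initiation time is `τ_h·exp(−FE/c_h)`:
tighter 5' folding (more negative `FE`, kcal/mol) slows initiation. `FE` is
an input — RNA folding is deliberately not computed here — and `c_h` can be
fit with a generic 1-D grid calibration against any target vector
(`calibrate_ch()`). Variant generation: method 1 recodes every amino acid
to its highest-scoring codon under a chosen per-codon score (typical
decoding rate, mean ESDR, inverse mean occupancy), ties broken
lexicographically; method 2 emits one variant per sense codon (all 61,
degenerate ones included and flagged). Four genome randomizations cover the
preservation combinations of codon usage at ORF vs genome level, exact
(permutation) vs in expectation (resampling); all four preserve every
protein sequence exactly. The mapping of the four modes to the original
four randomization types is reconstructed from their stated preservation
properties and is configurable.

# Regression machinery

`forward_select()` repeats a random ~67/33 train/test split `N_rep = 100`
times; within each repetition features are added greedily by maximal
R-squared change, evaluated on the held-out test set by default (the
description of where R² is measured is ambiguous; the test set matches the
overfitting behavior the procedure is meant to expose, and a switch
selects the training set instead). A feature picked i-th contributes `i`
to its SCR score; features never picked in a repetition contribute
`M + 1`. Ties in R² improvement break by feature-name order for
determinism. The per-repetition cap on selected features defaults to 15,
matching the observed onset of overfitting near ten features; it is a
parameter, not a law.

# What the synthetic generator does and does not emulate

`generate_transcriptome()` produces in-frame ORFs (AUG start, UAA stop)
with a geometric within-family codon bias ranked by pooled decoding
weight — mimicking codon-usage/tRNA co-adaptation — log-normal mRNA levels
(σ_log = 1) rescaled to the target molecule count, and log-normal local
initiation times normalized to the 0.95 s mean. `generate_trna_pool()`
apportions `H_tot` exactly (largest-remainder) with fractions proportional
to interaction-weighted codon demand, perturbed by log-normal noise
(σ_log = 0.25). These choices produce a self-consistent cell in which all
machinery is exercised without stalling artifacts.

They do **not** reproduce: real codon usage of any organism, the 5' ramp,
length-expression correlations, operon structure, measured tRNA
abundances, or ribo-seq noise models. A green test on synthetic data
therefore establishes mechanical correctness (conservation, exclusion,
timer arithmetic, calibration convergence, recovery of planted signal),
not empirical predictive power; the published correlations against
protein-abundance and profiling data require external datasets and are
out of scope by design.

# Numerical choices and degenerate inputs

* Timer quantization: half-away-from-zero rounding with a 1-tick floor,
  identical in the R helper and the C++ engine.
* Supply-demand ratios are floored at `1e-6` before division; demand at 1
  inside the ESDR denominator.
* A single available decoder is taken without consuming randomness, which
  keeps RNG streams aligned between runs that differ only in pool sizes
  (used by the starvation-monotonicity property).
* Zero-level genes contribute no lattice; an empty transcriptome is a
  well-defined no-op. Empty ORFs, internal stops, out-of-range
  coefficients, unknown tRNA ids, and releases of unbound species raise
  errors immediately.
* `insert_heterologous` rounds the payload to whole molecules; the share
  is exact within 1/total.

# Known limitations

Deterministic timers approximate the stochastic elongation process; the
approximation degrades under severe resource depletion (tracked by the
long-wait counter rather than corrected). Pools are constant — no
degradation, synthesis, or division. Termination is instantaneous, there
is no ribosome drop-off, frameshifting or collision-induced abortion, and
the codon state machines are a behavioral reconstruction at four states;
finer-grained machine inventories would slot into the same engine loop.
The CLI accepts JSON configuration only (no YAML parser in the supported
dependency set).
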