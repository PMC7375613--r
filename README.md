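# ribopool

Whole-cell, codon-resolution simulation of mRNA translation with shared,
conserved pools of ribosomes and tRNAs.

## The problem

Most translation models either resolve single mRNAs at codon level while
ignoring the rest of the cell, or treat the cell in bulk while ignoring
codon-level dynamics. Yet the phenomena that matter for heterologous
expression, synonymous recoding and codon-usage evolution live exactly at
the intersection: thousands of mRNAs compete for a finite ribosome pool and
for finite, wobble-shared tRNA species, so recoding one gene changes the
decoding speed of every other gene that shares its tRNAs. `ribopool` is for
systems/synthetic-biology work that needs that coupling: it simulates a
full transcriptome as a set of generalized deterministic TASEP lattices
(exclusion by a ribosome footprint of *s* codons, no overtaking) driven by
countdown timers whose durations respond to live supply-demand statistics.

## The model in brief

Ribosome availability enters through the ribosomal supply-demand ratio
RSDR = G_free / #(mRNAs awaiting initiation). tRNA availability enters
through the per-codon effective supply-demand ratio

    ESDR(c, t) = Σ_{j ∈ RT(c)}  α(c,j) · H_j(t) / max(D_j(t), 1)^(1 − exp(−w·d_c))

where α(c,j) ∈ (0,1] weights Watson-Crick vs wobble decoding, H_j is the
free count of tRNA species j, D_j the α-weighted number of codons currently
awaiting a tRNA that j could serve, and the exponent implements tRNA
recycling: codons that sit close to co-decoded codons (small distance score
d_c) feel less of the demand. Expected waits are `scale / SDR`, quantized
to ticks of ΔT = 0.05 s. Pools are conserved exactly at every tick.

On top of the engine the package provides: tAI/CAI codon indices with
wobble-coefficient optimization; pool-size calibration to 80% ribosomal
activity and initiation-time normalization to a 0.95 s mean; heterologous
payload insertion at 20% of the transcriptome with folding-energy-dependent
initiation τ_h·exp(−FE/c_h); two synonymous-variant generators and four
genome randomization modes; a repeated train/test greedy forward-selection
regressor with SCR feature ranking; and a synthetic-data module that
generates every input the simulator consumes, so the whole pipeline runs
offline. Full-cell preset: N = 5,100 mRNAs, G_tot = 70,000 ribosomes,
H_tot = 650,407 tRNAs.

## Worked example

```r
library(ribopool)

cell <- toy_cell(seed = 1)          # 50 genes, 500 molecules, pools /10
set.seed(1)
sim <- run_simulation(cell$cfg, cell$lattices, cell$table, cell$rec)
sim
#> simulation_result: 500 lattices, 2000 ticks, steady@471, %AR=0.261,
#>   19390 terminations (15680 post-steady)

head(sort(sim$rate, decreasing = TRUE), 5)   # proteins per second, per gene
#>     g031     g015     g020     g025     g004
#> 28.08371 24.91825 22.07979 16.70373 10.58208

cal <- calibrate_pools(cell$cfg, cell$lattices, cell$table, cell$rec)
#> calibrated G_tot = 846, achieved %AR = 0.814 (scale 0.121, 6 iterations)

v <- variants_method2(gfp_payload())         # 61 synonymous variants
#> variants: 61   degenerate: 2

insert_heterologous(cell$levels, 0.20, "gfp")["gfp"]
#> payload copies: 125 (20.0% of 625 molecules)
```

The first run shows the raw toy cell: steady state is reached at tick 471,
after which 15,680 termination events define the per-gene synthesis rates;
only 26% of ribosomes are active because the tenth-scale pools are generous
for 500 short mRNAs. `calibrate_pools` then shrinks both pools by a common
factor (ribosome:tRNA ratio fixed) until 80% of ribosomes are engaged —
the physiological operating point. The variant and payload calls set up a
heterologous-expression experiment: simulate each variant with
`run_simulation`, collect per-codon mean ESDR features with
`esdr_feature_table`, and rank features with `forward_select`.

## Command line

```sh
Rscript inst/cli/ribopool.R synth    --config cfg.json --outdir inputs
Rscript inst/cli/ribopool.R simulate --config run.json --outdir out
# also: calibrate | variants | randomize | regress
```

Every run writes TSV outputs plus a `manifest.json` (config snapshot, seed,
input checksums) sufficient to re-run bit-identically.

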