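# Shared fixtures: all built in code, no files.

# One dedicated Watson-Crick tRNA per sense codon: single-decoder table with
# alpha = 1 everywhere, convenient for closed-form engine oracles.
wc_table <- function() {
  sense <- sense_codons()
  build_recognition_table(
    data.frame(codon = sense, trna_id = paste0("t_", sense),
               class = "watson_crick"))
}

# Two-decoder toy: GGG read by a Watson-Crick and a 0.5-wobble species.
ggg_table <- function() {
  build_recognition_table(
    data.frame(codon = c("GGG", "GGG"),
               trna_id = c("tRNA-Gly-CCC", "tRNA-Gly-UCC"),
               class = c("watson_crick", "wobble")),
    class_coeffs = c(watson_crick = 1, wobble = 0.5), partial = TRUE)
}

# Recycling parameters with all distance scores zero (demand exponent 0).
rec_zero <- function() {
  recycling_params(stats::setNames(rep(0, 61), sense_codons()), 0)
}

# Saturating per-species pool for a table (default: effectively infinite).
full_pool <- function(table, n = 1e6) {
  stats::setNames(rep(n, length(table$trna_ids)), table$trna_ids)
}

# Random all-sense ORF as a codon vector (no stop).
random_orf <- function(len, codons = sense_codons()) {
  sample(codons, len, replace = TRUE)
}

# Small self-contained engine world: one or more lattices over wc_table().
engine_world <- function(orfs, init_time = 0.5, G_tot = 100,
                         H = 100, cfg = engine_config(rsdr_ref = G_tot)) {
  tb <- wc_table()
  lats <- lapply(seq_along(orfs), function(i)
    mrna_lattice(orfs[[i]], paste0("g", i), init_time))
  Hp <- if (length(H) == 1L) full_pool(tb, H) else H
  list(table = tb, rec = rec_zero(), cfg = cfg, lattices = lats,
       G_tot = G_tot, H = Hp)
}

run_world <- function(w, ticks, seed = 1, record_positions = FALSE) {
  set.seed(seed)
  run_engine(w$lattices, w$table, w$rec, w$cfg, w$G_tot, w$H, ticks,
             record_positions = record_positions)
}

# Per-tick footprint / ordering violations from a recorded positions log.
count_violations <- function(positions, s) {
  gap_bad <- 0L; order_bad <- 0L
  for (pm in positions) {
    if (is.null(pm) || nrow(pm) == 0L) next
    for (li in unique(pm[, 1L])) {
      sub <- pm[pm[, 1L] == li, , drop = FALSE]
      sub <- sub[order(sub[, 3L]), , drop = FALSE]  # ascending position
      if (nrow(sub) > 1L) {
        gaps <- diff(sub[, 3L])
        gap_bad <- gap_bad + sum(gaps < s)
        # earlier-placed ribosomes (smaller id) must sit further downstream
        order_bad <- order_bad + sum(diff(sub[, 2L]) > 0)
      }
    }
  }
  c(gap = gap_bad, order = order_bad)
}
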