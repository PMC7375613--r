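#' Folding-energy-dependent heterologous initiation time
#'
#' `tau_h * exp(-FE / c_h)`: a more negative 5' folding energy (tighter mRNA
#' structure around the start) yields a longer initiation time.
#'
#' @param FE Folding energy of the ORF 5' region, kcal/mol (typically <= 0).
#' @param tau_h Baseline initiation time, seconds.
#' @param c_h Positive calibration factor, kcal/mol.
#' @return Initiation time in seconds.
#' @export
heterologous_init_time <- function(FE, tau_h, c_h) {
  stopifnot(tau_h > 0, c_h > 0)
  tau_h * exp(-FE / c_h)
}

#' Calibrate the folding-energy factor against a target vector
#'
#' Generic 1-D grid search for `c_h`: picks the value whose implied
#' initiation *rates* `1 / heterologous_init_time(FE, tau_h, c_h)` best
#' Spearman-correlate with `target` (e.g. measured protein abundance).
#'
#' @param FE Folding energies of the variants.
#' @param target Per-variant objective values.
#' @param tau_h Baseline initiation time.
#' @param grid Candidate `c_h` values.
#' @return Best `c_h`, with attribute `objective`.
#' @export
calibrate_ch <- function(FE, target, tau_h = 0.95,
                         grid = exp(seq(log(0.5), log(50), length.out = 60))) {
  if (stats::sd(target) == 0) stop("constant target vector")
  obj <- vapply(grid, function(ch)
    stats::cor(1 / heterologous_init_time(FE, tau_h, ch), target,
               method = "spearman"), 0)
  structure(grid[which.max(obj)], objective = max(obj))
}

#' Insert a heterologous payload at a fixed fraction of the transcriptome
#'
#' Adds `round(f / (1 - f) * sum(levels))` payload copies so the payload
#' makes up `copy_fraction` of the new total molecule count (default 20%);
#' native levels are untouched.
#'
#' @param levels Named numeric vector of native mRNA levels.
#' @param copy_fraction Payload share of the post-insertion total, in
#'   `[0, 1)`.
#' @param payload_name Name for the payload entry.
#' @return Updated levels vector with the payload appended.
#' @export
insert_heterologous <- function(levels, copy_fraction = 0.20,
                                payload_name = "payload") {
  if (copy_fraction < 0 || copy_fraction >= 1)
    stop("copy_fraction must be in [0, 1)")
  if (payload_name %in% names(levels))
    stop("payload name collides with a native gene")
  payload <- round(copy_fraction / (1 - copy_fraction) * sum(levels))
  c(levels, stats::setNames(payload, payload_name))
}

#' Synonymous variant, method 1: one best codon per amino acid
#'
#' Replaces every codon by the highest-scoring synonymous codon under the
#' given per-codon score (e.g. typical decoding rate, mean ESDR, or inverse
#' mean occupancy); ties break to the lexicographically smallest codon. The
#' amino-acid sequence is preserved; a terminal stop is kept as is.
#'
#' @param orf Codon vector (terminal stop allowed).
#' @param scores `codon_scores` defined on all sense codons used.
#' @return Recoded codon vector.
#' @export
variants_method1 <- function(orf, scores) {
  orf <- codons_of(orf)
  gc <- genetic_code()
  sense <- sense_codons()
  best <- vapply(unique(gc[sense]), function(aa) {
    fam <- sort(synonymous_codons(aa))  # lexicographic tie-break
    w <- unclass(scores)[fam]
    if (anyNA(w)) stop("scores undefined for codon(s) of amino acid ", aa)
    fam[which.max(w)]
  }, "")
  unname(ifelse(gc[orf] == "*", orf, best[gc[orf]]))
}

#' Synonymous variants, method 2: one representative codon per variant
#'
#' For each of the 61 sense codons `x`, emits a variant in which every
#' synonym of `x`'s amino acid is replaced by `x` (all other amino acids
#' untouched). Exactly 61 variants are always returned; a variant equal to
#' the input (the amino acid is absent or already uniformly coded) is still
#' emitted and flagged in the `degenerate` attribute.
#'
#' @param orf Codon vector (terminal stop allowed).
#' @return Named list of 61 codon vectors (names = representative codon),
#'   with logical attribute `degenerate`.
#' @export
variants_method2 <- function(orf) {
  orf <- codons_of(orf)
  gc <- genetic_code()
  sense <- sense_codons()
  out <- vector("list", length(sense))
  names(out) <- sense
  degen <- stats::setNames(logical(length(sense)), sense)
  for (x in sense) {
    fam <- synonymous_codons(gc[[x]])
    v <- ifelse(orf %in% fam, x, orf)
    out[[x]] <- v
    degen[[x]] <- identical(v, orf)
  }
  attr(out, "degenerate") <- degen
  out
}

#' Randomize a genome's codon usage under four preservation regimes
#'
#' All four modes preserve every amino-acid sequence exactly; they differ in
#' what they preserve of codon usage bias (CUB):
#' * `orf_shuffle` - synonymous codons permuted within each ORF (each ORF's
#'   codon multiset, hence its CUB, preserved exactly);
#' * `genome_swap` - synonymous codons permuted across the whole genome
#'   (genome-level multiset preserved exactly, ORF-level scrambled);
#' * `orf_resample` - each codon redrawn i.i.d. from its own ORF's
#'   synonymous frequencies (ORF CUB preserved in expectation);
#' * `genome_resample` - redrawn from genome-wide synonymous frequencies
#'   (genome CUB preserved in expectation).
#'
#' @param orfs Named list of codon vectors (terminal stops kept in place).
#' @param mode One of the four modes above.
#' @return Named list of randomized codon vectors.
#' @export
randomize_genome <- function(orfs, mode = c("orf_shuffle", "genome_swap",
                                            "orf_resample",
                                            "genome_resample")) {
  mode <- match.arg(mode)
  orfs <- lapply(orfs, codons_of)
  gc <- genetic_code()
  aas <- setdiff(unique(gc[sense_codons()]), "*")

  shuffle_within <- function(codons) {
    aa <- gc[codons]
    for (a in unique(aa[aa != "*"])) {
      idx <- which(aa == a)
      if (length(idx) > 1L) codons[idx] <- codons[sample(idx)]
    }
    codons
  }
  resample_within <- function(codons, freq_by_aa) {
    aa <- gc[codons]
    for (a in unique(aa[aa != "*"])) {
      idx <- which(aa == a)
      f <- freq_by_aa[[a]]
      codons[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
    }
    codons
  }
  fam_freq <- function(codons_all) {
    out <- list()
    for (a in aas) {
      fam <- synonymous_codons(a)
      cnt <- table(factor(codons_all[gc[codons_all] == a], levels = fam))
      if (sum(cnt) > 0) out[[a]] <- cnt / sum(cnt)
    }
    out
  }

  switch(mode,
    orf_shuffle = lapply(orfs, shuffle_within),
    genome_swap = {
      pooled <- unlist(orfs, use.names = FALSE)
      aa <- gc[pooled]
      for (a in aas) {
        idx <- which(aa == a)
        if (length(idx) > 1L) pooled[idx] <- pooled[sample(idx)]
      }
      lens <- vapply(orfs, length, 0L)
      stats::setNames(
        split(pooled, factor(rep(seq_along(orfs), lens),
                             levels = seq_along(orfs))),
        names(orfs))
    },
    orf_resample = lapply(orfs, function(o)
      resample_within(o, fam_freq(o))),
    genome_resample = {
      freq <- fam_freq(unlist(orfs, use.names = FALSE))
      lapply(orfs, resample_within, freq_by_aa = freq)
    })
}
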