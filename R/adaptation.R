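#' Construct a named per-codon score vector
#'
#' Light container used for tAI/CAI weights, typical decoding rates, mean
#' ESDR values and similar per-codon quantities.
#'
#' @param values Named numeric vector over (a subset of) the 61 sense codons.
#' @param name Score label.
#' @return Object of class `codon_scores`: a named numeric vector over all 61
#'   sense codons (missing entries `NA`) with attribute `score_name`.
#' @export
codon_scores <- function(values, name = "score") {
  sense <- sense_codons()
  out <- stats::setNames(rep(NA_real_, length(sense)), sense)
  nm <- codons_of(names(values))
  out[nm] <- as.numeric(values)
  structure(out, score_name = name, class = c("codon_scores", "numeric"))
}

#' tAI codon weights from a recognition table and tRNA levels
#'
#' Raw weight `W(c) = sum_{j in rt(c)} alpha(c,j) * level(j)`, normalized by
#' the maximum so the best-adapted codon has weight 1. Codons whose decoders
#' all have zero abundance receive the geometric mean of the nonzero
#' normalized weights (the standard tAI convention for unobserved supply).
#'
#' @param table A `recognition_table`.
#' @param trna_levels Named numeric vector of tRNA abundances (>= 0), names
#'   matching `table$trna_ids`.
#' @return `codon_scores` of tAI weights in `(0, 1]`.
#' @export
tai_weights <- function(table, trna_levels) {
  stopifnot(inherits(table, "recognition_table"))
  lv <- stats::setNames(rep(0, length(table$trna_ids)), table$trna_ids)
  lv[names(trna_levels)] <- trna_levels
  if (any(lv < 0)) stop("tRNA abundances must be nonnegative")
  if (all(lv == 0)) stop("all tRNA levels are zero")
  W <- drop(table$alpha %*% lv)
  covered <- rowSums(table$alpha > 0) > 0
  if (all(W[covered] == 0)) stop("all covered codons have zero supply")
  w <- W / max(W)
  zero <- covered & w == 0
  if (any(zero)) w[zero] <- exp(mean(log(w[covered & w > 0])))
  w[!covered] <- NA_real_
  codon_scores(w, "tAI weight")
}

geom_mean_weights <- function(orf, weights, what) {
  codons <- codon_index(orf, what)  # errors on stops / invalid
  if (length(codons) == 0L) stop(what, " is empty")
  w <- unclass(weights)[codons]
  if (anyNA(w)) stop(what, " contains codon(s) with undefined weight")
  exp(mean(log(w)))
}

#' tAI of a coding sequence
#'
#' Geometric mean of per-codon tAI weights over the ORF (start codon
#' included, stop codon must be removed first, e.g. via [strip_stop()]).
#'
#' @param orf Codon vector or nucleotide string (no stop codons).
#' @param weights `codon_scores` from [tai_weights()].
#' @return tAI value in `(0, 1]`.
#' @export
tai_of_sequence <- function(orf, weights) {
  geom_mean_weights(orf, weights, "ORF")
}

#' CAI relative-adaptiveness weights from a reference ORF set
#'
#' Within each synonymous family, a codon's weight is its reference count
#' divided by the count of the family's most frequent codon. Codons unseen
#' in the reference get a pseudo-count of 0.5 before normalization, so every
#' weight is positive.
#'
#' @param reference_orfs List of codon vectors (stops stripped or terminal).
#' @return `codon_scores` of CAI weights in `(0, 1]`.
#' @export
cai_weights <- function(reference_orfs) {
  sense <- sense_codons()
  counts <- stats::setNames(numeric(length(sense)), sense)
  for (orf in reference_orfs) {
    tab <- table(strip_stop(orf))
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts[counts == 0] <- 0.5
  gc <- genetic_code()
  w <- counts
  for (aa in unique(gc[sense])) {
    fam <- sense[gc[sense] == aa]
    w[fam] <- counts[fam] / max(counts[fam])
  }
  codon_scores(w, "CAI weight")
}

#' CAI of a coding sequence
#'
#' @inheritParams tai_of_sequence
#' @param cai_w `codon_scores` from [cai_weights()].
#' @return CAI value in `(0, 1]`.
#' @export
cai_of_sequence <- function(orf, cai_w) {
  geom_mean_weights(orf, cai_w, "ORF")
}

#' Optimize wobble-class interaction coefficients against expression targets
#'
#' Re-fits the non-Watson-Crick pairing-class coefficients of a recognition
#' table so that per-gene tAI (computed from the table and the supplied tRNA
#' levels) best rank-correlates with one or two per-gene target vectors
#' (e.g. protein abundance and a typical-decoding-rate index). The objective
#' is the sum of Spearman correlations over the supplied targets; the search
#' is an exhaustive per-class grid with coordinate ascent (Watson-Crick is
#' pinned at 1).
#'
#' @param table A `recognition_table` built from class rules (must retain a
#'   `class` column in `table$rules`).
#' @param trna_levels Named tRNA abundance vector.
#' @param orfs List of codon vectors (stops stripped internally).
#' @param targets Numeric vector, or list/data.frame of up to two numeric
#'   vectors, one value per ORF.
#' @param grid Candidate coefficient values per class, in `(0, 1]`.
#' @param max_sweeps Maximum coordinate-ascent sweeps over the classes.
#' @return The re-parameterized `recognition_table`, with attributes
#'   `objective` (achieved summed correlation) and `coefficients`.
#' @export
optimize_interaction_coefficients <- function(table, trna_levels, orfs,
                                              targets,
                                              grid = seq(0.05, 1, by = 0.05),
                                              max_sweeps = 5L) {
  stopifnot(inherits(table, "recognition_table"))
  if (!"class" %in% names(table$rules))
    stop("table was built from explicit alphas; class structure unknown")
  if (!is.list(targets) && !is.data.frame(targets)) targets <- list(targets)
  targets <- lapply(targets, as.numeric)
  if (length(orfs) < 2L) stop("need at least two genes")
  for (tv in targets) {
    if (length(tv) != length(orfs)) stop("target length must match orfs")
    if (!all(is.finite(tv))) stop("targets must be finite")
    if (stats::sd(tv) == 0) stop("constant target vector: correlation undefined")
  }
  orfs <- lapply(orfs, strip_stop)

  classes <- setdiff(unique(table$rules$class), "watson_crick")
  coeffs <- table$class_coeffs
  coeffs["watson_crick"] <- 1.0
  # make sure all free classes have a starting value on the grid
  for (cl in classes)
    if (is.na(coeffs[cl])) coeffs[cl] <- grid[length(grid)]

  objective <- function(cf) {
    tb <- build_recognition_table(table$rules[, c("codon", "trna_id", "class")],
                                  class_coeffs = cf, partial = TRUE)
    w <- tai_weights(tb, trna_levels)
    tai <- vapply(orfs, tai_of_sequence, 0, weights = w)
    sum(vapply(targets, function(tv)
      stats::cor(tai, tv, method = "spearman"), 0))
  }

  best <- objective(coeffs)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (cl in classes) {
      vals <- vapply(grid, function(g) {
        cf <- coeffs; cf[cl] <- g; objective(cf)
      }, 0)
      k <- which.max(vals)
      if (vals[k] > best + 1e-12) {
        best <- vals[k]
        coeffs[cl] <- grid[k]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  out <- build_recognition_table(table$rules[, c("codon", "trna_id", "class")],
                                 class_coeffs = coeffs,
                                 partial = anyNA(match(sense_codons(),
                                                       table$rules$codon)))
  attr(out, "objective") <- best
  attr(out, "coefficients") <- coeffs
  out
}
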