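#' Conserved ribosome and tRNA resource pools
#'
#' Creates a mutable (environment-backed) resource state tracking the free
#' ribosome pool, per-species free and on-mRNA tRNA amounts, and the live
#' demand counters used by the supply-demand statistics: the number of mRNAs
#' awaiting an initiation complex and the number of codons currently in the
#' tRNA-awaiting state. Conservation
#' `G_free + bound ribosomes = G_tot` and
#' `H_free(j) + bound(j) = H_tot(j)` holds under every operation.
#'
#' @param G_tot Total ribosome count.
#' @param H_tot_per Named integer vector of per-species total tRNA counts.
#' @return Object of class `resource_state` (an environment with fields
#'   `G_free`, `G_tot`, `H_free`, `H_tot_per`, `bound_trna`, `bound_ribo`,
#'   `init_demand`, `codon_demand`).
#' @export
resource_state <- function(G_tot, H_tot_per) {
  stopifnot(G_tot >= 0, all(H_tot_per >= 0), !is.null(names(H_tot_per)))
  e <- new.env(parent = emptyenv())
  e$G_tot <- as.numeric(G_tot)
  e$G_free <- as.numeric(G_tot)
  e$bound_ribo <- 0
  e$H_tot_per <- H_tot_per
  e$H_free <- H_tot_per
  e$bound_trna <- stats::setNames(numeric(length(H_tot_per)),
                                  names(H_tot_per))
  e$init_demand <- 0
  e$codon_demand <- stats::setNames(numeric(61), sense_codons())
  class(e) <- "resource_state"
  e
}

#' Ribosomal supply-demand ratio
#'
#' Free ribosomes divided by the number of mRNAs currently awaiting an
#' initiation complex (demand floored at 1).
#'
#' @param state A `resource_state`.
#' @return Nonnegative real.
#' @export
rsdr <- function(state) {
  state$G_free / max(state$init_demand, 1)
}

#' Effective demand for a tRNA species
#'
#' `D_j = sum_c alpha(c, j) * codon_demand(c)` over the codons decoded by
#' species `j`: the interaction-weighted count of codons currently awaiting
#' a tRNA that `j` could serve.
#'
#' @param j tRNA species id.
#' @param state A `resource_state`.
#' @param table A `recognition_table`.
#' @return Nonnegative real.
#' @export
effective_demand <- function(j, state, table) {
  if (!j %in% table$trna_ids) stop("unknown tRNA id: ", j)
  a <- table$alpha[, j]
  sum(a * state$codon_demand[rownames(table$alpha)])
}

#' tRNA recycling parameters
#'
#' @param d Named numeric vector of per-codon distance scores (>= 0) over the
#'   61 sense codons.
#' @param w Positive normalization factor; the ESDR demand exponent for codon
#'   `c` is `1 - exp(-w * d_c)`, in `[0, 1)`.
#' @return Object of class `recycling_params` with fields `d`, `w`,
#'   `exponent`.
#' @export
recycling_params <- function(d, w) {
  sense <- sense_codons()
  dd <- stats::setNames(numeric(61), sense)
  dd[codons_of(names(d))] <- d
  stopifnot(all(dd >= 0), w >= 0)
  structure(list(d = dd, w = w, exponent = 1 - exp(-w * dd)),
            class = "recycling_params")
}

#' Effective supply-demand ratio of a codon
#'
#' `ESDR(c) = sum_{j in rt(c)} alpha(c,j) * H_free(j) /
#' max(D_j, 1)^(1 - exp(-w * d_c))`. The demand is floored at 1 so the
#' expression stays finite at zero demand (with exponent 0 the floor is
#' inert). A larger distance score `d_c` (less recycling benefit) pushes the
#' exponent toward 1, penalizing supply by the full per-species demand.
#'
#' @param c Sense codon.
#' @param state A `resource_state`.
#' @param table A `recognition_table`.
#' @param rec A `recycling_params`.
#' @return Nonnegative real.
#' @export
esdr <- function(c, state, table, rec) {
  c <- codons_of(c)
  if (c %in% stop_codons()) stop("ESDR undefined for stop codon ", c)
  ex <- rec$exponent[[c]]
  js <- table$rt[[c]]
  total <- 0
  for (j in js) {
    D <- effective_demand(j, state, table)
    total <- total + table$alpha[c, j] * state$H_free[[j]] / max(D, 1)^ex
  }
  total
}

#' Allocate a tRNA for a codon
#'
#' Among the decoders of `c` with free molecules, picks species `j` with
#' probability proportional to `alpha(c, j) * H_free(j)` (a single candidate
#' is chosen without consuming randomness), moves one molecule from the free
#' pool to the bound ledger, and returns its id. Returns `NULL` (no state
#' change) if all decoders are exhausted.
#'
#' @param c Sense codon.
#' @param state A `resource_state` (mutated in place).
#' @param table A `recognition_table`.
#' @return tRNA id, or `NULL`.
#' @export
allocate_trna <- function(c, state, table) {
  c <- codons_of(c)
  js <- table$rt[[c]]
  avail <- js[state$H_free[js] > 0]
  if (length(avail) == 0L) return(NULL)
  if (length(avail) == 1L) {
    j <- avail
  } else {
    wts <- table$alpha[c, avail] * state$H_free[avail]
    j <- sample(avail, 1L, prob = wts)
  }
  state$H_free[[j]] <- state$H_free[[j]] - 1
  state$bound_trna[[j]] <- state$bound_trna[[j]] + 1
  j
}

#' Release a bound tRNA back to the free pool
#'
#' Instantaneous re-aminoacylation: the molecule returns to the available
#' pool. Releasing a species with zero bound molecules signals an engine
#' accounting bug and raises an error.
#'
#' @param j tRNA species id.
#' @param state A `resource_state` (mutated in place).
#' @return The state, invisibly.
#' @export
release_trna <- function(j, state) {
  if (is.na(state$bound_trna[j]) || state$bound_trna[[j]] <= 0)
    stop("accounting error: release of tRNA '", j, "' with zero bound")
  state$bound_trna[[j]] <- state$bound_trna[[j]] - 1
  state$H_free[[j]] <- state$H_free[[j]] + 1
  invisible(state)
}

#' Codon distance scores and recycling normalization from a transcriptome
#'
#' For each occurrence of codon `c` at position `p` in an ORF of length `L`,
#' the downstream distance is the number of codons to the nearest position
#' `q > p` whose codon shares a decoding tRNA with `c`, capped at the
#' distance to the ORF's 3' end (`L - p + 1`) when no co-decoded codon
#' follows. `d_c` is the copy-number-weighted mean over all occurrences of
#' `c`; codons absent from the transcriptome get the median observed score.
#' The normalization `w` is set so the median demand exponent
#' `1 - exp(-w * d_c)` over codons equals 1/2. Codons that tend to sit close
#' to co-decoded codons therefore get a small exponent: their effective
#' demand is discounted, reflecting reuse of just-released tRNAs.
#'
#' @param transcriptome List of `list(codons =, copies =)` entries (codon
#'   vectors may carry a terminal stop, which is stripped).
#' @param table A `recognition_table`.
#' @return A `recycling_params`.
#' @export
distance_scores <- function(transcriptome, table) {
  stopifnot(length(transcriptome) > 0)
  co <- co_decoded_matrix(table)
  sense <- sense_codons()
  num <- stats::setNames(numeric(61), sense)
  den <- num
  for (entry in transcriptome) {
    codons <- strip_stop(entry$codons)
    copies <- if (is.null(entry$copies)) 1 else entry$copies
    idx <- codon_index(codons)
    L <- length(idx)
    for (p in seq_len(L)) {
      c_p <- idx[p]
      d <- L - p + 1  # cap: distance to ORF 3' end, inclusive
      if (p < L) {
        hits <- which(co[c_p, idx[(p + 1L):L]])
        if (length(hits)) d <- hits[1L]
      }
      num[c_p] <- num[c_p] + copies * d
      den[c_p] <- den[c_p] + copies
    }
  }
  d <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  med <- stats::median(d, na.rm = TRUE)
  d[is.na(d)] <- med
  w <- if (med > 0) log(2) / med else 0
  recycling_params(d, w)
}
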