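#' Engine configuration
#'
#' Parameters of the timer-driven lattice engine. Waiting times are mapped
#' from supply-demand ratios by `T = scale / max(SDR, sdr_floor)` and
#' quantized to ticks of `dt` seconds (1-tick floor); initiation uses the
#' gene's local initiation time rescaled by `rsdr_ref / RSDR`, so an mRNA
#' experiencing the reference ribosomal supply-demand ratio initiates at
#' exactly its local time.
#'
#' @param dt Tick length, seconds.
#' @param s Ribosome footprint, codons (A-site gap between neighbors is
#'   never below `s`).
#' @param transloc_ticks Fixed translocation duration, ticks.
#' @param scale_elong Elongation timer scale (seconds x ESDR units): the
#'   expected A-site tRNA wait is `scale_elong / ESDR(c)`.
#' @param rsdr_ref Reference RSDR at which initiation runs at its local time.
#' @param sdr_floor Floor applied to any supply-demand ratio before division
#'   (keeps waits finite under total starvation).
#' @param warn_wait Waits above this bound (seconds) are counted and
#'   reported; timer-based dynamics assume waits are short relative to pool
#'   turnover (the small-error regime).
#' @return Object of class `engine_config`.
#' @export
engine_config <- function(dt = 0.05, s = 10L, transloc_ticks = 1L,
                          scale_elong = 25, rsdr_ref = 10,
                          sdr_floor = 1e-6, warn_wait = 30) {
  stopifnot(dt > 0, s >= 1, transloc_ticks >= 1, scale_elong > 0,
            rsdr_ref > 0, sdr_floor > 0)
  structure(list(dt = dt, s = as.integer(s),
                 transloc_ticks = as.integer(transloc_ticks),
                 scale_elong = scale_elong, rsdr_ref = rsdr_ref,
                 sdr_floor = sdr_floor, warn_wait = warn_wait),
            class = "engine_config")
}

#' Map a supply-demand ratio to a timer duration in ticks
#'
#' Expected wait `T = scale / max(sdr, sdr_floor)` seconds, quantized to
#' `max(1, round(T / dt))` ticks: monotone nonincreasing in the ratio,
#' finite even at zero supply, never below one tick.
#'
#' @param sdr Nonnegative supply-demand ratio.
#' @param scale Timer scale, seconds.
#' @param dt Tick length, seconds.
#' @param sdr_floor Ratio floor.
#' @return Integer tick count >= 1.
#' @export
#' @examples
#' set_timer(10, scale = 1, dt = 0.05)  # 0.1 s -> 2 ticks
set_timer <- function(sdr, scale, dt, sdr_floor = 1e-6) {
  stopifnot(sdr >= 0, scale > 0, dt > 0)
  T <- scale / pmax(sdr, sdr_floor)
  # half-away-from-zero rounding, matching the C++ engine's lround()
  pmax(1L, as.integer(floor(T / dt + 0.5)))
}

#' One mRNA lattice
#'
#' @param codons Codon vector or nucleotide string; a terminal stop codon is
#'   stripped (termination is instantaneous after the last sense codon).
#'   Internal stops are an error.
#' @param gene_id Gene identifier (copies of the same gene share it).
#' @param local_init_time Local initiation time, seconds.
#' @return Object of class `mrna_lattice` with fields `gene_id`, `codons`
#'   (RNA), `codon_idx` (1..61), `local_init_time`.
#' @export
mrna_lattice <- function(codons, gene_id, local_init_time = 0.95) {
  codons <- strip_stop(codons)
  stopifnot(length(codons) >= 1, local_init_time > 0)
  structure(list(gene_id = gene_id, codons = codons,
                 codon_idx = codon_index(codons),
                 local_init_time = local_init_time),
            class = "mrna_lattice")
}

#' Run the lattice engine for a fixed number of ticks
#'
#' Low-level driver: advances all initiation and elongation state machines
#' tick by tick against the shared pools, visiting mRNAs in a fresh
#' uniformly random order each tick. Reproducible under `set.seed()`.
#' Most users want [run_simulation()], which adds steady-state handling and
#' result assembly.
#'
#' @param lattices List of `mrna_lattice` objects.
#' @param table A `recognition_table`.
#' @param rec A `recycling_params`.
#' @param cfg An `engine_config`.
#' @param G_tot Total ribosome count.
#' @param H_tot_per Named per-species total tRNA counts (names matching
#'   `table$trna_ids`).
#' @param ticks Number of ticks to simulate.
#' @param record_positions If `TRUE`, also return per-tick ribosome
#'   `(lattice, id, pos)` snapshots (memory-heavy; meant for small runs and
#'   property tests).
#' @return List with per-tick `traj` (pools, event counts), `term_ticks`
#'   (per-gene termination tick vectors), `occupancy` (gene x codon A-site
#'   iteration counts), `esdr_mean` (time-averaged per-codon ESDR), `inits`,
#'   `warn_count`, `final` state snapshot, and optional `positions`.
#' @export
run_engine <- function(lattices, table, rec, cfg, G_tot, H_tot_per, ticks,
                       record_positions = FALSE) {
  stopifnot(inherits(table, "recognition_table"),
            inherits(rec, "recycling_params"),
            inherits(cfg, "engine_config"), ticks >= 1)
  if (is.null(names(H_tot_per)) ||
      !all(names(H_tot_per) %in% table$trna_ids))
    stop("H_tot_per must be named by tRNA ids present in the table")
  H <- stats::setNames(rep(0, length(table$trna_ids)), table$trna_ids)
  H[names(H_tot_per)] <- H_tot_per
  decoders <- lapply(rownames(table$alpha), function(cc)
    match(table$rt[[cc]], table$trna_ids))
  gene_ids <- vapply(lattices, function(l) as.character(l$gene_id), "")
  gene_levels <- unique(gene_ids)
  out <- engine_run_cpp(
    codon_seqs = lapply(lattices, `[[`, "codon_idx"),
    gene_of = match(gene_ids, gene_levels),
    init_times = vapply(lattices, `[[`, 0, "local_init_time"),
    alpha = table$alpha, decoders = decoders,
    H_tot_per = as.numeric(H), G_tot = as.numeric(G_tot),
    exponent = as.numeric(rec$exponent), cfg = unclass(cfg),
    ticks = as.integer(ticks), record_positions = record_positions)
  names(out$term_ticks) <- gene_levels
  rownames(out$occupancy) <- gene_levels
  names(out$esdr_mean) <- rownames(table$alpha)
  names(out$final$H_free) <- table$trna_ids
  names(out$final$bound_trna) <- table$trna_ids
  names(out$final$codon_demand) <- rownames(table$alpha)
  out$gene_ids <- gene_levels
  out$G_tot <- G_tot
  out$H_tot <- sum(H)
  out
}
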