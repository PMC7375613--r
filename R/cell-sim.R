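#' Whole-cell run configuration
#'
#' Bundles the pool sizes, engine parameters, steady-state detection
#' settings and run length for a whole-cell simulation. The default
#' parameter set for a full E. coli-scale cell is `N = 5100` mRNA
#' molecules, `G_tot = 70000` ribosomes, `H_tot = 650407` tRNAs and a mean
#' local initiation time of 0.95 s; [toy_cell()] provides a
#' desk-scale variant (pools divided by 10, preserving the ribosome:tRNA
#' ratio).
#'
#' @param N Target total mRNA molecule count.
#' @param G_tot Ribosome pool size.
#' @param H_tot_per Named per-species tRNA totals (sums to `H_tot`).
#' @param mean_init_time Transcriptome-mean local initiation time, seconds.
#' @param steady_window,steady_tol Trailing-window length (ticks) and
#'   relative-range tolerance for steady-state detection on the free
#'   ribosome trajectory.
#' @param run_ticks Default simulation length in ticks.
#' @param seed Seed applied before every stochastic stage.
#' @param engine An `engine_config`.
#' @return Object of class `cell_config`.
#' @export
cell_config <- function(N = 5100, G_tot = 70000, H_tot_per,
                        mean_init_time = 0.95, steady_window = 300L,
                        steady_tol = 0.01, run_ticks = 2000L, seed = 1L,
                        engine = engine_config()) {
  stopifnot(N > 0, G_tot > 0, all(H_tot_per >= 0), sum(H_tot_per) > 0,
            mean_init_time > 0, steady_window >= 2, steady_tol > 0)
  structure(list(N = N, G_tot = G_tot, H_tot_per = H_tot_per,
                 H_tot = sum(H_tot_per), mean_init_time = mean_init_time,
                 steady_window = as.integer(steady_window),
                 steady_tol = steady_tol, run_ticks = as.integer(run_ticks),
                 seed = as.integer(seed), engine = engine),
            class = "cell_config")
}

#' @export
print.cell_config <- function(x, ...) {
  cat(sprintf(
    "cell_config: N=%g  G_tot=%g  H_tot=%g (%d species)  ticks=%d  dt=%gs\n",
    x$N, x$G_tot, x$H_tot, length(x$H_tot_per), x$run_ticks, x$engine$dt))
  invisible(x)
}

#' Instantiate mRNA lattices from per-gene expression levels
#'
#' Each gene contributes `floor(level)` full copies plus one extra copy with
#' probability `frac(level)` (one Bernoulli draw per gene, fixed for the
#' run), so genes with mean copy number below one are represented
#' stochastically but conserve the expected total.
#'
#' @param levels Named nonnegative numeric vector of mRNA copy levels.
#' @param orfs Named list of codon vectors (terminal stops allowed).
#' @param init_times Named numeric vector of local initiation times,
#'   seconds.
#' @return List of `mrna_lattice` objects (possibly empty), with attribute
#'   `copies` (realized per-gene copy counts).
#' @export
instantiate_transcriptome <- function(levels, orfs, init_times) {
  if (any(levels < 0)) stop("negative mRNA level")
  stopifnot(!is.null(names(levels)), all(names(levels) %in% names(orfs)),
            all(names(levels) %in% names(init_times)))
  extra <- stats::runif(length(levels)) < (levels - floor(levels))
  copies <- floor(levels) + extra
  names(copies) <- names(levels)
  lattices <- list()
  for (g in names(levels)) {
    if (copies[[g]] < 1) next
    lat <- mrna_lattice(orfs[[g]], g, init_times[[g]])
    lattices <- c(lattices, rep(list(lat), copies[[g]]))
  }
  attr(lattices, "copies") <- copies
  lattices
}

#' Detect steady state on a free-ribosome trajectory
#'
#' Returns the first tick at which the relative range
#' `(max - min) / max(mean, 1)` of `g_traj` over the trailing `window`
#' ticks drops to `tol` or below, i.e. the epoch where consumption of the
#' ribosomal pool has stabilized. `NA` if never satisfied.
#'
#' @param g_traj Numeric free-ribosome trajectory (one value per tick).
#' @param window Trailing window length, ticks.
#' @param tol Relative-range tolerance.
#' @return Tick index, or `NA_integer_`.
#' @export
detect_steady_state <- function(g_traj, window, tol) {
  n <- length(g_traj)
  if (n < window) return(NA_integer_)
  for (t in window:n) {
    seg <- g_traj[(t - window + 1L):t]
    if ((max(seg) - min(seg)) / max(mean(seg), 1) <= tol)
      return(t)
  }
  NA_integer_
}

#' Run a whole-cell simulation
#'
#' Executes the tick loop for `cfg$run_ticks`, then locates steady state on
#' the free-ribosome trajectory and derives post-steady statistics: per-gene
#' termination counts and rates, the active-ribosome fraction
#' `%AR = 1 - mean(G_free)/G_tot` (time-averaged after steady state), codon
#' occupancy profiles and time-averaged per-codon ESDR.
#'
#' @param cfg A `cell_config`.
#' @param lattices List of `mrna_lattice` (e.g. from
#'   [instantiate_transcriptome()]); may be empty.
#' @param table A `recognition_table`.
#' @param rec A `recycling_params`.
#' @param ticks Override of `cfg$run_ticks`.
#' @param record_positions Passed to [run_engine()].
#' @return Object of class `simulation_result`.
#' @export
run_simulation <- function(cfg, lattices, table, rec,
                           ticks = cfg$run_ticks, record_positions = FALSE) {
  stopifnot(inherits(cfg, "cell_config"))
  gene_ids <- vapply(lattices, function(l) as.character(l$gene_id), "")
  if (length(lattices) == 0L) {
    traj <- data.frame(tick = seq_len(ticks), G_free = cfg$G_tot,
                       bound_ribo = 0, H_free_total = cfg$H_tot,
                       bound_trna_total = 0, n_init = 0L, n_term = 0L)
    return(structure(list(
      traj = traj, term_total = numeric(0), term_steady = numeric(0),
      rate = numeric(0), copies = integer(0), occupancy = NULL,
      esdr_mean = NULL, steady_tick = cfg$steady_window, steady = TRUE,
      ar_fraction = 0, inits = 0, warn_count = 0, final = NULL,
      n_lattices = 0L, ticks = ticks, cfg = cfg),
      class = "simulation_result"))
  }
  eng <- run_engine(lattices, table, rec, cfg$engine, cfg$G_tot,
                    cfg$H_tot_per, ticks, record_positions)
  st <- detect_steady_state(eng$traj$G_free, cfg$steady_window,
                            cfg$steady_tol)
  steady <- !is.na(st)
  # flagged non-steady: post-steady statistics fall back to the trailing
  # detection window so they remain defined (and comparable across pilots)
  if (!steady) st <- max(ticks - cfg$steady_window + 1L, 1L)
  dur_s <- max(ticks - st, 1L) * cfg$engine$dt
  term_total <- vapply(eng$term_ticks, length, 0L)
  term_steady <- vapply(eng$term_ticks, function(v) sum(v > st), 0L)
  post <- eng$traj$G_free[st:ticks]
  copies <- table(factor(gene_ids, levels = eng$gene_ids))
  structure(list(
    traj = eng$traj, term_total = term_total, term_steady = term_steady,
    term_ticks = eng$term_ticks,
    rate = term_steady / dur_s, copies = copies,
    occupancy = eng$occupancy, esdr_mean = eng$esdr_mean,
    steady_tick = st, steady = steady,
    ar_fraction = mean(1 - post / cfg$G_tot),
    inits = eng$inits, warn_count = eng$warn_count, final = eng$final,
    positions = eng$positions, n_lattices = length(lattices),
    ticks = ticks, cfg = cfg),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    paste0("simulation_result: %d lattices, %d ticks, steady@%s, ",
           "%%AR=%.3f, %d terminations (%d post-steady)\n"),
    x$n_lattices, x$ticks,
    if (x$steady) x$steady_tick else "never", x$ar_fraction,
    sum(x$term_total), sum(x$term_steady)))
  invisible(x)
}

#' Calibrate pool sizes to a target active-ribosome fraction
#'
#' Bisection over a single global pool scale applied to both `G_tot` and
#' every tRNA species (so the ribosome:tRNA ratio is held fixed), until the
#' simulated post-steady active-ribosome fraction reaches the target
#' (default 80% ribosomal activity). The fraction is monotone nonincreasing
#' in the scale over the bracket, which the bisection relies on. Each
#' evaluation reseeds with `cfg$seed`, making the objective a deterministic
#' function of the scale.
#'
#' @param cfg A `cell_config` (its pools define scale 1).
#' @param lattices Transcriptome lattices.
#' @param table,rec Recognition table and recycling parameters.
#' @param target Target active fraction in (0, 1).
#' @param tol Absolute tolerance on the achieved fraction.
#' @param bracket Scale search interval (must bracket the target).
#' @param max_iter Maximum bisection iterations.
#' @param ticks Pilot-run length per evaluation.
#' @return Updated `cell_config` with scaled pools and attributes
#'   `achieved_ar`, `scale`, `iterations`.
#' @export
calibrate_pools <- function(cfg, lattices, table, rec, target = 0.80,
                            tol = 0.02, bracket = c(0.02, 2),
                            max_iter = 12L, ticks = 1200L) {
  if (target <= 0 || target >= 1) stop("target activity must be in (0, 1)")
  scaled <- function(sc) {
    H <- pmax(round(cfg$H_tot_per * sc), 1)  # arg order keeps the names
    cfg2 <- cfg
    cfg2$G_tot <- max(1, round(cfg$G_tot * sc))
    cfg2$H_tot_per <- H
    cfg2$H_tot <- sum(H)
    cfg2
  }
  measure <- function(sc) {
    set.seed(cfg$seed)
    run_simulation(scaled(sc), lattices, table, rec, ticks = ticks)$ar_fraction
  }
  lo <- bracket[1]; hi <- bracket[2]
  ar_lo <- measure(lo); ar_hi <- measure(hi)
  if (ar_lo < target - tol || ar_hi > target + tol)
    stop(sprintf(
      "target %.2f not bracketed: %%AR(%.3g)=%.3f, %%AR(%.3g)=%.3f",
      target, lo, ar_lo, hi, ar_hi))
  ar_mid <- NA_real_; mid <- sqrt(lo * hi); iter <- 0L
  for (iter in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect in log scale
    ar_mid <- measure(mid)
    if (abs(ar_mid - target) <= tol) break
    if (ar_mid > target) lo <- mid else hi <- mid
  }
  out <- scaled(mid)
  attr(out, "achieved_ar") <- ar_mid
  attr(out, "scale") <- mid
  attr(out, "iterations") <- iter
  out
}

#' Normalize local initiation times to the configured mean
#'
#' Multiplicative rescaling so the transcriptome mean equals `mean_target`
#' (default 0.95 s) exactly; relative order and ratios are preserved.
#' Optionally runs a short pilot simulation and warns when the resulting
#' ribosomal density (ribosomes per 10 codons) falls outside
#' `density_range`.
#'
#' @param local_times Positive numeric vector of per-gene local initiation
#'   times, seconds.
#' @param mean_target Target mean, seconds.
#' @param pilot Optional list with elements `cfg`, `lattices`, `table`,
#'   `rec`, `ticks` to run the density check.
#' @param density_range Acceptable ribosome density per 10 codons.
#' @return Rescaled vector with `mean(x) == mean_target`.
#' @export
calibrate_initiation <- function(local_times, mean_target = 0.95,
                                 pilot = NULL, density_range = c(0.1, 0.3)) {
  if (any(local_times <= 0)) stop("local initiation times must be positive")
  out <- local_times * (mean_target / mean(local_times))
  if (!is.null(pilot)) {
    lats <- lapply(pilot$lattices, function(l) {
      l$local_init_time <- out[[as.character(l$gene_id)]]
      l
    })
    set.seed(pilot$cfg$seed)
    sim <- run_simulation(pilot$cfg, lats, pilot$table, pilot$rec,
                          ticks = if (is.null(pilot$ticks)) 600L
                                  else pilot$ticks)
    n_cod <- sum(vapply(lats, function(l) length(l$codon_idx), 0L))
    dens <- 10 * mean(sim$traj$bound_ribo[sim$steady_tick:sim$ticks]) / n_cod
    if (dens < density_range[1] || dens > density_range[2])
      warning(sprintf(
        "pilot ribosomal density %.3f per 10 codons outside [%g, %g]",
        dens, density_range[1], density_range[2]))
    attr(out, "pilot_density") <- dens
  }
  out
}
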