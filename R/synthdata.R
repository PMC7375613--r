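# Synthetic-data generation: every input the simulator consumes (ORFs with
# configurable codon bias, log-normal mRNA levels, tRNA pools, initiation
# times) can be generated offline, so the full pipeline is testable with no
# downloads. All generators are pure functions of spec + RNG state.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for the synthetic-cell generators
#'
#' @param n_genes Number of gene types.
#' @param N Target total mRNA molecule count.
#' @param len_range Inclusive ORF length range in sense codons (start codon
#'   included, stop excluded).
#' @param G_tot,H_tot Ribosome and tRNA pool sizes. The defaults preserve
#'   the full-cell ribosome:tRNA ratio (70,000 : 650,407) at one tenth
#'   scale.
#' @param level_sdlog Log-sd of the log-normal mRNA level distribution
#'   (levels are rescaled to sum to `N`).
#' @param mean_init_time Target mean local initiation time, seconds.
#' @param init_sdlog Log-sd of the initiation-time distribution before
#'   normalization.
#' @param bias_ratio Within-family codon preference: probabilities are
#'   proportional to `bias_ratio^(rank - 1)` with codons ranked by their
#'   pooled decoding weight `sum_j alpha(c, j)` under `table` (ties by
#'   codon name). `bias_ratio = 1` gives unbiased usage.
#' @param trna_sdlog Log-normal noise applied on top of demand-proportional
#'   tRNA pool fractions.
#' @param table `recognition_table` defining the tRNA species set.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 50L, N = 500, len_range = c(30L, 60L),
                       G_tot = 7000, H_tot = 65041, level_sdlog = 1,
                       mean_init_time = 0.95, init_sdlog = 0.4,
                       bias_ratio = 0.5, trna_sdlog = 0.25,
                       table = default_recognition_table()) {
  stopifnot(n_genes >= 1, N > 0, len_range[1] >= 2,
            len_range[2] >= len_range[1], G_tot > 0, H_tot > 0,
            bias_ratio > 0, bias_ratio <= 1)
  structure(list(n_genes = as.integer(n_genes), N = N,
                 len_range = as.integer(len_range), G_tot = G_tot,
                 H_tot = H_tot, level_sdlog = level_sdlog,
                 mean_init_time = mean_init_time, init_sdlog = init_sdlog,
                 bias_ratio = bias_ratio, trna_sdlog = trna_sdlog,
                 table = table),
            class = "synth_spec")
}

# Per-amino-acid codon probabilities implied by a spec (geometric preference
# ranked by pooled decoding weight).
codon_bias_profile <- function(spec) {
  gc <- genetic_code()
  sense <- sense_codons()
  supply <- rowSums(spec$table$alpha)
  out <- list()
  for (aa in unique(gc[sense])) {
    fam <- sort(synonymous_codons(aa))
    p <- spec$bias_ratio^(rank(-supply[fam], ties.method = "first") - 1)
    out[[aa]] <- p / sum(p)
  }
  out
}

#' Generate a synthetic transcriptome
#'
#' Emits in-frame ORFs (AUG start, sense codons drawn from the spec's codon
#' bias profile, UAA stop), log-normal mRNA levels rescaled to sum to the
#' target molecule count, and mean-normalized local initiation times.
#' Deterministic given the RNG state.
#'
#' @param spec A `synth_spec`.
#' @return List with `orfs` (named codon vectors incl. terminal stop),
#'   `levels`, `init_times` (both named by gene).
#' @export
generate_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  profile <- codon_bias_profile(spec)
  aas <- names(profile)
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  cand <- seq(spec$len_range[1], spec$len_range[2])
  lens <- cand[sample.int(length(cand), spec$n_genes, replace = TRUE)]
  orfs <- lapply(seq_len(spec$n_genes), function(i) {
    aa_seq <- sample(aas, lens[i] - 1L, replace = TRUE)
    body <- vapply(aa_seq, function(a) {
      p <- profile[[a]]
      if (length(p) == 1L) names(p)
      else sample(names(p), 1L, prob = p)
    }, "")
    c("AUG", unname(body), "UAA")
  })
  names(orfs) <- genes
  levels <- stats::rlnorm(spec$n_genes, 0, spec$level_sdlog)
  levels <- stats::setNames(levels / sum(levels) * spec$N, genes)
  init <- stats::rlnorm(spec$n_genes, log(spec$mean_init_time),
                        spec$init_sdlog)
  init <- calibrate_initiation(stats::setNames(init, genes),
                               spec$mean_init_time)
  list(orfs = orfs, levels = levels, init_times = init)
}

#' Generate an integer tRNA pool summing exactly to the total
#'
#' Per-species counts are `fractions * H_tot` rounded by the
#' largest-remainder method, so they always sum to `H_tot` exactly. When
#' `fractions` is `NULL` they are made proportional to the
#' interaction-weighted codon demand of `transcriptome` (supply-demand
#' co-adaptation), perturbed by log-normal noise of sd `spec$trna_sdlog`.
#'
#' @param spec A `synth_spec`.
#' @param fractions Optional named per-species fractions (normalized
#'   internally).
#' @param transcriptome Result of [generate_transcriptome()]; required when
#'   `fractions` is `NULL`.
#' @return Named integer vector over `spec$table$trna_ids`, summing to
#'   `spec$H_tot`.
#' @export
generate_trna_pool <- function(spec, fractions = NULL,
                               transcriptome = NULL) {
  ids <- spec$table$trna_ids
  if (is.null(fractions)) {
    stopifnot(!is.null(transcriptome))
    usage <- stats::setNames(numeric(61), sense_codons())
    for (g in names(transcriptome$orfs)) {
      tab <- table(strip_stop(transcriptome$orfs[[g]]))
      usage[names(tab)] <- usage[names(tab)] +
        as.numeric(tab) * transcriptome$levels[[g]]
    }
    demand <- drop(usage %*% spec$table$alpha)
    demand[demand <= 0] <- min(demand[demand > 0])
    fractions <- demand * stats::rlnorm(length(ids), 0, spec$trna_sdlog)
    names(fractions) <- ids
  }
  f <- stats::setNames(rep(0, length(ids)), ids)
  f[names(fractions)] <- fractions
  if (any(f < 0) || sum(f) <= 0) stop("invalid pool fractions")
  f <- f / sum(f)
  largest_remainder(f, spec$H_tot)
}

# Largest-remainder apportionment of `total` over fractions `f` (sums
# exactly; ties broken by index order).
largest_remainder <- function(f, total) {
  raw <- f * total
  base <- floor(raw)
  left <- round(total - sum(base))
  if (left > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(f))
}

#' Generate a planted linear-regression fixture
#'
#' `y = X beta + noise` with standard-normal features; only the planted
#' columns carry signal. Used for forward-selection recovery tests.
#'
#' @param n_rows Observations.
#' @param n_features Total feature columns (`f1..fM`).
#' @param planted Indices or names of signal-bearing columns.
#' @param coefficients Coefficients of the planted columns.
#' @param noise_sd Gaussian noise sd. The attribute `snr` records
#'   `var(signal)/noise_sd^2`.
#' @return List with `X`, `y`, `planted` (names), `beta`, and attribute
#'   `snr`.
#' @export
generate_regression_fixture <- function(n_rows = 150L, n_features = 20L,
                                        planted = 1:3,
                                        coefficients = c(3, -2, 1.5),
                                        noise_sd = 1) {
  stopifnot(length(planted) == length(coefficients),
            max(planted) <= n_features)
  X <- matrix(stats::rnorm(n_rows * n_features), n_rows, n_features,
              dimnames = list(NULL, sprintf("f%02d", seq_len(n_features))))
  signal <- drop(X[, planted, drop = FALSE] %*% coefficients)
  y <- signal + stats::rnorm(n_rows, 0, noise_sd)
  structure(list(X = X, y = y, planted = colnames(X)[planted],
                 beta = coefficients),
            snr = stats::var(signal) / noise_sd^2)
}

#' A synthetic GFP-like payload ORF
#'
#' A fixed 240-codon synthetic coding sequence (239 sense codons + stop)
#' standing in for a real fluorescent-protein gene in heterologous-
#' expression examples and tests. It is generated from the default codon
#' bias profile under an internal fixed seed, so it is byte-stable across
#' sessions; it is **not** any deposited GFP sequence.
#'
#' @return Character vector of 240 codons (terminal UAA included).
#' @export
gfp_payload <- function() {
  with_local_seed(240807L, {
    spec <- synth_spec(n_genes = 1L, len_range = c(239L, 239L))
    generate_transcriptome(spec)$orfs[[1L]]
  })
}

#' The standard desk-scale synthetic cell fixture
#'
#' Builds a complete toy cell: default recognition table, a biased
#' synthetic transcriptome (50 gene types, 500 molecules, short ORFs),
#' a demand-adapted tRNA pool, recycling parameters fit on the
#' transcriptome, and a `cell_config`. With `paper_pools = TRUE` the pool
#' sizes are the full-cell preset (`G_tot = 70000`, `H_tot = 650407`)
#' instead of the tenth-scale default, keeping the same transcriptome.
#'
#' @param seed Seed controlling all generation.
#' @param paper_pools Use full-cell pool sizes.
#' @param run_ticks Default run length stored in the config.
#' @return List with `table`, `spec`, `orfs`, `levels`, `init_times`,
#'   `rec`, `cfg`, `lattices`.
#' @export
toy_cell <- function(seed = 1L, paper_pools = FALSE, run_ticks = 2000L) {
  table <- default_recognition_table()
  spec <- synth_spec(
    G_tot = if (paper_pools) 70000 else 7000,
    H_tot = if (paper_pools) 650407 else 65041,
    table = table)
  with_local_seed(seed, {
    tx <- generate_transcriptome(spec)
    pool <- generate_trna_pool(spec, transcriptome = tx)
    rec <- distance_scores(
      lapply(names(tx$orfs), function(g)
        list(codons = tx$orfs[[g]], copies = tx$levels[[g]])),
      table)
    cfg <- cell_config(N = spec$N, G_tot = spec$G_tot, H_tot_per = pool,
                       mean_init_time = spec$mean_init_time,
                       run_ticks = run_ticks, seed = seed)
    lattices <- instantiate_transcriptome(tx$levels, tx$orfs, tx$init_times)
    list(table = table, spec = spec, orfs = tx$orfs, levels = tx$levels,
         init_times = tx$init_times, rec = rec, cfg = cfg,
         lattices = lattices)
  })
}
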