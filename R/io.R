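# Plain-text I/O glue: FASTA for coding sequences (DNA or RNA alphabet
# accepted; RNA used internally), simple two-column TSVs for levels and
# pools. Coordinates in all outputs are 1-based codon indices.

#' Read in-frame ORFs from FASTA
#'
#' @param path FASTA file (uppercase/lowercase DNA or RNA).
#' @return Named list of RNA codon vectors.
#' @export
read_orfs_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  orfs <- lapply(as.character(ss), codons_of)
  names(orfs) <- sub("\\s.*$", "", names(ss))
  orfs
}

#' Write ORFs to FASTA
#'
#' @param orfs Named list of codon vectors.
#' @param path Output path.
#' @param headers Optional header lines (default the names).
#' @return `path`, invisibly.
#' @export
write_orfs_fasta <- function(orfs, path, headers = names(orfs)) {
  seqs <- vapply(orfs, function(o) paste(codons_of(o), collapse = ""), "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

read_two_col_tsv <- function(path, key, value) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c(key, value) %in% names(df)))
    stop(path, ": expected columns '", key, "', '", value, "'")
  stats::setNames(df[[value]], df[[key]])
}

write_two_col_tsv <- function(x, path, key, value) {
  df <- stats::setNames(data.frame(names(x), unname(x)), c(key, value))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-column TSV readers/writers for simulator inputs
#'
#' mRNA levels (`gene_id`, `level`), tRNA pools (`trna_id`, `abundance`)
#' and local initiation times (`gene_id`, `init_time`).
#'
#' @param path File path.
#' @param x Named numeric vector to write.
#' @return Readers return named numeric vectors.
#' @export
read_levels_tsv <- function(path) read_two_col_tsv(path, "gene_id", "level")

#' @rdname read_levels_tsv
#' @export
write_levels_tsv <- function(x, path)
  write_two_col_tsv(x, path, "gene_id", "level")

#' @rdname read_levels_tsv
#' @export
read_trna_tsv <- function(path) read_two_col_tsv(path, "trna_id", "abundance")

#' @rdname read_levels_tsv
#' @export
write_trna_tsv <- function(x, path)
  write_two_col_tsv(x, path, "trna_id", "abundance")

#' @rdname read_levels_tsv
#' @export
read_init_times_tsv <- function(path)
  read_two_col_tsv(path, "gene_id", "init_time")

#' @rdname read_levels_tsv
#' @export
write_init_times_tsv <- function(x, path)
  write_two_col_tsv(x, path, "gene_id", "init_time")

#' Write simulation results as TSV files
#'
#' Emits `results.tsv` (per-gene copies, termination counts and rates),
#' `occupancy.tsv` (bedGraph-style `gene_id`, `codon_start`, `codon_end`,
#' `count`, 1-based inclusive), `metagene.tsv` (transcriptome-average
#' occupancy per codon position), `trajectory.tsv` (per-tick pools),
#' `pool_final.tsv` (per-species free/bound tRNA at the final tick) and
#' `esdr.tsv` (per-codon time-averaged ESDR).
#'
#' @param sim A `simulation_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_simulation_tsvs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "results.tsv")
  res <- data.frame(gene_id = names(sim$term_total),
                    copies = as.integer(sim$copies),
                    terminations_total = as.integer(sim$term_total),
                    terminations_steady = as.integer(sim$term_steady),
                    rate_per_s = sim$rate)
  utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(sim$occupancy)) {
    occ <- sim$occupancy
    rows <- which(occ > 0, arr.ind = TRUE)
    df <- data.frame(gene_id = rownames(occ)[rows[, 1L]],
                     codon_start = rows[, 2L], codon_end = rows[, 2L],
                     count = occ[rows])
    df <- df[order(df$gene_id, df$codon_start), ]
    p <- file.path(dir, "occupancy.tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)

    meta <- data.frame(codon = seq_len(ncol(occ)),
                       mean_occupancy = colMeans(occ))
    p <- file.path(dir, "metagene.tsv")
    utils::write.table(meta, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "trajectory.tsv")
  utils::write.table(sim$traj, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(sim$final)) {
    p <- file.path(dir, "pool_final.tsv")
    utils::write.table(
      data.frame(trna_id = names(sim$final$H_free),
                 H_free = as.numeric(sim$final$H_free),
                 bound = as.numeric(sim$final$bound_trna)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(sim$esdr_mean)) {
    p <- file.path(dir, "esdr.tsv")
    utils::write.table(
      data.frame(codon = names(sim$esdr_mean),
                 mean_esdr = as.numeric(sim$esdr_mean)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
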