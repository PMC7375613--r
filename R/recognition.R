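#' Build a codon-tRNA recognition table
#'
#' The recognition table holds the interaction coefficient `alpha(c, j)` in
#' `(0, 1]` for every (codon, tRNA) pair that can decode, together with the
#' derived recognizer sets `rt(c) = {j : alpha(c, j) > 0}`. Watson-Crick
#' pairings default to coefficient 1; wobble pairings carry class-specific
#' coefficients that can later be re-optimized against expression targets
#' (see [optimize_interaction_coefficients()]).
#'
#' @param rules Data frame with columns `codon`, `trna_id` and either
#'   `class` (a pairing-class label looked up in `class_coeffs`) or a numeric
#'   `alpha` column giving coefficients directly.
#' @param class_coeffs Named numeric vector mapping pairing classes to
#'   coefficients in `(0, 1]`. `watson_crick` defaults to 1 if absent.
#' @param partial If `FALSE` (default), every one of the 61 sense codons must
#'   have at least one recognizing tRNA; uncovered codons raise an error
#'   naming them. Set `TRUE` for deliberately small toy tables.
#' @return An object of class `recognition_table`: list with `trna_ids`,
#'   dense `alpha` matrix (61 x n_tRNA, rownames = sense codons), `rt`
#'   (named list of recognizer ids per codon), plus the input `rules` and
#'   `class_coeffs` for re-parameterization.
#' @export
#' @examples
#' rules <- data.frame(codon = "UGG", trna_id = "tRNA-Trp-CCA",
#'                     class = "watson_crick")
#' tb <- build_recognition_table(rules, partial = TRUE)
#' tb$rt[["UGG"]]
build_recognition_table <- function(rules,
                                    class_coeffs = default_class_coeffs(),
                                    partial = FALSE) {
  stopifnot(is.data.frame(rules), all(c("codon", "trna_id") %in% names(rules)))
  rules$codon <- codons_of(rules$codon)
  sense <- sense_codons()
  bad <- setdiff(rules$codon, sense)
  if (length(bad))
    stop("recognition rules contain non-sense codon(s): ",
         paste(unique(bad), collapse = ", "))

  if (!"alpha" %in% names(rules)) {
    if (!"class" %in% names(rules))
      stop("rules need either an 'alpha' or a 'class' column")
    if (!"watson_crick" %in% names(class_coeffs))
      class_coeffs <- c(class_coeffs, watson_crick = 1.0)
    unknown <- setdiff(unique(rules$class), names(class_coeffs))
    if (length(unknown))
      stop("no coefficient for pairing class(es): ",
           paste(unknown, collapse = ", "))
    rules$alpha <- unname(class_coeffs[rules$class])
  }
  if (any(!is.finite(rules$alpha)) ||
      any(rules$alpha <= 0) || any(rules$alpha > 1))
    stop("interaction coefficients must lie in (0, 1]")
  if (length(class_coeffs) &&
      (any(class_coeffs <= 0) || any(class_coeffs > 1)))
    stop("class coefficients must lie in (0, 1]")

  trna_ids <- sort(unique(rules$trna_id))
  alpha <- matrix(0, nrow = length(sense), ncol = length(trna_ids),
                  dimnames = list(sense, trna_ids))
  # later duplicates override earlier ones (user overrides after defaults)
  for (k in seq_len(nrow(rules)))
    alpha[rules$codon[k], rules$trna_id[k]] <- rules$alpha[k]

  uncovered <- sense[rowSums(alpha > 0) == 0]
  if (!partial && length(uncovered))
    stop("sense codon(s) with no recognizing tRNA: ",
         paste(uncovered, collapse = ", "))

  rt <- apply(alpha > 0, 1L, function(z) trna_ids[z], simplify = FALSE)
  structure(
    list(trna_ids = trna_ids, alpha = alpha, rt = rt,
         rules = rules[, c("codon", "trna_id",
                           intersect("class", names(rules)), "alpha")],
         class_coeffs = class_coeffs),
    class = "recognition_table")
}

#' @export
print.recognition_table <- function(x, ...) {
  cat("Codon-tRNA recognition table:", length(x$trna_ids), "tRNA species,",
      sum(x$alpha > 0), "decoding pairs,",
      sum(rowSums(x$alpha > 0) > 0), "of 61 sense codons covered\n")
  invisible(x)
}

#' Default wobble pairing-class coefficients
#'
#' Package defaults for the interaction coefficient of each pairing class:
#' Watson-Crick = 1; the wobble classes follow the relative ordering of
#' tAI-style selective constraints (G:U read of U-ending codons, modified-U
#' read of G-ending codons, inosine reads of U/C/A, lysidine-like read of
#' AUA). All are overridable and tunable via
#' [optimize_interaction_coefficients()].
#'
#' @return Named numeric vector of class coefficients in `(0, 1]`.
#' @export
default_class_coeffs <- function() {
  c(watson_crick = 1.0,  # anticodon 34 complements codon 3
    gu  = 0.64,          # G34 reading U-ending codons
    ug  = 0.41,          # modified U34 reading G-ending codons
    iu  = 0.90,          # inosine reading U
    ic  = 0.72,          # inosine reading C
    ia  = 0.10,          # inosine reading A
    k2c = 0.90)          # lysidine-modified C34 reading AUA only
}

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", vapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = ""), ""))
}

aa3 <- function(aa) {
  tab <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val")
  unname(tab[aa])
}

#' Default eubacterial wobble decoding rules
#'
#' Generates a reduced, E. coli-like tRNA species set and its decoding rules
#' from standard eubacterial wobble conventions, applied per amino acid and
#' codon box (codons sharing the first two bases):
#' * codons ending C/U are read by a G34 anticodon (Watson-Crick with C,
#'   `gu` wobble with U);
#' * codons ending A are read by a U34 anticodon (Watson-Crick), which also
#'   reads the G-ending codon of the same family via the modified-U `ug`
#'   class;
#' * G-ending codons in one-codon families (Met, Trp) get a dedicated C34
#'   anticodon;
#' * the Arg CGN box is read by an inosine anticodon ICG (CGU/CGC/CGA) plus
#'   a C34 anticodon for CGG;
#' * Ile AUA is read by a dedicated lysidine-like tRNA (`k2c` class).
#'
#' Every sense codon is covered. The set reproduces the canonical sharing
#' structure (e.g. tRNA-Gly-UCC reads GGA and GGG; tRNA-Gly-GCC reads GGU
#' and GGC). tRNA ids are `tRNA-<Aaa>-<anticodon>`.
#'
#' @return Data frame with columns `codon`, `trna_id`, `class`.
#' @export
default_wobble_rules <- function() {
  gc <- genetic_code()
  sense <- sense_codons()
  out <- list()
  add <- function(codon, trna, class)
    out[[length(out) + 1L]] <<- data.frame(codon = codon, trna_id = trna,
                                           class = class)
  for (aa in sort(unique(gc[sense]))) {
    fam <- sense[gc[sense] == aa]
    for (box in unique(substr(fam, 1L, 2L))) {
      f <- fam[substr(fam, 1L, 2L) == box]
      thirds <- substr(f, 3L, 3L)
      if (aa == "I") {  # AUU/AUC via G34; AUA via lysidine-like reader
        t_g <- paste0("tRNA-Ile-", rna_revcomp(paste0(box, "C")))
        add(paste0(box, "C"), t_g, "watson_crick")
        add(paste0(box, "U"), t_g, "gu")
        add("AUA", "tRNA-Ile-k2CAU", "k2c")
        next
      }
      if (aa == "R" && box == "CG") {  # inosine box + C34 for CGG
        add(c("CGU", "CGC", "CGA"), "tRNA-Arg-ICG", c("iu", "ic", "ia"))
        add("CGG", "tRNA-Arg-CCG", "watson_crick")
        next
      }
      if ("C" %in% thirds) {
        t_g <- paste0("tRNA-", aa3(aa), "-", rna_revcomp(paste0(box, "C")))
        add(paste0(box, "C"), t_g, "watson_crick")
        if ("U" %in% thirds) add(paste0(box, "U"), t_g, "gu")
      }
      if ("A" %in% thirds) {
        t_u <- paste0("tRNA-", aa3(aa), "-", rna_revcomp(paste0(box, "A")))
        add(paste0(box, "A"), t_u, "watson_crick")
        if ("G" %in% thirds) {
          # G-ending codons in split boxes are shared: modified-U wobble
          # read plus a dedicated C34 isoacceptor (e.g. Gly GGG by both
          # tRNA-Gly-UCC and tRNA-Gly-CCC)
          add(paste0(box, "G"), t_u, "ug")
          add(paste0(box, "G"),
              paste0("tRNA-", aa3(aa), "-", rna_revcomp(paste0(box, "G"))),
              "watson_crick")
        }
      } else if ("G" %in% thirds) {
        t_c <- paste0("tRNA-", aa3(aa), "-", rna_revcomp(paste0(box, "G")))
        add(paste0(box, "G"), t_c, "watson_crick")
      }
    }
  }
  do.call(rbind, out)
}

#' Default recognition table
#'
#' Convenience wrapper: [build_recognition_table()] applied to
#' [default_wobble_rules()] with [default_class_coeffs()].
#'
#' @inheritParams build_recognition_table
#' @return A `recognition_table` covering all 61 sense codons.
#' @export
default_recognition_table <- function(class_coeffs = default_class_coeffs()) {
  build_recognition_table(default_wobble_rules(), class_coeffs)
}

#' Read / write a recognition table as TSV
#'
#' The TSV has columns `codon`, `trna_id`, `alpha` (tab-separated, header).
#'
#' @param path File path.
#' @param partial Passed to [build_recognition_table()].
#' @return `read_recognition_tsv()` returns a `recognition_table`.
#' @export
read_recognition_tsv <- function(path, partial = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_recognition_table(df, class_coeffs = numeric(0), partial = partial)
}

#' @rdname read_recognition_tsv
#' @param table A `recognition_table`.
#' @export
write_recognition_tsv <- function(table, path) {
  idx <- which(table$alpha > 0, arr.ind = TRUE)
  df <- data.frame(codon = rownames(table$alpha)[idx[, 1L]],
                   trna_id = colnames(table$alpha)[idx[, 2L]],
                   alpha = table$alpha[idx])
  df <- df[order(df$codon, df$trna_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: 61 x 61 logical matrix, TRUE when two codons share a decoder.
co_decoded_matrix <- function(table) {
  m <- (table$alpha > 0) %*% t(table$alpha > 0) > 0
  dimnames(m) <- list(sense_codons(), sense_codons())
  m
}
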