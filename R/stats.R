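#' Assemble a per-variant feature table from simulation results
#'
#' Rows are variants (or genes), ESDR columns are the time-averaged
#' per-codon effective supply-demand ratios from each variant's whole-cell
#' simulation (`ESDR_AUG` doubles as the start-codon feature), and `extra`
#' supplies additional per-variant covariates such as folding energy and
#' CAI. Rows with missing values should be dropped by the caller before
#' regression (only variants with complete data are usable).
#'
#' @param sims Named list of `simulation_result` objects, one per variant.
#' @param extra Optional data frame / matrix of additional columns (e.g.
#'   `FE`, `CAI`), same row order.
#' @return Numeric feature matrix with informative column names.
#' @export
esdr_feature_table <- function(sims, extra = NULL) {
  X <- t(vapply(sims, function(s) as.numeric(s$esdr_mean), numeric(61)))
  colnames(X) <- paste0("ESDR_", sense_codons())
  rownames(X) <- names(sims)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  X
}

#' Ordinary least squares with explicit rank checking
#'
#' Fits `y ~ 1 + X` by QR and reports the in-sample coefficient of
#' determination. Rank-deficient designs raise an error naming the
#' collinear columns rather than silently dropping them.
#'
#' @param X Numeric matrix (rows = observations); column names are used in
#'   diagnostics.
#' @param y Numeric response.
#' @return List with `coefficients` (named vector, `(Intercept)` first),
#'   `r2`, `fitted`, `residuals`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X))
    stop("need more rows than columns (", nrow(X), " <= ", ncol(X), ")")
  M <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    dropped <- colnames(M)[qr_$pivot[(qr_$rank + 1L):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_, y)
  fitted <- drop(M %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(coefficients = beta, r2 = 1 - ss_res / ss_tot,
       fitted = fitted, residuals = y - fitted)
}

# Fast inner fit for the greedy search: train on (Xtr, ytr), return R^2 on
# the evaluation set; -Inf when the design is numerically singular.
r2_eval <- function(Xtr, ytr, Xev, yev) {
  M <- cbind(1, Xtr)
  f <- tryCatch(.lm.fit(M, ytr), error = function(e) NULL)
  if (is.null(f) || f$rank < ncol(M)) return(-Inf)
  pred <- drop(cbind(1, Xev) %*% f$coefficients)
  1 - sum((yev - pred)^2) / sum((yev - mean(yev))^2)
}

#' Repeated train/test greedy forward feature selection with SCR scoring
#'
#' Runs `n_rep` random train/test splits. Within each repetition, features
#' are added greedily: the next feature is the one whose addition maximizes
#' the change in R-squared, evaluated by default on the held-out test set
#' (switchable to the training set). A feature selected i-th in a
#' repetition contributes i to its SCR (selection-rank) score; features
#' never selected in a repetition contribute `M + 1`. Features are then
#' ranked by ascending SCR - the lower the score, the earlier and more
#' consistently the feature was picked.
#'
#' @param X Feature matrix with column names; no missing values.
#' @param y Objective vector.
#' @param n_rep Number of train/test repetitions.
#' @param train_frac Training fraction (`floor(train_frac * n)` rows).
#' @param max_features Features selected per repetition (capped at `M`).
#' @param eval_on `"test"` (default) or `"train"`: where the greedy
#'   R-squared is measured.
#' @return Object of class `selection_result`: `scr` (named scores),
#'   `ranked` (features by ascending SCR, ties by name), `orders`
#'   (`n_rep x max_features` matrix of selected feature names), `r2_train`
#'   and `r2_test` (`n_rep x max_features` curves), `n_rep`.
#' @export
forward_select <- function(X, y, n_rep = 100L, train_frac = 2 / 3,
                           max_features = min(15L, ncol(X)),
                           eval_on = c("test", "train")) {
  eval_on <- match.arg(eval_on)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in feature table")
  if (n_rep < 1L) stop("n_rep must be >= 1")
  n <- nrow(X); M <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(M))
  feats <- colnames(X)
  max_features <- min(max_features, M)
  n_tr <- floor(train_frac * n)
  if (n_tr < 3L || n_tr >= n) stop("not enough rows for the split")

  scr <- stats::setNames(numeric(M), feats)
  orders <- matrix(NA_character_, n_rep, max_features)
  r2_train <- matrix(NA_real_, n_rep, max_features)
  r2_test <- matrix(NA_real_, n_rep, max_features)

  for (rep in seq_len(n_rep)) {
    tr <- sample.int(n, n_tr)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[-tr, , drop = FALSE]; yte <- y[-tr]
    chosen <- integer(0)
    for (i in seq_len(max_features)) {
      cand <- setdiff(seq_len(M), chosen)
      # tie-break by feature-name order: evaluate in that order, strict >
      cand <- cand[order(feats[cand])]
      best_r2 <- -Inf; best <- NA_integer_
      for (k in cand) {
        cols <- c(chosen, k)
        r2 <- if (eval_on == "test")
          r2_eval(Xtr[, cols, drop = FALSE], ytr,
                  Xte[, cols, drop = FALSE], yte)
        else
          r2_eval(Xtr[, cols, drop = FALSE], ytr,
                  Xtr[, cols, drop = FALSE], ytr)
        if (r2 > best_r2 + 1e-12) { best_r2 <- r2; best <- k }
      }
      if (is.na(best)) break  # every remaining candidate singular
      chosen <- c(chosen, best)
      orders[rep, i] <- feats[best]
      cols <- chosen
      r2_train[rep, i] <- r2_eval(Xtr[, cols, drop = FALSE], ytr,
                                  Xtr[, cols, drop = FALSE], ytr)
      r2_test[rep, i] <- r2_eval(Xtr[, cols, drop = FALSE], ytr,
                                 Xte[, cols, drop = FALSE], yte)
    }
    rank_this <- stats::setNames(rep(M + 1, M), feats)
    sel <- orders[rep, !is.na(orders[rep, ])]
    rank_this[sel] <- seq_along(sel)
    scr <- scr + rank_this
  }
  ranked <- feats[order(scr, feats)]
  structure(list(scr = scr, ranked = ranked, orders = orders,
                 r2_train = r2_train, r2_test = r2_test, n_rep = n_rep),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  top <- utils::head(x$ranked, 8L)
  cat("selection_result:", x$n_rep, "repetitions;",
      length(x$ranked), "features\n  top:",
      paste(sprintf("%s(%g)", top, x$scr[top]), collapse = " "), "\n")
  invisible(x)
}

#' Correlation curves over increasing numbers of ranked features
#'
#' For each `k`, fits OLS on the full table using the top-`k` ranked
#' features and records Pearson and Spearman correlation between the fitted
#' values and the objective.
#'
#' @param X Feature matrix.
#' @param y Objective vector.
#' @param ranked Feature names in priority order (e.g. from
#'   [forward_select()]).
#' @param ks Feature counts to evaluate.
#' @return Data frame with columns `k`, `pearson`, `spearman`.
#' @export
evaluate_ranked <- function(X, y, ranked, ks = seq_along(ranked)) {
  X <- as.matrix(X)
  stopifnot(all(ranked %in% colnames(X)), max(ks) <= length(ranked))
  rows <- lapply(ks, function(k) {
    fit <- tryCatch(fit_ols(X[, ranked[seq_len(k)], drop = FALSE], y),
                    error = function(e) NULL)
    if (is.null(fit)) return(data.frame(k = k, pearson = NA, spearman = NA))
    data.frame(k = k,
               pearson = stats::cor(fit$fitted, y),
               spearman = stats::cor(fit$fitted, y, method = "spearman"))
  })
  do.call(rbind, rows)
}

#' Partial Spearman correlation
#'
#' Spearman correlation between `x` and `y` after regressing the ranks of
#' both on the ranks of the control variables and correlating the
#' residuals. With no controls this reduces to the ordinary Spearman
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param controls Optional numeric matrix/data.frame of control variables.
#' @return Correlation in `[-1, 1]`.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  if (is.null(controls) || NCOL(controls) == 0L)
    return(stats::cor(rx, ry))
  rc <- apply(as.matrix(controls), 2L, rank)
  ex <- stats::lm.fit(cbind(1, rc), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rc), ry)$residuals
  # residual variance at numerical zero (control spans the variable)
  tiny <- 1e-10 * n^3  # rank sums of squares scale like n^3
  if (sum(ex^2) < tiny || sum(ey^2) < tiny) return(0)
  stats::cor(ex, ey)
}
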