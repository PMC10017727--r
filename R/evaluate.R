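#' Regression metrics for genotype prediction
#'
#' @param y_true observed additive genotype codes (length >= 2).
#' @param y_pred predicted values, same length.
#' @return list with `rmse` (root mean squared error), `cc` (Pearson
#'   correlation between predicted and observed; 0 with `degenerate = TRUE`
#'   when either vector has zero variance), and `degenerate`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (length(y_true) < 2L) stop("need at least two observations", call. = FALSE)
  rmse <- sqrt(mean((y_true - y_pred)^2))
  degenerate <- stats::sd(y_pred) == 0 || stats::sd(y_true) == 0
  cc <- if (degenerate) 0 else stats::cor(y_true, y_pred)
  list(rmse = rmse, cc = cc, degenerate = degenerate)
}

#' Default regularization ladder
#'
#' The half-decade grid `1e-5, 3e-5, 1e-4, 3e-4, ..., 1, 3` (12 values) used
#' for both penalty weights.
#' @return numeric vector of length 12.
#' @export
lambda_ladder <- function() {
  as.numeric(outer(c(1, 3), 10^(-5:0)))
}

# stratified k-fold assignment: within each stage, subjects are shuffled and
# dealt round-robin so every fold sees every stage when counts allow
make_folds <- function(stages, k, seed) {
  n <- length(stages)
  if (k < 2L || k > n) stop("k must be in [2, N]", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    for (s in unique(stages)) {
      idx <- which(stages == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

fit_and_score <- function(X, y, stages, train, test, variant, modality,
                          lambda1, lambda2, max_iter, tol) {
  Xtr <- lapply(X, function(Xm) Xm[train, , drop = FALSE])
  Xte <- lapply(X, function(Xm) Xm[test, , drop = FALSE])
  fit <- suppressWarnings(msdmm_fit(
    Xtr, y[train], stages = stages[train], lambda1 = lambda1,
    lambda2 = lambda2, variant = variant, modality = modality,
    max_iter = max_iter, tol = tol))
  pred_tr <- predict(fit, Xtr)
  pred_te <- predict(fit, Xte)
  list(fit = fit, pred_train = pred_tr, pred_test = pred_te)
}

#' Repeated nested cross-validated evaluation
#'
#' Outer k-fold cross-validation (stratified by diagnosis stage), repeated
#' `repeats` times with fold seeds `seed + r`. Within each outer training
#' set an inner k-fold grid search selects `(lambda1, lambda2)` minimizing
#' the mean inner-test RMSE (averaged over modalities); the model is then
#' refit on the full outer-training set and scored on the held-out fold.
#' Weight magnitudes are averaged across all outer folds and repeats for
#' downstream ROI ranking.
#'
#' @param X list of M feature matrices (N x d) with shared ROI column names.
#' @param y length-N additive genotype vector.
#' @param stages length-N diagnosis-stage labels used for stratification and
#'   (in `MSD-*` variants) the Laplacian term.
#' @param variant model variant, see [msdmm_fit()].
#' @param lambda1_grid,lambda2_grid candidate penalty weights (defaults:
#'   [lambda_ladder()]; `lambda2_grid` collapses to 0 for non-MSD variants).
#' @param repeats number of independent cross-validation repeats.
#' @param k number of outer (and inner) folds.
#' @param seed base RNG seed; repeat r uses `seed + r`.
#' @param modality modality used by `SM`/`MSD-SM`.
#' @param max_iter,tol solver controls used for every fit.
#' @return a `cv_result`: list with `metrics` (data frame: repeat, fold,
#'   modality, train/test rmse and cc, degenerate flag), `selected`
#'   (per-fold chosen penalties), `weights_mean_abs` and `weights_mean`
#'   (d x M matrices averaged over folds and repeats), `folds`, and the
#'   configuration.
#' @export
nested_cv <- function(X, y, stages, variant = "MSD-MM",
                      lambda1_grid = lambda_ladder(),
                      lambda2_grid = lambda_ladder(),
                      repeats = 5L, k = 5L, seed = 1L, modality = 1L,
                      max_iter = 500L, tol = 1e-5) {
  X <- lapply(if (is.matrix(X)) list(X) else X, as.matrix)
  y <- as.numeric(y)
  stages <- as.character(stages)
  n <- length(y)
  if (n < 2L * k) stop("need at least 2k subjects", call. = FALSE)
  if (!startsWith(variant, "MSD")) lambda2_grid <- 0
  if (length(lambda1_grid) == 0L || length(lambda2_grid) == 0L)
    stop("empty penalty grid", call. = FALSE)
  grid <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid,
                      KEEP.OUT.ATTRS = FALSE)

  metrics <- list()
  selected <- list()
  W_abs_sum <- NULL
  W_sum <- NULL
  n_fits <- 0L
  fold_table <- list()

  for (r in seq_len(repeats)) {
    folds <- make_folds(stages, k, seed + r)
    fold_table[[r]] <- folds
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- which(folds != f)
      inner <- make_folds(stages[train], k, seed + 1000L * r + f)
      # grid search on the outer-training part only
      mean_rmse <- vapply(seq_len(nrow(grid)), function(g) {
        rmses <- c()
        for (fi in seq_len(k)) {
          i_te <- train[inner == fi]
          i_tr <- train[inner != fi]
          if (length(i_te) == 0L) next
          sc <- fit_and_score(X, y, stages, i_tr, i_te, variant, modality,
                              grid$lambda1[g], grid$lambda2[g],
                              max_iter, tol)
          per_mod <- vapply(seq_len(ncol(sc$pred_test)), function(m)
            compute_metrics(y[i_te], sc$pred_test[, m])$rmse, numeric(1))
          rmses <- c(rmses, mean(per_mod))
        }
        mean(rmses)
      }, numeric(1))
      best <- which.min(mean_rmse)  # ties: first in grid order
      l1 <- grid$lambda1[best]
      l2 <- grid$lambda2[best]
      sc <- fit_and_score(X, y, stages, train, test, variant, modality,
                          l1, l2, max_iter, tol)
      W <- sc$fit$W
      if (is.null(W_abs_sum)) {
        W_abs_sum <- abs(W)
        W_sum <- W
      } else {
        W_abs_sum <- W_abs_sum + abs(W)
        W_sum <- W_sum + W
      }
      n_fits <- n_fits + 1L
      selected[[length(selected) + 1L]] <-
        data.frame(rep = r, fold = f, lambda1 = l1, lambda2 = l2)
      for (m in seq_len(ncol(sc$pred_test))) {
        mtr <- compute_metrics(y[train], sc$pred_train[, m])
        mte <- compute_metrics(y[test], sc$pred_test[, m])
        metrics[[length(metrics) + 1L]] <- data.frame(
          rep = r, fold = f, modality = colnames(sc$pred_test)[m],
          rmse_train = mtr$rmse, cc_train = mtr$cc,
          rmse_test = mte$rmse, cc_test = mte$cc,
          degenerate = mte$degenerate)
      }
    }
  }

  structure(list(
    metrics = do.call(rbind, metrics),
    selected = do.call(rbind, selected),
    weights_mean_abs = W_abs_sum / n_fits,
    weights_mean = W_sum / n_fits,
    folds = fold_table,
    variant = variant,
    seed = seed,
    k = k,
    repeats = repeats,
    lambda1_grid = lambda1_grid,
    lambda2_grid = lambda2_grid
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d repeat(s) x %d-fold CV\n",
              x$variant, x$repeats, x$k))
  agg <- stats::aggregate(cbind(rmse_test, cc_test) ~ modality,
                          data = x$metrics, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Summarize mean test metrics of a cross-validation run
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data frame of mean/sd train and test RMSE and CC per modality.
#' @export
summary.cv_result <- function(object, ...) {
  m <- object$metrics
  agg <- stats::aggregate(
    cbind(rmse_train, cc_train, rmse_test, cc_test) ~ modality,
    data = m, FUN = mean)
  sds <- stats::aggregate(cbind(rmse_test, cc_test) ~ modality,
                          data = m, FUN = stats::sd)
  agg$rmse_test_sd <- sds$rmse_test
  agg$cc_test_sd <- sds$cc_test
  agg
}

#' Rank ROIs by cross-validated weight magnitude
#'
#' Sorts features of one modality by the mean absolute fitted weight across
#' all outer folds and repeats (absolute value prevents sign cancellation
#' when averaging; the signed mean is reported alongside).
#'
#' @param cv a `cv_result`.
#' @param modality modality name or column index.
#' @param top_k how many ROIs to return (default: all).
#' @return data frame with `rank`, `roi`, `mean_abs_weight`, `mean_weight`.
#' @export
rank_rois <- function(cv, modality = 1L, top_k = NULL) {
  Wa <- cv$weights_mean_abs
  if (is.character(modality) && !modality %in% colnames(Wa))
    stop(sprintf("unknown modality: %s", modality), call. = FALSE)
  wa <- Wa[, modality]
  ws <- cv$weights_mean[, modality]
  top_k <- top_k %||% length(wa)
  stopifnot(top_k >= 1, top_k <= length(wa))
  nm <- rownames(Wa) %||% as.character(seq_len(nrow(Wa)))
  ord <- order(-wa, nm)
  sel <- ord[seq_len(top_k)]
  data.frame(rank = seq_len(top_k),
             roi = nm[sel],
             mean_abs_weight = unname(wa[sel]),
             mean_weight = unname(ws[sel]),
             stringsAsFactors = FALSE)
}

#' Screen candidate SNPs by cross-validated association strength
#'
#' Runs [nested_cv()] once per SNP column, using that SNP's additive codes
#' as the response, and reports the mean and standard deviation of the test
#' correlation coefficient per modality, sorted by overall mean CC.
#' Constant (monomorphic) SNP columns are skipped with a message.
#'
#' @param X list of modality feature matrices.
#' @param stages diagnosis-stage labels.
#' @param genotypes N x S matrix of additive codes, one column per SNP.
#' @param variant model variant.
#' @param ... further arguments passed to [nested_cv()].
#' @return a `screen_result` data frame: one row per screened SNP with mean
#'   and sd test CC per modality and an overall ranking.
#' @export
screen_snps <- function(X, stages, genotypes, variant = "MSD-MM", ...) {
  genotypes <- as.matrix(genotypes)
  snp_ids <- colnames(genotypes) %||% paste0("SNP", seq_len(ncol(genotypes)))
  rows <- list()
  for (s in seq_len(ncol(genotypes))) {
    g <- genotypes[, s]
    if (length(unique(g)) < 2L) {
      message(sprintf("skipping constant SNP column: %s", snp_ids[s]))
      next
    }
    cv <- nested_cv(X, g, stages, variant = variant, ...)
    m <- cv$metrics
    agg <- stats::aggregate(cc_test ~ modality, data = m, FUN = mean)
    sds <- stats::aggregate(cc_test ~ modality, data = m, FUN = stats::sd)
    row <- data.frame(snp = snp_ids[s], mean_cc = mean(agg$cc_test))
    for (i in seq_len(nrow(agg))) {
      row[[paste0("cc_", agg$modality[i])]] <- agg$cc_test[i]
      row[[paste0("sd_", sds$modality[i])]] <- sds$cc_test[i]
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("no screenable SNP columns", call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_cc), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_result", class(out))
  out
}

#' Penalty-sensitivity grid
#'
#' Fixed-hyperparameter (non-nested) k-fold cross-validation for every
#' `(lambda1, lambda2)` cell, reporting the mean test correlation per
#' modality. The same fold assignment is used for every cell so cells are
#' directly comparable and independent of evaluation order.
#'
#' @inheritParams nested_cv
#' @return list of matrices (one per modality), rows indexed by `lambda1`,
#'   columns by `lambda2`, entries = mean test CC; attribute `degenerate`
#'   marks cells whose predictions had zero variance in every fold.
#' @export
sensitivity_grid <- function(X, y, stages, variant = "MSD-MM",
                             lambda1_grid = lambda_ladder(),
                             lambda2_grid = lambda_ladder(),
                             k = 5L, seed = 1L, modality = 1L,
                             max_iter = 500L, tol = 1e-5) {
  X <- lapply(if (is.matrix(X)) list(X) else X, as.matrix)
  y <- as.numeric(y)
  stages <- as.character(stages)
  if (!startsWith(variant, "MSD")) lambda2_grid <- 0
  folds <- make_folds(stages, k, seed)
  mod_names <- prepare_variant(X, variant, modality)$modality_names
  out <- lapply(mod_names, function(m)
    matrix(NA_real_, length(lambda1_grid), length(lambda2_grid),
           dimnames = list(format(lambda1_grid, trim = TRUE),
                           format(lambda2_grid, trim = TRUE))))
  names(out) <- mod_names
  degen <- matrix(FALSE, length(lambda1_grid), length(lambda2_grid))
  for (i in seq_along(lambda1_grid)) {
    for (j in seq_along(lambda2_grid)) {
      ccs <- matrix(NA_real_, k, length(mod_names))
      dg <- logical(k)
      for (f in seq_len(k)) {
        test <- which(folds == f)
        train <- which(folds != f)
        sc <- fit_and_score(X, y, stages, train, test, variant, modality,
                            lambda1_grid[i], lambda2_grid[j], max_iter, tol)
        for (m in seq_along(mod_names)) {
          met <- compute_metrics(y[test], sc$pred_test[, m])
          ccs[f, m] <- met$cc
          dg[f] <- dg[f] || met$degenerate
        }
      }
      for (m in seq_along(mod_names)) out[[m]][i, j] <- mean(ccs[, m])
      degen[i, j] <- all(dg)
    }
  }
  attr(out, "degenerate") <- degen
  attr(out, "folds") <- folds
  out
}

#' Permutation null distribution of the test correlation
#'
#' Repeats a fixed-penalty cross-validated evaluation with the response
#' permuted, giving a null distribution of mean test CC for calibration of
#' screening results.
#'
#' @inheritParams nested_cv
#' @param lambda1,lambda2 fixed penalty weights for the null fits.
#' @param n_perm number of permutations.
#' @return numeric vector of length `n_perm`: mean test CC (over folds and
#'   modalities) under permuted responses.
#' @export
permutation_null_cc <- function(X, y, stages, variant = "MSD-MM",
                                lambda1 = 0.1, lambda2 = 0.1,
                                n_perm = 100L, k = 5L, seed = 1L,
                                modality = 1L, max_iter = 300L, tol = 1e-5) {
  X <- lapply(if (is.matrix(X)) list(X) else X, as.matrix)
  y <- as.numeric(y)
  perms <- with_seed(seed, replicate(n_perm, sample.int(length(y)),
                                     simplify = FALSE))
  vapply(seq_len(n_perm), function(p) {
    yp <- y[perms[[p]]]
    g <- sensitivity_grid(X, yp, stages, variant = variant,
                          lambda1_grid = lambda1, lambda2_grid = lambda2,
                          k = k, seed = seed, modality = modality,
                          max_iter = max_iter, tol = tol)
    mean(vapply(g, function(m) m[1, 1], numeric(1)))
  }, numeric(1))
}
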