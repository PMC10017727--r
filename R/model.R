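#' Same-stage subject similarity matrix
#'
#' `S[i, j] = 1` when subjects i and j carry the same diagnosis stage and 0
#' otherwise; the diagonal is 1. Any finite label set is accepted (the
#' canonical stages are `HC`, `MD`, `SD`).
#'
#' @param stages length-N vector of stage labels.
#' @return N x N binary symmetric matrix.
#' @export
build_similarity <- function(stages) {
  if (length(stages) == 0L) stop("empty stage vector", call. = FALSE)
  stages <- as.character(stages)
  S <- outer(stages, stages, `==`) * 1
  S
}

#' Graph Laplacian of a subject-similarity matrix
#'
#' Returns the unnormalized Laplacian `L = D - S` with `D` the diagonal
#' degree matrix `D_ii = sum_j S_ij`. Its quadratic form
#' `w' X' L X w` equals half the similarity-weighted sum of squared
#' differences between predicted values of subject pairs, so penalizing it
#' pulls same-stage predictions together.
#'
#' @param S symmetric binary similarity matrix (see [build_similarity()]).
#' @return a `stage_graph`: list with elements `S`, `D`, `L`.
#' @export
build_laplacian <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 0)
    stop("similarity matrix must be square and symmetric", call. = FALSE)
  if (!all(S %in% c(0, 1)))
    stop("similarity matrix must be binary", call. = FALSE)
  D <- diag(rowSums(S), nrow(S))
  structure(list(S = S, D = D, L = D - S), class = "stage_graph")
}

#' Row-wise L2,1 norm of a weight matrix
#' @param W d x M matrix.
#' @return sum over rows of the Euclidean row norm.
#' @export
l21_norm <- function(W) {
  sum(sqrt(rowSums(as.matrix(W)^2)))
}

#' Proximal operator of the L2,1 norm
#'
#' Solves `argmin_X 0.5 ||X - V||_F^2 + tau * sum_j ||x_j||_2` row by row:
#' each row is shrunk toward zero by `max(0, 1 - tau / ||v_j||_2)`, so rows
#' with norm at most `tau` vanish exactly. This is the group soft-threshold
#' behind joint (row-wise) feature selection across modalities.
#'
#' @param V numeric matrix (d x M).
#' @param tau nonnegative threshold.
#' @return matrix of the same shape.
#' @export
prox_l21 <- function(V, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  V <- as.matrix(V)
  rn <- sqrt(rowSums(V^2))
  scale <- ifelse(rn > 0, pmax(0, 1 - tau / rn), 0)
  V * scale
}

# internal: per-modality quadratic pieces A^m = X'X + 2*lambda2*X'LX, b^m = X'y
build_quadratics <- function(X, y, L = NULL, lambda2 = 0) {
  lapply(X, function(Xm) {
    A <- crossprod(Xm)
    if (lambda2 > 0 && !is.null(L)) A <- A + 2 * lambda2 * crossprod(Xm, L %*% Xm)
    list(A = (A + t(A)) / 2, b = as.numeric(crossprod(Xm, y)))
  })
}

#' Objective of the stage-regularized multi-modal model
#'
#' Evaluates
#' \deqn{\tfrac12\sum_m \|y - X^m w^m\|_2^2 + \lambda_1 \|W\|_{2,1}
#'       + \lambda_2 \sum_m (w^m)' (X^m)' L^m X^m w^m.}
#'
#' @param W d x M weight matrix (columns = modalities).
#' @param X list of M feature matrices, each N x d.
#' @param y length-N response (additively coded genotype).
#' @param graphs `stage_graph`, or list of one per modality, or `NULL` when
#'   `lambda2 = 0`.
#' @param lambda1,lambda2 nonnegative regularization weights.
#' @return scalar objective value.
#' @export
objective_value <- function(W, X, y, graphs = NULL, lambda1 = 0, lambda2 = 0) {
  W <- as.matrix(W)
  X <- check_modalities(X, y, d = nrow(W))
  Ls <- graphs_to_laplacians(graphs, length(X), length(y), lambda2)
  loss <- 0
  for (m in seq_along(X)) {
    r <- y - X[[m]] %*% W[, m]
    loss <- loss + 0.5 * sum(r^2)
    if (lambda2 > 0) {
      p <- X[[m]] %*% W[, m]
      loss <- loss + lambda2 * as.numeric(crossprod(p, Ls[[m]] %*% p))
    }
  }
  loss + lambda1 * l21_norm(W)
}

#' Gradient of the smooth part of the objective
#'
#' Column m is `(X^m)'(X^m w^m - y) + 2*lambda2*(X^m)' L^m X^m w^m`; the
#' nonsmooth L2,1 term is handled by its proximal operator, not here.
#'
#' @inheritParams objective_value
#' @return d x M gradient matrix.
#' @export
smooth_gradient <- function(W, X, y, graphs = NULL, lambda2 = 0) {
  W <- as.matrix(W)
  X <- check_modalities(X, y, d = nrow(W))
  Ls <- graphs_to_laplacians(graphs, length(X), length(y), lambda2)
  G <- W * 0
  for (m in seq_along(X)) {
    p <- X[[m]] %*% W[, m]
    g <- crossprod(X[[m]], p - y)
    if (lambda2 > 0) g <- g + 2 * lambda2 * crossprod(X[[m]], Ls[[m]] %*% p)
    G[, m] <- g
  }
  G
}

check_modalities <- function(X, y, d = NULL) {
  if (is.matrix(X)) X <- list(X)
  N <- length(y)
  for (m in seq_along(X)) {
    X[[m]] <- as.matrix(X[[m]])
    if (nrow(X[[m]]) != N)
      stop(sprintf("modality %d has %d rows but y has length %d",
                   m, nrow(X[[m]]), N), call. = FALSE)
    if (!is.null(d) && ncol(X[[m]]) != d)
      stop(sprintf("modality %d has %d columns, expected %d",
                   m, ncol(X[[m]]), d), call. = FALSE)
  }
  X
}

graphs_to_laplacians <- function(graphs, M, N, lambda2) {
  if (lambda2 == 0 || is.null(graphs)) return(vector("list", M))
  if (inherits(graphs, "stage_graph")) graphs <- rep(list(graphs), M)
  if (length(graphs) == 1L) graphs <- rep(graphs, M)
  lapply(graphs, function(g) {
    L <- if (inherits(g, "stage_graph")) g$L else as.matrix(g)
    if (nrow(L) != N) stop("Laplacian size does not match N", call. = FALSE)
    L
  })
}

# accelerated proximal gradient (FISTA with backtracking and a monotone
# function-value restart) on 0.5 w'Aw - b'w per column + lambda1 * L2,1
apg_solve <- function(quads, lambda1, max_iter = 1000L, tol = 1e-6,
                      const = 0) {
  d <- length(quads[[1]]$b)
  M <- length(quads)
  fval <- function(W) {
    s <- const
    for (m in seq_len(M))
      s <- s + 0.5 * sum(W[, m] * (quads[[m]]$A %*% W[, m])) -
        sum(quads[[m]]$b * W[, m])
    s
  }
  grad <- function(W) {
    G <- W
    for (m in seq_len(M))
      G[, m] <- quads[[m]]$A %*% W[, m] - quads[[m]]$b
    G
  }
  Lip <- max(vapply(quads, function(q) power_lambda_max(q$A), numeric(1)))
  if (Lip <= 0) Lip <- 1
  step_L <- Lip  # backtracking only increases from this estimate

  W <- matrix(0, d, M)
  Z <- W
  tk <- 1
  fW <- fval(W)
  obj <- fW + lambda1 * l21_norm(W)
  trace <- obj
  converged <- FALSE
  iters <- 0L

  prox_step <- function(Y, fY, GY) {
    # backtracking: halve the step (double step_L) until the quadratic
    # upper bound holds at the prox point
    repeat {
      P <- prox_l21(Y - GY / step_L, lambda1 / step_L)
      fP <- fval(P)
      dP <- P - Y
      if (fP <= fY + sum(GY * dP) + 0.5 * step_L * sum(dP^2) + 1e-12 * abs(fP))
        return(list(P = P, fP = fP))
      step_L <<- 2 * step_L
      if (!is.finite(step_L)) stop("backtracking diverged", call. = FALSE)
    }
  }

  for (it in seq_len(max_iter)) {
    iters <- it
    GZ <- grad(Z)
    fZ <- fval(Z)
    st <- prox_step(Z, fZ, GZ)
    obj_new <- st$fP + lambda1 * l21_norm(st$P)
    if (!is.finite(obj_new))
      stop(sprintf("divergent objective at iteration %d (step size %.3e)",
                   it, 1 / step_L), call. = FALSE)
    if (obj_new > obj) {
      # monotone safeguard: momentum overshot; restart from the best iterate
      GW <- grad(W)
      st <- prox_step(W, fW, GW)
      obj_new <- st$fP + lambda1 * l21_norm(st$P)
      tk <- 1
      if (obj_new > obj) {  # numerically at a fixed point
        trace <- c(trace, obj)
        converged <- TRUE
        break
      }
    }
    W_new <- st$P
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- W_new + ((tk - 1) / t_new) * (W_new - W)
    rel <- abs(obj - obj_new) / max(1, abs(obj))
    W <- W_new
    fW <- st$fP
    obj <- obj_new
    tk <- t_new
    trace <- c(trace, obj)
    if (rel <= tol) {
      converged <- TRUE
      break
    }
  }
  list(W = W, objective_trace = trace, converged = converged,
       iterations = iters, lipschitz = Lip)
}

#' Fit the stage-regularized multi-modal association model
#'
#' Minimizes
#' \deqn{\tfrac12\sum_m \|y - X^m w^m\|_2^2 + \lambda_1 \|W\|_{2,1}
#'       + \lambda_2 \sum_m (w^m)'(X^m)' L^m X^m w^m}
#' by accelerated proximal gradient (backtracking line search on the smooth
#' part, group soft-threshold step, momentum with a function-value restart
#' that keeps the objective trace non-increasing).
#'
#' Variants follow the standard ablation grid: `SM` uses a single modality,
#' `CM` concatenates all modalities into one feature block (the L2,1 penalty
#' then reduces to the lasso), `MM` keeps modalities as separate tasks; the
#' `MSD-` prefixed variants add the diagnosis-stage Laplacian term, the plain
#' ones force `lambda2 = 0`.
#'
#' By default each feature column is z-scored with training statistics and
#' the model is fit to the centered response; `mean(y)` is stored as the
#' per-modality intercept so predictions return to the 0-2 genotype scale.
#'
#' @param X list of M feature matrices (N x d), or a single matrix.
#' @param y length-N numeric response (additive genotype codes).
#' @param stages length-N stage labels; required for `MSD-*` variants.
#' @param lambda1 L2,1 (group sparsity) weight.
#' @param lambda2 stage-Laplacian weight; ignored (forced to 0) for
#'   `SM`, `CM`, `MM`.
#' @param variant one of `"MSD-MM"`, `"MM"`, `"MSD-CM"`, `"CM"`,
#'   `"MSD-SM"`, `"SM"`.
#' @param modality which modality `SM`/`MSD-SM` uses (index or name).
#' @param standardize z-score feature columns with training statistics
#'   (default `TRUE`). Constant columns get a unit divisor with a warning.
#' @param max_iter,tol solver controls: iteration cap and relative
#'   objective-change tolerance.
#' @return an object of class `msdmm_fit` with elements `W` (d x M weight
#'   matrix on the standardized scale), `intercepts`, `objective_trace`,
#'   `converged`, `iterations`, the variant/penalty configuration, and the
#'   training standardization parameters.
#' @seealso [predict.msdmm_fit()], [nested_cv()]
#' @export
msdmm_fit <- function(X, y, stages = NULL, lambda1 = 0.1, lambda2 = 0.1,
                      variant = c("MSD-MM", "MM", "MSD-CM", "CM",
                                  "MSD-SM", "SM"),
                      modality = 1L, standardize = TRUE,
                      max_iter = 1000L, tol = 1e-6) {
  variant <- match.arg(variant)
  if (lambda1 < 0 || lambda2 < 0)
    stop("lambda1 and lambda2 must be nonnegative", call. = FALSE)
  y <- as.numeric(y)
  prep <- prepare_variant(X, variant, modality)
  Xv <- check_modalities(prep$X, y)
  uses_stages <- startsWith(variant, "MSD")
  if (!uses_stages) lambda2 <- 0
  graph <- NULL
  if (uses_stages && lambda2 > 0) {
    if (is.null(stages)) stop("MSD variants require stage labels", call. = FALSE)
    if (length(stages) != length(y))
      stop("stages must have one label per subject", call. = FALSE)
    graph <- build_laplacian(build_similarity(stages))
  }

  std <- standardize_modalities(Xv, standardize)
  y_mean <- mean(y)
  yc <- y - y_mean

  quads <- build_quadratics(std$X, yc,
                            L = if (!is.null(graph)) graph$L else NULL,
                            lambda2 = lambda2)
  sol <- apg_solve(quads, lambda1, max_iter = max_iter, tol = tol,
                   const = 0.5 * sum(yc^2) * length(std$X))
  W <- sol$W
  rownames(W) <- prep$feature_names
  colnames(W) <- prep$modality_names

  structure(list(
    W = W,
    intercepts = stats::setNames(rep(y_mean, length(std$X)), prep$modality_names),
    objective_trace = sol$objective_trace,
    converged = sol$converged,
    iterations = sol$iterations,
    variant = variant,
    modality = modality,
    lambda1 = lambda1,
    lambda2 = lambda2,
    standardize = standardize,
    centers = std$centers,
    scales = std$scales,
    feature_names = prep$feature_names,
    modality_names = prep$modality_names
  ), class = "msdmm_fit")
}

# map the input list of modalities to what a variant actually fits
prepare_variant <- function(X, variant, modality = 1L) {
  if (is.matrix(X) || is.data.frame(X)) X <- list(as.matrix(X))
  X <- lapply(X, as.matrix)
  mod_names <- names(X) %||% paste0("modality", seq_along(X))
  names(X) <- mod_names
  feat_names <- colnames(X[[1]]) %||% paste0("f", seq_len(ncol(X[[1]])))
  for (m in seq_along(X)) {
    fn <- colnames(X[[m]]) %||% feat_names
    if (!identical(fn, feat_names) && variant %in% c("MM", "MSD-MM"))
      stop("modalities must share feature (ROI) names", call. = FALSE)
    colnames(X[[m]]) <- fn
  }
  if (variant %in% c("SM", "MSD-SM")) {
    Xs <- X[modality]
    list(X = Xs, feature_names = colnames(Xs[[1]]),
         modality_names = names(Xs))
  } else if (variant %in% c("CM", "MSD-CM")) {
    wide <- do.call(cbind, lapply(seq_along(X), function(m) {
      Xm <- X[[m]]
      colnames(Xm) <- paste(names(X)[m], colnames(Xm), sep = ".")
      Xm
    }))
    list(X = list(combined = wide), feature_names = colnames(wide),
         modality_names = "combined")
  } else {
    if (length(X) < 2L)
      stop("multi-modality variants need at least two modalities", call. = FALSE)
    list(X = X, feature_names = feat_names, modality_names = mod_names)
  }
}

standardize_modalities <- function(X, standardize) {
  centers <- list()
  scales <- list()
  Xs <- X
  for (m in seq_along(X)) {
    if (standardize) {
      mu <- colMeans(X[[m]])
      sdv <- apply(X[[m]], 2, stats::sd)
      if (any(sdv == 0)) {
        warning(sprintf("constant feature column(s) in modality %d: unit divisor used", m),
                call. = FALSE)
        sdv[sdv == 0] <- 1
      }
    } else {
      mu <- rep(0, ncol(X[[m]]))
      sdv <- rep(1, ncol(X[[m]]))
    }
    Xs[[m]] <- sweep(sweep(X[[m]], 2, mu), 2, sdv, "/")
    centers[[m]] <- mu
    scales[[m]] <- sdv
  }
  list(X = Xs, centers = centers, scales = scales)
}

#' Per-modality predictions from a fitted model
#'
#' Applies the training standardization to new feature matrices and returns
#' one predicted genotype vector per modality
#' (`yhat^m = X^m_std w^m + intercept_m`).
#'
#' @param object an `msdmm_fit`.
#' @param newdata list of feature matrices matching the training modalities
#'   (a single matrix is accepted for single-modality fits).
#' @param ... unused.
#' @return N x M matrix of predictions, one column per modality.
#' @export
predict.msdmm_fit <- function(object, newdata, ...) {
  prep <- prepare_variant(newdata, object$variant, object$modality)
  Xv <- prep$X
  if (length(Xv) != ncol(object$W))
    stop("newdata modality count does not match the fit", call. = FALSE)
  out <- matrix(NA_real_, nrow(Xv[[1]]), length(Xv),
                dimnames = list(rownames(Xv[[1]]), object$modality_names))
  for (m in seq_along(Xv)) {
    if (ncol(Xv[[m]]) != nrow(object$W))
      stop("newdata feature dimension does not match the fit", call. = FALSE)
    Xs <- sweep(sweep(Xv[[m]], 2, object$centers[[m]]), 2,
                object$scales[[m]], "/")
    out[, m] <- as.numeric(Xs %*% object$W[, m]) + object$intercepts[[m]]
  }
  out
}

#' @export
print.msdmm_fit <- function(x, ...) {
  nz <- sum(sqrt(rowSums(x$W^2)) > 0)
  cat(sprintf("<msdmm_fit> variant=%s  lambda1=%g  lambda2=%g\n",
              x$variant, x$lambda1, x$lambda2))
  cat(sprintf("  %d features x %d modalities; %d nonzero rows; %s in %d iterations\n",
              nrow(x$W), ncol(x$W), nz,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Smallest L2,1 weight that zeroes the whole solution
#'
#' For `lambda1` at or above the maximum row norm of the stacked gradient
#' columns `(X^m)' y` (computed on the same standardized/centered scale the
#' solver uses), `W = 0` satisfies the optimality condition and the fitted
#' model is exactly zero.
#'
#' @inheritParams msdmm_fit
#' @return scalar threshold.
#' @export
lambda1_max <- function(X, y, variant = "MSD-MM", modality = 1L,
                        standardize = TRUE) {
  y <- as.numeric(y)
  prep <- prepare_variant(X, variant, modality)
  std <- standardize_modalities(check_modalities(prep$X, y), standardize)
  yc <- y - mean(y)
  B <- vapply(std$X, function(Xm) as.numeric(crossprod(Xm, yc)),
              numeric(length(prep$feature_names)))
  max(sqrt(rowSums(as.matrix(B)^2)))
}
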