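# Independent brute-force oracles used across the suite. These deliberately
# use naive scalar loops so they share no code path with the package.

# clustering coefficient by exhaustive enumeration of neighbour pairs
cc_oracle <- function(w, negative = "abs", geometric = FALSE) {
  if (negative == "abs") w <- abs(w) else w[w < 0] <- 0
  d <- nrow(w)
  maxw <- max(w[row(w) != col(w)], 0)
  out <- numeric(d)
  if (maxw == 0) return(out)
  wb <- w / maxw
  for (i in seq_len(d)) {
    nbr <- setdiff(which(w[i, ] != 0), i)
    k <- length(nbr)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nbr[a]; h <- nbr[b]
      term <- wb[i, j] * wb[i, h] * wb[j, h]
      if (geometric) term <- term^(1 / 3)
      s <- s + term
    }
    out[i] <- 2 / (k * (k - 1)) * s
  }
  out
}

# objective by term-by-term scalar summation
objective_oracle <- function(W, X, y, L = NULL, lambda1 = 0, lambda2 = 0) {
  M <- length(X)
  total <- 0
  for (m in seq_len(M)) {
    pred <- numeric(length(y))
    for (i in seq_along(y))
      for (j in seq_len(ncol(X[[m]])))
        pred[i] <- pred[i] + X[[m]][i, j] * W[j, m]
    total <- total + 0.5 * sum((y - pred)^2)
    if (lambda2 > 0) {
      for (i in seq_along(y)) for (jj in seq_along(y))
        total <- total + lambda2 * pred[i] * L[i, jj] * pred[jj]
    }
  }
  for (j in seq_len(nrow(W)))
    total <- total + lambda1 * sqrt(sum(W[j, ]^2))
  total
}

# plain (unaccelerated) proximal-gradient reference solver on the same
# quadratic; fixed step 1/L from an eigendecomposition, run to a numerical
# fixed point (capped at max_iter iterations)
pg_oracle <- function(X, y, L = NULL, lambda1, lambda2 = 0,
                      max_iter = 1e6, tol = 0) {
  M <- length(X)
  d <- ncol(X[[1]])
  A <- vector("list", M); b <- vector("list", M)
  for (m in seq_len(M)) {
    Am <- crossprod(X[[m]])
    if (lambda2 > 0) Am <- Am + 2 * lambda2 * crossprod(X[[m]], L %*% X[[m]])
    A[[m]] <- (Am + t(Am)) / 2
    b[[m]] <- as.numeric(crossprod(X[[m]], y))
  }
  lip <- max(vapply(A, function(a)
    max(eigen(a, symmetric = TRUE, only.values = TRUE)$values), numeric(1)))
  W <- matrix(0, d, M)
  for (it in seq_len(max_iter)) {
    G <- W
    for (m in seq_len(M)) G[, m] <- A[[m]] %*% W[, m] - b[[m]]
    V <- W - G / lip
    rn <- sqrt(rowSums(V^2))
    W_new <- V * ifelse(rn > 0, pmax(0, 1 - (lambda1 / lip) / rn), 0)
    if (max(abs(W_new - W)) <= tol) { W <- W_new; break }
    W <- W_new
  }
  W
}

pg_objective <- function(W, X, y, L = NULL, lambda1, lambda2 = 0) {
  M <- length(X)
  total <- 0
  for (m in seq_len(M)) {
    r <- y - X[[m]] %*% W[, m]
    total <- total + 0.5 * sum(r^2)
    if (lambda2 > 0) {
      p <- X[[m]] %*% W[, m]
      total <- total + lambda2 * as.numeric(crossprod(p, L %*% p))
    }
  }
  total + lambda1 * sum(sqrt(rowSums(W^2)))
}

random_fc <- function(d, density = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, d, d)
  up <- upper.tri(w)
  vals <- runif(sum(up), -1, 1) * (runif(sum(up)) < density)
  w[up] <- vals
  w <- w + t(w)
  diag(w) <- 0
  dimnames(w) <- list(paste0("R", 1:d), paste0("R", 1:d))
  w
}

random_instance <- function(N, d, M = 2, seed = 1) {
  set.seed(seed)
  X <- lapply(seq_len(M), function(m) matrix(rnorm(N * d), N, d))
  names(X) <- paste0("mod", seq_len(M))
  y <- rnorm(N)
  stages <- sample(c("HC", "MD", "SD"), N, replace = TRUE)
  list(X = X, y = y, stages = stages)
}

f1_score <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (tp == 0) return(0)
  prec <- tp / length(selected)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
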