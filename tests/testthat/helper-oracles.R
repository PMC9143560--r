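# Independent brute-force oracles used to check the package's algorithms.
# Each is deliberately naive: different algorithm, same mathematical object.

# kNN imputation by direct double loop over missing cells, pairwise-complete
# RMS distance, unweighted mean over the k nearest donors with the target
# feature observed.
brute_knn_impute <- function(x, k) {
  n <- nrow(x)
  out <- x
  dist_ij <- function(a, b) {
    shared <- which(!is.na(x[a, ]) & !is.na(x[b, ]))
    if (length(shared) == 0) return(Inf)
    sqrt(sum((x[a, shared] - x[b, shared])^2) / length(shared))
  }
  for (i in seq_len(n)) {
    for (j in which(is.na(x[i, ]))) {
      d <- vapply(setdiff(seq_len(n), i), function(b) dist_ij(i, b), 0)
      cand <- setdiff(seq_len(n), i)
      cand <- cand[order(d)]
      d <- sort(d)
      cand <- cand[is.finite(d)]
      donors <- cand[!is.na(x[cand, j])]
      out[i, j] <- if (length(donors) == 0) mean(x[, j], na.rm = TRUE)
        else mean(x[donors[seq_len(min(k, length(donors)))], j])
    }
  }
  out
}

# Weighted LASSO objective on centered data (matches lasso_cd with
# standardize = FALSE up to the centering it performs internally).
lasso_objective <- function(X, y, b, b0, lambda, vf, w = rep(1, length(y))) {
  n <- length(y)
  w <- w * n / sum(w)
  r <- y - b0 - as.numeric(X %*% b)
  sum(w * r^2) / (2 * n) + lambda * sum(vf * abs(b))
}

# Exact weighted-LASSO solution by exhaustive enumeration of sign patterns
# (3^p candidates): for each support/sign pattern solve the stationarity
# system and keep solutions consistent with their pattern and the
# subgradient bound; returns the candidate with the lowest objective.
lasso_sign_oracle <- function(X, y, lambda, vf, w = rep(1, length(y))) {
  n <- nrow(X); p <- ncol(X)
  w <- w * n / sum(w)
  xbar <- colSums(w * X) / n
  Xc <- sweep(X, 2L, xbar, "-")
  ybar <- sum(w * y) / n
  yc <- y - ybar
  G <- crossprod(w * Xc, Xc) / n
  c0 <- as.numeric(crossprod(w * Xc, yc)) / n

  best <- NULL; best_obj <- Inf
  patterns <- expand.grid(rep(list(c(-1, 0, 1)), p))
  for (r in seq_len(nrow(patterns))) {
    s <- as.numeric(patterns[r, ])
    A <- which(s != 0)
    b <- numeric(p)
    if (length(A)) {
      rhs <- c0[A] - lambda * vf[A] * s[A]
      sol <- tryCatch(solve(G[A, A, drop = FALSE], rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) != s[A])) next
      b[A] <- sol
    }
    g <- c0 - as.numeric(G %*% b)
    if (any(abs(g[setdiff(seq_len(p), A)]) >
            lambda * vf[setdiff(seq_len(p), A)] + 1e-9)) next
    obj <- lasso_objective(Xc, yc, b, 0, lambda, vf, w)
    if (obj < best_obj) { best_obj <- obj; best <- b }
  }
  list(beta = best, intercept = ybar - sum(xbar * best), objective = best_obj)
}

# Dense grid search minimization of the 2-feature LASSO objective, with
# iterative zooming around the incumbent.
lasso_grid_oracle <- function(X, y, lambda, vf, w = rep(1, length(y)),
                              span = 3, steps = 61, zooms = 4) {
  n <- nrow(X)
  w <- w * n / sum(w)
  xbar <- colSums(w * X) / n
  Xc <- sweep(X, 2L, xbar, "-")
  ybar <- sum(w * y) / n
  yc <- y - ybar
  ctr <- c(0, 0); half <- span
  for (z in seq_len(zooms)) {
    g1 <- seq(ctr[1] - half, ctr[1] + half, length.out = steps)
    g2 <- seq(ctr[2] - half, ctr[2] + half, length.out = steps)
    grid <- expand.grid(b1 = g1, b2 = g2)
    obj <- apply(grid, 1L, function(b)
      lasso_objective(Xc, yc, as.numeric(b), 0, lambda, vf, w))
    ctr <- as.numeric(grid[which.min(obj), ])
    half <- half * 2.5 / steps * 2
  }
  list(beta = ctr, intercept = ybar - sum(xbar * ctr))
}

# Hypergeometric upper tail P(X >= k) by direct summation of binomial
# coefficients.
brute_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the textbook construction.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Exact betweenness on a small directed graph by enumerating every simple
# path between every ordered pair, keeping the shortest ones, and crediting
# interior vertices fractionally.
brute_betweenness <- function(edges, nodes) {
  adj <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- path; return() }
      for (nb in adj[[v]]) if (!nb %in% path) walk(c(path, nb))
    }
    walk(s)
    out
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in setdiff(nodes, s)) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    len <- vapply(paths, length, 0L)
    sp <- paths[len == min(len)]
    for (pp in sp) {
      interior <- setdiff(pp, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(sp)
    }
  }
  btw
}

# Small abundance_matrix builder for fixtures.
make_abund <- function(values, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  if (is.null(batch)) batch <- rep("B1", nrow(values))
  abundance_matrix(values, batch)
}
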