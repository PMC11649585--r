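# Independent oracle implementations shared across test files.
# Each is a deliberately naive second route (literal formulas,
# exhaustive enumeration) kept separate from the package code.

# Literal transcription of the 1984 two-population variance-component
# estimator, written independently of the package implementation.
wc_oracle_pair <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  a_l <- b_l <- c_l <- numeric(length(p1))
  for (l in seq_along(p1)) {
    nbar <- (n1[l] + n2[l]) / 2
    nc <- (r * nbar - (n1[l]^2 + n2[l]^2) / (r * nbar)) / (r - 1)
    pbar <- (n1[l] * p1[l] + n2[l] * p2[l]) / (r * nbar)
    s2 <- (n1[l] * (p1[l] - pbar)^2 + n2[l] * (p2[l] - pbar)^2) /
      ((r - 1) * nbar)
    hbar <- (n1[l] * h1[l] + n2[l] * h2[l]) / (r * nbar)
    a_l[l] <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                     hbar / 4) / (nbar - 1))
    b_l[l] <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                     (2 * nbar - 1) / (4 * nbar) * hbar)
    c_l[l] <- hbar / 2
  }
  sum(a_l) / sum(a_l + b_l + c_l)
}

# Brute-force least cost by enumerating every simple path on a small grid.
enumerate_paths_cost <- function(hab, from, to, neighbors = 8) {
  nr <- nrow(hab); nc <- ncol(hab)
  idx <- function(r, c) (c - 1) * nr + r
  nbrs <- function(r, c) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (neighbors == 4 && abs(dr) + abs(dc) == 2) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && hab[r2, c2] > 0)
        out[[length(out) + 1]] <- c(r2, c2)
    }
    out
  }
  best <- Inf
  walk <- function(r, c, visited, acc) {
    if (acc >= best) return()
    if (idx(r, c) == idx(to[1], to[2])) { best <<- acc; return() }
    for (nb in nbrs(r, c)) {
      i <- idx(nb[1], nb[2])
      if (i %in% visited) next
      step <- sqrt(sum((nb - c(r, c))^2)) / ((hab[r, c] + hab[nb[1], nb[2]]) / 2)
      walk(nb[1], nb[2], c(visited, i), acc + step)
    }
  }
  walk(from[1], from[2], idx(from[1], from[2]), 0)
  best
}

ref_matrices <- function(n = 10, seed = 3) {
  set.seed(seed)
  xy <- matrix(rnorm(2 * n), n, 2)
  A <- as.matrix(dist(xy))
  B <- as.matrix(dist(xy + rnorm(2 * n, sd = 0.3)))
  C <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
  ids <- paste0("p", seq_len(n))
  dimnames(A) <- dimnames(B) <- dimnames(C) <- list(ids, ids)
  list(A = A, B = B, C = C)
}

# Simulate site pairs whose response comes exactly from known splines.
simulate_gdm_truth <- function(seed, n_sites = 60, heights = c(0.5, 1, 0),
                               intercept = 0.05, noise = 0) {
  set.seed(seed)
  env <- data.frame(p1 = runif(n_sites), p2 = runif(n_sites),
                    p3 = runif(n_sites))
  rownames(env) <- paste0("s", seq_len(n_sites))
  bases <- lapply(env, function(x) ispline_basis_for(x))
  coefs <- lapply(seq_along(heights), function(j)
    heights[j] * c(0.3, 0.4, 0.3))
  ij <- which(upper.tri(diag(n_sites)), arr.ind = TRUE)
  eta <- rep(intercept, nrow(ij))
  for (j in seq_along(bases)) {
    I1 <- ispline_eval(bases[[j]], env[ij[, 1], j])
    I2 <- ispline_eval(bases[[j]], env[ij[, 2], j])
    eta <- eta + abs(I1 - I2) %*% coefs[[j]]
  }
  d <- 1 - exp(-as.vector(eta))
  if (noise > 0) d <- pmin(pmax(d + rnorm(length(d), sd = noise), 0), 1)
  D <- matrix(0, n_sites, n_sites)
  D[upper.tri(D)] <- d
  D <- D + t(D)
  list(env = env, D = D, heights = heights, intercept = intercept)
}

# Deterministic GDM-like response from spline heights on given env.
simulate_gdm_truth_env <- function(env, heights, seed = 1) {
  bases <- lapply(env, ispline_basis_for)
  n <- nrow(env)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  eta <- rep(0.02, nrow(ij))
  for (j in seq_along(bases)) {
    I1 <- ispline_eval(bases[[j]], env[ij[, 1], j])
    I2 <- ispline_eval(bases[[j]], env[ij[, 2], j])
    eta <- eta + abs(I1 - I2) %*% (heights[j] * c(0.3, 0.4, 0.3))
  }
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- 1 - exp(-as.vector(eta))
  D + t(D)
}
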