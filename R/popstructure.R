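# Population structure: PCA of imputed dosages, k-means with BIC model
# selection (the find.clusters convention), and discriminant-analysis
# assignment with location-holdout cross-validation.

#' Mean-impute missing dosages and run PCA
#'
#' Missing dosages are replaced by the per-SNP mean, columns centered (not
#' scaled), and scores computed by singular value decomposition.
#'
#' @param g a [geno_matrix()] or a numeric individuals x SNPs matrix
#' @param n_components number of PCs to return (reduced with a warning when
#'   above the matrix rank)
#' @return list: `scores` (individuals x PCs), `explained` (variance per
#'   PC, non-increasing), `center`, `rotation`
#' @export
impute_and_pca <- function(g, n_components = 20) {
  x <- if (inherits(g, "geno_matrix")) g$dosage else as.matrix(g)
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_components > rank) {
    warning("n_components reduced to matrix rank (", rank, ")")
    n_components <- rank
  }
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = pc$sdev[seq_len(n_components)]^2,
       total_variance = sum(pc$sdev^2),
       center = pc$center,
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE])
}

#' Choose the number of clusters by k-means + BIC
#'
#' For each candidate K the best of `n_starts` k-means runs is kept and
#' scored with `BIC = n * log(WSS / n) + K * log(n)` (the convention of
#' k-means-based genetic clustering); the returned solution is the argmin.
#'
#' @param scores individuals x PCs score matrix
#' @param k_range candidate K values (within `[1, n/2]`)
#' @param n_starts random starts per K
#' @param seed integer seed
#' @return list of class `cluster_solution`: `K` (argmin), `assignment`,
#'   `bic` (named vector over `k_range`), `centers`
#' @export
select_k_bic <- function(scores, k_range = 1:8, n_starts = 10, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (any(k_range < 1) || any(k_range > n / 2))
    stop("k_range must lie within [1, n/2]")
  set.seed(as.integer(seed))
  bic <- setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    if (K == 1) {
      wss <- sum(scale(scores, scale = FALSE)^2)
      fits[[i]] <- list(cluster = rep(1L, n),
                        centers = matrix(colMeans(scores), 1))
    } else {
      km <- suppressWarnings(
        kmeans(scores, centers = K, nstart = n_starts, iter.max = 50))
      wss <- km$tot.withinss
      fits[[i]] <- km
    }
    bic[i] <- n * log(wss / n) + K * log(n)
  }
  best <- which.min(bic)
  structure(list(K = k_range[best],
                 assignment = fits[[best]]$cluster,
                 bic = bic, k_range = k_range,
                 centers = fits[[best]]$centers),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: K =", x$K, "(BIC argmin over",
      paste(range(x$k_range), collapse = ".."), ")\n")
  invisible(x)
}

#' Discriminant-analysis assignment with location-holdout cross-validation
#'
#' Linear discriminant functions on retained PCs; the number of PCs is
#' chosen by cross-validation withholding whole sampling locations (20% at a
#' time) and maximizing held-out assignment success. Membership
#' probabilities are the discriminant posterior probabilities.
#'
#' @param scores individuals x PCs score matrix
#' @param groups per-individual group labels (>= 2 groups, each >= 2
#'   members)
#' @param locations per-individual sampling-location labels used for the
#'   holdout blocks
#' @param n_pc_grid candidate retained-PC counts (default: 5 values up to
#'   2/3 of the available PCs)
#' @param holdout fraction of locations withheld per fold (default 0.2)
#' @param n_rep cross-validation repetitions per candidate
#' @param seed integer seed
#' @return list of class `dapc_result`: `n_pc`, `cv` (mean held-out success
#'   per candidate), `assignment`, `posterior` (rows sum to 1), `lda`
#' @export
dapc_assign <- function(scores, groups, locations, n_pc_grid = NULL,
                        holdout = 0.2, n_rep = 10, seed = 1) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  p_max <- min(ncol(scores), nrow(scores) - nlevels(groups) - 1)
  n_pc_grid <- n_pc_grid %||% unique(pmax(1, round(seq(2, max(2, floor(
    p_max * 2 / 3)), length.out = 5))))
  n_pc_grid <- n_pc_grid[n_pc_grid <= p_max]
  set.seed(as.integer(seed))
  locs <- unique(locations)
  n_hold <- max(1, round(holdout * length(locs)))
  cv <- setNames(numeric(length(n_pc_grid)), n_pc_grid)
  for (k in seq_along(n_pc_grid)) {
    npc <- n_pc_grid[k]
    succ <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      hold <- sample(locs, n_hold)
      test <- locations %in% hold
      # folds must keep every group represented in training
      if (nlevels(droplevels(groups[!test])) < nlevels(groups)) {
        succ[r] <- NA; next
      }
      fit <- MASS::lda(scores[!test, seq_len(npc), drop = FALSE],
                       grouping = droplevels(groups[!test]))
      pred <- predict(fit, scores[test, seq_len(npc), drop = FALSE])$class
      succ[r] <- mean(as.character(pred) == as.character(groups[test]))
    }
    cv[k] <- mean(succ, na.rm = TRUE)
  }
  n_pc <- n_pc_grid[which.max(cv)]
  fit <- MASS::lda(scores[, seq_len(n_pc), drop = FALSE], grouping = groups)
  pr <- predict(fit, scores[, seq_len(n_pc), drop = FALSE])
  structure(list(n_pc = n_pc, cv = cv,
                 assignment = pr$class, posterior = pr$posterior,
                 lda = fit),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat("dapc_result:", x$n_pc, "PCs retained; mean held-out success",
      sprintf("%.2f\n", max(x$cv, na.rm = TRUE)))
  invisible(x)
}
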