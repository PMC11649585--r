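# Seed transfer zones: Ward clustering of GDM-predicted dissimilarities,
# silhouette / perMANOVA model selection, and the weighted least-cost
# nearest-neighbor cell assignment with future-climate projection.

#' Cluster sampling locations on GDM-predicted dissimilarity
#'
#' Builds the pairwise GDM-predicted dissimilarity matrix among the
#' locations, applies hierarchical agglomerative clustering with Ward's
#' linkage (the squared-increase "ward.D2" update), and scores each
#' candidate cut with the mean silhouette width and the perMANOVA R2. The
#' chosen `k` is the silhouette argmax; any `k` in the range can be
#' requested afterwards via the returned dendrogram cuts.
#'
#' @param gdm_model a [fit_gdm()] model
#' @param env sampling locations x predictors table (row names = location
#'   IDs)
#' @param matrix_predictors aligned [pairwise_matrix()] list for the
#'   model's matrix predictors
#' @param k_range candidate cluster counts (clipped to `[2, n - 1]`)
#' @param k override for the chosen k (`NULL` = silhouette argmax)
#' @param w_resistance,w_environment cost weights for [assign_zones()]
#'   (must sum to 1; defaults 0.6 / 0.4)
#' @param clip_threshold habitat-probability clip (default 0.2)
#' @param n_perm perMANOVA permutations
#' @param seed integer seed
#' @return object of class `zone_solution`: `hclust`, `k`, `clusters`
#'   (location to cluster map at `k`), `silhouette` and `permanova_r2`
#'   per candidate k, `dissimilarity`, the weights and clip threshold
#' @export
cluster_populations <- function(gdm_model, env, matrix_predictors = list(),
                                k_range = 2:8, k = NULL,
                                w_resistance = 0.6, w_environment = 0.4,
                                clip_threshold = 0.2, n_perm = 199,
                                seed = 1) {
  if (abs(w_resistance + w_environment - 1) > 1e-9)
    stop("cost weights must sum to 1")
  D <- predict_gdm_matrix(gdm_model, env, matrix_predictors)
  n <- nrow(D)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("no valid k in range [2, n-1]")
  hc <- hclust(as.dist(D), method = "ward.D2")
  sil <- setNames(numeric(length(k_range)), k_range)
  r2 <- setNames(numeric(length(k_range)), k_range)
  cuts <- list()
  for (i in seq_along(k_range)) {
    cl <- cutree(hc, k_range[i])
    cuts[[i]] <- cl
    sil[i] <- mean_silhouette(D, cl)
    r2[i] <- permanova_r2(D, cl, n_perm = 0)$r2
  }
  k_star <- k %||% k_range[which.max(sil)]
  clusters <- cutree(hc, k_star)
  perm <- permanova_r2(D, clusters, n_perm = n_perm, seed = seed)
  structure(list(hclust = hc, k = k_star, clusters = clusters,
                 k_range = k_range, silhouette = sil, permanova_r2 = r2,
                 permanova_p = perm$p,
                 dissimilarity = D,
                 w_resistance = w_resistance,
                 w_environment = w_environment,
                 clip_threshold = clip_threshold),
            class = "zone_solution")
}

#' @export
print.zone_solution <- function(x, ...) {
  cat(sprintf("zone_solution: k = %d (silhouette %.3f, perMANOVA R2 %.1f%%)\n",
              x$k, x$silhouette[as.character(x$k)],
              100 * x$permanova_r2[as.character(x$k)]))
  invisible(x)
}

# Fill in grid row/col for location tables that only carry x/y.
ensure_rowcol <- function(populations, raster) {
  if (!all(c("row", "col") %in% names(populations))) {
    cc <- cell_at(raster, populations[, c("x", "y")])
    populations$row <- cc$row
    populations$col <- cc$col
  }
  populations
}

# Mean silhouette width directly from a dissimilarity matrix.
mean_silhouette <- function(D, labels) {
  s <- cluster::silhouette(as.integer(factor(labels)), dmatrix = as.matrix(D))
  if (is.null(dim(s))) return(NA_real_)
  mean(s[, "sil_width"])
}

#' perMANOVA R-squared of a grouping on a distance matrix
#'
#' `R2 = SS_among / SS_total` from the standard squared-distance partition
#' (`SS_total = sum d^2 / n`, `SS_within` summed per group); the p-value
#' comes from permuting labels and comparing pseudo-F.
#'
#' @param D square distance matrix
#' @param labels group labels (>= 2 groups)
#' @param n_perm permutations (0 = no test)
#' @param seed integer seed
#' @return list: `r2`, `f`, `p` (NA when `n_perm = 0`)
#' @export
permanova_r2 <- function(D, labels, n_perm = 199, seed = 1) {
  D <- as.matrix(D)
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 groups")
  n <- nrow(D)
  d2 <- D^2
  ss <- function(lab) {
    tot <- sum(d2[upper.tri(d2)]) / n
    wit <- 0
    for (g in unique(lab)) {
      i <- which(lab == g)
      if (length(i) > 1)
        wit <- wit + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    c(total = tot, within = wit)
  }
  s <- ss(labels)
  r2 <- (s["total"] - s["within"]) / s["total"]
  a <- length(unique(labels))
  fstat <- ((s["total"] - s["within"]) / (a - 1)) / (s["within"] / (n - a))
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    exceed <- 0
    for (b in seq_len(n_perm)) {
      sp <- ss(sample(labels))
      fp <- ((sp["total"] - sp["within"]) / (a - 1)) /
        (sp["within"] / (n - a))
      if (fp >= fstat) exceed <- exceed + 1
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(r2 = unname(r2), f = unname(fstat), p = p)
}

#' Assign every raster cell to a seed transfer zone
#'
#' For each sampling location `p`: an accumulated least-cost surface over
#' the habitat conductance raster and a Euclidean distance surface in
#' GDM-transformed environmental space from `p`'s cell. Both component
#' surfaces are min-max normalized to `[0, 1]` over all (location, cell)
#' values, combined as `w_resistance * ACD' + w_environment * ED'`, and
#' each cell joins the cluster of the location with minimum combined cost
#' (ties to the lowest location index). Cells with habitat probability
#' below the clip threshold, or unreachable from every location, become
#' nodata.
#'
#' @param solution a [cluster_populations()] solution
#' @param habitat habitat-probability [grid_raster()]
#' @param transformed named list of GDM-transformed predictor rasters
#'   ([transform_predictors()])
#' @param populations data.frame with id, row, col (or x, y) aligned with
#'   the solution's locations
#' @return object of class `zone_raster`: `zones` ([grid_raster()] of
#'   integer labels, `NA` outside suitable habitat), `legend` (zone to
#'   member locations), `n_unreachable`
#' @export
assign_zones <- function(solution, habitat, transformed, populations) {
  stopifnot(inherits(solution, "zone_solution"))
  populations <- ensure_rowcol(populations, habitat)
  tr <- build_transition(habitat)
  vid <- locate_vertices(tr, populations)
  acd <- igraph::distances(tr$graph, v = vid)   # pops x passable cells
  nr <- nrow(habitat$values); nc <- ncol(habitat$values)
  K <- nrow(populations)
  cell_idx <- which(!is.na(tr$id))              # linear indices of passable
  ACD <- matrix(Inf, K, nr * nc)
  ACD[, cell_idx] <- acd[, tr$id[cell_idx]]
  # environmental distance in transformed space
  tv <- sapply(transformed, function(r) as.vector(r$values))
  if (is.null(dim(tv))) tv <- matrix(tv, ncol = length(transformed))
  pop_lin <- (populations$col - 1) * nr + populations$row
  ED <- matrix(Inf, K, nr * nc)
  for (k in seq_len(K)) {
    dd <- sweep(tv, 2, tv[pop_lin[k], ], `-`)
    ED[k, ] <- sqrt(rowSums(dd^2))
  }
  norm01 <- function(m) {
    fin <- is.finite(m)
    rng <- range(m[fin])
    if (diff(rng) == 0) return(ifelse(fin, 0, Inf))
    out <- (m - rng[1]) / diff(rng)
    out[!fin] <- Inf
    out
  }
  # zero-weight components drop out entirely (0 * Inf must not poison cells)
  C <- if (solution$w_resistance == 0) norm01(ED)
  else if (solution$w_environment == 0) norm01(ACD)
  else solution$w_resistance * norm01(ACD) +
    solution$w_environment * norm01(ED)
  best <- apply(C, 2, function(col) {
    if (all(!is.finite(col))) NA_integer_ else which.min(col)
  })
  zones <- solution$clusters[best]
  hab <- as.vector(habitat$values)
  suitable <- !is.na(hab) & hab >= solution$clip_threshold
  zones[!suitable] <- NA
  n_unreach <- sum(suitable & is.na(best))
  zr <- grid_raster(matrix(as.numeric(zones), nr, nc),
                    xll = habitat$xll, yll = habitat$yll,
                    cellsize = habitat$cellsize, nodata = 0,
                    crs = habitat$crs)
  legend <- split(populations$id, solution$clusters)
  structure(list(zones = zr, legend = legend, k = solution$k,
                 n_unreachable = n_unreach,
                 clip_threshold = solution$clip_threshold),
            class = "zone_raster")
}

#' @export
print.zone_raster <- function(x, ...) {
  tab <- table(x$zones$values)
  cat("zone_raster:", x$k, "zones;", sum(tab), "suitable cells (",
      x$n_unreachable, "unreachable )\n")
  print(tab)
  invisible(x)
}

#' Project seed transfer zones under future climate
#'
#' Re-runs the identical assignment algorithm on future inputs (a
#' future-projected habitat raster and future GDM-transformed predictors)
#' and summarizes cell-level change versus the current zones.
#'
#' @param solution a [cluster_populations()] solution
#' @param current_zones the current [assign_zones()] result
#' @param future_habitat future habitat-probability raster
#' @param future_transformed future GDM-transformed predictor stack
#' @param populations as in [assign_zones()]
#' @return list: `zones` (future `zone_raster`), `change` ([grid_raster()]
#'   coded 1 same / 2 changed / 3 lost / 4 gained), `summary` (cell counts)
#' @export
project_future_zones <- function(solution, current_zones, future_habitat,
                                 future_transformed, populations) {
  fz <- assign_zones(solution, future_habitat, future_transformed,
                     populations)
  cur <- current_zones$zones$values
  fut <- fz$zones$values
  change <- matrix(NA_real_, nrow(cur), ncol(cur))
  change[!is.na(cur) & !is.na(fut) & cur == fut] <- 1
  change[!is.na(cur) & !is.na(fut) & cur != fut] <- 2
  change[!is.na(cur) & is.na(fut)] <- 3
  change[is.na(cur) & !is.na(fut)] <- 4
  cr <- grid_raster(change, xll = future_habitat$xll,
                    yll = future_habitat$yll,
                    cellsize = future_habitat$cellsize,
                    crs = future_habitat$crs)
  counts <- c(same = sum(change == 1, na.rm = TRUE),
              changed = sum(change == 2, na.rm = TRUE),
              lost = sum(change == 3, na.rm = TRUE),
              gained = sum(change == 4, na.rm = TRUE))
  list(zones = fz, change = cr, summary = counts)
}

#' Concordance between seed zones and ancestry clusters
#'
#' Adjusted Rand index between the zone membership of the sampling
#' locations and an independent ancestry-based partition (e.g. from
#' [select_k_bic()] majority vote per location).
#'
#' @param zones an [assign_zones()] result
#' @param populations data.frame with row, col per location
#' @param ancestry per-location cluster labels, same order
#' @return scalar ARI
#' @export
zone_concordance <- function(zones, populations, ancestry) {
  populations <- ensure_rowcol(populations, zones$zones)
  z <- zones$zones$values[cbind(populations$row, populations$col)]
  if (any(is.na(z)))
    warning(sum(is.na(z)), " location(s) fall on nodata zone cells")
  ok <- !is.na(z)
  adjusted_rand(z[ok], ancestry[ok])
}
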