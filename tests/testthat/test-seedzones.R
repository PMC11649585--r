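# A compact landscape with a fitted GDM, reused across the zone tests.
make_zone_fixture <- function(seed = 21) {
  cfg <- tiny_cfg(seed = seed, n_populations = 18, n_individuals = 8,
                  n_neutral = 150, n_adaptive = 12, beta = 2)
  sim <- simulate_landscape(cfg)
  env <- as.data.frame(sim$env_at_pops)
  freqs <- sim$freqs[, sim$truth$adaptive_idx]
  sp <- assemble_site_pairs(freqs, env)
  model <- fit_gdm(sp)
  list(sim = sim, env = env, model = model)
}

test_that("silhouette and perMANOVA match brute-force oracles", {
  # perfect 2-cluster matrix: within 0, between 1 -> mean silhouette 1
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0
  lab <- rep(1:2, each = 3)
  expect_equal(genoscaper:::mean_silhouette(D, lab), 1)
  # textbook per-point silhouette by explicit loops on a 6-point toy
  set.seed(2)
  pts <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 3), 3, 2))
  Dt <- as.matrix(dist(pts))
  lab2 <- rep(1:2, each = 3)
  sil_oracle <- sapply(1:6, function(i) {
    a <- mean(Dt[i, setdiff(which(lab2 == lab2[i]), i)])
    b <- min(sapply(setdiff(unique(lab2), lab2[i]), function(g)
      mean(Dt[i, lab2 == g])))
    (b - a) / max(a, b)
  })
  expect_equal(genoscaper:::mean_silhouette(Dt, lab2), mean(sil_oracle),
               tolerance = 1e-10)
  # perMANOVA R2 against an explicit sums-of-squares double loop (8 points)
  set.seed(3)
  pts8 <- rbind(matrix(rnorm(8, 0), 4, 2), matrix(rnorm(8, 2), 4, 2))
  D8 <- as.matrix(dist(pts8))
  lab8 <- rep(1:2, each = 4)
  got <- permanova_r2(D8, lab8, n_perm = 0)
  d2 <- D8^2; n <- 8
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- sum(d2[1:4, 1:4][upper.tri(d2[1:4, 1:4])]) / 4 +
    sum(d2[5:8, 5:8][upper.tri(d2[5:8, 5:8])]) / 4
  expect_equal(got$r2, (ss_tot - ss_w) / ss_tot, tolerance = 1e-12)
  # perfect block structure -> R2 = 1
  expect_equal(permanova_r2(D, lab, n_perm = 0)$r2, 1)
  # random labels: E[R2] ~ (k-1)/(n-1)
  set.seed(4)
  Dn <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  r2s <- replicate(60, permanova_r2(Dn, sample(rep(1:3, 10)),
                                    n_perm = 0)$r2)
  expect_lt(abs(mean(r2s) - 2 / 29), 0.02)
  expect_error(permanova_r2(D8, rep(1, 8)), "2 groups")
})

test_that("perMANOVA agrees with the vegan cross-check", {
  skip_if_not_installed("vegan")
  set.seed(5)
  pts <- matrix(rnorm(40), 20, 2)
  D <- as.matrix(dist(pts))
  lab <- rep(letters[1:4], each = 5)
  got <- permanova_r2(D, lab, n_perm = 0)
  ref <- vegan::adonis2(as.dist(D) ~ g, data = data.frame(g = lab),
                        permutations = 2)
  expect_equal(got$r2, ref$R2[1], tolerance = 1e-10)
})


test_that("clustering on GDM dissimilarities selects sensible k", {
  # two clearly separated environmental groups -> silhouette peak at k = 2
  set.seed(6)
  n <- 16
  env <- data.frame(p1 = c(rnorm(8, -2, 0.2), rnorm(8, 2, 0.2)),
                    p2 = rnorm(n, 0, 0.2))
  rownames(env) <- paste0("s", 1:n)
  truth <- simulate_gdm_truth_env(env, heights = c(1.2, 0.1), seed = 1)
  sp <- assemble_site_pairs(NULL, env, response = truth)
  model <- fit_gdm(sp)
  sol <- cluster_populations(model, env, k_range = 2:6, n_perm = 19)
  expect_equal(sol$k, 2)
  expect_equal(unname(sol$clusters[1:8]), rep(sol$clusters[[1]], 8))
  # k override is honoured and weights must sum to one
  sol4 <- cluster_populations(model, env, k_range = 2:6, k = 4, n_perm = 0)
  expect_equal(sol4$k, 4)
  expect_error(cluster_populations(model, env, w_resistance = 0.9,
                                   w_environment = 0.4), "sum to 1")
})


test_that("zone assignment tiles suitable habitat and honours the weights", {
  fx <- make_zone_fixture()
  sim <- fx$sim
  tf <- transform_predictors(fx$model, sim$env)
  sol <- cluster_populations(fx$model, fx$env, k_range = 2:5, n_perm = 0,
                             seed = 2)
  zr <- assign_zones(sol, sim$habitat, tf, sim$populations)
  hab <- sim$habitat$values
  suitable <- !is.na(hab) & hab >= 0.2
  z <- zr$zones$values
  # every suitable (reachable) cell labeled; nothing labeled outside
  expect_true(all(is.na(z[!suitable])))
  expect_equal(sum(is.na(z[suitable])), zr$n_unreachable)
  expect_true(all(z[!is.na(z)] %in% seq_len(sol$k)))
  # single population: every suitable cell in its zone
  sol1 <- sol
  sol1$clusters <- sol$clusters[1]
  zr1 <- assign_zones(sol1, sim$habitat, tf, sim$populations[1, ])
  expect_true(all(zr1$zones$values[suitable] == sol1$clusters[[1]],
                  na.rm = TRUE))
  # pure-environment weights on uniform habitat give the Voronoi partition
  # in transformed-environment space
  uni <- grid_raster(matrix(1, nrow(hab), ncol(hab)),
                     cellsize = sim$habitat$cellsize)
  sole <- sol; sole$w_resistance <- 0; sole$w_environment <- 1
  zre <- assign_zones(sole, uni, tf, sim$populations)
  tv <- sapply(tf, function(r) as.vector(r$values))
  nr <- nrow(hab)
  pop_lin <- (sim$populations$col - 1) * nr + sim$populations$row
  vor <- apply(sapply(seq_len(nrow(sim$populations)), function(k)
    rowSums(sweep(tv, 2, tv[pop_lin[k], ], `-`)^2)), 1, which.min)
  expect_equal(as.vector(zre$zones$values), unname(sol$clusters[vor]))
  # raising the clip threshold only removes cells, never relabels
  solh <- sol; solh$clip_threshold <- 0.5
  zrh <- assign_zones(solh, sim$habitat, tf, sim$populations)
  zh <- zrh$zones$values
  keep <- !is.na(zh)
  expect_true(all(zh[keep] == z[keep]))
  expect_lte(sum(!is.na(zh)), sum(!is.na(z)))
})

test_that("future projection is idempotent and conserves cell counts", {
  fx <- make_zone_fixture(seed = 33)
  sim <- fx$sim
  tf <- transform_predictors(fx$model, sim$env)
  sol <- cluster_populations(fx$model, fx$env, k_range = 2:5, n_perm = 0)
  cur <- assign_zones(sol, sim$habitat, tf, sim$populations)
  # unchanged inputs: identical zones, all cells "same"
  prj <- project_future_zones(sol, cur, sim$habitat, tf, sim$populations)
  expect_equal(prj$zones$zones$values, cur$zones$values)
  expect_equal(unname(prj$summary[c("changed", "lost", "gained")]),
               c(0, 0, 0))
  # degrading habitat in one region shrinks its suitable area monotonically
  fut_hab <- sim$habitat
  fut_hab$values[, 1:12] <- fut_hab$values[, 1:12] * 0.25
  fut_env <- lapply(sim$env, function(r) { r$values <- r$values + 0.3; r })
  names(fut_env) <- names(sim$env)
  ftf <- transform_predictors(fx$model, fut_env)
  prj2 <- project_future_zones(sol, cur, fut_hab, ftf, sim$populations)
  expect_lte(sum(!is.na(prj2$zones$zones$values[, 1:12])),
             sum(!is.na(cur$zones$values[, 1:12])))
  # change summary partitions the current suitable cells
  expect_equal(unname(prj2$summary["same"] + prj2$summary["changed"] +
                        prj2$summary["lost"]),
               sum(!is.na(cur$zones$values)))
})

test_that("zone concordance is an adjusted Rand index with its invariances", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand(a, a), 1)
  expect_equal(adjusted_rand(a, c(2, 2, 3, 3, 1, 1)), 1)  # relabeling
  set.seed(8)
  r <- replicate(200, adjusted_rand(sample(rep(1:3, 8)),
                                    sample(rep(1:3, 8))))
  expect_lt(abs(mean(r)), 0.05)                            # ~0 under null
  # zones broadly mirror the ancestry clusters on simulated IBR data
  fx <- make_zone_fixture(seed = 55)
  sim <- fx$sim
  tf <- transform_predictors(fx$model, sim$env)
  sol <- cluster_populations(fx$model, fx$env, k_range = 2:6, n_perm = 0)
  zr <- assign_zones(sol, sim$habitat, tf, sim$populations)
  got <- zone_concordance(zr, sim$populations, sol$clusters)
  expect_equal(got, 1)   # locations sit inside their own zones
})
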