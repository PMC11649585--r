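# Synthetic landscapes, populations and genotypes with known truth.
#
# The generator emulates the sampling design of a Mojave Desert landscape
# genomics study: ~60 sampling locations of ~12 diploid individuals, several
# hundred biallelic SNPs whose neutral structure follows habitat resistance
# (isolation by resistance), and a small minority of adaptive loci with
# logistic allele-frequency clines along chosen environmental layers.
# Allele frequencies follow a logit-normal model (not a coalescent): cheap,
# with closed-form control of differentiation via the covariance
# sigma^2 * exp(-resistance / phi) on the logit scale.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-landscape generator. Defaults are the
#' study conditions the pipeline is validated under: a 40 x 40 grid of 1 km
#' cells, 4 correlated environmental layers, 60 sampling locations of 12
#' diploid plants, 780 neutral + 40 adaptive SNPs (~5% adaptive) with cline
#' slope `beta = 2` on standardized environments.
#'
#' @param nrow,ncol grid shape (each >= 8)
#' @param cellsize cell edge length in projected units
#' @param n_env_layers number of environmental layers
#' @param autocorr_range Gaussian smoothing range of the layers, in cells
#' @param trend_weight weight of a linear spatial trend mixed into each layer
#'   (0 = pure smoothed noise)
#' @param habitat_coef logistic coefficients of habitat on the layers
#'   (recycled to `n_env_layers`)
#' @param habitat_intercept logistic intercept of the habitat surface
#' @param n_populations number of sampling locations
#' @param n_individuals diploid individuals per location
#' @param min_spacing minimum separation between locations, in cells
#' @param n_neutral,n_adaptive neutral / adaptive SNP counts
#' @param beta logistic cline slope per adaptive locus (recycled); finite
#' @param adaptive_layers environmental layer index driving each adaptive
#'   locus (recycled over `n_adaptive`)
#' @param sigma2 variance of the neutral logit-frequency deviations
#' @param phi neutral covariance decay scale in resistance units; `NULL`
#'   (default) sets it to half the median pairwise resistance distance of the
#'   realized landscape
#' @param adaptive_noise_sd residual SD on adaptive logit frequencies
#' @param snps_per_locus SNPs sharing one synthetic RAD-locus ID (exercises
#'   the one-SNP-per-locus thinning filter)
#' @param structure_driver which distance generates the neutral covariance:
#'   habitat resistance (the default, isolation by resistance), geographic
#'   distance, or environmental distance — contrast scenarios for the causal
#'   modeling battery
#' @param seed integer seed; recorded in all outputs
#' @return a `sim_config` list, validated
#' @export
sim_config <- function(nrow = 40, ncol = 40, cellsize = 1000,
                       n_env_layers = 4, autocorr_range = 6,
                       trend_weight = 0.3,
                       habitat_coef = c(1.5, -1, 0.5, 0),
                       habitat_intercept = 0.5,
                       n_populations = 60, n_individuals = 12,
                       min_spacing = 2,
                       n_neutral = 780, n_adaptive = 40,
                       beta = 2, adaptive_layers = NULL,
                       sigma2 = 1.2, phi = NULL,
                       adaptive_noise_sd = 0.2,
                       snps_per_locus = 1,
                       structure_driver = c("resistance", "geographic",
                                            "environmental"),
                       seed = 1) {
  structure_driver <- match.arg(structure_driver)
  cfg <- list(
    nrow = nrow, ncol = ncol, cellsize = cellsize,
    n_env_layers = n_env_layers, autocorr_range = autocorr_range,
    trend_weight = trend_weight,
    habitat_coef = rep_len(habitat_coef, n_env_layers),
    habitat_intercept = habitat_intercept,
    n_populations = n_populations, n_individuals = n_individuals,
    min_spacing = min_spacing,
    n_neutral = n_neutral, n_adaptive = n_adaptive,
    beta = rep_len(beta, max(1, n_adaptive)),
    adaptive_layers = rep_len(adaptive_layers %||% seq_len(n_env_layers),
                              max(1, n_adaptive)),
    sigma2 = sigma2, phi = phi, adaptive_noise_sd = adaptive_noise_sd,
    snps_per_locus = snps_per_locus,
    structure_driver = structure_driver,
    seed = as.integer(seed))
  if (cfg$nrow < 8 || cfg$ncol < 8)
    stop("degenerate grid: both dimensions must be >= 8")
  counts <- c(cfg$n_env_layers, cfg$n_populations, cfg$n_individuals,
              cfg$n_neutral, cfg$snps_per_locus, cfg$cellsize)
  if (any(counts <= 0) || cfg$n_adaptive < 0)
    stop("all counts must be positive")
  if (any(!is.finite(cfg$beta))) stop("beta must be finite")
  if (any(cfg$adaptive_layers < 1 | cfg$adaptive_layers > cfg$n_env_layers))
    stop("adaptive_layers out of range")
  class(cfg) <- "sim_config"
  cfg
}

# Separable Gaussian smoothing with edge renormalization. range = 0 is the
# identity (pure white noise layer).
smooth_gaussian <- function(m, range) {
  if (range <= 0) return(m)
  half <- max(1L, ceiling(3 * range))
  k <- exp(-(seq(-half, half))^2 / (2 * range^2))
  band <- function(n) {
    w <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= half,
                                     exp(-(i - j)^2 / (2 * range^2)), 0))
    w / rowSums(w)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate standardized, spatially autocorrelated environmental layers
#'
#' Each layer is white noise smoothed with a Gaussian kernel of the
#' configured range, optionally mixed with a linear trend in a random
#' direction, then standardized to zero mean and unit variance over cells.
#'
#' @param config a [sim_config()]
#' @return named list of [grid_raster()] layers (`env_1`, `env_2`, ...)
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  nr <- config$nrow; nc <- config$ncol
  out <- vector("list", config$n_env_layers)
  rowc <- matrix(seq_len(nr), nr, nc)
  colc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (l in seq_len(config$n_env_layers)) {
    z <- smooth_gaussian(matrix(rnorm(nr * nc), nr, nc),
                         config$autocorr_range)
    if (config$trend_weight > 0) {
      ang <- runif(1, 0, 2 * pi)
      tr <- cos(ang) * colc + sin(ang) * rowc
      z <- (1 - config$trend_weight) * scale_mat(z) +
        config$trend_weight * scale_mat(tr)
    }
    out[[l]] <- grid_raster(scale_mat(z), cellsize = config$cellsize,
                            crs = "synthetic-projected")
  }
  names(out) <- paste0("env_", seq_along(out))
  out
}

scale_mat <- function(m) {
  s <- sd(as.vector(m))
  if (s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

#' Habitat-probability surface from environmental layers
#'
#' Cellwise logistic model standing in for a fitted species distribution
#' model: `plogis(intercept + sum(coef * layer))`, values in (0, 1).
#'
#' @param env list of aligned [grid_raster()] layers
#' @param coefficients one coefficient per layer
#' @param intercept logistic intercept
#' @return habitat [grid_raster()] with values in (0, 1)
#' @export
generate_habitat <- function(env, coefficients, intercept = 0) {
  if (length(coefficients) != length(env))
    stop("need exactly one coefficient per environmental layer (",
         length(env), " layers, ", length(coefficients), " coefficients)")
  eta <- matrix(intercept, nrow(env[[1]]$values), ncol(env[[1]]$values))
  for (l in seq_along(env)) {
    check_same_grid(env[[1]], env[[l]])
    eta <- eta + coefficients[l] * env[[l]]$values
  }
  grid_raster(plogis(eta), xll = env[[1]]$xll, yll = env[[1]]$yll,
              cellsize = env[[1]]$cellsize, crs = env[[1]]$crs)
}

#' Place sampling locations on suitable habitat
#'
#' Draws `n` distinct cells with habitat probability >= `min_habitat`,
#' pairwise separated by at least `min_spacing` cells (Euclidean in cell
#' units), by randomized greedy selection under the seed.
#'
#' @param habitat habitat [grid_raster()]
#' @param n number of locations
#' @param min_spacing minimum pairwise separation in cells
#' @param seed integer seed
#' @param min_habitat suitability cutoff (default 0.2)
#' @return data.frame (id, row, col, x, y, habitat)
#' @export
place_populations <- function(habitat, n, min_spacing = 2, seed = 1,
                              min_habitat = 0.2) {
  set.seed(as.integer(seed))
  v <- habitat$values
  ok <- which(!is.na(v) & v >= min_habitat, arr.ind = TRUE)
  if (nrow(ok) < n)
    stop("infeasible placement: only ", nrow(ok),
         " suitable cells for n = ", n)
  ord <- sample.int(nrow(ok))
  chosen <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    cand <- ok[i, ]
    if (nrow(chosen) == 0 ||
        all(sqrt(rowSums((t(t(chosen) - cand))^2)) >= min_spacing)) {
      chosen <- rbind(chosen, cand)
      if (nrow(chosen) == n) break
    }
  }
  if (nrow(chosen) < n)
    stop("infeasible spacing: max feasible n at spacing ", min_spacing,
         " is ", nrow(chosen), " (requested ", n, ")")
  xy <- cell_center(habitat, chosen[, 1], chosen[, 2])
  data.frame(id = paste0("pop_", sprintf("%02d", seq_len(n))),
             row = unname(chosen[, 1]), col = unname(chosen[, 2]),
             x = xy[, 1], y = xy[, 2],
             habitat = v[chosen])
}

#' Simulate per-population allele frequencies with planted clines
#'
#' Neutral locus `l`: `logit(p_kl)` is drawn jointly over populations `k`
#' from a Gaussian with mean `logit(p0_l)` and covariance
#' `sigma2 * exp(-D_kj / phi)` where `D` is the structuring distance matrix
#' (habitat resistance by default). Adaptive locus `l` driven by layer `m`:
#' `logit(p_kl) = alpha_l + beta_l * env_k(m) + noise`.
#'
#' @param populations output of [place_populations()]
#' @param distance structuring [pairwise_matrix()] (symmetric, zero diagonal)
#' @param env_at_pops populations x layers matrix of standardized
#'   environmental values at the locations
#' @param config a [sim_config()]
#' @return list with `freqs` (populations x loci, in (0,1)) and `truth`
#'   (adaptive indices, driving layers, betas, neutral base frequencies,
#'   population coordinates, seed)
#' @export
simulate_allele_frequencies <- function(populations, distance, env_at_pops,
                                        config) {
  stopifnot(inherits(config, "sim_config"))
  K <- nrow(populations)
  D <- as.matrix(distance)
  if (nrow(D) != K) stop("distance matrix does not match populations")
  if (any(abs(diag(D)) > 1e-9)) stop("distance matrix must have zero diagonal")
  set.seed(derive_seed(config$seed, 2L))
  phi <- config$phi %||% (0.5 * median(D[upper.tri(D)]))
  Sigma <- config$sigma2 * exp(-D / phi)
  ch <- NULL; jitter <- 0
  for (try in 0:6) {
    jitter <- if (try == 0) 0 else 10^(try - 7) * config$sigma2
    ch <- tryCatch(chol(Sigma + diag(jitter, K)), error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) stop("neutral covariance could not be factorized")
  if (jitter > 0)
    message("neutral covariance repaired with diagonal jitter ", jitter)

  n_loci <- config$n_neutral + config$n_adaptive
  adaptive_idx <- if (config$n_adaptive > 0)
    sort(sample.int(n_loci, config$n_adaptive)) else integer(0)
  neutral_idx <- setdiff(seq_len(n_loci), adaptive_idx)

  logit_p <- matrix(NA_real_, K, n_loci)
  p0 <- runif(length(neutral_idx), 0.05, 0.95)
  z <- t(ch) %*% matrix(rnorm(K * length(neutral_idx)), K)
  logit_p[, neutral_idx] <- sweep(z, 2, qlogis(p0), `+`)

  alpha <- numeric(0)
  if (config$n_adaptive > 0) {
    alpha <- qlogis(runif(config$n_adaptive, 0.2, 0.8))
    for (j in seq_len(config$n_adaptive)) {
      e <- env_at_pops[, config$adaptive_layers[j]]
      logit_p[, adaptive_idx[j]] <- alpha[j] + config$beta[j] * e +
        rnorm(K, sd = config$adaptive_noise_sd)
    }
  }
  freqs <- plogis(logit_p)
  rownames(freqs) <- populations$id
  colnames(freqs) <- paste0("snp_", sprintf("%04d", seq_len(n_loci)))
  truth <- list(adaptive_idx = adaptive_idx,
                adaptive_layers = config$adaptive_layers[
                  seq_len(config$n_adaptive)],
                beta = config$beta[seq_len(config$n_adaptive)],
                alpha = alpha,
                neutral_idx = neutral_idx,
                neutral_base_freq = p0,
                phi = phi, sigma2 = config$sigma2,
                populations = populations[, c("id", "row", "col", "x", "y")],
                seed = config$seed)
  list(freqs = freqs, truth = truth)
}

#' Draw diploid genotypes from population allele frequencies
#'
#' Genotype of an individual at a locus is Binomial(2, p) with p the allele
#' frequency of its population.
#'
#' @param freqs populations x loci frequency matrix in (0,1)
#' @param n_ind individuals per population (scalar or per-population vector)
#' @param seed integer seed
#' @return a [geno_matrix()] with samples labeled by population and SNPs
#'   grouped into synthetic RAD loci of `snps_per_locus` members
#' @param snps_per_locus SNPs per synthetic RAD locus ID
#' @export
sample_genotypes <- function(freqs, n_ind, seed = 1, snps_per_locus = 1) {
  set.seed(as.integer(seed))
  K <- nrow(freqs); L <- ncol(freqs)
  n_ind <- rep_len(n_ind, K)
  dosage <- matrix(NA_integer_, sum(n_ind), L)
  sample_ids <- character(sum(n_ind)); loc <- character(sum(n_ind))
  at <- 0
  for (k in seq_len(K)) {
    rows <- at + seq_len(n_ind[k])
    dosage[rows, ] <- matrix(
      rbinom(n_ind[k] * L, 2, rep(freqs[k, ], each = n_ind[k])),
      n_ind[k], L)
    sample_ids[rows] <- paste0(rownames(freqs)[k], "_i",
                               sprintf("%02d", seq_len(n_ind[k])))
    loc[rows] <- rownames(freqs)[k]
    at <- at + n_ind[k]
  }
  locus_id <- paste0("loc_", sprintf("%05d",
    rep(seq_len(ceiling(L / snps_per_locus)), each = snps_per_locus)[1:L]))
  # position within locus: 1-based, SNPs spaced 25 bp apart
  within <- sequence(rle(locus_id)$lengths)
  snps <- data.frame(id = colnames(freqs), locus = locus_id,
                     chrom = locus_id, pos = 10L + 25L * (within - 1L),
                     depth = NA_real_)
  geno_matrix(dosage,
              snps = snps,
              samples = data.frame(id = sample_ids, location = loc))
}

#' Run the full synthetic-landscape generator
#'
#' Chains environment, habitat, population placement, the structuring
#' distance (per `config$structure_driver`), allele frequencies and
#' genotypes. All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list: `config`, `env` (layer list), `habitat`, `populations`,
#'   `distance` (structuring pairwise matrix), `env_at_pops`, `freqs`,
#'   `truth`, `geno`
#' @export
simulate_landscape <- function(config = sim_config()) {
  env <- generate_environment(config)
  habitat <- generate_habitat(env, config$habitat_coef,
                              config$habitat_intercept)
  pops <- place_populations(habitat, config$n_populations,
                            config$min_spacing,
                            seed = derive_seed(config$seed, 3L))
  env_at_pops <- sapply(env, function(r) extract_at(r, pops[, c("x", "y")]))
  rownames(env_at_pops) <- pops$id
  dist_mat <- switch(config$structure_driver,
    resistance = {
      tr <- build_transition(habitat)
      least_cost_matrix(tr, pops)
    },
    geographic = geographic_distance_matrix(pops),
    environmental = environmental_distance_matrix(
      scale(env_at_pops), ids = pops$id))
  sim <- simulate_allele_frequencies(pops, dist_mat, env_at_pops, config)
  geno <- sample_genotypes(sim$freqs, config$n_individuals,
                           seed = derive_seed(config$seed, 4L),
                           snps_per_locus = config$snps_per_locus)
  list(config = config, env = env, habitat = habitat, populations = pops,
       distance = dist_mat, env_at_pops = env_at_pops,
       freqs = sim$freqs, truth = sim$truth, geno = geno)
}

#' Write a simulated landscape to disk as plain-text fixtures
#'
#' Outputs a GT-only VCF v4.2, `coords.csv` (pop_id, x, y), one `.asc`
#' raster per environmental layer plus `habitat.asc`, and `truth.json`
#' (adaptive indices, betas, seed). Round-tripping the VCF through
#' [read_vcf()] reproduces the dosage matrix exactly.
#'
#' @param sim output of [simulate_landscape()]
#' @param dir output directory (created if absent)
#' @return invisibly, the list of written paths
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                coords = file.path(dir, "coords.csv"),
                habitat = file.path(dir, "habitat.asc"),
                truth = file.path(dir, "truth.json"))
  write_vcf(sim$geno, paths$vcf, seed = sim$config$seed)
  write.csv(sim$populations[, c("id", "x", "y")], paths$coords,
            row.names = FALSE, quote = FALSE)
  for (l in seq_along(sim$env)) {
    p <- file.path(dir, paste0(names(sim$env)[l], ".asc"))
    write_ascii_grid(sim$env[[l]], p)
    paths[[names(sim$env)[l]]] <- p
  }
  write_ascii_grid(sim$habitat, paths$habitat)
  tr <- sim$truth
  tr$populations <- NULL
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
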